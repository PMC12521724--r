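#' Split a scan into two independent halves
#'
#' Disjoint halves covering the same field of view, for independent
#' reconstructions feeding the Fourier ring correlation. Positions are
#' preserved exactly.
#'
#' @param stack a [diffraction_stack()].
#' @param scheme `"odd_even_rows"` or `"checkerboard"`.
#' @return list of two [diffraction_stack()]s.
#' @export
split_scan <- function(stack, scheme = c("odd_even_rows", "checkerboard")) {
  scheme <- match.arg(scheme)
  pos <- stack$grid$positions
  if (length(unique(pos$row)) < 2) stop("need at least 2 scan rows", call. = FALSE)
  inA <- switch(scheme,
    odd_even_rows = pos$row %% 2 == 1,
    checkerboard = (pos$row + pos$col) %% 2 == 0
  )
  take <- function(sel) {
    g <- stack$grid
    g$positions <- pos[sel, ]
    diffraction_stack(stack$frames[, , sel, drop = FALSE], stack$mask, g,
                      stack$energy_kev, stack$reciprocal_pixel_invA,
                      center = stack$center)
  }
  list(take(inA), take(!inA))
}

#' Half-bit information threshold
#'
#' Per-ring half-bit threshold
#' `T(n) = (0.2071 + 1.9102/sqrt(n)) / (1.2071 + 0.9102/sqrt(n))`,
#' strictly decreasing in the ring pixel count `n` with asymptote
#' 0.2071/1.2071 ~ 0.1716.
#'
#' @param n_pixels_per_ring pixel counts, >= 1.
#' @return threshold values.
#' @export
half_bit_threshold <- function(n_pixels_per_ring) {
  if (any(n_pixels_per_ring < 1)) stop("ring pixel counts must be >= 1", call. = FALSE)
  sn <- sqrt(n_pixels_per_ring)
  (0.2071 + 1.9102 / sn) / (1.2071 + 0.9102 / sn)
}

#' Convert between an FRC threshold and the equivalent SNR
#'
#' A correlation `T` between two half-dataset images corresponds, through
#' `T = (s/2) / (s/2 + 1)`, to a full-dataset signal-to-noise ratio
#' `s = 2 T / (1 - T)`. The asymptotic half-bit threshold 0.1716 maps to
#' `sqrt(2) - 1 ~ 0.41`.
#'
#' @param threshold correlation value in [0, 1).
#' @return equivalent full-dataset SNR.
#' @export
frc_equivalent_snr <- function(threshold) {
  2 * threshold / (1 - threshold)
}

#' @rdname frc_equivalent_snr
#' @param snr full-dataset SNR.
#' @export
snr_equivalent_frc <- function(snr) {
  (snr / 2) / (snr / 2 + 1)
}

#' Fourier ring correlation
#'
#' Ring-wise normalized cross-correlation of the Fourier transforms of two
#' real images (reconstruction intensity or phase), after rigid subpixel
#' alignment by the cross-correlation peak. Ring width is one reciprocal
#' pixel; the half-bit threshold is evaluated with the actual per-ring pixel
#' counts.
#'
#' @param image_A,image_B real matrices, equal square shapes.
#' @param pixel_size_pm pixel size, pm.
#' @param align subpixel-align B to A before correlating (default TRUE).
#' @return an `frc_curve` tibble: `ring_freq_invA`, `correlation`, `n_ring`,
#'   `threshold`.
#' @export
frc <- function(image_A, image_B, pixel_size_pm, align = TRUE) {
  if (!all(dim(image_A) == dim(image_B))) stop("image shapes differ", call. = FALSE)
  n <- nrow(image_A)
  if (n != ncol(image_A)) stop("images must be square", call. = FALSE)
  if (align) image_B <- register_translation(image_A, image_B)
  FA <- fftshift2(fft2(image_A - mean(image_A)))
  FB <- fftshift2(fft2(image_B - mean(image_B)))
  ci <- centre_index(n)
  rpx <- sqrt(outer((seq_len(n) - ci)^2, rep(1, n)) +
              outer(rep(1, n), (seq_len(n) - ci)^2))
  ring <- round(rpx)
  nmax <- n - ci
  sel <- ring >= 1 & ring <= nmax
  rg <- ring[sel]
  num <- tapply(Re(FA[sel] * Conj(FB[sel])), rg, sum)
  dA <- tapply(Mod(FA[sel])^2, rg, sum)
  dB <- tapply(Mod(FB[sel])^2, rg, sum)
  cnt <- tapply(rg, rg, length)
  corr <- as.numeric(num / sqrt(dA * dB))
  corr[!is.finite(corr)] <- 0
  rp <- 1 / (n * pixel_size_pm / 100)
  out <- tibble::new_tibble(list(
    ring_freq_invA = as.integer(names(num)) * rp,
    correlation = pmin(pmax(corr, -1), 1),
    n_ring = as.integer(cnt),
    threshold = half_bit_threshold(as.integer(cnt))
  ), nrow = length(num), class = "frc_curve")
  attr(out, "pixel_size_pm") <- pixel_size_pm
  out
}

# rigid subpixel registration of B onto A via the phase of the
# cross-correlation peak (parabolic refinement), applied with Fourier shift
register_translation <- function(A, B) {
  FA <- fft2(A - mean(A)); FB <- fft2(B - mean(B))
  xc <- Re(ifft2(FA * Conj(FB)))
  pk <- which(xc == max(xc), arr.ind = TRUE)[1, ]
  n <- nrow(A); m <- ncol(A)
  refine <- function(v, i, len) {
    im <- ((i - 2) %% len) + 1; ip <- (i %% len) + 1
    den <- v[im] - 2 * v[i] + v[ip]
    if (den >= 0) 0 else 0.5 * (v[im] - v[ip]) / den
  }
  dr <- pk[1] - 1; dc <- pk[2] - 1
  dr <- dr + refine(xc[, pk[2]], pk[1], n)
  dc <- dc + refine(xc[pk[1], ], pk[2], m)
  if (dr > n / 2) dr <- dr - n
  if (dc > m / 2) dc <- dc - m
  if (abs(dr) < 1e-9 && abs(dc) < 1e-9) return(B)
  Re(fourier_shift(B, dr, dc))
}

#' Resolution from an FRC curve
#'
#' Frequency of the last downward crossing of the threshold curve (the
#' maximal crossing), with linear interpolation between rings; resolution is
#' its reciprocal.
#'
#' @param curve an `frc_curve` from [frc()], or any tibble with
#'   `ring_freq_invA`, `correlation`, `threshold`.
#' @return tibble with `crossing_freq_invA` and `resolution_A`; both `NA`
#'   (with a warning) when the curve never rises above the threshold.
#' @export
resolution_from_frc <- function(curve) {
  f <- curve$ring_freq_invA; y <- curve$correlation; t <- curve$threshold
  if (length(f) != length(t)) stop("curve and threshold lengths differ", call. = FALSE)
  above <- y > t
  if (!any(above)) {
    warning("FRC never exceeds the threshold; resolution undefined")
    return(tibble::tibble(crossing_freq_invA = NA_real_, resolution_A = NA_real_))
  }
  d <- y - t
  cross <- which(d[-length(d)] > 0 & d[-1] <= 0)
  if (!length(cross)) {
    # above threshold through the last ring: resolution at the grid Nyquist
    return(tibble::tibble(crossing_freq_invA = f[length(f)],
                          resolution_A = 1 / f[length(f)]))
  }
  i <- cross[length(cross)]
  frac <- d[i] / (d[i] - d[i + 1])
  fc <- f[i] + frac * (f[i + 1] - f[i])
  tibble::tibble(crossing_freq_invA = fc, resolution_A = 1 / fc)
}

#' Phase contrast transfer and SNR against ground truth
#'
#' Ring-wise fidelity of a reconstruction relative to a known simulated
#' truth: PCTF is the cross-term-normalized ratio of recovered to true phase
#' spectral amplitude, `Re<R T*> / <|T|^2>`; SNR is the ring-wise ratio of
#' true signal power to residual power.
#'
#' @param reconstruction,truth complex images, equal square shapes.
#' @param pixel_size_pm pixel size, pm.
#' @param snr_cap value reported for rings with zero residual power.
#' @return tibble: `ring_freq_invA`, `pctf`, `snr`, `n_ring`; rings with no
#'   truth power are `NA`.
#' @export
pctf_and_snr <- function(reconstruction, truth, pixel_size_pm, snr_cap = 1e12) {
  if (!all(dim(reconstruction) == dim(truth))) stop("shapes differ", call. = FALSE)
  n <- nrow(truth)
  # remove the global phase offset (ptychographic reconstructions carry an
  # arbitrary one) in the complex domain, so no wrap-around can scramble it
  off <- Arg(sum(reconstruction * Conj(truth)))
  phR <- Arg(reconstruction * exp(-1i * off)); phT <- Arg(truth)
  FR <- fftshift2(fft2(phR - mean(phR)))
  FT <- fftshift2(fft2(phT - mean(phT)))
  ci <- centre_index(n)
  rpx <- sqrt(outer((seq_len(n) - ci)^2, rep(1, n)) +
              outer(rep(1, n), (seq_len(n) - ci)^2))
  ring <- round(rpx)
  sel <- ring >= 1 & ring <= n - ci
  rg <- ring[sel]
  cross <- tapply(Re(FR[sel] * Conj(FT[sel])), rg, sum)
  pT <- tapply(Mod(FT[sel])^2, rg, sum)
  resid <- tapply(Mod(FR[sel] - FT[sel])^2, rg, sum)
  cnt <- tapply(rg, rg, length)
  pctf <- as.numeric(cross / pT)
  snr <- as.numeric(pT / resid)
  snr[resid == 0] <- snr_cap
  pctf[pT == 0] <- NA_real_
  snr[pT == 0] <- NA_real_
  rp <- 1 / (n * pixel_size_pm / 100)
  tibble::tibble(ring_freq_invA = as.integer(names(pT)) * rp,
                 pctf = pctf, snr = pmin(snr, snr_cap),
                 n_ring = as.integer(cnt))
}
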