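#' Relativistic electron wavelength
#'
#' de Broglie wavelength of an electron accelerated through `energy` kilovolts,
#' with the relativistic mass correction:
#' \deqn{\lambda = h / \sqrt{2 m_0 e V (1 + eV / 2 m_0 c^2)}}
#'
#' @param energy_kev beam energy in keV; must be positive.
#' @return wavelength in Angstrom.
#' @examples
#' electron_wavelength(20)       # ~0.0859 A; Ewald sphere radius 1/lambda ~ 11.6 1/A
#' @export
electron_wavelength <- function(energy_kev) {
  if (any(!is.finite(energy_kev)) || any(energy_kev <= 0)) {
    stop("beam energy must be positive and finite (keV)", call. = FALSE)
  }
  V <- energy_kev * 1e3                      # volts
  eV <- codata$e * V                         # joules
  p <- sqrt(2 * codata$m0 * eV * (1 + eV / (2 * codata$m0 * codata$c^2)))
  (codata$h / p) * 1e10
}

#' Diffraction-limited resolution of a convergent probe
#'
#' Abbe (`lambda / 2 alpha`) and Rayleigh (`0.61 lambda / alpha`) limits for an
#' aperture-limited illumination of convergence semi-angle `alpha`.
#'
#' @param wavelength_A electron wavelength, Angstrom.
#' @param alpha_rad convergence semi-angle, rad; must be positive.
#' @return resolution in Angstrom.
#' @export
abbe_resolution <- function(wavelength_A, alpha_rad) {
  check_alpha(alpha_rad)
  wavelength_A / (2 * alpha_rad)
}

#' @rdname abbe_resolution
#' @export
rayleigh_resolution <- function(wavelength_A, alpha_rad) {
  check_alpha(alpha_rad)
  0.61 * wavelength_A / alpha_rad
}

check_alpha <- function(alpha_rad) {
  if (any(!is.finite(alpha_rad)) || any(alpha_rad <= 0)) {
    stop("convergence semi-angle must be positive (rad)", call. = FALSE)
  }
  invisible(alpha_rad)
}

#' Beam parameter bundle
#'
#' @param energy_kev beam energy, keV.
#' @param alpha_rad convergence semi-angle, rad; must lie in (0, 0.3).
#' @return a `beam_parameters` list with the derived wavelength in Angstrom.
#' @export
beam_parameters <- function(energy_kev, alpha_rad) {
  check_alpha(alpha_rad)
  if (alpha_rad >= 0.3) stop("convergence semi-angle out of range (0, 0.3) rad", call. = FALSE)
  structure(list(
    energy_kev = energy_kev,
    wavelength_A = electron_wavelength(energy_kev),
    alpha_rad = alpha_rad
  ), class = "beam_parameters")
}

#' Mean electron dose
#'
#' Dose = I t / (e A): beam current integrated over the acquisition time,
#' divided by the elementary charge and the illuminated area.
#'
#' @param current_pA beam current, pA.
#' @param time_s total acquisition time, s.
#' @param area_A2 field-of-view area, square Angstrom.
#' @return dose in electrons per square Angstrom.
#' @examples
#' electron_dose(85, 40.5, 450^2)   # ~1.06e5 e-/A^2
#' @export
electron_dose <- function(current_pA, time_s, area_A2) {
  if (any(c(current_pA, time_s, area_A2) <= 0)) {
    stop("current, time and area must all be positive", call. = FALSE)
  }
  (current_pA * 1e-12) * time_s / (codata$e * area_A2)
}

#' Detector count budget
#'
#' Total detector count rate and the electron current it corresponds to at a
#' stated counting gain.
#'
#' @param mean_counts_per_pixel mean counts per detector pixel per frame.
#' @param n_pixels number of detector pixels.
#' @param frame_time_s exposure per frame, s.
#' @param gain detector gain, counts per electron; must be positive.
#' @return tibble with `total_rate` (counts/s) and `detector_current_pA`.
#' @examples
#' detector_count_budget(5.035, 512^2, 5e-3, 0.85)  # ~2.64e8 counts/s, ~49.8 pA
#' @export
detector_count_budget <- function(mean_counts_per_pixel, n_pixels, frame_time_s, gain) {
  if (gain <= 0) stop("gain must be positive (counts per electron)", call. = FALSE)
  if (any(c(mean_counts_per_pixel, n_pixels, frame_time_s) <= 0)) {
    stop("counts, pixel count and frame time must be positive", call. = FALSE)
  }
  total_rate <- mean_counts_per_pixel * n_pixels / frame_time_s
  electrons_per_s <- total_rate / gain
  tibble::tibble(
    total_rate = total_rate,
    detector_current_pA = electrons_per_s * codata$e * 1e12
  )
}

#' Illumination overlap between adjacent scan positions
#'
#' Linear-overlap convention `1 - step / diameter`. The area-overlap of two
#' discs at the same spacing is returned alongside as a secondary read-only
#' quantity.
#'
#' @param step_nm scan step, nm.
#' @param probe_diameter_nm effective illumination diameter, nm.
#' @return tibble with `overlap` (linear convention) and `area_overlap`.
#' @examples
#' illumination_overlap(0.5, 4)    # 0.875
#' illumination_overlap(0.9, 3.5)  # ~0.74
#' @export
illumination_overlap <- function(step_nm, probe_diameter_nm) {
  if (step_nm <= 0 || probe_diameter_nm <= 0) {
    stop("step and diameter must be positive", call. = FALSE)
  }
  if (step_nm >= probe_diameter_nm) {
    warning("scan step >= probe diameter: illumination regions do not overlap")
    return(tibble::tibble(overlap = 0, area_overlap = 0))
  }
  d <- step_nm / probe_diameter_nm
  # lens-shaped intersection of two unit-diameter discs at centre spacing d
  area <- (2 * acos(d) - sin(2 * acos(d))) / pi
  tibble::tibble(overlap = 1 - d, area_overlap = area)
}

#' Aberration coefficient set
#'
#' Defocus, spherical aberration and twofold astigmatism of the probe-forming
#' system. Sign convention: underfocus is negative defocus.
#'
#' @param defocus_nm defocus, nm (underfocus negative).
#' @param cs_mm spherical aberration coefficient, mm.
#' @param astig_nm twofold astigmatism magnitude, nm.
#' @param astig_azimuth_rad astigmatism azimuth, rad.
#' @return an `aberration_set` list.
#' @export
aberration_set <- function(defocus_nm = 0, cs_mm = 0, astig_nm = 0, astig_azimuth_rad = 0) {
  vals <- c(defocus_nm, cs_mm, astig_nm, astig_azimuth_rad)
  if (any(!is.finite(vals))) stop("aberration coefficients must be finite", call. = FALSE)
  structure(list(
    defocus_nm = defocus_nm, cs_mm = cs_mm,
    astig_nm = astig_nm, astig_azimuth_rad = astig_azimuth_rad
  ), class = "aberration_set")
}

#' Aberration phase surface
#'
#' Evaluates the aberration function on a reciprocal-space grid:
#' \deqn{\chi(k) = \pi \lambda |k|^2 \Delta f + \frac{\pi}{2} C_s \lambda^3 |k|^4
#'   + \pi \lambda |k|^2 A_2 \cos 2(\theta - \theta_0)}
#' with all lengths in Angstrom and k in 1/Angstrom.
#'
#' @param kx,ky reciprocal-space coordinate matrices, 1/Angstrom.
#' @param beam a [beam_parameters()] object.
#' @param ab an [aberration_set()] object.
#' @return matrix of phase values, rad.
#' @export
aberration_phase <- function(kx, ky, beam, ab) {
  lam <- beam$wavelength_A
  k2 <- kx^2 + ky^2
  df_A <- ab$defocus_nm * 10          # nm -> A
  cs_A <- ab$cs_mm * 1e7              # mm -> A
  chi <- pi * lam * k2 * df_A + (pi / 2) * cs_A * lam^3 * k2^2
  if (ab$astig_nm != 0) {
    theta <- atan2(ky, kx)
    chi <- chi + pi * lam * k2 * (ab$astig_nm * 10) * cos(2 * (theta - ab$astig_azimuth_rad))
  }
  chi
}

#' Fit probe aberrations from a complex probe image
#'
#' Unwraps the phase of the probe's Fourier transform inside the bright-field
#' aperture (quality-guided flood fill from the aperture centre) and fits the
#' aberration function by linear least squares in the basis
#' {1, |k|^2, |k|^4, |k|^2 cos 2theta, |k|^2 sin 2theta}. Pixels within 5% of
#' the aperture edge are excluded from the fit (edge ringing).
#'
#' @param probe complex probe image (real-space, square).
#' @param beam a [beam_parameters()] object.
#' @param pixel_size_pm real-space pixel size, pm.
#' @return an `aberration_set` with attributes `residual_rms` (rad) and
#'   `converged`; residual is `Inf` when the unwrap fails.
#' @export
fit_probe_aberrations <- function(probe, beam, pixel_size_pm) {
  n <- nrow(probe)
  stopifnot(ncol(probe) == n)
  P <- fftshift2(stats::fft(probe))
  # the probe array is centred by a half-array real-space shift, which puts a
  # checkerboard (-1)^(i+j) phase on its transform; remove it before unwrapping
  ci <- centre_index(n)
  cb <- outer((-1)^(seq_len(n) - ci), (-1)^(seq_len(n) - ci))
  P <- P * cb
  k <- kgrid(n, pixel_size_pm)
  kr <- sqrt(k$kx^2 + k$ky^2)
  k_ap <- beam$alpha_rad / beam$wavelength_A
  inside <- kr <= 0.95 * k_ap
  if (sum(inside) < 12) stop("aperture support too small to fit aberrations", call. = FALSE)

  phase <- unwrap_phase_region(Arg(P), Mod(P), inside)
  if (anyNA(phase[inside])) {
    res <- aberration_set()
    attr(res, "residual_rms") <- Inf
    attr(res, "converged") <- FALSE
    return(res)
  }
  lam <- beam$wavelength_A
  k2 <- (k$kx^2 + k$ky^2)[inside]
  th <- atan2(k$ky, k$kx)[inside]
  # chi carried as -Arg(FT probe): probe is built as A * exp(-i chi)
  y <- -phase[inside]
  X <- cbind(1, pi * lam * k2, (pi / 2) * lam^3 * k2^2,
             pi * lam * k2 * cos(2 * th), pi * lam * k2 * sin(2 * th))
  w <- Mod(P)[inside]
  fit <- stats::lm.wfit(X, y, w)
  cf <- unname(fit$coefficients)
  astig_c <- cf[4]; astig_s <- cf[5]
  res <- aberration_set(
    defocus_nm = cf[2] / 10,
    cs_mm = cf[3] / 1e7,
    astig_nm = sqrt(astig_c^2 + astig_s^2) / 10,
    astig_azimuth_rad = 0.5 * atan2(-astig_s, astig_c)
  )
  attr(res, "residual_rms") <- sqrt(sum(w * fit$residuals^2) / sum(w))
  attr(res, "converged") <- TRUE
  res
}

# Quality-guided 2-D phase unwrap over a connected pixel region.
# Pixels are admitted in decreasing magnitude order via a neighbour frontier
# seeded at the region's quality maximum; each new pixel is unwrapped against
# its already-resolved neighbour.
unwrap_phase_region <- function(phase, quality, region) {
  n <- nrow(phase); m <- ncol(phase)
  out <- matrix(NA_real_, n, m)
  idx <- which(region)
  if (!length(idx)) return(out)
  seed <- idx[which.max(quality[idx])]
  out[seed] <- phase[seed]
  # frontier as a quality-ordered candidate pool
  in_frontier <- rep(FALSE, n * m)
  frontier <- integer(0)
  push_neighbours <- function(p, frontier, in_frontier) {
    r <- (p - 1) %% n + 1; c <- (p - 1) %/% n + 1
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > n || cc < 1 || cc > m) next
      q <- (cc - 1L) * n + rr
      if (region[q] && is.na(out[q]) && !in_frontier[q]) {
        in_frontier[q] <- TRUE
        frontier <- c(frontier, q)
      }
    }
    list(frontier = frontier, in_frontier = in_frontier)
  }
  st <- push_neighbours(seed, frontier, in_frontier)
  frontier <- st$frontier; in_frontier <- st$in_frontier
  while (length(frontier)) {
    pick <- which.max(quality[frontier])
    p <- frontier[pick]
    frontier <- frontier[-pick]
    # unwrap against the best already-resolved neighbour
    r <- (p - 1) %% n + 1; c <- (p - 1) %/% n + 1
    ref <- NA_real_; refq <- -Inf
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > n || cc < 1 || cc > m) next
      q <- (cc - 1L) * n + rr
      if (!is.na(out[q]) && quality[q] > refq) { ref <- out[q]; refq <- quality[q] }
    }
    out[p] <- ref + ((phase[p] - ref + pi) %% (2 * pi)) - pi
    st <- push_neighbours(p, frontier, in_frontier)
    frontier <- st$frontier; in_frontier <- st$in_frontier
  }
  out
}
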