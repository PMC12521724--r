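#' Pincushion distortion model of the diffraction plane
#'
#' Radial mapping between undistorted (`r`) and distorted (`s`) reciprocal
#' distances: `s = M r (1 + k r^2)`. `M` is an overall magnification, `k` the
#' pincushion coefficient (1/A^-2, i.e. A^2 when r is in 1/A).
#'
#' @param M magnification, dimensionless, > 0.
#' @param k pincushion coefficient, A^2.
#' @return a `distortion_model`.
#' @export
distortion_model <- function(M = 1, k = 0) {
  if (M <= 0) stop("magnification M must be positive", call. = FALSE)
  structure(list(M = M, k = k), class = "distortion_model")
}

distort_radius <- function(r, model) model$M * r * (1 + model$k * r^2)

# invert s = M r (1 + k r^2) for r, by Newton iteration (monotone branch)
undistort_radius <- function(s, model) {
  r <- s / model$M
  for (i in 1:30) {
    f <- model$M * r * (1 + model$k * r^2) - s
    fp <- model$M * (1 + 3 * model$k * r^2)
    r <- r - f / fp
  }
  r
}

#' Radial intensity profile
#'
#' Tibble of intensity versus reciprocal-space radius, with an optional peak
#' table attribute (`label`, `d_A`, `r_invA`, `rel_intensity`). Used for both
#' powder references and reconstruction power spectra.
#'
#' @param r_invA strictly increasing radii, 1/A.
#' @param intensity nonnegative intensities.
#' @param peaks optional peak tibble.
#' @return a `radial_profile` tibble.
#' @export
radial_profile <- function(r_invA, intensity, peaks = NULL) {
  if (is.unsorted(r_invA, strictly = TRUE)) {
    stop("radii must be strictly increasing", call. = FALSE)
  }
  if (any(intensity < 0)) stop("intensities must be nonnegative", call. = FALSE)
  out <- tibble::new_tibble(list(r_invA = as.numeric(r_invA),
                                 intensity = as.numeric(intensity)),
                            nrow = length(r_invA),
                            class = "radial_profile")
  attr(out, "peaks") <- peaks
  out
}

# Doyle-Turner 4-Gaussian electron scattering factor for gold,
# f(s) = sum a_i exp(-b_i s^2), s = sin(theta)/lambda = 1/(2d) in 1/A.
au_scattering_factor <- function(s_half) {
  a <- c(2.388, 4.226, 2.689, 1.255)
  b <- c(42.866, 9.743, 2.264, 0.3067)
  rowSums(vapply(seq_along(a),
                 function(i) a[i] * exp(-b[i] * s_half^2),
                 numeric(length(s_half))))
}

#' Ideal gold powder diffraction profile
#'
#' Kinematic ring profile for randomly oriented FCC gold (a = 4.0782 A):
#' allowed reflections (h, k, l all even or all odd) up to `r_max`, with
#' relative intensities from multiplicity times the squared electron
#' scattering factor, each ring a Gaussian of width `peak_sigma`.
#'
#' @param energy_kev beam energy, keV (recorded; ring positions are
#'   energy-independent in 1/d units).
#' @param r_max maximum reciprocal radius, 1/A (default includes the {135}
#'   ring at 1.45 1/A).
#' @param peak_sigma Gaussian ring width, 1/A.
#' @param n_points samples in the returned profile.
#' @return a [radial_profile()] with a peak table attribute.
#' @examples
#' p <- gold_powder_profile()
#' attr(p, "peaks")   # {111} at 1/2.355 A^-1 ... {135} at 1.45 A^-1
#' @export
gold_powder_profile <- function(energy_kev = 20, r_max = 1.46,
                                peak_sigma = 0.02, n_points = 1024) {
  a0 <- AU_LATTICE_A
  hmax <- ceiling(r_max * a0)
  hkl <- expand.grid(h = -hmax:hmax, k = -hmax:hmax, l = -hmax:hmax)
  hkl <- hkl[rowSums(hkl^2) > 0, ]
  # FCC selection rule: h, k, l all even or all odd
  par_ok <- with(hkl, (abs(h) %% 2 + abs(k) %% 2 + abs(l) %% 2) %in% c(0, 3))
  hkl <- hkl[par_ok, ]
  n2 <- rowSums(hkl^2)
  tab <- table(n2)
  n2u <- as.integer(names(tab))
  r <- sqrt(n2u) / a0
  keep <- r <= r_max
  n2u <- n2u[keep]; mult <- as.integer(tab)[keep]; r <- r[keep]
  f <- au_scattering_factor(r / 2)
  rel <- mult * f^2
  rel <- rel / max(rel)
  label <- vapply(n2u, function(m) {
    cand <- hkl[rowSums(hkl^2) == m, ]
    cand <- abs(as.matrix(cand))
    cand <- t(apply(cand, 1, sort, decreasing = TRUE))
    best <- cand[which.max(cand %*% c(100, 10, 1)), ]
    paste0("{", paste(best, collapse = ""), "}")
  }, character(1))
  peaks <- tibble::tibble(label = label, d_A = 1 / r, r_invA = r,
                          rel_intensity = rel)
  peaks <- peaks[order(peaks$r_invA), ]
  rr <- seq(0, r_max, length.out = n_points + 1)[-1]
  inten <- rep(0, length(rr))
  for (i in seq_len(nrow(peaks))) {
    inten <- inten + peaks$rel_intensity[i] *
      exp(-(rr - peaks$r_invA[i])^2 / (2 * peak_sigma^2))
  }
  radial_profile(rr, inten, peaks = peaks)
}

#' Radially averaged power spectrum
#'
#' Azimuthal mean of the squared Fourier magnitude of a real image, in
#' unit-pixel-width annuli, with radii in 1/A.
#'
#' @param image real matrix.
#' @param pixel_size_pm real-space pixel size, pm.
#' @param pad_factor zero-padding factor applied before the transform;
#'   values > 1 interpolate the spectrum, giving finer radial sampling of
#'   ring positions without changing their locations.
#' @return a [radial_profile()]; the per-ring pixel counts are kept in an
#'   `n_ring` attribute.
#' @export
radial_average_power_spectrum <- function(image, pixel_size_pm,
                                          pad_factor = 1) {
  if (!all(is.finite(image))) stop("image must be finite", call. = FALSE)
  n <- nrow(image); m <- ncol(image)
  if (n != m) stop("image must be square", call. = FALSE)
  if (pad_factor > 1) {
    n2 <- round(n * pad_factor)
    big <- matrix(mean(image), n2, n2)
    off <- (n2 - n) %/% 2
    big[off + seq_len(n), off + seq_len(n)] <- image
    image <- big
    n <- m <- n2
  }
  P <- Mod(fftshift2(fft2(image)))^2
  ci <- centre_index(n); cj <- centre_index(m)
  rpx <- sqrt(outer((seq_len(n) - ci)^2, rep(1, m)) +
              outer(rep(1, n), (seq_len(m) - cj)^2))
  ring <- round(rpx)
  nmax <- min(n - ci, m - cj)
  sel <- ring <= nmax & ring >= 1
  mean_I <- tapply(P[sel], ring[sel], mean)
  counts <- tapply(P[sel], ring[sel], length)
  rp <- 1 / (n * pixel_size_pm / 100)   # annulus width: one reciprocal pixel
  out <- radial_profile(as.integer(names(mean_I)) * rp, as.numeric(mean_I))
  attr(out, "n_ring") <- as.integer(counts)
  out
}

#' Apply a distortion model to a radial profile
#'
#' Remaps the profile's radii through `s = M r (1 + k r^2)`; intensities are
#' carried unchanged (profile-level map; pixel-level Jacobian weighting is
#' handled by [undistort_stack()]).
#'
#' @param profile a [radial_profile()].
#' @param model a [distortion_model()].
#' @return a [radial_profile()] on the remapped radii.
#' @export
distort_profile <- function(profile, model) {
  s <- distort_radius(profile$r_invA, model)
  if (is.unsorted(s, strictly = TRUE)) {
    stop("distortion mapping is non-monotone over the profile range", call. = FALSE)
  }
  pk <- attr(profile, "peaks")
  if (!is.null(pk)) {
    pk <- pk
    pk$r_invA <- distort_radius(pk$r_invA, model)
  }
  radial_profile(s, profile$intensity, peaks = pk)
}

#' Locate peaks in a radial profile
#'
#' Baseline-subtracted local maxima with parabolic sub-bin refinement; a
#' short running-mean smooth suppresses speckle-split maxima before the
#' parabola is applied.
#'
#' @param profile a [radial_profile()].
#' @param min_rel minimum peak height relative to the strongest peak.
#' @param baseline_width running-median window (bins) for the baseline;
#'   0 disables baseline removal.
#' @param r_min ignore radii below this (the DC/low-frequency ramp), 1/A.
#' @param smooth_bins running-mean window (bins); 1 disables smoothing.
#' @return tibble with `r_invA` and `height`.
#' @export
find_profile_peaks <- function(profile, min_rel = 0.05, baseline_width = 31,
                               r_min = 0.15, smooth_bins = 3) {
  r <- profile$r_invA; y <- profile$intensity
  if (baseline_width > 0) {
    bw <- min(baseline_width, 2 * (length(y) %/% 2) - 1)
    y <- y - stats::runmed(y, bw)
    y[y < 0] <- 0
  }
  if (smooth_bins > 1) {
    y <- as.numeric(stats::filter(y, rep(1 / smooth_bins, smooth_bins),
                                  sides = 2))
    y[is.na(y)] <- 0
  }
  n <- length(y)
  is_pk <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  is_pk <- is_pk & r >= r_min
  if (!any(is_pk)) return(tibble::tibble(r_invA = numeric(0), height = numeric(0)))
  idx <- which(is_pk)
  idx <- idx[y[idx] >= min_rel * max(y[idx])]
  refine <- vapply(idx, function(i) {
    if (i <= 1 || i >= n) return(r[i])
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (denom >= 0) return(r[i])
    r[i] + 0.5 * (y[i - 1] - y[i + 1]) / denom * (r[2] - r[1])
  }, numeric(1))
  tibble::tibble(r_invA = refine, height = y[idx])
}

#' Fit a distortion model from matched peak positions
#'
#' Linearizes `s = M r (1 + k r^2)` as `s/r = M + (M k) r^2` and fits a
#' least-squares line through the (r^2, s/r) points: intercept = M,
#' slope / intercept = k. Exact on noiseless peaks.
#'
#' @param measured_s observed (distorted) peak radii, 1/A.
#' @param expected_r reference (undistorted) peak radii, 1/A.
#' @return a [distortion_model()] with attributes `linearity_r2` and `fit`
#'   (the lm object).
#' @export
fit_distortion_peaks <- function(measured_s, expected_r) {
  if (length(measured_s) != length(expected_r) || length(measured_s) < 3) {
    stop("need >= 3 matched peak pairs", call. = FALSE)
  }
  x <- expected_r^2; y <- measured_s / expected_r
  fit <- stats::lm(y ~ x)
  M <- unname(stats::coef(fit)[1])
  k <- unname(stats::coef(fit)[2]) / M
  out <- distortion_model(M, k)
  attr(out, "linearity_r2") <- suppressWarnings(summary(fit)$r.squared)
  attr(out, "fit") <- fit
  out
}

#' Fit a distortion model to a radial profile by simulated annealing
#'
#' Minimizes the Euclidean distance between the observed profile and the
#' distortion-mapped reference profile over (M, k), with seeded geometric
#' cooling followed by a deterministic compass-search polish. Both profiles
#' are baseline-subtracted and unit-normalized, and the reference is resampled
#' onto the observed radii at each evaluation.
#'
#' @param observed,reference [radial_profile()] objects with overlapping
#'   radial ranges.
#' @param seed annealing seed.
#' @param M_range,k_range search box.
#' @param n_steps annealing steps.
#' @param baseline_width running-median window for baseline removal (bins).
#' @param r_min ignore radii below this, 1/A.
#' @param r_max ignore radii above this (default: the full observed range);
#'   restricting the fit to the band that actually shows ring signal keeps
#'   featureless high-frequency noise from steering the optimizer.
#' @return a [distortion_model()] with attributes `fit_residual` and
#'   `converged`.
#' @export
fit_distortion_profile <- function(observed, reference, seed = 1L,
                                   M_range = c(0.8, 1.2), k_range = c(-0.1, 0.1),
                                   n_steps = 2000, baseline_width = 31,
                                   r_min = 0.15, r_max = NULL) {
  if (is.null(r_max)) r_max <- max(observed$r_invA)
  sel <- observed$r_invA >= r_min & observed$r_invA <= r_max
  robs <- observed$r_invA[sel]
  yobs <- detrend_norm(observed$intensity[sel], baseline_width)
  yref_raw <- reference$intensity
  rref <- reference$r_invA
  objective <- function(p) {
    s <- p[1] * rref * (1 + p[2] * rref^2)
    yref <- stats::approx(s, yref_raw, xout = robs, rule = 2)$y
    yref <- detrend_norm(yref, baseline_width)
    sqrt(sum((yobs - yref)^2))
  }
  old <- local_seed(seed); on.exit(restore_seed(old))
  cur <- c(mean(M_range), mean(k_range))
  cur_E <- objective(cur)
  best <- cur; best_E <- cur_E
  Temp <- cur_E + 0.1
  step <- c(diff(M_range), diff(k_range)) / 4
  for (i in seq_len(n_steps)) {
    cand <- cur + stats::rnorm(2) * step
    cand[1] <- min(max(cand[1], M_range[1]), M_range[2])
    cand[2] <- min(max(cand[2], k_range[1]), k_range[2])
    E <- objective(cand)
    if (E < cur_E || stats::runif(1) < exp(-(E - cur_E) / Temp)) {
      cur <- cand; cur_E <- E
      if (E < best_E) { best <- cand; best_E <- E }
    }
    Temp <- Temp * 0.996
    step <- pmax(step * 0.9985, c(2e-4, 2e-5))
  }
  # deterministic compass-search polish for bit-stable reruns (box-clamped)
  h <- c(2e-3, 2e-4)
  for (it in 1:200) {
    improved <- FALSE
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      cand <- best + d * h
      cand[1] <- min(max(cand[1], M_range[1]), M_range[2])
      cand[2] <- min(max(cand[2], k_range[1]), k_range[2])
      E <- objective(cand)
      if (E < best_E) { best <- cand; best_E <- E; improved <- TRUE }
    }
    if (!improved) {
      h <- h / 2
      if (all(h < c(1e-6, 1e-7))) break
    }
  }
  out <- distortion_model(best[1], best[2])
  attr(out, "fit_residual") <- best_E
  attr(out, "converged") <- best_E < 0.5 * sqrt(sum(yobs^2))
  out
}

detrend_norm <- function(y, baseline_width) {
  if (baseline_width > 0 && length(y) > baseline_width) {
    bw <- baseline_width
    if (bw %% 2 == 0) bw <- bw + 1
    y <- y - stats::runmed(y, bw)
    y[y < 0] <- 0
    # envelope normalization: equalize ring heights so the fit is driven by
    # peak positions rather than by relative ring intensities
    env <- running_max(y, bw)
    y <- y / pmax(env, 0.05 * max(env))
  }
  nrm <- sqrt(sum(y^2))
  if (nrm > 0) y / nrm else y
}

running_max <- function(y, w) {
  n <- length(y)
  half <- w %/% 2
  vapply(seq_len(n), function(i) {
    max(y[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Apply pincushion distortion to a detector frame (forward model)
#'
#' Count-conserving forward distortion used by the simulator: the distorted
#' frame samples the ideal pattern at the undistorted radius, weighted by the
#' inverse Jacobian of the radial map. `M` is taken as 1 for the pixel map.
#'
#' @param frame real matrix of expected counts.
#' @param model a [distortion_model()].
#' @param reciprocal_pixel_invA detector pixel size, 1/A.
#' @param supersample sub-pixel sampling factor per axis for the gather.
#' @return distorted frame, same shape.
#' @export
apply_pincushion <- function(frame, model, reciprocal_pixel_invA, supersample = 3) {
  radial_resample(frame, function(s) undistort_radius(s, distortion_model(1, model$k)),
                  function(s) {
                    r <- undistort_radius(s, distortion_model(1, model$k))
                    1 / ((1 + model$k * r^2) * (1 + 3 * model$k * r^2))
                  },
                  reciprocal_pixel_invA, supersample)
}

#' Undistort a diffraction stack (count conserving)
#'
#' Resamples each frame from distorted to undistorted coordinates with
#' area-weighted bilinear gathering and Jacobian intensity weighting, so that
#' integrated counts over corresponding patches are preserved. The
#' magnification `M` is absorbed by rescaling `reciprocal_pixel_invA` rather
#' than by resampling (the pixel map uses M = 1). The mask is resampled
#' conservatively: a target pixel stays valid only if every contributing
#' source pixel is valid.
#'
#' @param stack a [diffraction_stack()].
#' @param model a [distortion_model()].
#' @param supersample sub-pixel sampling factor per axis.
#' @return the undistorted [diffraction_stack()].
#' @export
undistort_stack <- function(stack, model, supersample = 3) {
  rp <- stack$reciprocal_pixel_invA
  k <- model$k
  r_corner <- max(dim(stack$frames)[1:2]) * rp / sqrt(2)
  if (1 + 3 * k * r_corner^2 <= 0) {
    stop("distortion model is non-monotone over the detector radius", call. = FALSE)
  }
  if (k == 0) {
    # pure magnification: absorbed entirely by the reciprocal pixel rescale
    out <- diffraction_stack(stack$frames, stack$mask, stack$grid,
                             stack$energy_kev, rp / model$M,
                             center = stack$center)
    attr(out, "distortion_history") <-
      c(attr(stack, "distortion_history"), list(model))
    return(out)
  }
  map_r <- function(r) distort_radius(r, distortion_model(1, k))
  jac <- function(r) (1 + k * r^2) * (1 + 3 * k * r^2)
  d <- dim(stack$frames)
  frames <- stack$frames
  for (j in seq_len(d[3])) {
    frames[, , j] <- radial_resample(stack$frames[, , j], map_r, jac, rp, supersample)
  }
  # conservative mask: resample the invalidity indicator without Jacobian and
  # invalidate any target pixel touched by an invalid source pixel
  bad <- radial_resample(1 - stack$mask * 1, map_r, function(r) rep(1, length(r)),
                         rp, supersample, fill = 1)
  mask <- stack$mask & (bad < 1e-6)
  for (j in seq_len(d[3])) {
    f <- frames[, , j]
    f[!mask] <- 0
    frames[, , j] <- f
  }
  out <- diffraction_stack(frames, mask, stack$grid, stack$energy_kev,
                           rp / model$M, center = stack$center)
  prov <- attr(stack, "distortion_history")
  attr(out, "distortion_history") <- c(prov, list(model))
  out
}

# Shared radial resampler: for each target pixel at radius r_t (in 1/A about
# the array centre), gather the source frame at radius map_r(r_t) along the
# same azimuth with bilinear interpolation, weight by jac(r_t), and average
# over supersample^2 sub-pixel target samples (area-weighted gather).
radial_resample <- function(frame, map_r, jac, reciprocal_pixel_invA,
                            supersample = 3, fill = 0) {
  n <- nrow(frame); m <- ncol(frame)
  ci <- centre_index(n); cj <- centre_index(m)
  ss <- supersample
  offs <- (seq_len(ss) - (ss + 1) / 2) / ss
  acc <- matrix(0, n, m)
  for (oy in offs) for (ox in offs) {
    Y <- outer(seq_len(n) - ci + oy, rep(1, m))
    X <- outer(rep(1, n), seq_len(m) - cj + ox)
    r_px <- sqrt(Y^2 + X^2)
    r <- r_px * reciprocal_pixel_invA
    scale <- ifelse(r_px > 0, map_r(r) / pmax(r, 1e-300) , 1)
    Ys <- Y * scale + ci; Xs <- X * scale + cj
    acc <- acc + bilinear_gather(frame, Ys, Xs, fill) * jac(r)
  }
  acc / (ss * ss)
}

bilinear_gather <- function(img, Y, X, fill = 0) {
  n <- nrow(img); m <- ncol(img)
  y0 <- floor(Y); x0 <- floor(X)
  fy <- Y - y0; fx <- X - x0
  inb <- y0 >= 1 & y0 <= n - 1 & x0 >= 1 & x0 <= m - 1
  out <- matrix(fill, n, m)
  idx <- which(inb)
  if (!length(idx)) return(out)
  y0i <- y0[idx]; x0i <- x0[idx]
  i00 <- (x0i - 1) * n + y0i
  v <- (1 - fy[idx]) * (1 - fx[idx]) * img[i00] +
       fy[idx] * (1 - fx[idx]) * img[i00 + 1] +
       (1 - fy[idx]) * fx[idx] * img[i00 + n] +
       fy[idx] * fx[idx] * img[i00 + n + 1]
  out[idx] <- v
  out
}

#' Self-calibrating distortion correction loop
#'
#' Iterates reconstruct -> radial power spectrum -> distortion fit ->
#' undistort until the maximum disagreement between matched reconstruction
#' and reference ring positions falls to `tol_peak_pct` percent, or
#' `max_cycles` cycles. Successive fits are composed into one cumulative
#' model (refit to the `s = M r (1 + k r^2)` form).
#'
#' @param stack a [diffraction_stack()].
#' @param reference a reference [radial_profile()] with a peak table.
#' @param recon_config a [reconstruction_config()] used for the interim
#'   reconstructions.
#' @param tol_peak_pct convergence tolerance, percent of each expected ring
#'   radius (max over matched rings).
#' @param max_cycles maximum reconstruct/fit cycles.
#' @param gain detector gain passed to the reconstructions.
#' @param fit_method `"auto"` (default: the annealed profile fit resolves
#'   ring assignment, then the exact linear (r^2, s/r) fit on the matched
#'   unblended rings delivers the coefficients), `"profile"` (annealing
#'   only) or `"peaks"` (linear fit on peaks matched directly to the
#'   reference rings).
#' @param seed seed for the reconstructions and (if used) the annealer.
#' @return list with `model` (the cumulative [distortion_model()]: the
#'   composition of the per-cycle fits at the best-measured cycle), `stack`
#'   (the undistorted stack of that cycle), `report` (per-cycle tibble:
#'   cycle, cumulative M and k, max_disagreement_pct, n_matched), `state`
#'   (the best reconstruction) and `converged`.
#' @export
calibration_loop <- function(stack, reference, recon_config,
                             tol_peak_pct = 1.0, max_cycles = 4,
                             fit_method = c("auto", "peaks", "profile"),
                             seed = 1L, gain = 1) {
  fit_method <- match.arg(fit_method)
  ref_peaks <- attr(reference, "peaks")
  if (is.null(ref_peaks)) stop("reference profile needs a peak table", call. = FALSE)
  probe_rings <- NULL   # measured from the reference with the same operator
  report <- NULL
  cum <- distortion_model(1, 0)
  cur <- stack
  converged <- FALSE
  best <- list(dis = Inf, model = cum, stack = stack, state = NULL)
  first_obs <- NULL
  for (cycle in seq_len(max_cycles)) {
    state <- run_reconstruction(cur, recon_config, gain = gain,
                                seed = seed + cycle - 1)
    ew <- exit_wave(state)
    prof <- radial_average_power_spectrum(Mod(ew)^2, state$pixel_size_pm)
    if (is.null(probe_rings)) {
      fit_rings <- NULL
      # convergence targets: peak positions of the reference profile
      # resampled onto the observed radial grid and measured with the same
      # detector (baseline + smooth + parabola), so that unresolved ring
      # blends displace the target and the measurement identically
      ref_int <- stats::approx(reference$r_invA, reference$intensity,
                               xout = prof$r_invA, rule = 1)$y
      ref_int[is.na(ref_int)] <- 0     # outside the reference range
      ref_grid <- radial_profile(prof$r_invA, ref_int)
      rp <- find_profile_peaks(ref_grid, min_rel = 0.1)
      probe_rings <- rp$r_invA[rp$height >= 0.15 * max(rp$height)]
      # rings suitable for the exact (r^2, s/r) fit: measured reference
      # positions that coincide with a single kinematic ring (no blend)
      d_ring <- vapply(probe_rings,
                       function(p) min(abs(ref_peaks$r_invA - p) / p),
                       numeric(1))
      fit_rings <- probe_rings[d_ring < 0.003]
    }
    obs <- find_profile_peaks(prof, min_rel = 0.04)
    if (cycle == 1) first_obs <- obs
    m <- match_peaks(obs$r_invA, probe_rings, heights = obs$height)
    max_dis <- if (nrow(m) >= 3) {
      max(100 * abs(m$measured - m$expected) / m$expected)
    } else {
      warning("fewer than 3 reference rings located in the reconstruction FT")
      NA_real_
    }
    report <- rbind(report, tibble::tibble(
      cycle = cycle, M = cum$M, k = cum$k,
      max_disagreement_pct = max_dis, n_matched = nrow(m)))
    improved <- is.finite(max_dis) && max_dis < best$dis
    if (improved) {
      best <- list(dis = max_dis, model = cum, stack = cur, state = state,
                   matches = m)
    }
    if (isTRUE(max_dis <= tol_peak_pct)) { converged <- TRUE; break }
    if (!improved && cycle > 1) break   # measurement no longer improving
    # fitting strategy ("auto"): the annealed profile fit is robust to ring
    # misassignment under a large unknown distortion but suffers an M-k
    # tradeoff; the exact (r^2, s/r) peak fit is precise but needs correct
    # assignment. So the anneal solves the assignment (predicting where each
    # unblended single ring should sit), and the peak fit on those matches
    # delivers the numbers whenever enough rings are matched.
    fit_profile <- function() {
      fit_distortion_profile(prof, reference, seed = seed + 100 * cycle,
                             k_range = c(-0.03, 0.1),
                             r_max = if (nrow(obs)) max(obs$r_invA) + 0.1 else NULL)
    }
    fit <- switch(fit_method,
      profile = fit_profile(),
      peaks = {
        mf <- match_peaks(obs$r_invA, fit_rings, gate = 0.03,
                          heights = obs$height)
        if (nrow(mf) >= 3) fit_distortion_peaks(mf$measured, mf$expected)
        else fit_profile()
      },
      auto = {
        m0 <- fit_profile()
        s_pred <- distort_radius(fit_rings, m0)
        mf <- match_peaks(obs$r_invA, s_pred, gate = 0.025,
                          heights = obs$height)
        if (nrow(mf) >= 4) {
          r_of <- fit_rings[match(mf$expected, s_pred)]
          fit_distortion_peaks(mf$measured, r_of)
        } else m0
      })
    if (fit$M < 0.8 || fit$M > 1.2 || fit$k < -0.03 || fit$k > 0.1) {
      warning("distortion fit outside the physical search box; cycle skipped")
      break
    }
    cum2 <- compose_distortion(cum, fit)
    # always resample the *original* stack through the cumulative model, so
    # the data suffer one interpolation regardless of the cycle count
    cur2 <- tryCatch(undistort_stack(stack, cum2), error = function(e) {
      warning("cumulative model rejected: ", conditionMessage(e))
      NULL
    })
    if (is.null(cur2)) break
    cum <- cum2
    cur <- cur2
  }
  list(model = best$model, stack = best$stack, report = report,
       converged = converged, state = best$state)
}

# reference rings suitable for unambiguous position checks: relative
# intensity >= min_rel; of any pair closer than min_sep_pct percent, only
# the stronger ring is kept
select_reference_rings <- function(ref_peaks, min_rel = 0.1, min_sep_pct = 5) {
  r <- ref_peaks$r_invA
  w <- ref_peaks$rel_intensity
  keep <- w >= min_rel
  for (i in seq_along(r)) {
    sep <- abs(r - r[i]) / r[i]
    close_stronger <- sep > 0 & sep < min_sep_pct / 100 & w >= w[i]
    if (any(close_stronger)) keep[i] <- FALSE
  }
  r[keep]
}

# one-to-one expected-ring assignment within a +/-10% radial gate: pairs are
# claimed greedily by increasing relative distance, so no measured peak
# serves two rings and no ring steals a peak already claimed by a nearer one;
# unmatched rings are dropped
match_peaks <- function(measured, expected, gate = 0.10, heights = NULL) {
  if (!length(measured) || !length(expected)) {
    return(data.frame(expected = numeric(0), measured = numeric(0)))
  }
  d <- abs(outer(expected, measured, "-")) / expected
  pairs <- which(d <= gate, arr.ind = TRUE)
  if (!nrow(pairs)) return(data.frame(expected = numeric(0), measured = numeric(0)))
  ord <- order(d[pairs])
  used_e <- rep(FALSE, length(expected)); used_m <- rep(FALSE, length(measured))
  out <- NULL
  for (p in ord) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    if (used_e[i] || used_m[j]) next
    used_e[i] <- TRUE; used_m[j] <- TRUE
    out <- rbind(out, data.frame(expected = expected[i], measured = measured[j]))
  }
  out[order(out$expected), , drop = FALSE]
}

# Compose two successive (M, k) maps and refit the composition to the
# single-model form; the refit residual is attached.
compose_distortion <- function(first, second) {
  r <- seq(0.05, 1.6, length.out = 200)
  s <- distort_radius(distort_radius(r, second), first)
  x <- r^2; y <- s / r
  fit <- stats::lm(y ~ x)
  M <- unname(stats::coef(fit)[1]); k <- unname(stats::coef(fit)[2]) / M
  out <- distortion_model(M, k)
  attr(out, "compose_residual") <- sqrt(mean(stats::resid(fit)^2))
  out
}
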