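#' Multi-slice object model
#'
#' An ordered stack of complex transmission functions with a common pixel size
#' and a uniform inter-slice spacing.
#'
#' @param slices list of complex matrices (all the same shape).
#' @param pixel_size_pm real-space pixel size, pm.
#' @param slice_spacing_A spacing between adjacent slices, Angstrom (>= 0).
#' @return an `object_model`.
#' @export
object_model <- function(slices, pixel_size_pm, slice_spacing_A = 0) {
  if (!is.list(slices)) slices <- list(slices)
  dims <- vapply(slices, dim, integer(2))
  if (any(dims != dims[, 1])) stop("all slices must share one shape", call. = FALSE)
  if (pixel_size_pm <= 0) stop("pixel size must be positive", call. = FALSE)
  if (slice_spacing_A < 0) stop("slice spacing must be >= 0", call. = FALSE)
  if (!all(vapply(slices, function(s) all(is.finite(Mod(s))), logical(1)))) {
    stop("slice amplitudes must be finite", call. = FALSE)
  }
  structure(list(slices = lapply(slices, as.complex_matrix),
                 pixel_size_pm = pixel_size_pm,
                 slice_spacing_A = slice_spacing_A),
            class = "object_model")
}

as.complex_matrix <- function(x) {
  if (!is.complex(x)) x <- matrix(complex(real = x, imaginary = 0), nrow(x), ncol(x))
  x
}

#' Mixed-mode probe model
#'
#' A set of complex probe modes whose intensities sum incoherently. Weights
#' are the normalized mode powers.
#'
#' @param modes list of complex matrices on the object pixel grid.
#' @param pixel_size_pm pixel size, pm.
#' @return a `probe_model`.
#' @export
probe_model <- function(modes, pixel_size_pm) {
  if (!is.list(modes)) modes <- list(modes)
  pw <- vapply(modes, function(m) sum(Mod(m)^2), numeric(1))
  structure(list(modes = modes, mode_weights = pw / sum(pw),
                 pixel_size_pm = pixel_size_pm),
            class = "probe_model")
}

probe_intensity <- function(probe) {
  Reduce(`+`, lapply(probe$modes, function(m) Mod(m)^2))
}

#' Form an aberrated convergent probe
#'
#' Inverse transform of a top-hat aperture of radius `alpha / lambda`
#' multiplied by `exp(-i chi)`, normalized to unit total intensity.
#'
#' @param beam a [beam_parameters()] object.
#' @param ab an [aberration_set()].
#' @param pixel_size_pm real-space pixel size, pm.
#' @param n_pixels array size (square).
#' @param defocus_override_nm optional defocus replacing `ab$defocus_nm`.
#' @return single-mode [probe_model()].
#' @export
make_probe <- function(beam, ab = aberration_set(), pixel_size_pm, n_pixels,
                       defocus_override_nm = NULL) {
  if (!is.null(defocus_override_nm)) ab$defocus_nm <- defocus_override_nm
  k <- kgrid(n_pixels, pixel_size_pm)
  kr <- sqrt(k$kx^2 + k$ky^2)
  k_ap <- beam$alpha_rad / beam$wavelength_A
  nyq <- 1 / (2 * pixel_size_pm / 100)
  if (k_ap >= nyq) {
    stop("aperture radius alpha/lambda exceeds the grid Nyquist frequency; ",
         "reduce pixel size or convergence angle", call. = FALSE)
  }
  A <- matrix(0, n_pixels, n_pixels)
  A[kr <= k_ap] <- 1
  chi <- aberration_phase(k$kx, k$ky, beam, ab)
  P <- ifft2(ifftshift2(A * exp(-1i * chi)))
  P <- fftshift2(P)                       # probe centred in the array
  P <- P / sqrt(sum(Mod(P)^2))
  probe_model(list(P), pixel_size_pm)
}

#' Probe diameter by encircled intensity
#'
#' Diameter of the circle (about the intensity centroid) containing `fraction`
#' of the probe's total intensity. Default 80%, the package's reporting
#' convention for the "approximate diameter".
#'
#' @param probe a [probe_model()].
#' @param fraction encircled-intensity fraction in (0, 1).
#' @return diameter in nm.
#' @export
probe_diameter <- function(probe, fraction = 0.8) {
  I <- probe_intensity(probe)
  n <- nrow(I)
  xs <- (seq_len(n) - centre_index(n))
  cx <- sum(I * matrix(rep(xs, each = n), n, n)) / sum(I)
  cy <- sum(I * matrix(rep(xs, times = n), n, n)) / sum(I)
  r <- sqrt(outer((xs - cy)^2, rep(1, n)) + outer(rep(1, n), (xs - cx)^2))
  o <- order(r)
  csum <- cumsum(I[o]) / sum(I)
  r50 <- r[o][which(csum >= fraction)[1]]
  2 * r50 * probe$pixel_size_pm * 1e-3     # pm -> nm
}

#' Angular-spectrum free-space propagation
#'
#' Exactly unitary Fresnel propagation over `distance_A`, applied in the
#' Fourier domain with the phase factor `exp(-i pi lambda z k^2)`.
#'
#' @param wave complex matrix.
#' @param distance_A propagation distance, Angstrom (may be negative).
#' @param wavelength_A wavelength, Angstrom.
#' @param pixel_size_pm pixel size, pm.
#' @return propagated complex matrix of the same shape.
#' @export
fresnel_propagate <- function(wave, distance_A, wavelength_A, pixel_size_pm) {
  if (distance_A == 0) return(wave)
  k <- kgrid_fft(nrow(wave), pixel_size_pm)
  H <- exp(-1i * pi * wavelength_A * distance_A * (k$kx^2 + k$ky^2))
  ifft2(fft2(wave) * H)
}

#' Multi-slice exit wave
#'
#' Alternates pointwise transmission through each slice with free-space
#' propagation over the inter-slice spacing; no propagation after the final
#' slice.
#'
#' @param incident complex incident wave (same shape as the slices).
#' @param object an [object_model()].
#' @param wavelength_A wavelength, Angstrom.
#' @return complex exit wave.
#' @export
multislice_exit_wave <- function(incident, object, wavelength_A) {
  if (!all(dim(incident) == dim(object$slices[[1]]))) {
    stop("incident wave shape must match the object slices", call. = FALSE)
  }
  w <- incident
  ns <- length(object$slices)
  for (s in seq_len(ns)) {
    w <- w * object$slices[[s]]
    if (s < ns) {
      w <- fresnel_propagate(w, object$slice_spacing_A, wavelength_A,
                             object$pixel_size_pm)
    }
  }
  w
}

#' Jittered scan grid
#'
#' Regular square grid of scan positions with pseudorandom but known offsets
#' of at most `jitter_fraction` of the step per axis. Positions are stored,
#' never re-inferred.
#'
#' @param step_nm nominal scan step, nm.
#' @param grid_shape integer (rows, cols).
#' @param jitter_fraction maximum offset as a fraction of the step (default
#'   0.5, i.e. +/- 50%).
#' @param seed integer seed for the offsets.
#' @return a `scan_grid` with a `positions` tibble (x_nm, y_nm, row, col).
#' @export
scan_grid <- function(step_nm, grid_shape, jitter_fraction = 0.5, seed = 1L) {
  rows <- grid_shape[1]; cols <- grid_shape[2]
  g <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  x0 <- (g$col - (cols + 1) / 2) * step_nm
  y0 <- (g$row - (rows + 1) / 2) * step_nm
  old <- local_seed(seed)
  jx <- stats::runif(nrow(g), -jitter_fraction, jitter_fraction) * step_nm
  jy <- stats::runif(nrow(g), -jitter_fraction, jitter_fraction) * step_nm
  restore_seed(old)
  structure(list(
    nominal_step_nm = step_nm, grid_shape = c(rows, cols),
    jitter_fraction = jitter_fraction, seed = seed,
    positions = tibble::tibble(row = g$row, col = g$col,
                               x_nm = x0 + jx, y_nm = y0 + jy)
  ), class = "scan_grid")
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Acquisition geometry
#'
#' Detector and scan bookkeeping for a 4D-STEM acquisition.
#'
#' @param detector_pixels detector side length, pixels.
#' @param detector_pixel_pitch_um physical pixel pitch, micrometres.
#' @param frame_time_s exposure per frame, s.
#' @param gain detector gain, counts per electron.
#' @param beam_current_pA beam current, pA.
#' @param scan_step_nm scan step, nm.
#' @param grid_shape scan grid (rows, cols).
#' @return an `acquisition_geometry`.
#' @export
acquisition_geometry <- function(detector_pixels, detector_pixel_pitch_um = 75,
                                 frame_time_s, gain = 0.85, beam_current_pA,
                                 scan_step_nm, grid_shape) {
  vals <- c(detector_pixels, detector_pixel_pitch_um, frame_time_s, gain,
            beam_current_pA, scan_step_nm, grid_shape)
  if (any(vals <= 0)) stop("all geometry fields must be positive", call. = FALSE)
  structure(list(
    detector_pixels = detector_pixels,
    detector_pixel_pitch_um = detector_pixel_pitch_um,
    frame_time_s = frame_time_s, gain = gain,
    beam_current_pA = beam_current_pA, scan_step_nm = scan_step_nm,
    grid_shape = grid_shape,
    field_of_view_nm2 = prod((grid_shape - 1) * scan_step_nm)
  ), class = "acquisition_geometry")
}

#' 4D-STEM diffraction stack
#'
#' Per-scan-position detector frames plus a shared floating validity mask.
#' Frames are stored as an (ny, nx, n_positions) array of nonnegative counts;
#' masked-out pixels carry value 0 and are excluded from every modulus
#' constraint and error metric.
#'
#' @param frames numeric array (ny, nx, n_pos), counts.
#' @param mask logical matrix (ny, nx); TRUE = valid pixel.
#' @param grid a [scan_grid()].
#' @param energy_kev beam energy, keV.
#' @param reciprocal_pixel_invA detector pixel size in reciprocal space, 1/A.
#' @param center stored bright-field disc centre (row, col), subpixel.
#' @return a `diffraction_stack`.
#' @export
diffraction_stack <- function(frames, mask, grid, energy_kev,
                              reciprocal_pixel_invA, center = NULL) {
  d <- dim(frames)
  if (length(d) != 3) stop("frames must be an (ny, nx, n_pos) array", call. = FALSE)
  if (!all(dim(mask) == d[1:2])) stop("mask shape must equal the frame shape", call. = FALSE)
  if (min(frames) < 0) stop("frames must be nonnegative", call. = FALSE)
  if (is.null(center)) center <- c(centre_index(d[1]), centre_index(d[2]))
  frames[array(!mask, dim = d)] <- 0
  structure(list(frames = frames, mask = mask, grid = grid,
                 energy_kev = energy_kev,
                 reciprocal_pixel_invA = reciprocal_pixel_invA,
                 center = center),
            class = "diffraction_stack")
}

#' @export
print.diffraction_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<diffraction_stack> %d frames of %dx%d px, %.4g 1/A per px, %.0f%% mask valid\n",
              d[3], d[1], d[2], x$reciprocal_pixel_invA, 100 * mean(x$mask)))
  invisible(x)
}

#' Synthetic test phantoms
#'
#' Seeded, reproducible multi-slice phantoms:
#' \describe{
#'   \item{powder_rings}{randomly oriented crystalline patches whose power
#'     spectrum peaks at the ring positions of a supplied reference profile
#'     (peak table required).}
#'   \item{lattice_patches}{a few single-orientation lattice patches.}
#'   \item{double_dots}{Gaussian dot pairs at specified separations.}
#'   \item{amorphous_plus_crystal}{smooth random phase background plus one
#'     crystalline patch.}
#' }
#'
#' @param kind phantom kind (see above).
#' @param n_pixels array side, pixels.
#' @param pixel_size_pm pixel size, pm.
#' @param n_slices number of slices.
#' @param slice_spacing_A inter-slice spacing, Angstrom.
#' @param phase_max peak phase shift per slice, rad.
#' @param amplitude_min minimum transmission amplitude.
#' @param reference [RadialProfile][gold_powder_profile()] with a `peaks`
#'   attribute, for `powder_rings`.
#' @param separations_pm dot-pair separations, pm, for `double_dots`.
#' @param n_patches number of crystalline patches.
#' @param patch_radius_px envelope sigma range of the crystalline patches,
#'   pixels; larger patches give sharper spectral rings.
#' @param seed integer seed.
#' @return an [object_model()].
#' @export
make_phantom <- function(kind = c("powder_rings", "lattice_patches",
                                  "double_dots", "amorphous_plus_crystal"),
                         n_pixels, pixel_size_pm, n_slices = 1,
                         slice_spacing_A = 20, phase_max = 0.5,
                         amplitude_min = 0.9, reference = NULL,
                         separations_pm = c(67), n_patches = 24,
                         patch_radius_px = c(6, 14), seed = 1L) {
  kind <- match.arg(kind)
  old <- local_seed(seed); on.exit(restore_seed(old))
  n <- n_pixels
  px_A <- pixel_size_pm / 100
  xs <- (seq_len(n) - centre_index(n)) * px_A
  X <- matrix(rep(xs, each = n), n, n)   # columns -> x
  Y <- matrix(rep(xs, times = n), n, n)  # rows -> y

  lattice_patch <- function(freqs_invA, weights = NULL) {
    if (is.null(weights)) weights <- rep(1, length(freqs_invA))
    ph <- matrix(0, n, n)
    for (i in seq_len(n_patches)) {
      cx <- stats::runif(1, min(xs), max(xs))
      cy <- stats::runif(1, min(xs), max(xs))
      rad <- stats::runif(1, patch_radius_px[1], patch_radius_px[2]) * px_A
      theta <- stats::runif(1, 0, pi)
      # cycle through the ring list so every ring gets patches
      j <- 1 + (i - 1) %% length(freqs_invA)
      f <- freqs_invA[j]
      env <- exp(-((X - cx)^2 + (Y - cy)^2) / (2 * rad^2))
      fringe <- cos(2 * pi * f * ((X - cx) * cos(theta) + (Y - cy) * sin(theta)) +
                      stats::runif(1, 0, 2 * pi))
      ph <- ph + sqrt(weights[j]) * env * fringe
    }
    ph / max(abs(ph))
  }

  slice_phase <- switch(kind,
    powder_rings = {
      pk <- attr(reference, "peaks")
      if (is.null(pk)) stop("powder_rings phantom needs a reference with a peak table",
                            call. = FALSE)
      replicate(n_slices, lattice_patch(pk$r_invA, pk$rel_intensity),
                simplify = FALSE)
    },
    lattice_patches = {
      nyq <- 1 / (2 * px_A)
      replicate(n_slices, lattice_patch(nyq * c(0.3, 0.5, 0.8)),
                simplify = FALSE)
    },
    double_dots = {
      ph <- matrix(0, n, n)
      for (s in separations_pm) {
        cx <- stats::runif(1, min(xs) / 2, max(xs) / 2)
        cy <- stats::runif(1, min(xs) / 2, max(xs) / 2)
        half <- s / 200                       # pm -> A, half separation
        sig <- max(s / 600, px_A / 2)
        ph <- ph + exp(-((X - cx - half)^2 + (Y - cy)^2) / (2 * sig^2)) +
                   exp(-((X - cx + half)^2 + (Y - cy)^2) / (2 * sig^2))
      }
      smooth_bg <- smooth_random_field(n, 8)
      replicate(n_slices, ph / max(ph) + 0.2 * smooth_bg, simplify = FALSE)
    },
    amorphous_plus_crystal = {
      lapply(seq_len(n_slices), function(s) {
        0.6 * smooth_random_field(n, 6) + 0.8 * lattice_patch(c(0.4, 0.7))
      })
    }
  )
  slices <- lapply(slice_phase, function(ph) {
    amp <- 1 - (1 - amplitude_min) * (ph - min(ph)) / max(1e-12, diff(range(ph)))
    amp * exp(1i * phase_max * ph)
  })
  object_model(slices, pixel_size_pm, slice_spacing_A)
}

# Band-limited unit-range random field (Gaussian blur of white noise in
# Fourier space), used for amorphous backgrounds.
smooth_random_field <- function(n, corr_px) {
  z <- matrix(stats::rnorm(n * n), n, n)
  k <- kgrid_fft(n, 100)                 # pixel units: pixel_size 1 A
  H <- exp(-2 * (pi * corr_px)^2 * (k$kx^2 + k$ky^2))
  f <- Re(ifft2(fft2(z) * H))
  f <- f - min(f)
  f / max(f)
}

#' Simulate a 4D-STEM acquisition
#'
#' For each scan position: shift the probe to the (jittered) position, form
#' the multi-slice exit wave, take the far-field intensity, scale to the
#' electron budget implied by beam current and frame time, optionally apply
#' pincushion distortion (count-conserving), apply the detector gain, Poisson
#' sample, then apply the central-cross dead mask and the stored off-centre
#' shift.
#'
#' @param object an [object_model()] covering the scanned field of view.
#' @param probe a [probe_model()] (modes on the detector-conjugate grid).
#' @param grid a [scan_grid()].
#' @param geometry an [acquisition_geometry()].
#' @param distortion optional [distortion_model()] applied to the ideal
#'   patterns before sampling.
#' @param noise_seed integer seed for the Poisson sampling; `NULL` disables
#'   noise (noiseless expected counts, "infinite dose" diagnostics).
#' @param center_offset_px integer (rows, cols) displacement of the
#'   bright-field disc from the array centre; recorded in the output.
#' @param cross_width_px width of the central dead cross, pixels (0 disables).
#' @param electrons_per_position override for the electron budget per frame;
#'   default from `beam_current_pA * frame_time_s / e`.
#' @param energy_kev beam energy, keV.
#' @return a [diffraction_stack()].
#' @export
simulate_4dstem <- function(object, probe, grid, geometry, distortion = NULL,
                            noise_seed = 1L, center_offset_px = c(0, 0),
                            cross_width_px = 2, electrons_per_position = NULL,
                            energy_kev = 20) {
  np <- nrow(probe$modes[[1]])
  nobj <- nrow(object$slices[[1]])
  stopifnot(probe$pixel_size_pm == object$pixel_size_pm)
  if (nobj < np) stop("object array must be at least as large as the probe array", call. = FALSE)
  beam_energy <- energy_kev
  lam <- electron_wavelength(beam_energy)
  px_A <- object$pixel_size_pm / 100
  rp <- 1 / (np * px_A)                   # reciprocal pixel, 1/A (conjugate grid)
  if (is.null(electrons_per_position)) {
    electrons_per_position <-
      geometry$beam_current_pA * 1e-12 * geometry$frame_time_s / codata$e
  }
  pos <- grid$positions
  npos <- nrow(pos)
  frames <- array(0, dim = c(np, np, npos))
  # dead cross + detector bounds mask
  mask <- matrix(TRUE, np, np)
  if (cross_width_px > 0) {
    mid <- centre_index(np)
    half <- cross_width_px %/% 2
    rows <- pmax(1, mid - half):pmin(np, mid + (cross_width_px - 1 - half))
    mask[rows, ] <- FALSE
    mask[, rows] <- FALSE
  }
  old <- if (!is.null(noise_seed)) local_seed(noise_seed) else NULL
  for (j in seq_len(npos)) {
    sub <- extract_probe_region(object, pos$x_nm[j], pos$y_nm[j], np)
    obj_j <- object_model(sub, object$pixel_size_pm, object$slice_spacing_A)
    I <- matrix(0, np, np)
    for (m in seq_along(probe$modes)) {
      ew <- multislice_exit_wave(probe$modes[[m]], obj_j, lam)
      Psi <- fftshift2(fft2(ew)) / np      # unitary scaling
      I <- I + Mod(Psi)^2
    }
    I <- I * electrons_per_position        # expected electrons per pixel
    if (!is.null(distortion)) I <- apply_pincushion(I, distortion, rp)
    counts <- I * geometry$gain
    if (!is.null(noise_seed)) {
      counts <- matrix(stats::rpois(length(counts), pmax(counts, 0)), np, np)
    }
    # off-centre shift: integer roll recorded in `center`
    if (any(center_offset_px != 0)) {
      counts <- roll2(counts, center_offset_px[1], center_offset_px[2])
    }
    counts[!mask] <- 0
    frames[, , j] <- counts
  }
  if (!is.null(old)) restore_seed(old)
  diffraction_stack(frames, mask, grid, beam_energy, rp,
                    center = c(centre_index(np) + center_offset_px[1],
                               centre_index(np) + center_offset_px[2]))
}

# integer circular roll of a matrix
roll2 <- function(x, dr, dc) {
  n <- nrow(x); m <- ncol(x)
  x[((seq_len(n) - 1 - dr) %% n) + 1, ((seq_len(m) - 1 - dc) %% m) + 1]
}

# Extract the np x np object patch illuminated at scan position (x, y) nm,
# with subpixel registration via Fourier shift of the patch.
extract_probe_region <- function(object, x_nm, y_nm, np) {
  nobj <- nrow(object$slices[[1]])
  px_nm <- object$pixel_size_pm * 1e-3
  cy <- centre_index(nobj) + y_nm / px_nm
  cx <- centre_index(nobj) + x_nm / px_nm
  r0 <- floor(cy) - centre_index(np) + 1
  c0 <- floor(cx) - centre_index(np) + 1
  fy <- cy - floor(cy); fx <- cx - floor(cx)
  rows <- r0:(r0 + np - 1); cols <- c0:(c0 + np - 1)
  if (min(rows) < 1 || max(rows) > nobj || min(cols) < 1 || max(cols) > nobj) {
    stop("scan position falls outside the object array; enlarge the object", call. = FALSE)
  }
  lapply(object$slices, function(s) {
    patch <- s[rows, cols]
    if (fy != 0 || fx != 0) patch <- fourier_shift(patch, -fy, -fx)
    patch
  })
}
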