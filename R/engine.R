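#' Reconstruction configuration
#'
#' Describes a staged reconstruction: an ordered schedule of solver phases,
#' the probe Fourier-aperture constraint, the incoherent-background model,
#' super-resolution padding and initialization.
#'
#' @param schedule list of phases, each a list with `algorithm` ("ePIE",
#'   "LSQML" or "MS-LSQML"), `iterations`, `n_slices`, `slice_spacing_A`,
#'   `n_probe_modes`.
#' @param alpha_rad probe convergence semi-angle used for the initial probe
#'   and the aperture constraint, rad.
#' @param probe_defocus_guess_nm initial probe defocus, nm.
#' @param probe_ft_aperture list(`enabled`, `radius_invA` (NULL = 1.5 x
#'   alpha/lambda), `strength` in (0, 1]).
#' @param background list(`enabled`, `blur_width_px`).
#' @param padding_factor 1, 2 or 4; frames are zero-padded before solving.
#' @param step_object,step_probe update step sizes.
#' @param initial_object "constant" or "constant_plus_random_imag"
#'   (max imaginary part 1e-6 of the real part, seeded).
#' @param seed base seed for position ordering and initialization.
#' @return a `reconstruction_config`.
#' @export
reconstruction_config <- function(schedule = list(list(algorithm = "ePIE",
                                                       iterations = 50,
                                                       n_slices = 1,
                                                       slice_spacing_A = 20,
                                                       n_probe_modes = 1)),
                                  alpha_rad = 7.2e-3,
                                  probe_defocus_guess_nm = 0,
                                  probe_ft_aperture = list(enabled = FALSE,
                                                           radius_invA = NULL,
                                                           strength = 0.5),
                                  background = list(enabled = FALSE,
                                                    blur_width_px = 4),
                                  padding_factor = 1,
                                  step_object = 1, step_probe = 1,
                                  initial_object = c("constant",
                                                     "constant_plus_random_imag"),
                                  seed = 1L) {
  initial_object <- match.arg(initial_object)
  if (!padding_factor %in% c(1, 2, 4)) {
    stop("padding_factor must be 1, 2 or 4", call. = FALSE)
  }
  for (ph in schedule) {
    if (ph$iterations <= 0) stop("each phase needs iterations > 0", call. = FALSE)
    if (ph$n_slices < 1) stop("n_slices must be >= 1", call. = FALSE)
    if (ph$n_slices >= 2 && ph$slice_spacing_A <= 0) {
      stop("multi-slice phases need a positive slice spacing", call. = FALSE)
    }
  }
  structure(list(schedule = schedule, alpha_rad = alpha_rad,
                 probe_defocus_guess_nm = probe_defocus_guess_nm,
                 probe_ft_aperture = probe_ft_aperture,
                 background = background, padding_factor = padding_factor,
                 step_object = step_object, step_probe = step_probe,
                 initial_object = initial_object, seed = seed),
            class = "reconstruction_config")
}

#' Recenter diffraction frames on the bright-field disc
#'
#' Integer-pixel shift placing the stored disc centre at the geometric array
#' centre. Vacated pixels are set to zero and excluded from the validity mask
#' (left to float), so they never enter a modulus constraint or error metric.
#'
#' @param stack a [diffraction_stack()].
#' @return the recentred [diffraction_stack()].
#' @export
recenter_frames <- function(stack) {
  d <- dim(stack$frames)
  tgt <- c(centre_index(d[1]), centre_index(d[2]))
  sh <- tgt - round(stack$center)
  if (any(round(stack$center) < 1) || any(round(stack$center) > d[1:2])) {
    stop("stored centre lies outside the frame", call. = FALSE)
  }
  if (all(sh == 0)) return(stack)
  frames <- stack$frames
  for (j in seq_len(d[3])) {
    frames[, , j] <- shift_pad(stack$frames[, , j], sh[1], sh[2], fill = 0)
  }
  mask <- shift_pad(stack$mask * 1, sh[1], sh[2], fill = 0) > 0.5
  diffraction_stack(frames, mask, stack$grid, stack$energy_kev,
                    stack$reciprocal_pixel_invA,
                    center = stack$center + sh)
}

# non-circular integer shift with fill
shift_pad <- function(x, dr, dc, fill = 0) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(fill, n, m)
  src_r <- seq_len(n) - dr; src_c <- seq_len(m) - dc
  ok_r <- src_r >= 1 & src_r <= n; ok_c <- src_c >= 1 & src_c <= m
  out[ok_r, ok_c] <- x[src_r[ok_r], src_c[ok_c]]
  out
}

#' Pad diffraction frames for super-resolution reconstruction
#'
#' Zero-pads each frame symmetrically to `factor` times its size; padded
#' pixels are mask-false (they float). The reconstructed real-space pixel
#' size shrinks by `factor`.
#'
#' @param stack a [diffraction_stack()].
#' @param factor 2 or 4 (1 returns the stack unchanged).
#' @return the padded [diffraction_stack()].
#' @export
pad_diffraction <- function(stack, factor) {
  if (!factor %in% c(1, 2, 4)) stop("padding factor must be 1, 2 or 4", call. = FALSE)
  if (factor == 1) return(stack)
  d <- dim(stack$frames)
  n2 <- d[1] * factor; m2 <- d[2] * factor
  off <- c(centre_index(n2) - centre_index(d[1]),
           centre_index(m2) - centre_index(d[2]))
  frames <- array(0, dim = c(n2, m2, d[3]))
  frames[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), ] <- stack$frames
  mask <- matrix(FALSE, n2, m2)
  mask[off[1] + seq_len(d[1]), off[2] + seq_len(d[2])] <- stack$mask
  diffraction_stack(frames, mask, stack$grid, stack$energy_kev,
                    stack$reciprocal_pixel_invA,
                    center = stack$center + off)
}

#' Orthogonalize mixed probe modes
#'
#' SVD-based orthogonalization: returns intensity-ordered orthogonal modes
#' spanning the same subspace, with weights equal to the normalized mode
#' powers. Total intensity is preserved.
#'
#' @param probe a [probe_model()].
#' @return an orthogonalized [probe_model()].
#' @export
orthogonalize_probe_modes <- function(probe) {
  m <- length(probe$modes)
  if (m == 1) return(probe)
  n <- nrow(probe$modes[[1]])
  A <- vapply(probe$modes, as.vector, complex(n * n))
  sv <- svd(A)
  modes <- lapply(seq_len(m), function(i) {
    matrix(sv$u[, i] * sv$d[i], n, n)
  })
  probe_model(modes, probe$pixel_size_pm)
}

#' Constrain the probe's Fourier transform to an aperture
#'
#' Multiplies the FT amplitude of every mode outside `radius_invA` by
#' `1 - strength` (strength 1 = hard truncation). Applied after each probe
#' update during reconstruction when enabled.
#'
#' @param probe a [probe_model()].
#' @param radius_invA aperture radius, 1/A.
#' @param strength suppression strength in (0, 1].
#' @return the constrained [probe_model()].
#' @export
apply_probe_ft_aperture <- function(probe, radius_invA, strength) {
  if (strength == 0) return(probe)
  n <- nrow(probe$modes[[1]])
  k <- kgrid(n, probe$pixel_size_pm)
  outside <- sqrt(k$kx^2 + k$ky^2) > radius_invA
  if (!any(outside)) return(probe)
  damp <- matrix(1, n, n); damp[outside] <- 1 - strength
  modes <- lapply(probe$modes, function(m) {
    ifft2(ifftshift2(fftshift2(fft2(m)) * damp))
  })
  probe_model(modes, probe$pixel_size_pm)
}

#' Estimate the incoherent diffraction background
#'
#' Mask-aware mean of the diffraction frames convolved with a normalized
#' Gaussian blur kernel. The returned image is the unit-fraction template;
#' the fraction actually added to the model intensity is fitted (clamped to
#' [0, 1]) during reconstruction.
#'
#' @param stack a [diffraction_stack()].
#' @param blur_width_px Gaussian sigma, detector pixels (0 = no blur).
#' @param gain detector gain used to convert counts to electrons.
#' @return nonnegative background image in electron units.
#' @export
estimate_background <- function(stack, blur_width_px = 4, gain = 1) {
  d <- dim(stack$frames)
  if (d[3] < 1) stop("empty stack", call. = FALSE)
  mean_frame <- apply(stack$frames, c(1, 2), mean) / gain
  if (blur_width_px > 0) {
    k <- kgrid_fft(d[1], 100)  # pixel units
    H <- exp(-2 * (pi * blur_width_px)^2 * (k$kx^2 + k$ky^2))
    num <- Re(ifft2(fft2(mean_frame * stack$mask) * H))
    den <- Re(ifft2(fft2(stack$mask * 1) * H))
    bg <- ifelse(den > 1e-9, num / pmax(den, 1e-9), 0)
  } else {
    bg <- mean_frame
  }
  pmax(bg, 0)
}

# ---- state ------------------------------------------------------------

#' Initialize a reconstruction state
#'
#' Builds the object canvas covering the scan field of view plus the probe
#' support, the initial probe (aperture transform at the nominal convergence
#' angle and defocus guess, scaled to the measured electron budget), and an
#' empty background.
#'
#' @param stack a (recentred) [diffraction_stack()].
#' @param config a [reconstruction_config()].
#' @return a `reconstruction_state`.
#' @export
init_state <- function(stack, config) {
  np <- dim(stack$frames)[1]
  rp <- stack$reciprocal_pixel_invA
  px_A <- 1 / (np * rp)
  px_pm <- px_A * 100
  beam <- beam_parameters(stack$energy_kev, config$alpha_rad)
  pos <- stack$grid$positions
  px_nm <- px_pm * 1e-3
  extent_px <- max(abs(c(pos$x_nm, pos$y_nm))) / px_nm
  nobj <- np + 2 * ceiling(extent_px) + 8
  nobj <- nobj + nobj %% 2
  old <- local_seed(config$seed); on.exit(restore_seed(old))
  O <- matrix(complex(real = 1, imaginary = 0), nobj, nobj)
  if (config$initial_object == "constant_plus_random_imag") {
    O <- O + 1i * matrix(stats::runif(nobj * nobj, 0, 1e-6), nobj, nobj)
  }
  pr <- make_probe(beam, aberration_set(defocus_nm = config$probe_defocus_guess_nm),
                   px_pm, np)
  budget <- median(apply(stack$frames, 3, function(f) sum(f[stack$mask])))
  pr$modes[[1]] <- pr$modes[[1]] * sqrt(max(budget, 1))
  structure(list(
    object = object_model(list(O), px_pm, 0),
    probe = pr, background = matrix(0, np, np), background_fraction = 0,
    error_history = numeric(0), pixel_size_pm = px_pm, beam = beam
  ), class = "reconstruction_state")
}

#' @export
print.reconstruction_state <- function(x, ...) {
  cat(sprintf("<reconstruction_state> object %dx%d px (%d slice(s), %.3g pm/px), %d probe mode(s), %d iterations logged\n",
              nrow(x$object$slices[[1]]), ncol(x$object$slices[[1]]),
              length(x$object$slices), x$pixel_size_pm,
              length(x$probe$modes), length(x$error_history)))
  invisible(x)
}

# data amplitudes in electron units; NA where mask-false never used
stack_amplitudes <- function(stack, gain = 1) {
  sqrt(pmax(stack$frames, 0) / gain)
}

# forward model for one position: per-mode detector wave (list) given slices
forward_position <- function(state, x_nm, y_nm, np, lam) {
  patches <- extract_probe_region(state$object, x_nm, y_nm, np)
  obj_j <- object_model(patches, state$object$pixel_size_pm,
                        state$object$slice_spacing_A)
  lapply(state$probe$modes, function(P) {
    ew <- multislice_exit_wave(P, obj_j, lam)
    fftshift2(fft2(ew)) / np
  })
}

#' Masked Fourier amplitude error
#'
#' Normalized amplitude residual `sqrt(sum((|model| - sqrt(data))^2) /
#' sum(data))` over mask-true pixels, averaged over scan positions.
#' Mask-false pixels never contribute. Identically 0 when the model matches
#' the data; 1 for a zero model.
#'
#' @param state a `reconstruction_state`.
#' @param stack a [diffraction_stack()].
#' @param gain detector gain (counts per electron).
#' @param positions optional subset of position indices.
#' @return nonnegative scalar.
#' @export
fourier_error <- function(state, stack, gain = 1, positions = NULL) {
  if (!any(stack$mask)) stop("validity mask is empty", call. = FALSE)
  d <- dim(stack$frames)
  np <- d[1]
  lam <- state$beam$wavelength_A
  pos <- stack$grid$positions
  if (is.null(positions)) positions <- seq_len(d[3])
  msk <- stack$mask
  errs <- vapply(positions, function(j) {
    Psis <- forward_position(state, pos$x_nm[j], pos$y_nm[j], np, lam)
    I <- Reduce(`+`, lapply(Psis, function(z) Mod(z)^2)) +
      state$background_fraction * state$background
    a <- sqrt(stack$frames[, , j][msk] / gain)
    mdl <- sqrt(I[msk])
    den <- sum(a^2)
    if (den <= 0) return(0)
    sqrt(sum((mdl - a)^2) / den)
  }, numeric(1))
  mean(errs)
}

#' One ePIE iteration
#'
#' Sequential extended-ptychographic-iterative-engine sweep: for each scan
#' position in a seeded random order, forms the exit wave, replaces the
#' Fourier modulus by the measured amplitude at mask-true pixels only, and
#' applies the conjugate-weighted object and probe corrections.
#' Single-slice, single-mode.
#'
#' @param state a `reconstruction_state` (single slice, single probe mode).
#' @param stack a [diffraction_stack()].
#' @param order_seed seed for the position permutation.
#' @param gain detector gain.
#' @param update_probe logical; probe update on by default.
#' @return the updated state (error history appended).
#' @export
epie_iteration <- function(state, stack, order_seed = 1L, gain = 1,
                           update_probe = TRUE) {
  if (length(state$object$slices) != 1 || length(state$probe$modes) != 1) {
    stop("ePIE operates on a single slice and a single probe mode", call. = FALSE)
  }
  np <- dim(stack$frames)[1]
  lam <- state$beam$wavelength_A
  pos <- stack$grid$positions
  msk <- stack$mask
  old <- local_seed(order_seed); ord <- sample.int(nrow(pos)); restore_seed(old)
  P <- state$probe$modes[[1]]
  if (sum(Mod(P)^2) == 0) stop("zero-norm probe", call. = FALSE)
  O <- state$object$slices[[1]]
  px_pm <- state$object$pixel_size_pm
  err_acc <- 0
  for (j in ord) {
    ext <- extract_region_idx(O, pos$x_nm[j], pos$y_nm[j], np, px_pm)
    Opatch <- ext$patch
    psi <- Opatch * P
    Psi <- fftshift2(fft2(psi)) / np
    a <- sqrt(stack$frames[, , j] / gain)
    modPsi <- Mod(Psi)
    err_acc <- err_acc + sqrt(sum((modPsi[msk] - a[msk])^2) / max(sum(a[msk]^2), 1e-30))
    Psi2 <- Psi
    repl <- msk & (modPsi > 0)
    Psi2[repl] <- a[repl] * Psi[repl] / modPsi[repl]
    Psi2[msk & modPsi == 0] <- a[msk & modPsi == 0]
    dpsi <- ifft2(ifftshift2(Psi2 - Psi)) * np
    newOpatch <- Opatch + 1 * Conj(P) / max(Mod(P)^2) * dpsi
    if (update_probe) {
      P <- P + 1 * Conj(Opatch) / max(Mod(Opatch)^2) * dpsi
    }
    O <- insert_region_idx(O, ext, newOpatch)
  }
  state$object$slices[[1]] <- O
  state$probe$modes[[1]] <- P
  state$error_history <- c(state$error_history, err_acc / nrow(pos))
  state
}

# patch extraction bookkeeping shared by the sequential engines: returns the
# integer window and the subpixel remainder so the adjoint can restore it
extract_region_idx <- function(O, x_nm, y_nm, np, px_pm) {
  nobj <- nrow(O)
  px_nm <- px_pm * 1e-3
  cy <- centre_index(nobj) + y_nm / px_nm
  cx <- centre_index(nobj) + x_nm / px_nm
  r0 <- floor(cy) - centre_index(np) + 1
  c0 <- floor(cx) - centre_index(np) + 1
  fy <- cy - floor(cy); fx <- cx - floor(cx)
  rows <- r0:(r0 + np - 1); cols <- c0:(c0 + np - 1)
  if (min(rows) < 1 || max(rows) > nobj || min(cols) < 1 || max(cols) > nobj) {
    stop("scan position outside the object canvas", call. = FALSE)
  }
  patch <- O[rows, cols]
  if (fy != 0 || fx != 0) patch <- fourier_shift(patch, -fy, -fx)
  list(patch = patch, rows = rows, cols = cols, fy = fy, fx = fx)
}

insert_region_idx <- function(O, ext, newpatch) {
  delta <- newpatch - ext$patch
  if (ext$fy != 0 || ext$fx != 0) delta <- fourier_shift(delta, ext$fy, ext$fx)
  O[ext$rows, ext$cols] <- O[ext$rows, ext$cols] + delta
  O
}

#' One LSQ-ML epoch (single-slice)
#'
#' Batch amplitude-metric gradient update over all positions with a
#' least-squares scalar step length found on a position subsample. Supports
#' mixed probe modes (incoherent intensity sum) and the fitted-fraction
#' incoherent background.
#'
#' @param state a `reconstruction_state`.
#' @param stack a [diffraction_stack()].
#' @param config a [reconstruction_config()].
#' @param gain detector gain.
#' @param update_probe logical.
#' @return the updated state.
#' @export
lsqml_epoch <- function(state, stack, config, gain = 1, update_probe = TRUE) {
  ms_lsqml_epoch(state, stack, config, gain = gain, update_probe = update_probe)
}

#' One multi-slice LSQ-ML epoch
#'
#' Forward-propagates every probe mode through the object slices
#' (transmit/propagate chain), compares the summed mode intensities plus
#' background with the data amplitudes at mask-true pixels, and chain-rules
#' the residual back onto each slice and the probe. With one slice this is
#' exactly the single-slice LSQ-ML update.
#'
#' @inheritParams lsqml_epoch
#' @return the updated state.
#' @export
ms_lsqml_epoch <- function(state, stack, config, gain = 1, update_probe = TRUE) {
  d <- dim(stack$frames); np <- d[1]
  lam <- state$beam$wavelength_A
  pos <- stack$grid$positions
  msk <- stack$mask
  px_pm <- state$object$pixel_size_pm
  dz <- state$object$slice_spacing_A
  ns <- length(state$object$slices)
  nm <- length(state$probe$modes)
  nobj <- nrow(state$object$slices[[1]])

  dO <- lapply(seq_len(ns), function(s) matrix(0i, nobj, nobj))
  wO <- lapply(seq_len(ns), function(s) matrix(0, nobj, nobj))
  dP <- lapply(seq_len(nm), function(m) matrix(0i, np, np))
  wP <- matrix(0, np, np)
  err_acc <- 0

  exts <- vector("list", d[3])
  for (j in seq_len(d[3])) {
    ext_slices <- lapply(state$object$slices, function(S)
      extract_region_idx(S, pos$x_nm[j], pos$y_nm[j], np, px_pm))
    exts[[j]] <- ext_slices
    Tj <- lapply(ext_slices, `[[`, "patch")
    # forward chains per mode: w[[m]][[s]] is the wave hitting slice s
    wlist <- vector("list", nm)
    philist <- vector("list", nm)
    Psis <- vector("list", nm)
    for (m in seq_len(nm)) {
      w <- vector("list", ns); phi <- vector("list", ns)
      w[[1]] <- state$probe$modes[[m]]
      for (s in seq_len(ns)) {
        phi[[s]] <- w[[s]] * Tj[[s]]
        if (s < ns) phi_prop <- fresnel_propagate(phi[[s]], dz, lam, px_pm)
        if (s < ns) w[[s + 1]] <- phi_prop
      }
      wlist[[m]] <- w; philist[[m]] <- phi
      Psis[[m]] <- fftshift2(fft2(phi[[ns]])) / np
    }
    I <- Reduce(`+`, lapply(Psis, function(z) Mod(z)^2)) +
      state$background_fraction * state$background
    a2 <- stack$frames[, , j] / gain
    sqI <- sqrt(pmax(I, 1e-30))
    err_acc <- err_acc + sqrt(sum((sqI[msk] - sqrt(a2[msk]))^2) /
                                max(sum(a2[msk]), 1e-30))
    chi <- matrix(0, np, np)
    chi[msk] <- 1 - sqrt(a2[msk]) / sqI[msk]
    for (m in seq_len(nm)) {
      dPsi <- -chi * Psis[[m]]
      dphi <- ifft2(ifftshift2(dPsi)) * np
      for (s in ns:1) {
        w_s <- wlist[[m]][[s]]
        ds <- Conj(w_s) * dphi
        dOp <- ds
        ext <- exts[[j]][[s]]
        if (ext$fy != 0 || ext$fx != 0) dOp <- fourier_shift(dOp, ext$fy, ext$fx)
        dO[[s]][ext$rows, ext$cols] <- dO[[s]][ext$rows, ext$cols] + dOp
        wmag <- Mod(w_s)^2
        if (ext$fy != 0 || ext$fx != 0) {
          wmag <- Re(fourier_shift(matrix(complex(real = wmag), np, np),
                                   ext$fy, ext$fx))
        }
        wO[[s]][ext$rows, ext$cols] <- wO[[s]][ext$rows, ext$cols] + pmax(wmag, 0)
        dw <- Conj(Tj[[s]]) * dphi
        if (s > 1) {
          dphi <- fresnel_propagate(dw, -dz, lam, px_pm)
        } else if (update_probe) {
          dP[[m]] <- dP[[m]] + dw
        }
      }
    }
    if (update_probe) {
      Oin <- Tj[[1]]
      wP <- wP + Mod(Oin)^2
    }
  }
  eps_O <- 0.01 * max(unlist(lapply(wO, max)))
  dirO <- lapply(seq_len(ns), function(s) dO[[s]] / (wO[[s]] + eps_O))
  dirP <- NULL
  if (update_probe) {
    eps_P <- 0.01 * max(wP)
    dirP <- lapply(dP, function(z) z / (wP + eps_P))
  }

  # scalar step via quadratic fit of the subsampled error along the direction
  nsub <- min(d[3], 24)
  old <- local_seed(config$seed + length(state$error_history))
  sub <- sort(sample.int(d[3], nsub)); restore_seed(old)
  try_state <- function(alpha) {
    st <- state
    for (s in seq_len(ns)) {
      st$object$slices[[s]] <- state$object$slices[[s]] +
        alpha * config$step_object * dirO[[s]]
    }
    if (update_probe) {
      for (m in seq_len(nm)) {
        st$probe$modes[[m]] <- state$probe$modes[[m]] +
          alpha * config$step_probe * dirP[[m]]
      }
    }
    st
  }
  e0 <- fourier_error(state, stack, gain, positions = sub)
  e1 <- fourier_error(try_state(1), stack, gain, positions = sub)
  e_half <- fourier_error(try_state(0.5), stack, gain, positions = sub)
  # parabola through (0, e0), (0.5, e_half), (1, e1)
  A <- 2 * e0 - 4 * e_half + 2 * e1
  B <- -3 * e0 + 4 * e_half - e1
  alpha <- if (A > 1e-15) max(min(-B / (2 * A), 2), 0.05) else
    if (e1 < e0) 1 else if (e_half < e0) 0.5 else 0.1
  cand <- try_state(alpha)
  e_cand <- fourier_error(cand, stack, gain, positions = sub)
  if (e_cand > e0) {
    alpha <- alpha / 4
    cand <- try_state(alpha)
    e_cand <- fourier_error(cand, stack, gain, positions = sub)
    if (e_cand > e0) { cand <- state; alpha <- 0 }
  }
  state <- cand
  state$error_history <- c(state$error_history, err_acc / d[3])
  check_divergence(state)
  state
}

check_divergence <- function(state) {
  eh <- state$error_history
  n <- length(eh)
  if (n >= 21 && eh[n] > 10 * eh[n - 20] && eh[n] > 1e-8) {
    stop(sprintf("solver divergence: error grew from %.3g to %.3g over 20 iterations",
                 eh[n - 20], eh[n]), call. = FALSE)
  }
  invisible(state)
}

# split slices for a schedule handoff (e.g. 2 -> 4): equal phase partition,
# amplitude split as the square root
split_slices <- function(object, new_n) {
  ns <- length(object$slices)
  if (new_n == ns) return(object)
  if (new_n %% ns != 0) stop("slice count may only grow by integer factors", call. = FALSE)
  f <- new_n / ns
  slices <- list()
  for (s in seq_len(ns)) {
    Ts <- object$slices[[s]]
    frac <- Mod(Ts)^(1 / f) * exp(1i * Arg(Ts) / f)
    for (i in seq_len(f)) slices <- c(slices, list(frac))
  }
  object_model(slices, object$pixel_size_pm,
               object$slice_spacing_A * ns / new_n)
}

#' Run a staged reconstruction
#'
#' Executes the configured schedule: optional recentring and padding, then
#' the ePIE / LSQ-ML / MS-LSQ-ML phases with slice-count handoffs, probe-mode
#' growth with orthogonalization, the probe Fourier-aperture constraint after
#' each probe update, and the fitted-fraction background model.
#'
#' @param stack a [diffraction_stack()].
#' @param config a [reconstruction_config()].
#' @param gain detector gain (counts per electron).
#' @param seed overrides `config$seed` when given.
#' @return the final `reconstruction_state`.
#' @export
run_reconstruction <- function(stack, config, gain = 1, seed = NULL) {
  if (!is.null(seed)) config$seed <- seed
  stack <- recenter_frames(stack)
  stack <- pad_diffraction(stack, config$padding_factor)
  state <- init_state(stack, config)
  if (config$background$enabled) {
    state$background <- estimate_background(stack, config$background$blur_width_px,
                                            gain)
  }
  ap_radius <- config$probe_ft_aperture$radius_invA
  if (is.null(ap_radius)) {
    ap_radius <- 1.5 * state$beam$alpha_rad / state$beam$wavelength_A
  }
  it_global <- 0
  for (ph in config$schedule) {
    # slice-count handoff
    if (ph$n_slices != length(state$object$slices)) {
      state$object <- split_slices(state$object, ph$n_slices)
      state$object$slice_spacing_A <- ph$slice_spacing_A
    } else {
      state$object$slice_spacing_A <- ph$slice_spacing_A
    }
    # probe-mode growth
    nm_cur <- length(state$probe$modes)
    if (!is.null(ph$n_probe_modes) && ph$n_probe_modes > nm_cur) {
      old <- local_seed(config$seed + 7 * it_global)
      np <- nrow(state$probe$modes[[1]])
      base_pw <- sum(Mod(state$probe$modes[[1]])^2)
      for (m in seq_len(ph$n_probe_modes - nm_cur)) {
        z <- matrix(complex(real = stats::rnorm(np * np),
                            imaginary = stats::rnorm(np * np)), np, np)
        z <- z * sqrt(0.01 * base_pw / sum(Mod(z)^2))
        state$probe$modes <- c(state$probe$modes, list(z))
      }
      restore_seed(old)
      state$probe <- orthogonalize_probe_modes(state$probe)
    }
    for (it in seq_len(ph$iterations)) {
      it_global <- it_global + 1
      if (ph$algorithm == "ePIE") {
        state <- epie_iteration(state, stack, order_seed = config$seed + it_global,
                                gain = gain)
      } else {
        state <- ms_lsqml_epoch(state, stack, config, gain = gain)
      }
      if (config$probe_ft_aperture$enabled) {
        state$probe <- apply_probe_ft_aperture(state$probe, ap_radius,
                                               config$probe_ft_aperture$strength)
      }
      if (length(state$probe$modes) > 1) {
        state$probe <- orthogonalize_probe_modes(state$probe)
      }
      if (config$background$enabled && it %% 5 == 1) {
        state <- fit_background_fraction(state, stack, gain)
      }
    }
  }
  state
}

# background fraction by regression of the residual intensity onto the
# template over a position subsample, clamped to [0, 1]. A grid search on
# the error metric is too greedy here: once the coherent model has partly
# absorbed the floor, any added background looks harmful even when jointly
# refitting would prefer it.
fit_background_fraction <- function(state, stack, gain = 1) {
  d <- dim(stack$frames)
  nsub <- min(d[3], 16)
  old <- local_seed(42L); sub <- sort(sample.int(d[3], nsub))
  restore_seed(old)
  lam <- state$beam$wavelength_A
  pos <- stack$grid$positions
  msk <- stack$mask
  bg <- state$background
  num <- 0; den <- 0
  for (j in sub) {
    Psis <- forward_position(state, pos$x_nm[j], pos$y_nm[j], d[1], lam)
    I_coh <- Reduce(`+`, lapply(Psis, function(z) Mod(z)^2))
    resid <- stack$frames[, , j] / gain - I_coh
    num <- num + sum(resid[msk] * bg[msk])
    den <- den + sum(bg[msk]^2)
  }
  state$background_fraction <- min(max(num / max(den, 1e-30), 0), 1)
  state
}

#' Plane-wave exit wave of a reconstructed object
#'
#' Numerically propagates a unit plane wave through the reconstructed slices
#' (transmit/propagate chain). Optionally crops to the scanned region.
#'
#' @param state a `reconstruction_state`.
#' @param crop_margin_px pixels to trim from each edge (default: half the
#'   probe array, removing the unconstrained canvas border); 0 keeps all.
#' @return complex exit-wave image.
#' @export
exit_wave <- function(state, crop_margin_px = NULL) {
  O <- state$object
  inc <- matrix(complex(real = 1), nrow(O$slices[[1]]), ncol(O$slices[[1]]))
  ew <- multislice_exit_wave(inc, O, state$beam$wavelength_A)
  if (is.null(crop_margin_px)) {
    crop_margin_px <- nrow(state$probe$modes[[1]]) %/% 2
  }
  if (crop_margin_px > 0) {
    n <- nrow(ew)
    sel <- (crop_margin_px + 1):(n - crop_margin_px)
    ew <- ew[sel, sel]
  }
  ew
}
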