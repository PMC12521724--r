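# Engine tests run on a small 8x8-scan, 64x64-detector lattice phantom.

test_that("recentring shifts the disc to the array centre and floats vacated pixels", {
  fx <- fixture_4dstem(grid = c(2, 2), noise_seed = NULL,
                       center_offset_px = c(3, -2), cross_width_px = 0)
  stk <- fx$stack
  rec <- recenter_frames(stk)
  np <- dim(stk$frames)[1]
  expect_equal(rec$center, c(np %/% 2 + 1, np %/% 2 + 1))
  # frames agree with the uncentred simulation wherever both are defined
  fx0 <- fixture_4dstem(grid = c(2, 2), noise_seed = NULL,
                        center_offset_px = c(0, 0), cross_width_px = 0)
  valid <- rec$mask
  expect_equal(rec$frames[, , 1][valid], fx0$stack$frames[, , 1][valid],
               tolerance = 1e-10)
  # vacated strip area leaves the mask
  expect_equal(sum(!rec$mask) - sum(!stk$mask), np * 3 + (np - 3) * 2)
  # already-centred stack is untouched
  expect_identical(recenter_frames(fx0$stack), fx0$stack)
})

test_that("padding preserves counts, floats the new pixels, and shrinks the pixel", {
  fx <- fixture_4dstem(grid = c(2, 2), noise_seed = 6)
  stk <- fx$stack
  pad <- pad_diffraction(stk, 2)
  expect_equal(dim(pad$frames)[1:2], 2 * dim(stk$frames)[1:2])
  expect_equal(sum(pad$frames), sum(stk$frames))
  expect_equal(sum(pad$mask), sum(stk$mask))
  expect_identical(pad_diffraction(stk, 1), stk)
  expect_error(pad_diffraction(stk, 3), "factor")
  # reconstructed pixel size halves: 33.14 pm -> 16.57 pm at factor 2
  px_of <- function(s) 100 / (dim(s$frames)[1] * s$reciprocal_pixel_invA)
  stk$reciprocal_pixel_invA <- 1 / (dim(stk$frames)[1] * 0.3314)
  expect_equal(px_of(stk), 33.14, tolerance = 1e-10)
  expect_equal(px_of(pad_diffraction(stk, 2)), 16.57, tolerance = 1e-10)
})

test_that("truth-initialized states are stationary for every algorithm", {
  fx <- fixture_4dstem(noise_seed = NULL)
  cfg <- basic_config(phase_schedule("ePIE", 1))
  st <- fixture_truth_state(fx, cfg)
  e0 <- fourier_error(st, fx$stack)
  expect_lt(e0, 1e-10)
  st_e <- epie_iteration(st, fx$stack, order_seed = 1)
  expect_lt(max(Mod(st_e$object$slices[[1]] - st$object$slices[[1]])), 1e-6)
  expect_lt(max(Mod(st_e$probe$modes[[1]] - st$probe$modes[[1]])), 1e-6)
  st_l <- lsqml_epoch(st, fx$stack, cfg)
  expect_lt(max(Mod(st_l$object$slices[[1]] - st$object$slices[[1]])), 1e-6)
  expect_lt(max(Mod(st_l$probe$modes[[1]] - st$probe$modes[[1]])), 1e-6)
})

test_that("mask-false pixels influence neither updates nor the error metric", {
  fx <- fixture_4dstem(noise_seed = 5)
  stk <- fx$stack
  cfg <- basic_config(phase_schedule("ePIE", 1))
  st <- fixture_truth_state(fx, cfg)
  # corrupt every mask-false pixel wildly
  stk2 <- stk
  bad <- array(rep(!stk$mask, dim(stk$frames)[3]), dim(stk$frames))
  stk2$frames[bad] <- 1e9
  expect_identical(fourier_error(st, stk), fourier_error(st, stk2))
  a <- epie_iteration(st, stk, order_seed = 2)
  b <- epie_iteration(st, stk2, order_seed = 2)
  expect_identical(a$object$slices[[1]], b$object$slices[[1]])
  expect_identical(a$probe$modes[[1]], b$probe$modes[[1]])
})

test_that("the error metric is anchored at 0 for perfect models and 1 for empty ones", {
  fx <- fixture_4dstem(noise_seed = NULL)
  cfg <- basic_config(phase_schedule("ePIE", 1))
  st <- fixture_truth_state(fx, cfg)
  expect_lt(fourier_error(st, fx$stack), 1e-10)
  st0 <- st
  st0$object$slices[[1]] <- st0$object$slices[[1]] * 0
  expect_equal(fourier_error(st0, fx$stack), 1)
  stm <- st
  stm_stack <- fx$stack
  stm_stack$mask[] <- FALSE
  expect_error(fourier_error(stm, stm_stack), "mask")
})

test_that("ePIE reduces the Fourier error at least tenfold on noiseless data", {
  fx <- fixture_4dstem(noise_seed = NULL)
  cfg <- basic_config(phase_schedule("ePIE", 100))
  st <- run_reconstruction(fx$stack, cfg)
  eh <- st$error_history
  expect_gte(eh[1] / min(eh), 10)
  # and the recovered phase correlates with the truth over the scanned band
  nobj <- nrow(st$object$slices[[1]])
  offs <- (220 - nobj) %/% 2
  sel <- 33:(nobj - 32)
  tr <- fx$phantom$slices[[1]][offs + sel, offs + sel]
  rc <- st$object$slices[[1]][sel, sel]
  rc <- rc * exp(-1i * Arg(sum(rc * Conj(tr))))   # remove the global phase
  expect_gt(cor(as.vector(Arg(tr)), as.vector(Arg(rc))), 0.9)
})

test_that("warm-started LSQ-ML beats an equal-budget pure-ePIE run", {
  fx <- fixture_4dstem(noise_seed = NULL)
  cfg_epie <- basic_config(phase_schedule("ePIE", 50))
  cfg_mix <- basic_config(c(phase_schedule("ePIE", 25),
                            phase_schedule("LSQML", 25)))
  e_pure <- tail(run_reconstruction(fx$stack, cfg_epie)$error_history, 1)
  e_mix <- tail(run_reconstruction(fx$stack, cfg_mix)$error_history, 1)
  expect_lt(e_mix, e_pure)
})

test_that("LSQ-ML error history is non-increasing after burn-in on Poisson data", {
  worsts <- vapply(1:5, function(s) {
    fx <- fixture_4dstem(noise_seed = 100 + s, electrons = 1e4)
    cfg <- basic_config(c(phase_schedule("ePIE", 10), phase_schedule("LSQML", 15)),
                        seed = 200 + s)
    eh <- run_reconstruction(fx$stack, cfg)$error_history
    tail_eh <- eh[15:length(eh)]
    max(diff(tail_eh) / tail_eh[-length(tail_eh)])
  }, numeric(1))
  expect_lte(median(worsts), 0)
})

test_that("a single-slice MS update equals the single-slice LSQ-ML update", {
  fx <- fixture_4dstem(noise_seed = 3)
  cfg <- basic_config(phase_schedule("LSQML", 1))
  st <- init_state(fx$stack, cfg)
  a <- lsqml_epoch(st, fx$stack, cfg)
  b <- ms_lsqml_epoch(st, fx$stack, cfg)
  expect_identical(a$object$slices[[1]], b$object$slices[[1]])
  expect_identical(a$probe$modes[[1]], b$probe$modes[[1]])
})

test_that("two-slice MS-LSQ-ML recovers per-slice phase at high dose", {
  fx <- fixture_4dstem(n_obj = 200, step_nm = 0.2, noise_seed = NULL,
                       electrons = 1e6, n_slices = 2, slice_spacing_A = 20,
                       phantom_seed = 7)
  cfg <- basic_config(c(phase_schedule("ePIE", 25, slice_spacing_A = 20),
                        phase_schedule("MS-LSQML", 150, n_slices = 2,
                                       slice_spacing_A = 20)))
  st <- run_reconstruction(fx$stack, cfg)
  nobj <- nrow(st$object$slices[[1]])
  offs <- (200 - nobj) %/% 2
  sel <- 33:(nobj - 32)
  for (s in 1:2) {
    tr <- fx$phantom$slices[[s]][offs + sel, offs + sel]
    rc <- st$object$slices[[s]][sel, sel]
    rc <- rc * exp(-1i * Arg(sum(rc * Conj(tr))))
    expect_gt(cor(as.vector(Arg(tr)), as.vector(Arg(rc))), 0.8)
  }
  # the summed recovered phase tracks the projected truth closely
  trsum <- Arg(fx$phantom$slices[[1]] * fx$phantom$slices[[2]])[offs + sel, offs + sel]
  rcsum <- Arg(st$object$slices[[1]] * st$object$slices[[2]])[sel, sel]
  expect_gt(cor(as.vector(trsum), as.vector(rcsum)), 0.95)
})

test_that("probe-mode orthogonalization yields an ordered orthogonal basis", {
  set.seed(13)
  n <- 32
  mk <- function() matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
  pm <- probe_model(list(mk(), mk(), mk()), 50)
  og <- orthogonalize_probe_modes(pm)
  for (i in 1:2) for (j in (i + 1):3) {
    ip <- abs(sum(Conj(og$modes[[i]]) * og$modes[[j]]))
    expect_lt(ip, 1e-8 * sqrt(sum(Mod(og$modes[[i]])^2) * sum(Mod(og$modes[[j]])^2)))
  }
  expect_true(all(diff(og$mode_weights) <= 0))
  # total intensity and subspace projector preserved
  tot0 <- sum(vapply(pm$modes, function(m) sum(Mod(m)^2), numeric(1)))
  tot1 <- sum(vapply(og$modes, function(m) sum(Mod(m)^2), numeric(1)))
  expect_equal(tot1, tot0, tolerance = 1e-10)
  A0 <- vapply(pm$modes, as.vector, complex(n^2))
  A1 <- vapply(og$modes, as.vector, complex(n^2))
  P0 <- A0 %*% solve(Conj(t(A0)) %*% A0) %*% Conj(t(A0))
  q1 <- qr.Q(qr(A1))
  P1 <- q1 %*% Conj(t(q1))
  expect_lt(max(Mod(P0 - P1)), 1e-8)
  # duplicated mode collapses onto the first
  dup <- orthogonalize_probe_modes(probe_model(list(pm$modes[[1]], pm$modes[[1]]), 50))
  expect_lt(sum(Mod(dup$modes[[2]])^2), 1e-12 * sum(Mod(dup$modes[[1]])^2))
  # modelled intensity equals the incoherent per-mode sum (brute force)
  I_mix <- Reduce(`+`, lapply(og$modes, function(m) Mod(m)^2))
  I_brute <- matrix(0, n, n)
  for (m in og$modes) I_brute <- I_brute + Mod(m)^2
  expect_identical(I_mix, I_brute)
})

test_that("the probe Fourier aperture suppresses injected high-frequency fringes", {
  beam <- fixture_beam()
  pr <- make_probe(beam, aberration_set(defocus_nm = -30), 50, 64)
  k_ap <- beam$alpha_rad / beam$wavelength_A
  # inject fringes well outside 1.5 x aperture radius
  n <- 64
  xs <- (seq_len(n) - 33) * 0.5   # A
  fringe <- 0.05 * max(Mod(pr$modes[[1]])) *
    exp(2i * pi * 0.8 * outer(xs, rep(1, n)))
  pr$modes[[1]] <- pr$modes[[1]] + fringe
  power_outside <- function(p) {
    P <- Mod(stats::fft(p$modes[[1]]))^2
    k <- sqrt(outer(c(0:32, 31:1)^2, rep(1, n)) +
              outer(rep(1, n), c(0:32, 31:1)^2)) / (n * 0.5)
    sum(P[k > 1.5 * k_ap])
  }
  p0 <- power_outside(pr)
  pr10 <- pr
  for (i in 1:10) pr10 <- apply_probe_ft_aperture(pr10, 1.5 * k_ap, 0.5)
  expect_gt(p0 / power_outside(pr10), 100)
  # identity cases
  expect_equal(apply_probe_ft_aperture(pr, 1.5 * k_ap, 0)$modes[[1]],
               pr$modes[[1]])
  nyq <- 1 / (2 * 0.5)
  expect_equal(apply_probe_ft_aperture(pr, nyq * 1.5, 1)$modes[[1]],
               pr$modes[[1]], tolerance = 1e-12)
})

test_that("background estimation is mask-aware and bounded by the mean frame", {
  fx <- fixture_4dstem(noise_seed = 4)
  stk <- fx$stack
  bg <- estimate_background(stk, blur_width_px = 3, gain = 1)
  expect_true(all(bg >= 0))
  mean_frame <- apply(stk$frames, c(1, 2), mean)
  # bounded by the measured counts over the valid region (the template may
  # legitimately inpaint the dead cross, so masked pixels are excluded)
  expect_lte(sum(bg[stk$mask]), sum(mean_frame[stk$mask]) * 1.05)
  # identical frames, no blur: background template equals the frame
  stk2 <- stk
  for (j in seq_len(dim(stk2$frames)[3])) stk2$frames[, , j] <- stk$frames[, , 1]
  bg0 <- estimate_background(stk2, blur_width_px = 0, gain = 1)
  expect_equal(bg0, stk$frames[, , 1], tolerance = 1e-12)
})

test_that("modelling a smooth incoherent floor lowers the reconstruction error", {
  fx <- fixture_4dstem(noise_seed = NULL, electrons = 1e5)
  stk <- fx$stack
  # add an incoherent floor of the modelled family: a fraction of the blurred
  # mean pattern (the chromatic halo surrounding the diffraction discs)
  floor_img <- 0.15 * estimate_background(stk, blur_width_px = 3, gain = 1)
  for (j in seq_len(dim(stk$frames)[3])) {
    f <- stk$frames[, , j] + floor_img
    f[!stk$mask] <- 0
    stk$frames[, , j] <- f
  }
  sched <- c(phase_schedule("ePIE", 10), phase_schedule("LSQML", 15))
  cfg_off <- basic_config(sched)
  cfg_on <- basic_config(sched, background = list(enabled = TRUE, blur_width_px = 3))
  e_off <- tail(run_reconstruction(stk, cfg_off)$error_history, 1)
  e_on <- tail(run_reconstruction(stk, cfg_on)$error_history, 1)
  expect_lt(e_on, e_off)
})
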