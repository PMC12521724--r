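test_that("make_probe produces a normalized, aperture-limited probe", {
  beam <- fixture_beam()
  pr <- make_probe(beam, aberration_set(), 500, 128)
  P <- pr$modes[[1]]
  expect_equal(sum(Mod(P)^2), 1, tolerance = 1e-10)
  # no aberrations: mirror symmetric about the array centre (n/2 + 1)
  I <- Mod(P)^2
  expect_equal(I[2:128, 2:128], I[128:2, 128:2], tolerance = 1e-8 * max(I))
  expect_equal(I[2:128, 2:128], I[2:128, 128:2], tolerance = 1e-8 * max(I))
  # experiment-scale defocused probe is about 4 nm across
  prd <- make_probe(beam, aberration_set(defocus_nm = -390, cs_mm = 3.9), 500, 256)
  expect_equal(probe_diameter(prd), 4, tolerance = 0.15)
  # aperture beyond Nyquist rejected
  expect_error(make_probe(beam, aberration_set(), 3000, 64), "Nyquist")
})

test_that("angular-spectrum propagation is unitary and invertible", {
  lam <- electron_wavelength(20)
  set.seed(42)
  for (i in 1:100) {
    w <- matrix(complex(real = rnorm(32^2), imaginary = rnorm(32^2)), 32, 32)
    z <- runif(1, 1, 500)
    w2 <- fresnel_propagate(w, z, lam, 50)
    expect_equal(sum(Mod(w2)^2), sum(Mod(w)^2), tolerance = 1e-10)
  }
  w <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64, 64)
  expect_identical(fresnel_propagate(w, 0, lam, 50), w)
  back <- fresnel_propagate(fresnel_propagate(w, 77, lam, 50), -77, lam, 50)
  expect_lt(max(Mod(back - w)), 1e-10 * max(Mod(w)))
})

test_that("a propagated Gaussian beam follows the analytic waist law", {
  lam <- electron_wavelength(20)
  n <- 256; px_pm <- 50
  px_A <- px_pm / 100
  xs <- (seq_len(n) - (n %/% 2 + 1)) * px_A
  w0 <- 4                                     # waist, A
  g <- exp(-(outer(xs^2, rep(1, n)) + outer(rep(1, n), xs^2)) / w0^2)
  g <- g / sqrt(sum(Mod(g)^2))
  for (z in c(200, 500)) {
    wz <- fresnel_propagate(g, z, lam, px_pm)
    I <- Mod(wz)^2
    # measured 1/e^2 radius from second moments: w^2 = 4 <r^2> / 2 per axis
    sig2 <- sum(I * outer(xs^2, rep(1, n))) / sum(I)
    w_meas <- 2 * sqrt(sig2)   # 1/e^2 field radius from the intensity moment
    w_true <- w0 * sqrt(1 + (lam * z / (pi * w0^2))^2)
    expect_equal(w_meas, w_true, tolerance = 0.005)
  }
})

test_that("multislice transmission reduces correctly in degenerate cases", {
  lam <- electron_wavelength(20)
  n <- 64
  set.seed(7)
  inc <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
  ones <- matrix(complex(real = 1), n, n)
  # all-ones slices: pure free-space propagation over (n_slices - 1) spacings
  obj <- object_model(list(ones, ones, ones), 50, 20)
  expect_equal(multislice_exit_wave(inc, obj, lam),
               fresnel_propagate(inc, 40, lam, 50), tolerance = 1e-12)
  # single slice: pointwise product, no propagation
  slice <- matrix(complex(modulus = runif(n^2, 0.8, 1), argument = runif(n^2)), n, n)
  obj1 <- object_model(list(slice), 50, 20)
  expect_equal(multislice_exit_wave(inc, obj1, lam), inc * slice)
  expect_error(multislice_exit_wave(inc[1:32, 1:32], obj1, lam), "shape")
})

test_that("two thin slices at 20 A spacing differ measurably from their projection", {
  lam <- electron_wavelength(20)
  n <- 128
  set.seed(8)
  mkphase <- function() {
    z <- matrix(rnorm(n^2), n, n)
    Re(stats::fft(stats::fft(z) * exp(-(outer(c(0:(n / 2), (n / 2 - 1):1)^2 / 40,
                                              rep(1, n)) +
                                        outer(rep(1, n),
                                              c(0:(n / 2), (n / 2 - 1):1)^2 / 40))),
                  inverse = TRUE)) / n^2
  }
  p1 <- mkphase(); p2 <- mkphase()
  p1 <- 0.5 * p1 / max(abs(p1)); p2 <- 0.5 * p2 / max(abs(p2))
  probe <- make_probe(fixture_beam(30e-3), aberration_set(defocus_nm = -20),
                      100, n)$modes[[1]]
  two <- object_model(list(exp(1i * p1), exp(1i * p2)), 100, 20)
  proj <- object_model(list(exp(1i * (p1 + p2))), 100, 0)
  ew2 <- multislice_exit_wave(probe, two, lam)
  ewp <- multislice_exit_wave(probe, proj, lam)
  rel <- sqrt(sum(Mod(ew2 - ewp)^2) / sum(Mod(ewp)^2))
  expect_gt(rel, 1e-3)
})

test_that("scan grids are reproducible with bounded jitter", {
  g1 <- scan_grid(0.5, c(6, 7), jitter_fraction = 0.5, seed = 12)
  g2 <- scan_grid(0.5, c(6, 7), jitter_fraction = 0.5, seed = 12)
  expect_identical(g1$positions, g2$positions)
  expect_equal(nrow(g1$positions), 42)
  # offsets bounded by half the step about the nominal grid, per axis
  nomx <- (g1$positions$col - 4) * 0.5
  nomy <- (g1$positions$row - 3.5) * 0.5
  expect_true(all(abs(g1$positions$x_nm - nomx) <= 0.25 + 1e-12))
  expect_true(all(abs(g1$positions$y_nm - nomy) <= 0.25 + 1e-12))
})

test_that("phantoms are deterministic and double dots sit at the stated separation", {
  p1 <- make_phantom("double_dots", n_pixels = 128, pixel_size_pm = 25,
                     separations_pm = 67, seed = 4)
  p2 <- make_phantom("double_dots", n_pixels = 128, pixel_size_pm = 25,
                     separations_pm = 67, seed = 4)
  expect_identical(p1$slices[[1]], p2$slices[[1]])
  # autocorrelation of the phase has a satellite peak at the dot separation
  ph <- Arg(p1$slices[[1]])
  F <- stats::fft(ph - mean(ph))
  ac <- Re(stats::fft(F * Conj(F), inverse = TRUE))
  ac <- ac / max(ac)
  n <- 128
  ac_s <- ac[c((n / 2 + 1):n, 1:(n / 2)), c((n / 2 + 1):n, 1:(n / 2))]
  ci <- n / 2 + 1
  rr <- sqrt(outer((seq_len(n) - ci)^2, rep(1, n)) +
             outer(rep(1, n), (seq_len(n) - ci)^2))
  sep_px <- 67 / 25
  shell <- ac_s[abs(rr - sep_px) <= 0.5]
  # satellite at the separation distance (peak flanked by lower shells)
  inner <- ac_s[abs(rr - 3 * sep_px / 2) <= 0.5]
  expect_gt(max(shell), max(inner))
  expect_error(make_phantom("nonsense", 64, 25), "arg")
})

test_that("powder-ring phantoms put spectral power on the reference rings", {
  ref <- gold_powder_profile(peak_sigma = 0.03)
  ph <- make_phantom("powder_rings", n_pixels = 384, pixel_size_pm = 25,
                     phase_max = 0.6, reference = ref, n_patches = 60, seed = 21)
  prof <- radial_average_power_spectrum(Arg(ph$slices[[1]]), 25)
  pks <- find_profile_peaks(prof, min_rel = 0.03)
  ref_pk <- attr(ref, "peaks")
  dr <- prof$r_invA[2] - prof$r_invA[1]
  for (r0 in c(0.4247, 0.6943, 0.8135)) {    # {111}, {220}, {311}
    expect_lt(min(abs(pks$r_invA - r0)), 2 * dr)
  }
})

test_that("the simulator conserves electrons and places the bright-field disc", {
  fx <- fixture_4dstem(grid = c(2, 2), noise_seed = NULL, cross_width_px = 0)
  stk <- fx$stack
  # noiseless frames sum to incident electrons x transmitted fraction (<= 1)
  sums <- apply(stk$frames, 3, sum)
  expect_true(all(sums <= fx$electrons * 1.0000001))
  expect_true(all(sums >= 0.9 * fx$electrons))
  # vacuum object: frame is the bright-field disc of the expected radius
  beam <- fx$beam
  vac <- object_model(list(matrix(complex(real = 1), 220, 220)), 100, 0)
  stkv <- simulate_4dstem(vac, fx$probe, fx$grid, fx$geometry,
                          noise_seed = NULL, cross_width_px = 0,
                          electrons_per_position = 1e6)
  f <- stkv$frames[, , 1]
  r_expect <- beam$alpha_rad / beam$wavelength_A / stkv$reciprocal_pixel_invA
  r_meas <- sqrt(sum(f > 0.1 * max(f)) / pi)
  expect_equal(r_meas, r_expect, tolerance = 0.5 / r_expect)
  # zero dose -> all-zero frames
  stk0 <- simulate_4dstem(vac, fx$probe, fx$grid, fx$geometry,
                          noise_seed = 17, electrons_per_position = 0)
  expect_true(all(stk0$frames == 0))
})

test_that("detector gain scales expected counts linearly", {
  fx1 <- fixture_4dstem(grid = c(2, 2), noise_seed = NULL, gain = 1)
  fx2 <- fixture_4dstem(grid = c(2, 2), noise_seed = NULL, gain = 2.5)
  expect_equal(fx2$stack$frames, 2.5 * fx1$stack$frames, tolerance = 1e-12)
})

test_that("the stored centre matches the off-centre shift applied by the simulator", {
  fx <- fixture_4dstem(grid = c(2, 2), noise_seed = NULL,
                       center_offset_px = c(4, -3), cross_width_px = 0)
  stk <- fx$stack
  np <- dim(stk$frames)[1]
  expect_equal(stk$center, c(np %/% 2 + 1 + 4, np %/% 2 + 1 - 3))
  # centroid of the vacuum disc lands at the stored centre
  vac <- object_model(list(matrix(complex(real = 1), 220, 220)), 100, 0)
  stkv <- simulate_4dstem(vac, fx$probe, fx$grid, fx$geometry,
                          noise_seed = NULL, center_offset_px = c(4, -3),
                          cross_width_px = 0, electrons_per_position = 1e6)
  f <- stkv$frames[, , 1]
  cy <- sum(row(f) * f) / sum(f); cx <- sum(col(f) * f) / sum(f)
  expect_equal(c(cy, cx), stkv$center, tolerance = 0.1)
})

test_that("identical seeds give bit-identical simulations", {
  fx1 <- fixture_4dstem(grid = c(2, 2), noise_seed = 9)
  fx2 <- fixture_4dstem(grid = c(2, 2), noise_seed = 9)
  expect_identical(fx1$stack$frames, fx2$stack$frames)
  fx3 <- fixture_4dstem(grid = c(2, 2), noise_seed = 10)
  expect_false(identical(fx1$stack$frames, fx3$stack$frames))
})
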