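# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

fixture_beam <- function(alpha_rad = 7.2e-3) beam_parameters(20, alpha_rad)

# a small single-slice lattice phantom plus matching probe/scan/stack
fixture_4dstem <- function(n_obj = 220, px_pm = 100, np = 64,
                           grid = c(8, 8), step_nm = 0.4,
                           defocus_nm = -20, electrons = 1e5,
                           noise_seed = NULL, n_slices = 1,
                           slice_spacing_A = 0, phantom_seed = 5,
                           jitter_seed = 3, alpha_rad = 30e-3,
                           cross_width_px = 2, distortion = NULL,
                           center_offset_px = c(0, 0), gain = 1) {
  beam <- fixture_beam(alpha_rad)
  ph <- make_phantom("lattice_patches", n_pixels = n_obj, pixel_size_pm = px_pm,
                     n_slices = n_slices, slice_spacing_A = slice_spacing_A,
                     phase_max = 0.5, seed = phantom_seed)
  pr <- make_probe(beam, aberration_set(defocus_nm = defocus_nm), px_pm, np)
  g <- scan_grid(step_nm, grid, jitter_fraction = 0.5, seed = jitter_seed)
  geo <- acquisition_geometry(np, 75, 5e-3, gain, 85, step_nm, grid)
  stk <- simulate_4dstem(ph, pr, g, geo, distortion = distortion,
                         noise_seed = noise_seed,
                         center_offset_px = center_offset_px,
                         cross_width_px = cross_width_px,
                         electrons_per_position = electrons)
  list(beam = beam, phantom = ph, probe = pr, grid = g, geometry = geo,
       stack = stk, electrons = electrons)
}

# embed the phantom truth into an engine-sized canvas, centre-aligned
fixture_truth_state <- function(fx, config) {
  st <- init_state(fx$stack, config)
  nobj <- nrow(st$object$slices[[1]])
  nph <- nrow(fx$phantom$slices[[1]])
  st$object$slice_spacing_A <- fx$phantom$slice_spacing_A
  st$object$slices <- lapply(fx$phantom$slices, function(S) {
    if (nobj <= nph) {
      s0 <- (nph - nobj) %/% 2
      S[s0 + seq_len(nobj), s0 + seq_len(nobj)]
    } else {
      O <- matrix(complex(real = 1), nobj, nobj)
      offs <- (nobj - nph) %/% 2
      O[offs + seq_len(nph), offs + seq_len(nph)] <- S
      O
    }
  })
  st$probe$modes <- lapply(fx$probe$modes, function(m) m * sqrt(fx$electrons))
  st
}

basic_config <- function(schedule, alpha_rad = 30e-3, defocus = -20, seed = 11,
                         ...) {
  reconstruction_config(schedule = schedule, alpha_rad = alpha_rad,
                        probe_defocus_guess_nm = defocus, seed = seed, ...)
}

phase_schedule <- function(algorithm, iterations, n_slices = 1,
                           slice_spacing_A = 0, n_probe_modes = 1) {
  list(list(algorithm = algorithm, iterations = iterations,
            n_slices = n_slices, slice_spacing_A = slice_spacing_A,
            n_probe_modes = n_probe_modes))
}
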