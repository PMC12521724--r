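# eptycho

Ptychographic reconstruction and self-calibration tools for low-beam-energy
4D-STEM, in R.

A scanning electron microscope operated in transmission at ~20 keV can, with
ptychography, resolve structure far beyond its conventional imaging limit —
but only if the diffraction-plane calibration is right. A simple
projector-lens column imposes a radial **pincushion distortion**
`s = M·r·(1 + k·r²)` on every recorded pattern, and ptychography inherits
that error directly into its reconstruction. This package implements the
full analysis chain for that regime:

* **Electron-optical bookkeeping** — relativistic wavelength, Abbe/Rayleigh
  limits, dose, detector count budget, illumination overlap, aberration
  phase surfaces and probe-aberration fitting (`electron_wavelength()`,
  `electron_dose()`, `fit_probe_aberrations()`, …).
* **A synthetic 4D-STEM simulator** — aberrated convergent probes,
  multi-slice (transmit/propagate) exit waves, jittered scan grids, Poisson
  detection at a stated gain, a dead central cross, an off-centre
  bright-field disc, and count-conserving injected distortion
  (`make_probe()`, `make_phantom()`, `simulate_4dstem()`).
* **Iterative solvers** — ePIE, batch least-squares maximum-likelihood
  (LSQ-ML) and its multi-slice extension, with mixed probe modes, a probe
  Fourier-aperture constraint, a floating validity mask, an incoherent
  background model, and factor-2/4 super-resolution diffraction padding
  (`run_reconstruction()`, `epie_iteration()`, `ms_lsqml_epoch()`, …).
* **Self-calibrating distortion correction** — fit `(M, k)` by seeded
  simulated annealing of the reconstruction's radial power spectrum against
  a kinematic gold powder reference, undistort the data with
  Jacobian-weighted, count-conserving resampling, and iterate to
  sub-percent ring agreement (`calibration_loop()`, `undistort_stack()`,
  `gold_powder_profile()`).
* **Resolution assessment** — Fourier ring correlation between half-scan
  reconstructions against the half-bit information threshold, and PCTF/SNR
  against simulated ground truth (`split_scan()`, `frc()`,
  `resolution_from_frc()`, `pctf_and_snr()`).

Results that are naturally tabular (radial profiles, FRC curves, fit
reports) come back as tibbles with `tidy()`, `glance()` and `autoplot()`
methods.

## Worked example

Twenty-keV beam optics in four lines:

```r
library(eptycho)

lam <- electron_wavelength(20)
1 / lam                                  # Ewald sphere radius: 11.64346 1/Å
rayleigh_resolution(lam, 7.2e-3)         # 7.276378 Å at α = 7.2 mrad
electron_dose(85, 40.5, 450^2)           # 106105.7 e-/Å² (85 pA, 40.5 s, 45 nm FOV)
detector_count_budget(5.035, 512^2, 5e-3, 0.85)
#> # A tibble: 1 × 2
#>   total_rate detector_current_pA
#>        <dbl>               <dbl>
#> 1  263979008                49.8
```

A miniature end-to-end self-calibration on synthetic data (a gold-ring
phantom with an injected pincushion `k ≈ 0.071 Å²`, about 15% displacement
at the outermost ring):

```r
beam <- beam_parameters(20, 7.2e-3)
ref  <- gold_powder_profile(peak_sigma = 0.02)
ph   <- make_phantom("powder_rings", n_pixels = 460, pixel_size_pm = 25,
                     phase_max = 0.6, reference = ref, n_patches = 78,
                     patch_radius_px = c(16, 36), seed = 21)
pr   <- make_probe(beam, aberration_set(defocus_nm = -100), 25, 128)
g    <- scan_grid(0.5, c(16, 16), seed = 22)
geo  <- acquisition_geometry(128, 75, 5e-3, 0.85, 85, 0.5, c(16, 16))
stk  <- simulate_4dstem(ph, pr, g, geo,
                        distortion = distortion_model(1, 0.15 / 1.45^2),
                        noise_seed = 23, center_offset_px = c(3, -2),
                        electrons_per_position = 1e7)

cfg <- reconstruction_config(
  schedule = list(list(algorithm = "ePIE", iterations = 30, n_slices = 1,
                       slice_spacing_A = 0, n_probe_modes = 1)),
  alpha_rad = 7.2e-3, probe_defocus_guess_nm = -100, seed = 31)
res <- calibration_loop(stk, ref, cfg, tol_peak_pct = 0.5, seed = 31,
                        gain = 0.85)
res$report
#> # A tibble: 2 × 5
#>   cycle     M      k max_disagreement_pct n_matched
#>   <int> <dbl>  <dbl>                <dbl>     <int>
#> 1     1 1     0                     4.71          6
#> 2     2 0.997 0.0718                0.479         4
res$model
#> <distortion_model> s = M r (1 + k r^2) with M = 0.99740, k = 0.071765 A^2
```

One reconstruct-and-fit cycle takes the worst matched ring disagreement
from several percent on the distorted data to half a percent, and the
fitted `k` lands within one percent of the injected 0.0713 Å². The
resolution machinery reads off an FRC curve in the same spirit:

```r
halves <- split_scan(stk, "checkerboard")
# ... reconstruct each half, then:
# cv <- frc(intensity_A, intensity_B, pixel_size_pm)
# resolution_from_frc(cv)    # last crossing of the half-bit threshold
frc_equivalent_snr(half_bit_threshold(1e12))   # 0.4142: the half-bit SNR anchor
```

A thin command-line front end over the same functions lives in
`inst/cli/eptycho` (subcommands `simulate`, `reconstruct`,
`calibrate-distortion`, `frc`, `exitwave`, `probe-analyze`).

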