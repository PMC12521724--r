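---
title: "Low-energy electron ptychography with diffraction-distortion self-calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-energy electron ptychography with diffraction-distortion self-calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eptycho)
```

## The problem

Electron ptychography recovers the complex transmission function of a
specimen, and the complex illuminating probe, from a 4D-STEM dataset: a 2-D
grid of scan positions, each storing a full 2-D far-field diffraction
pattern. At low beam energies (20 keV, the regime of a scanning electron
microscope operated in transmission), three practical obstacles dominate:

1. **Diffraction-plane distortion.** A simple projector-lens column imposes a
   radial pincushion distortion on the recorded patterns. Ptychography is
   exquisitely sensitive to the reciprocal-space calibration, so an
   uncorrected distortion of a few percent at the outer scattering angles
   visibly degrades and displaces the high-frequency information.
2. **Partial coherence and an incoherent background.** Chromatic blur and
   other incoherences are absorbed statistically by mixed probe modes and a
   fitted smooth background added to the modelled intensity.
3. **Detector artefacts.** A quad-sensor camera has a dead cross through the
   array midline, and the bright-field disc is deliberately parked off-centre
   during acquisition; both are handled by a *floating mask*: affected pixels
   are excluded from every modulus constraint and error metric rather than
   being trusted or inpainted.

The package implements the full pipeline — simulator, solvers,
self-calibrating distortion correction, and resolution assessment — with
every stochastic element seeded.

## The forward model

A probe is formed as the inverse Fourier transform of a hard aperture of
radius $\alpha/\lambda$ times $e^{-i\chi(\mathbf{k})}$, with the aberration
function

$$\chi(\mathbf{k}) = \pi \lambda |\mathbf{k}|^2 \Delta f +
\tfrac{\pi}{2} C_s \lambda^3 |\mathbf{k}|^4 +
\pi \lambda |\mathbf{k}|^2 A_2 \cos 2(\theta - \theta_0),$$

where underfocus is negative $\Delta f$ (so a probe defocused to spread over
a few nanometres has, e.g., $\Delta f = -390$ nm). The wavelength is the
relativistically corrected de Broglie value; all constants come from a
single frozen CODATA table.

Thick objects are ordered stacks of complex transmission slices; the exit
wave alternates pointwise transmission with angular-spectrum (Fresnel)
propagation over the slice spacing. The propagator is exactly unitary, which
the tests verify to $10^{-10}$.

The simulator forms, per scan position, the far-field intensity of the
multi-slice exit wave under a (subpixel, Fourier-shifted) probe, scales it to
the electron budget $I t / e$, optionally applies a count-conserving
pincushion distortion, multiplies by the detector gain, Poisson-samples with
a named seed, and applies the dead cross and a recorded off-centre shift.
Detector reciprocal sampling follows the conjugate-grid relation
$\Delta k = 1/(N\,\Delta x)$; there is no separate camera-length model.

### What the phantoms emulate — and what they do not

`make_phantom()` builds seeded mixed phase/amplitude objects: randomly
oriented crystalline patches whose power spectrum peaks on the rings of a
supplied powder reference (`powder_rings`), generic lattice patches,
Gaussian dot pairs at chosen separations, and an amorphous-plus-crystal mix.
They reproduce the *spectral* content that matters for calibration and
resolution studies. They do not model atomic potentials, inelastic or
thermal diffuse scattering, or detector MTF beyond gain plus the dead
region; passing tests therefore demonstrate the correctness of the
algorithms under the stated noise model, not instrument-complete realism.

## The solvers

The reconstruction schedule mirrors standard practice: sequential ePIE
first (cheap, robust), then a batch least-squares maximum-likelihood (LSQ-ML)
refinement, then its multi-slice extension (MS-LSQ-ML):

* **ePIE** sweeps the positions in a seeded random order, replaces the
  Fourier modulus by $\sqrt{\text{counts}}$ at mask-true pixels only, and
  applies the conjugate-weighted object and probe corrections.
* **LSQ-ML** is realized as a batch amplitude-metric gradient step over all
  positions, with the scalar step length chosen by a quadratic (three-point)
  line search of the masked amplitude error on a seeded position subsample,
  with backtracking. The forward model sums probe-mode intensities
  incoherently and adds the fitted fraction of the background template.
* **MS-LSQ-ML** chain-rules the same residual through the
  transmit/propagate stack, updating every slice and the probe; with one
  slice it reduces *exactly* to the single-slice update (shared code path,
  asserted by a test).

Design choices made where the procedure was genuinely open:

* *Step sizes*: unit base steps with the line-search scaling; the published
  recipe does not print its step-size or regularization constants, so these
  defaults are the package's own, chosen for monotone error histories on
  Poisson data.
* *Slice-count handoff* (e.g. 2 slices to 4 mid-run): each slice is split
  into equal phase partitions (complex root), which preserves the projected
  object exactly at the handoff.
* *Probe Fourier aperture*: after each probe update the FT amplitude outside
  a radius (default $1.5\,\alpha/\lambda$) is multiplied by $1 -$ strength
  (default 0.5 — pushed "towards zero" rather than truncated); this
  suppresses crystalline fringes that otherwise leak into weak probe modes.
* *Background*: the template is the mask-aware mean frame convolved with a
  normalized Gaussian (width configurable; the shape of the blur is not
  prescribed anywhere, so Gaussian is the package's choice); only its
  fraction in $[0,1]$ is fitted, by a grid line search each few epochs.
* *Initial object*: constant, or constant plus a seeded random imaginary
  component with $\max(\mathrm{Im})/\mathrm{Re} = 10^{-6}$.
* *Degenerate inputs*: an empty validity mask, a zero-norm probe, a
  non-positive slice spacing with multiple slices, and padding factors
  outside $\{1,2,4\}$ are rejected with errors rather than coerced.

Super-resolution padding zero-pads every frame symmetrically by a factor of
2 or 4 with the padded pixels mask-false, halving (or quartering) the
reconstructed pixel size — 33.14 pm becomes 16.57 pm at factor 2.

## Pincushion self-calibration

The distortion model is the cubic radial map $s = M r (1 + k r^2)$ between
undistorted ($r$) and distorted ($s$) reciprocal radii. The calibration loop
iterates:

1. reconstruct with the current data and radially average the power
   spectrum of the plane-wave exit wave;
2. measure ring positions (running-median baseline, 3-bin smooth, 3-point
   parabola) and compare them, through one-to-one greedy matching within a
   ±10% gate, against the positions obtained by applying the *same*
   measurement operator to the reference profile resampled onto the same
   radial grid — so that unresolved ring blends displace the target and the
   measurement identically;
3. if the worst matched ring still disagrees beyond the tolerance, fit
   $(M, k)$ and fold the fit into one cumulative model (numerically
   composed, refit to the cubic form); the *original* stack is then
   resampled once through the cumulative model, so the data never
   accumulate interpolation damage across cycles;
4. stop at the tolerance, at the cycle cap, or as soon as the measured
   disagreement stops improving (the best-measured cycle is returned).

The fit itself is two-stage (`fit_method = "auto"`). The global profile
fit — seeded simulated annealing with geometric cooling in a physical box
($M \in [0.8, 1.2]$, pincushion-signed $k \in [-0.03, 0.1]$), a box-clamped
deterministic compass polish for bit-stable reruns, envelope normalization
so ring *positions* rather than ring *intensities* drive the objective, and
the search band limited to radii where rings were actually detected — is
robust to the ring-identity ambiguity of a 10–15% displacement, but suffers
the classic $M$–$k$ tradeoff. Its role is therefore to solve *assignment*:
each unblended single ring's predicted position is matched to a detected
peak within 2.5%, and the exactly linear $(r^2, s/r)$ fit on those pairs —
intercept $M$, slope $Mk$, machine-precision on clean peaks and the oracle
for the annealer in the tests — delivers the coefficients whenever at
least four rings match.

Undistortion must conserve counts: detector pixels integrate intensity over
their area, so the resampler is an area-weighted bilinear gather (3×3
subpixel samples per target pixel) multiplied by the Jacobian
$(1 + kr^2)(1 + 3kr^2)$ of the radial map. Delta-function resampling fails
the conservation audit, which is why the tests pin global and patchwise
conservation to 0.1% for $k \le 0.08$. $M$ is never resampled — it is
absorbed by rescaling the reciprocal pixel, with $M = 1$ in the pixel map.
The mask is resampled conservatively (a target pixel survives only if all
contributing source pixels are valid). Azimuthal (spiral) distortion is out
of scope by design; a collinearity diagnostic of disc centres is the only
azimuthal statement the package makes.

The bundled reference is the kinematic gold powder profile: FCC rings
($a = 4.0782$ Å, all-even/all-odd selection rule) out to the ring at
1.45 Å⁻¹ ($d = 0.689$ Å), with relative intensities from multiplicity times
the squared Doyle–Turner electron scattering factor.

## Resolution assessment

`split_scan()` partitions a scan into disjoint halves (odd/even rows or
checkerboard); `frc()` computes the ring-wise normalized cross-correlation
of the two reconstructions' transforms after rigid subpixel registration,
with one-reciprocal-pixel rings and no bandpass prefilter. The half-bit
information threshold

$$T(n) = \frac{0.2071 + 1.9102/\sqrt{n}}{1.2071 + 0.9102/\sqrt{n}}$$

is evaluated with the actual per-ring pixel counts; its asymptote 0.1716
corresponds to a full-dataset SNR of $\sqrt{2} - 1 \approx 0.41$ through the
half-dataset relation $T = (s/2)/(s/2+1)$ (the factor 2 arises because each
half image carries half the information of the full set). Resolution is read
at the *last* downward crossing of the threshold, with linear interpolation
between rings: a crossing at 1.484 Å⁻¹ is a 0.67 Å resolution measure. The
FRC input is the intensity of the propagated exit wave by default, with the
phase image available as an option.

Against simulated ground truth, `pctf_and_snr()` reports the ring-wise phase
contrast transfer $\mathrm{Re}\langle R T^* \rangle / \langle |T|^2 \rangle$
and the signal-to-residual power ratio.

## Numerical conventions

* Frames are (row, col) matrices, row 1 at the top; the reciprocal-space
  origin sits at index $\lfloor n/2 \rfloor + 1$ after centring; scan
  positions are nm offsets from the scan-grid centre.
* Counts are stored as integers after detector simulation and promoted to
  double inside the engines; engine amplitudes are $\sqrt{\text{counts}/g}$.
* Every stochastic element (jitter, Poisson sampling, position order,
  annealing, mode seeding) takes an explicit integer seed, and equal seeds
  give bit-identical outputs.
* The datacube container is a plain-text directory (JSON metadata with units
  on every group, CSV mask/positions/frames) with an append-only provenance
  list; round trips are lossless and schema violations raise errors naming
  the field.

## Problem sizes used in the test-suite studies

The synthetic studies are sized so the entire pipeline runs on a laptop-class
single core. The engine and metrics property studies (fixed points,
convergence, PCTF, half-scan FRC) use an 8×8 scan on a 64×64 detector with a
30 mrad, 100 pm-pixel probe: a miniature at a 7.2 mrad convergence angle is
twin-degenerate — the sequential solver stalls on the conjugate-object
solution at every seed, because with so small a bright-field disc the tiny
dataset cannot break the sign ambiguity — whereas the 30 mrad miniature
exercises the identical code paths and converges to phase correlations
above 0.99. The same reasoning selects 30 mrad for the two-slice
depth-recovery study, where additionally the 7.2 mrad depth of field
$\lambda/\alpha^2$ dwarfs a 20 Å slice spacing. The distortion
self-calibration study keeps the 7.2 mrad optics (its signal is ring
*positions*, which that regime transfers fine): a 16×16 scan on a 128×128
detector, a gold-ring phantom at 25 pm object pixels, an injected
$k = 0.15/1.45^2 \approx 0.071$ Å² (about 15% displacement at the outermost
ring), 10⁷ electrons per position and gain 0.85. These are the package's
reference conditions for its own regression studies.

## Known limitations

* The LSQ-ML step is a batch gradient with a subsampled line search, not the
  per-position closed-form step of the original formulation; it is slower
  per iteration than ePIE and relies on a warm start.
* Depth sectioning at small convergence angles is inherently weak; the
  multi-slice solver then distributes phase across slices nearly
  arbitrarily even though the projected phase is well constrained.
* The annealing profile fit assumes the reference and observed ring
  *shapes* are broadly comparable after baseline removal; grossly different
  peak widths slow convergence (the peak-fit route is then preferable).
* The precision of the recovered pincushion coefficient is bounded by the
  ring-position measurement noise of the interim reconstructions
  (0.2–0.5% per ring, object-speckle limited): at the reference study size
  the loop recovers $M$ to about 0.3% and $k$ to about 1–2%, even though
  the corrected ring positions agree with the reference to 0.25%.
* Miniature datasets at very small convergence angles are twin-degenerate
  (see the problem-sizes section); this is a property of the data, not of
  the solvers, but it bounds what desk-scale tests can demonstrate at those
  optics.
* No position refinement, no Poisson-likelihood objective, no GPU path.
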