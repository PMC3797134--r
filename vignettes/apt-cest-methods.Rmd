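---
title: "Quantifying amide proton transfer contrast: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying amide proton transfer contrast: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(aptcest)
```

## The measurement

Chemical exchange saturation transfer (CEST) MRI detects dilute labile
protons indirectly. A long off-resonance radio-frequency pulse saturates a
solute pool — here the backbone amide protons of mobile proteins and
peptides, resonating about +3.5 ppm downfield of water — and chemical
exchange carries that saturation into the bulk-water pool, depressing the
water signal. Sweeping the saturation offset and recording the normalized
water signal $Z(\Delta\omega) = S_\mathrm{sat}/S_0$ yields the
*z-spectrum*. Amide proton transfer (APT) contrast is read out as the
magnetization-transfer-ratio asymmetry

$$\mathrm{MTR}_\mathrm{asym}(\Delta\omega)
  = \mathrm{MTR}(+\Delta\omega) - \mathrm{MTR}(-\Delta\omega)
  = Z(-\Delta\omega) - Z(+\Delta\omega),
\qquad \mathrm{MTR} = 1 - S_\mathrm{sat}/S_0,$$

evaluated at 3.5 ppm. Tumors carry more mobile protein than normal tissue,
so the APT-weighted map delineates them as bright regions.

The modeled protocol is a small-animal acquisition at 7 T: a
continuous-wave block saturation pulse of $B_1 = 1.7\ \mu\mathrm{T}$ and 4 s
duration, 25 offsets from +6 to $-6$ ppm in 0.5 ppm steps, one unsaturated
control image ($S_0$), 30 mm field of view. `pipeline_config()` carries
exactly these defaults.

## The exchange model

`simulate_zspectrum()` integrates the Bloch-McConnell equations: coupled
Bloch equations for the $x/y/z$ magnetization of every proton pool, with
first-order exchange between each solute pool and water. Exchange satisfies
detailed balance — a solute pool of proton fraction $f$ and solute-to-water
rate $k$ receives magnetization from water at rate $f k$ — so the exchange
operator conserves total magnetization (its columns sum to zero;
`build_bm_generator()` exposes the full system for inspection).

Under continuous-wave irradiation the system is linear and
time-invariant, $\dot M = A M + b$, so the package's default propagator is
the exact solution by eigendecomposition of $A$ (`method = "matexp"`). Two
independent routes guard it: a stiff implicit Runge-Kutta integration
(Radau IIA, relative tolerance $10^{-8}$, `method = "ode"`), and the
analytic steady state from the direct linear solve $M_{ss} = -A^{-1}b$
(`bm_steady_state()`). The tests require the ODE route to match the exact
propagator to $10^{-6}$ and to converge to the steady state within
$10^{-3}$ after 30 s of saturation.

### Pool parameters

The acquisition parameters are protocol facts; the tissue parameters are
not reported for this system and are chosen once, as plausible high-field
tissue values calibrated to land the simulated contrast in the
few-percent range observed in vivo:

| pool  | $T_1$ (s) | $T_2$ (s) | shift (ppm) | fraction | $k$ (s$^{-1}$) |
|-------|-----------|-----------|-------------|----------|-----------------|
| water | 1.8 | 0.05 | 0 | 1 | — |
| amide | 1.0 | 0.01 | +3.5 | $10^{-3}$ (normal) – $7.5\times10^{-3}$ (tumor) | 30 |
| MT    | 1.0 | $4\times10^{-5}$ | $-2.4$ | 0.08 | 25 |

The broad semisolid magnetization-transfer (MT) pool is centered slightly
upfield of water, which gives normal tissue the *negative* intrinsic
asymmetry seen in reference tissue (simulated spinal cord:
$-1.5\%$ at 3.5 ppm, within the $-4$ to $-1\%$ range reported for cord and
brain). It is deliberately absent from `default_pools()` so that two-pool
analytic checks (symmetry, zero-amide limits) stay exact; phantom tissues
from `default_tissues()` include it. With these defaults a tumor amide
fraction of $3\times10^{-3}$ yields a cord-corrected asymmetry of about
$+2.7\%$ and $7.5\times10^{-3}$ about $+7.8\%$, bracketing the magnitudes
the method is meant to resolve. These are magnitude calibrations, not
claims about tumor biology; `amide_fraction_for_asym()` inverts the
simulator so a study design can dial in any target contrast.

A physical caveat encoded in the tests: $Z \in [0, 1]$ holds only after
transverse coherence has damped out. A short, weak pulse (say 0.5 s at
0.5 µT) leaves on-resonance nutation still ringing and $Z(0)$ dips a few
$10^{-3}$ below zero — real physics, not a numerical artifact. The
property suite therefore asserts the bound for durations of 2 s and more;
the protocol's 4 s pulse is deep inside that regime.

## The synthetic phantom and what it does (not) emulate

`generate_phantom_stack()` builds a mouse-thorax-like axial slice: an
elliptical muscle body on an air background, two air-filled lung fields
(near-zero signal, as lung parenchyma gives almost none), one tumor nodule
in each lung, and a spinal-cord disc dorsally. Each tissue's z-spectrum is
simulated once on a dense offset grid (0.05 ppm; the nominal offsets are
always evaluated exactly, so noise-free phantoms reproduce the simulated
spectra bit-for-bit) and each pixel reads it at
$\Delta\omega - b_0(\mathrm{pixel})$, where $b_0$ is a smooth surface with
±0.3 ppm default amplitude. Sign convention, used consistently across the
package: a *positive* local field offset shifts the apparent water center
*downfield* (to $+b_0$), and `estimate_b0()` returns that apparent shift.

Noise is additive zero-mean Gaussian on the magnitude images (default
$\sigma$ = 1% of muscle $S_0$), seeded and bit-reproducible. Rician
statistics at very low SNR, readout/echo-train effects, respiratory motion
and multi-slice geometry are not modeled: the simulator validates the
*analysis*, not the acquisition. Passing tests therefore demonstrate
correctness of the pipeline's arithmetic, fitting, correction, and
statistics on data whose ground truth is known — they do not certify
accuracy on in-vivo data, where the noise floor, B0 structure, and
background MT spectrum are less benign.

`generate_cohort()` draws per-animal tumor amide fractions around group
means (default fractional variability 0.2, a round value giving per-group
asymmetry SDs comparable to the 1.9-3.9 percentage-point spreads printed
for real cohorts) and gives each animal its own noise seed.

## B0 correction

Air-tissue interfaces shift the local water resonance by a few tenths of a
ppm, which moves the whole z-spectrum sideways and corrupts the asymmetry
at every offset. The correction in `fit_zspectrum()` /
`center_zspectrum()` follows the classical recipe — Gaussian fitting, then
12th-order polynomial fitting per offset side, then interpolation and
re-centering — with the stage roles declared explicitly, since the recipe
itself is ambiguous about them:

1. **Gaussian stage.** A Gaussian well
   $Z = b - a\,e^{-(x-c)^2/2\sigma^2}$ is fitted over the central window
   (default $|x| \le 2$ ppm, Levenberg-Marquardt). The direct-water
   -saturation well is deep and locally symmetric, so the center $c$
   localizes the water resonance to a few thousandths of a ppm — far below
   the 0.5 ppm sampling. `estimate_b0()` returns $c$; an estimate is
   flagged unreliable (and the pixel masked) when the fit fails, finds no
   real well, or pins $c$ to the window edge.
2. **Split-side polynomial stage.** Order-12 polynomials are fitted to the
   positive-offset and negative-offset points separately (13 points per
   side, so they interpolate; the 0 ppm point stabilizes both sides).
   Offsets are rescaled to $[-1, 1]$ per side first — order 12 on raw ppm
   values is numerically hostile — and a rank-deficient side falls back to
   a lower order with a recorded warning. This interpolant is the
   evaluable fitted curve (`predict()` on a 0.01 ppm fine grid).
3. **Re-centering.** The corrected spectrum is the fitted curve evaluated
   at (nominal offset $+ b_0$); offsets pushed beyond the measured range
   are evaluated by polynomial extrapolation and flagged, and the pipeline
   excludes the extreme $|{\pm}6|$ ppm offset from ROI statistics whenever
   correction is on. Estimates with $|b_0| > 1$ ppm are refused.

The deliberate deviation from a pure argmin-of-the-curve estimator is a
measured necessity: the interpolating polynomial oscillates between the
0.5 ppm samples, and its minimum errs by more than 0.1 ppm even on an
unshifted noise-free spectrum, whereas the Gaussian center is stable to
about 0.005 ppm across injected shifts of ±0.5 ppm. On the default
noise-free phantom the pixel-wise B0 map recovers the ground-truth field
with RMS error below 0.01 ppm, and correction is idempotent (a second pass
estimates ≤ 0.02 ppm and moves the 3.5 ppm asymmetry by < 0.05 points).

### The resampling accuracy floor

Re-centering must evaluate the spectrum *between* samples, and there is a
hard limit to how well that can be done: under this protocol the
power-broadened amide dip is roughly 1 ppm FWHM, i.e. about two samples
across. For shifts that are not multiples of the sampling interval, the
mid-node truth error of *any* shape-agnostic interpolant (the split-side
polynomials, cubic splines, and band-limited sinc reconstruction were all
measured) is 0.1-0.9 percentage points of Z at the dip, scaling with dip
depth: ~0.35 points for the two-pool default tissue, ~0.5 for a strong
tumor, ~0.12 for reference tissue. The package documents this as its
round-trip accuracy floor and the unit tests assert it at those levels.
The floor largely cancels in *group differences* (all animals share the
schedule and similar dip shapes), which is why cohort recovery below is an
order of magnitude tighter than the single-spectrum floor.

## ROI statistics and group comparison

ROIs are circles (center in 0-based row/col pixel coordinates, area in
mm²; a pixel belongs to the ROI iff its center falls within the radius,
and a sub-pixel ROI reads its nearest pixel). Per animal,
`animal_summary()` averages tumor ROIs unweighted — one value per animal
however many nodules were measured — and subtracts the spinal-cord
reference offset-wise: $\mathrm{corrected} = \mathrm{tumor} -
\mathrm{cord}$. The subtraction removes the shared background MT/NOE
asymmetry; it is exact arithmetic, asserted to machine precision.

`group_compare()` applies the two-sample, two-tailed, pooled-variance
Student's t-test at each offset, with significance at 0.05 and no
multiple-testing adjustment across the twelve positive offsets — matching
the per-frequency testing convention of the studies this emulates — while
`build_group_table(holm = TRUE)` offers a Holm adjustment for users who
want it. The pooled (rather than Welch) variance is deliberate: on the
printed example summaries (6.0 ± 1.8 vs 2.9 ± 1.5, n = 6 per group) the
pooled two-tailed test reproduces the published $P = 0.01$ after rounding.
`summary_from_stats()` computes the identical test from means, SDs and
sizes alone so printed tables can be checked without raw data; a
zero-pooled-variance comparison returns $p = 1$ at equal means and is
flagged degenerate otherwise.

## Numerical and design choices

- **Offsets** are stored high-to-low (+6 → −6 ppm) in acquisition order
  and normalized to ascending order on assembly; asymmetry spectra list
  positive offsets ascending.
- **Masking**: a pixel is valid iff $S_0 > 5\times$ the background noise
  level, estimated from a corner patch of the $S_0$ image spanning 1/8 of
  the image side (the corner is always air in this geometry). Masked
  pixels propagate as absent, never as imputed values; raising the
  threshold can only shrink the mask.
- **Determinism**: every stochastic step (phantom noise, cohort draws) is
  seeded; regenerating with the same seed is bit-identical, and pipeline
  reruns produce byte-identical CSVs.
- **File formats**: NIfTI volumes are written as float32 with the S0 image
  as the last plane and a CSV schedule sidecar. Multi-page TIFF goes
  through an affine scaling to $[0,1]$ (baseline 32-bit TIFF samples are
  integer-scaled) recorded in a YAML sidecar; quantization is ~4e-9,
  below float32 resolution, and both encodings yield identical pipeline
  results to ~1e-6.
- **Problem sizes in the test-suite and acceptance runs** (the package's
  own choice of desk-scale conditions): phantoms of 24-48 pixels per side,
  cohorts of 6 animals per group, 100 seeded cohort replicates for the
  detection-rate estimate, 2000 replicates for the type-I-error estimate.
- **Respiratory gating** in the emulated protocol fixes the saturation
  timing exactly, so the simulator treats the 4 s pulse as uninterrupted
  continuous-wave irradiation and ignores gating arithmetic entirely.

## Worked example

```{r, eval = FALSE}
library(aptcest)

# simulate one animal
ph <- generate_phantom_stack(phantom_spec(image_size = 64, seed = 1))
res <- analyze_stack(ph$stack, phantom_rois(ph, area_mm2 = 2),
                     config = pipeline_config(granularity = "pixel"))
plot(res$apt_map)          # APT-weighted image
plot(res$b0)               # recovered field map
print(res$animal)          # tumor / cord / corrected asymmetries

# simulate and analyze a two-group cohort
animals <- generate_cohort(cohort_spec(seed = 1),
                           phantom_spec(image_size = 48))
summaries <- lapply(animals, function(a)
  analyze_stack(a$phantom$stack, phantom_rois(a$phantom, area_mm2 = 4),
                animal = a$id, group = a$group)$animal)
build_group_table(summaries)
```

## Known limitations

- The resampling floor above bounds single-spectrum asymmetry recovery
  after B0 correction at ~0.1-0.5 percentage points depending on dip
  depth; denser offset sampling around ±2-5 ppm would lift it.
- NOE and asymmetric-MT contributions are not separated from the amide
  signal; like the studies it models, the package reports raw and
  reference-corrected asymmetry only.
- Gaussian noise is assumed throughout; air regions (Rician-dominated)
  are masked rather than modeled.
- The simulator's exchange rates and fractions are calibrated to contrast
  magnitude, not measured tissue biochemistry.
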