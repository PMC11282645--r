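---
title: "Methods: simulating and quantifying intrathecal tracer dispersion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying intrathecal tracer dispersion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the science and the numerical choices behind
`csfdispersion`: what the pipeline computes, what the synthetic-data
generator does and does not emulate, and where genuinely open design
decisions were made.

## The problem

After a lumbar intrathecal injection, the injected solute is dispersed along
the spinal subarachnoid space by the oscillatory motion of the CSF, which
pulses with the cardiac and respiratory cycles but carries almost no net
flow. Whether a clinically useful fraction of the dose reaches the cranial
CSF within hours depends on injection parameters — site, bolus volume and
rate, flush volume and rate. The package reproduces an in vitro analysis of
this question: a rigid, subject-specific cynomolgus CSF phantom is imaged
for three hours after injection of a fluorescent tracer, and delivery to the
brain is summarized as the percent of injected dose (%ID) in the extra-axial
CSF (eaCSF) and as per-slice area-under-curve (AUC) exposure.

## Coordinates and geometry

All axial quantities live on a 1 mm slice grid with `z = 0` at the foramen
magnum and `z` positive cranially; the eaCSF is the half-open interval
`[0, 60)` mm, and spinal locations are negative. The geometry is carried
entirely by the slice-volume profile `V(z)`, which weights every mass
metric.

The synthetic phantom (`build_synthetic_geometry()`) is a smooth stand-in
for the segmented model: a unit-area canal with a mild lumbosacral
enlargement, a caudal taper to 5% of the canal area (the thecal sac narrows
toward the filum terminale), and a half-sine cranial bulge holding 42% of
the total volume, all rescaled so the total is exactly 16.86 ml. The spinal
length below the foramen magnum is not a measured quantity and defaults to
280 mm; the two lumbar injection ports default to `z = -272` mm (L4/L5,
8 mm above the caudal end) and `z = -264` mm (L3/L4, one 8 mm vertebral
spacing higher). All three are configurable. The caudal terminus area
matters more than it may appear: under the rigid-domain closure below it
sets the fraction of injected volume that exits caudally, and with an
anatomically narrow terminus nearly all flush-driven drift is directed
cranially, which is what makes a post-injection flush beneficial.

`slice_volumes_from_mask()` provides the measured route: it bins a binary
segmentation stack into 1 mm slabs by voxel counting, truncating partial
slabs at the ends, and `compare_profiles()` verifies two segmentations of
the same geometry by ordinary least squares of one profile on the other
(slope, intercept, R²) — the printed-model-vs-MRI check reported for the
physical phantom. The regression direction (second argument on first) was
chosen so a slope slightly above one reads as "printed model slightly larger
than MRI".

## The flow waveform

`combined_waveform()` builds the oscillatory boundary condition. The cardiac
component is a zero-mean periodic shape at 120 bpm; because the measured
C2–C3 waveform exists only as a figure, the default template is a parametric
stand-in — a fundamental plus a 0.3-weight second harmonic, giving a skewed
systolic peak — and a sampled one-period series can be supplied instead. The
respiratory component is sinusoidal with peak amplitude 0.52 of the cardiac
peak and frequency 1/4.29 of the cardiac frequency (≈ 28 breaths/min).

Normalization order: the respiratory amplitude is scaled from the cardiac
amplitude, the components are summed, the sum is rescaled so its stroke
volume equals 0.2597 ml, and any residual sample mean is removed. Stroke
volume is defined as the integral of the positive part of the flow per
cardiac cycle, averaged over the whole cardiac cycles in the record — the
standard phase-contrast-MRI convention; the printed value is attached to the
combined waveform, and the default targets that reading. Since the
respiratory period is incommensurate with the sample grid, the combined
record is treated as non-periodic and all cycle metrics average over whole
cardiac cycles only. Every synthesized waveform satisfies
`|mean(Q)| < 1e-6` ml/s.

## The transport simulator

`simulate_transport()` is the stand-in for the physical dispersion
experiment: cross-section-averaged 1D advection–dispersion on the slice
grid, with area `A(z) = V(z)/Δz`.

**Dispersion closure.** Resolving each 0.5 s oscillation over three hours is
unnecessary for tracer maps that evolve over minutes, so oscillatory mixing
is closed cycle-averaged:
`D_eff(z) = D_mol + k · ⟨|u(z)|⟩ · h(z)`, with `⟨|u|⟩ = mean(|Q|)/A(z)` and
`h(z) = sqrt(A(z))` a local hydraulic length. The molecular diffusivity
defaults to 5·10⁻⁴ mm²/s (small-molecule dye in water). The dimensionless
factor `k` is the one tuned constant: it was fixed once at 0.012 so that the
flushed L4/L5 protocol first delivers 1 µM to the foramen magnum between 15
and 45 minutes — the qualitative arrival timing of the bench experiment —
and is documented as a tuning, not a measurement. No in vitro transport
coefficients are available, so the simulator's absolute %ID values are not
comparable to the bench values; only orderings and signs are meaningful.

**Sources, sinks and the rigid-domain closure.** The bolus adds fluid and
tracer at the injection cell over `bolus volume / bolus rate` minutes; the
flush adds fluid only; production adds tracer-free fluid at the ventricular
port (`z = 40` mm) and absorption removes fluid carrying the local
concentration at the intracranial port (`z = 30` mm), both at 0.018 ml/min.
The domain is rigid, so net added volume leaves through the two domain ends
in proportion to the end areas, advecting the local concentration out. With
the default anatomical taper the caudal end takes only ~5% of that outflow.

**Numerics.** Finite volume; the dispersion term is solved implicitly
(unconditionally stable, tridiagonal sparse LU, factorizations cached per
step size), the slow drift explicitly with first-order upwinding under a CFL
guard that errors with the stability bound if the user-chosen step is too
large. The step defaults to 0.5 s while injection flow is active and up to
5 s otherwise (only the 3·10⁻⁴ ml/s production drift is then explicit). The
scheme conserves tracer mass exactly up to solver precision; the returned
mass budget (domain + absorbed + end outflow vs injected) closes to
well below the 0.5% documentation threshold at every frame, and with
dispersion switched to a constant the impulse response matches the Gaussian
heat kernel within 2% L2 error.

## Synthetic imaging and quantification

Two linear cameras with Gaussian read noise and hard saturation image the
field every 30 s for 3 h. The low-exposure camera is unsaturated to ~52 µM;
the high-exposure camera saturates near 20 µM and resolves the dilute range
finely. Synthetic frames are 32 transverse pixels wide (not the physical
2168 × 4096 — quantification averages rows, so transverse resolution only
sets the noise floor of the row mean). Calibration stacks render one
uniform-concentration frame per known level; `fit_calibration()` builds a
monotone piecewise-linear intensity→concentration map through the level
means, excluding saturated levels and clamping extrapolation. The map's
functional form is a package choice — only its existence per camera is given.

Per frame, `axial_concentration()` averages intensity transversely *before*
mapping (with near-linear maps the difference from per-pixel mapping is
second order, and averaging-first matches the stated order of operations).
The two exposures merge by the strict rule: points whose low-exposure
estimate is `< 10 µM` take the high-exposure estimate; ties keep the
low-exposure value. From the merged map, AUC is the per-slice trapezoidal
time-integral (µM·hr) over `(0,1)` and `(0,3)` h windows, the region AUC is
an unweighted slice mean (a volume-weighted option exists but is off, since
the reported "average AUC" states no weights), and %ID to eaCSF evaluates
the volume-weighted sum at the single frame nearest 3 h, not a time
average.

With noise-free cameras the full render–calibrate–merge–integrate chain
recovers the ground-truth %ID to within 0.02 %ID (tested against a 1 %ID
tolerance for every default protocol).

## Repeatability and group statistics

Repetition-to-repetition variability in the synthetic study comes from
camera noise and a ±5 s uniform jitter on the injection start, mimicking
the observation that bench repetitions differ mainly near the injection
site. Across repetitions the package computes pointwise mean and sample SD
maps, a 95% CI map as 1.96 × SD — the limits-of-agreement convention, which
the published SD/CI pairs satisfy to printed rounding, unlike SEM-based
intervals — and `%DR = max CI / C_max × 100` with `C_max` the maximum of
the repetition-mean map (the published definition does not pin down
`C_max`'s scope; the repetition-mean maximum makes %DR scale-invariant).
Bland–Altman analysis uses differences of each repetition from the
repetition mean with ±1.96 SD limits.

Group contrasts are Student's pooled-variance unpaired t-tests (the source
analysis says only "unpaired t-test"; Welch is available via
`var_equal = FALSE`) at α = 0.05 on `mean(B) − mean(A)` for the five pairs:
location (2NHP2→3G1), bolus volume (1NHP1→3G2), bolus rate (1NHP3→1NHP2),
flush volume (1NHP2→2G2) and flush rate (5NHP1→2G2). Zero-variance
degenerate inputs return finite sentinels (p = 1 for equal means) rather
than erroring, so fully deterministic synthetic studies still tabulate.
Published p-values are not reproduction targets: they cannot all be
recovered from the published summary statistics, so the test inputs are
uncertain at the source.

## What the generator does and does not emulate

Emulated: the rigid 16.86 ml domain with a cranial compartment, zero-net
oscillatory flow with the stated cardiac/respiratory structure,
production/absorption at 0.018 ml/min, the eight bolus+flush protocols at
constant 165.5 µM·ml dose, dual-exposure imaging at 30 s for 3 h, and
repetition noise concentrated near the injection event.

Not emulated: three-dimensional flow features (steady streaming around
nerve roots, cross-sectional secondary flows), posture and compliance
effects, tissue uptake, optical artifacts (vignetting, flat-field error,
depth-dependent absorption), and any real camera nonlinearity. Passing
tests therefore demonstrate that the *quantification chain* is correct and
that the transport model reproduces the qualitative parameter orderings —
not that a 1D closure predicts bench-top %ID magnitudes. In the synthetic
study the contrast magnitudes are indeed compressed relative to the
physical experiment (tenths of a %ID rather than several), because the
cycle-averaged closure mixes the domain more thoroughly by 3 h.

## Problem sizes and determinism

The default study is 8 protocols × 3 repetitions on a 340-slice grid with
361 frames — about one minute end to end — and the test suite runs
scaled-down variants (30-minute imaging windows, 8–16-pixel-wide frames,
shorter domains) chosen to exercise every code path at comfortable desk
scale. Per-repetition seeds derive collision-free from
`(base seed, protocol index, repetition)`; identical seeds give
bit-identical image stacks and study results.

## Known limitations

- The effective-dispersion constant is a single global tuning; real
  oscillatory dispersion varies with local Womersley number and geometry in
  ways a 1D closure cannot capture. An advection-resolving mode would
  cross-check it at considerable runtime cost.
- The caudal-end outflow split is a modelling convenience for a rigid,
  actuator-terminated domain; the physical boundary is a moving piston.
- %ID can exceed bench-top magnitudes because the simulated eaCSF
  equilibrates faster than the physical model; comparisons should stay
  within a single parameter set.
- The calibration/merge chain assumes pre-corrected frames; no flat-field,
  registration or background machinery is included beyond the camera
  offset.
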