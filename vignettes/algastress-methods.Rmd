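---
title: "Models and methods behind algastress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind algastress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`algastress` quantifies how *Chlamydomonas reinhardtii* microalgae respond
to silver (Ag⁺) ion stress along three axes: population growth kinetics
(OD750 curves fitted with the Gompertz model), chlorophyll content
(two-wavelength spectrophotometry), and single-cell swimming motility
(detection, tracking, and per-step speed / turning-angle statistics from
phase-contrast video). Because raw laboratory videos and growth tables are
not distributed with the package, every analysis stage is validated against
a synthetic-data generator that produces ground-truth swimmers, rendered
image stacks, replicated growth curves and absorbance triplets with the
statistical structure the analyses assume. This vignette documents the
models, the tunable parameters, the numerical choices, and what passing the
synthetic benchmarks does and does not demonstrate about real data.

```{r setup}
library(algastress)
```

## The swimmer model

`simulate_swimmers()` implements a two-state active-particle model:

* Each cell draws a cruising speed once from a Gamma distribution
  parameterized by its **mode** `v_mode` (default 45 µm/s, the location of
  the untreated population's single-peaked instantaneous-speed
  distribution) and **shape** `v_shape` (default 60, i.e. a
  population SD of about 6 µm/s). The Gamma family was chosen for its
  positive support and single peak. The default width is on the narrow
  side of what a raw speed histogram from video shows, deliberately: the
  printed distributions also contain within-track measurement noise that
  the constant-per-cell cruising speed does not model, and a narrow
  population keeps the modal histogram bin a stable statistic at the
  40-cell field density used throughout.
* While swimming, the heading performs a wrapped-Gaussian random walk with
  step SD `sigma_rot` (default 0.2 rad/frame) and the cell advances by
  `speed * dt` along it each frame (`dt` = 0.0396 s, the frame interval of
  the imaging protocol; pixel size 0.4 µm, field 512 px).
* Under silver stress a swimming cell enters a **stalled** state with
  per-frame probability `1 - exp(-r dt)` where
  `r = stall_rate_0 + stall_gain * ag_conc * min(exposure_min / ramp_min, 1)`.
  The linear-saturating exposure ramp (saturation at `ramp_min` = 45 min)
  reproduces the progressive dominance of the zero-speed peak between 15
  and 60 min of exposure. Stalling is absorbing within a video: silver
  interference with the flagellar apparatus is not expected to reverse on
  the 40 s timescale of one recording, and the model needs no recovery
  parameter to reproduce the observed distributions.
* A stalled cell shows no directed displacement; its position is its stall
  anchor plus fresh Gaussian jitter of SD `jitter_sd` (default 0.1 µm) each
  frame. Differenced white jitter has lag-one correlation −1/2, which makes
  consecutive steps anti-align: the turning-angle density of a stalled cell
  rises monotonically toward π. The 0-and-π bimodality seen in strongly
  treated populations is therefore a *mixture* signature — residual
  swimmers contribute the 0 peak, stalled cells the π peak — and the
  package's distribution checks are run on such mixed fixtures rather than
  on an artificial 100 %-stalled population.
* Boundaries are reflective in both position and heading (specular
  reflection). Reflecting the position alone would leave cells pushing
  into the wall for many frames and produce spurious edge crowding.

The stall kinetics are a stand-in: no quantitative stall-rate measurements
exist to calibrate against, so `stall_gain` (default 0.06 /s/µM) was set
once so that the strongest condition studied (2.35 µM, 60 min) stalls the
large majority of cells within a 1000-frame video, and only the qualitative
trends — monotone speed decrease and turning-angle increase with dose and
exposure — are treated as contracts.

## Rendering and detection

`render_video()` draws each cell as an isotropic Gaussian spot
(`cell_sigma`, default 1 µm — the bright compact core a 40× phase-contrast
objective produces, not the full ~10 µm cell body) on a constant
background, adds white Gaussian noise scaled to a target `snr` (peak
amplitude / noise SD; the benchmark suite uses 10), and quantizes to 8 or
16 bits. It does not model halo rings, defocus, or illumination gradients.

`detect_cells()` is a classical multi-scale Laplacian-of-Gaussian blob
detector: frames are normalized to zero mean and unit variance (making the
response threshold transferable across bit depths and lamp settings),
filtered with scale-normalized LoG kernels on a small geometric scale grid
(defaults 0.8–1.2 µm), and local maxima above `threshold` (default 1.5, set
on rendered fixtures so that pure-noise frames stay clean by a wide margin)
are kept per scale, pooled, and pruned by non-maximum suppression at
`min_separation` (default 1.2 µm). Sub-pixel positions come from an
intensity-weighted centroid.

Touching cells are the dominant error mode at realistic densities: two
1 µm spots merge into a single maximum once their centers are closer than
roughly twice the blurred spot width. The detector therefore applies a
least-squares **declumping** test to every detection: a single-Gaussian
model (augmented with first-order shift and width derivative columns, so
sub-pixel centering error cannot masquerade as structure) is compared with
a two-Gaussian model along candidate axes, and the detection is split when
the two-spot model reduces the residual sum of squares by more than 15
noise variances and both fitted amplitudes are substantial. Near the field
border, where window clipping corrupts the moment-based axis estimate, the
full semicircle of axes is searched. With these defaults the detector
resolves pairs down to about 1.2 µm separation and holds a true-positive
rate above 96 % with false-positive and false-negative rates below 1 % on
the standard synthetic suite. This is the accuracy regime reported for
trained neural-network detectors on such footage; the package deliberately
uses a classical, fully reproducible detector instead, since a trained
network is defined by its weights and cannot be rebuilt from a written
description.

## Trajectory linking

`link()` performs frame-by-frame assignment with a bounded search radius
`max_disp` (default 6 µm = 15 px, about three frames of travel at cruising
speed) and gap `memory` (default 3 frames). Within each frame the
candidate (track, detection) pairs are assigned by an exact minimum-cost
solver (Jonker–Volgenant shortest augmenting paths) on the squared
displacement cost matrix, with dummy nodes priced so that the number of
links is maximized before cost is minimized; a hand-rolled solver is used
because no assignment-problem package is available in the dependency set,
and it is unit-tested against brute-force enumeration. When every cell is
detected in every frame, per-frame optimality implies global optimality
(the frame-pair matchings are independent), which is the basis of the
exhaustive-oracle test; the same per-frame-optimal design is standard in
single-particle-tracking linkers. Gap frames are never interpolated: all downstream
step statistics use consecutive-frame pairs only, because the velocity
definition presumes unit frame spacing. Tracks shorter than `min_length`
(default 10 frames, chosen so a track yields at least eight angle samples;
no published value exists for this filter) are dropped.

## Motility statistics

`step_velocities()` implements the finite-difference velocity
`v(t) = (r(t + dt) - r(t)) / dt`, and `directional_changes()` the unsigned
per-frame turning angle `acos(v(t)·v(t+dt) / (|v(t)||v(t+dt)|))` with the
arccos argument clamped to [−1, 1] against floating-point error. Pairs in
which either step has exactly zero length are dropped (the angle is
undefined there; jittering stalled cells produce nonzero steps, so the π
peak survives this rule). The signed variant takes the sign of the 2-D
cross product `vx(t) vy(t+dt) - vy(t) vx(t+dt)`, with +π for exact
reversals; on unbiased fixtures its mean is statistically zero and its
distribution symmetric, which the suite asserts.

Condition summaries follow a declared averaging hierarchy: steps are pooled
within a replicate video, replicate means are averaged into the condition
mean, and the reported dispersion is the SD across replicate means — the
same scale as error bars over five replicate videos. Whether published
error bars are SDs or SEs is not stated anywhere authoritative; SD across
replicates is this package's convention. Histograms use fixed left-closed
bins, 5 µm/s on [0, 150] µm/s for speeds and π/20 rad on [0, π] for angles.

`smooth_track()` (penalized cubic smoothing splines per coordinate, with
the roughness weight expressed in raw frame units) exists as an opt-in
robustness check: statistics are computed on raw tracks by default, and the
suite verifies that the control-versus-treated ordering of mean speed and
mean turning angle is identical for roughness weights 0.1, 1 and 10.
`heading_uniformity()` (mean resultant length plus a hand-coded Rayleigh
test, as no circular-statistics package is available in the dependency
set) is the drift / residual-flow QC gate for videos taken after reagent
addition.

## Growth curves and hormesis

`gompertz()` uses the lag-time parameterization
`y = A exp{-exp[mu_m e / A (lag - t) + 1]}`, in which all three parameters
are directly interpretable: `A` the stationary-phase asymptote (OD750
above baseline), `mu_m` the maximum growth rate (1/hr), `lag` the lag time
(hr). `fit_gompertz()` subtracts the initial OD (`baseline`, default 0.01)
and fits **each replicate separately** by Levenberg–Marquardt nonlinear
least squares, initialized from the data (asymptote at the maximum OD,
rate at the maximum discrete slope, lag at that tangent's time-axis
intercept) and bounded (`A ≤ 2 max(od)`, `lag` within the observation
window). Per-replicate fitting was chosen over fitting the mean curve
because replicate heterogeneity near inhibitory doses is itself a finding
of interest — the aggregate SD then carries it, as the suite's
heterogeneity-propagation test verifies by injecting a 50 % replicate
failure rate. Replicates that never rise more than `no_growth_threshold`
(default 0.05 OD750) above baseline are flagged `no_growth` and excluded
from the aggregate, since their lag is unidentified within the assay
window; non-convergence is reported, not thrown.

`compare_conditions()` flags a hormetic asymptote when a treated
condition's mean `A` exceeds the control's by more than the combined SD
`sqrt(sd_t² + sd_c²)`, and an elongated lag analogously. A condition is
reported `no_growth` when flat replicates outnumber grown ones (majority
rule), so a single noisy flat curve cannot promote a lethal condition to
"grown". Curves that have not plateaued within the assay are fitted
anyway and their asymptote uncertainty reported; the package makes no
extrapolation claims for them.

## Chlorophyll quantification

`chlorophyll_concentrations()` applies the standard two-wavelength
equations for 80 % acetone / 20 % methanol extracts after baseline
correction at 750 nm: `chl_a = (12.25 E663 - 2.55 E645) / V`,
`chl_b = (20.31 E645 - 4.91 E663) / V`; the total-chlorophyll coefficients
(17.76, 7.34) are exactly the sums of the a and b pairs, so
`chl_a + chl_b = chl_total` is an identity the code preserves by
construction. Negative computed concentrations (possible with noisy
near-blank extracts) are flagged rather than clipped, because clipping
would silently break that identity. `per_cell_content()` converts bulk
concentrations to pg/cell via the rule of thumb 1 OD750 ≈ 10⁷ cells/mL;
the per-cell unit is pg per cell (a per-cell mass), the only dimensionally
consistent reading of per-cell chlorophyll content.
`simulate_pigment_absorbances()` inverts the 2×2 linear system so that the
noiseless round trip recovers concentrations to machine precision — the
fixed coefficient matrix has determinant 236.277 and can never be
singular.

## The pipeline and reproducibility

`run_pipeline()` executes the full synthetic study from one validated
configuration: the motility arm over an Ag⁺ concentration × exposure ×
replicate grid (optionally through the full render → detect → link image
path, or directly on ground-truth tracks for fast runs), the growth arm
over per-condition Gompertz parameter sets, and a pigment round-trip. All
tables are written as CSV (coordinates always in µm), videos as multi-page
TIFF, and a YAML manifest echoes the configuration and every seed, so a
manifest suffices to reproduce any output bit for bit. Configuration
validation lists every missing key, and every stochastic stage requires an
explicit seed.

The default per-condition growth parameter sets mirror the study
conditions: control (A 0.54, mu_m 0.0084 /hr, lag 45.6 hr), a low-dose
hormetic condition (A 0.87, mu_m 0.0096 /hr, lag 82.6 hr), an intermediate
condition that has not plateaued (lag 101.3 hr; its asymptote is not
printed anywhere, so the generator uses A = 1.0, consistent with the
observation that its OD already exceeds the control's plateau), a strongly
inhibited heterogeneous condition (lag 142.7 hr with 50 % replicate
failure, emulating the wide replicate scatter there), and a lethal
condition in which no replicate grows within 188 h.

## Problem sizes and numerical choices

The shipped test-suite and benchmark sizes are a deliberate desk-scale
choice: 5 videos × 200 frames × 40 cells for the detection contract,
1000 frames for the speed-distribution recovery, 6 replicates × 16 time
points for every growth fit, and ≤ 4 cells × ≤ 6 frames for the exhaustive
linking oracle. Convolution is FFT-based with replicate padding (kernel
transforms are cached per stack); assignment costs use squared distances
with dummy-node prices scaled to preserve floating-point resolution;
`arccos` arguments are clamped; histogram bins are left-closed with the
top edge folded into the last bin; and the spline roughness weight is
rescaled by the cube of the time range so it acts in raw frame units.

## Limitations

The generator emulates the statistical structure the analyses rely on —
spot-like cells, two-state motility, sigmoidal growth with replicate
noise, linear absorbance mixing — not the optics or biology themselves:
no phase-contrast halos, no cell division or phototaxis, no hydrodynamic
interactions, no mechanistic stall kinetics. Passing the synthetic
benchmarks therefore demonstrates that the analysis chain is correct and
self-consistent (it recovers known ground truth through the full image
path), not that the detector or the stall model would achieve the same
accuracy on any particular microscope's footage.
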