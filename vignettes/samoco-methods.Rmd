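---
title: "Single-angle-based motion compensation for 4D cone-beam CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-angle-based motion compensation for 4D cone-beam CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cone-beam CT gantries rotate slowly (around 60 s per turn), so every
projection view of a thorax scan sees the patient in a different breathing
state. A standard FDK reconstruction superimposes all states and blurs
moving anatomy; retrospective gating reconstructs each phase bin from its
own view subset, which works only when breathing is periodic enough that
every bin is well filled, and it discards temporal resolution.

This package implements gating-free, single-view-resolution motion
compensation. The key objects are *single-angle reconstructions* (SARs):
the FDK contribution of one view, $X_i^{-1} p_i$. A motion-compensated
reconstruction of the state at any reference view $n$ is the warped sum

$$ f_{n} = \sum_{i=1}^{N} T_i^{\,n} \circ X_i^{-1} p_i, $$

where $T_i^{\,n}: r \mapsto r + u_i^{\,n}(r)$ pulls view $i$'s SAR into
state $n$ with a displacement vector field (DVF). Every view can serve as
the reference, so the scan yields as many motion states as views.

Because the warp is applied *after* backprojection, the identity
$T\circ(X^{-1}Xf) = X^{-1}X(T\circ f)$ holds only approximately, and
residual streaks remain even with exact DVFs. The package quantifies this
with a toy experiment (a cylinder scaled per view by
$s(i) = 1 + 0.1\sin(0.15\,i)$, reconstructed with the exact inverse
scaling) and corrects it with a residual network (below).

# Coordinate and operator conventions

* World coordinates in mm, isocenter at the origin, $z$ the rotation
  axis; view angle = source azimuth, counter-clockwise from $+x$.
* DVFs use the backward (pull) convention on the *target* grid:
  `warp(vol, u)(r) = vol(r + u(r))`, trilinear, edge-clamped. A positive
  constant $x$-displacement therefore moves image content toward $-x$.
  Components are ordered $(x, y, z)$ in mm.
* Volumes are attenuation fields internally
  ($\mu = \mu_w(1 + \mathrm{HU}/1000)$, $\mu_w = 0.02\,$mm$^{-1}$) and HU
  for reporting.
* The forward projector is ray-driven with trilinear sampling at half a
  voxel per step; the unfiltered backprojector is its exact scatter
  adjoint (the dot-product identity holds to machine precision), which
  makes the SART-type modified-SAR update well behaved. The filtered
  backprojector is voxel-driven with $\mathrm{SID}^2/U^2$ distance
  weighting; summing all SARs equals the FDK volume exactly because both
  run through the same per-view filtering and accumulation.

# FDK details and the shifted detector

Clinical geometry (available as `truebeam_geometry()`): SID 1000 mm,
SDD 1500 mm, 1024 × 768 detector at 0.388 mm, laterally off-centred by
160 mm to enlarge the field of measurement; full-rotation scans.
Shifted-detector scans need redundancy weighting: rays measured twice
(once per conjugate view) receive raised-sine feathering weights
$w(u) + w(-u) = 1$ over a band near the detector's inner edge (default
width 10% of the detector). With a centered detector the same scheme
degenerates to the classical factor $1/2$ for the doubly covered full
circle. A shifted-detector scan covering less than the full rotation is
rejected as data-insufficient.

The ramp filter is the band-limited Ramachandran–Lakshminarayanan kernel,
zero-padded to the next power of two, with a selectable apodization
window (`"ramlak"` = none, `"cosine"`, `"hann"`). At the desk-scale
resolutions used throughout (2–2.6 mm detector pixels, 2.5–3 mm voxels)
smooth roll-off windows visibly blur thin high-contrast structures (ribs,
nodules): on a static phantom the body-mask reconstruction error is about
26 HU with the pure band-limited ramp versus 31 HU with the cosine
window. The simulation-study and acceptance configurations therefore pin
`window = "ramlak"`, a choice made on *static* (motion-free) scans; the
smooth windows remain available and are the better choice in the presence
of measurement noise.

# The digital 4D thorax phantom

The clinical prior here is synthetic: an analytic thorax (superellipsoid
body at 0 HU, two lung ellipsoids at −800 HU clipped by a paraboloid
diaphragm dome, a heart ellipsoid at +40 HU, rib bands at +700 HU on the
chest-wall shell, spherical lung nodules at +50 HU, a +40 HU diaphragm
band) deformed by a one-parameter family of breathing maps

$$ \phi_a(x,y,z) = \bigl(x,\; y + a\,h(y),\; z + a\,g(x,y)\,\psi(z)\bigr), $$

where $g$ is a lateral envelope (1 over the diaphragm dome, decaying to 0
at the chest wall, so ribs stay nearly static), $\psi$ decays from 1
below the diaphragm to 0 at the lung apex, and $h$ is a mild anterior
chest expansion. The motion state with amplitude $a$ is
$f_a = f_0 \circ \phi_a$. Each component of $\phi_a$ is a monotone 1-D
map, so $\phi_a^{-1}$ is computed per voxel by a few safeguarded Newton
steps and the DVF between ANY two amplitudes is exact:
$u_{s\to t}(r) = \phi_{a_s}^{-1}(\phi_{a_t}(r)) - r$. This replaces
registration-derived ground truth with an analytic oracle — the main
reason to use a synthetic prior at all.

Ten phases follow a 1−cos waveform (phase 1 = end-exhale, $a = 0$;
phase 6 = end-inhale, $a$ = the configured excursion, default 15 mm peak
at the dome apex; supported range 5–25 mm). Amplitudes at fractional
phases $\varphi\in[1,11)$ interpolate linearly between the bracketing
integer phases, with phase 11 wrapping to phase 1 (cyclic breathing).
Excursions whose Jacobian would fold the map are rejected at
construction. Tissue interfaces are blended over 4 mm (2 mm for small
unit-test phantoms) so that the rendered volumes are approximately
band-limited at the grid resolution; both reconstructions and their
ground-truth comparisons see the same blending. With a seed,
`thorax_params()` draws moderate anatomical variability (body habitus,
lung size, dome height, heart position, nodule placement), emulating a
patient population for network training.

What the phantom does *not* model: cardiac motion (deliberately — the
largest DVF errors in clinical material occur in the heart, driven by
motion this respiratory-only model excludes), sliding pleural interfaces,
hysteresis between inhale and exhale paths, realistic texture, scatter,
beam hardening and detector effects. Passing tests on this phantom
demonstrate the correctness of the operators and the learnability of the
synthetic motion family, not clinical performance.

## Scan simulation

`simulate_scan()` renders, for every view, the phantom at that view's
(fractional) phase and forward-projects that single view — emulating the
continuous transitions of a real scan. The per-view state is rendered
analytically at the linearly interpolated amplitude rather than by
warping the gridded phase volume with the fractional displacement (the
generic `interpolate_phase_state()` operation, which is implemented and
tested separately): the two constructions agree to first order in the
phase fraction, and the analytic route keeps the simulator's per-view
volume and DVF oracles exact. The displacement-scaling reading of
fractional interpolation is the default everywhere; the literal
intensity-scaling reading (which fades gray values and is non-physical)
is available behind `mode = "intensity"` for comparison only.

Phase signals: `periodic_signal()` sweeps the cycle linearly (default 15
breaths per scan, a typical free-breathing rate for a 60 s acquisition);
`nonperiodic_signal()` integrates a seeded piecewise phase-velocity
process with drifting rate, a guaranteed extended breath-hold plateau
(about a third of the scan) plus a shorter one, and a slow baseline
drift — the qualitative features of highly irregular respiration. Only
those qualitative features are modelled; no attempt is made to match any
specific measured trace. Projections are noiseless by default; optional
Poisson noise at a stated incident photon count is available and seeded.

# Gated reconstruction

`gated_reconstruct()` sums the SARs of views whose phase lies within a
cyclic window (default 20% of the cycle, closed at both ends) around the
target phase. The selected subset is re-weighted with Voronoi angular
weights — each view carries half the angular gap to its selected
neighbours — so sparse subsets remain quantitatively calibrated; with the
full-cycle window this reduces exactly to FDK. The unnormalized variant
(full-scan uniform weights) is available via `renormalize = FALSE` for
comparison. An unvisited phase raises an error naming the empty bin.

# Modified SARs and the DVF network

A SAR alone carries little morphology, so the network input enriches it
with one SART-type update of the motion-blurred full reconstruction
$\bar f$:

$$ g_i = \bar f + \frac{X_i^T\!\bigl((p_i - X_i \bar f)/(X_i 1)\bigr)}{X_i^T 1}, $$

with $\varepsilon$-guarded divisions and out-of-cone voxels left at
$\bar f$. On data consistent with $\bar f$ the update is an exact fixed
point.

The DVF predictor is a 3-D U-Net mapping the two-channel pair
$(g_i, g_n)$ to $u_i^{\,n}$: two 3×3×3 convolutions with PReLU per stage,
filter count doubling per stage, 2×2×2 max pooling / nearest-neighbour
upsampling, skip connections, and a linear 3-filter head. The full-scale
configuration is 6 stages starting at 8 filters; the desk-scale defaults
are smaller (3–4 stages, 4–8 base filters on 40–64 voxel grids), chosen
so that training runs in minutes on one CPU core. No deep-learning
framework is used: the network, its analytic backward pass and the Adam
optimizer are implemented in compiled code, single-threaded and
bit-reproducible (the analytic gradients are verified against finite
differences in the test suite).

Training follows the on-the-fly paired-sampling scheme: per sample, two
phases and two view angles are drawn uniformly, single-view projections
of the two states are rendered, both modified SARs are computed against
the phantom's $\bar f$, and the exact phantom DVF is the regression
target (MSE loss, Adam, default learning rate $10^{-4}$ at full scale —
the desk-scale configurations use larger rates of order $10^{-3}$ because
they take orders of magnitude fewer steps). $\bar f$ itself comes from
one simulated scan per phantom with a randomized periodic signal, reused
for all samples of that phantom. Validation-best parameters are kept.
Choices the protocol leaves open, fixed here: inputs are normalized from
[−1000, 1000] HU to [0, 1] (clipped); the network predicts displacements
in voxels, converted to mm at the boundary so weights are
resolution-independent; training uses full volumes, not patches.

# Residual artifact correction (RAC)

The RAC network shares the U-Net architecture with a single input channel
(the SAMoCo reconstruction) and a single output channel (the additive
artifact estimate $A$), applied through a residual connection
`corrected = input + A`; a zero-initialized head makes the untrained
network exactly the identity. Training examples are scans of per-view
*uniformly random integer* phase sequences (no fractional interpolation),
reconstructed with SAMoCo using the exact oracle DVFs — isolating the
warp-after-backprojection approximation from DVF estimation error. The
"ideal motion compensation" label is realized operationally as the FDK
reconstruction of a static scan of the reference state, which is the
residual-free limit of the warped-sum reconstruction. A fixed set of
sequences per phantom is generated once and iterated over the epochs.
Whether RAC inputs use oracle or network DVFs is switchable; the default
isolates the residual mechanism with oracle DVFs.

# Evaluation tools

*Diaphragm tracking.* Line profiles are cast perpendicular to the local
diaphragm surface (normals from the smoothed gradient of the lung-class
indicator, Gaussian σ = 1.5 voxels), 40 mm long, sampled every 0.5 mm by
trilinear interpolation; each profile is fitted with the sigmoid
$s(z) = h/(1+e^{-c(z-z_0)}) + b$ by Levenberg–Marquardt least squares
(initialized at the half-maximum crossing, $c = 1\,$mm$^{-1}$, jittered
retries), and converged inflection points are averaged (default 400
profiles). Placement is a seeded uniform draw of diaphragm-class voxels:
evaluating a reconstruction and its ground truth with the same seed uses
identical profiles, so placement and voxelization effects cancel and the
difference isolates reconstruction error — this is what lets the
estimate resolve sub-voxel displacements.

*Anatomy-specific DVF statistics.* Per-class mean displacement magnitude
and pixelwise MAE versus ground truth over a DVF collection, with binary
class weights from the target state's label map and the normalizer
generalized to $K_c = \sum_k \sum_r w_{k,c}(r)$ for arbitrary collection
sizes (for a full 10-phase × 10-draw collection with state-independent
class counts this reduces to the fixed $10^4\sum_r w$ form). Verified in
the tests against a scalar quadruple-loop summation to $10^{-12}$.

*HU accuracy.* `mae_hu()` over a mask; the default body mask is
truth > −300 HU, and for phantom states the label-based mask (all six
anatomical classes) is used. Whole-volume evaluation is available by
passing an all-`TRUE` mask.

# Problem sizes and reproducibility

The simulation study and the acceptance script use an 80 × 80 × 56 grid
at 2.5 mm, a 160 × 120 detector at 2.0 mm with 60 mm lateral offset, and
240 views per rotation — sized so that the static-scan reconstruction
floor (≈ 22 HU body-mask MAE, dominated by thin ribs) sits well below
the motion-compensation effects being measured, while one full study runs
in minutes on one CPU. Network training tests use 40 × 40 × 28 grids at
5 mm with 2–3 phantoms and tens of examples; these are the package's
desk-scale study conditions, config-reachable up to the full clinical
scale. All stochastic steps (phantom variability, signals, noise,
sampling, initialization) consume explicit seeds; training is
single-threaded, so repeated runs are bit-identical.

# Known limitations

* The residual-streak floor of warped-sum reconstruction depends on the
  angular sampling and grid resolution; at desk scale it is a larger
  fraction of the total error than at clinical scale. In particular, the
  ideal-motion-compensation target itself sits roughly 22-24 HU from the
  rendered truth at 2.5-3 mm voxels (thin ribs dominate), so absolute HU
  bounds quoted for clinical-resolution reconstructions are only partly
  transferable to desk scale.
* The desk-scale training runs in the test suite take a few hundred Adam
  steps. They demonstrate that both networks optimize correctly
  (single-example overfitting to below 1% of the initial loss) and
  improve over their initialization on held-out phantoms; they do not
  reach the regime of the full-scale protocol. Notably, the desk-scale
  DVF network's held-out error (~1.3 mm, well below the voxel size)
  is comparable to that of a zero-displacement predictor: with this few
  steps it learns the displacement scale rather than patient-specific
  fields. The patch-trained residual-correction network improves every
  held-out state by a uniform but modest margin.
* The analytic breathing family is smooth and cycle-consistent; real
  respiratory motion includes hysteresis and sliding interfaces that the
  DVF network never sees during synthetic training.
* The gated baseline's empty-bin behaviour is strict (error), which is
  the honest failure mode for non-periodic signals rather than silently
  reconstructing from too few views.
* `dvf_provider_network()` recomputes modified SARs per view on first
  use; for long scans this dominates inference time and is cached in
  memory only.
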