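---
title: "Quantifying calf-muscle perfusion from dynamic water PET: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying calf-muscle perfusion from dynamic water PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petperf)
```

## The measurement problem

In peripheral arterial occlusive disease the clinically relevant question
is whether *muscle tissue* — not just the large arteries — receives enough
blood. Radiolabelled water ([15O]H2O) is freely diffusible and
metabolically inert, so under a one-tissue compartment model its influx
rate constant K1 *is* tissue perfusion. A dynamic PET acquisition over the
lower legs, together with an arterial input function read from the image
itself, therefore yields perfusion in mL/100 cm³/min per muscle region.

`petperf` implements that analysis chain — input-function extraction,
muscle VOI construction, kinetic fitting, and the reliability statistics
used to judge whether two readers produce the same numbers — and couples
it to a digital lower-leg phantom with known ground truth, so each stage
can be verified quantitatively without patient data.

## The kinetic model

Tissue concentration follows the one-tissue compartment model (1TCM)

$$C_T(t) \;=\; K_1 \int_0^t C_a(s - \Delta)\, e^{-k_2 (t-s)}\, ds,$$

with arterial input $C_a$, influx $K_1$ (reported as mL/100 cm³/min),
efflux $k_2$ (1/min) and a blood delay $\Delta$ (s) between the arterial
sampling site (superficial femoral artery) and the calf muscle. No blood
volume fraction term is included: for a highly extracted, freely
diffusible tracer in muscle its contribution is negligible, and omitting
it keeps the model identifiable on 22 frames. No partial-volume
correction is applied anywhere in the chain.

Two conventions run through everything:

* **Frame-average semantics.** A reconstructed frame value is the time
  average of the activity over the frame interval, not a point sample at
  the mid-time. The simulator produces frame averages, and the fit
  averages its model curve over the same intervals before comparing.
* **Units.** Time is seconds internally; rate constants cross the user
  interface per minute, and K1 is converted to the reporting unit
  (×100) only at the boundary (`convert_k1_units()`).

### Numerical core

The convolution is evaluated by interpolating the input piecewise-linearly
onto a uniform fine grid (default 0.05 s) and convolving each linear
segment with $e^{-k_2 t}$ analytically, which reduces to a first-order
recursion evaluated in C (`stats::filter`). The only discretisation error
left is the linear interpolation of the input itself; halving the step
changes results by well under $10^{-6}$ relative, and the forward curve
matches an independent Runge-Kutta integration of the 1TCM ODE to about
$10^{-8}$ relative at frame mid-times.

### Fitting: basis functions plus a delay grid

Given $k_2$ and $\Delta$, the optimal $K_1 \ge 0$ is a closed-form
weighted-least-squares coefficient. The fit therefore searches a log-spaced
$k_2$ basis grid (default 40 points over 0.03–2 /min) crossed with a delay
grid (default 0–15 s in 0.5 s steps), keeps the triple with minimal
weighted residual sum of squares, and finally polishes $k_2$ continuously
around the best grid point. This is convex in $K_1$, fully deterministic,
and free of starting-value pathologies — the standard basis-function
approach for water kinetics. Frame weights are proportional to frame
duration (longer frames collect more counts, hence have smaller relative
variance); uniform weighting is available for sensitivity analysis.

On noiseless phantom curves this recovers $K_1$ to within ~1.5% across
the clinically observed range (1.5–5.2 mL/100 cm³/min crossed with
$k_2 \in \{0.2, 0.4, 0.6\}$/min) with the delay within one grid step. The
residual bias is not an optimiser failure: the input function enters the
fit as 22 frame averages, and linearly interpolating those averages
slightly smooths the bolus peak. It is the same discretisation any
frame-based analysis accepts.

## The acquisition being emulated

The framing scheme is the 22-frame clinical protocol (8×5, 3×10, 4×15,
6×30, 1×60 s; 370 s), on a 1.65 × 1.65 × 1.5 mm voxel grid. Radioactive
decay of oxygen-15 uses the physical half-life 122.24 s (a standard
constant, configurable in `decay_spec()`), with the decay reference time
at scan start — the usual convention when injection coincides with
acquisition start. The frame decay-correction factor

$$F = e^{\lambda(t_0 - t_\mathrm{ref})}\,
      \frac{\lambda\,\Delta t}{1 - e^{-\lambda \Delta t}}$$

is exact for activity constant over the frame; applying decay and then
the correction recovers a constant activity to $10^{-9}$ on every frame.

## The digital phantom

`leg_phantom()` is deliberately parametric: a cylindrical leg, two bone
cylinders (tibia, fibula), an arterial cylinder standing in for the
superficial femoral artery, and muscle split into posterior and anterior
compartments by a coronal plane. The analysis consumes label volumes, so
geometric realism is irrelevant to what is being tested; cylinders keep
every geometric expectation (volumes, distances, slice counts) exact.

The arterial input is a peak-normalised gamma-variate bolus with a
recirculation plateau — appearance ~10 s, peak ~25 s at 60 kBq/mL,
15% recirculation — emulating a 400 MBq intravenous bolus. Ground-truth
kinetics default to the middle of the observed clinical range
(posterior K1 = 3.0 mL/100 cm³/min, k2 = 0.3/min, delay 5 s). Published
tissue k2 values for this protocol are scarce, so the default sits in
the regime the recovery grid tests;
users preferring the physiological water coupling $k_2 = K_1/p$ with
partition coefficient $p \approx 0.9$ mL/cm³ can use
`k2_from_partition()`.

Noise is Poisson on pseudo-counts: a voxel at concentration $C$ in a
frame of duration $\Delta t$ contributes expected counts
$\kappa\, C\, \Delta t\, V$. This reproduces the dominant structure of
PET noise — variance inversely proportional to frame duration and VOI
size — without modelling reconstruction. The study-level default
$\kappa = 0.4$ was chosen once so the contour-VOI TAC has ~5% frame CV at
the late-frame plateau on the default phantom. What the phantom does
*not* emulate: OSEM reconstruction and its correlated noise, attenuation
and scatter residuals, point-spread blurring (and hence spill-over into
the artery), patient motion, and inter-subject anatomical variation.
Passing tests demonstrate the *analysis chain* is correct and stable
under count noise and placement variability; they do not certify
accuracy on real scanners.

## VOI rules

* **IDIF**: at the frame where the artery region's mean is highest (the
  first pass of the bolus), the 4 highest-intensity voxels in each of 10
  consecutive axial planes are selected; the 40-voxel mask is then applied
  unchanged to all frames. The start plane sits 3 cm distal (toward the
  foot) to the common femoral bifurcation. Ties in intensity break by
  lexicographic voxel index so manual "pick the hottest voxels" becomes
  deterministic. Because selection maximises over noise, the extracted
  peak is biased upward at high noise — a property the tests assert
  qualitatively, and one reason noisy-study K1 values sit slightly below
  ground truth while remaining highly reproducible.
* **Contour VOI**: the posterior-compartment label in ten 1.5-mm axial
  slices around 60% of the lower-leg length (malleolus → knee), minus a
  20-mm Euclidean exclusion zone around tibia and fibula. Ten slices
  cannot be symmetric about one slice; the stack runs 4 below to 5 above
  the level slice, centred within half a slice. The margin is 3-D
  Euclidean in world mm (for axially uniform bones this equals the
  in-plane margin). The exclusion zone is computed by FFT dilation with a
  ball kernel, verified against brute-force distances.
* **Sphere VOI**: two 7.5-mm-radius spheres (analytically 3534 mm³
  ≈ 3.5 mL combined) placed medially and laterally in the posterior
  compartment; voxel membership is by voxel-centre inclusion, consistent
  with the no-partial-volume stance. Voxelised volume converges to the
  analytic value under grid refinement; at the native grid it is within a
  few percent, alignment-dependent.

Boundary conventions are explicit: voxel indices are 1-based (R), world
coordinates put voxel centres at $(i-\tfrac12)\,d$, and an axial
coordinate on a slice boundary belongs to the upper slice.

## Agreement statistics

Reliability uses ICC(2,1): two-way random effects, absolute agreement,
single measures,

$$\mathrm{ICC} = \frac{MSR - MSE}{MSR + (k-1) MSE + \tfrac{k}{n}(MSC - MSE)},$$

with 95% confidence intervals by the McGraw–Wong F-distribution method.
Absolute agreement is the right form here because a systematic offset
between raters is a real disagreement. The consistency form (ICC(3,1)) is
available only as a labelled alternative. Interpretation bands are the
conventional ones (poor < 0.5, moderate to 0.75, good to 0.9, excellent
above); the published band edges overlap, so the half-open convention
`[0.5, 0.75)`, `[0.75, 0.9]`, `(0.9, 1]` is documented output. A constant
ratings matrix returns an explicit `undefined` status rather than an
error or a fabricated value. Bland–Altman limits use 1.96 × SD of the
differences literally (not a t quantile), and the bias is reported with a
t-interval so "no systematic bias" is checkable.

The in-silico reading study (`virtual_rater_study()`) simulates 10 legs
spanning K1 1.5–5.2, scans each once (both virtual raters analyse the
same noisy scan, as in a real reading study), then re-places VOIs per
rater-session under small perturbations: sphere centres jittered with
σ = 1 mm, the contour dilated/eroded by up to one voxel step, the IDIF
start plane shifted by up to one plane. Intrarater ICCs compare a rater's
two sessions; interrater ICCs are emitted for all four rater-session
pairings, labelled, since pooling conventions differ between reports.
With these defaults both VOI methods sit in the excellent range
(ICC > 0.9, occasionally grazing 0.9 for the sphere method at some seeds)
with bias intervals covering zero — the same qualitative regime reported
for the manual analyses this emulates.

## Problem sizes and runtime choices

Defaults are sized for a laptop-class single core: a 64 × 64 × 48 voxel
phantom (the calf cross-section at full voxel resolution, a short axial
slab), 22 frames, 0.05 s convolution step, 40 × 31 basis/delay grid
(< 1 s per fit), 50 replicates for noise studies, and 10 legs × 2 raters
× 2 sessions (80 fits, ~1–2 min) for the reproducibility study. All
stochastic steps take explicit seeds and restore the caller's RNG state;
identical seeds give bit-identical scans and studies.

## Known limitations

* K1 equals perfusion only for a freely diffusible tracer; nothing here
  generalises to tracers needing two-tissue models, which are
  deliberately out of scope.
* The IDIF carries no spill-over/partial-volume correction; on real data
  this is a known source of scale error, here it is exact by construction
  (homogeneous artery cylinder).
* The phantom's noise is uncorrelated Poisson; reconstructed PET noise is
  spatially correlated, so real-VOI variance at matched counts will be
  somewhat higher than simulated.
* Agreement conclusions transfer to real readings only insofar as the
  jitter magnitudes (1 mm, one voxel step, one plane) describe real rater
  variability; they are inputs, not findings.
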