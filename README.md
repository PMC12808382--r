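# petperf

Quantification of skeletal-muscle perfusion from dynamic [15O]H2O PET-CT
of the lower leg, for imaging scientists studying peripheral arterial
occlusive disease (PAOD) and for anyone who needs a fully testable,
ground-truth-driven implementation of the water-PET analysis chain.

Radiolabelled water is freely diffusible and inert, so under the
one-tissue compartment model (1TCM)

```
C_T(t) = K1 · ∫₀ᵗ C_a(s − Δ) · exp(−k2 (t − s)) ds
```

the influx rate constant **K1** (reported in mL/100 cm³/min) *is* tissue
perfusion; `C_a` is the arterial input, `k2` the washout rate (1/min) and
`Δ` the blood delay (s) between artery and muscle. The package provides:

* **Framing & decay** — the 22-frame dynamic protocol
  (8×5, 3×10, 4×15, 6×30, 1×60 s; 370 s), frame decay correction for
  oxygen-15, JSON sidecar I/O.
* **Digital phantom** — a parametric lower-leg (bones, posterior/anterior
  muscle compartments, artery) with a gamma-variate arterial bolus, 1TCM
  tissue curves with known K1/k2/delay, radioactive decay and
  frame-duration-dependent Poisson count noise. Every downstream stage is
  verifiable against exact ground truth.
* **IDIF extraction** — the image-derived input function from the
  superficial femoral artery: 4 highest-intensity voxels × 10 consecutive
  planes at the first-pass peak frame, mask applied to all frames.
* **VOI construction** — the contour VOI (posterior compartment in ten
  1.5-mm slices at 60% of lower-leg length, minus a 20-mm bone exclusion
  zone) and the standardised dual 7.5-mm-sphere VOI (3.5 mL).
* **Kinetic fitting** — basis-function 1TCM fit with delay estimation on
  a grid, duration weighting, closed-form non-negative K1.
* **Agreement statistics** — ICC(2,1) (two-way random, absolute
  agreement, single measures) with McGraw–Wong confidence intervals,
  Bland–Altman limits of agreement, and an in-silico intra-/interrater
  reproducibility study with virtual raters.

Tabular results are tibbles; fitted objects support `tidy()`/`glance()`
and `autoplot()`; images and masks travel as NIfTI via RNifti.

## Worked example

Simulate a noiseless scan, run the full analysis on it, and compare with
the known truth (posterior-compartment K1 = 3.0 mL/100 cm³/min,
k2 = 0.3/min, delay 5 s):

```r
library(petperf)

scan <- simulate_dynamic_scan(noise = noise_model(0), seed = 1)
#> <pet_scan> 64 x 64 x 48 voxels, 22 frames (370 s), decay-corrected

artery <- label_voi(scan$labels, scan$grid, "artery")
plane  <- locate_start_plane(scan$phantom$artery_bifurcation_z_mm, scan$grid)
idif   <- extract_idif(scan, artery, plane)
#> <idif_selection> 40 voxels (10 planes x 4), peak frame 6, start plane 25

level   <- lower_leg_level(scan$phantom$malleolus_z_mm, scan$phantom$knee_z_mm)
zone    <- bone_exclusion_zone(voi_mask(scan$labels %in% 1:2, scan$grid))
contour <- muscle_contour_voi(scan$labels, scan$grid, level, bone_zone = zone)
#> <voi_mask> contour: 10180 voxels, 41.57 mL
spheres <- sphere_voi(default_sphere_centers(scan$labels, scan$grid, level),
                      scan$grid)
#> <voi_mask> spheres: 856 voxels, 3.50 mL

fit <- fit_1tcm(extract_tac(scan, contour), idif$tac)
#> <pet_fit> K1 = 2.953 mL/100cm^3/min, k2 = 0.295 /min, delay = 4.5 s, WRSS = 6.792e-06
```

K1 comes back within 1.6% of truth, the delay within one 0.5-s grid step;
the small bias is the frame-discretisation of the input function, not the
optimiser (see the methods vignette). The reliability analysis the
package exists for:

```r
study <- virtual_rater_study(seed = 42)   # 10 legs, 2 raters x 2 sessions
tidy(study)[, c("method", "design", "comparison", "icc", "interpretation")]
#>    method  design     comparison                 icc interpretation
#>  1 contour intrarater rater 1: session 1 vs 2  0.985 excellent
#>  2 contour intrarater rater 2: session 1 vs 2  0.996 excellent
#>  3 contour interrater rater 1 s1 vs rater 2 s1 0.998 excellent
#>  ...
#>  7 spheres intrarater rater 1: session 1 vs 2  0.977 excellent
#>  9 spheres interrater rater 1 s1 vs rater 2 s1 0.955 excellent
```

Ten simulated legs spanning K1 1.5–5.2 mL/100 cm³/min, each analysed
twice by two virtual raters under small placement jitter (1-mm sphere
jitter, ±1 contour voxel step, ±1 IDIF plane): both VOI strategies land
in the excellent-reliability band, contour slightly above spheres, with
Bland–Altman bias indistinguishable from zero — the reproducibility
regime this protocol is designed to deliver.

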