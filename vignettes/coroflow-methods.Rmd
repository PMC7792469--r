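---
title: "Virtual FFR on coronary vessel graphs: models, numerics and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual FFR on coronary vessel graphs: models, numerics and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coroflow)
```

# The problem

The fractional flow reserve (FFR) is the ratio of mean pressure distal to a
coronary stenosis to mean aortic pressure under maximal hyperemia; values
below 0.80 mark a stenosis as hemodynamically significant. Measuring FFR
requires an invasive pressure wire. `coroflow` implements the noninvasive
alternative: extract the coronary geometry from a contrast-enhanced
volumetric image, build a one-dimensional blood-flow model on the resulting
vessel graph, personalize it from routine clinical data, and read FFR off
the simulation. Because clinical images and invasive measurements cannot be
redistributed, the package ships generators for synthetic coronary trees,
CTA-like voxel phantoms, and paired virtual/invasive cohorts, which is what
all tests run on.

# From image to graph

The extraction chain is `preprocess_volume()` →
`segment_vessels()` → `skeletonize_and_measure()` → `build_artery_graph()`,
wrapped by `extract_graph()`.

**Preprocessing.** Optionally drops the first axial slices and suppresses
bright structures far from the contrast-filled heart region: only
structures that survive a morphological opening with radius
`opening_radius_mm` (default 4 mm — in practice the aorta) seed the region
of interest, which is grown by `roi_margin_mm` (default 80 mm, enough to
cover the full coronary extent); bright voxels outside it are set to
background. This emulates the shadowing of lung vessels.

**Segmentation.** Fixed threshold (default 200 on an HU-like scale where
lumen is about 400) plus 26-connected region growth from seed points. The
paper-level method's actual segmentation algorithm is not public; this is a
documented, reproducible stand-in, not a reconstruction. The aorta is
separated from the arteries by scale: voxels within
`aorta_core_radius_mm + one voxel diagonal` of the deep-core region
(distance transform ≥ 3 mm) are aorta; fragments smaller than 50 voxels are
despeckled. Ostia are the centroids of artery voxels in contact with the
aorta, pulled back onto the true aortic surface by the expansion margin.

**Centerlines.** Rather than iterative thinning, centerlines are traced
geodesically: a Dijkstra front propagates from the ostium through the mask
with edge cost weighted by `1/(EDT + half voxel)` so paths hug the medial
axis; branches are then peeled off iteratively — the voxel whose geodesic
distance to the current skeleton most exceeds its own radius starts a new
branch, traced back along the Dijkstra parents. A branch whose candidate
lies within the lumen tube of the existing skeleton is a spur and is
discarded. This yields ordered centerline polylines with per-voxel radii
(EDT values) directly, which is exactly what graph construction needs.

Sub-voxel accuracy comes from three refinements, each calibrated on
analytic cylinder phantoms and documented here because they are where the
measurement accuracy is decided:

* every lumen voxel is assigned to its geodesically nearest skeleton voxel;
  the skeleton voxel is moved to the centroid of its claimed territory and
  its radius re-estimated from claimed volume per unit length (the raw EDT
  value is biased by up to half a voxel depending on where the axis falls
  within the lattice);
* junctions are located as the least-squares intersection of the three
  branch axes (parent, continuation, daughter), each fitted by total least
  squares on windows that stay clear of the junction bulge; the polylines
  are regularized onto those axes inside the bulge;
* terminal tips overshoot the true branch end by about one radius (the
  rounded cap); the tip node is pulled back along the terminal axis and
  lengths corrected accordingly. Arc lengths are integrated on a low-df
  smoothing spline of the polyline, since lattice noise otherwise inflates
  them by 2–4%.

On noise-free phantoms this recovers tree topology exactly and diameters
within max(half voxel, 5%). Lengths are within 5% for all but the
occasional short branch at a shallow bifurcation, where junction
localisation at 0.5 mm voxels bounds the error near 5–6% (the acceptance
suite records one such segment at 5.5%). These are the honest limits of the
estimator at the emulated acquisition resolution, not parameters one can
tune away.

# The 1D haemodynamic model

On each segment the solver advances the canonical 1D elastic-tube system

$$\partial_t A + \partial_x (Au) = 0, \qquad
\partial_t u + \partial_x\!\left(\tfrac{u^2}{2} + \tfrac{p}{\rho}\right)
 = -\frac{8\pi\mu u}{\rho A},$$

with the linear tube law \(p = p_\mathrm{ext} + \rho c_0^2 (A/A_0 - 1)\),
which gives wave speed \(c = c_0\sqrt{A/A_0}\) and Riemann invariants
\(W_\pm = u \pm 2(c - c_0)\). The original method's wall-state relation and
junction treatment are not public; these closures are this package's design
choices, stated as such. Constants: \(\rho = 1060\) kg/m³, \(\mu = 4\)
mPa·s, mmHg↔Pa via 133.322.

* **Numerics**: explicit MacCormack predictor–corrector (second order in
  the interior), CFL default 0.8, grid spacing default 1 mm, adaptive time
  step. Boundaries use first-order characteristic extrapolation.
* **Inlet**: prescribed pressure. The waveform template is a squared-sine
  systolic ejection occupying two thirds of the cycle over a diastolic
  baseline, so max = SBP, min = DBP, and the time mean equals the classical
  estimate DBP + (SBP − DBP)/3 exactly.
* **Terminals**: algebraic resistance \(Q = (p - P_\mathrm{out})/R\) with
  \(P_\mathrm{out} = 8\) mmHg (venous) by default, solved by damped Newton.
* **Junctions**: mass conservation plus continuity of total pressure
  \(p + \rho u^2/2\), solved by damped Newton per step. Under severe
  stenosis and hyperemia the throat flow can turn supercritical, where this
  system has no subcritical root; the solver then drops the
  dynamic-pressure term (static-pressure continuity) at that junction and
  step, and reports how often it did. This is the regime in which any 1D
  description of a stenosis is already questionable.
* **Convergence**: the run stops when the pointwise cycle-mean pressure
  changes by less than `tolerance_mmHg` (default 0.1) between cycles, or
  after `n_cycles` (default 5) with a warning.

`solve_steady()` is the deliberately independent companion: a linear
Poiseuille resistor network (\(g = \pi D^4 / 128 \mu L\)) solved exactly.
Under constant inflow at baseline (friction-dominated) resistances the
unsteady solver converges to it within a fraction of a percent; under
hyperemia the two differ by a few percent because the dynamic-pressure term
matters at hyperemic velocities. The steady mode doubles as the fast path
for cohort-scale runs.

Cycle-mean node pressures are reported from the largest-calibre segment end
meeting at the node — static pressure differs between the ends of a
junction (total pressure is what is continuous), and a pressure wire sits
in the normal-calibre vessel, never inside a stenotic throat.

# Personalization and FFR

`personalize()` maps a patient record to model parameters: the inflow
waveform from SBP/DBP/HR; the wall speed \(c_0\) from age brackets (<50:
8 m/s, 50–65: 10 m/s, >65: 12 m/s — a config-exposed lookup, since the
original grouping is unspecified); terminal resistances distributed in
proportion to \(D^{-3}\) of the terminal diameters (Murray's law flow
split) and scaled so baseline coronary flow equals 4% of cardiac output
(estimated from the Du Bois body surface area at a cardiac index of
3 L/min/m², or a scaled 5 L/min default when anthropometrics are missing).
Proximal network resistance is neglected in that scaling; it is two orders
of magnitude below the microvascular resistance for healthy calibres.

`induce_hyperemia()` divides every terminal resistance by a factor (default
3.5, papaverine-level vasodilation; the source study gives no number).
`compute_ffr()` takes the cycle-averaged pressure at the distal end of a
marked stenotic edge over the cycle-averaged ostial pressure. Each marked
site is assessed individually against the same aortic numerator — the
per-lesion convention; with sequential stenoses the distal site's value is
necessarily the lower one, and no cumulative pullback-style FFR is
attempted. A vessel's summary is the minimum over its sites, a patient is
positive if any vessel is, and the decision rule is strict: FFR < 0.80 is
ischemic, exactly 0.80 is not.

The stenosis itself is purely geometric: `apply_stenosis()` splits the host
segment so the narrowed extent is its own edge with
\(D_\mathrm{eff} = D (1 - r)\). No empirical stenosis pressure-loss element
is added in this version; post-stenotic pressure recovery is therefore
optimistic for severe, geometrically complex lesions — the same limitation
the source method reports for itself.

# The synthetic world

`make_coronary_tree()` grows a left-coronary-like binary tree: a 4 mm,
22 mm trunk, Murray-law daughter diameters with a random 0.38–0.62 flow
split, branch lengths shrinking by 0.72–0.95 per generation, all diameters
≥ 2 mm (the method's inclusion calibre). Daughters partition their parent's
angular sector in-plane and tilt out of plane in opposite directions,
giving 3D bifurcation angles in the realistic 30–70° range — early
versions with near-collinear planar daughters were both anatomically wrong
and adversarial for junction localisation.

`make_voxel_phantom()` rasterizes the tree as capsules at 0.5 mm isotropic
spacing (the emulated minimum slice thickness), lumen 400 over background
0, with an aortic-root tube tangent to the ostium; optional artefacts are a
non-touching bright vein tube, calcification blobs (≥ 800) against the
lumen wall, a far bright distractor for the preprocessing test, and
Gaussian noise. What the phantom does *not* emulate: beating-heart motion,
partial-volume blur, contrast gradients, gaps in enhancement. A green
recovery test therefore establishes correctness of the geometry pipeline,
not clinical robustness.

`make_cohort()` samples records with the study population's moments (age
63.6 ± 9, SBP 133.4 ± 9.4, DBP 84.0 ± 5.3, HR 65.2 ± 5), places 1–3
lesions of 45–75% diameter stenosis (the study's inclusion range) on
distinct vessels, runs the steady-mode pipeline for virtual FFR, and
emulates the invasive reference as
`virtual − bias + patient_offset + noise`, clipped to (0.05, 1]. The bias
parameter is defined as the expected virtual-minus-invasive difference so
that Bland–Altman analysis of the generated cohort recovers it directly
(the reference summary being +0.092 ± 0.191); the offset/noise split is
even, sd/√2 each, a stand-in calibrated only against those two aggregate
moments. Every generator is a pure function of its arguments and seed and
restores the global RNG state.

# Diagnostic statistics

`confusion_table()` counts strictly-below-threshold calls on both sides,
per vessel or per patient (any-ischemic-vessel rule).
`proportion_metrics()` returns sensitivity, specificity, PPV and NPV with
two-sided Wilson score intervals *without* continuity correction — the
method that reproduces the reference bounds exactly at all moderate
proportions (e.g. 16/24 → 46.71–82.03). At extreme proportions (7/8,
16/17) some published upper bounds differ in the second decimal,
consistent with a hybrid interval in the original statistics software; the
plain Wilson interval is implemented and the discrepancy documented rather
than guessed at. Zero-denominator metrics are flagged undefined. Display
rounding is half-up to 2 decimals; stored values are full precision.

`roc_auc()` is the Mann–Whitney concordance of `1 − virtual FFR` against
invasive-derived labels with ties counted ½ (identical to the trapezoidal
area under the empirical ROC); `bland_altman()` and `spearman_rho()` are
the direct formulas (mean/SD of differences with 1.96·SD limits; Pearson
correlation of mid-ranks). Each has an independent brute-force oracle in
the test suite.

# Known limitations

* One effective diameter per edge; no per-edge diameter profile.
* No stenosis loss element: severe (≥ 80%) lesions read lower in the
  unsteady solver than a loss-element model would predict, and the
  supercritical fallback degrades the junction model exactly there.
* Skeleton tracing assumes tree topology; a lumen loop (e.g. a touching
  vein) is resolved into a tree, not detected as a cycle — vein removal
  relies on labels (`prune_nonarterial()`) or on the vein being a separate
  component, which is how the phantom generates it.
* Length recovery at 0.5 mm voxels is accurate to about half a millimetre
  per node; on short branches this can exceed the 5% target (worst observed
  5.5%).
* Scar/infarct-adjusted microvascular response is out of scope; the
  hyperemia factor is uniform.
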