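---
title: "Quantifying stent-graft apposition and endoleak risk from deployed geometry"
author: "eritwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stent-graft apposition and endoleak risk from deployed geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eritwin)
```

## The problem

After endovascular aneurysm repair (EVAR), the most dangerous failure mode is
the type IA endoleak: blood re-entering the aneurysm sac because the
stent-graft never sealed against the proximal aortic neck. Whether a seal
will hold is a question about the *deployed three-dimensional geometry* of
the device inside the patient's aorta — how conical the neck is, how far the
graft cross-section is squeezed out of round, and whether a gap between
fabric and wall persists long enough along the vessel to form a channel.
Static preoperative diameter and angle measurements answer none of these
directly.

`eritwin` works on the deployed configuration itself: two watertight
triangulated surfaces (aortic lumen and deployed graft) plus a centerline.
From these it measures a dense radial apposition field, reduces it to three
physics-informed features, and combines them into a single Endoleak Risk
Index (ERI) with a decision cutoff.

## The measurement scheme

Cross-sections are taken every $\Delta s = 0.5$ mm along the centerline over
a 20 mm proximal sealing region (the first two covered stents), giving 40
slices. Each slice plane carries a parallel-transported in-plane frame so an
angular index refers to the same circumferential position on every slice.
Both contours are discretized into $n = 200$ radial "dots" from a shared
center — the aortic slice centroid — so the aortic radius $r_A(s,\varphi)$
and graft radius $r_G(s,\varphi)$ at the same angle are directly comparable:

$$ g(s, \varphi) = r_A(s, \varphi) - r_G(s, \varphi) $$

That is $40 \times 200 \times 2 = 16{,}000$ radius measurements per case.
Two conventions matter:

* **Slice placement.** Slices sit at interval midpoints
  $s_i = s_0 + (i - \tfrac12)\Delta s$, so $\lfloor L/\Delta s\rfloor$ slices
  tile the region exactly and a contiguous run of $k$ malapposed slices
  corresponds to exactly $k\,\Delta s$ mm of vessel.
* **First-crossing rule.** A radius is the distance to the *first* outward
  boundary crossing, so folded graft fabric is measured at its lumen-facing
  surface.

The shared-center convention is a deliberate choice (the alternative —
per-structure centroids — is available via `centers = "separate"` in
`radial_sampling()`): with separate centers, a rigid offset of the graft
inside the lumen would vanish from the gap field.

## The three features and the index

* **Aortic conicity (AC)** — taper or widening of the sealing zone:
  $|\bar r_A(s_1) - \bar r_A(s_N)| / \max(\bar r_A(s_1), \bar r_A(s_N))$,
  using the first and last slice of the region as the proximal/distal
  boundaries. Symmetric in taper vs widening, 0 for a cylinder.
* **Stent-graft shape (SGS₂)** — deviation from circularity:
  per-slice $(r_{G,\max} - r_{G,\min})/r_{G,\max}$, summed over slices and
  normalized by the slice count (i.e. the mean). The unnormalized sum over
  40 slices could exceed 1, which would contradict a score meant to live in
  $[0, 1]$; the mean interpretation is therefore the default and the raw sum
  remains available (`method = "sum"`).
* **Stent-graft malapposition (SGM₂)** — longitudinal persistence of the
  gap: a sample is malapposed when $g > \varepsilon$; for each angle the
  longest contiguous longitudinal run of malapposed slices is found, and the
  maximum run over angles, divided by the region length, is the score.
  "Maximum length" is read as a longitudinal extent — it is the
  *persistence* of a gap along the vessel that creates a leak channel, not
  its depth at one slice. The maximum relative depth is retained as a
  diagnostic (`measure = "depth"`).

The gap threshold $\varepsilon$ defaults to 0.1 mm, the mesh-noise floor
observed on synthetic tolerance tests (a defect-free synthetic pair
reproduces $|g| < 0.05$ mm everywhere); no physical apposition threshold is
established in the literature, so $\varepsilon$ is exposed in the
configuration.

The composite index is

$$ \mathrm{ERI}_\mathrm{raw} = AC + SGS_2 + \tfrac12 SGM_2, \qquad
   \mathrm{ERI} = \mathrm{ERI}_\mathrm{raw} / 2.5 $$

The divisor 2.5 is the maximum attainable raw score when each feature lies
in $[0,1]$; it is the normalization that maps the printed formula onto a
$[0,1]$ index, which the formula's source asserts but does not specify. The
binary prediction is positive when ERI ≥ 0.80, boundary inclusive — only an
index strictly below the cutoff rules the risk out. Per-slice oversizing,
$(R_{G0} - \bar r_A)/\bar r_A$ with $R_{G0}$ the mean graft radius of the
most proximal slice (measured, not nominal, for self-containedness), is
reported alongside but does not enter the index.

```{r example}
report <- run_case(list(id = "tapered-neck",
                        synthetic = list(r_prox = 12, r_dist = 10)))
report
```

## The synthetic deployed-geometry generator

No deposited deployed-geometry data exist, so the package carries a
first-class parametric generator (`synthetic_case()`, `generate_aorta()`,
`generate_deployed_graft()`) that emulates what a contact/deployment
simulation produces, with controllable:

* neck taper (proximal/distal radii; default 10.6 mm radius, matching a
  typical 21 mm neck diameter), neck length (20 mm), centerline angulation,
  and an optional fusiform sac bulge;
* cross-section **ovalization**, defined as $(r_\max - r_\min)/r_\max$ and
  applied to the *shared* cross-section shape: the neck is non-circular and
  the graft conforms to it. Ovalization therefore changes SGS₂ without by
  itself opening a gap — gaps are declared explicitly;
* **gap defects**: cosine-tapered radial depressions of the graft surface
  (smooth in both the longitudinal and circumferential directions, peaking
  at the declared depth), which avoids slicing artifacts at defect edges and
  resembles the smooth separations a deployment simulation produces.

Because the generator knows its own geometry, `analytic_features()`
evaluates AC, SGS₂ and SGM₂ on the continuous surface description without
meshing; agreement between this route and the mesh-measurement route is
itself a test.

`generate_cohort()` adds the population layer: clinical covariates (age,
gender, BMI, comorbidity flags, neck length/angle/diameter at realistic
elderly-EVAR rates), a per-case geometry, and a **declared label rule** — a
case leaks when its gap exceeds 1 mm in depth persisting ≥ 5 mm
longitudinally, or when conicity exceeds 0.25, with 5% label noise. A
`leak_fraction` share of cases is drawn from leak-prone geometry, three
quarters via deep long defects and one quarter via strong conicity, so the
declared generating-weight ordering is SGM₂ > AC > SGS₂ (SGS₂ carries no
weight). The planning-group flag has a 15% base rate — the treated group
must be a minority for 1:3 matching without replacement to be feasible with
caliper headroom — and is tilted by age, smoking, hostile neck and neck
angle in proportion to the `confounding` parameter (zero means identical
group distributions).

What the generator does *not* emulate: fabric wrinkling, calcification,
thrombus, stress-induced ovalization gradients, or any actual mechanics —
labels follow the declared geometric rule, not a physical simulation.
Passing tests on these phantoms certifies the measurement and evaluation
machinery, not clinical validity on real anatomy.

## Geometric-fidelity validation

Reconstruction fidelity is certified with the two standard mesh-vs-volume
metrics: the volumetric Dice coefficient $2|A\cap B|/(|A|+|B|)$ between
occupancy grids, and the exact symmetric Hausdorff distance (maximum
surface deviation, not a percentile variant) via dense deterministic
surface sampling with exact point-to-triangle distances. The package's
reconstruction stage (`reconstruct_surface()`) rebuilds a tube from the
pipeline's own 0.5 mm × 200-dot samples; a synthetic aorta and its
reconstruction must achieve Dice > 0.95 and Hausdorff < 0.5 mm at 0.25 mm
voxel spacing — the voxel pitch is deliberately finer than the 0.5 mm
surface bound being certified. These gates run over 10 seeded geometries in
`scripts/acceptance.R` and 3 in the test suite.

Numerical details that matter: voxel occupancy is decided by parity of
axis-parallel ray crossings per grid column, with grid offsets chosen
differently per axis so ray-through-vertex degeneracies have measure zero,
and coincident crossings (a column through a shared mesh edge) collapsed;
Hausdorff sampling uses vertices, edge midpoints, face centroids and a
barycentric refinement grid, so it is fully deterministic.

## The risk model and evaluation layer

`fit_risk_model()` is ordinary maximum-likelihood logistic regression of
the label on (AC, SGS₂, SGM₂) via `glm`; if the data are separable the fit
falls back to a small-ridge penalized IRLS so coefficients stay finite.
`select_cutoff_roc()` sweeps all thresholds, computes the exact
Mann–Whitney AUC (ties counted half), and picks the optimal cutoff by
Youden's J, breaking ties toward higher specificity — the criterion is a
choice; "optimal" is not otherwise defined for this index.

`confusion_metrics()` reports sensitivity, specificity, predictive values,
accuracy, likelihood ratios and the binary-prediction AUC
($(\mathrm{sens}+\mathrm{spec})/2$, equal to exhaustive pair counting) with
95% intervals. Interval conventions, which reproduce the standard
diagnostic-calculator outputs exactly:

* proportions (sensitivity, specificity, NPV, accuracy): exact
  Clopper–Pearson;
* likelihood ratios: the log method;
* PPV: the LR⁺ interval propagated through the sample prevalence (the
  convention of the common diagnostic-test calculators); when a likelihood
  ratio is degenerate (LR⁻ = 0 with no false negatives), the predictive
  value falls back to its exact binomial interval;
* AUC: Hanley–McNeil.

Group ERI comparison uses the Welch two-tailed t-test with a Mann–Whitney U
as a secondary rank-based report — with n = 5 vs 10 and near-boundary
values, normality is not a safe assumption, so both are always shown.

Propensity matching follows the standard 1:3 greedy nearest-neighbour
recipe on the logit of a logistic propensity score, without replacement,
processing treated units in descending propensity order (a common
convention; the order is otherwise arbitrary), with a caliper of 0.2 SD of
the logit score. A treated unit with fewer than 3 in-caliper controls is
dropped entirely and counted. Balance is reported as standardized mean
differences with the usual |SMD| < 0.1 reading. Note that with ~13
covariates and a few hundred units per arm, the *maximum* pre-matching
|SMD| under identical distributions is routinely above 0.1 by chance alone;
matching on the estimated score removes precisely those chance imbalances,
which is why post-matching balance is the meaningful check.

## Wall-material utility

The orthotropic compliance transformation
$1/E_\theta = \cos^4\theta/E_L + \sin^4\theta/E_C +
\tfrac14(1/G_{LC} - 2\nu_{LC}/E_L)\sin^2 2\theta$
is exposed as `elastic_modulus_at_angle()` and recorded as metadata in each
case report. It parameterizes the directional stiffness of the aortic wall
(stiffer longitudinally than circumferentially, following fibre
orientation). No solver consumes it here — deployment mechanics are out of
scope — and published numeric values for $E_L, E_C, G_{LC}, \nu_{LC}$ are
not established, so the defaults (3.0, 1.5, 0.6 MPa, 0.27) are placeholder
magnitudes of the right order, overridable from the case YAML.

## Problem sizes and determinism

Checks in this package run at desk scale by design: cohorts of 500 (risk
model, 350/150 train/test) and 1000 (matching), 3–10 seeded geometries for
the fidelity gates, meshes at ~0.7 mm edge length (≈ 9,000 triangles per
surface). Every stochastic step is seeded; `run_case()` reports are
byte-identical across reruns, and generated meshes are byte-identical for a
fixed specification.

## Known limitations

* The centroid-based centerline fallback assumes a roughly tubular mesh;
  strongly curved vessels near their ends rely on a two-pass re-slicing and
  marching scheme that recovers bends up to moderate angulation but is not
  a medial-axis method.
* SGS₂ and SGM₂ interpretations (mean vs sum; extent vs depth) are
  under-determined by their source; both switches are exposed and the
  defaults documented above.
* ERI values produced on synthetic phantoms are *not* calibrated to any
  clinical cohort; the 0.80 cutoff is carried as the published decision
  rule, and on phantom cohorts data-driven cutoffs from
  `select_cutoff_roc()` are the meaningful operating points.
* The evaluation layer intentionally does not attempt to reproduce
  conventional-planning comparison columns whose published counts are
  mutually inconsistent.
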