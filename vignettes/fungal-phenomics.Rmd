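---
title: "Methods: quantitative phenomics of fungal fermentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative phenomics of fungal fermentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycophenom)
```

# Scope and model

`mycophenom` analyses conditional-expression screens in filamentous fungi.
A screen crosses a panel of strains (mutants plus their progenitor control)
with a titratable inducer — by default doxycycline at 0, 0.2, 2 and
20 µg/ml, modelling null, minor, moderate and over-expression — and records,
in triplicate, phenotypes at three scales: colony (radial growth on solid
medium, with and without abiotic stress), hypha (length and tip number after
germination), and submerged macromorphology (pellet geometry from
micrographs), together with biomass-normalized secreted protein. The package
treats protein titre as a linear function of the condition-level phenotypes
and asks which phenotypes carry predictive weight.

# Pellet morphometrics

## Measurement definitions

Bright structures on a black background are segmented by a global intensity
threshold (automatic between-class-variance maximization by default, with a
fixed-intensity override), labelled as 8-connected components, and hole-filled
before measurement — pellets are solid bodies, and concavity is already
penalized through solidity. Components touching the image border are excluded
by default because their truncated calipers bias diameter statistics; the
exclusion is configurable and counted in the output.

Per object:

* **area** = pixel count × `pixel_scale²` (µm²);
* **Feret diameters**: maximum and minimum caliper widths over the convex
  hull of the object's boundary contour;
* **aspect ratio** = max / min Feret;
* **solidity** = object pixel count / pixel count of the rasterized convex
  hull (≤ 1 exactly);
* **morphology number** MN = 2√Area · Solidity / (√π · Feret · AspectRatio),
  1 for a perfect circle, → 0 for a line;
* **size class**: discarded (< 95 µm²), dispersed (95–500 µm², lower bound
  inclusive), pellet (≥ 500 µm², inclusive), applied in physical units after
  pixel-scale conversion.

## Sub-pixel boundary treatment

Naive boundary representations bias caliper statistics by half a pixel per
edge, which is material for the MN of medium-sized objects. The boundary
contour used here is the *mid-crack* contour — the midpoints of pixel edges
separating object from background. For an axis-aligned digitized rectangle
this measures width, area and solidity exactly; for a digitized disk the
residual error is the ± half-pixel staircase oscillation. That oscillation is
zero-mean, so the implementation additionally smooths the contour with a
short circular moving average (window scaled to contour length, at most 9
points) before taking calipers and the hull. Smoothing is applied only when
the contour is star-shaped with respect to the centroid (checked via
nearest-neighbour gaps after angular ordering); otherwise the raw contour is
used. Two guard rails keep the estimates honest:

* the reported maximum Feret is clamped to within 0.45 px of the raw-contour
  value, so it never drifts more than half a pixel from the brute-force
  pairwise-distance oracle over the actual boundary points;
* the measured MN is capped at 1 — sub-pixel bias can push the raw formula
  marginally past the theoretical circle limit.

With these choices a digitized disk of radius 30 px measures MN ≥ 0.97
(within 3% of the ideal 1), which the test suite verifies across grid
phases, and a 40 × 20 px rectangle measures area 800, minimum Feret 20 and
solidity 1 exactly.

Degenerate objects (single pixels, minimum caliper 0) are kept in the object
table, flagged, and excluded from MN summaries. Per-condition summaries
(mean, median, quartiles of MN and diameter) pool pellets only; dispersed
and discarded structures are counted separately.

## What a green morphometrics test establishes

The synthetic image generator renders star-shaped objects — an ellipse whose
boundary radius is modulated by a fixed-frequency cosine plus seeded smooth
jitter — with analytic truth for area and calipers. It emulates the
geometry of pellet micrographs (bright solid objects, dark field, known
µm/px scale), not their photometric texture: no blur, no uneven
illumination, no touching pellets, no hyphal halo. Green tests therefore
establish correctness of segmentation and measurement on well-separated
solid objects, and accuracy of the geometry estimators against closed
forms; they do not establish robustness to the optical artefacts of real
stereomicroscopy.

# Phenotype statistics

* **Radial growth rate** = (radius at 120 h − radius at 72 h) / 2 days, in
  mm/day; shrinking colonies are rejected as measurement faults. Radii are
  the stored quantity; divide diameters by 2 on ingest.
* **Growth coefficient** for a stress condition is the ratio of
  mutant-to-progenitor rate ratios, stress over standard medium. It is 1
  when the mutant's stress penalty equals the progenitor's, > 1 when milder.
  It is scale-invariant and undefined when any rate is 0 — such conditions
  are recorded as missing rather than 0, because zeros would poison the
  regression.
* **Hyphal growth unit** = hyphal length / tip number (µm per tip), a proxy
  for branching frequency.
* **Protein titre** = total secreted protein (mg) / dry biomass (g).
* **Control comparisons** use the two-sided two-sample Student's *t*-test
  with equal-variance pooling (the procedure matching the screen's reported
  statistics), starred at 0.05/0.01/0.001. When both groups are constant the
  p-value is defined by continuity (1 for equal means, else 0). Tests are
  per biological replicate; replicates are averaged per condition before any
  regression.

# Titre regression

The design matrix has one row per strain × inducer condition (28 in the
default study) and one column per independent variable. The default
variable list has 11 entries — radial growth rate, six stress growth
coefficients, hyphal length, pellet diameter, aspect ratio and solidity —
giving 11 × 28 = 308 independent values; an extended 13-variable list adds
tip number and biomass dry weight. The 11-variable enumeration is the
default because it is the set consistent with the condition-level
observation count; the extended list is exposed for sensitivity analyses.
Conditions missing any value are dropped and logged.

Fitting is ordinary least squares with an always-included intercept,
two-sided t-distribution p-values (n − k − 1 df) and R² — standard
spreadsheet-regression output. Variables are used untransformed, so
coefficients are in raw units (mg/g per mm/day, per µm, per
growth-coefficient unit). Rank-deficient designs raise an error naming the
collinear columns rather than silently dropping them.

**Two-stage backward elimination**: the first fit removes, simultaneously,
every variable with p > 0.15; subsequent refits remove one variable at a
time — the largest p, ties broken by variable-list order for determinism —
while it exceeds 0.05. Batch removal in round 1 follows the screening
convention of discarding clearly uninformative variables at a permissive
threshold; one-at-a-time removal afterwards avoids over-pruning near the
decision boundary, since each removal changes the remaining p-values. The
procedure terminates with all retained p ≤ 0.05 or an intercept-only model
(with a warning), and the full trace (round, removals, threshold) is kept.
Exactly-interpolating fits have undefined p-values (zero residual
variance); these are treated as perfectly significant. No multiple-testing
correction is applied beyond the stated thresholds.

Predictions are linear: a `percent_change` shift in a retained variable away
from its control value moves the predicted titre by
coefficient × (percent_change/100) × control_value from the zero-change
baseline. Control values and baseline are explicit inputs — they are
measured quantities, not model constants. Observed-vs-predicted concordance
is reported as the squared Pearson correlation between observed titres and
model predictions.

# Synthetic phenotype generator

The generator draws one dataset with the study's design: for each
strain × dox condition every variable takes the control baseline times
`1 + U(−spread, spread)` (control strains sit exactly at baseline), each
replicate observes it with multiplicative noise `1 + N(0, replicate_cv)`,
and replicate titres follow the true linear model evaluated on the
replicate's observed values plus Gaussian noise. Because the response is
generated from the observed predictor values, condition means satisfy the
model exactly at zero noise and OLS is conditionally unbiased — both
properties are tested.

Defaults state one fixed world:

* four nonzero effects — growth rate +0.6592 mg/g per mm/day, heat-stress
  fitness +10.6824 per coefficient unit, cell-wall-stress fitness −13.4059,
  pellet diameter −0.0020 per µm — all other variables truly null;
* control baselines at the progenitor operating point: 10 mm/day growth,
  heat growth coefficient 1.1, cell-wall growth coefficient 0.8, pellet
  diameter 2000 µm, hyphal length 250 µm, aspect ratio 1.2, solidity 0.9,
  remaining stress coefficients 1; the intercept is solved so the control
  titre is 2.83 mg/g;
* mutant spread ±30% around baseline, matching the 10–30% hypothetical
  changes the prediction tables explore; replicate CV 5%;
* replicate noise s.d. 4.3 mg/g. Derivation: the four effects contribute a
  condition-level signal s.d. of ≈ 3.06 mg/g under ±30% uniform spread
  (per-variable contribution |β|·baseline·0.3/√3); a target condition-level
  R² of 0.6 requires noise s.d. ≈ 3.06·√(0.4/0.6) ≈ 2.5 at condition level,
  i.e. 2.5·√3 ≈ 4.3 per replicate with triplicates.

These defaults were chosen once, from the screen conditions the package
models, and are not tuned to test outcomes. Negative simulated titres are
possible in the tails (the linear model has no positivity constraint); they
are retained because the regression machinery is linear and unconstrained.

The selection-recovery experiment re-simulates many datasets and tabulates
retained variable sets. Its "strong effect / moderate noise" reference world
scales four true effects to unit condition-level signal s.d. each with unit
condition-level noise, giving per-variable t ≈ 5 at n = 28 — strong enough
to be retained almost always while null variables are retained at roughly
the nominal rate, so the modal retained-set size equals the number of true
effects.

# Pipeline

`run_pipeline()` executes simulate → measure → phenotypes → regress →
predict with a validated configuration (thresholds, dox grid, seeds,
elimination thresholds — defaults equal the screen's printed settings),
writing per-stage outputs and a manifest with config echo, seed, version and
per-stage row counts. When simulating, one image per condition is rendered
from that condition's pellet geometry (diameter → equivalent radius, aspect
ratio → elongation, solidity → boundary roughness via a fixed monotone map),
measured, and the *measured* pellet diameter/aspect/solidity replace the
simulated columns before regression — closing the loop between the imaging
and modelling branches and injecting realistic measurement error into the
pellet variables. Runs are byte-identical under a fixed seed; failures abort
with the stage name.

Images are written as portable graymaps (binary P5 at run time, ASCII P2
for text fixtures) because PGM round-trips 8-bit grayscale exactly and needs
no external imaging library; tables are CSV, models and manifests JSON.

# Numerical choices and degenerate inputs

* Otsu threshold on the 256-bin histogram; foreground is strictly greater
  than the threshold.
* 8-connectivity for objects (4-connectivity available); background
  hole-filling uses the dual 4-connectivity.
* Convex hulls via Andrew-monotone `chull`; minimum caliper width over hull
  edge normals (exact for convex polygons); maximum Feret as the hull
  diameter, equal to the maximum pairwise distance of the full point set.
* Empty images yield an empty result with a warning, not an error.
* Single-pixel objects: minimum Feret 0, MN undefined, flagged.
* Elimination ties broken by variable-list order; intercept never a removal
  candidate.
* All seeded code paths restore the caller's RNG state.

# Limitations

* The morphometrics branch assumes well-separated solid objects; touching
  pellets are not split (no watershed), and dispersed-mycelium
  skeletonization is out of scope.
* The regression is descriptive, not causal: retained variables are
  predictive under the linear model and the screen's design, nothing more.
* Aspect ratio is the literal caliper ratio; fitted-ellipse axes would give
  slightly different values for irregular objects.
* The generator's linear titre model and uniform spread are a stated world
  for validation, not a mechanistic fermentation model; dose–response along
  the inducer axis is not modelled.
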