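---
title: "Methods: spatial statistics of the T-cell microenvironment"
author: "spatialTME"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial statistics of the T-cell microenvironment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialTME)
```

This vignette documents the models, parameters and design choices behind
the package, and what the synthetic validation does and does not
establish about real tissue data.

## The data model

The unit of analysis is a per-cell table for one tissue sample: cell
positions in micrometers and one positivity flag per marker of a
20-marker multiplex immunofluorescence panel. Positivity calls are
consumed as given — marker calling belongs to the upstream segmentation
pipeline. Coordinates are translation- and rotation-invariant inputs; no
axis convention is imposed. Optional 0-255 intensities may accompany the
flags, and a threshold utility exists for synthetic data, but no default
analysis path gates on intensity.

## Phenotyping

Gating is a deterministic decision list evaluated in priority order
(first match wins). T cells are CD3+; cytotoxic T cells CD3+CD8+CD4-,
helpers CD3+CD4+CD8-. Within each arm the sublineage is the
highest-priority positive subset factor, FOXP3 > T-bet > GATA3 > RORgt >
BCL6 > CD56, so a FOXP3+T-bet+ cell is regulatory first — the
convention that regulatory identity dominates. Two choices deserve
mention:

* **CD4+CD8+ double positives** (and CD3+ double negatives) go to an
  `OTHER_T` lineage ("T-other"). Assigning them to either arm would
  double-count cells in the fraction denominator; keeping them separate
  preserves an exact partition of CD3+ cells, so subpopulation fractions
  always sum to 100%.
* **The taxonomy is configurable.** The full functional-subpopulation
  catalogue of the motivating study (45 functional T-cell classes) is
  not enumerated in print; the default rules reproduce every named
  subpopulation (Tc1/Tc2/Tc17/Tcreg/Tcf/Tc-NKT/Tc-other, the helper
  counterparts including Tfh, DC, NK), and rule sets are plain data
  frames the user can replace.

Fractions are percentages of CD3+ T cells; densities divide by the
tissue area — the 0.283 mm² disc of a 0.6 mm TMA core, the rectangle
area for synthetic sections, or the convex hull of all cells when no
area is known. Any ratio with a zero denominator (a sample without
T cells, an empty subpopulation) is *excluded* — flagged and reported as
missing, never NaN — and group statistics drop such samples per feature.

## Contact graph and interaction statistics

Two cells are in contact when their center distance is **≤ 8 μm**,
boundary inclusive. Contacts are unordered pairs; within-type contacts
(A, A) count once per cell pair. This makes the *(p)-normalized
interaction* — pair contacts over total immune contacts — a proper
distribution: summed over all unordered pairs it equals 1, a conserved
quantity the tests assert to 1e-9. The *normalized interaction* divides
pair contacts by the combined size `n_A + n_B` of the two subpopulations
(`n_A` for A = A). Tumor and endothelial cells are excluded from all
totals; the immune cell set is the T lineages plus DC and NK.

Enrichment over random background interactions is assessed with a
**label-permutation null**: subpopulation labels are shuffled across the
immune-cell positions, the geometry — and with it the overall random
contact rate per area — stays fixed, and the pair statistic is
recomputed each round. The p-value is `(1 + #{null ≥ obs}) / (1 +
n_perm)` (one-sided enrichment, add-one so p is never 0), with `z = (obs
− null mean)/null sd` as effect size; contacts per area is also reported
descriptively. Because the test statistic is a discrete count, ties make
the test slightly conservative: calibration simulations on
label-exchangeable cores (five subpopulations at 600 cells/mm² each,
n_perm = 1,000) give an empirical type-I error around 0.04 at nominal
0.05, inside the tolerated [0.03, 0.07] band. With a single
subpopulation the null is degenerate and a warning is raised.

The graph is built with a grid spatial index (bins of one contact
radius), so construction is subquadratic; its definition — and a
dedicated oracle test on every random instance — is the O(n²) all-pairs
rule, including the inclusive 8.0 boundary.

## T-cell nests

Nests are DBSCAN clusters of T-cell positions with **Eps = 40 μm** and
**MinPts = 27**, neighbor counts including the point itself (the
convention of the standard R implementations; a 27-cell accumulation is
a nest, a 26-cell one is not). Two deterministic conventions replace
DBSCAN's historical order-dependence: core points are clustered as
connected components of the core-core reachability graph, and a border
cell joins the cluster of its **smallest-index core neighbor**. Output
is therefore invariant to row order. A border cell adjacent to two
clusters is claimed by exactly one of them, so in rare adjacent-cluster
geometries a cluster can end up marginally smaller than MinPts — the
classic DBSCAN corner case, shared with the reference implementations.

Eps calibration mirrors practice: given cells annotated as nest /
non-nest, sensitivity (nest cells labeled in-nest) and specificity
(non-nest cells labeled noise) are computed per candidate Eps, and the
value minimizing |sensitivity − specificity| — the crossing point of the
two curves — is returned, ties to the smaller Eps. Note that DBSCAN
labelings are locally constant in Eps: on sparse backgrounds several
neighboring Eps values can yield identical partitions, and the tie rule
then walks to the smallest member of the plateau. The calibration tests
use backgrounds dense enough (250 cells/mm²) that adjacent grid values
are distinguishable.

## Tumor center and invasive margin

The tumor-stroma borderline is an open polyline with a declared tumor
side. Each cell gets a signed distance via nearest-segment projection
(the side is the sign of the cross product on the nearest segment; at
shared-vertex ties the segment with the larger perpendicular offset
wins, the more robust witness). Cells within **360 μm** of the line on
either side (boundary inclusive) are invasive margin (IM_TUMOR /
IM_STROMA by side); tumor-side cells beyond the band are tumor center
(CT); stroma-side cells beyond it are OUTSIDE. Cells exactly on the
line count as tumor-side. A degenerate borderline (all vertices
coincident) is an error.

For heterogeneity analysis, large sections are split into **k = 48**
spatially contiguous regions: k-means on cell coordinates under a fixed
seed, followed by capacity-balanced assignment to the fitted centers so
region cell counts differ by at most one.

## Cohort statistics

Group comparisons use **Welch's two-sided t-test** per feature — the
unequal-variance form is the safer default where only "t-test" is
specified — with log2 fold-changes of group means (finite only when both
means are positive) and **Benjamini-Hochberg** adjustment across the
plotted feature family (Bonferroni selectable). Significance is
two-sided α = 0.05.

Patient subgrouping re-implements X-shift in simplified form: the
density of each patient profile is the inverse mean distance to its
**K = 20** nearest neighbors (features z-scored first, since fractions
and interaction values differ in scale); each point links to the densest
point in its K-neighborhood that is denser than itself (exact ties break
to the smaller index, so coincident points form one cluster); points
with no denser neighbor are modes, and clusters are the ascent trees.
The Mahalanobis weighting and Kolmogorov-Smirnov-gap cluster merging of
the original are deliberately omitted. The practical consequence: a
Gaussian blob of ~100 points can carry more than one density mode at
K = 20, so blob benchmarks recover the planted cluster count exactly in
a stability window of larger K (40-60 for 3 × 100 points) and may split
— never mix — blobs below it. The elbow rule for K runs the clustering
over a grid, records cluster counts, and returns the K of maximum
discrete curvature `|y''| / (1 + y'²)^{3/2}` (central differences over
the grid; a plain second difference would always favor the steep head of
the curve rather than the flattening). A flat curve returns the smallest
K with a warning.

MSI-like discovery clusters the MSS arm on subpopulation fractions
(fractions only — checkpoint features are deliberately left out of the
distance) and flags the cluster whose raw-scale mean profile is nearest
(Euclidean) to the MSI arm's mean profile; ties to the smaller cluster
id, and a single-cluster result flags all-or-nothing with a warning.
Subgroup discovery by density ascent structurally requires the subgroup
to exceed K members — neighborhoods of subgroup points otherwise contain
denser majority points and the subgroup is absorbed. The validation
cohorts therefore use 600 MSS patients (8% MSI-like = 48 > 2·K),
mirroring the proportions of the motivating cohort (87 MSI-like among
1,039 MSS, about 4·K).

## The synthetic tissue generator

The generator is a first-class, tested module; it defines the study
conditions under which the pipeline is validated.

* **Geometry.** TMA cores are 300 μm-radius discs (0.6 mm format);
  large sections are rectangles with a borderline. Points are generated
  on a 10% enlarged region and clipped, so intensities are unbiased at
  the border.
* **Populations.** Each population is homogeneous Poisson at its
  planted density (cells/mm²). Presets: MSI plants 1,628 total T
  cells/mm² with a Tc1 (24%) / Th1 (15%)-dominant composition and
  elevated TIM-3/PD-1/CTLA-4 rates; MSS plants 1,028 cells/mm² with
  Treg/Th17/Th2-enriched composition; MSI_LIKE is the MSI configuration
  carried under an MSS group label.
* **Heterogeneity.** Patients differ: immune densities are jittered by
  a global lognormal infiltration factor (sdlog 0.6) and per-population
  lognormal factors (sdlog 0.25), chosen once to echo the large
  between-patient spread of the motivating cohort (1,628 ± 1,687).
  Mean-preserving (meanlog = −sdlog²/2). The ground-truth sidecar
  records the realized per-sample expected fractions; conditional on
  them, subpopulation counts are exactly multinomial, which is what the
  binomial-interval recovery tests exploit.
* **Attraction.** A pair (A, B, κ, σ) makes a Bernoulli(κ) subset of A
  cells each spawn one B offspring at an isotropic Gaussian(σ)
  displacement — a Neyman-Scott coupling that is exactly simulable (no
  MCMC) and directly controls contact enrichment. B's independent base
  intensity is reduced by κ·intensity(A), floored at zero, so B's total
  planted density is preserved. Composition-recovery experiments use a
  κ = 0 configuration because offspring coupling deliberately breaks
  the multinomial sampling the binomial check presumes; attraction
  recovery is tested through the interaction statistics instead.
* **Nests and regions.** Planted nests are uniform discs of extra
  cells. Large-section region factors scale densities per zone by
  thinning against the analytic region of each point.
* **Consistency.** Positivity flags are generated from the true
  subpopulation's defining markers, so `assignPhenotypes()` recovers the
  truth with accuracy 1 by construction — phenotyping errors are out of
  scope of the generator. Functional flags are independent Bernoulli
  draws at configured rates.

What the generator does **not** emulate: segmentation and
marker-calling errors, spillover between markers, anisotropic tissue
architecture, density gradients within a zone, cell-size variation
(contacts are center-based), and the full 45-class functional taxonomy.
Passing tests therefore certify the statistical machinery against its
own model assumptions, not the upstream imaging pipeline.

## Validation scales and numerical conventions

The test suite validates, at full scale on one CPU: oracle equivalence
of the contact graph (200 instances up to n = 2,000, inclusive-boundary
case planted), conservation of the p-normalized distribution (1e-9),
null calibration (500 replicates × 1,000 permutations), planted
Tc1-Th1 / Treg-Th17 attraction recovery (100 samples per preset),
DBSCAN oracle identity (200 configurations plus the 26/27-cell
controls), Eps-calibration recovery within one grid step, binomial
recovery of compositions and marker rates (200 cores), volcano direction
recovery and null-cohort FDR (100 + 100 cohorts of 30 + 30), MSI-like
recovery (50 cohorts, Jaccard ≥ 0.8 in ≥ 80%), and analytic zoning with
end-to-end tumor-center-only enrichment detection. Monte-Carlo checks of
expectation-level guarantees (the null-cohort FDR) allow two binomial
standard errors of simulation error, declared up front.

Conventions for degenerate inputs: thresholds and margins are boundary
inclusive; all tie-breaks (priority gating, border cells, crossing
point, elbow, cluster flagging) resolve deterministically toward the
smaller index or value and are stated in the function documentation;
zero-denominator ratios are excluded, never NaN; an expected synthetic
cell count above 10⁶ is refused by a resource guard.

## Known limitations

* The permutation null conditions on the observed label multiset and
  geometry; it tests label exchangeability, not any parametric contact
  model, and its discreteness makes it mildly conservative on sparse
  pairs.
* Without the merge refinement, KNN-density clustering over-segments at
  small K; cluster counts should be read together with the stability
  window, and subgroup discovery needs subgroups larger than K.
* Signed distance to an open polyline is ambiguous exactly at convex
  vertex bisectors; the larger-offset tie rule resolves this but
  cells lying precisely on a bisector beyond the endpoints inherit the
  side of the longer-reaching segment.
* Densities for large sections default to the convex hull of observed
  cells when no area is supplied, which underestimates sparse samples.
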