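# spatialTME

Spatial analysis of the T-cell microenvironment in multiplex
immunofluorescence tissue maps.

Multiplex immunofluorescence panels (CD3, CD8, CD4, FOXP3, T-bet, GATA3,
RORgt, BCL6, CD56, CD11c, panCK, CD31, plus checkpoint/functional markers
TIM-3, PD-1, CTLA-4, GranzymeB, Ki67, HLA-DR, CD27, CD45RA) produce one
row per segmented cell: coordinates in micrometers and a positivity flag
per marker. This package turns such per-cell tables into the immunology
readouts used to contrast microsatellite-instable (MSI) and -stable (MSS)
colorectal cancer:

* **Phenotyping** — deterministic marker gating into cytotoxic
  (CD3+CD8+CD4-) and helper (CD3+CD4+CD8-) T cells and their Type 1 /
  Type 2 / Type 17 / regulatory / follicular / NKT-like sublineages
  (priority FOXP3 > T-bet > GATA3 > RORgt > BCL6 > CD56), plus dendritic
  cells, NK cells, tumor and endothelium; per-sample subpopulation
  fractions (% of CD3+ cells), densities (cells/mm²) and
  functional-marker positive fractions.
* **Spatial interactions** — a contact graph joining cells whose centers
  are ≤ 8 μm apart; per subpopulation pair (A, B) the
  *(p)-normalized interaction* `contacts(A,B) / total immune contacts`
  and the *normalized interaction* `contacts(A,B) / (n_A + n_B)`, with
  enrichment tested against random background interactions via a
  label-permutation null on fixed cell positions:
  `p = (1 + #{null ≥ obs}) / (1 + n_perm)`.
* **T-cell nests** — DBSCAN on T-cell positions (Eps = 40 μm,
  MinPts = 27, self-inclusive neighbor counts) with sensitivity /
  specificity-crossing calibration of Eps against annotated
  accumulations.
* **Zoning** — signed distance to a tumor-stroma borderline; the
  invasive margin is the band extending 360 μm into the stroma and
  360 μm into the tumor; plus a balanced random split of large sections
  into 48 contiguous regions for heterogeneity analysis.
* **Cohort statistics** — per-feature Welch t-tests with
  Benjamini-Hochberg adjustment (volcano logic, two-sided α = 0.05,
  zero-denominator samples excluded per feature), and KNN-density
  (X-shift-style, K = 20) clustering of patient composition profiles to
  flag the *MSI-like* subgroup of MSS patients.
* **Synthetic tissue generator** — Poisson and parent-offspring
  (Neyman-Scott) point processes on TMA cores and bordered large
  sections, with MSI/MSS presets (planted total T densities 1,628 and
  1,028 cells/mm², Tc1/Th1- vs Treg/Th17-dominant compositions, planted
  Tc1-Th1 / Treg-Th17 attraction, checkpoint rates) and row-level ground
  truth, so every pipeline stage can be validated against known answers.

Note on marker names: the Th17/Tc17 transcription factor is written
`RORgt` (ASCII) throughout.

## Worked example

```r
library(spatialTME)

g <- generateSample(preset("MSI"), seed = 11, sampleId = "core01")
g$table
#> CellTable: 765 cells, 1 sample(s), 20 markers
#>   area: 0.2827 mm^2

asg  <- assignPhenotypes(g$table)
prof <- composition(g$table, asg)
round(prof[c("t_density", "frac_Tc1", "frac_Th1", "frac_Treg")], 1)
#>   t_density frac_Tc1 frac_Th1 frac_Treg
#> 1     912.5     26.4       14         7

graph <- buildContactGraph(g$table)   # 8-um contact rule
graph
#> ContactGraph: 765 cells, 210 contacts (threshold 8 um)

res <- interactionStatistics(graph, asg, nPerm = 1000, seed = 11)
subset(res, subpop_a == "Tc1" & subpop_b == "Th1")
#>    subpop_a subpop_b n_a n_b contacts p_normalized normalized  null_mean
#> 84      Tc1      Th1  68  36       17    0.3617021  0.1634615 0.02347115
#>       null_sd        z      p_perm excluded
#> 84 0.01496712 9.353196 0.000999001    FALSE

detectNests(g$table, asg)             # eps = 40 um, MinPts = 27
#> NestLabeling: 258 cells, 0 nest(s); eps = 40 um, MinPts = 27
```

This synthetic MSI core carries 765 cells (912 T cells/mm²; patient-level
density heterogeneity is part of the preset, so individual cores scatter
widely around the cohort mean of 1,628). The gated profile is
Tc1-dominant (26.4% of T cells). Of the 210 cell-cell contacts, 17 join
Tc1 with Th1 — 36% of all immune contacts, 9.4 standard deviations above
the permutation null (p ≈ 0.001): the planted Tc1-Th1 attraction is
recovered. At this density the T cells form no DBSCAN nest, matching a
core without planted accumulations.

The full synthetic cohort analysis (simulate → phenotype → contacts →
interactions → nests → zones → cohort volcano + clustering) runs with

```sh
Rscript inst/scripts/run_pipeline.R --out run1 --seed 1 --n-msi 8 --n-mss 8
```

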