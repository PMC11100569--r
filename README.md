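# gliospat

Spatial statistics for myeloid-cell organization in the tumor
microenvironment.

Multiplexed tissue imaging of glioblastoma (imaging mass cytometry and
similar, ~1 µm resolution) produces segmented, phenotyped single-cell
tables: centroid coordinates, a population label (microglia-like and
macrophage-like states, suppressive myeloid cells, tumor, vascular, ...),
and marker intensities per cell. Spot-level spatial transcriptomics of the
same disease adds hex-grid gene counts with deconvolved population
abundances. `gliospat` is for analysts who want to ask, quantitatively and
with a calibrated null: **which populations attract or avoid each other,
how strongly do they cluster, what microenvironment do they occupy, which
recurring myeloid niches exist, and do those niches matter for survival?**

## The core statistic

Everything interaction-related is referred to a **label-permutation null**:
cell positions stay fixed while population labels are reshuffled (default
300 draws per region), conserving each population's count. For a statistic
T computed on region r, the package reports

```
diff(r) = T_observed(r) − mean_k T(label permutation k of r)
```

so diff reads as enrichment (+) or depletion (−) relative to what geometry
and abundances alone predict. On this null the package offers mean
nearest-neighbour distances between populations, edge-endpoint interaction
proportions on 6-nearest-neighbour graphs, abundance-corrected clustering
coefficients of population subgraphs, and a cross-pair count at fixed
radius (default 20 µm) with an empirical add-one p-value. Group-level
tests are one-sample Wilcoxon signed-rank on per-region diffs
(edge vs core tissue separately) with Benjamini–Hochberg adjustment.

Around that core: Newman label assortativity; Rao's quadratic entropy
Q = Σᵢⱼ pᵢpⱼ d(i,j) over contact neighbourhoods; mean marker expression in
40-µm windows via exact summed-area tables; vascular/perivascular/
infiltrated distance classes (10-µm default boundary); nested linear mixed
models (cells ⊂ regions ⊂ cases) with Holm–Šídák contrast families;
hex-grid niche discovery by standardized k-means (k = 5) with
spot-connectivity matrices, non-myeloid marker-gene extraction (Wilcoxon,
P < 0.01, 1.5-fold), hypergeometric signature scoring; and univariate Cox
models of environment proportions (hazard ratios per percentage point,
Holm–Šídák, median-split Kaplan–Meier). Synthetic-tissue generators
(Thomas-process clustering, vascular skeletons, hypoxia/fibrinogen rasters,
planted niches, planted hazards) make every stage testable without any
external data.

## Worked example

```r
library(gliospat)

# one synthetic core region: Thomas-clustered myeloid populations,
# vessel-tropic suppressive cells, CSR tumor cells, vascular skeleton
sim <- simulate_region(region_id = "core_01", region_class = "core", seed = 7)
sim$cells
#> cell_table: 1293 cells, 1 regions, 5 populations, 5 markers

de <- distance_enrichment(sim$cells, "core_01", n_perm = 300, seed = 7)
round(de$diff, 1)
#>             Mg TAM-Mac TAM-Supp Tumor Vascular
#> Mg       -14.4    83.9     62.4   3.6    100.6
#> TAM-Mac   68.2   -13.9     53.7   0.8     88.5
#> TAM-Supp  52.3    65.0    -13.1   1.2    -10.3
#> Tumor     69.6    72.6     80.1   2.5    118.8
#> Vascular  50.7    52.9    -21.2   2.8    -30.4
```

Negative diagonal entries: every myeloid population sits 13–30 µm closer
to itself than a random labeling predicts (homotypic clustering). The
TAM-Supp row/column shows the planted vessel tropism — suppressive cells
are ~10–21 µm closer to vascular cells than chance.

```r
g  <- build_graph(sim$cells, "core_01", k = 6)
cc <- corrected_clustering(sim$cells, "core_01", graph = g,
                           n_perm = 300, seed = 7)
cc[c("population", "observed", "expected", "corrected")]
#>   population  observed   expected corrected
#> 1         Mg 0.6139821 0.25412059 0.3598615
#> 2    TAM-Mac 0.5660827 0.29565483 0.2704279
#> 3   TAM-Supp 0.2961631 0.10607594 0.1900871
#> 4      Tumor 0.5095548 0.45622867 0.0533261
#> 5   Vascular 0.3673077 0.06389744 0.3034103

label_assortativity(g)
#> [1] 0.4236129
```

After abundance correction the clustered populations keep corrected
coefficients of 0.19–0.36, while the CSR-placed tumor cells fall to ~0.05:
their apparent clustering was abundance alone.

```r
vc <- vascular_classes(sim$cells, "core_01", "Vascular", far_um = 10)
round(attr(vc, "infiltration_rate"), 2)
#>       Mg  TAM-Mac TAM-Supp    Tumor
#>     1.00     0.99     0.76     0.98
```

Only 76% of TAM-Supp cells are fully infiltrated (> 10 µm from the nearest
vessel); the rest sit on or around vessels, again reflecting the planted
tropism.

```r
cohort <- simulate_cohort(n = 400, betas = c(0.05, 0, 0, 0, 0), seed = 7)
sa <- survival_association(cohort)
sa[c("environment", "coef", "hr", "p_adj", "km_p")]
#>   environment         coef        hr      p_adj         km_p
#> 1       env_1  0.045773688 1.0468375 0.00000000 1.139896e-17
#> 2       env_2 -0.006521809 0.9934994 0.10357398 9.706649e-01
#> 3       env_3 -0.007738759 0.9922911 0.09643353 9.394599e-02
#> 4       env_4 -0.010703801 0.9893533 0.01338756 3.991045e-04
#> 5       env_5 -0.007295542 0.9927310 0.10357398 5.138792e-01
```

The planted hazard (+0.05 log-HR per percentage point of environment 1) is
recovered at 0.0458 — an estimated 4.7% extra risk of death per percentage
point, with the median-split Kaplan–Meier log-rank agreeing. The small
negative coefficients on the null environments are the compositional
shadow of the real effect: proportions sum to one, so abundance of a
harmful environment depresses the others.

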