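# soilnet

Analysis pipeline for replicated fertilizer field trials that profile soil
bacterial communities (16S amplicon feature tables) together with soil
chemistry and crop traits. The scientific question it serves: how do
long-term fertilizer regimes (N, P, K, compost) restructure the soil
bacterial community, which chemical factors and key taxa organize that
structure, and which taxa track the crop's cultivation stages?

The pipeline works on a trial of six plots (0, PK, NK, NP, NPK, C) sampled
at five cultivation stages (B, A, F, R, H) with four replicate soil batches
each. Its stages, each exposed as package functions:

- **Preprocessing** — relative frequencies per replicate, per-cell medians
  over batches, removal of absent taxa, per-feature z-scaling across the
  30 plot-stage cells; replicate coefficients of variation as a
  reproducibility summary.
- **Alpha diversity** — rarefaction to a common depth with a
  rarefaction-slope coverage diagnostic, Shannon *H′* (nats), per-plot
  Tukey–Kramer letters, pooled *H′*.
- **Ordination** — PCA of the standardized community; chemical vectors
  fitted to the PC1–PC2 plane (permutation *r²* test); the *load quantity*
  contributor score on PC3, `LQ3_i = √l₃ · h₃ᵢ`, z-standardized with
  contributors flagged at |z-LQ3| > 2.33 and compared against crop traits.
- **Clustering** — complete-linkage clustering of taxa into three
  fertilizer-linked clusters (cutree at k = 3) with semantic labels
  (N-linked / plain / compost-linked) and pooled cluster–trait
  correlations.
- **Co-occurrence network** — edges at |Pearson r| > 0.6 over the 30
  cells; greedy degree-ordered extraction of complete-graph *centers*;
  Guimerà-style cartography: within-group degree z (> 1.96 → intragroup
  hub), participation coefficient `P = 1 − Σ (κₛ/k)²` (> 0.5 → intergroup
  hub), betweenness z (> 2.24 → network hub); per-plot/per-stage network
  comparisons.
- **Temporal dynamics** — stage-to-stage frequency differences
  `Δf_xpn = f_xpn − f_xp(n−1)`, their ordination with a PERMANOVA of the
  ripening transition, and selection of stage-associated taxa (positive
  median Δf in all six plots plus a t-test at p < 0.05).
- **Statistics** — self-contained PERMANOVA (Anderson-style pseudo-F from
  pairwise Euclidean distances, label permutation), Tukey–Kramer with a
  compact letter display, variance-gated (F-test) Student/Welch t-tests,
  and correlation tests.

A synthetic field-trial generator (`generate_study()`) draws ground-truthed
studies — 870 taxa in planted clusters of 340/234/296, phosphate-linked
contributor taxa, ripening/flowering-associated taxa, planted pH/TOC
contrasts, replicate noise calibrated to the trial's observed CVs — so the
whole pipeline is testable end-to-end without any downloads.

## Worked example

```r
library(soilnet)
res <- run_pipeline(pipeline_config(seed = 1))
print(res)
#> pipeline_result: 870 taxa retained; clusters 340/234/296; 135155 edges; centers 266/220/218
res$cluster_labels
#>   cluster          label size
#> 1       1       N-linked  340
#> 2       2          plain  234
#> 3       3 compost-linked  296
res$alpha
#> alpha_result: depth 18840 ; pooled H' 6.163
#>  plot   mean_h       sd_h letters
#>     0 5.905954 0.05070274      ab
#>    PK 5.865263 0.03980317      bc
#>    NK 5.926229 0.02421881      ab
#>    NP 5.797666 0.03350594      cd
#>   NPK 5.775622 0.04641396       d
#>     C 5.941900 0.02328834       a
res$stage_taxa
#> stage_taxa (mode replicate , alpha 0.05 ):
#>   A : 5 taxa
#>   F : 5 taxa
#>   R : 10 taxa
#>   H : 0 taxa
```

Reading this: the planted fertilizer clusters are recovered at their exact
sizes (340/234/296) and labeled by the plot group where their members are
most frequent; the co-occurrence network over the 884 features has three
complete-graph centers larger than 5% of the nodes (the largest, 266
nodes, becomes cartography group 0); rarefied Shannon diversity separates
the compost plot (letter `a`) from the nitrogen-fertilized plots; and the
ripening transition selects 10 taxa, which include all 9 planted
ripening-associated taxa (`res$truth$stage_assoc`). The PC3 contributor
table is in `res$load_quantity$table` (18 positive and 9 negative
contributors at the 2.33 cutoff for this seed) and hub classes in
`res$topology`.

The same pipeline runs as a narrative workflow in `analysis/01_simulate.R`
… `analysis/07_temporal.R`; each stage reads its predecessor's files and
writes its tables under `results/`.

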