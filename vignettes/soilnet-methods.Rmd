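---
title: "Methods: fertilizer-driven soil community structure, networks and dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fertilizer-driven soil community structure, networks and dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The study design soilnet analyses

soilnet implements the analysis pipeline of a replicated fertilizer field
trial: six plots under fixed fertilizer regimes (unfertilized `0`, `PK`,
`NK`, `NP`, `NPK`, and compost `C`), sampled at five cultivation stages
(before fertilization `B`, after fertilization `A`, flowering `F`, ripening
`R`, post-harvest `H`), with four replicate soil batches per plot-stage
cell. Each sample carries a 16S amplicon feature table (taxon read counts)
and fourteen soil chemical measurements (TOC, NO3, NH4, Na, Cl, SO4,
soluble and exchangeable K/Ca/Mg, available PO4, pH). Plot-level plant
traits (heights at two dates, stem/leaf and seed yields) connect the
community to the crop.

All downstream analyses run on a features x 30 plot-stage matrix obtained
by (i) converting taxon counts to relative frequencies per replicate
sample, (ii) taking the median of the available replicates per cell (the
even-count median is the mean of the two central values; a lost sample
simply leaves three replicates — no imputation), (iii) removing taxa that
are zero in all 30 cells, and (iv) z-scaling every feature row across the
cells (sample sd, n-1). Relative frequencies are computed *before* median
aggregation so that medians stay in [0, 1]. Standardization is per feature,
so scaling taxa and chemicals jointly or separately is identical; constant
rows cannot be scaled and are dropped with a warning.

# Core quantities

**Alpha diversity.** Shannon `H' = -sum p_i ln p_i` in nats. Communities
are rarefied (sampling without replacement) to a common depth, by default
the minimum cell total; "coverage-based" is operationalized as a
rarefaction-slope diagnostic: the expected-richness increment
`E[S_d] - E[S_{d-1}]` at the chosen depth must not exceed 0.01 taxa/read,
and violators are reported rather than dropped. Expected richness uses the
exact hypergeometric form with log-gamma terms for stability. One
rarefaction draw per cell is taken under a recorded seed (`n_draws`
averages over more). Per-plot means over the five stages are compared by
Tukey-Kramer with a compact letter display; the pooled `H'` of all six
plots combined is reported alongside. Whether `H'` should be computed on
replicate-level or median-cell counts is not fixed by the design; the
median-cell default was chosen because every other stage of the pipeline
runs on the median matrix.

**Ordination and load quantity.** PCA is computed by SVD of the centered
30 x p matrix (observations are cells); eigenvalues are `d_k^2/(n-1)` and
eigenvector signs are fixed so each axis's largest-magnitude loading is
positive, making runs platform-reproducible. The contributor score of
taxon *i* on axis *a* is the load quantity `LQ_i = sqrt(l_a) h_{ai}`;
z-LQ standardizes LQ over taxa and taxa with `|z-LQ| > 2.33` are flagged as
contributors. The "share of the cumulative contribution" of the flagged set
is reported both as `sum |LQ|` and `sum LQ^2` shares, since the denominator
convention is not uniquely determined. Because the sign of a principal axis
is arbitrary, the axis is oriented so its score correlation with seed yield
is positive before labeling contributors positive/negative; the flags
themselves are sign-invariant. Chemical vectors are projected onto a score
plane by least squares: direction = normalized coefficients, `r^2 = 1 -
RSS/TSS`, and `p = (1 + #\{r^2_perm >= r^2\})/(1 + n_perm)` under
permutation of the chemical (999 permutations by default).

**Clustering.** Taxa are clustered by complete-linkage agglomeration on
Euclidean distances between standardized 30-cell profiles and cut at
k = 3. Cluster ids are numbered by first appearance in the input order and
then labeled semantically by the plot group (nitrogen = NK/NP/NPK,
plain = 0/PK, compost = C) with the highest mean standardized frequency
over the cluster's members; ties break toward the order N < plain <
compost with a warning. The pooled cluster-trait correlation correlates
all (member taxon, cell) values against the plot's seed yield — this
pooling convention is used because it is the only one yielding the very
large degrees of freedom implied by the reported significance levels; a
`collapse_stages` switch provides the per-plot alternative.

**Co-occurrence network.** Nodes are the 870 retained taxa plus the 14
chemicals; an edge joins two features when their Pearson correlation over
the 30 cells exceeds 0.6 in absolute value, strictly — a pair at exactly
0.6 gets no edge. Centralities (degree, betweenness, closeness, average
path length) are computed on the unweighted graph: edge weights derived
from correlations are ill-defined for negative r, and a `1 - |r|` weighting
is available only as a sensitivity option in `node_centralities()`'s
underlying igraph calls. Closeness and mean path length are computed within
components over connected pairs.

**Center extraction.** The network "center" is found greedily: sort the
candidate nodes by their degree within the candidate set (ties by node
id), keep the largest n whose n-th node has within-candidate degree at
least n-1, recompute degrees, and repeat; when n stops shrinking every
kept node has degree n-1, i.e. the kept set induces a complete graph.
Degrees are recomputed each round because that is the only reading under
which the procedure's stated termination condition (all kept nodes of
degree n-1) is guaranteed. Further centers come from removing the
extracted set and rerunning; only sets larger than 5% of the node count
are reported, and since the greedy pass is not monotone in size, centers
are reported largest-first (group 0 is defined as the largest). The
procedure is a heuristic: on dense Erdos-Renyi graphs G(12, 0.5) it
returns the true maximum clique in roughly half of the draws (and never a
larger, incomplete, or overlapping set).

**Cartography.** Group 0 is the largest center; groups 1-3 are the taxon
clusters minus group 0; chemicals outside the center form group `chem`.
For every node, the within-group degree kappa (edges to its own group) is
z-standardized within its group, and the participation coefficient is
`P = 1 - sum_s (kappa_s/k)^2` over the five groups. Hubs: betweenness
z-score > 2.24 (network hub), within-group degree z > 1.96 (intragroup),
P > 0.5 (intergroup); all comparisons strict, and a node can be intra- and
intergroup at once. Both z-scores use the population sd (isolates
included) so that thresholds match standard-normal quantiles on the full
node set.

**Temporal dynamics.** For taxon x, plot p and stage n the difference is
`delta-f_xpn = f_xpn - f_xp(n-1)` over the four transitions B-A, A-F, F-R,
R-H; the four transitions telescope to `f(H) - f(B)` by construction. The
24 (plot, transition) delta-f profiles are ordinated by the same PCA, and
the ripening transition is tested against the others by PERMANOVA. A taxon
is stage-associated when its median delta-f is positive in all six plots at
that transition *and* a two-sided one-sample t-test rejects zero at 0.05.
The test pools the 6 plots x 4 batches = 24 replicate-level differences
(batches paired by index within plot — a labeling convention, since
batches are independent soil samples; `mode = "median"` tests the six plot
medians instead). Two-sided testing is used even though the positivity
screen fixes the direction, making the selection conservative.

**Statistics.** PERMANOVA partitions pairwise squared Euclidean distances:
`SS_total = (1/N) sum_{i<j} d_ij^2`, within-group sums analogously per
group, pseudo-F = `(SS_B/(a-1))/(SS_W/(N-a))`, p by label permutation
(999 by default; the permutation count is configurable since the smallest
reportable p is `1/(n_perm+1)`). Tukey-Kramer uses the studentized range
distribution with the unequal-n correction and builds its compact letter
display from maximal cliques of the non-significance graph, lettered by
descending group mean — a valid clique cover by construction. Two-sample
comparisons are gated by the variance-ratio F-test at 0.05: pooled Student
when the gate does not reject, Welch-Satterthwaite otherwise, with both
sub-results retained. Correlation tests use `t = r sqrt((n-2)/(1-r^2))`.

# The synthetic field-trial generator

`generate_study()` draws ground-truthed studies with the statistical
structure the pipeline assumes, so that every stage can be validated
end-to-end without external data.

*Count model.* Each taxon has a baseline log-abundance `mu_x ~ N(0, 1)`
(`base_log_sd`). Sample rates are `exp(mu_x + shifts + eps)` with
replicate log-noise `eps ~ N(0, 0.45)` (`taxa_log_sd`); counts are Poisson
at a per-sample library size drawn from N(26,851, 6,974). The replicate
noise and the per-chemical CVs were calibrated once so the averaged
replicate coefficients of variation land near 0.26 (chemistry) and 0.59
(taxa), the trial's observed reproducibility.

*Planted structure.* The 870 taxa split into three clusters of 340, 234
and 296 members whose log-rates rise by `effect_size` (1.5, in units of
the cross-taxon log-abundance sd) in their favored plot group (N / plain /
compost). The cross-taxon reading of "1.5 sd" was chosen over the
replicate-noise reading because the latter leaves the planted clusters
marginal: relative-frequency closure couples the clusters (a bloom in one
group depresses everything else there), and complete linkage then
intermittently merges the plain and compost clusters. 27 trait-linked taxa
(17 up, 10 down) shift by `trait_effect = 3.0` replicate-noise sd (about
1.35 log units, jittered per taxon by U(0.85, 1.15)) in the
phosphate-fertilized plots PK/NP/NPK, on top of a weak diffuse phosphate
response (sd 0.3 noise units) carried by the rest of the community. The
diffuse term reflects how real communities respond as a continuum — the
flagged contributors are its strong tail — and it keeps the strong
responders from forming a coherent block that complete linkage would
otherwise split off as a spurious fourth cluster. Nine ripening-associated
taxa gain 1.2 log units from stage R onward and three flowering taxa at
stage F only; 1.2 was chosen so the all-six-plots positivity screen is
satisfiable at the trial's noise level. Special taxa have their baselines
floored at the community mean so their signal is not drowned by count
noise.

*Chemistry and traits.* Chemicals are homoscedastic normal around
plot/stage means: pH is 0.6 units lower under nitrogen, TOC 7 g/kg higher
in NP/NPK/C, nitrate spikes after fertilization in N plots and decays with
crop growth, sulfate peaks 1.7-fold at flowering in N plots, exchangeable
K is high where K or compost is applied, and NH4/aPO4 sit near their
detection limits with CVs near 1. Traits are deterministic in the
phosphate flag plus noise.

*What the generator does not emulate.* Sequencing error and chimeras,
compositional artifacts beyond closure, plot-specific taxa (every
synthetic taxon is detectable everywhere, so plot-specificity counts are
exercised only by constructed fixtures), taxonomic realism (lineages are
synthetic labels), spatial autocorrelation, and weather covariates.
Passing recovery tests therefore show that the pipeline detects the
planted effects at realistic noise, not that it would reproduce any
particular field result.

# Problem sizes and numerical choices

The validation suite runs the full 870-taxon study once (about 10 s) and
uses 120-300-taxon studies for replicated null simulations; statistical
calibration uses 1,000 Gaussian-null replicates with 99 permutations each;
exhaustive graph oracles run on graphs of at most 12-15 nodes where
betweenness and maximum cliques can be enumerated. Tolerances: PCA
orthonormality and variance conservation at 1e-8, standardization at 1e-9,
telescoping at 1e-15, exact oracle agreement at 1e-10. Ties in
agglomeration follow `stats::hclust`; ties in the greedy center ordering
break lexicographically by node id; the compact-letter ordering breaks
mean ties lexicographically.

# Known limitations

Per-plot and per-stage networks rest on correlations over only 5-6 cells
and are low-power screens; the default keeps the global 0.6 threshold
there. The greedy center extraction is a heuristic with no optimality
guarantee (see above). The pooled cluster-trait correlation treats
taxon-cell pairs as independent, which they are not; its p-values are
anti-conservative and should be read as descriptive. With only six plots,
per-taxon trait correlations have four degrees of freedom, so the
contributor-vs-others comparisons are informative only in aggregate.
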