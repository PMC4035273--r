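# metadiverge

Comparative metabolomics asks how much of a tissue's metabolome has
changed on each branch of a species tree, and whether some lineage —
in particular the human one — has changed more than its branch length
predicts. `metadiverge` implements the full analysis for a four-species
(human, chimpanzee, rhesus macaque, mouse), five-tissue (PFC, V1, CBC,
kidney, skeletal muscle) mass-spectrometry design:

* multistep LC-MS and GC-MS peak filtering with PCA outlier removal and
  per-criterion bookkeeping;
* log2 + within-tissue quantile normalization and exclusion of
  postmortem-delay-affected peaks (top/bottom 5% of the delayed-vs-control
  difference distribution, per tissue);
* per-peak permutation ANOVA (sequential model: tissue, species, sex,
  age, RIN, tissue:species) with permutation p values and a permutation
  FDR (q value) estimated from within-design label permutations —
  significance means p < 0.01 with q < 0.05;
* species-specific classification per tissue category (the five tissues
  plus the composite categories cortex = PFC+V1 and brain = PFC+V1+CBC),
  testing each lineage against its comparison species, with a
  multi-tissue exclusion rule for the per-tissue "unique" analysis;
* regression of per-lineage divergence proportions on phylogenetic branch
  lengths (MY) over the 21 nonhuman points, with per-tissue
  human/chimpanzee fold excess and a one-sided excess test for the human
  points;
* complete-linkage clustering of cross-tissue concentration profiles with
  a silhouette-chosen cluster count, small-cluster dropping and tissue
  specificity labels;
* accurate-mass adduct annotation ([M+H], [M+NH4], [M+Na] positive;
  [M−H], [M+FA−H] negative; 5 ppm), hypergeometric + resampling pathway
  enrichment, environment-effect detection, quantile-rule classification
  of tissue-/species-specific enzyme expression, metabolite–enzyme
  agreement tests, and functional-unit grouping of enriched pathways;
* a synthetic-data generator emulating the whole study design (pooled QC
  samples, postmortem-delayed and environment-condition macaques,
  detection-limit censoring) with a planted-effects truth ledger, so
  every stage is testable without any data download.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` for the divergence fit and the
silhouette curve.

## Worked example

Simulate a study with the default design (4 species x 5 tissues x 14
individuals; human lineage accelerated 4x in PFC and 8x in muscle),
normalize, gate with the primate permutation ANOVA, classify
species-specific peaks, and regress divergence on branch length:

```r
library(metadiverge)

sim  <- simulate_metabolome(sim_config(n_peaks = 1200, seed = 7))
norm <- normalize_peaks(sim$mset)

pf_sp  <- permutation_fdr(norm, "species",        mode = "primates",
                          n_perm = 200, seed = 11)
pf_int <- permutation_fdr(norm, "tissue:species", mode = "primates",
                          n_perm = 200, seed = 12)
gate <- gate_peaks(pf_sp, pf_int)

cl  <- classify_species_specific(norm, gate_primate = gate,
                                 lineages = c("human", "chimp", "macaque_anc"),
                                 n_perm = 200, seed = 13)
fit <- divergence_regression(cl,
         tested = cl$families[, c("tissue", "lineage", "n_tested")])

fit$human[fit$human$tissue %in% c("muscle", "PFC", "kidney"),
          c("tissue", "human_proportion", "chimp_proportion",
            "fold_vs_chimp", "p_excess")]
```

prints

```
# A tibble: 3 × 5
  tissue human_proportion chimp_proportion fold_vs_chimp   p_excess
  <chr>             <dbl>            <dbl>         <dbl>      <dbl>
1 kidney           0.0394           0.0263          1.5  0.330
2 muscle           0.255            0.0356          7.16 0.00000264
3 PFC              0.118            0.0300          3.94 0.00449
```

25% of tested peaks diverge on the human lineage in muscle against 3.6%
on the chimpanzee lineage — a 7.2-fold excess, far above the nonhuman
regression's prediction for a 6.5 MY branch (one-sided p ≈ 3e-6) —
while kidney sits on the line (fold 1.5, p = 0.33). The planted truth
(`sim$truth`) lets you verify the calls peak by peak;
`autoplot(fit)` draws the divergence-vs-branch-length figure.

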