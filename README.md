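# lncluster

Tumor cohorts can be stratified by the expression of their long non-coding
RNAs (lncRNAs) alone: lncRNA expression is strongly tissue- and
subtype-specific, and clusters found in lncRNA space line up with DNA
methylation, mutation patterns, viral infection status, and survival.
`lncluster` implements that analysis as a reusable, fully tested R pipeline
for anyone working with RPKM-like expression matrices of tumor cohorts
(e.g., head and neck squamous cell carcinoma, where an HPV-infected subgroup
carries a distinctive lncRNA landscape):

1. **Feature selection** — keep detectable lncRNAs (mean RPKM >= 0.3) and the
   top-k (default 500) most variable ones on the log2(RPKM + 1) scale.
2. **Consensus clustering** — repeatedly subsample 80% of the samples,
   partition each subsample with k-medoids (PAM) on Euclidean distance, and
   accumulate, for each k in 2..6, the consensus matrix
   `M_k(i, j) = C(i, j) / N(i, j)` (co-clustering over co-sampling counts).
   The number of clusters is chosen by the **proportion of ambiguous
   clustering**: `PAC_k = P(lower < M_k(i,j) < upper)` over sample pairs,
   with the standard window (0.1, 0.9); the smallest k within tolerance
   (0.01) of the minimum PAC wins. Final labels come from complete-linkage
   clustering of `1 - M_k`.
3. **Guilt-by-association (GBA)** — for each cluster, a binary template over
   the samples selects *surrogate lncRNAs* (Pearson r > 0.3 vs the template,
   p < 1e-6, mean cluster RPKM >= 0.1, overexpressed vs normal tissue at
   BH-corrected Welch-t p < 0.05); protein-coding genes correlated with the
   cluster's mean surrogate profile (|r| > 0.3, p < 1e-9) are reported as
   directly (up) or inversely (down) associated, and annotated by
   hypergeometric gene-set over-representation against a GMT collection.
4. **Clinical association** — chi-square (global) and Fisher-exact
   (per-cluster, with odds ratios and direction calls) tests of cluster
   versus categorical covariates; Welch t for continuous ones.
5. **Survival** — Kaplan-Meier curves per cluster and the k-sample log-rank
   test, for any number of endpoints, with optional administrative
   censoring at a horizon (e.g., 5 years).

A synthetic cohort generator (`simulate_cohort()`) plants known clusters,
marker lncRNAs, co-expressed PCGs, covariates and survival hazards, so the
whole pipeline is testable end to end without access to controlled data.
Real matrices (e.g., TCGA/TANRIC exports) drop in as TSV files.

## Worked example

```r
library(lncluster)

cohort <- simulate_cohort(simulation_config(seed = 7))
cohort
#> synthetic_cohort: 200 tumors in 5 planted clusters, 20 normals
#> expr_matrix: 3000 genes x 220 samples (1000 lncRNA, 2000 PCG; 200 tumor, 20 normal)

lnc <- expr_subset(cohort$expression,
                   genes = which(cohort$expression$gene_class == "lncRNA"),
                   samples = which(cohort$expression$sample_role == "tumor"))
sel <- top_variable(filter_detectable(lnc, 0.3), 300)
fit <- consensus_cluster(log2p1(sel),
                         params = consensus_params(n_resamples = 250, seed = 7))
fit
#> Consensus clustering fit
#>   items: 200, k range: 2..6, resamples per k: 250
#>   PAC by k: k=2: 0.913, k=3: 0.753, k=4: 0.379, k=5: 0.000, k=6: 0.078
#>   selected k = 5 (tolerance 0.01)
#>   cluster sizes: 40, 40, 40, 40, 40
```

PAC drops to 0 at the planted k = 5 (every sample pair is either always or
never co-clustered) and rises again at k = 6; the selection rule prefers the
smaller k. The recovered labels match the planted ones exactly:

```r
compare_partitions(fit$labels, cohort$truth_labels)   # adjusted Rand index
#> [1] 1
```

Downstream stages run from the fit:

```r
gba <- gba_analysis(cohort$expression, fit$labels)
gba
#> Guilt-by-association result:
#>   cluster1: 30 surrogate lncRNA(s), 40 up-PCG(s), 40 down-PCG(s)
#>   ...
#>   cluster5: 30 surrogate lncRNA(s), 40 up-PCG(s), 40 down-PCG(s)

cluster_survival(fit$labels, cohort$clinical, "os", horizon = 60)
#> Survival by cluster, endpoint 'os' (censored at 60)
#>   log-rank: chi-square = 32.04, df = 4, p = 1.881e-06
#>   group sizes: 40, 40, 40, 40, 40

idx <- match(names(fit$labels), cohort$clinical$sample_id)
cluster_feature_association(fit$labels, cohort$clinical$hpv[idx])
#> Global: chi_square: statistic = 92.82, df = 4, p = 3.308e-19
#> Per-cluster calls at alpha = 0.05:
#>  cluster    level  odds_ratio      p_value  direction
#>        5 positive 42.42857143 5.153048e-19   enriched
#>        ...
```

The generator plants all 30 markers per cluster (recovered above as the 30
surrogates), 40 up- and 40 down-PCGs (recovered 39-40), an HPV-enriched
cluster (recovered with OR = 42 in cluster 5), and a low-hazard cluster
(driving the log-rank separation). `run_full()` chains all stages from one
config and writes per-stage TSVs plus a JSON manifest; see
`vignette` source `vignettes/lncluster-methods.Rmd` for the modelling
details and design choices.

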