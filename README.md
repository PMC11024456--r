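# metadiet

Multi-marker DNA-metabarcoding diet analysis for small herbivores, built as
a tidyverse-native R package. It covers the full post-demultiplexing
workflow used in faecal-diet studies of cyclic vole populations:

1. **Replicate QC** — PCR replicates are screened by comparing each
   replicate's Euclidean distance to its own sample's mean profile (*dw*)
   against the distribution of distances between sample means (*db*);
   replicates beyond the intersection of the two distributions are removed
   iteratively until a fixpoint, then survivors are averaged with equal
   weight.
2. **MOTU filtering** — global filters (sequences < 10 bp or ≤ 10 reads
   dataset-wide), the per-sample 1 % tag-jump filter, restriction of each
   marker to its taxonomic scope, and advisory screening of PCR controls.
3. **Marker fusion** — the broad eukaryote (18S) marker provides per-sample
   dietary-category proportions (plants, bryophytes, arthropods, lichens,
   mushrooms); each category's mass is distributed over the taxa resolved by
   the specialized marker in proportion to their within-marker relative
   read abundance (RRA). Fused rows sum to 1 and conserve category mass.
4. **Diet metrics** — RRA, weighted percent of occurrence
   (wPOO: each occurrence weighted by 1/k for a sample with k occurring
   taxa, averaged over samples), Hill diversity
   ^qD = (Σᵢ pᵢ^q)^{1/(1−q)} with the analytic limit
   ^1D = exp(−Σᵢ pᵢ ln pᵢ), and functional-group/taxon aggregations.
5. **Composition statistics** — Hellinger transform (√RRA), PERMANOVA with
   sequential sums of squares and permutation p-values, PCA and (partial)
   RDA with adjusted R², and a permutation ANOVA for scalar responses such
   as diversity ~ phase × season.
6. **A study simulator** — Dirichlet-multinomial replicate counts with
   known per-sample diet truths, tag jumps, spiked outlier replicates,
   failed PCRs, marker scopes/biases and PCR controls, so every stage's
   operating characteristics are measurable.

Every user-facing function takes a data frame first and returns a tibble;
fitted objects have `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
graphics.

## Worked example

Simulate a bank-vole study, run the QC and the full pipeline core, and test
composition against the population-cycle design:

```r
library(metadiet)

cfg <- sim_config(species = "bank", n_per_cell = 10, seed = 2017)
sim <- simulate_study(cfg)

qc <- filter_replicates_iterative(filter_global(sim$tables$sper01, sim$records))
qc$report
#> <qc_report> 3 iteration(s) (converged); 8 replicate(s) removed, 0 failed, 1 sample(s) dropped
```

Eight of 120 plant-marker replicates fell outside the dw/db threshold
(the simulator spiked ~2 % of replicates with another sample's diet), and
one sample lost all its replicates. Fusing all five markers and testing:

```r
res <- process_study(sim$tables, sim$records, sim$metadata)
hill_diversity(res$fused, q = 1) |> head(3)
#>   sample_id     q diversity
#> 1 bank_001      1      5.90
#> 2 bank_002      1      8.23
#> 3 bank_003      1      9.44

hel <- hellinger(res$fused)
md  <- sim$metadata[match(res$fused$sample_id, sim$metadata$sample_id), ]
permanova(hel, md, ~ phase + season, n_perm = 999, seed = 1)
#> <permanova_fit> 999 permutations
#>       term df sum_of_squares         R2 statistic p_value
#> 1    phase  1      0.5205224 0.06893553  2.829941   0.001
#> 2   season  1      0.2247787 0.02976862  1.222062   0.201
#> 3 Residual 37      6.8055580 0.90129585        NA      NA

rda_ordination(hel, md, ~ phase + season)
#> <ordination> RDA, 2 axes
#>   % explained: 6.9, 3.0
#>   R2 = 0.0987, adjusted R2 = 0.0500
```

The per-sample diversity of ~6–9 effective taxa reflects the simulated diet
breadth; the PERMANOVA detects the simulated phase effect (p = 0.001,
pseudo-F = 2.8) while the season shift at this sample size does not reach
significance, and the RDA attributes ~5 % of adjusted variance to the
design — composition effects in such data are real but small relative to
among-individual variation.

An end-to-end run from a config file (writes all intermediate tables, QC
reports, metrics, statistics and a manifest):

```r
run_pipeline(list(simulate = list(species = "bank", seed = 1),
                  statistics = list(terms = "phase + season", n_perm = 999)),
             out_dir = "run1")
summarize_figures("run1")   # per-taxon RRA/wPOO mean ± SE, functional groups
```

A thin CLI wrapper lives at `inst/cli/metadiet.R`
(`metadiet.R run|simulate|recovery -c config.yaml -o out`).

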