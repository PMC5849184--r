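# coexscreen

Guilt-by-association analysis of a single query gene in a large
expression panel, as an offline, fully testable R pipeline.

The question this package answers: given a gene-by-sample log2
expression matrix (hundreds to a thousand samples), what do the
genome-wide expression correlates of one query gene say about its
function — and which transcription factor is the best candidate
regulator of that program? It is written for computational biologists
who want the complete chain — correlation screen, gene-set bias
statistics, over-representation, TF prioritization, promoter motif
scan — reproducible on their own machine, with no web enrichment
services and no undeclared backgrounds.

## The method

1. **Coexpression screen** (`screen_coexpression`): Pearson correlation
   of the query against every other gene; two-sided p-values from the
   exact t-transform `t = r·sqrt((n−2)/(1−r²))`; one Benjamini–Hochberg
   family over all defined correlations; classification *positive*
   (r > r_min, q < q_max), *negative* (r < −r_min, q < q_max) or *none*,
   with defaults r_min = 0.2, q_max = 1e-4 (i.e. FDR < 0.01% and
   |r| > 0.2).
2. **Set bias** (`bias_analysis`): is a curated gene list skewed toward
   the negative correlates? One-sided Fisher exact test on the
   membership × class table, an exact binomial sign test of positive vs
   negative correlates at p₀ = 0.5, and an optional two-proportion
   comparison against a second list. Supporting statistics:
   `compare_distributions` (pooled t / one-way ANOVA, F = t²) and
   `gaussian_kde` for density plots.
3. **Over-representation** (`enrich_sets`): hypergeometric upper tail
   per GMT term within a declared universe, BH across the library,
   deterministic ranking (q, then p, then overlap, then name).
4. **Master-regulator prioritization** (`prioritize_tfs`): the same
   engine over a TF-target library, full ranking returned.
5. **Promoter scan** (`scan_sequence`): base-2 log-odds PWM (total
   pseudocount 1, distributed by background) scored over both strands,
   hits in TSS-relative coordinates (no position 0).

A seeded synthetic generator (`generate_dataset`, `generate_promoter`)
plants a highly expressed hub gene, a TF correlated with it (r = 0.18),
a 50-gene module negatively correlated with both (r = −0.35), matched
gene lists and TF-target libraries, and a promoter with a motif at a
known site — so every stage is verifiable against ground truth. See the
methods vignette (`vignettes/coexpression-screening.Rmd`) for the model
and every default.

## Worked example

```r
library(coexscreen)

ds <- generate_dataset(synthetic_config(seed = 1))   # 2000 genes x 400 samples
screen <- screen_coexpression(ds$matrix, "HUB1")
screen
#> coex_screen of 'HUB1' over 400 samples (1999 genes tested)
#>   thresholds: |r| > 0.2, q < 0.0001
#>   positive 0, negative 50, none 1949

bias_analysis(screen, ds$gene_set)
#> bias_report for 'SYNTH_IMMUNE' (200 genes in screen)
#>   in-set classes: 0 positive, 50 negative, 150 none
#>   negative proportion: 25.0% in set vs 2.5% panel-wide
#>   Fisher p (negative enrichment) = 2.33195e-53; sign test p = 1.77636e-15

neg <- screen$records$gene[screen$records$klass == "negative"]
ranking <- prioritize_tfs(gene_set("negative_class", neg),
                          ds$tf_library, genes(ds$matrix))
head(as.data.frame(ranking)[, c("term", "k", "K", "p", "q", "rank")], 3)
#>         term  k  K            p            q rank
#> 1        TF1 50 51 2.554893e-99 5.365276e-98    1
#> 2 DECOY_TF13  3 51 1.328269e-01 7.700398e-01    2
#> 3 DECOY_TF03  2 51 3.666856e-01 7.700398e-01    3

summarize_gene(ds$matrix, "HUB1")
#> HUB1: min percentile rank 99.9, fold range 66.52, sd(log2) 0.963
```

Reading the output: the screen recovers exactly the 50 planted module
genes as negative correlates (no false positives among 1,949 background
genes at these thresholds); the curated set is overwhelmingly biased
toward negative correlation (25.0% of its members negative vs 2.5%
panel-wide; Fisher p ≈ 2e-53); the planted TF's target set tops the
ranking ahead of 20 size-matched decoys; and the hub sits above the
99th percentile of expression in every sample.

The same analysis runs from a declarative YAML config over files on
disk — `run_pipeline("config.yaml")` — or from the shell via
`inst/scripts/coexscreen-cli.R` (subcommands `run`, `simulate`,
`screen`, `enrich`, `scan`), writing TSV tables plus a JSON summary
that are byte-identical across reruns.

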