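---
title: "Guilt-by-association screening: models, defaults and design choices"
author: "coexscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guilt-by-association screening: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexscreen)
```

## The analysis

`coexscreen` implements the classical guilt-by-association workflow for a
single query gene in a large expression panel. The premise: genes that
maintain a consistent expression relationship with the query across many
heterogeneous samples are likely co-regulated with it or functionally
coupled to it. The workflow has five stages.

**1. Coexpression screen.** For a query gene $g_0$ and every other gene
$g_i$ in a log2-scale matrix of $n$ samples, we compute the Pearson
product-moment correlation $r_i$ and its two-sided p-value from the exact
Student-$t$ transform

$$t_i = r_i\sqrt{\frac{n-2}{1-r_i^2}}, \qquad p_i = 2\,P(T_{n-2} \ge |t_i|).$$

All defined p-values form one Benjamini–Hochberg family; a gene is called
*positive* when $r_i > r_{\min}$ and $q_i < q_{\max}$, *negative* when
$r_i < -r_{\min}$ and $q_i < q_{\max}$, and *none* otherwise (strict
inequalities). The defaults $r_{\min} = 0.2$ and $q_{\max} = 10^{-4}$
encode a screen at FDR < 0.01% with $|r| > 0.2$. At panel scale
($n \approx 1000$, family $\le 20{,}000$) the p-value at $|r| = 0.2$ is
$\sim 8\times10^{-11}$, so the effect-size cut, not the FDR cut, is the
binding constraint — a property the test suite asserts. Zero-variance
genes have no defined correlation; they are flagged degenerate and
excluded from the BH family rather than assigned $p = 1$, because an
undefined statistic is not evidence of a null.

**2. Set bias.** Given a curated gene set (for instance an immune-response
list), we ask whether its members are skewed toward the negative class.
Three complementary tests are reported:

- a one-sided Fisher exact test on the 2×2 table
  (in-set / out-of-set) × (negative / not negative);
- an exact binomial sign test of positive versus negative correlates
  within the set at $p_0 = 1/2$ — the natural test when only the
  direction of each correlate is considered informative;
- optionally, a two-sided Fisher comparison of negative proportions
  against a second curated list.

Published panel analyses of this design often quote the *panel-wide*
negative count over the *panel* total as the background percentage, even
though the panel includes the curated set itself. `bias_report()`
therefore carries both conventions: the headline proportions use the
panel-wide counts (so published percentages are reproduced verbatim),
while the Fisher table is the internally consistent one with out-of-set
negatives equal to panel negatives minus in-set negatives. Percentages
are formatted to one decimal with round-half-to-even.

**3. Over-representation.** The coexpressed genes are tested against GMT
libraries with the hypergeometric upper tail
$p = P(X \ge k),\; X \sim \mathrm{Hyp}(N, K, n)$, BH-adjusted across the
terms of one library (never pooled across libraries). Terms with no
member in the universe are dropped *before* adjustment: they carry no
information and would only distort the family size. Ranking is fully
deterministic: ascending $q$, then ascending $p$, then descending $k$,
then term name. The default universe is the set of genes in the loaded
expression matrix — the only background that is well-defined offline;
web enrichment services use internal backgrounds of their own, which is
why we treat published per-term p-values as order-of-magnitude
references rather than targets.

**4. Master-regulator prioritization.** The same engine over a library
whose sets are transcription-factor target lists, with no q filter, gives
a full TF ranking. The query is the negative (or full coexpressed) class
of the screen: a TF whose targets are over-represented there is a
candidate upstream regulator of the query gene's program.

**5. Promoter scan.** A JASPAR-style count matrix is turned into base-2
log-odds weights with a total pseudocount of 1 distributed by the
background ($b_A,b_C,b_G,b_T$, uniform by default):

$$w_{b,j} = \log_2 \frac{c_{b,j} + \lambda b}{(\sum_b c_{b,j} + \lambda)\, b}.$$

Every window on both strands is scored (reverse strand via reverse
complement); windows containing N are skipped. Coordinates are reported
TSS-relative with no position 0 (−1 abuts +1), the promoter-construct
convention. We state the scoring convention explicitly because published
motif scores are frequently quoted without one; a score produced by a
different pseudocount or background is not comparable, so an external
matrix and promoter may legitimately reproduce a published site's
*location* while differing in its numeric score. All overlapping hits
are reported; no greedy masking.

## Data loading and normalization

Inputs are gene-level: TSV/GCT expression matrices, one-symbol-per-line
gene lists, GMT libraries, JASPAR PFM text, and FASTA promoters with a
declared TSS offset. All symbols are upper-cased on load so that
list/matrix intersections are deterministic; a curated list is *defined*
as its intersection with the matrix. Duplicate symbols are collapsed by
keeping the row with the highest mean — the common microarray convention
when probe-level provenance is unavailable. Missing values are rejected
at load rather than imputed, because every downstream statistic assumes
complete vectors.

`quantile_normalize()` implements the standard order-statistic
definition: the value at within-column rank $i$ becomes the mean across
columns of the $i$-th order statistics, and ties within a column receive
the mean of the reference values at the tied ranks. We implement the
definition directly (it is ten lines) rather than delegating, because
common library implementations interpolate at the average rank for odd
tie runs, which differs from the tied-rank mean and breaks exact
idempotence at our 1e-9 tolerance.

`summarize_gene()` reports the three descriptive statistics used to say
"this gene is highly and stably expressed": the minimum over samples of
the within-sample percentile rank (weak inequality, ×100), the
linear-scale fold range $2^{\max - \min}$ of the log2 values, and the
population SD of the log2 values.

## The synthetic generator

`generate_dataset()` draws from a single-latent-factor Gaussian model on
the log2 scale. Each sample has a factor $F \sim N(0,1)$ and each gene a
loading $\ell$: $x = \mu + \sigma(\ell F + \sqrt{1-\ell^2}\,\varepsilon)$,
so the population correlation between genes is exactly the product of
their loadings. This is the simplest generative model in which planted
pairwise correlations are exactly controllable. Structure planted at the
defaults:

| parameter | default | why |
|---|---|---|
| `n_samples` | 400 | large-panel regime where $r = -0.35$ is unmissable but $r = 0.18$ is still modest |
| `n_genes` | 2000 | large enough for a meaningful BH family and stable percentile ranks, small enough for hundred-replicate simulations |
| `module_size` | 50 | a recognizable functional module |
| `r_module_hub` | −0.35 | comfortably past the −0.2 screen threshold; screens report thresholds, not true effects, so recovery tests need headroom |
| `r_hub_tf` | 0.18 | a weak single-pair correlation of the magnitude typically reported for TF–target coexpression |
| `baseline_mean`, `baseline_sd` | 7, 1 | mid-range log2 microarray intensity |
| `hub_percentile_boost` | 6 | see below |
| `module_extra_sd` | 0.5 | the curated-set analog is more variable than background, so the SD-comparison stage has something to find |
| `n_set_distractors` | 150 | set:module ratio near the ~10:1 seen in curated immune lists (most members of a real list do not correlate with any given query) |
| `n_decoy_tfs` | 20 | size-matched random target sets make rank-1 recovery non-trivial |

The hub must sit above the 95th percentile *in every sample*. The
minimum of 400 unit-variance draws sits about 3.2 SD below its mean, and
the 95th percentile of the background is 1.645 SD above its mean, so the
boost must exceed $3.2 + 1.645 \approx 4.8$ plus a margin for the
binomial fluctuation of the empirical count; 6 satisfies this with room
to spare and corresponds to a top-of-scale transcript (mean 13 on a log2
scale that saturates near 14).

Factor loadings are $a = \sqrt{|r_{\text{module,hub}}|}$ for the hub,
$r_{\text{module,hub}}/a$ for module genes and $r_{\text{hub,tf}}/a$ for
the TF; the configuration is rejected as unrealizable when a loading
would leave $(-1, 1)$. One consequence worth knowing: module genes are
also correlated with the TF (loading product
$r_{\text{module,hub}}\, r_{\text{hub,tf}} / |r_{\text{module,hub}}| =
-0.18$ at defaults), which is exactly the biological scenario being
emulated — a TF driving both the hub and, oppositely, the module.

`generate_promoter()` plants the motif's consensus string into an
i.i.d. background of chosen GC content spanning −1761/+37 by default
(the geometry of a typical promoter-reporter construct), at −1411 by
default.

**What the generator does not emulate** — and hence what passing
recovery tests do *not* establish about real panels: tissue-structured
covariance (samples are exchangeable here; real panels have lineage
blocks that inflate correlations), heavy-tailed and saturated
intensities, probe-level artifacts, more than one latent factor, and
curated lists whose members correlate with the query at heterogeneous
strengths. Recovery at defaults demonstrates that the machinery is
correct and well-calibrated, not that any particular biological claim
is true.

## Numerical and statistical conventions

- **Two-sided exact tests** (Fisher, binomial sign) use the
  minimum-likelihood definition — sum the probabilities of all outcomes
  no more likely than the observed one — with $10^{-7}$ relative slack
  for floating-point ties, matching the convention of standard
  statistical environments. The sign test is our reading of a
  "16 positive versus 61 negative" bias claim: the direction of each
  correlate as a Bernoulli(1/2) trial; the published bound (< $10^{-4}$)
  is insensitive to reasonable alternatives.
- **Fisher implementation**: hypergeometric point masses over the
  margin-constrained support. `stats::fisher.test` agrees (it is an
  independent cross-check in the tests) but spends most of its time on
  the odds-ratio confidence interval, which we never use.
- **Perfect correlation** reports the smallest representable positive
  double rather than 0, preserving $p \in (0, 1]$.
- **KDE**: direct Gaussian sum on an arbitrary grid, Silverman's rule
  $h = 0.9\min(\mathrm{sd}, \mathrm{IQR}/1.34)\,n^{-1/5}$ for the
  automatic bandwidth.
- **Degenerate inputs**: zero-variance vectors are flagged, not scored;
  two identical-constant groups compare with $p = 1$ by convention;
  zero-margin contingency tables give $p = 1$.
- **Tie-breaks** are always resolved lexicographically (gene symbol,
  term name, A<C<G<T for consensus calls) so every table the package
  writes is byte-reproducible.

## Problem sizes used by the test suite

Simulation-backed tests run at the defaults above (100 replicates for
the recovery-rate checks; 10–30 replicates at reduced gene counts for
per-module unit tests), chosen so the full suite completes in about two
minutes on a single core while keeping every Monte-Carlo assertion far
from its decision boundary. Exhaustive oracle sweeps cover all 2×2
tables with total ≤ 40 and all hypergeometric instances with $N \le 60$.

## Known limitations

- The Pearson screen is linear; monotone-but-nonlinear coupling is
  attenuated (rank correlation is not implemented).
- Over-representation p-values depend strongly on the universe;
  cross-tool comparisons are meaningful only at order-of-magnitude
  resolution unless backgrounds are identical.
- The scanner accepts only N as an ambiguity code and reports raw
  log-odds scores; no per-position p-value calibration is provided.
- BH controls FDR under independence or positive regression dependence;
  correlated genes violate independence, which is the standard caveat
  for all screens of this design.
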