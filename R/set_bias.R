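#' Fisher exact test for a 2x2 contingency table
#'
#' One-sided p-values are exact hypergeometric tails over all tables with
#' the observed margins; the two-sided p-value is the minimum-likelihood
#' sum (all tables whose point probability does not exceed that of the
#' observed table, with 1e-7 relative slack for floating-point ties) --
#' the convention used by standard statistical environments. A table with
#' a zero row or column margin has p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts; rows index set
#'   membership, columns index class membership.
#' @param sided `"two"` (default), `"greater"` (enrichment of cell
#'   `tab[1,1]`), or `"less"`.
#' @return The exact p-value.
#' @export
fisher_exact_2x2 <- function(tab, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  if (is.data.frame(tab)) tab <- as.matrix(tab)
  if (!is.matrix(tab) || !identical(dim(tab), c(2L, 2L)))
    abort_args("'tab' must be a 2x2 matrix")
  if (any(!is.finite(tab)) || any(tab < 0) || any(tab != floor(tab)))
    abort_args("table cells must be non-negative integers")
  if (sum(tab) < 1) abort_args("table total must be at least 1")
  a <- tab[1L, 1L]
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ]); c1 <- sum(tab[, 1L])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  d <- stats::dhyper(support, r1, r2, c1)
  switch(sided,
         greater = sum(d[support >= a]),
         less = sum(d[support <= a]),
         two = {
           obs <- stats::dhyper(a, r1, r2, c1)
           min(1, sum(d[d <= obs * (1 + 1e-7)]))
         })
}

#' Exact binomial sign test
#'
#' Two-sided minimum-likelihood exact test of `k` successes in `n`
#' Bernoulli(p0) trials: sums the probabilities of all outcomes whose point
#' probability does not exceed that of `k` (with 1e-7 relative slack).
#' Used to test whether positive and negative correlates of a query gene
#' within a curated set are balanced (p0 = 0.5).
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials.
#' @param p0 Null success probability in (0, 1).
#' @return The exact two-sided p-value.
#' @export
binomial_sign_test <- function(k, n, p0 = 0.5) {
  if (!is_count(k) || !is_count(n) || k > n)
    abort_args("'k' and 'n' must be integers with 0 <= k <= n")
  if (n < 1L) abort_args("'n' must be at least 1")
  if (!is_scalar_number(p0) || p0 <= 0 || p0 >= 1)
    abort_args("'p0' must lie strictly in (0, 1)")
  stats::binom.test(k, n, p = p0)$p.value
}

#' Directional-bias report from class counts
#'
#' The count-level engine behind [bias_analysis()]: given the number of
#' positively and negatively classified genes inside a curated set and the
#' total and negative counts of the whole background, it reports
#' \itemize{
#'   \item the set and background negative proportions in the conventional
#'     "count over full panel" form (`proportion_negative_background` uses
#'     the panel-wide negative count over the panel total, so published
#'     headline percentages are reproduced verbatim);
#'   \item a one-sided Fisher exact p-value for enrichment of the negative
#'     class in the set, computed from the internally consistent table in
#'     which the out-of-set negatives are the panel negatives minus the
#'     in-set negatives;
#'   \item an exact binomial sign test of positive versus negative
#'     correlates within the set (p0 = 0.5);
#'   \item optionally, a two-sided Fisher comparison of negative
#'     proportions against a second set.
#' }
#'
#' @param set_name Name of the curated set.
#' @param n_set Number of set genes present in the screen.
#' @param set_negative,set_positive Negative/positive class counts within
#'   the set.
#' @param bg_total Total number of genes in the panel (set included).
#' @param bg_negative Panel-wide negative class count (set included).
#' @param bg_positive Optional panel-wide positive class count.
#' @param comparison Optional list with `name`, `n_set` and `set_negative`
#'   describing a second set for the two-proportion comparison.
#' @return An object of class `bias_report`.
#' @export
bias_report <- function(set_name, n_set, set_negative, set_positive,
                        bg_total, bg_negative, bg_positive = NA_integer_,
                        comparison = NULL) {
  for (v in list(n_set, set_negative, set_positive, bg_total, bg_negative))
    if (!is_count(v)) abort_args("all counts must be non-negative integers")
  if (set_negative + set_positive > n_set)
    abort_args("set class counts exceed the set size")
  if (n_set > bg_total || bg_negative > bg_total || set_negative > bg_negative)
    abort_args("set counts are inconsistent with the background counts")

  tab <- matrix(c(set_negative, n_set - set_negative,
                  bg_negative - set_negative,
                  (bg_total - n_set) - (bg_negative - set_negative)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("in_set", "out_set"),
                                c("negative", "not_negative")))
  if (any(tab < 0)) abort_args("set counts are inconsistent with the background counts")

  sign_p <- if (set_negative + set_positive > 0)
    binomial_sign_test(set_positive, set_positive + set_negative, 0.5)
  else NA_real_

  two_prop <- NA_real_
  if (!is.null(comparison)) {
    if (!is_count(comparison$n_set %||% -1) || !is_count(comparison$set_negative %||% -1))
      abort_args("'comparison' must carry integer 'n_set' and 'set_negative'")
    two_prop <- fisher_exact_2x2(matrix(c(set_negative, n_set - set_negative,
                                          comparison$set_negative,
                                          comparison$n_set - comparison$set_negative),
                                        nrow = 2L, byrow = TRUE), "two")
  }

  structure(list(set_name = set_name,
                 n_set = n_set,
                 n_background = bg_total - n_set,
                 set_counts = c(positive = set_positive, negative = set_negative,
                                none = n_set - set_positive - set_negative),
                 background_counts = c(positive = if (is.na(bg_positive)) NA_integer_
                                       else bg_positive - set_positive,
                                       negative = bg_negative - set_negative),
                 proportion_negative_set = 100 * set_negative / n_set,
                 proportion_negative_background = 100 * bg_negative / bg_total,
                 contingency = tab,
                 fisher_p_negative = fisher_exact_2x2(tab, "greater"),
                 sign_test_p = sign_p,
                 two_proportion_p = two_prop,
                 comparison_name = if (is.null(comparison)) NA_character_
                                   else comparison$name %||% "comparison"),
            class = "bias_report")
}

#' Directional bias of a curated gene set in a coexpression screen
#'
#' Restricts the set to genes present in the screen, tallies the
#' positive/negative/none classes inside and outside the set, and hands the
#' counts to [bias_report()]. Answers: are set genes over-represented among
#' the negative (or positive) correlates of the query?
#'
#' @param screen A [screen_coexpression()] result.
#' @param set A [gene_set()].
#' @param comparison_set Optional second [gene_set()] for the
#'   two-proportion comparison of negative rates.
#' @return A [bias_report()].
#' @export
bias_analysis <- function(screen, set, comparison_set = NULL) {
  stopifnot(inherits(screen, "coex_screen"), inherits(set, "gene_set"))
  rec <- screen$records
  members <- intersect(set$members, rec$gene)
  if (length(members) == 0L)
    abort_data(sprintf("gene set '%s' shares no genes with the screen", set$name))
  in_set <- rec$gene %in% members
  comparison <- NULL
  if (!is.null(comparison_set)) {
    stopifnot(inherits(comparison_set, "gene_set"))
    cmem <- intersect(comparison_set$members, rec$gene)
    if (length(cmem) == 0L)
      abort_data(sprintf("comparison set '%s' shares no genes with the screen",
                         comparison_set$name))
    cin <- rec$gene %in% cmem
    comparison <- list(name = comparison_set$name, n_set = sum(cin),
                       set_negative = sum(cin & rec$klass == "negative"))
  }
  bias_report(set_name = set$name,
              n_set = sum(in_set),
              set_negative = sum(in_set & rec$klass == "negative"),
              set_positive = sum(in_set & rec$klass == "positive"),
              bg_total = nrow(rec),
              bg_negative = sum(rec$klass == "negative"),
              bg_positive = sum(rec$klass == "positive"),
              comparison = comparison)
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("bias_report for '%s' (%d genes in screen)\n", x$set_name, x$n_set))
  cat(sprintf("  in-set classes: %d positive, %d negative, %d none\n",
              x$set_counts[["positive"]], x$set_counts[["negative"]],
              x$set_counts[["none"]]))
  cat(sprintf("  negative proportion: %s%% in set vs %s%% panel-wide\n",
              format_percent(x$proportion_negative_set),
              format_percent(x$proportion_negative_background)))
  cat(sprintf("  Fisher p (negative enrichment) = %s; sign test p = %s\n",
              format_pvalue(x$fisher_p_negative), format_pvalue(x$sign_test_p)))
  if (!is.na(x$two_proportion_p))
    cat(sprintf("  two-proportion p vs '%s' = %s\n",
                x$comparison_name, format_pvalue(x$two_proportion_p)))
  invisible(x)
}

# Reporting layer: percentages to one decimal (round-half-to-even),
# p-values in 6-significant-digit scientific notation.
format_percent <- function(x) formatC(round(x, 1L), format = "f", digits = 1L)
format_pvalue <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "e", digits = 5L))
}

#' Compare two samples by pooled-variance t-test or one-way ANOVA
#'
#' The classical two-tailed unpaired t-test with pooled variance, or the
#' one-way ANOVA F-test over the two groups; for two groups the statistics
#' satisfy F = t^2. When every value in both groups is identical the test
#' is degenerate and p = 1 is reported with a flag.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @param method `"t_test"` (default) or `"anova"`.
#' @return A list with `stat`, `p`, `method`, and `degenerate`.
#' @export
compare_distributions <- function(x, y, method = c("t_test", "anova")) {
  method <- match.arg(method)
  if (!is.numeric(x) || !is.numeric(y) || length(x) < 2L || length(y) < 2L)
    abort_args("'x' and 'y' must be numeric with at least 2 values each")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    abort_args("'x' and 'y' must be finite")
  vals <- c(x, y)
  if (stats::var(vals) == 0)
    return(list(stat = 0, p = 1, method = method, degenerate = TRUE))
  if (method == "t_test") {
    ht <- stats::t.test(x, y, var.equal = TRUE)
    list(stat = unname(ht$statistic), p = ht$p.value, method = method,
         degenerate = FALSE)
  } else {
    g <- factor(rep(c("x", "y"), c(length(x), length(y))))
    ht <- stats::oneway.test(vals ~ g, var.equal = TRUE)
    list(stat = unname(ht$statistic), p = ht$p.value, method = method,
         degenerate = FALSE)
  }
}

#' Gaussian kernel density estimate on an arbitrary grid
#'
#' Direct-sum estimator: `density(g) = (1/(n h)) * sum_i phi((g - v_i)/h)`
#' with `phi` the standard normal density. The automatic bandwidth is
#' Silverman's rule of thumb, `h = 0.9 * min(sd, IQR/1.34) * n^(-1/5)`.
#'
#' @param values Numeric data vector (length >= 2 for automatic bandwidth).
#' @param grid Numeric vector of evaluation points.
#' @param bandwidth Positive numeric bandwidth, or `"auto"` for Silverman's
#'   rule.
#' @return Numeric vector of densities, one per grid point.
#' @export
gaussian_kde <- function(values, grid, bandwidth = "auto") {
  if (!is.numeric(values) || length(values) < 1L || !all(is.finite(values)))
    abort_args("'values' must be a non-empty finite numeric vector")
  if (!is.numeric(grid) || length(grid) < 1L)
    abort_args("'grid' must be a non-empty numeric vector")
  if (identical(bandwidth, "auto")) {
    if (length(values) < 2L)
      abort_args("automatic bandwidth needs at least 2 values")
    h <- stats::bw.nrd0(values)
  } else {
    if (!is_scalar_number(bandwidth) || bandwidth <= 0)
      abort_args("'bandwidth' must be a positive number or \"auto\"")
    h <- bandwidth
  }
  n <- length(values)
  vapply(grid, function(g) sum(stats::dnorm((g - values) / h)) / (n * h),
         numeric(1L))
}
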