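#' Hypergeometric upper-tail probability
#'
#' Over-representation p-value `P(X >= k)` for `X ~ Hypergeometric(N, K,
#' n)`: the probability of drawing at least `k` members of a size-`K` term
#' when sampling `n` genes from a universe of `N`. Evaluated through the
#' log-space hypergeometric tail for numerical stability; `k = 0` gives
#' p = 1.
#'
#' @param k Observed overlap, `0 <= k <= min(K, n)`.
#' @param K Term size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return The upper-tail probability.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  for (v in list(k, K, n, N)) if (!is_count(v)) abort_args("counts must be non-negative integers")
  if (K > N || n > N || k > min(K, n))
    abort_args(sprintf("impossible counts: k=%d, K=%d, n=%d, N=%d", k, K, n, N))
  if (k == 0L) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Over-representation of a query gene set against a library
#'
#' For every term of the library, counts the overlap with the query inside
#' the declared universe, computes the hypergeometric upper-tail p-value,
#' adjusts across all informative terms of the library (Benjamini-Hochberg;
#' terms with no universe members are dropped first, since they carry no
#' information and would distort the family size), and ranks terms by
#' ascending adjusted p, then ascending raw p, then descending overlap,
#' then term name -- a fully deterministic ordering.
#'
#' @param query A [gene_set()].
#' @param library A [gene_set_library()].
#' @param universe Character vector of background gene symbols (typically
#'   the genes of the expression matrix under analysis).
#' @param q_cut Report only terms with adjusted p below this cut; `1`
#'   (used by [prioritize_tfs()]) keeps every term. Default 0.1.
#' @return An object of class `enrichment_result`: a data frame with
#'   columns term, k, K, n, N, p, q, rank, plus attributes `library`,
#'   `n_terms_tested` and `q_cut`.
#' @export
enrich_sets <- function(query, library, universe, q_cut = 0.1) {
  stopifnot(inherits(query, "gene_set"), inherits(library, "gene_set_library"))
  universe <- unique(norm_symbols(universe))
  universe <- universe[nzchar(universe)]
  if (length(universe) == 0L) abort_args("'universe' must be non-empty")
  if (!is_scalar_number(q_cut) || q_cut <= 0 || q_cut > 1)
    abort_args("'q_cut' must lie in (0, 1]")
  qry <- intersect(query$members, universe)
  if (length(qry) == 0L)
    abort_data("query set shares no genes with the universe")

  N <- length(universe)
  n <- length(qry)
  term <- vapply(library$sets, `[[`, "", "name")
  K <- vapply(library$sets, function(s) length(intersect(s$members, universe)), 0L)
  k <- vapply(library$sets, function(s) length(intersect(s$members, qry)), 0L)
  keep <- K >= 1L
  term <- term[keep]; K <- K[keep]; k <- k[keep]
  if (length(term) == 0L) abort_data("no library term intersects the universe")

  p <- vapply(seq_along(term), function(i) hypergeom_upper_tail(k[i], K[i], n, N),
              numeric(1L))
  q <- bh_adjust(p)
  ord <- order(q, p, -k, term, method = "radix")
  res <- data.frame(term = term[ord], k = k[ord], K = K[ord],
                    n = n, N = N, p = p[ord], q = q[ord],
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE, row.names = NULL)
  n_tested <- nrow(res)
  if (q_cut < 1) res <- res[res$q < q_cut, , drop = FALSE]
  row.names(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"),
            library = library$name, n_terms_tested = n_tested, q_cut = q_cut)
}

#' Prioritize candidate master transcription factors
#'
#' Runs [enrich_sets()] with `q_cut = 1` over a library whose set names are
#' transcription factors and whose members are their targets; the full
#' deterministic ranking is returned so the rank of any named TF can be
#' read off. A TF whose target set is over-represented among the correlates
#' of a query gene is a candidate master regulator of that gene's program.
#'
#' @param query A [gene_set()] (e.g. the negative class of a screen).
#' @param tf_library A [gene_set_library()] of TF target sets.
#' @param universe Background gene symbols.
#' @return An object of class `tf_ranking` (also an `enrichment_result`).
#' @export
prioritize_tfs <- function(query, tf_library, universe) {
  res <- enrich_sets(query, tf_library, universe, q_cut = 1)
  class(res) <- c("tf_ranking", class(res))
  res
}

#' Rank of a named transcription factor in a ranking
#'
#' @param ranking A [prioritize_tfs()] result.
#' @param tf TF name.
#' @return Integer rank, or `NA` if the TF was not tested.
#' @export
tf_rank <- function(ranking, tf) {
  stopifnot(inherits(ranking, "tf_ranking"))
  i <- match(tf, ranking$term)
  if (is.na(i)) NA_integer_ else ranking$rank[i]
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment against '%s': %d terms tested, %d reported (q < %g)\n",
              attr(x, "library"), attr(x, "n_terms_tested"), nrow(x),
              attr(x, "q_cut")))
  NextMethod()
}
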