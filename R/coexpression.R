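#' Pearson correlation with a two-sided parametric p-value
#'
#' Computes the sample Pearson product-moment correlation and its two-sided
#' p-value from the exact Student-t transform `t = r * sqrt((n-2)/(1-r^2))`
#' on `n - 2` degrees of freedom. Perfect correlation (`|r| = 1`) reports
#' the smallest representable positive p-value; a zero-variance vector
#' yields no correlation at all (a degenerate flag), since r is undefined
#' there rather than non-significant.
#'
#' @param x,y Finite numeric vectors of equal length `n >= 3`.
#' @return A list with `r`, `p`, and `degenerate`. When `degenerate` is
#'   `TRUE`, `r` and `p` are `NA`.
#' @export
pearson_with_pvalue <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    abort_args("'x' and 'y' must be numeric vectors of equal length")
  n <- length(x)
  if (n < 3L) abort_args("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    abort_args("'x' and 'y' must be finite")
  dx <- x - mean(x); dy <- y - mean(y)
  ssx <- sum(dx^2);  ssy <- sum(dy^2)
  if (ssx == 0 || ssy == 0)
    return(list(r = NA_real_, p = NA_real_, degenerate = TRUE))
  r <- sum(dx * dy) / sqrt(ssx * ssy)
  r <- max(-1, min(1, r))
  p <- if (1 - r^2 <= 0) {
    .Machine$double.xmin
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    max(2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE),
        .Machine$double.xmin)
  }
  list(r = r, p = min(p, 1), degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment: the adjusted value of the i-th
#' smallest p-value is `min_{j >= i} (p_(j) * m / j)`, capped at 1 and
#' mapped back to input order. Adjusted values never fall below the raw
#' p-values and tied p-values receive equal adjusted values.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || length(p) < 1L)
    abort_args("'p' must be a non-empty numeric vector")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    abort_args("all p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Genome-wide coexpression screen of a query gene
#'
#' Correlates the query gene with every other gene in the matrix
#' ([pearson_with_pvalue()]), applies one Benjamini-Hochberg adjustment
#' across all genes with defined correlations, and classifies each gene as
#' `positive` (r > r_min and q < q_max), `negative` (r < -r_min and
#' q < q_max) or `none` (strict inequalities throughout). Zero-variance
#' genes are flagged degenerate and excluded from the adjustment family.
#' The defaults reproduce a screen at FDR < 0.01% with |r| > 0.2.
#'
#' @param m An [expr_matrix()] with at least 3 samples.
#' @param query Query gene symbol (excluded from its own screen).
#' @param r_min Minimum absolute correlation for classification (>= 0).
#' @param q_max Maximum adjusted p-value for classification, in (0, 1].
#' @return An object of class `coex_screen`: a list with `query`,
#'   `n_samples`, `r_min`, `q_max`, `m_tested`, `counts`, and `records`, a
#'   data frame (gene, r, p, q, klass, degenerate) sorted by descending r
#'   with gene symbol as the deterministic tiebreak and degenerate genes
#'   last.
#' @export
screen_coexpression <- function(m, query, r_min = 0.2, q_max = 1e-4) {
  stopifnot(inherits(m, "expr_matrix"))
  query <- norm_symbols(query)
  if (length(query) != 1L || !query %in% rownames(m$values))
    abort_key(sprintf("query gene '%s' not present in the matrix", query))
  if (!is_scalar_number(r_min) || r_min < 0)
    abort_args("'r_min' must be a non-negative number")
  if (!is_scalar_number(q_max) || q_max <= 0 || q_max > 1)
    abort_args("'q_max' must lie in (0, 1]")
  v <- m$values
  n <- ncol(v)
  if (n < 3L) abort_args("need at least 3 samples to screen")

  qv <- v[query, ]
  others <- v[setdiff(rownames(v), query), , drop = FALSE]
  qc <- qv - mean(qv)
  qss <- sum(qc^2)
  oc <- others - rowMeans(others)
  oss <- rowSums(oc^2)

  degenerate <- (oss == 0) | (qss == 0)
  r <- rep(NA_real_, nrow(others))
  if (qss > 0) {
    ok <- oss > 0
    r[ok] <- as.vector(oc[ok, , drop = FALSE] %*% qc) / sqrt(oss[ok] * qss)
    r[ok] <- pmax(-1, pmin(1, r[ok]))
  }
  p <- rep(NA_real_, length(r))
  defined <- !degenerate
  if (any(defined)) {
    rr <- r[defined]
    pp <- ifelse(1 - rr^2 <= 0, .Machine$double.xmin,
                 2 * stats::pt(abs(rr) * sqrt((n - 2) / pmax(1 - rr^2, .Machine$double.eps)),
                               df = n - 2, lower.tail = FALSE))
    p[defined] <- pmin(pmax(pp, .Machine$double.xmin), 1)
  }
  q <- rep(NA_real_, length(p))
  m_tested <- sum(defined)
  if (m_tested > 0L) q[defined] <- bh_adjust(p[defined])

  klass <- rep("none", length(r))
  klass[defined & r > r_min & q < q_max] <- "positive"
  klass[defined & r < -r_min & q < q_max] <- "negative"

  rec <- data.frame(gene = rownames(others), r = r, p = p, q = q,
                    klass = klass, degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  # descending r, gene symbol tiebreak, degenerate genes last
  key_r <- ifelse(is.na(rec$r), -Inf, rec$r)
  ord <- order(rec$degenerate, -key_r, rec$gene, method = "radix")
  rec <- rec[ord, , drop = FALSE]
  row.names(rec) <- NULL

  structure(list(query = query, n_samples = n, r_min = r_min, q_max = q_max,
                 m_tested = m_tested,
                 counts = c(positive = sum(klass == "positive"),
                            negative = sum(klass == "negative"),
                            none = sum(klass == "none")),
                 records = rec),
            class = "coex_screen")
}

#' @export
print.coex_screen <- function(x, ...) {
  cat(sprintf("coex_screen of '%s' over %d samples (%d genes tested)\n",
              x$query, x$n_samples, x$m_tested))
  cat(sprintf("  thresholds: |r| > %g, q < %g\n", x$r_min, x$q_max))
  cat(sprintf("  positive %d, negative %d, none %d\n",
              x$counts[["positive"]], x$counts[["negative"]], x$counts[["none"]]))
  invisible(x)
}
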