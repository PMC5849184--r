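#' Build a log-odds position weight matrix from counts
#'
#' Converts a count matrix to base-2 log-odds weights:
#' `weight[b, j] = log2((counts[b, j] + pc * bg[b]) / ((colsum_j + pc) * bg[b]))`,
#' i.e. a total pseudocount `pc` distributed over the bases in proportion
#' to the background. With the default uniform background and total
#' pseudocount 1 this is the common motif-scanning convention; a uniform
#' count column scores 0 everywhere. The maximum attainable (consensus)
#' score is the sum over columns of the column-maximum weights.
#'
#' @param x A [pfm()].
#' @param pseudocount Total pseudocount, > 0. Default 1.
#' @param background Length-4 vector of strictly positive base
#'   probabilities (A, C, G, T) summing to 1. Default uniform.
#' @return An object of class `pwm` with `name`, `weights` (4 x L),
#'   `pseudocount`, `background` and `max_score`.
#' @export
pwm_from_counts <- function(x, pseudocount = 1,
                            background = rep(0.25, 4)) {
  stopifnot(inherits(x, "pfm"))
  if (!is_scalar_number(pseudocount) || pseudocount <= 0)
    abort_args("'pseudocount' must be a positive number")
  if (!is.numeric(background) || length(background) != 4L ||
      any(!is.finite(background)) || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9)
    abort_args("'background' must be 4 positive probabilities summing to 1")
  counts <- x$counts
  cs <- colSums(counts)
  w <- log2(sweep(counts + pseudocount * background, 2L, (cs + pseudocount), "/") /
              background)
  rownames(w) <- c("A", "C", "G", "T")
  structure(list(name = x$name, weights = w, pseudocount = pseudocount,
                 background = background,
                 max_score = sum(apply(w, 2L, max))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': %d positions, max score %.3f bits\n",
              x$name, ncol(x$weights), x$max_score))
  invisible(x)
}

#' Consensus sequence of a position frequency matrix
#'
#' Per-column argmax base; ties are broken in A < C < G < T order and
#' recorded in the `"tie_positions"` attribute.
#'
#' @param x A [pfm()].
#' @return The consensus string, with an integer attribute
#'   `tie_positions` naming the columns whose maximum was not unique.
#' @export
consensus_of <- function(x) {
  stopifnot(inherits(x, "pfm"))
  bases <- c("A", "C", "G", "T")
  idx <- apply(x$counts, 2L, which.max)
  ties <- which(apply(x$counts, 2L, function(col) sum(col == max(col)) > 1L))
  structure(paste(bases[idx], collapse = ""), tie_positions = as.integer(ties))
}

# base codes A=1 C=2 G=3 T=4, N (and anything else) = NA
encode_dna <- function(seq) {
  code <- match(strsplit(seq, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"))
  code
}

# score every window of length L on the coded strand; windows with NA -> -Inf
score_windows <- function(code, weights) {
  L <- ncol(weights)
  nwin <- length(code) - L + 1L
  scores <- numeric(nwin)
  for (j in seq_len(L)) {
    b <- code[seq_len(nwin) + j - 1L]
    s <- weights[cbind(b, j)]
    scores <- scores + ifelse(is.na(s), -Inf, s)
  }
  scores
}

# 0-based sequence offset -> TSS coordinate (no position 0; -1 abuts +1)
offset_to_tss <- function(offset, tss_offset) {
  rel <- offset - tss_offset
  ifelse(rel < 0, rel, rel + 1L)
}

#' Scan a promoter with a position weight matrix
#'
#' Scores every window of the promoter on both strands (the reverse strand
#' scores the reverse complement of each window); windows containing N are
#' skipped. Hits at or above the threshold are reported in TSS-relative
#' coordinates -- the promoter convention with no position 0, where -1
#' immediately abuts +1 -- sorted by descending score, then genomic
#' position, then strand. All overlapping hits are reported; consumers may
#' filter.
#'
#' @param pwm A [pwm_from_counts()] result.
#' @param promoter A [promoter_sequence()].
#' @param min_score Numeric absolute score threshold, or a string like
#'   `"90%"` meaning that fraction of the maximum (consensus) score.
#' @return A data frame of class `motif_hits` with columns `start_tss`,
#'   `end_tss`, `strand`, `score`, plus attributes `threshold` and
#'   `max_score`.
#' @export
scan_sequence <- function(pwm, promoter, min_score = "80%") {
  stopifnot(inherits(pwm, "pwm"), inherits(promoter, "promoter_sequence"))
  L <- ncol(pwm$weights)
  seqlen <- nchar(promoter$sequence)
  if (seqlen < L)
    abort_data(sprintf("promoter (%d bp) is shorter than the motif (%d bp)",
                       seqlen, L))
  if (is.character(min_score)) {
    if (length(min_score) != 1L || !grepl("^[0-9.]+%$", min_score))
      abort_args("string 'min_score' must look like \"90%\"")
    threshold <- as.numeric(sub("%$", "", min_score)) / 100 * pwm$max_score
  } else if (is.numeric(min_score) && length(min_score) == 1L && !is.na(min_score)) {
    threshold <- min_score   # -Inf is allowed: report every scorable window
  } else abort_args("'min_score' must be a number or a percentage string")

  code <- encode_dna(promoter$sequence)
  fwd <- score_windows(code, pwm$weights)
  # reverse strand: score the reverse complement of the sequence, then map
  # its window offsets back to forward-strand coordinates
  rc <- rev(5L - code)  # A<->T, C<->G on codes 1..4; NA stays NA
  rev_scores <- score_windows(rc, pwm$weights)
  nwin <- seqlen - L + 1L
  rev_fwd_offset <- seqlen - L - (seq_len(nwin) - 1L)  # 0-based forward offset

  offs <- c(seq_len(nwin) - 1L, rev_fwd_offset)
  strand <- rep(c("+", "-"), each = nwin)
  score <- c(fwd, rev_scores)
  keep <- is.finite(score) & score >= threshold
  offs <- offs[keep]; strand <- strand[keep]; score <- score[keep]

  ord <- order(-score, offs, strand, method = "radix")
  hits <- data.frame(start_tss = offset_to_tss(offs[ord], promoter$tss_offset),
                     end_tss = offset_to_tss(offs[ord] + L - 1L, promoter$tss_offset),
                     strand = strand[ord],
                     score = score[ord],
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(hits, class = c("motif_hits", "data.frame"),
            threshold = threshold, max_score = pwm$max_score,
            motif = pwm$name, promoter = promoter$id)
}

#' @export
print.motif_hits <- function(x, ...) {
  cat(sprintf("motif '%s' on promoter '%s': %d hits at score >= %.3f (max %.3f)\n",
              attr(x, "motif"), attr(x, "promoter"), nrow(x),
              attr(x, "threshold"), attr(x, "max_score")))
  NextMethod()
}
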