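#' Construct an expression matrix object
#'
#' An `expr_matrix` holds log2-scale expression values with genes in rows and
#' samples in columns, plus optional per-sample tissue labels. Gene symbols
#' are upper-cased; duplicated symbols (after case normalization) and
#' non-finite values are rejected -- the loaders collapse duplicates and
#' refuse missing values before construction.
#'
#' @param values Numeric matrix, rows = genes, columns = samples, with
#'   complete `dimnames`. Values are log2 intensities.
#' @param tissue Optional named character vector mapping sample id to tissue
#'   label; names must match the column names of `values`.
#' @return An object of class `expr_matrix` with elements `values` and
#'   `tissue`.
#' @examples
#' m <- expr_matrix(matrix(1:4, 2, dimnames = list(c("G1", "G2"), c("s1", "s2"))))
#' dim(m)
#' @export
expr_matrix <- function(values, tissue = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    abort_args("'values' must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    abort_data("expression matrix is empty")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort_args("'values' must have gene row names and sample column names")
  rownames(values) <- norm_symbols(rownames(values))
  if (anyDuplicated(rownames(values)))
    abort_data(sprintf("duplicate gene symbol after case normalization: %s",
                       rownames(values)[duplicated(rownames(values))][1L]))
  if (anyDuplicated(colnames(values)))
    abort_data("duplicate sample ids")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    abort_data(sprintf("non-finite value at gene '%s', sample '%s'",
                       rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  if (!is.null(tissue)) {
    tissue <- as.character(tissue)[match(colnames(values), names(tissue))]
    names(tissue) <- colnames(values)
  }
  structure(list(values = values, tissue = tissue), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (log2 scale)\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$tissue))
    cat(sprintf("  tissues: %d distinct labels\n", length(unique(x$tissue))))
  invisible(x)
}

#' Gene and sample identifiers of an expression matrix
#' @param m An `expr_matrix`.
#' @return Character vector of gene symbols / sample ids.
#' @export
genes <- function(m) rownames(m$values)

#' @rdname genes
#' @export
samples <- function(m) colnames(m$values)

#' Read an expression matrix from TSV or GCT
#'
#' The TSV dialect is a header row of sample ids with gene symbols in the
#' first column. The GCT 1.2 dialect carries a `#1.2` preamble, a dimension
#' line, and `Name`/`Description` lead columns. Duplicate gene symbols
#' (after upper-casing) are collapsed by keeping the row with the highest
#' mean expression; missing or non-numeric cells are refused with the
#' offending gene and sample named, because every downstream statistic
#' assumes complete vectors.
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (default; GCT is detected from the `#1.2`
#'   preamble), `"tsv"`, or `"gct"`.
#' @param tissue Optional named character vector of tissue labels per sample.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, dialect = c("auto", "tsv", "gct"),
                            tissue = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_args(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto")
    dialect <- if (length(lines) > 0L && grepl("^#1\\.[0-9]", lines[1L])) "gct" else "tsv"

  if (dialect == "gct") {
    if (length(lines) < 3L || !grepl("^#1\\.2\\s*$", lines[1L]))
      abort_format("GCT file must start with a '#1.2' version line")
    dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]][1:2]))
    if (any(is.na(dims)))
      abort_format("GCT dimension line must give row and column counts")
    header <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
    if (length(header) < 3L || toupper(header[1L]) != "NAME")
      abort_format("GCT header must be 'Name<TAB>Description<TAB>samples...'")
    body <- lines[-(1:3)]
    body <- body[nzchar(body)]
    if (length(body) != dims[1L])
      abort_format(sprintf("GCT declares %d data rows but file has %d",
                           dims[1L], length(body)))
    if (length(header) - 2L != dims[2L])
      abort_format(sprintf("GCT declares %d samples but header has %d",
                           dims[2L], length(header) - 2L))
    fields <- split_tabs(body)
    sample_ids <- header[-(1:2)]
    gene_ids <- vapply(fields, `[`, "", 1L)
    cells <- lapply(fields, function(f) f[-(1:2)])
  } else {
    if (length(lines) < 2L) abort_data("expression matrix is empty")
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (length(header) < 2L)
      abort_format("TSV header must hold the gene column plus sample ids")
    sample_ids <- header[-1L]
    body <- lines[-1L]
    body <- body[nzchar(body)]
    fields <- split_tabs(body)
    gene_ids <- vapply(fields, `[`, "", 1L)
    cells <- lapply(fields, function(f) f[-1L])
  }

  n_s <- length(sample_ids)
  bad_len <- which(lengths(cells) != n_s)
  if (length(bad_len))
    abort_format(sprintf("row for gene '%s' has %d values, expected %d",
                         gene_ids[bad_len[1L]], lengths(cells)[bad_len[1L]], n_s))
  vals <- matrix(NA_real_, nrow = length(gene_ids), ncol = n_s,
                 dimnames = list(gene_ids, sample_ids))
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    bad <- which(is.na(v) | !nzchar(trimws(cells[[i]])))
    if (length(bad))
      abort_data(sprintf("non-numeric or missing value for gene '%s', sample '%s'",
                         gene_ids[i], sample_ids[bad[1L]]))
    vals[i, ] <- v
  }
  if (nrow(vals) < 1L) abort_data("expression matrix is empty")

  rownames(vals) <- norm_symbols(rownames(vals))
  if (anyDuplicated(rownames(vals))) {
    sym <- rownames(vals)
    keep <- tapply(seq_len(nrow(vals)), sym, function(idx) {
      idx[which.max(rowMeans(vals[idx, , drop = FALSE]))]
    })
    keep <- sort(unname(unlist(keep)))  # keep original file order
    message(sprintf("collapsed %d duplicate gene symbols, keeping max-mean rows",
                    nrow(vals) - length(keep)))
    vals <- vals[keep, , drop = FALSE]
  }
  expr_matrix(vals, tissue = tissue)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share one reference distribution: the
#' value at within-column rank *i* becomes the mean, across columns, of each
#' column's *i*-th order statistic. Ties within a column receive the mean of
#' the reference values at the tied ranks. The transform is idempotent and,
#' in the absence of ties, leaves all columns with identical sorted values.
#'
#' @param m An [expr_matrix()].
#' @return A quantile-normalized `expr_matrix` with unchanged ids.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- m$values
  if (ncol(v) == 1L) return(m)
  ref <- rowMeans(apply(v, 2L, sort))
  out <- apply(v, 2L, function(col) {
    r <- numeric(length(col))
    r[order(col)] <- ref
    stats::ave(r, factor(col), FUN = mean)
  })
  dimnames(out) <- dimnames(v)
  expr_matrix(out, tissue = m$tissue)
}

#' Expression summary of one gene
#'
#' Reports three descriptive statistics for a query gene: the minimum, over
#' samples, of its within-sample percentile rank (100 x the fraction of
#' genes with value <= the query's value in that sample); the linear-scale
#' fold range `2^(max - min)` of its log2 values; and the population
#' standard deviation of its log2 values. A gene sitting above the 95th
#' percentile in every sample has `min_percentile_rank >= 95`.
#'
#' @param m An [expr_matrix()].
#' @param gene Gene symbol (case-insensitive).
#' @return A list of class `gene_summary` with `gene`,
#'   `min_percentile_rank`, `fold_range`, and `sd_log2`.
#' @export
summarize_gene <- function(m, gene) {
  stopifnot(inherits(m, "expr_matrix"))
  gene <- norm_symbols(gene)
  if (length(gene) != 1L || !gene %in% rownames(m$values))
    abort_key(sprintf("gene '%s' not present in the matrix", gene))
  v <- m$values
  g <- v[gene, ]
  pct <- vapply(seq_along(g),
                function(j) 100 * sum(v[, j] <= g[j]) / nrow(v), numeric(1L))
  structure(list(gene = gene,
                 min_percentile_rank = min(pct),
                 fold_range = 2^(max(g) - min(g)),
                 sd_log2 = sqrt(mean((g - mean(g))^2))),
            class = "gene_summary")
}

#' @export
print.gene_summary <- function(x, ...) {
  cat(sprintf("%s: min percentile rank %.1f, fold range %.2f, sd(log2) %.3f\n",
              x$gene, x$min_percentile_rank, x$fold_range, x$sd_log2))
  invisible(x)
}
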