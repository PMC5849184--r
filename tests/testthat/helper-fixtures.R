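# Programmatic fixtures: every file is built in a tempdir at test time.

write_tsv_fixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

tiny_expression_tsv <- function() {
  write_tsv_fixture(c("GENE\ts1\ts2",
                      "G1\t1.0\t2.0",
                      "G2\t3.0\t4.0"))
}

tiny_expression_gct <- function(declared_rows = 2L) {
  f <- tempfile(fileext = ".gct")
  writeLines(c("#1.2",
               sprintf("%d\t2", declared_rows),
               "Name\tDescription\ts1\ts2",
               "G1\tfoo\t1.0\t2.0",
               "G2\tbar\t3.0\t4.0"), f)
  f
}

# expr_matrix straight from a numeric matrix with default dimnames
make_matrix <- function(vals, genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("G%d", seq_len(nrow(vals)))
  samples <- samples %||% sprintf("s%d", seq_len(ncol(vals)))
  dimnames(vals) <- list(genes, samples)
  expr_matrix(vals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

jaspar_fixture <- function(bracketed = TRUE) {
  f <- tempfile(fileext = ".pfm")
  if (bracketed)
    writeLines(c(">M1 TESTTF", "A [4 0]", "C [0 4]", "G [0 0]", "T [0 0]"), f)
  else
    writeLines(c(">M1 TESTTF", "A 4 0", "C 0 4", "G 0 0", "T 0 0"), f)
  f
}

# an 8-position motif with a sharp consensus, used for scanning tests
sharp_pfm <- function(consensus = "GTAAACAA", weight = 18L, other = 1L) {
  bases <- c("A", "C", "G", "T")
  cons <- strsplit(consensus, "")[[1]]
  counts <- matrix(other, nrow = 4, ncol = length(cons),
                   dimnames = list(bases, NULL))
  for (j in seq_along(cons)) counts[cons[j], j] <- weight
  pfm("SHARP", counts)
}
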