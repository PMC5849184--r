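test_that("TSV expression load preserves dimensions, order and values", {
  m <- read_expression(tiny_expression_tsv())
  expect_s3_class(m, "expr_matrix")
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(genes(m), c("G1", "G2"))
  expect_equal(samples(m), c("s1", "s2"))
  expect_equal(unname(m$values["G2", ]), c(3, 4))
})

test_that("duplicate symbols collapse to the max-mean row, case-insensitively", {
  f <- write_tsv_fixture(c("GENE\ts1\ts2",
                           "brd4\t4.0\t6.0",   # mean 5
                           "BRD4\t5.0\t7.0",   # mean 6 -> kept
                           "OTHER\t1.0\t1.0"))
  expect_message(m <- read_expression(f), "collapsed 1 duplicate")
  expect_equal(genes(m), c("BRD4", "OTHER"))
  expect_equal(unname(m$values["BRD4", ]), c(5, 7))
})

test_that("GCT dialect is parsed and its declared dimensions enforced", {
  m <- read_expression(tiny_expression_gct())          # auto-detected
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(m$values["G1", "s2"]), 2)
  expect_error(read_expression(tiny_expression_gct(declared_rows = 3L)),
               class = "coex_format_error")
})

test_that("malformed and incomplete expression inputs are rejected with context", {
  bad_cell <- write_tsv_fixture(c("GENE\ts1\ts2", "G1\t1.0\tx"))
  expect_error(read_expression(bad_cell), "G1.*s2", class = "coex_data_error")
  missing <- write_tsv_fixture(c("GENE\ts1\ts2", "G1\t1.0\t"))
  expect_error(read_expression(missing), class = "coex_data_error")
  short_row <- write_tsv_fixture(c("GENE\ts1\ts2", "G1\t1.0"))
  expect_error(read_expression(short_row), class = "coex_format_error")
  empty <- write_tsv_fixture("GENE\ts1\ts2")
  expect_error(read_expression(empty), class = "coex_data_error")
})

test_that("GMT round trip: membership, dropped empties, and format errors", {
  f <- write_tsv_fixture(c("S1\tdesc\tA\tB", "S2\tother\tb\t\tC"))
  lib <- read_gmt(f)
  expect_length(lib, 2L)
  expect_setequal(lib$sets[["S1"]]$members, c("A", "B"))
  expect_setequal(lib$sets[["S2"]]$members, c("B", "C"))  # upper-cased, empty dropped

  expect_error(read_gmt(write_tsv_fixture("S1\tdesc")),
               "line 1", class = "coex_format_error")
  expect_error(read_gmt(write_tsv_fixture(c("S1\td\tA", "S1\td\tB"))),
               class = "coex_format_error")
})

test_that("JASPAR PFM parsing tolerates both bracketed and plain rows", {
  p1 <- read_jaspar_pfm(jaspar_fixture(bracketed = TRUE))
  p2 <- read_jaspar_pfm(jaspar_fixture(bracketed = FALSE))
  expect_equal(p1$counts, p2$counts)
  expect_equal(ncol(p1$counts), 2L)
  expect_equal(as.character(consensus_of(p1)), "AC")
  expect_equal(p1$name, "M1 TESTTF")
})

test_that("defective PFMs are refused", {
  uneven <- write_tsv_fixture(c("A 4 0 1", "C 0 4", "G 0 0", "T 0 0"))
  expect_error(read_jaspar_pfm(uneven), class = "coex_format_error")
  missing <- write_tsv_fixture(c("A 4 0", "C 0 4", "G 0 0"))
  expect_error(read_jaspar_pfm(missing), "T", class = "coex_format_error")
  negative <- write_tsv_fixture(c("A 4 -1", "C 0 4", "G 0 0", "T 0 0"))
  expect_error(read_jaspar_pfm(negative), class = "coex_data_error")
})

test_that("gene lists honor comments and case normalization", {
  f <- write_tsv_fixture(c("# curated list", "tp53", "BRCA1  ", "", "brca1"))
  gs <- read_gene_list(f, name = "L")
  expect_setequal(gs$members, c("TP53", "BRCA1"))
})

test_that("promoter FASTA load resolves the TSS offset from header or argument", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">prom tss=10", "ACGTACGTACGTACGTACGT"), f)
  p <- read_promoter(f)
  expect_equal(p$tss_offset, 10L)
  p2 <- read_promoter(f, tss_offset = 5)
  expect_equal(p2$tss_offset, 5L)
  writeLines(c(">prom no offset here", "ACGT"), f)
  expect_error(read_promoter(f), class = "coex_argument_error")
  expect_error(promoter_sequence("x", "ACGTX", 0), class = "coex_data_error")
  expect_error(promoter_sequence("x", "ACGT", 5), class = "coex_argument_error")
})

test_that("quantile normalization matches the hand order-statistic example", {
  m <- make_matrix(matrix(c(1, 2, 3, 4), 2))   # columns [1,2] and [3,4]
  qn <- quantile_normalize(m)
  expect_equal(unname(qn$values), matrix(c(2, 3, 2, 3), 2))
})

test_that("quantile normalization equalizes columns and is idempotent", {
  set.seed(11)
  for (rep in 1:5) {
    m <- make_matrix(matrix(rnorm(60 * 8), 60))
    qn <- quantile_normalize(m)
    sorted <- apply(qn$values, 2, sort)
    for (j in 2:ncol(sorted)) expect_equal(sorted[, j], sorted[, 1])
    qn2 <- quantile_normalize(qn)
    expect_equal(qn2$values, qn$values, tolerance = 1e-9)
  }
  one_col <- make_matrix(matrix(rnorm(5), 5))
  expect_equal(quantile_normalize(one_col)$values, one_col$values)
})

test_that("ties receive the mean of the reference values at the tied ranks", {
  # column 1 has a 3-way tie at ranks 1..3; reference = rowMeans of sorted cols
  m <- make_matrix(matrix(c(1, 1, 1, 5,
                            2, 4, 8, 16), ncol = 2))
  ref <- rowMeans(cbind(c(1, 1, 1, 5), c(2, 4, 8, 16)))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn$values[, 1]), c(rep(mean(ref[1:3]), 3), ref[4]))
  expect_equal(unname(qn$values[, 2]), ref)
})

test_that("summarize_gene computes percentile floor, fold range and sd", {
  m <- make_matrix(matrix(c(9, 1, 2,  8, 3, 1,  7, 2, 0), nrow = 3))
  s <- summarize_gene(m, "G1")   # maximum in every sample
  expect_equal(s$min_percentile_rank, 100)

  const <- make_matrix(matrix(c(5, 5, 1, 2), nrow = 2, byrow = TRUE))
  sc <- summarize_gene(const, "G1")
  expect_equal(sc$fold_range, 1)
  expect_equal(sc$sd_log2, 0)

  two <- make_matrix(matrix(c(10.0, 10.83, 0, 0), nrow = 2, byrow = TRUE))
  expect_equal(summarize_gene(two, "G1")$fold_range, 2^0.83, tolerance = 1e-12)
  expect_equal(2^0.83, 1.778, tolerance = 1e-3)

  expect_error(summarize_gene(m, "NOPE"), class = "coex_key_error")
})

test_that("percentile ranks are invariant to strictly monotone per-sample maps", {
  set.seed(21)
  vals <- matrix(rnorm(40 * 6), 40)
  m <- make_matrix(vals)
  trans <- vals
  trans[, 1] <- exp(trans[, 1]); trans[, 2] <- trans[, 2]^3
  trans[, 3] <- 2 * trans[, 3] + 7; trans[, 4] <- atan(trans[, 4])
  trans[, 5] <- rank(trans[, 5]); trans[, 6] <- trans[, 6]
  mt <- make_matrix(trans)
  for (g in c("G1", "G17", "G40"))
    expect_equal(summarize_gene(mt, g)$min_percentile_rank,
                 summarize_gene(m, g)$min_percentile_rank)
})
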