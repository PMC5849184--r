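test_that("fisher_exact_2x2 matches hand-enumerated tables", {
  t1 <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(t1, "two"), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(t1, "greater"), 17 / 70, tolerance = 1e-12)
  t2 <- matrix(c(0, 5, 5, 0), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(t2, "two"), 2 / 252, tolerance = 1e-12)
  # degenerate margins
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE), "two"), 1)
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 3, 0), 2), "two"), 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)),
               class = "coex_argument_error")
})

test_that("fisher p agrees with enumeration and with stats::fisher.test", {
  set.seed(91)
  for (rep in 1:100) {
    tab <- matrix(sample(0:12, 4, TRUE), 2)
    if (sum(tab) == 0) tab[1, 1] <- 1
    for (sided in c("two", "greater", "less")) {
      expect_equal(fisher_exact_2x2(tab, sided), fisher_oracle(tab, sided),
                   tolerance = 1e-12)
    }
    alt <- c(two = "two.sided", greater = "greater", less = "less")
    for (sided in names(alt))
      expect_equal(fisher_exact_2x2(tab, sided),
                   fisher.test(tab, alternative = alt[[sided]])$p.value,
                   tolerance = 1e-9)
  }
})

test_that("fisher p is invariant under simultaneous row and column swaps", {
  set.seed(101)
  for (rep in 1:50) {
    tab <- matrix(sample(0:15, 4, TRUE), 2)
    if (sum(tab) == 0) tab[2, 2] <- 2
    swapped <- tab[2:1, 2:1]
    expect_equal(fisher_exact_2x2(tab, "two"), fisher_exact_2x2(swapped, "two"),
                 tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab, "greater"),
                 fisher_exact_2x2(swapped, "greater"), tolerance = 1e-12)
  }
})

test_that("the exact sign test matches enumeration and the published bound", {
  expect_equal(binomial_sign_test(0, 4, 0.5), 2 / 16, tolerance = 1e-12)
  expect_equal(binomial_sign_test(3, 6, 0.5), 1)
  # 16 positive vs 61 negative correlates: the reported bias is P < 0.0001
  expect_lt(binomial_sign_test(16, 77, 0.5), 1e-4)
  set.seed(111)
  for (rep in 1:60) {
    n <- sample(1:40, 1); k <- sample(0:n, 1)
    p0 <- sample(c(0.3, 0.5, 0.7), 1)
    expect_equal(binomial_sign_test(k, n, p0), binom_oracle(k, n, p0),
                 tolerance = 1e-9)
  }
  expect_error(binomial_sign_test(5, 4), class = "coex_argument_error")
  expect_error(binomial_sign_test(1, 4, 1), class = "coex_argument_error")
})

test_that("bias_report reproduces the published panel worked example", {
  rep_ <- bias_report("immune_genes", n_set = 627L, set_negative = 61L,
                      set_positive = 16L, bg_total = 18901L,
                      bg_negative = 702L, bg_positive = 637L)
  expect_equal(round(rep_$proportion_negative_set, 1), 9.7)
  expect_equal(round(rep_$proportion_negative_background, 1), 3.7)
  expect_lt(rep_$fisher_p_negative, 0.001)
  expect_lt(rep_$sign_test_p, 0.0001)
  # internally consistent table: out-set negatives exclude the in-set ones
  expect_equal(unname(rep_$contingency["out_set", "negative"]), 702L - 61L)
  expect_equal(rep_$n_background, 18901L - 627L)
})

test_that("bias_analysis counts classes from a screen and flags a planted set", {
  set.seed(121)
  q <- rnorm(50)
  vals <- rbind(Q = q,
                N1 = -q + rnorm(50, sd = 0.1), N2 = -2 * q + rnorm(50, sd = 0.1),
                P1 = q + rnorm(50, sd = 0.1),
                matrix(rnorm(20 * 50), 20))
  m <- make_matrix(vals, genes = c("Q", "N1", "N2", "P1", sprintf("B%02d", 1:20)))
  s <- screen_coexpression(m, "Q", r_min = 0.2, q_max = 0.05)
  rep_ <- bias_analysis(s, gene_set("NEGS", c("N1", "N2", "NOT_IN_SCREEN")))
  expect_equal(rep_$n_set, 2L)
  expect_equal(unname(rep_$set_counts["negative"]), 2L)
  expect_equal(rep_$proportion_negative_set, 100)
  expect_lt(rep_$fisher_p_negative, 0.05)
  expect_error(bias_analysis(s, gene_set("ALIEN", "ZZZ")),
               class = "coex_data_error")
})

test_that("under a random null, the set-bias Fisher p is approximately uniform", {
  # counts large enough that the discrete exact p has fine support; the
  # uniformity of the null p-value only holds up to that discreteness
  set.seed(131)
  n_genes <- 10000; n_neg <- 2500; set_size <- 400
  reps <- 500
  pvals <- numeric(reps)
  for (i in seq_len(reps)) {
    neg <- sample(n_genes, n_neg)
    in_set <- sample(n_genes, set_size)
    k <- sum(in_set %in% neg)
    tab <- matrix(c(k, set_size - k, n_neg - k,
                    (n_genes - set_size) - (n_neg - k)), 2, byrow = TRUE)
    pvals[i] <- fisher_exact_2x2(tab, "greater")
  }
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(pvals) - 0.5), 0.1)
  # exact-test guarantee: the null p-value is super-uniform at any level
  for (t in c(0.01, 0.05, 0.1, 0.25))
    expect_lte(mean(pvals <= t), t + 2.6 * sqrt(t * (1 - t) / reps))
})

test_that("compare_distributions: t and F agree (F = t^2) and degenerate flags", {
  same <- compare_distributions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$stat, 0)
  expect_equal(same$p, 1)
  degen <- compare_distributions(c(2, 2), c(2, 2, 2))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 1)
  set.seed(141)
  for (rep in 1:20) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1), mean = 0.5)
    tt <- compare_distributions(x, y, "t_test")
    ff <- compare_distributions(x, y, "anova")
    expect_equal(ff$stat, tt$stat^2, tolerance = 1e-9)
    expect_equal(ff$p, tt$p, tolerance = 1e-9)
    expect_equal(tt$p, t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("a planted high-variance gene set is detected by the SD comparison", {
  detected <- logical(0)
  for (seed in 1:5) {
    ds <- generate_dataset(synthetic_config(n_genes = 400, n_samples = 200,
                                            seed = seed))
    sds <- apply(ds$matrix$values, 1, sd)
    mod <- names(sds) %in% ds$truth$module_members
    res <- compare_distributions(sds[mod], sds[!mod], "t_test")
    detected <- c(detected, res$p < 0.05)
  }
  expect_true(all(detected))
})

test_that("gaussian_kde equals the closed form, integrates to 1, matches the loop", {
  expect_equal(gaussian_kde(0, grid = 0, bandwidth = 1), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  set.seed(151)
  vals <- rnorm(100)
  grid <- seq(-6, 6, length.out = 241)
  d <- gaussian_kde(vals, grid)
  area <- sum((d[-1] + d[-length(d)]) / 2 * diff(grid))
  expect_equal(area, 1, tolerance = 1e-3)
  h <- 0.37
  expect_equal(gaussian_kde(vals, grid[1:50], bandwidth = h),
               kde_oracle(vals, grid[1:50], h), tolerance = 1e-12)
  expect_error(gaussian_kde(vals, grid, bandwidth = -1),
               class = "coex_argument_error")
  expect_error(gaussian_kde(0, grid = 0), class = "coex_argument_error")
})
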