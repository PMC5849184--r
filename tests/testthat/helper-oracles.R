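# Independent oracles: definitional implementations kept deliberately free
# of the package's code paths (and of the stats shortcuts they wrap).

# BH step-up by the definition: q_(i) = min_{j >= i} p_(j) * m / j, capped.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[i] <- min(1, min(ps[js] * m / js))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Pearson r by the covariance / product-of-SDs formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  cv <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  cv / (sd(x) * sd(y))
}

# Hypergeometric pmf and upper tail from binomial coefficients only.
hyper_pmf_oracle <- function(N, K, n) {
  lo <- max(0L, n - (N - K)); hi <- min(K, n)
  x <- lo:hi
  list(x = x, pr = choose(K, x) * choose(N - K, n - x) / choose(N, n))
}

hyper_tail_oracle <- function(k, K, n, N) {
  pm <- hyper_pmf_oracle(N, K, n)
  sum(pm$pr[pm$x >= k])
}

# Fisher 2x2 p-values by enumeration over the margin-constrained tables.
fisher_oracle <- function(tab, sided) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  pm <- hyper_pmf_oracle(r1 + r2, r1, c1)   # x = top-left cell
  obs <- pm$pr[pm$x == a]
  switch(sided,
         greater = sum(pm$pr[pm$x >= a]),
         less = sum(pm$pr[pm$x <= a]),
         two = min(1, sum(pm$pr[pm$pr <= obs * (1 + 1e-7)])))
}

# Exact binomial two-sided (minimum likelihood) by enumeration.
binom_oracle <- function(k, n, p0) {
  x <- 0:n
  pr <- choose(n, x) * p0^x * (1 - p0)^(n - x)
  min(1, sum(pr[pr <= pr[k + 1] * (1 + 1e-7)]))
}

# Gaussian KDE by the plain double loop.
kde_oracle <- function(values, grid, h) {
  out <- numeric(length(grid))
  for (i in seq_along(grid)) {
    s <- 0
    for (v in values) s <- s + exp(-0.5 * ((grid[i] - v) / h)^2) / sqrt(2 * pi)
    out[i] <- s / (length(values) * h)
  }
  out
}

# Brute-force PWM rescan: character-level loops, no shared code with
# scan_sequence. Returns every finite window score on both strands.
scan_oracle <- function(weights, seq, tss_offset) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(seq, "")[[1]]
  L <- ncol(weights)
  nw <- length(chars) - L + 1
  starts <- integer(2 * nw); ends <- integer(2 * nw)
  strands <- character(2 * nw); scores <- numeric(2 * nw)
  cnt <- 0
  for (o in 0:(nw - 1)) {
    win <- chars[(o + 1):(o + L)]
    for (str in c("+", "-")) {
      w <- if (str == "+") win else rev(unname(comp[win]))
      if (any(w == "N")) next
      sc <- 0
      for (j in seq_len(L)) sc <- sc + weights[w[j], j]
      rel_s <- o - tss_offset; if (rel_s >= 0) rel_s <- rel_s + 1
      rel_e <- o + L - 1 - tss_offset; if (rel_e >= 0) rel_e <- rel_e + 1
      cnt <- cnt + 1
      starts[cnt] <- rel_s; ends[cnt] <- rel_e
      strands[cnt] <- str; scores[cnt] <- sc
    }
  }
  idx <- seq_len(cnt)
  data.frame(start_tss = starts[idx], end_tss = ends[idx],
             strand = strands[idx], score = scores[idx])
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
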