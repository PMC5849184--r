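#' Configuration for the synthetic expression generator
#'
#' Describes a single-latent-factor Gaussian dataset on the log2 scale: a
#' highly expressed hub gene, a transcription factor correlated with the
#' hub (population r = `r_hub_tf`), a gene module negatively correlated
#' with both (population r = `r_module_hub` with the hub), and independent
#' background genes. The defaults mirror the study conditions this
#' generator is meant to emulate: 400 samples, a 50-gene module planted at
#' r = -0.35 (comfortably past a |r| > 0.2 screen threshold at that sample
#' size), a hub-TF correlation of 0.18, baseline log2 intensities of mean
#' 7 and SD 1, a hub boost that places it above the 95th percentile in
#' every sample, and a more variable module (SD inflated by 50%).
#'
#' @param n_genes Total genes (module + hub + TF + background).
#' @param n_samples Samples (columns).
#' @param hub_name,tf_name Symbols for the planted hub and TF.
#' @param module_size Genes in the planted module.
#' @param r_hub_tf Target population correlation between hub and TF.
#' @param r_module_hub Target population correlation between each module
#'   gene and the hub (negative by default).
#' @param baseline_mean,baseline_sd Log2-scale mean and SD of every gene.
#' @param hub_percentile_boost Added to the hub's mean so it outranks the
#'   background in every sample.
#' @param module_extra_sd Fractional SD inflation of module genes (>= 0).
#' @param n_set_distractors Background genes mixed into the emitted
#'   curated set alongside the module.
#' @param n_decoy_tfs Decoy TF target sets in the emitted library.
#' @param seed Integer seed; same seed and config give identical output.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000, n_samples = 400,
                             hub_name = "HUB1", tf_name = "TF1",
                             module_size = 50,
                             r_hub_tf = 0.18, r_module_hub = -0.35,
                             baseline_mean = 7, baseline_sd = 1,
                             hub_percentile_boost = 6,
                             module_extra_sd = 0.5,
                             n_set_distractors = 150,
                             n_decoy_tfs = 20,
                             seed = 1) {
  if (!is_count(n_genes) || !is_count(n_samples) || n_samples < 3L)
    abort_args("'n_genes' and 'n_samples' must be integers (n_samples >= 3)")
  if (!is_count(module_size) || module_size + 2L > n_genes)
    abort_args("'module_size' + 2 must not exceed 'n_genes'")
  if (!is_scalar_number(r_hub_tf) || abs(r_hub_tf) >= 1 ||
      !is_scalar_number(r_module_hub) || abs(r_module_hub) >= 1)
    abort_args("planted correlations must lie strictly in (-1, 1)")
  if (!is_scalar_number(baseline_sd) || baseline_sd <= 0)
    abort_args("'baseline_sd' must be positive")
  if (!is_scalar_number(module_extra_sd) || module_extra_sd < 0)
    abort_args("'module_extra_sd' must be non-negative")
  if (!is_count(n_set_distractors) || !is_count(n_decoy_tfs))
    abort_args("'n_set_distractors' and 'n_decoy_tfs' must be non-negative integers")
  if (n_set_distractors > n_genes - module_size - 2L)
    abort_args("'n_set_distractors' exceeds the number of background genes")
  if (!is_count(seed)) abort_args("'seed' must be a non-negative integer")

  # factor loadings: hub = a*F, module = -c*F, tf = b*F (unit total variance)
  a <- if (r_module_hub != 0) sqrt(abs(r_module_hub))
       else if (r_hub_tf != 0) sqrt(abs(r_hub_tf)) else 0.5
  cc <- if (r_module_hub != 0) abs(r_module_hub) / a else 0
  b <- r_hub_tf / a
  if (abs(b) >= 1 || cc >= 1)
    abort_args("planted correlations are jointly unrealizable by one latent factor")

  structure(list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
                 hub_name = norm_symbols(hub_name), tf_name = norm_symbols(tf_name),
                 module_size = as.integer(module_size),
                 r_hub_tf = r_hub_tf, r_module_hub = r_module_hub,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 hub_percentile_boost = hub_percentile_boost,
                 module_extra_sd = module_extra_sd,
                 n_set_distractors = as.integer(n_set_distractors),
                 n_decoy_tfs = as.integer(n_decoy_tfs),
                 seed = as.integer(seed),
                 loading_hub = a,
                 loading_module = if (a == 0) 0 else r_module_hub / a,
                 loading_tf = b),
            class = "synthetic_config")
}

#' Generate a synthetic dataset with planted coexpression structure
#'
#' Builds the expression matrix from one latent factor F per sample:
#' `gene = mean + sd * (loading * F + sqrt(1 - loading^2) * noise)`, so the
#' population correlation between any two genes is the product of their
#' loadings. The hub carries loading `a = sqrt(|r_module_hub|)`, module
#' genes `-a` (giving hub-module correlation `r_module_hub`), and the TF
#' `r_hub_tf / a`. Alongside the matrix it emits the curated gene set
#' (module plus background distractors -- the "immune list" analog), a TF
#' target library (the planted TF's targets are the module plus the hub,
#' decoys get size-matched random target sets), and a ground-truth record
#' for recovery tests. Identical config and seed give identical output.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `matrix` ([expr_matrix()]), `gene_set`
#'   ([gene_set()]), `tf_library` ([gene_set_library()]), and `truth`.
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    ng <- cfg$n_genes; ns <- cfg$n_samples
    n_bg <- ng - cfg$module_size - 2L
    module_names <- sprintf("MOD%04d", seq_len(cfg$module_size))
    bg_names <- sprintf("BG%05d", seq_len(n_bg))
    gene_names <- c(cfg$hub_name, cfg$tf_name, module_names, bg_names)

    # population corr(gene_i, gene_j) = loading_i * loading_j
    loading <- c(cfg$loading_hub, cfg$loading_tf,
                 rep(cfg$loading_module, cfg$module_size),
                 rep(0, n_bg))

    sdvec <- rep(cfg$baseline_sd, ng)
    sdvec[3:(2 + cfg$module_size)] <- cfg$baseline_sd * (1 + cfg$module_extra_sd)
    meanvec <- rep(cfg$baseline_mean, ng)
    meanvec[1L] <- cfg$baseline_mean + cfg$hub_percentile_boost

    f <- stats::rnorm(ns)
    eps <- matrix(stats::rnorm(ng * ns), nrow = ng)
    z <- loading %o% f + sqrt(pmax(0, 1 - loading^2)) * eps
    vals <- meanvec + sdvec * z
    dimnames(vals) <- list(gene_names, sprintf("S%04d", seq_len(ns)))
    tissue <- stats::setNames(
      rep_len(c("TISSUE_A", "TISSUE_B", "TISSUE_C", "TISSUE_D"), ns),
      colnames(vals))
    m <- expr_matrix(vals, tissue = tissue)

    distractors <- sample(bg_names, cfg$n_set_distractors)
    curated <- gene_set("SYNTH_IMMUNE", c(module_names, distractors),
                        "planted module plus background distractors")

    target_size <- cfg$module_size + 1L
    planted_targets <- gene_set(cfg$tf_name, c(module_names, cfg$hub_name),
                                "planted TF target set")
    decoys <- lapply(seq_len(cfg$n_decoy_tfs), function(i)
      gene_set(sprintf("DECOY_TF%02d", i),
               sample(gene_names, target_size),
               "decoy TF with random targets"))
    tf_library <- gene_set_library("SYNTH_TF_TARGETS",
                                   c(list(planted_targets), decoys))

    truth <- list(hub_name = cfg$hub_name, tf_name = cfg$tf_name,
                  module_members = module_names,
                  r_hub_tf = cfg$r_hub_tf, r_module_hub = cfg$r_module_hub,
                  set_distractors = distractors, seed = cfg$seed)
    list(matrix = m, gene_set = curated, tf_library = tf_library, truth = truth)
  })
}

#' Generate a promoter with a planted motif consensus
#'
#' Emits an i.i.d. random background sequence with the requested GC
#' content spanning `-upstream` to `+downstream` in TSS coordinates (no
#' position 0), with the consensus string of the motif written at the
#' planted start position. Deterministic under the seed.
#'
#' @param x A [pfm()] whose consensus is planted.
#' @param upstream,downstream Bases upstream/downstream of the TSS;
#'   the sequence length is their sum and the TSS offset equals `upstream`.
#' @param plant_at TSS coordinate of the first planted base (e.g. -1411).
#' @param gc GC content of the background, in (0, 1).
#' @param seed Integer seed.
#' @return A [promoter_sequence()] with attribute `plant` giving the
#'   planted TSS-relative interval and the planted string.
#' @export
generate_promoter <- function(x, upstream = 1761, downstream = 37,
                              plant_at = -1411, gc = 0.5, seed = 1) {
  stopifnot(inherits(x, "pfm"))
  if (!is_count(upstream) || !is_count(downstream) || upstream + downstream < 1)
    abort_args("'upstream' and 'downstream' must be non-negative integers")
  if (!is_scalar_number(gc) || gc <= 0 || gc >= 1)
    abort_args("'gc' must lie strictly in (0, 1)")
  if (!is_scalar_number(plant_at) || plant_at == 0 || plant_at != floor(plant_at))
    abort_args("'plant_at' must be a non-zero integer TSS coordinate")
  len <- upstream + downstream
  consensus <- consensus_of(x)
  L <- nchar(consensus)
  offset <- if (plant_at < 0) plant_at + upstream else plant_at - 1L + upstream
  if (offset < 0 || offset + L > len)
    abort_args("planted interval does not fit inside the promoter")
  with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    bases <- sample(names(probs), len, replace = TRUE, prob = probs)
    bases[(offset + 1L):(offset + L)] <- strsplit(consensus, "")[[1L]]
    prom <- promoter_sequence("synthetic_promoter",
                              paste(bases, collapse = ""),
                              tss_offset = upstream)
    attr(prom, "plant") <- list(start_tss = offset_to_tss(offset, upstream),
                                end_tss = offset_to_tss(offset + L - 1L, upstream),
                                consensus = as.character(consensus))
    prom
  })
}
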