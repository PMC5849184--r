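#' Read a pipeline configuration from YAML
#'
#' The configuration is one declarative file naming the inputs and
#' thresholds of a full run; see [run_pipeline()] for the recognized keys.
#' Referenced files are checked for existence before any computation.
#'
#' @param path Path to a YAML file.
#' @return A list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p), p, file.path(base, p))
  }
  for (key in c("expression", "pfm", "promoter"))
    if (!is.null(cfg[[key]]) && !is.null(cfg[[key]]$path))
      cfg[[key]]$path <- resolve(cfg[[key]]$path)
  for (key in c("gene_lists", "libraries"))
    if (!is.null(cfg[[key]])) cfg[[key]] <- lapply(cfg[[key]], resolve)
  if (!is.null(cfg$tf_library)) cfg$tf_library <- resolve(cfg$tf_library)
  pipeline_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param cfg A named list. Required: `expression` (list with `path` and
#'   optional `dialect`), `query`. Optional: `normalize` (logical; apply
#'   quantile normalization after load), `r_min`, `q_max`, `gene_lists`
#'   (named list of gene-list paths), `libraries` (named list of GMT
#'   paths), `tf_library` (GMT path), `q_cut`, `pfm` (list with `path`),
#'   `promoter` (list with `path` and optional `tss_offset`),
#'   `scan_min_score`, `output_dir`, `seed`.
#' @return The validated list, classed `pipeline_config`.
#' @export
pipeline_config <- function(cfg) {
  if (!is.list(cfg)) abort_config("config must be a named list")
  if (is.null(cfg$expression) || is.null(cfg$expression$path))
    abort_config("config must name an expression matrix under 'expression: path:'")
  if (!file.exists(cfg$expression$path))
    abort_config(sprintf("expression file not found: %s", cfg$expression$path))
  if (is.null(cfg$query) || !nzchar(cfg$query))
    abort_config("config must name a 'query' gene")
  cfg$r_min <- cfg$r_min %||% 0.2
  cfg$q_max <- cfg$q_max %||% 1e-4
  cfg$q_cut <- cfg$q_cut %||% 0.1
  cfg$normalize <- isTRUE(cfg$normalize)
  cfg$scan_min_score <- cfg$scan_min_score %||% "80%"
  cfg$seed <- cfg$seed %||% 1L
  if (!is_scalar_number(cfg$r_min) || cfg$r_min < 0)
    abort_config("'r_min' must be a non-negative number")
  if (!is_scalar_number(cfg$q_max) || cfg$q_max <= 0 || cfg$q_max > 1)
    abort_config("'q_max' must lie in (0, 1]")
  if (!is_scalar_number(cfg$q_cut) || cfg$q_cut <= 0 || cfg$q_cut > 1)
    abort_config("'q_cut' must lie in (0, 1]")
  for (p in c(unlist(cfg$gene_lists), unlist(cfg$libraries), cfg$tf_library,
              cfg$pfm$path, cfg$promoter$path))
    if (!is.null(p) && !file.exists(p))
      abort_config(sprintf("configured input not found: %s", p))
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full guilt-by-association pipeline
#'
#' Executes the stages in order: load (and optionally quantile-normalize)
#' the expression matrix; screen the query gene genome-wide; test each
#' configured gene list for directional bias; run over-representation of
#' the screen's coexpressed genes against each GMT library; prioritize
#' transcription factors against the TF-target library using the negative
#' class as the query; scan the promoter with the configured motif. Stages
#' whose optional inputs are absent are skipped with a notice. Output
#' tables are written as TSV with fixed column order (p/q in
#' 6-significant-digit scientific notation, percentages to one decimal),
#' plus a machine-readable `summary.json`; reruns on identical inputs give
#' byte-identical tables.
#'
#' @param cfg A [pipeline_config()] (or path to a YAML file).
#' @param output_dir Directory for the report tables; overrides
#'   `cfg$output_dir`. `NULL` suppresses writing.
#' @return A list of class `report_bundle` with elements `screen`, `bias`
#'   (one [bias_report()] per gene list), `enrichment` (one table per
#'   library), `tf_ranking`, `motif_hits`, `summary` and `meta`.
#' @export
run_pipeline <- function(cfg, output_dir = cfg$output_dir) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)

  message("stage data_io: loading expression matrix")
  m <- read_expression(cfg$expression$path,
                       dialect = cfg$expression$dialect %||% "auto")
  if (cfg$normalize) {
    message("stage data_io: quantile normalization")
    m <- quantile_normalize(m)
  }
  universe <- genes(m)
  message(sprintf("stage data_io: %d genes x %d samples", nrow(m$values),
                  ncol(m$values)))

  message(sprintf("stage coexpression: screening '%s' (|r| > %g, q < %g)",
                  cfg$query, cfg$r_min, cfg$q_max))
  screen <- screen_coexpression(m, cfg$query, r_min = cfg$r_min,
                                q_max = cfg$q_max)
  message(sprintf("stage coexpression: m_tested = %d; %d positive, %d negative",
                  screen$m_tested, screen$counts[["positive"]],
                  screen$counts[["negative"]]))

  bias <- list()
  if (length(cfg$gene_lists)) {
    lists <- lapply(cfg$gene_lists, read_gene_list)
    if (is.null(names(lists)) || any(!nzchar(names(lists))))
      names(lists) <- vapply(lists, `[[`, "", "name")
    for (nm in names(lists)) {
      message(sprintf("stage set_bias: gene list '%s'", nm))
      others <- setdiff(names(lists), nm)
      bias[[nm]] <- bias_analysis(screen, lists[[nm]],
                                  comparison_set = if (length(others))
                                    lists[[others[1L]]] else NULL)
    }
  } else message("stage set_bias: no gene lists configured; skipped")

  coexpressed <- screen$records$gene[screen$records$klass != "none"]
  negatives <- screen$records$gene[screen$records$klass == "negative"]
  enrichment <- list()
  if (length(cfg$libraries) && length(coexpressed)) {
    for (nm in names(cfg$libraries)) {
      message(sprintf("stage enrichment: library '%s'", nm))
      lib <- read_gmt(cfg$libraries[[nm]], name = nm)
      enrichment[[nm]] <- enrich_sets(gene_set("coexpressed", coexpressed),
                                      lib, universe, q_cut = cfg$q_cut)
    }
  } else message("stage enrichment: no libraries configured; skipped")

  tf_ranking <- NULL
  if (!is.null(cfg$tf_library)) {
    message("stage enrichment: TF-target prioritization")
    tf_lib <- read_gmt(cfg$tf_library, name = "tf_targets")
    tf_query <- if (length(negatives)) negatives else coexpressed
    if (length(tf_query))
      tf_ranking <- prioritize_tfs(gene_set("tf_query", tf_query), tf_lib,
                                   universe)
    else message("stage enrichment: no coexpressed genes; TF ranking skipped")
  } else message("stage enrichment: no TF library configured; skipped")

  motif_hits <- NULL
  if (!is.null(cfg$pfm) && !is.null(cfg$promoter)) {
    message("stage promoter_scan: scanning promoter")
    motif <- read_jaspar_pfm(cfg$pfm$path)
    prom <- read_promoter(cfg$promoter$path,
                          tss_offset = cfg$promoter$tss_offset)
    motif_hits <- scan_sequence(pwm_from_counts(motif), prom,
                                min_score = cfg$scan_min_score)
  } else message("stage promoter_scan: no promoter/PFM configured; skipped")

  meta <- list(package_version = as.character(utils::packageVersion("coexscreen")),
               seed = cfg$seed,
               config_hash = config_hash(cfg),
               universe_size = length(universe),
               m_tested = screen$m_tested)
  bundle <- structure(list(screen = screen, bias = bias,
                           enrichment = enrichment, tf_ranking = tf_ranking,
                           motif_hits = motif_hits, meta = meta),
                      class = "report_bundle")
  if (!is.null(output_dir)) write_report_bundle(bundle, output_dir)
  bundle
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null",
                              digits = NA), f)
  unname(tools::md5sum(f))
}

fmt_sci <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "e", digits = 5L))
fmt_num <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 6L))

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a report bundle as TSV tables plus a JSON summary
#'
#' @param bundle A [run_pipeline()] result.
#' @param output_dir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_report_bundle <- function(bundle, output_dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- bundle$screen$records
  write_tsv(data.frame(gene = rec$gene, r = fmt_num(rec$r),
                       p = fmt_sci(rec$p), q = fmt_sci(rec$q),
                       class = rec$klass, degenerate = rec$degenerate),
            file.path(output_dir, "screen.tsv"))
  if (length(bundle$bias)) {
    rows <- lapply(bundle$bias, function(b)
      data.frame(set = b$set_name, n_set = b$n_set,
                 positive = b$set_counts[["positive"]],
                 negative = b$set_counts[["negative"]],
                 none = b$set_counts[["none"]],
                 pct_negative_set = format_percent(b$proportion_negative_set),
                 pct_negative_background = format_percent(b$proportion_negative_background),
                 fisher_p_negative = fmt_sci(b$fisher_p_negative),
                 sign_test_p = fmt_sci(b$sign_test_p),
                 two_proportion_p = fmt_sci(b$two_proportion_p)))
    write_tsv(do.call(rbind, c(rows, list(make.row.names = FALSE))),
              file.path(output_dir, "bias.tsv"))
  }
  for (nm in names(bundle$enrichment)) {
    e <- bundle$enrichment[[nm]]
    write_tsv(data.frame(term = e$term, overlap = sprintf("%d/%d", e$k, e$K),
                         n = e$n, N = e$N, p = fmt_sci(e$p), q = fmt_sci(e$q),
                         rank = e$rank),
              file.path(output_dir, sprintf("enrichment_%s.tsv", nm)))
  }
  if (!is.null(bundle$tf_ranking)) {
    e <- bundle$tf_ranking
    write_tsv(data.frame(tf = e$term, overlap = sprintf("%d/%d", e$k, e$K),
                         n = e$n, N = e$N, p = fmt_sci(e$p), q = fmt_sci(e$q),
                         rank = e$rank),
              file.path(output_dir, "tf_ranking.tsv"))
  }
  hits <- bundle$motif_hits
  if (is.null(hits))
    hits <- data.frame(start_tss = integer(), end_tss = integer(),
                       strand = character(), score = numeric())
  write_tsv(data.frame(start_tss = hits$start_tss, end_tss = hits$end_tss,
                       strand = hits$strand, score = fmt_num(hits$score)),
            file.path(output_dir, "motif_hits.tsv"))
  summary <- list(meta = bundle$meta,
                  screen_counts = as.list(bundle$screen$counts),
                  n_bias_sets = length(bundle$bias),
                  n_libraries = length(bundle$enrichment),
                  top_tf = if (!is.null(bundle$tf_ranking) &&
                               nrow(bundle$tf_ranking))
                    bundle$tf_ranking$term[1L] else NA,
                  n_motif_hits = nrow(hits))
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(output_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle\n")
  print(x$screen)
  cat(sprintf("  bias reports: %d; enrichment tables: %d; TF ranking: %s; motif hits: %s\n",
              length(x$bias), length(x$enrichment),
              if (is.null(x$tf_ranking)) "none" else sprintf("%d TFs", nrow(x$tf_ranking)),
              if (is.null(x$motif_hits)) "none" else nrow(x$motif_hits)))
  invisible(x)
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' Materializes a [generate_dataset()] result (expression TSV, curated
#' gene list, TF-target GMT), a motif and promoter when a PFM is given,
#' and a ready-to-run `config.yaml` pointing at the files.
#'
#' @param cfg A [synthetic_config()].
#' @param output_dir Output directory.
#' @param pfm Optional [pfm()] to plant into a synthetic promoter.
#' @return Invisibly, the path to the written `config.yaml`.
#' @export
write_synthetic_inputs <- function(cfg, output_dir, pfm = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_dataset(cfg)
  expr_path <- file.path(output_dir, "expression.tsv")
  vals <- ds$matrix$values
  write_tsv(data.frame(GENE = rownames(vals),
                       as.data.frame(vals, check.names = FALSE)), expr_path)
  list_path <- file.path(output_dir, "curated_set.txt")
  writeLines(c("# planted module plus distractors", ds$gene_set$members),
             list_path)
  tf_path <- file.path(output_dir, "tf_targets.gmt")
  write_gmt(ds$tf_library, tf_path)
  config <- list(expression = list(path = "expression.tsv", dialect = "tsv"),
                 query = ds$truth$hub_name,
                 gene_lists = list(curated = "curated_set.txt"),
                 tf_library = "tf_targets.gmt",
                 seed = cfg$seed)
  if (!is.null(pfm)) {
    pfm_path <- file.path(output_dir, "motif.pfm")
    writeLines(c(sprintf(">%s", pfm$name),
                 vapply(c("A", "C", "G", "T"), function(b)
                   sprintf("%s [ %s ]", b,
                           paste(pfm$counts[b, ], collapse = " ")), "")),
               pfm_path)
    prom <- generate_promoter(pfm, seed = cfg$seed)
    prom_path <- file.path(output_dir, "promoter.fa")
    writeLines(c(sprintf(">%s tss=%d", prom$id, prom$tss_offset),
                 prom$sequence), prom_path)
    config$pfm <- list(path = "motif.pfm")
    config$promoter <- list(path = "promoter.fa", tss_offset = prom$tss_offset)
  }
  cfg_path <- file.path(output_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  jsonlite::write_json(ds$truth, file.path(output_dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(cfg_path)
}
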