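# Internal helpers: classed error conditions and symbol normalization.

coex_abort <- function(msg, class, call = sys.call(-2)) {
  stop(errorCondition(msg, class = c(class, "coex_error", "error"), call = call))
}

abort_format <- function(msg) coex_abort(msg, "coex_format_error")
abort_data   <- function(msg) coex_abort(msg, "coex_data_error")
abort_args   <- function(msg) coex_abort(msg, "coex_argument_error")
abort_key    <- function(msg) coex_abort(msg, "coex_key_error")
abort_config <- function(msg) coex_abort(msg, "coex_config_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# All gene symbols are compared after upper-casing, so that list/matrix
# intersections are deterministic regardless of source capitalization.
norm_symbols <- function(x) toupper(trimws(as.character(x)))

# tab-split that keeps trailing empty fields (strsplit drops them)
split_tabs <- function(lines) {
  lapply(strsplit(paste0(lines, "\t\x01"), "\t", fixed = TRUE),
         function(f) f[-length(f)])
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
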