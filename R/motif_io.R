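#' Construct a position frequency matrix
#'
#' @param name Motif name.
#' @param counts 4 x L non-negative numeric matrix, rows in A, C, G, T
#'   order. Every column must have a positive sum.
#' @return An object of class `pfm`.
#' @export
pfm <- function(name, counts) {
  if (!is.matrix(counts) || !is.numeric(counts) || nrow(counts) != 4L)
    abort_args("'counts' must be a 4-row numeric matrix (A, C, G, T)")
  if (ncol(counts) < 1L) abort_format("PFM must have at least one column")
  if (any(!is.finite(counts)) || any(counts < 0))
    abort_data("PFM counts must be finite and non-negative")
  if (any(colSums(counts) <= 0))
    abort_format("every PFM column must have a positive count sum")
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(name = as.character(name), counts = counts), class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("pfm '%s': %d positions, consensus %s\n",
              x$name, ncol(x$counts), consensus_of(x)))
  invisible(x)
}

#' Read a JASPAR-format position frequency matrix
#'
#' Accepts the JASPAR text dialect: an optional `>` header line followed by
#' four rows labeled A/C/G/T holding whitespace-separated counts, with or
#' without surrounding brackets (`A [ 4 0 ]` or `A 4 0`).
#'
#' @param path Path to the matrix file.
#' @return A [pfm()].
#' @export
read_jaspar_pfm <- function(path) {
  if (!file.exists(path)) abort_args(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  name <- tools::file_path_sans_ext(basename(path))
  if (length(lines) > 0L && startsWith(trimws(lines[1L]), ">")) {
    name <- trimws(sub("^>", "", trimws(lines[1L])))
    lines <- lines[-1L]
  }
  rows <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([ACGTacgt])\\s*[:|]?\\s*\\[?([^]]*)\\]?\\s*$", ln))[[1L]]
    if (length(m) != 3L)
      abort_format(sprintf("unparseable PFM row: '%s'", ln))
    base <- toupper(m[2L])
    nums <- strsplit(trimws(m[3L]), "\\s+")[[1L]]
    nums <- suppressWarnings(as.numeric(nums[nzchar(nums)]))
    if (length(nums) == 0L || any(is.na(nums)))
      abort_format(sprintf("non-numeric counts in PFM row for base %s", base))
    if (any(nums < 0))
      abort_data(sprintf("negative count in PFM row for base %s", base))
    if (base %in% names(rows))
      abort_format(sprintf("duplicate PFM row for base %s", base))
    rows[[base]] <- nums
  }
  missing <- setdiff(c("A", "C", "G", "T"), names(rows))
  if (length(missing))
    abort_format(sprintf("PFM is missing row(s): %s", paste(missing, collapse = ", ")))
  if (length(unique(lengths(rows))) != 1L)
    abort_format("PFM rows have unequal lengths")
  pfm(name, rbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T))
}

#' Construct a promoter sequence with a declared TSS
#'
#' @param id Sequence identifier.
#' @param sequence DNA string over A, C, G, T, N (case-insensitive).
#' @param tss_offset 0-based index, within the sequence, of the +1 base
#'   (the transcription start site); may equal the sequence length when the
#'   whole sequence is upstream.
#' @return An object of class `promoter_sequence`.
#' @export
promoter_sequence <- function(id, sequence, tss_offset) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || !nzchar(sequence))
    abort_args("'sequence' must be a single non-empty string")
  if (grepl("[^ACGTN]", sequence))
    abort_data("promoter sequence may contain only A, C, G, T or N")
  if (!is_count(tss_offset) || tss_offset > nchar(sequence))
    abort_args("'tss_offset' must be an integer in [0, sequence length]")
  structure(list(id = as.character(id), sequence = sequence,
                 tss_offset = as.integer(tss_offset)),
            class = "promoter_sequence")
}

#' @export
print.promoter_sequence <- function(x, ...) {
  cat(sprintf("promoter '%s': %d bp, TSS at offset %d (-%d/+%d)\n",
              x$id, nchar(x$sequence), x$tss_offset, x$tss_offset,
              nchar(x$sequence) - x$tss_offset))
  invisible(x)
}

#' Read a promoter sequence from FASTA
#'
#' The first record is used. The TSS offset may be supplied as an argument
#' or embedded in the FASTA description line as a `tss=<int>` key.
#'
#' @param path Path to the FASTA file.
#' @param tss_offset 0-based offset of the +1 base; overrides any `tss=` key.
#' @return A [promoter_sequence()].
#' @export
read_promoter <- function(path, tss_offset = NULL) {
  if (!file.exists(path)) abort_args(sprintf("file not found: %s", path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) abort_format("FASTA file holds no sequence")
  desc <- names(seqs)[1L]
  if (is.null(tss_offset)) {
    m <- regmatches(desc, regexec("tss=([0-9]+)", desc))[[1L]]
    if (length(m) == 2L) tss_offset <- as.integer(m[2L])
    else abort_args("no 'tss_offset' given and no 'tss=<int>' key in the FASTA header")
  }
  id <- strsplit(trimws(desc), "\\s+")[[1L]][1L]
  promoter_sequence(id, as.character(seqs[[1L]]), tss_offset)
}
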