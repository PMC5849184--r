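#' Construct a gene set
#'
#' @param name Set name.
#' @param members Character vector of gene symbols; upper-cased and
#'   de-duplicated, must be non-empty.
#' @param description Free-text description (may be empty).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, members, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    abort_args("'name' must be a non-empty string")
  members <- unique(norm_symbols(members))
  members <- members[nzchar(members)]
  if (length(members) == 0L)
    abort_data(sprintf("gene set '%s' has no members", name))
  structure(list(name = name, description = as.character(description),
                 members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d members\n", x$name, length(x$members)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

#' Construct a gene-set library
#'
#' @param name Library name.
#' @param sets List of [gene_set()] objects with unique names.
#' @return An object of class `gene_set_library`.
#' @export
gene_set_library <- function(name, sets) {
  if (!is.list(sets) || length(sets) == 0L ||
      !all(vapply(sets, inherits, TRUE, "gene_set")))
    abort_args("'sets' must be a non-empty list of gene_set objects")
  nm <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(nm))
    abort_format(sprintf("duplicate set name in library: %s", nm[duplicated(nm)][1L]))
  names(sets) <- nm
  structure(list(name = name, sets = sets), class = "gene_set_library")
}

#' @export
print.gene_set_library <- function(x, ...) {
  cat(sprintf("gene_set_library '%s': %d sets\n", x$name, length(x$sets)))
  invisible(x)
}

#' @export
length.gene_set_library <- function(x) length(x$sets)

#' Read a gene list (one symbol per line)
#'
#' Blank lines and `#` comments are ignored; symbols are upper-cased and
#' de-duplicated.
#'
#' @param path Path to the list file.
#' @param name Set name; defaults to the file name without extension.
#' @param description Optional description.
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, name = NULL, description = "") {
  if (!file.exists(path)) abort_args(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  gene_set(name %||% tools::file_path_sans_ext(basename(path)),
           lines, description)
}

#' Read a GMT gene-set library
#'
#' Each line is `name<TAB>description<TAB>member<TAB>member...`. Empty member
#' fields are dropped; symbols are upper-cased. Lines with fewer than three
#' fields and duplicate set names are format errors.
#'
#' @param path Path to the GMT file.
#' @param name Library name; defaults to the file name without extension.
#' @return A [gene_set_library()].
#' @export
read_gmt <- function(path, name = NULL) {
  if (!file.exists(path)) abort_args(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort_format("GMT file has no records")
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      abort_format(sprintf("GMT line %d has %d fields; need name, description and members",
                           i, length(f)))
    members <- f[-(1:2)]
    members <- members[nzchar(trimws(members))]
    if (length(members) == 0L)
      abort_format(sprintf("GMT line %d ('%s') has no non-empty members", i, f[1L]))
    sets[[i]] <- gene_set(f[1L], members, f[2L])
  }
  nm <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(nm))
    abort_format(sprintf("duplicate set name in GMT: %s", nm[duplicated(nm)][1L]))
  gene_set_library(name %||% tools::file_path_sans_ext(basename(path)), sets)
}

#' Write a gene-set library to GMT
#'
#' @param library A [gene_set_library()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(library, path) {
  stopifnot(inherits(library, "gene_set_library"))
  lines <- vapply(library$sets, function(s)
    paste(c(s$name, s$description, s$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
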