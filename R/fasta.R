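#' Read a protein FASTA file into a tibble
#'
#' One row per record. The header up to the first whitespace is the record
#' id (must be unique); the remainder is kept as `description`. Residues are
#' uppercased and wrapped lines concatenated. Trailing stop symbols (`*`)
#' emitted by gene callers are stripped; an internal `*` indicates a broken
#' ORF and is a hard error, as is any character outside the 20 standard
#' amino-acid letters plus `X`.
#'
#' @param path Path to a protein FASTA file.
#' @return A tibble with columns `id`, `description`, `residues`, in file
#'   order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- Biostrings::readAAStringSet(path)
  nm <- names(set)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  res <- toupper(as.character(set))
  validate_records(id, res)
  tibble(id = id, description = desc,
         residues = vapply(res, clean_residues, "", USE.NAMES = FALSE))
}

validate_records <- function(id, res) {
  dup <- unique(id[duplicated(id)])
  if (length(dup)) abort(paste0("duplicate sequence id(s): ",
                                paste(dup, collapse = ", ")))
  if (any(grepl("\\s", id)) || any(!nzchar(id))) {
    abort("sequence ids must be non-empty and contain no whitespace")
  }
  invisible(TRUE)
}

# strip trailing '*' stops, then enforce the residue alphabet
clean_residues <- function(x, what = "sequence") {
  x <- sub("\\*+$", "", x)
  if (!nzchar(x)) abort(paste0("empty ", what, " after removing stop symbols"))
  bad <- regexpr(paste0("[^", paste(AA20, collapse = ""), "X]"), x)
  if (bad > 0) {
    abort(sprintf("invalid residue '%s' at position %d (internal '*' or non-amino-acid letter)",
                  substr(x, bad, bad), bad))
  }
  x
}

#' Write protein records to FASTA
#'
#' @param records Tibble with columns `id`, `residues` and optionally
#'   `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "residues") %in% names(records)))
  nm <- records$id
  if (!is.null(records$description)) {
    nm <- ifelse(nzchar(records$description),
                 paste(records$id, records$description), records$id)
  }
  set <- Biostrings::AAStringSet(setNames(records$residues, nm))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
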