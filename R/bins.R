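#' Read a candidate-to-MAG membership table
#'
#' Two tab-separated columns, candidate id and bin (MAG) label, no header;
#' lines starting with `#` are ignored. Candidates absent from the table are
#' treated downstream as bin `"UNBINNED"`. Listing one candidate under two
#' different bins is an error.
#'
#' @param path Path to the table; an empty file yields an empty mapping.
#' @return A tibble with columns `candidate_id`, `bin_id`.
#' @export
read_bins <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble(candidate_id = character(), bin_id = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 0L) < 2)) {
    abort("bins table rows must have two tab-separated columns")
  }
  out <- tibble(candidate_id = vapply(parts, `[[`, "", 1),
                bin_id = vapply(parts, `[[`, "", 2))
  out <- dplyr::distinct(out)
  dup <- out$candidate_id[duplicated(out$candidate_id)]
  if (length(dup)) {
    abort(paste0("candidate(s) assigned to more than one bin: ",
                 paste(unique(dup), collapse = ", ")))
  }
  out
}

#' Write a bins table
#' @param bins Tibble with columns `candidate_id`, `bin_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bins <- function(bins, path) {
  writeLines(paste(bins$candidate_id, bins$bin_id, sep = "\t"), path)
  invisible(path)
}
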