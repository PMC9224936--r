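#' Scoring scheme for pairwise protein alignment
#'
#' Bundles a symmetric amino-acid substitution matrix with affine gap
#' penalties. The default is BLOSUM62 with gap open 11 and gap extend 1,
#' the classic BLASTP protein defaults. A gap run of length \eqn{L} costs
#' \eqn{\mathrm{open} + L \cdot \mathrm{extend}} (NCBI semantics, so a
#' single-residue gap under 11/1 costs 12).
#'
#' The matrix is restricted to the 20 standard residues plus `X`; the `X`
#' row and column are forced to 0 so an unknown residue neither rewards nor
#' penalizes any pairing (and can never demonstrate site conservation).
#'
#' @param matrix Either the string `"BLOSUM62"` (the packaged default) or a
#'   symmetric numeric matrix with single-letter row/column names covering
#'   at least the 20 standard residues.
#' @param gap_open Nonnegative gap-opening penalty (positive number; it is
#'   subtracted).
#' @param gap_extend Nonnegative gap-extension penalty, `<= gap_open`.
#' @return An object of class `mco_scheme`: a list with elements `matrix`
#'   (21 x 21 named matrix incl. `X`), `gap_open`, `gap_extend`.
#' @examples
#' sc <- mco_scheme()
#' sc$matrix["H", "H"]
#' @export
mco_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (is.character(matrix) && length(matrix) == 1) {
    if (!identical(matrix, "BLOSUM62")) {
      abort(paste0("unknown named matrix '", matrix, "'"))
    }
    m <- blosum62_matrix()
  } else if (is.matrix(matrix) && is.numeric(matrix)) {
    if (!all(AA20 %in% rownames(matrix)) || !all(AA20 %in% colnames(matrix))) {
      abort("custom matrix must cover the 20 standard amino-acid letters")
    }
    keep <- c(AA20, intersect("X", rownames(matrix)))
    m <- matrix[keep, keep, drop = FALSE]
    if (!"X" %in% rownames(m)) {
      m <- rbind(cbind(m, X = 0), X = 0)
      colnames(m)[ncol(m)] <- "X"
    }
  } else {
    abort("`matrix` must be \"BLOSUM62\" or a numeric matrix")
  }
  m["X", ] <- 0
  m[, "X"] <- 0
  if (!isTRUE(all.equal(m, t(m)))) abort("substitution matrix must be symmetric")
  if (!is.numeric(gap_open) || gap_open < 0) abort("gap_open must be nonnegative")
  if (!is.numeric(gap_extend) || gap_extend < 0 || gap_extend > gap_open) {
    abort("gap_extend must be nonnegative and <= gap_open")
  }
  structure(
    list(matrix = m, gap_open = as.numeric(gap_open),
         gap_extend = as.numeric(gap_extend)),
    class = "mco_scheme"
  )
}

#' @export
print.mco_scheme <- function(x, ...) {
  cat("<mco_scheme> ", nrow(x$matrix), "-letter matrix, gap open ",
      x$gap_open, " / extend ", x$gap_extend, "\n", sep = "")
  invisible(x)
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[c(AA20, "X"), c(AA20, "X")]
  storage.mode(m) <- "double"
  m
}

#' Background amino-acid frequencies of BLOSUM62
#'
#' The marginal residue frequencies underlying the BLOSUM62 target
#' distribution, used as the default profile background and as the sampling
#' distribution for synthetic ancestors.
#'
#' @return Named numeric vector over the 20 standard residues, summing to 1.
#' @export
blosum62_background <- function() {
  bg <- c(
    A = 0.07422, R = 0.05161, N = 0.04465, D = 0.05363, C = 0.02469,
    Q = 0.03426, E = 0.05431, G = 0.07415, H = 0.02621, I = 0.06792,
    L = 0.09891, K = 0.05816, M = 0.02499, F = 0.04742, P = 0.03854,
    S = 0.05723, T = 0.05089, W = 0.01303, Y = 0.03228, V = 0.07292
  )
  bg / sum(bg)
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-separated matrix format used by NCBI BLAST data
#' files (`#` comment lines, a header row of letters, one labelled row per
#' letter). The packaged copy of BLOSUM62 lives at
#' `system.file("extdata", "BLOSUM62.txt", package = "mcoscreen")`.
#'
#' @param path Path to the matrix file.
#' @return Symmetric numeric matrix with letter dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) abort("matrix file has no data")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  lab <- vapply(rows, `[[`, "", 1)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
  dimnames(vals) <- list(lab, header)
  vals
}

write_score_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(" ", paste(colnames(m), collapse = "  ")), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(rownames(m)[i], paste(format(m[i, ], trim = TRUE),
                                           collapse = " ")), con)
  }
  invisible(path)
}
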