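#' Pairwise protein alignment with affine gaps
#'
#' Optimal local (Smith-Waterman) or global (Needleman-Wunsch, end gaps
#' penalized) alignment of two protein sequences under an [mco_scheme()].
#' Co-optimal alignments are resolved deterministically: a residue pair is
#' preferred over a deletion (query residue against a gap), which is
#' preferred over an insertion. A local alignment may be empty (score 0, no
#' columns) when every pairing scores negatively.
#'
#' @param query,subject Protein sequences as character scalars (uppercase,
#'   20 standard letters plus `X`).
#' @param scheme An [mco_scheme()].
#' @param mode `"local"` or `"global"`.
#' @return An object of class `mco_alignment`: list with `score`, `mode`,
#'   `identity_pct`, and `pairs`, a tibble of aligned columns with 1-based
#'   `q_pos`/`s_pos` (`NA` marks a gap) and the paired letters
#'   `q_res`/`s_res`. Percent identity counts columns with equal letters
#'   over *all* alignment columns, gap columns included (BLAST convention);
#'   see `identity_gapless` in the returned object for the gap-free
#'   denominator variant.
#' @examples
#' sc <- mco_scheme()
#' align_pair("MKHLV", "MKHIV", sc, "global")$identity_pct
#' @export
align_pair <- function(query, subject, scheme, mode = c("local", "global")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "mco_scheme"))
  if (!nzchar(query) || !nzchar(subject)) abort("sequences must be non-empty")
  raw <- .align_affine_cpp(query, subject, scheme$matrix, scheme$gap_open,
                           scheme$gap_extend, identical(mode, "local"))
  q_pos <- ifelse(raw$q_pos == 0L, NA_integer_, raw$q_pos)
  s_pos <- ifelse(raw$s_pos == 0L, NA_integer_, raw$s_pos)
  qc <- strsplit(query, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  pairs <- tibble(
    q_pos = q_pos, s_pos = s_pos,
    q_res = ifelse(is.na(q_pos), "-", qc[q_pos]),
    s_res = ifelse(is.na(s_pos), "-", sc[s_pos])
  )
  n_cols <- nrow(pairs)
  resres <- !is.na(pairs$q_pos) & !is.na(pairs$s_pos)
  n_ident <- sum(resres & pairs$q_res == pairs$s_res)
  structure(
    list(
      score = raw$score, mode = mode, pairs = pairs,
      identity_pct = if (n_cols) 100 * n_ident / n_cols else 0,
      identity_gapless = if (sum(resres)) 100 * n_ident / sum(resres) else 0,
      n_identical = n_ident, n_columns = n_cols,
      query_length = length(qc), subject_length = length(sc)
    ),
    class = "mco_alignment"
  )
}

#' @export
print.mco_alignment <- function(x, ...) {
  cat(sprintf("<mco_alignment> %s, score %.1f, %d columns, identity %.1f%%\n",
              x$mode, x$score, x$n_columns, x$identity_pct))
  if (x$n_columns) {
    cat(" query:   ", paste(x$pairs$q_res, collapse = ""), "\n", sep = "")
    cat(" subject: ", paste(x$pairs$s_res, collapse = ""), "\n", sep = "")
  }
  invisible(x)
}

#' @describeIn align_pair Aligned columns as a tibble.
#' @param x An `mco_alignment`.
#' @param ... Unused.
#' @export
tidy.mco_alignment <- function(x, ...) x$pairs

#' Criterion 1: homology to known Mn-oxidizing genes
#'
#' Aligns the candidate locally against every POSITIVE reference and keeps
#' the reference maximizing percent identity of the best local alignment
#' (ties: higher alignment score, then lexicographic `ref_id`). The
#' criterion passes when identity is *strictly* greater than
#' `threshold_pct` (the screen's ">30%" rule). The winning reference
#' becomes the candidate's assigned known Mn-oxidizing gene, reused by
#' criteria 3 and 4.
#'
#' @param candidate Candidate residues (character scalar).
#' @param refs Reference tibble as from [read_refdb()]; rows with role
#'   other than `POSITIVE` are ignored.
#' @param scheme An [mco_scheme()].
#' @param threshold_pct Identity threshold in percent, in (0, 100).
#' @return A one-row tibble: `pass`, `best_ref_id`, `best_gene_name`,
#'   `identity_pct`, `score`.
#' @export
criterion1 <- function(candidate, refs, scheme, threshold_pct = 30) {
  refs <- refs[refs$role == "POSITIVE", , drop = FALSE]
  if (nrow(refs) == 0) abort("criterion 1 requires at least one POSITIVE reference")
  if (threshold_pct <= 0 || threshold_pct >= 100) {
    abort("threshold_pct must lie in (0, 100)")
  }
  hits <- purrr::map(refs$residues,
                     ~align_pair(candidate, .x, scheme, "local"))
  tab <- tibble(
    ref_id = refs$ref_id, gene_name = refs$gene_name,
    identity_pct = vapply(hits, `[[`, 0, "identity_pct"),
    score = vapply(hits, `[[`, 0, "score")
  )
  tab <- tab[order(-tab$identity_pct, -tab$score, tab$ref_id), ]
  best <- tab[1, ]
  tibble(
    pass = best$identity_pct > threshold_pct,
    best_ref_id = best$ref_id, best_gene_name = best$gene_name,
    identity_pct = best$identity_pct, score = best$score
  )
}
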