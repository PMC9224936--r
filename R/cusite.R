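#' Transfer copper-binding sites onto a candidate
#'
#' Globally aligns the candidate to its assigned reference and reads off,
#' for each annotated T1/T2/T3a/T3b position, the candidate residue aligned
#' to it. A reference position that falls in a gap column is `UNMAPPED`
#' (`candidate_position = NA`) and counts as unconserved — a gapped-out
#' copper ligand cannot bind copper. A site is conserved when the observed
#' candidate letter belongs to the annotated allowed set; `X` never
#' satisfies a site (an unknown residue cannot demonstrate conservation).
#'
#' @param candidate Candidate residues (character scalar).
#' @param ref One row of a [read_refdb()] tibble (with non-empty `sites`).
#' @param scheme An [mco_scheme()].
#' @return Tibble of site checks: `label`, `ref_position`,
#'   `candidate_position` (`NA` if unmapped), `observed` (`NA` if
#'   unmapped), `allowed`, `conserved`.
#' @export
map_sites <- function(candidate, ref, scheme) {
  st <- ref$sites[[1]]
  if (is.null(st) || nrow(st) == 0) {
    abort("reference has no annotated copper-binding sites")
  }
  al <- align_pair(candidate, ref$residues, scheme, "global")
  ok <- !is.na(al$pairs$q_pos) & !is.na(al$pairs$s_pos)
  q_at <- rep(NA_integer_, nchar(ref$residues))
  q_at[al$pairs$s_pos[ok]] <- al$pairs$q_pos[ok]
  cand_letters <- strsplit(candidate, "")[[1]]
  cand_pos <- q_at[st$position]
  observed <- ifelse(is.na(cand_pos), NA_character_, cand_letters[cand_pos])
  conserved <- purrr::map2_lgl(observed, st$allowed, function(o, a) {
    !is.na(o) && o != "X" && o %in% strsplit(a, "")[[1]]
  })
  tibble(
    label = st$label, ref_position = st$position,
    candidate_position = cand_pos, observed = observed,
    allowed = st$allowed, conserved = conserved
  )
}

#' Criterion 3: conservation of the four copper-binding centres
#'
#' Passes only when the reference annotates all four labels (T1, T2, T3a,
#' T3b) and *every* annotated site position is conserved in the candidate.
#' A missing label fails closed.
#'
#' @inheritParams map_sites
#' @return A list with `pass` (flag) and `checks` (the [map_sites()]
#'   tibble).
#' @export
criterion3 <- function(candidate, ref, scheme) {
  checks <- map_sites(candidate, ref, scheme)
  all_labels <- all(c("T1", "T2", "T3a", "T3b") %in% checks$label)
  list(pass = all_labels && all(checks$conserved), checks = checks)
}

# serialize site evidence for the report, e.g. "T1:H45=H(ok);T2:C80=A(miss)"
format_site_evidence <- function(checks, ref_residues) {
  ref_letters <- strsplit(ref_residues, "")[[1]]
  status <- ifelse(is.na(checks$observed), "unmapped",
                   ifelse(checks$conserved, "ok", "miss"))
  obs <- ifelse(is.na(checks$observed), "-", checks$observed)
  paste(sprintf("%s:%s%d=%s(%s)", checks$label,
                ref_letters[checks$ref_position], checks$ref_position,
                obs, status),
        collapse = ";")
}
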