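#' Criterion 2 profile: reference-derived position-specific scoring matrix
#'
#' Builds a log-odds profile over the coordinates of an anchor reference
#' (the longest POSITIVE reference; ties broken by lexicographic `ref_id`).
#' Every other reference is globally aligned to the anchor and residue
#' counts are accumulated per anchor column; the anchor's own residues are
#' counted too. Columns where more than half of the references are gapped
#' are dropped. Per-column letter scores are
#' \deqn{s_a = \log\frac{(c_a + \tau b_a)/(n + \tau)}{b_a}}
#' with count \eqn{c_a}, column total \eqn{n}, pseudocount \eqn{\tau} and
#' background frequency \eqn{b_a}. As \eqn{\tau \to \infty} all scores
#' shrink to 0. This profile is the in-package analogue of an external
#' domain-model check: a candidate "compatible with the domain" scores far
#' above composition-matched noise.
#'
#' @param refs Reference tibble; only `POSITIVE` rows are used and at least
#'   two are required.
#' @param scheme An [mco_scheme()] used for the anchor alignments.
#' @param pseudocount Nonnegative pseudocount \eqn{\tau} (default 1).
#' @param background Named background frequencies over the 20 residues
#'   (default [blosum62_background()]).
#' @return An object of class `mco_profile`: `anchor_ref`, `anchor_seq`,
#'   `positions` (kept anchor coordinates), `scores` (20 x n matrix),
#'   `background`, `pseudocount`.
#' @export
build_profile <- function(refs, scheme, pseudocount = 1,
                          background = blosum62_background()) {
  refs <- refs[refs$role == "POSITIVE", , drop = FALSE]
  if (nrow(refs) < 2) abort("profile needs at least two POSITIVE references")
  if (pseudocount < 0) abort("pseudocount must be nonnegative")
  bg <- background[AA20]
  if (anyNA(bg) || any(bg <= 0)) abort("background must be positive over the 20 letters")
  bg <- bg / sum(bg)

  len <- nchar(refs$residues)
  ord <- order(-len, refs$ref_id)
  anchor <- refs[ord[1], ]
  others <- refs[refs$ref_id != anchor$ref_id, , drop = FALSE]
  L <- nchar(anchor$residues)
  counts <- matrix(0, nrow = 20, ncol = L, dimnames = list(AA20, NULL))
  gapped <- integer(L)

  add_seq <- function(letters_at) {
    # letters_at: character vector over anchor positions, NA = gap
    for (p in which(!is.na(letters_at))) {
      a <- letters_at[p]
      if (a %in% AA20) counts[a, p] <<- counts[a, p] + 1
    }
    gapped <<- gapped + as.integer(is.na(letters_at))
  }

  anchor_letters <- strsplit(anchor$residues, "")[[1]]
  add_seq(anchor_letters)
  for (i in seq_len(nrow(others))) {
    al <- align_pair(others$residues[i], anchor$residues, scheme, "global")
    letters_at <- rep(NA_character_, L)
    ok <- !is.na(al$pairs$q_pos) & !is.na(al$pairs$s_pos)
    letters_at[al$pairs$s_pos[ok]] <- al$pairs$q_res[ok]
    add_seq(letters_at)
  }

  n_refs <- nrow(refs)
  keep <- which(gapped <= n_refs / 2)
  tot <- colSums(counts)[keep]
  scores <- log(sweep(counts[, keep, drop = FALSE] + pseudocount * bg,
                      2, tot + pseudocount, "/") / bg)
  structure(
    list(anchor_ref = anchor$ref_id, anchor_seq = anchor$residues,
         positions = keep, scores = scores, background = bg,
         pseudocount = pseudocount),
    class = "mco_profile"
  )
}

#' @export
print.mco_profile <- function(x, ...) {
  cat(sprintf("<mco_profile> anchor %s, %d/%d columns kept, pseudocount %g\n",
              x$anchor_ref, length(x$positions), nchar(x$anchor_seq),
              x$pseudocount))
  invisible(x)
}

#' @describeIn build_profile Long tibble of per-column letter scores.
#' @param x An `mco_profile`.
#' @param ... Unused.
#' @export
tidy.mco_profile <- function(x, ...) {
  tibble(
    position = rep(x$positions, each = 20),
    letter = rep(AA20, times = length(x$positions)),
    score = as.vector(x$scores)
  )
}

profile_colmap <- function(profile) {
  colmap <- integer(nchar(profile$anchor_seq))
  colmap[profile$positions] <- seq_along(profile$positions)
  colmap
}

#' Score a candidate against a profile
#'
#' The candidate is globally aligned to the profile anchor; the score is the
#' sum of column log-odds of the candidate letter over residue-residue
#' columns whose anchor position the profile retained, plus a fixed penalty
#' per gap column. `X` and dropped columns contribute 0.
#'
#' @param profile An [build_profile()] result.
#' @param candidate Candidate residues (character scalar).
#' @param scheme An [mco_scheme()].
#' @param gap_penalty Per-gap-column contribution (default -1).
#' @return Numeric score in nats.
#' @export
profile_score <- function(profile, candidate, scheme, gap_penalty = -1) {
  stopifnot(inherits(profile, "mco_profile"))
  .profile_score_cpp(candidate, profile$anchor_seq, scheme$matrix,
                     scheme$gap_open, scheme$gap_extend,
                     profile_colmap(profile), profile$scores, gap_penalty)
}

#' Criterion 2: domain compatibility via a permutation null
#'
#' Compares the candidate's profile score with the scores of `n_perm`
#' uniform residue shuffles of the candidate (composition- and
#' length-preserving null), each re-aligned and re-scored. The empirical
#' p-value is \eqn{(1 + k)/(1 + n_{perm})} with \eqn{k} the number of
#' shuffles scoring at least as high as the observed candidate; the
#' criterion passes when \eqn{p \le \alpha}.
#'
#' @inheritParams profile_score
#' @param n_perm Number of shuffles, at least 99 (default 999).
#' @param alpha Significance level (default 0.005).
#' @param rng_seed Integer seed driving the shuffles.
#' @return A one-row tibble: `pass`, `pvalue`, `observed`.
#' @export
criterion2 <- function(profile, candidate, scheme, n_perm = 999,
                       alpha = 0.005, rng_seed = 1, gap_penalty = -1) {
  if (n_perm < 99) abort("n_perm must be at least 99")
  if (1 / (1 + n_perm) > alpha) {
    abort(sprintf(paste0("alpha = %g is unattainable with %d permutations ",
                         "(minimum p-value is %g); raise n_perm or alpha"),
                  alpha, n_perm, 1 / (1 + n_perm)))
  }
  obs <- profile_score(profile, candidate, scheme, gap_penalty)
  set.seed(as.integer(rng_seed))
  perm <- .perm_profile_scores_cpp(candidate, profile$anchor_seq,
                                   scheme$matrix, scheme$gap_open,
                                   scheme$gap_extend, profile_colmap(profile),
                                   profile$scores, gap_penalty,
                                   as.integer(n_perm))
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  tibble(pass = p <= alpha, pvalue = p, observed = obs)
}
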