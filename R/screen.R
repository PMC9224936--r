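#' Screen configuration
#'
#' Thresholds and knobs of the four-criterion screen. Defaults: identity
#' threshold 30% (strict `>`), permutation-null significance alpha = 0.005
#' with 999 shuffles, BLOSUM62 with gap open 11 / extend 1, profile
#' pseudocount 1, per-gap-column profile penalty -1, Poisson-distance
#' saturation cap 10.
#'
#' @param identity_threshold_pct Criterion-1 percent-identity threshold,
#'   in (0, 100).
#' @param alpha Criterion-2 significance level. Must be attainable under
#'   the permutation null, i.e. `alpha >= 1/(n_perm + 1)`.
#' @param n_perm Criterion-2 shuffle count (>= 99).
#' @param scheme An [mco_scheme()].
#' @param rng_seed Integer master seed; each candidate's permutation null
#'   is seeded from this plus a hash of the candidate id, so results for
#'   one candidate do not depend on which other candidates are screened.
#' @param run_criterion2 Run the permutation-null domain check? When
#'   `FALSE` criterion 2 is recorded as not evaluated and the final call
#'   rests on criteria 1, 3 and 4 only (the pass set can only grow).
#' @param pseudocount,gap_col_penalty Profile parameters, see
#'   [build_profile()] and [profile_score()].
#' @param distance_cap Saturation cap for [pairwise_distance()].
#' @return An object of class `mco_config`.
#' @export
screen_config <- function(identity_threshold_pct = 30, alpha = 0.005,
                          n_perm = 999, scheme = mco_scheme(), rng_seed = 1,
                          run_criterion2 = TRUE, pseudocount = 1,
                          gap_col_penalty = -1, distance_cap = 10) {
  if (identity_threshold_pct <= 0 || identity_threshold_pct >= 100) {
    abort("identity_threshold_pct must lie in (0, 100)")
  }
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  if (n_perm < 99) abort("n_perm must be at least 99")
  if (run_criterion2 && 1 / (1 + n_perm) > alpha) {
    abort(sprintf(paste0("alpha = %g is unattainable with %d permutations ",
                         "(minimum p-value is %g); raise n_perm or alpha"),
                  alpha, n_perm, 1 / (1 + n_perm)))
  }
  stopifnot(inherits(scheme, "mco_scheme"))
  structure(
    list(identity_threshold_pct = identity_threshold_pct, alpha = alpha,
         n_perm = as.integer(n_perm), scheme = scheme,
         rng_seed = as.integer(rng_seed),
         run_criterion2 = isTRUE(run_criterion2), pseudocount = pseudocount,
         gap_col_penalty = gap_col_penalty, distance_cap = distance_cap),
    class = "mco_config"
  )
}

# deterministic, candidate-local seed for the permutation null
candidate_seed <- function(master, id) {
  h <- sum(utf8ToInt(id) * seq_along(utf8ToInt(id))) %% 1000003L
  (as.integer(master) %% 1000003L) * 1009L %% 2147483647L + h
}

#' Run the four-criterion Mn-oxidase screen
#'
#' Evaluates each candidate against criteria 1-4 in order, short-circuiting
#' on the first failure (later criteria are recorded as not evaluated,
#' `NA`). Criterion 1 assigns the best-hit known Mn-oxidizing gene, reused
#' by criteria 3 and 4. A single neighbor-joining tree is built per run
#' over all references plus every candidate that survived criteria 1-3
#' (candidate leaves are prefixed `"Q|"` to avoid label collisions), rooted
#' on the OUTGROUP references.
#'
#' @param candidates Tibble with columns `id`, `residues` (e.g. from
#'   [read_fasta()]); may be empty.
#' @param refdb Reference tibble from [read_refdb()]; must contain at least
#'   2 POSITIVE, 1 NEGATIVE and 1 OUTGROUP rows.
#' @param bins Optional tibble from [read_bins()]; unlisted candidates are
#'   reported as bin `"UNBINNED"`.
#' @param config An [screen_config()].
#' @return An object of class `mco_screen` with elements `report`
#'   (per-candidate tibble, lexicographic id order), `summary` (per-bin
#'   roll-up), `tree` (rooted `phylo`, or `NULL` when no candidate reached
#'   criterion 4 and fewer than 3 reference taxa exist), and `config`.
#'   `final_call` is `TRUE` only when every evaluated criterion passed.
#' @examples
#' synth <- generate_synthetic(synth_spec(rng_seed = 7, n_pos = 2,
#'   n_ablate = 1, n_far = 1, n_shuffle = 1, n_bins = 2, family_length = 120))
#' res <- run_screen(synth$candidates, synth$refdb, synth$bins,
#'                   screen_config(n_perm = 199, rng_seed = 7))
#' res$summary
#' @export
run_screen <- function(candidates, refdb, bins = NULL,
                       config = screen_config()) {
  stopifnot(inherits(config, "mco_config"))
  check_refdb_composition(refdb)
  if (is.null(bins)) bins <- tibble(candidate_id = character(), bin_id = character())

  ids <- sort(candidates$id)
  candidates <- candidates[match(ids, candidates$id), , drop = FALSE]
  bin_of <- setNames(bins$bin_id, bins$candidate_id)
  profile <- if (config$run_criterion2) {
    build_profile(refdb, config$scheme, config$pseudocount)
  } else NULL

  rows <- purrr::map(seq_len(nrow(candidates)), function(i) {
    id <- candidates$id[i]
    resid <- candidates$residues[i]
    bin <- if (!is.na(bin_of[id]) && id %in% names(bin_of)) bin_of[[id]] else "UNBINNED"
    c1 <- criterion1(resid, refdb, config$scheme,
                     config$identity_threshold_pct)
    out <- tibble(
      candidate_id = id, bin_id = bin,
      best_ref_id = c1$best_ref_id, best_gene_name = c1$best_gene_name,
      identity_pct = c1$identity_pct, c1_pass = c1$pass,
      c2_pass = NA, c2_pvalue = NA_real_, c3_pass = NA,
      c3_sites = NA_character_, c4_pass = NA, final_call = FALSE
    )
    if (!c1$pass) return(out)
    if (config$run_criterion2) {
      c2 <- criterion2(profile, resid, config$scheme, config$n_perm,
                       config$alpha, candidate_seed(config$rng_seed, id),
                       config$gap_col_penalty)
      out$c2_pass <- c2$pass
      out$c2_pvalue <- c2$pvalue
      if (!c2$pass) return(out)
    }
    ref <- refdb[refdb$ref_id == c1$best_ref_id, , drop = FALSE]
    c3 <- criterion3(resid, ref, config$scheme)
    out$c3_pass <- c3$pass
    out$c3_sites <- format_site_evidence(c3$checks, ref$residues)
    out
  })
  report <- dplyr::bind_rows(rows)
  if (nrow(report) == 0) {
    report <- tibble(
      candidate_id = character(), bin_id = character(),
      best_ref_id = character(), best_gene_name = character(),
      identity_pct = numeric(), c1_pass = logical(), c2_pass = logical(),
      c2_pvalue = numeric(), c3_pass = logical(), c3_sites = character(),
      c4_pass = logical(), final_call = logical()
    )
  }

  survivors <- report$candidate_id[!is.na(report$c3_pass) & report$c3_pass]
  tree <- NULL
  seqs <- setNames(refdb$residues, refdb$ref_id)
  if (length(survivors)) {
    cand_seqs <- setNames(
      candidates$residues[match(survivors, candidates$id)],
      paste0("Q|", survivors)
    )
    seqs <- c(seqs, cand_seqs)
  }
  if (length(seqs) >= 3) {
    dm <- distance_matrix(seqs, config$scheme, config$distance_cap)
    tree <- root_at_outgroup(nj_tree(dm),
                             refdb$ref_id[refdb$role == "OUTGROUP"])
  }
  if (length(survivors)) {
    negative_ids <- refdb$ref_id[refdb$role == "NEGATIVE"]
    for (id in survivors) {
      k <- which(report$candidate_id == id)
      c4 <- criterion4(tree, paste0("Q|", id), report$best_ref_id[k],
                       negative_ids)
      report$c4_pass[k] <- c4$pass
      report$final_call[k] <- isTRUE(report$c1_pass[k]) &&
        (!config$run_criterion2 || isTRUE(report$c2_pass[k])) &&
        isTRUE(report$c3_pass[k]) && c4$pass
    }
  }

  structure(
    list(report = report, summary = summarize_bins(report), tree = tree,
         config = config),
    class = "mco_screen"
  )
}

#' Per-MAG roll-up of screen results
#'
#' A bin (MAG) possesses a putative Mn-oxidizing gene when at least one of
#' its candidates passes all criteria. `pass_gene_names` lists the distinct
#' assigned gene names among that bin's passers (comma-separated, sorted).
#'
#' @param report The `report` tibble of an [run_screen()] result.
#' @return Tibble with columns `bin_id`, `n_candidates`, `n_pass`,
#'   `pass_gene_names`, sorted by `bin_id`.
#' @export
summarize_bins <- function(report) {
  if (nrow(report) == 0) {
    return(tibble(bin_id = character(), n_candidates = integer(),
                  n_pass = integer(), pass_gene_names = character()))
  }
  report |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::summarise(
      n_candidates = dplyr::n(),
      n_pass = sum(.data$final_call),
      pass_gene_names = paste(sort(unique(.data$best_gene_name[.data$final_call])),
                              collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$bin_id)
}

#' @export
print.mco_screen <- function(x, ...) {
  cat(sprintf("<mco_screen> %d candidates, %d pass all criteria, %d/%d bins flagged\n",
              nrow(x$report), sum(x$report$final_call),
              sum(x$summary$n_pass > 0), nrow(x$summary)))
  invisible(x)
}

#' @describeIn run_screen Per-candidate report tibble.
#' @param x An `mco_screen`.
#' @param ... Unused.
#' @export
tidy.mco_screen <- function(x, ...) x$report

#' @describeIn run_screen One-row run summary.
#' @export
glance.mco_screen <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$report),
    n_pass = sum(x$report$final_call),
    n_bins = nrow(x$summary),
    n_bins_flagged = sum(x$summary$n_pass > 0),
    mean_pass_identity_pct = if (any(x$report$final_call)) {
      mean(x$report$identity_pct[x$report$final_call])
    } else NA_real_
  )
}

fmt_flag <- function(x) ifelse(is.na(x), "NOT_EVALUATED",
                               ifelse(x, "TRUE", "FALSE"))

#' Write screen report files
#'
#' Writes `report.tsv` (one row per candidate, lexicographic id order) and
#' the companion `summary.tsv` per-bin roll-up into `dir`; when the screen
#' built a tree, also `tree.nwk` (Newick). Criteria skipped after an
#' earlier failure are written as `NOT_EVALUATED`. Output is byte-stable
#' for identical inputs and seed.
#'
#' @param x An `mco_screen` result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "mco_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- x$report
  out <- tibble(
    candidate_id = r$candidate_id, bin_id = r$bin_id,
    best_ref_id = r$best_ref_id, best_gene_name = r$best_gene_name,
    identity_pct = sprintf("%.4f", r$identity_pct),
    c1_pass = fmt_flag(r$c1_pass), c2_pass = fmt_flag(r$c2_pass),
    c2_pvalue = ifelse(is.na(r$c2_pvalue), "NOT_EVALUATED",
                       sprintf("%.6f", r$c2_pvalue)),
    c3_pass = fmt_flag(r$c3_pass),
    c3_sites = ifelse(is.na(r$c3_sites), "NOT_EVALUATED", r$c3_sites),
    c4_pass = fmt_flag(r$c4_pass), final_call = fmt_flag(r$final_call)
  )
  readr::write_tsv(out, file.path(dir, "report.tsv"), progress = FALSE)
  readr::write_tsv(x$summary, file.path(dir, "summary.tsv"), progress = FALSE)
  if (!is.null(x$tree)) {
    ape::write.tree(x$tree, file.path(dir, "tree.nwk"))
  }
  invisible(dir)
}
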