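#' Read the reference-gene table
#'
#' The reference database lists known Mn-oxidizing genes (role `POSITIVE`),
#' multicopper oxidases without Mn-oxidation evidence (`NEGATIVE`) and
#' outgroup sequences (`OUTGROUP`), each with its copper-binding site
#' annotation. The file is tab-separated with columns `ref_id`, `gene_name`,
#' `locus_id`, `family`, `role`, `sites`, `sequence`; extra columns are
#' ignored with a warning.
#'
#' Sites are serialized as semicolon-separated entries `LABEL:POS=ALLOWED`,
#' e.g. `"T1:45=H;T1:110=M"`, where `LABEL` is one of `T1`, `T2`, `T3a`,
#' `T3b`, `POS` is a 1-based position in the sequence and `ALLOWED` is the
#' set of residues accepted at that position (several letters permitted, so
#' e.g. the variable axial ligand of the T1 centre can be annotated `MLF`).
#' An empty `sites` field is allowed only for `OUTGROUP` rows; a `POSITIVE`
#' MCO must annotate all four site labels.
#'
#' @param path Path to the tab-separated reference table.
#' @return A tibble with columns `ref_id`, `gene_name`, `locus_id`,
#'   `family`, `role`, `residues`, and a list-column `sites` of tibbles
#'   (`label`, `position`, `allowed`).
#' @seealso [write_refdb()], [synthetic_refdb_path()]
#' @export
read_refdb <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("ref_id", "gene_name", "locus_id", "family", "role", "sites",
            "sequence")
  miss <- setdiff(need, names(tab))
  if (length(miss)) abort(paste0("reference table missing column(s): ",
                                 paste(miss, collapse = ", ")))
  extra <- setdiff(names(tab), need)
  if (length(extra)) {
    warn(paste0("ignoring unknown reference-table column(s): ",
                paste(extra, collapse = ", ")))
  }
  tab$sites[is.na(tab$sites)] <- ""
  out <- tibble(
    ref_id = tab$ref_id, gene_name = tab$gene_name, locus_id = tab$locus_id,
    family = tab$family, role = tab$role,
    residues = vapply(toupper(tab$sequence), clean_residues, "",
                      USE.NAMES = FALSE),
    sites = vector("list", nrow(tab))
  )
  for (i in seq_len(nrow(out))) {
    line <- i + 1L # header line is line 1
    if (!out$family[i] %in% c("MCO", "AHP")) {
      abort(sprintf("line %d: unknown family '%s'", line, out$family[i]))
    }
    if (!out$role[i] %in% c("POSITIVE", "NEGATIVE", "OUTGROUP")) {
      abort(sprintf("line %d: unknown role '%s'", line, out$role[i]))
    }
    st <- tryCatch(parse_sites(tab$sites[i]), error = function(e) {
      abort(sprintf("line %d: %s", line, conditionMessage(e)))
    })
    if (nrow(st) == 0 && out$role[i] != "OUTGROUP") {
      abort(sprintf("line %d: empty sites allowed only for OUTGROUP", line))
    }
    if (any(st$position > nchar(out$residues[i]))) {
      abort(sprintf("line %d: site position out of range (sequence length %d)",
                    line, nchar(out$residues[i])))
    }
    if (out$role[i] == "POSITIVE" && out$family[i] == "MCO" &&
        !all(c("T1", "T2", "T3a", "T3b") %in% st$label)) {
      abort(sprintf("line %d: POSITIVE MCO must annotate all of T1, T2, T3a, T3b",
                    line))
    }
    out$sites[[i]] <- st
  }
  dup <- unique(out$ref_id[duplicated(out$ref_id)])
  if (length(dup)) abort(paste0("duplicate ref_id(s): ", paste(dup, collapse = ", ")))
  out
}

SITE_LABELS <- c("T1", "T2", "T3a", "T3b")

parse_sites <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) {
    return(tibble(label = character(), position = integer(),
                  allowed = character()))
  }
  parts <- strsplit(trimws(x), ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(T1|T2|T3a|T3b):([0-9]+)=([A-Z]+)$", parts))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) abort(paste0("malformed site entry '", parts[bad][1], "'"))
  lab <- vapply(m, `[[`, "", 2)
  pos <- as.integer(vapply(m, `[[`, "", 3))
  allowed <- vapply(m, `[[`, "", 4)
  if (any(pos < 1)) abort("site position must be >= 1")
  ok <- vapply(strsplit(allowed, ""), function(a) all(a %in% AA20), TRUE)
  if (!all(ok)) abort(paste0("allowed set '", allowed[!ok][1],
                             "' contains a non-standard letter"))
  tibble(label = lab, position = pos, allowed = allowed)
}

format_sites <- function(st) {
  if (is.null(st) || nrow(st) == 0) return("")
  paste(sprintf("%s:%d=%s", st$label, st$position, st$allowed), collapse = ";")
}

#' Write a reference-gene table
#'
#' Inverse of [read_refdb()]; round-trips up to site ordering.
#'
#' @param refdb Tibble as returned by [read_refdb()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_refdb <- function(refdb, path) {
  tab <- tibble(
    ref_id = refdb$ref_id, gene_name = refdb$gene_name,
    locus_id = refdb$locus_id, family = refdb$family, role = refdb$role,
    sites = vapply(refdb$sites, format_sites, ""),
    sequence = refdb$residues
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Path to the packaged synthetic reference database
#'
#' The packaged reference table is a *synthetic* stand-in: its rows carry
#' the names and locus ids of known Mn-oxidizing genes (moxA CAJ19378,
#' mcoA ABY98562, mnxG PputGB1_2447) so screens read naturally, but the
#' sequences are simulated members of one synthetic MCO-like family, not
#' the real loci. Curators with access to the real reference set can drop
#' in their own table in the same format.
#'
#' @return Path to `refdb_synthetic.tsv` inside the installed package.
#' @export
synthetic_refdb_path <- function() {
  system.file("extdata", "refdb_synthetic.tsv", package = "mcoscreen",
              mustWork = TRUE)
}

check_refdb_composition <- function(refdb) {
  n_pos <- sum(refdb$role == "POSITIVE")
  n_neg <- sum(refdb$role == "NEGATIVE")
  n_out <- sum(refdb$role == "OUTGROUP")
  if (n_pos < 2 || n_neg < 1 || n_out < 1) {
    abort(sprintf(paste0("reference database must contain >=2 POSITIVE, >=1 ",
                         "NEGATIVE and >=1 OUTGROUP entries (found %d/%d/%d)"),
                  n_pos, n_neg, n_out))
  }
  invisible(TRUE)
}
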