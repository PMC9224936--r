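sc <- mco_scheme()

test_that("simple alignments match hand-derived expectations", {
  al <- align_pair("HCH", "HCH", sc, "local")
  expect_equal(al$score, 2 * sc$matrix["H", "H"] + sc$matrix["C", "C"])
  expect_equal(al$identity_pct, 100)

  # all pairings negative: the optimal local alignment is empty
  al <- align_pair("AAAA", "GGGG", sc, "local")
  expect_equal(al$score, 0)
  expect_equal(al$n_columns, 0)

  # global MKH vs MH: exactly one deletion column
  al <- align_pair("MKH", "MH", sc, "global")
  expect_equal(sum(is.na(al$pairs$s_pos)), 1)
  expect_equal(sum(is.na(al$pairs$q_pos)), 0)
  expect_equal(al$score,
               sc$matrix["M", "M"] + sc$matrix["H", "H"] -
                 (sc$gap_open + sc$gap_extend))
})

test_that("the memoized score oracle agrees with explicit path enumeration", {
  set.seed(4)
  aa <- c("A", "C", "D", "E")
  for (k in 1:12) {
    q <- paste(sample(aa, sample(1:4, 1), TRUE), collapse = "")
    s <- paste(sample(aa, sample(1:4, 1), TRUE), collapse = "")
    expect_equal(oracle_align_score(q, s, sc, "global"),
                 enumerate_global_score(q, s, sc),
                 info = paste(q, s))
  }
})

test_that("kernel scores equal the exhaustive oracle on short 4-letter pairs", {
  set.seed(2)
  aa <- c("A", "C", "D", "E")
  for (k in 1:40) {
    q <- paste(sample(aa, sample(1:7, 1), TRUE), collapse = "")
    s <- paste(sample(aa, sample(1:7, 1), TRUE), collapse = "")
    expect_equal(align_pair(q, s, sc, "global")$score,
                 oracle_align_score(q, s, sc, "global"), info = paste(q, s))
    expect_equal(align_pair(q, s, sc, "local")$score,
                 oracle_align_score(q, s, sc, "local"), info = paste(q, s))
  }
})

test_that("kernel scores match Biostrings pairwiseAlignment on random pairs", {
  suppressPackageStartupMessages(requireNamespace("Biostrings"))
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  set.seed(12)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:25) {
    q <- paste(sample(aa, sample(5:80, 1), TRUE), collapse = "")
    s <- paste(sample(aa, sample(5:80, 1), TRUE), collapse = "")
    for (mode in c("local", "global")) {
      ref <- Biostrings::score(Biostrings::pairwiseAlignment(
        q, s, substitutionMatrix = e$BLOSUM62,
        gapOpening = sc$gap_open, gapExtension = sc$gap_extend, type = mode))
      if (mode == "local") ref <- max(ref, 0)
      expect_equal(align_pair(q, s, sc, mode)$score, ref, info = mode)
    }
  }
})

test_that("identity is 100 on self, symmetric, and monotone under extension", {
  set.seed(31)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:10) {
    a <- paste(sample(aa, sample(3:40, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(3:40, 1), TRUE), collapse = "")
    expect_equal(align_pair(a, a, sc, "global")$identity_pct, 100)
    f <- align_pair(a, b, sc, "global")
    r <- align_pair(b, a, sc, "global")
    expect_equal(f$score, r$score)
    expect_equal(f$identity_pct, r$identity_pct)
    # mirrored coordinate map
    expect_equal(f$pairs$q_pos, r$pairs$s_pos)
    # appending identical residues never reduces the identical-column count
    g <- align_pair(paste0(a, "WWW"), paste0(b, "WWW"), sc, "global")
    expect_gte(g$n_identical, f$n_identical)
  }
})

test_that("alignment coordinates are strictly increasing along each sequence", {
  set.seed(8)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (mode in c("local", "global")) for (k in 1:10) {
    q <- paste(sample(aa, 30, TRUE), collapse = "")
    s <- paste(sample(aa, 25, TRUE), collapse = "")
    p <- align_pair(q, s, sc, mode)$pairs
    expect_true(all(diff(p$q_pos[!is.na(p$q_pos)]) == 1) ||
                  sum(!is.na(p$q_pos)) <= 1)
    expect_true(all(diff(p$s_pos[!is.na(p$s_pos)]) == 1) ||
                  sum(!is.na(p$s_pos)) <= 1)
  }
})

test_that("criterion 1 assigns the best positive hit with a strict threshold", {
  db <- toy_refdb()
  # candidate identical to P1: perfect hit
  hit <- criterion1(db$residues[1], db, sc, 30)
  expect_true(hit$pass)
  expect_equal(hit$best_ref_id, "P1")
  expect_equal(hit$identity_pct, 100)

  # engineered 30.0% best local identity fails the strict ">" rule ...
  p30 <- identity30_pair()
  refs30 <- tibble::tibble(
    ref_id = "R30", gene_name = "moxA", locus_id = "L", family = "MCO",
    role = "POSITIVE", residues = p30$ref,
    sites = list(tibble::tibble(label = character(), position = integer(),
                                allowed = character()))
  )
  hit30 <- criterion1(p30$candidate, refs30, sc, 30)
  expect_equal(hit30$identity_pct, 30)
  expect_false(hit30$pass)
  # ... while just above 30% passes, all else equal
  p31 <- identity31_pair()
  refs31 <- refs30
  refs31$residues <- p31$ref
  hit31 <- criterion1(p31$candidate, refs31, sc, 30)
  expect_gt(hit31$identity_pct, 30)
  expect_lt(hit31$identity_pct, 31)
  expect_true(hit31$pass)

  expect_error(criterion1("MKH", db[db$role == "NEGATIVE", ], sc),
               "POSITIVE")
})

test_that("criterion 1 best hit equals brute-force recomputation over refs", {
  db <- read_refdb(synthetic_refdb_path())
  set.seed(1)
  cand <- paste(sample(strsplit(db$residues[1], "")[[1]], 200), collapse = "")
  hit <- criterion1(cand, db, sc, 30)
  pos <- db[db$role == "POSITIVE", ]
  tab <- purrr::map_dfr(seq_len(nrow(pos)), function(i) {
    al <- align_pair(cand, pos$residues[i], sc, "local")
    tibble::tibble(ref_id = pos$ref_id[i], gene_name = pos$gene_name[i],
                   identity_pct = al$identity_pct, score = al$score)
  })
  tab <- tab[order(-tab$identity_pct, -tab$score, tab$ref_id), ]
  expect_equal(hit$best_ref_id, tab$ref_id[1])
  expect_equal(hit$identity_pct, tab$identity_pct[1])
})
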