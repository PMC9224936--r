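test_that("FASTA reading parses headers, wraps, case and trailing stops", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">a first candidate", "MKH", ">b", "mk", "HL", ">c", "MKH*"), f)
  recs <- read_fasta(f)
  expect_equal(recs$id, c("a", "b", "c"))
  expect_equal(recs$description, c("first candidate", "", ""))
  expect_equal(recs$residues, c("MKH", "MKHL", "MKH"))
})

test_that("FASTA validation fails hard on duplicates, empties and bad letters", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">a", "MKH", ">a", "MKH"), f)
  expect_error(read_fasta(f), "duplicate.*a")
  writeLines(c(">a", "*"), f)
  expect_error(read_fasta(f), "empty")
  writeLines(c(">a", "MK*H"), f) # internal stop = broken ORF
  expect_error(read_fasta(f), "position 3")
  writeLines(c(">a", "MKOH"), f) # O is not a standard residue
  expect_error(read_fasta(f), "position 3")
})

test_that("FASTA round-trip preserves ids, descriptions and residues", {
  recs <- tibble::tibble(
    id = c("q1", "q2"), description = c("hypothetical protein", ""),
    residues = c("MKHLVWX", "ACDEFGHIKLMNPQRSTVWY")
  )
  f <- withr::local_tempfile(fileext = ".faa")
  write_fasta(recs, f)
  expect_equal(read_fasta(f), recs)
})

test_that("reference table parses sites and enforces its invariants", {
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "ref_id\tgene_name\tlocus_id\tfamily\trole\tsites\tsequence"
  writeLines(c(hdr, "r1\tmoxA\tL1\tMCO\tNEGATIVE\tT1:3=H\tMKH"), f)
  db <- read_refdb(f)
  expect_equal(db$sites[[1]],
               tibble::tibble(label = "T1", position = 3L, allowed = "H"))

  writeLines(c(hdr, "r1\tmoxA\tL1\tMCO\tNEGATIVE\tT1:9=H\tMKH"), f)
  expect_error(read_refdb(f), "line 2.*out of range")
  writeLines(c(hdr, "r1\tmoxA\tL1\tMCO\tNEGATIVE\tT9:1=H\tMKH"), f)
  expect_error(read_refdb(f), "malformed site")
  writeLines(c(hdr, "r1\tmoxA\tL1\tBAD\tNEGATIVE\tT1:3=H\tMKH"), f)
  expect_error(read_refdb(f), "unknown family")
  writeLines(c(hdr, "r1\tmoxA\tL1\tMCO\tSOMETIMES\tT1:3=H\tMKH"), f)
  expect_error(read_refdb(f), "unknown role")
  writeLines(c(hdr, "r1\tmoxA\tL1\tMCO\tPOSITIVE\tT1:3=H\tMKH"), f)
  expect_error(read_refdb(f), "T1, T2, T3a, T3b")
  writeLines(c(hdr, "r1\tmoxA\tL1\tMCO\tNEGATIVE\t\tMKH"), f)
  expect_error(read_refdb(f), "OUTGROUP")
  writeLines(c(paste0(hdr, "\tnote"),
               "r1\tmoxA\tL1\tMCO\tNEGATIVE\tT1:3=H\tMKH\thello"), f)
  expect_warning(read_refdb(f), "ignoring unknown")
})

test_that("packaged synthetic reference table parses with the named anchors", {
  db <- read_refdb(synthetic_refdb_path())
  moxa <- db[db$gene_name == "moxA", ]
  expect_equal(moxa$locus_id, "CAJ19378")
  expect_equal(moxa$role, "POSITIVE")
  expect_equal(moxa$family, "MCO")
  expect_setequal(unique(moxa$sites[[1]]$label), c("T1", "T2", "T3a", "T3b"))
  expect_equal(db$locus_id[db$gene_name == "mcoA"], "ABY98562")
  expect_equal(db$locus_id[db$gene_name == "mnxG"], "PputGB1_2447")
})

test_that("reference table round-trips through serialize/parse", {
  db <- read_refdb(synthetic_refdb_path())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_refdb(db, f)
  db2 <- read_refdb(f)
  expect_equal(db2, db)
})

test_that("bins table reads mappings, skips comments, rejects conflicts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# candidate\tbin", "p1\tMAG7", "p2\tMAG8"), f)
  b <- read_bins(f)
  expect_equal(b$bin_id[b$candidate_id == "p1"], "MAG7")
  writeLines(c("p1\tMAG7", "p1\tMAG8"), f)
  expect_error(read_bins(f), "more than one bin.*p1")
  writeLines(character(0), f)
  expect_equal(nrow(read_bins(f)), 0)
})

test_that("report files are consistent with the screen result", {
  synth <- generate_synthetic(synth_spec(rng_seed = 5, n_pos = 2, n_ablate = 1,
                                         n_far = 0, n_shuffle = 1, n_bins = 2,
                                         family_length = 150))
  res <- run_screen(synth$candidates, synth$refdb, synth$bins,
                    screen_config(n_perm = 199, rng_seed = 5))
  dir <- withr::local_tempdir()
  write_report(res, dir)
  rep <- readr::read_tsv(file.path(dir, "report.tsv"), col_types = readr::cols(),
                         progress = FALSE)
  summ <- readr::read_tsv(file.path(dir, "summary.tsv"), col_types = readr::cols(),
                          progress = FALSE)
  expect_equal(nrow(rep), nrow(synth$candidates))
  expect_equal(rep$candidate_id, sort(rep$candidate_id)) # lexicographic order
  expect_equal(sum(summ$n_pass), sum(rep$final_call == "TRUE"))
  expect_equal(sum(summ$n_candidates), nrow(rep))
  expect_named(rep, c("candidate_id", "bin_id", "best_ref_id", "best_gene_name",
                      "identity_pct", "c1_pass", "c2_pass", "c2_pvalue",
                      "c3_pass", "c3_sites", "c4_pass", "final_call"))
})

test_that("an empty screen writes header-only report files", {
  db <- read_refdb(synthetic_refdb_path())
  res <- run_screen(tibble::tibble(id = character(), residues = character()),
                    db, NULL, screen_config(n_perm = 199))
  dir <- withr::local_tempdir()
  write_report(res, dir)
  expect_equal(length(readLines(file.path(dir, "report.tsv"))), 1)
  expect_equal(length(readLines(file.path(dir, "summary.tsv"))), 1)
})

test_that("the packaged NCBI-format BLOSUM62 matches the in-memory matrix", {
  m <- read_score_matrix(system.file("extdata", "BLOSUM62.txt",
                                     package = "mcoscreen"))
  sc <- mco_scheme()
  aa <- setdiff(rownames(sc$matrix), "X")
  expect_equal(m[aa, aa], sc$matrix[aa, aa])
  expect_true(isSymmetric(m))
  # the scheme forces X to score 0 against everything
  expect_true(all(sc$matrix["X", ] == 0) && all(sc$matrix[, "X"] == 0))
})
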