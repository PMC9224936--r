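sc <- mco_scheme()

test_that("Poisson-corrected distance follows the formula and saturates", {
  expect_equal(pairwise_distance("MKHLV", "MKHLV", sc), 0)
  # gapless half-different alignment: p = 0.5 -> -ln(0.5)
  a <- "WWWWWWHHHH"
  b <- "WWWWWHHHHH" # 10 columns, diagonal alignment, 2 mismatches? construct carefully below
  a <- "WCWCWCWCWC"
  b <- "WCWCWHYHYH" # positions 1-5 identical, 6-10 all differ
  d <- pairwise_distance(a, b, sc)
  expect_equal(d, -log(0.5))
  # saturation cap
  expect_equal(pairwise_distance("WWWW", "PPPP", sc, cap = 10), 10)
})

test_that("distance is symmetric over random pairs", {
  set.seed(3)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:30) {
    a <- paste(sample(aa, sample(10:60, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(10:60, 1), TRUE), collapse = "")
    expect_equal(pairwise_distance(a, b, sc), pairwise_distance(b, a, sc))
  }
})

test_that("NJ recovers a 4-taxon additive topology and the 3-taxon closed form", {
  # additive matrix from topology ((A,B),(C,D)) with internal edge 0.3
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  bl <- c(A = 0.1, B = 0.2, C = 0.15, D = 0.25)
  for (x in rownames(d)) for (y in colnames(d)) {
    if (x != y) {
      d[x, y] <- bl[x] + bl[y] +
        (if (xor(x %in% c("A", "B"), y %in% c("A", "B"))) 0.3 else 0)
    }
  }
  tr <- nj_tree(d)
  truth <- ape::read.tree(text = "((A:0.1,B:0.2):0.15,C:0.15,D:0.25);")
  expect_true(same_topology(tr, truth))
  # branch lengths are recovered exactly on additive input
  expect_equal(sort(tr$edge.length),
               sort(c(0.1, 0.2, 0.15, 0.25, 0.3)), tolerance = 1e-9)

  # 3 taxa: three-point formulas
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(d3)
  lens <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(lens[c("a", "b", "c")], c(a = 1, b = 2, c = 3),
               ignore_attr = TRUE)

  expect_error(nj_tree(d3[1:2, 1:2]), "at least 3")
})

test_that("NJ is consistent on random additive matrices and agrees with ape", {
  set.seed(11)
  for (k in 1:25) {
    case <- random_additive_case(sample(5:8, 1))
    mine <- nj_tree(case$dm)
    expect_true(same_topology(mine, case$tree), info = paste("case", k))
    expect_true(same_topology(mine, ape::nj(case$dm)), info = paste("ape", k))
  }
})

test_that("Newick round-trip preserves topology and branch lengths", {
  set.seed(19)
  case <- random_additive_case(7)
  tr <- nj_tree(case$dm)
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  tr2 <- ape::read.tree(f)
  expect_true(same_topology(tr, tr2))
  expect_equal(sort(tr2$edge.length), sort(tr$edge.length), tolerance = 1e-6)
})

test_that("outgroup rooting splits the separating edge and keeps bipartitions", {
  set.seed(23)
  case <- random_additive_case(8)
  tr <- nj_tree(case$dm)
  rooted <- root_at_outgroup(tr, "L01")
  expect_true(ape::is.rooted(rooted))
  # single-leaf outgroup: root on its pendant edge, at the midpoint
  root_children <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1L, 2]
  expect_true(which(rooted$tip.label == "L01") %in% root_children)
  root_lens <- rooted$edge.length[rooted$edge[, 1] == ape::Ntip(rooted) + 1L]
  expect_equal(root_lens[1], root_lens[2])
  # rooting never changes the unrooted bipartition set
  expect_true(same_topology(tr, rooted))

  expect_error(root_at_outgroup(tr, "nope"), "not in tree")
  expect_error(root_at_outgroup(tr, tr$tip.label), "every leaf")
})

test_that("rooting on the complement of one leaf equals rooting on that leaf", {
  set.seed(29)
  case <- random_additive_case(6)
  tr <- nj_tree(case$dm)
  r1 <- root_at_outgroup(tr, "L03")
  r2 <- root_at_outgroup(tr, setdiff(tr$tip.label, "L03"))
  expect_true(same_topology(r1, r2))
  expect_equal(sort(smallest_clade(r2, setdiff(tr$tip.label, "L03"))),
               sort(setdiff(tr$tip.label, "L03")))
})

test_that("a non-monophyletic outgroup is refused with the violators named", {
  # caterpillar tree: A,B are not a clade away from C with D inside
  tr <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  tr <- ape::unroot(tr)
  expect_error(root_at_outgroup(tr, c("A", "B")), "not monophyletic")
})

test_that("smallest_clade equals brute-force clade enumeration", {
  expect_equal(smallest_clade(ape::read.tree(text = "((A:1,B:1):1,C:2);"), "A"),
               "A")
  set.seed(13)
  for (k in 1:20) {
    n <- sample(4:16, 1)
    tr <- ape::rtree(n)
    tr$tip.label <- sprintf("T%02d", seq_len(n))
    ids <- sample(tr$tip.label, sample(1:min(4, n), 1))
    expect_equal(smallest_clade(tr, ids), brute_smallest_clade(tr, ids),
                 info = paste("case", k))
  }
  tr <- ape::rtree(5)
  expect_equal(smallest_clade(tr, tr$tip.label), sort(tr$tip.label))
  expect_error(smallest_clade(tr, "missing_leaf"), "unknown leaf")
})

test_that("criterion 4 tests clade contamination by negatives", {
  tr <- ape::read.tree(
    text = "(((Q1:1,REF:1):1,(P2:1,N1:1):1):1,(N2:1,OUT:2):1);")
  # Q1 sister to its assigned reference, negatives outside the MRCA
  c4 <- criterion4(tr, "Q1", "REF", c("N1", "N2"))
  expect_true(c4$pass)
  expect_equal(c4$clade, c("Q1", "REF"))
  # a negative inside the connecting clade fails
  c4b <- criterion4(tr, "Q1", "P2", c("N1", "N2"))
  expect_false(c4b$pass)
  # monotone: a negative sitting outside the clade cannot flip a pass
  c4c <- criterion4(tr, "Q1", "REF", c("N1", "N2", "OUT"))
  expect_true(c4c$pass)
})
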