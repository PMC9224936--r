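# Independent oracles used across the suite. These deliberately take a
# different route than the package internals (top-down memoized recursion /
# explicit path enumeration in R vs the iterative C++ kernel; ape's tools vs
# the package's tree code).

# ---- affine alignment score oracle (top-down memoized recursion) ----------
# Same cost convention as mco_scheme(): a gap run of length L costs
# open + L * extend; switching gap direction re-opens.
oracle_align_score <- function(q, s, scheme, mode = "global") {
  sub <- scheme$matrix
  open <- scheme$gap_open + scheme$gap_extend
  ext <- scheme$gap_extend
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  memo <- new.env(parent = emptyenv())
  # f(i, j, st): best score of an alignment of q[1..i], s[1..j] ending in
  # state st (1 = pair, 2 = gap-in-subject, 3 = gap-in-query)
  f <- function(i, j, st) {
    key <- paste(i, j, st)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (st == 1) {
      if (i == 0 && j == 0) 0
      else if (i == 0 || j == 0) -Inf
      else sub[qc[i], sc[j]] + max(f(i - 1, j - 1, 1), f(i - 1, j - 1, 2),
                                   f(i - 1, j - 1, 3))
    } else if (st == 2) {
      if (i == 0) -Inf
      else max(f(i - 1, j, 1) - open, f(i - 1, j, 2) - ext,
               f(i - 1, j, 3) - open)
    } else {
      if (j == 0) -Inf
      else max(f(i, j - 1, 1) - open, f(i, j - 1, 3) - ext,
               f(i, j - 1, 2) - open)
    }
    memo[[key]] <- val
    val
  }
  if (mode == "global") {
    return(max(f(n, m, 1), f(n, m, 2), f(n, m, 3)))
  }
  # local: best over all end cells of alignments that start fresh anywhere;
  # h(i, j) = best alignment ending with pair (i, j)
  hmemo <- new.env(parent = emptyenv())
  g <- function(i, j, st) { # like f but allowed to restart before a pair
    key <- paste(i, j, st)
    if (!is.null(hmemo[[key]])) return(hmemo[[key]])
    val <- if (st == 1) {
      if (i == 0 || j == 0) -Inf
      else sub[qc[i], sc[j]] +
        max(0, g(i - 1, j - 1, 1), g(i - 1, j - 1, 2), g(i - 1, j - 1, 3))
    } else if (st == 2) {
      if (i == 0) -Inf
      else max(g(i - 1, j, 1) - open, g(i - 1, j, 2) - ext,
               g(i - 1, j, 3) - open)
    } else {
      if (j == 0) -Inf
      else max(g(i, j - 1, 1) - open, g(i, j - 1, 3) - ext,
               g(i, j - 1, 2) - open)
    }
    hmemo[[key]] <- val
    val
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) best <- max(best, g(i, j, 1))
  best
}

# ---- exhaustive path enumeration (true brute force, tiny inputs only) -----
# Enumerates every monotone alignment path as a move string over M/D/I and
# scores gap runs directly. Validates the memoized oracle itself.
enumerate_global_score <- function(q, s, scheme) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  sub <- scheme$matrix
  open <- scheme$gap_open + scheme$gap_extend
  ext <- scheme$gap_extend
  best <- -Inf
  score_path <- function(moves) {
    i <- 0; j <- 0; score <- 0; run <- ""
    for (mv in moves) {
      if (mv == "M") {
        i <- i + 1; j <- j + 1
        score <- score + sub[qc[i], sc[j]]
        run <- ""
      } else {
        score <- score - if (run == mv) ext else open
        run <- mv
        if (mv == "D") i <- i + 1 else j <- j + 1
      }
    }
    score
  }
  rec <- function(i, j, moves) {
    if (i == length(qc) && j == length(sc)) {
      best <<- max(best, score_path(moves)); return(invisible())
    }
    if (i < length(qc) && j < length(sc)) rec(i + 1, j + 1, c(moves, "M"))
    if (i < length(qc)) rec(i + 1, j, c(moves, "D"))
    if (j < length(sc)) rec(i, j + 1, c(moves, "I"))
  }
  rec(0, 0, character(0))
  best
}

# ---- additive distance matrices from random trees -------------------------
random_additive_case <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, br = function(k) stats::runif(k, 0.05, 1))
  tr$tip.label <- sprintf("L%02d", seq_len(n_leaves))
  list(tree = tr, dm = as.matrix(ape::cophenetic.phylo(tr)))
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# ---- brute-force clade oracle (via ape::prop.part) ------------------------
all_clades <- function(tree) {
  pp <- ape::prop.part(tree)
  clades <- lapply(pp, function(idx) sort(tree$tip.label[idx]))
  c(clades, as.list(sort(tree$tip.label)))
}

brute_smallest_clade <- function(tree, ids) {
  cl <- all_clades(tree)
  containing <- cl[vapply(cl, function(x) all(ids %in% x), TRUE)]
  containing[[which.min(lengths(containing))]]
}

# ---- tiny in-code reference sets ------------------------------------------
toy_refdb <- function() {
  # one tight positive family with annotated ligands, one negative, outgroup
  pos1 <- "MKAHLVCDEHGGTWMKLVHEDFAHSTYHQPLHNDR"
  sites <- tibble::tibble(
    label = c("T1", "T1", "T2", "T3a", "T3b"),
    position = c(4L, 7L, 19L, 24L, 28L),
    allowed = c("H", "C", "H", "H", "H")
  )
  stopifnot(identical(substring(pos1, sites$position, sites$position),
                      c("H", "C", "H", "H", "H")))
  pos2 <- sub("GGT", "GAT", pos1) # one substitution away, sites untouched
  neg <- "MKAALVADEAGGTWMKLVAEDFAASTYAQPLANDRXK"
  out <- "WWPGQQNNRRSSTTKKDDEEIIVVLLFFYYAAGGHH"
  tibble::tibble(
    ref_id = c("P1", "P2", "N1", "O1"),
    gene_name = c("moxA", "mcoA", "mcoX", "out"),
    locus_id = c("CAJ19378", "ABY98562", "SYN_NEG", "SYN_OUT"),
    family = "MCO",
    role = c("POSITIVE", "POSITIVE", "NEGATIVE", "OUTGROUP"),
    residues = c(pos1, pos2, neg, out),
    sites = list(sites, sites, sites,
                 tibble::tibble(label = character(), position = integer(),
                                allowed = character()))
  )
}

# a candidate/reference pair engineered so the optimal local alignment is a
# fixed ungapped 10-column block with exactly 3 identities (30.0%)
identity30_pair <- function() {
  list(candidate = "WAAAWAAAAW", ref = "WDDDWDDDDW")
}
# 13-column variant with 4 identities (30.77% > 30)
identity31_pair <- function() {
  list(candidate = "WAAAWAAAWAAAW", ref = "WDDDWDDDWDDDW")
}
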