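#' Poisson-corrected protein distance
#'
#' From the global alignment of two sequences, the uncorrected distance is
#' the fraction \eqn{p} of differing residue-residue columns (gap columns
#' are excluded from the denominator). The returned distance is the Poisson
#' correction \eqn{-\ln(1 - p)}; saturated pairs (\eqn{p \to 1}, including
#' the degenerate case of no residue-residue columns) are capped at `cap`.
#'
#' @param a,b Protein sequences (character scalars).
#' @param scheme An [mco_scheme()].
#' @param cap Saturation cap (default 10).
#' @return Nonnegative numeric distance.
#' @export
pairwise_distance <- function(a, b, scheme, cap = 10) {
  al <- align_pair(a, b, scheme, "global")
  resres <- !is.na(al$pairs$q_pos) & !is.na(al$pairs$s_pos)
  n <- sum(resres)
  if (n == 0) return(cap)
  p <- 1 - sum(resres & al$pairs$q_res == al$pairs$s_res) / n
  if (p >= 1) return(cap)
  min(-log(1 - p), cap)
}

#' All-against-all Poisson-corrected distances
#'
#' @param seqs Named character vector of sequences (unique names become the
#'   matrix labels).
#' @inheritParams pairwise_distance
#' @return Symmetric numeric matrix with zero diagonal, labelled dimnames.
#' @export
distance_matrix <- function(seqs, scheme, cap = 10) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    abort("seqs must be uniquely named")
  }
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- pairwise_distance(seqs[[i]], seqs[[j]], scheme, cap)
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor-joining over a symmetric distance matrix, returning
#' an unrooted `ape::phylo` tree (final three lineages joined at a
#' trifurcation). Pair selection is deterministic: the pair minimizing the
#' Q criterion, ties broken by the lexicographically smallest label pair
#' (a cluster is labelled by its smallest leaf). Negative branch-length
#' estimates are clamped to zero with the deficit shifted to the sibling
#' branch so that the joined pair's path length is preserved.
#'
#' @param dm Symmetric numeric matrix with labelled dimnames (>= 3 taxa),
#'   e.g. from [distance_matrix()].
#' @return An unrooted `phylo` object.
#' @export
nj_tree <- function(dm) {
  labels <- rownames(dm)
  n <- length(labels)
  if (is.null(labels) || n < 3) abort("neighbor-joining needs at least 3 labelled taxa")
  if (!isTRUE(all.equal(dm, t(dm)))) abort("distance matrix must be symmetric")

  # each active cluster: newick fragment + lexicographic tie-break key
  nwk <- labels
  key <- labels
  D <- dm
  eps <- 1e-12

  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    best <- NULL
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      if (Q[i, j] <= qmin + eps) {
        pair_key <- sort(c(key[i], key[j]))
        if (is.null(best) || pair_key[1] < best$k1 ||
            (pair_key[1] == best$k1 && pair_key[2] < best$k2)) {
          best <- list(i = i, j = j, k1 = pair_key[1], k2 = pair_key[2])
        }
      }
    }
    i <- best$i; j <- best$j
    di <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    dj <- D[i, j] - di
    if (di < 0) { dj <- dj + di; di <- 0 }
    if (dj < 0) { di <- di + dj; dj <- 0 }
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], di, nwk[j], dj)
    new_key <- min(key[i], key[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    dnew <- pmax(dnew, 0)
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    D <- D2
    nwk <- c(nwk[keep], new_nwk)
    key <- c(key[keep], new_key)
  }

  # trifurcating root from the three-point formulas
  d1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  d2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  d3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  b <- pmax(c(d1, d2, d3), 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", nwk[1], b[1], nwk[2], b[2],
                 nwk[3], b[3])
  ape::read.tree(text = txt)
}

#' Root a tree on a monophyletic outgroup
#'
#' Places the root at the midpoint of the edge separating the outgroup
#' leaves from the rest. The outgroup must form a split of the unrooted
#' tree; otherwise the error lists the intruding leaves.
#'
#' @param tree An unrooted `phylo`.
#' @param outgroup_ids Nonempty character vector of leaf labels.
#' @return A rooted `phylo`.
#' @export
root_at_outgroup <- function(tree, outgroup_ids) {
  if (!length(outgroup_ids)) abort("outgroup_ids must be nonempty")
  missing <- setdiff(outgroup_ids, tree$tip.label)
  if (length(missing)) {
    abort(paste0("outgroup leaves not in tree: ", paste(missing, collapse = ", ")))
  }
  ingroup <- setdiff(tree$tip.label, outgroup_ids)
  if (!length(ingroup)) abort("outgroup cannot contain every leaf")
  # monophyly relative to any rooting outside the outgroup
  probe <- ape::root(tree, outgroup = ingroup[1], resolve.root = TRUE)
  if (length(outgroup_ids) > 1) {
    mrca <- ape::getMRCA(probe, outgroup_ids)
    below <- clade_tips(probe, mrca)
    intruders <- setdiff(below, outgroup_ids)
    if (length(intruders)) {
      abort(paste0("outgroup is not monophyletic; intruding leaves: ",
                   paste(sort(intruders), collapse = ", ")))
    }
  }
  # when only one leaf remains in the ingroup the separating edge is that
  # leaf's pendant edge; root there directly (ape cannot take a
  # complement-of-one-leaf outgroup)
  rooted <- if (length(ingroup) == 1) {
    ape::root(tree, outgroup = ingroup, resolve.root = TRUE)
  } else {
    ape::root(tree, outgroup = outgroup_ids, resolve.root = TRUE)
  }
  root_node <- ape::Ntip(rooted) + 1L
  root_edges <- which(rooted$edge[, 1] == root_node)
  total <- sum(rooted$edge.length[root_edges])
  rooted$edge.length[root_edges] <- total / 2
  rooted
}

# tips descending from `node` (which may itself be a tip)
clade_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  tree$tip.label[out]
}

#' Smallest clade containing a set of leaves
#'
#' Leaf set of the most recent common ancestor of `ids` in a rooted tree.
#'
#' @param tree A rooted `phylo`.
#' @param ids Character vector of leaf labels (subset of the tips).
#' @return Character vector of leaf labels (sorted).
#' @export
smallest_clade <- function(tree, ids) {
  unknown <- setdiff(ids, tree$tip.label)
  if (length(unknown)) {
    abort(paste0("unknown leaf id(s): ", paste(unknown, collapse = ", ")))
  }
  if (length(unique(ids)) == 1) return(unique(ids))
  mrca <- ape::getMRCA(tree, unique(ids))
  sort(clade_tips(tree, mrca))
}

#' Criterion 4: co-clade placement with the assigned known gene
#'
#' The candidate passes when the smallest clade containing it and its
#' assigned known Mn-oxidizing gene contains no NEGATIVE reference — the
#' candidate sits in a clade of the assigned gene uncontaminated by MCOs
#' without Mn-oxidation evidence. Outgroup leaves sit on the far side of
#' the root by construction.
#'
#' @param tree A rooted `phylo` (see [root_at_outgroup()]).
#' @param candidate_id,assigned_ref_id Leaf labels.
#' @param negative_ids Character vector of NEGATIVE reference leaf labels.
#' @return A list with `pass` (flag) and `clade` (leaf labels).
#' @export
criterion4 <- function(tree, candidate_id, assigned_ref_id, negative_ids) {
  clade <- smallest_clade(tree, c(candidate_id, assigned_ref_id))
  list(pass = length(intersect(clade, negative_ids)) == 0, clade = clade)
}
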