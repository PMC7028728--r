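#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the Studier-Keppler selection criterion
#' Q(i,j) = (N-2) d(i,j) - R_i - R_j, branch lengths
#' v_i = d(i,j)/2 + (R_i - R_j) / (2(N-2)) and reduction
#' d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2. Ties are broken by the lowest
#' (row, column) index pair in current matrix order, so runs are
#' bit-reproducible. Negative branch lengths are clamped to zero with the
#' deficit transferred to the sibling branch.
#'
#' @param mat A `k2p_matrix` or plain symmetric matrix with dimnames
#'   (>= 3 taxa, no NA entries).
#' @return An unrooted [ape::phylo] tree over all ids.
#' @export
nj_tree <- function(mat) {
  d <- as_dist_matrix(mat)
  check_complete(d, min_n = 3L)
  labels <- rownames(d)
  frag <- labels   # newick fragment per active node
  active <- seq_along(labels)
  n_clamped <- 0L
  while (length(active) > 3L) {
    N <- length(active)
    dd <- d[active, active, drop = FALSE]
    R <- rowSums(dd)
    Q <- (N - 2) * dd - outer(R, R, "+")
    diag(Q) <- Inf
    pick <- lowest_min_pair(Q)
    i <- pick[1L]; j <- pick[2L]
    dij <- dd[i, j]
    vi <- dij / 2 + (R[i] - R[j]) / (2 * (N - 2))
    vj <- dij - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0; n_clamped <- n_clamped + 1L }
    if (vj < 0) { vi <- vi + vj; vj <- 0; n_clamped <- n_clamped + 1L }
    ai <- active[i]; aj <- active[j]
    new_frag <- sprintf("(%s:%.12g,%s:%.12g)", frag[ai], vi, frag[aj], vj)
    # reuse slot ai for the new node u
    others <- active[-c(i, j)]
    d[ai, others] <- d[others, ai] <- (d[ai, others] + d[aj, others] - dij) / 2
    d[ai, ai] <- 0
    frag[ai] <- new_frag
    active <- active[-j]
  }
  a <- active
  # three-taxon star: closed-form branch lengths
  v1 <- (d[a[1], a[2]] + d[a[1], a[3]] - d[a[2], a[3]]) / 2
  v2 <- (d[a[1], a[2]] + d[a[2], a[3]] - d[a[1], a[3]]) / 2
  v3 <- (d[a[1], a[3]] + d[a[2], a[3]] - d[a[1], a[2]]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  if (any(c(v1, v2, v3) < 0)) n_clamped <- n_clamped + sum(c(v1, v2, v3) < 0)
  if (n_clamped > 0L) message("nj_tree: ", n_clamped, " negative branch length(s) clamped to 0")
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[a[1]], v[1], frag[a[2]], v[2], frag[a[3]], v[3])
  ape::read.tree(text = txt)
}

check_complete <- function(d, min_n) {
  if (is.null(rownames(d))) stop("distance matrix must carry dimnames")
  if (nrow(d) < min_n) stop("need at least ", min_n, " taxa")
  if (anyNA(d)) {
    bad <- which(is.na(d), arr.ind = TRUE)[1L, ]
    stop("NA distance between '", rownames(d)[bad[1L]], "' and '",
         colnames(d)[bad[2L]], "'")
  }
  invisible(TRUE)
}

# index pair (i < j) of the matrix minimum, ties broken by lowest row then
# lowest column in current order
lowest_min_pair <- function(m) {
  m[lower.tri(m, diag = TRUE)] <- Inf
  hits <- which(m == min(m), arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  c(hits[1L, 1L], hits[1L, 2L])
}

#' UPGMA tree from a distance matrix
#'
#' Classic size-weighted average linkage: the merged cluster's distance to
#' any other cluster is the member-count-weighted mean, and each merge sits
#' at height equal to half the merged pair's distance. The result is a
#' rooted ultrametric tree, usable as a built-in stand-in chronogram.
#'
#' @param mat A `k2p_matrix` or plain symmetric matrix (>= 2 taxa, no NA).
#' @return A rooted ultrametric [ape::phylo] tree.
#' @export
upgma_tree <- function(mat) {
  d <- as_dist_matrix(mat)
  check_complete(d, min_n = 2L)
  labels <- rownames(d)
  frag <- labels
  height <- rep(0, length(labels))
  size <- rep(1L, length(labels))
  active <- seq_along(labels)
  while (length(active) > 1L) {
    dd <- d[active, active, drop = FALSE]
    pick <- lowest_min_pair(dd)
    i <- pick[1L]; j <- pick[2L]
    ai <- active[i]; aj <- active[j]
    h <- dd[i, j] / 2
    new_frag <- sprintf("(%s:%.12g,%s:%.12g)",
                        frag[ai], h - height[ai], frag[aj], h - height[aj])
    others <- active[-c(i, j)]
    if (length(others)) {
      w <- (size[ai] * d[ai, others] + size[aj] * d[aj, others]) /
        (size[ai] + size[aj])
      d[ai, others] <- d[others, ai] <- w
    }
    frag[ai] <- new_frag
    height[ai] <- h
    size[ai] <- size[ai] + size[aj]
    active <- active[-j]
  }
  ape::read.tree(text = paste0(frag[active], ";"))
}

#' Node heights of a rooted tree
#'
#' Heights are measured backward from the most distant tip (the present, for
#' an ultrametric tree): tips of an ultrametric tree sit at height 0 and the
#' root at the tree height.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @return Numeric vector of length `Ntip + Nnode`, indexed by ape node
#'   number.
#' @export
node_heights <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Test whether a rooted tree is ultrametric
#' @param tree A rooted [ape::phylo] tree.
#' @param tol Absolute tolerance on root-to-tip path differences.
#' @return Logical.
#' @export
tree_is_ultrametric <- function(tree, tol = 1e-8) {
  depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  diff(range(depth)) <= tol
}

#' Root a tree on the edge separating an outgroup
#'
#' The outgroup must form one side of a bipartition of the unrooted tree;
#' the root is placed at the midpoint of that edge. Non-monophyletic
#' outgroups are rejected with the intruding tip labels.
#'
#' @param tree An [ape::phylo] tree.
#' @param outgroup_ids Tip labels of the outgroup.
#' @return A rooted [ape::phylo] tree with the outgroup sister to the rest.
#' @export
root_with_outgroup <- function(tree, outgroup_ids) {
  missing <- setdiff(outgroup_ids, tree$tip.label)
  if (length(missing)) stop("outgroup id(s) absent from tree: ",
                            paste(missing, collapse = ", "))
  if (length(outgroup_ids) >= ape::Ntip(tree)) stop("outgroup cannot cover all tips")
  if (length(outgroup_ids) > 1L) {
    anchor <- setdiff(tree$tip.label, outgroup_ids)[1L]
    probe <- ape::root(tree, outgroup = anchor, resolve.root = TRUE)
    tipnos <- match(outgroup_ids, probe$tip.label)
    mrca <- ape::getMRCA(probe, tipnos)
    clade <- ape::extract.clade(probe, mrca)$tip.label
    intruders <- setdiff(clade, outgroup_ids)
    if (length(intruders)) {
      stop("outgroup not monophyletic; intruding tips: ",
           paste(intruders, collapse = ", "))
    }
  }
  rooted <- ape::root(tree, outgroup = outgroup_ids, resolve.root = TRUE)
  # split the stem edge evenly across the two root children
  root_node <- ape::Ntip(rooted) + 1L
  kid_edges <- which(rooted$edge[, 1L] == root_node)
  stem <- sum(rooted$edge.length[kid_edges])
  rooted$edge.length[kid_edges] <- stem / 2
  rooted
}

#' Scale an ultrametric tree from substitutions to time
#'
#' Divides all branch lengths (hence node heights) by a strict-clock rate,
#' e.g. 0.012 substitutions/site/My for the conventional 1.2% pairwise COI
#' divergence per million years.
#'
#' @param tree A rooted ultrametric [ape::phylo] tree with branch lengths in
#'   substitutions/site.
#' @param rate Clock rate in substitutions/site per time unit (> 0).
#' @param tol Ultrametricity tolerance.
#' @return The tree with branch lengths in time units.
#' @export
scale_to_time <- function(tree, rate = 0.012, tol = 1e-8) {
  stopifnot(rate > 0)
  if (!tree_is_ultrametric(tree, tol)) stop("scale_to_time requires an ultrametric tree")
  tree$edge.length <- tree$edge.length / rate
  tree
}

#' Resolve polytomies deterministically
#'
#' Multifurcations are resolved into arbitrary zero-length bifurcations
#' (first-listed children grouped first) so downstream delimiters can assume
#' binary trees.
#'
#' @param tree An [ape::phylo] tree.
#' @return A binary [ape::phylo] tree.
#' @export
resolve_polytomies <- function(tree) {
  if (ape::is.binary(tree)) return(tree)
  message("resolving polytomies with zero-length branches")
  ape::multi2di(tree, random = FALSE)
}
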