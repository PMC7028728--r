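#' Poisson tree process (PTP) species delimitation
#'
#' Branch lengths (in substitutions/site) are modelled as exponential draws
#' from two classes: speciation-level branches (ancestral to, and entering,
#' each species' root node) and coalescent-level branches (inside species
#' subtrees). A delimitation is a set of species-root nodes covering every
#' tip exactly once. For a class of n branches with total length S the ML
#' exponential rate is n/S and the profile log-likelihood contribution is
#' n log(n/S) - n. `mode = "single"` pools all coalescent branches into one
#' class (PTP); `mode = "multi"` gives each species its own coalescent rate
#' (mPTP-style).
#'
#' The optimum is sought by first-improvement hill climbing over moves
#' \{split a species at its root into its two children, merge two sibling
#' species\}, started from the one-species and all-tips delimitations plus
#' `n_restarts` random seeded starts.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths in
#'   substitutions/site (>= 2 tips). Polytomies are resolved with zero-length
#'   branches.
#' @param mode `"single"` (one coalescent rate) or `"multi"` (one per
#'   species).
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Integer seed for the random restarts.
#' @param min_br Branches shorter than this are excluded from the likelihood
#'   (default 1e-4 substitutions/site).
#' @return List with `model` (class `ptp_model`: rates, species roots,
#'   `log_likelihood`) and `partition` (a [partition]).
#' @export
ptp_fit <- function(tree, mode = c("single", "multi"), n_restarts = 10L,
                    seed = NULL, min_br = 1e-4) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 2L) stop("PTP requires a tree with at least 2 tips")
  tree <- resolve_polytomies(tree)
  st <- tree_struct(tree)
  used <- st$edge_len_by_child >= min_br
  used[is.na(used)] <- FALSE
  if (!any(used, na.rm = TRUE)) stop("all branch lengths below min_br = ", min_br)
  # per-node stats over branches strictly inside the subtree (min_br-filtered)
  sub_n <- integer(st$n_nodes); sub_s <- numeric(st$n_nodes)
  for (v in rev(st$preorder)) {
    kids <- st$children[[v]]
    for (c in kids) {
      sub_n[v] <- sub_n[v] + sub_n[c] + as.integer(used[c])
      sub_s[v] <- sub_s[v] + sub_s[c] + if (used[c]) st$edge_len_by_child[c] else 0
    }
  }
  tot_n <- sub_n[st$root]; tot_s <- sub_s[st$root]

  loglik <- function(roots) ptp_loglik(roots, sub_n, sub_s, tot_n, tot_s, mode)

  # steepest-ascent hill climbing; ties broken by first candidate in the
  # deterministic move enumeration order
  climb <- function(roots) {
    repeat {
      cur <- loglik(roots)
      step <- NULL
      for (cand in all_moves(st, roots)) {
        ll <- loglik(cand)
        if (ll > cur + 1e-12 && (is.null(step) || ll > step$logL + 1e-12)) {
          step <- list(roots = cand, logL = ll)
        }
      }
      if (is.null(step)) return(list(roots = roots, logL = cur))
      roots <- step$roots
    }
  }

  # deterministic starts: trivial delimitations plus the frontier of every
  # branch-length threshold (edges >= t form the speciation subgraph)
  starts <- list(st$root, which(st$is_tip))
  for (t in sort(unique(st$edge_len_by_child[!is.na(st$edge_len_by_child)]))) {
    starts <- c(starts, list(threshold_antichain(st, t)))
  }
  if (n_restarts > 0L) {
    if (!is.null(seed)) set.seed(seed)
    for (r in seq_len(n_restarts)) {
      starts <- c(starts, list(random_antichain(st, stats::runif(1, 0.15, 0.85))))
    }
  }
  best <- NULL
  for (s in starts) {
    res <- climb(s)
    # strict-improvement tolerance: exact likelihood ties (e.g. all-equal
    # branch lengths) keep the earlier, simpler start
    if (is.null(best) || res$logL > best$logL + 1e-12) best <- res
  }
  # basin hop: take each single move from the optimum (including worsening
  # ones), re-climb, keep strict improvements; repeat up to 5 rounds
  for (round in seq_len(5L)) {
    improved <- FALSE
    for (s in all_moves(st, best$roots)) {
      res <- climb(s)
      if (res$logL > best$logL + 1e-12) { best <- res; improved <- TRUE; break }
    }
    if (!improved) break
  }
  roots <- sort(best$roots)
  assignment <- character(0)
  for (v in roots) {
    tips <- st$tip_labels[subtree_tips(st, v)]
    assignment[tips] <- sort(tips)[1L]
  }
  model <- structure(list(mode = mode, species_roots = roots,
                          log_likelihood = best$logL, min_br = min_br,
                          n_species = length(roots),
                          rates = ptp_rates(roots, sub_n, sub_s, tot_n, tot_s, mode)),
                     class = "ptp_model")
  part <- partition(assignment[st$tip_labels],
                    method = if (mode == "single") "ptp" else "mptp",
                    params = list(min_br = min_br, n_restarts = n_restarts))
  list(model = model, partition = part)
}

#' @export
print.ptp_model <- function(x, ...) {
  cat(sprintf("ptp_model [%s]: %d species, logL = %.4f\n",
              x$mode, x$n_species, x$log_likelihood))
  invisible(x)
}

# n log(n/S) - n; empty class contributes 0
exp_class_loglik <- function(n, S) {
  if (n == 0L) return(0)
  if (S <= 0) return(-Inf)
  n * log(n / S) - n
}

ptp_loglik <- function(roots, sub_n, sub_s, tot_n, tot_s, mode) {
  cn <- sub_n[roots]; cs <- sub_s[roots]
  spec_ll <- exp_class_loglik(tot_n - sum(cn), tot_s - sum(cs))
  if (mode == "single") {
    spec_ll + exp_class_loglik(sum(cn), sum(cs))
  } else {
    spec_ll + sum(vapply(seq_along(roots),
                         function(i) exp_class_loglik(cn[i], cs[i]), 0))
  }
}

ptp_rates <- function(roots, sub_n, sub_s, tot_n, tot_s, mode) {
  ns <- tot_n - sum(sub_n[roots]); ss <- tot_s - sum(sub_s[roots])
  lambda_s <- if (ns > 0L) ns / ss else NA_real_
  if (mode == "single") {
    nc <- sum(sub_n[roots]); sc <- sum(sub_s[roots])
    list(lambda_s = lambda_s, lambda_c = if (nc > 0L) nc / sc else NA_real_)
  } else {
    lc <- ifelse(sub_n[roots] > 0L, sub_n[roots] / sub_s[roots], NA_real_)
    list(lambda_s = lambda_s, lambda_c = lc)
  }
}

# every delimitation one move away (splits, sibling merges, collapses)
all_moves <- function(st, roots) {
  out <- list()
  for (v in sort(roots)) {
    kids <- st$children[[v]]
    if (length(kids)) out <- c(out, list(c(setdiff(roots, v), kids)))
  }
  spec_nodes <- integer(0)
  for (v in roots) {
    p <- st$parent[v]
    while (!is.na(p) && !(p %in% spec_nodes)) { spec_nodes <- c(spec_nodes, p); p <- st$parent[p] }
  }
  for (u in sort(spec_nodes)) {
    under <- roots[vapply(roots, function(r) is_descendant(st, r, u), TRUE)]
    if (length(under) >= 2L) out <- c(out, list(c(setdiff(roots, under), u)))
  }
  out
}

is_descendant <- function(st, v, anc) {
  while (!is.na(v)) { if (v == anc) return(TRUE); v <- st$parent[v] }
  FALSE
}

# antichain at the frontier of the rootward subgraph of edges >= t
threshold_antichain <- function(st, t) {
  roots <- integer(0)
  stack <- st$root
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    kids <- st$children[[v]]
    long <- kids[!st$is_tip[kids] & st$edge_len_by_child[kids] >= t]
    roots <- c(roots, setdiff(kids, long))
    stack <- c(stack, long)
  }
  if (length(roots)) roots else st$root
}

# random antichain covering all tips: stop at each node with prob p_stop
# (varied across restarts so starts span shallow to deep delimitations)
random_antichain <- function(st, p_stop = 0.5) {
  roots <- integer(0)
  stack <- st$root
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    if (st$is_tip[v] || stats::runif(1) < p_stop) roots <- c(roots, v)
    else stack <- c(stack, st$children[[v]])
  }
  roots
}

# adjacency/height scaffolding shared by the tree-based delimiters
tree_struct <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_nodes <- n_tip + tree$Nnode
  parent <- rep(NA_integer_, n_nodes)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen <- rep(NA_real_, n_nodes)
  elen[tree$edge[, 2L]] <- tree$edge.length
  children <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge))) {
    children[[tree$edge[i, 1L]]] <- c(children[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  }
  root <- n_tip + 1L
  pre <- integer(0); stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    pre <- c(pre, v); stack <- c(stack, children[[v]])
  }
  list(n_tip = n_tip, n_nodes = n_nodes, root = root, parent = parent,
       children = children, edge_len_by_child = elen, preorder = pre,
       is_tip = seq_len(n_nodes) <= n_tip, tip_labels = tree$tip.label)
}

subtree_tips <- function(st, v) {
  out <- integer(0); stack <- v
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (st$is_tip[u]) out <- c(out, u) else stack <- c(stack, st$children[[u]])
  }
  out
}

#' Generalized mixed Yule-coalescent (GMYC) species delimitation
#'
#' On an ultrametric chronogram, branching events older than a threshold
#' time T are modelled as Yule speciations (rate `lambda_yule` per
#' lineage) and events inside the clusters hanging below T as neutral
#' coalescences (rate `lambda_coal * m (m - 1)` for a cluster with m
#' lineages). The likelihood is a point process over inter-node intervals:
#' each interval of duration x with k diversification lineages (cluster
#' stems included) and cluster sizes m_j contributes
#' `log(rate of its closing event) - (lambda_yule k + lambda_coal sum m_j (m_j - 1)) x`,
#' with lineage counts taken on the tipward side of each event. Both rates
#' have closed-form ML estimates given T; T is profiled over all internal
#' node heights (plus the no-threshold null). Clusters are the subtrees
#' whose root is the first node younger than T on each root-to-tip path.
#' The single-threshold model is compared to the one-cluster pure-coalescent
#' null by a likelihood-ratio test (chi-square, `df = 2` by convention,
#' configurable).
#'
#' `mode = "multi"` (mGMYC-style) greedily refines the single-threshold
#' solution: each cluster may adopt its own, younger threshold, and a
#' refinement is kept when it improves AIC (one extra parameter per added
#' threshold). This is a stand-in for the published multiple-threshold
#' search heuristics.
#'
#' @param chronogram A rooted ultrametric [ape::phylo] tree (>= 3 tips).
#' @param mode `"single"` or `"multi"`.
#' @param df Degrees of freedom of the LR test (default 2).
#' @param tol Ultrametricity tolerance.
#' @return List with `model` (class `gmyc_model`: `lambda_yule`,
#'   `lambda_coal`, `threshold_T`, `n_clusters`, `log_likelihood`,
#'   `logL_null`, `lr_stat`, `p_value`) and `partition` (a [partition]).
#' @export
gmyc_fit <- function(chronogram, mode = c("single", "multi"), df = 2,
                     tol = 1e-8) {
  mode <- match.arg(mode)
  stopifnot(inherits(chronogram, "phylo"))
  if (ape::Ntip(chronogram) < 3L) stop("GMYC requires at least 3 tips")
  if (!tree_is_ultrametric(chronogram, tol)) {
    stop("GMYC requires an ultrametric chronogram")
  }
  chronogram <- resolve_polytomies(chronogram)
  st <- tree_struct(chronogram)
  h <- node_heights(chronogram)
  h[st$is_tip] <- 0                       # clamp numerical tip noise
  internal <- which(!st$is_tip)
  heights <- h[internal]

  null_fit <- gmyc_eval(st, h, rep(FALSE, st$n_nodes))
  # candidate thresholds: every internal node height (that node and all
  # older ones diversify) plus the all-diversification boundary
  cand_T <- sort(unique(heights))
  cand_T <- c(cand_T, if (min(cand_T) > 0) min(cand_T) / 2 else 0)
  best <- null_fit                        # null = no threshold, one cluster
  best$threshold_T <- Inf
  best$div <- rep(FALSE, st$n_nodes)
  for (T in cand_T) {
    div <- !st$is_tip & h >= T   # ancestor-closed: parents are always older
    fit <- gmyc_eval(st, h, div)
    if (is.finite(fit$logL) && fit$logL > best$logL + 1e-12) {
      best <- fit; best$threshold_T <- T; best$div <- div
    }
  }
  n_par <- 3                              # lambda_yule, lambda_coal, T
  if (mode == "multi") {
    best <- gmyc_refine(st, h, best)
    n_par <- 2 + best$n_thresholds
  }
  lr <- lr_test(null_fit$logL, max(best$logL, null_fit$logL), df = df)
  assignment <- character(0)
  for (v in best$cluster_roots) {
    tips <- st$tip_labels[subtree_tips(st, v)]
    assignment[tips] <- sort(tips)[1L]
  }
  model <- structure(list(mode = mode,
                          lambda_yule = best$lambda_yule,
                          lambda_coal = best$lambda_coal,
                          threshold_T = best$threshold_T,
                          n_clusters = length(best$cluster_roots),
                          log_likelihood = best$logL,
                          logL_null = null_fit$logL, n_par = n_par,
                          lr_stat = lr$lr_stat, p_value = lr$p_value),
                     class = "gmyc_model")
  part <- partition(assignment[st$tip_labels],
                    method = if (mode == "single") "gmyc" else "mgmyc",
                    params = list(threshold_T = best$threshold_T, df = df))
  list(model = model, partition = part)
}

#' @export
print.gmyc_model <- function(x, ...) {
  cat(sprintf("gmyc_model [%s]: %d clusters, T = %.5g, logL = %.4f, LR = %.3f (p = %.4g)\n",
              x$mode, x$n_clusters, x$threshold_T, x$log_likelihood,
              x$lr_stat, x$p_value))
  invisible(x)
}

# Likelihood of one diversification-node set (must be ancestor-closed:
# parent(div) is div). div = FALSE everywhere is the one-cluster null.
#
# Point process on the ordered branching times, read tipward-to-rootward:
# during the interval closed by each event, k diversification lineages
# (cluster stems included) and cluster sizes m_j give the total branching
# rate b = lambda_yule k + lambda_coal sum_j m_j (m_j - 1); every event
# contributes log(b) - b x. Rates are profiled out numerically (closed-form
# when only one class is active).
gmyc_eval <- function(st, h, div) {
  # cluster root of each node: first non-div node on its rootward path
  croot <- rep(NA_integer_, st$n_nodes)
  for (v in st$preorder) {
    if (div[v]) next
    p <- st$parent[v]
    croot[v] <- if (is.na(p) || div[p]) v else croot[p]
  }
  cluster_roots <- which(!is.na(croot) & croot == seq_len(st$n_nodes))
  # state at the present: tipward lineage counts
  m <- integer(st$n_nodes)                # per cluster root
  k <- 0L                                 # diversification lineages (stems incl.)
  for (tip in which(st$is_tip)) {
    j <- croot[tip]
    if (j == tip) k <- k + 1L else m[j] <- m[j] + 1L
  }
  Bsum <- sum(m[cluster_roots] * (m[cluster_roots] - 1L))
  events <- order(h * !st$is_tip, seq_len(st$n_nodes))
  events <- events[!st$is_tip[events]]    # internal nodes, youngest first
  ne <- length(events)
  ki <- numeric(ne); Bi <- numeric(ne); xi <- numeric(ne)
  n_y <- 0L; n_c <- 0L; h_prev <- 0
  for (idx in seq_len(ne)) {
    e <- events[idx]
    ki[idx] <- k; Bi[idx] <- Bsum; xi[idx] <- h[e] - h_prev
    h_prev <- h[e]
    if (div[e]) {
      if (k < 2L) return(list(logL = -Inf))
      n_y <- n_y + 1L
      k <- k - 1L
    } else {
      j <- croot[e]
      if (m[j] < 2L) return(list(logL = -Inf))
      n_c <- n_c + 1L
      Bsum <- Bsum - m[j] * (m[j] - 1L)
      if (e == j) { m[j] <- 0L; k <- k + 1L }
      else { m[j] <- m[j] - 1L; Bsum <- Bsum + m[j] * (m[j] - 1L) }
    }
  }
  A_tot <- sum(ki * xi); B_tot <- sum(Bi * xi)
  loglik <- function(ly, lc) {
    b <- ly * ki + lc * Bi
    if (any(b <= 0)) return(-Inf)
    sum(log(b)) - ly * A_tot - lc * B_tot
  }
  # one-class cases have closed-form ML rates
  if (n_y == 0L) {
    lc <- ne / B_tot; ly <- 0
    logL <- loglik(0, lc)
  } else if (n_c == 0L) {
    ly <- ne / A_tot; lc <- 0
    logL <- loglik(ly, 0)
  } else {
    # initialise from per-class event shares
    init <- c(log(n_y / A_tot), log(n_c / B_tot))
    opt <- stats::optim(init, function(p) -loglik(exp(p[1L]), exp(p[2L])),
                        method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    ly <- exp(opt$par[1L]); lc <- exp(opt$par[2L])
    logL <- -opt$value
  }
  list(logL = logL, lambda_yule = ly, lambda_coal = lc,
       cluster_roots = cluster_roots, croot = croot, n_thresholds = 1L)
}

# greedy per-cluster threshold refinement: each sweep applies the single
# best AIC-improving within-cluster threshold, until none improves
gmyc_refine <- function(st, h, best) {
  best$n_thresholds <- 1L
  repeat {
    cur_aic <- 2 * (2 + best$n_thresholds) - 2 * best$logL
    step <- NULL
    for (j in sort(best$cluster_roots)) {
      if (st$is_tip[j]) next
      sub <- subtree_nodes(st, j)
      sub <- sub[!st$is_tip[sub]]
      for (Tj in sort(unique(h[sub]))) {
        div2 <- best$div
        div2[sub] <- h[sub] >= Tj
        fit <- gmyc_eval(st, h, div2)
        if (!is.finite(fit$logL)) next
        aic <- 2 * (2 + best$n_thresholds + 1L) - 2 * fit$logL
        if (aic < cur_aic - 1e-9 && (is.null(step) || aic < step$aic)) {
          fit$aic <- aic
          fit$div <- div2
          step <- fit
        }
      }
    }
    if (is.null(step)) return(best)
    step$threshold_T <- best$threshold_T
    step$n_thresholds <- best$n_thresholds + 1L
    best <- step
  }
}

subtree_nodes <- function(st, v) {
  out <- integer(0); stack <- v
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, u); stack <- c(stack, st$children[[u]])
  }
  out
}

#' Likelihood-ratio test
#'
#' @param logL_null,logL_alt Log-likelihoods of the nested null and
#'   alternative models (`logL_alt >= logL_null` up to numerical noise).
#' @param df Degrees of freedom (> 0).
#' @return List with `lr_stat` (2 * (logL_alt - logL_null), clipped at 0)
#'   and `p_value` (chi-square upper tail).
#' @export
lr_test <- function(logL_null, logL_alt, df = 2) {
  if (df <= 0) stop("df must be positive")
  if (logL_alt < logL_null - 1e-9) {
    stop("alternative log-likelihood below null: models not nested or fit failed")
  }
  lr <- max(0, 2 * (logL_alt - logL_null))
  list(lr_stat = lr, p_value = stats::pchisq(lr, df = df, lower.tail = FALSE))
}
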