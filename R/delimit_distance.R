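#' Delimitation partitions
#'
#' A partition assigns every record id to exactly one OTU label and carries
#' its provenance (method name, parameters).
#'
#' @param assignment Named character vector: record id -> OTU label.
#' @param method Method name string.
#' @param params Named list of parameters used.
#' @return An object of class `partition` with fields `method`, `params`,
#'   `assignment`, `n_otus`.
#' @export
partition <- function(assignment, method, params = list()) {
  if (is.null(names(assignment)) || any(!nzchar(names(assignment)))) {
    stop("assignment must be named by record id")
  }
  if (anyDuplicated(names(assignment))) stop("duplicate record id in assignment")
  if (anyNA(assignment)) stop("every record must be assigned an OTU label")
  structure(list(method = method, params = params,
                 assignment = assignment,
                 n_otus = length(unique(assignment))),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition [%s]: %d records in %d OTUs\n",
              x$method, length(x$assignment), x$n_otus))
  invisible(x)
}

# Connected components of the graph with edges where d < threshold (strict).
# Returns integer component index per id; NA distances never create an edge.
components_below <- function(d, threshold) {
  n <- nrow(d)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (!is.na(d[i, j]) && d[i, j] < threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  vapply(seq_len(n), find, 1L)
}

# Deterministic OTU labels: lexicographically smallest member id per group
label_components <- function(ids, comp) {
  labs <- vapply(split(ids, comp), function(m) sort(m)[1L], "")
  stats::setNames(labs[as.character(comp)], ids)
}

#' Single-linkage threshold clustering (RESL-like)
#'
#' OTUs are the connected components of the graph joining records closer
#' than `threshold`. This is the single-linkage core of BOLD's Refined
#' Single Linkage (RESL); BOLD's proprietary Markov re-clustering refinement
#' is not reproduced, so outputs are labelled "resl_like". The default
#' threshold is BOLD's documented 2.2% seed threshold.
#'
#' @param mat A `k2p_matrix` or plain symmetric matrix.
#' @param threshold Distance threshold in substitutions/site (>= 0).
#' @return A `partition`; OTU labels are each cluster's lexicographically
#'   smallest member id.
#' @export
single_linkage_cluster <- function(mat, threshold = 0.022) {
  stopifnot(threshold >= 0)
  d <- as_dist_matrix(mat)
  comp <- components_below(d, threshold)
  partition(label_components(rownames(d), comp),
            method = "resl_like", params = list(threshold = threshold))
}

#' ABGD-style recursive barcode-gap partitioning
#'
#' For each prior maximal intraspecific divergence P (a geometric series
#' from `p_min` to `p_max`), all pairwise distances are sorted; scanning
#' successive sorted pairs whose upper value exceeds P, the first gap
#' g = d(k+1) - d(k) wider than `gap_width_x` times the mean successive gap
#' among the distances up to d(k) defines a partition threshold at the gap
#' midpoint. Groups (connected components below the threshold) are then
#' re-partitioned recursively on their own submatrices until no further gap
#' is found. When no gap exists at a prior the partition is a single group.
#'
#' @param mat A `k2p_matrix` or plain symmetric matrix (no NA).
#' @param p_min,p_max Prior intraspecific divergence bounds
#'   (substitutions/site), 0 < p_min <= p_max < 1.
#' @param n_steps Number of priors in the geometric series (>= 1).
#' @param gap_width_x Relative gap width multiplier (> 0).
#' @return List of `partition` objects, one per prior; each carries its
#'   prior in `params$prior`.
#' @export
abgd_partition <- function(mat, p_min = 0.001, p_max = 0.1, n_steps = 10,
                           gap_width_x = 1.5) {
  stopifnot(p_min > 0, p_min <= p_max, p_max < 1, n_steps >= 1, gap_width_x > 0)
  d <- as_dist_matrix(mat)
  check_complete(d, min_n = 1L)
  ids <- rownames(d)
  priors <- if (n_steps == 1L) p_min else
    exp(seq(log(p_min), log(p_max), length.out = n_steps))
  lapply(priors, function(P) {
    comp <- if (length(ids) < 2L) rep(1L, length(ids)) else
      abgd_recurse(d, P, gap_width_x)
    partition(label_components(ids, comp), method = "abgd",
              params = list(prior = P, p_min = p_min, p_max = p_max,
                            n_steps = n_steps, gap_width_x = gap_width_x))
  })
}

# One prior, full recursion; returns integer component vector over rows of d
abgd_recurse <- function(d, prior, gap_width_x) {
  n <- nrow(d)
  comp <- rep(1L, n)
  if (n < 3L) return(comp)        # need >= 2 pairwise distances for a gap
  thr <- abgd_gap_threshold(d[upper.tri(d)], prior, gap_width_x)
  if (is.na(thr)) return(comp)
  sub <- components_below(d, thr)
  if (length(unique(sub)) == 1L) return(comp)
  nxt <- 0L
  for (g in unique(sub)) {
    idx <- which(sub == g)
    inner <- abgd_recurse(d[idx, idx, drop = FALSE], prior, gap_width_x)
    comp[idx] <- nxt + inner
    nxt <- nxt + max(inner)
  }
  comp
}

# First significant gap beyond the prior in the sorted distance vector;
# returns the gap midpoint or NA when none qualifies. A gap qualifies when
# its upper end exceeds the prior and its width exceeds gap_width_x times
# the mean successive gap among all distances up to its lower end.
abgd_gap_threshold <- function(dist_vec, prior, gap_width_x) {
  ds <- sort(dist_vec)
  m <- length(ds)
  if (m < 2L) return(NA_real_)
  gaps <- diff(ds)
  for (k in seq_len(m - 1L)) {
    if (ds[k + 1L] <= prior) next
    ref <- if (k == 1L) 0 else (ds[k] - ds[1L]) / (k - 1L)
    if (gaps[k] > gap_width_x * ref && gaps[k] > 0) {
      return(ds[k] + gaps[k] / 2)
    }
  }
  NA_real_
}

#' Select one ABGD partition across priors
#'
#' Default rule: the modal OTU count across the prior series wins; among
#' equally frequent counts the smaller count wins, and the partition from
#' the smallest prior achieving it is returned.
#'
#' @param partitions List of `partition` objects (>= 1).
#' @return A single `partition`.
#' @export
select_abgd_partition <- function(partitions) {
  stopifnot(length(partitions) >= 1L)
  counts <- vapply(partitions, function(p) p$n_otus, 1L)
  tab <- table(counts)
  best_counts <- as.integer(names(tab)[tab == max(tab)])
  target <- min(best_counts)
  partitions[[which(counts == target)[1L]]]
}

#' Write a partition as TSV
#' @param p A `partition`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_partition <- function(p, path) {
  utils::write.table(
    data.frame(record_id = names(p$assignment), otu_label = unname(p$assignment),
               method = p$method,
               params = paste(names(p$params), unlist(p$params),
                              sep = "=", collapse = ";")),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
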