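#' Majority-rule consensus across delimitation partitions
#'
#' The co-assignment frequency of a record pair is the fraction of input
#' partitions placing the two records in the same OTU. The consensus
#' partition is the set of connected components of the graph joining pairs
#' whose co-assignment frequency reaches `quorum` (default 0.5, the "50%
#' consensus"). Components can form by transitivity (a chain of
#' above-quorum pairs containing below-quorum pairs); these are counted and
#' reported so the rule stays auditable.
#'
#' @param partitions List of [partition] objects over identical id sets.
#' @param quorum Minimum co-assignment frequency, in (0, 1].
#' @return An object of class `consensus_result`: `input_methods`,
#'   `co_assignment` (symmetric matrix in \[0, 1\]), `consensus` (a
#'   [partition]), `n_otus`, `n_transitive_pairs`.
#' @export
consensus_partition <- function(partitions, quorum = 0.5) {
  stopifnot(length(partitions) >= 1L, quorum > 0, quorum <= 1)
  ids <- sort(names(partitions[[1L]]$assignment))
  for (p in partitions) {
    if (!identical(sort(names(p$assignment)), ids)) {
      stop("partitions cover mismatched id sets")
    }
  }
  n <- length(ids)
  co <- matrix(0, n, n, dimnames = list(ids, ids))
  for (p in partitions) {
    same <- outer(p$assignment[ids], p$assignment[ids], "==")
    co <- co + same
  }
  co <- co / length(partitions)
  comp <- components_below(-co, -quorum + 1e-12)   # edges where co >= quorum
  assignment <- label_components(ids, comp)
  # pairs merged only transitively: same component but below-quorum pair
  same_comp <- outer(comp, comp, "==")
  trans <- same_comp & co < quorum - 1e-12
  n_trans <- sum(trans[upper.tri(trans)])
  if (n_trans > 0L) {
    message("consensus_partition: ", n_trans,
            " record pair(s) merged only by transitivity")
  }
  cons <- partition(assignment, method = "consensus",
                    params = list(quorum = quorum,
                                  methods = vapply(partitions, function(p) p$method, "")))
  structure(list(input_methods = vapply(partitions, function(p) p$method, ""),
                 co_assignment = co, consensus = cons, n_otus = cons$n_otus,
                 n_transitive_pairs = n_trans),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d methods (%s) -> %d OTUs; %d transitive pair(s)\n",
              length(x$input_methods), paste(x$input_methods, collapse = ", "),
              x$n_otus, x$n_transitive_pairs))
  invisible(x)
}

#' Barcoding-gap statistics
#'
#' Summaries of the separation between maximum intraspecific and
#' nearest-neighbor distances over the groups of a labelling (morphological
#' species or OTUs). Singleton groups have no intraspecific distance and are
#' excluded from the max-intra mean and from per-group ratios, but their
#' nearest-neighbor distances count. Two fold-change summaries are reported
#' because "X-fold higher on average" is ambiguous: `ratio_of_means` =
#' mean(nn) / mean(max_intra), the headline value, and `mean_of_ratios` =
#' mean over groups of nn/max_intra (groups with max_intra 0 excluded).
#'
#' @param mat A `k2p_matrix` or plain symmetric distance matrix.
#' @param labels Named character vector: record id -> group label.
#' @param level Label for the grouping, e.g. `"species"` or `"otu"`.
#' @param bin_width Histogram bin width on the percent scale (default 1).
#' @return An object of class `gap_stats`: `level`, `groups` (the
#'   [group_stats] table with an `overlap` flag per group), `overlap_exists`,
#'   `ratio_of_means`, `mean_of_ratios`, `histogram` (binned max-intra and
#'   nn counts, percent scale).
#' @export
gap_stats <- function(mat, labels, level = "species", bin_width = 1) {
  gs <- group_stats(mat, labels)
  gs$overlap <- !is.na(gs$max_intra) & !is.na(gs$nn_dist) &
    gs$max_intra > gs$nn_dist
  non_single <- !is.na(gs$max_intra)
  ratio_of_means <- if (any(non_single)) {
    mean(gs$nn_dist, na.rm = TRUE) / mean(gs$max_intra[non_single])
  } else NA_real_
  pos <- non_single & gs$max_intra > 0 & !is.na(gs$nn_dist)
  mean_of_ratios <- if (any(pos)) {
    mean(gs$nn_dist[pos] / gs$max_intra[pos])
  } else NA_real_
  if (!any(non_single)) message("gap_stats: all groups are singletons; ratios NA")
  # percent-scale histograms, 1%-wide bins
  brk <- seq(0, 100 + bin_width, by = bin_width)
  hist_of <- function(x) {
    x <- x[!is.na(x)] * 100
    table(cut(x, breaks = brk, right = FALSE))
  }
  histogram <- data.frame(bin_low = brk[-length(brk)],
                          max_intra = as.integer(hist_of(gs$max_intra)),
                          nn_dist = as.integer(hist_of(gs$nn_dist)))
  histogram <- histogram[histogram$max_intra > 0 | histogram$nn_dist > 0, , drop = FALSE]
  structure(list(level = level, groups = gs,
                 overlap_exists = any(gs$overlap),
                 ratio_of_means = ratio_of_means,
                 mean_of_ratios = mean_of_ratios,
                 histogram = histogram),
            class = "gap_stats")
}

#' @export
print.gap_stats <- function(x, ...) {
  cat(sprintf("gap_stats [%s]: %d groups; nn/max-intra ratio of means %.3g (mean of ratios %.3g); overlap: %s\n",
              x$level, nrow(x$groups), x$ratio_of_means, x$mean_of_ratios,
              x$overlap_exists))
  invisible(x)
}

#' Species-by-OTU report table
#'
#' Lists every morphological species split into more than one consensus OTU,
#' with a species row (max intraspecific and nearest-neighbor K2P distances,
#' percent) followed by one sub-row per OTU restricted to that species'
#' members. Singleton OTUs show `NA` for the max-intra cell.
#'
#' @param consensus A [partition] (e.g. the consensus) over the same ids as
#'   `labels`.
#' @param labels Named character vector: record id -> morphological species.
#' @param mat A `k2p_matrix` or plain symmetric distance matrix over the
#'   same ids.
#' @return Data frame with columns `species`, `otu` (`NA` on species rows),
#'   `n_members`, `max_intra_pct`, `nn_dist_pct`; attribute
#'   `otus_per_species` tabulates how many species have 2, 3, ... OTUs.
#' @export
species_otu_table <- function(consensus, labels, mat) {
  d <- as_dist_matrix(mat)
  ids <- rownames(d)
  stopifnot(all(ids %in% names(labels)), all(ids %in% names(consensus$assignment)))
  sp <- labels[ids]
  otu <- consensus$assignment[ids]
  sp_stats <- group_stats(d, sp)
  otu_stats <- group_stats(d, otu)
  counts <- tapply(otu, sp, function(x) length(unique(x)))
  multi <- names(counts)[counts > 1L]
  rows <- list()
  for (s in sort(multi)) {
    srow <- sp_stats[sp_stats$group == s, ]
    rows[[length(rows) + 1L]] <- data.frame(
      species = s, otu = NA_character_, n_members = srow$n_members,
      max_intra_pct = 100 * srow$max_intra, nn_dist_pct = 100 * srow$nn_dist,
      stringsAsFactors = FALSE)
    for (o in sort(unique(otu[sp == s]))) {
      orow <- otu_stats[otu_stats$group == o, ]
      rows[[length(rows) + 1L]] <- data.frame(
        species = s, otu = o, n_members = orow$n_members,
        max_intra_pct = 100 * orow$max_intra, nn_dist_pct = 100 * orow$nn_dist,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), otu = character(0),
               n_members = integer(0), max_intra_pct = numeric(0),
               nn_dist_pct = numeric(0))
  attr(out, "otus_per_species") <- table(counts[counts > 1L])
  out
}
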