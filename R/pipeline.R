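#' Run the full delimitation pipeline
#'
#' Replicates the standard single-locus workflow: QC (length filter,
#' stop-codon screen) -> haplotype pruning -> K2P distances -> NJ tree (and
#' UPGMA chronogram, or an imported chronogram) -> the requested
#' delimitation methods -> majority consensus -> barcoding-gap statistics
#' and the species-by-OTU table. Haplotype pruning applies to the
#' delimitation inputs only; distance statistics are computed on the full
#' post-QC library, and OTU labels are propagated from each haplotype
#' representative back to all of its members.
#'
#' @param library A `barcode_library`, or `NULL` to read from `fasta`/
#'   `metadata` paths.
#' @param fasta,metadata Input file paths (used when `library` is `NULL`).
#' @param methods Character vector of delimitation methods, any of
#'   `"resl_like"`, `"abgd"`, `"ptp"`, `"mptp"`, `"gmyc"`, `"mgmyc"`.
#' @param min_len Minimum ungapped length for QC (bp).
#' @param resl_threshold Single-linkage threshold (substitutions/site).
#' @param quorum Consensus quorum in (0, 1].
#' @param outgroup_ids Optional outgroup tip ids; the NJ tree is rooted on
#'   them (required for `ptp`/`mptp`) and they are excluded from
#'   delimitation and gap statistics.
#' @param chronogram Optional imported ultrametric [ape::phylo] used for
#'   GMYC instead of the built-in UPGMA stand-in.
#' @param seed Integer seed for the stochastic searches.
#' @param out_dir Optional directory for artifacts (partitions, matrix,
#'   trees, summary JSON).
#' @return List of class `pipeline_result`: `qc` (reports), `matrix`,
#'   `nj_tree`, `chronogram`, `partitions` (per method, over all post-QC
#'   ingroup records), `consensus` (a `consensus_result`), `gap_species`,
#'   `gap_otu` (both `gap_stats`), `species_otu_table`, `summary` (named
#'   list with per-method OTU counts and the consensus count).
#' @export
run_pipeline <- function(library = NULL, fasta = NULL, metadata = NULL,
                         methods = c("resl_like", "abgd", "ptp", "mptp",
                                     "gmyc", "mgmyc"),
                         min_len = 400, resl_threshold = 0.022, quorum = 0.5,
                         outgroup_ids = NULL, chronogram = NULL, seed = 1L,
                         out_dir = NULL) {
  known <- c("resl_like", "abgd", "ptp", "mptp", "gmyc", "mgmyc")
  if (length(methods) == 0L || !all(methods %in% known)) {
    stop("methods must be a non-empty subset of: ", paste(known, collapse = ", "))
  }
  if (is.null(library)) library <- read_library(fasta, metadata)

  lf <- length_filter(library, min_len)
  if (is.null(lf$library)) stop("pipeline stage qc: no record passed the length filter")
  lib <- lf$library
  stops <- stop_codon_screen(lib)
  if (stops$n_flagged > 0L) {
    warning("pipeline stage qc: ", stops$n_flagged,
            " record(s) with stop codons in all frames: ",
            paste(utils::head(stops$flagged_ids, 5L), collapse = ", "))
  }

  ingroup_ids <- setdiff(names(lib$sequences), outgroup_ids)
  mat <- pairwise_matrix(lib)

  hap <- collapse_haplotypes(lib)
  hap_ids <- names(hap$library$sequences)
  hap_ingroup <- setdiff(hap_ids, outgroup_ids)
  mat_hap <- list(d = mat$d[hap_ids, hap_ids, drop = FALSE])
  mat_hap_in <- mat$d[hap_ingroup, hap_ingroup, drop = FALSE]

  nj <- NULL
  if (length(hap_ids) >= 3L) {
    nj <- nj_tree(mat_hap$d)
    if (!is.null(outgroup_ids) && any(outgroup_ids %in% hap_ids)) {
      nj <- root_with_outgroup(nj, intersect(outgroup_ids, hap_ids))
    }
  }
  chrono <- chronogram
  if (is.null(chrono) && any(c("gmyc", "mgmyc") %in% methods)) {
    chrono <- upgma_tree(mat_hap_in)
  }

  nj_ingroup <- NULL
  if (any(c("ptp", "mptp") %in% methods)) {
    nj_ingroup <- if (!is.null(outgroup_ids) && !is.null(nj)) {
      ape::drop.tip(nj, intersect(outgroup_ids, hap_ids))
    } else nj
    if (is.null(nj_ingroup)) stop("pipeline stage trees: PTP requires >= 3 haplotypes")
  }

  partitions <- list()
  for (m in methods) {
    p <- switch(m,
      resl_like = single_linkage_cluster(mat_hap_in, resl_threshold),
      abgd = select_abgd_partition(abgd_partition(mat_hap_in)),
      ptp = ptp_fit(nj_ingroup, mode = "single", seed = seed)$partition,
      mptp = ptp_fit(nj_ingroup, mode = "multi", seed = seed)$partition,
      gmyc = gmyc_fit(chrono, mode = "single")$partition,
      mgmyc = gmyc_fit(chrono, mode = "multi")$partition
    )
    partitions[[m]] <- expand_to_members(p, hap$members, ingroup_ids)
  }

  cons <- consensus_partition(partitions, quorum = quorum)

  labels <- stats::setNames(lib$metadata$species_label, lib$metadata$record_id)
  mat_in <- mat$d[ingroup_ids, ingroup_ids, drop = FALSE]
  gap_sp <- gap_stats(mat_in, labels[ingroup_ids], level = "species")
  gap_otu <- gap_stats(mat_in, cons$consensus$assignment, level = "otu")
  sp_table <- species_otu_table(cons$consensus, labels, mat_in)

  summary <- c(lapply(partitions, function(p) p$n_otus),
               list(consensus = cons$n_otus,
                    n_records = n_records(lib),
                    n_haplotypes = length(hap_ids),
                    gap_ratio_of_means_species = gap_sp$ratio_of_means,
                    gap_ratio_of_means_otu = gap_otu$ratio_of_means,
                    seed = seed))

  result <- structure(list(qc = list(length = lf$report, stop_codons = stops),
                           matrix = mat, nj_tree = nj, chronogram = chrono,
                           haplotype_members = hap$members,
                           partitions = partitions, consensus = cons,
                           gap_species = gap_sp, gap_otu = gap_otu,
                           species_otu_table = sp_table, summary = summary),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

# propagate OTU labels from haplotype representatives back to all members,
# restricted to the ingroup
expand_to_members <- function(p, members, ingroup_ids) {
  full <- character(0)
  for (rep_id in names(p$assignment)) {
    for (mid in members[[rep_id]]) full[mid] <- p$assignment[[rep_id]]
  }
  partition(full[intersect(names(full), ingroup_ids)],
            method = p$method, params = p$params)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", x$summary$n_records, "records,",
      x$summary$n_haplotypes, "haplotypes\n  OTU counts:\n")
  for (m in names(x$partitions)) {
    cat(sprintf("    %-10s %d\n", m, x$partitions[[m]]$n_otus))
  }
  cat(sprintf("    %-10s %d\n", "consensus", x$consensus$n_otus))
  invisible(x)
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_distance_matrix(result$matrix, file.path(out_dir, "k2p_matrix.tsv"))
  if (!is.null(result$nj_tree)) {
    write_newick(result$nj_tree, file.path(out_dir, "nj_tree.nwk"))
  }
  if (!is.null(result$chronogram)) {
    write_newick(result$chronogram, file.path(out_dir, "chronogram.nwk"))
  }
  for (m in names(result$partitions)) {
    write_partition(result$partitions[[m]],
                    file.path(out_dir, paste0("partition_", m, ".tsv")))
  }
  write_partition(result$consensus$consensus,
                  file.path(out_dir, "partition_consensus.tsv"))
  utils::write.table(result$species_otu_table,
                     file.path(out_dir, "species_otu_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$gap_otu$histogram,
                     file.path(out_dir, "gap_histogram_otu.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
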