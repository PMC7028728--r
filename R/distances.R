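#' Kimura 2-parameter distance between two aligned sequences
#'
#' Compares only sites where both sequences carry an unambiguous base
#' (pairwise deletion: gaps, N and other IUPAC ambiguity codes are skipped).
#' With transition proportion P (A<->G, C<->T) and transversion proportion Q
#' over the compared sites,
#' \deqn{d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).}
#'
#' @param seq_a,seq_b Aligned sequences of equal length (character strings).
#' @return List with `distance` (substitutions/site; `NA` when no site is
#'   comparable or the correction saturates), `n_sites` (compared positions)
#'   and `saturated` (logical).
#' @export
k2p_distance <- function(seq_a, seq_b) {
  a <- charToRaw(toupper(seq_a))
  b <- charToRaw(toupper(seq_b))
  if (length(a) != length(b)) stop("sequences must be aligned to equal length")
  k2p_from_codes(base_codes(a), base_codes(b))
}

# A=1, C=2, G=3, T=4, anything else (gap, N, ambiguity) = NA
base_codes <- function(raw) {
  code <- rep(NA_integer_, length(raw))
  code[raw == charToRaw("A")] <- 1L
  code[raw == charToRaw("C")] <- 2L
  code[raw == charToRaw("G")] <- 3L
  code[raw == charToRaw("T")] <- 4L
  code
}

# purine = codes {1,3}; a substitution within purines or within pyrimidines
# is a transition, across is a transversion
k2p_from_codes <- function(ca, cb) {
  ok <- !is.na(ca) & !is.na(cb)
  n <- sum(ok)
  if (n == 0L) {
    return(list(distance = NA_real_, n_sites = 0L, saturated = FALSE))
  }
  ca <- ca[ok]; cb <- cb[ok]
  diff <- ca != cb
  pur_a <- ca == 1L | ca == 3L
  pur_b <- cb == 1L | cb == 3L
  ts <- sum(diff & (pur_a == pur_b))
  tv <- sum(diff) - ts
  P <- ts / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(distance = NA_real_, n_sites = n, saturated = TRUE))
  }
  list(distance = -0.5 * log(w1) - 0.25 * log(w2), n_sites = n, saturated = FALSE)
}

#' Pairwise K2P distance matrix for a barcode library
#'
#' @param lib A `barcode_library` with at least 2 records.
#' @return A `k2p_matrix`: list with `ids`, `d` (symmetric matrix of
#'   distances in substitutions/site, `NA` where undefined/saturated),
#'   `n_sites` (symmetric matrix of compared-site counts) and `n_saturated`.
#' @export
pairwise_matrix <- function(lib) {
  n <- n_records(lib)
  if (n < 2L) stop("need at least 2 records for a distance matrix")
  ids <- names(lib$sequences)
  codes <- lapply(lib$sequences, function(s) base_codes(charToRaw(s)))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  ns <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(ns) <- vapply(codes, function(x) sum(!is.na(x)), 1L)
  n_sat <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- k2p_from_codes(codes[[i]], codes[[j]])
      d[i, j] <- d[j, i] <- r$distance
      ns[i, j] <- ns[j, i] <- r$n_sites
      if (r$saturated) n_sat <- n_sat + 1L
    }
  }
  if (n_sat > 0L) message("pairwise_matrix: ", n_sat, " saturated pair(s) set to NA")
  structure(list(ids = ids, d = d, n_sites = ns, n_saturated = n_sat),
            class = "k2p_matrix")
}

#' @export
print.k2p_matrix <- function(x, ...) {
  cat("k2p_matrix:", length(x$ids), "records; max distance",
      format(max(x$d, na.rm = TRUE), digits = 4),
      "subs/site;", x$n_saturated, "saturated pair(s)\n")
  invisible(x)
}

as_dist_matrix <- function(x) {
  if (inherits(x, "k2p_matrix")) return(x$d)
  if (is.matrix(x)) return(x)
  stop("expected a k2p_matrix or a plain symmetric matrix")
}

#' Per-group maximum intraspecific and nearest-neighbor distances
#'
#' For each group (species or OTU): the maximum pairwise distance among its
#' members (`NA` for singletons) and the minimum distance from any member to
#' any non-member, together with the label of that nearest-neighbor group.
#' `NA` (saturated/undefined) cells are excluded with a warning.
#'
#' @param mat A `k2p_matrix` or plain symmetric distance matrix with
#'   dimnames.
#' @param labels Named character vector mapping every record id in `mat` to
#'   a group label.
#' @return Data frame with columns `group`, `n_members`, `max_intra`,
#'   `nn_dist`, `nn_label`.
#' @export
group_stats <- function(mat, labels) {
  d <- as_dist_matrix(mat)
  ids <- rownames(d)
  if (!all(ids %in% names(labels))) {
    stop("unlabelled record ids: ",
         paste(utils::head(setdiff(ids, names(labels)), 5L), collapse = ", "))
  }
  lab <- labels[ids]
  groups <- sort(unique(lab))
  if (length(groups) < 2L) {
    stop("nearest-neighbor distance undefined with a single group")
  }
  if (anyNA(d[upper.tri(d)])) {
    warning("group_stats: NA (saturated/undefined) distances excluded")
  }
  out <- data.frame(group = groups, n_members = NA_integer_,
                    max_intra = NA_real_, nn_dist = NA_real_,
                    nn_label = NA_character_, stringsAsFactors = FALSE)
  for (g in seq_along(groups)) {
    in_g <- lab == groups[g]
    out$n_members[g] <- sum(in_g)
    if (sum(in_g) > 1L) {
      intra <- d[in_g, in_g, drop = FALSE]
      vals <- intra[upper.tri(intra)]
      out$max_intra[g] <- if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
    }
    between <- d[in_g, !in_g, drop = FALSE]
    if (all(is.na(between))) next
    idx <- which(between == min(between, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    out$nn_dist[g] <- between[idx[1L], idx[2L]]
    out$nn_label[g] <- unname(lab[!in_g][idx[2L]])
  }
  out
}

#' Write a distance matrix as square TSV
#' @param mat A `k2p_matrix` or plain matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(mat, path) {
  d <- as_dist_matrix(mat)
  utils::write.table(cbind(record_id = rownames(d), as.data.frame(d)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
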