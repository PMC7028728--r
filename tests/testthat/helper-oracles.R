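# Shared fixtures and independent oracles, all built in code.

random_seq <- function(n, gap_frac = 0, n_frac = 0) {
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (gap_frac > 0) s[sample.int(n, round(gap_frac * n))] <- "-"
  if (n_frac > 0) s[sample.int(n, round(n_frac * n))] <- "N"
  paste(s, collapse = "")
}

# independent K2P evaluation: count transitions/transversions over
# unambiguous site pairs, then the closed form in one line
k2p_reference <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[ok]; bv <- bv[ok]
  n <- length(av)
  if (n == 0) return(NA_real_)
  purine <- function(x) x %in% c("A", "G")
  ts <- sum(av != bv & purine(av) == purine(bv))
  tv <- sum(av != bv) - ts
  P <- ts / n; Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# mutate a reference sequence to hit exact transition/transversion counts
seq_pair_with_counts <- function(n, n_ts, n_tv) {
  base <- rep(c("A", "C", "G", "T"), length.out = n)
  other <- base
  ts_map <- c(A = "G", C = "T", G = "A", T = "C")
  tv_map <- c(A = "C", C = "A", G = "T", T = "G")
  idx <- seq_len(n_ts + n_tv)
  for (i in idx[seq_len(n_ts)]) other[i] <- ts_map[base[i]]
  for (i in idx[-seq_len(n_ts)]) other[i] <- tv_map[base[i]]
  list(a = paste(base, collapse = ""), b = paste(other, collapse = ""))
}

make_library <- function(seqs, species = NULL) {
  if (is.null(names(seqs))) names(seqs) <- sprintf("r%02d", seq_along(seqs))
  meta <- data.frame(record_id = names(seqs),
                     species_label = species %||% names(seqs),
                     stringsAsFactors = FALSE)
  barcode_library(seqs, meta)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# enumerate every delimitation (antichain covering all tips) of a tree
enum_delims <- function(st, v = st$root) {
  if (st$is_tip[v]) return(list(v))
  kids <- st$children[[v]]
  subs <- lapply(kids, function(c) enum_delims(st, c))
  out <- list(v)
  for (a in subs[[1]]) for (b in subs[[2]]) out <- c(out, list(c(a, b)))
  out
}

# naive PTP likelihood: classify every branch by walking rootward from its
# child, then sum per-class exponential profile log-likelihoods
naive_ptp_ll <- function(tree, roots, mode, min_br = 1e-4) {
  st <- barcodelim:::tree_struct(tree)
  cls <- function(n, S) if (n == 0) 0 else n * log(n / S) - n
  spec <- c(0, 0); coal <- list()
  for (ch in which(!is.na(st$parent))) {
    len <- st$edge_len_by_child[ch]
    if (len < min_br) next
    v <- st$parent[ch]; owner <- NA
    while (!is.na(v)) { if (v %in% roots) { owner <- v; break }; v <- st$parent[v] }
    if (ch %in% roots) owner <- NA   # the edge entering a species root speciates
    if (is.na(owner)) spec <- spec + c(1, len)
    else {
      key <- as.character(owner)
      coal[[key]] <- (coal[[key]] %||% c(0, 0)) + c(1, len)
    }
  }
  ll <- cls(spec[1], spec[2])
  if (mode == "single") {
    tot <- Reduce(`+`, coal)
    if (!is.null(tot)) ll <- ll + cls(tot[1], tot[2])
  } else for (k in coal) ll <- ll + cls(k[1], k[2])
  ll
}

# distance matrix with exact group structure (no sequences involved)
block_matrix <- function(sizes, intra, inter) {
  ids <- unlist(lapply(seq_along(sizes), function(g)
    sprintf("g%d_%d", g, seq_len(sizes[g]))))
  lab <- rep(seq_along(sizes), sizes)
  d <- outer(lab, lab, function(a, b) ifelse(a == b, intra, inter))
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  list(d = d, labels = stats::setNames(sprintf("sp%d", lab), ids))
}
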