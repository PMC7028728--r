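#' Simulation configuration for synthetic barcode libraries
#'
#' Defaults emulate a well-sampled COI barcode library of a moderately
#' recent radiation: 10 species, 10 specimens each, 651 bp, maximum
#' within-species divergence around 1% (expected within-species TMRCA of
#' 0.5% yields deepest intraspecific pairwise divergences near 1%, the
#' quantity barcoding-gap analyses compare against nearest neighbors) and
#' between-species divergence around 10%, under a strict clock of 0.012
#' substitutions/site/My (the conventional 1.2% pairwise COI divergence per
#' million years).
#'
#' All heights are handled internally in expected substitutions/site;
#' [scale_to_time()] converts trees to million-year units.
#'
#' @param n_species Number of species (>= 1).
#' @param samples_per_species Integer, or integer vector of length
#'   `n_species`.
#' @param yule_rate Speciation rate of the species tree, per lineage per
#'   unit of substitutions/site.
#' @param min_split Offset added to every species-tree node height
#'   (substitutions/site); keeps the shallowest split clear of the
#'   coalescent scale so intra- vs inter-specific divergence is controlled.
#' @param coal_depth_mean Expected within-species TMRCA in
#'   substitutions/site.
#' @param seq_length Alignment length in bp (default 651).
#' @param kappa Transition/transversion rate ratio (default 4).
#' @param clock_rate Substitutions/site/My (default 0.012).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param outgroup If `TRUE`, add one distant outgroup record.
#' @param outgroup_depth Divergence of the outgroup stem above the ingroup
#'   root (substitutions/site).
#' @param orf_preserving If `TRUE`, the root sequence is built from sense
#'   codons and substitutions creating an in-frame stop (frame 1,
#'   vertebrate mitochondrial code) are rejected, so the library passes
#'   [stop_codon_screen()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 10L, samples_per_species = 10L,
                       yule_rate = 40, min_split = 0.03,
                       coal_depth_mean = 0.005, seq_length = 651L,
                       kappa = 4, clock_rate = 0.012, seed,
                       outgroup = FALSE, outgroup_depth = 0.12,
                       orf_preserving = FALSE) {
  if (missing(seed)) stop("sim_config: a seed is mandatory")
  if (length(samples_per_species) == 1L) {
    samples_per_species <- rep(as.integer(samples_per_species), n_species)
  }
  stopifnot(n_species >= 1L, length(samples_per_species) == n_species,
            all(samples_per_species >= 1L), yule_rate > 0, min_split >= 0,
            coal_depth_mean > 0, seq_length >= 3L, kappa > 0, clock_rate > 0)
  structure(list(n_species = as.integer(n_species),
                 samples_per_species = samples_per_species,
                 yule_rate = yule_rate, min_split = min_split,
                 coal_depth_mean = coal_depth_mean,
                 seq_length = as.integer(seq_length), kappa = kappa,
                 clock_rate = clock_rate, seed = as.integer(seed),
                 outgroup = outgroup, outgroup_depth = outgroup_depth,
                 orf_preserving = orf_preserving),
            class = "sim_config")
}

# random joining of labelled lineages with per-stage exponential waiting
# times; rate_fun(k) = total event rate while k lineages remain.
# Returns a rooted ultrametric phylo.
join_lineages <- function(labels, rate_fun) {
  k <- length(labels)
  frag <- labels
  height <- rep(0, k)
  t <- 0
  while (k > 1L) {
    t <- t + stats::rexp(1L, rate_fun(k))
    pair <- sort(sample.int(k, 2L))
    i <- pair[1L]; j <- pair[2L]
    frag[i] <- sprintf("(%s:%.12g,%s:%.12g)",
                       frag[i], t - height[i], frag[j], t - height[j])
    height[i] <- t
    frag <- frag[-j]; height <- height[-j]
    k <- k - 1L
  }
  ape::read.tree(text = paste0(frag, ";"))
}

#' Simulate species and gene trees
#'
#' The species tree is a Yule (pure-birth) tree of `n_species` tips,
#' simulated backward as random joins with Exp(k * yule_rate) waiting times
#' while k lineages remain (so E(root height) = sum_{k=2..S} 1/(k lambda)),
#' then raised by `min_split`. Within each species a Kingman coalescent
#' genealogy of its samples is grafted at the species tip; genealogies
#' deeper than the species' attachment point are redrawn, so the gene tree
#' is ultrametric and species are monophyletic by construction (incomplete
#' lineage sorting is deliberately not modelled). Heights are expected
#' substitutions/site.
#'
#' @param config A [sim_config].
#' @return List with `species_tree` and `gene_tree` (rooted ultrametric
#'   [ape::phylo]); gene-tree tips are record ids `<species>_<k>`, species
#'   are `sp01`, `sp02`, ...
#' @export
simulate_trees <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  S <- config$n_species
  sp_names <- sprintf("sp%02d", seq_len(S))
  if (S == 1L) {
    species_tree <- NULL
  } else {
    species_tree <- join_lineages(sp_names, function(k) k * config$yule_rate)
    species_tree$edge.length <- species_tree$edge.length +
      config$min_split * (species_tree$edge[, 2L] <= ape::Ntip(species_tree))
  }
  # pendant-edge slack available below each species' attachment point
  slack <- if (S == 1L) Inf else {
    pe <- species_tree$edge.length[match(seq_len(S), species_tree$edge[, 2L])]
    stats::setNames(pe, species_tree$tip.label)[sp_names]
  }
  sub <- vector("list", S)
  for (s in seq_len(S)) {
    m <- config$samples_per_species[s]
    tips <- sprintf("%s_%02d", sp_names[s], seq_len(m))
    if (m == 1L) { sub[[s]] <- tips; next }
    # Kingman: Exp(choose(k,2)/nu) waits; nu set so E(TMRCA) = coal_depth_mean
    nu <- config$coal_depth_mean / (2 * (1 - 1 / m))
    repeat {
      g <- join_lineages(tips, function(k) k * (k - 1) / (2 * nu))
      depth <- max(ape::node.depth.edgelength(g))
      if (depth < slack[s]) break        # redraw genealogies deeper than the stem
    }
    sub[[s]] <- g
  }
  if (S == 1L) {
    gene_tree <- if (is.character(sub[[1L]])) {
      ape::read.tree(text = sprintf("(%s:0);", sub[[1L]]))
    } else sub[[1L]]
    return(list(species_tree = NULL, gene_tree = gene_tree))
  }
  # graft: replace each species tip by its genealogy, shortening the
  # pendant edge by the genealogy depth to keep the tree ultrametric
  frag <- ape::write.tree(species_tree)
  for (s in seq_len(S)) {
    if (is.character(sub[[s]])) {
      rep_txt <- sprintf("%s_01", sp_names[s])
      depth <- 0
    } else {
      rep_txt <- sub(";$", "", ape::write.tree(sub[[s]]))
      depth <- max(ape::node.depth.edgelength(sub[[s]]))
    }
    m <- regexpr(sprintf("%s:([0-9.eE+-]+)", sp_names[s]), frag)
    stopifnot(m > 0)
    token <- regmatches(frag, m)
    pe <- as.numeric(sub(sprintf("%s:", sp_names[s]), "", token))
    regmatches(frag, m) <- sprintf("%s:%.12g", rep_txt, pe - depth)
  }
  list(species_tree = species_tree, gene_tree = ape::read.tree(text = frag))
}

# K80 transition probabilities for expected divergence t (subs/site):
# alpha/(alpha+2beta)=kappa normalisation so that alpha+2beta = 1
k80_probs <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1          # each of the two transversion targets
  c(same = 1 - p_ts - 2 * p_tv, ts = p_ts, tv = p_tv)
}

BASES <- c("A", "C", "G", "T")
# transition partner (A<->G, C<->T) and the two transversion partners
TS_OF <- c(A = 3L, C = 4L, G = 1L, T = 2L)
TV_OF <- list(A = c(2L, 4L), C = c(1L, 3L), G = c(2L, 4L), T = c(1L, 3L))

#' Evolve sequences along a gene tree under the K80 model
#'
#' The root sequence is uniform over A, C, G, T per site (or built from
#' sense codons when `orf_preserving`); each branch applies the K80
#' (Kimura two-parameter) substitution process with expected `branch
#' length` substitutions/site and transition/transversion ratio `kappa`.
#' With `orf_preserving`, any codon that would acquire an in-frame stop
#' (frame 1, vertebrate mitochondrial code) is reverted to its parent
#' state, a small perturbation that keeps the reading frame open.
#'
#' @param gene_tree Rooted [ape::phylo] with branch lengths in
#'   substitutions/site; tip labels become record ids.
#' @param config A [sim_config] (uses `seq_length`, `kappa`,
#'   `orf_preserving`; the RNG state is taken as-is so the caller controls
#'   seeding).
#' @return A `barcode_library` with `species_label` parsed from tip ids
#'   (`<species>_<k>`).
#' @export
evolve_sequences <- function(gene_tree, config) {
  st <- tree_struct(gene_tree)
  L <- config$seq_length
  seqs <- vector("list", st$n_nodes)
  seqs[[st$root]] <- if (config$orf_preserving) random_orf(L) else
    sample.int(4L, L, replace = TRUE)
  for (v in st$preorder) {
    if (v == st$root) next
    parent_seq <- seqs[[st$parent[v]]]
    child <- mutate_k80(parent_seq, st$edge_len_by_child[v], config$kappa)
    if (config$orf_preserving) child <- revert_stop_codons(child, parent_seq)
    seqs[[v]] <- child
  }
  out <- vapply(which(st$is_tip),
                function(v) paste(BASES[seqs[[v]]], collapse = ""), "")
  names(out) <- st$tip_labels
  species <- sub("_[0-9]+$", "", names(out))
  meta <- data.frame(record_id = names(out), species_label = species,
                     site_id = NA_character_, region = NA_character_,
                     source = "generated", stringsAsFactors = FALSE)
  barcode_library(out, meta)
}

mutate_k80 <- function(seq_codes, t, kappa) {
  if (is.na(t) || t <= 0) return(seq_codes)
  p <- k80_probs(t, kappa)
  u <- stats::runif(length(seq_codes))
  out <- seq_codes
  is_ts <- u < p["ts"]
  is_tv <- !is_ts & u < p["ts"] + 2 * p["tv"]
  out[is_ts] <- TS_OF[seq_codes[is_ts]]
  if (any(is_tv)) {
    pick <- 1L + (stats::runif(sum(is_tv)) < 0.5)
    out[is_tv] <- mapply(function(b, k) TV_OF[[b]][k], seq_codes[is_tv], pick)
  }
  out
}

# codon table positions of vertebrate-mito stop codons in integer coding
is_stop_codon <- function(c1, c2, c3) {
  # TAA, TAG, AGA, AGG with A=1, C=2, G=3, T=4
  (c1 == 4L & c2 == 1L & (c3 == 1L | c3 == 3L)) |
    (c1 == 1L & c2 == 3L & (c3 == 1L | c3 == 3L))
}

random_orf <- function(L) {
  n_codons <- ceiling(L / 3)
  out <- integer(0)
  while (length(out) < L) {
    cod <- sample.int(4L, 3L * n_codons, replace = TRUE)
    m <- matrix(cod, nrow = 3L)
    keep <- !is_stop_codon(m[1L, ], m[2L, ], m[3L, ])
    out <- c(out, as.integer(m[, keep]))
  }
  out[seq_len(L)]
}

revert_stop_codons <- function(child, parent) {
  n_codons <- length(child) %/% 3L
  if (n_codons == 0L) return(child)
  idx <- 3L * (seq_len(n_codons) - 1L)
  bad <- is_stop_codon(child[idx + 1L], child[idx + 2L], child[idx + 3L])
  for (i in which(bad)) {
    child[idx[i] + 1:3] <- parent[idx[i] + 1:3]
  }
  child
}

#' Generate a benchmark barcode library with known truth
#'
#' One call simulates the trees, evolves sequences (ORF-preserving so the
#' stop-codon screen passes), optionally adds a distant outgroup record,
#' and returns the library together with its ground truth. With `out_dir`
#' the FASTA, metadata TSV, gene-tree newick and truth TSV are also written
#' to disk.
#'
#' @param config A [sim_config]; `make_benchmark(seed = 1)` uses defaults.
#' @param out_dir Optional output directory.
#' @param seed Convenience: used to build a default config when `config` is
#'   missing.
#' @return List with `library` (a `barcode_library`), `truth` (a
#'   [partition] named by the true species), `species_tree`, `gene_tree`.
#' @export
make_benchmark <- function(config, out_dir = NULL, seed = NULL) {
  if (missing(config)) {
    if (is.null(seed)) stop("provide a config or a seed")
    config <- sim_config(seed = seed, orf_preserving = TRUE)
  }
  trees <- simulate_trees(config)
  gene_tree <- trees$gene_tree
  if (config$outgroup) {
    h <- max(ape::node.depth.edgelength(gene_tree))
    txt <- sub(";$", "", ape::write.tree(gene_tree))
    gene_tree <- ape::read.tree(text = sprintf(
      "(%s:%.12g,outgroup_01:%.12g);", txt, config$outgroup_depth,
      h + config$outgroup_depth))
  }
  lib <- evolve_sequences(gene_tree, config)
  truth <- partition(
    stats::setNames(lib$metadata$species_label, lib$metadata$record_id),
    method = "truth", params = list(seed = config$seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_library(lib, file.path(out_dir, "benchmark.fasta"),
                  file.path(out_dir, "benchmark_metadata.tsv"))
    write_newick(gene_tree, file.path(out_dir, "benchmark_gene_tree.nwk"))
    write_partition(truth, file.path(out_dir, "benchmark_truth.tsv"))
  }
  list(library = lib, truth = truth,
       species_tree = trees$species_tree, gene_tree = gene_tree)
}
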