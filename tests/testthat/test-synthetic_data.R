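test_that("simulation is deterministic under a fixed seed", {
  a <- make_benchmark(seed = 42)
  b <- make_benchmark(seed = 42)
  expect_identical(a$library$sequences, b$library$sequences)
  expect_identical(ape::write.tree(a$gene_tree), ape::write.tree(b$gene_tree))
  c <- make_benchmark(seed = 43)
  expect_false(identical(a$library$sequences, c$library$sequences))
})

test_that("a single species yields a pure coalescent genealogy", {
  cfg <- sim_config(n_species = 1, samples_per_species = 12, seed = 5)
  tr <- simulate_trees(cfg)
  expect_null(tr$species_tree)
  expect_equal(ape::Ntip(tr$gene_tree), 12L)
  expect_true(tree_is_ultrametric(tr$gene_tree, tol = 1e-8))
})

test_that("yule root height matches the harmonic-sum expectation", {
  lambda <- 1
  n <- 5
  set.seed(6)
  heights <- replicate(300, {
    tr <- barcodelim:::join_lineages(sprintf("t%d", 1:n), function(k) k * lambda)
    max(ape::node.depth.edgelength(tr))
  })
  theory <- sum(1 / (2:n * lambda))   # E(height) = sum_k 1/(k lambda)
  expect_equal(mean(heights), theory, tolerance = 0.15)
})

test_that("zero-length branches leave sequences identical", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  cfg <- sim_config(seed = 1)
  set.seed(1)
  lib <- evolve_sequences(tr, cfg)
  expect_equal(length(unique(lib$sequences)), 1L)
})

test_that("k2p estimates are consistent for a known divergence", {
  cfg <- sim_config(seed = 2, seq_length = 651L)
  tr <- ape::read.tree(text = "(a_01:0.05,b_01:0.05);")   # divergence 0.1
  set.seed(2)
  d <- replicate(200, {
    lib <- evolve_sequences(tr, cfg)
    k2p_distance(lib$sequences[["a_01"]], lib$sequences[["b_01"]])$distance
  })
  expect_equal(mean(d), 0.1, tolerance = 0.01)      # within 10% of the truth
})

test_that("kappa = 1 gives the Kimura 1:2 transition:transversion ratio", {
  cfg <- sim_config(seed = 3, kappa = 1, seq_length = 6000L)
  tr <- ape::read.tree(text = "(a_01:0.01,b_01:0.01);")
  set.seed(3)
  ts <- 0; tv <- 0
  for (i in 1:20) {
    lib <- evolve_sequences(tr, cfg)
    a <- strsplit(lib$sequences[["a_01"]], "")[[1]]
    b <- strsplit(lib$sequences[["b_01"]], "")[[1]]
    diff <- a != b
    pur <- function(x) x %in% c("A", "G")
    ts <- ts + sum(diff & pur(a) == pur(b))
    tv <- tv + sum(diff & pur(a) != pur(b))
  }
  expect_equal(ts / tv, 0.5, tolerance = 0.15)
})

test_that("the default benchmark has 100 records and a 10-species truth", {
  bm <- make_benchmark(seed = 9)
  expect_equal(n_records(bm$library), 100L)
  expect_equal(bm$truth$n_otus, 10L)
  expect_equal(bm$library$alignment_length, 651L)
  expect_true(tree_is_ultrametric(bm$gene_tree, tol = 1e-8))
  expect_setequal(names(bm$truth$assignment), names(bm$library$sequences))
})

test_that("single-sample species become singletons; outgroup adds one record", {
  cfg <- sim_config(n_species = 4, samples_per_species = 1, seed = 10)
  bm <- make_benchmark(cfg)
  expect_equal(n_records(bm$library), 4L)
  expect_equal(bm$truth$n_otus, 4L)
  cfg_og <- sim_config(seed = 12, outgroup = TRUE, orf_preserving = TRUE)
  bm_og <- make_benchmark(cfg_og)
  expect_equal(n_records(bm_og$library), 101L)
  expect_true("outgroup" %in% bm_og$library$metadata$species_label)
  expect_true(tree_is_ultrametric(bm_og$gene_tree, tol = 1e-8))
})

test_that("within-species distances fall stochastically below between-species", {
  for (s in 1:3) {
    bm <- make_benchmark(seed = s)
    mat <- suppressMessages(pairwise_matrix(bm$library))
    sp <- sub("_[0-9]+$", "", mat$ids)
    same <- outer(sp, sp, "==") & upper.tri(mat$d)
    diffm <- outer(sp, sp, "!=") & upper.tri(mat$d)
    expect_lt(stats::quantile(mat$d[same], 0.95), min(mat$d[diffm]))
  }
})

test_that("benchmark files land on disk as plain text", {
  out <- file.path(tempdir(), "bm_out")
  bm <- make_benchmark(sim_config(n_species = 3, samples_per_species = 2, seed = 8,
                                  orf_preserving = TRUE), out_dir = out)
  expect_true(file.exists(file.path(out, "benchmark.fasta")))
  expect_true(file.exists(file.path(out, "benchmark_metadata.tsv")))
  expect_true(file.exists(file.path(out, "benchmark_gene_tree.nwk")))
  expect_true(file.exists(file.path(out, "benchmark_truth.tsv")))
  back <- read_library(file.path(out, "benchmark.fasta"),
                       file.path(out, "benchmark_metadata.tsv"))
  expect_identical(back$sequences, bm$library$sequences)
  unlink(out, recursive = TRUE)
})
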