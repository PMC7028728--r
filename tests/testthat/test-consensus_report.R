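mk_part <- function(groups, method = "m") {
  assignment <- unlist(lapply(groups, function(g) setNames(rep(g[1], length(g)), g)))
  partition(assignment, method = method)
}

test_that("consensus reproduces the hand-worked majority example", {
  p1 <- mk_part(list(c("A", "B"), "C"), "m1")
  p2 <- mk_part(list(c("A", "B"), "C"), "m2")
  p3 <- mk_part(list("A", "B", "C"), "m3")
  res <- consensus_partition(list(p1, p2, p3))
  expect_equal(res$co_assignment["A", "B"], 2 / 3)
  expect_equal(res$co_assignment["A", "C"], 0)
  expect_equal(res$n_otus, 2L)
  expect_equal(res$consensus$assignment[["A"]], res$consensus$assignment[["B"]])
  expect_equal(unname(diag(res$co_assignment)), rep(1, 3))
})

test_that("consensus of identical inputs, or one input, is that partition", {
  p <- mk_part(list(c("A", "B"), c("C", "D")))
  res1 <- consensus_partition(list(p))
  expect_identical(res1$consensus$assignment, p$assignment)
  res3 <- consensus_partition(list(p, p, p))
  expect_identical(res3$consensus$assignment, p$assignment)
  expect_equal(res3$n_transitive_pairs, 0L)
})

test_that("chained above-quorum pairs merge with a transitivity diagnostic", {
  p1 <- mk_part(list(c("A", "B"), "C"), "m1")
  p2 <- mk_part(list(c("B", "C"), "A"), "m2")
  expect_message(res <- consensus_partition(list(p1, p2)), "transitivity")
  expect_equal(res$co_assignment["A", "B"], 0.5)
  expect_equal(res$co_assignment["B", "C"], 0.5)
  expect_equal(res$co_assignment["A", "C"], 0)
  expect_equal(res$n_otus, 1L)          # A-B-C chained through B
  expect_equal(res$n_transitive_pairs, 1L)
})

test_that("consensus validates id sets and quorum bounds", {
  p1 <- mk_part(list(c("A", "B")))
  p2 <- mk_part(list(c("A", "C")))
  expect_error(consensus_partition(list(p1, p2)), "mismatched")
  expect_error(consensus_partition(list(p1), quorum = 0), "quorum")
})

test_that("consensus recovers the truth on a well-separated benchmark", {
  bm <- make_benchmark(seed = 11)
  res <- suppressMessages(suppressWarnings(
    run_pipeline(library = bm$library, seed = 11,
                 methods = c("resl_like", "abgd", "gmyc"))))
  truth <- bm$truth$assignment
  cons <- res$consensus$consensus$assignment[names(truth)]
  expect_true(all(outer(truth, truth, "==") == outer(cons, cons, "==")))
})

test_that("gap statistics compute both fold-change definitions exactly", {
  bm <- block_matrix(c(3, 3), intra = 0.01, inter = 0.05)
  gs <- gap_stats(bm$d, bm$labels, level = "species")
  expect_equal(gs$ratio_of_means, 5.0, tolerance = 1e-9)
  expect_equal(gs$mean_of_ratios, 5.0, tolerance = 1e-9)
  expect_false(gs$overlap_exists)
  expect_equal(gs$level, "species")
})

test_that("overlap is flagged when a group's max intra exceeds its nn distance", {
  ids <- c("a1", "a2", "b1", "b2")
  d <- matrix(c(0, .06, .02, .02,
                .06, 0, .02, .02,
                .02, .02, 0, .01,
                .02, .02, .01, 0), 4, 4, dimnames = list(ids, ids))
  labs <- setNames(c("a", "a", "b", "b"), ids)
  gs <- gap_stats(d, labs)
  expect_true(gs$overlap_exists)
  expect_true(gs$groups$overlap[gs$groups$group == "a"])
  expect_false(gs$groups$overlap[gs$groups$group == "b"])
})

test_that("singleton groups are excluded from max-intra means but keep nn", {
  ids <- c("a1", "a2", "b1")
  d <- matrix(c(0, .01, .05, .01, 0, .05, .05, .05, 0), 3, 3,
              dimnames = list(ids, ids))
  labs <- setNames(c("a", "a", "b"), ids)
  gs <- gap_stats(d, labs)
  expect_equal(gs$ratio_of_means, mean(c(0.05, 0.05)) / 0.01)
  # all-singleton grouping: ratios undefined
  d2 <- d[1:2, 1:2]
  expect_message(gs2 <- gap_stats(d2, setNames(c("x", "y"), ids[1:2])), "singleton")
  expect_true(is.na(gs2$ratio_of_means))
  # histogram uses 1%-wide bins on the percent scale
  expect_true(all(gs$histogram$bin_low %in% seq(0, 100)))
  expect_equal(sum(gs$histogram$nn_dist), 2L)
})

test_that("species-by-OTU table lists only species split into multiple OTUs", {
  ids <- c("s1a", "s1b", "s1c", "s2a", "s2b")
  species <- setNames(c("sp1", "sp1", "sp1", "sp2", "sp2"), ids)
  # sp1 splits into {s1a, s1b} + {s1c}; sp2 stays whole
  otus <- partition(setNames(c("o1", "o1", "o2", "o3", "o3"), ids), "consensus")
  d <- matrix(0.1, 5, 5, dimnames = list(ids, ids))
  d[1, 2] <- d[2, 1] <- 0.005
  d[1, 3] <- d[3, 1] <- d[2, 3] <- d[3, 2] <- 0.03
  d[4, 5] <- d[5, 4] <- 0.004
  diag(d) <- 0
  tab <- species_otu_table(otus, species, d)
  expect_setequal(unique(tab$species), "sp1")
  expect_equal(sum(is.na(tab$otu)), 1L)          # one species header row
  expect_equal(sum(!is.na(tab$otu)), 2L)         # two OTU sub-rows
  expect_equal(tab$max_intra_pct[is.na(tab$otu)], 3)
  expect_true(is.na(tab$max_intra_pct[which(tab$otu == "o2")]))  # singleton OTU
  expect_equal(unname(attr(tab, "otus_per_species")["2"]), 1L)
})
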