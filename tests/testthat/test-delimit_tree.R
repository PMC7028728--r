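test_that("ptp separates two divergent clades and matches the exhaustive optimum", {
  set.seed(41)
  # two 5-tip clades: coalescent-scale branches inside, long stems between
  mk_clade <- function(tag) {
    d <- matrix(0.002, 5, 5); diag(d) <- 0
    d <- d + matrix(runif(25, 0, 5e-4), 5, 5)
    d <- (d + t(d)) / 2; diag(d) <- 0
    dimnames(d) <- list(paste0(tag, 1:5), paste0(tag, 1:5))
    upgma_tree(d)
  }
  a <- ape::write.tree(mk_clade("a")); b <- ape::write.tree(mk_clade("b"))
  tr <- ape::read.tree(text = sprintf("(%s:0.2,%s:0.2);",
                                      sub(";$", "", a), sub(";$", "", b)))
  fit <- ptp_fit(tr, mode = "single", seed = 1)
  expect_equal(fit$partition$n_otus, 2L)
  st <- barcodelim:::tree_struct(tr)
  lls <- sapply(enum_delims(st), function(r) naive_ptp_ll(tr, r, "single"))
  expect_equal(fit$model$log_likelihood, max(lls), tolerance = 1e-9)
})

test_that("ptp prefers one species on a star-like equal-branch tree", {
  tr <- ape::read.tree(text = "(((a:.1,b:.1):.1,(c:.1,d:.1):.1):.1,((e:.1,f:.1):.1,(g:.1,h:.1):.1):.1);")
  for (mode in c("single", "multi")) {
    fit <- ptp_fit(tr, mode = mode, seed = 2)
    expect_equal(fit$partition$n_otus, 1L)
    st <- barcodelim:::tree_struct(tr)
    lls <- sapply(enum_delims(st), function(r) naive_ptp_ll(tr, r, mode))
    expect_equal(fit$model$log_likelihood, max(lls), tolerance = 1e-9)
  }
})

test_that("ptp search is robust to the number of restarts", {
  set.seed(42)
  tr <- ape::rtree(10, br = function(k) runif(k, 0.001, 0.3))
  f0 <- ptp_fit(tr, n_restarts = 0)
  f10 <- ptp_fit(tr, n_restarts = 10, seed = 7)
  expect_equal(f0$model$log_likelihood, f10$model$log_likelihood, tolerance = 1e-9)
})

test_that("ptp likelihood equals the naive evaluator on random delimitations", {
  set.seed(43)
  for (rep in 1:8) {
    tr <- ape::rtree(sample(8:12, 1), br = function(k) runif(k, 0.001, 0.3))
    st <- barcodelim:::tree_struct(tr)
    used <- st$edge_len_by_child >= 1e-4; used[is.na(used)] <- FALSE
    sub_n <- integer(st$n_nodes); sub_s <- numeric(st$n_nodes)
    for (v in rev(st$preorder)) for (c in st$children[[v]]) {
      sub_n[v] <- sub_n[v] + sub_n[c] + as.integer(used[c])
      sub_s[v] <- sub_s[v] + sub_s[c] + if (used[c]) st$edge_len_by_child[c] else 0
    }
    delims <- enum_delims(st)
    pick <- delims[sample(length(delims), min(10, length(delims)))]
    for (mode in c("single", "multi")) {
      for (r in pick) {
        expect_equal(barcodelim:::ptp_loglik(r, sub_n, sub_s,
                                             sub_n[st$root], sub_s[st$root], mode),
                     naive_ptp_ll(tr, r, mode), tolerance = 1e-9)
      }
      # the search never falls below both trivial delimitations
      fit <- ptp_fit(tr, mode = mode, seed = rep)
      expect_gte(fit$model$log_likelihood,
                 max(naive_ptp_ll(tr, st$root, mode),
                     naive_ptp_ll(tr, which(st$is_tip), mode)) - 1e-9)
    }
  }
})

test_that("ptp rejects degenerate trees", {
  tiny <- ape::read.tree(text = "(a:1);")
  expect_error(ptp_fit(tiny), "2 tips")
  flat <- ape::read.tree(text = "((a:1e-6,b:1e-6):1e-6,c:1e-6);")
  expect_error(ptp_fit(flat), "min_br")
})

test_that("gmyc recovers clusters when stems dwarf coalescent depths", {
  # deterministic fixture: five 8-tip coalescent clusters normalised to
  # depth 0.002, hanging from stems 25x deeper
  set.seed(77)
  clades <- vapply(1:5, function(i) {
    g <- ape::rcoal(8, tip.label = sprintf("sp%02d_%02d", i, 1:8))
    g$edge.length <- g$edge.length * 0.002 / max(ape::node.depth.edgelength(g))
    sub(";$", "", ape::write.tree(g))
  }, "")
  nest <- sprintf("(%s:%0.4f,%s:%0.4f)", clades[1], 0.05 - 0.002,
                  clades[2], 0.05 - 0.002)
  for (i in 3:5) {
    h <- 0.05 + 0.01 * (i - 2)
    nest <- sprintf("(%s:%0.4f,%s:%0.4f)", nest, 0.01,
                    clades[i], h - 0.002)
  }
  tr <- ape::read.tree(text = paste0(nest, ";"))
  expect_true(tree_is_ultrametric(tr, tol = 1e-6))
  fit <- gmyc_fit(tr, tol = 1e-6)
  expect_equal(fit$model$n_clusters, 5L)
  expect_lt(fit$model$p_value, 0.05)
  expect_equal(fit$partition$n_otus, 5L)
  # partition agrees with the constructed species labels
  truth <- sub("_[0-9]+$", "", names(fit$partition$assignment))
  expect_true(all(outer(truth, truth, "==") ==
                  outer(fit$partition$assignment, fit$partition$assignment, "==")))
})

test_that("gmyc threshold boundaries give one cluster and n_tips clusters", {
  set.seed(44)
  cfg <- sim_config(n_species = 3, samples_per_species = 5, seed = 44)
  tr <- simulate_trees(cfg)$gene_tree
  st <- barcodelim:::tree_struct(tr)
  h <- node_heights(tr); h[st$is_tip] <- 0
  # T older than the root: nothing diversifies, one cluster
  null <- barcodelim:::gmyc_eval(st, h, !st$is_tip & h >= max(h) * 2)
  expect_length(null$cluster_roots, 1L)
  # T at zero: every internal node diversifies, every tip its own cluster
  full <- barcodelim:::gmyc_eval(st, h, !st$is_tip)
  expect_length(full$cluster_roots, ape::Ntip(tr))
  # the fitted optimum always sits at or above the null
  fit <- gmyc_fit(tr)
  expect_gte(fit$model$lr_stat, 0)
  expect_gte(fit$model$log_likelihood, fit$model$logL_null - 1e-9)
})

test_that("gmyc cluster count is non-increasing in the threshold", {
  cfg <- sim_config(n_species = 4, samples_per_species = 6, seed = 45)
  tr <- simulate_trees(cfg)$gene_tree
  st <- barcodelim:::tree_struct(tr)
  h <- node_heights(tr); h[st$is_tip] <- 0
  Ts <- sort(unique(h[!st$is_tip]))
  counts <- sapply(Ts, function(T) {
    length(barcodelim:::gmyc_eval(st, h, !st$is_tip & h >= T)$cluster_roots)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("gmyc requires an ultrametric tree with at least 3 tips", {
  expect_error(gmyc_fit(ape::read.tree(text = "((a:1,b:2):1,c:1);")), "ultrametric")
  expect_error(gmyc_fit(ape::read.tree(text = "(a:1,b:1);")), "3 tips")
})

test_that("mgmyc refines on AIC and never lowers the likelihood", {
  cfg <- sim_config(n_species = 5, samples_per_species = 8, seed = 78,
                    coal_depth_mean = 0.002, min_split = 0.05)
  tr <- simulate_trees(cfg)$gene_tree
  single <- gmyc_fit(tr, mode = "single")
  multi <- gmyc_fit(tr, mode = "multi")
  expect_gte(multi$model$log_likelihood, single$model$log_likelihood - 1e-9)
  expect_gte(multi$model$n_clusters, single$model$n_clusters)
})

test_that("likelihood-ratio test matches the chi-square oracle", {
  eq <- lr_test(-10, -10)
  expect_equal(eq$lr_stat, 0)
  expect_equal(eq$p_value, 1)
  expect_equal(lr_test(0, 5.991 / 2, df = 2)$p_value, 0.05, tolerance = 1e-3)
  expect_equal(lr_test(0, 0.0005, df = 2)$p_value, 0.9995, tolerance = 1e-4)
  expect_error(lr_test(0, 1, df = 0), "df")
  expect_error(lr_test(0, -1), "below null")
})
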