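test_that("nj solves the 3-taxon case in closed form", {
  d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3,
              dimnames = list(c("A","B","C"), c("A","B","C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["A"]], 0.05)
  expect_equal(bl[["B"]], 0.15)
  expect_equal(bl[["C"]], 0.25)
})

test_that("nj recovers additive matrices exactly (consistency)", {
  skip_if_not_installed("phangorn")
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(6:10, 1)
    true <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.5))
    d <- ape::cophenetic.phylo(true)
    est <- nj_tree(d)
    expect_equal(phangorn::RF.dist(ape::unroot(true), est), 0)
    expect_equal(ape::cophenetic.phylo(est)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
  }
})

test_that("nj agrees with ape::nj on noisy matrices and rejects NA", {
  skip_if_not_installed("phangorn")
  set.seed(22)
  bm <- make_benchmark(seed = 3)
  sub <- make_library(bm$library$sequences[seq(1, 100, by = 5)])
  d <- pairwise_matrix(sub)
  expect_equal(phangorn::RF.dist(nj_tree(d), ape::nj(as.dist(d$d))), 0)
  dd <- d$d; dd[1, 2] <- dd[2, 1] <- NA
  expect_error(nj_tree(dd), "NA distance")
})

test_that("upgma produces ultrametric trees with hand-checkable heights", {
  d2 <- matrix(c(0, .02, .02, 0), 2, 2, dimnames = list(c("A","B"), c("A","B")))
  t2 <- upgma_tree(d2)
  expect_equal(max(node_heights(t2)), 0.01)
  d3 <- matrix(c(0, .02, .10, .02, 0, .10, .10, .10, 0), 3, 3,
               dimnames = list(c("A","B","C"), c("A","B","C")))
  t3 <- upgma_tree(d3)
  h <- sort(unique(round(node_heights(t3)[4:5], 12)))
  expect_equal(h, c(0.01, 0.05))
  expect_true(tree_is_ultrametric(t3, tol = 1e-9))
})

test_that("upgma is ultrametric with monotone heights on random matrices", {
  set.seed(23)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.01, 0.3)
    d <- d + t(d)
    dimnames(d) <- list(sprintf("t%d", 1:n), sprintf("t%d", 1:n))
    tr <- upgma_tree(d)
    expect_true(tree_is_ultrametric(tr, tol = 1e-9))
    h <- node_heights(tr)
    # every child sits strictly below (or at) its parent
    expect_true(all(h[tr$edge[, 1]] >= h[tr$edge[, 2]] - 1e-12))
  }
})

test_that("outgroup rooting places the root mid-stem and checks monophyly", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,O:5);")
  rooted <- root_with_outgroup(ape::unroot(tr), "O")
  root <- ape::Ntip(rooted) + 1L
  kids <- which(rooted$edge[, 1] == root)
  expect_equal(rooted$edge.length[kids][1], rooted$edge.length[kids][2])
  og <- ape::extract.clade(rooted, rooted$edge[kids[1], 2])$tip.label
  split_sets <- list(sort(og), sort(setdiff(rooted$tip.label, og)))
  expect_true(list(sort(c("O"))) %in% split_sets ||
              identical(split_sets[[1]], "O") || identical(split_sets[[2]], "O"))
  expect_error(root_with_outgroup(tr, "Z"), "absent")
  # two-tip outgroup clade roots on its stem
  tr2 <- ape::unroot(ape::read.tree(text = "(((A:1,B:1):1,C:2):2,(O1:1,O2:1):3);"))
  rooted2 <- root_with_outgroup(tr2, c("O1", "O2"))
  root2 <- ape::Ntip(rooted2) + 1L
  kid_tips <- lapply(which(rooted2$edge[, 1] == root2), function(e) {
    node <- rooted2$edge[e, 2]
    if (node <= ape::Ntip(rooted2)) rooted2$tip.label[node]
    else ape::extract.clade(rooted2, node)$tip.label
  })
  expect_true(any(vapply(kid_tips, function(x) setequal(x, c("O1", "O2")), TRUE)))
  # rooting preserves the unrooted bipartitions
  skip_if_not_installed("phangorn")
  expect_equal(phangorn::RF.dist(ape::unroot(rooted2), tr2), 0)
  # non-monophyletic outgroup names the intruders
  tr3 <- ape::unroot(ape::read.tree(text = "(((A:1,O1:1):1,C:2):2,O2:3);"))
  expect_error(root_with_outgroup(tr3, c("O1", "O2")), "A|C")
})

test_that("strict-clock scaling converts heights to time and back", {
  d <- matrix(c(0, .024, .024, 0), 2, 2, dimnames = list(c("A","B"), c("A","B")))
  tr <- upgma_tree(d)                      # height 0.012 substitutions/site
  my <- scale_to_time(tr, rate = 0.012)    # 1.2%/My clock
  expect_equal(max(node_heights(my)), 1.0)
  expect_identical(scale_to_time(tr, rate = 1)$edge.length, tr$edge.length)
  back <- scale_to_time(my, rate = 1 / 0.012)
  expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-12)
  nonult <- ape::read.tree(text = "((A:1,B:2):1,C:1);")
  expect_error(scale_to_time(nonult, 0.012), "ultrametric")
})
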