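test_that("TF selection intersects HVGs with the TF list in table order", {
  hvg <- data.frame(
    gene = c("Sox17", "Actb", "Runx1"),
    selected = c(TRUE, TRUE, TRUE)
  )
  expect_equal(select_tfs(hvg, c("Sox17", "Runx1", "Gata2")), c("Sox17", "Runx1"))
  expect_warning(out <- select_tfs(hvg, "Hoxa9"), "no selected HVG")
  expect_equal(out, character(0))
  expect_error(select_tfs(hvg, character(0)), "empty")

  set.seed(6)
  for (i in 1:10) {
    hvg2 <- data.frame(
      gene = sprintf("g%02d", 1:30),
      selected = runif(30) < 0.5
    )
    tfs <- sample(hvg2$gene, 10)
    out2 <- suppressWarnings(select_tfs(hvg2, tfs))
    expect_true(all(out2 %in% hvg2$gene[hvg2$selected]))
  }
})

test_that("the Pearson distance maps r = 1, 0.5, -1 to 0, 0.5, 1", {
  # three cells whose TF vectors realize the correlations exactly
  v <- rbind(
    t1 = c(1, 2, 3),
    t2 = c(2, 4, 6), # r(t1, t2) = 1
    t3 = c(3, 2, 1), # r(t1, t3) = -1
    t4 = c(1, 3, 2) # r(t1, t4) = 0.5
  )
  m <- make_em(v, genes = rownames(v), layer = "lognorm")
  d <- tf_distance_matrix(m, rownames(v))
  expect_equal(d["t1", "t2"], 0)
  expect_equal(d["t1", "t3"], 1)
  expect_equal(d["t1", "t4"], 0.5)
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("constant TFs get r = 0 with a warning, absent TFs an error", {
  v <- rbind(t1 = c(1, 2, 3), t2 = c(5, 5, 5))
  m <- make_em(v, genes = rownames(v), layer = "lognorm")
  expect_warning(d <- tf_distance_matrix(m, c("t1", "t2")), "constant")
  expect_equal(d["t1", "t2"], sqrt(0.5))
  expect_error(tf_distance_matrix(m, c("t1", "Gata2")), "Gata2")
})

test_that("UPGMA reproduces hand examples", {
  d2 <- matrix(c(0, 0.8, 0.8, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- upgma_cluster(d2)
  expect_equal(tr2$height, 0.8)
  expect_equal(tr2$merge, matrix(c(-1L, -2L), 1))

  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
  )
  tr3 <- upgma_cluster(d3)
  expect_equal(tr3$height, c(2, 4)) # (A,B) at 2, then C at avg(4, 4) = 4
  expect_equal(tr3$merge[1, ], c(-1L, -2L))
  expect_error(upgma_cluster(matrix(c(0, NA, NA, 0), 2, 2)), "NaN")
})

test_that("UPGMA matches an independent average-linkage reference on random inputs", {
  for (i in 1:100) {
    set.seed(i)
    n <- sample(3:8, 1)
    d <- as.matrix(stats::dist(matrix(runif(n * 3), n)))
    dimnames(d) <- list(paste0("x", 1:n), paste0("x", 1:n))
    tr <- upgma_cluster(d)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(sort(tr$height), sort(hc$height), tolerance = 1e-12)
    # ultrametric monotonicity
    expect_true(all(diff(tr$height) >= -1e-12))
  }
})

test_that("the Pearson distance satisfies the triangle inequality on random triples", {
  set.seed(15)
  for (i in 1:30) {
    v <- matrix(rnorm(3 * 50), nrow = 3)
    rownames(v) <- c("x", "y", "z")
    m <- make_em(v, genes = rownames(v), layer = "lognorm")
    d <- tf_distance_matrix(m, rownames(v))
    expect_lte(d["x", "z"], d["x", "y"] + d["y", "z"] + 1e-12)
  }
})

test_that("tree cutting recovers planted branches and handles degenerate cuts", {
  # two clean 5-leaf branches: within distance 0.1, between 0.9
  labs <- c(paste0("a", 1:5), paste0("b", 1:5))
  d <- matrix(0.9, 10, 10, dimnames = list(labs, labs))
  d[1:5, 1:5] <- 0.1
  d[6:10, 6:10] <- 0.1
  diag(d) <- 0
  tr <- upgma_cluster(d)
  cut <- cut_tree_min_size(tr, height = 0.5, min_size = 2)
  expect_equal(cut$n_modules, 2L)
  planted <- rep(1:2, each = 5)
  expect_equal(adjusted_rand_index(cut$assignment[labs], planted), 1)

  # the auto scan finds the same two modules
  auto <- cut_tree_min_size(tr, height = "auto", min_size = 2)
  expect_equal(auto$n_modules, 2L)
  expect_equal(adjusted_rand_index(auto$assignment[labs], planted), 1)

  # cut above the top merge: one module containing everything
  all_in <- cut_tree_min_size(tr, height = max(tr$height), min_size = 2)
  expect_equal(all_in$n_modules, 1L)
  expect_true(all(all_in$assignment == 1L))

  # a singleton branch stays unassigned under min_size 2
  labs3 <- c("a1", "a2", "lone")
  d3 <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3, 3,
    dimnames = list(labs3, labs3)
  )
  tr3 <- upgma_cluster(d3)
  cut3 <- cut_tree_min_size(tr3, height = 0.5, min_size = 2)
  expect_equal(unname(cut3$assignment[c("a1", "a2", "lone")]), c(1L, 1L, 0L))

  expect_warning(none <- cut_tree_min_size(tr3, min_size = 5), "exceeds leaf count")
  expect_true(all(none$assignment == 0L))
  expect_error(cut_tree_min_size(tr3, height = 2, min_size = 1), "outside")
})

test_that("module ids are ordered by decreasing module size", {
  labs <- c(paste0("big", 1:6), paste0("small", 1:3), "stray")
  d <- matrix(0.9, 10, 10, dimnames = list(labs, labs))
  d[1:6, 1:6] <- 0.1
  d[7:9, 7:9] <- 0.1
  diag(d) <- 0
  cut <- cut_tree_min_size(upgma_cluster(d), height = 0.5, min_size = 3)
  expect_equal(unname(cut$assignment[paste0("big", 1)]), 1L)
  expect_equal(unname(cut$assignment[paste0("small", 1)]), 2L)
  expect_equal(unname(cut$assignment["stray"]), 0L)
})

test_that("as_hclust produces a plottable tree with matching heights", {
  set.seed(2)
  d <- as.matrix(stats::dist(matrix(runif(15), 5)))
  dimnames(d) <- list(paste0("t", 1:5), paste0("t", 1:5))
  hc <- as_hclust(upgma_cluster(d))
  expect_s3_class(hc, "hclust")
  expect_equal(sort(hc$height), sort(stats::hclust(stats::as.dist(d), "average")$height))
  expect_setequal(hc$order, 1:5)
})
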