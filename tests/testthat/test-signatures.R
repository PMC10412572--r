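test_that("module scores vanish on constant data and are shift-invariant", {
  m <- make_em(matrix(2.5, 50, 10), layer = "lognorm")
  sc <- module_score(m, genes(m)[1:5], seed = 1)
  expect_equal(as.numeric(sc), rep(0, 10))

  m1 <- random_counts_em(200, 15, seed = 18, layer = "lognorm")
  m2 <- make_em(m1$values + 3.7, layer = "lognorm")
  s1 <- module_score(m1, genes(m1)[11:30], seed = 5)
  s2 <- module_score(m2, genes(m2)[11:30], seed = 5)
  expect_equal(as.numeric(s2), as.numeric(s1), tolerance = 1e-12)

  expect_error(module_score(m1, genes(m1)[1:3]), "seed")
  expect_error(module_score(m1, character(0), seed = 1), "empty")
  expect_error(module_score(m1, "nope", seed = 1), "absent")
  expect_error(module_score(random_counts_em(10, 5, 1), genes(m1)[1], seed = 1), "lognorm")
})

test_that("module scores are reproducible under the same seed only", {
  m <- random_counts_em(300, 20, seed = 25, layer = "lognorm")
  gs <- genes(m)[51:70]
  expect_identical(module_score(m, gs, seed = 7), module_score(m, gs, seed = 7))
  # the seeded draw must not disturb the global RNG stream
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(module_score(m, gs, seed = 7))
  expect_identical(runif(1), before)
})

test_that("pseudotime trends smooth, preserve monotonicity, and ignore cell order", {
  pt <- seq(0, 1, length.out = 50)
  const <- trend_along_pseudotime(rep(2, 50), pt)
  expect_equal(const$fitted, rep(2, 50))

  lin <- trend_along_pseudotime(pt, pt)
  mid <- 11:40 # away from window edges
  expect_equal(lin$fitted[mid], pt[mid], tolerance = 0.02)
  expect_true(all(diff(lin$fitted) >= -1e-12)) # monotone in, monotone out

  set.seed(3)
  vals <- cumsum(rnorm(50))
  perm <- sample(50)
  t1 <- trend_along_pseudotime(vals, pt)
  t2 <- trend_along_pseudotime(vals[perm], pt[perm])
  expect_equal(t2, t1)

  expect_error(trend_along_pseudotime(1:4, 1:4), "at least 5")
  expect_error(trend_along_pseudotime(1:5, c(1:4, NA)), "finite")
})

test_that("wilcoxon_de reproduces the exact rank-sum example and degenerate cases", {
  v <- rbind(
    gde = c(1, 2, 3, 4, 5, 6),
    gnull = c(2, 2, 2, 2, 2, 2)
  )
  m <- make_em(v, genes = rownames(v), layer = "lognorm")
  out <- wilcoxon_de(m, cells(m)[1:3], cells(m)[4:6])
  expect_equal(out$p[out$gene == "gde"], 0.1) # 2 of C(6,3)=20 assignments as extreme
  expect_equal(out$p[out$gene == "gnull"], 1)
  expect_equal(out$log_fc[out$gene == "gnull"], 0)
  expect_true(all(out$p_adj >= out$p))
  expect_identical(out$significant, out$p_adj < 1e-4)

  expect_error(wilcoxon_de(m, cells(m)[1:3], cells(m)[3:6]), "overlap")
  expect_error(wilcoxon_de(m, cells(m)[1:2], cells(m)[3:6]), "at least 3")
})

test_that("exact p values agree with wilcox.test and full enumeration on seeded cases", {
  enum_p <- function(xa, xb) {
    pooled <- c(xa, xb)
    na <- length(xa)
    r <- rank(pooled)
    w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    combos <- utils::combn(length(pooled), na)
    ws <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]) - na * (na + 1) / 2)
    min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
  }
  set.seed(55)
  for (i in 1:40) {
    na <- sample(3:7, 1)
    nb <- sample(3:7, 1)
    xa <- sample(seq_len(50), na) # distinct integers: no ties
    xb <- sample(setdiff(seq_len(50), xa), nb)
    v <- matrix(c(xa, xb), 1, dimnames = list("g", sprintf("c%02d", seq_len(na + nb))))
    m <- expression_matrix(v, "s", "lognorm")
    p_pkg <- wilcoxon_de(m, colnames(v)[1:na], colnames(v)[(na + 1):(na + nb)])$p
    expect_equal(p_pkg, enum_p(xa, xb), tolerance = 1e-12)
    expect_equal(p_pkg, stats::wilcox.test(xa, xb, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("large or tied groups use the corrected normal approximation", {
  set.seed(61)
  xa <- rpois(40, 4)
  xb <- rpois(35, 6)
  v <- matrix(c(xa, xb) + 0, 1, dimnames = list("g", sprintf("c%02d", 1:75)))
  m <- expression_matrix(v, "s", "lognorm")
  p_pkg <- wilcoxon_de(m, colnames(v)[1:40], colnames(v)[41:75])$p
  oracle <- stats::wilcox.test(xa, xb, exact = FALSE, correct = TRUE)$p.value
  expect_equal(p_pkg, oracle, tolerance = 1e-12)
})

test_that("BH adjustment in the DEG table equals the step-up definition", {
  bh_stepup <- function(p) {
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
  }
  m <- random_counts_em(100, 20, seed = 30, layer = "lognorm")
  out <- wilcoxon_de(m, cells(m)[1:10], cells(m)[11:20])
  expect_equal(out$p_adj, bh_stepup(out$p), tolerance = 1e-12)
  # adjusted p values are valid and monotone in sorted-p order
  expect_true(all(out$p_adj >= out$p & out$p_adj <= 1))
  expect_true(all(diff(out$p_adj[order(out$p)]) >= -1e-12))
})

test_that("marker signatures take the top-k upregulated by fold change with tie rules", {
  set.seed(44)
  deg <- data.frame(
    gene = sprintf("g%02d", 1:30),
    log_fc = c(seq(2.5, 0.1, length.out = 25), -1, -2, 0.5, 0.4, 0.3),
    p = 1e-9, p_adj = 1e-8,
    significant = c(rep(TRUE, 25), TRUE, TRUE, FALSE, FALSE, FALSE),
    direction = c(rep("up", 25), "down", "down", "up", "up", "up")
  )
  sig <- marker_signature(deg, k = 20)
  expect_length(sig, 20)
  expect_equal(sig, deg$gene[order(-deg$log_fc)][seq_len(20)])

  expect_warning(short <- marker_signature(deg[1:5, ], k = 20), "only 5")
  expect_length(short, 5)

  tie <- data.frame(
    gene = c("b", "a", "c"), log_fc = c(1, 1, 1),
    p = 1, p_adj = c(0.5e-5, 0.5e-5, 0.1e-5),
    significant = TRUE, direction = "up"
  )
  expect_equal(marker_signature(tie, k = 3), c("c", "a", "b"))
})

test_that("planted DE genes dominate the recovered marker signature", {
  for (s in 1:3) {
    sim <- generate_species_pair(synthetic_config(seed = s))
    ln <- log_normalize(sim$matrix_a)
    ann <- sim$annotation_a
    deg <- wilcoxon_de(
      ln,
      ann$cell_id[ann$label == "mT1"],
      ann$cell_id[ann$label != "mT1"]
    )
    sig <- suppressWarnings(marker_signature(deg, k = 20))
    # genes planted as upregulated in mT1: the DE genes plus the planted
    # variable genes whose high type is mT1
    planted_up <- c(
      sim$truth$de_genes$gene_a,
      sim$truth$planted_hvg$gene_a[sim$truth$planted_hvg$high_type_a == "mT1"]
    )
    expect_gte(sum(sig %in% planted_up), 18)
  }
})
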