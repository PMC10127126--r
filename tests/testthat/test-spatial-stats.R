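test_that("coverage filter applies the >= 30% boundary rule", {
  n <- 10
  cnt <- cbind(full = rep(1L, n),
               low = c(rep(1L, 2), rep(0L, 8)),        # 20%
               boundary = c(rep(1L, 3), rep(0L, 7)))   # exactly 30%
  expect_setequal(coverage_filter(cnt, 0.30), c("full", "boundary"))
  # 29 of 100 spots covered at threshold 0.30: removed
  cnt2 <- cbind(g = c(rep(1L, 29), rep(0L, 71)))
  expect_length(coverage_filter(cnt2, 0.30), 0)
  expect_error(coverage_filter(cnt, 0), "min_fraction")
})

test_that("Anscombe transform matches its closed form and is monotone", {
  expect_equal(anscombe(0), 2 * sqrt(3 / 8))
  expect_equal(anscombe(0), 1.224745, tolerance = 1e-6)
  expect_equal(anscombe(1), 2 * sqrt(11 / 8))
  expect_equal(anscombe(1), 2.345208, tolerance = 1e-6)
  x <- sort(runif(50, 0, 20))
  expect_true(all(diff(anscombe(x)) > 0))
  expect_error(anscombe(-1), "non-negative")
})

test_that("median pooling partitions by halved array indices", {
  g <- make_hex_grid(5, 6, pitch_px = 64, spot_diameter_px = 36)
  v <- seq_len(nrow(g))
  mp <- median_pool(g, v)
  expect_equal(nrow(mp$coords), ceiling(5 / 2) * ceiling(6 / 2))
  # block {1,2,3,4} pools to 2.5
  blk <- which(g$array_row < 2 & g$array_col < 2)
  vv <- rep(0, nrow(g)); vv[blk] <- c(1, 2, 3, 4)
  mp2 <- median_pool(g, vv)
  b1 <- unique(mp$block[blk])
  expect_equal(mp2$values[match(b1, unique(mp$block))], 2.5)
  # constant field stays constant
  expect_true(all(median_pool(g, rep(7, nrow(g)))$values == 7))
})

test_that("Moran's I equals the textbook double sum on small instances", {
  set.seed(12)
  for (rep in 1:5) {
    g <- make_hex_grid(5, 5, pitch_px = 64, spot_diameter_px = 36)
    W <- spotsight:::sv_weights(cbind(g$px_x, g$px_y))
    v <- rnorm(25)
    expect_equal(morans_i(v, W), oracle_morans_i(v, as.matrix(W)),
                 tolerance = 1e-10)
  }
  # two-colouring of a path graph (row-normalised weights): I = -1
  coords <- cbind(seq(0, 11) * 50, rep(0, 12))
  W <- spotsight:::sv_weights(coords)
  v <- rep(c(1, -1), 6)
  expect_equal(morans_i(v, W), -1, tolerance = 1e-12)
  expect_equal(oracle_morans_i(v, as.matrix(W)), -1, tolerance = 1e-12)
})

test_that("the permutation SV test detects gradients and respects nulls", {
  g <- make_hex_grid(10, 10, pitch_px = 64, spot_diameter_px = 36)
  coords <- cbind(g$px_x, g$px_y)
  # smooth gradient: the observed I beats all permutations
  v <- g$px_x + g$px_y
  r <- sv_test(v, coords, n_perm = 999, seed = 5)
  expect_equal(r$p_value, 1 / 1000)
  expect_gt(r$statistic, 0.9)
  # constant input: degenerate, p = 1
  rc <- sv_test(rep(1, 100), coords, n_perm = 99, seed = 1)
  expect_true(rc$degenerate)
  expect_equal(rc$p_value, 1)
  expect_error(sv_test(rnorm(5), coords[1:5, ]), "at least 10")
  # permutation p-values never fall below 1/(n_perm + 1)
  set.seed(2)
  ps <- replicate(20, sv_test(rnorm(100), coords, n_perm = 19,
                              seed = sample(1e6, 1))$p_value)
  expect_true(all(ps >= 1 / 20))
})

test_that("smoothing FSV separates smooth fields from noise", {
  g <- make_hex_grid(16, 16, pitch_px = 64, spot_diameter_px = 36)
  coords <- cbind(g$px_x, g$px_y)
  smooth <- sin(g$px_x / 500) + cos(g$px_y / 500)
  expect_gt(estimate_fsv(smooth, coords, 64), 0.9)
  set.seed(3)
  noise <- rnorm(nrow(g))
  expect_lt(estimate_fsv(noise, coords, 64), 0.2)
  # affine invariance
  expect_equal(estimate_fsv(5 * smooth - 2, coords, 64),
               estimate_fsv(smooth, coords, 64))
  # zero variance: 0 with degenerate attribute
  f0 <- estimate_fsv(rep(1, nrow(g)), coords, 64)
  expect_equal(as.numeric(f0), 0)
  expect_true(attr(f0, "degenerate"))
})

test_that("co-expression grouping recovers planted pattern families", {
  g <- make_hex_grid(10, 10, pitch_px = 64, spot_diameter_px = 36)
  coords <- cbind(g$px_x, g$px_y)
  set.seed(4)
  pat1 <- sin(g$px_x / 200); pat2 <- cos(g$px_y / 150)
  expr <- cbind(
    sapply(1:6, function(i) pat1 + rnorm(100, sd = 0.1)),
    sapply(1:6, function(i) pat2 + rnorm(100, sd = 0.1)))
  colnames(expr) <- sprintf("g%02d", 1:12)
  grp <- coexpression_groups(expr, coords, k = 2, seed = 6)
  truth <- rep(1:2, each = 6)
  expect_equal(adjusted_rand(grp, truth), 1)
  # determinism and the k = 1 degenerate case
  expect_identical(grp, coexpression_groups(expr, coords, k = 2, seed = 6))
  expect_true(all(coexpression_groups(expr, coords, k = 1, seed = 1) == 1))
  expect_error(coexpression_groups(expr[, 1:3], coords, k = 5), "fewer genes")
})

test_that("sv_test_genes runs filter, transform, pool, test in order", {
  b <- small_bundle()
  res <- sv_test_genes(b$counts, b$grid, n_perm = 99, seed = 8)
  keep <- coverage_filter(b$counts)
  expect_setequal(res$gene, keep)
  expect_true(all(res$p_value >= 1 / 100))
  # pooling reduces the lattice but keeps one row per gene
  resp <- sv_test_genes(b$counts, b$grid, n_perm = 49, seed = 8, pool = TRUE)
  expect_equal(nrow(resp), length(keep))
})
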