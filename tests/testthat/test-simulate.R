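test_that("zero inflation and spatial flags behave as specified", {
  g <- make_hex_grid(10, 10, pitch_px = 64, spot_diameter_px = 36)
  # pi = 1 forces all-zero counts
  des <- make_gene_design(n_genes = 4, sv_fraction = 0.5, seed = 1)
  des$pi[1] <- 1
  lat <- simulate_expression(g, seed = 5, design = des)
  expect_true(all(lat$counts[, 1] == 0))
  # non-SV genes have constant mean fields
  for (j in which(!des$sv_flag))
    expect_equal(sd(lat$mu[, j]), 0)
  # sv_fraction = 0: every mean field constant
  lat0 <- simulate_expression(g, n_genes = 6, sv_fraction = 0, seed = 2)
  expect_true(all(apply(lat0$mu, 2, sd) == 0))
})

test_that("empirical ZINB moments match the generative model", {
  # flat mean fields at > 5000 spots: large-sample check of the ZINB mean
  # (1 - pi) * mu and of the zero mass added by inflation
  g <- make_hex_grid(72, 72, pitch_px = 64, spot_diameter_px = 36)
  des <- make_gene_design(n_genes = 6, sv_fraction = 0, seed = 3)
  lat <- simulate_expression(g, seed = 8, design = des)
  n <- nrow(lat$counts)
  for (j in seq_len(6)) {
    mu <- lat$mu[, j]; pi <- des$pi[j]; sig <- des$sigma[j]
    expect_mean <- (1 - pi) * mean(mu)
    # Monte-Carlo se of the mean of ZINB draws
    v <- mean((1 - pi) * (mu + mu^2 / sig) + pi * (1 - pi) * mu^2)
    se <- sqrt(v / n)
    expect_lt(abs(mean(lat$counts[, j]) - expect_mean), 3 * se)
    # zero inflation only adds zeros on top of NB zeros
    expect_gte(mean(lat$counts[, j] == 0), pi - 3 * sqrt(pi * (1 - pi) / n))
  }
})

test_that("simulation is deterministic under a fixed seed", {
  g <- make_hex_grid(6, 6, pitch_px = 64, spot_diameter_px = 36)
  a <- simulate_expression(g, n_genes = 8, seed = 11)
  b <- simulate_expression(g, n_genes = 8, seed = 11)
  expect_identical(a$counts, b$counts)
  expect_identical(a$factors, b$factors)
})

test_that("group-differential genes are flat on non-met slides", {
  g <- make_hex_grid(8, 8, pitch_px = 64, spot_diameter_px = 36)
  des <- make_gene_design(n_genes = 20, seed = 4)
  gd <- which(des$group_differential_flag)
  expect_gt(length(gd), 0)
  met <- simulate_expression(g, group = "met", seed = 6, design = des)
  non <- simulate_expression(g, group = "nonmet", seed = 6, design = des)
  for (j in gd) {
    expect_gt(sd(met$mu[, j]), 0)
    expect_equal(sd(non$mu[, j]), 0)
  }
})

test_that("rendered image encodes local factors in channel means", {
  b <- small_bundle()
  pat <- extract_patches(b, 64)
  D <- 64 * 64
  f <- b$latents$factors
  r_mean <- rowMeans(pat$x[, seq_len(D)])
  g_mean <- rowMeans(pat$x[, D + seq_len(D)])
  expect_gt(cor(r_mean, f[, "f1"]), 0.9)
  expect_gt(cor(g_mean, f[, "f2"]), 0.9)
})

test_that("without image-encoded genes the discs carry no factor signal", {
  g <- make_hex_grid(8, 8, pitch_px = 64, spot_diameter_px = 36)
  lat <- simulate_expression(g, n_genes = 6, sv_fraction = 0, seed = 21)
  img <- render_slide(g, lat, seed = 22)
  b <- slide_bundle(g, img, lat$counts, lat, "met", "noise-slide")
  pat <- extract_patches(b, 64)
  r_mean <- rowMeans(pat$x[, seq_len(64 * 64)])
  ref <- local({ set.seed(33); rnorm(nrow(g)) })
  expect_lt(abs(cor(r_mean, ref)), 0.35)
})

test_that("SV genes are detectable and noise genes stay null at scale", {
  # 2000 spots: the permutation Moran test must reject (p < 0.01) for at
  # least 90% of the smooth-field SV genes, while noise-gene rejections at
  # alpha = 0.05 stay within the exact binomial 99% band
  g <- make_hex_grid(40, 50, pitch_px = 64, spot_diameter_px = 36)
  des <- make_gene_design(n_genes = 40, sv_fraction = 0.5,
                          contextual_fraction = 0,
                          group_differential_fraction = 0, seed = 9)
  lat <- simulate_expression(g, seed = 10, design = des)
  W <- spotsight:::sv_weights(cbind(g$px_x, g$px_y))
  p <- vapply(seq_len(40), function(j)
    sv_test(anscombe(lat$counts[, j]), n_perm = 199,
            seed = spotsight:::child_seed(11, j), W = W)$p_value, 0)
  sv <- des$sv_flag
  expect_gte(mean(p[sv] < 0.01), 0.9)
  band <- qbinom(c(0.005, 0.995), sum(!sv), 0.05)
  rej <- sum(p[!sv] <= 0.05)
  expect_true(rej >= band[1] && rej <= band[2])
})

test_that("rendering is byte-identical under a fixed seed", {
  g <- make_hex_grid(5, 5, pitch_px = 64, spot_diameter_px = 36)
  lat <- simulate_expression(g, n_genes = 5, seed = 1)
  expect_identical(render_slide(g, lat, seed = 9), render_slide(g, lat, seed = 9))
})
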