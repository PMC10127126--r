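# Contracts of the trainable models: learning signal, determinism, shapes,
# graph locality, and attention normalisation. Kept at miniature scale.

train_fixture <- local({
  env <- new.env()
  function() {
    if (is.null(env$fx)) {
      cohort <- mini_cohort()
      b <- cohort[[1]]
      patches <- extract_patches(b, 32)
      labels <- dichotomize(b$counts)
      env$fx <- list(b = b, patches = patches, labels = labels,
                     graph = build_spot_graph(b$grid))
    }
    env$fx
  }
})

test_that("local model training reduces the loss and is reproducible", {
  fx <- train_fixture()
  cfg <- list(epochs = 4, lr = 1e-3, seed = 7, channels = c(4L, 6L, 8L),
              embed_dim = 16L)
  m1 <- train_local_model(fx$patches, fx$labels, "binary", cfg)
  expect_lt(m1$losses[length(m1$losses)], m1$losses[1])
  m2 <- train_local_model(fx$patches, fx$labels, "binary", cfg)
  expect_identical(m1$losses, m2$losses)
  expect_identical(m1$net$params, m2$net$params)

  emb <- predict(m1, fx$patches, type = "embedding")
  expect_equal(dim(emb), c(nrow(fx$patches$x), 16L))
  pr <- predict(m1, fx$patches)
  expect_true(all(pr > 0 & pr < 1))
  # permuting input spots permutes outputs identically
  ord <- rev(seq_len(nrow(fx$patches$x)))
  shuf <- fx$patches; shuf$x <- shuf$x[ord, ]; shuf$spot_id <- shuf$spot_id[ord]
  expect_equal(unname(predict(m1, shuf)), unname(pr[ord, ]), tolerance = 1e-10)
})

test_that("zinb-objective training yields valid parameters and learns", {
  fx <- train_fixture()
  cfg <- list(epochs = 4, lr = 1e-3, seed = 3, channels = c(4L, 6L, 8L),
              embed_dim = 16L, augment = FALSE)
  m <- train_local_model(fx$patches, fx$b$counts, "zinb", cfg)
  expect_lt(m$losses[length(m$losses)], m$losses[1])
  pr <- predict(m, fx$patches)
  expect_s3_class(pr, "zinb_params")
  expect_true(all(pr$mu > 0) && all(pr$sigma > 0))
  expect_true(all(pr$pi >= 0 & pr$pi <= 1))
  expect_equal(dim(zinb_mean(pr)), dim(fx$b$counts))
  # objective/target mismatch
  expect_error(train_local_model(fx$patches, fx$labels, "zinb", cfg),
               "counts matrix")
  expect_error(train_local_model(fx$patches, fx$b$counts, "binary", cfg),
               "binary_targets")
})

test_that("GAT training learns, attention normalises, and is deterministic", {
  fx <- train_fixture()
  set.seed(1)
  emb <- matrix(rnorm(nrow(fx$b$grid) * 8), ncol = 8)
  cfg <- list(epochs = 60, lr = 1e-2, width = 16L, seed = 5)
  m1 <- train_gat(emb, fx$graph, fx$labels, "binary", n_layers = 1,
                  n_heads = 4, cfg = cfg)
  expect_lt(m1$losses[length(m1$losses)], m1$losses[1])
  m2 <- train_gat(emb, fx$graph, fx$labels, "binary", n_layers = 1,
                  n_heads = 4, cfg = cfg)
  expect_identical(m1$losses, m2$losses)
  at <- gat_attention(m1, emb, fx$graph)
  sums <- rowsum(at[[1]]$alpha, at[[1]]$tgt)
  expect_true(max(abs(sums - 1)) < 1e-5)
  pr <- predict(m1, list(embeddings = emb, graph = fx$graph))
  expect_true(all(pr > 0 & pr < 1))
  expect_error(train_gat(emb[-1, ], fx$graph, fx$labels, "binary"),
               "do not match")
})

test_that("a 0-layer GAT is a linear head independent of the graph", {
  fx <- train_fixture()
  set.seed(2)
  emb <- matrix(rnorm(nrow(fx$b$grid) * 6), ncol = 6)
  cfg <- list(epochs = 30, lr = 1e-2, seed = 9)
  m <- train_gat(emb, fx$graph, fx$labels, "binary", n_layers = 0, cfg = cfg)
  pr1 <- predict(m, list(embeddings = emb, graph = fx$graph))
  # a totally different graph over the same spots changes nothing
  g2 <- build_spot_graph(fx$b$grid, radius_px = 200)
  pr2 <- predict(m, list(embeddings = emb, graph = g2))
  expect_equal(pr1, pr2)
})

test_that("predictions are local: nodes beyond n_layers hops cannot matter", {
  # path graph: spots on a line
  g <- make_hex_grid(1, 12, pitch_px = 50, spot_diameter_px = 30)
  graph <- build_spot_graph(g, radius_px = 55)
  set.seed(3)
  emb <- matrix(rnorm(12 * 5), 12, 5)
  y <- structure(list(labels = matrix(rbinom(24, 1, 0.5), 12, 2),
                      medians = c(0, 0), degenerate = c(FALSE, FALSE)),
                 class = "binary_targets")
  for (L in c(1L, 2L)) {
    m <- train_gat(emb, graph, y, "binary", n_layers = L,
                   cfg = list(epochs = 10, lr = 1e-2, width = 8L, seed = 4))
    base <- predict(m, list(embeddings = emb, graph = graph))
    emb2 <- emb
    far <- 1L           # node 1 is > L hops from node 12
    emb2[far, ] <- emb2[far, ] + 10
    pert <- predict(m, list(embeddings = emb2, graph = graph))
    expect_equal(pert[12, ], base[12, ], tolerance = 1e-12)
    # but it must matter within the receptive field
    expect_gt(max(abs(pert[far + L, ] - base[far + L, ])), 0)
  }
})

test_that("conv and attention backprop match finite differences", {
  set.seed(6)
  # CNN with a linear probe loss (no kinks)
  p <- 16; G <- 2; B <- 3
  net <- cnn_init(p, G, c(2L, 3L, 4L), 5L)
  x <- matrix(runif(B * p * p * 3), B)
  R <- matrix(rnorm(B * G), B, G)
  fw <- cnn_forward(net, x, keep = TRUE)
  gr <- cnn_backward(net, fw, R)
  lossfun <- function(net) sum(cnn_forward(net, x)$logits * R)
  for (k in c("K1", "K2", "Wd", "Wh")) {
    pk <- net$params[[k]]
    for (i in sample(length(pk), 4)) {
      e <- 1e-6; n1 <- net; n2 <- net
      n1$params[[k]][i] <- pk[i] + e
      n2$params[[k]][i] <- pk[i] - e
      expect_equal((lossfun(n1) - lossfun(n2)) / (2 * e), gr[[k]][i],
                   tolerance = 1e-4)
    }
  }
  # GAT with the BCE loss
  g <- make_hex_grid(4, 4, pitch_px = 50, spot_diameter_px = 30)
  graph <- build_spot_graph(g)
  ed <- spotsight:::gat_edges(graph)
  X <- matrix(rnorm(16 * 6), 16, 6)
  y <- matrix(rbinom(32, 1, 0.5), 16, 2)
  gnet <- spotsight:::gat_init(6, 2, n_layers = 2, n_heads = 2, width = 8)
  fw <- spotsight:::gat_forward(gnet, X, ed, keep = TRUE)
  hd <- spotsight:::bce_head(fw$logits, y)
  gr <- spotsight:::gat_backward(gnet, fw, hd$dLogits, ed)
  lf <- function(net) {
    f <- spotsight:::gat_forward(net, X, ed)
    spotsight:::bce_head(f$logits, y)$loss
  }
  for (k in names(gnet$params)) {
    pk <- gnet$params[[k]]
    for (i in sample(length(pk), min(4, length(pk)))) {
      e <- 1e-6; n1 <- gnet; n2 <- gnet
      n1$params[[k]][i] <- pk[i] + e
      n2$params[[k]][i] <- pk[i] - e
      expect_equal((lf(n1) - lf(n2)) / (2 * e), gr[[k]][i], tolerance = 1e-4)
    }
  }
})
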