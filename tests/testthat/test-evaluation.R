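test_that("leave-one-slide-out splits cover every slide once", {
  sp <- make_cv_splits(c("A", "B", "C", "D"))
  expect_length(sp, 4)
  expect_setequal(vapply(sp, `[[`, "", "test_slide"), c("A", "B", "C", "D"))
  for (s in sp) {
    expect_length(s$train_slides, 3)
    expect_length(intersect(s$train_slides, s$test_slide), 0)
  }
  expect_length(make_cv_splits(c("A", "B")), 2)
  expect_error(make_cv_splits("A"), "at least 2")
  expect_error(make_cv_splits(c("A", "A")), "duplicate")
})

test_that("AUROC matches exhaustive pair counting", {
  expect_equal(auroc(c(0.9, 0.8, 0.4, 0.1), c(1, 0, 1, 0)), 0.75)
  # exhaustive small instances, with ties in scores
  set.seed(8)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    expect_equal(auroc(s, y), oracle_auroc(s, y))
  }
  # perfect ranking and constant predictions
  expect_equal(auroc(c(3, 2, 1), c(1, 1, 0)), 1)
  expect_equal(auroc(rep(1, 6), rbinom(6, 1, 0.5) * c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_true(is.na(auroc(runif(5), rep(1, 5))))
})

test_that("average precision is 1 for perfect ranking and handles ties", {
  expect_equal(average_precision(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # hand-computed: order .9(+), .7(-), .5(+): AP = 1/2*1 + 1/2*(2/3)
  expect_equal(average_precision(c(0.9, 0.7, 0.5), c(1, 0, 1)),
               0.5 * 1 + 0.5 * (2 / 3))
  # all scores tied: single block, precision = prevalence
  expect_equal(average_precision(rep(0.5, 8), c(1, 1, 0, 0, 1, 0, 0, 0)),
               3 / 8)
})

test_that("per-gene metrics flag degenerate genes instead of dropping them", {
  pred <- cbind(g1 = c(0.9, 0.1, 0.8, 0.2), g2 = c(0.5, 0.5, 0.5, 0.5))
  truth <- cbind(g1 = c(1, 0, 1, 0), g2 = c(1, 1, 1, 1))
  m <- per_gene_metrics(pred, truth, "binary")
  expect_equal(m$auroc[1], 1)
  expect_true(m$degenerate[2] && is.na(m$auroc[2]))
  counts <- cbind(g1 = c(9, 1, 8, 2), g2 = c(3, 3, 3, 3))
  mr <- per_gene_metrics(pred, counts, "regression")
  expect_equal(mr$spearman[1], 1)
  expect_true(mr$degenerate[2])
})

test_that("macro-median aggregation and gene bootstrap behave", {
  # one gene, one slide: estimate collapses to that value, CI to a point
  t1 <- data.frame(gene = "g1", model = "m", fold = "A", auroc = 0.8)
  a <- aggregate_metrics(t1, metrics = "auroc", n_boot = 200, seed = 1)
  expect_equal(a$estimate, 0.8)
  expect_equal(a$ci_lo, 0.8)
  expect_equal(a$ci_hi, 0.8)
  # fixed seed: identical CI endpoints
  set.seed(10)
  tb <- expand.grid(gene = sprintf("g%02d", 1:30), model = "m",
                    fold = c("A", "B"), stringsAsFactors = FALSE)
  tb$auroc <- runif(nrow(tb), 0.5, 1)
  a1 <- aggregate_metrics(tb, metrics = "auroc", n_boot = 500, seed = 3)
  a2 <- aggregate_metrics(tb, metrics = "auroc", n_boot = 500, seed = 3)
  expect_identical(a1, a2)
  # point estimate equals mean-over-folds of median-over-genes
  manual <- mean(tapply(tb$auroc, tb$fold, median))
  expect_equal(a1$estimate, manual)
  # CI contains the point estimate for a smooth metric distribution
  expect_true(a1$ci_lo <= a1$estimate && a1$estimate <= a1$ci_hi)
  expect_error(aggregate_metrics(tb[0, ]), "empty")
  expect_error(aggregate_metrics(tb, n_boot = 50), ">= 100")
})

test_that("pairwise comparison counts wins and ties", {
  tb <- data.frame(
    gene = rep(c("g1", "g2", "g3"), each = 2),
    model = rep(c("cnn", "gat"), 3),
    fold = "A",
    auroc = c(0.9, 0.7, 0.6, 0.8, 0.5, 0.5))
  cm <- compare_models(tb, "cnn", "gat")
  expect_equal(unname(cm$wins), c(1, 1, 1))
  expect_equal(sum(cm$wins), 3)
  # identical predictions: all differences zero
  tb$auroc <- rep(c(0.6, 0.6), 3)
  cm0 <- compare_models(tb, "cnn", "gat")
  expect_true(all(cm0$per_gene$diff == 0))
  expect_error(compare_models(tb, "cnn", "nope"), "not in table")
})

test_that("combined model selection dominates on the selection folds", {
  set.seed(11)
  tb <- expand.grid(gene = sprintf("g%02d", 1:12),
                    model = c("cnn", "gat"), fold = c("A", "B", "C"),
                    stringsAsFactors = FALSE)
  tb$auroc <- runif(nrow(tb), 0.4, 1)
  cmb <- combine_top_models(tb, holdout = FALSE)
  # pointwise max dominates every individual model's median
  med_comb <- median(tapply(cmb$combined$auroc, cmb$combined$gene, mean))
  for (m in c("cnn", "gat")) {
    tm <- tb[tb$model == m, ]
    expect_gte(med_comb, median(tapply(tm$auroc, tm$gene, mean)))
  }
  # single model: combined equals that model
  tb1 <- tb[tb$model == "cnn", ]
  cmb1 <- combine_top_models(tb1, holdout = FALSE)
  expect_equal(sort(cmb1$combined$auroc), sort(tb1$auroc))
  # ties broken by model priority: equal AUCs everywhere -> first in priority
  tb$auroc <- 0.7
  cmb2 <- combine_top_models(tb, priority = c("gat", "cnn"))
  expect_true(all(cmb2$assignment$model == "gat"))
})

test_that("training artifacts ignore the held-out slide entirely", {
  cohort <- mini_cohort()
  cfg <- list(epochs = 2, lr = 1e-3, seed = 13, channels = c(4L, 6L, 8L),
              embed_dim = 16L)
  cv1 <- run_loso_cv(cohort, patch_size_px = 32, models = "cnn",
                     cnn_cfg = cfg, seed = 21, keep_models = TRUE)
  # corrupt the first slide (the held-out slide of fold 1) completely
  cohort2 <- cohort
  set.seed(1)
  cohort2[[1]]$image[] <- runif(length(cohort2[[1]]$image))
  cohort2[[1]]$counts[] <- as.integer(rpois(length(cohort2[[1]]$counts), 3))
  cv2 <- run_loso_cv(cohort2, patch_size_px = 32, models = "cnn",
                     cnn_cfg = cfg, seed = 21, keep_models = TRUE)
  id1 <- names(cohort)[1]
  expect_identical(cv1$models[[id1]]$cnn$net$params,
                   cv2$models[[id1]]$cnn$net$params)
})
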