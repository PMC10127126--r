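## End-to-end orchestration: leave-one-slide-out cross-validation of the
## local patch model and the graph model, and the recapitulation analyses
## on the held-out predictions.

## block-diagonal union of per-slide spot graphs (node ids offset)
combine_graphs <- function(graphs) {
  ns <- vapply(graphs, `[[`, 0L, "n")
  offs <- cumsum(c(0L, ns[-length(ns)]))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(i)
    graphs[[i]]$edges + offs[i]))
  structure(
    list(spot_id = unlist(lapply(graphs, `[[`, "spot_id"), use.names = FALSE),
         edges = edges, radius_px = graphs[[1]]$radius_px, n = sum(ns)),
    class = "spot_graph"
  )
}

rbind_targets <- function(targets) {
  structure(
    list(labels = do.call(rbind, lapply(targets, `[[`, "labels")),
         medians = do.call(rbind, lapply(targets, `[[`, "medians")),
         degenerate = Reduce(`|`, lapply(targets, `[[`, "degenerate"))),
    class = "binary_targets"
  )
}

#' Leave-one-slide-out cross-validation of the patch and graph models
#'
#' For each fold, trains the local CNN on the training slides' patches
#' (labels dichotomized at each slide's own medians), extracts
#' penultimate-layer embeddings for every slide from that fold's CNN, trains
#' the graph attention model on the training slides' embeddings and spot
#' graphs, and predicts the held-out slide with both models. Per-gene
#' AUROC/AP (against the test slide's own median dichotomization) and
#' Spearman/Pearson (against raw counts) are recorded per model and fold.
#'
#' @param bundles named list of `slide_bundle`s with images.
#' @param patch_size_px patch side length.
#' @param models subset of `c("cnn", "gat")`.
#' @param gat_layers attention layers for the graph model.
#' @param cnn_cfg,gat_cfg training configuration overrides (see
#'   [train_local_model()], [train_gat()]).
#' @param seed base seed; per-fold training seeds are derived from it.
#' @param verbose print fold progress.
#' @return List: `metrics` (tidy data frame: gene, model, fold, auroc, ap,
#'   spearman, pearson, degenerate), `predictions` (per fold per model,
#'   held-out probability matrices), `splits`, `labels` (per-slide
#'   `binary_targets`).
#' @export
run_loso_cv <- function(bundles, patch_size_px = 64, models = c("cnn", "gat"),
                        gat_layers = 1L, cnn_cfg = list(), gat_cfg = list(),
                        seed = 1L, verbose = FALSE, keep_models = FALSE) {
  models <- match.arg(models, c("cnn", "gat"), several.ok = TRUE)
  ids <- names(bundles)
  patches <- lapply(bundles, extract_patches, patch_size_px = patch_size_px)
  labels <- lapply(bundles, function(b) dichotomize(b$counts))
  graphs <- lapply(bundles, function(b) build_spot_graph(b$grid))
  splits <- make_cv_splits(ids)
  metrics <- list(); predictions <- list(); kept <- list()

  for (sp in splits) {
    tr <- sp$train_slides; te <- sp$test_slide
    if (verbose) message("fold ", sp$fold_id, ": testing ", te)
    train_patches <- structure(
      list(x = do.call(rbind, lapply(patches[tr], `[[`, "x")),
           patch_size_px = patch_size_px,
           spot_id = unlist(lapply(patches[tr], `[[`, "spot_id"),
                            use.names = FALSE)),
      class = "patch_set")
    train_labels <- rbind_targets(labels[tr])
    cfg <- utils::modifyList(list(seed = child_seed(seed, sp$fold_id)), cnn_cfg)
    cnn <- train_local_model(train_patches, train_labels, "binary", cfg)
    predictions[[te]] <- list()
    if ("cnn" %in% models) {
      pr <- predict(cnn, patches[[te]])
      predictions[[te]]$cnn <- pr
      metrics[[length(metrics) + 1L]] <-
        fold_metric_rows(pr, bundles[[te]], labels[[te]], "cnn", te)
    }
    if ("gat" %in% models) {
      emb <- lapply(ids, function(i) predict(cnn, patches[[i]], type = "embedding"))
      names(emb) <- ids
      gcfg <- utils::modifyList(list(seed = child_seed(seed, 50L + sp$fold_id)),
                                gat_cfg)
      gat <- train_gat(do.call(rbind, emb[tr]), combine_graphs(graphs[tr]),
                       train_labels, "binary", n_layers = gat_layers,
                       cfg = gcfg)
      pr <- predict(gat, list(embeddings = emb[[te]], graph = graphs[[te]]))
      predictions[[te]]$gat <- pr
      metrics[[length(metrics) + 1L]] <-
        fold_metric_rows(pr, bundles[[te]], labels[[te]], "gat", te)
      if (keep_models) kept[[te]]$gat <- gat
    }
    if (keep_models) kept[[te]]$cnn <- cnn
  }
  out <- list(metrics = do.call(rbind, metrics), predictions = predictions,
              splits = splits, labels = labels)
  if (keep_models) out$models <- kept
  out
}

fold_metric_rows <- function(probs, bundle, label, model, fold) {
  mb <- per_gene_metrics(probs, label$labels, "binary")
  mr <- per_gene_metrics(probs, bundle$counts, "regression")
  data.frame(gene = mb$gene, model = model, fold = fold,
             auroc = mb$auroc, ap = mb$ap,
             spearman = mr$spearman, pearson = mr$pearson,
             degenerate = mb$degenerate | mr$degenerate,
             stringsAsFactors = FALSE)
}

#' Ground-truth predictions corrupted by spot-level noise
#'
#' Returns the variance-stabilised true expression plus independent
#' Gaussian noise per spot, with per-gene noise sd equal to the gene's
#' signal sd divided by `snr`. Used as a best-case "prediction" for
#' calibrating the recapitulation statistics.
#'
#' @param counts spots x genes counts.
#' @param snr signal-to-noise ratio (signal sd / noise sd).
#' @param seed RNG seed.
#' @return Matrix of noisy pseudo-predictions, same shape.
#' @export
noisy_truth_predictions <- function(counts, snr = 2, seed = 1L) {
  v <- anscombe(counts)
  sds <- apply(v, 2, stats::sd) / snr
  with_seed(seed, v + matrix(stats::rnorm(length(v), sd = rep(sds, each = nrow(v))),
                             nrow(v)))
}

#' Posterior-predictive draw from inferred expression
#'
#' Converts a model's inferred per-spot distribution into one data-like
#' realisation: Bernoulli draws for probability outputs of the binary
#' objective, zero-inflated negative binomial draws for `zinb_params`.
#' Spatial-autocorrelation tests are amplitude-invariant, so the
#' deterministic mean surface of any image-driven model is "spatial" for
#' every gene; testing a predictive draw instead asks whether the inferred
#' expression *distribution* carries the gene's spatial structure above its
#' own noise level.
#'
#' @param pred probability matrix (spots x genes) or a `zinb_params`.
#' @param seed RNG seed.
#' @return Matrix of drawn values, spots x genes.
#' @export
predictive_draw <- function(pred, seed = 1L) {
  with_seed(seed, {
    if (inherits(pred, "zinb_params")) {
      mu <- as.matrix(pred$mu)
      y <- stats::rnbinom(length(mu), size = as.vector(as.matrix(pred$sigma)),
                          mu = as.vector(mu))
      y[stats::rbinom(length(mu), 1L, as.vector(as.matrix(pred$pi))) == 1L] <- 0L
      matrix(y, nrow(mu), dimnames = dimnames(mu))
    } else {
      p <- as.matrix(pred)
      matrix(stats::rbinom(length(p), 1L, as.vector(p)), nrow(p),
             dimnames = dimnames(p))
    }
  })
}

#' Recapitulation analyses over a cross-validated cohort
#'
#' Runs, per held-out slide: the permutation spatial-variability test on
#' the ground-truth counts (coverage filter, Anscombe transform) and on the
#' model's held-out predicted values; the threshold-optimized Fisher
#' association between the two sets of calls; the association between
#' spatial variability and per-gene AUC; the Kruskal-Wallis comparison of
#' AUC across spatial co-expression groups; and, across slides, the
#' differentially spatially variable gene set between the slide groups.
#'
#' @param bundles the cohort (named as in [run_loso_cv()]).
#' @param cv result of [run_loso_cv()].
#' @param n_perm permutations per SV test.
#' @param seed base seed.
#' @param sv_cutoff p-value cutoff for the per-slide SV call used by
#'   [differential_sv()].
#' @param k_groups number of co-expression groups.
#' @param models models to analyse (default: those present in `cv`).
#' @param noisy_truth_snr if non-`NULL`, also run the recapitulation test
#'   with [noisy_truth_predictions()] at this signal-to-noise ratio as a
#'   best-case reference model (`model = "noisy_truth"` rows).
#' @return List with per-slide-per-model `recapitulation` and `sv_auc`
#'   tables, per-slide `groups_auc`, the `differential` gene sets (per
#'   model and for the ground truth), and the underlying `sv_truth` /
#'   `sv_pred` tables.
#' @export
recapitulate_cohort <- function(bundles, cv, n_perm = 499L, seed = 1L,
                                sv_cutoff = 0.01, k_groups = 5L,
                                models = NULL, noisy_truth_snr = NULL) {
  ids <- names(bundles)
  if (is.null(models)) models <- unique(cv$metrics$model)
  ## genes passing coverage on every slide, so calls align across slides
  keep <- Reduce(intersect, lapply(bundles, function(b)
    coverage_filter(b$counts)))
  sv_truth <- list(); sv_pred <- list()
  recap_rows <- list(); svauc_rows <- list(); groups_rows <- list()

  for (i in seq_along(ids)) {
    b <- bundles[[ids[i]]]
    sv_truth[[ids[i]]] <- sv_test_genes(
      b$counts[, keep, drop = FALSE], b$grid, n_perm = n_perm,
      seed = child_seed(seed, i), min_fraction = NULL)
    if (!is.null(noisy_truth_snr)) {
      ## best-case reference: truth + spot noise at the given SNR
      nt <- noisy_truth_predictions(b$counts[, keep, drop = FALSE],
                                    snr = noisy_truth_snr,
                                    seed = child_seed(seed, 300L + i))
      sv_nt <- sv_test_genes(nt, b$grid, n_perm = n_perm,
                             seed = child_seed(seed, 400L + i),
                             min_fraction = NULL, transform = "none")
      rec <- optimize_threshold_fisher(sv_truth[[ids[i]]]$p_value,
                                       sv_nt$p_value)
      recap_rows[[length(recap_rows) + 1L]] <- data.frame(
        slide = ids[i], model = "noisy_truth", t1 = rec$t1, t2 = rec$t2,
        a = rec$table[1, 1], b = rec$table[1, 2], c = rec$table[2, 1],
        d = rec$table[2, 2], odds_ratio = rec$odds_ratio,
        p_value = rec$p_value, degenerate = rec$degenerate,
        stringsAsFactors = FALSE)
    }
    for (mdl in models) {
      pr <- cv$predictions[[ids[i]]][[mdl]]
      ## one data-like realisation of the inferred expression; the mean
      ## surface itself is smooth for every gene and would be called SV
      ## regardless of amplitude
      drawn <- predictive_draw(pr[, keep, drop = FALSE],
                               seed = child_seed(seed, 500L + i))
      sv_pred[[ids[i]]][[mdl]] <- sv_test_genes(
        drawn, b$grid, n_perm = n_perm,
        seed = child_seed(seed, 100L + i), min_fraction = NULL,
        transform = "none")
      rec <- optimize_threshold_fisher(sv_truth[[ids[i]]]$p_value,
                                       sv_pred[[ids[i]]][[mdl]]$p_value)
      recap_rows[[length(recap_rows) + 1L]] <- data.frame(
        slide = ids[i], model = mdl, t1 = rec$t1, t2 = rec$t2,
        a = rec$table[1, 1], b = rec$table[1, 2], c = rec$table[2, 1],
        d = rec$table[2, 2], odds_ratio = rec$odds_ratio,
        p_value = rec$p_value, degenerate = rec$degenerate,
        stringsAsFactors = FALSE)
      met <- cv$metrics[cv$metrics$model == mdl & cv$metrics$fold == ids[i], ]
      auc <- met$auroc[match(keep, met$gene)]
      sa <- sv_vs_auc(sv_truth[[ids[i]]]$p_value, auc)
      svauc_rows[[length(svauc_rows) + 1L]] <- data.frame(
        slide = ids[i], model = mdl, t1 = sa$t1, t2 = sa$t2,
        odds_ratio = sa$odds_ratio, p_value = sa$p_value,
        degenerate = sa$degenerate, stringsAsFactors = FALSE)
      grp <- coexpression_groups(anscombe(b$counts[, keep, drop = FALSE]),
                                 cbind(b$grid$px_x, b$grid$px_y),
                                 k = k_groups, seed = child_seed(seed, 200L + i))
      ga <- groups_vs_auc(grp, stats::setNames(auc, keep))
      groups_rows[[length(groups_rows) + 1L]] <- data.frame(
        slide = ids[i], model = mdl, statistic = ga$statistic,
        p_value = ga$p_value, df = ga$df, stringsAsFactors = FALSE)
    }
  }

  truth_calls <- do.call(rbind, lapply(ids, function(i)
    sv_truth[[i]]$p_value < sv_cutoff))
  dimnames(truth_calls) <- list(ids, keep)
  slide_groups <- vapply(bundles, `[[`, "", "slide_group")
  differential <- list(
    truth = differential_sv(truth_calls, slide_groups))
  for (mdl in models) {
    pred_calls <- do.call(rbind, lapply(ids, function(i)
      sv_pred[[i]][[mdl]]$p_value < sv_cutoff))
    dimnames(pred_calls) <- list(ids, keep)
    differential[[mdl]] <- differential_sv(pred_calls, slide_groups)
  }

  list(recapitulation = do.call(rbind, recap_rows),
       sv_auc = do.call(rbind, svauc_rows),
       groups_auc = do.call(rbind, groups_rows),
       differential = differential,
       sv_truth = sv_truth, sv_pred = sv_pred, genes = keep)
}
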