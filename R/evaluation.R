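## Leave-one-slide-out cross-validation and per-gene performance metrics.

#' Leave-one-slide-out cross-validation splits
#'
#' @param slide_ids character vector of distinct slide identifiers.
#' @return List of folds, each `list(fold_id, train_slides, test_slide)`;
#'   every slide is the test slide exactly once, in input order.
#' @export
make_cv_splits <- function(slide_ids) {
  if (length(slide_ids) < 2) stop_invalid("need at least 2 slides")
  if (anyDuplicated(slide_ids)) stop_invalid("duplicate slide id")
  lapply(seq_along(slide_ids), function(i)
    list(fold_id = i, train_slides = slide_ids[-i], test_slide = slide_ids[i]))
}

#' Area under the ROC curve (rank formula, ties count one half)
#'
#' @param scores numeric predictions.
#' @param labels 0/1 labels.
#' @return AUROC in `[0, 1]`, or `NA` if one class is absent.
#' @export
auroc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (step-interpolated area under precision-recall)
#'
#' Computed over unique score thresholds in decreasing order, so tied
#' scores are handled as one block: `AP = sum_k (R_k - R_{k-1}) P_k`.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 labels.
#' @return AP in `[0, 1]`, or `NA` if no positive is present.
#' @export
average_precision <- function(scores, labels) {
  npos <- sum(labels == 1)
  if (npos == 0 || npos == length(labels)) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- c(s[-1] != s[-length(s)], TRUE)   # block ends of tied scores
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' Per-gene prediction metrics
#'
#' For the binary task: AUROC (probability a random positive outranks a
#' random negative, ties one half) and average precision. For the
#' regression task: Spearman (average-tie rank correlation) and Pearson
#' correlation between predicted and true counts. Genes whose truth is
#' single-class or constant get `NA` metrics and a degenerate flag rather
#' than being dropped.
#'
#' @param pred spots x genes matrix of predictions (probabilities or
#'   expected counts).
#' @param truth spots x genes matrix of 0/1 labels (binary) or counts
#'   (regression).
#' @param task `"binary"` or `"regression"`.
#' @return Data frame, one row per gene: `gene`, the metric columns, and
#'   `degenerate`.
#' @export
per_gene_metrics <- function(pred, truth, task = c("binary", "regression")) {
  task <- match.arg(task)
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth)))
    stop_invalid("pred and truth have different shapes")
  genes <- colnames(truth)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(ncol(truth)))
  if (task == "binary") {
    au <- vapply(seq_len(ncol(pred)), function(j)
      auroc(pred[, j], truth[, j]), 0)
    ap <- vapply(seq_len(ncol(pred)), function(j)
      average_precision(pred[, j], truth[, j]), 0)
    data.frame(gene = genes, auroc = au, ap = ap,
               degenerate = is.na(au), stringsAsFactors = FALSE)
  } else {
    sp <- vapply(seq_len(ncol(pred)), function(j) {
      if (stats::sd(truth[, j]) == 0 || stats::sd(pred[, j]) == 0)
        return(NA_real_)
      stats::cor(pred[, j], truth[, j], method = "spearman")
    }, 0)
    pe <- vapply(seq_len(ncol(pred)), function(j) {
      if (stats::sd(truth[, j]) == 0 || stats::sd(pred[, j]) == 0)
        return(NA_real_)
      stats::cor(pred[, j], truth[, j])
    }, 0)
    data.frame(gene = genes, spearman = sp, pearson = pe,
               degenerate = is.na(sp), stringsAsFactors = FALSE)
  }
}

#' Macro-averaged median metrics with bootstrap confidence intervals
#'
#' The summary statistic for a model is the mean over slides (folds) of the
#' median over genes of a per-gene metric. The 95% confidence interval is a
#' percentile bootstrap that resamples *genes* with replacement (the same
#' resample across folds) and recomputes the macro-median each time.
#' Degenerate (`NA`) entries are excluded from medians but counted.
#'
#' @param table data frame with columns `gene`, `model`, `fold`, and metric
#'   columns (as produced by [run_loso_cv()]).
#' @param metrics metric column names to summarise.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed RNG seed for resampling.
#' @return Data frame: `model`, `metric`, `estimate`, `ci_lo`, `ci_hi`,
#'   `n_degenerate`.
#' @export
aggregate_metrics <- function(table, metrics = intersect(
                                c("auroc", "ap", "spearman", "pearson"),
                                names(table)),
                              n_boot = 1000L, seed = 1L) {
  if (nrow(table) == 0) stop_invalid("empty metrics table")
  if (n_boot < 100) stop_invalid("'n_boot' must be >= 100")
  genes <- sort(unique(table$gene))
  out <- list()
  with_seed(seed, {
    boot_idx <- matrix(sample.int(length(genes), length(genes) * n_boot,
                                  replace = TRUE), ncol = n_boot)
    for (mdl in unique(table$model)) {
      tm <- table[table$model == mdl, , drop = FALSE]
      for (met in metrics) {
        ## genes x folds matrix of the metric
        m <- tapply(tm[[met]], list(factor(tm$gene, genes), tm$fold),
                    function(v) v[1])
        macro_median <- function(gi) {
          mean(apply(m[gi, , drop = FALSE], 2, stats::median, na.rm = TRUE))
        }
        est <- macro_median(seq_along(genes))
        bs <- vapply(seq_len(n_boot), function(b) macro_median(boot_idx[, b]), 0)
        ci <- stats::quantile(bs, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
        out[[length(out) + 1L]] <- data.frame(
          model = mdl, metric = met, estimate = est,
          ci_lo = ci[1], ci_hi = ci[2],
          n_degenerate = sum(is.na(tm[[met]])), stringsAsFactors = FALSE)
      }
    }
  })
  do.call(rbind, out)
}

#' Pairwise per-gene model comparison
#'
#' For each gene, the mean over folds of the metric for each of two models,
#' their difference, and the winner by sign; plus counts of genes won by
#' each model.
#'
#' @param table metrics table (see [aggregate_metrics()]).
#' @param model_a,model_b model names present in `table$model`.
#' @param metric metric column to compare (default `auroc`).
#' @return List with `per_gene` (data frame) and `wins` (named counts,
#'   including exact ties).
#' @export
compare_models <- function(table, model_a, model_b, metric = "auroc") {
  for (m in c(model_a, model_b))
    if (!m %in% table$model) stop_invalid("model '%s' not in table", m)
  genes <- sort(unique(table$gene))
  mean_by_gene <- function(mdl) {
    tm <- table[table$model == mdl, ]
    tapply(tm[[metric]], factor(tm$gene, genes), mean, na.rm = TRUE)
  }
  a <- mean_by_gene(model_a); b <- mean_by_gene(model_b)
  d <- a - b
  per_gene <- data.frame(gene = genes, a = as.vector(a), b = as.vector(b),
                         diff = as.vector(d), stringsAsFactors = FALSE)
  names(per_gene)[2:3] <- c(model_a, model_b)
  wins <- c(sum(d > 0, na.rm = TRUE), sum(d < 0, na.rm = TRUE),
            sum(d == 0, na.rm = TRUE))
  names(wins) <- c(model_a, model_b, "tie")
  list(per_gene = per_gene, wins = wins)
}

#' Per-gene best-model assignment and combined performance
#'
#' Assigns to each gene the model with the best cross-validated metric and
#' recomputes the combined metric from the assigned models' held-out
#' predictions. With `holdout = TRUE` (the default) the selection for fold
#' `f` uses only the other folds' values, so the evaluation fold never
#' informs its own model choice; with `holdout = FALSE` selection uses all
#' folds (the combined statistic then dominates every individual model by
#' construction). Ties are broken by the order of `priority` (first wins).
#'
#' @param table metrics table.
#' @param metric metric column (default `auroc`).
#' @param priority model names in tie-break order; defaults to the order of
#'   appearance in `table`.
#' @param holdout exclude the evaluation fold from selection.
#' @return List with `assignment` (per fold x gene) and `combined` (rows in
#'   the metrics-table format with `model = "combined"`).
#' @export
combine_top_models <- function(table, metric = "auroc", priority = NULL,
                               holdout = TRUE) {
  models <- unique(table$model)
  if (length(models) < 2 && holdout)
    models <- models  # a single model is allowed; combined equals it
  if (is.null(priority)) priority <- models
  genes <- sort(unique(table$gene))
  folds <- sort(unique(table$fold))
  ## value[gene, fold, model]
  arr <- array(NA_real_, c(length(genes), length(folds), length(models)),
               dimnames = list(genes, folds, models))
  for (k in seq_len(nrow(table))) {
    arr[table$gene[k], as.character(table$fold[k]), table$model[k]] <-
      table[[metric]][k]
  }
  prio_rank <- match(models, priority)
  rows <- list(); assign_rows <- list()
  for (fi in seq_along(folds)) {
    sel_folds <- if (holdout && length(folds) > 1) setdiff(seq_along(folds), fi)
                 else seq_along(folds)
    sel <- apply(arr[, sel_folds, , drop = FALSE], c(1, 3), mean, na.rm = TRUE)
    pick <- apply(sel, 1, function(v) {
      v[is.na(v)] <- -Inf
      best <- which(v == max(v))
      best[order(prio_rank[best])][1]
    })
    vals <- arr[cbind(seq_along(genes), fi, pick)]
    rows[[fi]] <- data.frame(gene = genes, model = "combined",
                             fold = folds[fi], value = vals,
                             stringsAsFactors = FALSE)
    names(rows[[fi]])[4] <- metric
    assign_rows[[fi]] <- data.frame(gene = genes, fold = folds[fi],
                                    model = models[pick],
                                    stringsAsFactors = FALSE)
  }
  list(assignment = do.call(rbind, assign_rows),
       combined = do.call(rbind, rows))
}
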