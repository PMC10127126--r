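## Validation statistics: does inferred expression recover the slide's
## spatial autocorrelation structure, is spatial variability associated
## with predictability, do co-expression groups differ in accuracy, and
## which genes are differentially spatially variable between slide groups.

## sample odds ratio of a 2x2 table, Haldane 0.5 correction when any cell
## is zero (keeps the headline statistic finite)
table_odds_ratio <- function(tab) {
  if (any(tab == 0)) tab <- tab + 0.5
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

fisher_cross <- function(high1, high2) {
  tab <- matrix(c(sum(high1 & high2), sum(high1 & !high2),
                  sum(!high1 & high2), sum(!high1 & !high2)),
                2, 2, byrow = TRUE)
  or <- table_odds_ratio(tab)
  p <- stats::fisher.test(tab)$p.value
  list(table = tab, odds_ratio = or, p_value = p)
}

## shared threshold search: dichotomize two per-gene score vectors over a
## cutoff grid, maximising |log OR| (ties: smaller Fisher p, then smaller
## cutoffs). `high` orientation is fixed by the callers.
search_thresholds <- function(x1, x2, grid1, grid2, high1_fn, high2_fn) {
  stopifnot(length(x1) == length(x2))
  best <- NULL
  for (t1 in sort(grid1)) for (t2 in sort(grid2)) {
    h1 <- high1_fn(x1, t1)
    h2 <- high2_fn(x2, t2)
    if (all(h1) || !any(h1) || all(h2) || !any(h2)) next
    f <- fisher_cross(h1, h2)
    cand <- list(t1 = t1, t2 = t2, table = f$table,
                 odds_ratio = f$odds_ratio, p_value = f$p_value,
                 degenerate = FALSE)
    if (is.null(best) ||
        abs(log(cand$odds_ratio)) > abs(log(best$odds_ratio)) + 1e-12 ||
        (abs(abs(log(cand$odds_ratio)) - abs(log(best$odds_ratio))) <= 1e-12 &&
         cand$p_value < best$p_value - 1e-15))
      best <- cand
  }
  if (is.null(best))
    best <- list(t1 = NA, t2 = NA, table = matrix(NA_integer_, 2, 2),
                 odds_ratio = NA_real_, p_value = NA_real_, degenerate = TRUE)
  best
}

default_p_grid <- c(0.001, 0.005, 0.01, 0.05, 0.1)
default_auc_grid <- seq(0.55, 0.9, by = 0.05)

#' Recapitulation of spatial autocorrelation: threshold-optimized Fisher test
#'
#' Dichotomizes per-gene spatial-variability p-values computed on the
#' ground truth (`high autocorrelation` = `p < t1`) and on the inferred
#' expression (`p < t2`) over a cutoff grid, cross-tabulates the calls over
#' genes, and returns the cutoff pair maximising the magnitude of the
#' association, `|log OR|` (ties broken by smaller Fisher p, then smaller
#' cutoffs). The odds ratio is the sample OR with a Haldane 0.5 correction
#' when any cell is empty; the p-value is the two-sided Fisher's exact
#' test. An OR above 1 means the model recovers which genes are spatially
#' autocorrelated.
#'
#' @param p_truth,p_pred aligned per-gene p-value vectors (truth and
#'   inferred expression).
#' @param grid cutoffs to search (used for both sides).
#' @return A `recap_result` list: `t1`, `t2`, `table` (2x2: rows = truth
#'   high/low, cols = predicted high/low), `odds_ratio`, `p_value`,
#'   `degenerate`.
#' @export
optimize_threshold_fisher <- function(p_truth, p_pred,
                                      grid = default_p_grid) {
  if (length(p_truth) != length(p_pred))
    stop_invalid("gene lists are not aligned")
  if (length(grid) == 0) stop_invalid("empty cutoff grid")
  res <- search_thresholds(p_truth, p_pred, grid, grid,
                           function(x, t) x < t, function(x, t) x < t)
  structure(res, class = "recap_result")
}

#' Association between spatial variability and model accuracy
#'
#' Cross-tabulates dichotomized ground-truth spatial autocorrelation
#' (`p < t1`) against dichotomized per-gene AUC (`AUC >= t2`), with cutoffs
#' chosen to maximise `|log OR|`. The orientation is fixed so that an odds
#' ratio above 1 means spatially variable genes are predicted *more*
#' accurately.
#'
#' @param p_truth per-gene spatial-variability p-values on ground truth.
#' @param auc per-gene AUC for one model.
#' @param p_grid cutoffs for the p-value side.
#' @param auc_grid cutoffs for the AUC side (over `[0.5, 1)`).
#' @return A `recap_result` (see [optimize_threshold_fisher()]).
#' @export
sv_vs_auc <- function(p_truth, auc, p_grid = default_p_grid,
                      auc_grid = default_auc_grid) {
  if (length(p_truth) != length(auc))
    stop_invalid("gene lists are not aligned")
  keep <- !is.na(auc)
  res <- search_thresholds(p_truth[keep], auc[keep], p_grid, auc_grid,
                           function(x, t) x < t, function(x, t) x >= t)
  structure(res, class = "recap_result")
}

#' Kruskal-Wallis comparison of accuracy across co-expression groups
#'
#' Tests whether per-gene model accuracies differ between spatial
#' co-expression groups, with the average-rank tie correction and a
#' chi-square reference with `k - 1` degrees of freedom.
#'
#' @param groups named group labels per gene (a [coexpression_groups()]
#'   result).
#' @param auc per-gene accuracies, aligned with `groups` (names matched
#'   when present).
#' @return List: `statistic` (H), `p_value`, `df`.
#' @export
groups_vs_auc <- function(groups, auc) {
  if (!is.null(names(auc)) && !is.null(names(groups)))
    auc <- auc[names(groups)]
  keep <- !is.na(auc)
  auc <- auc[keep]; groups <- groups[keep]
  if (length(unique(groups)) < 2)
    stop_invalid("need at least 2 non-empty groups")
  kt <- stats::kruskal.test(auc, factor(groups))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Genes differentially spatially variable between slide groups
#'
#' A gene is selected iff its dichotomized spatial-variability call is
#' uniform within each slide group and differs between the groups (for
#' example SV on every metastasis slide and non-SV on every non-metastasis
#' slide, or vice versa). No multiple-testing correction is applied: the
#' calls are already dichotomized per slide.
#'
#' @param sv_calls logical matrix, slides x genes: the per-slide
#'   dichotomized SV call.
#' @param slide_groups vector of group labels (two levels, e.g. `met` /
#'   `nonmet`), one per row of `sv_calls`.
#' @return Character vector of selected gene names.
#' @export
differential_sv <- function(sv_calls, slide_groups) {
  if (nrow(sv_calls) != length(slide_groups))
    stop_invalid("one group label per slide is required")
  lv <- unique(slide_groups)
  if (length(lv) != 2) stop_invalid("exactly two slide groups are required")
  g1 <- sv_calls[slide_groups == lv[1], , drop = FALSE]
  g2 <- sv_calls[slide_groups == lv[2], , drop = FALSE]
  uniform1 <- colSums(g1) %in% c(0L, nrow(g1))
  uniform2 <- colSums(g2) %in% c(0L, nrow(g2))
  differs <- (colSums(g1) > 0) != (colSums(g2) > 0)
  sel <- uniform1 & uniform2 & differs
  cn <- colnames(sv_calls)
  if (is.null(cn)) which(sel) else cn[sel]
}

#' @export
print.recap_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("recap_result: degenerate (no informative cutoff)\n")
  } else {
    cat(sprintf("recap_result: OR %.3g (Fisher p %.3g) at cutoffs (%g, %g)\n",
                x$odds_ratio, x$p_value, x$t1, x$t2))
    print(x$table)
  }
  invisible(x)
}
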