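# Shared small fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# 10x10 grid with a simulated slide; desk-size for unit tests
small_bundle <- function() {
  if (is.null(fixture_env$small)) {
    g <- make_hex_grid(10, 10, pitch_px = 64, spot_diameter_px = 36,
                       margin_px = 48)
    lat <- simulate_expression(g, n_genes = 20, seed = 42)
    img <- render_slide(g, lat, seed = 43)
    fixture_env$small <- slide_bundle(g, img, lat$counts, lat, "met", "sA")
  }
  fixture_env$small
}

# two-slide mini cohort with images, for model/pipeline contracts
mini_cohort <- function() {
  if (is.null(fixture_env$cohort)) {
    fixture_env$cohort <- simulate_cohort(
      n_slides = 2, n_rows = 8, n_cols = 8, n_genes = 12, seed = 99)
  }
  fixture_env$cohort
}

# brute-force Moran's I double-sum oracle
oracle_morans_i <- function(values, W) {
  W <- as.matrix(W)
  z <- values - mean(values)
  n <- length(z)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# brute-force AUROC: count positive-negative pairs, ties half
oracle_auroc <- function(scores, labels) {
  ip <- which(labels == 1); im <- which(labels == 0)
  if (!length(ip) || !length(im)) return(NA_real_)
  tot <- 0
  for (i in ip) for (j in im)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(ip) * length(im))
}

# exhaustive two-sided Fisher's exact p for a 2x2 table: sum the
# probabilities of all tables with the same margins whose probability does
# not exceed the observed one
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  prob_a <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    if (b < 0 || cc < 0 || d < 0) return(0)
    exp(lchoose(r1, a) + lchoose(r2, cc) - lchoose(n, c1))
  }
  p_obs <- prob_a(tab[1, 1])
  amax <- min(r1, c1)
  ps <- vapply(0:amax, prob_a, 0)
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# Kruskal-Wallis H with average-rank tie correction, by the rank formula
oracle_kruskal_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) sum(ri)^2 / length(ri))) - 3 * (n + 1)
  ties <- table(values)
  ct <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / ct
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
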