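## Training objectives: split-weighted binary cross-entropy for dichotomized
## expression, and the zero-inflated negative binomial likelihood for counts.

#' Split-weighted binary cross-entropy
#'
#' For each gene the loss is the mean of `-log p` over positive spots plus
#' the mean of `-log(1 - p)` over negative spots; averaging within each
#' class before summing makes the loss invariant to class imbalance
#' (duplicating every negative spot leaves it unchanged). The total is the
#' unweighted mean over genes. A gene missing one class contributes only the
#' defined term.
#'
#' @param probs matrix (spots x genes) of predicted probabilities.
#' @param labels matrix of 0/1 labels, same shape (a `binary_targets`
#'   object's `labels`, or any 0/1 matrix).
#' @param eps probabilities are clamped to `[eps, 1 - eps]`.
#' @return List with `per_gene` (named vector) and `total` (mean over genes).
#' @export
weighted_bce <- function(probs, labels, eps = 1e-7) {
  if (inherits(labels, "binary_targets")) labels <- labels$labels
  probs <- as.matrix(probs); labels <- as.matrix(labels)
  if (!all(dim(probs) == dim(labels)))
    stop_invalid("probs and labels have different shapes")
  p <- clamp(probs, eps, 1 - eps)
  pos <- labels == 1
  npos <- colSums(pos); nneg <- colSums(!pos)
  lp <- -log(p); ln <- -log1p(-p)
  pos_term <- colSums(lp * pos) / pmax(npos, 1)
  neg_term <- colSums(ln * !pos) / pmax(nneg, 1)
  per_gene <- ifelse(npos > 0, pos_term, 0) + ifelse(nneg > 0, neg_term, 0)
  names(per_gene) <- colnames(labels)
  list(per_gene = per_gene, total = mean(per_gene))
}

#' Construct zero-inflated negative binomial parameters
#'
#' @param mu,sigma,pi equally shaped arrays: NB mean (> 0), NB dispersion
#'   (> 0; variance is `mu + mu^2 / sigma`), and zero-inflation mass in
#'   `[0, 1]`.
#' @return A `zinb_params` list.
#' @export
zinb_params <- function(mu, sigma, pi) {
  if (any(mu <= 0) || any(sigma <= 0)) stop_invalid("mu and sigma must be positive")
  if (any(pi < 0 | pi > 1)) stop_invalid("pi must lie in [0, 1]")
  structure(list(mu = mu, sigma = sigma, pi = pi), class = "zinb_params")
}

#' Expected value of a zero-inflated negative binomial
#'
#' The inferred expression value: `(1 - pi) * mu`.
#'
#' @param params a `zinb_params`.
#' @return Array of expected counts, same shape as `params$mu`.
#' @export
zinb_mean <- function(params) {
  (1 - params$pi) * params$mu
}

#' Zero-inflated negative binomial negative log-likelihood
#'
#' Per observation: `-log[ pi * 1{y = 0} + (1 - pi) * NB(y; mu, sigma) ]`
#' with the NB parameterised by mean `mu` and dispersion `sigma`
#' (`size = sigma` in [stats::dnbinom()]), averaged over observations.
#'
#' @param params a `zinb_params` (elements recycled to the shape of `counts`).
#' @param counts non-negative integer counts.
#' @return Mean negative log-likelihood (scalar).
#' @export
zinb_nll <- function(params, counts) {
  y <- as.vector(counts)
  if (any(y < 0) || any(y != round(y)))
    stop_invalid("counts must be non-negative integers")
  mu <- as.vector(params$mu); sig <- as.vector(params$sigma)
  pi <- as.vector(params$pi)
  lnb <- stats::dnbinom(y, size = sig, mu = mu, log = TRUE)
  ll <- ifelse(y == 0,
               log(pi + (1 - pi) * exp(lnb)),
               log1p(-pi) + lnb)
  ## pi = 1 with y > 0 has likelihood 0; keep -Inf rather than NaN
  ll[pi >= 1 & y > 0] <- -Inf
  -mean(ll)
}

## gradient of the per-observation ZINB NLL wrt (mu, sigma, pi); internal,
## used by the model heads and the standalone fitter
zinb_nll_grad <- function(mu, sigma, pi, y) {
  is0 <- y == 0
  dmu <- dsig <- dpi <- numeric(length(y))
  ## y > 0 branch: NLL = -log(1-pi) - logNB
  dlnb_dmu <- y / mu - (y + sigma) / (sigma + mu)
  dlnb_dsig <- digamma(y + sigma) - digamma(sigma) +
    log(sigma / (sigma + mu)) + 1 - (y + sigma) / (sigma + mu)
  dmu[!is0] <- -dlnb_dmu[!is0]
  dsig[!is0] <- -dlnb_dsig[!is0]
  dpi[!is0] <- 1 / (1 - pi[!is0])
  ## y = 0 branch: NLL = -log(pi + (1-pi) q0), q0 = (sigma/(sigma+mu))^sigma
  lq0 <- sigma * log(sigma / (sigma + mu))
  q0 <- exp(lq0)
  m <- pi + (1 - pi) * q0
  dq0_dmu <- q0 * (-sigma / (sigma + mu))
  dq0_dsig <- q0 * (log(sigma / (sigma + mu)) + mu / (sigma + mu))
  dmu[is0] <- (-(1 - pi[is0]) * dq0_dmu[is0] / m[is0])
  dsig[is0] <- (-(1 - pi[is0]) * dq0_dsig[is0] / m[is0])
  dpi[is0] <- (-(1 - q0[is0]) / m[is0])
  list(dmu = dmu, dsigma = dsig, dpi = dpi)
}

#' Fit a zero-inflated negative binomial by maximum likelihood
#'
#' Fits a single `(mu, sigma, pi)` triplet to a vector of counts by
#' minimising [zinb_nll()] over the unconstrained parameters
#' `(log mu, log sigma, logit pi)` with BFGS and the analytic gradient. This
#' is the regression head fitted in isolation (no covariates).
#'
#' @param y non-negative integer counts.
#' @param init optional list with starting `mu`, `sigma`, `pi`.
#' @return List with `mu`, `sigma`, `pi`, `nll`, `convergence`.
#' @export
fit_zinb <- function(y, init = NULL) {
  y <- as.vector(y)
  if (any(y < 0) || any(y != round(y)))
    stop_invalid("counts must be non-negative integers")
  if (is.null(init)) {
    p0 <- max(min(mean(y == 0) / 2, 0.9), 0.05)
    m0 <- max(mean(y) / (1 - p0), 0.1)
    init <- list(mu = m0, sigma = 1, pi = p0)
  }
  theta0 <- c(log(init$mu), log(init$sigma), stats::qlogis(init$pi))
  unpack <- function(th) list(mu = exp(th[1]), sigma = exp(th[2]),
                              pi = stats::plogis(th[3]))
  fn <- function(th) {
    p <- unpack(th)
    zinb_nll(zinb_params(rep(p$mu, length(y)), rep(p$sigma, length(y)),
                         rep(p$pi, length(y))), y)
  }
  gr <- function(th) {
    p <- unpack(th)
    g <- zinb_nll_grad(rep(p$mu, length(y)), rep(p$sigma, length(y)),
                       rep(p$pi, length(y)), y)
    c(mean(g$dmu) * p$mu,
      mean(g$dsigma) * p$sigma,
      mean(g$dpi) * p$pi * (1 - p$pi))
  }
  fit <- stats::optim(theta0, fn, gr, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  out <- unpack(fit$par)
  out$nll <- fit$value
  out$convergence <- fit$convergence
  out
}
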