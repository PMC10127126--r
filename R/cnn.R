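## Local patch model: a small convolutional network trained from scratch.
## Three stride-2 conv-ReLU blocks, global average pooling, a dense
## embedding layer (the penultimate layer whose activations feed the graph
## models), and a multi-gene output head. The backbone sits behind this
## constructor, so a larger architecture can be substituted without touching
## the training loop.

cnn_init <- function(patch_size, n_out, channels = c(8L, 16L, 32L),
                     embed_dim = 64L) {
  p <- patch_size
  if (p %% 16 != 0) stop_invalid("patch size must be a multiple of 16")
  specs <- list(
    conv_spec(p, p, 3L, channels[1], 4L),
    conv_spec(p %/% 4, p %/% 4, channels[1], channels[2], 2L),
    conv_spec(p %/% 8, p %/% 8, channels[2], channels[3], 2L)
  )
  params <- list(
    K1 = he_init(9L * 3L, channels[1], 27),
    b1 = numeric(channels[1]),
    K2 = he_init(9L * channels[1], channels[2], 9 * channels[1]),
    b2 = numeric(channels[2]),
    K3 = he_init(9L * channels[2], channels[3], 9 * channels[2]),
    b3 = numeric(channels[3]),
    Wd = he_init(channels[3], embed_dim, channels[3]),
    bd = numeric(embed_dim),
    Wh = he_init(embed_dim, n_out, embed_dim) * 0.1,
    bh = numeric(n_out)
  )
  list(specs = specs, params = params, channels = channels,
       embed_dim = embed_dim, patch_size = p, n_out = n_out)
}

## fixed reference standardisation of patch pixels (analogue of scaling by
## a reference corpus mean/variance before training)
PATCH_REF_MEAN <- 0.7
PATCH_REF_SD <- 0.25

## forward pass over a batch given as rows of a patch matrix
cnn_forward <- function(net, xmat, keep = FALSE) {
  p <- net$patch_size
  B <- nrow(xmat)
  P <- net$params
  X0 <- array(t((xmat - PATCH_REF_MEAN) / PATCH_REF_SD), c(p, p, 3L, B))
  c1 <- conv_forward(net$specs[[1]], P$K1, P$b1, X0, B)
  a1 <- pmax(c1$out, 0)
  c2 <- conv_forward(net$specs[[2]], P$K2, P$b2, a1, B)
  a2 <- pmax(c2$out, 0)
  c3 <- conv_forward(net$specs[[3]], P$K3, P$b3, a2, B)
  a3 <- pmax(c3$out, 0)
  npos <- net$specs[[3]]$OH * net$specs[[3]]$OW
  ## a3 is (OH,OW,C3,B); average over the spatial positions
  m <- matrix(a3, npos, net$channels[3] * B)
  gap <- matrix(colMeans(m), net$channels[3], B)
  gap <- t(gap)                                   # B x C3
  zd <- sweep(gap %*% P$Wd, 2, P$bd, "+")
  emb <- pmax(zd, 0)                              # B x embed_dim
  logits <- sweep(emb %*% P$Wh, 2, P$bh, "+")     # B x n_out
  out <- list(logits = logits, embedding = emb)
  if (keep)
    out <- c(out, list(X0 = X0, c1 = c1, a1 = a1, c2 = c2, a2 = a2,
                       c3 = c3, a3 = a3, gap = gap, zd = zd, B = B,
                       npos = npos))
  out
}

## backward pass from dLogits; returns gradient list matching params
cnn_backward <- function(net, fw, dLogits) {
  P <- net$params
  B <- fw$B
  dWh <- crossprod(fw$embedding, dLogits)
  dbh <- colSums(dLogits)
  dEmb <- dLogits %*% t(P$Wh)
  dZd <- dEmb * (fw$zd > 0)
  dWd <- crossprod(fw$gap, dZd)
  dbd <- colSums(dZd)
  dGap <- dZd %*% t(P$Wd)                          # B x C3
  npos <- fw$npos
  dA3 <- array(rep(t(dGap) / npos, each = npos),
               c(npos, net$channels[3], B))
  dim(dA3) <- dim(fw$a3)
  dZ3 <- dA3 * (fw$c3$out > 0)
  g3 <- conv_backward(net$specs[[3]], P$K3, fw$c3$Xcol, dZ3, B, TRUE)
  dZ2 <- g3$dX * (fw$c2$out > 0)
  g2 <- conv_backward(net$specs[[2]], P$K2, fw$c2$Xcol, dZ2, B, TRUE)
  dZ1 <- g2$dX * (fw$c1$out > 0)
  g1 <- conv_backward(net$specs[[1]], P$K1, fw$c1$Xcol, dZ1, B, FALSE)
  list(K1 = g1$dK, b1 = g1$db, K2 = g2$dK, b2 = g2$db,
       K3 = g3$dK, b3 = g3$db, Wd = dWd, bd = dbd, Wh = dWh, bh = dbh)
}

## ---- objective gradients at the head -------------------------------------

## split-weighted BCE: per gene, class means; returns loss and dLogits
bce_head <- function(logits, y) {
  p <- stats::plogis(logits)
  pe <- clamp(p, 1e-7, 1 - 1e-7)
  G <- ncol(y)
  pos <- y == 1
  npos <- colSums(pos); nneg <- colSums(!pos)
  loss <- mean(ifelse(npos > 0, colSums(-log(pe) * pos) / pmax(npos, 1), 0) +
               ifelse(nneg > 0, colSums(-log1p(-pe) * !pos) / pmax(nneg, 1), 0))
  wpos <- ifelse(npos > 0, 1 / npos, 0) / G
  wneg <- ifelse(nneg > 0, 1 / nneg, 0) / G
  w <- matrix(0, nrow(y), G)
  w[pos] <- rep(wpos, each = nrow(y))[pos]
  w[!pos] <- rep(wneg, each = nrow(y))[!pos]
  dz <- (p - y) * w
  list(loss = loss, dLogits = dz)
}

## ZINB head: raw outputs (B x 3G) -> (mu, sigma, pi); returns loss and grad
zinb_head <- function(raw, y) {
  G <- ncol(y)
  a <- raw[, seq_len(G), drop = FALSE]
  b <- raw[, G + seq_len(G), drop = FALSE]
  cc <- raw[, 2L * G + seq_len(G), drop = FALSE]
  mu <- softplus(a) + 1e-4
  sig <- softplus(b) + 1e-4
  pii <- clamp(stats::plogis(cc), 1e-6, 1 - 1e-6)
  pars <- zinb_params(mu, sig, pii)
  loss <- zinb_nll(pars, y)
  g <- zinb_nll_grad(as.vector(mu), as.vector(sig), as.vector(pii),
                     as.vector(y))
  nobs <- length(y)
  dA <- matrix(g$dmu / nobs, nrow(y), G) * stats::plogis(a)
  dB <- matrix(g$dsigma / nobs, nrow(y), G) * stats::plogis(b)
  dC <- matrix(g$dpi / nobs, nrow(y), G) * pii * (1 - pii)
  list(loss = loss, dLogits = cbind(dA, dB, dC), params = pars)
}

## ---- augmentation ---------------------------------------------------------

rot_perm <- function(p, theta) {
  c0 <- (p + 1) / 2
  r <- rep(seq_len(p), times = p)
  cc <- rep(seq_len(p), each = p)
  x <- cc - c0; y <- r - c0
  th <- theta * pi / 180
  xs <- clamp(round(cos(th) * x + sin(th) * y + c0), 1, p)
  ys <- clamp(round(-sin(th) * x + cos(th) * y + c0), 1, p)
  idx <- ys + (xs - 1) * p
  c(idx, idx + p * p, idx + 2 * p * p)
}

flip_perm <- function(p, horizontal) {
  r <- rep(seq_len(p), times = p)
  cc <- rep(seq_len(p), each = p)
  idx <- if (horizontal) r + (p - cc) * p else (p + 1 - r) + (cc - 1) * p
  c(idx, idx + p * p, idx + 2 * p * p)
}

make_aug_perms <- function(p, angles = c(-15, -7.5, 0, 7.5, 15)) {
  list(rot = lapply(angles, function(a) rot_perm(p, a)),
       hflip = flip_perm(p, TRUE), vflip = flip_perm(p, FALSE),
       n_rot = length(angles))
}

## random rotation + flips + colour jitter on a batch (rows = patches)
augment_batch <- function(x, perms, flips = TRUE) {
  B <- nrow(x)
  rot_id <- sample.int(perms$n_rot, B, replace = TRUE)
  for (k in seq_len(perms$n_rot)) {
    rows <- which(rot_id == k)
    if (length(rows)) x[rows, ] <- x[rows, perms$rot[[k]], drop = FALSE]
  }
  if (flips) {
    hf <- stats::runif(B) < 0.5
    vf <- stats::runif(B) < 0.5
    if (any(hf)) x[hf, ] <- x[hf, perms$hflip, drop = FALSE]
    if (any(vf)) x[vf, ] <- x[vf, perms$vflip, drop = FALSE]
  }
  D3 <- ncol(x) / 3
  scale <- matrix(stats::runif(B * 3, 0.95, 1.05), B, 3)
  shift <- matrix(stats::runif(B * 3, -0.03, 0.03), B, 3)
  for (ch in 1:3) {
    cols <- (ch - 1) * D3 + seq_len(D3)
    x[, cols] <- x[, cols] * scale[, ch] + shift[, ch]
  }
  clamp(x, 0, 1)
}

## ---- training -------------------------------------------------------------

#' Train the local patch model
#'
#' Trains the small CNN on spot-centred patches, predicting all genes at
#' once: with the `binary` objective a sigmoid output per gene trained with
#' the split-weighted binary cross-entropy, with the `zinb` objective three
#' outputs per gene parameterising the zero-inflated negative binomial
#' (`mu`, `sigma` via softplus, `pi` via a logistic). Training is
#' deterministic given `cfg$seed`.
#'
#' @param patches a `patch_set`.
#' @param targets a `binary_targets` (for `objective = "binary"`) or a
#'   counts matrix (for `objective = "zinb"`), rows aligned with `patches`.
#' @param objective `"binary"` or `"zinb"`.
#' @param cfg list of training options: `epochs` (10), `lr` (1e-3),
#'   `batch_size` (32), `seed` (1), `channels` (8, 16, 32), `embed_dim`
#'   (64), `augment` (TRUE), `verbose` (FALSE).
#' @return A `spotsight_model` with the trained weights, the per-epoch
#'   training losses, and the training configuration.
#' @export
train_local_model <- function(patches, targets,
                              objective = c("binary", "zinb"), cfg = list()) {
  objective <- match.arg(objective)
  cfg <- utils::modifyList(
    list(epochs = 10L, lr = 1e-3, batch_size = 32L, seed = 1L,
         channels = c(8L, 16L, 32L), embed_dim = 64L, augment = TRUE,
         verbose = FALSE),
    cfg
  )
  if (!inherits(patches, "patch_set")) stop_invalid("'patches' must be a patch_set")
  if (objective == "binary") {
    if (!inherits(targets, "binary_targets"))
      stop_invalid("binary objective requires binary_targets")
    y <- targets$labels
  } else {
    if (inherits(targets, "binary_targets"))
      stop_invalid("zinb objective requires a counts matrix")
    y <- as.matrix(targets)
    if (any(y < 0) || any(y != round(y)))
      stop_invalid("zinb objective requires non-negative integer counts")
  }
  n <- nrow(patches$x)
  if (nrow(y) != n) stop_invalid("patches and targets are not aligned")
  G <- ncol(y)
  n_out <- if (objective == "binary") G else 3L * G

  net <- with_seed(cfg$seed,
                   cnn_init(patches$patch_size_px, n_out, cfg$channels,
                            cfg$embed_dim))
  opt <- adam_new(net$params)
  perms <- make_aug_perms(patches$patch_size_px)
  losses <- numeric(cfg$epochs)

  with_seed(child_seed(cfg$seed, 17L), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      tot <- 0; nb <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        xb <- patches$x[idx, , drop = FALSE]
        if (cfg$augment) xb <- augment_batch(xb, perms)
        yb <- y[idx, , drop = FALSE]
        fw <- cnn_forward(net, xb, keep = TRUE)
        hd <- if (objective == "binary") bce_head(fw$logits, yb)
              else zinb_head(fw$logits, yb)
        grads <- cnn_backward(net, fw, hd$dLogits)
        upd <- adam_step(net$params, grads, opt, cfg$lr)
        net$params <- upd$params; opt <- upd$state
        tot <- tot + hd$loss; nb <- nb + 1
      }
      losses[ep] <- tot / nb
      if (cfg$verbose)
        message(sprintf("epoch %d/%d: loss %.4f", ep, cfg$epochs, losses[ep]))
    }
  })

  structure(
    list(type = "cnn_local", net = net, objective = objective,
         gene_ids = colnames(y), cfg = cfg, losses = losses,
         embed_dim = cfg$embed_dim, patch_size_px = patches$patch_size_px),
    class = "spotsight_model"
  )
}

#' Predict from a trained model
#'
#' @param object a `spotsight_model` from [train_local_model()] or
#'   [train_gat()].
#' @param newdata a `patch_set` (local model) or a list with `embeddings`
#'   and `graph` (graph model).
#' @param type `"response"` (per-spot-per-gene probabilities for the binary
#'   objective, `zinb_params` for the zinb objective) or `"embedding"`
#'   (penultimate-layer activations; local model only).
#' @param batch_size forward-pass batch size (local model).
#' @param ... unused.
#' @return Matrix of probabilities, a `zinb_params`, or an embedding matrix.
#' @export
predict.spotsight_model <- function(object, newdata,
                                    type = c("response", "embedding"),
                                    batch_size = 128L, ...) {
  type <- match.arg(type)
  if (object$type == "cnn_local") {
    if (!inherits(newdata, "patch_set"))
      stop_invalid("local model expects a patch_set")
    if (newdata$patch_size_px != object$patch_size_px)
      stop_invalid("patch size %d does not match model (%d)",
                   newdata$patch_size_px, object$patch_size_px)
    n <- nrow(newdata$x)
    outs <- vector("list", ceiling(n / batch_size))
    for (i in seq_along(outs)) {
      idx <- ((i - 1L) * batch_size + 1L):min(i * batch_size, n)
      fw <- cnn_forward(object$net, newdata$x[idx, , drop = FALSE])
      outs[[i]] <- if (type == "embedding") fw$embedding else fw$logits
    }
    out <- do.call(rbind, outs)
    rownames(out) <- newdata$spot_id
    if (type == "embedding") return(out)
    finish_response(object, out)
  } else {
    if (type == "embedding")
      stop_invalid("embeddings are defined for the local model")
    gat_predict(object, newdata$embeddings, newdata$graph)
  }
}

## turn raw head outputs into the response for the model's objective
finish_response <- function(object, logits) {
  G <- length(object$gene_ids)
  if (object$objective == "binary") {
    pr <- stats::plogis(logits)
    pr <- clamp(pr, 1e-7, 1 - 1e-7)   # strictly inside (0, 1)
    colnames(pr) <- object$gene_ids
    pr
  } else {
    a <- logits[, seq_len(G), drop = FALSE]
    b <- logits[, G + seq_len(G), drop = FALSE]
    cc <- logits[, 2L * G + seq_len(G), drop = FALSE]
    out <- zinb_params(softplus(a) + 1e-4, softplus(b) + 1e-4,
                       clamp(stats::plogis(cc), 1e-6, 1 - 1e-6))
    for (k in 1:3) colnames(out[[k]]) <- object$gene_ids
    out
  }
}
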