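## Graph attention network over the spot adjacency graph, trained on frozen
## penultimate-layer embeddings of the local patch model. Attention follows
## the standard formulation: per head, edge logits are a LeakyReLU of
## source/target scores, softmax-normalised over each node's in-neighbourhood
## (self-edge included), and head outputs are concatenated.

## directed edge structure with self loops, plus slot tables for the
## per-target softmax
gat_edges <- function(graph) {
  e <- graph$edges
  n <- graph$n
  src <- c(e[, 1], e[, 2], seq_len(n))
  tgt <- c(e[, 2], e[, 1], seq_len(n))
  deg <- tabulate(tgt, n)
  maxdeg <- max(deg)
  o <- order(tgt)
  slot <- sequence(deg)          # within-target slot, in sorted order
  slot_row <- tgt[o]
  slot_idx <- cbind(slot_row, slot)
  list(src = src, tgt = tgt, n = n, E = length(src),
       o = o, slot_idx = slot_idx, maxdeg = maxdeg)
}

gat_init <- function(d_in, n_out, n_layers, n_heads = 8L, width = 64L) {
  if (width %% n_heads != 0) stop_invalid("width must be divisible by n_heads")
  params <- list()
  din <- d_in
  for (l in seq_len(n_layers)) {
    params[[paste0("W", l)]] <- he_init(din, width, din)
    params[[paste0("as", l)]] <- stats::rnorm(width, sd = 0.1)
    params[[paste0("ad", l)]] <- stats::rnorm(width, sd = 0.1)
    din <- width
  }
  params$Wh <- he_init(din, n_out, din) * 0.1
  params$bh <- numeric(n_out)
  list(params = params, n_layers = n_layers, n_heads = n_heads,
       width = width, d_in = d_in, n_out = n_out)
}

## block-diagonal a_src/a_dst matrices (width x heads)
attn_mat <- function(a, n_heads) {
  width <- length(a)
  dh <- width %/% n_heads
  m <- matrix(0, width, n_heads)
  for (h in seq_len(n_heads)) {
    idx <- (h - 1L) * dh + seq_len(dh)
    m[idx, h] <- a[idx]
  }
  m
}

gat_layer_forward <- function(X, W, a_src, a_dst, ed, n_heads) {
  Q <- X %*% W
  As <- attn_mat(a_src, n_heads)
  Ad <- attn_mat(a_dst, n_heads)
  Ss <- Q %*% As                       # n x heads
  Sd <- Q %*% Ad
  e0 <- Ss[ed$src, , drop = FALSE] + Sd[ed$tgt, , drop = FALSE]
  el <- ifelse(e0 > 0, e0, 0.2 * e0)   # LeakyReLU(0.2)
  ## per-(target, head) max for a stable softmax
  tmax <- matrix(-Inf, ed$n, n_heads)
  for (h in seq_len(n_heads)) {
    sm <- matrix(-Inf, ed$n, ed$maxdeg)
    sm[ed$slot_idx] <- el[ed$o, h]
    tmax[, h] <- do.call(pmax, c(as.data.frame(sm), na.rm = TRUE))
  }
  ex <- exp(el - tmax[ed$tgt, , drop = FALSE])
  denom <- rowsum(ex, ed$tgt)
  alpha <- ex / denom[ed$tgt, , drop = FALSE]
  dh <- ncol(Q) %/% n_heads
  aw <- alpha[, rep(seq_len(n_heads), each = dh), drop = FALSE]
  msg <- rowsum(aw * Q[ed$src, , drop = FALSE], ed$tgt)
  out <- pmax(msg, 0)
  list(X = X, Q = Q, e0 = e0, alpha = alpha, msg = msg, out = out,
       As = As, Ad = Ad, W = W)
}

gat_layer_backward <- function(fw, dOut, ed, n_heads) {
  dMsg <- dOut * (fw$msg > 0)
  dh <- ncol(fw$Q) %/% n_heads
  dMt <- dMsg[ed$tgt, , drop = FALSE]
  Qs <- fw$Q[ed$src, , drop = FALSE]
  dM <- dMt * Qs                                       # E x width
  dalpha <- vapply(seq_len(n_heads), function(h)
    rowSums(dM[, (h - 1L) * dh + seq_len(dh), drop = FALSE]),
    numeric(ed$E))
  aw <- fw$alpha[, rep(seq_len(n_heads), each = dh), drop = FALSE]
  dQ_src <- rowsum(aw * dMt, ed$src)                   # message path
  ## softmax backward
  s <- rowsum(fw$alpha * dalpha, ed$tgt)               # n x heads
  de <- fw$alpha * (dalpha - s[ed$tgt, , drop = FALSE])
  del <- de * ifelse(fw$e0 > 0, 1, 0.2)
  dSs <- rowsum(del, ed$src)
  dSd <- rowsum(del, ed$tgt)
  dQ <- dQ_src + dSs %*% t(fw$As) + dSd %*% t(fw$Ad)
  cps <- crossprod(fw$Q, dSs)                          # width x heads
  cpd <- crossprod(fw$Q, dSd)
  das <- numeric(ncol(fw$Q)); dad <- numeric(ncol(fw$Q))
  for (h in seq_len(n_heads)) {
    idx <- (h - 1L) * dh + seq_len(dh)
    das[idx] <- cps[idx, h]
    dad[idx] <- cpd[idx, h]
  }
  dW <- crossprod(fw$X, dQ)
  dX <- dQ %*% t(fw$W)
  list(dW = dW, das = das, dad = dad, dX = dX)
}

gat_forward <- function(net, X, ed, keep = FALSE) {
  fws <- vector("list", net$n_layers)
  H <- X
  for (l in seq_len(net$n_layers)) {
    fw <- gat_layer_forward(H, net$params[[paste0("W", l)]],
                            net$params[[paste0("as", l)]],
                            net$params[[paste0("ad", l)]], ed, net$n_heads)
    fws[[l]] <- fw
    H <- fw$out
  }
  logits <- sweep(H %*% net$params$Wh, 2, net$params$bh, "+")
  out <- list(logits = logits, H = H)
  if (keep) out$fws <- fws
  out
}

gat_backward <- function(net, fw, dLogits, ed) {
  grads <- list()
  grads$Wh <- crossprod(fw$H, dLogits)
  grads$bh <- colSums(dLogits)
  dH <- dLogits %*% t(net$params$Wh)
  for (l in rev(seq_len(net$n_layers))) {
    g <- gat_layer_backward(fw$fws[[l]], dH, ed, net$n_heads)
    grads[[paste0("W", l)]] <- g$dW
    grads[[paste0("as", l)]] <- g$das
    grads[[paste0("ad", l)]] <- g$dad
    dH <- g$dX
  }
  grads
}

#' Train a graph attention model on frozen patch embeddings
#'
#' Stacks `n_layers` graph-attention layers (multi-head, attention weights
#' softmax-normalised over each node's neighbourhood including a self edge)
#' over the fixed spot graph, followed by the same multi-gene head as the
#' local model. Embeddings are standardised per feature using training-set
#' statistics and are not updated. Training is full-batch Adam and is
#' deterministic given `cfg$seed`. `n_layers = 0` degenerates to a linear
#' head on the embeddings, with no graph dependence.
#'
#' @param embeddings numeric matrix, spots x features (penultimate-layer
#'   activations of a trained local model).
#' @param graph a `spot_graph` over the same spots.
#' @param targets `binary_targets` or a counts matrix, aligned to rows.
#' @param objective `"binary"` or `"zinb"`.
#' @param n_layers number of attention layers (0, 1, 2 or 4 are typical).
#' @param n_heads attention heads per layer (default 8).
#' @param cfg list: `epochs` (full-batch steps, default 300), `lr` (5e-3),
#'   `width` (64), `seed` (1), `verbose` (FALSE).
#' @return A `spotsight_model`.
#' @export
train_gat <- function(embeddings, graph, targets,
                      objective = c("binary", "zinb"),
                      n_layers = 1L, n_heads = 8L, cfg = list()) {
  objective <- match.arg(objective)
  cfg <- utils::modifyList(
    list(epochs = 300L, lr = 5e-3, width = 64L, seed = 1L, verbose = FALSE),
    cfg
  )
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) != graph$n)
    stop_invalid("embeddings rows (%d) do not match graph nodes (%d)",
                 nrow(embeddings), graph$n)
  if (objective == "binary") {
    if (!inherits(targets, "binary_targets"))
      stop_invalid("binary objective requires binary_targets")
    y <- targets$labels
  } else {
    y <- as.matrix(targets)
    if (any(y < 0) || any(y != round(y)))
      stop_invalid("zinb objective requires non-negative integer counts")
  }
  if (nrow(y) != nrow(embeddings))
    stop_invalid("targets are not aligned with embeddings")
  G <- ncol(y)
  n_out <- if (objective == "binary") G else 3L * G

  mu <- colMeans(embeddings)
  sd <- apply(embeddings, 2, stats::sd)
  sd[sd < 1e-8] <- 1
  X <- sweep(sweep(embeddings, 2, mu), 2, sd, "/")
  ed <- gat_edges(graph)

  net <- with_seed(cfg$seed,
                   gat_init(ncol(X), n_out, n_layers, n_heads, cfg$width))
  opt <- adam_new(net$params)
  losses <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    fw <- gat_forward(net, X, ed, keep = TRUE)
    hd <- if (objective == "binary") bce_head(fw$logits, y)
          else zinb_head(fw$logits, y)
    grads <- gat_backward(net, fw, hd$dLogits, ed)
    upd <- adam_step(net$params, grads, opt, cfg$lr)
    net$params <- upd$params; opt <- upd$state
    losses[ep] <- hd$loss
    if (cfg$verbose && ep %% 50 == 0)
      message(sprintf("step %d/%d: loss %.4f", ep, cfg$epochs, losses[ep]))
  }

  structure(
    list(type = "gat", net = net, objective = objective,
         gene_ids = colnames(y), cfg = cfg, losses = losses,
         scale = list(mu = mu, sd = sd), n_layers = n_layers,
         n_heads = n_heads),
    class = "spotsight_model"
  )
}

gat_predict <- function(model, embeddings, graph) {
  X <- sweep(sweep(as.matrix(embeddings), 2, model$scale$mu), 2,
             model$scale$sd, "/")
  if (nrow(X) != graph$n)
    stop_invalid("embeddings rows do not match graph nodes")
  ed <- gat_edges(graph)
  fw <- gat_forward(model$net, X, ed)
  logits <- fw$logits
  rownames(logits) <- graph$spot_id
  finish_response(model, logits)
}

#' Attention weights of a trained graph model
#'
#' Returns, per layer and head, the attention weight on every directed edge
#' (self edges included); weights over each node's incident edges sum to 1.
#'
#' @param model a `spotsight_model` of type `gat`.
#' @param embeddings,graph the inputs to attend over.
#' @return List per layer with `src`, `tgt`, and an `E x heads` weight
#'   matrix.
#' @export
gat_attention <- function(model, embeddings, graph) {
  X <- sweep(sweep(as.matrix(embeddings), 2, model$scale$mu), 2,
             model$scale$sd, "/")
  ed <- gat_edges(graph)
  fw <- gat_forward(model$net, X, ed, keep = TRUE)
  lapply(fw$fws, function(f)
    list(src = ed$src, tgt = ed$tgt, alpha = f$alpha))
}
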