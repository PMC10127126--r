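## Minimal neural-network machinery: 3x3 convolutions via im2col + BLAS,
## dense layers, Adam. Written for CPU-sized problems; shapes are fixed per
## model so gather/scatter index tables are precomputed and cached.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

## ---- Adam ----------------------------------------------------------------

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

## ---- conv layer (kernel 3x3, pad 1, arbitrary stride) ---------------------

conv_spec <- function(H, W, C_in, C_out, stride = 2L) {
  OH <- (H + 2L - 3L) %/% stride + 1L
  OW <- (W + 2L - 3L) %/% stride + 1L
  list(H = H, W = W, C_in = C_in, C_out = C_out, stride = stride,
       Hp = H + 2L, Wp = W + 2L, OH = OH, OW = OW,
       cache = new.env(parent = emptyenv()))
}

## im2col gather template and col2im scatter plan for batch size B
conv_plan <- function(sp, B) {
  key <- as.character(B)
  if (!is.null(sp$cache[[key]])) return(sp$cache[[key]])
  OH <- sp$OH; OW <- sp$OW; s <- sp$stride
  n0 <- OH * OW
  oh <- rep(0:(OH - 1L), times = OW)
  ow <- rep(0:(OW - 1L), each = OH)
  Tm <- matrix(0L, n0, 9L * sp$C_in)
  for (c0 in 0:(sp$C_in - 1L)) for (kw in 0:2) for (kh in 0:2) {
    j <- kh + 3L * kw + 9L * c0 + 1L
    Tm[, j] <- (oh * s + kh) + sp$Hp * (ow * s + kw) +
      sp$Hp * sp$Wp * c0 + 1L
  }
  img_len <- sp$Hp * sp$Wp * sp$C_in
  Tb <- Tm[rep.int(seq_len(n0), B), , drop = FALSE] +
    rep(0:(B - 1L) * img_len, each = n0)
  tv <- as.vector(Tb)
  o <- order(tv)
  srt <- tv[o]
  ends <- which(c(srt[-1L] != srt[-length(srt)], TRUE))
  plan <- list(B = B, n0 = n0, tv = tv, o = o, ends = ends, u = srt[ends],
               plen = img_len * B)
  sp$cache[[key]] <- plan
  plan
}

## X: array vector (H, W, C_in, B); returns list(out = (OH,OW,C_out,B) array,
## Xcol cached for backward)
conv_forward <- function(sp, K, bias, X, B) {
  pl <- conv_plan(sp, B)
  Xpad <- array(0, c(sp$Hp, sp$Wp, sp$C_in, B))
  Xpad[2:(sp$H + 1L), 2:(sp$W + 1L), , ] <- X
  Xcol <- Xpad[pl$tv]
  dim(Xcol) <- c(pl$n0 * B, 9L * sp$C_in)
  Y <- Xcol %*% K
  Y <- sweep(Y, 2, bias, "+")
  dim(Y) <- c(pl$n0, B, sp$C_out)
  out <- aperm(Y, c(1, 3, 2))
  dim(out) <- c(sp$OH, sp$OW, sp$C_out, B)
  list(out = out, Xcol = Xcol)
}

## dOut: array (OH,OW,C_out,B); returns grads and (optionally) dX
conv_backward <- function(sp, K, Xcol, dOut, B, need_dx = TRUE) {
  pl <- conv_plan(sp, B)
  dim(dOut) <- c(pl$n0, sp$C_out, B)
  dY <- aperm(dOut, c(1, 3, 2))
  dim(dY) <- c(pl$n0 * B, sp$C_out)
  dK <- crossprod(Xcol, dY)
  db <- colSums(dY)
  dX <- NULL
  if (need_dx) {
    dXcol <- tcrossprod(dY, K)
    v <- dXcol[pl$o]
    cs <- cumsum(v)
    segs <- cs[pl$ends] - c(0, cs[pl$ends[-length(pl$ends)]])
    dPvec <- numeric(pl$plen)
    dPvec[pl$u] <- segs
    dPad <- array(dPvec, c(sp$Hp, sp$Wp, sp$C_in, B))
    dX <- dPad[2:(sp$H + 1L), 2:(sp$W + 1L), , , drop = FALSE]
  }
  list(dK = dK, db = db, dX = dX)
}

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}
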