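# Minimal neural-network primitives used by the diffusion denoiser and the
# strength regressors: parameter init, Adam, 1-D convolution over stacked
# sequence blocks, layer norm, softmax, sinusoidal timestep features.
# All tensors are 2-D: a batch of B sequences of length L lives in a
# (B*L) x C matrix of contiguous row blocks.

nnInit <- function(nin, nout, scale = 1) {
  matrix(stats::rnorm(nin * nout, sd = scale * sqrt(2 / nin)), nin, nout)
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr = 1e-3,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / c1) / (sqrt(state$v[[k]] / c2) + eps)
  }
  list(params = params, state = state)
}

relu <- function(x) (x > 0) * x

softmaxRows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

# Same-padded 1-D convolution over B stacked L-row blocks; W is a
# (K*Cin) x Cout matrix of K stacked taps. Hot loops live in src/.
convForward <- function(X, W, b, B, L) {
  .conv1dForwardCpp(X, W, b, as.integer(B), as.integer(L))
}

convBackward <- function(dOut, X, W, B, L) {
  .conv1dBackwardCpp(dOut, X, W, as.integer(B), as.integer(L))
}

# Batched multi-head attention over B blocks of L rows; heads are
# contiguous column groups of Q/K/V.
mhaForward <- function(Q, K, V, B, L, nh) {
  .mhaForwardCpp(Q, K, V, as.integer(B), as.integer(L), as.integer(nh))
}

mhaBackward <- function(dO, Q, K, V, A, B, L, nh) {
  .mhaBackwardCpp(dO, Q, K, V, A, as.integer(B), as.integer(L),
                  as.integer(nh))
}

# Sinusoidal features of (integer) timesteps, one row per timestep.
timeEmbedding <- function(t, dim) {
  half <- dim %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1L) / max(1L, half - 1L))
  ang <- outer(t, freqs)
  cbind(sin(ang), cos(ang))[, seq_len(dim), drop = FALSE]
}

rowMeansFast <- function(X) drop(X %*% rep.int(1 / ncol(X), ncol(X)))

lnForward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeansFast(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeansFast(xc * xc) + eps)
  xhat <- xc * inv
  list(out = xhat * rep(g, each = nrow(X)) + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

lnBackward <- function(dOut, cache, g) {
  xhat <- cache$xhat
  dxhat <- dOut * rep(g, each = nrow(dOut))
  dX <- cache$inv * (dxhat - rowMeansFast(dxhat) -
                       xhat * rowMeansFast(dxhat * xhat))
  list(dX = dX, dg = colSums(dOut * xhat), db = colSums(dOut))
}
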