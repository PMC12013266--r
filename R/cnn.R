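# Convolutional baseline regressor: one-hot input, two same-padded conv
# layers with ReLU, a position-wise linear readout, trained with the same
# combined MSE + (1 - PCC) loss and evaluation pathway as the transformer.

#' Configuration for the CNN baseline predictor
#'
#' @param hidden Channel width of the two convolution layers.
#' @param kernel Convolution kernel width (odd).
#' @param wMse,wPcc Loss weights (see [combinedLoss()]).
#' @param lr Adam learning rate.
#' @param epochs Maximum training epochs.
#' @param batchSize Minibatch size (>= 2).
#' @param valFraction Held-out fraction for early stopping.
#' @param patience Early-stopping patience (0 disables).
#' @param pseudocount Passed to [logTransform()].
#' @param seed Integer seed.
#' @return A named list of settings for [trainCNNBaseline()].
#' @export
cnnConfig <- function(hidden = 32L, kernel = 7L, wMse = 1, wPcc = 1,
                      lr = 1e-3, epochs = 50L, batchSize = 64L,
                      valFraction = 0.1, patience = 20L,
                      pseudocount = NULL, seed = 1L) {
  if (kernel %% 2L != 1L) stop("kernel must be odd", call. = FALSE)
  if (batchSize < 2L) stop("batchSize must be >= 2", call. = FALSE)
  list(hidden = as.integer(hidden), kernel = as.integer(kernel),
       wMse = wMse, wPcc = wPcc, lr = lr, epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), valFraction = valFraction,
       patience = as.integer(patience), pseudocount = pseudocount,
       seed = as.integer(seed))
}

cnnInitParams <- function(L, cfg) {
  H <- cfg$hidden; K <- cfg$kernel
  list(cw1 = nnInit(K * 4L, H) / sqrt(K), cb1 = numeric(H),
       cw2 = nnInit(K * H, H) / sqrt(K), cb2 = numeric(H),
       Wpos = nnInit(L, H, scale = 0.5) * 0.1,
       bhead = 0)
}

cnnForward <- function(p, X, L, keepCache = FALSE) {
  B <- nrow(X) %/% L
  posIdx <- rep(seq_len(L), B)
  c1 <- convForward(X, p$cw1, p$cb1, B, L)
  h1 <- relu(c1)
  c2 <- convForward(h1, p$cw2, p$cb2, B, L)
  h2 <- relu(c2)
  pred <- drop(rowsum(rowSums(h2 * p$Wpos[posIdx, , drop = FALSE]),
                      rep(seq_len(B), each = L))) + p$bhead
  if (keepCache)
    list(pred = pred, cache = list(X = X, m1 = c1 > 0, h1 = h1,
                                   m2 = c2 > 0, h2 = h2, posIdx = posIdx))
  else pred
}

cnnBackward <- function(p, cache, dPred, L) {
  B <- length(dPred)
  dRow <- rep(dPred, each = L)
  Wp <- p$Wpos[cache$posIdx, , drop = FALSE]
  g <- list(Wpos = rowsum(cache$h2 * dRow, cache$posIdx),
            bhead = sum(dPred))
  dh2 <- (Wp * dRow) * cache$m2
  cb2 <- convBackward(dh2, cache$h1, p$cw2, B, L)
  g$cw2 <- cb2$dW; g$cb2 <- drop(cb2$db)
  dh1 <- cb2$dX * cache$m1
  cb1 <- convBackward(dh1, cache$X, p$cw1, B, L)
  g$cw1 <- cb1$dW; g$cb1 <- drop(cb1$db)
  g
}

#' Train the convolutional baseline strength predictor
#'
#' The reference point for the transformer: the same normalization, loss
#' and evaluation pathway, but one-hot input processed by a small 1-D
#' convolutional network instead of token embeddings and self-attention.
#'
#' @param x A labelled \linkS4class{PromoterSet}.
#' @param config A list from [cnnConfig()].
#' @param verbose Print held-out loss every 10 epochs.
#' @return A \linkS4class{CNNPredictor}.
#' @seealso [trainPredictor()], [evaluatePredictor()]
#' @export
trainCNNBaseline <- function(x, config = cnnConfig(), verbose = FALSE) {
  stopifnot(is(x, "PromoterSet"))
  if (!hasStrength(x))
    stop("every record needs a strength to train the predictor",
         call. = FALSE)
  seqs <- asSequenceVector(x)
  L <- nchar(seqs[1L])
  cfg <- config
  nm <- minMaxNormalize(logTransform(promoterStrengths(x), cfg$pseudocount))
  y <- nm$values
  n <- length(seqs)
  Xall <- stackOneHot(seqs)
  withSeed(cfg$seed, {
    p <- cnnInitParams(L, cfg)
    opt <- adamInit(p)
    nVal <- if (n >= 10L) max(2L, round(n * cfg$valFraction)) else 0L
    valIdx <- if (nVal) sample.int(n, nVal) else integer(0)
    trIdx <- setdiff(seq_len(n), valIdx)
    valRows <- as.vector(outer(seq_len(L), (valIdx - 1L) * L, "+"))
    best <- list(loss = Inf, params = p)
    bad <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(trIdx)
      for (start in seq(1L, length(ord), by = cfg$batchSize)) {
        sel <- ord[start:min(length(ord), start + cfg$batchSize - 1L)]
        if (length(sel) < 2L) next
        rows <- as.vector(outer(seq_len(L), (sel - 1L) * L, "+"))
        fw <- cnnForward(p, Xall[rows, , drop = FALSE], L,
                         keepCache = TRUE)
        lg <- lossAndGrad(fw$pred, y[sel], cfg$wMse, cfg$wPcc)
        if (!is.finite(lg$loss))
          stop("training diverged at epoch ", epoch, call. = FALSE)
        gr <- cnnBackward(p, fw$cache, lg$grad, L)
        upd <- adamStep(p, gr, opt, lr = cfg$lr)
        p <- upd$params; opt <- upd$state
      }
      if (nVal) {
        pv <- cnnForward(p, Xall[valRows, , drop = FALSE], L)
        vl <- lossAndGrad(pv, y[valIdx], cfg$wMse, cfg$wPcc)$loss
        if (verbose && epoch %% 10L == 0L)
          message(sprintf("epoch %d: held-out loss %.4f", epoch, vl))
        if (vl < best$loss - 1e-6) {
          best <- list(loss = vl, params = p); bad <- 0L
        } else {
          bad <- bad + 1L
          if (cfg$patience > 0L && bad >= cfg$patience) break
        }
      } else best$params <- p
    }
    new("CNNPredictor", params = best$params, norm = nm$params,
        config = cfg, seqLength = as.integer(L))
  })
}

setMethod("predictCore", "CNNPredictor", function(model, seqs) {
  L <- model@seqLength
  out <- numeric(length(seqs))
  chunk <- 512L
  for (start in seq(1L, length(seqs), by = chunk)) {
    sel <- start:min(length(seqs), start + chunk - 1L)
    X <- stackOneHot(seqs[sel])
    out[sel] <- cnnForward(model@params, X, L)
  }
  out
})
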