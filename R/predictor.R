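#' Scaled dot-product self-attention
#'
#' The attention primitive of the transformer encoder: similarity scores
#' \eqn{QK^\top/\sqrt{d_k}} (optionally masked), row-wise softmax to
#' weights summing to 1, then a weighted sum of the value rows.
#'
#' @param Q,K n x d_k query and key matrices.
#' @param V n x d_v value matrix.
#' @param mask Optional n x n logical matrix; `FALSE` entries are excluded
#'   from attention (score set to -Inf before the softmax). Every row must
#'   keep at least one admissible position.
#' @return An n x d_v matrix. The attention weight matrix is attached as
#'   attribute `"weights"`.
#' @examples
#' Q <- matrix(0, 2, 2); V <- matrix(1:4, 2, 2)
#' selfAttention(Q, Q, V)   # uniform weights: each row = column means of V
#' @export
selfAttention <- function(Q, K, V, mask = NULL) {
  if (!is.matrix(Q) || !is.matrix(K) || !is.matrix(V))
    stop("Q, K, V must be matrices", call. = FALSE)
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V) || nrow(Q) != nrow(K))
    stop("non-conformable Q/K/V shapes", call. = FALSE)
  S <- Q %*% t(K) / sqrt(ncol(Q))
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(S)))
      stop("mask must be n x n", call. = FALSE)
    if (any(rowSums(mask) == 0))
      stop("mask leaves a fully-excluded row", call. = FALSE)
    S[!mask] <- -Inf
  }
  A <- softmaxRows(S)
  out <- A %*% V
  attr(out, "weights") <- A
  out
}

#' Pearson correlation coefficient
#'
#' Direct evaluation of
#' \deqn{r = \frac{\sum_i (X_i-\bar X)(Y_i-\bar Y)}
#' {\sqrt{\sum_i (X_i-\bar X)^2}\sqrt{\sum_i (Y_i-\bar Y)^2}},}
#' ranging from -1 to 1. Used both as an evaluation metric and inside the
#' training loss. Constant input is an explicit error rather than a silent
#' zero, so degenerate model output surfaces to the caller.
#'
#' @param x,y Equal-length numeric vectors (n >= 2), both non-constant.
#' @return The correlation, a number in [-1, 1].
#' @examples
#' pcc(c(1, 2, 3), c(3, 2, 1))   # -1
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2", call. = FALSE)
  u <- x - mean(x); v <- y - mean(y)
  suu <- sum(u * u); svv <- sum(v * v)
  if (suu == 0 || svv == 0)
    stop("degenerate variance: constant input to pcc", call. = FALSE)
  sum(u * v) / sqrt(suu * svv)
}

#' Combined MSE + Pearson-correlation training loss
#'
#' \deqn{L = w_{mse}\,\mathrm{MSE}(p, y) + w_{pcc}\,(1 - r(p, y)),}
#' the regression loss combining accuracy of magnitudes with linear
#' agreement of the ranking. When the predictions are constant the
#' correlation term is undefined; the loss falls back to MSE alone for
#' that batch with a warning, which avoids NaN poisoning early in
#' training.
#'
#' @param pred,target Equal-length numeric vectors (n >= 2).
#' @param wMse,wPcc Nonnegative term weights (not both zero); equal
#'   weighting is the default.
#' @return A single nonnegative number; 0 iff `pred == target` (given
#'   `wMse > 0`).
#' @export
combinedLoss <- function(pred, target, wMse = 1, wPcc = 1) {
  if (length(pred) != length(target) || length(pred) < 2L)
    stop("pred and target must have equal length >= 2", call. = FALSE)
  if (wMse < 0 || wPcc < 0 || (wMse == 0 && wPcc == 0))
    stop("weights must be nonnegative and not both zero", call. = FALSE)
  loss <- wMse * mean((pred - target)^2)
  if (wPcc > 0) {
    u <- pred - mean(pred)
    if (sum(u * u) == 0 || stats::sd(target) == 0) {
      warning("constant batch: PCC term skipped, MSE-only loss")
    } else {
      loss <- loss + wPcc * (1 - pcc(pred, target))
    }
  }
  loss
}

# loss value + gradient wrt pred, shared by both regressors
lossAndGrad <- function(pred, y, wMse, wPcc) {
  B <- length(pred)
  resid <- pred - y
  loss <- wMse * mean(resid^2)
  grad <- wMse * 2 * resid / B
  pccSkipped <- FALSE
  if (wPcc > 0) {
    u <- pred - mean(pred); v <- y - mean(y)
    suu <- sum(u * u); svv <- sum(v * v)
    if (suu > 1e-12 && svv > 1e-12) {
      denom <- sqrt(suu * svv)
      r <- sum(u * v) / denom
      loss <- loss + wPcc * (1 - r)
      grad <- grad - wPcc * (v - u * sum(u * v) / suu) / denom
    } else pccSkipped <- TRUE
  }
  list(loss = loss, grad = grad, pccSkipped = pccSkipped)
}

#' Configuration for the transformer strength predictor
#'
#' Defaults: model width 64 split over 4 attention heads, 2 encoder
#' layers with feed-forward width 128, dropout 0.1, mean pooling, equal
#' MSE and PCC loss weights, Adam at 1e-3 with early stopping (patience
#' 20 epochs on the held-out loss).
#'
#' @param dModel Embedding/model width (divisible by `heads`).
#' @param heads Number of attention heads.
#' @param layers Encoder layers.
#' @param ff Feed-forward hidden width.
#' @param dropout Dropout rate on sublayer outputs.
#' @param wMse,wPcc Loss weights (see [combinedLoss()]).
#' @param lr Adam learning rate.
#' @param epochs Maximum training epochs.
#' @param batchSize Minibatch size (>= 2; the PCC term needs a batch).
#' @param valFraction Fraction of the training set held out for early
#'   stopping.
#' @param patience Early-stopping patience in epochs (0 disables).
#' @param pseudocount Passed to [logTransform()] for the strength
#'   normalization (`NULL` = strict positivity).
#' @param seed Integer seed.
#' @return A named list of settings for [trainPredictor()].
#' @export
predictorConfig <- function(dModel = 64L, heads = 4L, layers = 2L,
                            ff = 128L, dropout = 0.1, wMse = 1, wPcc = 1,
                            lr = 1e-3, epochs = 50L, batchSize = 64L,
                            valFraction = 0.1, patience = 20L,
                            pseudocount = NULL, seed = 1L) {
  if (dModel %% heads != 0L)
    stop("dModel must be divisible by heads", call. = FALSE)
  if (wMse < 0 || wPcc < 0 || (wMse == 0 && wPcc == 0))
    stop("loss weights must be nonnegative and not both zero", call. = FALSE)
  if (batchSize < 2L) stop("batchSize must be >= 2", call. = FALSE)
  list(dModel = as.integer(dModel), heads = as.integer(heads),
       dK = as.integer(dModel %/% heads), layers = as.integer(layers),
       ff = as.integer(ff), dropout = dropout, wMse = wMse, wPcc = wPcc,
       lr = lr, epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), valFraction = valFraction,
       patience = as.integer(patience), pseudocount = pseudocount,
       seed = as.integer(seed))
}

# ---- transformer internals -------------------------------------------------

tfInitParams <- function(L, cfg) {
  d <- cfg$dModel
  p <- list(Eseq = nnInit(4L, d) * 0.5,
            Edi  = nnInit(20L, d) * 0.5,
            Epos = nnInit(L, d) * 0.5)
  for (l in seq_len(cfg$layers)) {
    pre <- paste0("l", l, "_")
    p[[paste0(pre, "ln1g")]] <- rep(1, d)
    p[[paste0(pre, "ln1b")]] <- rep(0, d)
    p[[paste0(pre, "Wq")]] <- nnInit(d, d, scale = 0.5)
    p[[paste0(pre, "Wk")]] <- nnInit(d, d, scale = 0.5)
    p[[paste0(pre, "Wv")]] <- nnInit(d, d, scale = 0.5)
    p[[paste0(pre, "Wo")]] <- nnInit(d, d, scale = 0.5)
    p[[paste0(pre, "bo")]] <- rep(0, d)
    p[[paste0(pre, "ln2g")]] <- rep(1, d)
    p[[paste0(pre, "ln2b")]] <- rep(0, d)
    p[[paste0(pre, "W1")]] <- nnInit(d, cfg$ff)
    p[[paste0(pre, "b1")]] <- rep(0, cfg$ff)
    p[[paste0(pre, "W2")]] <- nnInit(cfg$ff, d, scale = 0.5)
    p[[paste0(pre, "b2")]] <- rep(0, d)
  }
  p$lnfg <- rep(1, d); p$lnfb <- rep(0, d)
  p$Whead <- nnInit(d, 1L, scale = 0.5)
  p$bhead <- 0
  p
}

# tok: list of integer vectors (flattened over B blocks of L): seq in 0..3,
# dinuc in 0..19 relative to 4, pos in 0..L-1.
tfForward <- function(p, tok, B, L, cfg, training = FALSE,
                      keepCache = FALSE) {
  d <- cfg$dModel; nh <- cfg$heads; dk <- cfg$dK
  X <- p$Eseq[tok$seq + 1L, , drop = FALSE] +
       p$Edi[tok$dinuc + 1L, , drop = FALSE] +
       p$Epos[tok$pos + 1L, , drop = FALSE]
  n <- B * L
  cache <- if (keepCache) list(layers = vector("list", cfg$layers))
  dropMask <- function() {
    if (training && cfg$dropout > 0)
      matrix((stats::runif(n * d) >= cfg$dropout) / (1 - cfg$dropout), n, d)
    else NULL
  }
  for (l in seq_len(cfg$layers)) {
    pre <- paste0("l", l, "_")
    ln1 <- lnForward(X, p[[paste0(pre, "ln1g")]], p[[paste0(pre, "ln1b")]])
    Q <- ln1$out %*% p[[paste0(pre, "Wq")]]
    K <- ln1$out %*% p[[paste0(pre, "Wk")]]
    V <- ln1$out %*% p[[paste0(pre, "Wv")]]
    att <- mhaForward(Q, K, V, B, L, nh)
    O <- att$O
    M <- O %*% p[[paste0(pre, "Wo")]] +
      matrix(p[[paste0(pre, "bo")]], n, d, byrow = TRUE)
    m1 <- dropMask()
    Xmid <- X + if (is.null(m1)) M else M * m1
    ln2 <- lnForward(Xmid, p[[paste0(pre, "ln2g")]], p[[paste0(pre, "ln2b")]])
    F1pre <- ln2$out %*% p[[paste0(pre, "W1")]] +
      matrix(p[[paste0(pre, "b1")]], n, cfg$ff, byrow = TRUE)
    F1 <- relu(F1pre)
    F2 <- F1 %*% p[[paste0(pre, "W2")]] +
      matrix(p[[paste0(pre, "b2")]], n, d, byrow = TRUE)
    m2 <- dropMask()
    Xout <- Xmid + if (is.null(m2)) F2 else F2 * m2
    if (keepCache)
      cache$layers[[l]] <- list(ln1 = ln1, ln1out = ln1$out, Q = Q, K = K,
                                V = V, A = att$A, O = O, m1 = m1,
                                ln2 = ln2, ln2out = ln2$out,
                                reluMask = F1pre > 0, F1 = F1, m2 = m2)
    X <- Xout
  }
  lnf <- lnForward(X, p$lnfg, p$lnfb)
  group <- rep(seq_len(B), each = L)
  pool <- rowsum(lnf$out, group) / L
  pred <- drop(pool %*% p$Whead) + p$bhead
  if (keepCache) {
    cache$lnf <- lnf; cache$pool <- pool; cache$group <- group
    list(pred = pred, cache = cache)
  } else pred
}

tfBackward <- function(p, tok, cache, dPred, B, L, cfg) {
  d <- cfg$dModel; nh <- cfg$heads; dk <- cfg$dK
  n <- B * L
  g <- list(Whead = crossprod(cache$pool, matrix(dPred)),
            bhead = sum(dPred))
  dPool <- matrix(dPred) %*% t(p$Whead)
  dLnfOut <- dPool[cache$group, , drop = FALSE] / L
  lb <- lnBackward(dLnfOut, cache$lnf, p$lnfg)
  g$lnfg <- lb$dg; g$lnfb <- lb$db
  dX <- lb$dX
  for (l in rev(seq_len(cfg$layers))) {
    pre <- paste0("l", l, "_")
    cl <- cache$layers[[l]]
    # FFN sublayer
    dF2 <- if (is.null(cl$m2)) dX else dX * cl$m2
    g[[paste0(pre, "W2")]] <- crossprod(cl$F1, dF2)
    g[[paste0(pre, "b2")]] <- colSums(dF2)
    dF1 <- (dF2 %*% t(p[[paste0(pre, "W2")]])) * cl$reluMask
    g[[paste0(pre, "W1")]] <- crossprod(cl$ln2out, dF1)
    g[[paste0(pre, "b1")]] <- colSums(dF1)
    lb2 <- lnBackward(dF1 %*% t(p[[paste0(pre, "W1")]]), cl$ln2,
                      p[[paste0(pre, "ln2g")]])
    g[[paste0(pre, "ln2g")]] <- lb2$dg
    g[[paste0(pre, "ln2b")]] <- lb2$db
    dXmid <- dX + lb2$dX
    # attention sublayer
    dM <- if (is.null(cl$m1)) dXmid else dXmid * cl$m1
    g[[paste0(pre, "Wo")]] <- crossprod(cl$O, dM)
    g[[paste0(pre, "bo")]] <- colSums(dM)
    dO <- dM %*% t(p[[paste0(pre, "Wo")]])
    ab <- mhaBackward(dO, cl$Q, cl$K, cl$V, cl$A, B, L, nh)
    dQ <- ab$dQ; dK <- ab$dK; dV <- ab$dV
    g[[paste0(pre, "Wq")]] <- crossprod(cl$ln1out, dQ)
    g[[paste0(pre, "Wk")]] <- crossprod(cl$ln1out, dK)
    g[[paste0(pre, "Wv")]] <- crossprod(cl$ln1out, dV)
    dLn1Out <- dQ %*% t(p[[paste0(pre, "Wq")]]) +
      dK %*% t(p[[paste0(pre, "Wk")]]) +
      dV %*% t(p[[paste0(pre, "Wv")]])
    lb1 <- lnBackward(dLn1Out, cl$ln1, p[[paste0(pre, "ln1g")]])
    g[[paste0(pre, "ln1g")]] <- lb1$dg
    g[[paste0(pre, "ln1b")]] <- lb1$db
    dX <- dXmid + lb1$dX
  }
  embGrad <- function(tokens, nRows) {
    out <- matrix(0, nRows, d)
    rs <- rowsum(dX, tokens)
    out[as.integer(rownames(rs)) + 1L, ] <- rs
    out
  }
  g$Eseq <- embGrad(tok$seq, 4L)
  g$Edi <- embGrad(tok$dinuc, 20L)
  g$Epos <- embGrad(tok$pos, L)
  g
}

tokenizeSet <- function(seqs) {
  L <- nchar(seqs[1L])
  seqTok <- integer(0); diTok <- integer(0)
  seqTok <- unlist(lapply(seqs, encodeSequenceTokens), use.names = FALSE)
  diTok <- unlist(lapply(seqs, encodeDinucleotideTokens), use.names = FALSE) - 4L
  posTok <- rep.int(encodePositionTokens(L), length(seqs))
  list(seq = seqTok, dinuc = diTok, pos = posTok)
}

tokSubset <- function(tok, sel, L) {
  rows <- as.vector(outer(seq_len(L), (sel - 1L) * L, "+"))
  list(seq = tok$seq[rows], dinuc = tok$dinuc[rows], pos = tok$pos[rows])
}

#' Train the transformer-encoder strength predictor
#'
#' Fits the three-stream token encoding (sequence, dinucleotide, position;
#' see [encodeSequenceTokens()]) through summed learned embeddings, a
#' stack of pre-norm transformer encoder layers (multi-head scaled
#' dot-product self-attention plus a position-wise feed-forward network),
#' mean pooling over positions and a linear regression head, minimizing
#' the combined MSE + (1 - PCC) loss on min-max-normalized log10
#' strengths. Strength normalization parameters are fitted on the training
#' set and stored in the model for inverse transformation.
#'
#' @param x A labelled \linkS4class{PromoterSet} (every record needs a
#'   strength).
#' @param config A list from [predictorConfig()].
#' @param verbose Print held-out loss every 10 epochs.
#' @return A \linkS4class{TransformerPredictor}.
#' @seealso [predictStrength()], [evaluatePredictor()],
#'   [trainCNNBaseline()]
#' @export
trainPredictor <- function(x, config = predictorConfig(), verbose = FALSE) {
  stopifnot(is(x, "PromoterSet"))
  if (!hasStrength(x))
    stop("every record needs a strength to train the predictor",
         call. = FALSE)
  seqs <- asSequenceVector(x)
  L <- nchar(seqs[1L])
  cfg <- config
  nm <- minMaxNormalize(logTransform(promoterStrengths(x), cfg$pseudocount))
  y <- nm$values
  tok <- tokenizeSet(seqs)
  n <- length(seqs)
  withSeed(cfg$seed, {
    p <- tfInitParams(L, cfg)
    opt <- adamInit(p)
    nVal <- if (n >= 10L) max(2L, round(n * cfg$valFraction)) else 0L
    valIdx <- if (nVal) sample.int(n, nVal) else integer(0)
    trIdx <- setdiff(seq_len(n), valIdx)
    best <- list(loss = Inf, params = p, epoch = 0L)
    bad <- 0L
    pccSkips <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(trIdx)
      for (start in seq(1L, length(ord), by = cfg$batchSize)) {
        sel <- ord[start:min(length(ord), start + cfg$batchSize - 1L)]
        if (length(sel) < 2L) next
        tb <- tokSubset(tok, sel, L)
        fw <- tfForward(p, tb, length(sel), L, cfg, training = TRUE,
                        keepCache = TRUE)
        lg <- lossAndGrad(fw$pred, y[sel], cfg$wMse, cfg$wPcc)
        if (!is.finite(lg$loss))
          stop("training diverged at epoch ", epoch, call. = FALSE)
        if (lg$pccSkipped) pccSkips <- pccSkips + 1L
        gr <- tfBackward(p, tb, fw$cache, lg$grad, length(sel), L, cfg)
        upd <- adamStep(p, gr, opt, lr = cfg$lr)
        p <- upd$params; opt <- upd$state
      }
      if (nVal) {
        tv <- tokSubset(tok, valIdx, L)
        pv <- tfForward(p, tv, nVal, L, cfg)
        vl <- lossAndGrad(pv, y[valIdx], cfg$wMse, cfg$wPcc)$loss
        if (verbose && epoch %% 10L == 0L)
          message(sprintf("epoch %d: held-out loss %.4f", epoch, vl))
        if (vl < best$loss - 1e-6) {
          best <- list(loss = vl, params = p, epoch = epoch)
          bad <- 0L
        } else {
          bad <- bad + 1L
          if (cfg$patience > 0L && bad >= cfg$patience) break
        }
      } else best$params <- p
    }
    if (pccSkips > 0L)
      warning(pccSkips,
        " constant-prediction batch(es): PCC loss term skipped for those")
    new("TransformerPredictor", params = best$params, norm = nm$params,
        config = cfg, seqLength = as.integer(L))
  })
}

#' @rdname predictStrength
#' @export
setMethod("predictStrength", "StrengthPredictor",
  function(model, sequences, scale = c("normalized", "raw")) {
    scale <- match.arg(scale)
    seqs <- asSequenceVector(sequences)
    L <- nchar(seqs[1L])
    if (L != model@seqLength)
      stop("sequence length ", L, " does not match training length ",
           model@seqLength, call. = FALSE)
    pred <- predictCore(model, seqs)
    names(pred) <- if (is(sequences, "PromoterSet")) names(sequences)
                   else names(seqs)
    if (scale == "raw") denormalizeStrengths(pred, model@norm) else pred
  })

setMethod("predictCore", "TransformerPredictor", function(model, seqs) {
  L <- model@seqLength
  cfg <- model@config
  out <- numeric(length(seqs))
  chunk <- 256L
  for (start in seq(1L, length(seqs), by = chunk)) {
    sel <- start:min(length(seqs), start + chunk - 1L)
    tok <- tokenizeSet(seqs[sel])
    out[sel] <- tfForward(model@params, tok, length(sel), L, cfg)
  }
  out
})

#' Evaluate a predictor on a labelled test set
#'
#' Computes the Pearson correlation between predictions and the true
#' strengths, both on the normalized scale the model was trained on
#' (test strengths are mapped through the training-set normalization
#' parameters stored in the model).
#'
#' @param model A trained \linkS4class{StrengthPredictor}.
#' @param test A labelled \linkS4class{PromoterSet} with >= 2 records.
#' @return The test-set PCC (see [pcc()]); constant predictions raise a
#'   degenerate-variance error.
#' @export
evaluatePredictor <- function(model, test) {
  stopifnot(is(test, "PromoterSet"))
  if (!hasStrength(test) || length(test) < 2L)
    stop("test set must be labelled with >= 2 records", call. = FALSE)
  truth <- normalizeStrengths(promoterStrengths(test), model@norm,
                              model@config$pseudocount)
  pcc(predictStrength(model, test), truth)
}

setMethod("show", "StrengthPredictor", function(object) {
  cat(sprintf("%s: L=%d, dModel=%s, trained with wMse=%g, wPcc=%g\n",
      class(object), object@seqLength,
      paste(object@config$dModel %||% object@config$hidden),
      object@config$wMse, object@config$wPcc))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
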