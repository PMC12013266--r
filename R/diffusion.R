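#' Build a linear variance schedule for the diffusion forward process
#'
#' Interpolates the per-step variance \eqn{\beta_t} linearly between
#' `betaStart` and `betaEnd` over `steps` steps and tabulates
#' \eqn{\alpha_t = 1 - \beta_t} and \eqn{\bar\alpha_t = \prod \alpha_s}.
#' The defaults (T = 1000, beta from 1e-4 to 0.02) are the canonical DDPM
#' schedule. When running with fewer steps, scale `betaEnd` up so that
#' \eqn{\bar\alpha_T} stays near zero (e.g. `betaEnd = 0.1` at T = 200);
#' otherwise residual signal at the final step conflicts with sampling
#' from pure noise.
#'
#' @param steps Total number of noising steps T (>= 1).
#' @param betaStart,betaEnd Endpoints of the linear beta ramp, with
#'   `0 < betaStart <= betaEnd < 1`.
#' @param shape Schedule family; only `"linear"` is implemented.
#' @return A \linkS4class{NoiseSchedule}.
#' @examples
#' sch <- buildSchedule(steps = 2, betaStart = 0.1, betaEnd = 0.2)
#' sch@alphaBars   # 0.9, 0.72
#' @export
buildSchedule <- function(steps = 1000L, betaStart = 1e-4, betaEnd = 0.02,
                          shape = c("linear")) {
  shape <- match.arg(shape)
  if (!is.numeric(steps) || steps < 1L)
    stop("steps must be a positive integer", call. = FALSE)
  if (betaStart <= 0 || betaEnd >= 1 || betaStart > betaEnd)
    stop("need 0 < betaStart <= betaEnd < 1", call. = FALSE)
  steps <- as.integer(steps)
  betas <- if (steps == 1L) betaStart else
    seq(betaStart, betaEnd, length.out = steps)
  alphas <- 1 - betas
  new("NoiseSchedule", steps = steps, betas = betas,
      alphas = alphas, alphaBars = cumprod(alphas))
}

setMethod("show", "NoiseSchedule", function(object) {
  cat(sprintf(
    "NoiseSchedule: T=%d, beta in [%.2g, %.2g], alphaBar_T=%.3g\n",
    object@steps, min(object@betas), max(object@betas),
    object@alphaBars[object@steps]))
})

#' Apply the closed-form forward noising kernel
#'
#' Jumps directly from the clean one-hot state \eqn{x_0} to step t:
#' \deqn{x_t = \sqrt{\bar\alpha_t}\, x_0 + \sqrt{1 - \bar\alpha_t}\,
#' \epsilon,\qquad \epsilon \sim N(0, I).}
#' Deterministic given the noise draw, which makes the Gaussian moments
#' directly testable.
#'
#' @param x0 An L x 4 one-hot matrix (see [oneHotEncode()]).
#' @param t Step index in 1..T.
#' @param schedule A \linkS4class{NoiseSchedule}.
#' @param noise An L x 4 matrix of standard-normal draws; freshly sampled
#'   when omitted.
#' @return The noised L x 4 state.
#' @export
forwardNoise <- function(x0, t, schedule, noise = NULL) {
  if (!is.matrix(x0) || ncol(x0) != 4L)
    stop("x0 must be an L x 4 matrix", call. = FALSE)
  if (t < 1L || t > schedule@steps)
    stop("t must lie in 1..T", call. = FALSE)
  if (is.null(noise)) noise <- matrix(stats::rnorm(length(x0)), nrow(x0), 4L)
  ab <- schedule@alphaBars[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * noise
}

# ---- convolutional noise predictor -----------------------------------------
# eps_hat = f(x_t, t): input projection + learned positional embedding +
# timestep features, then residual blocks of two same-padded convolutions,
# then a linear output head back to 4 channels.

ddpmInitParams <- function(L, hidden, blocks, kernel) {
  p <- list(
    Win = nnInit(4L, hidden),
    bin = numeric(hidden),
    P   = nnInit(L, hidden, scale = 0.5) * 0.1,
    Wt0 = nnInit(hidden, hidden),
    Wout = nnInit(hidden, 4L, scale = 0.5),
    bout = numeric(4L))
  for (b in seq_len(blocks)) {
    p[[paste0("tproj", b)]] <- nnInit(hidden, hidden, scale = 0.5)
    p[[paste0("cw1_", b)]] <- nnInit(kernel * hidden, hidden) / sqrt(kernel)
    p[[paste0("cb1_", b)]] <- numeric(hidden)
    p[[paste0("cw2_", b)]] <- nnInit(kernel * hidden, hidden) / sqrt(kernel)
    p[[paste0("cb2_", b)]] <- numeric(hidden)
  }
  p
}

# X: (B*L) x 4 noised states; tembRows: (B*L) x hidden timestep features.
ddpmForward <- function(p, X, tembRows, L, blocks, keepCache = FALSE) {
  B <- nrow(X) %/% L
  posIdx <- rep(seq_len(L), B)
  h <- X %*% p$Win + matrix(p$bin, nrow(X), length(p$bin), byrow = TRUE) +
    p$P[posIdx, , drop = FALSE] + tembRows %*% p$Wt0
  cache <- if (keepCache) list(X = X, posIdx = posIdx, blocks = vector("list", blocks))
  for (b in seq_len(blocks)) {
    a0 <- h + tembRows %*% p[[paste0("tproj", b)]]
    a <- relu(a0)
    c1 <- convForward(a, p[[paste0("cw1_", b)]], p[[paste0("cb1_", b)]], B, L)
    a2 <- relu(c1)
    c2 <- convForward(a2, p[[paste0("cw2_", b)]], p[[paste0("cb2_", b)]], B, L)
    if (keepCache)
      cache$blocks[[b]] <- list(m0 = a0 > 0, a = a, m1 = c1 > 0, a2 = a2)
    h <- h + c2
  }
  out <- h %*% p$Wout + matrix(p$bout, nrow(X), 4L, byrow = TRUE)
  if (keepCache) { cache$h <- h; list(out = out, cache = cache) } else out
}

ddpmBackward <- function(p, cache, dOut, tembRows, L, blocks) {
  B <- nrow(dOut) %/% L
  g <- list(Wout = crossprod(cache$h, dOut), bout = colSums(dOut))
  dh <- dOut %*% t(p$Wout)
  for (b in rev(seq_len(blocks))) {
    bl <- cache$blocks[[b]]
    cb2 <- convBackward(dh, bl$a2, p[[paste0("cw2_", b)]], B, L)
    g[[paste0("cw2_", b)]] <- cb2$dW
    g[[paste0("cb2_", b)]] <- drop(cb2$db)
    dc1 <- cb2$dX * bl$m1
    cb1 <- convBackward(dc1, bl$a, p[[paste0("cw1_", b)]], B, L)
    g[[paste0("cw1_", b)]] <- cb1$dW
    g[[paste0("cb1_", b)]] <- drop(cb1$db)
    da0 <- cb1$dX * bl$m0
    g[[paste0("tproj", b)]] <- crossprod(tembRows, da0)
    dh <- dh + da0
  }
  g$Win <- crossprod(cache$X, dh)
  g$bin <- colSums(dh)
  g$P <- rowsum(dh, cache$posIdx)
  g$Wt0 <- crossprod(tembRows, dh)
  g
}

ddpmPredictNoise <- function(p, X, t, schedule, L, blocks, hidden) {
  B <- nrow(X) %/% L
  temb <- timeEmbedding(t / schedule@steps * 100, hidden)
  tembRows <- temb[rep(seq_len(B), each = L), , drop = FALSE]
  ddpmForward(p, X, tembRows, L, blocks)
}

#' Train a denoising diffusion model on a promoter set
#'
#' Fits a convolutional noise predictor by the standard DDPM objective:
#' each step draws a timestep t uniformly from 1..T and Gaussian noise
#' \eqn{\epsilon}, forms \eqn{x_t} with the closed-form kernel, and
#' minimizes the mean absolute error (L1 loss) between \eqn{\epsilon} and
#' the prediction. A held-out fraction of sequences monitors the L1 loss
#' per epoch; the loss should drop sharply over early epochs and then
#' plateau. Training is fully determined by `seed`.
#'
#' @param x A \linkS4class{PromoterSet} (strengths are ignored; generation
#'   is unsupervised).
#' @param schedule A \linkS4class{NoiseSchedule}.
#' @param epochs Number of passes over the data.
#' @param batchSize Minibatch size.
#' @param hidden Channel width of the conv denoiser.
#' @param blocks Number of residual conv blocks.
#' @param kernel Convolution kernel width (odd).
#' @param lr Adam learning rate.
#' @param valFraction Fraction of sequences held out for the monitoring
#'   loss.
#' @param checkpointEvery Save a parameter snapshot every this many epochs
#'   (0 disables), for learning-trajectory analyses such as
#'   [kmerPccTrajectory()].
#' @param seed Integer seed controlling shuffling, timestep and noise
#'   draws.
#' @param verbose Print the held-out loss every 10 epochs.
#' @return A \linkS4class{DiffusionModel}.
#' @seealso [samplePromoters()], [trainingLog()]
#' @export
trainDDPM <- function(x, schedule = buildSchedule(),
                      epochs = 100L, batchSize = 64L, hidden = 64L,
                      blocks = 2L, kernel = 5L, lr = 1e-3,
                      valFraction = 0.1, checkpointEvery = 10L,
                      seed = 1L, verbose = FALSE) {
  seqs <- asSequenceVector(x)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  L <- nchar(seqs[1L])
  if (kernel %% 2L != 1L) stop("kernel must be odd", call. = FALSE)
  n <- length(seqs)
  withSeed(seed, {
    nVal <- max(1L, min(n - 1L, round(n * valFraction)))
    valIdx <- if (n >= 4L) sample.int(n, nVal) else integer(0)
    trIdx <- setdiff(seq_len(n), valIdx)
    Xtr <- stackOneHot(seqs[trIdx])
    Xval <- if (length(valIdx)) stackOneHot(seqs[valIdx])
    p <- ddpmInitParams(L, hidden, blocks, kernel)
    opt <- adamInit(p)
    nTr <- length(trIdx)
    log <- data.frame(epoch = integer(), train_l1 = numeric(),
                      heldout_l1 = numeric())
    checkpoints <- list()
    # fixed held-out corruption draws give a comparable loss across epochs
    valDraws <- if (length(valIdx)) list(
      t = sample.int(schedule@steps, length(valIdx), replace = TRUE),
      eps = matrix(stats::rnorm(length(Xval)), nrow(Xval), 4L))
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(nTr)
      epochLoss <- 0; nBatch <- 0L
      for (start in seq(1L, nTr, by = batchSize)) {
        sel <- ord[start:min(nTr, start + batchSize - 1L)]
        B <- length(sel)
        rows <- as.vector(outer(seq_len(L), (sel - 1L) * L, "+"))
        x0 <- Xtr[rows, , drop = FALSE]
        t <- sample.int(schedule@steps, B, replace = TRUE)
        ab <- schedule@alphaBars[t]
        sab <- rep(sqrt(ab), each = L)
        snb <- rep(sqrt(1 - ab), each = L)
        eps <- matrix(stats::rnorm(B * L * 4L), B * L, 4L)
        xt <- sab * x0 + snb * eps
        temb <- timeEmbedding(t / schedule@steps * 100, hidden)
        tembRows <- temb[rep(seq_len(B), each = L), , drop = FALSE]
        fw <- ddpmForward(p, xt, tembRows, L, blocks, keepCache = TRUE)
        resid <- fw$out - eps
        loss <- mean(abs(resid))
        if (!is.finite(loss))
          stop("training diverged: non-finite loss at epoch ", epoch,
               call. = FALSE)
        dOut <- sign(resid) / length(resid)
        gr <- ddpmBackward(p, fw$cache, dOut, tembRows, L, blocks)
        upd <- adamStep(p, gr, opt, lr = lr)
        p <- upd$params; opt <- upd$state
        epochLoss <- epochLoss + loss; nBatch <- nBatch + 1L
      }
      valLoss <- NA_real_
      if (length(valIdx)) {
        abv <- schedule@alphaBars[valDraws$t]
        xtv <- rep(sqrt(abv), each = L) * Xval +
          rep(sqrt(1 - abv), each = L) * valDraws$eps
        ev <- ddpmPredictNoise(p, xtv, valDraws$t, schedule, L, blocks,
                               hidden)
        valLoss <- mean(abs(ev - valDraws$eps))
      }
      log <- rbind(log, data.frame(epoch = epoch,
                                   train_l1 = epochLoss / nBatch,
                                   heldout_l1 = valLoss))
      if (checkpointEvery > 0L &&
          (epoch %% checkpointEvery == 0L || epoch == epochs))
        checkpoints[[as.character(epoch)]] <- p
      if (verbose && epoch %% 10L == 0L)
        message(sprintf("epoch %d: train L1 %.4f, held-out L1 %.4f",
                        epoch, epochLoss / nBatch, valLoss))
    }
    new("DiffusionModel", params = p, schedule = schedule,
        seqLength = as.integer(L),
        config = list(hidden = hidden, blocks = blocks, kernel = kernel,
                      batchSize = batchSize, lr = lr, epochs = epochs,
                      seed = seed),
        trainingLog = log, checkpoints = checkpoints)
  })
}

#' Training log of a fitted model
#' @param model A \linkS4class{DiffusionModel}.
#' @return A `data.frame` with per-epoch train and held-out L1 losses.
#' @export
trainingLog <- function(model) model@trainingLog

setMethod("show", "DiffusionModel", function(object) {
  lg <- object@trainingLog
  cat(sprintf(
    "DiffusionModel: L=%d, T=%d, hidden=%d, %d blocks, %d epochs\n",
    object@seqLength, object@schedule@steps, object@config$hidden,
    object@config$blocks, nrow(lg)))
  if (nrow(lg))
    cat(sprintf("  held-out L1: %.4f (first) -> %.4f (final)\n",
        lg$heldout_l1[1L], lg$heldout_l1[nrow(lg)]))
})

#' Sample new promoter sequences from a trained diffusion model
#'
#' Ancestral DDPM sampling: start from pure Gaussian noise \eqn{x_T},
#' repeatedly subtract the predicted noise,
#' \deqn{x_{t-1} = (x_t - \beta_t/\sqrt{1-\bar\alpha_t}\,
#' \hat\epsilon)/\sqrt{\alpha_t} + \sigma_t z,\quad \sigma_t^2 = \beta_t,}
#' (no noise is added at the final step), then decode \eqn{x_0} to
#' sequences by per-position argmax.
#'
#' @param model A trained \linkS4class{DiffusionModel} (or a raw parameter
#'   list via `params=` for checkpoint sampling).
#' @param count Number of sequences to draw (>= 0).
#' @param seed Integer seed; sampling is deterministic given it.
#' @param params Optional parameter snapshot (e.g. one element of
#'   `model@checkpoints`) overriding the final parameters.
#' @return A \linkS4class{PromoterSet} of `count` unlabelled sequences of
#'   the training length (ids `gen_1`, ...), or an empty character vector
#'   for `count = 0`.
#' @export
samplePromoters <- function(model, count, seed = 1L, params = NULL) {
  if (count < 0) stop("count must be >= 0", call. = FALSE)
  if (count == 0) return(character(0))
  p <- if (is.null(params)) model@params else params
  sch <- model@schedule
  L <- model@seqLength
  hidden <- model@config$hidden
  blocks <- model@config$blocks
  withSeed(seed, {
    xcur <- matrix(stats::rnorm(count * L * 4L), count * L, 4L)
    for (t in rev(seq_len(sch@steps))) {
      eps <- ddpmPredictNoise(p, xcur, rep(t, count), sch, L, blocks,
                              hidden)
      xcur <- (xcur - sch@betas[t] / sqrt(1 - sch@alphaBars[t]) * eps) /
        sqrt(sch@alphas[t])
      if (t > 1L)
        xcur <- xcur + sqrt(sch@betas[t]) *
          matrix(stats::rnorm(count * L * 4L), count * L, 4L)
    }
    PromoterSet(decodeStacked(xcur, L), ids = paste0("gen_", seq_len(count)))
  })
}
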