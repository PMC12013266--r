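#' Specification for the synthetic motif-promoter generator
#'
#' Describes a seeded generative law for promoter-like sequences with
#' known ground truth: an AT-rich i.i.d. background with position-weight
#' matrices planted at fixed windows — by default a TATAAT-like matrix
#' in the -10 region (start index L - 12) and a TTGACA-like matrix in the
#' -35 region (start index L - 36) — and a strictly positive, right-skewed
#' strength law
#' \deqn{S = 10^{a \cdot \mathrm{score} + b + N(0, \sigma)},}
#' where `score` is the summed log-odds of the drawn bases under the
#' planted PWMs versus the background. The exponential form reproduces
#' the skew that motivates the log10 transform, and the latent score gives
#' every downstream model a recoverable target.
#'
#' @param count Number of sequences m.
#' @param length Sequence length L.
#' @param motifs List of motifs, each `list(consensus=, start=, prob=)`
#'   with `start` a 0-based window start and `prob` the per-position
#'   consensus probability (other bases share the remainder equally).
#' @param background Named base probabilities (must sum to 1); AT-rich by
#'   default.
#' @param a,b Strength-law coefficients (slope on the log-odds score and
#'   log10 intercept).
#' @param sigma Standard deviation of the Gaussian noise on the log10
#'   strength scale.
#' @param seed Integer seed; generation is byte-identical given it.
#' @return A list of class `FixtureSpec`.
#' @export
fixtureSpec <- function(count = 2000L, length = 50L,
                        motifs = list(
                          list(consensus = "TATAAT", start = length - 12L,
                               prob = 0.7),
                          list(consensus = "TTGACA", start = length - 36L,
                               prob = 0.7)),
                        background = c(A = 0.3, T = 0.3, C = 0.2, G = 0.2),
                        a = 0.15, b = 1, sigma = 0.25, seed = 1L) {
  if (count < 1L || length < 1L)
    stop("count and length must be positive", call. = FALSE)
  if (abs(sum(background) - 1) > 1e-8 || any(background < 0))
    stop("background probabilities must be nonnegative and sum to 1",
         call. = FALSE)
  if (!setequal(names(background), .BASES))
    stop("background must be named over A, T, C, G", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  for (m in motifs) {
    k <- nchar(m$consensus)
    if (m$start < 0L || m$start + k > length)
      stop("motif window '", m$consensus, "' does not fit inside the ",
           "sequence", call. = FALSE)
    if (m$prob <= 0 || m$prob >= 1)
      stop("motif consensus probability must lie in (0, 1)", call. = FALSE)
  }
  structure(list(count = as.integer(count), length = as.integer(length),
                 motifs = motifs, background = background[.BASES],
                 a = a, b = b, sigma = sigma, seed = as.integer(seed)),
            class = "FixtureSpec")
}

# per-motif PWM (k x 4 probs, channel order ATCG) and its log-odds vs bg
.motifPwm <- function(m, background) {
  k <- nchar(m$consensus)
  cons <- match(strsplit(m$consensus, "", fixed = TRUE)[[1L]], .BASES)
  pwm <- matrix((1 - m$prob) / 3, k, 4L, dimnames = list(NULL, .BASES))
  pwm[cbind(seq_len(k), cons)] <- m$prob
  list(pwm = pwm, logOdds = log(pwm) - rep(log(background), each = k))
}

.fixtureScores <- function(spec, seqs) {
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                  nrow = length(seqs), byrow = TRUE)
  score <- numeric(length(seqs))
  for (m in spec$motifs) {
    lo <- .motifPwm(m, spec$background)$logOdds
    k <- nchar(m$consensus)
    for (j in seq_len(k)) {
      col <- match(chars[, m$start + j], .BASES)
      score <- score + lo[cbind(j, col)]
    }
  }
  score
}

#' Generate a synthetic motif-promoter dataset with known ground truth
#'
#' Draws sequences from the background distribution, overwrites the
#' planted windows with PWM draws, and assigns strengths by the
#' exponential law of [fixtureSpec()]. The generated set carries its
#' latent variables (PWM log-odds scores and noiseless strengths) in
#' `metadata` for parameter-recovery checks via [fixtureTruth()].
#'
#' @param spec A `FixtureSpec`.
#' @return A labelled \linkS4class{PromoterSet} with `metadata$truth`
#'   (data.frame: id, score, noiseless_strength) and `metadata$spec`.
#' @examples
#' ps <- generateFixture(fixtureSpec(count = 50, seed = 7))
#' range(promoterStrengths(ps)) > 0
#' @export
generateFixture <- function(spec) {
  if (!inherits(spec, "FixtureSpec"))
    stop("spec must come from fixtureSpec()", call. = FALSE)
  withSeed(spec$seed, {
    m <- spec$count; L <- spec$length
    chars <- matrix(sample(.BASES, m * L, replace = TRUE,
                           prob = spec$background), m, L)
    for (mo in spec$motifs) {
      pwm <- .motifPwm(mo, spec$background)$pwm
      for (j in seq_len(nrow(pwm)))
        chars[, mo$start + j] <- sample(.BASES, m, replace = TRUE,
                                        prob = pwm[j, ])
    }
    seqs <- apply(chars, 1L, paste, collapse = "")
    score <- .fixtureScores(spec, seqs)
    log10S0 <- spec$a * score + spec$b
    strength <- 10^(log10S0 + stats::rnorm(m, 0, spec$sigma))
    ids <- sprintf("fix_%d", seq_len(m))
    PromoterSet(seqs, strength = strength, ids = ids,
                metadata = list(
                  spec = spec,
                  truth = data.frame(id = ids, score = score,
                                     noiseless_strength = 10^log10S0,
                                     stringsAsFactors = FALSE)))
  })
}

#' Recover the generator's latent variables for a fixture dataset
#'
#' Recomputes each record's PWM log-odds score directly from its sequence
#' and checks it against the latents stored at generation time; a
#' mismatch (different spec or seed) is an error. Returns the ground
#' truth used by parameter-recovery tests.
#'
#' @param spec The `FixtureSpec` the dataset was generated from.
#' @param x The \linkS4class{PromoterSet} returned by
#'   [generateFixture()].
#' @return `data.frame` with `id`, `score`, `noiseless_strength`.
#' @export
fixtureTruth <- function(spec, x) {
  stopifnot(is(x, "PromoterSet"))
  truth <- x@metadata$truth
  if (is.null(truth))
    stop("dataset carries no fixture metadata", call. = FALSE)
  stored <- x@metadata$spec
  if (!identical(stored$seed, spec$seed) ||
      !identical(stored$count, spec$count) ||
      !identical(stored$length, spec$length))
    stop("spec/seed mismatch with the dataset's generation metadata",
         call. = FALSE)
  score <- .fixtureScores(spec, as.character(promoterSequences(x)))
  if (max(abs(score - truth$score)) > 1e-8)
    stop("recomputed scores disagree with stored latents; ",
         "spec does not match the generating spec", call. = FALSE)
  truth
}
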