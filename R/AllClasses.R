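#' @import methods
#' @importFrom stats rnorm runif quantile median sd cor setNames aggregate
#' @importFrom utils read.csv read.delim write.csv packageVersion head
NULL

#' PromoterSet: a set of fixed-length promoter sequences with optional strengths
#'
#' The central data container of the package: an ordered collection of
#' promoter sequences over the alphabet \{A, T, C, G\}, all of the same
#' length, each with a unique identifier and an optional strictly positive
#' strength value (expression level in arbitrary units, e.g. dRNA-seq
#' counts).
#'
#' Sequences are stored as a \linkS4class{DNAStringSet}; strengths as a
#' numeric vector parallel to the sequences (`NA` where unknown, or an
#' empty vector when the whole set is unlabelled, as for generated
#' promoters).
#'
#' @slot sequences A [Biostrings::DNAStringSet] of uniform width with
#'   unique names.
#' @slot strength Numeric vector of per-record strengths (length 0 when
#'   absent; positive and finite where not `NA`).
#' @slot metadata A free-form list (used e.g. by the synthetic fixture
#'   generator to carry ground truth).
#'
#' @seealso [PromoterSet()], [readPromoterTable()], [generateFixture()]
#' @export
setClass("PromoterSet",
  slots = c(
    sequences = "DNAStringSet",
    strength  = "numeric",
    metadata  = "list"
  )
)

setValidity("PromoterSet", function(object) {
  msgs <- character()
  n <- length(object@sequences)
  if (n == 0L) {
    msgs <- c(msgs, "a PromoterSet must contain at least one sequence")
  } else {
    w <- Biostrings::width(object@sequences)
    if (length(unique(w)) > 1L)
      msgs <- c(msgs, sprintf(
        "all sequences must have the same length; found lengths {%s}",
        paste(unique(w), collapse = ", ")))
    if (any(w == 0L))
      msgs <- c(msgs, "sequences must be non-empty")
    ids <- names(object@sequences)
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
      msgs <- c(msgs, "every record must have a non-empty id")
    else if (anyDuplicated(ids))
      msgs <- c(msgs, sprintf("record ids must be unique; duplicated: %s",
        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    af <- Biostrings::alphabetFrequency(object@sequences, baseOnly = TRUE)
    bad <- which(af[, "other"] > 0)
    if (length(bad))
      msgs <- c(msgs, sprintf(
        "sequences restricted to {A,T,C,G}; offending records: %s",
        paste(utils::head(names(object@sequences)[bad], 10L), collapse = ", ")))
  }
  if (length(object@strength)) {
    if (length(object@strength) != n)
      msgs <- c(msgs, "strength must be empty or parallel to sequences")
    s <- object@strength[!is.na(object@strength)]
    if (any(!is.finite(s)) || any(s <= 0))
      msgs <- c(msgs, "strengths must be finite and > 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' NoiseSchedule: per-step variances of the diffusion forward process
#'
#' Tabulates the variance schedule of a denoising diffusion probabilistic
#' model: per-step variances \eqn{\beta_t}, the survival factors
#' \eqn{\alpha_t = 1 - \beta_t}, and their cumulative products
#' \eqn{\bar\alpha_t = \prod_{s \le t} \alpha_s}, which govern how much of
#' the original one-hot signal remains after \eqn{t} noising steps.
#'
#' @slot steps Total number of noising steps \eqn{T}.
#' @slot betas Numeric vector \eqn{\beta_1 \ldots \beta_T}, each in (0, 1).
#' @slot alphas \eqn{1 - \beta_t}.
#' @slot alphaBars Cumulative products \eqn{\bar\alpha_t}, strictly
#'   decreasing.
#' @seealso [buildSchedule()], [forwardNoise()]
#' @export
setClass("NoiseSchedule",
  slots = c(steps = "integer", betas = "numeric",
            alphas = "numeric", alphaBars = "numeric"))

setValidity("NoiseSchedule", function(object) {
  msgs <- character()
  T <- object@steps
  if (length(T) != 1L || is.na(T) || T < 1L)
    msgs <- c(msgs, "steps must be a single positive integer")
  if (length(object@betas) != T || length(object@alphas) != T ||
      length(object@alphaBars) != T)
    msgs <- c(msgs, "betas, alphas, alphaBars must all have length = steps")
  if (any(object@betas <= 0) || any(object@betas >= 1))
    msgs <- c(msgs, "betas must lie strictly in (0, 1)")
  if (length(object@alphaBars) > 1L && any(diff(object@alphaBars) >= 0))
    msgs <- c(msgs, "alphaBars must be strictly decreasing")
  if (length(msgs)) msgs else TRUE
})

#' NormalizationParams: min-max parameters on the log10 strength scale
#'
#' Stores the minimum and maximum of log10-transformed strengths used to
#' map strengths onto [0, 1]; required to invert predictions back to raw
#' units.
#'
#' @slot logMin Minimum of the log10-transformed training strengths.
#' @slot logMax Maximum of the log10-transformed training strengths.
#' @seealso [minMaxNormalize()], [denormalizeStrengths()]
#' @export
setClass("NormalizationParams",
  slots = c(logMin = "numeric", logMax = "numeric"))

setValidity("NormalizationParams", function(object) {
  if (length(object@logMin) != 1L || length(object@logMax) != 1L)
    return("logMin and logMax must be single numbers")
  if (!is.finite(object@logMin) || !is.finite(object@logMax))
    return("logMin and logMax must be finite")
  if (object@logMax <= object@logMin)
    return("logMax must exceed logMin (degenerate range)")
  TRUE
})

#' DiffusionModel: a trained DDPM over one-hot promoter matrices
#'
#' Holds the learned noise-predictor parameters, the noise schedule used
#' for training, the sequence length, the training log, and (optionally)
#' periodic parameter checkpoints for learning-trajectory analyses.
#'
#' @slot params Named list of parameter matrices of the convolutional
#'   noise predictor.
#' @slot schedule The \linkS4class{NoiseSchedule} used in training.
#' @slot seqLength Length L of the training sequences.
#' @slot config List of architecture/training settings.
#' @slot trainingLog `data.frame` with columns `epoch`, `train_l1`,
#'   `heldout_l1`.
#' @slot checkpoints Named list (by epoch) of parameter snapshots.
#' @seealso [trainDDPM()], [samplePromoters()]
#' @export
setClass("DiffusionModel",
  slots = c(params = "list", schedule = "NoiseSchedule",
            seqLength = "integer", config = "list",
            trainingLog = "data.frame", checkpoints = "list"))

#' StrengthPredictor: virtual parent of trained strength regressors
#'
#' @slot params Named list of learned parameter matrices.
#' @slot norm The \linkS4class{NormalizationParams} fitted on the training
#'   strengths.
#' @slot config The configuration list used to fit the model.
#' @slot seqLength Training sequence length L.
#' @seealso [trainPredictor()], [trainCNNBaseline()], [predictStrength()]
#' @export
setClass("StrengthPredictor", representation("VIRTUAL",
  params = "list", norm = "NormalizationParams",
  config = "list", seqLength = "integer"))

#' @rdname StrengthPredictor-class
#' @export
setClass("TransformerPredictor", contains = "StrengthPredictor")

#' @rdname StrengthPredictor-class
#' @export
setClass("CNNPredictor", contains = "StrengthPredictor")
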