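# Shared test helpers: tiny data builders and oracle predictors.

randomSequences <- function(n, L) {
  vapply(seq_len(n),
         function(i) paste(sample(c("A", "T", "C", "G"), L, replace = TRUE),
                           collapse = ""),
         character(1))
}

tinyPromoterSet <- function(n = 10, L = 8, seed = 1, strengths = TRUE) {
  withr::with_seed(seed, {
    PromoterSet(randomSequences(n, L),
                strength = if (strengths) exp(rnorm(n)) else NULL)
  })
}

# Additive oracle predictor: strength is the sum of known per-position,
# per-base weights, so every mutagenesis delta has a closed form.
setClass("AdditivePredictor", representation(weights = "matrix"))

setMethod("predictStrength", "AdditivePredictor",
  function(model, sequences, scale = c("normalized", "raw")) {
    seqs <- if (is(sequences, "PromoterSet"))
      as.character(promoterSequences(sequences)) else sequences
    vapply(seqs, function(s) sum(oneHotEncode(s) * model@weights),
           numeric(1), USE.NAMES = FALSE)
  })

# Predictor stub that replays fixed values, for exercising the evaluation
# pathway with known outputs; norm params map log10 strengths untouched.
setClass("ReplayPredictor", contains = "StrengthPredictor",
         representation(lookup = "numeric"))

setMethod(promodiff:::predictCore, "ReplayPredictor",
  function(model, seqs) unname(model@lookup[seqs]))

replayPredictor <- function(sequences, values, L) {
  new("ReplayPredictor", lookup = setNames(values, sequences),
      params = list(), norm = new("NormalizationParams",
                                  logMin = 0, logMax = 1),
      config = list(wMse = 1, wPcc = 1, pseudocount = NULL),
      seqLength = as.integer(L))
}
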