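#' Extract the sequences of a PromoterSet
#' @param x A \linkS4class{PromoterSet}.
#' @return A [Biostrings::DNAStringSet].
#' @export
setGeneric("promoterSequences", function(x) standardGeneric("promoterSequences"))

#' Extract the strengths of a PromoterSet
#' @param x A \linkS4class{PromoterSet}.
#' @return Numeric vector of strengths (length 0 when the set is
#'   unlabelled).
#' @export
setGeneric("promoterStrengths", function(x) standardGeneric("promoterStrengths"))

#' Common sequence length of a PromoterSet
#' @param x A \linkS4class{PromoterSet}.
#' @return Integer sequence length L.
#' @export
setGeneric("promoterLength", function(x) standardGeneric("promoterLength"))

#' Does every record carry a strength label?
#' @param x A \linkS4class{PromoterSet}.
#' @return Logical scalar.
#' @export
setGeneric("hasStrength", function(x) standardGeneric("hasStrength"))

#' Predict promoter strength for new sequences
#'
#' @param model A trained \linkS4class{StrengthPredictor}.
#' @param sequences Character vector, [Biostrings::DNAStringSet] or
#'   \linkS4class{PromoterSet}; all sequences must have the model's
#'   training length.
#' @param scale `"normalized"` (the min-max scale the model was trained
#'   on) or `"raw"` (inverse-transformed back to original strength units).
#' @return Numeric vector, one finite prediction per sequence.
#' @export
setGeneric("predictStrength",
  function(model, sequences, scale = c("normalized", "raw"))
    standardGeneric("predictStrength"))

# internal: raw forward pass of a fitted regressor on a character vector
setGeneric("predictCore", function(model, seqs) standardGeneric("predictCore"))
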