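# Nucleotide channel order (A,T,C,G) matches the 0-3 integer codes.
.BASES <- c("A", "T", "C", "G")

.baseCodes <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  codes <- match(chars, .BASES) - 1L
  if (anyNA(codes))
    stop("invalid character(s) in sequence: ",
         paste(unique(chars[is.na(codes)]), collapse = ", "), call. = FALSE)
  codes
}

#' One-hot encode a promoter sequence
#'
#' Maps a sequence of length L to an L x 4 matrix with a single 1 per row,
#' channel order (A, T, C, G) — the diffusion model's clean state x0.
#'
#' @param sequence A single character string over \{A, T, C, G\}, or a
#'   [Biostrings::DNAString].
#' @return An L x 4 numeric matrix with colnames A, T, C, G.
#' @examples
#' oneHotEncode("ATCG")   # the 4x4 identity
#' @export
oneHotEncode <- function(sequence) {
  if (is(sequence, "DNAString")) sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nchar(sequence)) stop("sequence must be non-empty", call. = FALSE)
  codes <- .baseCodes(sequence)
  L <- length(codes)
  m <- matrix(0, L, 4L, dimnames = list(NULL, .BASES))
  m[cbind(seq_len(L), codes + 1L)] <- 1
  m
}

#' Decode a (possibly noisy) one-hot matrix back to a sequence
#'
#' Takes the per-row argmax over the four channels; ties are broken toward
#' the lowest channel index (A before T before C before G) for
#' determinism. The input need not be a clean one-hot matrix — decoded
#' diffusion samples are arbitrary real matrices.
#'
#' @param matrix An L x 4 real matrix, channel order (A, T, C, G).
#' @return A character string of length L.
#' @examples
#' oneHotDecode(rbind(c(0.1, 0.2, 0.6, 0.1)))  # "C"
#' @export
oneHotDecode <- function(matrix) {
  if (!is.matrix(matrix) || ncol(matrix) != 4L)
    stop("expected an L x 4 matrix", call. = FALSE)
  paste(.BASES[max.col(matrix, ties.method = "first")], collapse = "")
}

#' Integer token encodings of a promoter sequence
#'
#' Three parallel integer streams feed the strength predictor:
#' `encodeSequenceTokens()` maps A, T, C, G to 0-3;
#' `encodeDinucleotideTokens()` maps the overlapping base pair starting at
#' each position to 4-19 (row-major over (A,T,C,G) x (A,T,C,G): AA = 4,
#' AT = 5, ..., GG = 19), with the final position zero-padded to the codes
#' A0 = 20, T0 = 21, C0 = 22, G0 = 23 so all three streams share the
#' sequence length; `encodePositionTokens()` is simply 0 ... L-1, consumed
#' by a learned position embedding.
#'
#' @param sequence A character string over \{A, T, C, G\}.
#' @param length Sequence length L (for `encodePositionTokens`).
#' @return An integer vector of length L.
#' @examples
#' encodeSequenceTokens("ATCG")       # 0 1 2 3
#' encodeDinucleotideTokens("AA")     # 4 20
#' encodePositionTokens(3)            # 0 1 2
#' @export
encodeSequenceTokens <- function(sequence) {
  .baseCodes(sequence)
}

#' @rdname encodeSequenceTokens
#' @export
encodeDinucleotideTokens <- function(sequence) {
  if (!is.character(sequence) || !nchar(sequence))
    stop("sequence must be a non-empty string", call. = FALSE)
  codes <- .baseCodes(sequence)
  L <- length(codes)
  pad <- 20L + codes[L]
  if (L == 1L) return(pad)
  c(4L + 4L * codes[-L] + codes[-1L], pad)
}

#' @rdname encodeSequenceTokens
#' @export
encodePositionTokens <- function(length) {
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  seq_len(length) - 1L
}

#' @rdname encodeSequenceTokens
#' @return `tokenEncoding()` returns a list with integer vectors `seq`,
#'   `dinuc`, `pos`, all of length L.
#' @export
tokenEncoding <- function(sequence) {
  list(seq   = encodeSequenceTokens(sequence),
       dinuc = encodeDinucleotideTokens(sequence),
       pos   = encodePositionTokens(nchar(sequence)))
}

#' Log10-transform strength values
#'
#' Promoter strengths are right-skewed; strengths are log10-transformed
#' before min-max normalization. Values must be strictly positive unless a
#' pseudocount is supplied, in which case it is added first.
#'
#' @param strengths Numeric vector of strengths.
#' @param pseudocount `NULL` (strict: nonpositive values are an error) or a
#'   positive offset added before taking logs (1.0 is a common choice for
#'   count-like data).
#' @return Numeric vector `log10(strengths (+ pseudocount))`.
#' @examples
#' logTransform(c(10, 1000))   # 1 3
#' @export
logTransform <- function(strengths, pseudocount = NULL) {
  if (is.null(pseudocount)) {
    bad <- !is.finite(strengths) | strengths <= 0
    if (any(bad)) {
      lab <- if (!is.null(names(strengths))) names(strengths)[bad] else which(bad)
      stop("nonpositive strength for record(s): ",
           paste(utils::head(lab, 10L), collapse = ", "),
           "; supply pseudocount= to offset", call. = FALSE)
    }
  } else {
    stopifnot(pseudocount > 0)
    strengths <- strengths + pseudocount
    if (any(strengths <= 0))
      stop("strengths still nonpositive after pseudocount", call. = FALSE)
  }
  log10(strengths)
}

#' Min-max normalize log-scale strengths to [0, 1]
#'
#' Applies `(x - min(x)) / (max(x) - min(x))` and returns the parameters
#' needed to invert the map. The minimum maps to 0 and the maximum to 1.
#'
#' @param logValues Numeric vector (log10-transformed strengths) with at
#'   least two distinct values.
#' @return A list with `values` (normalized vector) and `params`
#'   (\linkS4class{NormalizationParams}).
#' @examples
#' minMaxNormalize(c(0, 1, 2))$values   # 0 0.5 1
#' @export
minMaxNormalize <- function(logValues) {
  if (length(logValues) < 2L)
    stop("need at least 2 values to normalize", call. = FALSE)
  lo <- min(logValues); hi <- max(logValues)
  if (hi <= lo)
    stop("constant input: min-max range is degenerate", call. = FALSE)
  list(values = (logValues - lo) / (hi - lo),
       params = new("NormalizationParams", logMin = lo, logMax = hi))
}

#' Map strengths onto the normalized training scale (and back)
#'
#' `normalizeStrengths()` composes the log10 transform with min-max
#' normalization using previously fitted parameters (new data may fall
#' outside [0, 1]). `denormalizeStrengths()` inverts both steps back to raw
#' strength units.
#'
#' @param strengths Raw strength values (> 0).
#' @param normValues Values on the normalized scale.
#' @param params A \linkS4class{NormalizationParams}.
#' @param pseudocount Passed to [logTransform()].
#' @return Numeric vector.
#' @export
normalizeStrengths <- function(strengths, params, pseudocount = NULL) {
  (logTransform(strengths, pseudocount) - params@logMin) /
    (params@logMax - params@logMin)
}

#' @rdname normalizeStrengths
#' @export
denormalizeStrengths <- function(normValues, params) {
  10^(normValues * (params@logMax - params@logMin) + params@logMin)
}

#' Split a PromoterSet into train and test partitions
#'
#' Random, seeded, disjoint and exhaustive; the default `testFraction` of
#' 0.2 gives the conventional 4:1 train/test ratio.
#'
#' @param x A \linkS4class{PromoterSet}.
#' @param testFraction Fraction of records assigned to the test set,
#'   strictly between 0 and 1.
#' @param seed Integer seed; the same seed always yields the same split.
#' @return A list with `train` and `test` PromoterSets.
#' @examples
#' ps <- PromoterSet(c("ATCG", "GGCC", "TTAA", "CCGG", "ATAT"),
#'                   strength = 1:5)
#' sp <- splitDataset(ps, 0.2, seed = 1)
#' length(sp$train); length(sp$test)
#' @export
splitDataset <- function(x, testFraction = 0.2, seed = 1L) {
  if (!is.numeric(testFraction) || testFraction <= 0 || testFraction >= 1)
    stop("testFraction must lie strictly between 0 and 1", call. = FALSE)
  n <- length(x)
  nTest <- max(1L, min(n - 1L, round(n * testFraction)))
  idx <- withSeed(seed, sample.int(n, nTest))
  list(train = x[setdiff(seq_len(n), idx)], test = x[sort(idx)])
}
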