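#' Construct a PromoterSet
#'
#' @param sequences Character vector or [Biostrings::DNAStringSet] of
#'   equal-length sequences over \{A, T, C, G\}.
#' @param strength Optional numeric vector of positive strengths (NA
#'   allowed per record), parallel to `sequences`. `NULL` for an
#'   unlabelled set.
#' @param ids Optional character vector of unique record ids; defaults to
#'   existing names or `seq_1`, `seq_2`, ...
#' @param metadata Optional list of free-form metadata.
#' @return A validated \linkS4class{PromoterSet}.
#' @examples
#' ps <- PromoterSet(c("ATCG", "GGCC"), strength = c(10, 20))
#' promoterLength(ps)
#' @export
PromoterSet <- function(sequences, strength = NULL, ids = NULL,
                        metadata = list()) {
  if (is.character(sequences)) {
    seqs <- toupper(sequences)
    bad <- grepl("[^ATCG]", seqs)
    if (any(bad)) {
      lab <- if (!is.null(ids)) ids[bad] else
        if (!is.null(names(sequences))) names(sequences)[bad] else which(bad)
      stop("sequences restricted to {A,T,C,G}; offending records: ",
           paste(utils::head(lab, 10L), collapse = ", "), call. = FALSE)
    }
    sequences <- Biostrings::DNAStringSet(seqs)
  }
  if (!is.null(ids)) names(sequences) <- ids
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq_", seq_along(sequences))
  new("PromoterSet",
      sequences = sequences,
      strength  = if (is.null(strength)) numeric(0) else as.numeric(strength),
      metadata  = metadata)
}

#' @rdname promoterSequences
#' @export
setMethod("promoterSequences", "PromoterSet", function(x) x@sequences)

#' @rdname promoterStrengths
#' @export
setMethod("promoterStrengths", "PromoterSet", function(x) {
  s <- x@strength
  if (length(s)) names(s) <- names(x@sequences)
  s
})

#' @rdname promoterLength
#' @export
setMethod("promoterLength", "PromoterSet",
  function(x) unique(Biostrings::width(x@sequences)))

#' @rdname hasStrength
#' @export
setMethod("hasStrength", "PromoterSet",
  function(x) length(x@strength) == length(x@sequences) &&
    !anyNA(x@strength))

#' @describeIn PromoterSet Number of records.
#' @param x A `PromoterSet`.
#' @export
setMethod("length", "PromoterSet", function(x) length(x@sequences))

#' @describeIn PromoterSet Record ids.
#' @export
setMethod("names", "PromoterSet", function(x) names(x@sequences))

#' @describeIn PromoterSet Subset by index, id or logical mask.
#' @param i Index vector.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "PromoterSet", function(x, i, j, ..., drop = FALSE) {
  new("PromoterSet",
      sequences = x@sequences[i],
      strength  = if (length(x@strength)) x@strength[.resolveIdx(x, i)]
                  else numeric(0),
      metadata  = x@metadata)
})

.resolveIdx <- function(x, i) {
  if (is.character(i)) match(i, names(x@sequences)) else i
}

#' @describeIn PromoterSet Coerce to a data.frame with columns `id`,
#'   `sequence` and (when labelled) `strength`.
#' @param row.names,optional Passed through for generic consistency;
#'   ignored.
#' @export
as.data.frame.PromoterSet <- function(x, row.names = NULL,
                                      optional = FALSE, ...) {
  df <- data.frame(id = names(x@sequences),
                   sequence = as.character(x@sequences),
                   stringsAsFactors = FALSE)
  if (length(x@strength)) df$strength <- x@strength
  df
}

setMethod("show", "PromoterSet", function(object) {
  cat(sprintf("PromoterSet with %d sequences of length %d (%s)\n",
      length(object), promoterLength(object),
      if (length(object@strength)) "with strengths" else "unlabelled"))
  n <- min(3L, length(object))
  for (i in seq_len(n))
    cat(sprintf("  %s  %s%s\n", names(object)[i],
        as.character(object@sequences[[i]]),
        if (length(object@strength))
          sprintf("  strength=%.4g", object@strength[i]) else ""))
  if (length(object) > n) cat(sprintf("  ... and %d more\n", length(object) - n))
})
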