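# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs the session stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a bounded sub-seed from a run seed and a stage label, so each
# stochastic stage gets an independent, reproducible stream.
subSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

# Coerce character / DNAStringSet / PromoterSet to a character vector of
# uniform-length ACGT sequences.
asSequenceVector <- function(x) {
  seqs <- if (is(x, "PromoterSet")) as.character(promoterSequences(x))
    else if (is(x, "DNAStringSet")) as.character(x)
    else if (is.character(x)) toupper(x)
    else stop("expected character, DNAStringSet or PromoterSet", call. = FALSE)
  if (!length(seqs)) stop("empty sequence set", call. = FALSE)
  if (any(grepl("[^ATCG]", seqs)))
    stop("sequences restricted to {A,T,C,G}", call. = FALSE)
  if (length(unique(nchar(seqs))) > 1L)
    stop("sequences must share a common length", call. = FALSE)
  seqs
}

# Stack one-hot encodings of B equal-length sequences into a (B*L) x 4
# matrix of row blocks (the layout all network code operates on).
stackOneHot <- function(seqs) {
  L <- nchar(seqs[1L])
  B <- length(seqs)
  codes <- match(unlist(strsplit(seqs, "", fixed = TRUE)), .BASES)
  m <- matrix(0, B * L, 4L)
  m[cbind(seq_len(B * L), codes)] <- 1
  m
}

# Decode B stacked L x 4 blocks back to sequences.
decodeStacked <- function(m, L) {
  calls <- .BASES[max.col(m, ties.method = "first")]
  B <- nrow(m) / L
  vapply(seq_len(B), function(b)
    paste(calls[((b - 1L) * L + 1L):(b * L)], collapse = ""), character(1))
}
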