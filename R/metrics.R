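allKmers <- function(k) {
  if (k == 1L) return(.BASES)
  grid <- do.call(expand.grid,
                  c(rep(list(.BASES), k), stringsAsFactors = FALSE))
  # row-major over the first position: vary last position fastest
  apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste, collapse = "")
}

#' Sliding-window k-mer frequency spectrum
#'
#' Slides a window of length k with step 1 over every sequence and counts
#' occurrences of each k-mer; the frequency of a k-mer is its count
#' divided by the total number of windows, m * (n - k + 1) for m
#' sequences of length n, so the spectrum sums to 1. Overlapping
#' occurrences each count.
#'
#' @param x Character vector, [Biostrings::DNAStringSet] or
#'   \linkS4class{PromoterSet} of uniform-length sequences.
#' @param k Window length, `1 <= k <= n`.
#' @param densify If `TRUE` (default), the result covers all 4^k k-mers
#'   with zeros for unobserved ones; otherwise only observed k-mers.
#' @return A named numeric vector of frequencies with attribute `k`.
#' @examples
#' kmerSpectrum("ATGAT", k = 2, densify = FALSE)  # AT 0.5, GA 0.25, TG 0.25
#' @export
kmerSpectrum <- function(x, k, densify = TRUE) {
  seqs <- asSequenceVector(x)
  n <- nchar(seqs[1L])
  if (k < 1L || k > n)
    stop("k must lie in 1..sequence length", call. = FALSE)
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = k, simplify.as = "collapsed")
  total <- length(seqs) * (n - k + 1L)
  freqs <- counts / total
  if (!densify) freqs <- freqs[freqs > 0]
  structure(freqs, k = as.integer(k))
}

#' Pearson correlation between the k-mer spectra of two sequence sets
#'
#' Densifies both spectra over all 4^k k-mers (absent k-mers enter as
#' zeros) and correlates the two frequency vectors — the fidelity metric
#' for synthetic versus natural promoters. Sets may have different
#' sequence lengths; each set must be internally uniform.
#'
#' @param a,b Sequence sets (character, DNAStringSet or PromoterSet).
#' @param k Window length.
#' @return The correlation (see [pcc()]).
#' @export
kmerPcc <- function(a, b, k) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  fa <- kmerSpectrum(a, k)
  fb <- kmerSpectrum(b, k)
  pcc(as.numeric(fa), as.numeric(fb))
}

#' k-mer correlation trajectory across diffusion training checkpoints
#'
#' For each parameter checkpoint saved during [trainDDPM()], draws
#' sequences and computes the k-mer spectrum correlation against a
#' reference (natural) set, tracing how generation fidelity evolves over
#' training.
#'
#' @param model A \linkS4class{DiffusionModel} trained with
#'   `checkpointEvery > 0`.
#' @param natural The reference sequence set.
#' @param ks Integer vector of window lengths (default 2:6).
#' @param samplesPerCheckpoint Sequences drawn per checkpoint.
#' @param seed Integer seed (one independent draw per checkpoint).
#' @return A tidy `data.frame` with columns `epoch`, `k`, `pcc`
#'   (`n_checkpoints * length(ks)` rows).
#' @export
kmerPccTrajectory <- function(model, natural, ks = 2:6,
                              samplesPerCheckpoint = 200L, seed = 1L) {
  if (!length(model@checkpoints))
    stop("model has no checkpoints; retrain with checkpointEvery > 0",
         call. = FALSE)
  epochs <- as.integer(names(model@checkpoints))
  out <- do.call(rbind, lapply(seq_along(epochs), function(i) {
    gen <- samplePromoters(model, samplesPerCheckpoint,
                           seed = subSeed(seed, paste0("ckpt", epochs[i])),
                           params = model@checkpoints[[i]])
    data.frame(epoch = epochs[i], k = as.integer(ks),
               pcc = vapply(ks, function(k) kmerPcc(gen, natural, k),
                            numeric(1)))
  }))
  out[order(out$epoch, out$k), , drop = FALSE]
}

#' Positional occurrence profile of a k-mer
#'
#' For each possible start position p (0-based; n - k + 1 positions), the
#' fraction of sequences carrying the k-mer at exactly that start. Start
#' positions are also reported on the TSS-relative scale, where 0-based
#' index i corresponds to position i - n (index n - 1 is -1, immediately
#' upstream of the transcription start site).
#'
#' @param x A uniform-length sequence set.
#' @param kmer The k-mer to profile (e.g. `"TATAAT"`).
#' @return A `data.frame` with columns `position` (0-based start),
#'   `tss_position` and `frequency` (each in [0, 1]).
#' @export
positionalProfile <- function(x, kmer) {
  seqs <- asSequenceVector(x)
  n <- nchar(seqs[1L])
  k <- nchar(kmer)
  if (k < 1L || k > n)
    stop("kmer longer than the sequences", call. = FALSE)
  starts <- 0:(n - k)
  hits <- vapply(starts, function(p)
    sum(substr(seqs, p + 1L, p + k) == kmer), numeric(1))
  data.frame(position = starts, tss_position = starts - n,
             frequency = hits / length(seqs))
}

#' Sequence-logo matrix: per-position base probabilities and information
#' content
#'
#' Computes, per position, the base probabilities p(base), the information
#' content \eqn{IC = 2 + \sum_b p_b \log_2 p_b} bits (0 for a uniform
#' column, 2 for a fully conserved one; zero probabilities contribute
#' nothing), and the letter heights \eqn{p_b \cdot IC} drawn in a sequence
#' logo. No small-sample correction is applied by default.
#'
#' @param x A uniform-length sequence set.
#' @param correction If `TRUE`, subtract the small-sample correction
#'   \eqn{e = 3 / (2 m \ln 2)} from each column's IC (clamped at 0).
#' @return A list of class `LogoMatrix` with `prob` (L x 4), `ic`
#'   (length-L vector of bits) and `heights` (L x 4); `as.data.frame()`
#'   yields tidy columns position, tss_position, base, probability,
#'   height.
#' @examples
#' lm <- logoMatrix(c("AATT", "AGTT"))
#' lm$ic   # 2, 1, 2, 2
#' @export
logoMatrix <- function(x, correction = FALSE) {
  seqs <- asSequenceVector(x)
  m <- length(seqs)
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs),
                                    baseOnly = TRUE)
  prob <- t(cm[.BASES, , drop = FALSE]) / m
  plogp <- prob * log2(prob)
  plogp[prob == 0] <- 0
  ic <- 2 + rowSums(plogp)
  if (correction) ic <- pmax(0, ic - 3 / (2 * m * log(2)))
  structure(list(prob = prob, ic = ic, heights = prob * ic),
            class = "LogoMatrix")
}

#' @rdname logoMatrix
#' @param row.names,optional,... Ignored; for generic consistency.
#' @export
as.data.frame.LogoMatrix <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  L <- length(x$ic)
  data.frame(position = rep(seq_len(L) - 1L, each = 4L),
             tss_position = rep(seq_len(L) - 1L - L, each = 4L),
             base = rep(.BASES, L),
             probability = as.vector(t(x$prob)),
             height = as.vector(t(x$heights)))
}

#' @export
print.LogoMatrix <- function(x, ...) {
  cat(sprintf("LogoMatrix over %d positions; IC range [%.3f, %.3f] bits\n",
      length(x$ic), min(x$ic), max(x$ic)))
  invisible(x)
}
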