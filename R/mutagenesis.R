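#' Classify a single-nucleotide substitution
#'
#' Two mutation classes: `within_group` swaps stay inside a base pairing
#' group (A with T, or C with G); `cross_group` substitutions cross
#' between the \{A, T\} and \{C, G\} groups. The classification is
#' symmetric in (ref, alt).
#'
#' @param ref,alt Distinct bases from \{A, T, C, G\}.
#' @return `"within_group"` or `"cross_group"`.
#' @examples
#' classifyMutation("A", "T")   # within_group
#' classifyMutation("A", "G")   # cross_group
#' @export
classifyMutation <- function(ref, alt) {
  if (!ref %in% .BASES || !alt %in% .BASES)
    stop("ref and alt must be bases in {A,T,C,G}", call. = FALSE)
  if (ref == alt)
    stop("ref and alt must differ", call. = FALSE)
  at <- c("A", "T")
  if ((ref %in% at) == (alt %in% at)) "within_group" else "cross_group"
}

#' In-silico saturation mutagenesis of test promoters
#'
#' Randomly samples `sampleSize` promoters from the test set and, for each
#' sampled sequence, every position and all three alternative bases,
#' predicts the strength change `delta = predict(mutant) -
#' predict(original)` with the trained model. Yields exactly
#' `sampleSize * L * 3` mutation records.
#'
#' @param test A \linkS4class{PromoterSet} with the model's training
#'   length.
#' @param model A trained \linkS4class{StrengthPredictor}, or any object
#'   with a [predictStrength()] method.
#' @param sampleSize Number of promoters to sample (default 200; capped at
#'   the set size).
#' @param seed Integer seed for the promoter sample.
#' @param scale `"normalized"` (the model's training scale, default) or
#'   `"raw"` strength units for the deltas.
#' @return A `data.frame` with one row per mutation: `sequence_id`,
#'   `index` (0-based), `tss_position` (index - L), `ref`, `alt`,
#'   `class` and `delta`.
#' @seealso [positionSummaries()], [regionContrast()]
#' @export
saturationMutagenesis <- function(test, model, sampleSize = 200L, seed = 1L,
                                  scale = c("normalized", "raw")) {
  scale <- match.arg(scale)
  seqs <- asSequenceVector(test)
  ids <- if (is(test, "PromoterSet")) names(test) else
    names(seqs) %||% paste0("seq_", seq_along(seqs))
  L <- nchar(seqs[1L])
  if (sampleSize < 1L) stop("sampleSize must be >= 1", call. = FALSE)
  if (sampleSize > length(seqs)) {
    warning("sampleSize exceeds the set size; using all ", length(seqs),
            " sequences")
    sampleSize <- length(seqs)
  }
  sel <- withSeed(seed, sample.int(length(seqs), sampleSize))
  seqs <- seqs[sel]; ids <- ids[sel]
  base0 <- predictStrength(model, seqs, scale = scale)
  recs <- vector("list", sampleSize)
  for (i in seq_len(sampleSize)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    refs <- rep(chars, each = 3L)
    alts <- unlist(lapply(chars, function(b) setdiff(.BASES, b)),
                   use.names = FALSE)
    posIdx <- rep(seq_len(L), each = 3L)
    mutants <- vapply(seq_along(refs), function(j) {
      s <- chars; s[posIdx[j]] <- alts[j]; paste(s, collapse = "")
    }, character(1))
    recs[[i]] <- data.frame(
      sequence_id = ids[i], index = posIdx - 1L,
      tss_position = posIdx - 1L - L, ref = refs, alt = alts,
      stringsAsFactors = FALSE)
    recs[[i]]$mutant <- mutants
    recs[[i]]$base <- base0[i]
  }
  recs <- do.call(rbind, recs)
  recs$delta <- unname(predictStrength(model, recs$mutant, scale = scale)) -
    recs$base
  recs$class <- ifelse((recs$ref %in% c("A", "T")) ==
                         (recs$alt %in% c("A", "T")),
                       "within_group", "cross_group")
  recs[, c("sequence_id", "index", "tss_position", "ref", "alt",
           "class", "delta")]
}

#' Per-position summaries of mutation effects
#'
#' Aggregates mutation records two ways: by (TSS position, mutation
#' class), giving the mean absolute strength change per class per
#' position; and by (TSS position, ref, alt), giving box-plot statistics
#' (median, quartiles, 1.5 IQR whiskers) of the signed deltas.
#'
#' @param records A `data.frame` from [saturationMutagenesis()].
#' @return A list with `classSummary` (columns `tss_position`, `class`,
#'   `mean_abs_delta`, `n`) and `pairSummary` (columns `tss_position`,
#'   `ref`, `alt`, `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `n`).
#' @export
positionSummaries <- function(records) {
  if (!nrow(records)) stop("no mutation records", call. = FALSE)
  cs <- aggregate(abs(records$delta),
                  by = list(tss_position = records$tss_position,
                            class = records$class),
                  FUN = mean)
  names(cs)[3L] <- "mean_abs_delta"
  cs$n <- aggregate(records$delta,
                    by = list(records$tss_position, records$class),
                    FUN = length)$x
  cs <- cs[order(cs$tss_position, cs$class), , drop = FALSE]
  rownames(cs) <- NULL
  ps <- do.call(rbind, lapply(
    split(records, list(records$tss_position, records$ref, records$alt),
          drop = TRUE),
    function(g) {
      bs <- grDevices::boxplot.stats(g$delta, do.conf = FALSE,
                                     do.out = FALSE)$stats
      data.frame(tss_position = g$tss_position[1L], ref = g$ref[1L],
                 alt = g$alt[1L], median = bs[3L], q1 = bs[2L],
                 q3 = bs[4L], whisker_lo = bs[1L], whisker_hi = bs[5L],
                 n = nrow(g), stringsAsFactors = FALSE)
    }))
  ps <- ps[order(ps$tss_position, ps$ref, ps$alt), , drop = FALSE]
  rownames(ps) <- NULL
  list(classSummary = cs, pairSummary = ps)
}

#' Contrast mutation sensitivity inside regions against the background
#'
#' Averages the per-position mean absolute deltas within each TSS-relative
#' interval (e.g. the -10 and -35 boxes) and over its complement, per
#' mutation class — the summary behind "mutations in the core elements
#' move strength more than elsewhere".
#'
#' @param summaries Output of [positionSummaries()] (or its
#'   `classSummary` data.frame).
#' @param regions A named list of `c(lo, hi)` TSS-position intervals,
#'   e.g. `list(minus10 = c(-12, -7))`.
#' @return A `data.frame` with columns `region`, `class`, `region_mean`,
#'   `complement_mean`; zero rows for an empty region list.
#' @export
regionContrast <- function(summaries, regions) {
  cs <- if (is.data.frame(summaries)) summaries else summaries$classSummary
  if (!length(regions))
    return(data.frame(region = character(), class = character(),
                      region_mean = numeric(), complement_mean = numeric()))
  if (is.null(names(regions)))
    names(regions) <- paste0("region", seq_along(regions))
  do.call(rbind, lapply(names(regions), function(rn) {
    iv <- regions[[rn]]
    if (length(iv) != 2L || iv[1L] > iv[2L])
      stop("malformed interval '", rn, "': need c(lo, hi)", call. = FALSE)
    inside <- cs$tss_position >= iv[1L] & cs$tss_position <= iv[2L]
    do.call(rbind, lapply(unique(cs$class), function(cl) {
      m <- cs$class == cl
      data.frame(region = rn, class = cl,
                 region_mean = mean(cs$mean_abs_delta[inside & m]),
                 complement_mean = mean(cs$mean_abs_delta[!inside & m]),
                 stringsAsFactors = FALSE)
    }))
  }))
}
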