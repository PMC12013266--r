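#' Read a promoter table (CSV/TSV) or FASTA file
#'
#' CSV/TSV files need a header row with a sequence column and, optionally,
#' strength and id columns. FASTA input yields an unlabelled set (strengths
#' absent). Records with characters outside \{A, T, C, G\} are rejected by
#' default (`strict = TRUE`) or dropped with a warning (`strict = FALSE`).
#'
#' @param path Path to a `.csv`, `.tsv`/`.txt` (tab-separated) or
#'   `.fa`/`.fasta` file.
#' @param seqColumn,strengthColumn,idColumn Column names for tabular input.
#'   Set `strengthColumn = NULL` to ignore strengths. A missing id column
#'   falls back to row numbering.
#' @param strict If `TRUE`, any record with ambiguous bases is an error; if
#'   `FALSE` such records are skipped with a warning.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"fasta"`.
#' @return A \linkS4class{PromoterSet}.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write.csv(data.frame(id = c("p1", "p2"),
#'                      sequence = c("ATCG", "GGCC"),
#'                      strength = c(10, 20)), tmp, row.names = FALSE)
#' readPromoterTable(tmp)
#' @export
readPromoterTable <- function(path, seqColumn = "sequence",
                              strengthColumn = "strength",
                              idColumn = "id", strict = TRUE,
                              format = c("auto", "csv", "tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      "csv" = "csv", "tsv" = "tsv", "txt" = "tsv",
      "fa" = "fasta", "fasta" = "fasta", "fna" = "fasta",
      stop("cannot infer format from extension '.", ext,
           "'; pass format= explicitly", call. = FALSE))
  }
  if (format == "fasta") {
    seqs <- Biostrings::readDNAStringSet(path)
    df <- data.frame(id = names(seqs), sequence = as.character(seqs),
                     stringsAsFactors = FALSE)
    strengthColumn <- NULL
  } else {
    df0 <- if (format == "csv") utils::read.csv(path, stringsAsFactors = FALSE)
           else utils::read.delim(path, stringsAsFactors = FALSE)
    if (!seqColumn %in% names(df0))
      stop("sequence column '", seqColumn, "' not found in ", path,
           call. = FALSE)
    df <- data.frame(sequence = toupper(as.character(df0[[seqColumn]])),
                     stringsAsFactors = FALSE)
    df$id <- if (!is.null(idColumn) && idColumn %in% names(df0))
      as.character(df0[[idColumn]]) else paste0("seq_", seq_len(nrow(df)))
    if (!is.null(strengthColumn)) {
      if (!strengthColumn %in% names(df0))
        stop("strength column '", strengthColumn, "' not found in ", path,
             call. = FALSE)
      df$strength <- as.numeric(df0[[strengthColumn]])
    }
  }
  bad <- grepl("[^ATCG]", df$sequence) | nchar(df$sequence) == 0L
  if (any(bad)) {
    if (strict)
      stop("records with characters outside {A,T,C,G}: ",
           paste(utils::head(df$id[bad], 10L), collapse = ", "),
           call. = FALSE)
    warning(sum(bad), " record(s) with ambiguous bases skipped")
    df <- df[!bad, , drop = FALSE]
    if (!nrow(df)) stop("no valid records remain", call. = FALSE)
  }
  lens <- nchar(df$sequence)
  if (length(unique(lens)) > 1L)
    stop("mixed sequence lengths; offending records: ",
         paste(utils::head(df$id[lens != lens[1L]], 10L), collapse = ", "),
         call. = FALSE)
  if (!is.null(strengthColumn) && "strength" %in% names(df)) {
    s <- df$strength
    if (any(is.na(s)) || any(!is.finite(s)) || any(s <= 0))
      stop("nonpositive or missing strengths for records: ",
           paste(utils::head(df$id[is.na(s) | !is.finite(s) | s <= 0], 10L),
                 collapse = ", "), call. = FALSE)
  }
  PromoterSet(df$sequence,
              strength = if ("strength" %in% names(df)) df$strength else NULL,
              ids = df$id)
}

#' Write promoter sequences to FASTA
#'
#' @param x A \linkS4class{PromoterSet} or [Biostrings::DNAStringSet].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writePromoterFasta <- function(x, path) {
  seqs <- if (is(x, "PromoterSet")) promoterSequences(x) else x
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a promoter table to CSV
#'
#' Columns `id`, `sequence` and, when the set is labelled, `strength`.
#'
#' @param x A \linkS4class{PromoterSet}.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writePromoterTable <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
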