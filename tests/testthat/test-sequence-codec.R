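test_that("promoter tables parse from CSV, TSV and FASTA", {
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = c("p1", "p2"), sequence = c("ATCG", "GGCC"),
                       strength = c(10, 20)),
            csv, row.names = FALSE)
  ps <- readPromoterTable(csv)
  expect_s4_class(ps, "PromoterSet")
  expect_equal(length(ps), 2L)
  expect_equal(promoterLength(ps), 4L)
  expect_equal(unname(promoterStrengths(ps)), c(10, 20))

  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(id = "p1", sequence = "ACGT", strength = 5),
              tsv, sep = "\t", row.names = FALSE)
  expect_equal(unname(as.character(promoterSequences(readPromoterTable(tsv)))),
               "ACGT")

  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">p1", "ACGT"), fa)
  pf <- readPromoterTable(fa)
  expect_false(hasStrength(pf))
  expect_length(promoterStrengths(pf), 0L)
})

test_that("parsing rejects bad records with informative errors", {
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = c("ok", "badrec"), sequence = c("ATCG", "ATNN"),
                       strength = c(1, 2)), csv, row.names = FALSE)
  expect_error(readPromoterTable(csv), "badrec")
  expect_warning(ps <- readPromoterTable(csv, strict = FALSE), "skipped")
  expect_equal(length(ps), 1L)

  write.csv(data.frame(id = 1:2, seqs = c("AT", "CG")), csv,
            row.names = FALSE)
  expect_error(readPromoterTable(csv), "sequence column")

  write.csv(data.frame(id = c("a", "blong"), sequence = c("AT", "ATG"),
                       strength = c(1, 1)), csv, row.names = FALSE)
  expect_error(readPromoterTable(csv), "blong")

  write.csv(data.frame(id = c("a", "bneg"), sequence = c("AT", "CG"),
                       strength = c(1, -1)), csv, row.names = FALSE)
  expect_error(readPromoterTable(csv), "bneg")
})

test_that("PromoterSet validity and accessors enforce the invariants", {
  expect_error(PromoterSet(c("ATCG", "ATNG")), "restricted")
  expect_error(PromoterSet(c("AT", "ATG")), "same length")
  expect_error(PromoterSet(c("AT", "CG"), ids = c("x", "x")), "unique")
  expect_error(PromoterSet("ATCG", strength = -1), "> 0")
  ps <- PromoterSet(c("ATCG", "GGCC"), strength = c(10, 20))
  expect_equal(names(ps), c("seq_1", "seq_2"))
  expect_equal(length(ps[2]), 1L)
  expect_equal(unname(promoterStrengths(ps["seq_2"])), 20)
  df <- as.data.frame(ps)
  expect_equal(df$sequence, c("ATCG", "GGCC"))
})

test_that("one-hot encoding and decoding are mutually inverse", {
  expect_equal(unname(oneHotEncode("A")), rbind(c(1, 0, 0, 0)))
  expect_equal(unname(oneHotEncode("ATCG")), diag(4))
  expect_error(oneHotEncode("AXT"), "invalid")
  expect_equal(oneHotDecode(oneHotEncode("A")), "A")
  expect_equal(oneHotDecode(rbind(c(0.1, 0.2, 0.6, 0.1))), "C")
  # tie broken toward the lowest channel index
  expect_equal(oneHotDecode(rbind(c(0.5, 0.5, 0, 0))), "A")
  expect_error(oneHotDecode(matrix(0, 2, 3)), "L x 4")
  withr::with_seed(42, {
    for (s in randomSequences(200, 17))
      expect_identical(oneHotDecode(oneHotEncode(s)), s)
  })
})

test_that("token maps follow the 0-3 / 4-19 / 20-23 integer scheme", {
  expect_equal(encodeSequenceTokens("G"), 3L)
  expect_equal(encodeSequenceTokens("ATCG"), 0:3)
  expect_equal(encodeSequenceTokens("AAAA"), rep(0L, 4))
  expect_error(encodeSequenceTokens("ATX"), "invalid")

  expect_equal(encodeDinucleotideTokens("G"), 23L)
  expect_equal(encodeDinucleotideTokens("AA"), c(4L, 20L))
  expect_error(encodeDinucleotideTokens(""), "non-empty")

  # independent oracle: enumerate the 16 pairs in the listing order of the
  # single-nucleotide codes and assign 4..19 sequentially, plus the four
  # padded codes 20..23
  bases <- c("A", "T", "C", "G")
  tok <- 4L
  for (x in bases) for (y in bases) {
    expect_equal(encodeDinucleotideTokens(paste0(x, y))[1L], tok,
                 label = paste0("pair ", x, y))
    tok <- tok + 1L
  }
  for (i in seq_along(bases))
    expect_equal(encodeDinucleotideTokens(bases[i]), 19L + i)

  expect_equal(encodePositionTokens(3), 0:2)
  expect_equal(encodePositionTokens(1), 0L)
  expect_equal(encodePositionTokens(50), 0:49)
  expect_error(encodePositionTokens(0), ">= 1")
})

test_that("the three token streams stay consistent and equal-length", {
  withr::with_seed(7, {
    for (s in randomSequences(25, 11)) {
      te <- tokenEncoding(s)
      L <- nchar(s)
      expect_equal(lengths(te), c(seq = L, dinuc = L, pos = L))
      # the dinucleotide token encodes the same first base as the
      # sequence token at every position
      first <- ifelse(te$dinuc >= 20L, te$dinuc - 20L,
                      (te$dinuc - 4L) %/% 4L)
      expect_equal(first, te$seq)
      expect_true(te$dinuc[L] >= 20L && te$dinuc[L] <= 23L)
    }
  })
})

test_that("log10 transform and min-max normalization obey their laws", {
  expect_equal(logTransform(c(100)), 2)
  expect_equal(logTransform(c(1)), 0)
  expect_equal(logTransform(c(10, 1000)), c(1, 3))
  expect_error(logTransform(setNames(c(1, 0), c("a", "bad"))), "bad")
  expect_equal(logTransform(0, pseudocount = 1), 0)

  nm <- minMaxNormalize(c(0, 1, 2))
  expect_equal(nm$values, c(0, 0.5, 1))
  expect_error(minMaxNormalize(c(3, 3)), "degenerate")

  withr::with_seed(1, {
    for (i in 1:20) {
      x <- rnorm(15)
      nm <- minMaxNormalize(x)
      expect_equal(min(nm$values), 0)
      expect_equal(max(nm$values), 1)
      expect_true(all(nm$values >= 0 & nm$values <= 1))
      # inverse round trip through the full Eq-style pipeline
      raw <- 10^x
      nv <- normalizeStrengths(raw, nm$params)
      expect_equal(denormalizeStrengths(nv, nm$params), raw,
                   tolerance = 1e-10)
      # affine invariance: a*x + b has the same normalized values
      expect_equal(minMaxNormalize(2.5 * x + 7)$values, nm$values,
                   tolerance = 1e-10)
      # monotone: ranking preserved from raw strengths
      expect_equal(order(nv), order(raw))
    }
  })
})

test_that("the dataset split is seeded, disjoint and exhaustive", {
  ps <- tinyPromoterSet(10, 6, seed = 3)
  sp <- splitDataset(ps, 0.2, seed = 9)
  expect_equal(length(sp$train), 8L)
  expect_equal(length(sp$test), 2L)
  expect_setequal(c(names(sp$train), names(sp$test)), names(ps))
  sp2 <- splitDataset(ps, 0.2, seed = 9)
  expect_identical(names(sp2$test), names(sp$test))
  seeds <- vapply(1:30, function(s)
    paste(sort(names(splitDataset(ps, 0.3, seed = s)$test)),
          collapse = ","), character(1))
  expect_gt(length(unique(seeds)), 1L)
  expect_error(splitDataset(ps, 1.5), "strictly between")
})
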