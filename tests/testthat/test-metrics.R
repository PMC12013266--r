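# independent quadratic-time k-mer counter used as oracle
bruteKmerSpectrum <- function(seqs, k) {
  counts <- list()
  for (s in seqs)
    for (p in 1:(nchar(s) - k + 1)) {
      km <- substr(s, p, p + k - 1)
      counts[[km]] <- (counts[[km]] %||% 0) + 1
    }
  unlist(counts) / (length(seqs) * (nchar(seqs[1]) - k + 1))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("kmerSpectrum counts sliding windows with step one", {
  sp <- kmerSpectrum("ATGAT", k = 2, densify = FALSE)
  expect_equal(sp[["AT"]], 0.5)
  expect_equal(sp[["TG"]], 0.25)
  expect_equal(sp[["GA"]], 0.25)
  expect_equal(unname(kmerSpectrum("AAAA", k = 1)["A"]), 1)
  expect_error(kmerSpectrum("ATG", k = 5), "k must")
})

test_that("kmerSpectrum matches a brute-force counter and sums to 1", {
  withr::with_seed(11, {
    for (i in 1:60) {
      seqs <- randomSequences(sample(1:6, 1), sample(4:9, 1))
      k <- sample(1:3, 1)
      sp <- kmerSpectrum(seqs, k)
      expect_equal(sum(sp), 1)
      expect_length(sp, 4^k)
      bf <- bruteKmerSpectrum(seqs, k)
      expect_equal(sp[names(bf)], bf[names(bf)], tolerance = 1e-12)
      expect_equal(sum(sp[setdiff(names(sp), names(bf))]), 0)
    }
  })
})

test_that("kmerPcc is symmetric, maximal on identical sets, and matches a
          direct densified-vector computation", {
  a <- c("ATGATG", "CCGATA")
  b <- c("TTTAGC", "GGCATA")
  expect_equal(kmerPcc(a, a, 3), 1)
  expect_equal(kmerPcc(a, b, 2), kmerPcc(b, a, 2))
  # reverse complement of a composition-skewed set differs
  skew <- c("AAAAAC", "AAAACA")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(skew)))
  expect_lt(kmerPcc(skew, rc, 2), 1)
  # disjoint single-sequence sets: negative correlation, checked against
  # the correlation formula applied to the densified vectors directly
  x <- "AAAAAA"; y <- "CCCCCC"
  va <- as.numeric(kmerSpectrum(x, 3)); vb <- as.numeric(kmerSpectrum(y, 3))
  direct <- sum((va - mean(va)) * (vb - mean(vb))) /
    sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
  expect_lt(direct, 0)
  expect_equal(kmerPcc(x, y, 3), direct)
})

test_that("positionalProfile locates k-mer starts as per-position fractions", {
  same <- rep("ACGTACGT", 5)
  pr <- positionalProfile(same, "GTAC")
  expect_equal(pr$frequency, c(0, 0, 1, 0, 0))
  expect_equal(pr$position, 0:4)
  expect_equal(pr$tss_position, -8:-4)
  expect_equal(positionalProfile(same, "TTTT")$frequency, rep(0, 5))
  expect_error(positionalProfile("ACG", "ACGT"), "longer")
  mixed <- c("AATTAA", "TTAATT")
  pr2 <- positionalProfile(mixed, "TT")
  expect_equal(pr2$frequency, c(0.5, 0, 0.5, 0, 0.5))
})

test_that("logoMatrix information content matches the closed forms", {
  lm <- logoMatrix(c("AATT", "AGTT"))
  expect_equal(unname(lm$prob[1, ]), c(1, 0, 0, 0))
  expect_equal(lm$ic, c(2, 1, 2, 2))
  expect_equal(unname(lm$heights[2, ]), c(0.5, 0, 0, 0.5))
  # uniform column: zero bits
  expect_equal(logoMatrix(c("A", "T", "C", "G"))$ic, 0)
  expect_true(all(abs(rowSums(lm$prob) - 1) < 1e-12))
  # invariant under record order
  withr::with_seed(3, {
    seqs <- randomSequences(40, 6)
    expect_equal(logoMatrix(seqs)$ic, logoMatrix(rev(seqs))$ic)
  })
  df <- as.data.frame(lm)
  expect_equal(nrow(df), 16L)
  expect_named(df, c("position", "tss_position", "base", "probability",
                     "height"))
})
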