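test_that("self-attention reduces to known closed forms", {
  # single position: softmax over one score is 1, output = the V row
  V1 <- matrix(c(2, 5), 1, 2)
  expect_equal(unname(selfAttention(matrix(1, 1, 3), matrix(2, 1, 3), V1)),
               unname(V1), ignore_attr = TRUE)
  # zero queries: uniform weights, every output row = column means of V
  V <- matrix(rnorm(8), 4, 2)
  out <- selfAttention(matrix(0, 4, 2), matrix(rnorm(8), 4, 2), V)
  for (i in 1:4) expect_equal(unname(out[i, ]), unname(colMeans(V)))
  expect_equal(unname(rowSums(attr(out, "weights"))), rep(1, 4))
})

test_that("self-attention matches direct evaluation of the formula", {
  withr::with_seed(13, {
    Q <- matrix(rnorm(4), 2, 2); K <- matrix(rnorm(4), 2, 2)
    V <- matrix(rnorm(4), 2, 2)
    # independent hand computation of softmax(QK^T/sqrt(dk)) V
    S <- (Q %*% t(K)) / sqrt(2)
    W <- t(apply(S, 1, function(r) exp(r) / sum(exp(r))))
    expect_equal(unname(selfAttention(Q, K, V)), unname(W %*% V),
                 ignore_attr = TRUE, tolerance = 1e-12)
    # attention rows always normalize
    for (i in 1:20) {
      n <- sample(2:6, 1)
      o <- selfAttention(matrix(rnorm(n * 3), n), matrix(rnorm(n * 3), n),
                         matrix(rnorm(n * 2), n))
      expect_equal(unname(rowSums(attr(o, "weights"))), rep(1, n),
                   tolerance = 1e-6)
    }
  })
  expect_error(selfAttention(matrix(0, 2, 2), matrix(0, 3, 2),
                             matrix(0, 3, 2)), "conformable")
})

test_that("masked attention excludes masked positions", {
  Q <- matrix(rnorm(6), 3, 2); K <- matrix(rnorm(6), 3, 2)
  V <- diag(3)[, 1:3]
  mask <- matrix(TRUE, 3, 3); mask[1, 3] <- FALSE
  out <- selfAttention(Q, K, V, mask)
  expect_equal(attr(out, "weights")[1, 3], 0)
  expect_equal(unname(rowSums(attr(out, "weights"))), rep(1, 3))
  expect_error(selfAttention(Q, K, V, matrix(FALSE, 3, 3)), "excluded")
})

test_that("the batched multi-head kernel agrees with selfAttention", {
  # dual route: the compiled batched path against the plain R primitive
  withr::with_seed(31, {
    B <- 3; L <- 5; nh <- 2; dk <- 4; d <- nh * dk
    Q <- matrix(rnorm(B * L * d), B * L, d)
    K <- matrix(rnorm(B * L * d), B * L, d)
    V <- matrix(rnorm(B * L * d), B * L, d)
    att <- promodiff:::mhaForward(Q, K, V, B, L, nh)
    for (b in seq_len(B)) for (h in seq_len(nh)) {
      rows <- ((b - 1) * L + 1):(b * L)
      cols <- ((h - 1) * dk + 1):(h * dk)
      ref <- selfAttention(Q[rows, cols], K[rows, cols], V[rows, cols])
      expect_equal(att$O[rows, cols], unname(ref), ignore_attr = TRUE,
                   tolerance = 1e-12)
      expect_equal(att$A[, , (b - 1) * nh + h],
                   unname(attr(ref, "weights")), tolerance = 1e-12)
    }
  })
})

test_that("pcc evaluates the correlation formula exactly", {
  expect_equal(pcc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pcc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pcc(c(1, 2, 3), c(1, 2, 4)), 0.98198051, tolerance = 1e-7)
  expect_error(pcc(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(pcc(1, 1), "length")
  withr::with_seed(17, {
    for (i in 1:200) {
      x <- rnorm(sample(3:40, 1)); y <- rnorm(length(x))
      expect_equal(pcc(x, y), cor(x, y), tolerance = 1e-12)
    }
  })
})

test_that("the combined loss behaves as w_mse*MSE + w_pcc*(1-PCC)", {
  y <- c(0.1, 0.5, 0.9, 0.3)
  expect_equal(combinedLoss(y, y), 0)
  # PCC term is shift-invariant
  expect_equal(combinedLoss(y + 5, y, wMse = 0, wPcc = 1), 0)
  # perfectly anticorrelated: 1 - (-1) = 2
  expect_equal(combinedLoss(-y, y, wMse = 0, wPcc = 1), 2)
  # joint permutation invariance
  o <- c(3, 1, 4, 2)
  expect_equal(combinedLoss(y[o] + 0.2, y[o]), combinedLoss(y + 0.2, y))
  expect_warning(l <- combinedLoss(rep(1, 4), y), "constant")
  expect_equal(l, mean((1 - y)^2))
  expect_error(combinedLoss(y, y, wMse = 0, wPcc = 0), "weights")
})

tinyConfig <- function(seed = 1, epochs = 4)
  predictorConfig(dModel = 16, heads = 2, layers = 1, ff = 24,
                  dropout = 0.1, epochs = epochs, batchSize = 16,
                  patience = 0, seed = seed)

test_that("transformer training is deterministic and predictions are
          pointwise functions of the sequence", {
  ps <- tinyPromoterSet(60, 10, seed = 6)
  m1 <- trainPredictor(ps, tinyConfig())
  m2 <- trainPredictor(ps, tinyConfig())
  expect_identical(m1@params, m2@params)
  seqs <- randomSequences(8, 10)
  p1 <- predictStrength(m1, seqs)
  expect_identical(p1, predictStrength(m2, seqs))
  expect_true(all(is.finite(p1)))
  # duplicates identical, permutation equivariant
  expect_equal(unname(predictStrength(m1, c(seqs[1], seqs[1]))),
               rep(unname(p1[1]), 2))
  o <- sample(8)
  expect_equal(unname(predictStrength(m1, seqs[o])), unname(p1[o]))
  # raw-scale output round-trips through the stored normalization
  raw <- predictStrength(m1, seqs, scale = "raw")
  expect_equal(unname(normalizeStrengths(raw, m1@norm)), unname(p1),
               tolerance = 1e-10)
  expect_error(predictStrength(m1, "ATCG"), "length")
  expect_error(trainPredictor(tinyPromoterSet(10, 8, strengths = FALSE),
                              tinyConfig()), "strength")
})

test_that("evaluatePredictor surfaces perfect and degenerate predictors", {
  ps <- tinyPromoterSet(12, 6, seed = 9)
  seqs <- as.character(promoterSequences(ps))
  truth <- normalizeStrengths(promoterStrengths(ps),
                              minMaxNormalize(logTransform(
                                promoterStrengths(ps)))$params)
  perfect <- replayPredictor(seqs, unname(truth), 6)
  perfect@norm <- minMaxNormalize(logTransform(promoterStrengths(ps)))$params
  expect_equal(evaluatePredictor(perfect, ps), 1)
  constant <- replayPredictor(seqs, rep(0.5, 12), 6)
  expect_error(evaluatePredictor(constant, ps), "degenerate")
})

test_that("the CNN baseline learns the fixture strength law", {
  fix <- generateFixture(fixtureSpec(count = 2000, seed = 11))
  sp <- splitDataset(fix, 0.2, seed = 5)
  m <- trainCNNBaseline(sp$train, cnnConfig(epochs = 12, seed = 7))
  expect_gt(evaluatePredictor(m, sp$test), 0.3)
  # determinism on a tiny instance
  ps <- tinyPromoterSet(40, 8, seed = 2)
  c1 <- trainCNNBaseline(ps, cnnConfig(hidden = 8, kernel = 3, epochs = 3,
                                       batchSize = 16, seed = 3))
  c2 <- trainCNNBaseline(ps, cnnConfig(hidden = 8, kernel = 3, epochs = 3,
                                       batchSize = 16, seed = 3))
  expect_identical(c1@params, c2@params)
})
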