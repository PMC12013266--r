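test_that("the linear schedule tabulates alpha-bar by cumulative product", {
  s1 <- buildSchedule(steps = 1, betaStart = 0.5, betaEnd = 0.5)
  expect_equal(s1@alphaBars, 0.5)
  s2 <- buildSchedule(steps = 2, betaStart = 0.1, betaEnd = 0.2)
  expect_equal(s2@betas, c(0.1, 0.2))
  expect_equal(s2@alphaBars, c(0.9, 0.72))
  s <- buildSchedule(200, 1e-4, 0.1)
  expect_true(all(diff(s@alphaBars) < 0))
  expect_lt(s@alphaBars[200], 1e-3)
  expect_error(buildSchedule(0), "positive")
  expect_error(buildSchedule(10, 0.5, 0.2), "betaStart")
  expect_error(buildSchedule(10, 0, 0.2), "betaStart")
})

test_that("forward noising interpolates between data and noise", {
  x0 <- oneHotEncode("ATCGATCG")
  eps <- matrix(rnorm(32), 8, 4)
  # beta -> 0: x_t is x0
  tiny <- buildSchedule(1, 1e-12, 1e-12)
  expect_equal(forwardNoise(x0, 1, tiny, eps), x0, tolerance = 1e-5,
               ignore_attr = TRUE)
  # alpha-bar -> 0: x_t is the noise draw
  heavy <- buildSchedule(60, 0.5, 0.5)
  expect_equal(forwardNoise(x0, 60, heavy, eps), eps, tolerance = 1e-4,
               ignore_attr = TRUE)
  # deterministic given the draw
  sch <- buildSchedule(50, 0.01, 0.2)
  expect_identical(forwardNoise(x0, 25, sch, eps),
                   forwardNoise(x0, 25, sch, eps))
  expect_error(forwardNoise(x0, 0, sch), "1..T")
  expect_error(forwardNoise(x0, 51, sch), "1..T")
  expect_error(forwardNoise(matrix(0, 3, 3), 1, sch), "L x 4")
})

test_that("closed-form noising matches the iterated single-step kernel in
          distribution", {
  sch <- buildSchedule(5, 0.05, 0.3)
  x0 <- c(1, 0, 0, 0)  # one one-hot row, tracked per channel
  n <- 20000
  withr::with_seed(21, {
    direct <- sapply(1:4, function(ch) {
      sqrt(sch@alphaBars[5]) * x0[ch] +
        sqrt(1 - sch@alphaBars[5]) * rnorm(n)
    })
    iterated <- matrix(rep(x0, each = n), n, 4)
    for (t in 1:5)
      iterated <- sqrt(sch@alphas[t]) * iterated +
        sqrt(sch@betas[t]) * matrix(rnorm(n * 4), n, 4)
    se <- sqrt(2 / n)  # rough SE for mean/var comparisons
    expect_lt(max(abs(colMeans(iterated) - colMeans(direct))), 5 * se)
    expect_lt(max(abs(apply(iterated, 2, var) - apply(direct, 2, var))),
              5 * se)
  })
})

test_that("training is seeded and reproducible end to end", {
  ps <- tinyPromoterSet(30, 8, seed = 4, strengths = FALSE)
  sch <- buildSchedule(20, 0.01, 0.3)
  fit <- function() trainDDPM(ps, sch, epochs = 3, batchSize = 16,
                              hidden = 16, blocks = 1, kernel = 3,
                              seed = 7, checkpointEvery = 2)
  m1 <- fit(); m2 <- fit()
  expect_identical(trainingLog(m1), trainingLog(m2))
  expect_identical(m1@params, m2@params)
  expect_equal(names(m1@checkpoints), c("2", "3"))
  g1 <- samplePromoters(m1, 5, seed = 1)
  g2 <- samplePromoters(m2, 5, seed = 1)
  expect_identical(as.character(promoterSequences(g1)),
                   as.character(promoterSequences(g2)))
  expect_false(identical(
    as.character(promoterSequences(samplePromoters(m1, 5, seed = 2))),
    as.character(promoterSequences(g1))))
  expect_error(trainDDPM(ps, sch, epochs = 0), "epochs")
})

test_that("samples have the training length and DNA alphabet", {
  ps <- tinyPromoterSet(20, 9, seed = 5, strengths = FALSE)
  m <- trainDDPM(ps, buildSchedule(10, 0.05, 0.4), epochs = 2,
                 batchSize = 8, hidden = 8, blocks = 1, kernel = 3,
                 seed = 1, checkpointEvery = 0)
  expect_identical(samplePromoters(m, 0, seed = 1), character(0))
  expect_error(samplePromoters(m, -1), ">= 0")
  g <- samplePromoters(m, 12, seed = 2)
  expect_equal(length(g), 12L)
  expect_equal(promoterLength(g), 9L)
  expect_false(any(grepl("[^ATCG]",
                         as.character(promoterSequences(g)))))
})

test_that("a zero noise predictor samples uniform bases (null model)", {
  p0 <- rapply(promodiff:::ddpmInitParams(8, 16, 1, 3),
               function(x) x * 0, how = "replace")
  m0 <- new("DiffusionModel", params = p0,
            schedule = buildSchedule(50, 0.01, 0.3), seqLength = 8L,
            config = list(hidden = 16L, blocks = 1L, kernel = 3L),
            trainingLog = data.frame(), checkpoints = list())
  g <- samplePromoters(m0, 400, seed = 9)
  chars <- strsplit(paste(as.character(promoterSequences(g)),
                          collapse = ""), "")[[1]]
  freqs <- table(factor(chars, levels = c("A", "T", "C", "G"))) /
    length(chars)
  # binomial SE at p = 0.25 over 3200 positions is ~0.0077
  expect_true(all(abs(freqs - 0.25) < 4 * sqrt(0.25 * 0.75 / length(chars))))
})

test_that("the DDPM memorizes a single-sequence dataset (overfit oracle)", {
  target <- "ATGCATTACGGA"
  one <- PromoterSet(rep(target, 300), ids = sprintf("r%d", 1:300))
  m <- trainDDPM(one, buildSchedule(100, 1e-4, 0.2), epochs = 100,
                 batchSize = 32, hidden = 32, blocks = 1, kernel = 3,
                 lr = 2e-3, seed = 2, checkpointEvery = 0)
  lg <- trainingLog(m)
  expect_lt(lg$heldout_l1[nrow(lg)], lg$heldout_l1[1L])
  g <- as.character(promoterSequences(samplePromoters(m, 200, seed = 3)))
  expect_gte(mean(g == target), 0.9)
})
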