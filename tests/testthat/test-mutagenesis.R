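additiveModel <- function(L, seed = 1) {
  withr::with_seed(seed,
    new("AdditivePredictor",
        weights = matrix(rnorm(L * 4), L, 4,
                         dimnames = list(NULL, c("A", "T", "C", "G")))))
}

test_that("mutation classification follows the A/T vs C/G group rule", {
  expect_equal(classifyMutation("A", "T"), "within_group")
  expect_equal(classifyMutation("G", "C"), "within_group")
  expect_equal(classifyMutation("A", "G"), "cross_group")
  bases <- c("A", "T", "C", "G")
  for (r in bases) for (a in setdiff(bases, r)) {
    # independent rule: within iff both bases sit in the same pairing group
    expected <- if ((r %in% c("A", "T")) == (a %in% c("A", "T")))
      "within_group" else "cross_group"
    expect_equal(classifyMutation(r, a), expected)
    expect_equal(classifyMutation(r, a), classifyMutation(a, r))
  }
  expect_error(classifyMutation("A", "A"), "differ")
  expect_error(classifyMutation("A", "N"), "bases")
})

test_that("saturation mutagenesis enumerates sampleSize x L x 3 records", {
  L <- 5
  ps <- tinyPromoterSet(4, L, seed = 2, strengths = FALSE)
  model <- additiveModel(L)
  recs <- saturationMutagenesis(ps, model, sampleSize = 2, seed = 1)
  expect_equal(nrow(recs), 2 * L * 3)
  expect_true(all(recs$ref != recs$alt))
  expect_equal(sort(unique(recs$index)), 0:(L - 1))
  expect_equal(recs$tss_position, recs$index - L)
  # every position contributes exactly 3 alternatives per sequence
  expect_true(all(table(recs$sequence_id, recs$index) == 3))
})

test_that("deltas from the additive oracle equal the weight differences", {
  L <- 6
  ps <- tinyPromoterSet(3, L, seed = 5, strengths = FALSE)
  model <- additiveModel(L, seed = 8)
  recs <- saturationMutagenesis(ps, model, sampleSize = 3, seed = 1)
  expected <- model@weights[cbind(recs$index + 1, match(recs$alt, colnames(model@weights)))] -
    model@weights[cbind(recs$index + 1, match(recs$ref, colnames(model@weights)))]
  expect_equal(recs$delta, expected, tolerance = 1e-12)
  # zero-weight model: every delta is exactly 0
  flat <- new("AdditivePredictor", weights = matrix(0, L, 4))
  expect_true(all(saturationMutagenesis(ps, flat, 3, seed = 1)$delta == 0))
})

test_that("position summaries aggregate by class and by base pair", {
  L <- 4
  ps <- tinyPromoterSet(2, L, seed = 3, strengths = FALSE)
  model <- additiveModel(L, seed = 4)
  recs <- saturationMutagenesis(ps, model, 2, seed = 1)
  summ <- positionSummaries(recs)
  expect_setequal(unique(summ$classSummary$class),
                  c("within_group", "cross_group"))
  expect_true(all(summ$classSummary$mean_abs_delta >= 0))
  # hand-check one cell against direct aggregation
  cell <- summ$classSummary[summ$classSummary$tss_position == -L &
                            summ$classSummary$class == "cross_group", ]
  manual <- mean(abs(recs$delta[recs$tss_position == -L &
                                recs$class == "cross_group"]))
  expect_equal(cell$mean_abs_delta, manual)
  # permutation invariance
  shuffled <- positionSummaries(recs[sample(nrow(recs)), ])
  expect_equal(shuffled$classSummary, summ$classSummary)
  expect_equal(shuffled$pairSummary, summ$pairSummary)
  # constant |delta|: mean_abs_delta = |d| everywhere
  recs2 <- recs; recs2$delta <- -0.7
  expect_true(all(positionSummaries(recs2)$classSummary$mean_abs_delta == 0.7))
})

test_that("region contrast compares intervals against their complement", {
  cs <- data.frame(tss_position = rep(-6:-1, 2),
                   class = rep(c("within_group", "cross_group"), each = 6),
                   mean_abs_delta = rep(0.5, 12))
  rc <- regionContrast(cs, list(core = c(-4, -3)))
  expect_equal(rc$region_mean, rc$complement_mean)
  cs$mean_abs_delta[cs$tss_position %in% c(-4, -3)] <- 2
  rc2 <- regionContrast(cs, list(core = c(-4, -3)))
  expect_true(all(rc2$region_mean > rc2$complement_mean))
  expect_equal(nrow(regionContrast(cs, list())), 0L)
  expect_error(regionContrast(cs, list(bad = c(-1, -5))), "malformed")
})
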