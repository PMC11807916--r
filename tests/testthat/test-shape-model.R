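# Statistical shape model: MVN sampling, plausibility scoring, filtering.

test_that("zero covariance returns the mean; sampling is seed-deterministic", {
  model <- defaultShapeModel(sdScale = 0)
  p <- sampleShapeParams(model, seed = 42)
  expect_equal(p, model@mean)
  model2 <- defaultShapeModel()
  expect_identical(sampleShapeParams(model2, 7), sampleShapeParams(model2, 7))
  expect_false(identical(sampleShapeParams(model2, 7),
                         sampleShapeParams(model2, 8)))
})

test_that("sample mean of a scalar parameter obeys the law of large numbers", {
  model <- defaultShapeModel()
  draws <- vapply(seq_len(1000), function(s)
    sampleShapeParams(model, s)[["body_a"]], numeric(1))
  sigma <- sqrt(model@covariance["body_a", "body_a"])
  expect_lt(abs(mean(draws) - model@mean[["body_a"]]),
            3 * sigma / sqrt(1000))
  # spread is right too (loose bound)
  expect_gt(sd(draws), 0.8 * sigma)
  expect_lt(sd(draws), 1.2 * sigma)
})

test_that("non-PSD covariance is rejected", {
  model <- defaultShapeModel()
  bad <- model
  bad@covariance[1, 1] <- -1
  expect_error(sampleShapeParams(bad, 1), "positive semi-definite")
})

test_that("plausibility score peaks at the mean and rejects outliers", {
  model <- defaultShapeModel()
  expect_equal(plausibilityScore(model@mean, model), 0)
  for (s in 1:20)
    expect_lte(plausibilityScore(sampleShapeParams(model, s), model), 0)
  # a point exactly 5 Mahalanobis units along one varying axis
  p <- model@mean
  sdv <- sqrt(model@covariance["body_a", "body_a"])
  p["body_a"] <- p["body_a"] + 5 * sdv
  expect_equal(plausibilityScore(p, model), -12.5)
  expect_false(isPlausible(p, model)) # threshold is Mahalanobis 3
  p3 <- model@mean; p3["body_a"] <- p3["body_a"] + 2.9 * sdv
  expect_true(isPlausible(p3, model))
})

test_that("score is invariant to reordering symmetric PV blocks", {
  model <- defaultShapeModel()
  # make the model block-symmetric: identical means/sds across the PV blocks
  nm <- names(model@mean)
  blocks <- lapply(atriarecon:::PV_NAMES, function(pv)
    grep(paste0("^", pv, "_"), nm))
  mu <- model@mean
  for (b in blocks) mu[b] <- mu[blocks[[1]]]
  sym <- new("ShapeModelSpec", mean = mu, covariance = model@covariance,
             threshold = model@threshold)
  params <- sampleShapeParams(sym, 5)
  permuted <- params
  perm <- c(3, 1, 4, 2) # arbitrary reordering of the four PV blocks
  for (i in seq_along(blocks))
    permuted[blocks[[i]]] <- params[blocks[[perm[i]]]]
  expect_equal(plausibilityScore(permuted, sym),
               plausibilityScore(params, sym), tolerance = 1e-12)
})
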