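test_that("identical strata average to the single-stratum parameters", {
  sim <- sampleCohort(simPreset("recovery", m = 3, n = 60, seed = 71))
  co <- sim$cohort
  st <- new("StratifiedCohort", strata = list(co, co), labels = c("a", "b"))
  mf <- metaFit(st, 0.5, 0.5, seed = 2)
  single <- fitCda(co, 0.5, 0.5)$params
  expect_equal(mf$params@h, single@h, tolerance = 1e-6)
  expect_equal(mf$params@J, single@J, tolerance = 1e-6)
  expect_equal(mf$weights, c(0.5, 0.5))
  expect_true(validObject(mf$params))  # averaging keeps the zero reference
})

test_that("stratum weights are proportional to sample sizes", {
  co <- randomCohort(100, 3, seed = 72)
  st <- stratifyCohort(co, rep(c("u", "v"), c(60, 40)), "binary-label")
  mf <- metaFit(st, 1, 1, seed = 1, refit = FALSE)
  expect_equal(mf$weights, c(0.6, 0.4))
  expect_length(mf$predictions, 100L)
  tiny <- stratifyCohort(randomCohort(8, 2, seed = 3), rep(c("u", "v"), 4),
                         "binary-label")
  expect_error(metaFit(tiny, 1, 1, folds = 5), "folds")
})

test_that("a single-stratum meta-analysis reduces to plain optimization", {
  sim <- sampleCohort(simPreset("power", m = 4, n = 80, seed = 73))
  co <- sim$cohort
  st <- new("StratifiedCohort", strata = list(co), labels = "all")
  grids <- c(0.1, 10)
  mm <- optimizeMetaPenalizers(st, lambda1Grid = grids,
                               lambda2Grid = c(grids, Inf), seed = 6,
                               refit = FALSE)
  oo <- optimizePenalizers(co, lambda1Grid = grids,
                           lambda2Grid = c(grids, Inf), seed = 6,
                           refit = FALSE)
  expect_equal(mm$R, oo@R, tolerance = 1e-10)
  expect_equal(mm$lambda1, oo@lambda1)
  expect_identical(mm$lambda2, oo@lambda2)
})

test_that("stratified averaging absorbs a covariate-driven phenotype shift", {
  # two strata with different allele frequencies and shifted trait means but
  # no genetic effect: the pooled naive fit sees a spurious association that
  # per-stratum fitting removes
  withr::with_seed(74, {
    naiveR <- metaR <- numeric(5)
    for (r in 1:5) {
      G <- rbind(matrix(rbinom(50 * 5, 1, 0.25), 50, 5),
                 matrix(rbinom(50 * 5, 1, 0.75), 50, 5))
      y <- c(rnorm(50, -0.8), rnorm(50, 0.8))
      co <- cdaCohort(G, phenotype = y, encoding = "dominant")
      st <- stratifyCohort(co, rep(c(1, 2), c(50, 50)), "binary-label")
      metaR[r] <- metaFit(st, 0.1, Inf, seed = r, refit = FALSE)$R
      naiveR[r] <- crossValidateCda(co, 0.1, Inf, seed = r,
                                    refit = FALSE)@R
    }
    expect_gt(median(naiveR), 0.3)
    expect_gt(median(naiveR), median(metaR) + 0.2)
  })
})

test_that("meta-analysis results are reproducible from the seed", {
  co <- randomCohort(60, 3, seed = 75)
  st <- stratifyCohort(co, rep(c("x", "y"), 30), "binary-label")
  a <- optimizeMetaPenalizers(st, lambda1Grid = c(0.1, 10),
                              lambda2Grid = c(1, Inf), seed = 8,
                              refit = FALSE)
  b <- optimizeMetaPenalizers(st, lambda1Grid = c(0.1, 10),
                              lambda2Grid = c(1, Inf), seed = 8,
                              refit = FALSE)
  expect_identical(a$R, b$R)
  expect_identical(a$lambda1, b$lambda1)
})
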