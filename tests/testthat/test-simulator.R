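test_that("parameter draws have the block structure and are reproducible", {
  sp <- simPreset("recovery", m = 5, n = 10, seed = 51)
  p <- drawCdaParams(sp)
  expect_equal(dim(p@h), c(5L, 2L))       # 5 field entries per order
  expect_equal(sum(p@J[, , 2] != 0) / 2, 10)  # 10 free couplings per order
  p2 <- drawCdaParams(sp)
  expect_identical(p@h, p2@h)
  # degenerate sd: all entries equal the block means
  sp0 <- simSpec(3, 5, "dominant", h0 = c(-0.3, 0), h1 = c(0.3, 0),
                 J0 = c(0.05, 0), J1 = c(0.1, 0), seed = 1)
  p0 <- drawCdaParams(sp0)
  expect_true(all(p0@h[, 1] == -0.3) && all(p0@h[, 2] == 0.3))
  up <- upper.tri(p0@J[, , 1])
  expect_true(all(p0@J[, , 1][up] == 0.05) && all(p0@J[, , 2][up] == 0.1))
  expect_error(simSpec(25, 10, "dominant"), "m <= 20")
  expect_error(simSpec(13, 10, "genotypic"), "m <= 12")
})

test_that("enumerated conditional tables are exact distributions", {
  pz <- newCdaParams(3, "dominant")
  expect_equal(as.numeric(enumerateConditional(pz, 0.7)), rep(1 / 8, 8))
  p1 <- newCdaParams(1, "dominant")
  p1@h[1, 1] <- log(3)
  tab <- enumerateConditional(p1, 0)
  expect_equal(as.numeric(tab), c(1 / 4, 3 / 4))
  expect_equal(attr(tab, "logZ"), log(4))
  pr <- randomParams(6, "dominant", seed = 52)
  for (y in seq(-2.5, 2.5, length.out = 11))
    expect_equal(sum(enumerateConditional(pr, y)), 1, tolerance = 1e-12)
  # the table depends on y iff some phenotype-linear parameter is nonzero
  pn <- drawCdaParams(simPreset("null", m = 4, n = 2, seed = 53))
  expect_equal(as.numeric(enumerateConditional(pn, -2)),
               as.numeric(enumerateConditional(pn, 2)), tolerance = 1e-14)
  pa <- drawCdaParams(simPreset("power", m = 4, n = 2, seed = 53))
  expect_gt(max(abs(enumerateConditional(pa, -2) -
                    enumerateConditional(pa, 2))), 1e-4)
})

test_that("sampled cohorts follow the enumerated distribution", {
  n <- 4000
  sp <- simPreset("null", m = 3, n = n, seed = 54)
  sim <- sampleCohort(sp)
  G <- genotypes(sim$cohort)
  y <- phenotype(sim$cohort)
  expect_lt(abs(mean(y)), 4 / sqrt(n))
  # null model: genotype distribution independent of y
  tab <- enumerateConditional(sim$params, 0)
  genos <- attr(tab, "genotypes")
  key <- apply(G, 1, paste, collapse = "")
  emp <- table(factor(key, levels = apply(genos, 1, paste, collapse = "")))
  expect_lt(max(abs(emp / n - as.numeric(tab))), 4 / sqrt(n))
  for (i in 1:3) expect_lt(abs(cor(G[, i], y)), 4 / sqrt(n))
  sim2 <- sampleCohort(sp)
  expect_identical(genotypes(sim2$cohort), G)
})

test_that("a single power-experiment replicate yields degenerate power", {
  sp <- simPreset("power", m = 4, n = 80, seed = 55)
  pe <- powerExperiment(sp, replicates = 1, lambdaGrid = c(0.1, 10),
                       nPerm = 3, seed = 5)
  expect_true(pe$summary$cda_power %in% c(0, 1))
  expect_true(pe$summary$rr_power %in% c(0, 1))
  expect_equal(nrow(pe$results), 1L)
})
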