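test_that("SNPs map to pathways by gene-window distance with a size filter", {
  info <- data.frame(snp_id = paste0("s", 1:6), chrom = "1",
                     pos = c(60000L, 49999L, 100500L, 155000L, 155001L,
                             500000L))
  spans <- data.frame(gene = c("GA", "GB"), chrom = "1",
                      start = c(100000L, 490000L), end = c(105000L, 495000L))
  sets <- list(pw1 = c("GA"), pw2 = c("GB", "MISSING"))
  expect_message(
    maps <- mapSnpsToPathways(info, spans, sets, windowBp = 50000,
                              minSnps = 1),
    "absent")
  # distance 40000 in; 50001 out; inside span in; exactly 50000 in
  expect_equal(maps$pw1$snpIndices, c(1L, 3L, 4L))
  expect_equal(maps$pw2$snpIndices, 6L)
  # the >= 5 SNP filter drops small pathways
  few <- mapSnpsToPathways(info, spans, list(pw1 = "GA"), windowBp = 50000,
                           minSnps = 5)
  expect_length(few, 0L)
  # gene order is irrelevant (set semantics)
  s1 <- mapSnpsToPathways(info, spans, list(p = c("GA", "GB")), minSnps = 1)
  s2 <- mapSnpsToPathways(info, spans, list(p = c("GB", "GA")), minSnps = 1)
  expect_identical(s1$p$snpIndices, s2$p$snpIndices)
})

test_that("BED and GMT files load with correct coordinate conventions", {
  bed <- writeTestBed(genes = data.frame(gene = c("GA", "GB"), chrom = "1",
                                         start0 = c(99999L, 200L),
                                         end = c(105000L, 300L)))
  spans <- readGeneSpansBed(bed)
  expect_equal(spans$start, c(100000L, 201L))  # 0-based half-open -> 1-based
  expect_equal(spans$end, c(105000L, 300L))
  gmt <- writeTestGmt(sets = list(alpha = c("GA", "GB"), beta = "GB"))
  sets <- readGmt(gmt)
  expect_equal(sets$alpha, c("GA", "GB"))
  expect_equal(sets$beta, "GB")
})

test_that("the pathway scan ranks a planted-signal pathway first", {
  # couplings among SNPs 1-5 carry the signal; SNPs 6-12 are null
  spec <- simSpec(12, 220, "dominant", h0 = c(0, 0.1), J0 = c(0, 0.1),
                  J1 = c(0.35, 0.05), seed = 81)
  params <- drawCdaParams(spec)
  mask <- matrix(0, 12, 12)
  mask[1:5, 1:5] <- 1
  params@J[, , 2] <- params@J[, , 2] * mask
  sim <- sampleCohort(spec, params)
  pws <- list(sig = list(name = "sig", snpIndices = 1:5, nSnpsPrePrune = 5L),
              bg = list(name = "bg", snpIndices = 6:12, nSnpsPrePrune = 7L))
  res <- pathwayScan(sim$cohort, pws, covariate = NULL, prune = FALSE,
                     lambda1Grid = c(0.1, 10), lambda2Grid = c(0.1, 10, Inf),
                     nPerm = 5, seed = 4)
  expect_equal(res$status, c("ok", "ok"))
  expect_lt(res$p[res$pathway == "sig"], res$p[res$pathway == "bg"])
  expect_lt(res$p[res$pathway == "sig"], 0.05)
  res2 <- pathwayScan(sim$cohort, pws, covariate = NULL, prune = FALSE,
                      lambda1Grid = c(0.1, 10),
                      lambda2Grid = c(0.1, 10, Inf), nPerm = 5, seed = 4)
  expect_identical(res$p, res2$p)
})

test_that("split-half heritability is null-safe, seeded and scale invariant", {
  sim <- sampleCohort(simPreset("power", m = 4, n = 200, seed = 82))
  G <- genotypes(sim$cohort)
  y <- phenotype(sim$cohort)
  grids <- c(0.1, 10)
  withr::with_seed(83, {
    r2Perm <- vapply(1:3, function(i)
      heritabilitySplitHalf(G, sample(y), lambda1Grid = grids,
                            lambda2Grid = c(grids, Inf), seed = 5,
                            encoding = "dominant")$r2, 0)
  })
  expect_lt(median(r2Perm), 0.1)
  h1 <- heritabilitySplitHalf(G, y, lambda1Grid = grids,
                              lambda2Grid = c(grids, Inf), seed = 5,
                              encoding = "dominant")
  h2 <- heritabilitySplitHalf(G, y, lambda1Grid = grids,
                              lambda2Grid = c(grids, Inf), seed = 5,
                              encoding = "dominant")
  expect_identical(h1$r2, h2$r2)
  expect_true(h1$r2 >= 0 && h1$r2 <= 1)
  expect_true(h1$ci95[1] <= h1$r2 && h1$r2 <= h1$ci95[2])
  # affine phenotype rescaling leaves r2 unchanged
  h3 <- heritabilitySplitHalf(G, 3 * y - 7, lambda1Grid = grids,
                              lambda2Grid = c(grids, Inf), seed = 5,
                              encoding = "dominant")
  expect_equal(h3$r2, h1$r2, tolerance = 1e-6)
  expect_error(heritabilitySplitHalf(G[1:30, ], y[1:30],
                                     encoding = "dominant"), "n >= 40")
})
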