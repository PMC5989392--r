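test_that("VCF genotypes load as alternate-allele counts with metadata", {
  path <- writeTestVcf()
  co <- loadGenotypes(path, "vcf")
  expect_s4_class(co, "CdaCohort")
  expect_equal(unname(genotypes(co)),
               rbind(c(0, 1, 2), c(1, 2, 0)))
  expect_equal(snpInfo(co)$snp_id, c("rs1", "rs2", "rs3"))
  expect_equal(snpInfo(co)$pos, c(100L, 200L, 300L))
  expect_length(phenotype(co), 0L)
})

test_that("VCF loading rejects empty and duplicate-id files", {
  empty <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "s1"), collapse = "\t")),
             empty)
  expect_error(readVcfGenotypes(empty), "no variant")
  dup <- writeTestVcf(ids = c("rs1", "rs1", "rs3"))
  expect_error(readVcfGenotypes(dup), "duplicate")
})

test_that("dosage TSV passes fractional values through and flags them", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tsnpA\tsnpB", "s1\t1.4\t0", "s2\t2\t1"), path)
  expect_message(co <- readDosageTsv(path), "fractional")
  expect_equal(genotypes(co)["s1", "snpA"], 1.4)
  bad <- tempfile(fileext = ".tsv")
  writeLines("sample", bad)
  expect_error(readDosageTsv(bad), "at least one SNP")
})

test_that("dosage rounding is nearest-integer, half away from zero, idempotent", {
  g <- matrix(c(1.4, 1.5, 0.0, 0.49, 2.0, 0.5), 2, 3)
  r <- roundDosages(g)
  expect_equal(as.numeric(r), c(1, 2, 0, 0, 2, 1))
  expect_identical(roundDosages(r), r)
  expect_error(roundDosages(matrix(2.1)), "0, 2")
})

test_that("phenotype transforms recompute the marginal model exactly", {
  tr <- transformPhenotype(0.5, "log_eps", eps = 0)
  expect_equal(tr$y, log(0.5))
  y <- runif(40)
  none <- transformPhenotype(y, "none")
  expect_identical(none$y, y)
  expect_equal(none$muHat, mean(y))
  lg <- transformPhenotype(y, "log_eps", eps = 0.01)
  expect_equal(lg$muHat, mean(lg$y), tolerance = 1e-12)
  expect_equal(lg$sigma2Hat, var(lg$y), tolerance = 1e-12)
  expect_error(transformPhenotype(c(0, 0.5), "log_eps", eps = 0),
               "y \\+ eps > 0")
})

test_that("dominant recoding collapses 2 to 1; genotypic is identity", {
  g <- matrix(c(0, 1, 2), 1, 3)
  expect_equal(as.numeric(recodeGenotypes(g, "dominant")), c(0, 1, 1))
  expect_equal(as.numeric(recodeGenotypes(g, "genotypic")), c(0, 1, 2))
  z <- matrix(0, 4, 1)
  expect_equal(recodeGenotypes(z, "dominant"), z)
  co <- cdaCohort(matrix(c(0, 2), 2, 1))
  expect_equal(encoding(recodeGenotypes(co, "dominant")), "dominant")
})

test_that("LD pruning removes later duplicates and keeps independent SNPs", {
  set.seed(4)
  a <- rbinom(200, 1, 0.5)
  b <- rbinom(200, 1, 0.5)
  G <- cbind(a, a, b)
  pruned <- ldPrune(G, window = 10, step = 2, r2Threshold = 0.9)
  expect_equal(attr(pruned, "kept"), c(1L, 3L))
  # exact-duplicate pair at threshold 1.0 is still removed
  pruned1 <- ldPrune(cbind(a, a), window = 5, step = 1, r2Threshold = 1)
  expect_equal(attr(pruned1, "kept"), 1L)
  expect_warning(ldPrune(cbind(a, rep(1, 200)), window = 5, step = 1),
                 "monomorphic")
})

test_that("no retained within-window pair exceeds the pruning threshold", {
  set.seed(11)
  for (rep in 1:5) {
    base <- matrix(rbinom(60 * 4, 1, 0.5), 60, 4)
    # interleave noisy copies to create high-LD pairs
    G <- cbind(base,
               apply(base, 2, function(col) {
                 flip <- rbinom(60, 1, 0.05)
                 ifelse(flip == 1, 1 - col, col)
               }))[, sample(8)]
    window <- 4L; thr <- 0.8
    pruned <- ldPrune(G, window = window, step = 2L, r2Threshold = thr)
    kept <- attr(pruned, "kept")
    for (st in seq(1, 7, by = 2)) {
      win <- kept[kept >= st & kept <= st + window - 1]
      if (length(win) < 2) next
      r2 <- suppressWarnings(cor(G[, win]))^2
      expect_true(all(r2[upper.tri(r2)] < thr, na.rm = TRUE))
    }
  }
})

test_that("stratification partitions the cohort", {
  co <- randomCohort(8, 3)
  st <- stratifyCohort(co, rep(c("M", "F"), 4), "binary-label")
  expect_equal(strataSizes(st), c(4L, 4L))
  ids <- unlist(lapply(strata(st), sampleIds))
  expect_setequal(ids, sampleIds(co))
  expect_equal(anyDuplicated(ids), 0L)
  st2 <- stratifyCohort(co, c(1, 2, 3, 4, 5, 6, 7, 8), "median-split")
  expect_equal(strataSizes(st2), c(4L, 4L))
  expect_error(stratifyCohort(co, rep(1, 8), "median-split"), "empty")
  expect_error(stratifyCohort(co, rep("x", 8), "binary-label"),
               "two distinct")
})

test_that("phenotype tables attach by sample id and drop missing", {
  co <- randomCohort(4, 2)
  ph <- data.frame(sample_id = c("sample2", "sample1", "sample4"),
                   bw = c(10, 20, NA))
  expect_message(out <- attachPhenotype(co, ph, "bw"), "dropped")
  expect_equal(sampleIds(out), c("sample1", "sample2"))
  expect_equal(phenotype(out), c(20, 10))
})

test_that("missing genotypes are mode-imputed or dropped", {
  G <- matrix(c(0, 1, 1, NA, 2, 2, NA, 2), 4, 2)
  co <- cdaCohort(G, phenotype = rnorm(4))
  expect_message(mi <- imputeMissing(co, "mode"), "imputed 2")
  expect_equal(genotypes(mi)[4, 1], 1)
  expect_equal(genotypes(mi)[3, 2], 2)
  expect_message(dr <- imputeMissing(co, "drop"), "dropped 2")
  expect_equal(nSamples(dr), 2L)
})
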