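# Small plain-text fixtures written on the fly, plus quick data builders.

writeTestVcf <- function(path = tempfile(fileext = ".vcf"),
                         gts = rbind(c("0/0", "0/1"), c("0/1", "1/1"),
                                     c("1/1", "0/0")),
                         ids = paste0("rs", seq_len(nrow(gts))),
                         chrom = rep("1", nrow(gts)),
                         pos = seq_len(nrow(gts)) * 100L,
                         samples = paste0("s", seq_len(ncol(gts)))) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t")), con)
  for (r in seq_len(nrow(gts)))
    writeLines(paste(c(chrom[r], pos[r], ids[r], "A", "G", ".", "PASS",
                       ".", "GT", gts[r, ]), collapse = "\t"), con)
  path
}

writeTestBed <- function(path = tempfile(fileext = ".bed"), genes) {
  # genes: data.frame(gene, chrom, start0, end) in BED 0-based half-open
  writeLines(sprintf("%s\t%d\t%d\t%s", genes$chrom, genes$start0,
                     genes$end, genes$gene), path)
  path
}

writeTestGmt <- function(path = tempfile(fileext = ".gmt"), sets) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), ""), path)
  path
}

# cohort with independent Bernoulli/binomial genotypes and N(0,1) phenotype
randomCohort <- function(n, m, encoding = "dominant", freq = 0.4, seed = 1) {
  withr::with_seed(seed, {
    L <- if (encoding == "dominant") 1L else 2L
    G <- matrix(rbinom(n * m, L, freq), n, m)
    cdaCohort(G, phenotype = rnorm(n), encoding = encoding)
  })
}

# random parameters with every free entry drawn N(0, sd)
randomParams <- function(m, encoding = "dominant", sd = 0.3, seed = 1) {
  sp <- simSpec(m, 2L, encoding, h0 = c(0, sd), h1 = c(0, sd),
                J0 = c(0, sd), J1 = c(0, sd), seed = seed)
  drawCdaParams(sp)
}
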