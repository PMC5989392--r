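#' Map SNPs to pathway gene sets
#'
#' A SNP belongs to a pathway when its position lies within
#' \code{windowBp} (boundary inclusive) of the span of any member gene,
#' distance zero inside the span; the pathway's SNP set is the union over
#' its genes.  Pathways with fewer than \code{minSnps} SNPs are dropped.
#' Genes absent from the span table are logged and skipped.  The result is
#' independent of gene listing order (set semantics).
#'
#' @param g a \code{\linkS4class{CdaCohort}} (SNP chromosome/position
#'   metadata required) or a \code{snpInfo}-style data.frame
#' @param spans data.frame from \code{\link{readGeneSpansBed}} (columns
#'   \code{gene}, \code{chrom}, \code{start}, \code{end}, 1-based
#'   inclusive)
#' @param sets named list of gene-symbol vectors (see \code{\link{readGmt}})
#' @param windowBp flanking window in base pairs
#' @param minSnps minimum SNP count for a pathway to be retained
#' @return named list; each element has \code{name}, \code{genes},
#'   \code{genesFound}, \code{snpIndices} (sorted, unique),
#'   \code{nSnpsPrePrune}
#' @export
mapSnpsToPathways <- function(g, spans, sets, windowBp = 50000L,
                              minSnps = 5L) {
  info <- if (is(g, "CdaCohort")) snpInfo(g) else g
  if (any(is.na(info$chrom)) || any(is.na(info$pos)))
    stop("SNP chromosome/position metadata required for pathway mapping")
  snpGR <- GenomicRanges::GRanges(info$chrom,
                                  IRanges::IRanges(info$pos, info$pos))
  geneGR <- GenomicRanges::GRanges(spans$chrom,
                                   IRanges::IRanges(spans$start, spans$end))
  names(geneGR) <- spans$gene
  out <- list()
  for (nm in names(sets)) {
    genes <- unique(sets[[nm]])
    found <- genes[genes %in% spans$gene]
    if (length(found) < length(genes))
      message("pathway '", nm, "': ", length(genes) - length(found),
              " gene(s) absent from the span table, skipped")
    if (!length(found)) next
    sel <- spans$gene %in% found
    ext <- GenomicRanges::GRanges(spans$chrom[sel],
      IRanges::IRanges(pmax(1L, spans$start[sel] - windowBp),
                       spans$end[sel] + windowBp))
    hits <- sort(unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(snpGR, ext))))
    if (length(hits) < minSnps) next
    out[[nm]] <- list(name = nm, genes = genes, genesFound = found,
                      snpIndices = hits, nSnpsPrePrune = length(hits))
  }
  out
}

#' Pathway-level collective association scan
#'
#' For each pathway: extract its SNPs, LD-prune (optional), stratify the
#' samples by the covariate, run the stratified meta-analysis with
#' penalizer optimization, estimate the null mean R0 from phenotype
#' permutations, and compute the Fisher-transform p-value.  Multiplicity
#' columns (Bonferroni, Benjamini-Hochberg FDR) are added across all
#' scanned pathways.  Deterministic given the seed, and pathway results do
#' not depend on scan order.
#'
#' @param cohort a \code{\linkS4class{CdaCohort}} with phenotype set
#' @param pathways list from \code{\link{mapSnpsToPathways}}
#' @param covariate stratification covariate (length n), or \code{NULL}
#'   for an unstratified scan
#' @param stratRule passed to \code{\link{stratifyCohort}}
#' @param prune apply \code{\link{ldPrune}} per pathway
#' @param pruneWindow,pruneStep,pruneR2 pruning parameters
#' @param lambda1Grid,lambda2Grid penalizer grids
#' @param folds,nPerm,seed,alpha as elsewhere
#' @return data.frame, one row per pathway: SNP counts before/after
#'   pruning, selected penalizers, \code{R}, \code{R0}, \code{z}, \code{p},
#'   multiplicity columns and \code{status}
#' @export
pathwayScan <- function(cohort, pathways, covariate = NULL,
                        stratRule = "binary-label", prune = TRUE,
                        pruneWindow = 50L, pruneStep = 5L, pruneR2 = 0.9,
                        lambda1Grid = defaultLambdaGrid(),
                        lambda2Grid = c(defaultLambdaGrid(), Inf),
                        folds = 5L, nPerm = 10L, seed = 1L, alpha = 0.05) {
  stopifnot(is(cohort, "CdaCohort"), length(phenotype(cohort)) > 0L)
  rows <- vector("list", length(pathways))
  for (k in seq_along(pathways)) {
    pw <- pathways[[k]]
    t0 <- proc.time()[3L]
    sub <- cohort[, pw$snpIndices]
    if (prune) sub <- ldPrune(sub, pruneWindow, pruneStep, pruneR2)
    nPost <- nSnps(sub)
    if (nPost == 0L) {
      rows[[k]] <- data.frame(pathway = pw$name,
                              n_snps_pre = pw$nSnpsPrePrune,
                              n_snps_post = 0L, lambda1 = NA_real_,
                              lambda2 = NA_real_, R = NA_real_,
                              R0 = NA_real_, z = NA_real_, p = NA_real_,
                              seconds = NA_real_, status = "skipped")
      next
    }
    strat <- if (is.null(covariate))
      new("StratifiedCohort", strata = list(sub), labels = "all")
    else stratifyCohort(sub, covariate, stratRule)
    mf <- optimizeMetaPenalizers(strat, lambda1Grid = lambda1Grid,
                                 lambda2Grid = lambda2Grid, folds = folds,
                                 seed = seed, refit = FALSE)
    R0 <- estimateNullR0(strat, list(lambda1Grid = lambda1Grid,
                                     lambda2Grid = lambda2Grid),
                         nPerm = nPerm, folds = folds, seed = seed + k)
    sig <- fisherPvalue(mf$R, R0, mf$nSamples)
    rows[[k]] <- data.frame(pathway = pw$name,
                            n_snps_pre = pw$nSnpsPrePrune,
                            n_snps_post = nPost, lambda1 = mf$lambda1,
                            lambda2 = mf$lambda2, R = mf$R, R0 = R0,
                            z = sig$z, p = sig$p,
                            seconds = round(proc.time()[3L] - t0, 2),
                            status = "ok")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- out$status == "ok"
  out$p_bonferroni <- NA_real_
  out$bonferroni_flag <- NA
  out$p_bh <- NA_real_
  out$fdr_flag <- NA
  if (any(ok)) {
    adj <- adjustMultiplicity(out$p[ok], alpha = alpha)
    out$p_bonferroni[ok] <- adj$p_bonferroni
    out$bonferroni_flag[ok] <- adj$bonferroni_flag
    out$p_bh[ok] <- adj$p_bh
    out$fdr_flag[ok] <- adj$fdr_flag
  }
  out
}

#' Split-half broad-sense heritability of a SNP set
#'
#' The cohort is split into random halves (seeded).  Penalizers are tuned
#' by cross-validated R on the first half; the model is then fitted on the
#' second half at those penalizers and the broad-sense proportion of
#' variance explained is the squared correlation r^2 between the
#' self-predicted and actual trait values of the second half.  The 95%
#' interval comes from the Fisher transform of the correlation.  Unlike
#' the cross-validated score R, r^2 includes the (penalized) in-sample
#' fit, which is the intended proportion-of-variance reading.
#'
#' @param g a \code{\linkS4class{CdaCohort}} or genotype matrix
#' @param y phenotype (taken from the cohort when omitted)
#' @param lambda1Grid,lambda2Grid penalizer grids for the tuning half
#' @param folds,seed,encoding as elsewhere
#' @return list of class \code{"HeritabilityEstimate"}: \code{r2},
#'   \code{ci95}, \code{lambda1}, \code{lambda2}, \code{n}
#' @export
heritabilitySplitHalf <- function(g, y = NULL,
                                  lambda1Grid = defaultLambdaGrid(),
                                  lambda2Grid = c(defaultLambdaGrid(), Inf),
                                  folds = 5L, seed = 1L, encoding = NULL) {
  d <- .resolveData(g, y, encoding)
  n <- nrow(d$G)
  if (n < 40L) stop("split-half heritability needs n >= 40")
  perm <- .withSeed(seed, sample.int(n))
  half1 <- perm[seq_len(n %/% 2L)]
  half2 <- perm[(n %/% 2L + 1L):n]
  tune <- optimizePenalizers(d$G[half1, , drop = FALSE], d$y[half1],
                             lambda1Grid = lambda1Grid,
                             lambda2Grid = lambda2Grid, folds = folds,
                             seed = seed, refit = FALSE,
                             encoding = d$encoding)
  G2 <- d$G[half2, , drop = FALSE]
  y2 <- d$y[half2]
  fit <- fitCda(G2, tune@lambda1, tune@lambda2, y = y2,
                encoding = d$encoding)
  yhat <- bayesPredict(fit$params, G2, mean(y2), var(y2))
  if (sd(yhat) == 0) {
    warning("degenerate self-predictions; r2 set to 0")
    r <- 0
  } else r <- cor(y2, yhat)
  n2 <- length(y2)
  lo <- tanh(atanh(r) - 1.96 / sqrt(n2 - 3))
  hi <- tanh(atanh(r) + 1.96 / sqrt(n2 - 3))
  ci <- if (lo <= 0 && hi >= 0) c(0, max(lo^2, hi^2))
        else sort(c(lo^2, hi^2))
  structure(list(r2 = r^2, ci95 = ci, lambda1 = tune@lambda1,
                 lambda2 = tune@lambda2, n = n2, r = r),
            class = "HeritabilityEstimate")
}

#' @export
print.HeritabilityEstimate <- function(x, ...) {
  cat(sprintf(
    "HeritabilityEstimate: r2 = %.4f [%.4f, %.4f] at lambda1 = %.4g, lambda2 = %s (n = %d)\n",
    x$r2, x$ci95[1], x$ci95[2], x$lambda1,
    if (is.infinite(x$lambda2)) "Inf" else sprintf("%.4g", x$lambda2), x$n))
  invisible(x)
}
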