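#' Round fractional dosages to integral allele counts
#'
#' Nearest integer in \{0, 1, 2\}, half-values rounded away from zero
#' (1.5 becomes 2).  Idempotent.
#'
#' @param g a \code{\linkS4class{CdaCohort}} or numeric matrix with entries
#'   in [0, 2]
#' @return same type as the input
#' @export
roundDosages <- function(g) {
  G <- if (is(g, "CdaCohort")) g@genotypes else as.matrix(g)
  if (any(G < 0 | G > 2, na.rm = TRUE))
    stop("dosages must lie in [0, 2]")
  R <- floor(G + 0.5)  # half away from zero for non-negative input
  if (is(g, "CdaCohort")) { g@genotypes <- R; g } else R
}

#' Transform a phenotype
#'
#' \code{kind = "log_eps"} applies y -> ln(y + eps), the transform used for
#' fractional traits bounded in [0, 1]; \code{eps} defaults to 1e-3 of the
#' trait range.  The sample mean and variance defining the marginal
#' phenotype model are recomputed from the transformed values.
#'
#' @param y numeric trait values, or a \code{\linkS4class{CdaCohort}} whose
#'   phenotype is transformed in place
#' @param kind \code{"none"} or \code{"log_eps"}
#' @param eps small positive constant added inside the log
#' @return for numeric input, a list with \code{y}, \code{muHat},
#'   \code{sigma2Hat}, \code{transform}; for a cohort, the updated cohort
#' @examples
#' transformPhenotype(c(0.2, 0.5, 0.9), "log_eps", eps = 0)$y
#' @export
transformPhenotype <- function(y, kind = c("none", "log_eps"), eps = NULL) {
  kind <- match.arg(kind)
  if (is(y, "CdaCohort")) {
    tr <- transformPhenotype(phenotype(y), kind, eps)
    y@phenotype <- tr$y
    y@transform <- tr$transform
    return(y)
  }
  y <- as.numeric(y)
  if (kind == "log_eps") {
    if (is.null(eps)) eps <- 1e-3 * diff(range(y))
    if (any(y + eps <= 0))
      stop("log transform needs y + eps > 0 for every value")
    y <- log(y + eps)
  } else eps <- NA_real_
  list(y = y, muHat = mean(y), sigma2Hat = var(y),
       transform = list(kind = kind, eps = eps))
}

#' Recode genotypes
#'
#' The dominant scheme collapses allele count 2 to 1, so genotype levels
#' become \{0, 1\}; the genotypic scheme keeps \{0, 1, 2\} (identity).
#'
#' @param g a \code{\linkS4class{CdaCohort}} or integer matrix in \{0,1,2\}
#' @param scheme \code{"genotypic"} or \code{"dominant"}
#' @return same type as the input (cohorts get their encoding slot updated)
#' @export
recodeGenotypes <- function(g, scheme = c("genotypic", "dominant")) {
  scheme <- match.arg(scheme)
  G <- if (is(g, "CdaCohort")) g@genotypes else as.matrix(g)
  if (any(!G %in% c(0, 1, 2) & !is.na(G)))
    stop("genotype entries must be in {0, 1, 2}; round dosages first")
  if (scheme == "dominant") G[G == 2] <- 1
  if (is(g, "CdaCohort")) { g@genotypes <- G; g@encoding <- scheme; g }
  else G
}

#' Impute or drop missing genotypes
#'
#' \code{"mode"} replaces each missing entry by the per-SNP modal allele
#' count (logging the count); \code{"drop"} removes samples with any
#' missing genotype.
#'
#' @param cohort a \code{\linkS4class{CdaCohort}}
#' @param method \code{"mode"} or \code{"drop"}
#' @return a \code{CdaCohort}
#' @export
imputeMissing <- function(cohort, method = c("mode", "drop")) {
  method <- match.arg(method)
  G <- cohort@genotypes
  nNA <- sum(is.na(G))
  if (nNA == 0L) return(cohort)
  if (method == "drop") {
    keep <- rowSums(is.na(G)) == 0L
    if (!any(keep)) stop("every sample has missing genotypes")
    message("dropped ", sum(!keep), " sample(s) with missing genotypes")
    return(cohort[which(keep), ])
  }
  for (j in which(colSums(is.na(G)) > 0L)) {
    obs <- G[!is.na(G[, j]), j]
    if (!length(obs)) stop("SNP ", j, " has no observed genotypes")
    mode <- as.numeric(names(which.max(table(obs))))
    G[is.na(G[, j]), j] <- mode
  }
  message("imputed ", nNA, " missing genotype(s) to the per-SNP mode")
  cohort@genotypes <- G
  cohort
}

# Greedy within-window pruning of one chromosome; returns retained indices
# (relative to the columns given).  Windows are `window` SNPs wide and slide
# by `step`; within a window, for every pair at or above the r2 threshold
# the later-index SNP is removed.  Monomorphic SNPs are excluded from the
# r2 computation and always retained.
.pruneChromosome <- function(G, window, step, thr) {
  m <- ncol(G)
  keep <- rep(TRUE, m)
  mono <- apply(G, 2L, var) == 0
  if (any(mono))
    warning(sum(mono), " monomorphic SNP(s) excluded from r2 pruning ",
            "and retained")
  if (m < 2L) return(seq_len(m))
  starts <- unique(pmin(seq(1L, m, by = step), m - 1L))
  for (st in starts) {
    en <- min(st + window - 1L, m)
    idx <- (st:en)[keep[st:en] & !mono[st:en]]
    if (length(idx) < 2L) next
    r2 <- suppressWarnings(cor(G[, idx, drop = FALSE]))^2
    for (ii in seq_len(length(idx) - 1L)) {
      if (!keep[idx[ii]]) next
      for (jj in (ii + 1L):length(idx)) {
        if (!keep[idx[jj]]) next
        if (!is.na(r2[ii, jj]) && r2[ii, jj] >= thr - 1e-12)
          keep[idx[jj]] <- FALSE
      }
    }
    if (en == m) break
  }
  which(keep)
}

#' Linkage-disequilibrium pruning
#'
#' Sliding-window greedy pruning of highly correlated SNPs before set-level
#' testing: within each window of \code{window} SNPs (shifted by
#' \code{step}), every pair whose squared Pearson correlation of allele
#' counts reaches \code{r2Threshold} loses its later-index member.  Applied
#' per chromosome when chromosome labels are available.  Deterministic; the
#' retained subset preserves the original SNP order.
#'
#' @param g a \code{\linkS4class{CdaCohort}} or genotype matrix
#' @param window window width in SNPs (>= 2)
#' @param step window shift in SNPs (>= 1)
#' @param r2Threshold pruning threshold in (0, 1]
#' @return pruned object of the same type, with attribute \code{"kept"}
#'   giving the retained column indices
#' @export
ldPrune <- function(g, window = 50L, step = 5L, r2Threshold = 0.9) {
  stopifnot(window >= 2L, step >= 1L, r2Threshold > 0, r2Threshold <= 1)
  G <- if (is(g, "CdaCohort")) g@genotypes else as.matrix(g)
  chrom <- if (is(g, "CdaCohort")) g@snpInfo$chrom
           else rep(NA_character_, ncol(G))
  if (all(is.na(chrom))) chrom <- rep("*", ncol(G))
  kept <- integer(0)
  for (ch in unique(chrom)) {
    cols <- which(chrom == ch | (is.na(chrom) & is.na(ch)))
    if (!length(cols)) cols <- which(is.na(chrom))
    ki <- .pruneChromosome(G[, cols, drop = FALSE], window, step,
                           r2Threshold)
    kept <- c(kept, cols[ki])
  }
  kept <- sort(kept)
  out <- if (is(g, "CdaCohort")) g[, kept] else G[, kept, drop = FALSE]
  attr(out, "kept") <- kept
  out
}

#' Stratify a cohort by a covariate
#'
#' \code{"binary-label"} splits on exactly two distinct covariate labels;
#' \code{"median-split"} assigns values at or below the median to the first
#' stratum.  Strata partition the cohort and must both be non-empty.
#'
#' @param cohort a \code{\linkS4class{CdaCohort}} with phenotype set
#' @param covariate vector of length n
#' @param rule \code{"binary-label"} or \code{"median-split"}
#' @return a \code{\linkS4class{StratifiedCohort}} with two strata
#' @export
stratifyCohort <- function(cohort, covariate,
                           rule = c("binary-label", "median-split")) {
  rule <- match.arg(rule)
  n <- nSamples(cohort)
  if (length(covariate) != n)
    stop("covariate length must equal the sample count")
  if (rule == "binary-label") {
    lev <- sort(unique(as.character(covariate)))
    if (length(lev) != 2L)
      stop("binary-label stratification needs exactly two distinct labels")
    grp <- ifelse(as.character(covariate) == lev[1L], 1L, 2L)
    labels <- lev
  } else {
    md <- median(as.numeric(covariate))
    grp <- ifelse(as.numeric(covariate) <= md, 1L, 2L)
    labels <- c(sprintf("<=%g", md), sprintf(">%g", md))
  }
  if (any(tabulate(grp, 2L) == 0L))
    stop("stratification produced an empty stratum")
  new("StratifiedCohort",
      strata = list(cohort[which(grp == 1L), ], cohort[which(grp == 2L), ]),
      labels = labels)
}
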