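#' Fisher-transform p-value for the prediction score
#'
#' One-sided upper-tail p-value for an observed prediction score R against
#' the null mean R0: P = 1 - Phi(z) with
#' z = sqrt(n - 3) (f - f0), f = atanh(R) = (1/2) ln[(1 + R)/(1 - R)].
#' R0 is typically estimated by phenotype permutation and may be negative;
#' fixing R0 = 0 miscalibrates the upper quantiles.
#'
#' @param R observed prediction score (|R| < 1)
#' @param R0 null mean score (|R0| < 1)
#' @param n effective sample count (> 3); under full cross-validation the
#'   pooled test sets cover the cohort, so n is the cohort size
#' @return list with \code{R}, \code{R0}, \code{nEff}, \code{z}, \code{p},
#'   \code{method = "fisher"}
#' @examples
#' fisherPvalue(0.2, 0, 103)  # z ~ 2.03, p ~ 0.021
#' @export
fisherPvalue <- function(R, R0 = 0, n) {
  if (n <= 3) stop("Fisher transformation needs n > 3")
  if (abs(R) >= 1 || abs(R0) >= 1) stop("|R| and |R0| must be < 1")
  z <- sqrt(n - 3) * (atanh(R) - atanh(R0))
  list(R = R, R0 = R0, nEff = n, z = z,
       p = pnorm(z, lower.tail = FALSE), method = "fisher")
}

# Normalize the `pen` argument: a length-2 numeric c(lambda1, lambda2)
# means the inference is repeated at fixed penalizers; a list with
# lambda1Grid (and optionally lambda2Grid, paired) means the whole
# penalizer optimization is repeated.
.penSpec <- function(pen) {
  if (is.numeric(pen) && length(pen) == 2L)
    return(list(mode = "fixed", lambda1 = pen[1L], lambda2 = pen[2L]))
  if (is.list(pen)) {
    l1 <- if (!is.null(pen$lambda1Grid)) pen$lambda1Grid
          else defaultLambdaGrid()
    l2 <- if (!is.null(pen$lambda2Grid)) pen$lambda2Grid
          else c(defaultLambdaGrid(), Inf)
    return(list(mode = "grid", lambda1Grid = l1, lambda2Grid = l2,
                paired = isTRUE(pen$paired)))
  }
  stop("pen must be c(lambda1, lambda2) or a list with lambda1Grid/",
       "lambda2Grid")
}

# Observed or permuted prediction score following the penalizer treatment.
.scoreOnce <- function(G, y, encoding, ps, folds, seed) {
  if (ps$mode == "fixed") {
    fit <- crossValidateCda(G, ps$lambda1, ps$lambda2, y = y, folds = folds,
                            seed = seed, refit = FALSE, encoding = encoding)
  } else {
    fit <- optimizePenalizers(G, y, lambda1Grid = ps$lambda1Grid,
                              lambda2Grid = ps$lambda2Grid, folds = folds,
                              seed = seed, paired = ps$paired,
                              refit = FALSE, encoding = encoding)
  }
  fit@R
}

#' Permutation-estimated null mean prediction score
#'
#' Mean prediction score over \code{nPerm} refits with phenotype labels
#' permuted: the null center R0 for \code{\link{fisherPvalue}}.  The
#' permuted refits repeat the observed inference exactly: at fixed
#' penalizers when \code{pen = c(lambda1, lambda2)}, or including the
#' penalizer grid optimization when \code{pen} is a list with
#' \code{lambda1Grid}/\code{lambda2Grid} (and optionally
#' \code{paired = TRUE} for a single shared penalizer).  When the observed
#' score came from an optimized grid, the grid form must be used, since the
#' selection maximum has a positive null mean that a fixed-penalizer
#' permutation underestimates.  For a
#' \code{\linkS4class{StratifiedCohort}}, labels are permuted within each
#' stratum (preserving the covariate structure) and the meta-analysis
#' inference is repeated.
#'
#' @param g a \code{CdaCohort}, genotype matrix, or \code{StratifiedCohort}
#' @param pen \code{c(lambda1, lambda2)} or a grid list (see above)
#' @param y phenotype (ignored for stratified cohorts)
#' @param nPerm number of permutations (default 10)
#' @param folds,seed,encoding as in \code{\link{crossValidateCda}}
#' @return numeric scalar, the mean permuted R (may be negative)
#' @export
estimateNullR0 <- function(g, pen, y = NULL, nPerm = 10L, folds = 5L,
                           seed = 1L, encoding = NULL) {
  stopifnot(nPerm >= 1L)
  ps <- .penSpec(pen)
  if (is(g, "StratifiedCohort")) {
    perms <- .withSeed(seed, lapply(seq_len(nPerm), function(t)
      lapply(strata(g), function(s) sample.int(nSamples(s)))))
    Rs <- vapply(seq_len(nPerm), function(t) {
      gp <- g
      for (s in seq_along(gp@strata)) {
        ys <- phenotype(gp@strata[[s]])
        gp@strata[[s]]@phenotype <- ys[perms[[t]][[s]]]
      }
      if (ps$mode == "fixed")
        metaFit(gp, ps$lambda1, ps$lambda2, folds = folds, seed = seed,
                refit = FALSE)$R
      else
        optimizeMetaPenalizers(gp, lambda1Grid = ps$lambda1Grid,
                               lambda2Grid = ps$lambda2Grid, folds = folds,
                               seed = seed, refit = FALSE)$R
    }, 0)
    return(mean(Rs))
  }
  d <- .resolveData(g, y, encoding)
  n <- nrow(d$G)
  perms <- .withSeed(seed, lapply(seq_len(nPerm), function(t) sample.int(n)))
  Rs <- vapply(seq_len(nPerm), function(t)
    .scoreOnce(d$G, d$y[perms[[t]]], d$encoding, ps, folds, seed), 0)
  mean(Rs)
}

#' Direct permutation p-value for the prediction score
#'
#' Recomputes the prediction score under \code{nPerm} phenotype-label
#' permutations, repeating the observed inference (fixed penalizers or
#' grid optimization, as in \code{\link{estimateNullR0}}), and returns the
#' add-one upper-tail estimate
#' p = (1 + #\{permuted R >= observed R\}) / (1 + nPerm).
#'
#' @inheritParams estimateNullR0
#' @param nPerm number of permutations (>= 100 recommended, ~1000 typical)
#' @return list with \code{R} (observed), \code{R0} (mean permuted R),
#'   \code{permutedR}, \code{nEff}, \code{p}, \code{method = "permutation"}
#' @export
permutationPvalue <- function(g, pen, y = NULL, nPerm = 999L, folds = 5L,
                              seed = 1L, encoding = NULL) {
  stopifnot(nPerm >= 1L)
  ps <- .penSpec(pen)
  d <- .resolveData(g, y, encoding)
  n <- nrow(d$G)
  obs <- .scoreOnce(d$G, d$y, d$encoding, ps, folds, seed)
  perms <- .withSeed(seed + 1L,
                     lapply(seq_len(nPerm), function(t) sample.int(n)))
  Rs <- vapply(seq_len(nPerm), function(t)
    .scoreOnce(d$G, d$y[perms[[t]]], d$encoding, ps, folds, seed), 0)
  list(R = obs, R0 = mean(Rs), permutedR = Rs, nEff = n,
       p = (1 + sum(Rs >= obs)) / (1 + nPerm), method = "permutation")
}

#' Multiplicity adjustment across SNP sets
#'
#' Bonferroni-adjusted p-values (threshold alpha / K) and
#' Benjamini-Hochberg false discovery rate flags for a vector of per-set
#' p-values.
#'
#' @param pvals numeric p-values in [0, 1]
#' @param alpha significance level for the flags
#' @return data.frame with \code{p}, \code{p_bonferroni},
#'   \code{bonferroni_flag}, \code{p_bh}, \code{fdr_flag}
#' @export
adjustMultiplicity <- function(pvals, alpha = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  pb <- p.adjust(pvals, method = "bonferroni")
  pbh <- p.adjust(pvals, method = "BH")
  data.frame(p = pvals, p_bonferroni = pb, bonferroni_flag = pb <= alpha,
             p_bh = pbh, fdr_flag = pbh <= alpha)
}

# Fill the significance slots of a CdaFit from a null mean R0.
.attachSignificance <- function(fit, R0) {
  sig <- fisherPvalue(fit@R, R0, fit@nSamples)
  fit@R0 <- R0
  fit@z <- sig$z
  fit@p <- sig$p
  fit
}
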