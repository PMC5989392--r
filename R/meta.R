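#' Covariate-stratified meta-analysis fit
#'
#' Collective inference with sample-size-weighted parameter averaging
#' across covariate strata, which controls inflation from covariates that
#' shift both the phenotype and allele frequencies.  Within each
#' cross-validation fold, the model is fitted separately on each stratum's
#' training portion; the per-stratum parameters are averaged elementwise
#' with weights n_s / sum(n_s); and the averaged model predicts the pooled
#' held-out samples of all strata, using the marginal phenotype model of
#' the pooled training samples.  R is the correlation over the pooled
#' held-out predictions.  Fold boundaries are drawn within each stratum
#' (synchronized by the seed) so pooled test sets never contain training
#' samples.
#'
#' @param cohort a \code{\linkS4class{StratifiedCohort}} (>= 1 stratum;
#'   every stratum must have at least \code{folds} samples)
#' @param lambda1,lambda2 penalizers shared across strata
#' @param folds,seed,tol,maxIter as in \code{\link{crossValidateCda}}
#' @param refit also fit each full stratum and return the averaged
#'   parameters
#' @return list of class \code{"MetaFit"}: \code{R}, \code{predictions} and
#'   \code{phenotypes} (pooled, in stratum order), \code{weights},
#'   \code{params} (averaged; \code{NULL} when \code{refit = FALSE}),
#'   \code{perStratumParams}, \code{lambda1}, \code{lambda2},
#'   \code{converged}, \code{nSamples}
#' @export
metaFit <- function(cohort, lambda1, lambda2, folds = 5L, seed = 1L,
                    tol = 1e-5, maxIter = 500L, refit = TRUE) {
  stopifnot(is(cohort, "StratifiedCohort"))
  S <- length(cohort@strata)
  ds <- lapply(cohort@strata, function(s) .resolveData(s))
  enc <- ds[[1L]]$encoding
  L <- ds[[1L]]$L
  m <- ncol(ds[[1L]]$G)
  if (any(vapply(ds, function(d) d$encoding, "") != enc))
    stop("strata must share the genotype encoding")
  ns <- vapply(ds, function(d) nrow(d$G), 0L)
  if (any(ns < folds)) stop("every stratum needs at least `folds` samples")
  foldIds <- lapply(seq_len(S), function(s)
    .seededFolds(ns[s], folds, seed + s - 1L))
  noJ <- is.infinite(lambda2)
  yAll <- unlist(lapply(ds, function(d) d$y))
  yhatAll <- rep(NA_real_, sum(ns))
  off <- cumsum(c(0L, ns))
  conv <- TRUE
  for (f in seq_len(folds)) {
    thetas <- vector("list", S)
    wts <- numeric(S)
    ytrPool <- numeric(0)
    for (s in seq_len(S)) {
      tr <- foldIds[[s]] != f
      ytr <- ds[[s]]$y[tr]
      mu <- mean(ytr); sdev <- sd(ytr)
      if (sdev == 0) stop("zero phenotype variance in a training stratum")
      ft <- .fitTheta(ds[[s]]$G[tr, , drop = FALSE], (ytr - mu) / sdev, L,
                      lambda1, lambda2, tol = tol, maxIter = maxIter)
      conv <- conv && ft$converged
      thetas[[s]] <- .destandardizeTheta(ft$theta, m, L, noJ, mu, sdev)
      wts[s] <- sum(tr)
      ytrPool <- c(ytrPool, ytr)
    }
    wts <- wts / sum(wts)
    thAvg <- Reduce(`+`, Map(`*`, thetas, wts))
    pars <- .thetaToParams(thAvg, m, L, enc, ds[[1L]]$snpIds, noJ)
    muP <- mean(ytrPool); s2P <- var(ytrPool)
    gr <- yGrid(muP, s2P)
    for (s in seq_len(S)) {
      te <- foldIds[[s]] == f
      yhatAll[off[s] + which(te)] <-
        bayesPredict(pars, ds[[s]]$G[te, , drop = FALSE], muP, s2P, gr)
    }
  }
  R <- if (sd(yhatAll) == 0) { warning("zero-variance predictions"); 0 }
       else cor(yAll, yhatAll)
  weights <- ns / sum(ns)
  params <- NULL
  perStratum <- NULL
  if (refit) {
    fits <- lapply(seq_len(S), function(s)
      fitCda(ds[[s]]$G, lambda1, lambda2, y = ds[[s]]$y, tol = tol,
             maxIter = maxIter, encoding = enc)$params)
    perStratum <- fits
    thAvg <- Reduce(`+`, Map(function(p, w) .paramsToTheta(p, noJ) * w,
                             fits, as.list(weights)))
    params <- .thetaToParams(thAvg, m, L, enc, ds[[1L]]$snpIds, noJ)
  }
  structure(list(R = R, predictions = yhatAll, phenotypes = yAll,
                 weights = weights, params = params,
                 perStratumParams = perStratum, lambda1 = lambda1,
                 lambda2 = lambda2, converged = conv,
                 nSamples = sum(ns)),
            class = "MetaFit")
}

#' @export
print.MetaFit <- function(x, ...) {
  cat(sprintf("MetaFit: R = %.4f at lambda1 = %.4g, lambda2 = %s (n = %d, %d strata)\n",
              x$R, x$lambda1,
              if (is.infinite(x$lambda2)) "Inf" else sprintf("%.4g", x$lambda2),
              x$nSamples, length(x$weights)))
  invisible(x)
}

#' Penalizer optimization for the meta-analysis fit
#'
#' Grid search over (lambda1, lambda2) pairs, shared across strata and
#' including the couplings-off candidate, maximizing the pooled
#' cross-validated R of \code{\link{metaFit}}; ties go to larger
#' penalizers.
#'
#' @inheritParams metaFit
#' @param lambda1Grid,lambda2Grid candidate penalizer values
#' @return the winning \code{"MetaFit"} (with full-data averaged parameters
#'   when \code{refit = TRUE})
#' @export
optimizeMetaPenalizers <- function(cohort, lambda1Grid = defaultLambdaGrid(),
                                   lambda2Grid = c(defaultLambdaGrid(), Inf),
                                   folds = 5L, seed = 1L, tol = 1e-5,
                                   maxIter = 500L, refit = TRUE) {
  combos <- expand.grid(l2 = sort(lambda2Grid), l1 = sort(lambda1Grid))
  combos <- combos[order(combos$l1, combos$l2), c("l1", "l2")]
  best <- NULL
  for (r in seq_len(nrow(combos))) {
    mf <- metaFit(cohort, combos$l1[r], combos$l2[r], folds = folds,
                  seed = seed, tol = tol, maxIter = maxIter, refit = FALSE)
    if (is.null(best) || mf$R >= best$R) best <- mf
  }
  if (refit)
    best <- metaFit(cohort, best$lambda1, best$lambda2, folds = folds,
                    seed = seed, tol = tol, maxIter = maxIter, refit = TRUE)
  best
}
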