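# Cross-validated prediction score machinery shared by the tuning,
# significance, meta-analysis and pathway layers.

# One full CV pass at fixed penalizers on validated inputs.  `warm` carries
# per-fold starting points from a neighbouring penalizer (same dimension).
.cvR <- function(G, y, L, encoding, lam1, lam2, fold, tol = 1e-5,
                 maxIter = 500L, grid = NULL, warm = NULL,
                 warnZeroVar = TRUE) {
  n <- nrow(G)
  folds <- max(fold)
  yhat <- numeric(n)
  conv <- TRUE
  iter <- 0L
  noJ <- is.infinite(lam2)
  thetas <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    ytr <- y[tr]
    mu <- mean(ytr)
    s <- sd(ytr)
    if (s == 0) stop("zero phenotype variance in a training fold")
    init <- if (!is.null(warm)) warm[[f]] else NULL
    ft <- .fitTheta(G[tr, , drop = FALSE], (ytr - mu) / s, L, lam1, lam2,
                    init = init, tol = tol, maxIter = maxIter)
    thetas[[f]] <- ft$theta
    conv <- conv && ft$converged
    iter <- max(iter, ft$iterations)
    thRaw <- .destandardizeTheta(ft$theta, ncol(G), L, noJ, mu, s)
    pars <- .thetaToParams(thRaw, ncol(G), L, encoding, NULL, noJ)
    gr <- if (is.null(grid)) yGrid(mu, s^2) else grid
    yhat[!tr] <- bayesPredict(pars, G[!tr, , drop = FALSE], mu, s^2, gr)
  }
  if (sd(yhat) == 0) {
    if (warnZeroVar) warning("held-out predictions have zero variance; R set to 0")
    R <- 0
  } else R <- cor(y, yhat)
  list(R = R, predictions = yhat, converged = conv, iterations = iter,
       warm = thetas)
}

#' Default penalizer grid
#'
#' Seven log-spaced values spanning [0.01, 100], the search range used for
#' both penalizers; combine with \code{Inf} for the couplings-off candidate.
#'
#' @return numeric vector
#' @export
defaultLambdaGrid <- function() 10^seq(-2, 2, length.out = 7)

#' Cross-validated prediction score at fixed penalizers
#'
#' Samples are split into \code{folds} folds by a seeded uniform shuffle
#' (the default 5 folds give the 4:1 training:test ratio).  For each fold
#' the model is fitted on the training portion and held-out phenotypes are
#' predicted by \code{\link{bayesPredict}} with the training-sample marginal
#' model; every sample is predicted exactly once and
#' R = Cor[y, yhat] over all held-out predictions.
#'
#' @inheritParams fitCda
#' @param folds number of CV folds (>= 2)
#' @param seed integer seed for the fold assignment
#' @param refit refit the model on the full data at these penalizers and
#'   return its parameters in the result
#' @return a \code{\linkS4class{CdaFit}}
#' @examples
#' set.seed(7)
#' G <- matrix(rbinom(300, 1, 0.5), 100, 3)
#' crossValidateCda(G, lambda1 = 1, lambda2 = 1, y = rnorm(100), seed = 1)
#' @export
crossValidateCda <- function(g, lambda1, lambda2, y = NULL, folds = 5L,
                             seed = 1L, tol = 1e-5, maxIter = 500L,
                             refit = TRUE, encoding = NULL) {
  d <- .resolveData(g, y, encoding)
  fold <- .seededFolds(nrow(d$G), folds, seed)
  cv <- .cvR(d$G, d$y, d$L, d$encoding, lambda1, lambda2, fold,
             tol = tol, maxIter = maxIter)
  params <- if (refit)
    fitCda(d$G, lambda1, lambda2, y = d$y, tol = tol, maxIter = maxIter,
           encoding = d$encoding)$params
  else newCdaParams(ncol(d$G), d$encoding, snpIds = d$snpIds,
                    interactions = !is.infinite(lambda2))
  new("CdaFit", params = params, lambda1 = lambda1, lambda2 = lambda2,
      R = cv$R, predictions = cv$predictions, foldId = fold,
      converged = cv$converged, iterations = cv$iterations,
      nSamples = nrow(d$G))
}

#' Penalizer optimization by grid search
#'
#' Maximizes the cross-validated prediction score over a grid of
#' (lambda1, lambda2) pairs, including the couplings-off candidate
#' lambda2 = Inf; all candidates share the same seeded fold assignment.
#' Ties are broken toward larger penalizers (the simpler model).  With
#' \code{paired = TRUE} a single penalizer lambda1 = lambda2 = lambda is
#' tuned over \code{lambda1Grid}.
#'
#' @inheritParams crossValidateCda
#' @param lambda1Grid,lambda2Grid candidate values (within [0.01, 100];
#'   \code{lambda2Grid} may contain \code{Inf})
#' @param paired tune a single shared penalizer instead of the full grid
#' @return a \code{\linkS4class{CdaFit}} for the winning candidate
#' @export
optimizePenalizers <- function(g, y = NULL, lambda1Grid = defaultLambdaGrid(),
                               lambda2Grid = c(defaultLambdaGrid(), Inf),
                               folds = 5L, seed = 1L, paired = FALSE,
                               tol = 1e-5, maxIter = 500L, refit = TRUE,
                               encoding = NULL) {
  d <- .resolveData(g, y, encoding)
  fold <- .seededFolds(nrow(d$G), folds, seed)
  if (paired) {
    l1 <- sort(lambda1Grid)
    combos <- data.frame(l1 = l1, l2 = l1)
  } else {
    combos <- expand.grid(l2 = sort(lambda2Grid), l1 = sort(lambda1Grid))
    combos <- combos[order(combos$l1, combos$l2), c("l1", "l2")]
  }
  best <- NULL
  warm <- NULL
  warmNoJ <- NA
  for (r in seq_len(nrow(combos))) {
    l1 <- combos$l1[r]; l2 <- combos$l2[r]
    noJ <- is.infinite(l2)
    w <- if (identical(noJ, warmNoJ)) warm else NULL
    cv <- .cvR(d$G, d$y, d$L, d$encoding, l1, l2, fold,
               tol = tol, maxIter = maxIter, warm = w, warnZeroVar = FALSE)
    warm <- cv$warm
    warmNoJ <- noJ
    if (is.null(best) || cv$R >= best$R)
      best <- list(R = cv$R, predictions = cv$predictions, l1 = l1, l2 = l2,
                   converged = cv$converged, iterations = cv$iterations)
  }
  params <- if (refit)
    fitCda(d$G, best$l1, best$l2, y = d$y, tol = tol, maxIter = maxIter,
           encoding = d$encoding)$params
  else newCdaParams(ncol(d$G), d$encoding, snpIds = d$snpIds,
                    interactions = !is.infinite(best$l2))
  new("CdaFit", params = params, lambda1 = best$l1, lambda2 = best$l2,
      R = best$R, predictions = best$predictions, foldId = fold,
      converged = best$converged, iterations = best$iterations,
      nSamples = nrow(d$G))
}

#' Per-SNP association scan (no interactions)
#'
#' Runs the single-SNP special case of the model (m = 1, lambda2 = Inf) for
#' every SNP: cross-validated prediction score, permutation-estimated null
#' mean R0 and Fisher-transform p-value.  Useful for comparing the method's
#' single-locus behaviour with linear regression.
#'
#' @inheritParams crossValidateCda
#' @param lambda1 field penalizer used for every SNP
#' @param nPerm permutations for the null mean R0
#' @return data.frame with one row per SNP: \code{snp_id}, \code{R},
#'   \code{R0}, \code{z}, \code{p}
#' @export
singleSnpScan <- function(g, y = NULL, lambda1 = 0.01, folds = 5L,
                          nPerm = 10L, seed = 1L, encoding = NULL) {
  d <- .resolveData(g, y, encoding)
  m <- ncol(d$G)
  out <- data.frame(snp_id = d$snpIds, R = NA_real_, R0 = NA_real_,
                    z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    Gj <- d$G[, j, drop = FALSE]
    fit <- crossValidateCda(Gj, lambda1, Inf, y = d$y, folds = folds,
                            seed = seed, refit = FALSE, encoding = d$encoding)
    R0 <- estimateNullR0(Gj, c(lambda1, Inf), y = d$y, nPerm = nPerm,
                         folds = folds, seed = seed + 1L,
                         encoding = d$encoding)
    sig <- fisherPvalue(fit@R, R0, nrow(d$G))
    out$R[j] <- fit@R; out$R0[j] <- R0; out$z[j] <- sig$z; out$p[j] <- sig$p
  }
  out
}
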