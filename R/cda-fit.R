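#' Hamiltonian of the phenotype-conditioned genotype model
#'
#' Evaluates H(a; y) = sum_l y^l [ sum_i h_i^(l)(a_i) +
#' sum_{i<j} J_ij^(l)(a_i, a_j) ].  With all parameters zero, or for the
#' all-reference genotype a = 0, H = 0.
#'
#' @param params a \code{\linkS4class{CdaParams}}
#' @param a genotype level vector of length m (entries 0..L)
#' @param y phenotype value (scalar)
#' @return numeric scalar
#' @examples
#' p <- newCdaParams(2, "dominant")
#' p@h[1, 1] <- 0.5  # h_1^(0)(1)
#' cdaHamiltonian(p, c(1, 0), y = 2)
#' @export
cdaHamiltonian <- function(params, a, y) {
  L <- .levelsOf(params@encoding)
  stopifnot(length(a) == params@m, all(a %in% 0:L), length(y) == 1L)
  b <- as.numeric(.indicatorMatrix(matrix(a, 1L), L))
  H <- 0
  for (l in 1:2) {
    Jl <- params@J[, , l]
    H <- H + y^(l - 1) * (sum(params@h[, l] * b) + 0.5 * sum(b * (Jl %*% b)))
  }
  H
}

#' Single-site conditional genotype probabilities
#'
#' Probability of each level at SNP \code{i} conditional on the remaining
#' genotypes and the phenotype, under the pseudo-likelihood factorization:
#' Pr(a | a_\{j != i\}, y) = exp(H_i(a)) / sum_b exp(H_i(b)) with
#' H_i(a) = sum_l y^l [ h_i^(l)(a) + sum_\{j != i\} J_ij^(l)(a, a_j) ].
#' Computed with max-subtraction so the result is finite for |H_i| up to
#' the double-precision exponent range.
#'
#' @param params a \code{\linkS4class{CdaParams}}
#' @param i SNP index
#' @param context genotype level vector of length m (entry i is ignored)
#' @param y phenotype value
#' @return numeric vector of probabilities over levels 0..L (sums to 1)
#' @export
siteConditional <- function(params, i, context, y) {
  L <- .levelsOf(params@encoding)
  stopifnot(i >= 1L, i <= params@m, length(context) == params@m)
  b <- as.numeric(.indicatorMatrix(matrix(context, 1L), L))
  eta <- numeric(L)
  for (a in seq_len(L)) {
    col <- (i - 1L) * L + a
    for (l in 1:2)
      eta[a] <- eta[a] + y^(l - 1) *
        (params@h[col, l] + sum(params@J[col, , l] * b))
  }
  eta <- c(0, eta)
  w <- exp(eta - max(eta))
  p <- w / sum(w)
  names(p) <- paste0("a", 0:L)
  p
}

#' Penalized pseudo-log-likelihood
#'
#' sum_k sum_i ln Pr(a_i^k | a_\{j != i\}^k, y_k) -
#' (n/2) [ lambda1 sum h^2 + lambda2 sum_\{i<j\} J^2 ], the objective whose
#' stationary points \code{\link{fitCda}} returns.  \code{lambda2 = Inf}
#' freezes the couplings at zero and drops their penalty term.
#'
#' @param g a \code{\linkS4class{CdaCohort}} or genotype level matrix
#' @param params a \code{\linkS4class{CdaParams}}
#' @param lambda1,lambda2 penalizers (positive; \code{lambda2} may be Inf)
#' @param y phenotype values (taken from the cohort when omitted)
#' @return numeric scalar
#' @export
pseudoLogLik <- function(g, params, lambda1, lambda2, y = NULL) {
  d <- .resolveData(g, y, params@encoding)
  idx <- .pairIndices(ncol(d$G), d$L)
  noJ <- is.infinite(lambda2)
  th <- .paramsToTheta(params, noJ = noJ)
  B <- .indicatorMatrix(d$G, d$L)
  val <- .plKernel(th, B, d$y, d$L, idx$upper - 1L, idx$lower - 1L,
                   lambda1, lambda2, FALSE)$value
  -nrow(d$G) * val
}

#' Analytic gradient of the penalized pseudo-log-likelihood
#'
#' Per-parameter derivatives on the 1/n scale: for fields,
#' fhat_i^(l)(a) - f_i^(l)(a) - lambda1 h_i^(l)(a), where fhat is the
#' (phenotype-weighted for l = 1) sample level frequency and f its model
#' average under the per-site conditional densities; couplings carry the
#' contributions of both site conditionals they enter.  Agrees with central
#' finite differences of \code{\link{pseudoLogLik}}/n.
#'
#' @inheritParams pseudoLogLik
#' @return list with matrix \code{h} ((m*L) x 2) and array \code{J}
#'   ((m*L) x (m*L) x 2, symmetric; all-zero when \code{lambda2 = Inf})
#' @export
pseudoGrad <- function(g, params, lambda1, lambda2, y = NULL) {
  d <- .resolveData(g, y, params@encoding)
  m <- ncol(d$G)
  idx <- .pairIndices(m, d$L)
  noJ <- is.infinite(lambda2)
  th <- .paramsToTheta(params, noJ = noJ)
  B <- .indicatorMatrix(d$G, d$L)
  kg <- .plKernel(th, B, d$y, d$L, idx$upper - 1L, idx$lower - 1L,
                  lambda1, lambda2, TRUE)$grad
  gp <- .thetaToParams(-kg, m, d$L, params@encoding, params@snpIds, noJ)
  list(h = gp@h, J = gp@J)
}

#' Fit the CDA model at fixed penalizers
#'
#' Maximizes the penalized pseudo-log-likelihood by L-BFGS on the free
#' parameter vector, starting from zeros (or \code{init}).  The phenotype is
#' standardized internally for numeric conditioning and the returned
#' parameters are mapped back to the raw phenotype scale; the L2 penalty
#' acts on the standardized-scale parameters.  Deterministic given the data
#' and the initial point.
#'
#' @param g a \code{\linkS4class{CdaCohort}} or genotype level matrix
#' @param lambda1 field penalizer (> 0)
#' @param lambda2 coupling penalizer (> 0, or Inf to switch couplings off)
#' @param y phenotype values (taken from the cohort when omitted)
#' @param init optional \code{CdaParams} starting point (raw scale)
#' @param standardize standardize the phenotype before conditioning
#' @param tol gradient max-norm convergence tolerance
#' @param maxIter iteration cap; non-convergence is flagged, not an error
#' @param encoding override the genotype encoding
#' @return list with elements \code{params} (\code{CdaParams}),
#'   \code{converged}, \code{iterations}, \code{value} (penalized negative
#'   PL per sample, standardized scale)
#' @examples
#' set.seed(1)
#' G <- matrix(rbinom(200, 1, 0.5), 50, 4)
#' fit <- fitCda(G, lambda1 = 0.1, lambda2 = 0.1, y = rnorm(50))
#' fit$converged
#' @export
fitCda <- function(g, lambda1, lambda2, y = NULL, init = NULL,
                   standardize = TRUE, tol = 1e-5, maxIter = 500L,
                   encoding = NULL) {
  d <- .resolveData(g, y, encoding)
  if (nrow(d$G) < 2L) stop("need at least two samples")
  stopifnot(lambda1 > 0, lambda2 > 0)
  m <- ncol(d$G)
  noJ <- is.infinite(lambda2)
  mu <- if (standardize) mean(d$y) else 0
  s <- if (standardize) sd(d$y) else 1
  if (s == 0) stop("phenotype has zero variance")
  z <- (d$y - mu) / s
  th0 <- NULL
  if (!is.null(init)) {
    th0 <- .paramsToTheta(init, noJ = noJ)
    # place the raw-scale start on the standardized scale
    th0 <- .destandardizeTheta(th0, m, d$L, noJ, mu = -mu / s, s = 1 / s)
  }
  ft <- .fitTheta(d$G, z, d$L, lambda1, lambda2, init = th0,
                  tol = tol, maxIter = maxIter)
  thRaw <- .destandardizeTheta(ft$theta, m, d$L, noJ, mu, s)
  list(params = .thetaToParams(thRaw, m, d$L, d$encoding, d$snpIds, noJ),
       converged = ft$converged, iterations = ft$iterations,
       value = ft$value)
}

#' Quadrature grid over phenotype values
#'
#' Equally spaced grid spanning mu +/- span * sigma with trapezoidal
#' weights, used by \code{\link{bayesPredict}}.
#'
#' @param mu,sigma2 marginal phenotype mean and variance
#' @param n number of grid points
#' @param span half-width in standard deviations
#' @return list with \code{points} and \code{weights}
#' @export
yGrid <- function(mu = 0, sigma2 = 1, n = 101L, span = 4) {
  stopifnot(n >= 3L, sigma2 > 0)
  pts <- seq(mu - span * sqrt(sigma2), mu + span * sqrt(sigma2),
             length.out = n)
  h <- diff(pts)
  w <- c(h[1] / 2, (h[-length(h)] + h[-1]) / 2, h[length(h)] / 2)
  list(points = pts, weights = w)
}

#' Bayes phenotype prediction
#'
#' Posterior-mean phenotype for each genotype row:
#' yhat(a) = int y Pr(a|y) Pr(y) dy / int Pr(a|y) Pr(y) dy, with Pr(a|y)
#' under the pseudo-likelihood factorization of the fitted model and
#' Pr(y) = Normal(mu, sigma2), integrated by the trapezoidal rule.  The
#' integrand is stabilized by max-subtraction per sample, which also makes
#' the prediction invariant to adding any y-wise constant to H.
#'
#' @param params a \code{\linkS4class{CdaParams}}
#' @param g genotype level matrix (samples x SNPs) or \code{CdaCohort}
#' @param mu,sigma2 marginal phenotype model (e.g. training mean/variance)
#' @param grid optional \code{\link{yGrid}}; defaults to 101 points over
#'   mu +/- 4 sigma
#' @return numeric vector of predicted phenotypes
#' @export
bayesPredict <- function(params, g, mu, sigma2, grid = NULL) {
  G <- if (is(g, "CdaCohort")) g@genotypes else as.matrix(g)
  L <- .levelsOf(params@encoding)
  stopifnot(ncol(G) == params@m, sigma2 > 0)
  if (is.null(grid)) grid <- yGrid(mu, sigma2)
  pts <- grid$points; tw <- grid$weights
  n <- nrow(G); mL <- params@m * L
  B <- .indicatorMatrix(G, L)
  C0 <- B %*% params@J[, , 1L] + matrix(params@h[, 1L], n, mL, byrow = TRUE)
  C1 <- B %*% params@J[, , 2L] + matrix(params@h[, 2L], n, mL, byrow = TRUE)
  yhat <- as.numeric(.bayesKernel(B, C0, C1, L, pts, tw,
                                  dnorm(pts, mu, sqrt(sigma2), log = TRUE)))
  if (any(!is.finite(yhat)))
    stop("vanishing normalization in Bayes prediction; rescale H")
  yhat
}
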