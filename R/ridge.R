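#' Design matrix for ridge regression with pairwise interactions
#'
#' Columns in deterministic order: intercept, single-SNP allele counts by
#' SNP index, then products a_i * a_j for pairs i < j in lexicographic
#' order; p = 1 + m + m(m-1)/2.
#'
#' @param g a \code{\linkS4class{CdaCohort}} or numeric genotype matrix
#' @return numeric matrix n x p with descriptive column names
#' @examples
#' ncol(buildRidgeDesign(matrix(0:5, 2, 3)))  # 1 + 3 + 3
#' @export
buildRidgeDesign <- function(g) {
  G <- if (is(g, "CdaCohort")) g@genotypes else as.matrix(g)
  m <- ncol(G)
  if (m < 1L) stop("need at least one SNP")
  nm <- colnames(G)
  if (is.null(nm)) nm <- paste0("snp", seq_len(m))
  cols <- list("(Intercept)" = rep(1, nrow(G)))
  for (i in seq_len(m)) cols[[nm[i]]] <- G[, i]
  if (m >= 2L)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
      cols[[paste0(nm[i], ":", nm[j])]] <- G[, i] * G[, j]
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' Ridge regression fit
#'
#' Solves b = (X'X + lambda I)^-1 X'y with a single uniform penalizer on
#' every coefficient, including the intercept.  For p > n the dual/SVD form
#' b = V (D^2 + lambda I)^-1 D U'y is used (identical result, cheaper);
#' \code{method = "primal"} and \code{"svd"} force one route for
#' cross-checking.  \code{lambda = 0} is allowed only when X'X is
#' invertible.
#'
#' @param X design matrix from \code{\link{buildRidgeDesign}}
#' @param y numeric response
#' @param lambda ridge penalizer (>= 0)
#' @param method solve route
#' @return list of class \code{"RidgeFit"}: \code{b}, \code{lambda},
#'   \code{sigma2y} (residual variance, divisor n), \code{fitted}
#' @export
ridgeFit <- function(X, y, lambda, method = c("auto", "primal", "svd")) {
  method <- match.arg(method)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, lambda >= 0)
  if (method == "auto") method <- if (p <= n) "primal" else "svd"
  if (lambda == 0 && p > n)
    stop("lambda = 0 requires p <= n and an invertible X'X")
  if (method == "primal") {
    A <- crossprod(X) + diag(lambda, p)
    b <- tryCatch(solve(A, crossprod(X, y)),
                  error = function(e)
                    stop("X'X + lambda I is rank deficient; ",
                         "increase lambda"))
  } else {
    sv <- svd(X)
    if (lambda == 0 && min(sv$d) < 1e-10 * max(sv$d))
      stop("X is rank deficient at lambda = 0")
    b <- sv$v %*% ((sv$d / (sv$d^2 + lambda)) * crossprod(sv$u, y))
  }
  b <- as.numeric(b)
  names(b) <- colnames(X)
  fitted <- as.numeric(X %*% b)
  structure(list(b = b, lambda = lambda,
                 sigma2y = sum((y - fitted)^2) / n, fitted = fitted),
            class = "RidgeFit")
}

#' @export
print.RidgeFit <- function(x, ...) {
  cat(sprintf("RidgeFit: p = %d coefficients, lambda = %.4g, sigma2y = %.4g",
              length(x$b), x$lambda, x$sigma2y))
  if (!is.null(x$R)) cat(sprintf(", CV R = %.4f", x$R))
  cat("\n")
  invisible(x)
}

#' Cross-validated ridge regression with penalizer selection
#'
#' Same seeded fold scheme as \code{\link{crossValidateCda}} (identical
#' fold assignment when given the same seed, for paired method
#' comparisons).  Selects the lambda maximizing the correlation between
#' held-out predictions and phenotypes; ties go to the larger lambda.  The
#' per-fold SVD is computed once and reused across the grid.
#'
#' @param g a \code{\linkS4class{CdaCohort}} or genotype matrix
#' @param y phenotype (taken from the cohort when omitted)
#' @param lambdaGrid candidate penalizers (> 0)
#' @param folds,seed as in \code{\link{crossValidateCda}}
#' @return \code{"RidgeFit"} list with \code{b} (full-data refit at the
#'   winning lambda), \code{lambda}, \code{R}, \code{predictions},
#'   \code{sigma2y}
#' @export
rrCrossValidate <- function(g, y = NULL, lambdaGrid = defaultLambdaGrid(),
                            folds = 5L, seed = 1L) {
  if (is(g, "CdaCohort")) {
    if (is.null(y)) y <- phenotype(g)
    g <- genotypes(g)
  }
  G <- as.matrix(g)
  n <- nrow(G)
  stopifnot(length(y) == n)
  X <- buildRidgeDesign(G)
  fold <- .seededFolds(n, folds, seed)
  svs <- lapply(seq_len(folds), function(f) {
    tr <- fold != f
    sv <- svd(X[tr, , drop = FALSE])
    list(sv = sv, uty = crossprod(sv$u, y[tr]))
  })
  lambdaGrid <- sort(lambdaGrid)
  best <- NULL
  for (lam in lambdaGrid) {
    yhat <- numeric(n)
    for (f in seq_len(folds)) {
      sv <- svs[[f]]$sv
      b <- sv$v %*% ((sv$d / (sv$d^2 + lam)) * svs[[f]]$uty)
      yhat[fold == f] <- X[fold == f, , drop = FALSE] %*% b
    }
    R <- if (sd(yhat) == 0) 0 else cor(y, yhat)
    if (is.null(best) || R >= best$R)
      best <- list(R = R, lambda = lam, predictions = yhat)
  }
  full <- ridgeFit(X, y, best$lambda)
  structure(list(b = full$b, lambda = best$lambda, R = best$R,
                 predictions = best$predictions, sigma2y = full$sigma2y,
                 foldId = fold),
            class = "RidgeFit")
}

# Null mean CV score for ridge: each permutation repeats the observed
# inference including the lambda selection.  The per-fold SVD depends only
# on the genotypes, so all permutations and grid points reuse it.
.rrNullR0 <- function(G, y, lambdaGrid, nPerm = 10L, folds = 5L, seed = 1L) {
  X <- buildRidgeDesign(as.matrix(G))
  n <- nrow(X)
  fold <- .seededFolds(n, folds, seed)
  svs <- lapply(seq_len(folds), function(f)
    svd(X[fold != f, , drop = FALSE]))
  perms <- .withSeed(seed, lapply(seq_len(nPerm), function(t) sample.int(n)))
  lambdaGrid <- sort(lambdaGrid)
  Rs <- vapply(seq_len(nPerm), function(t) {
    yp <- y[perms[[t]]]
    bestR <- -Inf
    for (lam in lambdaGrid) {
      yhat <- numeric(n)
      for (f in seq_len(folds)) {
        sv <- svs[[f]]
        b <- sv$v %*% ((sv$d / (sv$d^2 + lam)) *
                         crossprod(sv$u, yp[fold != f]))
        yhat[fold == f] <- X[fold == f, , drop = FALSE] %*% b
      }
      R <- if (sd(yhat) == 0) 0 else cor(yp, yhat)
      if (R >= bestR) bestR <- R
    }
    bestR
  }, 0)
  mean(Rs)
}
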