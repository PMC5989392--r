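# Internal bridge between CdaParams and the compiled pseudo-likelihood
# kernel.  The flat parameter vector is theta = c(h0, h1, Ju0, Ju1) with Ju
# the free coupling entries, pairs (i < j) in lexicographic order and level
# combinations (a, b) row-major within each pair.  When lambda2 = Inf the Ju
# blocks are absent and the couplings are frozen at zero.

.pairCache <- new.env(parent = emptyenv())

.pairIndices <- function(m, L) {
  key <- paste0(m, ".", L)
  hit <- .pairCache[[key]]
  if (!is.null(hit)) return(hit)
  mL <- m * L
  if (m < 2L) {
    out <- list(mL = mL, upper = integer(0), lower = integer(0), nJ = 0L)
  } else {
    pr <- which(upper.tri(diag(m)), arr.ind = TRUE)
    pr <- pr[order(pr[, 1L], pr[, 2L]), , drop = FALSE]
    i <- rep(pr[, 1L], each = L * L)
    j <- rep(pr[, 2L], each = L * L)
    a <- rep(rep(seq_len(L), each = L), nrow(pr))
    b <- rep(seq_len(L), L * nrow(pr))
    r <- (i - 1L) * L + a
    cc <- (j - 1L) * L + b
    out <- list(mL = mL, upper = r + (cc - 1L) * mL, lower = cc + (r - 1L) * mL,
                nJ = length(r))
  }
  assign(key, out, envir = .pairCache)
  out
}

# n x (m*L) indicator expansion of a level matrix G (entries 0..L)
.indicatorMatrix <- function(G, L) {
  n <- nrow(G); m <- ncol(G)
  B <- matrix(0, n, m * L)
  for (a in seq_len(L)) B[, seq(a, m * L, by = L)] <- (G == a)
  B
}

.paramsToTheta <- function(params, noJ = FALSE) {
  L <- .levelsOf(params@encoding)
  idx <- .pairIndices(params@m, L)
  th <- c(params@h[, 1L], params@h[, 2L])
  if (!noJ && idx$nJ > 0)
    th <- c(th, params@J[, , 1L][idx$upper], params@J[, , 2L][idx$upper])
  th
}

.thetaToParams <- function(theta, m, L, encoding, snpIds = NULL, noJ = FALSE) {
  idx <- .pairIndices(m, L)
  mL <- m * L
  h <- cbind(theta[seq_len(mL)], theta[mL + seq_len(mL)])
  J <- array(0, c(mL, mL, 2))
  if (!noJ && idx$nJ > 0) {
    for (l in 1:2) {
      Ju <- theta[2L * mL + (l - 1L) * idx$nJ + seq_len(idx$nJ)]
      Jl <- matrix(0, mL, mL)
      Jl[idx$upper] <- Ju
      Jl[idx$lower] <- Ju
      J[, , l] <- Jl
    }
  }
  newCdaParams(m, encoding, snpIds = snpIds, h = h, J = J,
               interactions = !noJ)
}

# Penalized negative PL objective/gradient, per-sample scale.  Cached so the
# paired fn/gr calls of optim at the same point cost one kernel evaluation.
.plClosure <- function(B, y, L, idx, lam1, lam2) {
  last <- NULL
  lastTheta <- NULL
  eval_ <- function(theta) {
    if (!is.null(lastTheta) && identical(theta, lastTheta)) return(last)
    res <- .plKernel(theta, B, y, L, idx$upper - 1L, idx$lower - 1L,
                     lam1, lam2, TRUE)
    lastTheta <<- theta
    last <<- res
    res
  }
  list(fn = function(theta) eval_(theta)$value,
       gr = function(theta) eval_(theta)$grad)
}

# One penalized pseudo-likelihood fit on a level matrix G and phenotype y
# (already on the scale to be conditioned on).  Returns theta and optimizer
# diagnostics.
.fitTheta <- function(G, y, L, lam1, lam2, init = NULL,
                      tol = 1e-5, maxIter = 500L) {
  m <- ncol(G)
  idx <- .pairIndices(m, L)
  noJ <- is.infinite(lam2)
  np <- 2L * idx$mL + if (noJ) 0L else 2L * idx$nJ
  if (is.null(init)) init <- rep(0, np)
  stopifnot(length(init) == np)
  B <- .indicatorMatrix(G, L)
  cl <- .plClosure(B, y, L, idx, lam1, lam2)
  opt <- optim(init, fn = cl$fn, gr = cl$gr, method = "L-BFGS-B",
               control = list(maxit = maxIter, pgtol = tol, factr = 1e7))
  list(theta = opt$par, converged = opt$convergence == 0L,
       iterations = unname(opt$counts[1L]), value = opt$value)
}

# Resolve (cohort | matrix, phenotype) argument pairs used across the API.
.resolveData <- function(g, y = NULL, encoding = NULL) {
  if (is(g, "CdaCohort")) {
    G <- g@genotypes
    if (is.null(y)) {
      if (!length(g@phenotype)) stop("cohort has no phenotype")
      y <- g@phenotype
    }
    if (is.null(encoding)) encoding <- g@encoding
    snpIds <- g@snpInfo$snp_id
  } else {
    G <- as.matrix(g)
    if (is.null(y)) stop("phenotype y is required")
    if (is.null(encoding))
      encoding <- if (max(G, na.rm = TRUE) > 1) "genotypic" else "dominant"
    snpIds <- colnames(G)
    if (is.null(snpIds)) snpIds <- paste0("snp", seq_len(ncol(G)))
  }
  if (length(y) != nrow(G))
    stop("phenotype length does not match the number of samples")
  L <- .levelsOf(encoding)
  if (any(is.na(G))) stop("missing genotypes; see imputeMissing()")
  if (any(G < 0 | G > L) || any(G != round(G)))
    stop("genotype entries must be integers in 0..", L,
         " for the ", encoding, " encoding (round/recode first)")
  list(G = G, y = as.numeric(y), encoding = encoding, L = L, snpIds = snpIds)
}

# Seeded fold assignment: uniform shuffle, folds filled round-robin so sizes
# differ by at most one.  Restores the caller's RNG state.
.seededFolds <- function(n, folds, seed) {
  if (folds < 2L) stop("folds must be >= 2")
  if (n < folds) stop("need at least as many samples as folds")
  perm <- .withSeed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep_len(seq_len(folds), n)
  fold
}

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Map parameters fitted against standardized phenotype z = (y - mu)/s back
# to the raw phenotype scale: the y^l expansion h(0) + z h(1) rewrites as
# [h(0) - (mu/s) h(1)] + y [h(1)/s], and identically for J.
.destandardizeTheta <- function(theta, m, L, noJ, mu, s) {
  idx <- .pairIndices(m, L)
  mL <- idx$mL
  h0 <- theta[seq_len(mL)]; h1 <- theta[mL + seq_len(mL)]
  out <- c(h0 - (mu / s) * h1, h1 / s)
  if (!noJ && idx$nJ > 0) {
    J0 <- theta[2L * mL + seq_len(idx$nJ)]
    J1 <- theta[2L * mL + idx$nJ + seq_len(idx$nJ)]
    out <- c(out, J0 - (mu / s) * J1, J1 / s)
  }
  out
}
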