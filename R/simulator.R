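#' Specification of a model-drawn simulated cohort
#'
#' Defines the generative protocol: phenotypes are drawn from the standard
#' normal, the conditional genotype distribution Pr(a | y) is computed
#' exactly for all enumerable genotypes, and one genotype is drawn per
#' individual.  Parameter blocks are drawn i.i.d. from normal distributions
#' given as \code{c(mean, sd)}; zero-reference entries stay zero.
#' Enumeration caps: m <= 20 dominant (2^m states), m <= 12 genotypic
#' (3^m states).
#'
#' @param m SNP count
#' @param n sample size
#' @param encoding \code{"dominant"} or \code{"genotypic"}
#' @param h0,h1,J0,J1 \code{c(mean, sd)} for the four parameter blocks
#' @param seed integer seed
#' @return list of class \code{"SimSpec"}
#' @seealso \code{\link{simPreset}}, \code{\link{sampleCohort}}
#' @export
simSpec <- function(m, n, encoding = c("dominant", "genotypic"),
                    h0 = c(0, 0), h1 = c(0, 0), J0 = c(0, 0), J1 = c(0, 0),
                    seed = 1L) {
  encoding <- match.arg(encoding)
  cap <- if (encoding == "dominant") 20L else 12L
  if (m > cap)
    stop("enumeration limited to m <= ", cap, " for the ", encoding,
         " encoding")
  stopifnot(m >= 1L, n >= 1L, h0[2] >= 0, h1[2] >= 0, J0[2] >= 0, J1[2] >= 0)
  structure(list(m = as.integer(m), n = as.integer(n), encoding = encoding,
                 h0 = h0, h1 = h1, J0 = J0, J1 = J1,
                 seed = as.integer(seed)),
            class = "SimSpec")
}

#' Standard simulation regimes
#'
#' \code{"recovery"}: strong fields and couplings of both orders
#' (h0 ~ N(-0.3, 0.1^2), h1 ~ N(0.3, 0.1^2), J0 ~ N(0, 0.05^2),
#' J1 ~ N(0.1, 0.05^2)) - the parameter-recovery regime.
#' \code{"power"}: association carried by couplings only
#' (h0, h1, J0 ~ N(0, 0.1^2); J1 ~ N(0.1, 0.1^2)) - the power-comparison
#' regime.  \code{"null"}: no phenotype dependence (h1 = J1 = 0;
#' h0, J0 ~ N(0, 0.1^2)) - the type-I-error regime.
#'
#' @param preset regime name
#' @param m,n,encoding,seed as in \code{\link{simSpec}}
#' @return a \code{"SimSpec"}
#' @export
simPreset <- function(preset = c("recovery", "power", "null"), m, n,
                      encoding = "dominant", seed = 1L) {
  preset <- match.arg(preset)
  args <- switch(preset,
    recovery = list(h0 = c(-0.3, 0.1), h1 = c(0.3, 0.1),
                    J0 = c(0, 0.05), J1 = c(0.1, 0.05)),
    power = list(h0 = c(0, 0.1), h1 = c(0, 0.1),
                 J0 = c(0, 0.1), J1 = c(0.1, 0.1)),
    null = list(h0 = c(0, 0.1), h1 = c(0, 0),
                J0 = c(0, 0.1), J1 = c(0, 0)))
  do.call(simSpec, c(list(m = m, n = n, encoding = encoding, seed = seed),
                     args))
}

#' Draw model parameters from a simulation spec
#'
#' Independent normal draws per free parameter, in the fixed order h0, h1,
#' J0, J1; reproducible from the spec seed.
#'
#' @param spec a \code{"SimSpec"}
#' @return a \code{\linkS4class{CdaParams}}
#' @export
drawCdaParams <- function(spec) {
  L <- .levelsOf(spec$encoding)
  idx <- .pairIndices(spec$m, L)
  mL <- idx$mL
  .withSeed(spec$seed, {
    h <- cbind(rnorm(mL, spec$h0[1], spec$h0[2]),
               rnorm(mL, spec$h1[1], spec$h1[2]))
    J <- array(0, c(mL, mL, 2))
    if (idx$nJ > 0) {
      for (l in 1:2) {
        blk <- if (l == 1L) spec$J0 else spec$J1
        Ju <- rnorm(idx$nJ, blk[1], blk[2])
        Jl <- matrix(0, mL, mL)
        Jl[idx$upper] <- Ju
        Jl[idx$lower] <- Ju
        J[, , l] <- Jl
      }
    }
    newCdaParams(spec$m, spec$encoding, h = h, J = J)
  })
}

#' Enumerate all genotypes for a model size
#'
#' @param m SNP count
#' @param encoding \code{"dominant"} (2^m rows) or \code{"genotypic"}
#'   (3^m rows)
#' @return integer matrix, one genotype per row
#' @export
enumerateGenotypes <- function(m, encoding = c("dominant", "genotypic")) {
  encoding <- match.arg(encoding)
  L <- .levelsOf(encoding)
  cap <- if (encoding == "dominant") 20L else 12L
  if (m > cap) stop("enumeration limited to m <= ", cap)
  as.matrix(expand.grid(rep(list(0:L), m), KEEP.OUT.ATTRS = FALSE))
}

# H(a; y) for every enumerated genotype, split into the y^0 and y^1 parts
# so conditional tables at many y values are cheap.
.enumHParts <- function(params, genos) {
  L <- .levelsOf(params@encoding)
  B <- .indicatorMatrix(genos, L)
  Q <- matrix(0, nrow(genos), 2)
  for (l in 1:2) {
    BJ <- B %*% params@J[, , l]
    Q[, l] <- as.numeric(B %*% params@h[, l]) + 0.5 * rowSums(BJ * B)
  }
  Q
}

#' Exact conditional genotype distribution
#'
#' Pr(a | y) = exp(H(a; y)) / Z(y) over all enumerable genotypes, computed
#' exactly (max-stabilized).  The normalizer is returned in the
#' \code{"logZ"} attribute.
#'
#' @param params a \code{\linkS4class{CdaParams}}
#' @param y phenotype value (scalar)
#' @param genos optional pre-enumerated genotype matrix
#' @return numeric probability vector over genotype rows (sums to 1), with
#'   attributes \code{"genotypes"} and \code{"logZ"}
#' @export
enumerateConditional <- function(params, y, genos = NULL) {
  if (is.null(genos)) genos <- enumerateGenotypes(params@m, params@encoding)
  Q <- .enumHParts(params, genos)
  H <- Q[, 1] + y * Q[, 2]
  mx <- max(H)
  w <- exp(H - mx)
  p <- w / sum(w)
  attr(p, "genotypes") <- genos
  attr(p, "logZ") <- mx + log(sum(w))
  p
}

#' Draw a genotype-phenotype cohort from the model
#'
#' Phenotypes y_k are i.i.d. standard normal; each genotype is drawn from
#' the exact conditional distribution Pr(a | y_k).  Reproducible from the
#' spec seed (one stream: parameter draws, then phenotypes, then
#' genotypes).
#'
#' @param spec a \code{"SimSpec"}
#' @param params optional \code{\linkS4class{CdaParams}}; drawn from the
#'   spec when omitted
#' @return list with \code{cohort} (a \code{CdaCohort}) and \code{params}
#' @examples
#' sp <- simPreset("null", m = 4, n = 50, seed = 3)
#' sim <- sampleCohort(sp)
#' nSamples(sim$cohort)
#' @export
sampleCohort <- function(spec, params = NULL) {
  if (is.null(params)) params <- drawCdaParams(spec)
  genos <- enumerateGenotypes(spec$m, spec$encoding)
  Q <- .enumHParts(params, genos)
  .withSeed(spec$seed + 1L, {
    y <- rnorm(spec$n)
    G <- matrix(0L, spec$n, spec$m)
    for (k in seq_len(spec$n)) {
      H <- Q[, 1] + y[k] * Q[, 2]
      w <- exp(H - max(H))
      G[k, ] <- genos[sample.int(nrow(genos), 1L, prob = w), ]
    }
    info <- data.frame(snp_id = paste0("snp", seq_len(spec$m)),
                       chrom = "1", pos = seq_len(spec$m) * 1000L,
                       stringsAsFactors = FALSE)
    cohort <- cdaCohort(G, phenotype = y, snpInfo = info,
                        encoding = spec$encoding)
    list(cohort = cohort, params = params)
  })
}

#' Power comparison of CDA and ridge regression
#'
#' Repeats the simulation protocol: draw parameters, draw a cohort, tune a
#' single shared penalizer for each method by cross-validated R (same
#' seeded folds for both), estimate the null mean R0 from phenotype
#' permutations, and compute the Fisher-transform p-value.  Power is the
#' fraction of replicates with p below \code{alpha}.
#'
#' @param spec a \code{"SimSpec"} for one replicate (its seed is shifted
#'   per replicate)
#' @param replicates number of replicates
#' @param alpha type-I error level
#' @param methods subset of \code{c("cda", "rr")}
#' @param lambdaGrid shared penalizer grid
#' @param folds,nPerm,seed as elsewhere
#' @return list with \code{results} (per-replicate data.frame) and
#'   \code{summary} (mean R and power per method)
#' @export
powerExperiment <- function(spec, replicates, alpha = 0.05,
                            methods = c("cda", "rr"),
                            lambdaGrid = defaultLambdaGrid(), folds = 5L,
                            nPerm = 10L, seed = 1L) {
  stopifnot(replicates >= 1L)
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    rspec <- spec
    rspec$seed <- spec$seed + 101L * r
    sim <- sampleCohort(rspec)
    G <- genotypes(sim$cohort)
    y <- phenotype(sim$cohort)
    row <- list(replicate = r)
    if ("cda" %in% methods) {
      fit <- optimizePenalizers(G, y, lambda1Grid = lambdaGrid,
                                folds = folds, seed = seed + r,
                                paired = TRUE, refit = FALSE,
                                encoding = spec$encoding)
      R0 <- estimateNullR0(G, list(lambda1Grid = lambdaGrid, paired = TRUE),
                           y = y, nPerm = nPerm, folds = folds,
                           seed = seed + r, encoding = spec$encoding)
      sig <- fisherPvalue(fit@R, R0, length(y))
      row <- c(row, list(cda_R = fit@R, cda_lambda = fit@lambda1,
                         cda_R0 = R0, cda_p = sig$p))
    }
    if ("rr" %in% methods) {
      rr <- rrCrossValidate(G, y, lambdaGrid = lambdaGrid, folds = folds,
                            seed = seed + r)
      R0 <- .rrNullR0(G, y, lambdaGrid, nPerm = nPerm, folds = folds,
                      seed = seed + r)
      sig <- fisherPvalue(rr$R, R0, length(y))
      row <- c(row, list(rr_R = rr$R, rr_lambda = rr$lambda, rr_R0 = R0,
                         rr_p = sig$p))
    }
    rows[[r]] <- as.data.frame(row)
  }
  results <- do.call(rbind, rows)
  summary <- list()
  if ("cda" %in% methods)
    summary <- c(summary, list(cda_meanR = mean(results$cda_R),
                               cda_power = mean(results$cda_p < alpha)))
  if ("rr" %in% methods)
    summary <- c(summary, list(rr_meanR = mean(results$rr_R),
                               rr_power = mean(results$rr_p < alpha)))
  list(results = results, summary = summary)
}

#' Type-I error calibration under the null model
#'
#' Simulates replicate cohorts with no phenotype-dependent parameters
#' (h1 = J1 = 0; h0, J0 ~ N(0, sd0^2)), runs the full pipeline on each -
#' penalizer optimization over the grid including the couplings-off
#' candidate, null mean R0 from phenotype permutations, Fisher-transform
#' p-value - and reports the rejection fraction at \code{alpha}.
#'
#' @param replicates number of null cohorts
#' @param n,m cohort dimensions
#' @param encoding genotype encoding
#' @param sd0 standard deviation of the phenotype-independent blocks
#' @param lambda1Grid,lambda2Grid penalizer grids; the default uses four
#'   log-spaced values per axis (plus the couplings-off candidate), since
#'   every replicate repeats the grid search once per permutation on top of
#'   the observed fit
#' @param folds,nPerm,alpha,seed as elsewhere
#' @return data.frame with one row per replicate (\code{R}, \code{R0},
#'   \code{lambda1}, \code{lambda2}, \code{p}); the rejection fraction is
#'   in attribute \code{"rejectionRate"}
#' @export
nullCalibration <- function(replicates, n = 200L, m = 10L,
                            encoding = "dominant", sd0 = 0.1,
                            lambda1Grid = 10^seq(-2, 2, length.out = 4),
                            lambda2Grid = c(10^seq(-2, 2, length.out = 4),
                                            Inf),
                            folds = 5L, nPerm = 10L, alpha = 0.05,
                            seed = 1L) {
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    spec <- simSpec(m, n, encoding, h0 = c(0, sd0), J0 = c(0, sd0),
                    seed = seed + 101L * r)
    sim <- sampleCohort(spec)
    G <- genotypes(sim$cohort)
    y <- phenotype(sim$cohort)
    fit <- optimizePenalizers(G, y, lambda1Grid = lambda1Grid,
                              lambda2Grid = lambda2Grid, folds = folds,
                              seed = seed + r, refit = FALSE,
                              encoding = encoding)
    R0 <- estimateNullR0(G, list(lambda1Grid = lambda1Grid,
                                 lambda2Grid = lambda2Grid),
                         y = y, nPerm = nPerm, folds = folds,
                         seed = seed + r, encoding = encoding)
    sig <- fisherPvalue(fit@R, R0, n)
    rows[[r]] <- data.frame(replicate = r, R = fit@R, R0 = R0,
                            lambda1 = fit@lambda1, lambda2 = fit@lambda2,
                            p = sig$p)
  }
  out <- do.call(rbind, rows)
  attr(out, "rejectionRate") <- mean(out$p < alpha)
  out
}
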