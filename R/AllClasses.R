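#' Genotype-phenotype cohort
#'
#' Container for an n-sample, m-SNP cohort: an allele-count (or dosage)
#' matrix with samples in rows, per-SNP metadata (identifier, chromosome,
#' 1-based position), an optional continuous phenotype, and a record of any
#' phenotype transform applied.  Genotype entries are allele counts in
#' \{0, 1, 2\} after preprocessing; loaders may return fractional dosages,
#' which \code{\link{roundDosages}} converts to integers.
#'
#' @slot genotypes numeric matrix, samples x SNPs.
#' @slot phenotype numeric vector of length n, or length 0 if not yet set.
#' @slot snpInfo data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos} (1-based), one row per SNP.
#' @slot sampleIds character vector of length n.
#' @slot encoding \code{"genotypic"} (levels 0,1,2) or \code{"dominant"}
#'   (levels 0,1; allele count 2 recoded to 1).
#' @slot transform list recording the phenotype transform
#'   (\code{kind}, \code{eps}).
#'
#' @seealso \code{\link{cdaCohort}}, \code{\link{loadGenotypes}}
#' @export
setClass("CdaCohort",
  representation(genotypes = "matrix", phenotype = "numeric",
                 snpInfo = "data.frame", sampleIds = "character",
                 encoding = "character", transform = "list"),
  prototype(phenotype = numeric(0), encoding = "genotypic",
            transform = list(kind = "none", eps = NA_real_)))

setValidity("CdaCohort", function(object) {
  g <- object@genotypes
  msg <- character(0)
  if (nrow(g) < 1L || ncol(g) < 1L)
    msg <- c(msg, "cohort must contain at least one sample and one SNP")
  if (length(object@phenotype) > 0L && length(object@phenotype) != nrow(g))
    msg <- c(msg, "phenotype length must equal the number of samples")
  if (nrow(object@snpInfo) != ncol(g))
    msg <- c(msg, "snpInfo must have one row per SNP")
  if (!all(c("snp_id", "chrom", "pos") %in% names(object@snpInfo)))
    msg <- c(msg, "snpInfo needs columns snp_id, chrom, pos")
  else {
    if (anyDuplicated(object@snpInfo$snp_id))
      msg <- c(msg, "duplicate SNP ids")
    pos <- object@snpInfo$pos
    if (any(!is.na(pos) & pos < 0))
      msg <- c(msg, "SNP positions must be non-negative")
  }
  if (length(object@sampleIds) != nrow(g))
    msg <- c(msg, "sampleIds length must equal the number of samples")
  if (!object@encoding %in% c("genotypic", "dominant"))
    msg <- c(msg, "encoding must be 'genotypic' or 'dominant'")
  if (length(msg)) msg else TRUE
})

#' CDA model parameters
#'
#' Parameters of the phenotype-conditioned genotype distribution
#' Pr(a | y) = exp(H(a; y)) / Z(y) with
#' H(a; y) = sum_l y^l [ sum_i h_i^(l)(a_i) + sum_{i<j} J_ij^(l)(a_i, a_j) ],
#' l in \{0, 1\}.  Genotype level 0 is the zero-parameter reference:
#' h_i^(l)(0) = 0 and J_ij^(l)(a, b) = 0 whenever a = 0 or b = 0, so only
#' levels a = 1..L are stored (L = 1 dominant, L = 2 genotypic).
#'
#' Internally fields are kept as an mL x 2 matrix \code{h} (columns l = 0, 1;
#' row (i-1)L + a holds h_i^(l)(a)) and couplings as an mL x mL x 2 array
#' \code{J}, symmetric under (i,a) <-> (j,b) with zero same-SNP blocks.
#' Use \code{\link{singleEffects}}, \code{\link{pairEffects}} and
#' \code{\link{paramTable}} rather than the slots.
#'
#' @slot encoding \code{"genotypic"} or \code{"dominant"}.
#' @slot m integer SNP count.
#' @slot snpIds character SNP identifiers.
#' @slot h numeric matrix (m*L) x 2.
#' @slot J numeric array (m*L) x (m*L) x 2.
#' @slot interactions logical; \code{FALSE} when the model was fitted with
#'   couplings switched off (lambda2 = Inf).
#'
#' @seealso \code{\link{cdaParams}}, \code{\link{fitCda}}
#' @export
setClass("CdaParams",
  representation(encoding = "character", m = "integer", snpIds = "character",
                 h = "matrix", J = "array", interactions = "logical"),
  prototype(interactions = TRUE))

setValidity("CdaParams", function(object) {
  L <- if (object@encoding == "dominant") 1L else 2L
  mL <- object@m * L
  msg <- character(0)
  if (!object@encoding %in% c("genotypic", "dominant"))
    msg <- c(msg, "encoding must be 'genotypic' or 'dominant'")
  if (!identical(dim(object@h), c(mL, 2L)))
    msg <- c(msg, sprintf("h must be %d x 2", mL))
  if (!identical(dim(object@J), c(mL, mL, 2L)))
    msg <- c(msg, sprintf("J must be %d x %d x 2", mL, mL))
  else {
    for (l in 1:2) {
      Jl <- object@J[, , l]
      if (max(abs(Jl - t(Jl))) > 1e-10)
        msg <- c(msg, "J must be symmetric under (i,a) <-> (j,b)")
      blk <- rep(seq_len(object@m), each = L)
      if (any(abs(Jl[outer(blk, blk, "==")]) > 0))
        msg <- c(msg, "same-SNP blocks of J must be zero")
    }
  }
  if (length(object@snpIds) != object@m)
    msg <- c(msg, "snpIds length must equal m")
  if (length(msg)) msg else TRUE
})

#' Fitted CDA model with cross-validated prediction score
#'
#' Result of \code{\link{crossValidateCda}} / \code{\link{optimizePenalizers}}:
#' the penalizers used, the prediction score R (correlation between held-out
#' predicted and observed phenotypes), per-sample held-out predictions, and a
#' full-data refit of the parameters at those penalizers.  Significance
#' fields (R0, z, p) are filled by the significance layer.
#'
#' @slot params \code{CdaParams} fitted on the full data (may be an empty
#'   placeholder when \code{refit = FALSE}).
#' @slot lambda1,lambda2 penalizers; \code{lambda2 = Inf} disables couplings.
#' @slot R cross-validated prediction score in [-1, 1].
#' @slot predictions held-out predicted phenotypes, one per sample.
#' @slot foldId integer fold assignment used.
#' @slot R0,z,p permutation-estimated null mean score, Fisher z statistic and
#'   one-sided p-value (NA until computed).
#' @slot converged logical; all component fits reached the gradient tolerance.
#' @slot iterations maximum optimizer iteration count across component fits.
#' @slot nSamples sample count.
#' @export
setClass("CdaFit",
  representation(params = "CdaParams", lambda1 = "numeric",
                 lambda2 = "numeric", R = "numeric", predictions = "numeric",
                 foldId = "integer", R0 = "numeric", z = "numeric",
                 p = "numeric", converged = "logical", iterations = "integer",
                 nSamples = "integer"),
  prototype(R0 = NA_real_, z = NA_real_, p = NA_real_))

#' Covariate-stratified cohort
#'
#' Disjoint sample strata of one cohort, as produced by
#' \code{\link{stratifyCohort}}; every stratum shares the SNP set.
#'
#' @slot strata list of \code{CdaCohort} objects.
#' @slot labels character stratum names.
#' @export
setClass("StratifiedCohort",
  representation(strata = "list", labels = "character"))

setValidity("StratifiedCohort", function(object) {
  msg <- character(0)
  if (length(object@strata) < 1L) msg <- c(msg, "no strata")
  if (length(object@labels) != length(object@strata))
    msg <- c(msg, "labels must match strata")
  for (s in object@strata) {
    if (!is(s, "CdaCohort")) { msg <- c(msg, "strata must be CdaCohort"); break }
    if (nrow(s@genotypes) < 1L) msg <- c(msg, "empty stratum")
  }
  if (length(object@strata) > 1L) {
    m0 <- ncol(object@strata[[1L]]@genotypes)
    if (!all(vapply(object@strata, function(s) ncol(s@genotypes), 0L) == m0))
      msg <- c(msg, "strata must share the SNP set")
  }
  if (length(msg)) msg else TRUE
})
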