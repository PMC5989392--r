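#' @rdname CdaCohort-class
#' @param x,object a \code{CdaCohort}
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname CdaCohort-class
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname CdaCohort-class
#' @param value replacement value
#' @export
setGeneric("phenotype<-", function(x, value) standardGeneric("phenotype<-"))

#' @rdname CdaCohort-class
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname CdaCohort-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname CdaCohort-class
#' @export
setGeneric("encoding", function(x) standardGeneric("encoding"))

#' @rdname CdaCohort-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname CdaCohort-class
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' Marginal phenotype model
#'
#' Sample mean and variance of the (transformed) phenotype; together they
#' specify the normal marginal phenotype model used by Bayes prediction.
#'
#' @param x a \code{CdaCohort}
#' @return numeric scalar
#' @export
setGeneric("phenoMean", function(x) standardGeneric("phenoMean"))

#' @rdname phenoMean
#' @export
setGeneric("phenoVar", function(x) standardGeneric("phenoVar"))

#' Single-SNP effects of a CDA model
#'
#' @param object a \code{CdaParams}
#' @param l phenotype order, 0 (intercept) or 1 (slope)
#' @return \code{singleEffects}: an m x L matrix of h_i^(l)(a) for levels
#'   a = 1..L; \code{pairEffects}: an (m*L) x (m*L) symmetric matrix of
#'   J_ij^(l)(a, b), zero within same-SNP blocks.
#' @export
setGeneric("singleEffects", function(object, l = 1) standardGeneric("singleEffects"))

#' @rdname singleEffects
#' @export
setGeneric("pairEffects", function(object, l = 1) standardGeneric("pairEffects"))

#' @rdname CdaFit-class
#' @param object a \code{CdaFit}
#' @export
setGeneric("predictionScore", function(object) standardGeneric("predictionScore"))

#' @rdname CdaFit-class
#' @export
setGeneric("cdaParams", function(object) standardGeneric("cdaParams"))

#' @rdname StratifiedCohort-class
#' @param x a \code{StratifiedCohort}
#' @export
setGeneric("strata", function(x) standardGeneric("strata"))

#' @rdname StratifiedCohort-class
#' @export
setGeneric("strataSizes", function(x) standardGeneric("strataSizes"))
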