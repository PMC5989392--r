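#' Construct a genotype-phenotype cohort
#'
#' @param genotypes numeric matrix, samples x SNPs; allele counts in
#'   \{0,1,2\} or fractional dosages in [0,2].
#' @param phenotype optional numeric vector of trait values (length n).
#' @param snpInfo optional data.frame with columns \code{snp_id},
#'   \code{chrom}, \code{pos}; defaults are generated from column names.
#' @param sampleIds optional character vector; defaults to row names or
#'   \code{sample1..n}.
#' @param encoding \code{"genotypic"} or \code{"dominant"}.
#' @return a \code{\linkS4class{CdaCohort}}
#' @examples
#' g <- matrix(rbinom(20, 2, 0.4), 5, 4)
#' co <- cdaCohort(g, phenotype = rnorm(5))
#' nSnps(co)
#' @export
cdaCohort <- function(genotypes, phenotype = numeric(0), snpInfo = NULL,
                      sampleIds = NULL, encoding = "genotypic") {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  m <- ncol(genotypes)
  if (is.null(snpInfo)) {
    ids <- colnames(genotypes)
    if (is.null(ids)) ids <- paste0("snp", seq_len(m))
    snpInfo <- data.frame(snp_id = ids, chrom = rep(NA_character_, m),
                          pos = rep(NA_integer_, m),
                          stringsAsFactors = FALSE)
  }
  if (is.null(sampleIds)) {
    sampleIds <- rownames(genotypes)
    if (is.null(sampleIds)) sampleIds <- paste0("sample", seq_len(nrow(genotypes)))
  }
  new("CdaCohort", genotypes = genotypes, phenotype = as.numeric(phenotype),
      snpInfo = snpInfo, sampleIds = as.character(sampleIds),
      encoding = encoding)
}

#' @rdname CdaCohort-class
#' @export
setMethod("genotypes", "CdaCohort", function(x) x@genotypes)

#' @rdname CdaCohort-class
#' @export
setMethod("phenotype", "CdaCohort", function(x) x@phenotype)

#' @rdname CdaCohort-class
#' @export
setReplaceMethod("phenotype", "CdaCohort", function(x, value) {
  x@phenotype <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname CdaCohort-class
#' @export
setMethod("snpInfo", "CdaCohort", function(x) x@snpInfo)

#' @rdname CdaCohort-class
#' @export
setMethod("sampleIds", "CdaCohort", function(x) x@sampleIds)

#' @rdname CdaCohort-class
#' @export
setMethod("encoding", "CdaCohort", function(x) x@encoding)

#' @rdname CdaCohort-class
#' @export
setMethod("nSamples", "CdaCohort", function(x) nrow(x@genotypes))

#' @rdname CdaCohort-class
#' @export
setMethod("nSnps", "CdaCohort", function(x) ncol(x@genotypes))

#' @rdname phenoMean
#' @export
setMethod("phenoMean", "CdaCohort", function(x) {
  if (!length(x@phenotype)) stop("cohort has no phenotype")
  mean(x@phenotype)
})

#' @rdname phenoMean
#' @export
setMethod("phenoVar", "CdaCohort", function(x) {
  if (!length(x@phenotype)) stop("cohort has no phenotype")
  var(x@phenotype)
})

#' Subset a cohort by samples and/or SNPs
#'
#' @param x a \code{CdaCohort}
#' @param i sample index
#' @param j SNP index
#' @param ... ignored
#' @param drop ignored
#' @export
setMethod("[", "CdaCohort", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@genotypes))
  if (missing(j)) j <- seq_len(ncol(x@genotypes))
  new("CdaCohort",
      genotypes = x@genotypes[i, j, drop = FALSE],
      phenotype = if (length(x@phenotype)) x@phenotype[i] else numeric(0),
      snpInfo = x@snpInfo[j, , drop = FALSE],
      sampleIds = x@sampleIds[i], encoding = x@encoding,
      transform = x@transform)
})

setMethod("show", "CdaCohort", function(object) {
  cat("CdaCohort:", nrow(object@genotypes), "samples x",
      ncol(object@genotypes), "SNPs (", object@encoding, "encoding )\n")
  if (length(object@phenotype))
    cat(sprintf("  phenotype: mean %.4g, var %.4g, transform '%s'\n",
                mean(object@phenotype), var(object@phenotype),
                object@transform$kind))
  else cat("  phenotype: not set\n")
  frac <- any(object@genotypes != round(object@genotypes))
  if (frac) cat("  note: fractional dosages present; see roundDosages()\n")
})

## ---- CdaParams ----

.levelsOf <- function(encoding) if (encoding == "dominant") 1L else 2L

#' Construct (zero-initialized) CDA parameters
#'
#' @param m SNP count
#' @param encoding \code{"dominant"} or \code{"genotypic"}
#' @param snpIds optional SNP identifiers
#' @param h optional (m*L) x 2 field matrix
#' @param J optional (m*L) x (m*L) x 2 coupling array
#' @param interactions logical; \code{FALSE} marks a couplings-off model
#' @return a \code{\linkS4class{CdaParams}}
#' @export
newCdaParams <- function(m, encoding = "dominant", snpIds = NULL,
                         h = NULL, J = NULL, interactions = TRUE) {
  m <- as.integer(m)
  L <- .levelsOf(encoding)
  mL <- m * L
  if (is.null(snpIds)) snpIds <- paste0("snp", seq_len(m))
  if (is.null(h)) h <- matrix(0, mL, 2)
  if (is.null(J)) J <- array(0, c(mL, mL, 2))
  new("CdaParams", encoding = encoding, m = m, snpIds = as.character(snpIds),
      h = h, J = J, interactions = interactions)
}

#' @rdname singleEffects
#' @export
setMethod("singleEffects", "CdaParams", function(object, l = 1) {
  L <- .levelsOf(object@encoding)
  out <- matrix(object@h[, l + 1L], object@m, L, byrow = TRUE)
  rownames(out) <- object@snpIds
  colnames(out) <- paste0("a", seq_len(L))
  out
})

#' @rdname singleEffects
#' @export
setMethod("pairEffects", "CdaParams", function(object, l = 1) {
  out <- object@J[, , l + 1L]
  L <- .levelsOf(object@encoding)
  nm <- paste0(rep(object@snpIds, each = L), ".a", rep(seq_len(L), object@m))
  dimnames(out) <- list(nm, nm)
  out
})

setMethod("show", "CdaParams", function(object) {
  cat("CdaParams:", object@m, "SNPs,", object@encoding, "encoding,",
      if (object@interactions) "with" else "without", "couplings\n")
  cat(sprintf("  max |h^(1)| = %.4g, max |J^(1)| = %.4g\n",
              max(abs(object@h[, 2])), max(abs(object@J[, , 2]))))
})

## ---- CdaFit ----

#' @rdname CdaFit-class
#' @export
setMethod("predictionScore", "CdaFit", function(object) object@R)

#' @rdname CdaFit-class
#' @export
setMethod("cdaParams", "CdaFit", function(object) object@params)

setMethod("show", "CdaFit", function(object) {
  cat(sprintf("CdaFit: R = %.4f at lambda1 = %.4g, lambda2 = %s (n = %d)\n",
              object@R, object@lambda1,
              if (is.infinite(object@lambda2)) "Inf"
              else sprintf("%.4g", object@lambda2), object@nSamples))
  if (!is.na(object@p))
    cat(sprintf("  R0 = %.4f, z = %.3f, p = %.3g\n",
                object@R0, object@z, object@p))
  if (!object@converged) cat("  warning: some component fits did not converge\n")
})

## ---- StratifiedCohort ----

#' @rdname StratifiedCohort-class
#' @export
setMethod("strata", "StratifiedCohort", function(x) x@strata)

#' @rdname StratifiedCohort-class
#' @export
setMethod("strataSizes", "StratifiedCohort", function(x)
  vapply(x@strata, function(s) nrow(s@genotypes), 0L))

setMethod("show", "StratifiedCohort", function(object) {
  sz <- strataSizes(object)
  cat("StratifiedCohort:", length(object@strata), "strata (",
      paste(object@labels, "=", sz, collapse = ", "), ")\n")
})
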