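#' Load a genotype matrix from VCF or dosage-TSV
#'
#' Returns a \code{\linkS4class{CdaCohort}} without phenotype.  Dosages may
#' be fractional (e.g. imputed); \code{\link{roundDosages}} converts them to
#' integral allele counts.
#'
#' @param path file path
#' @param format \code{"vcf"} or \code{"dosage"}; guessed from the file
#'   extension when omitted
#' @return a \code{CdaCohort} (phenotype unset)
#' @seealso \code{\link{readVcfGenotypes}}, \code{\link{readDosageTsv}}
#' @export
loadGenotypes <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  switch(format, vcf = readVcfGenotypes(path), dosage = readDosageTsv(path))
}

#' Read genotypes from a VCF file
#'
#' Allele counts are taken from the GT field (number of alternate alleles
#' per sample); if GT is absent the DS dosage field is used.  Missing
#' genotypes become NA (see \code{\link{imputeMissing}}).
#'
#' @param path VCF file path (plain or bgzipped)
#' @return a \code{\linkS4class{CdaCohort}} (phenotype unset)
#' @export
readVcfGenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e)
                    stop("failed to parse VCF '", path, "': ",
                         conditionMessage(e)))
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L)
    stop("VCF '", path, "' contains no variant records")
  ids <- fix[, "ID"]
  noId <- is.na(ids) | ids == "."
  ids[noId] <- paste0(fix[noId, "CHROM"], ":", fix[noId, "POS"])
  if (anyDuplicated(ids))
    stop("duplicate SNP ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  fmt <- vcf@gt[, 1L]
  hasGT <- any(grepl("GT", fmt))
  if (hasGT) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    counts <- apply(gt, c(1, 2), function(x) {
      if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_real_)
      sum(strsplit(x, "[/|]")[[1L]] != "0")
    })
  } else {
    ds <- vcfR::extract.gt(vcf, element = "DS")
    if (all(is.na(ds))) stop("VCF '", path, "' has neither GT nor DS fields")
    counts <- apply(ds, c(1, 2), as.numeric)
  }
  G <- t(counts)  # samples x SNPs
  snpInfo <- data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        stringsAsFactors = FALSE)
  cdaCohort(G, snpInfo = snpInfo, sampleIds = rownames(G))
}

#' Read a tab-separated dosage matrix
#'
#' Expected layout: header row of SNP ids, first column sample id, remaining
#' cells numeric dosages in [0, 2] (fractional allowed).
#'
#' @param path TSV file path
#' @return a \code{\linkS4class{CdaCohort}} (phenotype unset)
#' @export
readDosageTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || nrow(df) < 1L)
    stop("dosage file '", path, "' must have a sample-id column and at ",
         "least one SNP column")
  ids <- as.character(df[[1L]])
  G <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(G)) stop("non-numeric dosage values in '", path, "'")
  if (anyDuplicated(colnames(G)))
    stop("duplicate SNP ids in '", path, "'")
  rownames(G) <- ids
  co <- cdaCohort(G, sampleIds = ids)
  if (any(G != round(G), na.rm = TRUE))
    message("fractional dosages present; apply roundDosages() before fitting")
  co
}

#' Read a phenotype table
#'
#' Tab-separated with a header: sample id in the first column, trait values
#' and covariates in the remaining columns.
#'
#' @param path TSV file path
#' @return data.frame
#' @export
readPhenotypeTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("phenotype file needs sample id + trait columns")
  names(df)[1L] <- "sample_id"
  df
}

#' Attach a phenotype to a cohort
#'
#' Matches the phenotype table to the cohort by sample id; samples missing
#' a trait value are dropped from the returned cohort.
#'
#' @param cohort a \code{\linkS4class{CdaCohort}}
#' @param pheno data.frame from \code{\link{readPhenotypeTsv}}
#' @param trait name of the trait column
#' @return a \code{CdaCohort} with phenotype set
#' @export
attachPhenotype <- function(cohort, pheno, trait) {
  stopifnot(is(cohort, "CdaCohort"), trait %in% names(pheno))
  idx <- match(sampleIds(cohort), pheno$sample_id)
  val <- pheno[[trait]][idx]
  keep <- !is.na(val)
  if (!any(keep)) stop("no cohort sample has a value for trait '", trait, "'")
  if (!all(keep))
    message(sum(!keep), " sample(s) without '", trait, "' dropped")
  out <- cohort[which(keep), ]
  out@phenotype <- as.numeric(val[keep])
  validObject(out)
  out
}

#' Read gene spans from a BED file
#'
#' BED intervals (0-based half-open) are converted to 1-based inclusive
#' coordinates; the BED name column supplies the gene symbol.
#'
#' @param path BED file path
#' @return data.frame with \code{gene}, \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive)
#' @export
readGeneSpansBed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm) || all(is.na(nm)))
    stop("BED file '", path, "' needs a name column with gene symbols")
  data.frame(gene = as.character(nm),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),  # import() already 1-based
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene symbols, all
#' tab-separated.
#'
#' @param path GMT file path
#' @return named list of character vectors of gene symbols
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(ln, 1, 60))
    out[[parts[1L]]] <- unique(parts[-(1:2)])
  }
  out
}
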