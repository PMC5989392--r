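#' Tabular view of CDA parameters
#'
#' One row per free parameter: phenotype order \code{l}, SNP indices
#' \code{i} and \code{j} (\code{j = NA} for fields), genotype levels
#' \code{a} and \code{b} (\code{b = NA} for fields), and the value.  This
#' is the serialization format consumed by the meta-analysis and
#' heritability stages.
#'
#' @param params a \code{\linkS4class{CdaParams}}
#' @return data.frame with columns \code{l}, \code{i}, \code{j}, \code{a},
#'   \code{b}, \code{value}
#' @export
paramTable <- function(params) {
  L <- .levelsOf(params@encoding)
  m <- params@m
  idx <- .pairIndices(m, L)
  rows <- list()
  for (l in 0:1) {
    hv <- params@h[, l + 1L]
    rows[[length(rows) + 1L]] <- data.frame(
      l = l, i = rep(seq_len(m), each = L), j = NA_integer_,
      a = rep(seq_len(L), m), b = NA_integer_, value = hv)
    if (idx$nJ > 0) {
      Jl <- params@J[, , l + 1L]
      ar <- arrayInd(idx$upper, c(idx$mL, idx$mL))
      rows[[length(rows) + 1L]] <- data.frame(
        l = l, i = (ar[, 1L] - 1L) %/% L + 1L, j = (ar[, 2L] - 1L) %/% L + 1L,
        a = (ar[, 1L] - 1L) %% L + 1L, b = (ar[, 2L] - 1L) %% L + 1L,
        value = Jl[idx$upper])
    }
  }
  do.call(rbind, rows)
}

#' Write / read CDA parameters as tab-separated text
#'
#' The file carries a header comment with the encoding, SNP count and SNP
#' ids, followed by the \code{\link{paramTable}} columns.
#'
#' @param params a \code{\linkS4class{CdaParams}}
#' @param path output file
#' @return \code{writeCdaParams}: the path, invisibly;
#'   \code{readCdaParams}: a \code{CdaParams}
#' @export
writeCdaParams <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# encoding=%s m=%d interactions=%d snps=%s",
                     params@encoding, params@m,
                     as.integer(params@interactions),
                     paste(params@snpIds, collapse = ",")), con)
  tb <- paramTable(params)
  writeLines(paste(names(tb), collapse = "\t"), con)
  write.table(tb, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeCdaParams
#' @export
readCdaParams <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1L)
  if (!grepl("^# encoding=", hdr)) stop("not a CDA parameter file: ", path)
  fields <- strsplit(sub("^# ", "", hdr), " ")[[1L]]
  kv <- strsplit(fields, "=")
  vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  encoding <- vals[["encoding"]]
  m <- as.integer(vals[["m"]])
  snpIds <- strsplit(vals[["snps"]], ",")[[1L]]
  tb <- read.delim(path, skip = 1L)
  L <- .levelsOf(encoding)
  params <- newCdaParams(m, encoding, snpIds = snpIds,
                         interactions = vals[["interactions"]] == "1")
  hrows <- is.na(tb$j)
  for (l in 0:1) {
    sel <- hrows & tb$l == l
    params@h[(tb$i[sel] - 1L) * L + tb$a[sel], l + 1L] <- tb$value[sel]
    sel <- !hrows & tb$l == l
    if (any(sel)) {
      r <- (tb$i[sel] - 1L) * L + tb$a[sel]
      cc <- (tb$j[sel] - 1L) * L + tb$b[sel]
      mL <- m * L
      Jl <- params@J[, , l + 1L]
      Jl[r + (cc - 1L) * mL] <- tb$value[sel]
      Jl[cc + (r - 1L) * mL] <- tb$value[sel]
      params@J[, , l + 1L] <- Jl
    }
  }
  validObject(params)
  params
}
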