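#' Load an expression matrix from a delimited file
#'
#' Reads a genes x samples table: first column gene identifiers, header row
#' sample identifiers. The delimiter is auto-detected between tab and comma.
#'
#' @param path path to a TSV or CSV file.
#' @param units expression units tag, `"FPKM"` or `"counts"`; stored in the
#'   `"units"` attribute of the returned matrix.
#' @return numeric matrix with gene rownames, sample colnames, all values
#'   finite and non-negative.
#' @export
loadExpression <- function(path, units = c("FPKM", "counts")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("expression file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA, quote = "\"", comment.char = "")
  geneIds <- as.character(df[[1L]])
  dup <- geneIds[duplicated(geneIds)]
  if (length(dup))
    stop("duplicate gene identifier(s): ", paste(unique(dup), collapse = ", "))
  sampleIds <- colnames(df)[-1L]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample identifier(s) in header")
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1L]
      stop("non-numeric value at gene '", geneIds[bad],
           "', sample '", sampleIds[j], "'")
    }
  }
  x <- as.matrix(vals)
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression values must be finite (missing/NaN/Inf found)")
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1L, ]
    stop("negative expression value at gene '", geneIds[bad[1L]],
         "', sample '", sampleIds[bad[2L]], "'")
  }
  dimnames(x) <- list(geneIds, sampleIds)
  attr(x, "units") <- units
  x
}

#' Convert read counts to FPKM
#'
#' Standard fragments-per-kilobase-per-million normalization:
#' `fpkm(g, s) = counts(g, s) * 1e9 / (length(g) * totalCounts(s))`.
#'
#' @param counts genes x samples matrix of read counts.
#' @param geneLengths named numeric vector of gene lengths in bases, or a
#'   two-column data.frame (gene_id, length_bp).
#' @return matrix of FPKM values with `"units"` attribute `"FPKM"`.
#' @export
countsToFpkm <- function(counts, geneLengths) {
  if (is.data.frame(geneLengths))
    geneLengths <- stats::setNames(as.numeric(geneLengths[[2L]]),
                                   as.character(geneLengths[[1L]]))
  genes <- rownames(counts)
  missing <- setdiff(genes, names(geneLengths))
  if (length(missing))
    stop("missing gene length(s): ", paste(missing, collapse = ", "))
  len <- geneLengths[genes]
  if (any(len <= 0))
    stop("non-positive gene length(s): ",
         paste(genes[len <= 0], collapse = ", "))
  tot <- colSums(counts)
  if (any(tot <= 0))
    stop("zero total counts in sample(s): ",
         paste(colnames(counts)[tot <= 0], collapse = ", "))
  fpkm <- sweep(counts * 1e9 / len, 2L, tot, "/")
  attr(fpkm, "units") <- "FPKM"
  fpkm
}

#' Remove genes with too many zero observations
#'
#' Drops genes whose fraction of zero-valued samples exceeds
#' `maxZeroFraction`; genes at exactly the threshold are kept.
#'
#' @param x genes x samples expression matrix.
#' @param maxZeroFraction maximum tolerated fraction of zeros per gene
#'   (default 0.2, i.e. genes that are zero in more than 20% of samples are
#'   removed).
#' @return the filtered matrix (gene order preserved, samples unchanged).
#' @export
filterLowExpression <- function(x, maxZeroFraction = 0.2) {
  stopifnot(maxZeroFraction >= 0, maxZeroFraction <= 1)
  zf <- rowMeans(x == 0)
  keep <- zf <= maxZeroFraction
  if (!any(keep))
    warning("all genes removed by the zero-fraction filter")
  out <- x[keep, , drop = FALSE]
  attr(out, "units") <- attr(x, "units")
  out
}

#' Select differentially expressed genes
#'
#' A gene is selected when its fold change (ratio of arithmetic means,
#' case over control) is `>= x` or `<= 1/x` and a two-sided two-sample
#' t-test gives `p < alpha`.
#'
#' @param case,control genes x samples matrices sharing the same gene set.
#' @param x fold-change cutoff (`>= 1`); `x = 1` makes the fold-change arms
#'   vacuous so the test alone decides.
#' @param alpha significance level (default 0.05).
#' @param varEqual use Student's equal-variance t statistic (default);
#'   `FALSE` gives Welch.
#' @return character vector of selected gene identifiers.
#' @export
selectDegs <- function(case, control, x, alpha = 0.05, varEqual = TRUE) {
  stopifnot(x >= 1)
  if (!identical(rownames(case), rownames(control)))
    stop("case and control must share the same gene set, in order")
  genes <- rownames(case)
  mc <- rowMeans(case)
  mn <- rowMeans(control)
  sel <- logical(length(genes))
  for (i in seq_along(genes)) {
    if (mc[i] == 0 && mn[i] == 0) next  # no signal either way
    fc <- if (mn[i] == 0) Inf else mc[i] / mn[i]
    if (!(fc >= x || fc <= 1 / x)) next
    p <- tryCatch(
      stats::t.test(case[i, ], control[i, ], var.equal = varEqual)$p.value,
      error = function(e) NA_real_)  # constant data: no testable difference
    sel[i] <- is.finite(p) && p < alpha
  }
  genes[sel]
}
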