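#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats approx cor fisher.test median p.adjust quantile rnorm runif
#'   setNames var sd filter
#' @importFrom utils read.delim read.csv write.table head
NULL

#' GenotypePanel: line-by-marker genotypes of a segment substitution panel
#'
#' Holds the allele table of a mapping panel consisting of two parents,
#' chromosome segment substitution lines (CSSLs, one contiguous donor segment
#' each) and optionally backcross-inbred lines (BILs, mosaic genomes), together
#' with the marker map, the background parent of every line and the
#' days-to-heading table used to compute scaled age.
#'
#' Alleles are coded categorically as \code{"P1"}/\code{"P2"} (the two parental
#' roles), never as 0/1 integers, so that a silent parent swap cannot occur.
#' Markers are kept sorted by (chromosome, position).
#'
#' @slot alleles character matrix, lines x markers, entries "P1" or "P2".
#' @slot markerMap data.frame with columns \code{marker}, \code{chrom},
#'   \code{pos_bp}, sorted by (chrom, pos_bp); one row per marker.
#' @slot background named character vector, line -> "P1"/"P2".
#' @slot lineType named character vector, line -> "parent", "cssl" or "bil".
#' @slot headingDays data.frame with columns \code{line_id},
#'   \code{transplant_set}, \code{heading_days} (days from sowing to heading).
#'
#' @export
setClass("GenotypePanel",
  slots = c(
    alleles     = "matrix",
    markerMap   = "data.frame",
    background  = "character",
    lineType    = "character",
    headingDays = "data.frame"
  )
)

.validGenotypePanel <- function(object) {
  msg <- character(0)
  al <- object@alleles
  mm <- object@markerMap
  if (!all(al %in% c("P1", "P2")))
    msg <- c(msg, "alleles must all be 'P1' or 'P2'")
  if (is.null(rownames(al)) || anyDuplicated(rownames(al)))
    msg <- c(msg, "line ids must be present and unique")
  if (is.null(colnames(al)) || anyDuplicated(colnames(al)))
    msg <- c(msg, "marker ids must be present and unique")
  if (!all(c("marker", "chrom", "pos_bp") %in% names(mm)))
    msg <- c(msg, "markerMap needs columns marker, chrom, pos_bp")
  else {
    if (!identical(colnames(al), as.character(mm$marker)))
      msg <- c(msg, "markerMap rows must match allele columns (same order)")
    if (anyDuplicated(mm[, c("chrom", "pos_bp")]))
      msg <- c(msg, "each marker must have a unique (chrom, pos_bp)")
    o <- order(mm$chrom, mm$pos_bp)
    if (!identical(o, seq_len(nrow(mm))))
      msg <- c(msg, "markers must be sorted by (chrom, pos_bp)")
  }
  if (!identical(sort(names(object@background)), sort(rownames(al))))
    msg <- c(msg, "background must be named by every line")
  if (!all(object@background %in% c("P1", "P2")))
    msg <- c(msg, "background values must be 'P1' or 'P2'")
  if (!all(object@lineType %in% c("parent", "cssl", "bil")))
    msg <- c(msg, "lineType values must be parent/cssl/bil")
  for (p in names(object@lineType)[object@lineType == "parent"]) {
    if (length(unique(al[p, ])) != 1L)
      msg <- c(msg, sprintf("parent line '%s' must carry a uniform allele", p))
  }
  if (length(msg)) msg else TRUE
}
setValidity("GenotypePanel", .validGenotypePanel)

#' MeteoSeries: a minute- or coarser-resolution weather series
#'
#' Air temperature (degrees C) and global solar radiation (kJ m-2 min-1) on a
#' strictly increasing time grid at one site. Timestamps are ISO-8601 local
#' time stored as POSIXct in UTC; no timezone arithmetic is performed
#' (single-site assumption).
#'
#' @slot time POSIXct, strictly increasing.
#' @slot temperature numeric, degrees Celsius.
#' @slot radiation numeric, kJ m-2 min-1, non-negative.
#'
#' @export
setClass("MeteoSeries",
  slots = c(time = "POSIXct", temperature = "numeric", radiation = "numeric")
)

.validMeteoSeries <- function(object) {
  msg <- character(0)
  n <- length(object@time)
  if (length(object@temperature) != n || length(object@radiation) != n)
    msg <- c(msg, "time, temperature and radiation must have equal length")
  if (n > 1 && any(diff(as.numeric(object@time)) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing (no duplicates)")
  if (any(!is.finite(object@temperature)))
    msg <- c(msg, "temperature must be finite")
  if (any(!is.finite(object@radiation)) || any(object@radiation < 0))
    msg <- c(msg, "radiation must be finite and >= 0")
  if (length(msg)) msg else TRUE
}
setValidity("MeteoSeries", .validMeteoSeries)

#' FieldExpression: field time-series expression data
#'
#' A \linkS4class{SummarizedExperiment} whose columns are individual field
#' samples (one leaf, one timestamp) and whose rows are genes. Raw data carry
#' a \code{counts} assay; after \code{\link{preprocessExpression}} the object
#' additionally carries a \code{log2rpm} assay, per-gene precision weights in
#' \code{rowData()$weight} and per-sample scaled age in
#' \code{colData()$scaled_age}.
#'
#' Required colData columns: \code{line_id}, \code{transplant_set},
#' \code{sowing_date} (POSIXct midnight), \code{sampling_time} (POSIXct,
#' minute resolution).
#'
#' @export
setClass("FieldExpression", contains = "SummarizedExperiment")

.validFieldExpression <- function(object) {
  msg <- character(0)
  cd <- SummarizedExperiment::colData(object)
  need <- c("line_id", "transplant_set", "sowing_date", "sampling_time")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("colData misses column(s):", paste(miss, collapse = ", ")))
  if (!length(SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "at least one assay (counts or log2rpm) is required")
  if ("counts" %in% SummarizedExperiment::assayNames(object)) {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
  }
  if (all(need %in% colnames(cd)) && nrow(cd) > 0) {
    if (any(as.numeric(cd$sampling_time) <= as.numeric(cd$sowing_date)))
      msg <- c(msg, "sampling_time must be after sowing_date for every sample")
  }
  if (length(msg)) msg else TRUE
}
setValidity("FieldExpression", .validFieldExpression)

#' GeneModelSet: fitted per-gene expression models for one parent
#'
#' One entry per gene. Each model is a linear predictor on the log2rpm scale
#' with an intercept and optional circadian clock (cos/sin of fractional hour),
#' scaled-age, and gated-window environmental terms; the term set and the
#' environmental feature (variable, window, gate threshold) are selected by
#' an information criterion over a grid (see \code{\link{fitGeneModels}}).
#'
#' @slot parent "P1" or "P2" (which parental background the fit used).
#' @slot models named list (by gene id); each element a list with fields
#'   \code{gene_id}, \code{terms} (subset of clock/age/env), \code{coef}
#'   (named numeric: mu, clock_cos, clock_sin, age, env as present),
#'   \code{env} (NULL or list(variable, window_hours, threshold)),
#'   \code{rssw} (weighted residual sum of squares), \code{n}, \code{k},
#'   \code{aic} (classic 2k-penalty AIC), \code{ic} (the BIC-type selection
#'   criterion actually minimised), \code{weight} (the gene's precision
#'   weight).
#' @slot grid data.frame of candidate environmental features used in fitting.
#' @slot sampleIds character, the training sample ids.
#'
#' @export
setClass("GeneModelSet",
  slots = c(parent = "character", models = "list", grid = "data.frame",
            sampleIds = "character")
)

#' EqtlScan: residual-error profiles of a marker scan
#'
#' For every scanned gene, the weighted residual error sum obtained when each
#' marker in turn is assumed to control which parental model predicts each
#' sample, plus the background-assignment baseline and the per-line error
#' aggregates needed for permutation nulls and multi-eQTL selection.
#'
#' @slot geneIds scanned genes.
#' @slot markerIds markers, in map order.
#' @slot statistic genes x markers matrix of T = RSS_BG - RSS_marker.
#' @slot rssMarker genes x markers matrix of weighted residual error sums.
#' @slot rssBg per-gene weighted residual error under background assignment.
#' @slot lineErrors list(P1 = genes x lines, P2 = genes x lines) of per-line
#'   weighted squared-error totals under each parental model.
#' @slot lines line ids (columns of lineErrors).
#' @slot background background parent per line (named).
#'
#' @export
setClass("EqtlScan",
  slots = c(geneIds = "character", markerIds = "character",
            statistic = "matrix", rssMarker = "matrix", rssBg = "numeric",
            lineErrors = "list", lines = "character", background = "character")
)
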