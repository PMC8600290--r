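# Accessors and show methods for the S4 containers.

#' @rdname GenotypePanel-class
#' @export
setMethod("lineIds", "GenotypePanel", function(x) rownames(x@alleles))

#' @rdname GenotypePanel-class
#' @export
setMethod("markerIds", "GenotypePanel", function(x) colnames(x@alleles))

#' @rdname GenotypePanel-class
#' @export
setMethod("markerMap", "GenotypePanel", function(x) x@markerMap)

#' @rdname GenotypePanel-class
#' @export
setMethod("alleles", "GenotypePanel", function(x) x@alleles)

#' @rdname GenotypePanel-class
#' @export
setMethod("background", "GenotypePanel", function(x) x@background)

#' @rdname GenotypePanel-class
#' @export
setMethod("lineType", "GenotypePanel", function(x) x@lineType)

#' @rdname GenotypePanel-class
#' @export
setMethod("headingDays", "GenotypePanel", function(x) x@headingDays)

setMethod("show", "GenotypePanel", function(object) {
  tt <- table(factor(object@lineType, c("parent", "cssl", "bil")))
  cat("GenotypePanel:", nrow(object@alleles), "lines x",
      ncol(object@alleles), "markers\n")
  cat("  parents:", tt[["parent"]], " CSSLs:", tt[["cssl"]],
      " BILs:", tt[["bil"]], "\n")
  cat("  chromosomes:", length(unique(object@markerMap$chrom)), "\n")
})

#' @rdname MeteoSeries-class
#' @export
setMethod("timestamps", "MeteoSeries", function(x) x@time)

#' @rdname MeteoSeries-class
#' @export
setMethod("temperature", "MeteoSeries", function(x) x@temperature)

#' @rdname MeteoSeries-class
#' @export
setMethod("radiation", "MeteoSeries", function(x) x@radiation)

setMethod("show", "MeteoSeries", function(object) {
  n <- length(object@time)
  cat("MeteoSeries:", n, "time points",
      format(object@time[1]), "..", format(object@time[n]), "\n")
  cat(sprintf("  temperature %.1f..%.1f degC, radiation 0..%.2f kJ m-2 min-1\n",
              min(object@temperature), max(object@temperature),
              max(object@radiation)))
})

#' @rdname FieldExpression-class
#' @export
setMethod("log2rpm", "FieldExpression", function(x) {
  if (!"log2rpm" %in% SummarizedExperiment::assayNames(x))
    stop("no 'log2rpm' assay; run preprocessExpression() first")
  SummarizedExperiment::assay(x, "log2rpm")
})

#' @rdname FieldExpression-class
#' @export
setMethod("geneWeights", "FieldExpression", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"weight" %in% colnames(rd))
    stop("no precision weights; run preprocessExpression() first")
  setNames(rd$weight, rownames(x))
})

#' @rdname FieldExpression-class
#' @export
setMethod("scaledAges", "FieldExpression", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"scaled_age" %in% colnames(cd))
    stop("no scaled_age; run preprocessExpression() first")
  setNames(cd$scaled_age, colnames(x))
})

setMethod("show", "FieldExpression", function(object) {
  callNextMethod()
  cd <- SummarizedExperiment::colData(object)
  cat("lines:", length(unique(cd$line_id)),
      " transplant sets:", length(unique(cd$transplant_set)), "\n")
})

#' @rdname GeneModelSet-class
#' @export
setMethod("modelTable", "GeneModelSet", function(x) {
  rows <- lapply(x@models, function(m) {
    data.frame(
      gene_id = m$gene_id,
      parent = x@parent,
      terms = paste(m$terms, collapse = "+"),
      mu = m$coef[["mu"]],
      clock_cos = if ("clock_cos" %in% names(m$coef)) m$coef[["clock_cos"]] else NA_real_,
      clock_sin = if ("clock_sin" %in% names(m$coef)) m$coef[["clock_sin"]] else NA_real_,
      age = if ("age" %in% names(m$coef)) m$coef[["age"]] else NA_real_,
      env = if ("env" %in% names(m$coef)) m$coef[["env"]] else NA_real_,
      env_variable = if (is.null(m$env)) NA_character_ else m$env$variable,
      env_window_hours = if (is.null(m$env)) NA_real_ else m$env$window_hours,
      env_threshold = if (is.null(m$env)) NA_real_ else m$env$threshold,
      rssw = m$rssw, n = m$n, k = m$k, aic = m$aic, ic = m$ic,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
})

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet: parent", object@parent, "-", length(object@models),
      "genes fitted on", length(object@sampleIds), "samples\n")
  trm <- vapply(object@models, function(m) paste(sort(m$terms), collapse = "+"),
                character(1))
  trm[trm == ""] <- "(intercept)"
  print(table(trm))
})

setMethod("show", "EqtlScan", function(object) {
  cat("EqtlScan:", length(object@geneIds), "genes x",
      length(object@markerIds), "markers\n")
  cat("  max T per gene: median",
      signif(median(apply(object@statistic, 1, max)), 4), "\n")
})
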