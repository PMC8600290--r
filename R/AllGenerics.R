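#' @rdname GenotypePanel-class
#' @param x,object a \linkS4class{GenotypePanel}
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("background", function(x) standardGeneric("background"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("lineType", function(x) standardGeneric("lineType"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("headingDays", function(x) standardGeneric("headingDays"))

#' @rdname MeteoSeries-class
#' @param x a \linkS4class{MeteoSeries}
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' @rdname MeteoSeries-class
#' @export
setGeneric("temperature", function(x) standardGeneric("temperature"))

#' @rdname MeteoSeries-class
#' @export
setGeneric("radiation", function(x) standardGeneric("radiation"))

#' @rdname FieldExpression-class
#' @param x a \linkS4class{FieldExpression}
#' @export
setGeneric("log2rpm", function(x) standardGeneric("log2rpm"))

#' @rdname FieldExpression-class
#' @export
setGeneric("geneWeights", function(x) standardGeneric("geneWeights"))

#' @rdname FieldExpression-class
#' @export
setGeneric("scaledAges", function(x) standardGeneric("scaledAges"))

#' @rdname GeneModelSet-class
#' @param x a \linkS4class{GeneModelSet}
#' @export
setGeneric("modelTable", function(x) standardGeneric("modelTable"))
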