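#' @importFrom methods setGeneric setMethod setClass setValidity validObject new is
#' @importFrom stats var sd setNames median rlnorm rmultinom rpois runif rnorm
#'   kruskal.test p.adjust pnorm aggregate
#' @importFrom utils read.delim write.table packageVersion head tail combn
NULL

#' @rdname sampleDates
#' @export
setGeneric("sampleDates", function(x) standardGeneric("sampleDates"))

#' @rdname sampleDates
#' @export
setGeneric("sizeFraction", function(x) standardGeneric("sizeFraction"))

#' @rdname sampleDates
#' @export
setGeneric("isFungal", function(x) standardGeneric("isFungal"))

#' @rdname sampleDates
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @rdname sampleDates
#' @export
setGeneric("sampleTotals", function(x) standardGeneric("sampleTotals"))
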