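#' @include AllClasses.R
NULL

#' CNA value matrix
#'
#' @param x a [CNAProfile-class].
#' @return numeric genes x cells matrix of smoothed CNA values, rows in
#'   genomic order.
#' @export
setGeneric("cnaMatrix", function(x) standardGeneric("cnaMatrix"))

#' @rdname cnaMatrix
#' @export
setMethod("cnaMatrix", "CNAProfile", function(x) assay(x, "cna"))

#' Chromosome row blocks of a CNA profile
#'
#' @param x a [CNAProfile-class].
#' @return data.frame with columns \code{chromosome}, \code{first},
#'   \code{last}: the 1-based row-index range of each chromosome block.
#' @export
setGeneric("chromosomeBoundaries",
           function(x) standardGeneric("chromosomeBoundaries"))

#' @rdname chromosomeBoundaries
#' @export
setMethod("chromosomeBoundaries", "CNAProfile", function(x) {
  r <- rle(as.character(rowData(x)$chromosome))
  last <- cumsum(r$lengths)
  data.frame(chromosome = r$values, first = last - r$lengths + 1L,
             last = last, row.names = NULL, stringsAsFactors = FALSE)
})

#' @rdname filterQC
#' @export
setGeneric("filterQC",
           function(x, thresholds = qcThresholds(), ...)
             standardGeneric("filterQC"))

#' @rdname logNormalize
#' @export
setGeneric("logNormalize",
           function(x, scaleFactor = 1e4, ...)
             standardGeneric("logNormalize"))

#' @rdname scaleGenes
#' @export
setGeneric("scaleGenes",
           function(x, cap = 10, ...) standardGeneric("scaleGenes"))

#' @rdname inferCNA
#' @export
setGeneric("inferCNA",
           function(x, annotation, params, ...) standardGeneric("inferCNA"))

#' @rdname cnaBurden
#' @export
setGeneric("cnaBurden", function(x) standardGeneric("cnaBurden"))
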