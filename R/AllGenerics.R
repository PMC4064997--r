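#' @rdname ResponseMatrix-class
#' @param x,object a `ResponseMatrix`
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname ResponseMatrix-class
#' @export
setGeneric("assayIds", function(x) standardGeneric("assayIds"))

#' @rdname ResponseMatrix-class
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))

#' @rdname ResponseMatrix-class
#' @export
setGeneric("activesPerAssay", function(x) standardGeneric("activesPerAssay"))

#' @rdname ResponseMatrix-class
#' @export
setGeneric("inactivesPerAssay",
           function(x) standardGeneric("inactivesPerAssay"))

#' @rdname ToxicityLabels-class
#' @export
setGeneric("toxClass", function(x) standardGeneric("toxClass"))

#' @rdname ToxicityLabels-class
#' @export
setGeneric("negLogLD50", function(x) standardGeneric("negLogLD50"))

#' Remove marginal compounds from a label set
#'
#' Compounds whose -log10 LD50 (mol/kg) falls in the closed band
#' \[2.00, 3.00\] are neither clearly toxic nor clearly nontoxic and are
#' excluded before any assay-relevance computation, leaving a binary
#' endpoint.
#'
#' @param x a [ToxicityLabels-class] object.
#' @return a `ToxicityLabels` containing only toxic and nontoxic compounds,
#'   in their original order.
#' @examples
#' lab <- ToxicityLabels(c("c1", "c2", "c3"), neg_log_ld50 = c(3.5, 2.5, 1.2))
#' length(dropMarginal(lab))
#' @export
setGeneric("dropMarginal", function(x) standardGeneric("dropMarginal"))

#' @rdname AssaySelection-class
#' @export
setGeneric("candidateAssays", function(x) standardGeneric("candidateAssays"))

#' @rdname AssaySelection-class
#' @export
setGeneric("panelAssays", function(x) standardGeneric("panelAssays"))

#' @rdname AssaySelection-class
#' @export
setGeneric("relevanceTable", function(x) standardGeneric("relevanceTable"))
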