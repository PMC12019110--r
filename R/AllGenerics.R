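#' @rdname nodes
#' @export
setGeneric("nodes", function(object) standardGeneric("nodes"))

#' @rdname nodes
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))

#' @rdname weightMatrix
#' @export
setGeneric("weightMatrix", function(object) standardGeneric("weightMatrix"))

#' @rdname edgeList
#' @export
setGeneric("edgeList", function(object, ...) standardGeneric("edgeList"))

#' @rdname bidirectionalStrength
#' @export
setGeneric("bidirectionalStrength", function(net, left, right)
  standardGeneric("bidirectionalStrength"))

#' @rdname minCut
#' @export
setGeneric("minCut", function(net, subset = NULL, bruteForceLimit = 12L)
  standardGeneric("minCut"))

#' @rdname listComplexes
#' @export
setGeneric("listComplexes", function(net, bruteForceLimit = 12L)
  standardGeneric("listComplexes"))

#' @rdname coreness
#' @export
setGeneric("coreness", function(net, bruteForceLimit = 12L,
                                conditionLabel = "")
  standardGeneric("coreness"))

#' @rdname symmetrize
#' @export
setGeneric("symmetrize", function(net) standardGeneric("symmetrize"))

#' @rdname weightedDegree
#' @export
setGeneric("weightedDegree", function(net) standardGeneric("weightedDegree"))

#' @rdname sCore
#' @export
setGeneric("sCore", function(net) standardGeneric("sCore"))

#' @rdname fricScore
#' @export
setGeneric("fricScore", function(net, subset) standardGeneric("fricScore"))
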