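#' @include AllClasses.R
NULL

#' @export
setGeneric("centroids", function(x, ...) standardGeneric("centroids"))

#' @export
setGeneric("tissueLabels", function(x) standardGeneric("tissueLabels"))

#' @export
setGeneric("tissueLabels<-",
           function(x, value) standardGeneric("tissueLabels<-"))

#' @export
setGeneric("embryoIDs", function(x) standardGeneric("embryoIDs"))

#' @export
setGeneric("nucleusKeys", function(x) standardGeneric("nucleusKeys"))

#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @export
setGeneric("edgeLengths", function(x) standardGeneric("edgeLengths"))

#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))

#' @export
setGeneric("adjacencyList", function(x) standardGeneric("adjacencyList"))
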