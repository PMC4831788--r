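#' @include AllClasses.R
NULL

#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @export
setGeneric("hemisphere", function(x) standardGeneric("hemisphere"))
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))
#' @export
setGeneric("connValues", function(x) standardGeneric("connValues"))
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))
#' @export
setGeneric("edgeLabels", function(x) standardGeneric("edgeLabels"))
#' @export
setGeneric("hemiClass", function(x) standardGeneric("hemiClass"))
#' @export
setGeneric("panelValues", function(x) standardGeneric("panelValues"))
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))
#' @export
setGeneric("isStandardized", function(x) standardGeneric("isStandardized"))
#' @export
setGeneric("canonicalU", function(x) standardGeneric("canonicalU"))
#' @export
setGeneric("canonicalV", function(x) standardGeneric("canonicalV"))
#' @export
setGeneric("canonicalCor", function(x) standardGeneric("canonicalCor"))
#' @export
setGeneric("selectionCounts",
           function(x, panel = c("structural", "functional"))
             standardGeneric("selectionCounts"))
#' @export
setGeneric("selectionProbabilities",
           function(x, panel = c("structural", "functional"))
             standardGeneric("selectionProbabilities"))
#' @export
setGeneric("chanceProbability", function(x, ...)
  standardGeneric("chanceProbability"))
#' @export
setGeneric("selectedEdges", function(x) standardGeneric("selectedEdges"))
#' @export
setGeneric("rejectedEdges", function(x) standardGeneric("rejectedEdges"))
#' @export
setGeneric("decisionTable", function(x) standardGeneric("decisionTable"))
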