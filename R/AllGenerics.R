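#' @rdname dosageMatrix
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' @rdname siteInfo
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @rdname FilterReport-class
#' @export
setGeneric("passingSites", function(x) standardGeneric("passingSites"))

#' @rdname FilterReport-class
#' @export
setGeneric("ruleCounts", function(x) standardGeneric("ruleCounts"))

#' @rdname SelectionResult-class
#' @export
setGeneric("selectedSites", function(x, ...) standardGeneric("selectedSites"))

#' @rdname PedigreeGraph-class
#' @export
setGeneric("pedigreeEdges", function(x, ...) standardGeneric("pedigreeEdges"))

#' @rdname PedigreeGraph-class
#' @export
setGeneric("activeParents", function(x, ...) standardGeneric("activeParents"))
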