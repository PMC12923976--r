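#' @rdname PresenceMatrix-class
#' @export
setGeneric("presence", function(x, ...) standardGeneric("presence"))

#' @rdname PresenceMatrix-class
#' @export
setGeneric("librarySizes", function(x, ...) standardGeneric("librarySizes"))

#' @rdname OncRNACatalog-class
#' @export
setGeneric("stageFlags", function(x, ...) standardGeneric("stageFlags"))

#' @rdname OncRNACatalog-class
#' @export
setGeneric("stageCounts", function(x, ...) standardGeneric("stageCounts"))

#' @rdname OncRNACatalog-class
#' @export
setGeneric("enrichment", function(x, ...) standardGeneric("enrichment"))

#' @rdname OncRNACatalog-class
#' @export
setGeneric("finalLoci", function(x, ...) standardGeneric("finalLoci"))

#' @rdname OncRNACatalog-class
#' @export
setGeneric("catalogParams", function(x, ...) standardGeneric("catalogParams"))
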