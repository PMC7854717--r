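#' @rdname FabricSet-accessors
#' @export
setGeneric("geneNames", function(x, ...) standardGeneric("geneNames"))

#' @rdname FabricSet-accessors
#' @export
setGeneric("chambers", function(x, ...) standardGeneric("chambers"))

#' @rdname FabricSet-accessors
#' @export
setGeneric("replicas", function(x, ...) standardGeneric("replicas"))

#' @rdname FabricSet-accessors
#' @export
setGeneric("redundancy", function(x, ...) standardGeneric("redundancy"))

#' @rdname GeneSets-accessors
#' @export
setGeneric("geneSet", function(x, name) standardGeneric("geneSet"))

#' @rdname GeneSets-accessors
#' @export
setGeneric("geneSetNames", function(x) standardGeneric("geneSetNames"))
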