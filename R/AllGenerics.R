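#' @rdname GeneModel-class
#' @param object,x a \code{GeneModel} or \code{TranscriptSet}.
#' @export
setGeneric("geneId", function(object) standardGeneric("geneId"))

#' @rdname GeneModel-class
#' @export
setGeneric("geneExons", function(object) standardGeneric("geneExons"))

#' @rdname GeneModel-class
#' @export
setGeneric("startCodon", function(object) standardGeneric("startCodon"))

#' @rdname GeneModel-class
#' @export
setGeneric("geneStrand", function(object) standardGeneric("geneStrand"))

#' @rdname GeneModel-class
#' @export
setGeneric("genomeSeq", function(object) standardGeneric("genomeSeq"))

#' @rdname GeneModel-class
#' @export
setGeneric("annotatedChains", function(object) standardGeneric("annotatedChains"))

#' @rdname TranscriptSet-class
#' @export
setGeneric("txIds", function(object) standardGeneric("txIds"))

#' @rdname TranscriptSet-class
#' @export
setGeneric("exonChains", function(object) standardGeneric("exonChains"))

#' @rdname TranscriptSet-class
#' @export
setGeneric("supportCounts", function(object) standardGeneric("supportCounts"))

#' @rdname TranscriptSet-class
#' @export
setGeneric("exonLabels", function(object) standardGeneric("exonLabels"))

#' @rdname TranscriptSet-class
#' @export
setGeneric("spliceEvents", function(object) standardGeneric("spliceEvents"))
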