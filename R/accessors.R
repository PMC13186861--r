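#' @rdname GeneModel-class
#' @export
setMethod("geneId", "GeneModel", function(object) object@geneId)

#' @rdname GeneModel-class
#' @export
setMethod("geneExons", "GeneModel", function(object) object@exons)

#' @rdname GeneModel-class
#' @export
setMethod("startCodon", "GeneModel", function(object) object@startCodon)

#' @rdname GeneModel-class
#' @export
setMethod("geneStrand", "GeneModel", function(object)
    as.character(GenomicRanges::strand(object@exons))[1])

#' @rdname GeneModel-class
#' @export
setMethod("genomeSeq", "GeneModel", function(object) object@genome)

#' @rdname GeneModel-class
#' @export
setMethod("annotatedChains", "GeneModel", function(object) object@txExons)

#' @rdname GeneModel-class
#' @export
setMethod("show", "GeneModel", function(object) {
    ex <- object@exons
    cat("GeneModel:", object@geneId, "\n")
    cat("  ", length(ex), " annotated exons on ",
        as.character(GenomicRanges::seqnames(ex))[1],
        " (", geneStrand(object), "), span ",
        min(GenomicRanges::start(ex)), "-", max(GenomicRanges::end(ex)),
        "\n", sep = "")
    cat("  ", length(object@txExons), " annotated transcript(s); canonical: ",
        object@canonical, "\n", sep = "")
    cat("  start codon (A of ATG) at ", object@startCodon, "\n", sep = "")
    if (length(object@genome))
        cat("  genome sequence attached (",
            sum(lengths(object@genome)), " nt)\n", sep = "")
    invisible(NULL)
})

#' @rdname TranscriptSet-class
#' @export
setMethod("txIds", "TranscriptSet", function(object)
    SummarizedExperiment::rowData(object)$txId)

#' @rdname TranscriptSet-class
#' @export
setMethod("exonChains", "TranscriptSet", function(object)
    SummarizedExperiment::rowRanges(object))

#' @rdname TranscriptSet-class
#' @export
setMethod("supportCounts", "TranscriptSet", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' @rdname TranscriptSet-class
#' @export
setMethod("exonLabels", "TranscriptSet", function(object)
    SummarizedExperiment::rowData(object)$exonLabels)

#' @rdname TranscriptSet-class
#' @export
setMethod("spliceEvents", "TranscriptSet", function(object)
    SummarizedExperiment::rowData(object)$events)

#' @rdname TranscriptSet-class
#' @export
setMethod("show", "TranscriptSet", function(object) {
    cat("TranscriptSet with ", nrow(object), " transcript model(s) across ",
        ncol(object), " library(ies)\n", sep = "")
    if (nrow(object)) {
        tot <- rowSums(supportCounts(object))
        cat("  ids:", paste(utils::head(txIds(object), 8), collapse = ", "),
            if (nrow(object) > 8) "...", "\n")
        cat("  full-length support: total ", sum(tot), ", per model ",
            paste(utils::head(tot, 8), collapse = ", "),
            if (nrow(object) > 8) " ...", "\n", sep = "")
    }
    fs <- S4Vectors::metadata(object)$filterStats
    if (!is.null(fs))
        cat("  reads: ", fs$parsed, " parsed, ", fs$mapqPass,
            " passed MAPQ, ", fs$fullLength, " full-length\n", sep = "")
    invisible(NULL)
})
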