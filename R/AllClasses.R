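#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom Biostrings DNAStringSet AAStringSet DNAString AAString
#'   reverseComplement translate subseq readDNAStringSet writeXStringSet
#'   pairwiseAlignment alignedPattern alignedSubject xscat AA_ALPHABET
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges rowData
#'   colData assay assays
#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

#' GeneModel: annotation of one gene locus
#'
#' Holds the annotated exon structure of a single gene: its exons in
#' transcription order (exon 1 is the 5'-most exon regardless of strand),
#' the exon chains of all annotated transcripts, the genomic position of
#' the A of the annotated start codon, and the genome sequence of the
#' locus' chromosome(s).
#'
#' @slot geneId single gene identifier.
#' @slot exons \code{GRanges} of annotated exons of the canonical
#'   transcript, stored in transcription order and named
#'   \code{exon1 ... exonN}.
#' @slot transcripts named list of integer vectors; each vector indexes
#'   \code{exons} for one annotated transcript, in transcription order.
#'   Transcripts whose exons differ from the canonical set are stored as
#'   \code{GRanges} exon chains in \code{txExons} instead.
#' @slot txExons named \code{GRangesList}: the literal exon chain of every
#'   annotated transcript (genomic order), used for matching discovered
#'   models against the annotation.
#' @slot canonical name of the canonical transcript.
#' @slot startCodon genomic coordinate (1-based) of the A of the annotated
#'   ATG on the canonical transcript.
#' @slot genome \code{DNAStringSet} holding the reference sequence, named
#'   by chromosome; may be empty when sequence is not needed.
#' @export
setClass("GeneModel",
    representation(
        geneId = "character",
        exons = "GRanges",
        transcripts = "list",
        txExons = "GRangesList",
        canonical = "character",
        startCodon = "integer",
        genome = "DNAStringSet"
    )
)

setValidity("GeneModel", function(object) {
    ex <- object@exons
    if (length(ex) == 0L)
        return("gene has no annotated exons")
    if (length(unique(as.character(GenomicRanges::seqnames(ex)))) != 1L)
        return("annotated exons must lie on one chromosome")
    std <- as.character(GenomicRanges::strand(ex))
    if (length(unique(std)) != 1L || !std[1] %in% c("+", "-"))
        return("annotated exons must share one strand, '+' or '-'")
    so <- sort(ex)
    if (std[1] == "-") so <- rev(so)
    if (!identical(GenomicRanges::start(so), GenomicRanges::start(ex)))
        return("annotated exons must be stored in transcription order")
    if (length(ex) > 1L &&
        any(GenomicRanges::countOverlaps(ex, ex) > 1L))
        return("annotated exons overlap")
    sc <- object@startCodon
    if (length(sc) != 1L || is.na(sc))
        return("startCodon must be a single genomic position")
    hit <- GenomicRanges::start(ex) <= sc & GenomicRanges::end(ex) >= sc
    if (!any(hit))
        return("startCodon does not fall inside an annotated exon")
    TRUE
})

#' TranscriptSet: discovered transcript models with support counts
#'
#' A \code{RangedSummarizedExperiment} whose rows are transcript models
#' discovered from spliced long-read alignments and whose columns are
#' sequencing libraries. \code{rowRanges} holds one exon chain
#' (\code{GRanges}, genomic order) per model; the \code{counts} assay holds
#' full-length read support per model and library. Row metadata carries
#' per-exon classifications and called splicing events; \code{metadata}
#' carries the \code{GeneModel} and read-filtering statistics.
#'
#' @export
setClass("TranscriptSet", contains = "RangedSummarizedExperiment")

setValidity("TranscriptSet", function(object) {
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0))
        return("support counts must be non-negative")
    rd <- SummarizedExperiment::rowData(object)
    need <- c("txId", "exonLabels", "events")
    if (!all(need %in% colnames(rd)))
        return(paste("rowData must contain:", paste(need, collapse = ", ")))
    TRUE
})
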