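## Per-library abundance of each transcript model, from full-length read
## counts only, expressed in transcripts per million (TPM).

#' Count full-length read support per model and library
#'
#' Re-screens alignments with the full-length filter and partitions the
#' retained reads by (intron chain, library); reads whose chain matches no
#' model are dropped (they either failed the discovery support threshold
#' or are fragments).
#'
#' @param txset a \linkS4class{TranscriptSet}.
#' @param reads \code{GRangesList} from
#'   \code{\link{readSplicedAlignments}}.
#' @param mapqMin minimum MAPQ (default 1).
#' @return integer matrix, models x libraries.
#' @export
countSupport <- function(txset, reads, mapqMin = 1) {
    gene <- S4Vectors::metadata(txset)$gene
    mc <- S4Vectors::mcols(reads)
    reads <- reads[mc$mapq >= mapqMin]
    mc <- mc[mc$mapq >= mapqMin, , drop = FALSE]
    chains <- exonChains(txset)
    modelKeys <- vapply(seq_along(chains), function(i) {
        ic <- extractIntronChain(chains[[i]])
        paste(GenomicRanges::start(ic), GenomicRanges::end(ic),
              sep = "-", collapse = ";")
    }, "")
    libsSeen <- sort(unique(mc$library))
    libs <- union(colnames(txset), libsSeen)
    extra <- setdiff(libsSeen, colnames(txset))
    if (length(extra))
        warning("library label(s) not in the model set: ",
                paste(extra, collapse = ", "), "; included anyway")
    cts <- matrix(0L, nrow(txset), length(libs),
                  dimnames = list(txIds(txset), libs))
    flt <- .screenReads(reads, gene)
    fl <- which(flt$fullLength)
    if (length(fl) == 0L) return(cts)
    pairStr <- paste(flt$intronStart, flt$intronEnd, sep = "-")
    keys <- vapply(split(pairStr, factor(flt$intronGroup,
                                         levels = seq_along(reads))),
                   paste, collapse = ";", FUN.VALUE = "")
    hit <- match(keys[fl], modelKeys)
    libIdx <- match(mc$library[fl], libs)
    ok <- !is.na(hit)
    for (k in which(ok))
        cts[hit[k], libIdx[k]] <- cts[hit[k], libIdx[k]] + 1L
    cts
}

#' Transcripts-per-million from full-length counts
#'
#' \code{length_normalized} (standard TPM, the default): per library,
#' \eqn{rate_i = count_i / length_i} and
#' \eqn{tpm_i = rate_i / \sum_j rate_j \times 10^6}.
#' \code{count_based}: \eqn{tpm_i = count_i / \sum_j count_j \times 10^6}
#' (full-length counts are already whole-molecule counts, so length
#' correction is arguably unnecessary). Each library is normalized
#' independently; a library with all-zero counts gets all-zero TPM with a
#' warning.
#'
#' @param counts integer matrix, transcripts x libraries.
#' @param lengths transcript lengths in nt (all > 0).
#' @param mode \code{"length_normalized"} or \code{"count_based"}.
#' @return data.frame with one row per (transcript, library):
#'   \code{transcript_id}, \code{library}, \code{count}, \code{length_nt},
#'   \code{tpm}.
#' @export
computeTPM <- function(counts, lengths,
                       mode = c("length_normalized", "count_based")) {
    mode <- match.arg(mode)
    stopifnot(nrow(counts) == length(lengths), all(lengths > 0))
    if (nrow(counts) == 0L)
        return(data.frame(transcript_id = character(0),
                          library = character(0), count = integer(0),
                          length_nt = integer(0), tpm = numeric(0)))
    tpm <- matrix(0, nrow(counts), ncol(counts),
                  dimnames = dimnames(counts))
    for (j in seq_len(ncol(counts))) {
        cj <- counts[, j]
        if (sum(cj) == 0) {
            if (nrow(counts) > 0)
                warning("library '", colnames(counts)[j],
                        "' has zero full-length counts; TPM set to 0")
            next
        }
        rate <- if (mode == "length_normalized") cj / lengths else cj
        tpm[, j] <- rate / sum(rate) * 1e6
    }
    data.frame(
        transcript_id = rep(rownames(counts), ncol(counts)),
        library = rep(colnames(counts), each = nrow(counts)),
        count = as.integer(counts),
        length_nt = rep(as.integer(lengths), ncol(counts)),
        tpm = as.numeric(tpm),
        stringsAsFactors = FALSE)
}

#' Quantify a TranscriptSet
#'
#' Computes TPM from the stored full-length support counts and transcript
#' lengths (sum of exon widths).
#'
#' @param txset a \linkS4class{TranscriptSet}.
#' @param mode see \code{\link{computeTPM}}.
#' @return long-format data.frame of expression records.
#' @export
quantifyExpression <- function(txset,
                               mode = c("length_normalized",
                                        "count_based")) {
    mode <- match.arg(mode)
    cts <- supportCounts(txset)
    rownames(cts) <- txIds(txset)
    lens <- vapply(exonChains(txset),
                   function(g) sum(GenomicRanges::width(g)), 0L)
    computeTPM(cts, lens, mode = mode)
}

#' Wide TPM matrix (transcripts x libraries)
#'
#' @param expr output of \code{\link{computeTPM}} or
#'   \code{\link{quantifyExpression}}.
#' @return numeric matrix.
#' @export
tpmMatrix <- function(expr) {
    txs <- unique(expr$transcript_id)
    libs <- unique(expr$library)
    m <- matrix(0, length(txs), length(libs),
                dimnames = list(txs, libs))
    for (k in seq_len(nrow(expr)))
        m[expr$transcript_id[k], expr$library[k]] <- expr$tpm[k]
    m
}
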