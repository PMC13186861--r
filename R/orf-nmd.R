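## ATG-anchored ORF prediction and NMD classification. The ORF of every
## model starts at the annotated initiation codon of the canonical
## transcript (alternative upstream/downstream AUGs are deliberately not
## scanned); translation uses the standard nuclear genetic code. A
## transcript is an NMD candidate when its termination codon lies more
## than a threshold (default 50 nt, strict inequality) upstream of the
## final exon-exon junction.

#' Coordinate map between genomic and transcript positions
#'
#' @param chain \code{GRanges} exon chain (genomic order).
#' @param strand \code{"+"} or \code{"-"}.
#' @return an opaque list used by \code{\link{genomicToTranscript}} and
#'   \code{\link{transcriptToGenomic}}.
#' @export
coordinateMap <- function(chain, strand = as.character(
                              GenomicRanges::strand(chain))[1]) {
    chain <- sort(chain)
    txo <- if (strand == "-") rev(chain) else chain
    w <- GenomicRanges::width(txo)
    list(st = GenomicRanges::start(txo), en = GenomicRanges::end(txo),
         cum = cumsum(c(0L, w)), strand = strand,
         length = sum(w))
}

#' Map a genomic position to a transcript position
#'
#' Positions are 1-based on both axes; transcript positions run 5' to 3'.
#' Returns \code{NA} for intronic positions or positions outside the
#' model.
#'
#' @param pos genomic position(s).
#' @param map a \code{\link{coordinateMap}}.
#' @return integer transcript position(s) or \code{NA}.
#' @export
genomicToTranscript <- function(pos, map) {
    vapply(pos, function(p) {
        for (k in seq_along(map$st)) {
            if (p >= map$st[k] && p <= map$en[k]) {
                off <- if (map$strand == "+") p - map$st[k]
                       else map$en[k] - p
                return(map$cum[k] + off + 1L)
            }
        }
        NA_integer_
    }, 0L)
}

#' Map a transcript position to a genomic position
#'
#' @param tpos transcript position(s), 1-based.
#' @param map a \code{\link{coordinateMap}}.
#' @return integer genomic position(s) or \code{NA} when out of range.
#' @export
transcriptToGenomic <- function(tpos, map) {
    vapply(tpos, function(t) {
        if (is.na(t) || t < 1L || t > map$length) return(NA_integer_)
        k <- findInterval(t - 1L, map$cum)
        off <- t - map$cum[k] - 1L
        if (map$strand == "+") map$st[k] + off else map$en[k] - off
    }, 0L)
}

#' Spliced transcript sequence of an exon chain
#'
#' @param chain \code{GRanges} exon chain.
#' @param gene a \linkS4class{GeneModel} with genome attached.
#' @return \code{DNAString}, 5' to 3' on the transcript strand.
#' @export
transcriptSequence <- function(chain, gene) {
    chain <- sort(chain)
    chrom <- as.character(GenomicRanges::seqnames(chain))[1]
    contig <- genomeSeq(gene)[[chrom]]
    s <- do.call(Biostrings::xscat, lapply(seq_along(chain), function(k)
        subseq(contig, GenomicRanges::start(chain)[k],
               GenomicRanges::end(chain)[k])))
    if (geneStrand(gene) == "-") s <- reverseComplement(s)
    s
}

#' ATG-anchored ORF prediction for one exon chain
#'
#' Maps the annotated start codon into the model; if the position is lost
#' (its exon skipped or truncated away, or the mapped codon is no longer
#' ATG) the model is \code{no_start}. Otherwise codons are scanned from
#' the ATG to the first in-frame stop. Models with a stop are classified
#' \code{coding} or \code{nmd_candidate} by the 50-nt rule
#' (\code{\link{nmdClassify}}); models without any in-frame stop are
#' reported \code{coding_no_stop} (an artifact of 3'-truncated models) and
#' are not counted as coding.
#'
#' @param chain \code{GRanges} exon chain (genomic order).
#' @param gene a \linkS4class{GeneModel} with genome attached.
#' @param id transcript id used in the result.
#' @param thresholdNt,strict see \code{\link{nmdClassify}}.
#' @return one-row data.frame: \code{transcript_id}, \code{status},
#'   \code{start_tpos}, \code{stop_tpos}, \code{protein},
#'   \code{protein_len_aa}, \code{stop_to_last_junction_nt}. Transcript
#'   positions are 1-based; \code{stop_tpos} is the first base of the stop
#'   codon.
#' @export
findOrf <- function(chain, gene, id = "tx", thresholdNt = 50,
                    strict = TRUE) {
    map <- coordinateMap(chain, geneStrand(gene))
    res <- data.frame(transcript_id = id, status = "no_start",
                      start_tpos = NA_integer_, stop_tpos = NA_integer_,
                      protein = "", protein_len_aa = 0L,
                      stop_to_last_junction_nt = NA_integer_,
                      stringsAsFactors = FALSE)
    startT <- genomicToTranscript(startCodon(gene), map)
    if (is.na(startT) || map$length - startT + 1L < 3L)
        return(res)
    txseq <- transcriptSequence(chain, gene)
    orfSeq <- subseq(txseq, startT, map$length)
    if (as.character(subseq(orfSeq, 1L, 3L)) != "ATG")
        return(res)
    nCodon <- length(orfSeq) %/% 3L
    aa <- as.character(translate(subseq(orfSeq, 1L, nCodon * 3L),
                                 if.fuzzy.codon = "X"))
    stopAt <- regexpr("*", aa, fixed = TRUE)[1]
    res$start_tpos <- startT
    if (stopAt < 0L) {
        res$status <- "coding_no_stop"
        res$protein <- aa
        res$protein_len_aa <- nchar(aa)
        return(res)
    }
    prot <- substr(aa, 1L, stopAt - 1L)
    stopT <- startT + (stopAt - 1L) * 3L     # first base of the stop codon
    ## distance from the base after the stop codon to the final junction
    ## (= transcript position of the first base of the last exon)
    nEx <- length(chain)
    d <- if (nEx < 2L) NA_integer_ else {
        lastExonStartT <- map$cum[nEx] + 1L
        as.integer(lastExonStartT - (stopT + 3L))
    }
    res$stop_tpos <- stopT
    res$protein <- prot
    res$protein_len_aa <- nchar(prot)
    res$stop_to_last_junction_nt <- d
    res$status <- nmdClassify(d, thresholdNt = thresholdNt, strict = strict)
    res
}

#' NMD classification by the 50-nt rule
#'
#' A transcript whose termination codon lies more than \code{thresholdNt}
#' nucleotides upstream of the final exon-exon junction is an NMD
#' candidate. A stop inside the last exon (negative distance) and a
#' mono-exonic model (no junction; \code{NA} distance) are coding.
#'
#' @param stopToLastJunctionNt distance in nt from the base after the stop
#'   codon to the final junction; \code{NA} for mono-exonic models.
#' @param thresholdNt threshold in nt (default 50; the commonly cited
#'   range is 50-55).
#' @param strict use strict inequality ("more than", the default).
#' @return \code{"coding"} or \code{"nmd_candidate"}.
#' @export
nmdClassify <- function(stopToLastJunctionNt, thresholdNt = 50,
                        strict = TRUE) {
    if (is.na(stopToLastJunctionNt) || stopToLastJunctionNt < 0)
        return("coding")
    hit <- if (strict) stopToLastJunctionNt > thresholdNt
           else stopToLastJunctionNt >= thresholdNt
    if (hit) "nmd_candidate" else "coding"
}

#' Predict ORFs for every model in a TranscriptSet
#'
#' @param txset a \linkS4class{TranscriptSet} whose gene has genome
#'   sequence attached.
#' @param thresholdNt,strict see \code{\link{nmdClassify}}.
#' @return data.frame, one row per model (see \code{\link{findOrf}}).
#' @export
predictOrfs <- function(txset, thresholdNt = 50, strict = TRUE) {
    gene <- S4Vectors::metadata(txset)$gene
    chains <- exonChains(txset)
    ids <- txIds(txset)
    if (length(chains) == 0L)
        return(data.frame(transcript_id = character(0),
                          status = character(0), start_tpos = integer(0),
                          stop_tpos = integer(0), protein = character(0),
                          protein_len_aa = integer(0),
                          stop_to_last_junction_nt = integer(0)))
    out <- lapply(seq_along(chains), function(i)
        findOrf(chains[[i]], gene, id = ids[i], thresholdNt = thresholdNt,
                strict = strict))
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write predicted protein isoforms as FASTA
#'
#' Only models with a translated product (status \code{coding},
#' \code{nmd_candidate} or \code{coding_no_stop}) are written.
#'
#' @param orfs output of \code{\link{predictOrfs}}.
#' @param path output FASTA path.
#' @export
writeProteinFasta <- function(orfs, path) {
    keep <- orfs$protein_len_aa > 0L
    aa <- AAStringSet(orfs$protein[keep])
    names(aa) <- paste0(orfs$transcript_id[keep], " ",
                        orfs$status[keep], " len=",
                        orfs$protein_len_aa[keep], "aa")
    writeXStringSet(aa, path)
    invisible(path)
}
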