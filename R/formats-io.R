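## Format boundary: GTF and SAM are 1-based inclusive on disk; everything in
## memory is GRanges (1-based inclusive); BED output converts to 0-based
## half-open at write time.

#' Read a gene annotation from GTF
#'
#' Parses a GTF (v2.2) file describing the transcripts of a single gene and
#' builds a \linkS4class{GeneModel}. Exons are numbered strand-aware in
#' transcription order (exon 1 is the 5'-most). The canonical transcript is
#' either named explicitly, or chosen as the transcript with the longest
#' total CDS (falling back to the longest exonic span when no CDS features
#' are present). The canonical transcript must carry a \code{start_codon}
#' feature.
#'
#' @param path path to a GTF file with \code{exon} (and \code{start_codon})
#'   features for at least one transcript of one gene.
#' @param genome optional genome sequence: a FASTA path or a
#'   \code{DNAStringSet} named by chromosome.
#' @param canonical optional transcript id to use as the canonical
#'   transcript.
#' @return a \linkS4class{GeneModel}.
#' @export
readGeneGTF <- function(path, genome = NULL, canonical = NULL) {
    gr <- rtracklayer::import(path, format = "gtf")
    ex <- gr[gr$type == "exon"]
    if (length(ex) == 0L)
        stop("no exon features in ", path)
    gid <- unique(ex$gene_id)
    if (length(gid) != 1L)
        stop("expected exons of exactly one gene, found: ",
             paste(gid, collapse = ", "))
    txids <- unique(ex$transcript_id)
    chains <- lapply(txids, function(t) {
        e <- sort(ex[ex$transcript_id == t])
        S4Vectors::mcols(e) <- NULL
        e
    })
    names(chains) <- txids

    sc <- gr[gr$type == "start_codon"]
    cds <- gr[gr$type == "CDS"]
    if (is.null(canonical)) {
        if (length(cds)) {
            cdslen <- vapply(txids, function(t)
                sum(GenomicRanges::width(cds[cds$transcript_id == t])), 0)
            canonical <- txids[which.max(cdslen)]
        } else {
            exlen <- vapply(chains, function(e)
                sum(GenomicRanges::width(e)), 0)
            canonical <- txids[which.max(exlen)]
        }
    }
    if (!canonical %in% txids)
        stop("canonical transcript '", canonical, "' not present in ", path)
    scc <- sc[sc$transcript_id == canonical]
    if (length(scc) == 0L)
        stop("transcript '", canonical, "' has no start_codon feature")

    cex <- chains[[canonical]]               # genomic order
    std <- as.character(GenomicRanges::strand(cex))[1]
    if (!std %in% c("+", "-"))
        stop("gene strand must be '+' or '-'")
    if (length(cex) > 1L &&
        any(GenomicRanges::countOverlaps(cex, cex) > 1L))
        stop("overlapping annotated exons in canonical transcript '",
             canonical, "'")
    txo <- if (std == "-") rev(cex) else cex # transcription order
    names(txo) <- paste0("exon", seq_along(txo))

    startCodonPos <- if (std == "+") min(GenomicRanges::start(scc))
                     else max(GenomicRanges::end(scc))

    idx <- lapply(chains, function(e) {
        m <- GenomicRanges::match(if (std == "-") rev(e) else e, txo)
        as.integer(m)
    })

    gseq <- DNAStringSet()
    if (!is.null(genome)) {
        gseq <- if (is.character(genome)) readDNAStringSet(genome)
                else genome
        names(gseq) <- sub("\\s.*$", "", names(gseq))
    }

    methods::new("GeneModel",
        geneId = gid, exons = txo, transcripts = idx,
        txExons = GenomicRanges::GRangesList(chains),
        canonical = canonical,
        startCodon = as.integer(startCodonPos), genome = gseq)
}

## -- SAM consumption ---------------------------------------------------------

.CIGAR_RE <- "([0-9]+)([MIDNSHP=X])"

## CIGAR walk on plain integers; returns a 2-column matrix (start, end)
.cigarBlocks <- function(cigar, pos) {
    m <- gregexpr(.CIGAR_RE, cigar)[[1]]
    toks <- regmatches(cigar, gregexpr(.CIGAR_RE, cigar))[[1]]
    if (length(toks) == 0L || sum(attr(m, "match.length")) != nchar(cigar))
        stop("malformed CIGAR: ", cigar)
    n <- as.integer(sub("[MIDNSHP=X]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    starts <- integer(0); ends <- integer(0)
    cur_start <- pos; cur <- pos
    open <- FALSE
    for (i in seq_along(op)) {
        if (op[i] %in% c("M", "=", "X", "D")) {
            if (!open) { cur_start <- cur; open <- TRUE }
            cur <- cur + n[i]
        } else if (op[i] == "N") {
            if (open) {
                starts <- c(starts, cur_start); ends <- c(ends, cur - 1L)
                open <- FALSE
            }
            cur <- cur + n[i]
        }
        ## I, S, H, P: no reference consumed
    }
    if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur - 1L) }
    cbind(starts, ends)
}

#' Convert one CIGAR string and 1-based POS into aligned genomic blocks
#'
#' M/=/X and D consume reference within the current block; N closes the
#' block and opens the next one; I/S/H/P consume no reference.
#'
#' @param cigar CIGAR string.
#' @param pos 1-based leftmost mapping position.
#' @return \code{IRanges} of aligned blocks (1-based inclusive).
#' @export
cigarToBlocks <- function(cigar, pos) {
    b <- .cigarBlocks(cigar, pos)
    IRanges::IRanges(start = b[, 1], end = b[, 2])
}

#' Read spliced long-read alignments from a SAM file
#'
#' Parses a headered SAM file and returns one entry per primary alignment,
#' with aligned genomic blocks derived from the CIGAR (introns are N
#' operations). Unmapped, secondary and supplementary records are skipped
#' (supplementary skips are reported via \code{message}). The library label
#' of each read is taken from the given SAM tag (default \code{RG}); reads
#' without the tag are labelled \code{"default"} with a warning.
#'
#' @param path path to a SAM file.
#' @param libraryTag SAM tag carrying the library/barcode label.
#' @return a \code{GRangesList}: one \code{GRanges} of aligned blocks per
#'   read, with metadata columns \code{readId}, \code{library},
#'   \code{mapq}.
#' @export
readSplicedAlignments <- function(path, libraryTag = "RG") {
    lines <- readLines(path)
    rec <- lines[!startsWith(lines, "@") & nzchar(lines)]
    fields <- strsplit(rec, "\t", fixed = TRUE)
    flag <- vapply(fields, function(f) as.integer(f[2]), 0L)
    drop <- bitwAnd(flag, 4L) > 0L | bitwAnd(flag, 256L) > 0L
    n_suppl <- sum(!drop & bitwAnd(flag, 2048L) > 0L)
    if (n_suppl > 0L)
        message("skipped ", n_suppl, " supplementary alignment record(s)")
    keep <- !drop & bitwAnd(flag, 2048L) == 0L
    fields <- fields[keep]; flag <- flag[keep]
    n <- length(fields)
    readId <- vapply(fields, `[`, "", 1L)
    chrom <- vapply(fields, `[`, "", 3L)
    pos <- vapply(fields, function(f) as.integer(f[4]), 0L)
    mapq <- vapply(fields, function(f) as.integer(f[5]), 0L)
    cig <- vapply(fields, `[`, "", 6L)
    ori <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
    tag_re <- paste0("^", libraryTag, ":[AZif]:")
    lib <- vapply(fields, function(f) {
        tags <- f[-(1:11)]
        hit <- grep(tag_re, tags, value = TRUE)
        if (length(hit)) sub(tag_re, "", hit[1]) else NA_character_
    }, "")
    if (n == 0L) {
        grl <- GenomicRanges::GRangesList()
        S4Vectors::mcols(grl) <- S4Vectors::DataFrame(
            readId = character(0), library = character(0),
            mapq = integer(0))
        return(grl)
    }
    blocks <- vector("list", n)
    for (i in seq_len(n))
        blocks[[i]] <- tryCatch(.cigarBlocks(cig[i], pos[i]),
            error = function(e) stop("read '", readId[i], "': ",
                                     conditionMessage(e), call. = FALSE))
    if (anyNA(lib)) {
        warning(sum(is.na(lib)), " read(s) had no ", libraryTag,
                " tag; assigned library 'default'")
        lib[is.na(lib)] <- "default"
    }
    nb <- vapply(blocks, nrow, 0L)
    flat <- do.call(rbind, blocks)
    gr <- GenomicRanges::GRanges(rep(chrom, nb),
        IRanges::IRanges(flat[, 1], flat[, 2]),
        strand = rep(ori, nb))
    grl <- GenomicRanges::split(gr, factor(rep(seq_len(n), nb),
                                           levels = seq_len(n)))
    S4Vectors::mcols(grl) <- S4Vectors::DataFrame(
        readId = readId, library = lib, mapq = mapq)
    names(grl) <- readId
    grl
}

## flatten a GRangesList of read blocks into plain vectors once; all hot
## paths work on this table instead of per-read S4 objects
.readsTable <- function(reads) {
    df <- as.data.frame(reads)
    list(group = df$group, start = df$start, end = df$end,
         n = length(reads))
}

## -- GTF / BED / TSV output --------------------------------------------------

#' Write transcript models as GTF
#'
#' Writes \code{transcript} and \code{exon} features (1-based inclusive)
#' for every model. Reading the file back with
#' \code{\link{readTranscriptChains}} reproduces every exon chain exactly.
#'
#' @param models a \code{TranscriptSet} or a named \code{GRangesList} of
#'   exon chains.
#' @param path output path.
#' @param geneId gene id written to the attributes.
#' @param source value of the GTF source column.
#' @export
writeTranscriptGTF <- function(models, path, geneId = "gene",
                               source = "IsoScope") {
    if (methods::is(models, "TranscriptSet")) {
        geneId <- S4Vectors::metadata(models)$gene@geneId %||% geneId
        chains <- SummarizedExperiment::rowRanges(models)
        names(chains) <- txIds(models)
        models <- chains
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##description: transcript models", con)
    for (tx in names(models)) {
        e <- models[[tx]]
        if (length(e) == 0L) next
        chr <- as.character(GenomicRanges::seqnames(e))[1]
        std <- as.character(GenomicRanges::strand(e))[1]
        attr0 <- sprintf('gene_id "%s"; transcript_id "%s";', geneId, tx)
        writeLines(sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
            chr, source, min(GenomicRanges::start(e)),
            max(GenomicRanges::end(e)), std, attr0), con)
        eo <- sort(e)
        if (std == "-") eo <- rev(eo)
        for (k in seq_along(eo))
            writeLines(sprintf(
                "%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s exon_number \"%d\";",
                chr, source, GenomicRanges::start(eo)[k],
                GenomicRanges::end(eo)[k], std, attr0, k), con)
    }
    invisible(path)
}

#' Read transcript exon chains from a GTF file
#'
#' @param path GTF path.
#' @return named \code{GRangesList} of exon chains in genomic order.
#' @export
readTranscriptChains <- function(path) {
    body <- readLines(path)
    if (!any(nzchar(body) & !startsWith(body, "#")))
        return(GenomicRanges::GRangesList())
    gr <- rtracklayer::import(path, format = "gtf")
    ex <- gr[gr$type == "exon"]
    if (length(ex) == 0L) return(GenomicRanges::GRangesList())
    txids <- unique(ex$transcript_id)
    chains <- lapply(txids, function(t) {
        e <- sort(ex[ex$transcript_id == t])
        S4Vectors::mcols(e) <- NULL
        e
    })
    names(chains) <- txids
    GenomicRanges::GRangesList(chains)
}

#' Write cryptic exons as BED6 (0-based half-open)
#'
#' @param txset a \code{TranscriptSet}.
#' @param path output BED path.
#' @export
writeCrypticBed <- function(txset, path) {
    rows <- list()
    chains <- exonChains(txset)
    labs <- exonLabels(txset)
    ids <- txIds(txset)
    for (i in seq_along(chains)) {
        w <- which(labs[[i]] == "cryptic")
        for (k in w) {
            e <- chains[[i]][k]
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = as.character(GenomicRanges::seqnames(e)),
                start = GenomicRanges::start(e) - 1L,
                end = GenomicRanges::end(e),
                name = paste0(ids[i], "_cryptic"),
                score = 0L,
                strand = as.character(GenomicRanges::strand(e)))
        }
    }
    df <- if (length(rows)) do.call(rbind, rows) else
        data.frame(chrom = character(), start = integer(), end = integer(),
                   name = character(), score = integer(), strand = character())
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a conserved-domain definition table
#'
#' Three-column TSV with a header: \code{name}, \code{aa_start},
#' \code{aa_end} (1-based inclusive amino-acid coordinates on the canonical
#' protein). Overlapping or abutting domains are permitted.
#'
#' @param path TSV path.
#' @return data.frame sorted by \code{aa_start}.
#' @export
readDomainTable <- function(path) {
    df <- read.delim(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    if (!all(c("name", "aa_start", "aa_end") %in% colnames(df)))
        stop("domain table must have columns name, aa_start, aa_end")
    if (nrow(df) == 0L)
        return(df[, c("name", "aa_start", "aa_end")])
    df$aa_start <- as.integer(df$aa_start)
    df$aa_end <- as.integer(df$aa_end)
    bad <- which(df$aa_end < df$aa_start | df$aa_start < 1L)
    if (length(bad))
        stop("invalid domain interval in row '", df$name[bad[1]],
             "': aa_end < aa_start or aa_start < 1")
    df <- df[order(df$aa_start), c("name", "aa_start", "aa_end")]
    rownames(df) <- NULL
    df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
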