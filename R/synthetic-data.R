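## Simulator of a targeted amplicon experiment: one multi-exon gene,
## isoforms defined by an event grammar, and truth-derived spliced SAM
## alignments. The amplicon runs from near the annotated ATG to the last
## annotated exon, so most simulated reads are full length; a configurable
## minority is truncated, standing in for library-preparation fragments.

.SENSE_CODONS <- {
    b <- c("A", "C", "G", "T")
    all <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
    setdiff(all, c("TAA", "TAG", "TGA"))
}
.STOP_CODONS <- c("TAA", "TAG", "TGA")

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

#' Build a synthetic multi-exon gene
#'
#' Generates a random gene locus with the structural guarantees the
#' downstream analysis assumes: canonical GT..AG dinucleotides at every
#' intron boundary (on the transcript strand), an ATG at a recorded offset
#' inside exon 1, a clean reading frame from that ATG through every exon
#' (no premature stop, by construction from sense codons), and a stop codon
#' placed inside the last exon. Deterministic given \code{seed}.
#'
#' @param nExons number of exons (>= 1).
#' @param exonLenRange,intronLenRange integer pairs; exon lengths must
#'   allow the ATG offset and a 3' UTR (minimum 80 nt per exon).
#' @param strand \code{"+"} or \code{"-"}.
#' @param seed integer seed.
#' @param chrom chromosome name of the synthetic contig.
#' @param geneId gene identifier.
#' @return a \linkS4class{GeneModel} with the genome sequence attached.
#' @export
buildGene <- function(nExons = 9, exonLenRange = c(90, 360),
                      intronLenRange = c(100, 800), strand = "+",
                      seed = 1, chrom = "chrS", geneId = "geneS") {
    stopifnot(nExons >= 1L, length(exonLenRange) == 2L,
              length(intronLenRange) == 2L)
    if (exonLenRange[1] < 80L || exonLenRange[1] > exonLenRange[2])
        stop("infeasible exon length range (minimum 80 nt)")
    if (nExons > 1L &&
        (intronLenRange[1] < 10L || intronLenRange[1] > intronLenRange[2]))
        stop("infeasible intron length range (minimum 10 nt)")
    if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
    set.seed(seed)

    exLen <- sample(seq(exonLenRange[1], exonLenRange[2]), nExons,
                    replace = TRUE)
    inLen <- if (nExons > 1L)
        sample(seq(intronLenRange[1], intronLenRange[2]), nExons - 1L,
               replace = TRUE) else integer(0)
    L <- sum(exLen)
    atgOff <- sample(seq(20L, min(60L, exLen[1] - 20L)), 1L)  # 0-based in exon 1
    atgT <- atgOff + 1L                                       # 1-based t-pos
    lastStartT <- L - exLen[nExons] + 1L
    sCand <- seq(L - 32L, lastStartT)                         # stop start t-pos
    sCand <- sCand[(sCand - atgT) %% 3L == 0L & sCand >= atgT + 3L]
    if (length(sCand) == 0L)
        stop("infeasible ranges: no room for a stop codon in the last exon")
    stopT <- max(sCand)

    nCodon <- (stopT - atgT) %/% 3L - 1L   # sense codons after the ATG
    tx <- paste0(.randSeq(atgT - 1L), "ATG",
                 paste(sample(.SENSE_CODONS, nCodon, replace = TRUE),
                       collapse = ""),
                 sample(.STOP_CODONS, 1L),
                 .randSeq(L - stopT - 2L))
    stopifnot(nchar(tx) == L)

    ## lay out contig in transcript orientation, then flip for minus strand
    cum <- cumsum(c(0L, exLen))
    exSeq <- substring(tx, cum[-length(cum)] + 1L, cum[-1L])
    pad <- 100L
    pieces <- character(0)
    st <- integer(nExons); en <- integer(nExons)
    pos <- pad
    for (i in seq_len(nExons)) {
        st[i] <- pos + 1L; en[i] <- pos + exLen[i]
        pieces <- c(pieces, exSeq[i])
        pos <- en[i]
        if (i < nExons) {
            pieces <- c(pieces, paste0("GT", .randSeq(inLen[i] - 4L), "AG"))
            pos <- pos + inLen[i]
        }
    }
    contig <- paste0(.randSeq(pad), paste(pieces, collapse = ""),
                     .randSeq(pad))
    atgG <- st[1] + atgOff                       # built-orientation position

    if (strand == "-") {
        Lg <- nchar(contig)
        contig <- as.character(reverseComplement(DNAString(contig)))
        newSt <- Lg - en + 1L; newEn <- Lg - st + 1L
        st <- newSt; en <- newEn                 # still transcription order
        atgG <- Lg - atgG + 1L
    }
    exons <- GenomicRanges::GRanges(chrom, IRanges::IRanges(st, en),
                                    strand = strand)
    names(exons) <- paste0("exon", seq_len(nExons))
    chain <- sort(exons)
    names(chain) <- NULL
    genome <- DNAStringSet(contig)
    names(genome) <- chrom
    methods::new("GeneModel",
        geneId = geneId, exons = exons,
        transcripts = list(v.1 = seq_len(nExons)),
        txExons = GenomicRanges::GRangesList(v.1 = chain),
        canonical = "v.1", startCodon = as.integer(atgG), genome = genome)
}

## -- event grammar -----------------------------------------------------------

#' Event constructors for \code{\link{realizeIsoform}}
#'
#' \code{skipExon(i)} drops annotated exon i; \code{retainIntron(i)} fuses
#' exons i and i+1 across intron i; \code{altDonor(i, delta)} and
#' \code{altAcceptor(i, delta)} shift the 5' (donor) or 3' (acceptor)
#' splice site of intron i by \code{delta} nt in the transcript direction
#' (positive = downstream); \code{crypticExon(i, offset, length)} inserts a
#' novel exon into intron i, \code{offset} nt downstream of the donor.
#' Indices are in transcription order.
#'
#' @param i annotated exon (skipExon) or intron (others) index.
#' @param delta signed splice-site shift in nt.
#' @param offset,length cryptic exon placement within the intron.
#' @name splice-events
#' @export
skipExon <- function(i) list(type = "skip_exon", exon = as.integer(i))

#' @rdname splice-events
#' @export
retainIntron <- function(i) list(type = "retain_intron",
                                 intron = as.integer(i))

#' @rdname splice-events
#' @export
altDonor <- function(i, delta) list(type = "alt_donor",
    intron = as.integer(i), delta = as.integer(delta))

#' @rdname splice-events
#' @export
altAcceptor <- function(i, delta) list(type = "alt_acceptor",
    intron = as.integer(i), delta = as.integer(delta))

#' @rdname splice-events
#' @export
crypticExon <- function(i, offset, length) list(type = "cryptic_exon",
    intron = as.integer(i), offset = as.integer(offset),
    length = as.integer(length))

#' Apply splicing events to the canonical exon chain
#'
#' Builds the exon chain of an isoform by applying a list of mutually
#' compatible events (see \link{splice-events}) to the canonical chain of a
#' gene.
#'
#' @param gene a \linkS4class{GeneModel}.
#' @param events list of event specs; empty list returns the canonical
#'   chain.
#' @return \code{GRanges} exon chain in genomic order.
#' @export
realizeIsoform <- function(gene, events = list()) {
    ex <- gene@exons                              # transcription order
    n <- length(ex)
    std <- geneStrand(gene)
    st <- GenomicRanges::start(ex); en <- GenomicRanges::end(ex)
    keep <- rep(TRUE, n)
    fuse <- rep(FALSE, max(n - 1L, 0L))           # junction i fused
    skipped <- integer(0); altJunc <- integer(0)
    cryptic <- list()

    for (ev in events) {
        switch(ev$type,
        skip_exon = {
            i <- ev$exon
            if (i < 1L || i > n) stop("skip_exon: no exon ", i)
            keep[i] <- FALSE; skipped <- c(skipped, i)
        },
        retain_intron = {
            i <- ev$intron
            if (i < 1L || i > n - 1L) stop("retain_intron: no intron ", i)
            fuse[i] <- TRUE
        },
        alt_donor = {
            i <- ev$intron
            if (i < 1L || i > n - 1L) stop("alt_donor: no intron ", i)
            if (std == "+") en[i] <- en[i] + ev$delta
            else st[i] <- st[i] - ev$delta
            altJunc <- c(altJunc, i)
        },
        alt_acceptor = {
            i <- ev$intron
            if (i < 1L || i > n - 1L) stop("alt_acceptor: no intron ", i)
            if (std == "+") st[i + 1L] <- st[i + 1L] + ev$delta
            else en[i + 1L] <- en[i + 1L] - ev$delta
            altJunc <- c(altJunc, i)
        },
        cryptic_exon = {
            i <- ev$intron
            if (i < 1L || i > n - 1L) stop("cryptic_exon: no intron ", i)
            if (std == "+") {
                s <- en[i] + ev$offset + 1L
                cryptic[[length(cryptic) + 1L]] <-
                    c(after = i, st = s, en = s + ev$length - 1L)
            } else {
                e <- st[i] - ev$offset - 1L
                cryptic[[length(cryptic) + 1L]] <-
                    c(after = i, st = e - ev$length + 1L, en = e)
            }
        },
        stop("unknown event type: ", ev$type))
    }

    ## compatibility checks
    if (any(fuse)) {
        fi <- which(fuse)
        if (any(!keep[fi] | !keep[fi + 1L]))
            stop("incompatible events: intron retention on a skipped exon")
        if (any(fi %in% altJunc))
            stop("incompatible events: intron retention and alternative ",
                 "splice site on the same intron")
        if (any(vapply(cryptic, function(x) x["after"] %in% fi, logical(1))))
            stop("incompatible events: cryptic exon inside a retained intron")
    }
    if (any(!keep[unique(c(altJunc, altJunc + 1L))] &
            seq_len(n)[unique(c(altJunc, altJunc + 1L))] %in% skipped))
        stop("incompatible events: alternative splice site on a skipped exon")

    ## assemble transcription-order chain
    rows <- list()
    i <- 1L
    while (i <= n) {
        if (keep[i]) {
            s <- st[i]; e <- en[i]
            while (i <= n - 1L && fuse[i]) {      # extend across fused introns
                if (std == "+") e <- en[i + 1L] else s <- st[i + 1L]
                i <- i + 1L
            }
            rows[[length(rows) + 1L]] <- c(s, e)
        }
        cr <- Filter(function(x) x["after"] == i, cryptic)
        for (x in cr) rows[[length(rows) + 1L]] <- c(x[["st"]], x[["en"]])
        i <- i + 1L
    }
    m <- do.call(rbind, rows)
    if (std == "-") m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    if (any(m[, 2] < m[, 1]) ||
        (nrow(m) > 1L && any(diff(m[, 1]) <= 0)) ||
        (nrow(m) > 1L && any(m[-1L, 1] <= m[-nrow(m), 2])))
        stop("incompatible events: resulting exon chain is not a sorted, ",
             "non-overlapping set")
    chrom <- as.character(GenomicRanges::seqnames(ex))[1]
    GenomicRanges::GRanges(chrom, IRanges::IRanges(m[, 1], m[, 2]),
                           strand = std)
}

## -- read simulation ---------------------------------------------------------

## exon layout of an isoform in transcription order, precomputed once
.isoLayout <- function(chain, strand) {
    chain <- sort(chain)
    st <- GenomicRanges::start(chain); en <- GenomicRanges::end(chain)
    if (strand == "-") { st <- rev(st); en <- rev(en) }
    w <- en - st + 1L
    list(st = st, en = en, cum = cumsum(c(0L, w)), L = sum(w))
}

## map a transcript-coordinate interval [a, b] (1-based) onto genomic blocks
.tIntervalToBlocks <- function(lay, strand, a, b) {
    st <- integer(0); en <- integer(0)
    for (k in seq_along(lay$st)) {
        lo <- max(a, lay$cum[k] + 1L); hi <- min(b, lay$cum[k + 1L])
        if (lo > hi) next
        off1 <- lo - lay$cum[k] - 1L; off2 <- hi - lay$cum[k] - 1L
        if (strand == "+") {
            st <- c(st, lay$st[k] + off1)
            en <- c(en, lay$st[k] + off2)
        } else {
            en <- c(en, lay$en[k] - off1)
            st <- c(st, lay$en[k] - off2)
        }
    }
    o <- order(st)
    cbind(st = st[o], en = en[o])
}

.blocksToCigar <- function(m) {
    parts <- character(0)
    for (i in seq_len(nrow(m))) {
        parts <- c(parts, paste0(m[i, 2] - m[i, 1] + 1L, "M"))
        if (i < nrow(m))
            parts <- c(parts, paste0(m[i + 1L, 1] - m[i, 2] - 1L, "N"))
    }
    paste(parts, collapse = "")
}

#' Simulate spliced alignments of a targeted amplicon experiment
#'
#' Draws reads from a weighted set of truth isoforms, assigns each read a
#' library, truncates a configurable fraction (library-preparation
#' fragments), optionally jitters junction coordinates, and writes the
#' resulting truth-derived spliced alignments directly as a headered SAM
#' file (no aligner is invoked). Deterministic given \code{seed}.
#'
#' @param gene a \linkS4class{GeneModel} with genome attached.
#' @param isoforms named \code{GRangesList} of truth exon chains.
#' @param weights isoform abundance weights (normalized internally).
#' @param nReads total number of reads.
#' @param samPath output SAM path.
#' @param fullLengthFrac fraction of reads spanning their whole isoform.
#' @param truncationModel \code{"uniform_5p"}, \code{"uniform_3p"} or
#'   \code{"both"}.
#' @param junctionJitterSd sd (nt) of Gaussian jitter applied to each
#'   junction edge; 0 disables jitter.
#' @param libraries named numeric vector of library weights.
#' @param seed integer seed.
#' @return invisibly, the truth table: one row per read with columns
#'   \code{read_id}, \code{isoform_id}, \code{library},
#'   \code{is_full_length}.
#' @export
simulateAlignments <- function(gene, isoforms, weights, nReads, samPath,
                               fullLengthFrac = 0.8,
                               truncationModel = c("both", "uniform_5p",
                                                   "uniform_3p"),
                               junctionJitterSd = 0,
                               libraries = c(breast = 1, ovarian = 1,
                                             cervical = 1),
                               seed = 1) {
    truncationModel <- match.arg(truncationModel)
    if (nReads < 0) stop("nReads must be non-negative")
    stopifnot(length(weights) == length(isoforms), all(weights >= 0),
              sum(weights) > 0)
    set.seed(seed)
    chrom <- names(genomeSeq(gene))[1]
    std <- geneStrand(gene)
    contig <- genomeSeq(gene)[[chrom]]
    contigChr <- as.character(contig)
    flag <- if (std == "-") 16L else 0L

    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, length(contig)),
             sprintf("@RG\tID:%s\tSM:%s", names(libraries),
                     names(libraries)),
             "@PG\tID:IsoScope\tPN:IsoScope")
    con <- file(samPath, "w")
    on.exit(close(con))
    writeLines(hdr, con)

    truth <- data.frame(read_id = character(0), isoform_id = character(0),
                        library = character(0),
                        is_full_length = logical(0))
    if (nReads == 0)
        return(invisible(truth))

    isoIdx <- sample(seq_along(isoforms), nReads, replace = TRUE,
                     prob = weights / sum(weights))
    lib <- sample(names(libraries), nReads, replace = TRUE,
                  prob = libraries / sum(libraries))
    isFL <- stats::runif(nReads) < fullLengthFrac
    minKeep <- 50L

    truth <- data.frame(
        read_id = sprintf("read%06d", seq_len(nReads)),
        isoform_id = names(isoforms)[isoIdx],
        library = lib, is_full_length = isFL,
        stringsAsFactors = FALSE)

    lays <- lapply(isoforms, .isoLayout, strand = std)
    samLines <- character(nReads)
    for (r in seq_len(nReads)) {
        lay <- lays[[isoIdx[r]]]
        L <- lay$L
        a <- 1L; b <- L
        if (!isFL[r] && L > minKeep + 2L) {
            room <- L - minKeep
            if (truncationModel == "uniform_5p") {
                a <- 1L + sample(seq(0L, room), 1L)
            } else if (truncationModel == "uniform_3p") {
                b <- L - sample(seq(0L, room), 1L)
            } else {
                a <- 1L + sample(seq(0L, room %/% 2L), 1L)
                b <- L - sample(seq(0L, room %/% 2L), 1L)
            }
        }
        m <- .tIntervalToBlocks(lay, std, a, b)
        if (junctionJitterSd > 0 && nrow(m) > 1L) {
            for (j in seq_len(nrow(m) - 1L)) {
                j1 <- as.integer(round(stats::rnorm(1, 0, junctionJitterSd)))
                j2 <- as.integer(round(stats::rnorm(1, 0, junctionJitterSd)))
                newEnd <- m[j, 2] + j1
                newStart <- m[j + 1L, 1] + j2
                if (newEnd >= m[j, 1] + 5L && newStart <= m[j + 1L, 2] - 5L &&
                    newStart > newEnd + 1L) {
                    m[j, 2] <- newEnd; m[j + 1L, 1] <- newStart
                }
            }
        }
        seq <- paste(substring(contigChr, m[, 1], m[, 2]), collapse = "")
        samLines[r] <- sprintf(
            "%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*\tRG:Z:%s",
            truth$read_id[r], flag, chrom, m[1, 1], .blocksToCigar(m),
            seq, lib[r])
    }
    writeLines(samLines, con)
    invisible(truth)
}

#' Write a gene annotation (with start codon) as GTF
#'
#' @param gene a \linkS4class{GeneModel}.
#' @param path output GTF path.
#' @export
writeGeneGTF <- function(gene, path) {
    writeTranscriptGTF(annotatedChains(gene), path, geneId = geneId(gene))
    std <- geneStrand(gene)
    sc <- startCodon(gene)
    chrom <- as.character(GenomicRanges::seqnames(gene@exons))[1]
    scLine <- sprintf(
        "%s\tIsoScope\tstart_codon\t%d\t%d\t.\t%s\t.\t%s",
        chrom, if (std == "+") sc else sc - 2L,
        if (std == "+") sc + 2L else sc, std,
        sprintf('gene_id "%s"; transcript_id "%s";', geneId(gene),
                gene@canonical))
    cat(scLine, "\n", sep = "", file = path, append = TRUE)
    invisible(path)
}

#' Simulate a complete dataset on disk
#'
#' Convenience wrapper: builds a gene, realizes truth isoforms, simulates
#' alignments, and writes \code{genome.fa}, \code{annotation.gtf},
#' \code{reads.sam} and \code{truth.tsv} into a directory.
#'
#' @param dir output directory (created if needed).
#' @param isoformEvents named list: per isoform, a list of event specs
#'   (see \link{splice-events}); an empty list is the canonical transcript.
#' @param weights,nReads,fullLengthFrac,junctionJitterSd,libraries,seed
#'   passed to \code{\link{simulateAlignments}}.
#' @param ... passed to \code{\link{buildGene}}.
#' @return list with the \code{GeneModel}, the truth isoform
#'   \code{GRangesList}, the truth table, and the four file paths.
#' @export
simulateDataset <- function(dir, isoformEvents = list(iso_canonical = list()),
                            weights = rep(1, length(isoformEvents)),
                            nReads = 500, fullLengthFrac = 0.8,
                            junctionJitterSd = 0,
                            libraries = c(breast = 1, ovarian = 1,
                                          cervical = 1),
                            seed = 1, ...) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gene <- buildGene(seed = seed, ...)
    isoforms <- GenomicRanges::GRangesList(
        lapply(isoformEvents, function(ev) realizeIsoform(gene, ev)))
    paths <- list(genome = file.path(dir, "genome.fa"),
                  gtf = file.path(dir, "annotation.gtf"),
                  sam = file.path(dir, "reads.sam"),
                  truth = file.path(dir, "truth.tsv"))
    writeXStringSet(genomeSeq(gene), paths$genome)
    writeGeneGTF(gene, paths$gtf)
    truth <- simulateAlignments(gene, isoforms, weights, nReads, paths$sam,
        fullLengthFrac = fullLengthFrac,
        junctionJitterSd = junctionJitterSd,
        libraries = libraries, seed = seed + 1L)
    write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(gene = gene, isoforms = isoforms, truth = truth, paths = paths)
}
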