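## Isoform discovery: full-length reads are grouped by identical intron
## chain (optionally after merging junction coordinates within a window);
## each group becomes one transcript model whose terminal exon boundaries
## are the modal read ends. Exons are then classified against the
## annotation and named splicing events are called.

#' Extract the intron chain of a spliced alignment
#'
#' @param blocks \code{GRanges} of aligned blocks (genomic order).
#' @return \code{GRanges} of introns: exactly the gaps between consecutive
#'   blocks (empty for mono-block alignments).
#' @export
extractIntronChain <- function(blocks) {
    blocks <- sort(blocks)
    if (length(blocks) < 2L)
        return(GenomicRanges::GRanges())
    st <- GenomicRanges::end(blocks)[-length(blocks)] + 1L
    en <- GenomicRanges::start(blocks)[-1L] - 1L
    GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(blocks))[1],
                           IRanges::IRanges(st, en),
                           strand = as.character(
                               GenomicRanges::strand(blocks))[1])
}

#' Full-length read filter
#'
#' A read is full length when its aligned span covers the genomic position
#' of the annotated start codon and its 3'-most block overlaps the last
#' exon (by default the canonical last annotated exon; the amplicon's
#' reverse primer sits there, so every complete molecule must reach it).
#'
#' @param blocks \code{GRanges} of one read's aligned blocks.
#' @param gene a \linkS4class{GeneModel}.
#' @param lastExon optional \code{GRanges} of length 1 overriding the
#'   canonical last exon (e.g. a specific model's last exon).
#' @return logical scalar.
#' @export
isFullLength <- function(blocks, gene, lastExon = NULL) {
    if (length(blocks) == 0L) return(FALSE)
    sc <- startCodon(gene)
    spanStart <- min(GenomicRanges::start(blocks))
    spanEnd <- max(GenomicRanges::end(blocks))
    if (spanStart > sc || spanEnd < sc) return(FALSE)
    if (is.null(lastExon)) {
        ex <- gene@exons
        lastExon <- ex[length(ex)]
    }
    std <- geneStrand(gene)
    blocks <- sort(blocks)
    b3 <- if (std == "-") blocks[1L] else blocks[length(blocks)]
    GenomicRanges::start(b3) <= GenomicRanges::end(lastExon) &&
        GenomicRanges::end(b3) >= GenomicRanges::start(lastExon)
}

## vectorized per-read screening: spans, full-length flags and a flat
## table of intron coordinates (group = read index). Reads' blocks are
## coordinate-sorted within each read by construction.
.screenReads <- function(reads, gene) {
    tb <- .readsTable(reads)
    if (tb$n == 0L)
        return(list(spanStart = integer(0), spanEnd = integer(0),
                    fullLength = logical(0), intronStart = integer(0),
                    intronEnd = integer(0), intronGroup = integer(0)))
    g <- tb$group
    last <- cumsum(tabulate(g, nbins = tb$n))
    first <- c(1L, utils::head(last, -1L) + 1L)
    spanStart <- tb$start[first]
    spanEnd <- tb$end[last]
    sc <- startCodon(gene)
    ex <- gene@exons
    lastEx <- ex[length(ex)]
    std <- geneStrand(gene)
    b3i <- if (std == "-") first else last     # 3'-most block per read
    fullLength <- spanStart <= sc & spanEnd >= sc &
        tb$start[b3i] <= GenomicRanges::end(lastEx) &
        tb$end[b3i] >= GenomicRanges::start(lastEx)
    notLast <- rep(TRUE, length(g)); notLast[last] <- FALSE
    notFirst <- rep(TRUE, length(g)); notFirst[first] <- FALSE
    list(spanStart = spanStart, spanEnd = spanEnd,
         fullLength = fullLength,
         intronStart = tb$end[notLast] + 1L,
         intronEnd = tb$start[notFirst] - 1L,
         intronGroup = g[notLast])
}

## single-linkage clustering of junction coordinates within a window;
## representative = most frequent coordinate in the cluster (tie: smaller)
.coordMap <- function(coords, w) {
    if (length(coords) == 0L || w <= 0)
        return(function(x) x)
    tab <- table(coords)
    vals <- as.integer(names(tab)); cnt <- as.integer(tab)
    o <- order(vals); vals <- vals[o]; cnt <- cnt[o]
    grp <- cumsum(c(1L, as.integer(diff(vals) > w)))
    rep_ <- vapply(split(seq_along(vals), grp), function(ix) {
        ix[which.max(cnt[ix])]
    }, 0L)
    repval <- vals[rep_]
    lookup <- setNames(repval[grp], vals)
    function(x) unname(lookup[as.character(x)])
}

#' Collapse spliced alignments into transcript models
#'
#' Full-length reads passing the MAPQ filter are grouped by identical
#' intron chain (after an optional junction-merge window); each group with
#' at least \code{minSupport} reads becomes one transcript model. Terminal
#' exon boundaries are the modal terminal block boundaries of the group's
#' reads (ties broken toward the longer exon). Models are sorted by
#' descending total support, then by genomic position of the first intron.
#' Models whose intron chain matches an annotated transcript keep the
#' annotated id; novel models are numbered \code{sv.N} starting at one
#' past the number of annotated transcripts.
#'
#' @param reads \code{GRangesList} from
#'   \code{\link{readSplicedAlignments}}.
#' @param gene a \linkS4class{GeneModel}.
#' @param mapqMin minimum MAPQ (default 1).
#' @param minSupport minimum total full-length support per model
#'   (default 3).
#' @param mergeWindow junction-merge window in nt (default 0: exact
#'   chains, appropriate for polished reads).
#' @return a \linkS4class{TranscriptSet}.
#' @export
collapseAlignments <- function(reads, gene, mapqMin = 1, minSupport = 3,
                               mergeWindow = 0) {
    mc <- S4Vectors::mcols(reads)
    nParsed <- length(reads)
    pass <- mc$mapq >= mapqMin
    reads <- reads[pass]; mc <- mc[pass, , drop = FALSE]
    flt <- .screenReads(reads, gene)
    fl <- flt$fullLength
    nFL <- sum(fl)
    libs <- sort(unique(mc$library))
    if (length(libs) == 0L) libs <- "default"
    fstats <- list(parsed = nParsed, mapqPass = sum(pass), fullLength = nFL)

    if (nFL == 0L) {
        warning("no full-length reads; returning an empty TranscriptSet")
        return(.makeTranscriptSet(list(), character(0),
            matrix(0L, 0, length(libs), dimnames = list(NULL, libs)),
            list(), list(), gene, fstats))
    }
    flMc <- mc[fl, , drop = FALSE]

    inFl <- fl[flt$intronGroup]
    dmap <- .coordMap(flt$intronStart[inFl], mergeWindow)
    amap <- .coordMap(flt$intronEnd[inFl], mergeWindow)
    pairStr <- paste(dmap(flt$intronStart[inFl]),
                     amap(flt$intronEnd[inFl]), sep = "-")
    grpOfIntron <- match(flt$intronGroup[inFl], which(fl))
    keys <- vapply(split(pairStr,
                         factor(grpOfIntron, levels = seq_len(nFL))),
                   paste, collapse = ";", FUN.VALUE = "")

    flSpanStart <- flt$spanStart[fl]
    flSpanEnd <- flt$spanEnd[fl]
    groups <- split(seq_len(nFL), keys)
    chains <- list(); counts <- list(); firstIntron <- numeric(0)
    chrom <- as.character(GenomicRanges::seqnames(gene@exons))[1]
    std <- geneStrand(gene)
    for (key in names(groups)) {
        ix <- groups[[key]]
        ts <- .modalBoundary(flSpanStart[ix], tieLow = TRUE)
        te <- .modalBoundary(flSpanEnd[ix], tieLow = FALSE)
        if (nzchar(key)) {
            jm <- do.call(rbind, lapply(strsplit(
                strsplit(key, ";", fixed = TRUE)[[1]], "-", fixed = TRUE),
                as.integer))
            exSt <- c(ts, jm[, 2] + 1L)
            exEn <- c(jm[, 1] - 1L, te)
        } else {
            exSt <- ts; exEn <- te
        }
        chains[[length(chains) + 1L]] <- GenomicRanges::GRanges(
            chrom, IRanges::IRanges(exSt, exEn), strand = std)
        tabl <- table(factor(flMc$library[ix], levels = libs))
        counts[[length(chains)]] <- as.integer(tabl)
        firstIntron <- c(firstIntron,
                         if (nzchar(key)) jm[1, 1] else Inf)
    }
    cts <- do.call(rbind, counts)
    colnames(cts) <- libs
    tot <- rowSums(cts)
    keep <- tot >= minSupport
    nDropped <- sum(!keep)
    if (nDropped)
        message(nDropped, " chain group(s) below minSupport=", minSupport,
                " discarded (", sum(tot[!keep]), " reads)")
    chains <- chains[keep]; cts <- cts[keep, , drop = FALSE]
    firstIntron <- firstIntron[keep]; tot <- tot[keep]
    if (length(chains) == 0L)
        warning("no transcript model reached minSupport=", minSupport)

    o <- order(-tot, firstIntron,
               vapply(chains, function(g) min(GenomicRanges::start(g)), 0L))
    chains <- chains[o]; cts <- cts[o, , drop = FALSE]

    ids <- .assignIds(chains, gene)
    labels <- lapply(chains, classifyExons, gene = gene)
    events <- lapply(seq_along(chains), function(i)
        callEvents(chains[[i]], gene, labels[[i]]))
    .makeTranscriptSet(chains, ids, cts, labels, events, gene, fstats)
}

.modalBoundary <- function(x, tieLow) {
    tab <- table(x)
    best <- as.integer(names(tab)[tab == max(tab)])
    if (tieLow) min(best) else max(best)
}

## id assignment: annotated-matching models keep the annotated transcript
## name; novel models get sv.N from (n annotated transcripts + 1) onward
.assignIds <- function(chains, gene) {
    annChains <- annotatedChains(gene)
    annKeys <- vapply(seq_along(annChains), function(i) {
        ic <- extractIntronChain(annChains[[i]])
        paste(GenomicRanges::start(ic), GenomicRanges::end(ic),
              sep = "-", collapse = ";")
    }, "")
    names(annKeys) <- names(annChains)
    nextSv <- length(annChains) + 1L
    ids <- character(length(chains))
    for (i in seq_along(chains)) {
        ic <- extractIntronChain(chains[[i]])
        key <- paste(GenomicRanges::start(ic), GenomicRanges::end(ic),
                     sep = "-", collapse = ";")
        hit <- which(annKeys == key)
        if (length(hit)) {
            ids[i] <- names(annKeys)[hit[1]]
        } else {
            ids[i] <- paste0("sv.", nextSv)
            nextSv <- nextSv + 1L
        }
    }
    ids
}

.makeTranscriptSet <- function(chains, ids, cts, labels, events, gene,
                               fstats) {
    grl <- if (length(chains)) GenomicRanges::GRangesList(chains)
           else GenomicRanges::GRangesList()
    rd <- S4Vectors::DataFrame(
        txId = ids,
        nExons = vapply(chains, length, 0L),
        exonLabels = I(labels),
        events = I(events))
    names(grl) <- NULL
    S4Vectors::mcols(grl) <- rd
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = cts), rowRanges = grl,
        colData = S4Vectors::DataFrame(library = colnames(cts),
                                       row.names = colnames(cts)))
    rownames(se) <- ids
    S4Vectors::metadata(se)$gene <- gene
    S4Vectors::metadata(se)$filterStats <- fstats
    methods::as(se, "TranscriptSet")
}

#' Classify each model exon against the annotation
#'
#' Labels: \code{annotated} (identical to an annotated exon),
#' \code{truncated} (strictly inside one annotated exon), \code{extended}
#' (reaches beyond an annotated exon's boundary into the flanking intron),
#' \code{retained_fusion} (spans two or more annotated exons plus the
#' intervening intron(s)), \code{cryptic} (overlaps no annotated exon).
#'
#' @param chain \code{GRanges} exon chain (genomic order).
#' @param gene a \linkS4class{GeneModel}.
#' @return character vector, one label per exon.
#' @export
classifyExons <- function(chain, gene) {
    ann <- sort(gene@exons)
    vapply(seq_along(chain), function(i) {
        e <- chain[i]
        ov <- which(GenomicRanges::start(ann) <= GenomicRanges::end(e) &
                    GenomicRanges::end(ann) >= GenomicRanges::start(e))
        if (length(ov) == 0L) return("cryptic")
        if (length(ov) >= 2L) return("retained_fusion")
        a <- ann[ov]
        if (GenomicRanges::start(e) == GenomicRanges::start(a) &&
            GenomicRanges::end(e) == GenomicRanges::end(a))
            return("annotated")
        if (GenomicRanges::start(e) >= GenomicRanges::start(a) &&
            GenomicRanges::end(e) <= GenomicRanges::end(a))
            return("truncated")
        "extended"
    }, "")
}

## annotated intron chain of the canonical transcript, genomic order
.annIntrons <- function(gene) {
    chain <- sort(gene@exons)
    extractIntronChain(chain)
}

## transcription-order index of a genomic-order intron index
.tIdx <- function(gIdx, nIntrons, std) {
    if (std == "-") nIntrons + 1L - gIdx else gIdx
}

#' Call named splicing events of a transcript model
#'
#' Emits \code{exon_skipping} for every internal annotated exon absent from
#' the model and bridged by a model intron; \code{intron_retention} (one
#' per retained annotated intron) for every fused exon;
#' \code{alt_donor}/\code{alt_acceptor} for every model junction sharing
#' exactly one boundary with an annotated junction, with a signed,
#' strand-aware shift in nt (the donor is the 5' splice site; positive
#' delta points downstream in the transcript direction); and
#' \code{cryptic_exon} for every cryptic exon. Events are reported in
#' genomic order.
#'
#' @param chain \code{GRanges} exon chain (genomic order).
#' @param gene a \linkS4class{GeneModel}.
#' @param labels optional precomputed \code{\link{classifyExons}} output.
#' @return data.frame with columns \code{type}, \code{target},
#'   \code{delta}, \code{chrom}, \code{start}, \code{end}.
#' @export
callEvents <- function(chain, gene, labels = classifyExons(chain, gene)) {
    std <- geneStrand(gene)
    chrom <- as.character(GenomicRanges::seqnames(gene@exons))[1]
    annG <- sort(gene@exons)                       # genomic order
    n <- length(annG)
    annIn <- .annIntrons(gene)
    modIn <- extractIntronChain(chain)
    ev <- list()
    add <- function(type, target, delta, iv)
        ev[[length(ev) + 1L]] <<- data.frame(type = type, target = target,
            delta = delta, chrom = chrom,
            start = GenomicRanges::start(iv), end = GenomicRanges::end(iv))

    ## exon skipping: internal annotated exon not overlapped by any model
    ## exon and bridged by a model intron
    internalG <- setdiff(seq_len(n), c(1L, n))
    for (g in internalG) {
        a <- annG[g]
        ovAny <- any(GenomicRanges::start(chain) <= GenomicRanges::end(a) &
                     GenomicRanges::end(chain) >= GenomicRanges::start(a))
        if (ovAny) next
        bridged <- length(modIn) > 0L &&
            any(GenomicRanges::start(modIn) <= GenomicRanges::start(a) &
                GenomicRanges::end(modIn) >= GenomicRanges::end(a))
        if (bridged)
            add("exon_skipping", paste0("exon", .tIdx(g, n, std)), NA_integer_,
                a)
    }

    ## intron retention: annotated introns inside fused exons
    fused <- which(labels == "retained_fusion")
    for (i in fused) {
        e <- chain[i]
        inside <- which(GenomicRanges::start(annIn) >=
                            GenomicRanges::start(e) &
                        GenomicRanges::end(annIn) <= GenomicRanges::end(e))
        for (g in inside)
            add("intron_retention",
                paste0("intron", .tIdx(g, length(annIn), std)), NA_integer_,
                annIn[g])
    }

    ## alternative donor / acceptor sites; junctions whose novel boundary
    ## abuts a cryptic exon are explained by the cryptic_exon event and
    ## are not double-reported as alt sites
    crypticBounds <- integer(0)
    for (i in which(labels == "cryptic"))
        crypticBounds <- c(crypticBounds,
                           GenomicRanges::start(chain)[i] - 1L,
                           GenomicRanges::end(chain)[i] + 1L)
    if (length(modIn) && length(annIn)) {
        annD <- if (std == "+") GenomicRanges::start(annIn)
                else GenomicRanges::end(annIn)     # donor-side boundary
        annA <- if (std == "+") GenomicRanges::end(annIn)
                else GenomicRanges::start(annIn)
        for (j in seq_along(modIn)) {
            if (GenomicRanges::start(modIn)[j] %in% crypticBounds ||
                GenomicRanges::end(modIn)[j] %in% crypticBounds) next
            d <- if (std == "+") GenomicRanges::start(modIn)[j]
                 else GenomicRanges::end(modIn)[j]
            a <- if (std == "+") GenomicRanges::end(modIn)[j]
                 else GenomicRanges::start(modIn)[j]
            dHit <- which(annD == d); aHit <- which(annA == a)
            exact <- length(intersect(dHit, aHit)) > 0L
            if (exact) next
            if (length(dHit) && length(aHit)) next  # novel pairing of
                                                    # annotated boundaries
                                                    # (skipping junction)
            if (length(dHit) && !length(aHit)) {
                g <- dHit[1]
                delta <- if (std == "+") a - annA[g] else annA[g] - a
                add("alt_acceptor",
                    paste0("intron", .tIdx(g, length(annIn), std)),
                    as.integer(delta), modIn[j])
            } else if (length(aHit) && !length(dHit)) {
                g <- aHit[1]
                delta <- if (std == "+") d - annD[g] else annD[g] - d
                add("alt_donor",
                    paste0("intron", .tIdx(g, length(annIn), std)),
                    as.integer(delta), modIn[j])
            }
        }
    }

    ## cryptic exons
    for (i in which(labels == "cryptic")) {
        e <- chain[i]
        host <- which(GenomicRanges::start(annIn) <=
                          GenomicRanges::start(e) &
                      GenomicRanges::end(annIn) >= GenomicRanges::end(e))
        tgt <- if (length(host))
            paste0("intron", .tIdx(host[1], length(annIn), std))
        else NA_character_
        add("cryptic_exon", tgt, NA_integer_, e)
    }

    if (length(ev) == 0L)
        return(data.frame(type = character(0), target = character(0),
                          delta = integer(0), chrom = character(0),
                          start = integer(0), end = integer(0)))
    df <- do.call(rbind, ev)
    df <- df[order(df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
    df
}
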