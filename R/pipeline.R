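## One-call pipeline: discover -> quantify -> ORF/NMD -> domains, with
## filter counts logged at every boundary so read exclusions are
## auditable, and tabular reports written to an output directory.

#' Compare discovered models to the annotation
#'
#' Each model falls in exactly one category: \code{matches_annotated}
#' (intron chain identical to an annotated transcript),
#' \code{novel_with_cryptic_exons} (contains at least one cryptic exon) or
#' \code{novel_annotated_exons_only}.
#'
#' @param txset a \linkS4class{TranscriptSet}.
#' @return list with \code{perModel} (data.frame: transcript_id, category,
#'   matched_transcript) and \code{counts} (named integer vector).
#' @export
compareToAnnotation <- function(txset) {
    gene <- S4Vectors::metadata(txset)$gene
    annIds <- names(annotatedChains(gene))
    ids <- txIds(txset)
    labs <- exonLabels(txset)
    category <- character(length(ids))
    matched <- rep(NA_character_, length(ids))
    for (i in seq_along(ids)) {
        if (ids[i] %in% annIds) {
            category[i] <- "matches_annotated"
            matched[i] <- ids[i]
        } else if (any(labs[[i]] == "cryptic")) {
            category[i] <- "novel_with_cryptic_exons"
        } else {
            category[i] <- "novel_annotated_exons_only"
        }
    }
    lev <- c("matches_annotated", "novel_annotated_exons_only",
             "novel_with_cryptic_exons")
    list(perModel = data.frame(transcript_id = ids, category = category,
                               matched_transcript = matched,
                               stringsAsFactors = FALSE),
         counts = table(factor(category, levels = lev)))
}

#' Run the full characterization pipeline
#'
#' Reads annotation, genome and spliced alignments; discovers transcript
#' models; quantifies them per library in TPM; predicts ATG-anchored ORFs
#' with NMD classification; optionally calls conserved-domain retention;
#' and writes all result tables plus a summary into \code{outDir}.
#'
#' Outputs: \code{models.gtf}, \code{events.tsv}, \code{support.tsv},
#' \code{cryptic_exons.bed}, \code{expression.tsv}, \code{tpm_matrix.tsv},
#' \code{orf_results.tsv}, \code{proteins.fa}, and (when a domain table is
#' given) \code{domain_matrix.tsv} and \code{domain_coverage.tsv}, plus
#' \code{summary.tsv} and \code{report.md}.
#'
#' @param gtf,genome,sam input paths (annotation GTF, genome FASTA,
#'   spliced alignments SAM).
#' @param outDir output directory (created if needed).
#' @param domains optional domain-definition TSV
#'   (see \code{\link{readDomainTable}}).
#' @param canonical optional canonical transcript id.
#' @param mapqMin,minSupport,mergeWindow discovery parameters.
#' @param tpmMode \code{"length_normalized"} or \code{"count_based"}.
#' @param nmdThresholdNt,nmdStrict NMD rule parameters.
#' @param presentMin,absentMax domain-call thresholds.
#' @param libraryTag SAM tag carrying the library label.
#' @return invisibly, a list with the \code{TranscriptSet}, expression
#'   table, ORF table, domain calls (or NULL), novelty report and the
#'   summary data.frame.
#' @export
runPipeline <- function(gtf, genome, sam, outDir, domains = NULL,
                        canonical = NULL, mapqMin = 1, minSupport = 3,
                        mergeWindow = 0, tpmMode = "length_normalized",
                        nmdThresholdNt = 50, nmdStrict = TRUE,
                        presentMin = 0.9, absentMax = 0.3,
                        libraryTag = "RG") {
    for (p in c(gtf, genome, sam))
        if (!file.exists(p)) stop("input path does not exist: ", p)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    gene <- stage("annotation", readGeneGTF(gtf, genome = genome,
                                            canonical = canonical))
    reads <- stage("alignments", readSplicedAlignments(sam,
                                                       libraryTag = libraryTag))
    message("parsed ", length(reads), " primary alignment(s)")

    txset <- stage("discover", collapseAlignments(reads, gene,
        mapqMin = mapqMin, minSupport = minSupport,
        mergeWindow = mergeWindow))
    fs <- S4Vectors::metadata(txset)$filterStats
    message("reads: ", fs$parsed, " parsed / ", fs$mapqPass,
            " MAPQ-passed / ", fs$fullLength, " full-length; ",
            nrow(txset), " model(s) retained")

    writeTranscriptGTF(txset, file.path(outDir, "models.gtf"))
    writeCrypticBed(txset, file.path(outDir, "cryptic_exons.bed"))
    evtab <- do.call(rbind, lapply(seq_len(nrow(txset)), function(i) {
        df <- spliceEvents(txset)[[i]]
        if (nrow(df) == 0L) return(NULL)
        cbind(transcript_id = txIds(txset)[i], df)
    }))
    if (is.null(evtab))
        evtab <- data.frame(transcript_id = character(0), type = character(0),
                            target = character(0), delta = integer(0),
                            chrom = character(0), start = integer(0),
                            end = integer(0))
    write.table(evtab, file.path(outDir, "events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sup <- cbind(transcript_id = txIds(txset),
                 as.data.frame(supportCounts(txset)))
    write.table(sup, file.path(outDir, "support.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    expr <- stage("quantify", quantifyExpression(txset, mode = tpmMode))
    write.table(expr, file.path(outDir, "expression.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tm <- tpmMatrix(expr)
    write.table(cbind(transcript_id = rownames(tm), as.data.frame(tm)),
                file.path(outDir, "tpm_matrix.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    orfs <- stage("orf", predictOrfs(txset, thresholdNt = nmdThresholdNt,
                                     strict = nmdStrict))
    write.table(orfs[, c("transcript_id", "status", "protein_len_aa",
                         "stop_to_last_junction_nt")],
                file.path(outDir, "orf_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (nrow(orfs)) writeProteinFasta(orfs, file.path(outDir, "proteins.fa"))

    domCalls <- NULL
    if (!is.null(domains)) {
        domCalls <- stage("domains", {
            domTab <- readDomainTable(domains)
            canonChain <- sort(gene@exons)
            canonOrf <- findOrf(canonChain, gene, id = gene@canonical)
            domainCalls(orfs, canonOrf$protein, domTab,
                        presentMin = presentMin, absentMax = absentMax)
        })
        dm <- domainMatrix(domCalls)
        write.table(cbind(transcript_id = rownames(dm$status),
                          as.data.frame(dm$status)),
                    file.path(outDir, "domain_matrix.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(cbind(transcript_id = rownames(dm$coverage),
                          as.data.frame(round(dm$coverage, 4))),
                    file.path(outDir, "domain_coverage.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }

    novelty <- compareToAnnotation(txset)

    ## per-transcript summary
    smry <- data.frame(
        transcript_id = txIds(txset),
        n_exons = vapply(exonChains(txset), length, 0L),
        events = vapply(spliceEvents(txset), function(df)
            if (nrow(df) == 0L) "none" else
                paste(paste0(df$type, "(", df$target, ")"), collapse = ","),
            ""),
        category = novelty$perModel$category,
        stringsAsFactors = FALSE)
    smry <- cbind(smry, as.data.frame(tpmMatrix(expr))[smry$transcript_id, ,
                                                       drop = FALSE])
    smry$orf_status <- orfs$status[match(smry$transcript_id,
                                         orfs$transcript_id)]
    smry$protein_len_aa <- orfs$protein_len_aa[match(smry$transcript_id,
                                                     orfs$transcript_id)]
    if (!is.null(domCalls)) {
        dm <- domainMatrix(domCalls)
        smry$domains <- apply(dm$status[smry$transcript_id, , drop = FALSE],
                              1, paste, collapse = "")
    }
    write.table(smry, file.path(outDir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    rpt <- c("# Pipeline report", "",
             sprintf("- reads parsed: %d", fs$parsed),
             sprintf("- reads passing MAPQ >= %s: %d", mapqMin, fs$mapqPass),
             sprintf("- full-length reads: %d", fs$fullLength),
             sprintf("- transcript models (support >= %s): %d", minSupport,
                     nrow(txset)),
             sprintf("- matches_annotated: %d",
                     novelty$counts[["matches_annotated"]]),
             sprintf("- novel_annotated_exons_only: %d",
                     novelty$counts[["novel_annotated_exons_only"]]),
             sprintf("- novel_with_cryptic_exons: %d",
                     novelty$counts[["novel_with_cryptic_exons"]]),
             sprintf("- TPM mode: %s", tpmMode),
             sprintf("- NMD threshold: %d nt (%s)", nmdThresholdNt,
                     if (nmdStrict) "strict" else "inclusive"))
    writeLines(rpt, file.path(outDir, "report.md"))

    invisible(list(txset = txset, expression = expr, orfs = orfs,
                   domainCalls = domCalls, novelty = novelty,
                   summary = smry))
}

#' Run the pipeline from a YAML config file
#'
#' The config maps directly onto \code{\link{runPipeline}} arguments:
#' top-level keys \code{gtf}, \code{genome}, \code{sam}, \code{domains},
#' \code{outdir}, and optional \code{mapq_min}, \code{min_support},
#' \code{merge_window}, \code{tpm_mode}, \code{nmd_threshold_nt},
#' \code{nmd_strict}, \code{present_min}, \code{absent_max},
#' \code{canonical}, \code{library_tag}.
#'
#' @param configPath YAML file path.
#' @return see \code{\link{runPipeline}}.
#' @export
runPipelineConfig <- function(configPath) {
    cfg <- yaml::read_yaml(configPath)
    need <- c("gtf", "genome", "sam", "outdir")
    miss <- setdiff(need, names(cfg))
    if (length(miss))
        stop("config error: missing key(s): ", paste(miss, collapse = ", "))
    runPipeline(gtf = cfg$gtf, genome = cfg$genome, sam = cfg$sam,
        outDir = cfg$outdir, domains = cfg$domains,
        canonical = cfg$canonical,
        mapqMin = cfg$mapq_min %||% 1,
        minSupport = cfg$min_support %||% 3,
        mergeWindow = cfg$merge_window %||% 0,
        tpmMode = cfg$tpm_mode %||% "length_normalized",
        nmdThresholdNt = cfg$nmd_threshold_nt %||% 50,
        nmdStrict = cfg$nmd_strict %||% TRUE,
        presentMin = cfg$present_min %||% 0.9,
        absentMax = cfg$absent_max %||% 0.3,
        libraryTag = cfg$library_tag %||% "RG")
}
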