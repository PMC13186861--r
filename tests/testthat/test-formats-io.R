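test_that("GTF coordinates convert to the internal convention and exon
          numbering is strand-aware", {
    gtf <- tempfile(fileext = ".gtf")
    writeLines(c(
        'chrT\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g"; transcript_id "t1";',
        'chrT\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g"; transcript_id "t1";',
        'chrT\tsrc\tstart_codon\t151\t153\t.\t+\t.\tgene_id "g"; transcript_id "t1";'),
        gtf)
    g <- readGeneGTF(gtf)
    ex <- geneExons(g)
    ## 1-based inclusive 101-200 == 0-based half-open [100, 200)
    expect_equal(GenomicRanges::start(ex)[1] - 1L, 100L)
    expect_equal(GenomicRanges::end(ex)[1], 200L)
    expect_equal(startCodon(g), 151L)

    ## minus strand: exon 1 is the 5'-most = genomically rightmost
    gtfm <- tempfile(fileext = ".gtf")
    writeLines(c(
        'chrT\tsrc\texon\t101\t200\t.\t-\t.\tgene_id "g"; transcript_id "t1";',
        'chrT\tsrc\texon\t301\t400\t.\t-\t.\tgene_id "g"; transcript_id "t1";',
        'chrT\tsrc\tstart_codon\t398\t400\t.\t-\t.\tgene_id "g"; transcript_id "t1";'),
        gtfm)
    gm <- readGeneGTF(gtfm)
    exm <- geneExons(gm)
    expect_equal(GenomicRanges::start(exm)[1], 301L)
    expect_equal(GenomicRanges::end(exm)[1], 400L)
    expect_equal(names(exm)[1], "exon1")
    ## reversing strand leaves genomic intervals unchanged
    expect_setequal(GenomicRanges::start(exm), GenomicRanges::start(ex))

    ## missing start_codon names the transcript
    gtf2 <- tempfile(fileext = ".gtf")
    writeLines(
        'chrT\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g"; transcript_id "tX";',
        gtf2)
    expect_error(readGeneGTF(gtf2), "tX")
})

test_that("toy 5-exon fixture parses with 5 exons and the recorded start
          codon", {
    g <- toyGene()
    gtf <- tempfile(fileext = ".gtf")
    writeGeneGTF(g, gtf)
    g2 <- readGeneGTF(gtf)
    expect_equal(length(geneExons(g2)), 5L)
    expect_equal(startCodon(g2), 151L)          # 0-based 150
    expect_equal(GenomicRanges::start(geneExons(g2)),
                 GenomicRanges::start(geneExons(g)))
    expect_equal(GenomicRanges::end(geneExons(g2)),
                 GenomicRanges::end(geneExons(g)))
})

test_that("CIGAR semantics: M/=/X/D consume reference into blocks, N
          splits, I/S/H consume nothing", {
    b <- cigarToBlocks("10M50N10M", 1L)
    expect_equal(IRanges::start(b), c(1L, 61L))   # 0-based [0,10) [60,70)
    expect_equal(IRanges::end(b), c(10L, 70L))

    b <- cigarToBlocks("5S100M", 101L)
    expect_equal(IRanges::start(b), 101L)
    expect_equal(IRanges::end(b), 200L)           # 0-based [100,200)

    b <- cigarToBlocks("100M2D48M150N100M", 101L)
    expect_equal(IRanges::start(b), c(101L, 401L))
    expect_equal(IRanges::end(b), c(250L, 500L))  # [100,250) [400,500)

    expect_error(cigarToBlocks("10M5Q", 1L), "malformed CIGAR")
})

test_that("SAM reader keeps primary alignments only, labels libraries and
          flags malformed records", {
    sam <- tempfile(fileext = ".sam")
    writeLines(c(
        "@HD\tVN:1.6",
        "@SQ\tSN:chrT\tLN:2000",
        "r1\t0\tchrT\t1\t60\t10M50N10M\t*\t0\t0\t*\t*\tRG:Z:breast",
        "r2\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",                 # unmapped
        "r3\t256\tchrT\t1\t60\t20M\t*\t0\t0\t*\t*",          # secondary
        "r4\t2048\tchrT\t1\t60\t20M\t*\t0\t0\t*\t*",         # supplementary
        "r5\t0\tchrT\t5\t60\t20M\t*\t0\t0\t*\t*"),           # no RG
        sam)
    expect_warning(
        expect_message(reads <- readSplicedAlignments(sam), "supplementary"),
        "default")
    expect_equal(length(reads), 2L)
    expect_equal(S4Vectors::mcols(reads)$library, c("breast", "default"))
    expect_equal(GenomicRanges::start(reads[[1]]), c(1L, 61L))

    bad <- tempfile(fileext = ".sam")
    writeLines(c("@HD\tVN:1.6",
                 "rbad\t0\tchrT\t1\t60\t10Z\t*\t0\t0\t*\t*"), bad)
    expect_error(readSplicedAlignments(bad), "rbad")
})

test_that("CIGAR conservation: block lengths plus gaps equal the reference
          span of each parsed record", {
    dir <- tempfile()
    sim <- simulateDataset(dir,
        isoformEvents = list(c0 = list(), s3 = list(skipExon(3))),
        weights = c(0.6, 0.4), nReads = 80, nExons = 6, seed = 11)
    reads <- suppressMessages(readSplicedAlignments(sim$paths$sam))
    for (i in seq_along(reads)) {
        b <- reads[[i]]
        span <- max(GenomicRanges::end(b)) - min(GenomicRanges::start(b)) + 1L
        gaps <- if (length(b) > 1L)
            sum(GenomicRanges::start(b)[-1] -
                GenomicRanges::end(b)[-length(b)] - 1L) else 0L
        expect_equal(sum(GenomicRanges::width(b)) + gaps, span)
    }
})

test_that("transcript GTF writing round-trips every exon chain exactly", {
    g <- toyGene()
    models <- GenomicRanges::GRangesList(
        v.1 = realizeIsoform(g),
        m1 = realizeIsoform(g, list(skipExon(3))),
        m2 = realizeIsoform(g, list(crypticExon(4, 50, 100))),
        m3 = realizeIsoform(g, list(retainIntron(2), altDonor(3, 9))))
    path <- tempfile(fileext = ".gtf")
    writeTranscriptGTF(models, path, geneId = "toy")
    back <- readTranscriptChains(path)
    expect_setequal(names(back), names(models))
    for (nm in names(models)) {
        expect_equal(GenomicRanges::start(back[[nm]]),
                     GenomicRanges::start(models[[nm]]))
        expect_equal(GenomicRanges::end(back[[nm]]),
                     GenomicRanges::end(models[[nm]]))
    }
    ## exon line coordinates are written 1-based inclusive
    lines <- grep("\texon\t", readLines(path), value = TRUE)
    expect_true(any(grepl("\t101\t200\t", lines)))

    ## empty model list -> header-only file
    p0 <- tempfile(fileext = ".gtf")
    writeTranscriptGTF(GenomicRanges::GRangesList(), p0)
    expect_equal(length(readTranscriptChains(p0)), 0L)
})

test_that("domain table parsing validates and sorts intervals", {
    tsv <- tempfile(fileext = ".tsv")
    writeLines(c("name\taa_start\taa_end",
                 "RAD51_BD\t1002\t2085",
                 "PALB2_BD\t21\t39",
                 "Helical\t2481\t2667",
                 "OB_fold_1\t2670\t2803",
                 "OB_fold_2\t2809\t3048",
                 "OB_fold_3\t3052\t3190",
                 "DBD\t2481\t3190",
                 "CT_RAD51_BD\t3265\t3330"), tsv)
    d <- readDomainTable(tsv)
    expect_equal(nrow(d), 8L)
    expect_equal(d$name[1], "PALB2_BD")
    expect_true(!is.unsorted(d$aa_start))

    empty <- tempfile(fileext = ".tsv")
    writeLines("name\taa_start\taa_end", empty)
    expect_equal(nrow(readDomainTable(empty)), 0L)

    bad <- tempfile(fileext = ".tsv")
    writeLines(c("name\taa_start\taa_end", "BROKEN\t50\t10"), bad)
    expect_error(readDomainTable(bad), "BROKEN")

    ## the packaged example domain file parses
    ex <- system.file("extdata", "brca2_domains_example.tsv",
                      package = "IsoScope")
    expect_equal(nrow(readDomainTable(ex)), 8L)
})
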