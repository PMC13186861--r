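test_that("gene construction is deterministic and honours degenerate
          cases", {
    g1 <- buildGene(nExons = 5, seed = 13)
    g2 <- buildGene(nExons = 5, seed = 13)
    expect_equal(as.character(genomeSeq(g1)[[1]]),
                 as.character(genomeSeq(g2)[[1]]))
    expect_equal(GenomicRanges::start(geneExons(g1)),
                 GenomicRanges::start(geneExons(g2)))
    expect_equal(startCodon(g1), startCodon(g2))

    g3 <- buildGene(nExons = 5, seed = 14)
    expect_false(identical(as.character(genomeSeq(g1)[[1]]),
                           as.character(genomeSeq(g3)[[1]])))

    mono <- buildGene(nExons = 1, seed = 5)
    expect_equal(length(geneExons(mono)), 1L)

    expect_error(buildGene(exonLenRange = c(10, 20)), "infeasible")
})

test_that("the canonical transcript of any built gene translates from its
          ATG to a stop in the last exon with no internal stop", {
    for (seed in 1:4) for (std in c("+", "-")) {
        g <- buildGene(nExons = 6, seed = seed, strand = std)
        chain <- sort(geneExons(g))
        txseq <- as.character(transcriptSequence(chain, g))
        map <- coordinateMap(chain, std)
        atgT <- genomicToTranscript(startCodon(g), map)
        expect_false(is.na(atgT))
        expect_equal(substr(txseq, atgT, atgT + 2L), "ATG")
        orf <- bruteOrfProtein(txseq, atgT)
        expect_false(is.na(orf$stopT))
        ## stop lies inside the last exon (downstream of the last junction)
        lastExonStartT <- map$cum[length(chain)] + 1L
        expect_gte(orf$stopT, lastExonStartT)
        expect_false(grepl("*", orf$protein, fixed = TRUE))
    }
})

test_that("the event grammar applies to the canonical chain exactly", {
    g <- toyGene()
    ## identity
    can <- realizeIsoform(g, list())
    expect_equal(GenomicRanges::start(can),
                 GenomicRanges::start(sort(geneExons(g))))

    ## skip exon 3 on the fixture (0-based intervals asserted)
    sk <- realizeIsoform(g, list(skipExon(3)))
    expect_equal(GenomicRanges::start(sk) - 1L, c(100L, 300L, 800L, 1200L))
    expect_equal(GenomicRanges::end(sk), c(200L, 450L, 950L, 1500L))

    ## cryptic exon in intron 4 at offset 50, length 100 -> [1000,1100)
    cr <- realizeIsoform(g, list(crypticExon(4, 50, 100)))
    expect_equal(GenomicRanges::start(cr)[5] - 1L, 1000L)
    expect_equal(GenomicRanges::end(cr)[5], 1100L)
    expect_equal(length(cr), 6L)

    ## intron retention fuses flanking exons
    ir <- realizeIsoform(g, list(retainIntron(2)))
    expect_equal(length(ir), 4L)
    expect_equal(GenomicRanges::start(ir)[2], 301L)
    expect_equal(GenomicRanges::end(ir)[2], 700L)

    ## alternative donor of intron 2 by +20 extends exon 2 to 0-based 470
    ad <- realizeIsoform(g, list(altDonor(2, 20)))
    expect_equal(GenomicRanges::end(ad)[2], 470L)

    ## incompatible combinations are rejected
    expect_error(realizeIsoform(g, list(skipExon(3), retainIntron(3))),
                 "incompatible")
    expect_error(realizeIsoform(g, list(retainIntron(2), altDonor(2, 5))),
                 "incompatible")
    expect_error(realizeIsoform(g, list(retainIntron(2),
                                        crypticExon(2, 10, 20))),
                 "incompatible")
})

test_that("minus-strand event application mirrors the plus strand", {
    g <- buildGene(nExons = 5, seed = 21, strand = "-")
    ex <- geneExons(g)                      # transcription order
    sk <- realizeIsoform(g, list(skipExon(2)))
    expect_equal(length(sk), 4L)
    expect_false(GenomicRanges::start(ex)[2] %in% GenomicRanges::start(sk))
    ## altDonor(+d) lengthens exon i at its transcript-3' side, which on
    ## the minus strand is a smaller genomic start
    ad <- realizeIsoform(g, list(altDonor(1, 12)))
    adG <- sort(ad)
    expect_equal(GenomicRanges::start(adG)[5],
                 GenomicRanges::start(sort(ex))[5] - 12L)
})

test_that("simulated alignments conserve read counts and honour full-length
          construction", {
    g <- buildGene(nExons = 5, seed = 3)
    iso <- GenomicRanges::GRangesList(
        a = realizeIsoform(g),
        b = realizeIsoform(g, list(skipExon(3))))

    sam0 <- tempfile(fileext = ".sam")
    t0 <- simulateAlignments(g, iso, c(1, 1), 0, sam0, seed = 1)
    expect_equal(nrow(t0), 0L)
    expect_true(all(startsWith(readLines(sam0), "@")))
    expect_error(simulateAlignments(g, iso, c(1, 1), -5, sam0, seed = 1),
                 "non-negative")

    sam <- tempfile(fileext = ".sam")
    truth <- simulateAlignments(g, iso, c(0.5, 0.5), 200, sam,
                                fullLengthFrac = 1, seed = 9)
    expect_equal(nrow(truth), 200L)
    reads <- readSplicedAlignments(sam)
    expect_equal(length(reads), 200L)       # one record per read

    chainKey <- function(gr) {
        ic <- extractIntronChain(gr)
        paste(GenomicRanges::start(ic), GenomicRanges::end(ic),
              collapse = ";")
    }
    truthKeys <- vapply(iso, chainKey, "")
    readKeys <- vapply(seq_along(reads),
                       function(i) chainKey(reads[[i]]), "")
    expect_true(all(readKeys %in% truthKeys))
    ## with fullLengthFrac = 1 every read matches its own isoform's chain
    expect_equal(unname(readKeys),
                 unname(truthKeys[truth$isoform_id]))
})

test_that("isoform sampling follows the weights within binomial noise", {
    g <- buildGene(nExons = 5, seed = 3)
    iso <- GenomicRanges::GRangesList(
        a = realizeIsoform(g),
        b = realizeIsoform(g, list(skipExon(3))))
    sam <- tempfile(fileext = ".sam")
    truth <- simulateAlignments(g, iso, c(0.7, 0.3), 1000, sam, seed = 7)
    nA <- sum(truth$isoform_id == "a")
    expect_lt(abs(nA - 700), 3 * sqrt(1000 * 0.7 * 0.3))
})

test_that("identical simulator configuration yields byte-identical
          outputs", {
    d1 <- tempfile(); d2 <- tempfile()
    ev <- list(c0 = list(), s2 = list(skipExon(2)))
    s1 <- simulateDataset(d1, ev, c(0.6, 0.4), nReads = 60, seed = 17,
                          nExons = 5)
    s2 <- simulateDataset(d2, ev, c(0.6, 0.4), nReads = 60, seed = 17,
                          nExons = 5)
    for (f in c("genome.fa", "annotation.gtf", "reads.sam", "truth.tsv"))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
})
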