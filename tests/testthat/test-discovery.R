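test_that("intron chains are exactly the gaps between aligned blocks", {
    b <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(c(1L, 61L), c(10L, 70L)), strand = "+")
    ic <- extractIntronChain(b)
    expect_equal(GenomicRanges::start(ic) - 1L, 10L)   # 0-based [10,60)
    expect_equal(GenomicRanges::end(ic), 60L)

    expect_equal(length(extractIntronChain(b[1])), 0L)

    ## full-length fixture read over all 5 exons -> the 4 canonical introns
    g <- toyGene()
    blocks <- sort(geneExons(g))
    ic <- extractIntronChain(blocks)
    expect_equal(GenomicRanges::start(ic) - 1L, c(200L, 450L, 700L, 950L))
    expect_equal(GenomicRanges::end(ic), c(300L, 600L, 800L, 1200L))
})

test_that("full-length filter requires the start codon and the last
          exon", {
    g <- toyGene()
    full <- sort(geneExons(g))
    expect_true(isFullLength(full, g))

    ## read starting downstream of the ATG (0-based 160 > 150)
    late <- full
    GenomicRanges::start(late)[1] <- 161L
    expect_false(isFullLength(late, g))

    ## read never reaching the last exon (ends at 0-based 940)
    short <- full[1:4]
    GenomicRanges::end(short)[4] <- 940L
    expect_false(isFullLength(short, g))
})

test_that("collapsing groups identical chains, uses modal terminal
          boundaries and orders by support", {
    g <- toyGene()
    can <- sort(geneExons(g))
    mat <- cbind(GenomicRanges::start(can), GenomicRanges::end(can))
    ## 100 identical-chain reads -> one model with support 100
    reads <- makeReads(rep(list(mat), 100))
    tx <- collapseAlignments(reads, g, minSupport = 1)
    expect_equal(nrow(tx), 1L)
    expect_equal(sum(supportCounts(tx)), 100L)
    expect_equal(txIds(tx), "v.1")          # matches the annotated chain

    ## modal terminal boundary wins; tie breaks toward the longer exon
    m2 <- mat; m2[1, 1] <- 111L
    reads <- makeReads(c(rep(list(mat), 3), rep(list(m2), 2)))
    tx <- collapseAlignments(reads, g, minSupport = 1)
    expect_equal(GenomicRanges::start(exonChains(tx)[[1]])[1], 101L)
    readsTie <- makeReads(c(rep(list(mat), 2), rep(list(m2), 2)))
    txTie <- collapseAlignments(readsTie, g, minSupport = 1)
    expect_equal(GenomicRanges::start(exonChains(txTie)[[1]])[1], 101L)

    ## two chains with support 60/40: the 60-support chain is listed first
    skip <- realizeIsoform(g, list(skipExon(3)))
    mskip <- cbind(GenomicRanges::start(skip), GenomicRanges::end(skip))
    reads <- makeReads(c(rep(list(mskip), 60), rep(list(mat), 40)))
    tx <- collapseAlignments(reads, g, minSupport = 1)
    expect_equal(unname(rowSums(supportCounts(tx))), c(60L, 40L))
    expect_equal(txIds(tx)[2], "v.1")
    expect_equal(txIds(tx)[1], "sv.2")      # one annotated transcript -> sv.2

    ## support below minSupport never creates a model
    reads <- makeReads(c(rep(list(mat), 10), rep(list(mskip), 2)))
    tx <- suppressMessages(collapseAlignments(reads, g, minSupport = 3))
    expect_equal(nrow(tx), 1L)

    ## zero full-length reads -> empty set with warning
    frag <- mat[2:3, , drop = FALSE]
    expect_warning(tx0 <- collapseAlignments(makeReads(list(frag)), g),
                   "full-length")
    expect_equal(nrow(tx0), 0L)
})

test_that("discovery recovers the exact simulated isoform set with
          noise-free reads", {
    g <- buildGene(nExons = 6, seed = 42)
    iso <- GenomicRanges::GRangesList(
        canon = realizeIsoform(g),
        skip = realizeIsoform(g, list(skipExon(3))),
        ir = realizeIsoform(g, list(retainIntron(2))))
    sam <- tempfile(fileext = ".sam")
    truth <- simulateAlignments(g, iso, c(0.5, 0.3, 0.2), 300, sam,
                                fullLengthFrac = 1, seed = 4)
    tx <- collapseAlignments(readSplicedAlignments(sam), g)
    expect_equal(nrow(tx), 3L)
    key <- function(gr) {
        ic <- extractIntronChain(gr)
        paste(GenomicRanges::start(ic), GenomicRanges::end(ic),
              collapse = ";")
    }
    expect_setequal(vapply(seq_len(nrow(tx)),
                           function(i) key(exonChains(tx)[[i]]), ""),
                    vapply(iso, key, ""))
    ## partition: every full-length read contributes to exactly one model
    expect_equal(sum(supportCounts(tx)), nrow(truth))
})

test_that("exons are classified into exclusive structural categories", {
    g <- toyGene()
    ## annotated / cryptic / retained_fusion examples from the fixture
    chain <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(c(301L, 1001L), c(450L, 1100L)), strand = "+")
    expect_equal(classifyExons(chain, g), c("annotated", "cryptic"))

    fusion <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(301L, 700L), strand = "+")
    expect_equal(classifyExons(fusion, g), "retained_fusion")

    trunc <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(330L, 450L), strand = "+")
    expect_equal(classifyExons(trunc, g), "truncated")

    extend <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(301L, 470L), strand = "+")
    expect_equal(classifyExons(extend, g), "extended")

    ## exclusivity over a batch of random event models
    set.seed(1)
    evsets <- list(list(skipExon(2)), list(retainIntron(3)),
                   list(altDonor(2, 15)), list(crypticExon(1, 30, 50)),
                   list(skipExon(3), crypticExon(4, 50, 100)))
    for (ev in evsets) {
        lab <- classifyExons(realizeIsoform(g, ev), g)
        expect_true(all(lab %in% c("annotated", "truncated", "extended",
                                   "retained_fusion", "cryptic")))
    }
})

test_that("named splicing events are called with strand-aware signed
          shifts", {
    g <- toyGene()
    ## exon skipping
    ev <- callEvents(realizeIsoform(g, list(skipExon(3))), g)
    expect_equal(ev$type, "exon_skipping")
    expect_equal(ev$target, "exon3")

    ## alt donor: junction [470,600) vs annotated [450,600) -> +20
    ev <- callEvents(realizeIsoform(g, list(altDonor(2, 20))), g)
    expect_equal(ev$type, "alt_donor")
    expect_equal(ev$target, "intron2")
    expect_equal(ev$delta, 20L)

    ev <- callEvents(realizeIsoform(g, list(altAcceptor(2, -15))), g)
    expect_equal(ev$type, "alt_acceptor")
    expect_equal(ev$delta, -15L)

    ## intron retention reports one event per retained intron
    ev <- callEvents(realizeIsoform(g, list(retainIntron(2),
                                            retainIntron(3))), g)
    expect_equal(ev$type, c("intron_retention", "intron_retention"))
    expect_equal(ev$target, c("intron2", "intron3"))

    ## cryptic exon event, no spurious alt-site calls at its flanks
    ev <- callEvents(realizeIsoform(g, list(crypticExon(4, 50, 100))), g)
    expect_equal(ev$type, "cryptic_exon")
    expect_equal(ev$start - 1L, 1000L)

    ## canonical model: no events
    expect_equal(nrow(callEvents(realizeIsoform(g), g)), 0L)

    ## a model has a cryptic_exon event iff it has a cryptic exon
    for (evset in list(list(), list(skipExon(2)),
                       list(crypticExon(2, 20, 40)))) {
        ch <- realizeIsoform(g, evset)
        lab <- classifyExons(ch, g)
        calls <- callEvents(ch, g, lab)
        expect_equal(any(calls$type == "cryptic_exon"),
                     any(lab == "cryptic"))
    }
})

test_that("minus-strand alt events report transcript-direction deltas", {
    g <- buildGene(nExons = 5, seed = 21, strand = "-")
    ev <- callEvents(realizeIsoform(g, list(altDonor(2, 10))), g)
    expect_equal(ev$type, "alt_donor")
    expect_equal(ev$target, "intron2")
    expect_equal(ev$delta, 10L)
    ev <- callEvents(realizeIsoform(g, list(altAcceptor(3, -7))), g)
    expect_equal(ev$type, "alt_acceptor")
    expect_equal(ev$delta, -7L)
})

test_that("junction merging is monotone: a wider window never yields more
          models", {
    g <- buildGene(nExons = 6, seed = 8)
    iso <- GenomicRanges::GRangesList(
        a = realizeIsoform(g), b = realizeIsoform(g, list(skipExon(4))))
    sam <- tempfile(fileext = ".sam")
    simulateAlignments(g, iso, c(0.5, 0.5), 300, sam,
                       fullLengthFrac = 1, junctionJitterSd = 2, seed = 31)
    reads <- readSplicedAlignments(sam)
    n0 <- nrow(collapseAlignments(reads, g, minSupport = 1,
                                  mergeWindow = 0))
    n6 <- nrow(collapseAlignments(reads, g, minSupport = 1,
                                  mergeWindow = 6))
    expect_lte(n6, n0)
    expect_lte(n6, 2L + 2L)   # near the truth after merging at 3*sd
})
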