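## Shared fixtures and independent oracles. The toy gene is a 5-exon
## plus-strand gene with exons (0-based half-open) [100,200) [300,450)
## [600,700) [800,950) [1200,1500) and the A of the ATG at 0-based 150;
## its coding frame is built from sense codons so the canonical ORF runs
## cleanly from the ATG to a stop placed in the last exon.

.BASES <- c("A", "C", "G", "T")
.ALL_CODONS <- as.vector(outer(as.vector(outer(.BASES, .BASES, paste0)),
                               .BASES, paste0))
.STOPS <- c("TAA", "TAG", "TGA")
.SENSE <- setdiff(.ALL_CODONS, .STOPS)

## independent translation oracle: hand-built codon table, no Biostrings
.AA1 <- c("F","F","L","L","S","S","S","S","Y","Y","*","*","C","C","*","W",
          "L","L","L","L","P","P","P","P","H","H","Q","Q","R","R","R","R",
          "I","I","I","M","T","T","T","T","N","N","K","K","S","S","R","R",
          "V","V","V","V","A","A","A","A","D","D","E","E","G","G","G","G")
.TTABLE <- local({
    ord <- c("T", "C", "A", "G")
    codons <- as.vector(sapply(ord, function(b1)
        sapply(ord, function(b2) paste0(b1, b2, ord))))
    setNames(.AA1, codons)
})

bruteTranslate <- function(dna) {
    dna <- as.character(dna)
    n <- nchar(dna) %/% 3
    codons <- substring(dna, 3 * seq_len(n) - 2, 3 * seq_len(n))
    paste(.TTABLE[codons], collapse = "")
}

## ORF oracle: translate from a start position to the first stop
bruteOrfProtein <- function(txSeq, startT) {
    aa <- bruteTranslate(substr(txSeq, startT, nchar(txSeq)))
    stopAt <- regexpr("*", aa, fixed = TRUE)[1]
    if (stopAt < 0) list(protein = aa, stopT = NA_integer_)
    else list(protein = substr(aa, 1, stopAt - 1),
              stopT = startT + (stopAt - 1L) * 3L)
}

toyGene <- function() {
    set.seed(4711)
    st <- c(101L, 301L, 601L, 801L, 1201L)
    en <- c(200L, 450L, 700L, 950L, 1500L)
    w <- en - st + 1L
    L <- sum(w)                       # 800
    atgT <- 51L                       # exon 1 offset 50 (0-based)
    stopT <- 651L                     # in the last exon, frame of the ATG
    nCodon <- (stopT - atgT) %/% 3L - 1L
    tx <- paste0(paste(sample(.BASES, atgT - 1L, replace = TRUE),
                       collapse = ""),
                 "ATG",
                 paste(sample(.SENSE, nCodon, replace = TRUE),
                       collapse = ""),
                 "TAA",
                 paste(sample(.BASES, L - stopT - 2L, replace = TRUE),
                       collapse = ""))
    gchar <- sample(.BASES, 1600L, replace = TRUE)
    txchar <- strsplit(tx, "")[[1]]
    cum <- cumsum(c(0L, w))
    for (i in seq_along(st))
        gchar[st[i]:en[i]] <- txchar[(cum[i] + 1L):cum[i + 1L]]
    for (i in seq_len(length(st) - 1L)) {
        gchar[en[i] + 1L] <- "G"; gchar[en[i] + 2L] <- "T"
        gchar[st[i + 1L] - 2L] <- "A"; gchar[st[i + 1L] - 1L] <- "G"
    }
    genome <- Biostrings::DNAStringSet(paste(gchar, collapse = ""))
    names(genome) <- "chrT"
    ex <- GenomicRanges::GRanges("chrT", IRanges::IRanges(st, en),
                                 strand = "+")
    names(ex) <- paste0("exon", seq_along(ex))
    chain <- sort(ex); names(chain) <- NULL
    methods::new("GeneModel", geneId = "toy", exons = ex,
                 transcripts = list(v.1 = seq_along(ex)),
                 txExons = GenomicRanges::GRangesList(v.1 = chain),
                 canonical = "v.1", startCodon = 151L, genome = genome)
}

## GRangesList of reads built directly from block coordinates
makeReads <- function(blockList, libs = "default",
                      mapq = 60L, chrom = "chrT") {
    n <- length(blockList)
    libs <- rep_len(libs, n); mapq <- rep_len(mapq, n)
    grl <- GenomicRanges::GRangesList(lapply(blockList, function(m)
        GenomicRanges::GRanges(chrom,
            IRanges::IRanges(m[, 1], m[, 2]), strand = "+")))
    S4Vectors::mcols(grl) <- S4Vectors::DataFrame(
        readId = sprintf("r%03d", seq_len(n)), library = libs, mapq = mapq)
    grl
}

## brute-force global affine-gap alignment oracle (Gotoh dynamic
## programme), returning identity per position of b (the canonical
## sequence); same scoring convention as the package default
nwIdentity <- function(a, b, match = 1, mismatch = -1, open = 10,
                       ext = 0.5) {
    A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
    n <- length(A); m <- length(B)
    NEG <- -1e9
    M <- matrix(NEG, n + 1, m + 1)   # ends in a substitution
    Ix <- matrix(NEG, n + 1, m + 1)  # ends with a gap in b (consumes A)
    Iy <- matrix(NEG, n + 1, m + 1)  # ends with a gap in a (consumes B)
    M[1, 1] <- 0
    for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + ext * i)
    for (j in seq_len(m)) Iy[1, j + 1] <- -(open + ext * j)
    for (i in seq_len(n)) for (j in seq_len(m)) {
        s <- if (A[i] == B[j]) match else mismatch
        M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
        Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                                Ix[i, j + 1] - ext,
                                Iy[i, j + 1] - open - ext)
        Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                                Iy[i + 1, j] - ext,
                                Ix[i + 1, j] - open - ext)
    }
    ident <- logical(m)
    i <- n; j <- m
    state <- which.max(c(M[n + 1, m + 1], Ix[n + 1, m + 1],
                         Iy[n + 1, m + 1]))
    while (i > 0 || j > 0) {
        if (state == 1L && i > 0 && j > 0) {
            ident[j] <- A[i] == B[j]
            s <- if (A[i] == B[j]) match else mismatch
            prev <- c(M[i, j], Ix[i, j], Iy[i, j])
            state <- which.max(prev)
            i <- i - 1; j <- j - 1
        } else if (state == 2L && i > 0) {
            cand <- c(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext,
                      Iy[i, j + 1] - open - ext)
            state <- which.max(cand)
            i <- i - 1
        } else if (state == 3L && j > 0) {
            cand <- c(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext,
                      Ix[i + 1, j] - open - ext)
            state <- c(1L, 3L, 2L)[which.max(cand)]
            j <- j - 1
        } else if (i > 0) {
            state <- 2L
        } else {
            state <- 3L
        }
    }
    ident
}

randProtein <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], NULL),
                 n, replace = TRUE), collapse = "")
}
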