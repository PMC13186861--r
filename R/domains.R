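## Conserved-domain retention calling: each predicted protein isoform is
## globally aligned to the canonical protein; a domain's coverage is the
## fraction of its canonical positions aligned to an identical residue in
## the isoform. Coverage is thresholded into present / partial / absent.

.aaSubMatrix <- function(match = 1, mismatch = -1) {
    letters <- Biostrings::AA_ALPHABET
    m <- matrix(mismatch, length(letters), length(letters),
                dimnames = list(letters, letters))
    diag(m) <- match
    m
}

#' Globally align an isoform protein to the canonical protein
#'
#' Needleman-Wunsch-style global alignment with affine gap penalties
#' (defaults: match +1, mismatch -1, gap open -10, gap extend -0.5).
#' Returns, for every canonical position, whether it is aligned to an
#' identical isoform residue.
#'
#' @param isoProtein,canonicalProtein amino-acid strings (non-empty).
#' @param match,mismatch,gapOpen,gapExtend scoring parameters; gap
#'   penalties are positive costs.
#' @return logical vector of length \code{nchar(canonicalProtein)}:
#'   identity per canonical position.
#' @export
alignToCanonical <- function(isoProtein, canonicalProtein, match = 1,
                             mismatch = -1, gapOpen = 10, gapExtend = 0.5) {
    isoProtein <- as.character(isoProtein)
    canonicalProtein <- as.character(canonicalProtein)
    if (!nzchar(isoProtein) || !nzchar(canonicalProtein))
        stop("empty protein sequence")
    aln <- pairwiseAlignment(
        pattern = Biostrings::AAString(isoProtein),
        subject = Biostrings::AAString(canonicalProtein),
        type = "global",
        substitutionMatrix = .aaSubMatrix(match, mismatch),
        gapOpening = gapOpen, gapExtension = gapExtend)
    p <- strsplit(as.character(alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(alignedSubject(aln)), "")[[1]]
    ident <- logical(nchar(canonicalProtein))
    ci <- 0L
    for (k in seq_along(s)) {
        if (s[k] != "-") {
            ci <- ci + 1L
            ident[ci] <- p[k] != "-" && p[k] == s[k]
        }
    }
    ident
}

#' Call domain retention from an alignment
#'
#' @param identity logical per-canonical-position identity vector from
#'   \code{\link{alignToCanonical}} (or all-FALSE for a protein with no
#'   product).
#' @param domains data.frame from \code{\link{readDomainTable}}.
#' @param presentMin coverage at or above which a domain is
#'   \code{present} (default 0.9).
#' @param absentMax coverage below which a domain is \code{absent}
#'   (default 0.3); in between is \code{partial}.
#' @return data.frame: \code{domain}, \code{coverage}, \code{status}.
#' @export
callDomains <- function(identity, domains, presentMin = 0.9,
                        absentMax = 0.3) {
    if (nrow(domains) && max(domains$aa_end) > length(identity))
        stop("domain '",
             domains$name[which.max(domains$aa_end)],
             "' exceeds the canonical protein length (",
             length(identity), " aa)")
    cov <- vapply(seq_len(nrow(domains)), function(i)
        mean(identity[domains$aa_start[i]:domains$aa_end[i]]), 0)
    status <- ifelse(cov >= presentMin, "present",
                     ifelse(cov < absentMax, "absent", "partial"))
    data.frame(domain = domains$name, coverage = cov, status = status,
               stringsAsFactors = FALSE)
}

#' Domain retention calls for a set of protein isoforms
#'
#' @param orfs output of \code{\link{predictOrfs}} (or any data.frame with
#'   \code{transcript_id} and \code{protein} columns).
#' @param canonicalProtein canonical amino-acid sequence.
#' @param domains data.frame from \code{\link{readDomainTable}}.
#' @param presentMin,absentMax see \code{\link{callDomains}}.
#' @param ... alignment parameters for \code{\link{alignToCanonical}}.
#' @return long data.frame: \code{transcript_id}, \code{domain},
#'   \code{coverage}, \code{status}. Isoforms without a product get
#'   coverage 0 for every domain.
#' @export
domainCalls <- function(orfs, canonicalProtein, domains,
                        presentMin = 0.9, absentMax = 0.3, ...) {
    out <- lapply(seq_len(nrow(orfs)), function(i) {
        ident <- if (nzchar(orfs$protein[i]))
            alignToCanonical(orfs$protein[i], canonicalProtein, ...)
        else logical(nchar(canonicalProtein))
        calls <- callDomains(ident, domains, presentMin, absentMax)
        cbind(transcript_id = orfs$transcript_id[i], calls)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Wide domain presence/absence matrix
#'
#' Symbols: check mark = present, \code{~} = partial, en dash = absent.
#' With \code{strict = TRUE} partial collapses to absent, mirroring a
#' binary check/dash table.
#'
#' @param calls output of \code{\link{domainCalls}}.
#' @param strict collapse \code{partial} to absent.
#' @return list with \code{status} (character matrix of symbols) and
#'   \code{coverage} (numeric matrix), transcripts x domains.
#' @export
domainMatrix <- function(calls, strict = FALSE) {
    txs <- unique(calls$transcript_id)
    doms <- unique(calls$domain)
    sym <- matrix("", length(txs), length(doms),
                  dimnames = list(txs, doms))
    cov <- matrix(NA_real_, length(txs), length(doms),
                  dimnames = list(txs, doms))
    for (k in seq_len(nrow(calls))) {
        s <- calls$status[k]
        if (strict && s == "partial") s <- "absent"
        sym[calls$transcript_id[k], calls$domain[k]] <-
            switch(s, present = "\u2713", partial = "~",
                   absent = "\u2013")
        cov[calls$transcript_id[k], calls$domain[k]] <- calls$coverage[k]
    }
    list(status = sym, coverage = cov)
}
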