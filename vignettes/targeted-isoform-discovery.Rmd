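---
title: "Targeted long-read splice-variant discovery with IsoScope: methods and design"
author: "IsoScope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted long-read splice-variant discovery with IsoScope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Targeted amplicon long-read sequencing is a sensitive way to enumerate the
splice variants of a single gene: cDNA is amplified between a forward
primer near the annotated ATG and a reverse primer in the last annotated
exon, barcoded per sample pool, sequenced on a long-read platform,
error-polished, and aligned to the reference genome with a spliced aligner.
Each polished read then covers (ideally) a whole transcript molecule, and
its spliced alignment — maximal aligned blocks separated by `N` gaps —
directly exposes the molecule's intron chain.

IsoScope consumes such spliced alignments (SAM) together with the gene
annotation (GTF) and genome (FASTA) and carries out the downstream
characterization:

1. **Discovery** — collapse full-length reads into transcript models by
   intron chain; classify exons and call named splicing events (cassette
   exon skipping, intron retention, alternative donor/acceptor sites,
   cryptic exons).
2. **Quantification** — per-library transcript abundance in TPM from
   full-length read counts.
3. **Coding potential** — ATG-anchored ORF prediction, translation, and
   NMD classification by the 50-nt rule.
4. **Domain retention** — per-isoform presence/partial/absence of
   conserved protein domains by global alignment to the canonical protein.

A seeded simulator of the whole experiment is part of the package, so
every stage is testable without any sequencing data.

## Discovery model

**Variant identity is the exact intron chain.** Two reads describe the
same splice variant exactly when their ordered intron coordinates are
identical. Inputs are assumed to be error-polished reads, so junction
coordinates are trusted as-is and the junction-merge window defaults to
0 nt. For noisier input a window $w$ can be set: junction coordinates are
clustered single-linkage (coordinates within $w$ of each other join a
cluster) and each cluster is replaced by its most frequent coordinate.
Single-linkage clustering is hierarchical in $w$, so widening the window
can only merge models, never split them — the model count is monotone
non-increasing in $w$.

**Full-length filter.** Only reads whose aligned span covers the genomic
position of the annotated start codon *and* whose 3'-most block overlaps
the last annotated exon participate in discovery and quantification. This
mirrors the amplicon design: both primers must be present on a complete
molecule. Everything else is treated as a library-preparation fragment and
only counted in the filtering log.

**Terminal exon boundaries.** Intron chains say nothing about transcript
ends. Because the amplicon fixes both ends, the terminal boundaries of a
model are taken as the modal (most frequent) terminal block boundaries of
its supporting reads; ties break toward the longer exon. The mode is
robust against the minority of reads with ragged ends.

**Support threshold.** A chain needs at least `minSupport` full-length
reads (default 3) to become a model. There is no community-standard value
for targeted data; 3 rejects singleton artifacts while keeping rare
variants, and the parameter is exposed.

**Naming.** Models whose intron chain equals an annotated transcript keep
the annotated name. Novel models are numbered `sv.N` in order of
decreasing support, starting at one past the number of annotated
transcripts (with a six-transcript annotation the first novel model is
`sv.7`).

**Exon classification** is relative to the canonical annotated exons:
`annotated` (identical), `truncated` (strictly inside one annotated exon),
`extended` (reaching beyond an annotated boundary into the intron; an exon
that is truncated on one side and extended on the other is classified
`extended`, since an intronic inclusion is the stronger deviation),
`retained_fusion` (spanning two or more annotated exons and the introns
between them), and `cryptic` (overlapping no annotated exon).

**Event calling.** Exon skipping is emitted for every internal annotated
exon that no model exon overlaps and that a model intron bridges; intron
retention once per annotated intron inside a fused exon; alternative
donor/acceptor for junctions sharing exactly one boundary with an
annotated junction, with a signed strand-aware shift (positive =
downstream in transcript direction; the donor is the 5' splice site);
cryptic-exon events for cryptic exons. Junctions whose novel boundary
abuts a cryptic exon are explained by the cryptic-exon event and are not
double-reported as alternative splice sites, and a junction that joins two
annotated boundaries of different introns is the signature of skipping,
not of an alternative site.

## Quantification

TPM is computed per library over the discovered models from full-length
counts. Two modes are exposed because "the TPM method" is underdetermined
for full-length counting:

- `length_normalized` (default, the standard formula):
  $\mathrm{tpm}_i = 10^6 \, (c_i/l_i) / \sum_j (c_j/l_j)$;
- `count_based`: $\mathrm{tpm}_i = 10^6 \, c_i / \sum_j c_j$ — defensible
  here because a full-length count is already a molecule count and needs
  no length correction.

Both normalize each library independently to $10^6$; libraries with zero
counts are reported as all-zero with a warning, and transcripts absent
from a library get explicit zeros.

## ORF prediction and the NMD rule

Every model's ORF is anchored at the annotated initiation codon: the
genomic ATG position is mapped through the model's exon chain into
transcript coordinates (the genomic/transcript maps are strict bijections
on exonic positions, tested as such). If the position is lost — its exon
skipped or truncated away — or the mapped triplet is no longer ATG, the
model is `no_start`. Otherwise codons are scanned to the first in-frame
stop and translated with the standard nuclear code. Alternative upstream
or downstream AUGs are deliberately out of scope.

A transcript with a stop more than `thresholdNt` nucleotides upstream of
its final exon–exon junction is an `nmd_candidate`. The commonly cited
boundary is 50–55 nt; the default is the conservative 50 nt with a strict
inequality ("more than"), both configurable. A stop in the last exon and a
mono-exonic model are `coding`. Models with no in-frame stop at all (an
artifact of 3'-truncated chains) are reported `coding_no_stop` and
excluded from coding counts.

## Domain retention

Each predicted protein is globally aligned to the canonical protein
(Needleman–Wunsch with affine gaps; defaults match +1, mismatch −1, gap
open −10, gap extend −0.5). A domain's **coverage** is the fraction of its
canonical positions aligned to an *identical* isoform residue — counting
identity rather than mere alignment makes the measure robust to
frameshifted tails that still align as mismatches. Coverage ≥ 0.9 is
`present`, < 0.3 `absent`, otherwise `partial`; the thresholds reproduce
binary presence/absence behavior on clean in-frame deletions, and a strict
mode collapses `partial` to absent for a purely binary table. For clean
in-frame deletions, coordinate bookkeeping and alignment give identical
answers; they diverge only for frameshifts, where alignment-based identity
is the better-defined notion.

Domain boundaries ship as a user-editable TSV of amino-acid intervals on
the canonical protein; the packaged `brca2_domains_example.tsv` contains
illustrative intervals for the classic BRCA2 domain set (PALB2-binding,
BRC-repeat RAD51-binding region, DBD helical and OB folds, C-terminal
RAD51-binding) and is meant to be replaced with the user's curated
coordinates.

## The simulator: what it emulates and what it does not

`buildGene` generates a random multi-exon gene with the structural
guarantees the analysis needs: GT..AG intron boundaries on the transcript
strand, an ATG at a recorded offset in exon 1, a coding frame free of
premature stops (built directly from sense codons rather than rejection
sampling), and a stop codon inside the last exon. Defaults (9 exons of
90–360 nt, introns of 100–800 nt) give a desk-scale gene with enough
introns to host every event type; all are parameters.

`realizeIsoform` applies an event grammar — `skipExon`, `retainIntron`,
`altDonor`, `altAcceptor`, `crypticExon` — to the canonical chain and
rejects incompatible combinations. `simulateAlignments` draws per-read
isoform and library labels from weight vectors, truncates a configurable
fraction of reads (uniform prefix/suffix loss; the default emulates the
mostly-full-length amplicon with a minority of fragments,
`fullLengthFrac = 0.8`), optionally jitters junction edges with rounded
Gaussian noise, and writes alignments directly as truth-derived SAM. No
aligner is invoked, which keeps tests hermetic.

Deliberately **not** simulated: base-level sequencing errors inside
aligned blocks (the analysis targets polished reads, so junction jitter is
the only error knob), quality scores, PCR chimeras, internal fragments
missing both ends, and multi-gene backgrounds. Passing tests on this
simulator therefore demonstrate correctness of the downstream logic under
the stated read model — not robustness to raw-read error profiles or
mispriming, which are upstream concerns.

## Numerical and design choices

- **Coordinates.** All in-memory intervals are `GRanges` (1-based
  inclusive, the Bioconductor convention); GTF/SAM converge naturally and
  BED output converts to 0-based half-open at the boundary. One container,
  conversions only at edges.
- **MAPQ.** Default minimum 1: the data are a targeted amplicon of a
  single locus, so anything placed there non-ambiguously is acceptable;
  exposed for stricter use.
- **Secondary/supplementary alignments** are excluded: one molecule, one
  vote.
- **Tie-breaks** are all deterministic: modal terminal boundaries break
  toward the longer exon; junction-cluster representatives break toward
  the smaller coordinate; model ordering is by descending support, then
  genomic position.
- **Degenerate inputs.** Zero full-length reads, all-zero count libraries,
  empty model sets, header-only GTFs and mono-exonic genes all return
  well-formed empty results with warnings rather than errors.
- **Determinism.** Identical inputs and seeds give byte-identical outputs;
  the only randomness anywhere is in the simulator, which is seeded.

## Validation scale

The shipped test-suite and acceptance checks run a five-isoform mixture
(skip, intron retention, alternative donor, cryptic exon, canonical) at
weights 0.4/0.2/0.2/0.1/0.1 with 2,000 reads and 80% full-length fraction,
50 small randomized simulations for the TPM normalization laws, 100
randomized models for the translation oracle, and toy-protein suites for
the alignment laws. These sizes were chosen to exercise every code path
while completing in about two minutes on a single CPU.

## Known limitations

- Terminal-exon variation is not called as a named event; it shows up only
  through the modal-boundary model ends.
- Chains are matched exactly (or within the merge window); a systematic
  aligner bias at a junction larger than the window splits a variant in
  two.
- The NMD rule is the textbook 50-nt heuristic; it does not model
  EJC-independent decay or readthrough.
- Domain calls depend on the user-supplied domain intervals and on
  alignment parameters for heavily rearranged isoforms.

## A worked example

```{r example, eval = FALSE}
library(IsoScope)

## simulate an experiment into a directory
sim <- simulateDataset("sim",
    isoformEvents = list(
        iso_canonical = list(),
        iso_skip = list(skipExon(3)),
        iso_cryptic = list(crypticExon(2, 30, 60))),
    weights = c(0.6, 0.25, 0.15), nReads = 400, nExons = 6, seed = 23)

## run the whole pipeline
res <- runPipeline(sim$paths$gtf, sim$paths$genome, sim$paths$sam,
                   outDir = "out")
res$summary
```
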