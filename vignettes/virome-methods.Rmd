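---
title: "Methods: prophage mining, attachment sites and phage similarity networks"
author: "viromeKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prophage mining, attachment sites and phage similarity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromeKit)
```

viromeKit implements a desk-scale pipeline for the analysis of temperate
phages in bacterial genomes: census statistics over a packaged virome
catalog, completeness screening of prophage regions, GC-based boundary
refinement, attachment-site (attL/attR/attB/attP) discovery, reciprocal
protein-similarity networks, and all-vs-all nucleotide ribbon comparison.
This vignette explains the models behind each stage, the parameters that
matter, and what the synthetic-data generators do and do not emulate.

## The virome catalog

The packaged catalog (`loadCatalog()`) is a hand-transcribed table of the
66 members of the *Paracoccus* virome: five mitomycin C-induced active
temperate phages, 59 in-silico prophages across 29 lysogenic strains, and
two lytic phages known only by name. Each row carries family, lifestyle,
integration strategy (tyrosine recombinase, serine recombinase, or Mu-like
transposase), a normalised integration-site name, genome size, GC content,
gene count, replicon coordinates and — for the active phages — the
reported attB core sequence.

Conventions worth stating explicitly:

* **Coordinates are 1-based inclusive**, the convention under which the
  printed genome sizes and replicon coordinates agree (verified on
  multiple rows; `genomeSizeFromCoords(725048, 768929)` is 43,882).
* **Validation collects, never drops.** Row-level invariant violations
  (reversed coordinates, impossible GC, lytic entries carrying
  integration metadata) land in `validationReport()`; the rows stay in
  the table so a census is always over the full transcription.
* **`crossValidateSizes()` audits the transcription itself.** Two rows of
  the source table disagree with their own coordinates (one by more than
  100 kb, evidently a typographical coordinate; one by 30 bp). The audit
  reports both; the fixture remains verbatim. Prophages split across two
  contigs store both segments and are excluded from the audit.
* **Counting conventions follow the table, with discrepancies flagged.**
  The enumerated rows yield 39 tyrosine / 15 serine / 5 transposase
  integration modules and 30 tRNA-sited prophages, while the source prose
  gives 38/16 and 31; the package reports the table-derived numbers and
  leaves the discrepancy visible rather than asserting either.
* tRNA site names are canonicalised to `tRNA-Xaa(ANT)`; anticodon
  variants of one amino acid stay distinct, since they are different loci.

## The alignment engine

All similarity in the package reduces to exact affine-gap Smith–Waterman
(no seeding heuristics), implemented in C++ with full traceback. At desk
scale — proteomes of tens of proteins, genomes of a few tens of kb — exact
DP is affordable and removes an entire class of heuristic-sensitivity
questions.

* **Scoring defaults.** Proteins: BLOSUM62, gap open 11 / extend 1,
  Karlin–Altschul `λ = 0.267`, `K = 0.041` (standard gapped values).
  Nucleotides: match +2 / mismatch −3, gap open 5 / extend 2,
  `λ = 0.625`, `K = 0.41`. A gap of length L costs `open + L·extend`.
* **Statistics.** Bit score `= (λS − ln K)/ln 2`; E-value
  `= m·n·2^(−bit)` with `m` the query length and `n` the subject length
  (single pair) or the subject set's total residue count (database-style
  searches, used for the network thresholds). Threshold behaviour, not
  numeric parity with any particular BLAST build, is the contract.
* **Determinism.** Among co-optimal alignments the reported one has the
  earliest query start, then earliest subject start, then earliest ends;
  traceback prefers diagonal over gap-in-query over gap-in-subject. Every
  result is therefore bit-reproducible.
* **HSP iteration** (`findHsps()`) is greedy: report the optimal local
  alignment, mask its subject interval, recurse on the flanking subject
  segments until the best remaining raw score falls below
  `minRawScore`. HSPs never overlap on the subject. For genome ribbons
  the default `minRawScore = 300` makes the shortest reportable HSP at
  100% identity about 150 nt under +2/−3 scoring.

The test suite holds the engine to a brute-force pure-R DP oracle on
hundreds of random pairs and cross-checks scores against an independent
dynamic-programming implementation from Biostrings.

## Attachment-site discovery

In a lysogen the prophage is flanked by the direct repeats attL and attR,
the recombination products of attB × attP. `findDirectRepeats()`
enumerates *every* maximal exact common substring of the two flank
windows above a minimum length (seed-and-extend with left-maximality, so
each occurrence pair is reported exactly once); `callAtt()` then ranks
candidates by a total, documented order:

1. tRNA 3′-end reconstitution (an att copy overlapping or abutting the
   tRNA 3′ terminus such that excision restores an intact gene),
2. core length (longer first),
3. summed proximity of the copies to the rough prophage ends,
4. leftmost position.

Defaults: flank window 2,000 bp per side, minimum core 12 nt — just below
the shortest attB core reported for this genus (13 nt) — and exact
repeats only, since attL/attR are presented as identical repeats. These
are engineering choices, not published values, and are all configurable.
The derived attB joins 50 bp of host context on either side of the core
(the post-excision junction); attP joins the core with the
prophage-internal context in the circular-phage convention.

Flanks of 2 kb of random sequence contain a chance shared 12-mer with
probability of order one-half, so ranking rule (1) is what makes calling
robust: a spurious repeat essentially never reconstitutes a tRNA. On 100
simulated tRNA-end integrations with cores of 15–29 nt the caller
recovers the exact planted core and both intervals in ≥ 95 cases (the
acceptance suite measures this; in practice it is typically 100).

## Prophage completeness and GC boundary refinement

A candidate region is **complete** when its annotation carries at least
one gene from each of the five modules of a functional temperate phage:
integration, lysis/lysogeny switch, DNA packaging, head–tail assembly,
lysis. Module labels are consumed from GFF3 attributes; a conservative
keyword map (`productCategoryMap()`) can fill them from product text but
annotation itself is out of scope.

**Boundary refinement** handles prophages whose att sites cannot be
found: the prophage often differs from its host in GC content, so each
rough boundary is re-placed where the sequence best splits into a
background-like and a prophage-like segment. Concretely, the host
background GC is estimated from the replicon outside the rough interval
and the prophage GC from the interval's central half; each boundary then
maximises a base-level CUSUM statistic (cumulative deviation from the
midpoint composition) within four windows of its rough position, minus an
anchor penalty of `2 × minContrast` per 100 bases moved. The anchor
deserves a note: a plain changepoint fit at weak contrast (≈ 4 GC points)
makes long random excursions — window-scale GC fluctuation inside a
genuine prophage is of the same magnitude as the contrast itself, which
also rules out the naive alternative of thresholding individual windows
(we measured that variant at ~10% recovery). The penalty encodes the
prior that the rough boundary, usually derived from the annotated gene
span, is approximately right, and only decisive compositional evidence
should move it. The contrast gate (`minContrast`, default 2.5 points) is
applied to the *refined* interval, whose GC estimate is not contaminated
by mis-included host sequence; below the gate the rough interval is
returned with `refined = FALSE`. A windowed GC profile (window 500 bp,
step 100 bp by default) is returned for plotting.

On 100 simulated 3-kb insertions at exactly 4 points of contrast with
±300 bp rough-boundary jitter, refinement lands within one window
(±500 bp) of the planted boundaries in well over 90 cases.

**MTase locus classification** reflects the characteristic placement of
phage DNA methyltransferase genes: `ParB_Tls` when the MTase sits between
a ParB-like gene and the terminase large subunit gene (same strand,
within 10 genes) — the conserved locus upstream of the packaging module —
otherwise nearest-module rules (downstream/upstream of the integrase,
downstream of the lysis module, near the replication module) with a
window of two intervening genes.

## Gene-sharing and marker networks

Two proteins are **reciprocally similar** when their alignment passes
E ≤ 1e−10, identity ≥ 80% and HSP coverage ≥ 75% *evaluated on each
sequence in turn*, with the E-value computed against each proteome's
total residue count. Because the Smith–Waterman score is symmetric, one
DP per unordered pair suffices; the two directions differ only in
coverage side and search space. The E-value threshold is deliberately
permissive so that short (< 100 aa) proteins are not lost; identity and
coverage do the discriminating.

"Number of common proteins" (the edge weight) is defined here as the
count of **one-to-one reciprocal pairs**, resolved greedily by descending
bit score. This makes the weight symmetric and bounded by the smaller
proteome — properties the looser reading (count of proteins with at
least one partner) lacks. Pair-level reciprocity (the same pair passing
in both directions) was likewise chosen over any-hit reciprocity; both
choices are recorded on the edges, whose member pair lists are retained.

Marker networks (integrase, large terminase subunit, major capsid
protein) use the same thresholds with one protein per phage and weight 1;
phages lacking the marker remain as flagged isolated nodes. The
protein-level identity network used for MTase diversity maps applies
identity ≥ 80% over ≥ 75% coverage of the *shorter* sequence — the
natural convention when the compared proteins differ in length.

Components and orphans come from igraph; the test suite checks them
against a hand-written union-find oracle. GraphML export goes through
igraph; GEXF is written directly (typed node attributes, undirected
weighted edges) since no installed package provides it. Both round-trip
nodes, edges, weights, attributes and member pair lists losslessly. No
layout is computed — graphs are exported for external visualisation.

## Genome ribbon comparison

`allVsAllGenomes()` collects non-overlapping HSPs for every genome pair
on both strands (the subject is reverse-complemented and coordinates
mapped back) and filters at E ≤ 1e−100, the convention for whole-genome
ribbon plots of phage relatedness. Hits carry identity bins (<85, 85–95,
95–99, ≥99; configurable) — binned by identity rather than score ratio,
matching how such figures are read. Relationship calls:
**near-identical** when a partner's ≥ 99%-identity HSPs cover ≥ 95% of
both genomes (inferred from pairs described as sharing "99–100%
identity"), **unique** when a genome draws no hits at all, **local
similarity** otherwise. The figure-level counts from the original survey
(5 unique, 9 near-identical) require the deposited sequences and are not
reproduced here.

## Synthetic data and what passing tests mean

The generators produce i.i.d. sequences with per-base probabilities set
from the GC target; no repeat structure is injected except planted att
cores. This keeps the direct-repeat oracle clean, and it is also the
generators' main departure from real genomes, which contain IS elements,
rRNA operons and low-complexity tracts that a repeat search must contend
with. tRNA genes are labelled intervals with arbitrary internal sequence
(tRNA identification is out of scope); proteins are uniform draws over
the 20 standard residues, so chance similarity at network thresholds is
negligible — again unlike real proteomes with shared domains. Passing the
recovery suites therefore demonstrates correctness of the algorithms
under their stated models, not robustness to every artefact of real data.

Integration simulation duplicates the 3′-terminal `attCoreLength` bases
of the target tRNA around the inserted cassette, so the upstream copy
completes an intact gene, exactly as site-specific integration does; for
minus-strand tRNAs the geometry is mirrored. The cassette's terminal
bases are constrained to differ from the host bases adjoining the core,
so the planted core is *exactly* the maximal repeat — without this, the
maximal repeat extends past the planted core by one or more bases in a
substantial fraction of simulations and "exact recovery" would be
ill-defined. Truth records (interval, att copies, core, target, site
class) suffice to score every downstream call without reading generator
internals.

Default study conditions used by the test and acceptance suites, chosen
once as realistic for this genus: host replicon segments at 65% GC (the
*Paracoccus* chromosomal range), prophage cassettes at 58–61% GC
(prophages in this genus run several points below their hosts), att cores
of 15–29 nt (the reported attB range is 13–52 nt), 2-kb flank windows,
100 seeded replicates per recovery suite, and compact problem sizes
(6–12 kb hosts, 0.6–3 kb cassettes, proteomes of ~5–10 proteins of
100–250 aa, genomes of ~2.5 kb for ribbon tests) so the full suite runs
in minutes on one CPU.

## Known limitations

* Exact DP memory grows as the product of sequence lengths (byte-sized
  traceback matrices); the engine is meant for (pro)phage-scale
  sequences, not chromosomes. Screening a whole replicon should pass
  windows, not the full sequence.
* Only exact direct repeats are called by default; degenerate att cores
  (the catalog contains one, with a G/C polymorphism) will be recovered
  as their longest exact stretch.
* E-values are Karlin–Altschul idealisations without composition-based
  adjustment; they are used as thresholds, not as publishable statistics.
* The GC refinement assumes a single contiguous prophage whose interior
  is compositionally distinct; nested or mosaic elements violate the
  two-segment model.
* Family assignment, gene function and tRNA identification are consumed
  as annotations; the package neither validates nor re-derives them.
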