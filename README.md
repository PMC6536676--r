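# viromeKit

Tools for characterising the temperate-phage content of bacterial genomes,
built around the virome of the genus *Paracoccus* (*Alphaproteobacteria*).

Roughly half of sequenced *Paracoccus* strains are lysogens: their
chromosomes carry integrated temperate phages (prophages) that were
acquired by site-specific recombination between a bacterial attachment
site (*attB*) and its phage counterpart (*attP*), leaving the prophage
flanked by two direct repeats, *attL* and *attR*. Finding these elements,
delimiting them, and comparing them across strains is a recurring job in
phage genomics. viromeKit packages that workflow end to end:

* **Catalog census** — a packaged, validated catalog of the 66-member
  *Paracoccus* virome (5 mitomycin C-induced active phages, 59 *in
  silico*-predicted prophages, 2 lytic phages) with every published census
  statistic recomputable: lysogen and polylysogen counts, family tallies
  (*Siphoviridae*/*Podoviridae*/*Myoviridae*), integrase-class counts and
  integration-site usage.
* **Prophage screening** — completeness assessment of candidate regions
  from module-labelled annotations (a complete temperate phage carries
  integration, lysis/lysogeny switch, DNA packaging, head–tail assembly
  and lysis modules) and boundary refinement by GC contrast against the
  host background.
* **Attachment-site discovery** — exhaustive direct-repeat search in the
  flanks of a prophage interval, ranking by tRNA 3′-end reconstitution
  (phages preferentially integrate at the 3′ ends of tRNA genes, and
  integration regenerates an intact copy of the gene), with derived
  *attB*/*attP* sequences and site classification.
* **Alignment engine** — exact affine-gap Smith–Waterman (Rcpp) with
  deterministic tie-breaking, greedy non-overlapping HSP iteration, and
  Karlin–Altschul statistics: bit score `(λS − ln K)/ln 2` and E-value
  `E = m·n·2^(−bit)`.
* **Gene-sharing networks** — reciprocal protein-similarity networks at
  the standard thresholds (E ≤ 1e−10, HSP query coverage ≥ 75%, identity
  ≥ 80%): whole-proteome networks with edge weight equal to the number of
  one-to-one reciprocal pairs, marker networks (integrase, large
  terminase, major capsid) and protein-level identity networks; connected
  components, orphans, and lossless GraphML/GEXF export.
* **Genome ribbons** — all-vs-all nucleotide comparison on both strands at
  a stringent E-value (1e−100), identity-binned ribbon hits, per-window
  hit-frequency profiles, and unique / near-identical / local-similarity
  relationship calls.
* **Synthetic data with planted truth** — generators for host replicons,
  modular prophage cassettes integrated with duplicated att cores at tRNA
  3′ ends, GC contrast, and proteome clusters with planted pairwise
  identity, so that every stage is testable without downloads.

## Worked example

```r
library(viromeKit)

cat66 <- loadCatalog()     # the packaged Paracoccus virome catalog
cat66
#> ViromeCatalog with 66 entries (5 active, 59 prophage, 2 lytic)
viromeSize(cat66)          #> 66
countLysogens(cat66)       #> 29
polylysogenCensus(cat66)$polylysogens   #> 14
tallyByFamily(cat66)
#>   Myoviridae  Podoviridae Siphoviridae
#>            1            8           50
tallyIntegrationSites(cat66)[["tRNA-Met(CAT)"]]   #> 10

# simulate a lysogen and recover its attachment site
host <- generateHostGenome(hostGenomeSpec(
  length = 20000, gcTarget = 65,
  trnaGenes = data.frame(position = 10000, length = 76,
                         name = "tRNA-Met(CAT)", strand = "+")), seed = 42)
lys <- simulateIntegration(host,
  prophageSpec(length = 6000, gcTarget = 58, attCoreLength = 20),
  "tRNA-Met(CAT)", seed = 7)
call <- callAtt(lys$sequence, lys$truth$prophage_interval, lys$features)
call
#> AttCall: 20-nt core 'TGAGGTAGACTGCAACTGGA'
#>   attL 10056-10075, attR 16076-16095, site class tRNA (target tRNA-Met(CAT))
identical(attCore(call), lys$truth$att_core)   #> TRUE
```

The 20-nt core is the duplicated attL/attR repeat; excising
`[attL start, attR start)` restores the host chromosome with a single
copy — the *attB* site — at the junction
(`exciseProphage(lys$sequence, call)`).

A thin command-line wrapper over the same functions ships in
`inst/scripts/virokit.R` with subcommands `simulate`, `screen`, `att`,
`network`, `ribbon` and `catalog-stats`.

## Scope notes

Family assignments, functional annotation and tRNA gene identification are
consumed as metadata/attributes, not re-derived; no sequences are
downloaded. The methods vignette (`vignettes/virome-methods.Rmd`)
describes the models, parameter choices and known limitations.
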