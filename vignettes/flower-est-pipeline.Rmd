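---
title: "Comparative EST transcriptomics of two flower sex types: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative EST transcriptomics of two flower sex types: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(florest)
```

# The study design this package models

`florest` re-implements, as a tested pipeline, a comparative expressed
sequence tag (EST) analysis between two flower sex types of a monoecious
crop: two 454-style cDNA libraries, one per near-isogenic line (a gynoecious
line tagged `G` and a hermaphroditic line tagged `H`), each a single
sequencing run of short single-pass reads averaging 175 nt. From that one
data design the pipeline derives five analyses:

1. **Spliced mapping** of ESTs to flanked gene regions of the annotated
   genome, with a 95% identity / 80% query coverage acceptance rule.
2. **Alternative splicing (AS)**: intron–exon junctions are read off the
   spliced alignments, compared with the annotation, and classified into the
   five classical event types — alternative donor (AltD), alternative
   acceptor (AltA), alternative position (AltP), intron retention (IntronR)
   and exon skipping (ExonS).
3. **Digital expression**: per-gene tag counts in the two libraries are
   tested with the log-likelihood-ratio R statistic for multi-library tag
   sampling, p-values become q-values, and genes with fold change > 2 and
   q < 0.05 are called differentially expressed (DE).
4. **SSR mining**: perfect microsatellites of 2–6 nt motifs at the standard
   MISA thresholds (six repeats for dinucleotides, five for longer motifs),
   with 100 bp compound merging and motif-class canonicalization.
5. **SNP discovery**: a transparent per-column allele caller between the two
   lines followed by three filters targeting the pyrosequencing error mode
   (per-line coverage, homopolymer-adjacent indels, inter-line allele
   disjointness), with transition/transversion/indel classification.

Because no raw reads of the original study are publicly deposited, the
package ships a first-class synthetic-data generator whose output exhibits
the statistical structure every downstream stage assumes, together with
truth tables that make every stage testable end to end.

# The synthetic study

`simulation_config()` fixes the study conditions; `generate_genome()` and
`simulate_libraries()` realise them. The defaults encode:

* **Genes.** 60 genes on 2 chromosomes, 2–6 exons of 90–300 nt, introns of
  60–400 nt always carrying GT..AG splice signals on the transcribed strand,
  with up to 250 nt untranslated regions (UTRs) inside the terminal exons.
  Genes are spaced ≥ 2.1 kb apart so that the default 1 kb flanks rarely
  collide (when they do, the midpoint rule below resolves them).
* **Reads.** Exactly 2,000 reads per library, normal lengths (mean 175 nt,
  sd 50 nt, floor 60 nt — the floor and the transcript length are the only
  censoring, keeping the realised mean within a few nt of 175), sampled
  uniformly along transcripts in random orientation. Uniform sampling is a
  deliberate neutral choice: the positional bias of the original cDNA
  protocol is unknown, and a bias hook would add a parameter nothing
  downstream can check.
* **Expression.** Per-gene rates are gamma-distributed (shape 2, mean fixed
  by `base_expression = 25` expected reads per gene per library); counts are
  multinomial given the fixed library size. The gamma–Poisson form is a
  stand-in for an unknown real abundance distribution, not an inference
  about it.
* **Differential expression.** 6 genes carry a true fold of 4, half up in
  each library, implemented by scaling the library-G sampling weight.
* **Alternative splicing.** Two events of each of the five types, one event
  per gene. Each event adds an alternative isoform: shifted donor and/or
  acceptor (9 nt for AltD/AltA, 6 nt on both ends for AltP — both inside the
  spec of compact plant introns), a retained intron, or a skipped internal
  exon. New splice boundaries get canonical dinucleotides written into the
  genome. Half of an AS gene's reads come from the alternative isoform, and
  the generator additionally emits two deterministic junction-spanning reads
  per event per library so that injected truth is observable evidence, not
  just simulated intent — these count toward the library size.
* **Markers.** Six UTR microsatellites (motif length weighted toward di- and
  trinucleotides as seen in real EST collections), eight inter-line
  substitutions and four 1-nt indels, embedded in every library-H read of
  their genes. Indel sites are placed away from homopolymer runs and with
  locally unique bases, so their alignment placement is unambiguous and they
  survive the homopolymer filter — the generator injects variants the filter
  set is *supposed* to keep; the filter's rejection behaviour is tested on
  purpose-built column fixtures instead.
* **Errors.** Each homopolymer run of length ≥ 3 in a read suffers a 1-base
  insertion or deletion with probability 0.01 (equal odds) — the
  characteristic 454 error mode the SNP filters target. A single integer
  seed drives one RNG stream with sub-stages drawn in a fixed order, so a
  fixed seed reproduces the fixture byte for byte; library sampling takes a
  separate documented seed so several library realisations can share one
  genome.

What the generator does **not** emulate: flowgram-level base calling,
quality scores, vector/chimeric reads, paralogy, assembly artefacts, and 3'
sampling bias. Tests passing on this fixture therefore demonstrate the
correctness of the pipeline's logic under its stated assumptions, not its
robustness to every failure mode of real 454 data.

# Gene regions and the spliced aligner

Gene regions extend each gene by up to 1,000 nt beyond the translation start
and stop (gene bounds when no CDS is annotated), clipped at chromosome ends.
When two neighbours' full flanks would overlap, each is truncated at the
midpoint of the intergenic gap — the no-overlap constraint fixes *that*
regions must not collide, and the midpoint is the symmetric resolution.
Construction is idempotent and order-independent.

The aligner is a minimal splice-aware chain aligner built for this read
class (short, high-identity, few junctions), not a production DP aligner:

* exact k-mer anchors (k = 15) against a dense genome index, query k-mers
  sampled every 3 nt; k-mers with more than 20 genomic hits are skipped as
  repeats;
* same-diagonal anchors merge into blocks (gaps ≤ 30 nt bridge isolated
  substitutions), blocks chain collinearly by dynamic programming maximising
  aligned query length;
* an inter-block genomic gap of 40–10,000 nt is an intron; smaller
  diagonal shifts are indels. Junction placement searches ±10 nt around the
  anchor boundary, accepts only placements consistent with the read bases,
  prefers canonical GT..AG (or CT..AC on the other strand) dinucleotides,
  and breaks remaining ties deterministically (smallest shift, then
  leftmost). Indel gaps are placed leftmost;
* both read orientations are tried; the acceptance rule is identity ≥ 0.95
  and query coverage ≥ 0.80, with identity measured over aligned columns
  including indel columns and coverage over the read. The 80% coverage rule
  is applied to the query (the EST being aligned), the natural reading for
  single-pass reads.

`read_alignments()` ingests externally produced PSL or GFF3
(`match`/`match_part`) spliced alignments into the same representation and
applies the same acceptance rule, so the downstream modules are agnostic to
the aligner. `assign_to_gene()` resolves multi-gene candidates by identity ×
coverage, then aligned length, then lexicographic gene id — fully
deterministic.

Anchor k, the intron bounds, the shift window and the repeat cap are
declared package constants (`align_params()`), chosen for compact plant
genes and the fixture's scale; none is claimed to be optimal for other read
classes.

# Junctions and event classification

A junction is a distinct (gene, intron interval) with support counted in
distinct ESTs; junctions with fewer than 8 aligned nt on either flank are
discarded (guarding against spurious terminal gaps), and a configurable
support threshold (default 1) is available — on error-containing libraries,
raising it to 2 removes essentially all junctions created by isolated
homopolymer errors, at no cost to the injected truth, whose junctions carry
much higher support.

Classification works on the union of annotated introns and EST-derived
junctions, because the comparison of interest is EST evidence against the
gene models. The five types are assigned with an explicit precedence that
makes classification a function:

1. **ExonS**: introns `j1`, `j2` (disjoint) plus a long intron sharing
   `j1`'s start and `j2`'s end; the two side pairs of the triple are
   consumed so a skipping event is not double-reported as AltA + AltD.
2. **AltD / AltA**: overlapping introns sharing exactly one boundary;
   donor/acceptor are defined relative to the gene strand, so the same
   coordinate pattern swaps labels between strands.
3. **AltP**: overlapping introns sharing neither boundary, not part of a
   skipping triple.
4. **IntronR** (orthogonal to the pair logic): an intron for which some
   EST's contiguous aligned stretch covers the intron plus 8 nt beyond both
   boundaries — the margin distinguishes genuine retention from alignment
   truncation at the junction.

These operational definitions are declared, not inferred: the original
analysis used an unpublished script, and any reimplementation must fix the
ambiguous cases somehow. The precedence chosen makes the most specific
pattern (the two-boundary ExonS match) win.

# Digital expression

For a gene with counts \(x_j\) in libraries of sizes \(N_j\), the R
statistic is

\[ R = \sum_j x_j \ln \frac{x_j}{N_j f}, \qquad f = \frac{\sum_j x_j}{\sum_j N_j}, \]

the log-likelihood ratio of library-specific Poisson rates against a pooled
rate (\(0\ln 0 = 0\); genes with zero total count carry no evidence and are
excluded). The suite verifies \(R\) against direct numeric maximisation of
the two likelihoods to \(10^{-9}\).

The original analysis reports converting R to p-values without stating how;
here the default is the asymptotic \(\chi^2_{m-1}\) tail of \(2R\), with a
Monte-Carlo alternative (multinomial redistribution of the gene's total
across libraries, \((r+1)/(n+1)\) estimator) that agrees with the
\(\chi^2\) within Monte-Carlo error at moderate counts. q-values are BH by
default; a fixed-\(\lambda\) (0.5, no smoother) Storey variant multiplies BH
by \(\hat\pi_0\) and is exactly BH when \(\hat\pi_0 = 1\).

Fold changes use a +1 pseudocount on the raw counts before normalisation —
the original rule ("fold change greater than two") is silent on zero-count
genes, which plainly occur in single-run libraries, and the pseudocount
keeps them finite without changing calls at moderate counts. A gene is DE
iff fold > 2 and q < 0.05. Direction names the library with the higher
pseudocounted rate; exact ties resolve to the lexicographically smaller
library tag so column order never matters.

On null count simulations (2,000 genes, no injected DE) the fold filter plus
q threshold yields a DE-call fraction far below 0.05; on the read-level
fixture with fold-4 genes and expected counts ≥ 20 per library, sensitivity
and precision are high (the acceptance suite requires ≥ 0.8 / ≥ 0.9 over ten
library realisations).

# SSR mining

The scanner reports all maximal perfect tandem repeats of primitive 2–6 nt
motifs meeting the thresholds (di ≥ 6 repeats, tri–hexa ≥ 5), implemented as
anchored back-reference regular expressions and verified exactly against an
independent run-length enumerator on hundreds of random sequences with
planted repeats. Mononucleotide repeats are never reported — they are
indistinguishable from the platform's homopolymer errors. `N` breaks a
repeat (conservative for marker design). Where a stretch satisfies two motif
lengths, the shorter primitive motif wins, matching MISA's behaviour.
Compound SSRs chain transitively at interruptions ≤ 100 bp. Motif classes
are canonicalized to the lexicographic minimum over cyclic rotations of the
motif and its reverse complement (the familiar "AAG/CTT" grouping), which is
idempotent and strand-invariant.

Flanking sufficiency for primer design is a declared stand-in: ≥ 50 non-N nt
on both sides, configurable. The original study's criterion behind its
"sufficient flanking sequence" fraction is unstated; any threshold
reproduces the rule's shape but not its number. Primer design itself is
delegated (out of scope).

# SNP filtering

`pileup_columns()` is a transparent column caller: every aligned base is
tallied per genomic position and line, alignment deletions contribute gap
alleles, and read insertions create extra columns keyed by their left
flanking base, at which spanning reads without the insertion count as gaps.
It replaces a Bayesian caller deliberately: the analysis's own contribution
is the *filter set*, which is what is implemented and tested. Candidate
sites (≥ 2 alleles in the line union) then face three filters, each
recorded separately:

1. coverage ≥ 2 per line at the site;
2. indel sites rejected when a homopolymer run of length ≥ 3 in the
   consensus overlaps the window [pos−1, pos+1] — "surrounded by" is not
   operationalized in the source, so the window and the run measurement
   (on the consensus, including the affected base) are declared here, and
   the window is the narrowest reading that still catches runs adjacent to
   the call;
3. the two lines' allele sets must be disjoint; an optional stricter mode
   additionally demands within-line fixation (off by default — the lines
   are near-isogenic, but disjointness is all the stated rule requires).

Non-indel candidates with more than two alleles are rejected because the
transition/transversion dichotomy is defined for biallelic sites. Passing
records partition exactly into transitions, transversions and indels.

# Gene Ontology slims and enrichment

A minimal OBO parser (terms, `is_a` and `part_of` edges, obsolete terms
dropped with a logged count) feeds two operations. Slim mapping returns the
*minimal* slim ancestors: slim terms reachable from the input by at least
one path containing no other slim term — verified against exhaustive path
enumeration on a toy DAG, including the case of two slim ancestors on
independent paths. Slim classification counts a gene once per slim term.

Enrichment propagates annotations to ancestors (true-path rule), then tests
each term with the exact hypergeometric upper tail; BH is the default
adjustment (Bonferroni available) and a term is enriched iff the adjusted p
is below 0.05. The background population is the caller's choice; the
pipeline's natural default is the expressed set (genes with ≥ 1 assigned
read). The original tables' p-values are not numerically targetable because
that study's background set and adjustment are unstated.

# Numerical and engineering choices

* **Coordinates** are 1-based inclusive everywhere (the GFF3/Bioconductor
  convention), including in all I/O; there is no second internal convention
  to convert to.
* **Determinism**: every tie in every operation has a documented break
  (lexicographic gene ids, leftmost gaps, smallest junction shifts,
  smallest library tag), so identical inputs give identical outputs.
* **Problem sizes**: the bundled study runs at 60 genes × 4,000 reads, and
  the statistical acceptance checks use 50-gene fixtures over 5–10 library
  realisations and 2,000-gene count-level nulls — sizes at which every
  distributional claim the package makes is testable in minutes on a
  laptop, while preserving the structure (multi-exon genes, two libraries,
  error model) of the full-scale study.
* **Degenerate inputs**: empty truth tables round-trip as header-only
  files; genes with zero counts are excluded from testing rather than given
  fabricated p-values; empty junction sets yield `NaN` concordance rather
  than a silent 0 or 1.

# Known limitations

The chain aligner assumes high-identity reads and will not recover
alignments below ~90% identity (irrelevant under the 95% acceptance rule but
a real limitation for cross-species use). Junction placement can in
principle be fooled when an exon/intron boundary sits inside a long exact
repeat with a competing canonical dinucleotide — not observed on the
fixture, but not provably impossible. The SNP caller has no quality
weighting and no paralog disambiguation beyond the disjointness filter. The
enrichment module corrects for multiple testing but not for the correlation
between nested GO terms.
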