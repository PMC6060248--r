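---
title: "Methods: comparative T4aP gene-cluster architecture analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative T4aP gene-cluster architecture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Type IVa pili (T4aP) are retractile surface filaments whose machinery —
the major pilin PilA, the assembly/retraction ATPases PilB/PilT, the
platform PilC, the prepilin peptidase PilD, the alignment subcomplex
PilMNOP and the secretin PilQ, plus minor pilins and regulators — spans the
bacterial cell envelope.  Across bacteria these genes occur in two starkly
different genomic arrangements: one large chromosomal cluster carrying most
of the machinery (in *Myxococcus xanthus*, 17 T4aP genes form a single
locus), or genes dispersed around the chromosome with only the *pilMNOPQ*
alignment-subcomplex genes contiguous.  pilarch implements a reusable,
tested pipeline around that dichotomy: identify T4aP homologs in annotated
genomes, group them into positional clusters, classify the architecture,
call each genome clustered or dispersed, test the conserved riboflavin
kinase (*ribF*) synteny anchor downstream of *pilB*, compute PilA sequence
diagnostics, and test phylogenetic monophyly of cluster-resident homologs.

Because real comparative cohorts require genome downloads and curation that
are out of scope here, the package ships a first-class synthetic-genome
generator that plants known architectures, so every stage can be validated
against ground truth.

## Homolog identification

Each translated gene is aligned against a reference panel (one or two
reference sequences per family, plus decoys) by Smith–Waterman local
alignment under BLOSUM62 with affine gaps (open 11, extend 1; a gap of
length L costs `11 + L`).  Alignment itself is delegated to
`Biostrings::pairwiseAlignment`; panels are small, so exact dynamic
programming is affordable and removes any external-binary dependency.

A hit is retained only if it passes **all three** filters:

* **E-value ≤ 1e-5.**  We use the deliberately simplified model
  `E = m · n · 2^(-S)` with `S` a bit score obtained by scaling the raw
  Smith–Waterman score by 0.5 (configurable).  Fitting Karlin–Altschul
  parameters would change absolute E-values but not the relative cutoff
  behaviour at panel scale, which is all the filter uses.
* **Query coverage ≥ 35%**, computed on the *reference* sequence (the
  queries of the original searches were reference proteins, so coverage is
  reference-relative).
* **Similarity ≥ 35%**, defined as the percentage of alignment columns
  (gaps included) whose residue pair has a positive BLOSUM62 score — the
  standard "positives" reading of similarity.

The winning family per gene is the highest bit score (ties: lower E-value,
then alphabetical family).  Decoy families — synthetic T2SS-like paralogs
derived from the pilB/pilC/pilD ancestors — compete on equal terms but are
never reportable: a gene whose best hit is a decoy is reported UNASSIGNED
with `excluded_as_decoy = TRUE`.  This reproduces, as an automatic rule,
the manual removal of type II secretion machinery proteins that such
surveys require, T4P and T2SS components being ancient paralogs.

The regulator pair pilR/pilS is detected as one combined family `pilRS`:
both proteins resemble the many other response regulators and histidine
kinases in these genomes, so sequence evidence alone cannot number them.
Numbering into pilR1S1/pilR2S2 is positional, inside detected clusters.

## Cluster detection and architecture

Cluster membership is purely positional and uses `locus_index` (the rank of
a gene on its contig), never nucleotide distance: the field counts
*intervening genes*.  Consecutive family-assigned genes on a contig join
the same cluster when at most `max_gap` unassigned genes lie between them.
`max_gap` defaults to 5 — published cluster diagrams show only small
intervening-gene counts inside loci, but no numeric criterion is standard,
so the parameter is exposed prominently in the configuration.  Strand is
recorded but never affects membership.  The anchor family ribF is never a
cluster member; untranslated and decoy-excluded genes count as gap
occupants.

Architecture strings render a run of k intervening genes as `x` (k = 1) or
`[k]` (k > 1), e.g. `pilW-x-pilY1`; they parse back losslessly.

Clusters are labelled:

* `main` — at least `main_min_size` (10) members covering at least
  `min_core_families` (5) distinct core families.  Clustered-organization
  genomes carry 15+ genes in the main locus while the largest locus of a
  dispersed genome is pilMNOPQ (5 genes), so the defaults sit safely
  between the two regimes.
* `minor_pilin` — two or more members, all from
  {fimU, pilV, pilW, pilX, pilE, pilY1} (e.g. the fimU-pilWVY1X locus and
  the pilW-x-pilY1 remnant).  A lone minor pilin is a singleton, not a
  locus.
* `mnopq` — family set within {pilM, pilN, pilO, pilP, pilQ}, at least 4
  distinct.
* `other` — everything else, including singletons.

The per-genome organization call is `clustered` if any main cluster exists,
`dispersed` if none does but an mnopq cluster exists, else `ambiguous`.
Draft assemblies can cut the main locus across contigs; two clusters on
different contigs, each with ≥ 3 members and disjoint family sets, each
within `edge_window` (5) genes of a contig end, whose pooled members would
qualify as main, are flagged as split candidates and upgrade the call to
`clustered`.

## Synteny and the ribF anchor

For main/mnopq clusters the pipeline extracts the five genes up- and
downstream (`flank_k = 5`, truncated at contig ends) and summarises
per-offset family frequencies across genomes.  Flanking genes are labelled
by family where assigned, otherwise by their free-text product annotation;
no cross-genome orthology inference is attempted.

The anchor test asks whether a riboflavin kinase gene lies immediately
downstream of *pilB* — downstream in pilB's transcription direction, with
at most `anchor_max_intervening` (1) genes between.  Published locus
diagrams draw ribF abutting the cluster, but whether strict adjacency or
mere proximity was required is not stated, so the bound is configurable.
The verdict is strand-consistent: reversing a contig's coordinates and
strands leaves it unchanged.

## PilA diagnostics

* **Cleavage site.**  Prepilins are cleaved by PilD after the glycine of
  the class-III signal-peptide motif; the default motif
  `G[FY][ST]L[ILMV]E` within the first 50 residues is the canonical
  prepilin consensus and is configurable.  The mature sequence starts after
  the glycine (positions are 1-based in this package).
* **N-terminal conservation.**  Mature pilins are aligned and per-column
  modal-residue fractions computed; the headline statistic is the mean over
  the first 60 columns, reflecting the strong conservation of the
  filament-core α-helix against the divergent C-terminal domain.
* **Disulfide-bonded loop (DSL).**  Cysteines in the C-terminal half are
  scanned for the last pair separated by 6–60 residues; the pair is a
  `terminal_dsl` when the downstream Cys lies within 15 residues of the
  C-terminus, `mid_cterm_pair` otherwise (the arrangement described for
  some lineages), `none` without a qualifying pair.  These positional
  defaults are design decisions chosen to separate the two described Cys
  arrangements — the original positions derive from a structure-guided
  alignment not reproduced here — and all are configurable.  "Separation"
  is the index difference between the two Cys.  Classification operates on
  the mature sequence, so it is invariant to the signal peptide.
* **Paralog similarity.**  Pairwise global alignments give symmetric
  identity/similarity matrices (percent of alignment columns), used to read
  off signatures such as tandem duplicates with high mutual similarity.

## Phylogenetics

Full maximum-likelihood inference is out of scope; the monophyly and
congruence questions the pipeline asks are answered by distance methods:

* **Progressive alignment.**  Guide tree from pairwise global-alignment
  identity distances (average linkage); profiles merged leaf-to-root by
  profile–profile global alignment (expected BLOSUM62 column score, affine
  gaps, end gaps penalised; the dynamic program is a small C++ kernel).
  For two sequences this reduces exactly to the optimal pairwise global
  alignment.  This is a deterministic, desk-scale stand-in for a full MSA
  program — adequate for the conservation and distance summaries built on
  it, and a documented fidelity trade-off.
* **Distances.**  p-distances over shared ungapped columns with Poisson
  correction `d = -ln(1 - p)` for proteins (JC69 for nucleotide input);
  saturated pairs raise an error naming the pair.  An N-terminal-only
  pilin phylogeny is a column-range restriction (default first 60 mature
  columns) applied before distance computation.
* **Trees.**  Saitou–Nei neighbor joining (`ape::nj`); additive matrices
  are reproduced exactly; negative branch lengths (an NJ artefact on
  non-additive input) are clamped to zero.
* **Bootstrap.**  Columns are resampled with replacement; support of an
  internal edge is the percentage of replicate NJ trees containing its
  bipartition (100 replicates by default).  All draws come from one seeded
  stream generated up front, so supports depend only on the seed.
  Replicates whose resampled distances saturate are skipped and excluded
  from the denominator.
* **Monophyly.**  A taxon subset is monophyletic iff some edge's
  bipartition isolates exactly the subset; the defining edge's bootstrap
  support is attached.  Singletons and the full set are trivially true.

## The synthetic-genome generator

The generator defines the study conditions; its defaults are fixed, not
tuned:

* **Panel.**  One random ancestor per family: pilins 140–230 aa, pilQ
  600–900 aa, others 200–500 aa, pilRS as a sensor-kinase-like plus a
  response-regulator-like ancestor.  Pilin ancestors carry a signal prefix,
  the prepilin motif, a 54-residue conserved-N region and a variable
  C-terminal domain; pilA additionally carries the planted terminal Cys
  pair (separation 15, second Cys 5 residues from the end).  Decoys are
  pilB/pilC/pilD ancestors mutated to ~50% divergence and accepted only
  when their global identity to the source falls in (35%, 65%), mimicking
  T4P/T2SS paralogy.
* **Genomes.**  Clustered profiles plant the 17-gene main locus (order
  from the packaged layout file, pilB at the anchor-proximal end, ribF
  immediately downstream), two fimU-pilWVY1X loci, one pilW-x-pilY1 locus,
  and scattered singletons (pilD, pilF, pilE, extra pilA paralogs, decoys)
  between runs of background genes.  Dispersed profiles plant a contiguous
  pilMNOPQ and scatter everything else, with ribF unlinked from pilB.
  Background genes (80–160 aa, random composition) carry products from a
  neutral vocabulary so product-token synteny summaries see signal-free
  noise.  Planted loci are separated by at least six background genes —
  comfortably above the default `max_gap` of 5, so distinct loci never
  merge by construction.
* **Mutation model.**  Per-site substitution at the profile divergence
  (pilin N-termini at 0.2×, C-terminal domains at 1.5×, capped at 0.6),
  with BLOSUM62-biased replacements (weight `exp(score/2)`): similarity
  degrades more slowly than identity, as in real proteins, which keeps the
  35% similarity threshold meaningfully different from identity.  New
  cysteines are never introduced and planted Cys and motif positions are
  protected, so DSL ground truth is stable under mutation.  No indels are
  simulated; divergence is a per-site substitution probability (no
  multiple-hit correction at these scales).
* **Fragmentation.**  Draft assemblies are emulated by cutting contigs at
  random intergenic points (Poisson-distributed count), or
  deterministically via `fragment_genome()`.
* **Seeding.**  Panels, genomes and cohorts are bit-reproducible from one
  integer seed.  The genome stream is decoupled from the panel stream by a
  linear-congruential scramble so that a panel and a genome built from the
  same user seed never replay identical draws.

What the generator does **not** emulate — indels and domain rearrangements,
composition bias, gene-calling errors, HGT mosaicism, operon structure —
bounds what green tests show: they validate the pipeline's logic under the
stated model, not its robustness to every artefact of real annotations.

## Problem sizes and numerical choices

The test suite exercises: oracle equivalence of alignment scores on random
peptide pairs (length ≤ 12) against an independently coded dynamic
program (itself validated against exhaustive alignment enumeration at tiny
lengths); cluster detection against a union-find oracle on random contigs
of ≤ 20 genes; monophyly against brute-force bipartition enumeration on
random 10-leaf trees; and planted-architecture recovery over a 100-genome
cohort (50 clustered / 50 dispersed, divergence 0.05–0.35, pilA paralog
counts 1–7, seeds 1..100).  Phylogenetic checks use 8-leaf additive
recovery, clean-split saturation and a two-subfamily pilT scenario with
between-subfamily divergence three times the within-subfamily rate.  These
sizes keep the default test run in the minutes range on one CPU while
covering every code path.

Ties in family assignment are broken deterministically (bit score, then
E-value, then alphabetical family, then reference name); the cluster scan
is a deterministic left-to-right pass, so positional ties cannot arise;
profile-alignment traceback prefers diagonal over vertical over horizontal
moves.  Degenerate inputs — empty genomes, header-only GFF3, genes without
translations, clusters at contig ends, zero or one cysteine, fewer than
two sequences, saturated distances — are handled explicitly and tested.

## Known limitations

* The E-value model is relative, not calibrated; absolute values should
  not be compared with BLAST output.
* The progressive aligner has no iterative refinement; deep or indel-rich
  alignments will be worse than a dedicated MSA program's.
* Neighbor joining with Poisson distances is a stand-in for
  maximum-likelihood inference; branch lengths are not substitution-model
  estimates.
* pilR/pilS resolution is purely positional and assumes the two genes are
  adjacent within the cluster.
* The organization call trusts the supplied gene annotation; it does not
  re-call genes.
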