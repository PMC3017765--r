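---
title: "Methods: gene family architecture analysis with famarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene family architecture analysis with famarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famarch)
```

# Scope

famarch analyses the genomic architecture of a multigene family — the kind of
survey done for insect carboxyl/cholinesterases (CCEs), glutathione
S-transferases or other detoxification families: where the genes sit on
chromosomes, how their intron/exon structures relate, how the family tree
looks, and in which tissues the members are expressed. The package takes a
genome FASTA plus GFF3 gene models and optional EST hit tables and ortholog
maps, and returns intron tables, conserved intron positions, a bootstrap
phylogeny, tandem clusters, microsynteny events and expression summaries.
Because real surveys of this kind rest on curated gene sets that are rarely
redistributable, famarch ships a simulator that generates families with
known truth for every one of those stages; the test suite and the
acceptance script run entirely on simulated or transcribed data.

# Intron architecture

## Phase and coordinates

A splice site is classified by its position relative to codon boundaries:
phase 0 between two codons, phase 1 one base inside the codon in the 3'
direction, phase 2 two bases inside. With `cds_offset` coding nucleotides
upstream of the junction, the phase is `cds_offset mod 3`
(`intronPhase()`).

Intron positions are compared across genes in a shared coordinate system,
the *codon-expanded alignment position*

```
aln_nt_pos = 3 * (column - 1) + phase
```

where `column` is the alignment column of the residue whose codon hosts
(phase 1/2) or follows (phase 0) the junction. This convention is
self-consistent (`aln_nt_pos mod 3 == phase` always holds) and monotone in
`cds_offset` within a gene. Published surveys print alignment positions in
an unstated convention, so printed coordinates are not expected to be
bit-identical to ours; what is comparable is the *grouping* of sites.

Introns that fall after the final aligned residue (inside the stop codon)
have no hosting residue and are excluded from projection with a message.

## Conserved positions

`findConservedSites()` groups projected sites that share a phase and lie
within `toleranceNT` nucleotides (default 3 nt, i.e. one codon of alignment
jitter — the same reasoning that leads surveys to merge sites printed one
position apart). Grouping is single linkage on sorted positions, which is
deterministic and avoids fixed-bin boundary artifacts; because a
single-linkage chain can in principle drift wider than the tolerance, chains
are split at their largest internal gaps until every group spans at most
`toleranceNT`. A gene contributes at most one site per group (the site
closest to the group median is kept). Groups need `minMembers` distinct
genes (default 2) to be reported.

## Internal coordinates

All genomic intervals are 1-based and closed, the GFF3 and IRanges
convention, so disk I/O needs no conversion; BED export converts to 0-based
half-open at the boundary (`writeLociBED()`). Gene models keep exons in
ascending genomic order; transcription order on the minus strand is the
reverse, and donor/acceptor dinucleotides are read on the transcribed
strand, so intron records are invariant under reverse-complementing the
chromosome and flipping the features.

Terminal stop codons are part of the CDS on disk but trimmed from the
protein (`no.init.codon` translation is used so a non-ATG first codon is
translated literally rather than as an initiator methionine). Models whose
CDS length is not a multiple of 3 are flagged `incomplete_cds` and excluded
from the alignment/phase analysis by default; non-canonical (non-GT/AG)
splice sites are flagged, never dropped — junction positions come from the
gene models, the GT/AG rule is used to validate them. When one gene has
several transcripts the longest CDS is kept (disable with
`collapse = FALSE`).

# Alignment

External alignments (ClustalW, MAFFT, …) are first-class input via
`readAlignedFasta()` and are the recommended coordinate frame for large
families. The built-in aligner exists so that the package and its tests
have no external dependency: global Needleman–Wunsch with affine gaps
(Gotoh's three-state recursion, implemented in C++), default BLOSUM62 with
gap open −10 and extension −0.5 per additional gap position. A gap run of
length *k* costs `open + (k-1) * ext`. Traceback ties prefer diagonal, then
up, then left, making results deterministic. `progressiveAlignment()`
builds a neighbor-joining guide tree on 3-mer distances and merges profiles
in guide-tree postorder; profile columns are scored by frequency-weighted
substitution scores with gap mass contributing zero. No iterative
refinement is attempted — reproducing any specific external aligner's output
is a non-goal.

# Phylogeny

Distances are maximum-likelihood divergence times under the JTT
(Jones–Taylor–Thornton 1992) amino-acid replacement model: for each pair,
the count matrix of aligned residue pairs over shared (pairwise-deletion)
columns is fitted by a bounded Brent search of t in (0, 10] maximising
`sum N_ij log P_ij(t)` (tolerance 1e-6). The JTT exchangeabilities and
equilibrium frequencies are embedded as published constants; P(t) comes
from the eigendecomposition of the symmetrised generator. Pairs with no
shared columns are an error; pairs whose likelihood keeps rising at the
bound are capped at 10 and flagged saturated (with a warning), never
silently altered. No rate heterogeneity across sites is modelled.

Trees are built by Saitou–Nei neighbor joining. Negative branch lengths are
clamped to zero with the deficit moved to the adjacent branch so path
lengths are preserved. An all-zero distance matrix carries no information
and yields a star tree — this is what makes "identical sequences have no
supported clades" hold exactly. Minimum-evolution refinement
(`meRefine()`) is a nearest-neighbor-interchange hill climb minimising the
total tree length under non-negative OLS branch fitting; it returns the
input tree untouched when no interchange shortens it. This is an
approximation to the CNI search of classic ME software, so topology
identity with any particular program is not claimed.

Bootstrap support resamples alignment columns with replacement, rebuilds
the JTT distance matrix and NJ tree per replicate, and scores each internal
edge by the percentage of replicates containing the same leaf bipartition
(500 replicates by default, the conventional setting; a single integer seed
makes runs reproducible). `flagSupportedClades()` returns clades with
support strictly above the threshold, default 50 — the usual flagging
convention in family surveys.

# Chromosomal clusters and microsynteny

Two family genes chain into a tandem cluster when they lie on the same
chromosome and at most `maxInterlopers` non-family genes sit between them
(default 1, matching reported tandem arrays that harbour a single unrelated
gene). When the locus table carries no non-family annotation the rule falls
back to a genomic gap of at most `maxGapBP` (default 100 kb, a generous
tandem-duplication scale). Clusters record member order and strand pattern;
with chromosome lengths supplied, the relative distance of the cluster
midpoint to the nearer chromosome end is reported instead of any
categorical "telomeric" call, since assembly landmarks are rarely
available.

`compareSynteny()` contrasts two species' ortholog maps directly:
copy-number differences give duplications/losses; a chromosome of A whose
shared groups land on two or more chromosomes of B is a split; two or more
A chromosomes converging on one B chromosome is a fusion; a bijective
chromosome-to-chromosome match with equal copy numbers is conserved. One
shared group alone can never witness a split or fusion. This is a direct
partition comparison, not a minimal-rearrangement (DCJ/breakpoint) solver;
by construction splits of B relative to A are fusions of A relative to B.
The package does not decide orthology — weak homologs flagged by position
only should be assessed by the user.

# EST expression

`tabulateEST()` counts clone records per gene and tissue, keeping
zero-count family genes. The clone-frequency summary uses singleton bins
0–14 and an open ">15" bin, mirroring the layout of published CCE surveys;
that layout has no bin for exactly 15 clones, so a total of 15 is counted
in ">15". Clade/tissue association reports the fraction of clade members
expressed in a tissue; the optional Fisher-exact/Benjamini–Hochberg
enrichment layer is an explicit extension beyond descriptive EST
tabulation, off by default, since single-pass EST counts without library
normalisation support only coarse statements. Two transcribed summary
tables from a published survey of the 69 silkworm CCE genes ship in
`inst/extdata/` as worked-example fixtures (`estSummaryTables()`).

# The simulator

`simulateFamily()` generates: a Yule tree (`ape::rphylo`) rescaled so the
mean root-to-tip depth equals `branchScale` (default 0.5 expected
substitutions/site — an old, diverse family); an ancestral protein drawn
from JTT equilibrium (550 residues, a typical esterase length); JTT
substitutions along each branch; whole-codon indels (per-residue
probability 0.005 per branch, lengths 1–3) so residue homology, and with it
the intron-site truth, stays well defined without frameshift bookkeeping;
ancestral introns anchored to root residues with offsets spaced more than
3 nt apart so truth groups cannot collide, inherited minus per-branch
losses plus Poisson gains at uniform positions excluding 3 nt around
existing introns; uniform intron lengths (68–2000 nt; 68 nt is the shortest
intron reported in the silkworm CCE family) with GT..AG ends, a configurable
fraction GC..AG; back-translation with uniform synonymous codons plus a TAA
stop; chromosome layouts from `clusterSpec` (default one six-gene
same-orientation array containing one interloper and one four-gene array,
the two published cluster shapes), remaining genes placed as singletons
insulated by two interlopers; and EST clone counts per gene from a negative
binomial (mean 5, dispersion 0.5 — many silent genes, a few clone-rich
ones) spread over tissues by a Dirichlet-multinomial with concentration 0.5
(strongly tissue-biased).

Homology bookkeeping uses *position keys*: root residues carry keys 1..L,
insertions draw fresh real-valued keys uniformly inside the host interval,
deletions remove keys. The true alignment is the column-sorted union of
tip keys; an intron anchored to a deleted residue is lost in that lineage.
One RNG stream is seeded once and consumed in a fixed order (tree,
sequences and indels, introns, back-translation, splice sites, layout,
EST), so equal seed and configuration give byte-identical output files.

What the simulator does *not* emulate: realistic base composition or codon
usage, selection (dN/dS), alternative splicing, intron sequence motifs
beyond the terminal dinucleotides, assembly gaps, or EST library-depth
differences. Passing the synthetic checks therefore validates the
machinery — coordinate arithmetic, projection, grouping, tree building,
tabulation — not the biological realism of any particular genome.

## Problem sizes used by the checks

The acceptance checks run, per seed: conserved-site recovery on 50-gene
families with 5 ancestral introns (lossless exact recovery through the full
FASTA/GFF3 round trip; per-branch loss 0.2 over 20 seeds against a 99%
Monte-Carlo envelope of the loss process on each seed's true tree — survivor
counts of introns sharing branches are not binomial, so the envelope is
simulated rather than taken from a closed form); neighbor-joining recovery
on 100 random 8-taxon additive matrices; JTT distance recovery from 100
pairs of length 500 at t in {0.1, 0.5, 1.0}; and 500-replicate bootstraps on
8-taxon two-clade families (internal branch 0.5 substitutions/site, 300
columns) over 10 seeds. These sizes give stable statistics while keeping a
full run in the minutes range on one core.

# Design choices that were genuinely open

* **Pipeline coordinate frame.** The intron-projection frame is whatever
  alignment the user supplies; the pipeline uses the built-in aligner only
  when none is given. The simulator's true alignment is used by the
  acceptance checks — recovering the alignment itself is the aligner's
  test, not the projection's.
* **Splice-variant counting.** How a survey counts introns of splice
  variants sharing a locus is ambiguous; famarch counts one transcript per
  gene (longest CDS) by default and leaves variant-level analysis to
  `collapse = FALSE`.
* **Star trees for zero signal.** NJ on an all-zero matrix is arbitrary
  under tie-breaking; returning an explicit multifurcation makes "no
  information" visible instead of fabricating a resolved topology.
* **Envelope instead of per-draw bounds.** Because a 99% envelope is
  expected to miss about 1% of draws, the recovery checks require at least
  95% of observed counts inside, rather than all of them.

# Limitations

* The ME search is a local NNI hill climb; for families with weak signal it
  can stop short of the global minimum-evolution tree.
* JTT without rate heterogeneity underestimates distances for strongly
  heterogeneous proteins; distances are capped at 10 substitutions/site.
* Microsynteny events are descriptive partition contrasts; reconstructing
  event order or counts parsimoniously is out of scope.
* EST counts are used as-is; without library sizes no normalisation or
  quantitative expression comparison is attempted.
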