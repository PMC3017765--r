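# famarch

Comparative genomic analysis of multigene families, built for surveys of the
kind done on insect carboxyl/cholinesterases (CCEs): families of tens of
paralogs whose intron/exon architecture, chromosomal clustering, phylogeny
and tissue expression together tell the story of how the family expanded.

Given a genome (FASTA) and gene models (GFF3), famarch:

* extracts every intron with GT/AG splice-site validation and classifies its
  **phase** — 0 between codons, 1 or 2 that many bases inside the codon
  (`phase = cds_offset mod 3`);
* projects intron positions onto a protein multiple alignment
  (`aln_nt_pos = 3 (column − 1) + phase`) and finds **conserved intron
  positions** shared by two or more family members at the same phase, the
  classic evidence that introns predate the family's radiation;
* estimates **maximum-likelihood JTT distances** per pair (Brent search of
  t maximising Σ N<sub>ij</sub> log P<sub>ij</sub>(t) over shared columns),
  builds Saitou–Nei **neighbor-joining** trees, refines them toward
  **minimum evolution** by NNI over OLS branch lengths, and attaches
  **bootstrap support** (column resampling, 500 replicates by default);
* detects **tandem gene clusters** on chromosomes (chaining family loci with
  at most one interloping non-family gene by default) and checks their
  concordance with supported clades;
* infers **microsynteny events** between two species' ortholog maps —
  duplication, loss, split, fusion, conserved — by direct partition
  comparison;
* tabulates **EST clone counts** per gene and tissue, with clone-frequency
  and per-tissue summaries in the layout used by published CCE surveys.

Every stage is testable without external data: `simulateFamily()` evolves a
family along a known Yule tree under the JTT model with codon-aligned
indels, intron loss/gain, planted splice sites, tandem-cluster layouts and
tissue-biased EST counts, and returns the full ground truth next to standard
FASTA/GFF3/TSV files.

## Worked example

```r
library(famarch)

cfg <- simulationConfig(seed = 42, nGenes = 12, proteinLength = 300,
                        nTissues = 6)
dir <- file.path(tempdir(), "readme")
sim <- simulateFamily(cfg, outDir = dir)   # writes FASTA/GFF3/TSVs + truth

genome  <- readGenome(file.path(dir, "genome.fasta"))
models  <- readGeneModels(file.path(dir, "genes.gff3"), genome)
introns <- extractIntrons(models, genome)
aln     <- readAlignedFasta(file.path(dir, "truth_alignment.fasta"))
groups  <- findConservedSites(projectIntrons(introns, aln))
head(groups[, c("canonical_pos", "phase", "n_members")], 4)
#>   canonical_pos phase n_members
#> 1           742     1        12
#> 2           704     2        11
#> 3           801     0        11
#> 4           868     1        11
```

The family carries 72 introns (mean length 1032 nt here); the top conserved
site is a phase-1 intron at codon-expanded alignment position 742 present in
all 12 genes — an ancestral intron that survived in every lineage — while the
next three sites each lost one member.

```r
tree   <- bootstrapSupport(aln, nReps = 500, seed = 42)
clades <- flagSupportedClades(tree, threshold = 50)
length(clades)
#> [1] 8

detectClusters(readLoci(file.path(dir, "loci.tsv")))[
  , c("chrom", "n_members", "orientation_pattern", "n_interlopers")]
#>   chrom n_members orientation_pattern n_interlopers
#> 1  chr1         6              ++++++             1
#> 2  chr2         4                ---+             0
```

Eight bipartitions exceed 50% bootstrap support, and the two simulated
tandem arrays are recovered: a six-gene same-orientation cluster harbouring
one unrelated gene, and a mixed-orientation four-gene cluster.

```r
toy <- syntenyToyMaps()   # a neuroligin-like two-species layout
compareSynteny(toy$A, toy$B)[, c("kind", "groups")]
#>          kind              groups
#> 1 duplication                Nlg4
#> 2       split Nlg1,Nlg3,Nlg4,Nlg5
#> 3      fusion           Nlg2,Nlg5
```

Species B duplicated Nlg4, separated Nlg5 from the Nlg1/3/4 segment, and
fused it with the Nlg2 segment — the three rearrangement events this toy map
was built to illustrate.

Bundled in `inst/extdata/` (loaded by `estSummaryTables()`) are two
transcribed summary tables from a published EST survey of the 69 silkworm
CCE genes: 354 clones over 16 tissues, 47 genes with at least one clone, the
midgut the largest library with 104 clones from 23 genes.

A thin command-line front end with `simulate`, `introns`, `align`, `phylo`,
`map-sites`, `clusters`, `synteny`, `express` and `all` subcommands ships at
`inst/scripts/famarch-cli.R`; `runPipeline()` is the same orchestration as a
single R call driven by a YAML/JSON config.

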