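# synterna

Positional conservation analysis of plant long non-coding RNAs (lncRNAs).

## The problem

Plant lncRNAs (transcripts ≥ 200 nt with no ORF of ≥ 100 amino acids)
mutate at roughly intronic rates, so their sequences diverge beyond
recognition between related plant families even when the loci themselves
stay functional. A lncRNA that regulates its neighbouring gene can instead
be conserved *positionally*: the same locus next to the same orthologous
anchor gene, in the same relative orientation (upstream, downstream, or as
a natural antisense transcript). `synterna` is for comparative genomicists
who want to quantify that pattern across a set of annotated genomes and
transcriptomes: it finds lncRNA candidates, categorizes them
(LincRNA ≥ 500 bp from the nearest protein-coding gene, gene-associated
transcriptional units within 500 bp, antisense-overlapping NATs), clusters
them across species and labels lineage specificity, and then asks — through
anchor-gene synteny — whether a lineage-specific lncRNA has a counterpart
at the corresponding position in the other lineages.

## What is inside

| Stage | Core idea |
|---|---|
| `scanOrfs`, `isLncCandidate` | six-frame ORF scan, strict ATG, 200 nt / 100 aa filter |
| `locateTranscript`, `classifyLnc` | single-HSP ≥ 50 % coverage localization; NAT > GATU > LINC categories |
| `searchHits`, `smithWaterman` | 11-mer seeded local aligner with exact affine Smith–Waterman windows; Karlin–Altschul e-values |
| `buildRbhGraph`, `markovCluster`, `assignLineageSpecificity` | reciprocal-best-hit graph, MCL at ≥ 10/20/50 % identity-of-query cutoffs, lineage labels |
| `buildGeneOrder`, `chainAnchors`, `projectRegion` | collinear anchor chaining (rank-space DP, both orientations), region projection |
| `positionalCall`, `summarizePositional`, `telomereProximity` | the positional-conservation verdict, per-lineage summaries, distance to chromosome ends (2.5 Mb rule) |
| `foldNussinov`, `foldEnergy`, `classifyStability` | base-pair maximization and reduced nearest-neighbour MFE folding; −30/−80 kcal/mol stability contexts |
| `simulateCohort`, `writeCohort`, `scoreRecovery` | multi-lineage synthetic genomes with planted `sequence_conserved` / `positional_only` / `private` lncRNAs and recorded truth |

Standard formats throughout: FASTA and GFF3 in, BED6 / outfmt-6 TSV /
Vienna / JSON out. Containers are Bioconductor-native (`DNAStringSet`,
`GRanges` with `Seqinfo`).

## Worked example

```r
library(synterna)
cohort <- simulateCohort(simConfig(seed = 42))   # 3 lineages, 7 species,
report <- runPipeline(cohort)                    # 200 genes, 30 planted lncRNAs
report
#> synterna run report
#>   transcripts: 1564 | lncRNA candidates: 287
#>   clusters per cutoff: 10% = 122, 20% = 126, 50% = 126
#>   lineage-specific loci: 55 | positionally conserved: 28
#>       lineage n_lineage_specific n_positionally_conserved pct_positional
#>  Aethionemeae                 19                       10       52.63158
#>  Brassicaceae                 21                       10       47.61905
#>    Cleomaceae                 15                        8       53.33333
```

Reading: of the clusters that look lineage-specific at the 50 % nucleotide
identity cutoff, about half sit at a syntenic position occupied by a
lncRNA with the same anchor-relative direction in another lineage — these
are the "sequence-diverged, positionally conserved" loci. Against the
generator's recorded truth:

```r
scoreRecovery(report, cohort)
#> $positional_sensitivity           [1] 1
#> $positional_precision             [1] 1
#> $private_fp_rate                  [1] 0
#> $sequence_conserved_sensitivity   [1] 0.9
```

All ten planted positional-only loci are recovered with no false positives
from the planted private loci; nine of ten sequence-conserved loci cluster
across all lineages (the tenth lost its Cleomaceae copies to the coding
filter after lineage mutation created a long ORF).

See `vignettes/positional-conservation.Rmd` for the model, every tunable
parameter, and what the synthetic benchmark does and does not demonstrate.

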