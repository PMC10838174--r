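# mitocomp

Descriptive and comparative statistics for annotated animal mitochondrial
genomes, written for the workflow behind a mitogenome description paper:
you have a circular ~15 kb genome with 13 protein-coding genes (PCGs),
22 tRNAs and two rRNAs, and you need the standard battery of numbers —
base composition and strand skews, codon usage, gene overlaps and spacers,
selection pressure per gene, tRNA architecture — recomputed reproducibly
from the sequence and coordinates rather than assembled by hand. The
worked examples throughout use the mitogenome of the brown soft scale
*Coccus hesperidum* (Hemiptera, Coccidae; GenBank OR167606), whose
published annotation and summary tables ship with the package as input
data.

## What it computes

* **Composition and skews.** For any region (a gene's coding strand, a
  gene-class concatenation, or the whole plus strand): percentages of
  A/T/G/C, A+T content, and the strand-asymmetry statistics
  AT-skew = (A − T)/(A + T) and GC-skew = (G − C)/(G + C).
* **Codon usage.** Codon extraction under a selectable NCBI genetic code
  (default table 5, invertebrate mitochondrial, where ATA = Met,
  TGA = Trp and AGA/AGG join an 8-codon serine family), start-codon and
  stop-token calls including the incomplete stops ("T"/"TA") completed by
  polyadenylation, and relative synonymous codon usage
  RSCU(c) = count(c) · |F| / Σ<sub>F</sub> count for each synonym family
  F, with stop codons as their own 2-member family and fractional counts
  supported.
* **Gene architecture.** Intergenic lengths between consecutive genes on
  the circular molecule (start(next) − end(prev) − 1; negative values are
  overlaps), overlap/spacer enumeration, and the largest unannotated span
  (the putative control region).
* **Ka/Ks.** Pairwise Nei–Gojobori (1986) estimation on codon-aligned CDS:
  per-codon synonymous site fractions, equal-weight averaging over minimal
  substitution pathways, Jukes–Cantor correction
  d = −(3/4)·ln(1 − (4/3)·p), and per-gene means over species pairs.
* **tRNA structure.** Dot-bracket parsing, arm decomposition (acceptor, D,
  anticodon, T), architecture classification (cloverleaf / D-armless /
  T-armless / minimal), discriminator and anticodon extraction, and G-U
  wobble-pair counts.
* **Simulators.** Annotated circular genomes with planted gaps,
  start/stop codons and composition targets; codon pairs diverged at a
  chosen dN/dS; tRNAs with planted architectures — all deterministic under
  a seed, so every analysis stage can be checked against known truth.

## Worked example

```r
library(mitocomp)
gb <- system.file("extdata", "OR167606_synthetic.gb", package = "mitocomp")
genome <- read_genbank(gb)
genome
#> <mito_genome> OR167606_synthetic: 15,566 bp, circular, 37 features
#>   PCG: 13, rRNA: 2, tRNA: 22

rep <- run_genome_report(genome, rounding = "printed")
head(rep$gene_table[, c("gene", "start", "end", "size_bp", "strand",
                        "start_codon", "stop_codon", "intergenic")], 5)
#>    gene start  end size_bp strand start_codon stop_codon intergenic
#> 1  trnM   753  818      66      +        <NA>       <NA>         NA
#> 2  trnW   810  870      61      +        <NA>       <NA>         -9
#> 3  COX1   861 2387    1527      +         ATA        TAA        -10
#> 4 trnL2  2388 2449      62      +        <NA>       <NA>          0
#> 5  COX2  2450 3113     664      +         ATA          T          0
```

The intergenic column is recomputed from the coordinates: trnM/trnW
overlap by 9 bp, trnW/COX1 by 10 bp, and COX2 ends on the incomplete stop
"T". Composition rows are per coding strand; the Total row is the plus
strand:

```r
subset(rep$composition, region %in% c("13 PCGs", "22 tRNAs", "2 rRNAs", "Total"),
       c(region, at_content, at_skew, gc_skew))
#>      region at_content at_skew gc_skew
#> 14  13 PCGs       82.4    0.03   -0.11
#> 15 22 tRNAs       85.4    0.08   -0.12
#> 18  2 rRNAs       86.2   -0.25    0.35
#> 19    Total       83.4    0.22   -0.30

rep$architecture$largest_unannotated
#> $start 14448; $end 752; $length 1871   (the unannotated span wraps the origin)
```

(The sequence in this record is a simulator product carrying the real
annotation — see the file name — so the per-gene composition differs from
the published values while length, architecture, start/stop tokens and
whole-genome composition match.)

RSCU from the published codon counts reproduces the published values, e.g.
the most and least used leucine codons:

```r
counts <- read.delim(system.file("extdata", "coccus_hesperidum_codon_counts.tsv",
                                 package = "mitocomp"))
u <- rscu(setNames(counts$count, counts$codon))
subset(u, codon %in% c("TTA", "CTG"))
#>   aa codon count family_size       rscu
#>   L   CTG     3           6 0.04488778
#>   L   TTA   247           6 3.69576060
```

Ka/Ks on a simulated pair diverged under purifying selection:

```r
pair <- evolve_codon_pair(divergence_spec(500, omega = 0.2, seed = 1))
pairwise_ng86(pair$seqA, pair$seqB)
#> Nei-Gojobori Ka/Ks over 500 codons
#>   S = 374.50, N = 1125.50, Sd = 82.50, Nd = 49.50
#>   Ks = 0.2608, Ka = 0.0453, Ka/Ks = 0.1738
```

A command-line front end with the same capabilities is installed at
`system.file("scripts", "mitocomp", package = "mitocomp")` (subcommands
`stats`, `arch`, `rscu`, `kaks`, `trna`, `simulate`).

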