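---
title: "Methods and design notes for mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

mitocomp recomputes the descriptive statistics that accompany the report
of a newly sequenced animal mitochondrial genome. This vignette documents
the conventions, formulas and design decisions behind each stage, what the
simulators emulate, and where the package deliberately stops.

## The genome model

A `mito_genome` is a single nucleotide string plus an ordered feature
table. All coordinates are 1-based inclusive, the GenBank convention, and
internal arithmetic never converts: conversion happens only at I/O
boundaries. A feature spanning the circular origin is stored with
`start > end` and a `wraps` flag; its size is
`length − start + 1 + end`. Features sort by start coordinate with ties
broken by end coordinate, which is also the order used to define
adjacency. Ambiguity codes in the sequence are preserved verbatim;
downstream modules decide how to treat them.

GenBank flat files are read and written directly (LOCUS topology;
`CDS`/`tRNA`/`rRNA` keys; `complement()` and origin-spanning `join()`
locations; `/gene`, `/product` and `/anticodon` qualifiers). CDS features
map to the PCG class. The reader/writer pair is round-trip exact on every
feature field, and the test suite enforces this. Feature tables use a
plain TSV with columns `gene  start  end  strand  anticodon`; sizes are
always recomputed from coordinates, with a warning when a provided size
column disagrees — published tables occasionally contain transcription
errors, and coordinates are the more primitive datum.

The unannotated remainder of a genome (in most mitogenomes the AT-rich
control region) is deliberately *not* a feature: `largest_unannotated_span()`
reports it positionally, merging uncovered arcs across the origin, without
asserting any biology about it.

## Composition and skews

For a region with base counts A, T, G, C,

* AT-skew = (A − T) / (A + T),
* GC-skew = (G − C) / (G + C),

with an `NA` sentinel (never an error or NaN) when a denominator is zero.
Percentages are computed over unambiguous A/C/G/T only; IUPAC ambiguity
codes are excluded from numerator and denominator and reported separately.
This is the simplest defensible convention and matters only in records
with Ns.

Two conventions are load-bearing and easy to get wrong:

1. **Per-gene composition is computed on the gene's coding strand**
   (reverse-strand genes are reverse-complemented first). In an A-rich
   plus strand, the reverse-strand NADH genes then show T-rich, negative
   AT-skew compositions — the pattern seen in published per-gene tables,
   which is only consistent with coding-strand accounting.
2. **Aggregate rows (e.g. "22 tRNAs") are computed on the concatenation
   of member sequences**, i.e. length-weighted, never by averaging
   percentages. The whole-genome "Total" row uses the deposited plus
   strand.

When a printed table is the comparison target, `rounding = "printed"`
applies round-half-away-from-zero at the printed precision (percentages
1 decimal, skews 2, RSCU 3); internal values stay unrounded.

## Codon usage and RSCU

The genetic code is data, keyed by NCBI translation-table id (5, 2 and 1
are built in; 5, the invertebrate mitochondrial code, is the default).
Synonym families are derived from the table, so under table 5 serine is an
8-codon family (TCN + AGN), leucine 6, and the stops {TAA, TAG} form a
2-member family of their own. For codon c in family F,

RSCU(c) = count(c) × |F| / Σ count over F,

undefined (`NA`) for families with zero total. Stop codons are *included*
in counts and RSCU — published mitogenome codon tables carry `*` rows —
and terminal complete stop codons are counted while 1–2 nt incomplete-stop
fragments ("T"/"TA", completed to TAA by polyadenylation in vivo) are
never counted as codons. Counts may be fractional: under
`ambiguity_policy = "split"` a codon containing ambiguity codes
distributes weight 1/k over its k compatible concrete codons, which is the
plausible mechanism behind the 0.5 entries seen in published tables; the
default policy simply drops such codons. With no ambiguity codes the two
policies coincide exactly.

Conservation identity used in the tests: over all PCGs of an
unambiguous genome, 3 × Σ counts + Σ fragment lengths = Σ PCG lengths.

## Gene architecture

Adjacency is defined on start-coordinate order of the mixed-strand gene
list — the order description tables use — and strand is ignored. For
consecutive genes, intergenic length = start(next) − end(prev) − 1:
negative = overlap, 0 = abutting, positive = spacer. On a circular genome
the final adjacency links the last gene back to the first with gap
(L − end(last)) + (start(first) − 1); it is computed but flagged
(`is_wrap`), since description tables omit it. Pile-ups of three or more
genes are reported only pairwise for consecutive features. Overlap and
spacer lists sort by length descending with coordinate tie-break.

The package always reports counts recomputed from coordinates. For the
reference annotation this recomputation disagrees with the published
intergenic column at exactly one adjacency (trnC→trnI computes to +9 from
the published coordinates themselves), and with the published PCG total by
1 bp; the shipped annotation table carries the published column alongside
the coordinates so the comparison is explicit rather than silently forced.

## Ka/Ks (Nei–Gojobori 1986)

The estimator is the classic counting method, chosen because it is the
Ka/Ks that DnaSP and MEGA report in descriptive mitogenome work and it has
no free parameters to tune:

* Per codon, each position contributes the fraction of its three possible
  single-base changes that are synonymous to the synonymous site count
  (s + n = 3 per codon). Changes *to* stop codons count as nonsynonymous.
* Site counts S and N are averaged over the two sequences.
* Per codon pair differing at d positions, the d! orderings of the
  substitutions are enumerated with equal weights; orderings passing
  through a stop codon are excluded, and if every ordering is blocked all
  are used with stop-crossing steps counted as nonsynonymous (a degenerate
  case that essentially never occurs at realistic divergence).
* p<sub>S</sub> = Sd/S and p<sub>N</sub> = Nd/N are Jukes–Cantor
  corrected, d = −(3/4)·ln(1 − (4/3)·p), with an `NA` sentinel outside the
  log domain (p ≥ 3/4) — never NaN propagation.
* The ratio is `NA` when Ks = 0; per-gene means average the *defined*
  pairwise ratios and report how many pairs were excluded, rather than
  treating undefined ratios as 0 or infinity.

Codons containing gaps, ambiguity codes or stop codons in either sequence
are excluded pairwise. Codon alignments are an input: the package threads
nucleotides onto a user-supplied protein alignment
(`thread_protein_alignment()`) but does not align — alignment software
choices dominate Ka/Ks differences between studies, and reproducing them
is out of scope. For the same reason the published per-gene bar values for
the 16-genome scale-insect comparison are treated as descriptive, not as
targets: they depend on external accessions and unstated alignment and
program settings.

## tRNA structures

Structures are *input* as Vienna dot-bracket strings; the package
classifies, it does not fold. (The folds behind published mitogenome
papers come from external predictors, and re-predicting them would make
the classification untestable.) Parsing is stack-based, so pairs are
properly nested by construction; unbalanced input is rejected with the
position of the offending bracket.

Decomposition walks maximal stacked helices. The exterior helix chain —
helices enclosing all remaining pairs, bulges allowed — is the acceptor
stem. Remaining helices with stems of ≥ 2 bp are arms; the 2 bp threshold
admits the very short T arms (down to 2 bp) seen in reduced mitochondrial
tRNA sets while ignoring incidental 1 bp stacks. With three interior arms
the 5′→3′ assignment is D, anticodon, T (the canonical topology). With
two, the anticodon arm is the one whose loop lies closest to the middle of
the molecule — in both truncated layouts (D-armless and T-armless) the
anticodon loop stays central while the replacement loop sits near an end —
and the other helix is D if 5′ of it, T if 3′. With one, the structure is
the minimal architecture and the helix is the anticodon arm. The
discriminator is the last nucleotide of the unpaired 3′ overhang; the
anticodon is the middle three of the anticodon loop; G-U pairs are counted
over all paired positions, and non-Watson-Crick, non-wobble pairs are
counted as mismatches rather than rejected.

## Simulators and what passing tests mean

All generators are deterministic functions of (spec, seed), each drawing
from a decorrelated stream so adding one generator does not perturb
another's output.

**Genomes.** The default `genome_spec()` mirrors the reference annotation
shipped with the package: 15,566 bp, 37 genes in the reference order,
strand pattern and planted gap list, first gene at 753, A+T 83.4% with
plus-strand AT-skew 0.221 and GC-skew −0.305 — the published study
conditions. Generation places genes by coordinate arithmetic (so planted
gaps are recovered *exactly*), hard-plants each PCG's start codon and stop
token (incomplete stops realised by truncation, i.e. gene length ≡ 1 or
2 mod 3), fills PCG bodies codon-by-codon avoiding in-frame stops, and
samples everything else from strand-aware base probabilities derived from
the composition targets. Because stop avoidance slightly biases
composition, a correction pass flips unconstrained background positions
until each base hits its target count exactly; a rejection loop (capped at
100 attempts, then a warning) guards the ±1 percentage point / ±0.02 skew
contract. A validation pass re-analyses the genome and errors if any
planted codon failed to survive overlap constraints.

**Codon pairs.** `evolve_codon_pair()` applies sequential single-nucleotide
events: proposals uniform over positions and alternative bases, stop-
creating proposals rejected, nonsynonymous proposals accepted with
probability min(1, ω) and synonymous with min(1, 1/ω), so the realised
dN/dS has expectation ω. This acceptance model was chosen over a full
codon-model simulator for transparency: its realised dN/dS is verified by
the NG86 estimator itself (neutral calibration within Monte-Carlo error,
monotonicity across ω ∈ {0.2, 1, 2}). The default divergence is 0.3
events per codon (~0.1 per site), low enough that the Jukes–Cantor
correction is mild. Two caveats are documented rather than fixed: at ω = 0
the *events* are all synonymous but NG86's minimal-pathway counting can
still score a fractional nonsynonymous difference when multiple hits land
in one codon (the serine family makes this reachable), and stop-proposal
rejection removes a small fraction of nonsynonymous proposals, biasing the
neutral estimate a few percent below 1.

**tRNAs.** `generate_trna()` realises exactly the requested arms, makes
stems complementary, and plants an exact number of G-U pairs
(round(fraction × pairs)). The shipped 22-structure panel
(7 cloverleaf / 7 D-armless / 7 T-armless / 1 minimal, arm lengths drawn
from the ranges reported for reduced mitochondrial tRNA sets) is a
simulator product under a fixed seed — see `tools/make_fixtures.R` — as is
the `OR167606_synthetic.gb` record, which carries the real annotation on a
simulated sequence.

What passing tests therefore show: the analysis code recovers planted
architecture, codons and composition exactly, and the estimator recovers
planted ω within simulation error. What they do not show: robustness to
the messiness of real records (nonstandard qualifiers, annotation errors,
heteroplasmy, indel-containing alignments), realistic along-genome
composition heterogeneity, or the behaviour of Ka/Ks under the alignment
choices of any particular study.

## Problem sizes and numerical conventions

The test suite runs the full pipeline on 15.6 kb genomes, the NG86
estimator against an exhaustive pathway oracle on 100 random 200-codon
pairs, and the ω-recovery study at 10 replicates × 500 codons per ω —
sizes chosen so the whole suite completes in well under a minute while
keeping Monte-Carlo error small relative to the tested tolerances
(neutral case within ±0.15 of 1). Printed-table comparisons use
round-half-away-from-zero at the printed precision; one published RSCU
value sits exactly on a half-ulp boundary (count 21 in a 4-fold family of
total 64 gives 1.3125), so published-value checks use half-an-ulp
tolerance at 3 decimals rather than insisting on one rounding convention.
Undefined quantities (zero-denominator skews, zero-total RSCU families,
Ks = 0 ratios, out-of-domain JC distances) are `NA` sentinels throughout,
never exceptions or NaN.

## Known limitations

* GenBank parsing covers the subset of the format mitogenome records use;
  exotic location operators (`order()`, remote accessions) are not
  supported.
* Arm assignment assumes the canonical arm order (D before anticodon
  before T); permuted topologies would be mis-assigned, but none occur in
  mitochondrial tRNAs.
* The Ka/Ks module implements plain NG86; modified-NG, ML codon models
  and site/branch models are explicitly out of scope.
* The simulator evolves point substitutions only: no indels, no
  rearrangements, no along-genome rate variation.
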