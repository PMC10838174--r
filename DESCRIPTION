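Package: mitocomp
Title: Descriptive and Comparative Analysis of Animal Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the descriptive statistics that accompany the report of a
    newly sequenced animal mitochondrial genome: nucleotide composition with
    AT- and GC-skew for whole genomes, single genes and gene-class aggregates;
    relative synonymous codon usage (RSCU) under selectable mitochondrial
    genetic codes; start- and stop-codon determination including incomplete
    stops; overlap and intergenic-spacer architecture on circular genomes;
    pairwise Ka/Ks estimation by the Nei-Gojobori (1986) counting method with
    Jukes-Cantor correction; and classification of tRNA secondary structures
    (cloverleaf, D-armless, T-armless, minimal) from dot-bracket input.  A
    simulator generates annotated circular mitogenomes, codon alignments
    diverged at a known dN/dS, and tRNA structures with planted architectures,
    so every analysis stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
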