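# Regenerates the synthetic fixtures shipped under inst/extdata/.
# Run from the package root with the package installed:
#   Rscript tools/make_fixtures.R
library(mitocomp)

# Synthetic stand-in for the reference GenBank record: the reference gene
# order, coordinates, strands, anticodons and start/stop codons with a
# simulated sequence hitting the published whole-genome composition.
sim <- generate_mitogenome(genome_spec(seed = 20230926L))
g <- sim$genome
g$id <- "OR167606_synthetic"
write_genbank(g, "inst/extdata/OR167606_synthetic.gb")

# 22-structure tRNA panel: 7 cloverleaf, 7 D-armless, 7 T-armless, 1 minimal.
panel <- synthetic_trna_panel(seed = 11L)
write_trna_structures(panel, "inst/extdata/synthetic_trna22.txt")

cat("fixtures written\n")
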