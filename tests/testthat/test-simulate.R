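# Simulator contracts: determinism, planted truth, divergence limits.

test_that("genome generation is deterministic under the seed", {
  a <- generate_mitogenome(genome_spec(seed = 99))
  b <- generate_mitogenome(genome_spec(seed = 99))
  expect_identical(a$genome$sequence, b$genome$sequence)
  c <- generate_mitogenome(genome_spec(seed = 100))
  expect_false(identical(a$genome$sequence, c$genome$sequence))
})

test_that("planted gaps, sizes, starts and stops are recovered exactly", {
  sim <- generate_mitogenome(genome_spec(seed = 15))
  g <- sim$genome
  adj <- adjacency_gaps(g)
  expect_identical(adj$intergenic_length[!adj$is_wrap], sim$truth$gaps)
  expect_identical(g$features$size_bp, sim$truth$size_bp)
  ss <- start_stop_table(g)
  is_pcg <- sim$truth$gene_class == "PCG"
  m <- match(ss$gene, sim$truth$gene[is_pcg])
  expect_identical(ss$start_codon, sim$truth$start_codon[is_pcg][m])
  expect_identical(ss$stop_codon, sim$truth$stop_codon[is_pcg][m])
})

test_that("composition and skew land on the spec targets", {
  sim <- generate_mitogenome(genome_spec(seed = 44))
  comp <- base_composition(sim$genome$sequence)
  expect_lt(abs(comp$at_content / 100 - 0.834), 0.01)
  expect_lt(abs(comp$at_skew - 0.221), 0.02)
})

test_that("an all-zero gap template yields no overlaps and no spacers", {
  tpl <- data.frame(gene = c("g1", "trnA", "g2"),
                    gene_class = c("PCG", "tRNA", "PCG"),
                    size_bp = c(99L, 60L, 150L),
                    strand = c("+", "-", "+"),
                    anticodon = c(NA, "UGC", NA),
                    start_codon = c("ATG", NA, "ATA"),
                    stop_codon = c("TAA", NA, "TAA"),
                    stringsAsFactors = FALSE)
  spec <- genome_spec(template = tpl, gaps = c(0L, 0L), genome_length = 500L,
                      first_gene_start = 10L, seed = 1)
  sim <- generate_mitogenome(spec)
  adj <- adjacency_gaps(sim$genome)
  expect_equal(nrow(overlap_regions(adj)), 0L)
  expect_equal(nrow(spacer_regions(adj)), 0L)
})

test_that("infeasible and inconsistent specs are rejected", {
  tpl <- data.frame(gene = "g1", gene_class = "PCG", size_bp = 300L,
                    strand = "+", anticodon = NA, start_codon = "ATG",
                    stop_codon = "TAA", stringsAsFactors = FALSE)
  expect_error(genome_spec(template = tpl, gaps = integer(0),
                           genome_length = 200L, first_gene_start = 1L),
               "infeasible")
  tpl$stop_codon <- "T"   # inconsistent with size %% 3 == 0
  expect_error(genome_spec(template = tpl, gaps = integer(0),
                           genome_length = 500L, first_gene_start = 1L),
               "inconsistent")
  tpl$stop_codon <- "TAA"
  tpl$start_codon <- "GTG"
  expect_error(genome_spec(template = tpl, gaps = integer(0),
                           genome_length = 500L, first_gene_start = 1L),
               "ATN")
})

test_that("zero divergence returns identical sequences", {
  p <- evolve_codon_pair(divergence_spec(50, omega = 1, subs_per_codon = 0,
                                         seed = 2))
  expect_identical(p$seqA, p$seqB)
})

test_that("omega zero preserves the protein while diverging synonymously", {
  p <- evolve_codon_pair(divergence_spec(200, omega = 0, seed = 6))
  code <- genetic_code(5)
  expect_identical(translate_codons(split_codons(p$seqA)$codons, code),
                   translate_codons(split_codons(p$seqB)$codons, code))
  k <- pairwise_ng86(p$seqA, p$seqB)
  expect_gt(k$Sd, 0)
})

test_that("codon-pair evolution is deterministic and in-frame", {
  a <- evolve_codon_pair(divergence_spec(100, omega = 0.5, seed = 77))
  b <- evolve_codon_pair(divergence_spec(100, omega = 0.5, seed = 77))
  expect_identical(a, b)
  expect_equal(nchar(a$seqB) %% 3, 0)
  # no stop codons introduced
  code <- genetic_code(5)
  expect_false(any(is_stop_codon(split_codons(a$seqB)$codons, code)))
})

test_that("tRNA generation realises the requested arms and is deterministic", {
  x <- generate_trna("cloverleaf", arms = list(acceptor = 6L, d = 3L,
                                               ac = 4L, t = 2L), seed = 4)
  s <- decompose_arms(x$sequence, x$structure)
  expect_equal(s$acceptor_stem_bp, 6L)
  expect_equal(s$d_arm_bp, 3L)
  expect_equal(s$anticodon_arm_bp, 4L)
  expect_equal(s$t_arm_bp, 2L)
  expect_identical(generate_trna("cloverleaf", seed = 4),
                   generate_trna("cloverleaf", seed = 4))
})

test_that("the panel writer and reader round trip", {
  panel <- synthetic_trna_panel(seed = 2)
  expect_length(panel, 22L)
  txt <- write_trna_structures(panel)
  structs <- read_trna_structures(paste(txt, collapse = "\n"))
  expect_equal(vapply(structs, `[[`, character(1), "gene_name"),
               vapply(panel, `[[`, character(1), "name"))
})
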