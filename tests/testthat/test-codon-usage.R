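# Genetic-code tables, codon splitting, start/stop calls, counts and RSCU.

test_that("code tables partition the 64 codons and match the NCBI tables", {
  for (id in c(1, 2, 5)) {
    code <- genetic_code(id)
    expect_equal(sort(unlist(code$families, use.names = FALSE)),
                 sort(names(code$map)))
    expect_equal(unname(code$map[names(bstr_code_map(as.character(id)))]),
                 unname(bstr_code_map(as.character(id))))
  }
  code5 <- genetic_code(5)
  expect_equal(code5$map[["ATA"]], "M")
  expect_equal(code5$map[["TGA"]], "W")
  expect_equal(code5$map[["AGA"]], "S")
  expect_equal(length(code5$families$S), 8L)   # TCN + AGN
  expect_equal(length(code5$families$L), 6L)
  expect_equal(sort(code5$families$`*`), c("TAA", "TAG"))
  expect_error(genetic_code(99), "unknown")
})

test_that("codon splitting separates the incomplete-stop fragment", {
  cds <- strrep("ATA", 221)
  p <- split_codons(paste0(cds, "T"))     # 664 bp, the COX2 layout
  expect_equal(length(p$codons), 221L)
  expect_equal(p$trailing, "T")
  p2 <- split_codons("ATGAAA")
  expect_equal(length(p2$codons), 2L)
  expect_equal(p2$trailing, "")
  expect_error(split_codons("AT"), "shorter")
})

test_that("splitting conserves sequence length on random CDS", {
  for (seed in 1:5) {
    n_extra <- seed %% 3
    cds <- paste0(random_cds(40, bstr_code_map(), seed),
                  substr("TA", 1, n_extra))
    p <- split_codons(cds)
    expect_equal(3 * length(p$codons) + nchar(p$trailing), nchar(cds))
  }
})

test_that("start and stop tokens are identified, including incomplete stops", {
  expect_equal(identify_start_stop("ATAAAATAA"),
               list(start = "ATA", stop = "TAA"))
  expect_equal(identify_start_stop("ATTAAATAG")$stop, "TAG")
  expect_equal(identify_start_stop("ATGAAACCCT")$stop, "T")
  expect_equal(identify_start_stop("ATGAAACCCTA")$stop, "TA")
  expect_equal(identify_start_stop("ATGAAACCC")$stop, "none")
  expect_error(identify_start_stop("ATG"), "shorter")
})

test_that("RSCU reproduces the published worked examples", {
  leu <- rscu(c(TTA = 247, TTG = 47, CTT = 49, CTC = 7, CTA = 48, CTG = 3))
  expect_equal(round(leu$rscu[leu$codon == "TTA"], 3), 3.696)
  expect_equal(round(leu$rscu[leu$codon == "CTG"], 3), 0.045)
  met <- rscu(c(ATA = 463, ATG = 52))
  expect_equal(round(met$rscu[met$codon == "ATA"], 3), 1.798)
  stp <- rscu(c(TAA = 11, TAG = 1))
  expect_equal(round(stp$rscu[stp$codon == "TAA"], 3), 1.833)
  expect_equal(round(stp$rscu[stp$codon == "TAG"], 3), 0.167)
})

test_that("RSCU family sums, uniform counts and scale invariance hold", {
  counts <- stats::setNames(runif(64, 0, 50), names(genetic_code(5)$map))
  tab <- rscu(counts)
  sums <- tapply(tab$rscu, tab$aa, sum)
  sizes <- tapply(tab$family_size, tab$aa, unique)
  expect_equal(as.numeric(sums), as.numeric(sizes))
  tab10 <- rscu(counts * 10)
  expect_equal(tab10$rscu, tab$rscu)
  unif <- rscu(c(TTA = 4, TTG = 4, CTT = 4, CTC = 4, CTA = 4, CTG = 4))
  expect_true(all(unif$rscu[unif$aa == "L"] == 1))
  # zero-total families get NA, not zero
  expect_true(all(is.na(unif$rscu[unif$aa == "K"])))
  expect_error(rscu(c(TTA = -1)), "negative")
  expect_error(rscu(c(XXX = 1)), "unknown codon")
})

test_that("codon counts match a hand count on the toy genome", {
  g <- toy_genome()
  counts <- count_codons(g)
  # g1 = ATG AAA TGA TAA (stop included), g2 = ATA TTT CCC + trailing T
  expect_equal(counts[["ATG"]], 1)
  expect_equal(counts[["AAA"]], 1)
  expect_equal(counts[["TGA"]], 1)
  expect_equal(counts[["TAA"]], 1)
  expect_equal(counts[["ATA"]], 1)
  expect_equal(counts[["TTT"]], 1)
  expect_equal(counts[["CCC"]], 1)
  expect_equal(sum(counts), 7)
  ss <- start_stop_table(g)
  expect_equal(ss$stop_codon, c("TAA", "T"))
})

test_that("count reconciliation: 3 x counts + fragments = total PCG length", {
  sim <- generate_mitogenome(genome_spec(seed = 13))
  g <- sim$genome
  counts <- count_codons(g)
  pcg_len <- sum(g$features$size_bp[g$features$gene_class == "PCG"])
  n_frag <- sum(g$features$size_bp[g$features$gene_class == "PCG"] %% 3)
  expect_equal(3 * sum(counts) + n_frag, pcg_len)
})

test_that("ambiguity policies drop or split fractional weight", {
  seqs <- c(x = "ATGCGYTAA")   # CGY = CGC or CGT
  dropped <- count_codons(seqs)
  expect_equal(dropped[["CGC"]], 0)
  expect_equal(sum(dropped), 2)
  splitc <- count_codons(seqs, ambiguity_policy = "split")
  expect_equal(splitc[["CGC"]], 0.5)
  expect_equal(splitc[["CGT"]], 0.5)
  # identical results when no ambiguity codes are present
  clean <- c(x = "ATGAAATAA")
  expect_equal(count_codons(clean), count_codons(clean, ambiguity_policy = "split"))
  expect_warning(empty <- count_codons(stats::setNames(character(0), character(0))),
                 "no protein-coding")
  expect_equal(sum(empty), 0)
})
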