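# Adjacency gaps, overlaps/spacers and unannotated spans on circular genomes.

test_that("adjacency gaps reproduce the reference worked examples", {
  feats <- ref_features()
  adj <- adjacency_gaps(feats, genome_length = 15566L, circular = TRUE)
  gap <- function(up, dn)
    adj$intergenic_length[adj$upstream == up & adj$downstream == dn]
  expect_equal(gap("trnM", "trnW"), -9L)
  expect_equal(gap("trnW", "COX1"), -10L)
  expect_equal(gap("trnE", "trnF"), -10L)
  expect_equal(gap("ND4L", "ND6"), 40L)
  # wrap adjacency links the last gene back to the first across the origin
  w <- adj[adj$is_wrap, ]
  expect_equal(w$upstream, "rrnS")
  expect_equal(w$downstream, "trnM")
  expect_equal(w$intergenic_length, (15566L - 14447L) + (753L - 1L))
})

test_that("abutting genes give zero and unsorted input is rejected", {
  f <- gene_features(c("a", "b"), c(1, 101), c(100, 200), c("+", "+"),
                     gene_class = "PCG")
  adj <- adjacency_gaps(f, 300, circular = FALSE)
  expect_equal(adj$intergenic_length, 0L)
  f_bad <- f[2:1, ]
  expect_error(adjacency_gaps(f_bad, 300, circular = FALSE), "sorted")
})

test_that("overlaps and spacers partition the nonzero adjacencies", {
  feats <- ref_features()
  adj <- adjacency_gaps(feats, 15566L, circular = TRUE)
  ov <- overlap_regions(adj)
  sp <- spacer_regions(adj)
  nonwrap <- adj[!adj$is_wrap, ]
  expect_equal(nrow(ov) + nrow(sp), sum(nonwrap$intergenic_length != 0))
  expect_true(all(ov$length > 0))
  expect_true(all(sp$length > 0))
  # sorted by length descending
  expect_true(!is.unsorted(rev(ov$length)))
  expect_equal(ov$length[1], 10L)
  expect_equal(sp$length[1], 40L)
  # all-zero records give empty lists
  z <- adjacency_gaps(gene_features(c("a", "b"), c(1, 101), c(100, 200),
                                    c("+", "+"), gene_class = "PCG"),
                      300, circular = FALSE)
  expect_equal(nrow(overlap_regions(z)), 0L)
  expect_equal(nrow(spacer_regions(z)), 0L)
})

test_that("largest unannotated span honours linearity and circular wrap", {
  lin <- mito_genome(strrep("ACGT", 25),
                     gene_features("g", 1, 10, "+", gene_class = "PCG"),
                     circular = FALSE)
  expect_equal(largest_unannotated_span(lin),
               list(start = 11L, end = 100L, length = 90L))
  circ <- mito_genome(strrep("ACGT", 25),
                      gene_features("g", 6, 94, "+", gene_class = "PCG"),
                      circular = TRUE)
  # uncovered arcs 95..100 and 1..5 merge across the origin
  expect_equal(largest_unannotated_span(circ),
               list(start = 95L, end = 5L, length = 11L))
  full <- mito_genome("ACGTACGTAC",
                      gene_features("g", 1, 10, "+", gene_class = "PCG"),
                      circular = TRUE)
  expect_equal(largest_unannotated_span(full)$length, 0L)
})

test_that("unannotated span matches a brute-force position scan", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      len <- 200L
      n <- 4L
      starts <- sort(sample(len, n))
      ends <- pmin(starts + sample(10:30, n, replace = TRUE), len)
      feats <- gene_features(paste0("g", 1:n), starts, ends,
                             rep("+", n), gene_class = "rRNA")
      g <- mito_genome(strrep("A", len), feats, circular = TRUE)
      # oracle: scan the doubled circle for the longest uncovered run
      cov <- rep(FALSE, len)
      for (i in seq_len(nrow(feats))) cov[feats$start[i]:feats$end[i]] <- TRUE
      runs <- rle(c(cov, cov))
      free <- max(c(0, runs$lengths[!runs$values]))
      expect_equal(largest_unannotated_span(g)$length, min(free, len))
    }
  })
})

test_that("signed gaps plus feature sizes tile a fully annotated circle", {
  sim <- generate_mitogenome(genome_spec(seed = 21))
  g <- sim$genome
  adj <- adjacency_gaps(g)
  expect_equal(sum(g$features$size_bp) + sum(adj$intergenic_length),
               g$length_bp)
})

test_that("architecture is invariant to rotating the coordinate origin", {
  sim <- generate_mitogenome(genome_spec(seed = 8))
  g <- sim$genome
  shift <- 15000L   # a cut inside the unannotated span, so no feature splits
  rot_seq <- paste0(substr(g$sequence, shift + 1, g$length_bp),
                    substr(g$sequence, 1, shift))
  f <- g$features
  f$start <- ((f$start - 1L - shift) %% g$length_bp) + 1L
  f$end <- ((f$end - 1L - shift) %% g$length_bp) + 1L
  rot <- mito_genome(rot_seq, gene_features(f$gene, f$start, f$end, f$strand,
                                            gene_class = f$gene_class,
                                            anticodon = f$anticodon,
                                            genome_length = g$length_bp),
                     circular = TRUE)
  a1 <- adjacency_gaps(g)
  a2 <- adjacency_gaps(rot)
  expect_equal(sort(a1$intergenic_length), sort(a2$intergenic_length))
  expect_equal(largest_unannotated_span(rot)$length,
               largest_unannotated_span(g)$length)
})
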