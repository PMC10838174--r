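# Dot-bracket parsing, arm decomposition and architecture classification.

test_that("dot-bracket parsing builds a nested involution", {
  p <- parse_dot_bracket("((..))")
  expect_equal(p, c(6L, 5L, 0L, 0L, 2L, 1L))
  expect_equal(parse_dot_bracket("...."), rep(0L, 4))
  expect_error(parse_dot_bracket("(()"), "unbalanced")
  expect_error(parse_dot_bracket("())"), "unbalanced")
  expect_error(parse_dot_bracket("(a)"), "unexpected")
})

test_that("random balanced structures satisfy pairing invariants", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      # random balanced string via shuffled open/close with depth repair
      n <- 30L
      ops <- sample(c(rep("(", 8), rep(")", 8), rep(".", n - 16)))
      depth <- cumsum((ops == "(") - (ops == ")"))
      while (any(depth < 0)) {     # rotate until balanced prefix-wise
        ops <- c(ops[-1], ops[1])
        depth <- cumsum((ops == "(") - (ops == ")"))
      }
      db <- paste(ops, collapse = "")
      p <- parse_dot_bracket(db)
      # involution, no self-pairs
      paired <- which(p > 0)
      expect_true(all(p[p[paired]] == paired))
      expect_true(all(p[paired] != paired))
      # independent partner oracle: depth returns to entry level
      d <- cumsum((ops == "(") - (ops == ")"))
      for (i in which(ops == "(")) {
        partner <- i + which(d[(i + 1):n] == d[i] - 1)[1]
        expect_equal(p[i], partner)
      }
    }
  })
})

test_that("G-U pair counting matches a direct scan on random stems", {
  expect_equal(count_gu_pairs("GGGGUUUU", "(((())))"), 4L)
  expect_equal(count_gu_pairs("GCGCGCGC", "(((())))"), 0L)
  withr::with_seed(17, {
    for (rep in 1:10) {
      t <- generate_trna(sample(c("cloverleaf", "d_armless", "t_armless"), 1),
                         gu_fraction = runif(1, 0, 0.4),
                         seed = sample.int(1e6, 1))
      p <- parse_dot_bracket(t$structure)
      ch <- strsplit(t$sequence, NULL)[[1]]
      open <- which(p > seq_along(p))
      direct <- sum((ch[open] == "G" & ch[p[open]] == "U") |
                      (ch[open] == "U" & ch[p[open]] == "G"))
      expect_equal(count_gu_pairs(t$sequence, t$structure), direct)
      expect_equal(direct, t$n_gu)   # planting is exact
    }
  })
})

test_that("arm decomposition classifies canonical and truncated layouts", {
  cl <- generate_trna("cloverleaf", seed = 5)
  s <- decompose_arms(cl$sequence, cl$structure, "trnX")
  expect_equal(s$arch_class, "cloverleaf")
  expect_equal(s$acceptor_stem_bp, 7L)
  expect_equal(s$d_arm_bp, 4L)
  expect_equal(s$anticodon_arm_bp, 5L)
  expect_equal(s$anticodon_loop_nt, 7L)
  expect_equal(s$t_arm_bp, 5L)
  expect_equal(nchar(s$anticodon), 3L)
  expect_false(is.na(s$discriminator))

  da <- generate_trna("d_armless", seed = 6)
  expect_equal(decompose_arms(da$sequence, da$structure)$arch_class,
               "d_armless")
  ta <- generate_trna("t_armless", seed = 7)
  expect_equal(decompose_arms(ta$sequence, ta$structure)$arch_class,
               "t_armless")
  mi <- generate_trna("minimal", seed = 8)
  sm <- decompose_arms(mi$sequence, mi$structure)
  expect_equal(sm$arch_class, "minimal")
  expect_equal(sm$d_arm_bp, 0L)
  expect_equal(sm$t_arm_bp, 0L)
  expect_gt(sm$anticodon_arm_bp, 0L)
})

test_that("a planted anticodon lands in the middle of the anticodon loop", {
  t <- generate_trna("cloverleaf", anticodon = "CAU", seed = 12)
  s <- decompose_arms(t$sequence, t$structure)
  expect_equal(s$anticodon, "CAU")
})

test_that("structures without an acceptor stem are rejected as not tRNA-like", {
  expect_error(decompose_arms("ACGUACGU", "........"), "no base pairs")
  expect_error(decompose_arms("GGGAAACCCAAAGGGAAACCC",
                              "(((...)))...(((...)))"), "not tRNA-like")
})

test_that("arm counts are invariant under 5'-3' reversal with mirrored brackets", {
  for (arch in c("cloverleaf", "d_armless", "t_armless", "minimal")) {
    t <- generate_trna(arch, seed = 23)
    s1 <- decompose_arms(t$sequence, t$structure)
    rev_seq <- paste(rev(strsplit(t$sequence, NULL)[[1]]), collapse = "")
    rev_db <- chartr("()", ")(",
                     paste(rev(strsplit(t$structure, NULL)[[1]]), collapse = ""))
    s2 <- decompose_arms(rev_seq, rev_db)
    expect_equal(s2$acceptor_stem_bp, s1$acceptor_stem_bp)
    expect_equal(s2$anticodon_arm_bp, s1$anticodon_arm_bp)
    expect_equal(s2$d_arm_bp + s2$t_arm_bp, s1$d_arm_bp + s1$t_arm_bp)
    expect_equal(s2$gu_pairs, s1$gu_pairs)
  }
})

test_that("every pair is Watson-Crick, G-U, or counted as a mismatch", {
  t <- generate_trna("cloverleaf", gu_fraction = 0.25, seed = 19)
  s <- decompose_arms(t$sequence, t$structure)
  expect_equal(s$mismatch_pairs, 0L)   # generator plants no mismatches
  # plant one mismatch by hand and see it counted
  ch <- strsplit(t$sequence, NULL)[[1]]
  p <- parse_dot_bracket(t$structure)
  i <- which(p > seq_along(p))[1]
  ch[i] <- "A"; ch[p[i]] <- "G"
  s2 <- decompose_arms(paste(ch, collapse = ""), t$structure)
  expect_equal(s2$mismatch_pairs, 1L)
})

test_that("nucleotide accounting conserves sequence length", {
  t <- generate_trna("cloverleaf", seed = 3)
  s <- decompose_arms(t$sequence, t$structure)
  paired_nt <- 2L * (s$acceptor_stem_bp + s$d_arm_bp +
                       s$anticodon_arm_bp + s$t_arm_bp)
  unpaired_nt <- sum(s$pairing == 0L)
  expect_equal(paired_nt + unpaired_nt, nchar(s$sequence))
})

test_that("the shipped synthetic panel classifies as planted with zero errors", {
  structs <- read_trna_structures(extdata("synthetic_trna22.txt"))
  res <- classify_trna_set(structs)
  expect_equal(unname(res$counts),
               c(7L, 7L, 7L, 1L))
  expect_equal(names(res$counts),
               c("cloverleaf", "d_armless", "t_armless", "minimal"))
  # per-record truth is encoded in the record names
  planted <- sub("^trn\\d+_", "", res$table$gene)
  expect_equal(res$table$arch_class, planted)
  # single-structure and absent-class behaviour
  one <- classify_trna_set(structs[1])
  expect_equal(unname(one$counts["cloverleaf"]), 1L)
  expect_equal(unname(one$counts["minimal"]), 0L)
})
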