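# Shared fixtures and independent oracles used across the test files.

extdata <- function(f) system.file("extdata", f, package = "mitocomp",
                                   mustWork = TRUE)

ref_features <- function() {
  read_feature_table(extdata("coccus_hesperidum_genes.tsv"),
                     genome_length = 15566L)
}

ref_annotation_table <- function() {
  utils::read.delim(extdata("coccus_hesperidum_genes.tsv"),
                    stringsAsFactors = FALSE)
}

# Independent genetic-code source for cross-checks: Biostrings' NCBI tables.
bstr_code_map <- function(id = "5") {
  gc <- Biostrings::getGeneticCode(id)
  stats::setNames(as.vector(gc), chartr("U", "T", names(gc)))
}

# Independent NG86 oracle: exhaustive recursion over substitution orderings
# using the Biostrings code map (the implementation uses its own table and
# an iterative permutation walk).
oracle_pair_diffs <- function(ca, cb, map) {
  a <- strsplit(ca, NULL)[[1]]
  b <- strsplit(cb, NULL)[[1]]
  diff <- which(a != b)
  if (!length(diff)) return(c(0, 0))
  paths <- list()
  recurse <- function(cur, remaining, sd, nd) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- c(sd, nd)
      return(invisible())
    }
    for (k in seq_along(remaining)) {
      pos <- remaining[k]
      nxt <- cur
      nxt[pos] <- b[pos]
      if (map[[paste(nxt, collapse = "")]] == "*") next
      same <- map[[paste(cur, collapse = "")]] ==
        map[[paste(nxt, collapse = "")]]
      recurse(nxt, remaining[-k], sd + as.integer(same),
              nd + as.integer(!same))
    }
  }
  recurse(a, diff, 0L, 0L)
  if (!length(paths)) {
    # all pathways blocked: count every ordering, stop steps nonsynonymous
    recurse2 <- function(cur, remaining, sd, nd) {
      if (!length(remaining)) {
        paths[[length(paths) + 1L]] <<- c(sd, nd)
        return(invisible())
      }
      for (k in seq_along(remaining)) {
        pos <- remaining[k]
        nxt <- cur
        nxt[pos] <- b[pos]
        same <- map[[paste(cur, collapse = "")]] ==
          map[[paste(nxt, collapse = "")]]
        recurse2(nxt, remaining[-k], sd + as.integer(same),
                 nd + as.integer(!same))
      }
    }
    recurse2(a, diff, 0L, 0L)
  }
  m <- do.call(rbind, paths)
  colMeans(m)
}

# Random sense-codon sequence (no stops) under a code map.
random_cds <- function(n_codons, map, seed) {
  withr::with_seed(seed, {
    sense <- names(map)[map != "*"]
    paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  })
}

# Simple composition recount used as a brute-force oracle.
recount_bases <- function(seq) {
  ch <- strsplit(toupper(seq), NULL)[[1]]
  c(A = sum(ch == "A"), T = sum(ch == "T"),
    G = sum(ch == "G"), C = sum(ch == "C"))
}

# A small fully-specified synthetic genome used by several files:
# two forward PCGs, one reverse tRNA, known sequence.
toy_genome <- function() {
  # positions: gene1 PCG 4..15 (ATG AAA TGA TAA: 4 codons incl stop),
  # trnX tRNA 17..22 reverse, gene2 PCG 24..33 (ATA TTT CCC T: incomplete)
  seq <- paste0("GGG", "ATGAAATGATAA", "C", "AAATTT", "G", "ATATTTCCCT",
                "ACGT")
  feats <- gene_features(c("g1", "trnX", "g2"),
                         start = c(4L, 17L, 24L),
                         end = c(15L, 22L, 33L),
                         strand = c("+", "-", "+"),
                         gene_class = c("PCG", "tRNA", "PCG"),
                         anticodon = c(NA, "UUU", NA))
  mito_genome(seq, feats, id = "toy", circular = FALSE)
}
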