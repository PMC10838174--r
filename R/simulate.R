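# Synthetic-data generators with known ground truth: annotated circular
# mitogenomes, codon pairs diverged at a chosen dN/dS, and tRNA structures
# with planted architectures. Every generator is deterministic under its
# seed; each draws from its own decorrelated stream so adding one generator
# never perturbs another's output.

#' Specification for a synthetic mitogenome
#'
#' The default template, gap list and composition targets mirror the
#' *Coccus hesperidum* reference annotation shipped with the package: a
#' circular 15,566 bp genome, 37 genes in the reference order and strand
#' pattern starting at position 753, ~83% A+T with positive plus-strand
#' AT-skew, the reference overlap/spacer pattern, ATN starts, and
#' TAA/TAG/incomplete-T stops.
#'
#' @param template Data frame with columns `gene`, `gene_class`, `size_bp`,
#'   `strand`, `anticodon`, `start_codon`, `stop_codon` (stop `"T"`/`"TA"`
#'   marks an incomplete stop and must match `size_bp %% 3`).
#' @param gaps Integer vector of planted intergenic lengths, one per
#'   consecutive template pair (negative = overlap).
#' @param genome_length Total length in bp.
#' @param first_gene_start 1-based start coordinate of the first gene.
#' @param at_content,plus_at_skew,plus_gc_skew Plus-strand composition
#'   targets (fractions / skews).
#' @param code A [genetic_code()].
#' @param seed Integer seed.
#' @return Object of class `genome_spec`.
#' @export
genome_spec <- function(template = NULL, gaps = NULL,
                        genome_length = 15566L, first_gene_start = 753L,
                        at_content = 0.834, plus_at_skew = 0.221,
                        plus_gc_skew = -0.305,
                        code = genetic_code(5), seed = 1L) {
  if (is.null(template) || is.null(gaps)) {
    ref <- reference_annotation()
    if (is.null(template)) template <- ref$template
    if (is.null(gaps)) gaps <- ref$gaps
  }
  need <- c("gene", "gene_class", "size_bp", "strand", "start_codon",
            "stop_codon")
  stopifnot(all(need %in% names(template)))
  if (!"anticodon" %in% names(template)) template$anticodon <- NA_character_
  if (length(gaps) != nrow(template) - 1L)
    stop("need one planted gap per consecutive template pair (",
         nrow(template) - 1L, "), got ", length(gaps))
  # feasibility: the annotated block must fit inside the genome
  span <- sum(template$size_bp) + sum(gaps)
  if (first_gene_start - 1L + span > genome_length)
    stop("infeasible spec: genes plus gaps exceed genome length")
  for (i in which(template$gene_class == "PCG")) {
    frag <- template$size_bp[i] %% 3L
    st <- template$stop_codon[i]
    ok <- (frag == 1L && identical(st, "T")) ||
      (frag == 2L && identical(st, "TA")) ||
      (frag == 0L && isTRUE(is_stop_codon(st, code)))
    if (!ok)
      stop("stop token '", st, "' inconsistent with size ",
           template$size_bp[i], " for ", template$gene[i])
    if (!grepl("^AT[ACGT]$", template$start_codon[i]))
      stop("start codon must be ATN for ", template$gene[i])
  }
  structure(list(template = template, gaps = as.integer(gaps),
                 genome_length = as.integer(genome_length),
                 first_gene_start = as.integer(first_gene_start),
                 at_content = at_content, plus_at_skew = plus_at_skew,
                 plus_gc_skew = plus_gc_skew, code = code,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

# Reference gene order/sizes/strands/gaps and start/stop codons, read from
# the annotation table shipped in extdata.
reference_annotation <- function() {
  path <- system.file("extdata", "coccus_hesperidum_genes.tsv",
                      package = "mitocomp", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  tpl <- data.frame(gene = df$gene,
                    gene_class = infer_gene_class(df$gene),
                    size_bp = df$end - df$start + 1L,
                    strand = df$strand,
                    anticodon = ifelse(nzchar(df$anticodon), df$anticodon,
                                       NA_character_),
                    start_codon = ifelse(nzchar(df$start_codon),
                                         df$start_codon, NA_character_),
                    stop_codon = ifelse(nzchar(df$stop_codon),
                                        df$stop_codon, NA_character_),
                    stringsAsFactors = FALSE)
  list(template = tpl,
       gaps = df$start[-1L] - df$end[-nrow(df)] - 1L,
       first_gene_start = df$start[1L],
       features = gene_features(df$gene, df$start, df$end, df$strand,
                                anticodon = ifelse(nzchar(df$anticodon),
                                                   df$anticodon,
                                                   NA_character_)))
}

.base_probs <- function(at, at_sk, gc_sk) {
  gc <- 1 - at
  p <- c(A = at * (1 + at_sk) / 2, T = at * (1 - at_sk) / 2,
         G = gc * (1 + gc_sk) / 2, C = gc * (1 - gc_sk) / 2)
  if (any(p < 0)) stop("infeasible composition/skew targets")
  p
}

.COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G")

#' Generate an annotated circular mitogenome with known ground truth
#'
#' The plus strand is sampled to hit the spec's A+T-content target (within
#' 1 percentage point) and AT-skew target (within 0.02); protein-coding
#' genes are open reading frames under the spec's genetic code carrying the
#' planted start codons and stop tokens (incomplete stops realised by
#' truncation); overlaps and spacers are realised exactly by coordinate
#' arithmetic. Deterministic under the spec seed.
#'
#' @param spec A [genome_spec()].
#' @param max_attempts Resampling cap for the composition targets; after
#'   this many attempts the closest draw is returned with a warning.
#' @return List with `genome` (a [mito_genome()]) and `truth` (planted
#'   gaps, per-gene start/stop tokens, sizes, coordinates, targets, seed).
#' @export
generate_mitogenome <- function(spec, max_attempts = 100L) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, stream = 1L, expr = {
    tpl <- spec$template
    starts <- integer(nrow(tpl)); ends <- integer(nrow(tpl))
    starts[1] <- spec$first_gene_start
    ends[1] <- starts[1] + tpl$size_bp[1] - 1L
    for (i in seq_len(nrow(tpl))[-1]) {
      starts[i] <- ends[i - 1L] + spec$gaps[i - 1L] + 1L
      ends[i] <- starts[i] + tpl$size_bp[i] - 1L
    }
    if (any(starts < 1L) || any(ends > spec$genome_length))
      stop("infeasible spec: a gene falls outside the genome")
    best <- NULL; best_err <- Inf
    for (attempt in seq_len(max_attempts)) {
      seqc <- .sample_genome_sequence(spec, tpl, starts, ends)
      comp <- base_composition(seqc)
      err <- max(abs(comp$at_content / 100 - spec$at_content) / 0.01,
                 abs(comp$at_skew - spec$plus_at_skew) / 0.02)
      if (err < best_err) { best <- seqc; best_err <- err }
      if (err <= 1) break
    }
    if (best_err > 1)
      warning("composition targets not met after ", max_attempts,
              " attempts; returning closest draw")
    feats <- gene_features(tpl$gene, starts, ends, tpl$strand,
                           gene_class = tpl$gene_class,
                           anticodon = tpl$anticodon,
                           genome_length = spec$genome_length)
    genome <- mito_genome(best, feats, id = "synthetic", circular = TRUE)
    .validate_planted(genome, tpl, spec$code)
    truth <- list(gene = tpl$gene, gene_class = tpl$gene_class,
                  start = starts, end = ends, size_bp = tpl$size_bp,
                  strand = tpl$strand, gaps = spec$gaps,
                  start_codon = tpl$start_codon,
                  stop_codon = tpl$stop_codon,
                  at_content = spec$at_content,
                  plus_at_skew = spec$plus_at_skew, seed = spec$seed)
    list(genome = genome, truth = truth)
  })
}

# One draw of the plus strand honouring all planted codon constraints.
.sample_genome_sequence <- function(spec, tpl, starts, ends) {
  L <- spec$genome_length
  p_plus <- .base_probs(spec$at_content, spec$plus_at_skew,
                        spec$plus_gc_skew)
  chars <- rep(NA_character_, L)
  bases <- names(p_plus)
  code <- spec$code

  plus_pos <- function(i, coding_idx) {
    if (tpl$strand[i] == "+") starts[i] + coding_idx - 1L
    else ends[i] - coding_idx + 1L
  }
  write_coding <- function(i, coding_idx, coding_base, hard = FALSE) {
    p <- plus_pos(i, coding_idx)
    b <- if (tpl$strand[i] == "+") coding_base else .COMPLEMENT[coding_base]
    if (hard && !is.na(chars[p]) && chars[p] != b)
      stop("infeasible overlap: conflicting planted bases at position ", p)
    chars[p] <<- unname(b)
  }
  pcg_idx <- which(tpl$gene_class == "PCG")
  # planted start codons and stop tokens are hard constraints
  for (i in pcg_idx) {
    sc <- seq_chars(tpl$start_codon[i])
    for (k in 1:3) write_coding(i, k, sc[k], hard = TRUE)
    n <- tpl$size_bp[i]
    frag <- n %% 3L
    if (frag == 0L) {
      st <- seq_chars(tpl$stop_codon[i])
      for (k in 1:3) write_coding(i, n - 3L + k, st[k], hard = TRUE)
    } else {
      st <- seq_chars(tpl$stop_codon[i])  # "T" or "TA"
      for (k in seq_along(st)) write_coding(i, n - frag + k, st[k], hard = TRUE)
    }
  }
  # fill PCG bodies codon by codon, avoiding in-frame stops
  for (i in pcg_idx) {
    n <- tpl$size_bp[i]
    k_cod <- n %/% 3L
    frag <- n %% 3L
    body <- if (frag == 0L) seq_len(k_cod)[-c(1L, k_cod)] else
      seq_len(k_cod)[-1L]
    p_cod <- if (tpl$strand[i] == "+") p_plus else
      stats::setNames(p_plus[c("T", "A", "C", "G")], bases)
    for (cidx in body) {
      ci <- 3L * (cidx - 1L) + c(1L, 2L, 3L)
      pp <- vapply(ci, function(kk) plus_pos(i, kk), integer(1))
      fixed_plus <- chars[pp]
      fixed <- if (tpl$strand[i] == "+") fixed_plus else
        unname(.COMPLEMENT[fixed_plus])
      free <- which(is.na(fixed))
      codon_chars <- fixed
      if (length(free) == 0L) {
        if (isTRUE(is_stop_codon(paste(codon_chars, collapse = ""), code)))
          stop("infeasible overlap: forced in-frame stop in ", tpl$gene[i])
        next
      }
      ok <- FALSE
      for (try in seq_len(100L)) {
        codon_chars[free] <- sample(bases, length(free), replace = TRUE,
                                    prob = p_cod)
        if (!is_stop_codon(paste(codon_chars, collapse = ""), code)) {
          ok <- TRUE; break
        }
      }
      if (!ok) {
        # deterministic fallback: first compatible non-stop completion
        grid <- expand.grid(rep(list(bases), length(free)),
                            stringsAsFactors = FALSE)
        for (r in seq_len(nrow(grid))) {
          codon_chars[free] <- unlist(grid[r, ], use.names = FALSE)
          if (!is_stop_codon(paste(codon_chars, collapse = ""), code)) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("infeasible overlap: no stop-free codon in ",
                      tpl$gene[i])
      }
      for (kk in seq_along(ci)) write_coding(i, ci[kk], codon_chars[kk])
    }
  }
  # remaining positions (RNA genes, spacers, unannotated span): background
  nafill <- which(is.na(chars))
  free_pos <- nafill   # unconstrained; usable for the correction pass below
  chars[nafill] <- sample(bases, length(nafill), replace = TRUE,
                          prob = p_plus)
  # correction pass: codon constraints in the PCGs bias the realised
  # composition slightly, so flip unconstrained background positions until
  # each base hits its target count exactly
  target <- round(p_plus * L)
  target["A"] <- target["A"] + (L - sum(target))   # absorb rounding
  cur <- vapply(bases, function(b) sum(chars == b), integer(1))
  excess <- cur - target[bases]
  donors <- unlist(lapply(bases[excess > 0], function(b) {
    cand <- free_pos[chars[free_pos] == b]
    if (length(cand) > excess[b]) sample(cand, excess[b]) else cand
  }), use.names = FALSE)
  takers <- rep(bases[excess < 0], pmax(0, -excess[excess < 0]))
  n_fix <- min(length(donors), length(takers))
  if (n_fix > 0) chars[donors[seq_len(n_fix)]] <- takers[seq_len(n_fix)]
  paste(chars, collapse = "")
}

# Re-analyse the generated genome and insist every planted codon survives.
.validate_planted <- function(genome, tpl, code) {
  for (i in which(tpl$gene_class == "PCG")) {
    cds <- extract_gene_sequence(genome, tpl$gene[i])
    ss <- identify_start_stop(cds, code)
    if (!identical(ss$start, tpl$start_codon[i]) ||
        !identical(ss$stop, tpl$stop_codon[i]))
      stop("planted start/stop not realised for ", tpl$gene[i],
           " (got ", ss$start, "/", ss$stop, ")")
    parts <- split_codons(cds)
    body <- parts$codons[-1L]
    if (parts$trailing == "" && length(body)) body <- body[-length(body)]
    if (any(is_stop_codon(body, code)))
      stop("internal stop codon realised in ", tpl$gene[i])
  }
  invisible(TRUE)
}

#' Specification for a diverged codon pair
#'
#' @param n_codons Number of codons.
#' @param omega Target dN/dS (> 0, or 0 for purely synonymous divergence).
#' @param subs_per_codon Expected accepted substitution events per codon.
#' @param code A [genetic_code()].
#' @param seed Integer seed.
#' @return Object of class `divergence_spec`.
#' @export
divergence_spec <- function(n_codons, omega = 1, subs_per_codon = 0.3,
                            code = genetic_code(5), seed = 1L) {
  stopifnot(n_codons >= 1L, omega >= 0, subs_per_codon >= 0)
  structure(list(n_codons = as.integer(n_codons), omega = omega,
                 subs_per_codon = subs_per_codon, code = code,
                 seed = as.integer(seed)),
            class = "divergence_spec")
}

#' Evolve a codon-aligned sequence pair at a known dN/dS
#'
#' Sequence A is sampled over sense codons; sequence B accumulates single-
#' nucleotide substitution events: proposals are uniform over positions and
#' alternative bases, proposals creating stop codons are rejected,
#' nonsynonymous proposals are accepted with probability `min(1, omega)`
#' and synonymous ones with probability `min(1, 1/omega)`, so the realised
#' dN/dS has expectation `omega`. The event count is
#' `round(n_codons * subs_per_codon)`. Deterministic under the spec seed.
#'
#' @param spec A [divergence_spec()].
#' @return List `seqA`, `seqB` (equal-length in-frame strings) and
#'   `n_events`.
#' @export
evolve_codon_pair <- function(spec) {
  stopifnot(inherits(spec, "divergence_spec"))
  with_seed(spec$seed, stream = 2L, expr = {
    code <- spec$code
    sense <- names(code$map)[code$map != "*"]
    a_codons <- sample(sense, spec$n_codons, replace = TRUE)
    a <- unlist(strsplit(a_codons, NULL), use.names = FALSE)
    b <- a
    bases <- c("A", "C", "G", "T")
    n_events <- round(spec$n_codons * spec$subs_per_codon)
    p_nonsyn <- min(1, spec$omega)
    p_syn <- if (spec$omega == 0) 1 else min(1, 1 / spec$omega)
    events <- 0L
    guard <- 0L
    while (events < n_events) {
      guard <- guard + 1L
      if (guard > 2e5 + 1e3 * n_events)
        stop("substitution process failed to accept enough events")
      pos <- sample.int(length(b), 1L)
      alt <- sample(setdiff(bases, b[pos]), 1L)
      ci <- (pos - 1L) %/% 3L
      old_codon <- paste(b[(3L * ci + 1L):(3L * ci + 3L)], collapse = "")
      new <- b[(3L * ci + 1L):(3L * ci + 3L)]
      new[pos - 3L * ci] <- alt
      new_codon <- paste(new, collapse = "")
      if (code$map[[new_codon]] == "*") next
      syn <- code$map[[new_codon]] == code$map[[old_codon]]
      if (stats::runif(1) < (if (syn) p_syn else p_nonsyn)) {
        b[pos] <- alt
        events <- events + 1L
      }
    }
    list(seqA = paste(a, collapse = ""), seqB = paste(b, collapse = ""),
         n_events = n_events)
  })
}

#' Generate a tRNA sequence and dot-bracket structure with planted arms
#'
#' Builds a structure realising exactly the requested architecture, with
#' stems made complementary and a configurable, exactly planted number of
#' G-U pairs.
#'
#' @param arch One of `"cloverleaf"`, `"d_armless"`, `"t_armless"`,
#'   `"minimal"`.
#' @param arms Named list of stem/loop sizes; defaults give the canonical
#'   layout (acceptor 7 bp, D 4 bp + 6 nt loop, anticodon 5 bp + 7 nt
#'   loop, T 5 bp + 7 nt loop, 4 nt variable region, replacement loops of
#'   5 nt where an arm is absent).
#' @param gu_fraction Fraction of stem pairs planted as G-U (rounded to an
#'   exact count).
#' @param anticodon Optional 3-letter RNA anticodon planted in the middle
#'   of the anticodon loop.
#' @param seed Integer seed.
#' @param name Record name.
#' @return List `name`, `sequence` (RNA), `structure` (dot-bracket),
#'   `n_pairs`, `n_gu`.
#' @export
generate_trna <- function(arch = c("cloverleaf", "d_armless", "t_armless",
                                   "minimal"),
                          arms = list(), gu_fraction = 0,
                          anticodon = NULL, seed = 1L, name = "tRNA") {
  arch <- match.arg(arch)
  a <- utils::modifyList(list(acceptor = 7L, d = 4L, d_loop = 6L,
                              ac = 5L, ac_loop = 7L, t = 5L, t_loop = 7L,
                              var = 4L, link1 = 2L, link2 = 1L,
                              replace_loop = 5L), arms)
  with_seed(seed, stream = 3L, expr = {
    blocks <- c(
      strrep("(", a$acceptor), strrep(".", a$link1),
      if (arch %in% c("cloverleaf", "t_armless"))
        paste0(strrep("(", a$d), strrep(".", a$d_loop), strrep(")", a$d))
      else strrep(".", a$replace_loop),
      strrep(".", a$link2),
      paste0(strrep("(", a$ac), strrep(".", a$ac_loop), strrep(")", a$ac)),
      strrep(".", a$var),
      if (arch %in% c("cloverleaf", "d_armless"))
        paste0(strrep("(", a$t), strrep(".", a$t_loop), strrep(")", a$t))
      else "",
      strrep(")", a$acceptor), ".")
    db <- paste(blocks, collapse = "")
    pairing <- parse_dot_bracket(db)
    n <- length(pairing)
    ch <- character(n)
    unpaired <- which(pairing == 0L)
    ch[unpaired] <- sample(c("A", "U", "G", "C"), length(unpaired),
                           replace = TRUE, prob = c(.42, .42, .08, .08))
    open <- which(pairing > seq_len(n))
    n_gu <- round(gu_fraction * length(open))
    gu_at <- if (n_gu > 0) sample(open, n_gu) else integer(0)
    comp <- c(A = "U", U = "A", G = "C", C = "G")
    for (i in open) {
      if (i %in% gu_at) {
        if (stats::runif(1) < 0.5) { ch[i] <- "G"; ch[pairing[i]] <- "U" }
        else { ch[i] <- "U"; ch[pairing[i]] <- "G" }
      } else {
        b <- sample(c("A", "U", "G", "C"), 1L, prob = c(.35, .35, .15, .15))
        ch[i] <- b
        ch[pairing[i]] <- comp[[b]]
      }
    }
    if (!is.null(anticodon)) {
      stopifnot(nchar(anticodon) == 3L)
      acl <- .anticodon_loop_positions(pairing)
      mid <- acl[ceiling(length(acl) / 2) - 1L]
      ch[mid:(mid + 2L)] <- seq_chars(chartr("T", "U", toupper(anticodon)))
    }
    list(name = name, sequence = paste(ch, collapse = ""), structure = db,
         n_pairs = length(open), n_gu = n_gu)
  })
}

# Positions of the anticodon loop, using the same arm-assignment logic as
# decompose_arms.
.anticodon_loop_positions <- function(pairing) {
  dummy <- paste(rep("A", length(pairing)), collapse = "")
  hel <- .find_helices(pairing)
  repeat {
    if (length(hel) < 2L) break
    spans_i <- vapply(hel, `[[`, numeric(1), "i5")
    spans_j <- vapply(hel, `[[`, numeric(1), "j3")
    outer_idx <- which(spans_i == min(spans_i))[1]
    if (!all(spans_i >= hel[[outer_idx]]$i5 &
               spans_j <= hel[[outer_idx]]$j3)) break
    hel <- hel[-outer_idx]
  }
  interior <- Filter(function(h) h$nbp >= 2L, hel)
  interior <- interior[order(vapply(interior, `[[`, numeric(1), "i5"))]
  ac <- if (length(interior) == 3L) interior[[2]]
  else if (length(interior) == 2L) {
    mid <- (length(pairing) + 1) / 2
    lm <- vapply(interior, function(h) (h$i3 + h$j5) / 2, numeric(1))
    interior[[which.min(abs(lm - mid))]]
  } else interior[[1]]
  (ac$i3 + 1L):(ac$j5 - 1L)
}

#' A synthetic panel of 22 tRNA structures with planted architectures
#'
#' Seven cloverleaf, seven D-armless, seven T-armless and one minimal
#' structure, with arm lengths varied across the ranges seen in highly
#' reduced mitochondrial tRNA sets (acceptor 6-7 bp, D stem 2-5 bp,
#' anticodon stem 4-6 bp with 7-11 nt loops, T stem 2-5 bp).
#'
#' @param seed Integer seed.
#' @return List of 22 `list(name, sequence, structure, ...)` records.
#' @export
synthetic_trna_panel <- function(seed = 1L) {
  classes <- c(rep("cloverleaf", 7), rep("d_armless", 7),
               rep("t_armless", 7), "minimal")
  lapply(seq_along(classes), function(i) {
    arms <- with_seed(seed, stream = 40L + i, expr = list(
      acceptor = sample(6:7, 1),
      d = sample(2:5, 1), d_loop = sample(4:8, 1),
      ac = sample(4:6, 1), ac_loop = sample(c(7L, 9L, 11L), 1),
      t = sample(2:5, 1), t_loop = sample(5:9, 1),
      var = sample(3:6, 1)))
    generate_trna(classes[i], arms = arms,
                  gu_fraction = if (i %% 3 == 0) 0.2 else 0,
                  seed = seed + i, name = sprintf("trn%02d_%s", i, classes[i]))
  })
}
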