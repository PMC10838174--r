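# Pairwise Ka/Ks by the Nei-Gojobori (1986) counting method.
#
# Synonymous (S) and nonsynonymous (N) site counts come from per-codon
# enumeration of the nine single-base changes; differences between codon
# pairs are averaged over all minimal substitution pathways with equal
# weights (pathways through stop codons excluded); proportions are
# Jukes-Cantor corrected. This is the classic Ka/Ks of DnaSP/MEGA for
# descriptive mitogenome work.

#' Synonymous and nonsynonymous site counts of one codon
#'
#' For each of the three positions, the fraction of the three possible
#' single-base changes that are synonymous contributes to the synonymous
#' site count; changes to stop codons count as nonsynonymous.
#'
#' @param codon A sense codon (no ambiguity codes).
#' @param code A [genetic_code()].
#' @return Named numeric `c(s = ..., n = ...)` with `s + n = 3`.
#' @export
#' @examples
#' codon_site_counts("TTT")  # s = 1/3 under the invertebrate mito code
codon_site_counts <- function(codon, code = genetic_code(5)) {
  codon <- toupper(codon)
  if (!is_unambiguous(codon) || nchar(codon) != 3L)
    stop("codon must be an unambiguous triplet")
  aa <- code$map[[codon]]
  if (aa == "*") stop("stop codon has no site counts")
  bases <- c("A", "C", "G", "T")
  ch <- seq_chars(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(bases, ch[pos])) {
      mut <- ch
      mut[pos] <- b
      if (code$map[[paste(mut, collapse = "")]] == aa) s <- s + 1 / 3
    }
  }
  c(s = s, n = 3 - s)
}

# Pathway-averaged (Sd, Nd) for one codon pair. Minimal pathways are the
# orderings of the differing positions; pathways whose intermediate codons
# are stops are excluded (all pathways used as fallback when every one is
# blocked). Both codons are assumed to be sense codons.
.codon_pair_diffs <- function(ca, cb, code) {
  a <- seq_chars(ca)
  b <- seq_chars(cb)
  diff <- which(a != b)
  d <- length(diff)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(d,
                  list(diff),
                  list(diff, diff[2:1]),
                  {
                    idx <- list(c(1,2,3), c(1,3,2), c(2,1,3),
                                c(2,3,1), c(3,1,2), c(3,2,1))
                    lapply(idx, function(i) diff[i])
                  })
  walk <- function(order) {
    cur <- a
    sd <- 0; nd <- 0
    for (pos in order) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aa1 <- code$map[[paste(cur, collapse = "")]]
      aa2 <- code$map[[paste(nxt, collapse = "")]]
      if (aa2 == "*" || aa1 == "*") return(NULL)   # pathway through a stop
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- lapply(perms, walk)
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) {
    # every pathway blocked by a stop intermediate: use all pathways,
    # counting stop-crossing steps as nonsynonymous
    walk_all <- function(order) {
      cur <- a; sd <- 0; nd <- 0
      for (pos in order) {
        nxt <- cur
        nxt[pos] <- b[pos]
        if (code$map[[paste(cur, collapse = "")]] ==
            code$map[[paste(nxt, collapse = "")]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    res <- lapply(perms, walk_all)
    ok <- rep(TRUE, length(res))
  }
  m <- do.call(rbind, res[ok])
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# Jukes-Cantor correction; NA outside the log domain.
.jc_correct <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise Ka/Ks (Nei-Gojobori 1986)
#'
#' Codons containing gaps, ambiguity codes, or stop codons in either
#' sequence are excluded. Site counts are averaged over the two sequences;
#' per-codon differences are pathway-averaged; `ps = Sd/S`, `pn = Nd/N`;
#' `Ks = -(3/4) log(1 - (4/3) ps)` and likewise for `Ka`. The ratio is `NA`
#' when `Ks` is zero or a proportion falls outside the correction domain.
#'
#' @param seqA,seqB Codon-aligned coding-strand nucleotide strings of equal
#'   length, a multiple of 3.
#' @param code A [genetic_code()].
#' @return An object of class `kaks`: list with `S_sites`, `N_sites`, `Sd`,
#'   `Nd`, `ps`, `pn`, `Ks`, `Ka`, `ratio`, `n_codons_used`.
#' @export
pairwise_ng86 <- function(seqA, seqB, code = genetic_code(5)) {
  seqA <- toupper(seqA); seqB <- toupper(seqB)
  if (nchar(seqA) != nchar(seqB))
    stop("sequences must be codon-aligned to equal lengths")
  if (nchar(seqA) %% 3L != 0L)
    stop("alignment length must be a multiple of 3")
  ca <- split_codons(seqA)$codons
  cb <- split_codons(seqB)$codons
  usable <- is_unambiguous(ca) & is_unambiguous(cb) &
    !is_stop_codon(ca, code) & !is_stop_codon(cb, code)
  ca <- ca[usable]; cb <- cb[usable]
  S <- N <- Sd <- Nd <- 0
  for (i in seq_along(ca)) {
    sa <- codon_site_counts(ca[i], code)
    sb <- codon_site_counts(cb[i], code)
    S <- S + (sa[["s"]] + sb[["s"]]) / 2
    N <- N + (sa[["n"]] + sb[["n"]]) / 2
    d <- .codon_pair_diffs(ca[i], cb[i], code)
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  Ks <- .jc_correct(ps)
  Ka <- .jc_correct(pn)
  ratio <- if (is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  structure(list(S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
                 ps = ps, pn = pn, Ks = Ks, Ka = Ka, ratio = ratio,
                 n_codons_used = length(ca)),
            class = "kaks")
}

#' @export
print.kaks <- function(x, ...) {
  cat(sprintf(
    "Nei-Gojobori Ka/Ks over %d codons\n  S = %.2f, N = %.2f, Sd = %.2f, Nd = %.2f\n  Ks = %s, Ka = %s, Ka/Ks = %s\n",
    x$n_codons_used, x$S_sites, x$N_sites, x$Sd, x$Nd,
    format(round(x$Ks, 4)), format(round(x$Ka, 4)),
    if (is.na(x$ratio)) "undefined" else format(round(x$ratio, 4))))
  invisible(x)
}

#' Mean Ka/Ks ratio over species pairs
#'
#' Arithmetic mean of the defined pairwise ratios; undefined ratios
#' (`Ks = 0` or out-of-domain proportions) are excluded and counted.
#'
#' @param ratios Numeric vector of pairwise ratios (NA = undefined), or a
#'   list of `kaks` objects.
#' @return List `mean_ratio` (`NA` when no pair is defined), `n_used`,
#'   `n_undefined`.
#' @export
per_gene_mean_kaks <- function(ratios) {
  if (is.list(ratios) && all(vapply(ratios, inherits, logical(1), "kaks")))
    ratios <- vapply(ratios, `[[`, numeric(1), "ratio")
  ok <- !is.na(ratios)
  list(mean_ratio = if (any(ok)) mean(ratios[ok]) else NA_real_,
       n_used = sum(ok), n_undefined = sum(!ok))
}

#' Per-gene Ka/Ks table over a set of aligned CDS
#'
#' All pairwise comparisons within each gene's codon alignment, summarised
#' per gene.
#'
#' @param gene_alignments Named list: gene -> named character vector of
#'   codon-aligned CDS (one per species).
#' @param code A [genetic_code()].
#' @return Data frame: `gene`, `n_pairs`, mean `S`, `N`, `Sd`, `Nd`, `Ka`,
#'   `Ks` over pairs, and `mean_ratio` (mean of defined pairwise ratios).
#' @export
kaks_table <- function(gene_alignments, code = genetic_code(5)) {
  rows <- lapply(names(gene_alignments), function(g) {
    seqs <- gene_alignments[[g]]
    if (length(seqs) < 2L)
      return(data.frame(gene = g, n_pairs = 0L, S = NA, N = NA, Sd = NA,
                        Nd = NA, Ka = NA, Ks = NA, mean_ratio = NA,
                        n_undefined = 0L, stringsAsFactors = FALSE))
    idx <- utils::combn(length(seqs), 2)
    res <- lapply(seq_len(ncol(idx)), function(k)
      pairwise_ng86(seqs[[idx[1, k]]], seqs[[idx[2, k]]], code))
    gm <- function(f) mean(vapply(res, `[[`, numeric(1), f), na.rm = TRUE)
    mr <- per_gene_mean_kaks(res)
    data.frame(gene = g, n_pairs = length(res),
               S = gm("S_sites"), N = gm("N_sites"),
               Sd = gm("Sd"), Nd = gm("Nd"),
               Ka = gm("Ka"), Ks = gm("Ks"),
               mean_ratio = mr$mean_ratio, n_undefined = mr$n_undefined,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Thread nucleotide CDS onto a protein alignment
#'
#' Expands each in-frame CDS to a codon alignment by inserting `---` at the
#' positions where its protein sequence carries gaps in a user-supplied
#' protein alignment. Alignment itself is out of scope; this helper only
#' threads an existing one.
#'
#' @param cds Named character vector of in-frame CDS (no gaps).
#' @param aligned_aa Named character vector of aligned protein sequences
#'   (gaps as `-`), same names as `cds`.
#' @return Named character vector of codon-aligned CDS.
#' @export
thread_protein_alignment <- function(cds, aligned_aa) {
  stopifnot(setequal(names(cds), names(aligned_aa)))
  out <- vapply(names(cds), function(nm) {
    codons <- split_codons(cds[[nm]])$codons
    aa <- seq_chars(aligned_aa[[nm]])
    n_res <- sum(aa != "-")
    if (n_res > length(codons))
      stop("protein alignment for '", nm, "' has more residues than the CDS")
    res <- character(length(aa))
    j <- 0L
    for (i in seq_along(aa)) {
      if (aa[i] == "-") res[i] <- "---"
      else { j <- j + 1L; res[i] <- codons[j] }
    }
    paste(res, collapse = "")
  }, character(1))
  stats::setNames(out, names(cds))
}
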