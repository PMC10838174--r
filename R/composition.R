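# Base composition and strand-skew statistics.
#
# Skews follow the standard definitions AT-skew = (A - T)/(A + T) and
# GC-skew = (G - C)/(G + C). Per-gene values are computed on the gene's
# coding strand (reverse-strand genes reverse-complemented); whole-genome
# values are computed on the deposited plus strand.

#' AT skew
#'
#' `(A - T) / (A + T)`, computed on counts or percentages (the ratio is the
#' same). Returns `NA` when the denominator is zero.
#'
#' @param a,t A and T counts or percentages.
#' @return Numeric in `[-1, 1]`, or `NA` for an empty denominator.
#' @export
at_skew <- function(a, t) ifelse(a + t == 0, NA_real_, (a - t) / (a + t))

#' GC skew
#'
#' `(G - C) / (G + C)`; `NA` when `G + C` is zero.
#'
#' @param g,c G and C counts or percentages.
#' @return Numeric in `[-1, 1]`, or `NA` for an empty denominator.
#' @export
gc_skew <- function(g, c) ifelse(g + c == 0, NA_real_, (g - c) / (g + c))

#' Base composition of a nucleotide sequence
#'
#' Percentages are computed over unambiguous A/C/G/T only; IUPAC ambiguity
#' codes are excluded from both numerator and denominator and reported in
#' `n_ambiguous`.
#'
#' @param seq Nucleotide string (DNA alphabet; U is counted as T).
#' @param label Region label for the output row.
#' @return One-row data frame: `region`, `n_counted`, `n_ambiguous`,
#'   `pct_A`, `pct_T`, `pct_G`, `pct_C`, `at_content`, `at_skew`, `gc_skew`.
#' @export
#' @examples
#' base_composition("AATT")$at_content  # 100
base_composition <- function(seq, label = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nchar(seq)) stop("empty sequence")
  ch <- seq_chars(chartr("U", "T", toupper(seq)))
  n <- c(A = sum(ch == "A"), T = sum(ch == "T"),
         G = sum(ch == "G"), C = sum(ch == "C"))
  composition_from_counts(n, n_ambiguous = length(ch) - sum(n), label = label)
}

# Build a composition row from A/T/G/C counts.
composition_from_counts <- function(n, n_ambiguous = 0L, label = "sequence") {
  tot <- sum(n)
  pct <- if (tot > 0) 100 * n / tot else
    stats::setNames(rep(NA_real_, 4), c("A", "T", "G", "C"))
  data.frame(region = label,
             n_counted = as.integer(tot),
             n_ambiguous = as.integer(n_ambiguous),
             pct_A = pct[["A"]], pct_T = pct[["T"]],
             pct_G = pct[["G"]], pct_C = pct[["C"]],
             at_content = pct[["A"]] + pct[["T"]],
             at_skew = at_skew(n[["A"]], n[["T"]]),
             gc_skew = gc_skew(n[["G"]], n[["C"]]),
             stringsAsFactors = FALSE)
}

#' Composition rows for genes, gene-class aggregates, or the whole genome
#'
#' Per-gene rows use each gene's coding-strand sequence. Aggregate rows
#' (`"PCG"`, `"tRNA"`, `"rRNA"`) are computed on the concatenation of the
#' member coding-strand sequences -- i.e. length-weighted, never an average
#' of percentages. `"total"` uses the full plus strand.
#'
#' @param genome A [mito_genome()].
#' @param selector Either a character vector of gene names, or one of
#'   `"PCG"`, `"tRNA"`, `"rRNA"` (per-gene rows plus an aggregate row), or
#'   `"total"`.
#' @param aggregate_only For class selectors, return only the aggregate row.
#' @return Data frame of composition rows (possibly empty, with a warning,
#'   when the selector matches nothing).
#' @export
partition_composition <- function(genome, selector = "total",
                                  aggregate_only = FALSE) {
  stopifnot(inherits(genome, "mito_genome"))
  if (identical(selector, "total")) {
    return(base_composition(genome$sequence, label = "Total"))
  }
  f <- genome$features
  if (length(selector) == 1L && selector %in% c("PCG", "tRNA", "rRNA")) {
    sel <- f[f$gene_class == selector, , drop = FALSE]
    agg_label <- sprintf("%d %ss", nrow(sel), selector)
  } else {
    sel <- f[f$gene %in% selector, , drop = FALSE]
    agg_label <- NULL
  }
  if (!nrow(sel)) {
    warning("selector matched no features")
    return(composition_from_counts(c(A = 0L, T = 0L, G = 0L, C = 0L),
                                   label = "empty")[0, ])
  }
  seqs <- vapply(seq_len(nrow(sel)),
                 function(i) extract_gene_sequence(genome, sel[i, , drop = FALSE]),
                 character(1))
  rows <- do.call(rbind, Map(base_composition, seqs, sel$gene))
  if (!is.null(agg_label)) {
    rows <- rbind(rows,
                  base_composition(paste(seqs, collapse = ""), agg_label))
  }
  rownames(rows) <- NULL
  if (aggregate_only && !is.null(agg_label))
    rows <- rows[nrow(rows), , drop = FALSE]
  rows
}

#' Full composition table for a genome
#'
#' One row per protein-coding gene, an aggregate row for the tRNA set,
#' per-gene rows for the rRNAs plus their aggregate, an aggregate row for
#' the PCG set, and a `Total` row on the plus strand -- the layout used in
#' mitogenome description tables.
#'
#' @param genome A [mito_genome()].
#' @return Data frame of composition rows.
#' @export
composition_table <- function(genome) {
  stopifnot(inherits(genome, "mito_genome"))
  rows <- list()
  f <- genome$features
  if (any(f$gene_class == "PCG"))
    rows$pcg <- partition_composition(genome, "PCG")
  if (any(f$gene_class == "tRNA"))
    rows$trna <- partition_composition(genome, "tRNA", aggregate_only = TRUE)
  if (any(f$gene_class == "rRNA"))
    rows$rrna <- partition_composition(genome, "rRNA")
  rows$total <- base_composition(genome$sequence, "Total")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' GC content in sliding windows
#'
#' Plain windowed G+C fraction along the plus strand (circular wrap not
#' applied), for export alongside genome maps.
#'
#' @param genome A [mito_genome()] or a sequence string.
#' @param window Window size in bp.
#' @param step Step size in bp (defaults to `window`, i.e. non-overlapping).
#' @return Data frame `start`, `end`, `gc_pct`.
#' @export
windowed_gc <- function(genome, window = 50L, step = window) {
  seq <- if (inherits(genome, "mito_genome")) genome$sequence else genome
  ch <- seq_chars(seq)
  starts <- seq(1L, max(1L, length(ch) - window + 1L), by = step)
  gc <- vapply(starts, function(s) {
    w <- ch[s:min(s + window - 1L, length(ch))]
    100 * sum(w %in% c("G", "C")) / sum(w %in% c("A", "C", "G", "T"))
  }, numeric(1))
  data.frame(start = starts,
             end = pmin(starts + window - 1L, length(ch)),
             gc_pct = gc)
}
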