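# Codon extraction, start/stop identification and RSCU.
#
# RSCU for codon c in a synonym family F is
#   count(c) * |F| / sum(counts over F),
# i.e. the observed count divided by the expectation under uniform usage
# within the family. Stop codons form their own 2-member family under the
# mitochondrial codes used here and are included in counts and RSCU.

#' Split a CDS into codons and a trailing fragment
#'
#' Codons are consecutive non-overlapping triplets from position 1; a 1-2 nt
#' remainder (the incomplete stop of a polyadenylation-completed gene) is
#' returned separately and never counted as a codon.
#'
#' @param cds Coding-strand nucleotide string, length >= 3.
#' @return List with `codons` (character vector) and `trailing` (string,
#'   possibly empty).
#' @export
#' @examples
#' split_codons("ATGAAAT")$trailing  # "T"
split_codons <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 3L) stop("CDS shorter than one codon")
  k <- n %/% 3L
  starts <- 3L * (seq_len(k) - 1L) + 1L
  list(codons = substring(cds, starts, starts + 2L),
       trailing = if (n %% 3L) substr(cds, 3L * k + 1L, n) else "")
}

#' Identify the start codon and stop token of a CDS
#'
#' The start is the first triplet. The stop token is the final complete
#' triplet when it is a stop codon under `code`; otherwise a 1-2 nt trailing
#' fragment `"T"`/`"TA"` is reported as an incomplete stop; otherwise
#' `"none"`.
#'
#' @param cds Coding-strand nucleotide string, length >= 6.
#' @param code A [genetic_code()].
#' @return List with `start` (3-letter codon) and `stop` (codon, `"T"`,
#'   `"TA"`, or `"none"`).
#' @export
identify_start_stop <- function(cds, code = genetic_code(5)) {
  cds <- toupper(cds)
  if (nchar(cds) < 6L) stop("CDS shorter than two codons")
  parts <- split_codons(cds)
  last <- parts$codons[length(parts$codons)]
  stop_token <- if (nzchar(parts$trailing)) {
    parts$trailing
  } else if (isTRUE(is_stop_codon(last, code))) {
    last
  } else "none"
  list(start = parts$codons[1], stop = stop_token)
}

#' Start/stop codon table for all protein-coding genes of a genome
#'
#' @param genome A [mito_genome()].
#' @param code A [genetic_code()].
#' @return Data frame `gene`, `start_codon`, `stop_codon`.
#' @export
start_stop_table <- function(genome, code = genetic_code(5)) {
  seqs <- extract_class_sequences(genome, "PCG")
  if (!length(seqs))
    return(data.frame(gene = character(0), start_codon = character(0),
                      stop_codon = character(0), stringsAsFactors = FALSE))
  res <- lapply(seqs, identify_start_stop, code = code)
  data.frame(gene = names(seqs),
             start_codon = vapply(res, `[[`, character(1), "start"),
             stop_codon = vapply(res, `[[`, character(1), "stop"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pooled codon counts over the protein-coding genes of a genome
#'
#' Counts are pooled over all PCG coding strands, including terminal
#' complete stop codons but excluding 1-2 nt incomplete-stop fragments.
#' Codons containing IUPAC ambiguity codes are either dropped
#' (`ambiguity_policy = "drop"`, default) or distributed with weight `1/k`
#' over the `k` compatible concrete codons (`"split"`), which is how
#' fractional counts such as 0.5 arise.
#'
#' @param genome A [mito_genome()] (or a named character vector of
#'   coding-strand CDS sequences).
#' @param code A [genetic_code()].
#' @param ambiguity_policy `"drop"` or `"split"`.
#' @return Named numeric vector of length 64 (codon -> count, possibly
#'   fractional). Empty genomes yield all-zero counts with a warning.
#' @export
count_codons <- function(genome, code = genetic_code(5),
                         ambiguity_policy = c("drop", "split")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  seqs <- if (inherits(genome, "mito_genome"))
    extract_class_sequences(genome, "PCG") else genome
  counts <- stats::setNames(numeric(64), names(code$map))
  if (!length(seqs)) {
    warning("no protein-coding features; returning zero counts")
    return(counts)
  }
  for (s in seqs) {
    for (codon in split_codons(s)$codons) {
      if (is_unambiguous(codon)) {
        counts[codon] <- counts[codon] + 1
      } else if (ambiguity_policy == "split") {
        comp <- expand_ambiguous_codon(codon)
        if (length(comp))
          counts[comp] <- counts[comp] + 1 / length(comp)
      }
    }
  }
  counts
}

#' Relative synonymous codon usage
#'
#' @param counts Named numeric vector of codon counts (codons absent from
#'   the vector count as zero; fractional counts allowed).
#' @param code A [genetic_code()].
#' @return A data frame of class `codon_usage`: columns `aa`, `codon`,
#'   `count`, `family_size`, `rscu`. Families whose total count is zero get
#'   `NA` RSCU for all members.
#' @export
#' @examples
#' leu <- c(TTA = 247, TTG = 47, CTT = 49, CTC = 7, CTA = 48, CTG = 3)
#' subset(rscu(leu), codon == "TTA")$rscu  # 3.696...
rscu <- function(counts, code = genetic_code(5)) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  names(counts) <- toupper(names(counts))
  unknown <- setdiff(names(counts), names(code$map))
  if (length(unknown))
    stop("unknown codon(s): ", paste(unknown, collapse = ", "))
  if (any(counts < 0)) stop("negative codon count")
  full <- stats::setNames(numeric(64), names(code$map))
  full[names(counts)] <- counts
  rows <- lapply(names(code$families), function(aa) {
    fam <- code$families[[aa]]
    tot <- sum(full[fam])
    data.frame(aa = aa, codon = fam, count = unname(full[fam]),
               family_size = length(fam),
               rscu = if (tot > 0) unname(full[fam]) * length(fam) / tot
                      else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aa, out$codon), ]
  rownames(out) <- NULL
  class(out) <- c("codon_usage", "data.frame")
  out
}

#' @export
print.codon_usage <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y$rscu <- round_half_up(y$rscu, digits)
  print(y, row.names = FALSE, ...)
  invisible(x)
}

#' Codon-usage table for a genome
#'
#' Convenience wrapper: pooled PCG codon counts followed by RSCU.
#'
#' @inheritParams count_codons
#' @return A `codon_usage` data frame (see [rscu()]).
#' @export
codon_usage_table <- function(genome, code = genetic_code(5),
                              ambiguity_policy = c("drop", "split")) {
  rscu(count_codons(genome, code, match.arg(ambiguity_policy)), code)
}
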