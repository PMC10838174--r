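# Shared sequence helpers.

IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a nucleotide string
#'
#' Handles the full IUPAC ambiguity alphabet; characters outside it (gaps,
#' for instance) are passed through unchanged after reversal.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse-complemented strings.
#' @export
#' @examples
#' reverse_complement("ATGC")  # "GCAT"
reverse_complement <- function(x) {
  stopifnot(is.character(x))
  comp <- function(s) chartr("ACGTURYSWKMBDHVNacgturyswkmbdhvn",
                             "TGCAAYRSWMKVHDBNtgcaayrswmkvhdbn", s)
  vapply(x, function(s) {
    comp(paste(rev(strsplit(s, NULL, fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(x) strsplit(toupper(x), NULL, fixed = TRUE)[[1]]

# Round half away from zero at `digits` decimals, the convention used by the
# printed tables this package reproduces (base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
# `stream` decorrelates generators that share one user-facing seed.
with_seed <- function(seed, expr, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) + 97003L * as.integer(stream)) %% .Machine$integer.max)
  expr
}

# All concrete A/C/G/T codons compatible with a (possibly ambiguous) codon.
expand_ambiguous_codon <- function(codon) {
  ch <- seq_chars(codon)
  if (length(ch) != 3L) stop("codon must have exactly 3 bases")
  sets <- lapply(ch, function(b) {
    out <- IUPAC_EXPAND[[b]]
    if (is.null(out)) character(0) else out
  })
  if (any(lengths(sets) == 0L)) return(character(0))
  as.vector(outer(outer(sets[[1]], sets[[2]], paste0), sets[[3]], paste0))
}

is_unambiguous <- function(x) !grepl("[^ACGT]", toupper(x))
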