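# Genetic-code tables and synonym (degeneracy) families.
#
# Code tables are data, keyed by NCBI translation-table id, so switching
# between the invertebrate (5) and vertebrate (2) mitochondrial codes -- or
# the standard code (1) -- is a parameter, not a code change.

# Codons in NCBI layout: first base slowest, base order T, C, A, G.
.codon_order <- function() {
  b <- c("T", "C", "A", "G")
  paste0(rep(b, each = 16L), rep(rep(b, each = 4L), times = 4L), rep(b, times = 16L))
}

# One-letter amino-acid strings in NCBI table layout ('*' = stop).
.NCBI_AA <- c(
  `1` = "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `2` = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSS**VVVVAAAADDEEGGGG",
  `5` = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSSSSVVVVAAAADDEEGGGG"
)

#' Genetic-code table with degeneracy families
#'
#' Builds a genetic-code object for an NCBI translation table. The default,
#' table 5 (invertebrate mitochondrial), is the code under which insect
#' mitogenome protein-coding genes are read: ATA encodes Met, TGA encodes
#' Trp, and AGA/AGG join the serine family, giving an 8-codon Ser family,
#' a 6-codon Leu family and a 2-codon stop family {TAA, TAG}.
#'
#' @param table_id NCBI translation-table id: 5 (invertebrate mitochondrial,
#'   default), 2 (vertebrate mitochondrial) or 1 (standard).
#' @return An object of class `genetic_code`: a list with `table_id`, `map`
#'   (named character vector codon -> amino acid, `"*"` for stop) and
#'   `families` (list of codon vectors, one per amino acid including the
#'   stop family).
#' @export
#' @examples
#' code <- genetic_code(5)
#' code$map[["ATA"]]           # "M"
#' length(code$families$S)     # 8
genetic_code <- function(table_id = 5) {
  key <- as.character(table_id)
  if (!key %in% names(.NCBI_AA))
    stop("unknown genetic-code table id: ", table_id,
         " (available: ", paste(names(.NCBI_AA), collapse = ", "), ")")
  codons <- .codon_order()
  aa <- strsplit(.NCBI_AA[[key]], NULL)[[1]]
  map <- stats::setNames(aa, codons)
  families <- split(codons, aa)
  structure(list(table_id = as.integer(table_id), map = map,
                 families = families),
            class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  n_stop <- sum(x$map == "*")
  cat("Genetic code (NCBI translation table ", x$table_id, "): ",
      64L - n_stop, " sense codons, ", n_stop, " stop codons, ",
      length(x$families), " degeneracy families\n", sep = "")
  invisible(x)
}

#' Translate in-frame codons
#'
#' @param codons Character vector of 3-base codons (A/C/G/T); ambiguous
#'   codons translate to `NA`.
#' @param code A [genetic_code()] object.
#' @return Character vector of one-letter amino acids (`"*"` = stop).
#' @export
translate_codons <- function(codons, code = genetic_code(5)) {
  stopifnot(inherits(code, "genetic_code"))
  out <- unname(code$map[toupper(codons)])
  out
}

is_stop_codon <- function(codons, code) {
  aa <- code$map[toupper(codons)]
  !is.na(aa) & aa == "*"
}
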