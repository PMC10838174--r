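# Circular-genome container and feature handling.
#
# Coordinates are 1-based inclusive throughout (GenBank convention); a
# feature that spans the circular origin is stored with start > end and
# wraps = TRUE.

#' Construct a gene-feature table
#'
#' Builds the validated feature data frame used inside a [mito_genome()].
#' One row per annotated gene, sorted by start coordinate (ties broken by
#' end coordinate).
#'
#' @param gene Character vector of gene names (e.g. `"COX1"`, `"trnM"`,
#'   `"rrnL"`).
#' @param start,end 1-based inclusive coordinates. `start > end` marks a
#'   feature wrapping the circular origin.
#' @param strand `"+"` or `"-"`.
#' @param gene_class Optional; one of `"PCG"`, `"tRNA"`, `"rRNA"` per
#'   feature. Inferred from the gene name when omitted (names starting
#'   `trn` are tRNAs; `rrn`/`rRNA` names are rRNAs; the rest are PCGs).
#' @param anticodon Optional 3-letter anticodon (RNA alphabet) for tRNAs;
#'   must be `NA` for other classes.
#' @param genome_length Optional genome length used to compute the size of
#'   wrapping features.
#' @return A data frame with columns `gene`, `gene_class`, `start`, `end`,
#'   `strand`, `wraps`, `size_bp`, `anticodon`.
#' @export
gene_features <- function(gene, start, end, strand,
                          gene_class = NULL, anticodon = NA_character_,
                          genome_length = NA_integer_) {
  n <- length(gene)
  start <- as.integer(start); end <- as.integer(end)
  strand <- as.character(strand)
  stopifnot(length(start) == n, length(end) == n, length(strand) == n)
  if (n == 0L) {
    return(data.frame(gene = character(0), gene_class = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), wraps = logical(0),
                      size_bp = integer(0), anticodon = character(0),
                      stringsAsFactors = FALSE))
  }
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-numeric feature coordinates")
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-' (got: ",
         paste(unique(setdiff(strand, c("+", "-"))), collapse = ", "), ")")
  if (is.null(gene_class)) gene_class <- infer_gene_class(gene)
  gene_class <- rep_len(gene_class, n)
  if (!all(gene_class %in% c("PCG", "tRNA", "rRNA")))
    stop("gene_class must be PCG, tRNA or rRNA")
  anticodon <- rep_len(as.character(anticodon), n)
  bad_ac <- which(gene_class != "tRNA" & !is.na(anticodon) & nzchar(anticodon))
  if (length(bad_ac))
    stop("anticodon given for non-tRNA feature: ", gene[bad_ac[1]])
  wraps <- end < start
  if (any(wraps) && any(is.na(genome_length)))
    stop("genome_length required to size wrap-around features")
  size_bp <- ifelse(wraps,
                    as.integer(genome_length) - start + 1L + end,
                    end - start + 1L)
  if (any(size_bp < 1L)) stop("feature with non-positive size")
  small <- which(gene_class == "PCG" & size_bp < 3L)
  if (length(small))
    stop("protein-coding feature shorter than one codon: ", gene[small[1]])
  df <- data.frame(gene = as.character(gene), gene_class = gene_class,
                   start = start, end = end, strand = strand, wraps = wraps,
                   size_bp = as.integer(size_bp), anticodon = anticodon,
                   stringsAsFactors = FALSE)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Class from name: trnX -> tRNA, rrnL/rrnS/"16S rRNA" -> rRNA, else PCG.
infer_gene_class <- function(gene) {
  g <- tolower(gene)
  ifelse(grepl("^trn", g), "tRNA",
         ifelse(grepl("rrn|rrna|ribosomal", g), "rRNA", "PCG"))
}

# Synonym map so table-style names and GenBank product names interoperate.
.GENE_SYNONYMS <- c(
  "cob" = "CYTB", "cytb" = "CYTB", "cob/cytb" = "CYTB",
  "co1" = "COX1", "coi" = "COX1", "cox1" = "COX1",
  "co2" = "COX2", "coii" = "COX2", "cox2" = "COX2",
  "co3" = "COX3", "coiii" = "COX3", "cox3" = "COX3",
  "atp6" = "ATP6", "atp8" = "ATP8",
  "nad1" = "ND1", "nad2" = "ND2", "nad3" = "ND3", "nad4" = "ND4",
  "nad4l" = "ND4L", "nad5" = "ND5", "nad6" = "ND6",
  "nd1" = "ND1", "nd2" = "ND2", "nd3" = "ND3", "nd4" = "ND4",
  "nd4l" = "ND4L", "nd5" = "ND5", "nd6" = "ND6",
  "rrnl" = "rrnL", "16s" = "rrnL", "16s rrna" = "rrnL", "l-rrna" = "rrnL",
  "rrns" = "rrnS", "12s" = "rrnS", "12s rrna" = "rrnS", "s-rrna" = "rrnS"
)

#' Normalise a gene name
#'
#' Case-insensitive matching against a synonym map (CYTB/cob, rrnL/16S rRNA,
#' trnL1/trnL_1, ...) so annotation tables and GenBank records interoperate.
#'
#' @param gene Character vector of gene names.
#' @return Character vector of canonical names (`COX1..3`, `ATP6/8`,
#'   `ND1..6`, `ND4L`, `CYTB`, `rrnL`, `rrnS`, `trnX` forms).
#' @export
normalize_gene_name <- function(gene) {
  vapply(gene, function(g) {
    key <- tolower(trimws(g))
    if (key %in% names(.GENE_SYNONYMS)) return(.GENE_SYNONYMS[[key]])
    if (grepl("^trn", key)) {
      # trnL_1, trnL-1, trnL(uag) style -> trnL1
      core <- sub("^trn", "", key)
      core <- gsub("[ _()-]", "", core)
      return(paste0("trn", toupper(substr(core, 1, 1)),
                    substr(core, 2, nchar(core))))
    }
    toupper(g)
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a mitochondrial-genome object
#'
#' The central container: a (usually circular) nucleotide sequence plus an
#' ordered gene-feature table.
#'
#' @param sequence Single nucleotide string (IUPAC alphabet; ambiguity codes
#'   are preserved verbatim).
#' @param features A feature data frame from [gene_features()] (or with the
#'   same columns); may be empty.
#' @param id Identifier (accession or label).
#' @param circular Logical; is the molecule circular?
#' @return An object of class `mito_genome`: list with `id`, `sequence`,
#'   `length_bp`, `is_circular`, `features`.
#' @export
#' @examples
#' g <- mito_genome("ATGAAATAA",
#'                  gene_features("demo", 1, 9, "+", gene_class = "PCG"))
#' g$length_bp
mito_genome <- function(sequence, features = gene_features(character(0),
                        integer(0), integer(0), character(0)),
                        id = "genome", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(gsub("[ \n\r\t0-9]", "", sequence))
  len <- nchar(sequence)
  if (len < 1L) stop("empty genome sequence")
  req <- c("gene", "gene_class", "start", "end", "strand", "wraps",
           "size_bp", "anticodon")
  if (!all(req %in% names(features)))
    features <- gene_features(features$gene, features$start, features$end,
                              features$strand,
                              gene_class = features$gene_class,
                              anticodon = if (is.null(features$anticodon))
                                NA_character_ else features$anticodon,
                              genome_length = len)
  if (nrow(features)) {
    oob <- features$start < 1L | features$start > len |
      features$end < 1L | features$end > len
    if (any(oob))
      stop("feature outside sequence bounds: ",
           paste(features$gene[oob], collapse = ", "))
    if (any(features$wraps) && !circular)
      stop("wrap-around feature on a linear genome: ",
           paste(features$gene[features$wraps], collapse = ", "))
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(id = id, sequence = sequence, length_bp = len,
                 is_circular = isTRUE(circular), features = features),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s: %s bp, %s, %d features\n", x$id,
              format(x$length_bp, big.mark = ","),
              if (x$is_circular) "circular" else "linear",
              nrow(x$features)))
  if (nrow(x$features)) {
    tab <- table(x$features$gene_class)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.mito_genome <- function(object, ...) {
  print(object)
  comp <- base_composition(object$sequence, label = "Total")
  cat(sprintf("  A+T %.1f%%, AT-skew %.3f, GC-skew %.3f\n",
              comp$at_content, comp$at_skew, comp$gc_skew))
  invisible(comp)
}

#' Extract the coding-strand sequence of a feature
#'
#' Forward features return the plus-strand slice; reverse features return its
#' reverse complement; wrap-around features concatenate the two arcs (end of
#' sequence then start) before orientation.
#'
#' @param genome A [mito_genome()].
#' @param feature A single-row feature data frame, a row index, or a gene
#'   name present in `genome$features`.
#' @return Nucleotide string of length `size_bp`.
#' @export
extract_gene_sequence <- function(genome, feature) {
  stopifnot(inherits(genome, "mito_genome"))
  if (is.character(feature)) {
    i <- match(feature, genome$features$gene)
    if (is.na(i)) stop("no feature named '", feature, "'")
    feature <- genome$features[i, , drop = FALSE]
  } else if (is.numeric(feature)) {
    feature <- genome$features[feature, , drop = FALSE]
  }
  stopifnot(nrow(feature) == 1L)
  len <- genome$length_bp
  if (feature$start < 1L || feature$start > len ||
      feature$end < 1L || feature$end > len)
    stop("feature outside sequence bounds: ", feature$gene)
  s <- if (isTRUE(feature$wraps) || feature$start > feature$end) {
    if (!genome$is_circular) stop("wrap-around feature on linear genome")
    paste0(substr(genome$sequence, feature$start, len),
           substr(genome$sequence, 1L, feature$end))
  } else {
    substr(genome$sequence, feature$start, feature$end)
  }
  if (feature$strand == "-") reverse_complement(s) else s
}

# All coding-strand sequences for a class (or all features).
extract_class_sequences <- function(genome, gene_class = NULL) {
  f <- genome$features
  if (!is.null(gene_class)) f <- f[f$gene_class %in% gene_class, , drop = FALSE]
  if (!nrow(f)) return(stats::setNames(character(0), character(0)))
  stats::setNames(
    vapply(seq_len(nrow(f)),
           function(i) extract_gene_sequence(genome, f[i, , drop = FALSE]),
           character(1)),
    f$gene)
}
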