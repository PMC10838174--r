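# GenBank flat-file and feature-table input/output.
#
# The flat-file reader/writer covers the subset of the format that annotated
# mitogenome records use: LOCUS topology, source/CDS/tRNA/rRNA features with
# plain, complement() and origin-spanning join() locations, /gene, /product
# and /anticodon qualifiers, and the ORIGIN sequence block.

#' Read a GenBank flat-file record into a mito_genome
#'
#' @param x Path to a GenBank file, or the record text itself (single string
#'   or character vector of lines).
#' @return A [mito_genome()]. CDS features map to class PCG; `complement()`
#'   locations become reverse-strand features; `join()` locations spanning
#'   the origin become wrap-around features; topology is taken from the
#'   LOCUS line.
#' @export
read_genbank <- function(x) {
  lines <- .as_lines(x)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("GenBank parse error: no LOCUS line")
  circular <- grepl("\\bcircular\\b", locus[1], ignore.case = TRUE)
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]

  ori <- grep("^ORIGIN", lines)
  if (!length(ori))
    stop("GenBank parse error: missing ORIGIN sequence block")
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > ori[1]][1] else length(lines) + 1L
  if (is.na(endrec)) endrec <- length(lines) + 1L
  seq_lines <- lines[(ori[1] + 1L):(endrec - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence))
    stop("GenBank parse error: empty ORIGIN sequence block")

  feats <- .parse_genbank_features(lines, ori[1])
  features <- if (nrow(feats)) {
    gene_features(feats$gene, feats$start, feats$end, feats$strand,
                  gene_class = feats$gene_class, anticodon = feats$anticodon,
                  genome_length = nchar(sequence))
  } else {
    gene_features(character(0), integer(0), integer(0), character(0))
  }
  mito_genome(sequence, features, id = id, circular = circular)
}

.as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    return(readLines(x, warn = FALSE))
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

.parse_genbank_features <- function(lines, origin_at) {
  fstart <- grep("^FEATURES", lines)
  if (!length(fstart) || fstart[1] > origin_at)
    return(data.frame(gene = character(0)))
  block <- lines[(fstart[1] + 1L):(origin_at - 1L)]
  key_re <- "^ {2,8}(\\S+) +(\\S.*)$"
  is_key <- grepl(key_re, block) & !grepl("^ {10,}", block)
  out <- list()
  cur <- NULL
  flush <- function(cur, out) {
    if (is.null(cur)) return(out)
    if (!cur$key %in% c("CDS", "tRNA", "rRNA")) return(out)
    loc <- .parse_location(cur$loc)
    name <- cur$qual[["gene"]] %||% cur$qual[["product"]] %||% cur$key
    ac <- NA_character_
    if (cur$key == "tRNA") {
      acq <- cur$qual[["anticodon"]]
      if (!is.null(acq)) {
        m <- regmatches(acq, regexpr("seq:[A-Za-z]{3}", acq))
        ac <- if (length(m)) toupper(sub("seq:", "", m)) else
          toupper(gsub("[^A-Za-z]", "", acq))
        ac <- chartr("T", "U", ac)
        if (nchar(ac) != 3L) ac <- NA_character_
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      gene = name,
      gene_class = c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA")[[cur$key]],
      start = loc$start, end = loc$end, strand = loc$strand,
      anticodon = ac, stringsAsFactors = FALSE)
    out
  }
  i <- 1L
  while (i <= length(block)) {
    ln <- block[i]
    if (is_key[i]) {
      out <- flush(cur, out)
      m <- regmatches(ln, regexec(key_re, ln))[[1]]
      cur <- list(key = m[2], loc = m[3], qual = list(), in_loc = TRUE)
    } else if (!is.null(cur)) {
      t <- trimws(ln)
      if (startsWith(t, "/")) {
        cur$in_loc <- FALSE
        eq <- regexpr("=", t, fixed = TRUE)
        if (eq > 0) {
          nm <- substr(t, 2L, eq - 1L)
          val <- gsub('^"|"$', "", substr(t, eq + 1L, nchar(t)))
          cur$qual[[nm]] <- val
        }
      } else if (isTRUE(cur$in_loc)) {
        cur$loc <- paste0(cur$loc, t)   # continued location line
      }
    }
    i <- i + 1L
  }
  out <- flush(cur, out)
  if (!length(out)) return(data.frame(gene = character(0)))
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# "123..456", "complement(...)", "join(a..b,c..d)" (origin-spanning),
# with partial markers (<, >) tolerated.
.parse_location <- function(loc) {
  loc <- gsub("[<> ]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
    rng <- lapply(parts, .parse_span)
    # origin-spanning join: start of first arc, end of last arc
    return(list(start = rng[[1]][1], end = rng[[length(rng)]][2],
                strand = strand))
  }
  r <- .parse_span(loc)
  list(start = r[1], end = r[2], strand = strand)
}

.parse_span <- function(s) {
  p <- strsplit(s, "\\.\\.")[[1]]
  v <- suppressWarnings(as.integer(p))
  if (length(v) == 1L) v <- c(v, v)
  if (any(is.na(v))) stop("GenBank parse error: bad location '", s, "'")
  v
}

#' Write a mito_genome as a GenBank flat file
#'
#' Emits the subset of the format that [read_genbank()] consumes, so a
#' write/read round trip preserves every feature field.
#'
#' @param genome A [mito_genome()].
#' @param path Output file path; when `NULL` the record text is returned
#'   invisibly as a character vector of lines.
#' @export
write_genbank <- function(genome, path = NULL) {
  stopifnot(inherits(genome, "mito_genome"))
  topo <- if (genome$is_circular) "circular" else "linear"
  out <- c(sprintf("LOCUS       %-16s %d bp    DNA     %s   UNA",
                   genome$id, genome$length_bp, topo),
           sprintf("DEFINITION  %s mitochondrial genome.", genome$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", genome$length_bp))
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    key <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA")[[f$gene_class[i]]]
    span <- if (f$wraps[i])
      sprintf("join(%d..%d,1..%d)", f$start[i], genome$length_bp, f$end[i])
    else sprintf("%d..%d", f$start[i], f$end[i])
    if (f$strand[i] == "-") span <- sprintf("complement(%s)", span)
    out <- c(out, sprintf("     %-16s%s", key, span),
             sprintf("                     /gene=\"%s\"", f$gene[i]))
    if (!is.na(f$anticodon[i]) && nzchar(f$anticodon[i]))
      out <- c(out, sprintf(
        "                     /anticodon=\"(seq:%s)\"",
        tolower(f$anticodon[i])))
  }
  out <- c(out, "ORIGIN")
  s <- tolower(genome$sequence)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  invisible(out)
}

#' Read a tab-separated gene feature table
#'
#' Expects a header with columns `gene`, `start`, `end`, `strand` and
#' optionally `anticodon` and `size`. Coordinates are 1-based inclusive.
#' Gene class is inferred from the name ([infer_gene_class()]); a provided
#' `size` column is checked against the coordinates and a warning is issued
#' on disagreement (the recomputed size wins).
#'
#' @param x Path to a TSV file or its text.
#' @param genome_length Optional genome length (needed to size wrap-around
#'   rows).
#' @return Feature data frame as from [gene_features()].
#' @export
read_feature_table <- function(x, genome_length = NA_integer_) {
  lines <- .as_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(gene_features(character(0), integer(0), integer(0), character(0)))
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE, check.names = TRUE)
  names(df) <- tolower(names(df))
  need <- c("gene", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop("feature table parse error: need columns ",
         paste(need, collapse = ", "))
  # tolerate the typographic minus sign used in publication tables
  df$strand <- chartr("−–", "--", trimws(df$strand))
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.integer(gsub(",", "", df[[col]])))
    if (any(is.na(v)))
      stop("feature table parse error: non-numeric ", col,
           " at line ", which(is.na(v))[1] + 1L)
    df[[col]] <- v
  }
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad))
    stop("feature table parse error: unknown strand symbol '",
         df$strand[bad[1]], "' at line ", bad[1] + 1L)
  feats <- gene_features(df$gene, df$start, df$end, df$strand,
                         anticodon = if ("anticodon" %in% names(df)) {
                           ac <- trimws(as.character(df$anticodon))
                           ifelse(!is.na(ac) & nzchar(ac) &
                                    infer_gene_class(df$gene) == "tRNA",
                                  toupper(ac), NA_character_)
                         } else NA_character_,
                         genome_length = genome_length)
  if ("size" %in% names(df)) {
    given <- suppressWarnings(as.integer(df$size))
    m <- match(paste(feats$gene, feats$start), paste(df$gene, df$start))
    disagree <- which(!is.na(given[m]) & given[m] != feats$size_bp)
    if (length(disagree))
      warning("size column disagrees with coordinates for: ",
              paste(feats$gene[disagree], collapse = ", "),
              " (recomputed size used)")
  }
  feats
}

#' Write a gene feature table as TSV
#'
#' @param features Feature data frame.
#' @param path Output path; when `NULL` the TSV text lines are returned.
#' @export
write_feature_table <- function(features, path = NULL) {
  df <- features[, c("gene", "start", "end", "strand", "anticodon")]
  df$anticodon[is.na(df$anticodon)] <- ""
  txt <- c(paste(names(df), collapse = "\t"),
           apply(df, 1L, paste, collapse = "\t"))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  stats::setNames(toupper(vapply(recs, as.character, character(1))),
                  names(recs))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = 70)
  invisible(path)
}
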