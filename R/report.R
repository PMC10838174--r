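# Report orchestration: the per-genome description tables (gene table with
# intergenic column, composition table, RSCU table) and the multi-genome
# comparative table, with TSV/JSON emission. All derived numbers are
# recomputed from the sequence and coordinates, never copied from input.

#' Per-genome description report
#'
#' Computes the three standard description tables for one annotated
#' mitogenome: the gene table (coordinates, recomputed sizes, strand,
#' anticodon, start/stop codons, intergenic lengths), the composition table
#' (per PCG, class aggregates, total) and the RSCU table, plus an
#' architecture summary.
#'
#' @param genome A [mito_genome()].
#' @param code A [genetic_code()].
#' @param ambiguity_policy Codon-count handling of ambiguity codes
#'   ([count_codons()]).
#' @param rounding `"raw"` (full precision) or `"printed"` (percentages to
#'   1 decimal, skews to 2, RSCU to 3 -- the precision of published
#'   description tables).
#' @param out_dir Optional directory; when given, tables are written there
#'   as `gene_table`, `composition`, `rscu` (+ `.tsv`/`.json`).
#' @param format `"tsv"` or `"json"` for files written to `out_dir`.
#' @return (Invisibly when writing) list with `gene_table`, `composition`,
#'   `rscu`, `architecture`.
#' @export
run_genome_report <- function(genome, code = genetic_code(5),
                              ambiguity_policy = c("drop", "split"),
                              rounding = c("raw", "printed"),
                              out_dir = NULL, format = c("tsv", "json")) {
  stopifnot(inherits(genome, "mito_genome"))
  rounding <- match.arg(rounding)
  format <- match.arg(format)
  ambiguity_policy <- match.arg(ambiguity_policy)

  f <- genome$features
  gene_table <- data.frame(gene = f$gene, gene_class = f$gene_class,
                           start = f$start, end = f$end,
                           size_bp = f$size_bp, strand = f$strand,
                           anticodon = f$anticodon,
                           stringsAsFactors = FALSE)
  if (nrow(f)) {
    ss <- start_stop_table(genome, code)
    gene_table$start_codon <- ss$start_codon[match(gene_table$gene, ss$gene)]
    gene_table$stop_codon <- ss$stop_codon[match(gene_table$gene, ss$gene)]
    adj <- adjacency_gaps(genome)
    nonwrap <- adj[!adj$is_wrap, , drop = FALSE]
    gene_table$intergenic <- c(NA_integer_, nonwrap$intergenic_length)
  } else {
    warning("genome has no features; emitting composition Total row only")
    gene_table$start_codon <- character(0)
    gene_table$stop_codon <- character(0)
    gene_table$intergenic <- integer(0)
  }

  comp <- composition_table(genome)
  usage <- if (any(f$gene_class == "PCG"))
    codon_usage_table(genome, code, ambiguity_policy)
  else rscu(stats::setNames(numeric(0), character(0)), code)
  arch <- if (nrow(f) >= 2L) architecture_summary(genome) else NULL

  if (rounding == "printed") {
    pc <- c("pct_A", "pct_T", "pct_G", "pct_C", "at_content")
    comp[pc] <- lapply(comp[pc], round_half_up, digits = 1)
    comp[c("at_skew", "gc_skew")] <-
      lapply(comp[c("at_skew", "gc_skew")], round_half_up, digits = 2)
    usage$rscu <- round_half_up(usage$rscu, 3)
  }
  out <- list(gene_table = gene_table, composition = comp, rscu = usage,
              architecture = arch)
  if (!is.null(out_dir)) {
    .write_tables(out[c("gene_table", "composition", "rscu")],
                  out_dir, format)
    return(invisible(out))
  }
  out
}

#' Comparative report over several genomes
#'
#' One row per genome with length, A+T content and AT/GC skews for the
#' whole genome (plus strand) and for the concatenated PCG set (coding
#' strands), plus an optional per-gene Ka/Ks table when codon-aligned CDS
#' sets are supplied.
#'
#' @param genomes Named list of [mito_genome()] objects.
#' @param cds_alignments Optional named list gene -> named character vector
#'   of codon-aligned CDS across species, passed to [kaks_table()].
#' @param code A [genetic_code()].
#' @param rounding `"raw"` or `"printed"` (percentages 1 dp, skews 3 dp --
#'   comparative tables print skews to 3 decimals).
#' @param out_dir,format As in [run_genome_report()].
#' @return List with `genome_table` (one row per genome) and `kaks`
#'   (per-gene Ka/Ks data frame or `NULL`).
#' @export
run_comparative_report <- function(genomes, cds_alignments = NULL,
                                   code = genetic_code(5),
                                   rounding = c("raw", "printed"),
                                   out_dir = NULL, format = c("tsv", "json")) {
  stopifnot(is.list(genomes), length(genomes) >= 1L)
  rounding <- match.arg(rounding)
  format <- match.arg(format)
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, `[[`, character(1), "id")
  rows <- lapply(names(genomes), function(nm) {
    g <- genomes[[nm]]
    tot <- base_composition(g$sequence)
    has_pcg <- any(g$features$gene_class == "PCG")
    pcg <- if (has_pcg)
      partition_composition(g, "PCG", aggregate_only = TRUE) else NULL
    data.frame(species = nm, length_bp = g$length_bp,
               at_content = tot$at_content, at_skew = tot$at_skew,
               gc_skew = tot$gc_skew,
               pcg_length_bp = if (has_pcg)
                 sum(g$features$size_bp[g$features$gene_class == "PCG"])
               else NA_integer_,
               pcg_at_content = if (has_pcg) pcg$at_content else NA_real_,
               pcg_at_skew = if (has_pcg) pcg$at_skew else NA_real_,
               pcg_gc_skew = if (has_pcg) pcg$gc_skew else NA_real_,
               stringsAsFactors = FALSE)
  })
  genome_table <- do.call(rbind, rows)
  kk <- NULL
  if (!is.null(cds_alignments)) {
    if (length(genomes) < 2L)
      warning("Ka/Ks section skipped: fewer than two genomes")
    else kk <- kaks_table(cds_alignments, code)
  }
  if (rounding == "printed") {
    pc <- c("at_content", "pcg_at_content")
    genome_table[pc] <- lapply(genome_table[pc], round_half_up, digits = 1)
    sk <- c("at_skew", "gc_skew", "pcg_at_skew", "pcg_gc_skew")
    genome_table[sk] <- lapply(genome_table[sk], round_half_up, digits = 3)
  }
  out <- list(genome_table = genome_table, kaks = kk)
  if (!is.null(out_dir)) {
    .write_tables(Filter(Negate(is.null), out), out_dir, format)
    return(invisible(out))
  }
  out
}

.write_tables <- function(tables, out_dir, format) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    path <- file.path(out_dir, paste0(nm, ".", format))
    if (format == "tsv") {
      utils::write.table(tab, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "")
    } else {
      jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
    }
  }
  invisible(NULL)
}
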