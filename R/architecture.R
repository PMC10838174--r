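# Gene architecture on a circular genome: intergenic lengths (negative =
# overlap), overlap/spacer enumeration, and the largest unannotated span.
#
# Adjacency is defined on start-coordinate order of the mixed-strand gene
# list, matching how mitogenome description tables interleave strands;
# strand is ignored for adjacency purposes. The adjacency that crosses the
# circular origin (last gene back to first) is computed but flagged, since
# description tables usually omit it.

#' Intergenic lengths between consecutive genes
#'
#' For each consecutive pair in genome order the intergenic length is
#' `start(downstream) - end(upstream) - 1`: negative values are overlaps,
#' zero is abutting, positive values are spacers. On a circular genome a
#' final record links the last gene back to the first across the origin with
#' gap `(genome_length - end(last)) + (start(first) - 1)`.
#'
#' @param features Feature data frame sorted by start coordinate (as from
#'   [gene_features()]), or a [mito_genome()].
#' @param genome_length Genome length in bp (taken from the genome when one
#'   is supplied).
#' @param circular Include the origin-crossing adjacency?
#' @return Data frame: `upstream`, `downstream`, `intergenic_length`,
#'   `region_start`, `region_end` (the spacer/overlap span, `NA` when
#'   abutting), `is_wrap`.
#' @export
adjacency_gaps <- function(features, genome_length = NULL, circular = TRUE) {
  if (inherits(features, "mito_genome")) {
    genome_length <- features$length_bp
    circular <- features$is_circular
    features <- features$features
  }
  f <- features
  if (nrow(f) < 2L)
    return(data.frame(upstream = character(0), downstream = character(0),
                      intergenic_length = integer(0),
                      region_start = integer(0), region_end = integer(0),
                      is_wrap = logical(0), stringsAsFactors = FALSE))
  if (is.unsorted(f$start))
    stop("features must be sorted by start coordinate")
  up <- f[-nrow(f), ]
  dn <- f[-1L, ]
  gap <- dn$start - up$end - 1L
  rec <- data.frame(upstream = up$gene, downstream = dn$gene,
                    intergenic_length = gap,
                    region_start = ifelse(gap > 0, up$end + 1L,
                                          ifelse(gap < 0, dn$start, NA)),
                    region_end = ifelse(gap > 0, dn$start - 1L,
                                        ifelse(gap < 0, up$end, NA)),
                    is_wrap = FALSE, stringsAsFactors = FALSE)
  if (circular) {
    if (is.null(genome_length))
      stop("genome_length required for the circular wrap adjacency")
    last <- f[nrow(f), ]
    first <- f[1L, ]
    wgap <- (genome_length - last$end) + (first$start - 1L)
    rec <- rbind(rec, data.frame(
      upstream = last$gene, downstream = first$gene,
      intergenic_length = as.integer(wgap),
      region_start = if (wgap > 0) (last$end %% genome_length) + 1L else NA,
      region_end = if (wgap > 0) first$start - 1L else NA,
      is_wrap = TRUE, stringsAsFactors = FALSE))
  }
  rownames(rec) <- NULL
  rec
}

#' Overlap regions between adjacent genes
#'
#' Records with negative intergenic length, reported with positive overlap
#' length and sorted by length descending (ties by coordinate).
#'
#' @param records Adjacency records from [adjacency_gaps()].
#' @param include_wrap Include the origin-crossing adjacency?
#' @return Data frame with an added `length` column.
#' @export
overlap_regions <- function(records, include_wrap = FALSE) {
  r <- records[records$intergenic_length < 0 &
                 (include_wrap | !records$is_wrap), , drop = FALSE]
  r$length <- -r$intergenic_length
  r <- r[order(-r$length, r$region_start), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Spacer regions between adjacent genes
#'
#' Records with positive intergenic length, sorted by length descending.
#'
#' @inheritParams overlap_regions
#' @return Data frame with an added `length` column.
#' @export
spacer_regions <- function(records, include_wrap = FALSE) {
  r <- records[records$intergenic_length > 0 &
                 (include_wrap | !records$is_wrap), , drop = FALSE]
  r$length <- r$intergenic_length
  r <- r[order(-r$length, r$region_start), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Largest span covered by no feature
#'
#' The longest maximal run of positions not covered by any feature,
#' honouring the circular wrap (uncovered arcs abutting across the origin
#' merge into one span). In a typical mitogenome this is the putative
#' control region, but the function reports it purely positionally.
#'
#' @param genome A [mito_genome()].
#' @return List `start`, `end`, `length` (zero when fully covered; `start`
#'   may exceed `end` for a span crossing the origin).
#' @export
largest_unannotated_span <- function(genome) {
  stopifnot(inherits(genome, "mito_genome"))
  len <- genome$length_bp
  covered <- logical(len)
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    if (f$wraps[i]) {
      covered[f$start[i]:len] <- TRUE
      covered[1:f$end[i]] <- TRUE
    } else {
      covered[f$start[i]:f$end[i]] <- TRUE
    }
  }
  if (all(covered)) return(list(start = NA_integer_, end = NA_integer_,
                                length = 0L))
  if (!any(covered)) return(list(start = 1L, end = len, length = len))
  # runs of uncovered positions
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[!r$values], end = ends[!r$values],
                     length = r$lengths[!r$values])
  if (genome$is_circular && nrow(runs) > 1L &&
      runs$start[1] == 1L && runs$end[nrow(runs)] == len) {
    # merge the arc across the origin
    runs$length[nrow(runs)] <- runs$length[nrow(runs)] + runs$length[1]
    runs$end[nrow(runs)] <- runs$end[1]
    runs <- runs[-1L, , drop = FALSE]
  }
  best <- runs[which.max(runs$length), ]
  list(start = as.integer(best$start), end = as.integer(best$end),
       length = as.integer(best$length))
}

#' Architecture summary for a genome
#'
#' @param genome A [mito_genome()].
#' @return List: `adjacencies` (data frame), `n_overlaps`, `n_spacers`,
#'   `longest_overlap`, `longest_spacer`, `largest_unannotated`.
#' @export
architecture_summary <- function(genome) {
  adj <- adjacency_gaps(genome)
  ov <- overlap_regions(adj)
  sp <- spacer_regions(adj)
  list(adjacencies = adj,
       n_overlaps = nrow(ov), n_spacers = nrow(sp),
       longest_overlap = if (nrow(ov)) ov$length[1] else 0L,
       longest_spacer = if (nrow(sp)) sp$length[1] else 0L,
       largest_unannotated = largest_unannotated_span(genome))
}
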