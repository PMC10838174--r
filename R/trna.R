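# tRNA secondary-structure parsing and architecture classification.
#
# Structures are input as Vienna dot-bracket strings (the folds come from
# external predictors); this module decomposes them into acceptor, D,
# anticodon and T arms, classifies the architecture (cloverleaf, D-armless,
# T-armless, minimal), and counts G-U wobble pairs. A helix counts as an
# arm when its stem has at least 2 base pairs (mitochondrial T arms as
# short as 2 bp occur).

#' Parse a dot-bracket secondary structure
#'
#' @param structure Dot-bracket string over `.`, `(`, `)`.
#' @return Integer vector `pairing`: `pairing[i]` is the 1-based partner of
#'   position `i`, or 0 when unpaired. Pairs are properly nested by
#'   construction (single bracket type, no pseudoknots).
#' @export
#' @examples
#' parse_dot_bracket("((..))")  # 6 5 0 0 2 1
parse_dot_bracket <- function(structure) {
  ch <- strsplit(structure, NULL, fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), c(".", "(", ")"))
  if (length(bad))
    stop("dot-bracket parse error: unexpected character(s) ",
         paste(sQuote(bad), collapse = ", "))
  pairing <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack))
        stop("dot-bracket parse error: unbalanced ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairing[i] <- j
      pairing[j] <- i
    }
  }
  if (length(stack))
    stop("dot-bracket parse error: unbalanced '(' at position ", stack[1])
  pairing
}

# Helices: maximal runs of strictly stacked pairs (i, j), (i+1, j-1), ...
.find_helices <- function(pairing) {
  open <- which(pairing > seq_along(pairing))
  if (!length(open)) return(list())
  helices <- list()
  cur <- c(open[1])
  for (i in open[-1]) {
    last <- cur[length(cur)]
    if (i == last + 1L && pairing[i] == pairing[last] - 1L) {
      cur <- c(cur, i)
    } else {
      helices[[length(helices) + 1L]] <- cur
      cur <- i
    }
  }
  helices[[length(helices) + 1L]] <- cur
  lapply(helices, function(fi) {
    list(i5 = fi[1], i3 = fi[length(fi)],
         j5 = pairing[fi[length(fi)]], j3 = pairing[fi[1]],
         nbp = length(fi))
  })
}

#' Count G-U wobble pairs
#'
#' Paired positions whose nucleotides are G and U (or G and T for DNA
#' input), in either order.
#'
#' @param seq RNA/DNA string.
#' @param pairing Pairing vector from [parse_dot_bracket()] (or a
#'   dot-bracket string).
#' @return Integer count of G-U pairs.
#' @export
count_gu_pairs <- function(seq, pairing) {
  if (is.character(pairing)) pairing <- parse_dot_bracket(pairing)
  ch <- seq_chars(chartr("T", "U", toupper(seq)))
  stopifnot(length(ch) == length(pairing))
  open <- which(pairing > seq_along(pairing))
  sum(vapply(open, function(i) {
    setequal(c(ch[i], ch[pairing[i]]), c("G", "U"))
  }, logical(1)))
}

#' Decompose a tRNA secondary structure into arms
#'
#' The exterior helix chain (pairs enclosing all others, bulges allowed) is
#' the acceptor stem; the remaining top-level helices with stems of >= 2 bp
#' are assigned, in 5'-to-3' order, as D arm, anticodon arm and T arm.
#' With two interior helices the anticodon arm is the one whose loop lies
#' closest to the middle of the molecule (the canonical topology); with one,
#' it is the anticodon arm (the minimal, both-arms-lost architecture). The
#' last nucleotide of the unpaired 3' overhang is the discriminator; the
#' anticodon is the middle 3 nt of the anticodon loop.
#'
#' @param seq RNA string (U or T accepted).
#' @param structure Dot-bracket string, or a pairing vector.
#' @param gene_name Optional label.
#' @return Object of class `trna_structure`: list with `gene_name`,
#'   `sequence`, `pairing`, `acceptor_stem_bp`, `d_arm_bp`,
#'   `anticodon_arm_bp`, `anticodon_loop_nt`, `t_arm_bp`,
#'   `variable_region_nt`, `discriminator`, `anticodon`, `gu_pairs`,
#'   `mismatch_pairs`, `arch_class`.
#' @export
decompose_arms <- function(seq, structure, gene_name = NA_character_) {
  pairing <- if (is.character(structure)) parse_dot_bracket(structure)
             else as.integer(structure)
  rna <- chartr("T", "U", toupper(seq))
  ch <- seq_chars(rna)
  if (length(ch) != length(pairing))
    stop("sequence and structure lengths differ")
  hel <- .find_helices(pairing)
  if (!length(hel)) stop("not tRNA-like: no base pairs")
  # acceptor stem: chain of helices that enclose all remaining helices
  acceptor_bp <- 0L
  repeat {
    if (length(hel) < 2L) break
    spans_i <- vapply(hel, `[[`, numeric(1), "i5")
    spans_j <- vapply(hel, `[[`, numeric(1), "j3")
    outer_idx <- which(spans_i == min(spans_i))[1]
    encloses_all <- all(spans_i >= hel[[outer_idx]]$i5 &
                          spans_j <= hel[[outer_idx]]$j3)
    if (!encloses_all) break
    acceptor_bp <- acceptor_bp + hel[[outer_idx]]$nbp
    hel <- hel[-outer_idx]
  }
  if (acceptor_bp == 0L) {
    if (length(hel) == 1L)
      stop("not tRNA-like: no exterior (acceptor) stem")
    # single exterior helix enclosing nothing else cannot happen here;
    # reaching this point means several helices none of which encloses
    # the rest
    stop("not tRNA-like: no exterior (acceptor) stem")
  }
  interior <- Filter(function(h) h$nbp >= 2L, hel)
  interior <- interior[order(vapply(interior, `[[`, numeric(1), "i5"))]
  n_int <- length(interior)
  if (n_int == 0L)
    stop("not tRNA-like: no anticodon arm")
  if (n_int > 3L)
    stop("not tRNA-like: more than three interior helices")
  d <- ac <- t_arm <- NULL
  if (n_int == 3L) {
    d <- interior[[1]]; ac <- interior[[2]]; t_arm <- interior[[3]]
  } else if (n_int == 2L) {
    mid <- (length(ch) + 1) / 2
    loop_mid <- vapply(interior, function(h) (h$i3 + h$j5) / 2, numeric(1))
    ac_idx <- which.min(abs(loop_mid - mid))
    ac <- interior[[ac_idx]]
    other <- interior[[3L - ac_idx]]
    if (other$i5 < ac$i5) d <- other else t_arm <- other
  } else {
    ac <- interior[[1]]
  }
  ac_loop <- (ac$i3 + 1L):(ac$j5 - 1L)
  k <- length(ac_loop)
  anticodon <- if (k >= 3L) {
    m <- ac_loop[ceiling(k / 2) - 1L]
    paste(ch[m:(m + 2L)], collapse = "")
  } else NA_character_
  # discriminator: last nucleotide of the unpaired 3' overhang
  paired_pos <- which(pairing > 0L)
  disc <- if (max(paired_pos) < length(ch)) ch[length(ch)] else NA_character_
  # variable region: unpaired span between anticodon arm and T arm (or the
  # 3' acceptor strand when the T arm is absent)
  var_end <- if (!is.null(t_arm)) t_arm$i5 - 1L else {
    after <- paired_pos[paired_pos > ac$j3]
    if (length(after)) min(after) - 1L else length(ch)
  }
  variable_nt <- max(0L, var_end - ac$j3)
  open <- which(pairing > seq_along(pairing))
  wc <- c("AU", "UA", "GC", "CG", "GU", "UG")
  mism <- sum(!paste0(ch[open], ch[pairing[open]]) %in% wc)
  d_bp <- if (is.null(d)) 0L else d$nbp
  t_bp <- if (is.null(t_arm)) 0L else t_arm$nbp
  arch <- if (d_bp > 0L && t_bp > 0L) "cloverleaf"
          else if (d_bp == 0L && t_bp > 0L) "d_armless"
          else if (d_bp > 0L) "t_armless" else "minimal"
  structure(list(gene_name = gene_name, sequence = rna, pairing = pairing,
                 acceptor_stem_bp = as.integer(acceptor_bp),
                 d_arm_bp = as.integer(d_bp),
                 anticodon_arm_bp = as.integer(ac$nbp),
                 anticodon_loop_nt = as.integer(k),
                 t_arm_bp = as.integer(t_bp),
                 variable_region_nt = as.integer(variable_nt),
                 discriminator = disc, anticodon = anticodon,
                 gu_pairs = count_gu_pairs(rna, pairing),
                 mismatch_pairs = as.integer(mism),
                 arch_class = arch),
            class = "trna_structure")
}

#' @export
print.trna_structure <- function(x, ...) {
  cat(sprintf(
    "<trna_structure> %s: %s (%d nt)\n  acceptor %d bp, D %d bp, anticodon %d bp (loop %d nt), T %d bp\n  anticodon %s, discriminator %s, G-U pairs %d\n",
    ifelse(is.na(x$gene_name), "tRNA", x$gene_name), x$arch_class,
    nchar(x$sequence), x$acceptor_stem_bp, x$d_arm_bp, x$anticodon_arm_bp,
    x$anticodon_loop_nt, x$t_arm_bp,
    ifelse(is.na(x$anticodon), "?", x$anticodon),
    ifelse(is.na(x$discriminator), "?", x$discriminator), x$gu_pairs))
  invisible(x)
}

#' Classify a set of tRNA structures
#'
#' @param structures List of `trna_structure` objects (see
#'   [decompose_arms()]).
#' @return List with `counts` (named integer vector over the four
#'   architecture classes) and `table` (per-gene data frame).
#' @export
classify_trna_set <- function(structures) {
  stopifnot(length(structures) > 0)
  tab <- do.call(rbind, lapply(structures, function(s) {
    data.frame(gene = s$gene_name, arch_class = s$arch_class,
               acceptor_stem_bp = s$acceptor_stem_bp, d_arm_bp = s$d_arm_bp,
               anticodon_arm_bp = s$anticodon_arm_bp,
               anticodon_loop_nt = s$anticodon_loop_nt,
               t_arm_bp = s$t_arm_bp,
               variable_region_nt = s$variable_region_nt,
               discriminator = s$discriminator, anticodon = s$anticodon,
               gu_pairs = s$gu_pairs, mismatch_pairs = s$mismatch_pairs,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  classes <- c("cloverleaf", "d_armless", "t_armless", "minimal")
  counts <- stats::setNames(
    vapply(classes, function(cl) sum(tab$arch_class == cl), integer(1)),
    classes)
  list(counts = counts, table = tab)
}

#' Read a paired FASTA + dot-bracket structure file
#'
#' Vienna-style format: for each record a `>name` header line, the sequence
#' line, then the dot-bracket line.
#'
#' @param x Path or text.
#' @return List of `trna_structure` objects.
#' @export
read_trna_structures <- function(x) {
  lines <- .as_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no '>' records found")
  lapply(heads, function(h) {
    if (h + 2L > length(lines))
      stop("truncated record at ", lines[h])
    decompose_arms(lines[h + 1L], lines[h + 2L],
                   gene_name = sub("^>\\s*", "", lines[h]))
  })
}

#' Write tRNA structures as a Vienna-style text file
#'
#' @param structures List of `trna_structure` objects, or a list of
#'   `list(name=, sequence=, structure=)` entries.
#' @param path Output path; `NULL` returns the lines.
#' @export
write_trna_structures <- function(structures, path = NULL) {
  out <- unlist(lapply(structures, function(s) {
    if (inherits(s, "trna_structure")) {
      db <- character(length(s$pairing))
      db[s$pairing == 0] <- "."
      db[s$pairing > seq_along(s$pairing)] <- "("
      db[s$pairing > 0 & s$pairing < seq_along(s$pairing)] <- ")"
      c(paste0(">", ifelse(is.na(s$gene_name), "tRNA", s$gene_name)),
        s$sequence, paste(db, collapse = ""))
    } else {
      c(paste0(">", s$name), s$sequence, s$structure)
    }
  }))
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
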