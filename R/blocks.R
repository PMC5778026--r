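# Recombination-block analysis of variant alignments: polymorphic columns,
# gap-based block grouping, per-variant block alleles, the four-gamete test
# for recombination between block pairs, cross-group block-allele sharing,
# and uncorrected P distances (exported in PHYLIP / NEXUS formats for
# external split-network tools).

check_alignment <- function(alignment) {
  if (length(alignment) < 2L) abort_cid("alignment", "need >= 2 sequences")
  if (length(unique(nchar(alignment))) != 1L)
    abort_cid("alignment_ragged", "alignment rows have unequal lengths")
  if (is.null(names(alignment)) || anyDuplicated(names(alignment)))
    abort_cid("alignment", "alignment rows must be uniquely named")
  do.call(rbind, strsplit(toupper(alignment), ""))
}

#' Polymorphic columns of an alignment
#'
#' @param alignment named character vector of equal-length sequences.
#' @param gap_as_state treat "-" as a residue state (default FALSE: gap-only
#'   variation is not polymorphism and gapped cells are ignored).
#' @return 0-based indices of columns with >= 2 distinct residues.
#' @export
polymorphic_columns <- function(alignment, gap_as_state = FALSE) {
  mat <- check_alignment(alignment)
  poly <- apply(mat, 2L, function(col) {
    if (!gap_as_state) col <- col[col != "-"]
    length(unique(col)) > 1L
  })
  which(poly) - 1L
}

#' Group polymorphic columns into blocks
#'
#' Consecutive columns whose inter-column gap is at most `max_gap` are merged
#' into one interval.
#'
#' @param columns sorted 0-based column indices.
#' @param max_gap maximum gap (in columns) bridged within a block.
#' @return data.frame(start0, end0) of 0-based inclusive block intervals.
#' @export
detect_blocks <- function(columns, max_gap = 3L) {
  if (!length(columns)) return(data.frame(start0 = integer(), end0 = integer()))
  if (is.unsorted(columns, strictly = TRUE))
    abort_cid("blocks", "columns must be sorted, strictly ascending")
  brk <- which(diff(columns) > max_gap + 1L)
  starts <- columns[c(1L, brk + 1L)]
  ends <- columns[c(brk, length(columns))]
  data.frame(start0 = as.integer(starts), end0 = as.integer(ends))
}

#' Block alleles of an alignment
#'
#' Assigns, per block, an allele label to each sequence: identical block
#' substrings share a label (a1, a2, ... in order of first appearance).
#'
#' @param alignment named character vector.
#' @param blocks data.frame from [detect_blocks()].
#' @return `cid_blockset`: blocks plus an alleles matrix
#'   (rows = sequences, columns = blocks).
#' @export
block_alleles <- function(alignment, blocks) {
  mat <- check_alignment(alignment)
  lab <- matrix(NA_character_, nrow = nrow(mat), ncol = nrow(blocks),
                dimnames = list(names(alignment),
                                sprintf("block_%d", seq_len(nrow(blocks)))))
  for (b in seq_len(nrow(blocks))) {
    sub <- apply(mat[, seq.int(blocks$start0[b] + 1L, blocks$end0[b] + 1L),
                     drop = FALSE], 1L, paste, collapse = "")
    lab[, b] <- paste0("a", as.integer(factor(sub, levels = unique(sub))))
  }
  structure(list(blocks = blocks, alleles = lab), class = "cid_blockset")
}

#' Four-gamete test between two blocks
#'
#' For every pair of alleles at each block (binarization), checks whether all
#' four haplotype combinations occur among the sequences; if any binarized
#' pair realizes all four, recombination between the blocks is implied under
#' the infinite-sites assumption.
#'
#' @param blockset a `cid_blockset`.
#' @param block_i,block_j block column indices (1-based).
#' @return "recombination_detected" or "compatible", with attribute
#'   `witness` giving one four-gamete allele pair when detected.
#' @export
four_gamete <- function(blockset, block_i, block_j) {
  ai <- blockset$alleles[, block_i]
  aj <- blockset$alleles[, block_j]
  ui <- unique(ai); uj <- unique(aj)
  if (length(ui) < 2L || length(uj) < 2L)
    abort_cid("four_gamete", "both blocks need >= 2 alleles")
  for (x in ui) for (y in uj) {
    g <- unique(paste(ai == x, aj == y))
    if (length(g) == 4L) {
      out <- "recombination_detected"
      attr(out, "witness") <- c(block_i = x, block_j = y)
      return(out)
    }
  }
  "compatible"
}

#' Cross-group sharing of block alleles
#'
#' Reports, per block allele, the set of groups carrying it, and verifies
#' whether any full-length sequence is shared between groups.
#'
#' @param blockset a `cid_blockset`.
#' @param alignment the alignment the blockset came from.
#' @param group_labels named (by sequence) or positional character vector of
#'   group labels.
#' @return list(shared_block_alleles = data.frame(block, allele, groups),
#'   shared_full_variants = data.frame(seq_i, seq_j, group_i, group_j)).
#' @export
cross_group_sharing <- function(blockset, alignment, group_labels) {
  if (length(unique(group_labels)) < 2L)
    abort_cid("groups", "need >= 2 groups")
  if (!is.null(names(group_labels)))
    group_labels <- group_labels[rownames(blockset$alleles)]
  shared <- NULL
  for (b in colnames(blockset$alleles)) {
    for (al in unique(blockset$alleles[, b])) {
      gr <- sort(unique(group_labels[blockset$alleles[, b] == al]))
      if (length(gr) > 1L)
        shared <- rbind(shared, data.frame(block = b, allele = al,
                                           groups = paste(gr, collapse = ","),
                                           stringsAsFactors = FALSE))
    }
  }
  full <- NULL
  nm <- names(alignment)
  for (i in seq_along(alignment)) for (j in seq_along(alignment)) {
    if (i >= j) next
    if (alignment[[i]] == alignment[[j]] &&
        group_labels[i] != group_labels[j])
      full <- rbind(full, data.frame(seq_i = nm[i], seq_j = nm[j],
                                     group_i = group_labels[i],
                                     group_j = group_labels[j],
                                     stringsAsFactors = FALSE))
  }
  list(shared_block_alleles = shared %||%
         data.frame(block = character(), allele = character(),
                    groups = character()),
       shared_full_variants = full %||%
         data.frame(seq_i = character(), seq_j = character(),
                    group_i = character(), group_j = character()))
}

#' Uncorrected P distance matrix
#'
#' Entry (i,j) = mismatches / compared sites, with pairwise deletion of
#' positions where either row carries a gap.
#'
#' @param alignment named character vector of equal-length sequences.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(alignment) {
  mat <- check_alignment(alignment)
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(ok))
      abort_cid("p_distance", "no comparable sites between %s and %s",
                names(alignment)[i], names(alignment)[j])
    d <- sum(mat[i, ok] != mat[j, ok]) / sum(ok)
    D[i, j] <- d; D[j, i] <- d
  }
  D
}

#' Write a distance matrix in square PHYLIP format
#' @param D symmetric matrix with row names.
#' @param path output path.
#' @export
write_phylip <- function(D, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste0(formatC(substr(rownames(D)[i], 1, 10), width = -10),
                      paste(sprintf("%.6f", D[i, ]), collapse = " ")), con)
  invisible(path)
}

#' Write a distance matrix as a NEXUS DISTANCES block
#' @param D symmetric matrix with row names.
#' @param path output path.
#' @export
write_nexus_dist <- function(D, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN TAXA;",
               sprintf("  DIMENSIONS NTAX=%d;", nrow(D)),
               paste0("  TAXLABELS ", paste(rownames(D), collapse = " "), ";"),
               "END;", "BEGIN DISTANCES;",
               "  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;", "  MATRIX"), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste0("    ", rownames(D)[i], " ",
                      paste(sprintf("%.6f", D[i, ]), collapse = " ")), con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}
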