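# Coverage-based amplification detection. Reads are placed at their best
# exact/near-exact locus (leftmost on ties), so reads from every operon copy
# pile onto the reference's single copy — that pile-up IS the amplification
# signal. Per-base depth is normalized by the genome-wide mean, polymorphic
# regions (plus a read-length margin, where partially overlapping reads fail
# to place) and the identically-duplicated cidB tail are excluded, and the
# estimate is the ratio of the operon mean to the mean of the single-copy
# marker means. A qPCR route estimates the same quantity from Cq tables.

#' Place reads on a reference by exact/near-exact matching
#'
#' Each read is matched forward and as reverse complement; with
#' `max_mismatch > 0` the first `tb` bases must match exactly (trusted band)
#' and up to `max_mismatch` mismatches are allowed elsewhere. A read matching
#' several loci equally is placed once, at the leftmost match.
#'
#' @param reads named character vector of reads (equal length).
#' @param reference reference genome string.
#' @param max_mismatch mismatches tolerated outside the trusted band.
#' @param tb trusted-band width for mismatch-tolerant placement.
#' @return list(placements = data.frame(read_id, start0, width, strand),
#'   unplaced = integer count).
#' @export
map_reads_exact <- function(reads, reference, max_mismatch = 0L, tb = 32L) {
  if (!nchar(reference)) abort_cid("reference", "empty reference")
  if (!length(reads))
    return(list(placements = data.frame(read_id = character(),
                                        start0 = integer(), width = integer(),
                                        strand = character()), unplaced = 0L))
  widths <- nchar(reads)
  if (length(unique(widths)) != 1L)
    abort_cid("reads", "reads must share one length for dictionary matching")
  w <- widths[1]
  subj <- Biostrings::DNAString(reference)
  fset <- Biostrings::DNAStringSet(unname(reads))
  rset <- Biostrings::reverseComplement(fset)
  first_hit <- function(set) {
    pd <- if (max_mismatch > 0L)
      Biostrings::PDict(set, tb.start = 1L, tb.end = min(tb, w))
    else Biostrings::PDict(set)
    mi <- Biostrings::matchPDict(pd, subj, max.mismatch = max_mismatch)
    sl <- Biostrings::startIndex(mi)
    vapply(sl, function(s) if (length(s)) min(s) else NA_integer_, integer(1))
  }
  f <- first_hit(fset)
  r <- first_hit(rset)
  start0 <- ifelse(!is.na(f) & (is.na(r) | f <= r), f, r) - 1L
  strand <- ifelse(!is.na(f) & (is.na(r) | f <= r), "+", "-")
  placed <- !is.na(start0)
  list(placements = data.frame(read_id = unname(names(reads)[placed]),
                               start0 = unname(as.integer(start0[placed])),
                               width = w, strand = unname(strand[placed]),
                               row.names = NULL, stringsAsFactors = FALSE),
       unplaced = sum(!placed))
}

#' Per-base coverage from placements
#'
#' depth[i] = number of placed reads overlapping base i; the depth sum equals
#' the sum of placed read lengths exactly.
#'
#' @param placements data.frame with start0 and width.
#' @param reference_length reference length in bp.
#' @return `cid_coverage` with fields depth, genome_mean, normalized.
#' @export
compute_coverage <- function(placements, reference_length) {
  G <- as.integer(reference_length)
  delta <- numeric(G + 1L)
  if (nrow(placements)) {
    if (any(placements$start0 < 0L | placements$start0 + placements$width > G))
      abort_cid("coverage", "placement outside reference bounds")
    s <- placements$start0 + 1L
    e <- placements$start0 + placements$width + 1L
    for (i in seq_along(s)) {
      delta[s[i]] <- delta[s[i]] + 1
      delta[e[i]] <- delta[e[i]] - 1
    }
  }
  depth <- cumsum(delta[seq_len(G)])
  structure(list(depth = depth, genome_mean = mean(depth), normalized = FALSE),
            class = "cid_coverage")
}

#' Normalize a coverage profile by its genome-wide mean
#'
#' Idempotent; after normalization the genome-wide mean is 1.
#'
#' @param profile a `cid_coverage`.
#' @return normalized `cid_coverage`.
#' @export
normalize_coverage <- function(profile) {
  m <- mean(profile$depth)
  if (m <= 0) abort_cid("normalize", "cannot normalize an all-zero profile")
  structure(list(depth = profile$depth / m, genome_mean = 1,
                 normalized = TRUE), class = "cid_coverage")
}

#' Mean depth over a region, minus exclusions
#'
#' @param profile a `cid_coverage`.
#' @param start0,end0 region, 0-based half-open.
#' @param exclusions optional data.frame with start0/end0 intervals to drop.
#' @return mean depth over the surviving bases.
#' @export
region_mean <- function(profile, start0, end0, exclusions = NULL) {
  idx <- seq.int(start0 + 1L, end0)  # 1-based base indices
  if (!is.null(exclusions) && nrow(exclusions)) {
    drop <- unlist(lapply(seq_len(nrow(exclusions)), function(i) {
      s <- max(exclusions$start0[i], start0)
      e <- min(exclusions$end0[i], end0)
      if (s < e) seq.int(s + 1L, e) else integer()
    }))
    idx <- setdiff(idx, drop)
  }
  if (!length(idx))
    abort_cid("region_excluded", "region [%d,%d) fully excluded", start0, end0)
  mean(profile$depth[idx])
}

#' Expand exclusion intervals by a read-margin
#'
#' Reads partially overlapping a polymorphic region fail exact placement, so
#' coverage is depressed up to a read length beyond the region proper; the
#' exclusion is widened accordingly (clipped to the parent gene). The
#' identically-duplicated cidB tail needs no margin (reads crossing its
#' boundary still match) and is left as annotated.
#'
#' @param regions region table (as in `world$regions`).
#' @param margin bases to add on each side of polymorphic exclusions,
#'   typically read_length - 1.
#' @return region table with widened exclusion intervals.
#' @export
expand_exclusions <- function(regions, margin = 99L) {
  ex <- regions$role == "exclusion" & regions$name != "cidB_tail"
  for (i in which(ex)) {
    parent <- regions[regions$name == regions$parent[i], , drop = FALSE]
    regions$start0[i] <- max(regions$start0[i] - margin, parent$start0)
    regions$end0[i] <- min(regions$end0[i] + margin, parent$end0)
  }
  regions
}

#' Coverage-based operon copy number
#'
#' estimate = mean normalized operon-gene depth (after exclusions) divided by
#' the aggregate of the single-copy marker-gene normalized means.
#'
#' @param profile a `cid_coverage` (normalized; normalization is applied if
#'   not).
#' @param regions region table with roles operon_gene / marker / exclusion.
#' @param marker_agg "mean" (default) or "median" aggregation over markers.
#' @return `cid_cn` with estimate, per-marker means, operon mean,
#'   method = "coverage".
#' @export
estimate_copy_number <- function(profile, regions, marker_agg = c("mean", "median")) {
  marker_agg <- match.arg(marker_agg)
  if (!profile$normalized) profile <- normalize_coverage(profile)
  markers <- regions[regions$role == "marker", , drop = FALSE]
  if (!nrow(markers)) abort_cid("markers", "at least one marker gene required")
  exclusions <- regions[regions$role == "exclusion", , drop = FALSE]
  marker_means <- vapply(seq_len(nrow(markers)), function(i)
    region_mean(profile, markers$start0[i], markers$end0[i]), numeric(1))
  names(marker_means) <- markers$name
  zero <- marker_means == 0
  if (any(zero))
    abort_cid("marker_zero", "marker(s) with zero coverage: %s",
              paste(names(marker_means)[zero], collapse = ", "))
  op <- regions[regions$role == "operon_gene", , drop = FALSE]
  gene_means <- vapply(seq_len(nrow(op)), function(i)
    region_mean(profile, op$start0[i], op$end0[i],
                exclusions[exclusions$parent == op$name[i], , drop = FALSE]),
    numeric(1))
  names(gene_means) <- op$name
  operon_mean <- mean(gene_means)
  baseline <- if (marker_agg == "mean") mean(marker_means) else median(marker_means)
  structure(list(estimate = operon_mean / baseline,
                 operon_mean = operon_mean, gene_means = gene_means,
                 marker_means = marker_means, marker_agg = marker_agg,
                 method = "coverage"),
            class = "cid_cn")
}

#' @export
print.cid_cn <- function(x, ...) {
  cat(sprintf("Copy-number estimate (%s): %.3f\n", x$method, x$estimate))
  invisible(x)
}

#' qPCR relative copy number
#'
#' ratio = efficiency^(meanCq(reference locus) - meanCq(target locus)),
#' replicate means taken per locus.
#'
#' @param table a `cid_qpcr` data.frame (sample_id, locus, replicate, cq).
#' @param target_locus e.g. "cidA".
#' @param reference_locus single-copy reference, e.g. "wsp".
#' @param efficiency amplification efficiency (default 2, perfect doubling).
#' @return `cid_cn` with method = "qpcr".
#' @export
qpcr_copy_ratio <- function(table, target_locus, reference_locus = "wsp",
                            efficiency = 2) {
  for (loc in c(target_locus, reference_locus))
    if (!any(table$locus == loc))
      abort_cid("qpcr_locus", "locus '%s' missing from qPCR table", loc)
  mcq <- function(loc) mean(table$cq[table$locus == loc])
  ratio <- efficiency^(mcq(reference_locus) - mcq(target_locus))
  structure(list(estimate = ratio,
                 mean_cq = c(setNames(mcq(target_locus), target_locus),
                             setNames(mcq(reference_locus), reference_locus)),
                 efficiency = efficiency, method = "qpcr"),
            class = "cid_cn")
}
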