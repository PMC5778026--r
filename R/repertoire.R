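# Repertoire typing: clones are typed into named variants via exact allele
# assignment in the two polymorphic regions per gene; per-line repertoires
# tally clone support, discard sub-threshold singletons as putative
# chimera/error clones, and flag the incompatibility signature
# (any cidA *(δ/·) together with cidB *(a/2)).

#' Extract a polymorphic region from a gene sequence
#'
#' @param sequence nucleotide sequence covering the region; `cds_start`
#'   gives the 1-based position of the CDS start within it (clone sequences
#'   from [simulate_clones()] carry this as an attribute).
#' @param config a `cid_gene_config`.
#' @param region_id "upstream" or "downstream".
#' @param level "nt" or "aa" (translated, standard code, CDS frame).
#' @param cds_start 1-based CDS offset; defaults to the sequence attribute,
#'   else 1.
#' @return region sequence at the requested level.
#' @export
extract_region <- function(sequence, config, region_id, level = c("nt", "aa"),
                           cds_start = NULL) {
  level <- match.arg(level)
  cds_start <- cds_start %||% attr(sequence, "cds_start") %||% 1L
  iv <- config$region_coords[[region_id]]
  if (is.null(iv)) abort_cid("region", "unknown region '%s'", region_id)
  s <- cds_start + iv[1] - 1L
  e <- cds_start + iv[2] - 1L
  if (s < 1L || e > nchar(sequence))
    abort_cid("bounds", "region %s [%d,%d] outside sequence (len %d)",
              region_id, s, e, nchar(sequence))
  nt <- substr(sequence, s, e)
  if (level == "nt") return(nt)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           no.init.codon = TRUE))
  if (grepl("\\*", substr(aa, 1L, nchar(aa) - 1L)))
    abort_cid("stop_codon", "internal stop codon in %s %s", config$gene_id,
              region_id)
  aa
}

#' Assign an allele label to a region sequence
#'
#' Exact nucleotide match against the registry. In open mode an unseen
#' sequence is registered deterministically under the next unused label of a
#' fixed series ("n1", "n2", ...); in closed mode a miss is an error carrying
#' the nearest registered allele and its Hamming distance.
#'
#' @param region_sequence nucleotide string.
#' @param pool a `cid_allele_pool` (registry for this region).
#' @param open allow new labels.
#' @return list(label, pool) — `pool` is the (possibly grown) registry.
#' @export
assign_allele <- function(region_sequence, pool, open = FALSE) {
  hit <- which(pool$alleles == region_sequence)
  if (length(hit)) return(list(label = names(pool$alleles)[hit[1]], pool = pool))
  if (!open) {
    hd <- vapply(pool$alleles, function(a) {
      if (nchar(a) != nchar(region_sequence)) return(NA_integer_)
      sum(strsplit(a, "")[[1]] != strsplit(region_sequence, "")[[1]])
    }, integer(1))
    best <- which.min(hd)
    abort_cid("allele_miss",
              "no registered allele matches (%s %s); nearest is '%s' at Hamming distance %d",
              pool$gene_id, pool$region_id, names(pool$alleles)[best], hd[best],
              data = list(nearest = names(pool$alleles)[best],
                          distance = unname(hd[best])))
  }
  k <- 1L
  while (paste0("n", k) %in% names(pool$alleles)) k <- k + 1L
  lab <- paste0("n", k)
  pool$alleles <- c(pool$alleles, setNames(region_sequence, lab))
  list(label = lab, pool = pool)
}

#' Type one sequence into a variant name
#'
#' @param sequence gene sequence (clone or variant).
#' @param config a `cid_gene_config`.
#' @param pools list(upstream=, downstream=) registries.
#' @param open open-registry mode (see [assign_allele()]).
#' @param cds_start CDS offset within `sequence`.
#' @return list(name, upstream, downstream, pools).
#' @export
type_variant <- function(sequence, config, pools, open = FALSE,
                         cds_start = NULL) {
  labs <- list()
  for (r in c("upstream", "downstream")) {
    reg <- extract_region(sequence, config, r, "nt", cds_start = cds_start)
    res <- assign_allele(reg, pools[[r]], open = open)
    labs[[r]] <- res$label
    pools[[r]] <- res$pool
  }
  list(name = render_variant_name(config$gene_id, config$group,
                                  labs$upstream, labs$downstream),
       upstream = labs$upstream, downstream = labs$downstream, pools = pools)
}

#' Build a per-line repertoire from clones
#'
#' Clones are typed individually in open-registry mode (so error-bearing
#' clones become novel labels instead of failures); variants supported by
#' fewer than `min_support` clones are discarded as putative chimeras or
#' PCR/sequencing artifacts and reported, not silently dropped.
#'
#' @param clones named character vector of clone sequences (e.g. from
#'   [simulate_clones()]).
#' @param config a `cid_gene_config`.
#' @param pools registries for the gene.
#' @param min_support minimum clone support per retained variant.
#' @param line_id identifier.
#' @param cds_start CDS offset; defaults to the `cds_start` attribute.
#' @return `cid_repertoire`: variants data.frame(name, support), clones
#'   typed, discarded tally.
#' @export
build_repertoire <- function(clones, config, pools, min_support = 2L,
                             line_id = "line", cds_start = NULL) {
  if (!length(clones)) abort_cid("clones", "at least one clone required")
  cds_start <- cds_start %||% attr(clones, "cds_start") %||% 1L
  names_ <- character(length(clones))
  for (i in seq_along(clones)) {
    res <- type_variant(clones[[i]], config, pools, open = TRUE,
                        cds_start = cds_start)
    names_[i] <- res$name
    pools <- res$pools  # novel labels persist: same error seq -> same label
  }
  tab <- sort(table(names_), decreasing = TRUE)
  keep <- tab[tab >= min_support]
  disc <- tab[tab < min_support]
  if (!length(keep))
    abort_cid("repertoire_empty",
              "all %d clone-variants below min_support=%d", length(tab),
              min_support)
  structure(list(
    line_id = line_id, gene_id = config$gene_id,
    variants = data.frame(name = names(keep), support = as.integer(keep),
                          stringsAsFactors = FALSE),
    discarded = data.frame(name = names(disc), support = as.integer(disc),
                           stringsAsFactors = FALSE),
    clones_typed = length(clones)), class = "cid_repertoire")
}

#' @export
print.cid_repertoire <- function(x, ...) {
  cat(sprintf("%s %s: %d variant(s) from %d clones (%d clone(s) discarded)\n",
              x$line_id, x$gene_id, nrow(x$variants), x$clones_typed,
              sum(x$discarded$support)))
  for (i in seq_len(nrow(x$variants)))
    cat(sprintf("  %-18s support %d\n", x$variants$name[i], x$variants$support[i]))
  invisible(x)
}

#' Incompatibility signature flags of a line
#'
#' @param variants list(cidA = character names, cidB = character names), or a
#'   pair of `cid_repertoire` objects given as list(cidA=, cidB=).
#' @return `cid_flags`: has_cidA_delta, has_cidB_a2,
#'   category in both / cidA_only / cidB_only / neither.
#' @export
signature_flags <- function(variants) {
  getnames <- function(x) if (inherits(x, "cid_repertoire")) x$variants$name else x
  for (g in c("cidA", "cidB"))
    if (is.null(variants[[g]]) || !length(getnames(variants[[g]])))
      abort_cid("flags", "repertoire missing gene %s", g)
  pa <- lapply(getnames(variants$cidA), parse_variant_name)
  pb <- lapply(getnames(variants$cidB), parse_variant_name)
  has_delta <- any(vapply(pa, function(p) p$upstream == "δ", logical(1)))
  has_a2 <- any(vapply(pb, function(p) p$upstream == "a" && p$downstream == "2",
                       logical(1)))
  category <- if (has_delta && has_a2) "both" else if (has_delta) "cidA_only"
              else if (has_a2) "cidB_only" else "neither"
  structure(list(has_cidA_delta = has_delta, has_cidB_a2 = has_a2,
                 category = category), class = "cid_flags")
}

#' Check a repertoire against direct-trace mixed positions
#'
#' A line's direct Sanger trace shows mixed signals exactly where its variant
#' copies disagree. Predicted mixed positions are the columns (1-based, CDS
#' coordinates) at which the repertoire's variant sequences differ; the
#' report compares them with the observed list — an observed position absent
#' from the predictions flags a possible missing variant.
#'
#' @param variant_names character vector of variant names for one gene.
#' @param config,pools gene configuration and registries.
#' @param observed_mixed integer vector of observed mixed positions.
#' @return list(predicted, observed, missing_variant_positions,
#'   unexplained_predictions, consistent).
#' @export
check_trace_consistency <- function(variant_names, config, pools,
                                    observed_mixed = integer()) {
  if (!length(variant_names)) abort_cid("trace", "empty repertoire")
  seqs <- vapply(variant_names, function(nm) {
    p <- parse_variant_name(nm)
    make_variant(config, p$upstream, p$downstream, pools)$sequence
  }, character(1))
  mat <- do.call(rbind, strsplit(seqs, ""))
  predicted <- which(apply(mat, 2L, function(col) length(unique(col)) > 1L))
  missing <- setdiff(observed_mixed, predicted)
  unexplained <- setdiff(predicted, observed_mixed)
  list(predicted = predicted, observed = sort(observed_mixed),
       missing_variant_positions = missing,
       unexplained_predictions = unexplained,
       consistent = !length(missing) && !length(unexplained))
}
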