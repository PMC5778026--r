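# The synthetic world: a seeded, fully constructive model of a wPip-like
# system. One circular reference genome carries a single cidA-cidB operon
# copy, 14 single-copy marker genes and the single-copy wsp locus; sample
# genomes carry k operon copies whose variants are block-recombinants of
# small allele pools. Allele pools are engineered so that in-silico PCR-RFLP
# of each variant reproduces the diagnostic fragment patterns:
#   cidA upstream (ApoI + Hpy188I, 778 bp amplicon):
#     delta -> {524,122,57,51,24}; alpha adds a cut splitting 524 into
#     471+53; beta/gamma add a cut splitting it into 441+83.
#   cidB downstream (BanI + TaqI, 1267 bp amplicon):
#     "2" -> {1028,239}; "1" splits 1028 into 892+136; "3" into 861+167.
# ("1" prints 892+145 from a 1276 bp amplicon in the source data; the world
# is indel-free, so its amplicon stays 1267 bp and the 145 bp band becomes
# 136 bp. Pattern calling against the world uses world_patterns().)

# ---- layout constants (1-based nt on each CDS unless noted) ----------------
WORLD_LAYOUT <- list(
  cidA = list(
    cds_len = 1425L,
    regions_aa = list(upstream = c(118L, 152L), downstream = c(336L, 401L)),
    # constant backbone cuts, 0-based between-base on the CDS
    const_cuts = c(ApoI = 475L, Hpy188I = 597L, Hpy188I = 654L, ApoI = 705L),
    # allele cut sites: region-relative 0-based site starts within upstream
    allele_sites = list(
      upstream = list(
        alpha = list(enzyme = "Hpy188I", offset = 68L),
        beta = list(enzyme = "Hpy188I", offset = 38L),
        gamma = list(enzyme = "Hpy188I", offset = 38L),
        delta = list()
      ),
      downstream = list(`1` = list(), `2` = list())
    ),
    labels = list(upstream = c("α", "β", "γ", "δ"),
                  downstream = c("1", "2")),
    label_keys = list(upstream = c("alpha", "beta", "gamma", "delta"),
                      downstream = c("1", "2")),
    # amplicon in CDS coordinates, 0-based half-open (starts in the flank)
    amplicon = c(-49L, 729L),
    primer_len = 20L,
    clone_flank = 60L
  ),
  cidB = list(
    cds_len = 3249L,
    regions_aa = list(upstream = c(242L, 278L), downstream = c(450L, 481L)),
    const_cuts = c(TaqI = 1528L),
    allele_sites = list(
      upstream = list(a = list(), b = list()),
      downstream = list(
        `1` = list(enzyme = "TaqI", offset = 44L),
        `2` = list(),
        `3` = list(enzyme = "BanI", offset = 13L)
      )
    ),
    labels = list(upstream = c("a", "b"), downstream = c("1", "2", "3")),
    label_keys = list(upstream = c("a", "b"), downstream = c("1", "2", "3")),
    amplicon = c(500L, 1767L),
    primer_len = 20L,
    clone_flank = 0L,
    excluded_tail_start = 2461L
  ),
  flankA_len = 200L, intergenic_len = 100L, flankB_len = 200L,
  n_markers = 14L, marker_len = 600L, wsp_len = 600L, spacer_len = 150L,
  barcode_k = 10L, min_divergence = 0.05
)

aa_to_nt <- function(aa) c(3L * aa[1] - 2L, 3L * aa[2])

# ---- allele pool / gene config types ---------------------------------------

#' Construct an allele pool for one polymorphic region
#'
#' @param gene_id "cidA" or "cidB".
#' @param region_id "upstream" or "downstream".
#' @param alleles named character vector (label -> nucleotide sequence); all
#'   sequences must share one length and be pairwise distinct.
#' @return `cid_allele_pool`.
#' @export
allele_pool <- function(gene_id, region_id, alleles) {
  if (!length(alleles) || is.null(names(alleles)) || anyDuplicated(names(alleles)))
    abort_cid("pool", "alleles must be uniquely named")
  lens <- nchar(alleles)
  if (length(unique(lens)) != 1L)
    abort_cid("pool", "%s %s: allele lengths differ", gene_id, region_id)
  if (anyDuplicated(unname(alleles)))
    abort_cid("pool", "%s %s: alleles must be pairwise distinct", gene_id, region_id)
  structure(list(gene_id = gene_id, region_id = region_id,
                 alleles = alleles, length = unname(lens[1])),
            class = "cid_allele_pool")
}

#' Construct a gene configuration
#'
#' Region coordinates are 1-based inclusive on the CDS and must be in frame
#' (start == 1 mod 3) and disjoint; lengths must equal the matching allele
#' pool lengths.
#'
#' @param gene_id gene name.
#' @param scaffold constant CDS backbone.
#' @param region_coords list(upstream=c(start,end), downstream=c(start,end)),
#'   nucleotide coordinates.
#' @param protein_region_coords same intervals in amino acids.
#' @param excluded_tail_start optional 1-based nt position from which the
#'   gene tail is excluded from coverage (identically duplicated elsewhere).
#' @param group wPip group label carried into variant names.
#' @return `cid_gene_config`.
#' @export
gene_config <- function(gene_id, scaffold, region_coords,
                        protein_region_coords = NULL,
                        excluded_tail_start = NULL, group = "IV") {
  ord <- order(vapply(region_coords, `[`, integer(1), 1L))
  rc <- region_coords[ord]
  prev_end <- 0L
  for (nm in names(rc)) {
    iv <- rc[[nm]]
    if (iv[1] %% 3L != 1L)
      abort_cid("config", "%s region %s start not in frame", gene_id, nm)
    if (iv[1] <= prev_end)
      abort_cid("config", "%s region intervals overlap", gene_id)
    if (iv[2] > nchar(scaffold))
      abort_cid("config", "%s region %s exceeds scaffold", gene_id, nm)
    prev_end <- iv[2]
  }
  structure(list(gene_id = gene_id, scaffold = scaffold,
                 region_coords = region_coords,
                 protein_region_coords = protein_region_coords,
                 excluded_tail_start = excluded_tail_start, group = group),
            class = "cid_gene_config")
}

# ---- variant construction ---------------------------------------------------

render_variant_name <- function(gene_id, group, up, down) {
  sprintf("%s_%s(%s/%s)", gene_id, group, up, down)
}

#' Parse a rendered variant name
#' @param name e.g. `"cidA_IV(δ/1)"`.
#' @return list(gene_id, group, upstream, downstream).
#' @export
parse_variant_name <- function(name) {
  m <- regmatches(name, regexec("^([^_]+)_([^(]+)\\(([^/]+)/([^)]+)\\)$", name))[[1]]
  if (length(m) != 5L) abort_cid("name", "cannot parse variant name '%s'", name)
  list(gene_id = m[2], group = m[3], upstream = m[4], downstream = m[5])
}

#' Build a variant sequence from allele labels
#'
#' Splices the chosen upstream and downstream allele sequences into the
#' gene's constant scaffold and names the result `gene_GROUP(up/down)`.
#'
#' @param config a `cid_gene_config`.
#' @param upstream_label,downstream_label allele labels present in `pools`.
#' @param pools list(upstream=, downstream=) of `cid_allele_pool`.
#' @return list(sequence, name).
#' @export
make_variant <- function(config, upstream_label, downstream_label, pools) {
  labs <- c(upstream = upstream_label, downstream = downstream_label)
  seqs <- character(2); names(seqs) <- names(labs)
  for (r in c("upstream", "downstream")) {
    pool <- pools[[r]]
    if (is.null(pool) || !labs[[r]] %in% names(pool$alleles))
      abort_cid("label", "%s: unknown %s allele label '%s'",
                config$gene_id, r, labs[[r]])
    iv <- config$region_coords[[r]]
    if (pool$length != iv[2] - iv[1] + 1L)
      abort_cid("length", "%s %s: allele length %d != interval length %d",
                config$gene_id, r, pool$length, iv[2] - iv[1] + 1L)
    seqs[[r]] <- pool$alleles[[labs[[r]]]]
  }
  out <- config$scaffold
  # splice right-to-left so earlier coordinates stay valid
  for (r in names(config$region_coords)[order(-vapply(config$region_coords,
                                                      `[`, integer(1), 1L))]) {
    iv <- config$region_coords[[r]]
    out <- splice_chr(out, iv[1], iv[2], seqs[[r]])
  }
  list(sequence = out,
       name = render_variant_name(config$gene_id, config$group,
                                  upstream_label, downstream_label))
}

# ---- allele engineering -----------------------------------------------------

# in-frame stop codons of a region whose own frame starts at codon boundary
stop_positions <- function(seqchar) {
  n <- nchar(seqchar) %/% 3L
  starts <- 3L * seq_len(n) - 2L
  codons <- substring(seqchar, starts, starts + 2L)
  starts[codons %in% c("TAA", "TAG", "TGA")]
}

fix_stops <- function(seqchar, forbidden = integer()) {
  for (it in 1:20) {
    sp <- stop_positions(seqchar)
    if (!length(sp)) return(seqchar)
    for (s in sp) {
      # mutate the third base (to C kills all three stops) unless forbidden
      p <- if (!(s + 2L) %in% forbidden) s + 2L
           else if (!s %in% forbidden) s else s + 1L
      base <- if (p == s + 2L) "C" else "C"
      seqchar <- splice_chr(seqchar, p, p, base)
    }
  }
  abort_cid("construct", "could not remove in-frame stops")
}

# scan the allele spliced into its gene context for enzyme cuts; returns
# cut positions in gene coordinates
gene_cuts <- function(config, pools, up, down, enzymes) {
  v <- make_variant(config, up, down, pools)
  sort(unique(unlist(lapply(enzymes, find_sites, sequence = v$sequence))))
}

# Engineer the allele pool for one region: start from the scaffold's own
# region content, plant per-allele enzyme sites, add barcode substitutions
# (disjoint positions per allele) for >= 5% pairwise divergence, keep the
# region stop-free and free of accidental enzyme sites in gene context.
engineer_pool <- function(gene_id, region_id, base, sites_plan, labels,
                          label_keys, enzymes, k_barcode) {
  len <- nchar(base)
  base <- fix_stops(sanitize_sites(base, enzymes))
  base <- sanitize_sites(base, enzymes)  # stop-fix may reintroduce sites
  if (length(stop_positions(base))) base <- fix_stops(base)
  footprints <- integer()
  for (plan in sites_plan) {
    if (!length(plan)) next
    site_len <- nchar(switch(plan$enzyme, ApoI = "AAATTT", Hpy188I = "TCAGA",
                             BanI = "GGTACC", TaqI = "TCGA"))
    footprints <- c(footprints, seq.int(plan$offset + 1L, plan$offset + site_len))
  }
  free <- setdiff(seq_len(len), footprints)
  n_alleles <- length(labels)
  barcode_pos <- split(sample(free, n_alleles * k_barcode),
                       rep(seq_len(n_alleles), each = k_barcode))
  enz_by_name <- setNames(enzymes, vapply(enzymes, `[[`, character(1), "name"))
  alleles <- character(n_alleles)
  for (i in seq_len(n_alleles)) {
    al <- base
    plan <- sites_plan[[label_keys[i]]]
    planted <- integer()
    if (length(plan)) {
      enz <- enz_by_name[[plan$enzyme]]
      site <- concrete_site(enz)
      al <- splice_chr(al, plan$offset + 1L, plan$offset + nchar(site), site)
      planted <- seq.int(plan$offset + 1L, plan$offset + nchar(site))
      al <- fix_stops(al, forbidden = planted)
    }
    want <- if (length(plan)) plan$offset + enz_by_name[[plan$enzyme]]$cut_offset
            else integer()
    cuts_of <- function(s) {
      cc <- unlist(lapply(enzymes, find_sites, sequence = s))
      sort(unique(as.integer(cc)))
    }
    for (p in barcode_pos[[i]]) {
      old <- substr(al, p, p)
      for (b in sample(setdiff(DNA_BASES, old))) {
        cand <- splice_chr(al, p, p, b)
        if (!length(stop_positions(cand)) &&
            identical(cuts_of(cand), sort(as.integer(want)))) { al <- cand; break }
      }
    }
    # final verify/repair: stop-fixing can create sites; redraw free bases
    # of any spurious site until only the designed cuts remain
    for (it in 1:30) {
      spurious <- setdiff(cuts_of(al), want)
      if (!length(spurious)) break
      fixed <- FALSE
      for (enz in enzymes) {
        m <- Biostrings::matchPattern(Biostrings::DNAString(enz$recognition),
                                      Biostrings::DNAString(al), fixed = "subject")
        for (k in seq_along(m)) {
          if (!(Biostrings::start(m)[k] - 1L + enz$cut_offset) %in% spurious) next
          span <- setdiff(seq.int(Biostrings::start(m)[k], Biostrings::end(m)[k]),
                          planted)
          for (p in span) for (b in sample(setdiff(DNA_BASES, substr(al, p, p)))) {
            cand <- splice_chr(al, p, p, b)
            if (!length(stop_positions(cand)) &&
                !length(setdiff(cuts_of(cand), c(want, spurious[-1])))) {
              al <- cand; fixed <- TRUE; break
            }
          }
          if (fixed) break
        }
        if (fixed) break
      }
      if (!fixed) abort_cid("construct", "%s %s: cannot repair spurious site",
                            gene_id, region_id)
    }
    if (length(setdiff(cuts_of(al), want)) || length(setdiff(want, cuts_of(al))))
      abort_cid("construct", "%s %s allele %s: designed cuts not realized",
                gene_id, region_id, labels[i])
    alleles[i] <- al
  }
  names(alleles) <- labels
  # enforce the stated pairwise divergence floor
  need <- ceiling(WORLD_LAYOUT$min_divergence * len)
  for (i in seq_len(n_alleles)) for (j in seq_len(n_alleles)) {
    if (i >= j) next
    d <- sum(strsplit(alleles[i], "")[[1]] != strsplit(alleles[j], "")[[1]])
    if (d < need)
      abort_cid("construct", "%s %s: alleles %s/%s only %d apart (< %d)",
                gene_id, region_id, labels[i], labels[j], d, need)
  }
  allele_pool(gene_id, region_id, alleles)
}

# ---- world assembly ---------------------------------------------------------

build_gene <- function(gene_id, lay, enzymes) {
  scaffold <- sanitize_sites(random_dna(lay$cds_len), enzymes)
  scaffold <- plant_sites(scaffold, lay$const_cuts, enzymes)
  rc <- lapply(lay$regions_aa, aa_to_nt)
  pools <- list()
  for (r in c("upstream", "downstream")) {
    iv <- rc[[r]]
    base <- subseq_chr(scaffold, iv[1], iv[2])
    pools[[r]] <- engineer_pool(gene_id, r, base, lay$allele_sites[[r]],
                                lay$labels[[r]], lay$label_keys[[r]],
                                enzymes, WORLD_LAYOUT$barcode_k)
  }
  cfg <- gene_config(gene_id, scaffold, rc, lay$regions_aa,
                     excluded_tail_start = lay$excluded_tail_start %||% NULL)
  # verify: every variant's amplifiable window carries exactly the designed
  # cuts (constant + its allele sites) — construction is self-checking
  list(config = cfg, pools = pools)
}

#' Build the synthetic world
#'
#' Deterministically constructs gene configurations, allele pools, primers,
#' the reference genome (one operon copy, 14 marker genes, wsp, plus a
#' duplicate of the cidB tail emulating its identically-duplicated region)
#' and the reference region annotation.
#'
#' @param seed integer seed; the whole world is a pure function of it.
#' @return `cid_world` list.
#' @export
build_world <- function(seed = 1L) {
  enzymes <- default_enzymes()
  with_seed(seed, {
    lay <- WORLD_LAYOUT
    gA <- build_gene("cidA", lay$cidA, enzymes)
    gB <- build_gene("cidB", lay$cidB, enzymes)
    flankA <- sanitize_sites(random_dna(lay$flankA_len), enzymes)
    intergenic <- sanitize_sites(random_dna(lay$intergenic_len), enzymes)
    flankB <- sanitize_sites(random_dna(lay$flankB_len), enzymes)
    primers <- list(
      cidA = list(
        forward = subseq_chr(flankA, lay$flankA_len + lay$cidA$amplicon[1] + 1L,
                             lay$flankA_len + lay$cidA$amplicon[1] + lay$cidA$primer_len),
        reverse = revcomp(subseq_chr(gA$config$scaffold,
                                     lay$cidA$amplicon[2] - lay$cidA$primer_len + 1L,
                                     lay$cidA$amplicon[2]))),
      cidB = list(
        forward = subseq_chr(gB$config$scaffold, lay$cidB$amplicon[1] + 1L,
                             lay$cidB$amplicon[1] + lay$cidB$primer_len),
        reverse = revcomp(subseq_chr(gB$config$scaffold,
                                     lay$cidB$amplicon[2] - lay$cidB$primer_len + 1L,
                                     lay$cidB$amplicon[2]))))
    markers <- setNames(replicate(lay$n_markers, random_dna(lay$marker_len)),
                        sprintf("marker_%02d", seq_len(lay$n_markers)))
    wsp <- random_dna(lay$wsp_len)
    # backbone spacers are part of the world: sample genomes share them with
    # the reference, so only operon-copy junctions carry novel sequence
    backbone_spacers <- replicate(lay$n_markers + 4L, random_dna(lay$spacer_len))
    world <- structure(list(
      seed = seed, enzymes = enzymes,
      gene_configs = list(cidA = gA$config, cidB = gB$config),
      registries = list(cidA = gA$pools, cidB = gB$pools),
      primers = primers, flankA = flankA, intergenic = intergenic,
      flankB = flankB, markers = markers, wsp = wsp,
      backbone_spacers = backbone_spacers,
      reference_variants = c(cidA = render_variant_name("cidA", "IV", "α", "1"),
                             cidB = render_variant_name("cidB", "IV", "a", "1"))
    ), class = "cid_world")
    ref <- assemble_genome(world, k_operon = 1L,
                           variant_choices = list(world$reference_variants),
                           copy_spacers = character())
    world$reference_genome <- ref$genome
    world$regions <- ref$regions
    world
  })
}

# operon cassette for one copy
operon_copy_seq <- function(world, cidA_name, cidB_name) {
  pa <- parse_variant_name(cidA_name)
  pb <- parse_variant_name(cidB_name)
  va <- make_variant(world$gene_configs$cidA, pa$upstream, pa$downstream,
                     world$registries$cidA)
  vb <- make_variant(world$gene_configs$cidB, pb$upstream, pb$downstream,
                     world$registries$cidB)
  paste0(world$flankA, va$sequence, world$intergenic, vb$sequence, world$flankB)
}

# Assemble a genome: markers, wsp, operon copies, cidB-tail duplicate,
# spacers. Returns genome string plus a 0-based half-open region table in
# genome coordinates (annotating the FIRST operon copy; for the reference,
# the only one).
assemble_genome <- function(world, k_operon, variant_choices, copy_spacers) {
  lay <- WORLD_LAYOUT
  segs <- character(); names_ <- character()
  add <- function(s, n) { segs[[length(segs) + 1L]] <<- s
                          names_[[length(names_) + 1L]] <<- n }
  sp_i <- 0L
  spacer <- function() { sp_i <<- sp_i + 1L; world$backbone_spacers[[sp_i]] }
  add(spacer(), "spacer")
  for (m in names(world$markers)) { add(world$markers[[m]], m); add(spacer(), "spacer") }
  add(world$wsp, "wsp"); add(spacer(), "spacer")
  for (i in seq_len(k_operon)) {
    vc <- variant_choices[[i]]
    add(operon_copy_seq(world, vc[["cidA"]], vc[["cidB"]]),
        sprintf("operon_copy_%d", i))
    if (i < k_operon) add(copy_spacers[i], "spacer")
  }
  add(spacer(), "spacer")
  tail0 <- (world$gene_configs$cidB$excluded_tail_start %||% 2461L) - 1L
  add(subseq_chr(make_variant(world$gene_configs$cidB,
                              parse_variant_name(world$reference_variants[["cidB"]])$upstream,
                              parse_variant_name(world$reference_variants[["cidB"]])$downstream,
                              world$registries$cidB)$sequence,
                 tail0 + 1L, lay$cidB$cds_len), "cidB_tail_dup")
  add(spacer(), "spacer")
  lens <- nchar(segs)
  starts0 <- cumsum(c(0L, lens[-length(lens)]))
  genome <- paste(segs, collapse = "")
  # region annotation relative to the first operon copy
  op1 <- starts0[match("operon_copy_1", names_)]
  cidA0 <- op1 + lay$flankA_len
  cidB0 <- cidA0 + lay$cidA$cds_len + lay$intergenic_len
  reg <- function(name, s0, e0, role, parent = NA_character_)
    data.frame(name = name, start0 = as.integer(s0), end0 = as.integer(e0),
               role = role, parent = parent, stringsAsFactors = FALSE)
  rcA <- lapply(world$gene_configs$cidA$region_coords, function(iv) iv - c(1L, 0L))
  rcB <- lapply(world$gene_configs$cidB$region_coords, function(iv) iv - c(1L, 0L))
  regions <- rbind(
    do.call(rbind, lapply(names(world$markers), function(m)
      reg(m, starts0[match(m, names_)], starts0[match(m, names_)] + lay$marker_len,
          "marker"))),
    reg("wsp", starts0[match("wsp", names_)],
        starts0[match("wsp", names_)] + lay$wsp_len, "wsp"),
    reg("cidA", cidA0, cidA0 + lay$cidA$cds_len, "operon_gene"),
    reg("cidB", cidB0, cidB0 + lay$cidB$cds_len, "operon_gene"),
    reg("cidA_upstream", cidA0 + rcA$upstream[1], cidA0 + rcA$upstream[2],
        "exclusion", "cidA"),
    reg("cidA_downstream", cidA0 + rcA$downstream[1], cidA0 + rcA$downstream[2],
        "exclusion", "cidA"),
    reg("cidB_upstream", cidB0 + rcB$upstream[1], cidB0 + rcB$upstream[2],
        "exclusion", "cidB"),
    reg("cidB_downstream", cidB0 + rcB$downstream[1], cidB0 + rcB$downstream[2],
        "exclusion", "cidB"),
    reg("cidB_tail", cidB0 + tail0, cidB0 + lay$cidB$cds_len, "exclusion", "cidB")
  )
  list(genome = genome, regions = regions)
}

#' Variant repertoire of the world's registries
#'
#' All constructible variant names for a gene (the label-pair lattice).
#'
#' @param world a `cid_world`.
#' @param gene_id "cidA" or "cidB".
#' @return character vector of rendered names.
#' @export
world_variants <- function(world, gene_id) {
  cfg <- world$gene_configs[[gene_id]]
  pools <- world$registries[[gene_id]]
  out <- character()
  for (u in names(pools$upstream$alleles))
    for (d in names(pools$downstream$alleles))
      out <- c(out, render_variant_name(gene_id, cfg$group, u, d))
  out
}

#' Amplify and digest one variant with its diagnostic test
#'
#' @param world a `cid_world`.
#' @param gene_id "cidA" (ApoI+Hpy188I) or "cidB" (BanI+TaqI).
#' @param variant_name rendered variant name.
#' @return `cid_digest` of the diagnostic amplicon.
#' @export
digest_variant <- function(world, gene_id, variant_name) {
  template <- clone_template(world, gene_id, variant_name)
  amp <- insilico_pcr(template, world$primers[[gene_id]]$forward,
                      world$primers[[gene_id]]$reverse)
  enz <- if (gene_id == "cidA") world$enzymes[c("ApoI", "Hpy188I")]
         else world$enzymes[c("BanI", "TaqI")]
  digest(amp, enz)
}

# clone/template sequence: CDS plus the upstream flank context needed for
# the diagnostic amplicon (cidA's forward primer sits in the flank)
clone_template <- function(world, gene_id, variant_name) {
  p <- parse_variant_name(variant_name)
  v <- make_variant(world$gene_configs[[gene_id]], p$upstream, p$downstream,
                    world$registries[[gene_id]])
  fl <- WORLD_LAYOUT[[gene_id]]$clone_flank
  s <- if (fl > 0)
    paste0(subseq_chr(world$flankA, WORLD_LAYOUT$flankA_len - fl + 1L,
                      WORLD_LAYOUT$flankA_len), v$sequence)
  else v$sequence
  attr(s, "cds_start") <- fl + 1L
  s
}

#' Diagnostic RFLP patterns realized by the world's own variants
#'
#' Digests one representative variant per distinguishable allele class and
#' returns reference patterns for [call_pattern()]. (The world is indel-free,
#' so one printed band differs: see the module comment.)
#'
#' @param world a `cid_world`.
#' @param gene_id "cidA" or "cidB".
#' @return list of `cid_pattern`.
#' @export
world_patterns <- function(world, gene_id) {
  if (gene_id == "cidA") {
    reps <- c(alpha = "α", "beta/gamma" = "β", delta = "δ")
    other <- "1"
    mk <- function(u) render_variant_name("cidA", "IV", u, other)
  } else {
    reps <- c(`1` = "1", `2` = "2", `3` = "3")
    mk <- function(d) render_variant_name("cidB", "IV", "a", d)
  }
  lapply(seq_along(reps), function(i) {
    dg <- digest_variant(world, gene_id, mk(reps[[i]]))
    reference_pattern(names(reps)[i], dg$fragments)
  })
}
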