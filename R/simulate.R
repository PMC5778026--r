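# Simulators: multi-copy sample genomes, uniform read sampling, clone
# sampling (multinomial over variant copies), qPCR Cq tables, and line
# panels where crossing type follows a variant-signature rule with a
# configurable discordance rate. Every generator is pure given (inputs, seed).

#' Simulate a strain with k operon copies
#'
#' The sample genome shares the reference layout (markers, wsp, cidB-tail
#' duplicate) but carries `k_operon` operon copies, identical at
#' non-polymorphic positions, separated by unique random spacers.
#'
#' @param world a `cid_world` from [build_world()].
#' @param k_operon number of operon copies (>= 1).
#' @param variant_choices optional list of length `k_operon`; each element a
#'   named character vector `c(cidA=, cidB=)` of rendered variant names.
#'   Defaults to a seeded draw from the world's variant lattice.
#' @param seed RNG seed.
#' @param strain_id identifier.
#' @return `cid_strain` with reference_genome, sample_genome, regions,
#'   repertoire_truth, k_operon.
#' @export
simulate_strain <- function(world, k_operon, variant_choices = NULL, seed = 1L,
                            strain_id = "strain1") {
  if (!is_count(k_operon) || k_operon < 1L)
    abort_cid("k_operon", "k_operon must be a positive integer, got %s",
              deparse(k_operon))
  with_seed(seed, {
    if (is.null(variant_choices)) {
      va <- world_variants(world, "cidA")
      vb <- world_variants(world, "cidB")
      variant_choices <- lapply(seq_len(k_operon), function(i)
        c(cidA = sample(va, 1L), cidB = sample(vb, 1L)))
    }
    if (length(variant_choices) != k_operon)
      abort_cid("k_operon", "variant_choices length %d != k_operon %d",
                length(variant_choices), k_operon)
    spacers <- if (k_operon > 1L)
      vapply(seq_len(k_operon - 1L), function(i)
        random_dna(WORLD_LAYOUT$spacer_len), character(1))
    else character()
    smp <- assemble_genome(world, k_operon, variant_choices, spacers)
    truth <- data.frame(
      copy = seq_len(k_operon),
      cidA = vapply(variant_choices, `[[`, character(1), "cidA"),
      cidB = vapply(variant_choices, `[[`, character(1), "cidB"),
      stringsAsFactors = FALSE)
    structure(list(strain_id = strain_id, world = world,
                   reference_genome = world$reference_genome,
                   regions = world$regions,
                   sample_genome = smp$genome,
                   repertoire_truth = truth,
                   k_operon = as.integer(k_operon)),
              class = "cid_strain")
  })
}

#' @export
print.cid_strain <- function(x, ...) {
  cat(sprintf("Strain %s: reference %d bp, sample %d bp, %d operon cop%s\n",
              x$strain_id, nchar(x$reference_genome), nchar(x$sample_genome),
              x$k_operon, if (x$k_operon == 1L) "y" else "ies"))
  invisible(x)
}

#' Simulate uniform single-end reads from the sample genome
#'
#' Read count is Poisson with mean `mean_depth * G / read_length`; start
#' positions are uniform; strands random; substitution errors at
#' `error_rate` per base.
#'
#' @param strain a `cid_strain`.
#' @param mean_depth target fold-coverage.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution rate in [0, 0.5].
#' @param seed RNG seed.
#' @return named character vector of read sequences (as sequenced, i.e.
#'   reverse-complemented for minus-strand reads).
#' @export
simulate_reads <- function(strain, mean_depth, read_length = 100L,
                           error_rate = 0, seed = 1L) {
  if (error_rate < 0 || error_rate > 0.5)
    abort_cid("error_rate", "error_rate must be in [0, 0.5], got %g", error_rate)
  G <- nchar(strain$sample_genome)
  if (read_length > G)
    abort_cid("read_length", "read_length %d exceeds genome length %d",
              read_length, G)
  if (mean_depth <= 0) abort_cid("depth", "mean_depth must be positive")
  with_seed(seed, {
    n <- rpois(1L, mean_depth * G / read_length)
    starts <- sample.int(G - read_length + 1L, n, replace = TRUE)
    seqs <- substring(strain$sample_genome, starts, starts + read_length - 1L)
    minus <- runif(n) < 0.5
    if (any(minus)) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[minus])))
      seqs[minus] <- rc
    }
    if (error_rate > 0) seqs <- vapply(seqs, mutate_seq, character(1),
                                       rate = error_rate, USE.NAMES = FALSE)
    setNames(seqs, sprintf("read_%06d", seq_len(n)))
  })
}

#' Simulate cloned amplicon sequences for one gene
#'
#' Each clone is drawn (uniformly, or by `weights`) from the strain's variant
#' copies of the gene, with per-base substitution error. Clone sequences
#' carry the amplifiable flank context and a `cds_start` attribute.
#'
#' @param strain a `cid_strain`.
#' @param gene_id "cidA" or "cidB".
#' @param n_clones number of clones (>= 1).
#' @param error_rate per-base substitution rate.
#' @param seed RNG seed.
#' @param weights optional per-copy sampling weights (length k_operon).
#' @return named character vector of clone sequences, attribute
#'   `truth` = sampled variant name per clone, `cds_start`.
#' @export
simulate_clones <- function(strain, gene_id, n_clones, error_rate = 0,
                            seed = 1L, weights = NULL) {
  if (!gene_id %in% names(strain$world$gene_configs))
    abort_cid("gene", "gene '%s' absent from strain", gene_id)
  if (!is_count(n_clones) || n_clones < 1L)
    abort_cid("n_clones", "n_clones must be >= 1")
  copies <- strain$repertoire_truth[[gene_id]]
  w <- weights %||% rep(1, length(copies))
  if (length(w) != length(copies))
    abort_cid("weights", "weights length %d != %d copies", length(w), length(copies))
  with_seed(seed, {
    pick <- sample.int(length(copies), n_clones, replace = TRUE, prob = w)
    names_ <- copies[pick]
    tmpl <- vapply(unique(names_), function(v)
      as.character(clone_template(strain$world, gene_id, v)), character(1))
    seqs <- tmpl[names_]
    if (error_rate > 0) seqs <- vapply(seqs, mutate_seq, character(1),
                                       rate = error_rate, USE.NAMES = FALSE)
    out <- setNames(unname(seqs), sprintf("clone_%03d", seq_len(n_clones)))
    attr(out, "truth") <- unname(names_)
    attr(out, "cds_start") <- WORLD_LAYOUT[[gene_id]]$clone_flank + 1L
    out
  })
}

# ---- line panels ------------------------------------------------------------

#' Default incompatibility signature rule
#'
#' TRUE iff the repertoire carries any cidA variant with upstream allele
#' delta AND the cidB variant a/2.
#'
#' @param variants list(cidA = character vector of names, cidB = ...).
#' @export
signature_rule_default <- function(variants) {
  upA <- vapply(variants$cidA, function(v) parse_variant_name(v)$upstream,
                character(1))
  has_delta <- any(upA == "δ")
  has_a2 <- any(vapply(variants$cidB, function(v) {
    p <- parse_variant_name(v); p$upstream == "a" && p$downstream == "2"
  }, logical(1)))
  has_delta && has_a2
}

#' Planted category counts reproducing the study-scale panel
#'
#' 17 incompatible lines carrying both signature variants; among 163
#' compatible lines 8 carry both, 8 carry only the cidA delta variant and
#' 147 carry neither (n = 180).
#' @export
panel_paper_counts <- function() {
  c(incompatible_both = 17L, compatible_both = 8L,
    compatible_cidA_only = 8L, compatible_neither = 147L)
}

panel_repertoire <- function(category, group = "IV") {
  v <- function(g, u, d) render_variant_name(g, group, u, d)
  switch(category,
    both = list(cidA = c(v("cidA", "δ", "1"), v("cidA", "α", "1")),
                cidB = c(v("cidB", "a", "2"), v("cidB", "b", "1"))),
    cidA_only = list(cidA = c(v("cidA", "δ", "2"), v("cidA", "β", "1")),
                     cidB = c(v("cidB", "a", "1"), v("cidB", "b", "3"))),
    cidB_only = list(cidA = c(v("cidA", "α", "1")),
                     cidB = c(v("cidB", "a", "2"))),
    neither = list(cidA = c(v("cidA", "α", "1"), v("cidA", "γ", "2")),
                   cidB = c(v("cidB", "b", "2"), v("cidB", "a", "1"))))
}

#' Simulate a panel of isofemale lines
#'
#' Each line receives a variant repertoire; its crossing type is
#' "incompatible" iff `signature_rule` holds, then flipped with probability
#' `discordance_rate`. With `planted` counts (see [panel_paper_counts()])
#' the panel reproduces exact category totals and `discordance_rate` is
#' ignored (the planted compatible/both and compatible/cidA_only categories
#' ARE the discordant lines).
#'
#' @param n_lines number of lines.
#' @param signature_rule predicate on list(cidA=, cidB=) of variant names.
#' @param discordance_rate probability in [0, 1) of flipping the rule-implied
#'   crossing type.
#' @param seed RNG seed.
#' @param planted optional named integer vector of
#'   `<crossingtype>_<category>` counts; must sum to `n_lines`.
#' @param group wPip group label for all lines.
#' @return data.frame (class `cid_panel`): line_id, population_id,
#'   wpip_group, cidA/cidB variant lists, signature_truth, crossing_type.
#' @export
simulate_panel <- function(n_lines, signature_rule = signature_rule_default,
                           discordance_rate = 0, seed = 1L, planted = NULL,
                           group = "IV") {
  if (discordance_rate < 0 || discordance_rate >= 1)
    abort_cid("discordance", "discordance_rate must be in [0, 1)")
  with_seed(seed, {
    if (!is.null(planted)) {
      if (sum(planted) != n_lines)
        abort_cid("panel", "planted counts sum %d != n_lines %d",
                  sum(planted), n_lines)
      cats <- rep(names(planted), planted)
      cats <- sample(cats)  # shuffle line order
      parts <- strsplit(cats, "_", fixed = TRUE)
      ctype <- vapply(parts, `[[`, character(1), 1L)
      sigcat <- vapply(parts, function(p) paste(p[-1], collapse = "_"),
                       character(1))
      reps <- lapply(sigcat, panel_repertoire, group = group)
    } else {
      labels_up_A <- c("α", "β", "γ", "δ")
      reps <- lapply(seq_len(n_lines), function(i) {
        nA <- sample(1:3, 1L); nB <- sample(1:3, 1L)
        list(cidA = sample(unlist(lapply(labels_up_A, function(u)
               lapply(c("1", "2"), function(d)
                 render_variant_name("cidA", group, u, d)))), nA),
             cidB = sample(unlist(lapply(c("a", "b"), function(u)
               lapply(c("1", "2", "3"), function(d)
                 render_variant_name("cidB", group, u, d)))), nB))
      })
      sig <- vapply(reps, signature_rule, logical(1))
      ctype <- ifelse(sig, "incompatible", "compatible")
      flip <- runif(n_lines) < discordance_rate
      ctype[flip] <- ifelse(ctype[flip] == "incompatible",
                            "compatible", "incompatible")
    }
    out <- data.frame(
      line_id = sprintf("line_%03d", seq_len(n_lines)),
      population_id = sprintf("pop_%02d", ((seq_len(n_lines) - 1L) %% 15L) + 1L),
      wpip_group = group,
      crossing_type = ctype,
      signature_truth = vapply(reps, signature_rule, logical(1)),
      stringsAsFactors = FALSE)
    out$cidA <- lapply(reps, `[[`, "cidA")
    out$cidB <- lapply(reps, `[[`, "cidB")
    class(out) <- c("cid_panel", "data.frame")
    out
  })
}

# ---- qPCR -------------------------------------------------------------------

#' Simulate a qPCR Cq table for a strain
#'
#' Cq(locus) = baseline - log_efficiency(copy count) + Gaussian noise. wsp is
#' single copy; cidA and cidB carry `k_operon` copies each (equal, as for an
#' operon).
#'
#' @param strain a `cid_strain`.
#' @param efficiency amplification efficiency in (1, 2]; 2 = perfect doubling.
#' @param noise_sd per-replicate Gaussian Cq noise (cycles).
#' @param seed RNG seed.
#' @param baseline noiseless single-copy Cq.
#' @param replicates replicates per locus.
#' @return data.frame (class `cid_qpcr`): sample_id, locus, replicate, cq.
#' @export
simulate_qpcr <- function(strain, efficiency = 2, noise_sd = 0, seed = 1L,
                          baseline = 25, replicates = 3L) {
  if (efficiency <= 1 || efficiency > 2)
    abort_cid("efficiency", "efficiency must be in (1, 2], got %g", efficiency)
  if (noise_sd < 0) abort_cid("noise", "noise_sd must be >= 0")
  copies <- c(wsp = 1L, cidA = strain$k_operon, cidB = strain$k_operon)
  with_seed(seed, {
    rows <- do.call(rbind, lapply(names(copies), function(loc) {
      cq0 <- baseline - log(copies[[loc]], base = efficiency)
      data.frame(sample_id = strain$strain_id, locus = loc,
                 replicate = seq_len(replicates),
                 cq = cq0 + rnorm(replicates, 0, noise_sd),
                 stringsAsFactors = FALSE)
    }))
    if (any(rows$cq <= 0)) abort_cid("qpcr", "simulated Cq <= 0; raise baseline")
    class(rows) <- c("cid_qpcr", "data.frame")
    rows
  })
}
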