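# End-to-end pipeline on synthetic data: simulate -> coverage -> qPCR ->
# repertoire typing -> RFLP -> association, writing standard-format outputs
# and a manifest with checksums. Deterministic under a fixed seed.

#' Default pipeline configuration
#'
#' @param seed master seed; all stage seeds derive from it.
#' @return named list of parameters (serialized into the run manifest).
#' @export
default_run_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       k_operon = 3L, mean_depth = 50, read_length = 100L,
       read_error_rate = 0,
       n_clones = 48L, clone_error_rate = 0, min_support = 2L,
       n_lines = 180L, discordance_rate = 0, planted_panel = TRUE,
       qpcr_efficiency = 2, qpcr_noise_sd = 0.1,
       positive_rule = "any_variant",
       stages = c("simulate", "coverage", "qpcr", "type", "rflp", "associate"))
}

log_stage <- function(stage, msg, ...) {
  message(sprintf("[cidscope:%s] %s", stage, sprintf(msg, ...)))
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the enabled stages in order, writes FASTA/BED/TSV/JSON outputs
#' under `out_dir`, and returns (and writes) a manifest listing every output
#' with its md5 checksum plus the full configuration.
#'
#' @param config list from [default_run_config()] (fields may be overridden).
#' @param out_dir output directory (created if absent).
#' @return the manifest, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile("cidrun_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  seed <- cfg$seed
  outputs <- character()
  emit <- function(path) { outputs <<- c(outputs, path); path }
  results <- list()

  log_stage("simulate", "building world and strain (seed %d)", seed)
  world <- build_world(child_seed(seed, 1L))
  variants <- lapply(seq_len(cfg$k_operon), function(i)
    c(cidA = world_variants(world, "cidA")[i],
      cidB = world_variants(world, "cidB")[i]))
  strain <- simulate_strain(world, cfg$k_operon, variants,
                            seed = child_seed(seed, 2L))
  if ("simulate" %in% cfg$stages) {
    emit(write_fasta(c(reference = strain$reference_genome), file.path(out_dir, "reference.fa")))
    emit(write_fasta(c(sample = strain$sample_genome), file.path(out_dir, "sample_genome.fa")))
    bed <- data.frame(chrom = "reference", start0 = strain$regions$start0,
                      end0 = strain$regions$end0,
                      name = paste(strain$regions$name, strain$regions$role, sep = "|"))
    emit(write_bed(bed, file.path(out_dir, "regions.bed")))
    emit(write_json(list(seed = seed, k_operon = cfg$k_operon,
                         repertoire_truth = strain$repertoire_truth),
                    file.path(out_dir, "truth.json")))
  }

  if ("coverage" %in% cfg$stages) {
    log_stage("coverage", "simulating %gx reads and mapping", cfg$mean_depth)
    reads <- simulate_reads(strain, cfg$mean_depth, cfg$read_length,
                            cfg$read_error_rate, seed = child_seed(seed, 3L))
    mp <- map_reads_exact(reads, strain$reference_genome)
    prof <- normalize_coverage(compute_coverage(mp$placements,
                                                nchar(strain$reference_genome)))
    regions <- expand_exclusions(strain$regions, margin = cfg$read_length - 1L)
    cn <- estimate_copy_number(prof, regions)
    results$coverage <- cn
    emit(write_json(list(estimate = cn$estimate, operon_mean = cn$operon_mean,
                         gene_means = as.list(cn$gene_means),
                         marker_means = as.list(cn$marker_means),
                         unplaced_reads = mp$unplaced, method = "coverage"),
                    file.path(out_dir, "coverage_cn.json")))
    log_stage("coverage", "copy-number estimate %.3f (planted %d)",
              cn$estimate, cfg$k_operon)
  }

  if ("qpcr" %in% cfg$stages) {
    qt <- simulate_qpcr(strain, cfg$qpcr_efficiency, cfg$qpcr_noise_sd,
                        seed = child_seed(seed, 4L))
    emit(write_tsv(qt, file.path(out_dir, "qpcr.tsv")))
    qa <- qpcr_copy_ratio(qt, "cidA", "wsp", cfg$qpcr_efficiency)
    qb <- qpcr_copy_ratio(qt, "cidB", "wsp", cfg$qpcr_efficiency)
    results$qpcr <- list(cidA = qa$estimate, cidB = qb$estimate)
    emit(write_json(list(cidA_vs_wsp = qa$estimate, cidB_vs_wsp = qb$estimate,
                         cidA_vs_cidB = qa$estimate / qb$estimate,
                         efficiency = cfg$qpcr_efficiency, method = "qpcr"),
                    file.path(out_dir, "qpcr_cn.json")))
    log_stage("qpcr", "cidA:wsp %.2f, cidB:wsp %.2f", qa$estimate, qb$estimate)
  }

  if ("type" %in% cfg$stages) {
    reps <- list()
    for (g in c("cidA", "cidB")) {
      clones <- simulate_clones(strain, g, cfg$n_clones, cfg$clone_error_rate,
                                seed = child_seed(seed, 5L + (g == "cidB")))
      emit(write_fasta(setNames(as.character(clones), names(clones)),
                       file.path(out_dir, sprintf("clones_%s.fa", g))))
      reps[[g]] <- build_repertoire(clones, world$gene_configs[[g]],
                                    world$registries[[g]], cfg$min_support,
                                    line_id = strain$strain_id)
    }
    results$repertoires <- reps
    tsv <- do.call(rbind, lapply(reps, function(r)
      data.frame(line = r$line_id, gene = r$gene_id, variant = r$variants$name,
                 support = r$variants$support, stringsAsFactors = FALSE)))
    emit(write_tsv(tsv, file.path(out_dir, "repertoire.tsv")))
    fl <- signature_flags(list(cidA = reps$cidA, cidB = reps$cidB))
    emit(write_json(unclass(fl), file.path(out_dir, "signature_flags.json")))
    log_stage("type", "%d cidA + %d cidB variants, signature category %s",
              nrow(reps$cidA$variants), nrow(reps$cidB$variants), fl$category)
  }

  if ("rflp" %in% cfg$stages) {
    calls <- NULL
    for (g in c("cidA", "cidB")) {
      pats <- world_patterns(world, g)
      for (v in unique(strain$repertoire_truth[[g]])) {
        dg <- digest_variant(world, g, v)
        calls <- rbind(calls, data.frame(
          sample = strain$strain_id, test = g, variant = v,
          fragments = paste(dg$fragments, collapse = ";"),
          call = as.character(call_pattern(dg, pats)),
          stringsAsFactors = FALSE))
      }
    }
    results$rflp <- calls
    emit(write_tsv(calls, file.path(out_dir, "rflp_calls.tsv")))
    log_stage("rflp", "%d variant digests called", nrow(calls))
  }

  if ("associate" %in% cfg$stages) {
    planted <- if (isTRUE(cfg$planted_panel)) panel_paper_counts() else NULL
    panel <- simulate_panel(cfg$n_lines, discordance_rate = cfg$discordance_rate,
                            seed = child_seed(seed, 7L), planted = planted)
    flags <- lapply(seq_len(nrow(panel)), function(i)
      signature_flags(list(cidA = panel$cidA[[i]], cidB = panel$cidB[[i]])))
    ct <- build_contingency(panel$crossing_type, flags, cfg$positive_rule)
    assoc <- prop_test_yates(ct)
    results$association <- assoc
    ptab <- data.frame(line_id = panel$line_id, population = panel$population_id,
                       group = panel$wpip_group,
                       cidA = vapply(panel$cidA, paste, character(1), collapse = ","),
                       cidB = vapply(panel$cidB, paste, character(1), collapse = ","),
                       crossing_type = panel$crossing_type)
    emit(write_tsv(ptab, file.path(out_dir, "panel.tsv")))
    emit(write_json(list(chi2 = assoc$chi2, df = assoc$df, p = assoc$p,
                         corrected = assoc$corrected,
                         table = as.list(as.data.frame(assoc$table)),
                         positive_rule = cfg$positive_rule,
                         undetermined = ct$undetermined),
                    file.path(out_dir, "association.json")))
    disc <- discordance_report(panel$crossing_type, flags)
    emit(write_tsv(cbind(crossing_type = rownames(disc), as.data.frame(disc)),
                   file.path(out_dir, "discordance.tsv")))
    log_stage("associate", "chi2 = %.2f, p = %.3g", assoc$chi2, assoc$p)
  }

  manifest <- list(
    package = "cidscope",
    seed = seed,
    config = cfg[setdiff(names(cfg), "stages")],
    stages = cfg$stages,
    outputs = lapply(sort(outputs), function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  write_json(manifest, file.path(out_dir, "manifest.json"))
  manifest$results <- results
  invisible(manifest)
}
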