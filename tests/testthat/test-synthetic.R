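# synthetic-data module: variant splicing, strain/read/clone/panel/qPCR
# generators and their stated invariants.

test_that("make_variant splices alleles and round-trips through extraction", {
  for (g in c("cidA", "cidB")) {
    cfg <- tw$gene_configs[[g]]
    pools <- tw$registries[[g]]
    for (u in names(pools$upstream$alleles)) {
      for (d in names(pools$downstream$alleles)) {
        v <- make_variant(cfg, u, d, pools)
        expect_identical(v$name, sprintf("%s_IV(%s/%s)", g, u, d))
        # string-slicing oracle: extracted intervals equal the chosen alleles
        for (r in c("upstream", "downstream")) {
          iv <- cfg$region_coords[[r]]
          lab <- if (r == "upstream") u else d
          expect_identical(substr(v$sequence, iv[1], iv[2]),
                           unname(pools[[r]]$alleles[[lab]]))
        }
        # outside the regions the variant equals the scaffold
        expect_identical(substr(v$sequence, 1, cfg$region_coords$upstream[1] - 1),
                         substr(cfg$scaffold, 1, cfg$region_coords$upstream[1] - 1))
      }
    }
  }
})

test_that("make_variant is the identity splice for scaffold-content pools", {
  cfg <- tw$gene_configs$cidA
  pools <- list(
    upstream = allele_pool("cidA", "upstream", c(
      x = substr(cfg$scaffold, cfg$region_coords$upstream[1],
                 cfg$region_coords$upstream[2]))),
    downstream = allele_pool("cidA", "downstream", c(
      y = substr(cfg$scaffold, cfg$region_coords$downstream[1],
                 cfg$region_coords$downstream[2]))))
  v <- make_variant(cfg, "x", "y", pools)
  expect_identical(v$sequence, cfg$scaffold)
})

test_that("make_variant rejects unknown labels and length mismatches", {
  cfg <- tw$gene_configs$cidA
  pools <- tw$registries$cidA
  expect_error(make_variant(cfg, "ω", "1", pools), class = "cidscope_error_label")
  short <- list(upstream = allele_pool("cidA", "upstream", c(z = "ACGTACGTAC")),
                downstream = pools$downstream)
  expect_error(make_variant(cfg, "z", "1", short), class = "cidscope_error_length")
})

test_that("allele pools satisfy their declared invariants", {
  for (g in c("cidA", "cidB")) for (r in c("upstream", "downstream")) {
    pool <- tw$registries[[g]][[r]]
    lens <- nchar(pool$alleles)
    expect_true(all(lens == pool$length))
    expect_false(anyDuplicated(names(pool$alleles)) > 0)
    al <- strsplit(pool$alleles, "")
    need <- ceiling(0.05 * pool$length)
    for (i in seq_along(al)) for (j in seq_along(al)) {
      if (i >= j) next
      expect_gte(sum(al[[i]] != al[[j]]), need)
    }
  }
})

test_that("simulate_strain plants the requested copies deterministically", {
  expect_error(simulate_strain(tw, 0L), class = "cidscope_error_k_operon")
  # substring-scan oracle: a constant piece of the cidA scaffold occurs once
  # per copy (plus once nowhere else)
  probe <- substr(tw$gene_configs$cidA$scaffold, 1, 200)
  count_probe <- function(genome)
    length(gregexpr(probe, genome, fixed = TRUE)[[1]])
  st5 <- simulate_strain(tw, 5L, seed = 5L)
  expect_identical(count_probe(st5$sample_genome), 5L)
  expect_identical(count_probe(st5$reference_genome), 1L)
  expect_identical(st5$k_operon, 5L)
  expect_identical(nrow(st5$repertoire_truth), 5L)
  # reference carries exactly one wsp and one of each marker
  expect_identical(length(gregexpr(tw$wsp, st5$reference_genome, fixed = TRUE)[[1]]), 1L)
  # determinism
  st5b <- simulate_strain(tw, 5L, seed = 5L)
  expect_identical(st5$sample_genome, st5b$sample_genome)
  # k = 1 with the reference variants reproduces the reference operon
  st1 <- simulate_strain(tw, 1L, list(tw$reference_variants), seed = 3L)
  i <- regexpr(probe, st1$reference_genome, fixed = TRUE)
  expect_identical(substr(st1$sample_genome, i, i + 4000L),
                   substr(st1$reference_genome, i, i + 4000L))
})

test_that("simulate_reads: exact substrings, Poisson count, determinism", {
  st <- tw_strain3
  reads <- simulate_reads(st, 5, 100L, 0, seed = 21L)
  G <- nchar(st$sample_genome)
  lambda <- 5 * G / 100
  expect_lt(abs(length(reads) - lambda), 3 * sqrt(lambda))
  both <- paste0(st$sample_genome, "NNN", revcomp(st$sample_genome))
  for (r in reads[seq_len(30)])
    expect_true(grepl(r, both, fixed = TRUE))
  expect_identical(reads, simulate_reads(st, 5, 100L, 0, seed = 21L))
  expect_error(simulate_reads(st, 5, 100L, 0.9, seed = 1L),
               class = "cidscope_error_error_rate")
  expect_error(simulate_reads(st, 5, 10 * G, 0, seed = 1L),
               class = "cidscope_error_read_length")
})

test_that("read sampling is uniform over a single-copy locus", {
  st <- simulate_strain(tw, 1L, list(tw$reference_variants), seed = 31L)
  reads <- simulate_reads(st, 100, 100L, 0, seed = 32L)
  mp <- map_reads_exact(reads, st$reference_genome)
  prof <- compute_coverage(mp$placements, nchar(st$reference_genome))
  m <- tw$regions[tw$regions$name == "marker_07", ]
  mean_depth <- mean(prof$depth[(m$start0 + 1):m$end0])
  expect_lt(abs(mean_depth - 100) / 100, 0.05)
})

test_that("simulate_clones draws from the copy repertoire", {
  cl <- simulate_clones(tw_strain6, "cidA", 48L, 0, seed = 41L)
  expect_identical(length(unique(cl)), 6L)  # P(miss) = 6*(5/6)^48 ~ 1e-3
  expect_identical(length(cl), 48L)
  # weights concentrate sampling
  clw <- simulate_clones(tw_strain3, "cidA", 20L, 0, seed = 42L,
                         weights = c(1, 0, 0))
  expect_identical(unique(attr(clw, "truth")), "cidA_IV(α/1)")
  expect_identical(length(unique(clw)), 1L)
  expect_error(simulate_clones(tw_strain3, "cidX", 5L, 0, seed = 1L),
               class = "cidscope_error_gene")
})

test_that("simulate_panel: label conservation, planted counts, flip rate", {
  p0 <- simulate_panel(60L, discordance_rate = 0, seed = 51L)
  expect_identical(nrow(p0), 60L)
  # with no discordance the crossing type is the signature rule verbatim
  expect_identical(p0$crossing_type == "incompatible", p0$signature_truth)
  # recomputing flags from repertoires matches stored truth
  recomputed <- vapply(seq_len(nrow(p0)), function(i)
    signature_rule_default(list(cidA = p0$cidA[[i]], cidB = p0$cidB[[i]])),
    logical(1))
  expect_identical(recomputed, p0$signature_truth)

  pp <- simulate_panel(180L, seed = 52L, planted = panel_paper_counts())
  expect_identical(sum(pp$crossing_type == "incompatible"), 17L)
  expect_identical(sum(pp$crossing_type == "compatible"), 163L)
  flags <- lapply(seq_len(nrow(pp)), function(i)
    signature_flags(list(cidA = pp$cidA[[i]], cidB = pp$cidB[[i]])))
  cats <- vapply(flags, `[[`, character(1), "category")
  expect_identical(sum(cats == "both" & pp$crossing_type == "compatible"), 8L)
  expect_identical(sum(cats == "cidA_only"), 8L)
  expect_identical(sum(cats == "neither"), 147L)

  rate <- 0.1
  pf <- simulate_panel(10000L, discordance_rate = rate, seed = 53L)
  flipped <- mean((pf$crossing_type == "incompatible") != pf$signature_truth)
  expect_lt(abs(flipped - rate), 3 * sqrt(rate * (1 - rate) / 10000))
  expect_error(simulate_panel(10L, discordance_rate = 1),
               class = "cidscope_error_discordance")
})

test_that("simulate_qpcr encodes copy number in delta-Cq", {
  st4 <- simulate_strain(tw, 4L, seed = 61L)
  q <- simulate_qpcr(st4, efficiency = 2, noise_sd = 0, seed = 62L)
  cq <- tapply(q$cq, q$locus, mean)
  expect_equal(unname(cq["wsp"] - cq["cidA"]), 2, tolerance = 1e-12)  # log2(4)
  st1 <- simulate_strain(tw, 1L, seed = 63L)
  q1 <- simulate_qpcr(st1, efficiency = 2, noise_sd = 0, seed = 64L)
  expect_equal(length(unique(round(q1$cq, 12))), 1L)
  # noisy replicate mean recovers the planted Cq within 3 sigma / sqrt(n)
  qn <- simulate_qpcr(st4, efficiency = 2, noise_sd = 0.2, seed = 65L,
                      replicates = 30L)
  wsp <- qn$cq[qn$locus == "wsp"]
  expect_gt(length(unique(wsp)), 1L)
  expect_lt(abs(mean(wsp) - 25), 3 * 0.2 / sqrt(30))
  expect_error(simulate_qpcr(st4, efficiency = 2.5),
               class = "cidscope_error_efficiency")
})
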