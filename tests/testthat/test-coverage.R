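# coverage_cn module: placement, per-base depth, normalization, region means
# with exclusions, and both copy-number estimators.

test_that("map_reads_exact places reads at the leftmost best locus", {
  ref <- tw$reference_genome
  r1 <- substr(ref, 101, 200)
  r2 <- revcomp(substr(ref, 1, 100))
  mp <- map_reads_exact(c(a = r1, b = r2), ref)
  expect_identical(mp$placements$start0[mp$placements$read_id == "a"], 100L)
  expect_identical(mp$placements$start0[mp$placements$read_id == "b"], 0L)
  expect_identical(mp$placements$strand[mp$placements$read_id == "b"], "-")
  expect_identical(mp$unplaced, 0L)
  expect_error(map_reads_exact(c(a = r1), ""), class = "cidscope_error_reference")
})

test_that("placement agrees with a brute-force substring matcher", {
  st <- tw_strain3
  reads <- simulate_reads(st, 1, 80L, 0, seed = 71L)[1:40]
  mp <- map_reads_exact(reads, st$reference_genome)
  # oracle: leftmost occurrence over forward and reverse-complement
  oracle <- function(r) {
    f <- regexpr(r, st$reference_genome, fixed = TRUE)
    rv <- regexpr(revcomp(r), st$reference_genome, fixed = TRUE)
    pos <- c(if (f > 0) f, if (rv > 0) rv)
    if (length(pos)) min(pos) - 1L else NA_integer_
  }
  want <- vapply(reads, oracle, integer(1))
  got <- setNames(rep(NA_integer_, length(reads)), names(reads))
  got[mp$placements$read_id] <- mp$placements$start0
  expect_identical(unname(got), unname(want))
})

test_that("multi-copy reads pile onto the single reference operon", {
  st <- tw_strain3
  reads <- simulate_reads(st, 20, 100L, 0, seed = 72L)
  mp <- map_reads_exact(reads, st$reference_genome)
  prof <- compute_coverage(mp$placements, nchar(st$reference_genome))
  rg <- st$regions
  cidA <- rg[rg$name == "cidA", ]
  mk <- rg[rg$name == "marker_03", ]
  # constant 5' part of cidA (before the upstream region) vs a marker
  dens_op <- mean(prof$depth[(cidA$start0 + 1):(cidA$start0 + 300)])
  dens_mk <- mean(prof$depth[(mk$start0 + 1):mk$end0])
  expect_gt(dens_op / dens_mk, 2.4)
  expect_lt(dens_op / dens_mk, 3.6)
})

test_that("compute_coverage: interval stabbing and conservation", {
  empty <- compute_coverage(data.frame(start0 = integer(), width = integer()), 50L)
  expect_identical(empty$depth, rep(0, 50))
  one <- compute_coverage(data.frame(start0 = 0L, width = 100L), 200L)
  expect_identical(one$depth, c(rep(1, 100), rep(0, 100)))
  two <- compute_coverage(data.frame(start0 = c(0L, 50L), width = 100L), 200L)
  expect_identical(two$depth[51:100], rep(2, 50))
  expect_identical(two$depth[1:50], rep(1, 50))
  expect_identical(two$depth[101:150], rep(1, 50))
  # conservation over random placements
  set.seed(7)
  pl <- data.frame(start0 = sample.int(900, 200, replace = TRUE) - 1L,
                   width = sample.int(100, 200, replace = TRUE))
  prof <- compute_coverage(pl, 1000L)
  expect_identical(sum(prof$depth), sum(as.numeric(pl$width)))
  expect_error(compute_coverage(data.frame(start0 = 990L, width = 20L), 1000L),
               class = "cidscope_error_coverage")
})

test_that("normalization: hand arithmetic, idempotence, mean one", {
  p <- structure(list(depth = c(2, 2, 6, 6), genome_mean = 4,
                      normalized = FALSE), class = "cid_coverage")
  n1 <- normalize_coverage(p)
  expect_identical(n1$depth, c(0.5, 0.5, 1.5, 1.5))
  expect_lt(abs(mean(n1$depth) - 1), 1e-9)
  expect_identical(normalize_coverage(n1)$depth, n1$depth)
  zero <- structure(list(depth = rep(0, 4), genome_mean = 0,
                         normalized = FALSE), class = "cid_coverage")
  expect_error(normalize_coverage(zero), class = "cidscope_error_normalize")
})

test_that("region_mean honors exclusions", {
  p <- structure(list(depth = c(rep(3, 5), rep(1, 5)), genome_mean = 2,
                      normalized = TRUE), class = "cid_coverage")
  expect_identical(region_mean(p, 0L, 10L), 2)
  expect_identical(region_mean(p, 0L, 10L,
                               data.frame(start0 = 5L, end0 = 10L)), 3)
  expect_error(region_mean(p, 0L, 10L, data.frame(start0 = 0L, end0 = 10L)),
               class = "cidscope_error_region_excluded")
  # tail-duplication analogue: doubled depth over the tail disappears once
  # the tail is excluded
  d <- c(rep(1, 80), rep(2, 20))
  pt <- structure(list(depth = d, genome_mean = mean(d), normalized = TRUE),
                  class = "cid_coverage")
  expect_identical(region_mean(pt, 0L, 100L,
                               data.frame(start0 = 80L, end0 = 100L)), 1)
})

test_that("estimate_copy_number is exact on deterministic tiling", {
  # reference of 1000 bp: one marker [0,200), operon gene [500,700);
  # tile everything once, operon twice
  tile <- function(s0, e0) data.frame(start0 = seq.int(s0, e0 - 50L, by = 50L),
                                      width = 50L)
  pl <- rbind(tile(0L, 1000L), tile(500L, 700L))
  prof <- normalize_coverage(compute_coverage(pl, 1000L))
  regions <- data.frame(name = c("m1", "op"), start0 = c(0L, 500L),
                        end0 = c(200L, 700L), role = c("marker", "operon_gene"),
                        parent = NA_character_)
  cn <- estimate_copy_number(prof, regions)
  expect_identical(cn$estimate, 2)
  expect_identical(cn$method, "coverage")
  # a marker with zero coverage is a labeled error naming it
  regions2 <- rbind(regions,
                    data.frame(name = "m2", start0 = 300L, end0 = 400L,
                               role = "marker", parent = NA_character_))
  pl2 <- rbind(tile(0L, 250L), tile(500L, 700L))
  prof2 <- normalize_coverage(compute_coverage(pl2, 1000L))
  err <- tryCatch(estimate_copy_number(prof2, regions2), error = identity)
  expect_s3_class(err, "cidscope_error_marker_zero")
  expect_match(conditionMessage(err), "m2")
})

test_that("estimator recovers planted copy number across seeds (scaled down)", {
  # spec-level invariant sketched at 20 seeds x 50x; run at 5 seeds x 30x to
  # stay inside the suite budget — the acceptance test runs the stated 50x
  for (k in c(1L, 3L, 5L)) {
    est <- vapply(1:5, function(s) {
      st <- simulate_strain(tw, k, seed = 100L + 10L * k + s)
      reads <- simulate_reads(st, 30, 100L, 0, seed = 200L + 10L * k + s)
      mp <- map_reads_exact(reads, st$reference_genome)
      prof <- normalize_coverage(compute_coverage(mp$placements,
                                                  nchar(st$reference_genome)))
      estimate_copy_number(prof, expand_exclusions(st$regions, 99L))$estimate
    }, numeric(1))
    expect_lt(abs(mean(est) - k) / k, 0.10)
  }
})

test_that("qpcr_copy_ratio implements the efficiency^deltaCq rule", {
  tab <- data.frame(sample_id = "s", locus = rep(c("cidA", "wsp"), each = 3),
                    replicate = rep(1:3, 2), cq = c(22, 22, 22, 24, 24, 24))
  expect_identical(qpcr_copy_ratio(tab, "cidA", "wsp", 2)$estimate, 4)
  tab_eq <- transform(tab, cq = 20)
  expect_identical(qpcr_copy_ratio(tab_eq, "cidA", "wsp", 2)$estimate, 1)
  expect_error(qpcr_copy_ratio(tab, "cidB", "wsp"),
               class = "cidscope_error_qpcr_locus")
})

test_that("coverage and qPCR estimates agree on the same strain", {
  st <- simulate_strain(tw, 4L, seed = 81L)
  reads <- simulate_reads(st, 30, 100L, 0, seed = 82L)
  mp <- map_reads_exact(reads, st$reference_genome)
  prof <- normalize_coverage(compute_coverage(mp$placements,
                                              nchar(st$reference_genome)))
  cov_est <- estimate_copy_number(prof, expand_exclusions(st$regions, 99L))$estimate
  q <- simulate_qpcr(st, 2, noise_sd = 0.1, seed = 83L)
  q_est <- qpcr_copy_ratio(q, "cidA", "wsp", 2)$estimate
  expect_lt(abs(cov_est - q_est) / q_est, 0.20)
  # noiseless cidA:cidB ratio is exactly one (equal copies, an operon)
  q0 <- simulate_qpcr(st, 2, noise_sd = 0, seed = 84L)
  ab <- qpcr_copy_ratio(q0, "cidA", "cidB", 2)$estimate
  expect_equal(ab, 1, tolerance = 1e-12)
})
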