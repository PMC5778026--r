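# blocks module: polymorphic columns, block grouping, four-gamete test,
# cross-group sharing, P distances.

test_that("polymorphic_columns: examples and set-cardinality oracle", {
  expect_identical(polymorphic_columns(c(a = "AAAA", b = "AAAA")), integer())
  expect_identical(polymorphic_columns(c(a = "AAAA", b = "AATA")), 2L)
  expect_error(polymorphic_columns(c(a = "AAAA", b = "AA")),
               class = "cidscope_error_alignment_ragged")
  set.seed(301)
  for (rep in 1:20) {
    n <- sample(3:6, 1); len <- sample(20:50, 1)
    aln <- setNames(vapply(seq_len(n), function(i)
      paste(sample(c("A", "C"), len, replace = TRUE), collapse = ""),
      character(1)), paste0("s", seq_len(n)))
    mat <- do.call(rbind, strsplit(aln, ""))
    want <- which(apply(mat, 2, function(col) length(unique(col)) > 1)) - 1L
    expect_identical(polymorphic_columns(aln), as.integer(want))
  }
})

test_that("detect_blocks groups columns like a brute-force partition", {
  expect_identical(detect_blocks(c(5L, 6L, 7L), max_gap = 1L),
                   data.frame(start0 = 5L, end0 = 7L))
  expect_identical(nrow(detect_blocks(c(5L, 40L), max_gap = 10L)), 2L)
  brute <- function(cols, g) {
    out <- list(); cur <- cols[1]
    s <- cols[1]
    for (x in cols[-1]) {
      if (x - cur > g + 1L) { out[[length(out) + 1L]] <- c(s, cur); s <- x }
      cur <- x
    }
    out[[length(out) + 1L]] <- c(s, cur)
    do.call(rbind, out)
  }
  set.seed(302)
  for (rep in 1:25) {
    cols <- sort(sample(0:80, sample(2:15, 1)))
    g <- sample(0:5, 1)
    got <- detect_blocks(cols, g)
    want <- brute(cols, g)
    expect_identical(cbind(got$start0, got$end0),
                     matrix(as.integer(want), ncol = 2))
  }
  # block partition covers exactly the polymorphic columns
  cols <- c(1L, 2L, 9L, 10L, 30L)
  bl <- detect_blocks(cols, 3L)
  covered <- unlist(lapply(seq_len(nrow(bl)), function(i)
    seq.int(bl$start0[i], bl$end0[i])))
  expect_true(all(cols %in% covered))
})

test_that("four_gamete detects planted recombinants and matches enumeration", {
  # variants realizing all four combinations of two binary blocks
  aln4 <- c(v1 = "AAA TTT", v2 = "AAA GGG", v3 = "CCC TTT", v4 = "CCC GGG")
  aln4 <- gsub(" ", "", aln4)
  bs4 <- block_alleles(aln4, data.frame(start0 = c(0L, 3L), end0 = c(2L, 5L)))
  expect_identical(as.character(four_gamete(bs4, 1L, 2L)),
                   "recombination_detected")
  aln2 <- gsub(" ", "", c(v1 = "AAA TTT", v2 = "CCC GGG"))
  bs2 <- block_alleles(aln2, data.frame(start0 = c(0L, 3L), end0 = c(2L, 5L)))
  expect_identical(as.character(four_gamete(bs2, 1L, 2L)), "compatible")
  expect_error(four_gamete(block_alleles(c(a = "AATT", b = "AATT"),
                                         data.frame(start0 = c(0L, 2L),
                                                    end0 = c(1L, 3L))), 1L, 2L),
               class = "cidscope_error_four_gamete")
  # exhaustive-enumeration oracle on random two-block allele matrices
  set.seed(303)
  for (rep in 1:50) {
    n <- sample(4:8, 1)
    a1 <- sample(c("x", "y", "z"), n, replace = TRUE)
    a2 <- sample(c("p", "q"), n, replace = TRUE)
    if (length(unique(a1)) < 2 || length(unique(a2)) < 2) next
    oracle <- FALSE
    for (x in unique(a1)) for (y in unique(a2))
      if (length(unique(paste(a1 == x, a2 == y))) == 4L) oracle <- TRUE
    bs <- structure(list(blocks = NULL,
                         alleles = cbind(block_1 = a1, block_2 = a2)),
                    class = "cid_blockset")
    got <- as.character(four_gamete(bs, 1L, 2L)) == "recombination_detected"
    expect_identical(got, oracle)
  }
})

test_that("four_gamete never fires on recombination-free star phylogenies", {
  # infinite sites, star topology: every variant owns private mutations, so
  # no binarized pair can show all four haplotypes
  for (s in 1:100) {
    set.seed(400 + s)
    len <- 60L
    anc <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    n <- 5L
    pos_pool <- sample(len)  # disjoint private mutation positions
    aln <- vapply(seq_len(n), function(i) {
      x <- anc
      mine <- pos_pool[seq.int((i - 1L) * 6L + 1L, i * 6L)]
      x[mine] <- vapply(x[mine], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      paste(x, collapse = "")
    }, character(1))
    names(aln) <- paste0("v", seq_len(n))
    cols <- polymorphic_columns(aln)
    # four-gamete applies to biallelic sites: one block per column (merging
    # adjacent private mutations of different variants would create
    # multi-allelic blocks whose binarization can fire spuriously)
    bs <- block_alleles(aln, data.frame(start0 = cols, end0 = cols))
    multi <- which(apply(bs$alleles, 2, function(a) length(unique(a)) > 1))
    for (i in multi) for (j in multi) {
      if (i >= j) next
      expect_identical(as.character(four_gamete(bs, i, j)), "compatible")
    }
  }
})

test_that("cross_group_sharing finds shared block alleles but no shared variants", {
  # two groups share an upstream block allele, never a full sequence
  aln <- c(g1_v1 = "AAATTT", g1_v2 = "AAAGGG", g2_v1 = "AAACCC",
           g2_v2 = "CCCTTT")
  groups <- c(g1_v1 = "I", g1_v2 = "I", g2_v1 = "IV", g2_v2 = "IV")
  bs <- block_alleles(aln, data.frame(start0 = c(0L, 3L), end0 = c(2L, 5L)))
  rep <- cross_group_sharing(bs, aln, groups)
  expect_identical(nrow(rep$shared_full_variants), 0L)
  expect_true(any(rep$shared_block_alleles$block == "block_1"))
  # fully disjoint groups share nothing
  aln2 <- c(a = "AAATTT", b = "AAAGGG", c = "CCCTTC", d = "CCCGGA")
  groups2 <- c(a = "I", b = "I", c = "IV", d = "IV")
  bs2 <- block_alleles(aln2, data.frame(start0 = c(0L, 3L), end0 = c(2L, 5L)))
  rep2 <- cross_group_sharing(bs2, aln2, groups2)
  expect_identical(nrow(rep2$shared_block_alleles), 0L)
  # equality oracle for the shared-variant detector
  aln3 <- c(a = "AAATTT", b = "AAATTT", c = "CCCGGG")
  rep3 <- cross_group_sharing(block_alleles(aln3, data.frame(start0 = 0L, end0 = 5L)),
                              aln3, c(a = "I", b = "IV", c = "IV"))
  expect_identical(nrow(rep3$shared_full_variants), 1L)
  expect_error(cross_group_sharing(bs, aln, c("I", "I", "I", "I")),
               class = "cidscope_error_groups")
})

test_that("p_distance_matrix: examples, ape oracle, metric properties", {
  expect_identical(p_distance_matrix(c(a = "AAAA", b = "AAAA"))["a", "b"], 0)
  expect_identical(p_distance_matrix(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)
  # pairwise deletion of gapped positions
  D <- p_distance_matrix(c(a = "AA-A", b = "AATT"))
  expect_identical(D["a", "b"], 1 / 3)
  expect_error(p_distance_matrix(c(a = "--", b = "--")),
               class = "cidscope_error_p_distance")
  set.seed(304)
  aln <- random_seqs(6, 120, seed = 305)
  gappy <- vapply(aln, function(s) {
    p <- sample(nchar(s), 8); v <- strsplit(s, "")[[1]]; v[p] <- "-"
    paste(v, collapse = "")
  }, character(1))
  names(gappy) <- paste0("s", 1:6)
  bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(gappy), ""), identity)))
  rownames(bin) <- names(gappy)
  want <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  got <- p_distance_matrix(gappy)
  expect_equal(got, want[rownames(got), colnames(got)], tolerance = 1e-12)
  # metric on gap-free alignments: identity, symmetry, triangle inequality
  for (rep in 1:20) {
    tri <- setNames(random_seqs(3, 40, seed = 500 + rep), c("x", "y", "z"))
    M <- p_distance_matrix(tri)
    expect_identical(M, t(M))
    expect_identical(unname(diag(M)), rep(0, 3))
    expect_lte(M["x", "z"], M["x", "y"] + M["y", "z"] + 1e-12)
  }
})

test_that("distance exports are readable", {
  D <- p_distance_matrix(setNames(random_seqs(4, 50, seed = 306),
                                  c("w", "x", "y", "z")))
  fp <- tempfile(fileext = ".phy"); fn <- tempfile(fileext = ".nex")
  write_phylip(D, fp); write_nexus_dist(D, fn)
  lines <- readLines(fp)
  expect_identical(as.integer(trimws(lines[1])), 4L)
  vals <- as.numeric(strsplit(trimws(substr(lines[2], 11, 1000)), " +")[[1]])
  expect_equal(vals, unname(D[1, ]), tolerance = 1e-6)
  expect_true(any(grepl("BEGIN DISTANCES;", readLines(fn))))
})
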