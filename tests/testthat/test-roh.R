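test_that("a clean homozygous stretch is one maximal run", {
  g <- rep(c(0L, 2L), 50)                     # 100 hom calls, no hets
  gm <- make_gm(matrix(g, ncol = 1), spacing = 12 / 99)  # spans 12 cM
  segs <- detect_roh(gm, "S1", roh_params())
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$n_markers, 100L)
  expect_equal(segs$length_cM, 12, tolerance = 1e-9)
  expect_identical(segs$n_het, 0L)
})

test_that("a heterozygote triplet terminates the run (oracle-checked)", {
  g <- c(rep(0L, 20), 1L, 1L, 1L, rep(2L, 20))
  p <- roh_params(min_length_cM = 5, min_markers = 5)
  gm <- make_gm(matrix(g, ncol = 1), spacing = 0.5)
  segs <- detect_roh(gm, "S1", p)
  expect_identical(nrow(segs), 2L)
  expect_true(all(segs$n_het == 0L))
  expect_roh_matches_oracle(gm, "S1", p)
})

test_that("detector equals the brute-force maximal-interval oracle", {
  set.seed(11)
  for (rep in 1:120) {
    n <- sample(20:120, 1)
    g <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                prob = c(0.4, 0.3, 0.25, 0.05))
    p <- roh_params(max_consecutive_het = sample(1:3, 1),
                    max_het_per_window = sample(2:4, 1),
                    min_length_cM = stats::runif(1, 0, 3),
                    min_markers = sample(c(2L, 5L, 10L), 1))
    gm <- make_gm(matrix(g, ncol = 1), spacing = stats::runif(1, 0.05, 0.4))
    expect_roh_matches_oracle(gm, "S1", p)
  }
})

test_that("runs never begin or end on a het or missing call", {
  set.seed(21)
  for (rep in 1:40) {
    g <- sample(c(0L, 1L, 2L, NA), 80, replace = TRUE, prob = c(0.4, 0.25, 0.25, 0.1))
    gm <- make_gm(matrix(g, ncol = 1), spacing = 0.3)
    segs <- detect_roh(gm, "S1", roh_params(min_length_cM = 1, min_markers = 3))
    if (nrow(segs)) {
      expect_true(all(g[segs$first_marker_index] %in% c(0L, 2L)))
      expect_true(all(g[segs$last_marker_index] %in% c(0L, 2L)))
    }
  }
})

test_that("relaxing thresholds never shrinks detected homozygosity", {
  set.seed(31)
  for (rep in 1:20) {
    g <- sample(c(0L, 1L, 2L), 150, replace = TRUE, prob = c(0.45, 0.2, 0.35))
    gm <- make_gm(matrix(g, ncol = 1), spacing = 0.2)
    p_hi <- roh_params(min_length_cM = 4, min_markers = 10)
    p_lo <- roh_params(min_length_cM = 1, min_markers = 10)
    # total detected length measured as union coverage in cM: maximal runs
    # can overlap, and relaxing a rule may merge overlapping runs
    len <- function(p) {
      segs <- detect_roh(gm, "S1", p)
      covered <- rep(FALSE, nrow(gm$map))
      for (k in seq_len(nrow(segs)))
        covered[segs$first_marker_index[k]:segs$last_marker_index[k]] <- TRUE
      sum(covered)
    }
    expect_gte(len(p_lo), len(p_hi))
    p_tight <- roh_params(max_het_per_window = 2, min_length_cM = 1, min_markers = 10)
    p_loose <- roh_params(max_het_per_window = 4, min_length_cM = 1, min_markers = 10)
    expect_gte(len(p_loose), len(p_tight))
  }
})

test_that("homozygosity profile arithmetic", {
  map <- data.frame(marker_id = paste0("m", 1:101), chrom = "1",
                    bp = 1:101 * 1000L, cM = seq(0, 100, by = 1))
  expect_identical(summarize_homozygosity(empty_seg <- rohscan:::empty_roh_df(),
                                          map)$percent_genome_in_roh, 0)
  one <- data.frame(sample_id = "S", chrom = "1", first_marker_index = 1L,
                    last_marker_index = 101L, start_bp = 1000L, end_bp = 101000L,
                    start_cM = 0, end_cM = 100, length_cM = 100,
                    n_markers = 101L, n_het = 0L)
  expect_equal(summarize_homozygosity(one, map)$percent_genome_in_roh, 100)
  two <- rbind(one, one)
  two$length_cM <- c(6, 14); two$end_cM <- two$start_cM + two$length_cM
  map4 <- transform(map, cM = seq(0, 400, length.out = 101))
  prof <- summarize_homozygosity(two, map4)
  expect_equal(prof$percent_genome_in_roh, 5)
  expect_equal(prof$mean_segment_cM, 10)
  expect_error(summarize_homozygosity(one, map[0, ]), "empty")
})

test_that("shared ROH requires coverage, allele concordance, and no unaffected ROH", {
  p <- roh_params(min_length_cM = 2, min_markers = 10)
  n <- 60
  # heterozygous flanks pin every run to the homozygous core at markers 11:40
  mk <- function(core_val) { g <- rep(1L, n); g[11:40] <- core_val; g }
  a1 <- mk(2L); a2 <- mk(2L)
  u1 <- mk(1L)                               # unaffected het in the core
  gm <- make_gm(cbind(A1 = a1, A2 = a2, U1 = u1), spacing = 0.3)
  sh <- shared_roh(gm, c("A1", "A2"), "U1", p)
  expect_identical(nrow(sh), 1L)
  expect_identical(sh$first_marker_index, 11L)
  expect_identical(sh$last_marker_index, 40L)
  expect_equal(sh$length_cM, 29 * 0.3, tolerance = 1e-9)

  # opposite homozygous alleles in the overlap: no shared haplotype
  gm2 <- make_gm(cbind(A1 = mk(2L), A2 = mk(0L), U1 = u1), spacing = 0.3)
  expect_identical(nrow(shared_roh(gm2, c("A1", "A2"), "U1", p)), 0L)

  # an unaffected sibling whose own ROH covers the interval blocks it
  gm3 <- make_gm(cbind(A1 = a1, A2 = a2, U1 = mk(0L)), spacing = 0.3)
  expect_identical(nrow(shared_roh(gm3, c("A1", "A2"), "U1", p)), 0L)

  # single affected, no unaffected: own ROHs returned unchanged
  gm4 <- make_gm(cbind(A1 = a1), spacing = 0.3)
  own <- detect_roh(gm4, "A1", p)
  sh4 <- shared_roh(gm4, "A1", character(0), p)
  expect_identical(sh4$first_marker_index, own$first_marker_index)
  expect_identical(sh4$last_marker_index, own$last_marker_index)
})

test_that("male X is excluded from ROH scanning", {
  g <- rep(0L, 120)
  chrom <- rep(c("1", "X"), each = 60)
  gm <- make_gm(matrix(g, ncol = 1, dimnames = list(NULL, "M1")),
                spacing = 0.2, chrom = chrom, sex = c(M1 = "male"))
  segs <- detect_roh(gm, "M1", roh_params(min_length_cM = 2, min_markers = 10))
  expect_true(all(segs$chrom == "1"))
})
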