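one_sample_vt <- function(df) {
  geno <- matrix("hom_alt", nrow(df), 1, dimnames = list(NULL, "pro"))
  make_vt(df, geno)
}

test_that("mapping-quality thresholds are strict", {
  vt <- one_sample_vt(data.frame(
    id = c("s26", "s25", "i11", "i10"),
    pos = c(100L, 200L, 300L, 400L),
    alt = c("T", "T", "TA", "TA"),
    variant_class = c("snp", "snp", "indel", "indel"),
    mapping_quality = c(26, 25, 11, 10)))
  kept <- quality_filter(vt)
  expect_identical(kept$variants$id, c("s26", "i11"))
  empty <- vt[integer(0)]
  expect_identical(n_variants(quality_filter(empty)), 0L)
  vt_na <- one_sample_vt(data.frame(id = "x", pos = 1L, mapping_quality = NA_real_))
  expect_warning(res <- quality_filter(vt_na), "missing mapping quality")
  expect_identical(n_variants(res), 0L)
})

test_that("catalog removal is allele-aware and idempotent", {
  vt <- one_sample_vt(data.frame(id = paste0("v", 1:10), pos = 1:10 * 10L))
  catalog <- data.frame(chrom = "1", pos = c(10L, 20L, 30L, 40L),
                        ref = "C", alt = c("T", "T", "T", "A"))
  out <- remove_known(vt, catalog)
  expect_identical(n_variants(out), 7L)           # pos 40 alt mismatch retained
  expect_true("v4" %in% out$variants$id)
  expect_identical(remove_known(out, catalog)$variants, out$variants)
  # flag-based removal when no catalog is supplied
  vt$variants$known_variant[1:3] <- TRUE
  expect_identical(n_variants(remove_known(vt)), 7L)
})

test_that("filtration order does not matter", {
  set.seed(43)
  vt <- one_sample_vt(data.frame(
    id = paste0("v", 1:50), pos = 1:50 * 10L,
    mapping_quality = runif(50, 5, 60),
    variant_class = sample(c("snp", "indel"), 50, replace = TRUE),
    known_variant = runif(50) < 0.3))
  vt$variants$alt[vt$variants$variant_class == "indel"] <- "TA"
  a <- remove_known(quality_filter(vt))
  b <- quality_filter(remove_known(vt))
  expect_identical(a$variants$id, b$variants$id)
})

test_that("consequence classification handles the canonical cases", {
  # single-exon gene, CDS 11..40, + strand; codon 1 at 11..13
  seq <- paste(rep("AAA", 20), collapse = "")
  m <- transcript_model("G", "1", "+", data.frame(start = 1, end = 60),
                        11, 40, seq, seq_start = 1)
  expect_identical(classify_consequence("1", 13, "A", "G", m), "coding_synonymous")
  expect_identical(classify_consequence("1", 12, "A", "G", m), "coding_nonsynonymous")
  expect_identical(classify_consequence("1", 15, "AA", "A", m), "frameshift")
  expect_identical(classify_consequence("1", 15, "AAAA", "A", m), "coding_nonsynonymous")
  expect_identical(classify_consequence("1", 5, "A", "G", m), "noncoding")   # 5' UTR
  expect_identical(classify_consequence("2", 13, "A", "G", m), "noncoding")  # other chrom
  # two-exon gene: donor +1/+2 are splice sites, deeper intron is noncoding
  m2 <- transcript_model("G", "1", "+",
                         data.frame(start = c(1, 41), end = c(20, 60)),
                         5, 55, paste(rep("A", 60), collapse = ""), 1)
  expect_identical(classify_consequence("1", 21, "A", "G", m2), "splice_site")
  expect_identical(classify_consequence("1", 22, "A", "G", m2), "splice_site")
  expect_identical(classify_consequence("1", 23, "A", "G", m2), "noncoding")
  expect_identical(classify_consequence("1", 39, "A", "G", m2), "splice_site")  # acceptor
})

test_that("classifier agrees with the full-CDS translation oracle", {
  set.seed(47)
  n_done <- 0
  while (n_done < 250) {
    m <- random_transcript()
    if (is.null(m)) next
    for (k in 1:4) {
      v <- random_variant_for(m)
      got <- classify_consequence("1", v$pos, v$ref, v$alt, m)
      want <- oracle_classify(v$pos, v$ref, v$alt, m)
      expect_identical(got, want)
    }
    n_done <- n_done + 1
  }
})

test_that("candidate streams select by zygosity and are disjoint", {
  geno <- rbind(hom = c(pro = "hom_alt"), het = c(pro = "het"))
  vt <- make_vt(data.frame(id = c("hom", "het"), pos = c(10L, 20L)),
                matrix(c("hom_alt", "het"), 2, 1, dimnames = list(NULL, "pro")))
  hom <- candidate_homozygous(vt, "pro")
  expect_identical(hom$variants$id, "hom")
  expect_error(candidate_homozygous(vt, "nobody"), "not in variant table")

  # planted-count fixture: 700 common benign + 30 rare deleterious, 5 hom
  n <- 730
  df <- data.frame(id = sprintf("v%03d", 1:n), pos = 1:n * 10L,
                   gene = sprintf("g%03d", 1:n),
                   consequence = c(rep("coding_synonymous", 700),
                                   rep("coding_nonsynonymous", 30)),
                   known_variant = c(rep(TRUE, 700), rep(FALSE, 30)))
  geno <- matrix(c(rep("het", 700), rep("hom_alt", 5), rep("het", 25)),
                 ncol = 1, dimnames = list(NULL, "pro"))
  vt2 <- make_vt(df, geno)
  expect_identical(n_variants(candidate_homozygous(vt2, "pro")), 5L)

  # compound-het stream: >= 2 rare deleterious hets in one gene
  df3 <- data.frame(id = paste0("v", 1:6), pos = 1:6 * 10L,
                    gene = c("gA", "gA", "gB", "gB", "gC", "gC"),
                    known_variant = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  g3 <- matrix(c("het", "het", "het", "het", "hom_alt", "het"), 6, 1,
               dimnames = list(NULL, "pro"))
  chet <- candidate_compound_het(make_vt(df3, g3), "pro")
  expect_identical(names(chet), "gA")              # gB has 1 rare het; gC hom stream
  expect_identical(n_variants(chet$gA), 2L)
  hom3 <- candidate_homozygous(make_vt(df3, g3), "pro")
  expect_false(any(hom3$variants$id %in% chet$gA$variants$id))
})

test_that("hemizygous X stream requires a male proband", {
  df <- data.frame(id = c("x1", "x2", "a1"), chrom = c("X", "X", "1"),
                   pos = c(10L, 20L, 30L),
                   consequence = c("coding_nonsynonymous", "splice_site",
                                   "coding_nonsynonymous"))
  g <- matrix(c("hemi_alt", "hemi_ref", "hom_alt"), 3, 1,
              dimnames = list(NULL, "pro"))
  vt <- make_vt(df, g)
  xs <- candidate_hemizygous_x(vt, "pro", "male")
  expect_identical(xs$variants$id, "x1")
  xs2 <- candidate_hemizygous_x(vt["x2"], "pro", "male")
  expect_identical(n_variants(xs2), 0L)
  vt_splice <- make_vt(df, matrix(c("hemi_alt", "hemi_alt", "hom_alt"), 3, 1,
                                  dimnames = list(NULL, "pro")))
  expect_true("x2" %in% candidate_hemizygous_x(vt_splice, "pro", "male")$variants$id)
  expect_warning(res <- candidate_hemizygous_x(vt, "pro", "female"), "male proband")
  expect_identical(n_variants(res), 0L)
})
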