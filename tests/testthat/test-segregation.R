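trio_ped <- function(n_aff = 2, n_un = 1) make_outbred_pedigree(n_aff, n_un)

test_that("homozygous-recessive verdicts follow the family rules", {
  ped <- trio_ped(2, 1)
  base <- c(FA = "het", MO = "het", CH1 = "hom_alt", CH2 = "hom_alt", CH3 = "het")
  expect_identical(segregate_hom_recessive(base, ped)$verdict, "segregates")
  g <- base; g["CH3"] <- "hom_alt"
  expect_identical(segregate_hom_recessive(g, ped)$verdict, "fails")
  g <- base; g["FA"] <- "hom_ref"
  expect_identical(segregate_hom_recessive(g, ped)$verdict, "mendel_error")
  g <- base; g["CH2"] <- "het"
  expect_identical(segregate_hom_recessive(g, ped)$verdict, "fails")
  g <- base; g["CH2"] <- "missing"
  expect_identical(segregate_hom_recessive(g, ped)$verdict, "segregates_incomplete")
  g <- base; g["MO"] <- "hom_alt"
  expect_identical(segregate_hom_recessive(g, ped)$verdict, "fails")
})

test_that("monozygotic twins count as one informative genotype", {
  ped <- trio_ped(2, 1)
  g <- c(FA = "het", MO = "het", CH1 = "hom_alt", CH2 = "missing", CH3 = "het")
  expect_identical(segregate_hom_recessive(g, ped)$verdict, "segregates_incomplete")
  expect_identical(
    segregate_hom_recessive(g, ped, mz_twins = list(c("CH1", "CH2")))$verdict,
    "segregates")
})

chet_vt <- function(geno) {
  make_vt(data.frame(id = c("vA", "vB"), pos = c(10L, 20L), gene = "G1"), geno)
}

test_that("compound-het phasing distinguishes trans, cis and unphaseable", {
  ped <- trio_ped(1, 1)
  trans <- chet_vt(rbind(vA = c(FA = "het", MO = "hom_ref", CH1 = "het", CH2 = "hom_ref"),
                         vB = c(FA = "hom_ref", MO = "het", CH1 = "het", CH2 = "het")))
  v <- phase_compound_het(trans, ped)
  expect_identical(v$verdict, "segregates")
  expect_setequal(v$variants, c("vA", "vB"))

  cis <- chet_vt(rbind(vA = c(FA = "het", MO = "hom_ref", CH1 = "het", CH2 = "hom_ref"),
                       vB = c(FA = "het", MO = "hom_ref", CH1 = "het", CH2 = "hom_ref")))
  expect_identical(phase_compound_het(cis, ped)$verdict, "fails")

  both_carry <- chet_vt(rbind(vA = c(FA = "het", MO = "het", CH1 = "het", CH2 = "hom_ref"),
                              vB = c(FA = "hom_ref", MO = "het", CH1 = "het", CH2 = "hom_ref")))
  expect_identical(phase_compound_het(both_carry, ped)$verdict, "unphaseable")

  unaff_both <- chet_vt(rbind(vA = c(FA = "het", MO = "hom_ref", CH1 = "het", CH2 = "het"),
                              vB = c(FA = "hom_ref", MO = "het", CH1 = "het", CH2 = "het")))
  expect_identical(phase_compound_het(unaff_both, ped)$verdict, "fails")

  # affected sibling must share the trans pair
  ped2 <- trio_ped(2, 0)
  sib_missing_pair <- chet_vt(rbind(
    vA = c(FA = "het", MO = "hom_ref", CH1 = "het", CH2 = "hom_ref"),
    vB = c(FA = "hom_ref", MO = "het", CH1 = "het", CH2 = "het")))
  expect_identical(phase_compound_het(sib_missing_pair, ped2)$verdict, "fails")
})

test_that("X-linked verdicts follow maternal inheritance rules", {
  ped <- make_outbred_pedigree(1, 1, child_sex = c("male", "male"))
  base <- c(FA = "hemi_ref", MO = "het", CH1 = "hemi_alt", CH2 = "hemi_ref")
  expect_identical(segregate_x_linked(base, ped)$verdict, "segregates")
  g <- base; g["CH2"] <- "hemi_alt"
  expect_identical(segregate_x_linked(g, ped)$verdict, "fails")
  g <- base; g["MO"] <- "hom_ref"
  expect_identical(segregate_x_linked(g, ped)$verdict, "mendel_error")
  g <- base; g["FA"] <- "hemi_alt"
  expect_identical(segregate_x_linked(g, ped)$verdict, "fails")
  g <- base; g["MO"] <- "missing"
  expect_identical(segregate_x_linked(g, ped)$verdict, "segregates_incomplete")
})

test_that("implanted causal variants always segregate, with no Mendel errors", {
  for (i in 1:4) {
    cfg <- sim_config("first_cousin", causal = list(model = "hom_recessive"),
                      map_length_cM = 1500, marker_spacing_cM = 0.2,
                      n_background = 0, genotype_error_rate = 0,
                      missing_rate = 0, seed = 600 + i)
    fam <- simulate_family(cfg)
    v <- segregate_hom_recessive(vt_geno(fam$variants, "causal_1"), fam$pedigree)
    expect_identical(v$verdict, "segregates")
  }
  for (i in 1:3) {
    cfg <- sim_config("outbred", causal = list(model = "compound_het"),
                      map_length_cM = 1000, marker_spacing_cM = 0.2,
                      n_background = 0, genotype_error_rate = 0,
                      missing_rate = 0, seed = 620 + i)
    fam <- simulate_family(cfg)
    gene_vt <- fam$variants[c("causal_1", "causal_2")]
    expect_identical(phase_compound_het(gene_vt, fam$pedigree)$verdict, "segregates")
  }
  for (i in 1:3) {
    cfg <- sim_config("outbred", causal = list(model = "x_linked"),
                      map_length_cM = 1000, marker_spacing_cM = 0.2,
                      n_background = 0, genotype_error_rate = 0,
                      missing_rate = 0, seed = 640 + i)
    fam <- simulate_family(cfg)
    v <- segregate_x_linked(vt_geno(fam$variants, "causal_1"), fam$pedigree)
    expect_identical(v$verdict, "segregates")
  }
})

test_that("adding an unaffected sibling can only keep or demote a verdict", {
  rank <- c(mendel_error = 0, fails = 0, unphaseable = 0,
            segregates_incomplete = 1, segregates = 2)
  set.seed(53)
  for (rep in 1:40) {
    ped3 <- trio_ped(2, 0)
    ped4 <- trio_ped(2, 1)   # same family plus unaffected CH3
    base <- c(FA = "het", MO = "het",
              CH1 = sample(c("hom_alt", "het", "missing"), 1),
              CH2 = sample(c("hom_alt", "het", "missing"), 1))
    v3 <- segregate_hom_recessive(base, ped3)$verdict
    # unaffected sib drawn from het x het parents
    sib <- sample(c("hom_ref", "het", "hom_alt"), 1, prob = c(0.25, 0.5, 0.25))
    v4 <- segregate_hom_recessive(c(base, CH3 = sib), ped4)$verdict
    expect_lte(rank[[v4]], rank[[v3]])
  }
})
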