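test_that("meiosis follows the Haldane model", {
  set.seed(61)
  # a zero-length map transmits one whole parental haplotype
  map0 <- data.frame(marker_id = paste0("m", 1:5), chrom = "1",
                     bp = 1:5 * 1000L, cM = rep(0, 5))
  hap <- cbind(rep(0L, 5), rep(1L, 5))
  g0 <- meiosis(hap, map0)
  expect_true(all(g0$source == g0$source[1]))
  expect_true(all(g0$alleles %in% hap[cbind(1:5, g0$source)]))

  # 100 cM chromosome: mean crossover count ~ Poisson(1)
  map1 <- data.frame(marker_id = paste0("m", 1:101), chrom = "1",
                     bp = 1:101 * 1000L, cM = seq(0, 100, 1))
  ncross <- replicate(4000, {
    src <- meiosis(matrix(0L, 101, 2), map1)$source
    sum(diff(src) != 0)
  })
  se <- sqrt(1 / 4000)
  expect_lt(abs(mean(ncross) - 1), 3 * se + 0.05)

  # gamete alleles always come from the parent's two alleles
  hap2 <- cbind(sample(0:1, 101, TRUE), sample(0:1, 101, TRUE))
  g <- meiosis(hap2, map1)
  expect_true(all(g$alleles == hap2[cbind(1:101, g$source)]))
})

test_that("simulation is reproducible from its seed", {
  cfg <- sim_config("first_cousin", map_length_cM = 300, marker_spacing_cM = 0.2,
                    n_background = 50, causal = list(model = "hom_recessive"),
                    seed = 67)
  f1 <- simulate_family(cfg); f2 <- simulate_family(cfg)
  expect_identical(f1$genotypes$calls, f2$genotypes$calls)
  expect_identical(f1$variants$variants, f2$variants$variants)
  expect_identical(f1$variants$geno, f2$variants$geno)
  expect_identical(f1$truth$autozygous_fraction, f2$truth$autozygous_fraction)
})

test_that("outbred offspring have zero true autozygosity", {
  cfg <- sim_config("outbred", map_length_cM = 500, marker_spacing_cM = 0.2,
                    n_background = 0, seed = 71)
  fam <- simulate_family(cfg)
  expect_identical(unname(fam$truth$autozygous_fraction["CH1"]), 0)
})

test_that("true autozygosity means match pedigree inbreeding coefficients", {
  set.seed(73)
  frac <- function(topology, n) {
    replicate(n, {
      cfg <- sim_config(topology, n_affected = 1, n_unaffected = 0,
                        map_length_cM = 3500, marker_spacing_cM = 0.5,
                        n_background = 0, seed = sample.int(1e6, 1))
      100 * simulate_family(cfg)$truth$autozygous_fraction[["CH1"]]
    })
  }
  fc <- frac("first_cousin", 40)
  z1 <- abs(mean(fc) - 6.25) / (sd(fc) / sqrt(length(fc)))
  expect_lt(z1, 4)
  sc <- frac("second_cousin", 40)
  z2 <- abs(mean(sc) - 1.5625) / (sd(sc) / sqrt(length(sc)))
  expect_lt(z2, 4)
})

test_that("Mendelian consistency of error-free genotypes", {
  cfg <- sim_config("first_cousin", map_length_cM = 800, marker_spacing_cM = 0.2,
                    n_background = 0, genotype_error_rate = 0, missing_rate = 0,
                    seed = 79)
  fam <- simulate_family(cfg)
  calls <- fam$genotypes$calls
  ped <- fam$pedigree
  for (i in seq_len(nrow(ped))) {
    fa <- ped$father[i]
    if (is.na(fa)) next
    # child hom cannot face an opposite-hom parent
    expect_identical(sum(calls[, ped$id[i]] == 2L & calls[, fa] == 0L), 0L)
    expect_identical(sum(calls[, ped$id[i]] == 0L & calls[, fa] == 2L), 0L)
  }
})

test_that("detector recovers >= 95% of long true autozygous segment length", {
  lens_total <- lens_cov <- 0
  for (i in 1:4) {
    cfg <- sim_config("first_cousin", n_affected = 1, n_unaffected = 0,
                      n_background = 0, seed = 820 + i)
    fam <- simulate_family(cfg)
    segs <- detect_roh(fam$genotypes, "CH1")
    truth <- fam$truth$segments$CH1
    truth <- truth[truth$length_cM > 5, , drop = FALSE]
    covered <- rep(FALSE, nrow(fam$genotypes$map))
    for (k in seq_len(nrow(segs)))
      covered[segs$first_marker_index[k]:segs$last_marker_index[k]] <- TRUE
    for (k in seq_len(nrow(truth))) {
      idx <- truth$first_marker_index[k]:truth$last_marker_index[k]
      lens_total <- lens_total + length(idx)
      lens_cov <- lens_cov + sum(covered[idx])
    }
  }
  expect_gt(lens_cov / lens_total, 0.95)
})

test_that("outbred genomes with dense polymorphic markers stay below 1.6% detected", {
  pct <- numeric(3)
  for (i in 1:3) {
    cfg <- sim_config("outbred", n_affected = 1, n_unaffected = 0,
                      map_length_cM = 1500, marker_spacing_cM = 0.02,
                      n_background = 0, seed = 840 + i)
    fam <- simulate_family(cfg)
    pct[i] <- summarize_homozygosity(detect_roh(fam$genotypes, "CH1"),
                                     fam$genotypes$map)$percent_genome_in_roh
  }
  expect_lte(mean(pct), 1.6)
})

test_that("implant machinery places model-consistent causal genotypes", {
  cfg <- sim_config("first_cousin", causal = list(model = "hom_recessive",
                                                  gene = "MYGENE"),
                    map_length_cM = 1500, marker_spacing_cM = 0.2,
                    n_background = 0, genotype_error_rate = 0, missing_rate = 0,
                    seed = 87)
  fam <- simulate_family(cfg)
  g <- vt_geno(fam$variants, "causal_1")
  roles <- rohscan:::family_roles(fam$pedigree)
  expect_true(all(g[roles$affected] == "hom_alt"))
  expect_identical(unname(g[roles$father]), "het")
  expect_identical(unname(g[roles$mother]), "het")
  expect_false(any(g[roles$unaffected] == "hom_alt"))
  expect_identical(fam$variants$variants$gene[
    match("causal_1", fam$variants$variants$id)], "MYGENE")

  # X-linked: affected males hemizygous alt from a heterozygous mother
  cfgx <- sim_config("outbred", causal = list(model = "x_linked"),
                     map_length_cM = 800, marker_spacing_cM = 0.2,
                     n_background = 0, genotype_error_rate = 0, missing_rate = 0,
                     seed = 89)
  famx <- simulate_family(cfgx)
  gx <- vt_geno(famx$variants, "causal_1")
  rx <- rohscan:::family_roles(famx$pedigree)
  expect_true(all(gx[rx$affected] == "hemi_alt"))
  expect_identical(unname(gx[rx$mother]), "het")
  expect_identical(unname(gx[rx$father]), "hemi_ref")
})

test_that("incompatible causal configuration is rejected", {
  expect_error(sim_config("outbred",
                          causal = list(model = "hom_recessive",
                                        placement = "in_autozygous_segment")),
               "cousin loop")
})
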