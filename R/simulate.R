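# Pedigree/genotype simulator: founder haplotypes from a MAF spectrum,
# Haldane meiosis on a genetic map, descent through consanguinity loops,
# implanted causal variants, and IBD-traced ground truth.

# Approximate relative genetic lengths of the 22 human autosomes, scaled to
# the configured total map length.
.autosome_rel_cM <- c(2.84, 2.68, 2.23, 2.12, 2.04, 1.92, 1.87, 1.70, 1.68,
                      1.81, 1.58, 1.75, 1.26, 1.19, 1.41, 1.34, 1.29, 1.20,
                      1.08, 1.08, 0.62, 0.74)

#' Synthetic genetic map
#'
#' Lays markers at regular cM spacing over 22 autosomes whose relative
#' genetic lengths approximate the human map, scaled to `map_length_cM`
#' in total.  Physical positions are synthesized at 1 Mb per cM.  An X
#' chromosome of `x_length_cM` is appended only on request (X-linked
#' simulations).
#'
#' @param map_length_cM Total autosomal genetic length (default 3500).
#' @param marker_spacing_cM Marker spacing (default 0.1).
#' @param include_x Append an X chromosome?
#' @param x_length_cM Genetic length of the X when included.
#' @return A map data frame (`marker_id`, `chrom`, `bp`, `cM`).
#' @export
sim_map <- function(map_length_cM = 3500, marker_spacing_cM = 0.1,
                    include_x = FALSE, x_length_cM = 180) {
  stopifnot(map_length_cM > 0, marker_spacing_cM > 0)
  lens <- .autosome_rel_cM / sum(.autosome_rel_cM) * map_length_cM
  chroms <- as.character(seq_along(lens))
  if (include_x) { lens <- c(lens, x_length_cM); chroms <- c(chroms, "X") }
  pieces <- lapply(seq_along(lens), function(i) {
    cM <- seq(0, lens[i], by = marker_spacing_cM)
    data.frame(marker_id = sprintf("chr%s_%05d", chroms[i], seq_along(cM)),
               chrom = chroms[i], bp = as.integer(round(cM * 1e6)) + 1L, cM = cM,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Simulation configuration
#'
#' Defines the family topology, map, founder allele-frequency spectrum,
#' causal-variant specification and noise model of one simulated family.
#'
#' @param topology `"first_cousin"`, `"second_cousin"`, `"outbred"` or
#'   `"custom"` (supply `custom_pedigree`).
#' @param n_affected,n_unaffected Children in the sibship.
#' @param map_length_cM,marker_spacing_cM Map geometry (see [sim_map()]).
#' @param founder_maf Range of the uniform alt-allele-frequency spectrum
#'   for founder haplotypes (default U(0.05, 0.5)).
#' @param causal `NULL`, or a list with `gene` (label), `model`
#'   (`"hom_recessive"`, `"compound_het"` or `"x_linked"`) and `placement`
#'   (`"in_autozygous_segment"` or `"random"`).
#' @param n_background Number of background exome variants (default 700).
#' @param genotype_error_rate,missing_rate Per-call corruption rates applied
#'   to the SNP-array genotype matrix (defaults 0.002 and 0.005).
#' @param seed Integer seed; the family is fully reproducible from it.
#' @param custom_pedigree A [pedigree()] for `topology = "custom"`.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(topology = c("first_cousin", "second_cousin", "outbred", "custom"),
                       n_affected = 2, n_unaffected = 1,
                       map_length_cM = 3500, marker_spacing_cM = 0.1,
                       founder_maf = c(0.05, 0.5),
                       causal = NULL, n_background = 700,
                       genotype_error_rate = 0.002, missing_rate = 0.005,
                       seed = NULL, custom_pedigree = NULL) {
  topology <- match.arg(topology)
  stopifnot(marker_spacing_cM > 0, length(founder_maf) == 2,
            genotype_error_rate >= 0, genotype_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (!is.null(causal)) {
    stopifnot(is.list(causal))
    causal$model <- match.arg(causal$model, c("hom_recessive", "compound_het", "x_linked"))
    if (is.null(causal$gene)) causal$gene <- "CAUSAL_GENE"
    if (is.null(causal$placement))
      causal$placement <- if (causal$model == "hom_recessive") "in_autozygous_segment" else "random"
    if (causal$model == "hom_recessive" && causal$placement == "in_autozygous_segment" &&
        topology == "outbred")
      stop("hom_recessive causal placement in an autozygous segment requires a cousin loop")
  }
  if (topology == "custom" && is.null(custom_pedigree))
    stop("topology = 'custom' requires custom_pedigree")
  structure(list(topology = topology, n_affected = n_affected,
                 n_unaffected = n_unaffected, map_length_cM = map_length_cM,
                 marker_spacing_cM = marker_spacing_cM, founder_maf = founder_maf,
                 causal = causal, n_background = n_background,
                 genotype_error_rate = genotype_error_rate,
                 missing_rate = missing_rate, seed = seed,
                 custom_pedigree = custom_pedigree),
            class = "sim_config")
}

#' Simulate one meiosis on a genetic map
#'
#' Haldane (no-interference) model: the number of crossovers per chromosome
#' is Poisson with mean length_cM / 100, crossover positions are uniform in
#' cM, and the gamete switches source haplotype at each crossover (random
#' starting haplotype).
#'
#' @param haplotypes A markers x 2 matrix (one column per parental haplotype).
#' @param map Genetic map for the markers (rows aligned with `haplotypes`).
#' @return List with `alleles` (the gamete) and `source` (1 or 2 per marker).
#' @export
meiosis <- function(haplotypes, map) {
  haplotypes <- as.matrix(haplotypes)
  stopifnot(nrow(haplotypes) == nrow(map), ncol(haplotypes) == 2)
  src <- integer(nrow(map))
  for (ch in unique(map$chrom)) {
    i <- which(map$chrom == ch)
    src[i] <- meiosis_source(map$cM[i])
  }
  list(alleles = haplotypes[cbind(seq_len(nrow(map)), src)], source = src)
}

# crossover source vector for one chromosome
meiosis_source <- function(cM) {
  L <- max(cM) - min(cM)
  k <- rpois(1, L / 100)
  start <- sample.int(2, 1)
  if (k == 0 || L == 0) return(rep(start, length(cM)))
  cuts <- sort(runif(k, min(cM), max(cM)))
  (findInterval(cM, cuts, left.open = TRUE) + start - 1L) %% 2L + 1L
}

# --- descent machinery ----------------------------------------------------

# One individual's genome: alleles (n x 2, 0/1) and origin labels (n x 2,
# integers identifying founder haplotypes).  Male X rows: paternal column NA.
new_founder <- function(p_alt, labels, map, male, include_x) {
  n <- length(p_alt)
  al <- cbind(rbinom(n, 1, p_alt), rbinom(n, 1, p_alt))
  or <- cbind(rep(labels[1], n), rep(labels[2], n))
  if (include_x && male) {
    xr <- map$chrom == "X"
    al[xr, 1] <- NA_integer_; or[xr, 1] <- NA_integer_
  }
  list(al = al, or = or)
}

# gamete from `parent`; X rows handled by parent/child sex
parent_gamete <- function(parent, map, parent_male, child_male, include_x) {
  n <- nrow(map)
  src <- integer(n)
  for (ch in unique(map$chrom)) {
    i <- which(map$chrom == ch)
    if (include_x && ch == "X" && parent_male) next  # filled below
    src[i] <- meiosis_source(map$cM[i])
  }
  idx <- cbind(seq_len(n), src)
  al <- parent$al[idx]; or <- parent$or[idx]
  if (include_x && parent_male) {
    xr <- which(map$chrom == "X")
    if (child_male) { al[xr] <- NA_integer_; or[xr] <- NA_integer_ }
    else { al[xr] <- parent$al[xr, 2]; or[xr] <- parent$or[xr, 2] }
  }
  list(al = al, or = or)
}

simulate_descent <- function(ped, map, p_alt, include_x) {
  depth <- ped_depth(ped)
  founders <- pedigree_founders(ped)
  if (include_x && any(is.na(ped$sex)))
    stop("X-linked simulation requires known sexes for all pedigree members")
  genomes <- list()
  lab <- 0L
  for (id in founders) {
    genomes[[id]] <- new_founder(p_alt, c(lab + 1L, lab + 2L), map,
                                 identical(ped$sex[match(id, ped$id)], "male"),
                                 include_x)
    lab <- lab + 2L
  }
  for (id in ped$id[order(depth)]) {
    if (id %in% founders) next
    i <- match(id, ped$id)
    male <- identical(ped$sex[i], "male")
    gf <- parent_gamete(genomes[[ped$father[i]]], map, TRUE, male, include_x)
    gm <- parent_gamete(genomes[[ped$mother[i]]], map, FALSE, male, include_x)
    genomes[[id]] <- list(al = cbind(gf$al, gm$al), or = cbind(gf$or, gm$or))
  }
  genomes
}

# IBD-traced autozygous segments of one individual (autosomes).
truth_segments_one <- function(genome, map) {
  auto_lab <- !is.na(genome$or[, 1]) & !is.na(genome$or[, 2]) &
    genome$or[, 1] == genome$or[, 2]
  out <- list()
  for (ch in unique(map$chrom)) {
    if (ch == "X") next
    rows <- which(map$chrom == ch)
    r <- rle(auto_lab[rows])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      f <- rows[starts[k]]; l <- rows[ends[k]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, first_marker_index = f, last_marker_index = l,
        start_cM = map$cM[f], end_cM = map$cM[l],
        length_cM = map$cM[l] - map$cM[f], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), first_marker_index = integer(0),
                      last_marker_index = integer(0), start_cM = numeric(0),
                      end_cM = numeric(0), length_cM = numeric(0)))
  do.call(rbind, out)
}

# marker-level indicator: inside an autozygous run longer than min_cM
in_long_autozygous_run <- function(genome, map, min_cM) {
  ind <- rep(FALSE, nrow(map))
  segs <- truth_segments_one(genome, map)
  segs <- segs[segs$length_cM > min_cM, , drop = FALSE]
  for (k in seq_len(nrow(segs)))
    ind[segs$first_marker_index[k]:segs$last_marker_index[k]] <- TRUE
  ind
}

# --- implant-site search --------------------------------------------------

find_hom_site <- function(genomes, roles, map, min_seg_cM = 5.5) {
  auto <- map$chrom != "X"
  g1 <- genomes[[roles$affected[1]]]
  h <- g1$or[, 1]
  ok <- auto
  for (a in roles$affected) {
    g <- genomes[[a]]
    ok <- ok & !is.na(g$or[, 1]) & !is.na(g$or[, 2]) &
      g$or[, 1] == g$or[, 2] & g$or[, 1] == h &
      in_long_autozygous_run(g, map, min_seg_cM)
  }
  for (u in roles$unaffected) {
    g <- genomes[[u]]
    ok <- ok & !(!is.na(g$or[, 1]) & !is.na(g$or[, 2]) &
                   g$or[, 1] == g$or[, 2] & g$or[, 1] == h)
  }
  cand <- which(ok)
  if (!length(cand)) return(NULL)
  m <- if (length(cand) == 1) cand else sample(cand, 1)
  list(marker = m, label = h[m])
}

find_chet_site <- function(genomes, roles, map) {
  auto <- which(map$chrom != "X")
  g1 <- genomes[[roles$affected[1]]]
  f0 <- g1$or[, 1]; m0 <- g1$or[, 2]
  ok <- rep(FALSE, nrow(map)); ok[auto] <- TRUE
  ok <- ok & !is.na(f0) & !is.na(m0) & f0 != m0
  for (a in roles$affected) {
    g <- genomes[[a]]
    ok <- ok & g$or[, 1] == f0 & g$or[, 2] == m0
  }
  fa <- genomes[[roles$father]]; mo <- genomes[[roles$mother]]
  carries <- function(g, lab) (!is.na(g$or[, 1]) & g$or[, 1] == lab) |
    (!is.na(g$or[, 2]) & g$or[, 2] == lab)
  ok <- ok & !(fa$or[, 1] == f0 & fa$or[, 2] == f0)   # father het for varA
  ok <- ok & !(mo$or[, 1] == m0 & mo$or[, 2] == m0)   # mother het for varB
  ok <- ok & !carries(fa, m0) & !carries(mo, f0)      # unambiguous phase
  for (u in roles$unaffected) {
    g <- genomes[[u]]
    ok <- ok & !(carries(g, f0) & carries(g, m0))
  }
  ok[is.na(ok)] <- FALSE
  cand <- which(ok)
  if (!length(cand)) return(NULL)
  m <- if (length(cand) == 1) cand else sample(cand, 1)
  list(marker = m, f_label = f0[m], m_label = m0[m])
}

find_x_site <- function(genomes, roles, map) {
  xr <- which(map$chrom == "X")
  if (!length(xr)) return(NULL)
  aff_m <- roles$affected[roles$sex[roles$affected] == "male"]
  if (!length(aff_m)) return(NULL)
  h <- genomes[[aff_m[1]]]$or[, 2]
  ok <- rep(FALSE, nrow(map)); ok[xr] <- TRUE
  for (a in aff_m) ok <- ok & genomes[[a]]$or[, 2] == h
  mo <- genomes[[roles$mother]]
  ok <- ok & !(mo$or[, 1] == h & mo$or[, 2] == h)          # mother heterozygous
  ok <- ok & (mo$or[, 1] == h | mo$or[, 2] == h)
  fa <- genomes[[roles$father]]
  ok <- ok & !(!is.na(fa$or[, 2]) & fa$or[, 2] == h)       # father hemi_ref
  for (u in roles$unaffected) {
    g <- genomes[[u]]
    if (roles$sex[u] == "male") ok <- ok & g$or[, 2] != h
    else ok <- ok & !(g$or[, 1] == h & g$or[, 2] == h)
  }
  ok[is.na(ok)] <- FALSE
  cand <- which(ok)
  if (!length(cand)) return(NULL)
  m <- if (length(cand) == 1) cand else sample(cand, 1)
  list(marker = m, label = h[m])
}

# --- variant-table synthesis ----------------------------------------------

# genotype strings for one variant from founder-haplotype carrier status
variant_genotypes <- function(carriers, marker, genomes, ids) {
  vapply(ids, function(s) {
    o <- genomes[[s]]$or[marker, ]
    if (is.na(o[1])) {            # male X: single maternal origin
      if (is.na(o[2])) return("missing")
      if (carriers[o[2]]) "hemi_alt" else "hemi_ref"
    } else {
      dose <- carriers[o[1]] + carriers[o[2]]
      c("hom_ref", "het", "hom_alt")[dose + 1]
    }
  }, character(1))
}

.bg_consequences <- c("coding_nonsynonymous", "coding_synonymous",
                      "splice_site", "frameshift")
.bg_consequence_mix <- c(0.60, 0.30, 0.05, 0.05)

build_variant_table <- function(genomes, ped, map, config, site) {
  ids <- ped$id
  n_founder_haps <- 2L * length(pedigree_founders(ped))
  n_bg <- config$n_background
  rows <- list(); genos <- list()
  used_markers <- if (!is.null(site)) site$marker else integer(0)
  if (n_bg > 0) {
    pool <- setdiff(seq_len(nrow(map)), used_markers)
    mk <- sample(pool, min(n_bg, length(pool)))
    common <- runif(n_bg) < 0.95
    cons <- sample(.bg_consequences, n_bg, replace = TRUE, prob = .bg_consequence_mix)
    vclass <- ifelse(cons == "frameshift", "indel",
                     ifelse(runif(n_bg) < 0.95, "snp", "indel"))
    mq <- round(runif(n_bg, 15, 60), 1)
    for (j in seq_len(n_bg)) {
      m <- mk[j]
      p <- if (common[j]) runif(1, 0.05, 0.5) else runif(1, 0.005, 0.05)
      carriers <- runif(n_founder_haps) < p
      ref <- sample(c("A", "C", "G", "T"), 1)
      alt <- if (vclass[j] == "indel") paste0(ref, "T") else
        sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      ctrl_total <- 1400L
      ctrl_alt <- rbinom(1, ctrl_total, p)
      ctrl_hom <- rbinom(1, ctrl_total %/% 2L, p^2)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("var_%04d", j), chrom = map$chrom[m], pos = map$bp[m],
        ref = ref, alt = alt,
        gene = sprintf("G%s_%d", map$chrom[m], map$bp[m] %/% 2000000L),
        consequence = cons[j], variant_class = vclass[j],
        mapping_quality = mq[j], known_variant = common[j],
        brain_expressed = sample(c(TRUE, FALSE, NA), 1, prob = c(0.8, 0.1, 0.1)),
        known_disorder_gene = sample(c(TRUE, FALSE), 1, prob = c(0.05, 0.95)),
        noncanonical_splice = FALSE,
        control_alt = ctrl_alt, control_total = ctrl_total, control_hom = ctrl_hom,
        stringsAsFactors = FALSE)
      genos[[length(genos) + 1L]] <- variant_genotypes(carriers, m, genomes, ids)
    }
  }
  causal_ids <- character(0)
  if (!is.null(site)) {
    model <- config$causal$model
    m <- site$marker
    add_causal <- function(vid, pos_off, label) {
      carriers <- rep(FALSE, n_founder_haps); carriers[label] <- TRUE
      rows[[length(rows) + 1L]] <<- data.frame(
        id = vid, chrom = map$chrom[m], pos = map$bp[m] + pos_off,
        ref = "C", alt = "T", gene = config$causal$gene,
        consequence = "coding_nonsynonymous", variant_class = "snp",
        mapping_quality = 60, known_variant = FALSE,
        brain_expressed = TRUE, known_disorder_gene = FALSE,
        noncanonical_splice = FALSE,
        control_alt = 1L, control_total = 1400L, control_hom = 0L,
        stringsAsFactors = FALSE)
      genos[[length(genos) + 1L]] <<- variant_genotypes(carriers, m, genomes, ids)
      causal_ids <<- c(causal_ids, vid)
    }
    if (model == "hom_recessive" || model == "x_linked") {
      add_causal("causal_1", 0L, site$label)
    } else {
      add_causal("causal_1", 0L, site$f_label)
      add_causal("causal_2", 1L, site$m_label)
    }
  }
  if (!length(rows)) return(NULL)
  variants <- do.call(rbind, rows)
  geno <- do.call(rbind, genos)
  colnames(geno) <- ids
  ord <- order(match(variants$chrom, unique(map$chrom)), variants$pos)
  vt <- variant_table(variants[ord, , drop = FALSE], geno[ord, , drop = FALSE])
  attr(vt, "causal_ids") <- causal_ids
  vt
}

# --- top level ------------------------------------------------------------

#' Simulate a family: pedigree, SNP genotypes, variants and ground truth
#'
#' Draws founder haplotypes i.i.d. per marker from the configured allele
#' frequency spectrum, transmits them through the pedigree with Haldane
#' recombination, then emits (i) a SNP-array-style genotype matrix with
#' genotyping error and missingness applied, (ii) an exome-style variant
#' table with background variation and, if configured, implanted causal
#' variants whose genotypes follow descent exactly, and (iii) ground truth:
#' IBD-traced autozygous segments and the causal variant ids.  When a
#' causal implant site cannot be found (e.g. no sufficiently long shared
#' autozygous segment), descent is resimulated, up to 100 attempts.
#'
#' @param config A [sim_config()].
#' @return List of class `"simulated_family"` with elements `pedigree`,
#'   `genotypes` ([genotype_matrix()]), `variants` ([variant_table()] or
#'   `NULL`), and `truth` (causal ids/gene, per-individual autozygous
#'   segments and autozygous genome fraction).
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  model <- if (is.null(config$causal)) NULL else config$causal$model
  include_x <- identical(model, "x_linked")
  child_sex <- if (include_x)
    rep("male", config$n_affected + config$n_unaffected) else NULL
  ped <- switch(config$topology,
    first_cousin  = make_cousin_pedigree(1, config$n_affected, config$n_unaffected,
                                         child_sex = child_sex),
    second_cousin = make_cousin_pedigree(2, config$n_affected, config$n_unaffected,
                                         child_sex = child_sex),
    outbred       = make_outbred_pedigree(config$n_affected, config$n_unaffected,
                                          child_sex = child_sex),
    custom        = config$custom_pedigree)
  if (config$topology != "outbred" && length(pedigree_founders(ped)) < 4 &&
      !is.null(model) && model == "hom_recessive")
    stop("cousin-loop topology needs at least 4 founders")
  map <- sim_map(config$map_length_cM, config$marker_spacing_cM, include_x)
  roles <- family_roles(ped)
  p_alt <- runif(nrow(map), config$founder_maf[1], config$founder_maf[2])

  site <- NULL
  for (attempt in seq_len(100)) {
    genomes <- simulate_descent(ped, map, p_alt, include_x)
    if (is.null(model)) break
    site <- switch(model,
                   hom_recessive = find_hom_site(genomes, roles, map),
                   compound_het  = find_chet_site(genomes, roles, map),
                   x_linked      = find_x_site(genomes, roles, map))
    if (!is.null(site)) break
    if (attempt == 100)
      stop("no implant site found after 100 attempts; ",
           "consider a different topology or a longer map")
  }

  # SNP-array genotype matrix (calls corrupted by error/missingness)
  ids <- ped$id
  calls <- vapply(ids, function(s) {
    g <- genomes[[s]]
    cl <- g$al[, 1] + g$al[, 2]
    if (include_x) {
      xr <- which(map$chrom == "X")
      if (identical(ped$sex[match(s, ped$id)], "male"))
        cl[xr] <- 2L * g$al[xr, 2]
    }
    as.integer(cl)
  }, integer(nrow(map)))
  calls <- corrupt_calls(calls, map, ped, config)
  sex <- setNames(ped$sex, ped$id)
  gm <- genotype_matrix(calls, map, sample_ids = ids, sex = sex)

  vt <- if (config$n_background > 0 || !is.null(site))
    build_variant_table(genomes, ped, map, config, site) else NULL

  segs <- lapply(setNames(ids, ids), function(s) truth_segments_one(genomes[[s]], map))
  auto <- map[map$chrom != "X", , drop = FALSE]
  total_cM <- sum(tapply(auto$cM, auto$chrom, function(x) max(x) - min(x)))
  frac <- vapply(segs, function(s) sum(s$length_cM) / total_cM, numeric(1))

  structure(list(pedigree = ped, genotypes = gm, variants = vt,
                 truth = list(causal_ids = if (is.null(vt)) character(0)
                                           else attr(vt, "causal_ids"),
                              causal_gene = if (is.null(config$causal)) NA_character_
                                            else config$causal$gene,
                              segments = segs, autozygous_fraction = frac,
                              founder_freqs = p_alt, site = site),
                 config = config),
            class = "simulated_family")
}

corrupt_calls <- function(calls, map, ped, config) {
  e <- config$genotype_error_rate; miss <- config$missing_rate
  males <- ped$id[!is.na(ped$sex) & ped$sex == "male"]
  xr <- map$chrom == "X"
  if (e > 0) {
    for (s in colnames(calls)) {
      male_x <- xr & s %in% males
      idx <- which(!is.na(calls[, s]) & runif(nrow(calls)) < e)
      if (!length(idx)) next
      hemi <- idx[male_x[idx]]
      dip <- setdiff(idx, hemi)
      if (length(dip))
        calls[dip, s] <- (calls[dip, s] + sample.int(2, length(dip), replace = TRUE)) %% 3L
      if (length(hemi))
        calls[hemi, s] <- 2L - calls[hemi, s]
    }
  }
  if (miss > 0) {
    drop <- matrix(runif(length(calls)) < miss, nrow(calls))
    calls[drop] <- NA_integer_
  }
  calls
}

#' @export
print.simulated_family <- function(x, ...) {
  cat(sprintf("simulated_family: %d members, %d markers, %s variants\n",
              nrow(x$pedigree), nrow(x$genotypes$calls),
              if (is.null(x$variants)) "no" else nrow(x$variants$variants)))
  invisible(x)
}
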