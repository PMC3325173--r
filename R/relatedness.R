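#' Count IBS sharing states for a sample pair
#'
#' Each autosomal marker at which both samples have non-missing calls
#' contributes to exactly one of IBS0/IBS1/IBS2.  IBS0 counts discordant
#' homozygotes, IBS2 concordant genotypes; IBS2* is the subset of IBS2
#' where both samples are heterozygous.  The X chromosome is excluded.
#'
#' @param gm A [genotype_matrix()].
#' @param a,b Distinct sample ids.
#' @return Named list `ibs0`, `ibs1`, `ibs2`, `ibs2_star`, `n_markers`.
#' @export
count_ibs <- function(gm, a, b) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (identical(a, b)) stop("a and b must be distinct samples")
  if (!all(c(a, b) %in% gm$sample_ids)) stop("both samples must be present")
  auto <- gm$map$chrom != "X"
  da <- gm$calls[auto, a]
  db <- gm$calls[auto, b]
  ok <- !is.na(da) & !is.na(db)
  da <- da[ok]; db <- db[ok]
  d <- abs(da - db)
  list(ibs0 = sum(d == 2L), ibs1 = sum(d == 1L), ibs2 = sum(d == 0L),
       ibs2_star = sum(da == 1L & db == 1L), n_markers = length(da))
}

#' IBS2*_ratio
#'
#' IBS2*_ratio = IBS2* / (IBS2* + IBS0).  For unrelated individuals the
#' expectation is 2/3 regardless of the allele-frequency spectrum, because
#' per marker P(het, het) = 4 p^2 q^2 and P(opposite homozygotes) =
#' 2 p^2 q^2; parent-offspring pairs have IBS0 = 0 and ratio 1.
#'
#' @param counts Output of [count_ibs()].
#' @return A real in \[0, 1\], or `NA` when IBS2* + IBS0 = 0 (undefined).
#' @export
ibs2_star_ratio <- function(counts) {
  den <- counts$ibs2_star + counts$ibs0
  if (den == 0) {
    message("IBS2*_ratio undefined: IBS2* + IBS0 = 0")
    return(NA_real_)
  }
  counts$ibs2_star / den
}

#' Percent informative SNPs
#'
#' (IBS0 + IBS2*) / (IBS0 + IBS1 + IBS2): the fraction of jointly typed
#' markers that are informative for distinguishing relationship classes.
#'
#' @param counts Output of [count_ibs()].
#' @return A real in \[0, 1\].
#' @export
pct_informative <- function(counts) {
  tot <- counts$ibs0 + counts$ibs1 + counts$ibs2
  if (tot == 0) stop("no jointly typed markers")
  (counts$ibs0 + counts$ibs2_star) / tot
}

#' Method-of-moments IBD estimates for a sample pair
#'
#' Estimates the genome-wide probabilities Z0/Z1/Z2 that the pair shares
#' 0/1/2 alleles identical by descent, by matching observed IBS state
#' counts to their allele-frequency-dependent expectations, then truncates
#' negative components to zero and renormalizes onto the simplex.
#' PI_HAT = Z1/2 + Z2.
#'
#' Markers with minor allele frequency below `min_maf` are excluded
#' (unstable denominators), as is the X chromosome.  Frequencies default to
#' estimates from pedigree founders (to avoid kin inflation) or, failing a
#' pedigree, from all samples.
#'
#' @param gm A [genotype_matrix()].
#' @param a,b Sample ids.
#' @param allele_freqs Optional numeric vector of per-marker alt-allele
#'   frequencies (length = markers in `gm`).
#' @param ped Optional [pedigree()] whose founders are used to estimate
#'   frequencies.
#' @param min_maf Minimum minor allele frequency (default 0.01).
#' @return Named list `z0`, `z1`, `z2`, `pi_hat`.
#' @export
estimate_ibd <- function(gm, a, b, allele_freqs = NULL, ped = NULL,
                         min_maf = 0.01) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!all(c(a, b) %in% gm$sample_ids)) stop("both samples must be present")
  if (is.null(allele_freqs)) {
    src <- if (!is.null(ped)) intersect(pedigree_founders(ped), gm$sample_ids)
           else gm$sample_ids
    if (length(src) == 0) stop("no samples available to estimate allele frequencies")
    allele_freqs <- rowMeans(gm$calls[, src, drop = FALSE], na.rm = TRUE) / 2
  }
  stopifnot(length(allele_freqs) == nrow(gm$calls))
  p <- allele_freqs
  maf <- pmin(p, 1 - p)
  use <- gm$map$chrom != "X" & !is.na(maf) & maf >= min_maf
  if (!any(use)) stop("no polymorphic autosomal markers after MAF filtering")
  da <- gm$calls[use, a]; db <- gm$calls[use, b]
  ok <- !is.na(da) & !is.na(db)
  da <- da[ok]; db <- db[ok]; p <- p[use][ok]
  if (!length(p)) stop("no jointly typed markers")
  q <- 1 - p
  d <- abs(da - db)
  N0 <- sum(d == 2L); N1 <- sum(d == 1L); N2 <- sum(d == 0L)
  # expected per-marker IBS-state probabilities given IBD state
  S0_ibd0 <- sum(2 * p^2 * q^2)
  S1_ibd0 <- sum(4 * p^3 * q + 4 * p * q^3)
  S2_ibd0 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  S1_ibd1 <- sum(2 * p^2 * q + 2 * p * q^2)
  S2_ibd1 <- sum(p^3 + q^3 + p^2 * q + p * q^2)
  n <- length(p)
  z0 <- N0 / S0_ibd0
  z1 <- (N1 - z0 * S1_ibd0) / S1_ibd1
  z2 <- (N2 - z0 * S2_ibd0 - z1 * S2_ibd1) / n
  z <- pmax(c(z0, z1, z2), 0)
  z <- z / sum(z)
  list(z0 = z[1], z1 = z[2], z2 = z[3], pi_hat = z[2] / 2 + z[3])
}

#' Pairwise relatedness table
#'
#' Computes the full statistic set for sample pairs: IBS counts,
#' IBS2*_ratio, percent informative, and method-of-moments IBD estimates.
#'
#' @param gm A [genotype_matrix()].
#' @param pairs Either `"all"` (all sample pairs), `"parents"` (the
#'   parental pair of each family in `ped`), or a 2-column matrix of ids.
#' @param ped Optional [pedigree()] (required for `pairs = "parents"`;
#'   also used for founder allele frequencies).
#' @param allele_freqs Optional per-marker alt-allele frequencies.
#' @return Data frame, one row per pair.
#' @export
relatedness_table <- function(gm, pairs = "all", ped = NULL, allele_freqs = NULL) {
  if (identical(pairs, "all")) {
    pm <- t(utils::combn(gm$sample_ids, 2))
  } else if (identical(pairs, "parents")) {
    if (is.null(ped)) stop("pairs = 'parents' requires a pedigree")
    roles <- family_roles(ped)
    pm <- matrix(c(roles$father, roles$mother), ncol = 2)
  } else {
    pm <- as.matrix(pairs)
    stopifnot(ncol(pm) == 2)
  }
  rows <- lapply(seq_len(nrow(pm)), function(i) {
    a <- pm[i, 1]; b <- pm[i, 2]
    cts <- count_ibs(gm, a, b)
    ibd <- estimate_ibd(gm, a, b, allele_freqs = allele_freqs, ped = ped)
    data.frame(sample_a = a, sample_b = b,
               ibs0 = cts$ibs0, ibs1 = cts$ibs1, ibs2 = cts$ibs2,
               ibs2_star = cts$ibs2_star,
               ibs2_star_ratio = suppressMessages(ibs2_star_ratio(cts)),
               pct_informative = pct_informative(cts),
               z0 = ibd$z0, z1 = ibd$z1, z2 = ibd$z2, pi_hat = ibd$pi_hat,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
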