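# Case/control recessive burden: count individuals carrying qualifying
# recessive genotypes (homozygous, or two het variants in one gene —
# unphased compound het, as in a screen without parents) in a gene set,
# and test enrichment in cases with a one-tailed Fisher's exact test.

#' One-tailed Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric tail probability of observing at least `a` case
#' carriers given the table margins (enrichment-in-cases direction),
#' computed in log-space for numerical stability.  Table layout:
#' `a` = case carriers, `b` = case non-carriers, `c` = control carriers,
#' `d` = control non-carriers.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return The one-tailed p-value in (0, 1\].
#' @export
fisher_one_tailed <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  N <- a + b + c + d
  K <- a + c      # carriers
  n <- a + b      # cases
  if (N == 0) return(1)
  k <- a:min(K, n)
  if (!length(k)) return(1)
  logp <- lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)
  min(1, sum(exp(logp)))
}

#' Count individuals carrying qualifying recessive genotypes
#'
#' A cohort member counts (once) when, in any gene of the set, they are
#' homozygous (or hemizygous) alternate for a qualifying variant, or
#' heterozygous for at least two distinct qualifying variants (unphased
#' compound het).  Qualifying variants belong to the gene set, fall in
#' `classes`, and have cohort allele frequency <= `maf_ceiling` computed
#' within `freq_cohort` (default: the counting cohort).
#'
#' @param vt A [variant_table()].
#' @param cohort Sample ids to count within (non-empty).
#' @param gene_set Character vector of gene symbols.
#' @param maf_ceiling Allele-frequency ceiling (default 0.05).
#' @param classes Consequence classes that qualify.
#' @param freq_cohort Samples used for the frequency computation (default
#'   `cohort`; pass the combined case+control set for a joint screen).
#' @return Integer carrier count.
#' @export
count_recessive_carriers <- function(vt, cohort, gene_set, maf_ceiling = 0.05,
                                     classes = c("coding_nonsynonymous",
                                                 "frameshift", "splice_site"),
                                     freq_cohort = cohort) {
  if (length(cohort) == 0) stop("empty cohort")
  missing_genes <- setdiff(gene_set, vt$variants$gene)
  if (length(missing_genes))
    warning("gene(s) absent from variant table (zero carriers): ",
            paste(missing_genes, collapse = ", "))
  qual <- vt$variants$gene %in% gene_set & vt$variants$consequence %in% classes
  if (!any(qual)) return(0L)
  af <- variant_allele_freq(vt, freq_cohort)
  qual <- qual & !is.na(af) & af <= maf_ceiling
  if (!any(qual)) return(0L)
  sub <- vt[qual]
  carrier <- rep(FALSE, length(cohort))
  for (g in unique(sub$variants$gene)) {
    gg <- sub$geno[sub$variants$gene == g, cohort, drop = FALSE]
    hom <- colSums(gg == "hom_alt" | gg == "hemi_alt") >= 1
    chet <- colSums(gg == "het") >= 2
    carrier <- carrier | hom | chet
  }
  sum(carrier)
}

# cohort alternate-allele frequency per variant (hemizygous counts 1/1)
variant_allele_freq <- function(vt, cohort) {
  gg <- vt$geno[, cohort, drop = FALSE]
  alt <- rowSums(gg == "het") + 2 * rowSums(gg == "hom_alt") +
    rowSums(gg == "hemi_alt")
  dip <- matrix(gg %in% c("hom_ref", "het", "hom_alt"), nrow(gg))
  hemi <- matrix(gg %in% c("hemi_ref", "hemi_alt"), nrow(gg))
  tot <- 2 * rowSums(dip) + rowSums(hemi)
  ifelse(tot > 0, alt / tot, NA_real_)
}

#' Case/control recessive burden test for a gene set
#'
#' Counts qualifying recessive-genotype carriers (see
#' [count_recessive_carriers()]) among cases and controls — variant
#' frequencies are computed within the combined cohort — and tests
#' enrichment in cases with [fisher_one_tailed()].
#'
#' @param vt A [variant_table()] covering the union cohort.
#' @param cases,controls Sample id vectors.
#' @param gene_set Character vector of gene symbols.
#' @param maf_ceiling Allele-frequency ceiling (default 0.05).
#' @param classes Qualifying consequence classes.
#' @return List of class `"burden_result"`: cohort sizes, carrier counts,
#'   carrier percentages, and `p_one_tailed`.
#' @export
burden_test <- function(vt, cases, controls, gene_set, maf_ceiling = 0.05,
                        classes = c("coding_nonsynonymous", "frameshift",
                                    "splice_site")) {
  stopifnot(length(cases) > 0, length(controls) > 0)
  both <- c(cases, controls)
  ca <- count_recessive_carriers(vt, cases, gene_set, maf_ceiling, classes,
                                 freq_cohort = both)
  co <- suppressWarnings(
    count_recessive_carriers(vt, controls, gene_set, maf_ceiling, classes,
                             freq_cohort = both))
  p <- fisher_one_tailed(ca, length(cases) - ca, co, length(controls) - co)
  structure(list(gene_set = gene_set,
                 n_cases = length(cases), n_controls = length(controls),
                 carriers_cases = ca, carriers_controls = co,
                 pct_cases = 100 * ca / length(cases),
                 pct_controls = 100 * co / length(controls),
                 p_one_tailed = p),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("recessive burden: cases %d/%d (%.1f%%) vs controls %d/%d (%.1f%%), P = %.3f (one-tailed Fisher)\n",
              x$carriers_cases, x$n_cases, x$pct_cases,
              x$carriers_controls, x$n_controls, x$pct_controls,
              x$p_one_tailed))
  invisible(x)
}
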