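# Reconstruction of a case/control resequencing screen from a published
# per-variant summary (gene, variant pair, zygosity, case/control counts).
# The resulting cohort is synthetic: individuals are generated to be
# consistent with the printed counts, one distinct individual per counted
# carrier, with all other genotypes homozygous reference.

#' Build a synthetic case/control cohort from screen summary counts
#'
#' The summary table has one row per screen finding: `gene`, `zygosity`
#' (`homozygous` / `compound_heterozygous`), `var1`/`pos1` (and
#' `var2`/`pos2` for compound-het rows), `chrom`, and the number of
#' distinct carrier individuals among `cases` and `controls`.  Each counted
#' carrier becomes one synthetic individual: homozygous alternate at
#' `var1`, or heterozygous at both `var1` and `var2`.
#'
#' @param summary Data frame as described (see
#'   `system.file("extdata", "arra_screen_counts.tsv", package = "rohscan")`).
#' @param n_cases,n_controls Cohort sizes; must be at least the summed
#'   carrier counts.
#' @return List with `vt` (a [variant_table()]), `cases` and `controls`
#'   (sample id vectors).
#' @export
build_screen_cohort <- function(summary, n_cases, n_controls) {
  req <- c("gene", "chrom", "zygosity", "var1", "pos1", "var2", "pos2",
           "cases", "controls")
  stopifnot(all(req %in% names(summary)))
  stopifnot(sum(summary$cases) <= n_cases, sum(summary$controls) <= n_controls)
  v1 <- data.frame(id = summary$var1, chrom = summary$chrom, pos = summary$pos1,
                   gene = summary$gene, stringsAsFactors = FALSE)
  v2 <- data.frame(id = summary$var2, chrom = summary$chrom, pos = summary$pos2,
                   gene = summary$gene, stringsAsFactors = FALSE)
  vars <- rbind(v1, v2[!is.na(v2$id), , drop = FALSE])
  vars <- vars[!duplicated(vars$id), , drop = FALSE]
  vars <- vars[order(vars$chrom, vars$pos), , drop = FALSE]
  variants <- data.frame(
    id = vars$id, chrom = as.character(vars$chrom), pos = as.integer(vars$pos),
    ref = "C", alt = "T", gene = vars$gene,
    consequence = "coding_nonsynonymous", variant_class = "snp",
    mapping_quality = 60, known_variant = grepl("^rs", vars$id),
    stringsAsFactors = FALSE)
  cases <- sprintf("case_%03d", seq_len(n_cases))
  controls <- sprintf("ctrl_%03d", seq_len(n_controls))
  geno <- matrix("hom_ref", nrow(variants), n_cases + n_controls,
                 dimnames = list(variants$id, c(cases, controls)))
  next_case <- 1L; next_ctrl <- 1L
  for (i in seq_len(nrow(summary))) {
    hom <- summary$zygosity[i] == "homozygous"
    for (arm in c("cases", "controls")) {
      cnt <- summary[[arm]][i]
      if (cnt == 0) next
      if (arm == "cases") {
        who <- cases[next_case:(next_case + cnt - 1)]; next_case <- next_case + cnt
      } else {
        who <- controls[next_ctrl:(next_ctrl + cnt - 1)]; next_ctrl <- next_ctrl + cnt
      }
      if (hom) {
        geno[summary$var1[i], who] <- "hom_alt"
      } else {
        geno[summary$var1[i], who] <- "het"
        geno[summary$var2[i], who] <- "het"
      }
    }
  }
  list(vt = variant_table(variants, geno), cases = cases, controls = controls)
}

#' Read a screen summary table shipped with the package
#'
#' @param path TSV path; defaults to the bundled ARRA-style screen summary.
#' @return Data frame suitable for [build_screen_cohort()].
#' @export
read_screen_summary <- function(path = system.file("extdata", "arra_screen_counts.tsv",
                                                   package = "rohscan")) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = ".")
}
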