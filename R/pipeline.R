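#' Run the full discovery pipeline on one family
#'
#' Orchestrates simulate-or-load -> ROH detection -> shared-ROH ->
#' relatedness -> variant filtration -> segregation (all three models) ->
#' ROH overlay and exclusions -> cascade report.  Outputs are reproducible:
#' the same configuration and seed give identical artifacts.
#'
#' @param input A [sim_config()] (the family is simulated) or a list with
#'   elements `pedigree`, `genotypes` and `variants` (pre-loaded data).
#' @param roh_par A [roh_params()].
#' @param filt_par A [filter_params()].
#' @param freq_ceiling_pct Control allele-frequency ceiling in percent.
#' @param out_dir Optional directory; stage artifacts (ROH BED/TSV,
#'   relatedness, verdicts, candidates, cascade, run manifest JSON) are
#'   written there.
#' @return List with the family, per-sample ROH segments and
#'   homozygosity profiles, shared intervals, parental relatedness, the
#'   filtered variant table, per-model verdicts, prioritized candidates,
#'   surviving genes and the cascade report.
#' @export
run_pipeline <- function(input, roh_par = roh_params(), filt_par = filter_params(),
                         freq_ceiling_pct = 0.5, out_dir = NULL) {
  fam <- if (inherits(input, "sim_config")) simulate_family(input)
    else if (inherits(input, "simulated_family")) input
    else {
      stopifnot(all(c("pedigree", "genotypes", "variants") %in% names(input)))
      input
    }
  ped <- fam$pedigree
  gm <- fam$genotypes
  roles <- family_roles(ped)
  proband <- roles$affected[1]
  children <- c(roles$affected, roles$unaffected)

  segs <- lapply(setNames(children, children), function(s) detect_roh(gm, s, roh_par))
  profiles <- do.call(rbind, lapply(segs, summarize_homozygosity, map = gm$map))
  shared <- shared_roh(gm, roles$affected, roles$unaffected, roh_par)
  rel <- relatedness_table(gm, "parents", ped = ped)

  vt <- fam$variants
  verdicts <- list(); candidates <- NULL; survivors <- NULL; cascade <- NULL
  if (!is.null(vt)) {
    vt_f <- remove_known(suppressWarnings(quality_filter(vt, filt_par)))
    hom <- candidate_homozygous(vt_f, proband, filt_par)
    chet <- candidate_compound_het(vt_f, proband, filt_par)
    verdicts$hom_recessive <- segregate_variants(hom, ped, "hom_recessive")
    verdicts$compound_het <- segregate_variants(chet, ped, "compound_het")
    psex <- ped$sex[match(proband, ped$id)]
    if (identical(psex, "male") && any(vt_f$variants$chrom == "X")) {
      xcand <- candidate_hemizygous_x(vt_f, proband, psex, filt_par)
      verdicts$x_linked <- segregate_variants(xcand, ped, "x_linked")
    }
    candidates <- apply_exclusions(
      overlay_roh(verdicts$hom_recessive, shared), vt_f, freq_ceiling_pct)
    n_seg <- sum(verdicts$hom_recessive$verdict == "segregates")
    cascade <- data.frame(patient = proband,
                          wes = n_variants(hom), designed = n_variants(hom),
                          ran = n_variants(hom), validated = n_variants(hom),
                          segregating = n_seg,
                          in_roh = sum(candidates$in_shared_roh),
                          stringsAsFactors = FALSE)
    report <- final_report(cascade, candidates)
    survivors <- report$genes
    cascade <- report$cascade
  }

  out <- list(family = fam, roh = segs, profiles = profiles, shared = shared,
              relatedness = rel,
              variants_filtered = if (is.null(vt)) NULL else vt_f,
              verdicts = verdicts, candidates = candidates,
              survivors = survivors, cascade = cascade)
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  invisible(out)
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_segs <- do.call(rbind, res$roh)
  write_roh_bed(all_segs, file.path(out_dir, "roh.bed"))
  write.table(all_segs, file.path(out_dir, "roh.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$profiles, file.path(out_dir, "homozygosity_profiles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$shared, file.path(out_dir, "shared_roh.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$relatedness, file.path(out_dir, "relatedness.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (m in names(res$verdicts))
    write.table(res$verdicts[[m]], file.path(out_dir, paste0("verdicts_", m, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$candidates))
    write.table(res$candidates, file.path(out_dir, "candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(res$cascade))
    write.table(res$cascade, file.path(out_dir, "cascade.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("rohscan")),
    seed = if (inherits(res$family, "simulated_family"))
      res$family$config$seed else NULL,
    stages = c("roh", "shared_roh", "relatedness", "filter", "segregate",
               "prioritize"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(NULL)
}
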