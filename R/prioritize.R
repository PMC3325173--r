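# Candidate prioritization: overlay segregating variants on shared ROHs,
# apply control-prevalence and annotation exclusions in a fixed order
# (roh -> controls -> brain -> disorder -> splice), and report the cascade.

.exclusion_order <- c("not_in_roh", "prevalent_in_controls", "not_brain_expressed",
                      "known_other_disorder", "noncanonical_splice")

#' Overlay segregating candidates on shared ROH intervals
#'
#' @param verdicts Verdict data frame from [segregate_variants()]
#'   (hom-recessive model) with `variant_id`, `gene`, `chrom`, `pos`,
#'   `verdict`.
#' @param shared_intervals Intervals from [shared_roh()].
#' @param include Verdict values admitted to the candidate list (default:
#'   `segregates` only).
#' @return Candidate data frame with `in_shared_roh` and `roh_size_cM`.
#' @export
overlay_roh <- function(verdicts, shared_intervals,
                        include = "segregates") {
  cand <- verdicts[verdicts$verdict %in% include, , drop = FALSE]
  n <- nrow(cand)
  in_roh <- logical(n); size <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    hit <- shared_intervals$chrom == cand$chrom[i] &
      shared_intervals$start_bp <= cand$pos[i] &
      shared_intervals$end_bp >= cand$pos[i]
    if (any(hit)) {
      in_roh[i] <- TRUE
      size[i] <- max(shared_intervals$length_cM[hit])
    }
  }
  cbind(cand[, c("variant_id", "gene", "chrom", "pos")],
        data.frame(in_shared_roh = in_roh, roh_size_cM = size))
}

#' Prevalence of a variant in control chromosomes
#'
#' @param alt_alleles Alternate allele count among control chromosomes.
#' @param total_chromosomes Number of control chromosomes (> 0).
#' @param homozygotes Number of homozygous-alternate control individuals.
#' @param freq_ceiling_pct Allele-frequency ceiling in percent above which
#'   a candidate is excluded (default 0.5); any control homozygote excludes
#'   regardless.
#' @return List with `allele_freq_pct` (percent of chromosomes),
#'   `n_homozygotes`, `excluded`.
#' @export
control_prevalence <- function(alt_alleles, total_chromosomes, homozygotes = 0,
                               freq_ceiling_pct = 0.5) {
  if (total_chromosomes <= 0) stop("control chromosome count must be positive")
  stopifnot(alt_alleles >= 0, alt_alleles <= total_chromosomes, homozygotes >= 0)
  pct <- 100 * alt_alleles / total_chromosomes
  list(allele_freq_pct = pct, n_homozygotes = homozygotes,
       excluded = homozygotes > 0 || pct > freq_ceiling_pct)
}

#' Apply exclusion criteria to ROH-overlaid candidates
#'
#' Exclusions are applied in a fixed order — shared-ROH membership, control
#' prevalence, brain expression, involvement in another disorder,
#' noncanonical splice annotation — and the first failing criterion is
#' recorded (all failing criteria are kept in `all_failures`).  Unknown
#' (`NA`) annotations never exclude.
#'
#' @param candidates Output of [overlay_roh()].
#' @param vt The [variant_table()] carrying control counts and annotations.
#' @param freq_ceiling_pct See [control_prevalence()].
#' @return Candidate data frame with `exclusion` (`"none"` for survivors),
#'   `all_failures`, `control_freq_pct`, `control_homozygotes`.
#' @export
apply_exclusions <- function(candidates, vt, freq_ceiling_pct = 0.5) {
  n <- nrow(candidates)
  exclusion <- character(n); allf <- character(n)
  cf <- rep(NA_real_, n); ch <- rep(NA_integer_, n)
  va <- vt$variants
  for (i in seq_len(n)) {
    j <- match(candidates$variant_id[i], va$id)
    fails <- character(0)
    if (!candidates$in_shared_roh[i]) fails <- c(fails, "not_in_roh")
    if (!is.na(j) && all(c("control_alt", "control_total") %in% names(va)) &&
        !is.na(va$control_alt[j]) && !is.na(va$control_total[j])) {
      hom <- if ("control_hom" %in% names(va) && !is.na(va$control_hom[j]))
        va$control_hom[j] else 0L
      cp <- control_prevalence(va$control_alt[j], va$control_total[j], hom,
                               freq_ceiling_pct)
      cf[i] <- cp$allele_freq_pct; ch[i] <- cp$n_homozygotes
      if (cp$excluded) fails <- c(fails, "prevalent_in_controls")
    }
    if (!is.na(j)) {
      be <- if ("brain_expressed" %in% names(va)) va$brain_expressed[j] else NA
      kd <- if ("known_disorder_gene" %in% names(va)) va$known_disorder_gene[j] else NA
      ns <- if ("noncanonical_splice" %in% names(va)) va$noncanonical_splice[j] else NA
      if (isFALSE(be)) fails <- c(fails, "not_brain_expressed")
      if (isTRUE(kd)) fails <- c(fails, "known_other_disorder")
      if (isTRUE(ns)) fails <- c(fails, "noncanonical_splice")
    }
    fails <- .exclusion_order[.exclusion_order %in% fails]
    exclusion[i] <- if (length(fails)) fails[1] else "none"
    allf[i] <- paste(fails, collapse = ";")
  }
  cbind(candidates,
        data.frame(exclusion = exclusion, all_failures = allf,
                   control_freq_pct = cf, control_homozygotes = ch,
                   stringsAsFactors = FALSE))
}

# Percentage formatting used in the cascade report: rounds halves down
# (x = 77.5 prints 77), matching fixed-precision truncation of .5 cells.
cascade_pct <- function(numer, denom) {
  ifelse(denom > 0, as.integer(ceiling(100 * numer / denom - 0.5)), NA_integer_)
}

#' Per-family filtration cascade and candidate-gene report
#'
#' Summarizes the candidate cascade — homozygous variants found by
#' sequencing, assays designed, assays run, validated, segregating with
#' disease, and within shared ROHs — with the percentage of each
#' validation stage relative to its predecessor, plus the surviving gene
#' list with control prevalence and ROH size.
#'
#' @param cascade Data frame with columns `patient`, `wes`, `designed`,
#'   `ran`, `validated`, `segregating`, `in_roh` (one row per family).
#' @param candidates Output of [apply_exclusions()] (may be `NULL`).
#' @return List with `cascade` (counts + percentage columns) and `genes`
#'   (surviving candidates, `exclusion == "none"`).
#' @export
final_report <- function(cascade, candidates = NULL) {
  req <- c("patient", "wes", "designed", "ran", "validated", "segregating", "in_roh")
  stopifnot(all(req %in% names(cascade)))
  stages <- c("wes", "designed", "ran", "validated", "segregating", "in_roh")
  for (i in seq_len(nrow(cascade))) {
    v <- unlist(cascade[i, stages])
    if (any(diff(v) > 0))
      stop("cascade counts must be non-increasing left to right (row ",
           cascade$patient[i], ")")
  }
  cascade$pct_designed <- cascade_pct(cascade$designed, cascade$wes)
  cascade$pct_ran <- cascade_pct(cascade$ran, cascade$designed)
  cascade$pct_validated <- cascade_pct(cascade$validated, cascade$ran)
  genes <- if (!is.null(candidates))
    candidates[candidates$exclusion == "none", , drop = FALSE]
  else NULL
  list(cascade = cascade, genes = genes)
}
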