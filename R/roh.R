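#' Parameters for run-of-homozygosity detection
#'
#' Defaults encode the tolerance rules used throughout the package: a run
#' may contain at most 2 consecutive heterozygous SNPs, and at most 3
#' heterozygous calls in every window of 10 consecutive SNPs; runs must be
#' strictly longer than 5 cM and span at least 25 markers.
#'
#' @param max_consecutive_het Maximum length of a consecutive-heterozygote
#'   stretch tolerated inside a run.
#' @param window_size Sliding-window size in markers for the window rule.
#' @param max_het_per_window Maximum heterozygous calls tolerated in any
#'   window of `window_size` consecutive markers fully inside a run.
#' @param min_length_cM Runs must exceed this genetic length (strict).
#' @param min_markers Minimum number of markers spanned by a run.
#' @return A list of class `"roh_params"`.
#' @export
roh_params <- function(max_consecutive_het = 2, window_size = 10,
                       max_het_per_window = 3, min_length_cM = 5,
                       min_markers = 25) {
  stopifnot(max_het_per_window <= window_size, min_length_cM >= 0,
            max_consecutive_het >= 0, window_size >= 1, min_markers >= 1)
  structure(list(max_consecutive_het = max_consecutive_het,
                 window_size = window_size,
                 max_het_per_window = max_het_per_window,
                 min_length_cM = min_length_cM,
                 min_markers = min_markers),
            class = "roh_params")
}

# Core per-chromosome scan.  A candidate interval [i, j] is valid when
#  * markers i and j are homozygous (runs never begin/end on het or missing),
#  * every consecutive-het stretch inside has length <= max_consecutive_het,
#  * every window of window_size markers fully inside contains
#    <= max_het_per_window hets (runs shorter than the window apply only the
#    consecutive-het rule),
#  * missing calls are neutral: not het, do not break the run, but occupy
#    window positions.
# Validity is hereditary on hom-bounded subintervals, so maximal valid
# intervals are found with obstacle arithmetic: an interval is invalid iff
# it fully contains a "bad het run" (> max_consecutive_het) or a "bad
# window" (> max_het_per_window hets); both are intervals, and since run
# ends are homozygous, a het run intersecting the interval is always fully
# contained.  e(i) = min obstacle end starting at or after i, minus one,
# bounds the furthest valid right end from start i.
detect_roh_chrom <- function(g, params) {
  n <- length(g)
  hom <- !is.na(g) & (g == 0L | g == 2L)
  het <- !is.na(g) & g == 1L
  if (!any(hom)) return(NULL)

  ob_start <- integer(0); ob_end <- integer(0)
  r <- rle(het)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  bad <- r$values & r$lengths > params$max_consecutive_het
  if (any(bad)) { ob_start <- starts[bad]; ob_end <- ends[bad] }
  w <- params$window_size
  if (n >= w) {
    cs <- c(0L, cumsum(het))
    k <- seq_len(n - w + 1L)
    ws <- cs[k + w] - cs[k]
    badw <- which(ws > params$max_het_per_window)
    if (length(badw)) { ob_start <- c(ob_start, badw); ob_end <- c(ob_end, badw + w - 1L) }
  }

  # min_end[i] = min end over obstacles starting at or after i
  min_end <- rep(n + 1L, n)
  if (length(ob_start)) {
    agg <- tapply(ob_end, ob_start, min)
    min_end[as.integer(names(agg))] <- pmin(min_end[as.integer(names(agg))], agg)
    min_end <- rev(cummin(rev(min_end)))
  }
  idx <- seq_len(n)
  last_hom <- cummax(ifelse(hom, idx, 0L))

  starts_i <- which(hom)
  e_i <- pmin(min_end[starts_i] - 1L, n)
  r_i <- ifelse(e_i >= 1L, last_hom[pmax(e_i, 1L)], 0L)
  ok <- r_i >= starts_i
  starts_i <- starts_i[ok]; r_i <- r_i[ok]
  if (!length(starts_i)) return(NULL)
  # keep the leftmost start for each right end: those are the maximal runs
  keep <- !duplicated(r_i)
  data.frame(first = starts_i[keep], last = r_i[keep])
}

#' Detect runs of homozygosity for one sample
#'
#' Returns all maximal runs satisfying the heterozygote-tolerance rules and
#' the length/marker thresholds in `params` (see [roh_params()]).  Missing
#' calls are neutral; the X chromosome is skipped for male samples
#' (hemizygous by construction).
#'
#' @param gm A [genotype_matrix()].
#' @param sample Sample id.
#' @param params A [roh_params()].
#' @return Data frame with one row per segment: `sample_id`, `chrom`,
#'   `first_marker_index`/`last_marker_index` (rows of the map, inclusive),
#'   `start_bp`, `end_bp`, `start_cM`, `end_cM`, `length_cM`, `n_markers`,
#'   `n_het`.
#' @export
detect_roh <- function(gm, sample, params = roh_params()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!sample %in% gm$sample_ids) stop("sample '", sample, "' not in genotype matrix")
  check_map_sorted(gm$map)
  male <- identical(gm_sex(gm, sample), "male")
  out <- list()
  for (ch in unique(gm$map$chrom)) {
    if (male && ch == "X") next
    rows <- which(gm$map$chrom == ch)
    segs <- detect_roh_chrom(gm$calls[rows, sample], params)
    if (is.null(segs)) next
    first <- rows[segs$first]; last <- rows[segs$last]
    cM <- gm$map$cM; bp <- gm$map$bp
    len <- cM[last] - cM[first]
    nmk <- last - first + 1L
    keep <- len > params$min_length_cM & nmk >= params$min_markers
    if (!any(keep)) next
    first <- first[keep]; last <- last[keep]
    nhet <- vapply(seq_along(first), function(i) {
      sum(gm$calls[first[i]:last[i], sample] == 1L, na.rm = TRUE)
    }, integer(1))
    out[[length(out) + 1L]] <- data.frame(
      sample_id = sample, chrom = ch,
      first_marker_index = first, last_marker_index = last,
      start_bp = bp[first], end_bp = bp[last],
      start_cM = cM[first], end_cM = cM[last],
      length_cM = cM[last] - cM[first],
      n_markers = last - first + 1L, n_het = nhet,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_roh_df())
  do.call(rbind, out)
}

empty_roh_df <- function() {
  data.frame(sample_id = character(0), chrom = character(0),
             first_marker_index = integer(0), last_marker_index = integer(0),
             start_bp = integer(0), end_bp = integer(0),
             start_cM = numeric(0), end_cM = numeric(0),
             length_cM = numeric(0), n_markers = integer(0), n_het = integer(0),
             stringsAsFactors = FALSE)
}

#' Genome-wide homozygosity summary for one sample
#'
#' @param segments ROH segments from [detect_roh()] for one sample.
#' @param map The genetic map used for detection.
#' @return A one-row data frame: `sample_id`, `percent_genome_in_roh`
#'   (100 x total segment length / autosomal map length), `n_segments`,
#'   `mean_segment_cM`, `total_map_cM`.  The X chromosome is excluded from
#'   both numerator and denominator.
#' @export
summarize_homozygosity <- function(segments, map) {
  if (nrow(map) == 0) stop("empty genetic map")
  auto <- map[map$chrom != "X", , drop = FALSE]
  if (nrow(auto) == 0) stop("map has no autosomal markers")
  total <- sum(tapply(auto$cM, auto$chrom, function(x) max(x) - min(x)))
  if (total <= 0) stop("autosomal map has zero genetic length")
  segs <- segments[segments$chrom != "X", , drop = FALSE]
  if (nrow(segments) > 1 && length(unique(segments$sample_id)) > 1)
    stop("segments must come from a single sample")
  sample_id <- if (nrow(segments)) segments$sample_id[1] else NA_character_
  tot_seg <- sum(segs$length_cM)
  data.frame(sample_id = sample_id,
             percent_genome_in_roh = 100 * tot_seg / total,
             n_segments = nrow(segs),
             mean_segment_cM = if (nrow(segs)) mean(segs$length_cM) else NA_real_,
             total_map_cM = total,
             stringsAsFactors = FALSE)
}

#' Shared runs of homozygosity across a sibship
#'
#' Finds maximal intervals where (i) every affected individual has an ROH
#' covering the interval, (ii) affected individuals are homozygous for a
#' consistent allele — a marker at which two affected samples carry opposite
#' homozygous calls breaks the interval (tolerated heterozygous and missing
#' calls inside an ROH are neutral) — and (iii) no unaffected sibling has an
#' ROH covering the whole interval.
#'
#' @param gm A [genotype_matrix()].
#' @param affected Ids of affected individuals (at least one).
#' @param unaffected Ids of unaffected siblings (may be empty).
#' @param params A [roh_params()] passed to [detect_roh()].
#' @return Data frame of intervals with marker-index, bp and cM bounds.
#' @export
shared_roh <- function(gm, affected, unaffected = character(0),
                       params = roh_params()) {
  stopifnot(length(affected) >= 1)
  segs_a <- lapply(affected, function(s) detect_roh(gm, s, params))
  segs_u <- lapply(unaffected, function(s) detect_roh(gm, s, params))
  map <- gm$map
  out <- list()
  for (ch in unique(map$chrom)) {
    rows <- which(map$chrom == ch)
    n <- length(rows)
    covered <- rep(TRUE, n)
    for (sa in segs_a) {
      cov_s <- rep(FALSE, n)
      sa_ch <- sa[sa$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(sa_ch))) {
        a <- match(sa_ch$first_marker_index[k], rows)
        b <- match(sa_ch$last_marker_index[k], rows)
        cov_s[a:b] <- TRUE
      }
      covered <- covered & cov_s
    }
    if (!any(covered)) next
    calls <- gm$calls[rows, affected, drop = FALSE]
    has_ref <- rowSums(calls == 0L, na.rm = TRUE) > 0
    has_alt <- rowSums(calls == 2L, na.rm = TRUE) > 0
    ok <- covered & !(has_ref & has_alt)
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      s <- starts[k]; e <- ends[k]
      # (iii): drop if some unaffected sibling's ROH covers the whole interval
      blocked <- FALSE
      for (su in segs_u) {
        su_ch <- su[su$chrom == ch, , drop = FALSE]
        if (any(su_ch$first_marker_index <= rows[s] &
                  su_ch$last_marker_index >= rows[e])) { blocked <- TRUE; break }
      }
      if (blocked) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        first_marker_index = rows[s], last_marker_index = rows[e],
        start_bp = map$bp[rows[s]], end_bp = map$bp[rows[e]],
        start_cM = map$cM[rows[s]], end_cM = map$cM[rows[e]],
        length_cM = map$cM[rows[e]] - map$cM[rows[s]],
        n_markers = e - s + 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), first_marker_index = integer(0),
                      last_marker_index = integer(0), start_bp = integer(0),
                      end_bp = integer(0), start_cM = numeric(0),
                      end_cM = numeric(0), length_cM = numeric(0),
                      n_markers = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
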