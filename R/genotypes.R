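#' Genotype matrix over a genetic map
#'
#' Calls are stored as an integer matrix (markers x samples) coded
#' 0 = hom_ref, 1 = het, 2 = hom_alt, `NA` = missing.  On the male X the
#' codes 0/2 denote hemizygous reference/alternate; a heterozygous call on a
#' male X is invalid.  The map must be sorted by chromosome and physical
#' position, with non-decreasing genetic (cM) positions.
#'
#' @param calls Integer matrix, markers in rows, samples in columns.
#' @param map Data frame with columns `marker_id`, `chrom`, `bp`, `cM`.
#' @param sample_ids Sample names (default: column names of `calls`).
#' @param sex Optional named character vector (`"male"`/`"female"`) used to
#'   interpret X-chromosome calls.
#' @return An object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(calls, map, sample_ids = colnames(calls), sex = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(sample_ids)) stop("sample ids are required")
  stopifnot(nrow(calls) == nrow(map), ncol(calls) == length(sample_ids))
  req <- c("marker_id", "chrom", "bp", "cM")
  if (!all(req %in% names(map))) stop("map must have columns ", paste(req, collapse = ", "))
  if (!all(calls %in% c(0L, 1L, 2L) | is.na(calls))) stop("calls must be 0/1/2/NA")
  check_map_sorted(map)
  if (!is.null(sex)) {
    males <- sample_ids[!is.na(sex[sample_ids]) & sex[sample_ids] == "male"]
    xr <- which(map$chrom == "X")
    if (length(xr) && length(males) &&
        any(calls[xr, males, drop = FALSE] == 1L, na.rm = TRUE))
      stop("heterozygous calls on the male X are invalid (must be missing or hemizygous)")
  }
  colnames(calls) <- sample_ids
  structure(list(calls = calls, map = as.data.frame(map), sample_ids = sample_ids,
                 sex = sex),
            class = "genotype_matrix")
}

check_map_sorted <- function(map) {
  for (ch in unique(map$chrom)) {
    i <- which(map$chrom == ch)
    if (is.unsorted(map$bp[i])) stop("map not sorted by bp within chromosome ", ch)
    if (is.unsorted(map$cM[i])) stop("cM positions not non-decreasing on chromosome ", ch)
  }
  invisible(map)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d samples, %d chromosome(s)\n",
              nrow(x$calls), length(x$sample_ids), length(unique(x$map$chrom))))
  invisible(x)
}

gm_sex <- function(gm, sample) {
  if (is.null(gm$sex)) return(NA_character_)
  s <- gm$sex[sample]
  if (is.null(s)) NA_character_ else unname(s)
}
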