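.geno_states <- c("hom_ref", "het", "hom_alt", "hemi_ref", "hemi_alt", "missing")
.consequences <- c("coding_synonymous", "coding_nonsynonymous", "frameshift",
                   "splice_site", "noncoding")

#' Annotated variant table with per-sample genotypes
#'
#' Couples a variant data frame (one row per variant) with a character
#' matrix of per-sample genotype states (`hom_ref`, `het`, `hom_alt`,
#' `hemi_ref`, `hemi_alt`, `missing`).  Required variant columns: `id`,
#' `chrom`, `pos` (1-based), `ref`, `alt`, `gene`, `consequence`,
#' `variant_class` (`snp`/`indel`), `mapping_quality`, `known_variant`.
#' Optional annotation columns: `brain_expressed`, `known_disorder_gene`,
#' `noncanonical_splice`, `score`, and control counts `control_alt`,
#' `control_total`, `control_hom`.
#'
#' @param variants Variant data frame.
#' @param geno Character matrix, variants x samples.
#' @return An object of class `"variant_table"`.
#' @export
variant_table <- function(variants, geno) {
  req <- c("id", "chrom", "pos", "ref", "alt", "gene", "consequence",
           "variant_class", "mapping_quality", "known_variant")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  geno <- as.matrix(geno)
  stopifnot(nrow(geno) == nrow(variants))
  if (!all(geno %in% .geno_states)) stop("invalid genotype state in variant table")
  if (any(variants$pos < 1)) stop("variant positions must be >= 1 (1-based)")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  if (!all(is.na(variants$consequence) | variants$consequence %in% .consequences))
    stop("invalid consequence label")
  if (all(c("control_alt", "control_total") %in% names(variants))) {
    bad <- !is.na(variants$control_alt) & !is.na(variants$control_total) &
      variants$control_alt > variants$control_total
    if (any(bad)) stop("control alt allele count exceeds total chromosomes")
  }
  if (anyDuplicated(variants$id)) stop("duplicate variant ids")
  rownames(variants) <- NULL
  rownames(geno) <- variants$id
  structure(list(variants = variants, geno = geno), class = "variant_table")
}

#' Subset a variant table by variant rows
#' @param x A [variant_table()].
#' @param i Row index (logical, integer or variant-id character).
#' @param ... Unused.
#' @export
`[.variant_table` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$variants$id)
  variant_table(x$variants[i, , drop = FALSE], x$geno[i, , drop = FALSE])
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d variants x %d samples\n",
              nrow(x$variants), ncol(x$geno)))
  invisible(x)
}

#' Number of variants in a variant table
#' @param vt A [variant_table()].
#' @export
n_variants <- function(vt) nrow(vt$variants)

vt_samples <- function(vt) colnames(vt$geno)

#' Genotype states of one variant as a named vector
#' @param vt A [variant_table()].
#' @param id Variant id.
#' @export
vt_geno <- function(vt, id) {
  i <- match(id, vt$variants$id)
  if (is.na(i)) stop("unknown variant id: ", id)
  setNames(vt$geno[i, ], colnames(vt$geno))
}
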