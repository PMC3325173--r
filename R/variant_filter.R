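#' Variant filtration parameters
#'
#' Mapping-quality thresholds are strict: SNPs are kept when MQ > 25 and
#' indels when MQ > 10.  `deleterious_classes` defines which consequence
#' classes count as potentially pathogenic downstream.
#'
#' @param mq_min_snp,mq_min_indel Strict lower MQ bounds.
#' @param deleterious_classes Consequence classes treated as deleterious.
#' @param splice_window_bp Intronic distance (bp) from an exon boundary
#'   within which a variant is called `splice_site` (canonical GT/AG
#'   dinucleotides at the default of 2).
#' @return A list of class `"filter_params"`.
#' @export
filter_params <- function(mq_min_snp = 25, mq_min_indel = 10,
                          deleterious_classes = c("coding_nonsynonymous",
                                                  "frameshift", "splice_site"),
                          splice_window_bp = 2) {
  stopifnot(mq_min_snp >= 0, mq_min_indel >= 0, splice_window_bp >= 0)
  structure(list(mq_min_snp = mq_min_snp, mq_min_indel = mq_min_indel,
                 deleterious_classes = deleterious_classes,
                 splice_window_bp = splice_window_bp),
            class = "filter_params")
}

#' Mapping-quality filter
#'
#' @param vt A [variant_table()].
#' @param params A [filter_params()].
#' @return The filtered [variant_table()]; variants with missing MQ are
#'   dropped with a warning.
#' @export
quality_filter <- function(vt, params = filter_params()) {
  mq <- vt$variants$mapping_quality
  if (anyNA(mq))
    warning(sum(is.na(mq)), " variant(s) with missing mapping quality dropped")
  thr <- ifelse(vt$variants$variant_class == "indel",
                params$mq_min_indel, params$mq_min_snp)
  vt[!is.na(mq) & mq > thr]
}

#' Remove variants present in a common-variant catalog
#'
#' Allele-aware exact matching on (chrom, pos, ref, alt); idempotent.
#' With `catalog = NULL` the table's own `known_variant` flag is used
#' (e.g. when the catalog membership was annotated upstream).
#'
#' @param vt A [variant_table()].
#' @param catalog Data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (see [read_sites_catalog()]), or `NULL`.
#' @return The filtered [variant_table()].
#' @export
remove_known <- function(vt, catalog = NULL) {
  if (is.null(catalog)) return(vt[!vt$variants$known_variant])
  key <- function(ch, pos, r, a) paste(ch, pos, r, a, sep = "\r")
  hit <- key(vt$variants$chrom, vt$variants$pos, vt$variants$ref, vt$variants$alt) %in%
    key(catalog$chrom, catalog$pos, catalog$ref, catalog$alt)
  vt[!hit]
}

#' Transcript model for consequence annotation
#'
#' @param gene Gene symbol.
#' @param chrom Chromosome label.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with `start`/`end` (1-based inclusive genomic,
#'   sorted, non-overlapping).
#' @param cds_start,cds_end CDS bounds (genomic, within the exon span).
#' @param seq Reference sequence covering the transcript span, as a plain
#'   character string of A/C/G/T on the + strand.
#' @param seq_start Genomic position of the first base of `seq`.
#' @return A list of class `"transcript_model"`.
#' @export
transcript_model <- function(gene, chrom, strand, exons, cds_start, cds_end,
                             seq, seq_start = min(exons$start)) {
  stopifnot(strand %in% c("+", "-"), all(exons$start <= exons$end))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("exons must be non-overlapping")
  if (cds_start < min(exons$start) || cds_end > max(exons$end) || cds_start > cds_end)
    stop("CDS must lie within the exon span")
  if (seq_start > min(exons$start) ||
      seq_start + nchar(seq) - 1 < max(exons$end))
    stop("reference sequence does not cover the transcript span")
  structure(list(gene = gene, chrom = chrom, strand = strand, exons = exons,
                 cds_start = cds_start, cds_end = cds_end,
                 seq = toupper(seq), seq_start = seq_start),
            class = "transcript_model")
}

tm_base <- function(model, pos) {
  substr(model$seq, pos - model$seq_start + 1, pos - model$seq_start + 1)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# genomic positions of CDS bases, 5'->3' on the coding strand
cds_positions <- function(model) {
  pos <- unlist(lapply(seq_len(nrow(model$exons)), function(i) {
    lo <- max(model$exons$start[i], model$cds_start)
    hi <- min(model$exons$end[i], model$cds_end)
    if (lo > hi) return(integer(0))  # exon entirely outside the CDS
    seq(lo, hi)
  }))
  if (model$strand == "-") rev(pos) else pos
}

#' Classify the predicted consequence of a variant
#'
#' Categories: `splice_site` (within `splice_window_bp` of an intron
#' boundary, i.e. the canonical GT/AG dinucleotides at the default window),
#' `frameshift` (CDS indel with length change not divisible by 3),
#' `coding_synonymous` / `coding_nonsynonymous` (CDS SNV by codon
#' translation on the coding strand; in-frame CDS indels are
#' protein-altering and classed nonsynonymous), else `noncoding`
#' (including intronic positions beyond the splice window and positions
#' outside the transcript).
#'
#' @param chrom,pos,ref,alt Variant description (1-based `pos`; indels give
#'   `ref`/`alt` of unequal length with a shared anchor base).
#' @param model A [transcript_model()].
#' @param params A [filter_params()] (for `splice_window_bp`).
#' @return A consequence string.
#' @export
classify_consequence <- function(chrom, pos, ref, alt, model,
                                 params = filter_params()) {
  if (!identical(as.character(chrom), as.character(model$chrom))) return("noncoding")
  ex <- model$exons
  if (pos < min(ex$start) || pos > max(ex$end)) return("noncoding")
  w <- params$splice_window_bp
  if (nrow(ex) > 1 && w > 0) {
    for (i in seq_len(nrow(ex) - 1)) {
      int_s <- ex$end[i] + 1; int_e <- ex$start[i + 1] - 1
      if (pos >= int_s && pos <= min(int_s + w - 1, int_e)) return("splice_site")
      if (pos <= int_e && pos >= max(int_e - w + 1, int_s)) return("splice_site")
    }
  }
  in_exon <- any(pos >= ex$start & pos <= ex$end)
  if (!in_exon) return("noncoding")
  in_cds <- pos >= model$cds_start && pos <= model$cds_end
  if (!in_cds) return("noncoding")
  len_diff <- nchar(alt) - nchar(ref)
  if (len_diff != 0)
    return(if (len_diff %% 3 != 0) "frameshift" else "coding_nonsynonymous")
  # CDS SNV: translate the affected codon before/after
  cpos <- cds_positions(model)
  i <- match(pos, cpos)
  if (is.na(i)) return("noncoding")
  codon_i <- (i - 1) %/% 3
  cidx <- codon_i * 3 + 1:3
  cidx <- cidx[cidx <= length(cpos)]
  if (length(cidx) < 3) return("noncoding")  # incomplete terminal codon
  base_at <- function(p) {
    b <- if (p == pos) toupper(alt) else tm_base(model, p)
    if (model$strand == "-") revcomp(b) else b
  }
  codon_old <- paste(vapply(cpos[cidx], function(p) {
    b <- tm_base(model, p)
    if (model$strand == "-") revcomp(b) else b
  }, character(1)), collapse = "")
  codon_new <- paste(vapply(cpos[cidx], base_at, character(1)), collapse = "")
  aa_old <- Biostrings::GENETIC_CODE[[codon_old]]
  aa_new <- Biostrings::GENETIC_CODE[[codon_new]]
  if (identical(aa_old, aa_new)) "coding_synonymous" else "coding_nonsynonymous"
}

rare_deleterious <- function(vt, params) {
  !vt$variants$known_variant &
    vt$variants$consequence %in% params$deleterious_classes
}

#' Candidate homozygous variants for a proband
#'
#' Rare (catalog-absent), deleterious-class autosomal variants at which the
#' proband is homozygous alternate — the stream entering the
#' homozygous-recessive segregation test.
#'
#' @param vt A filtered [variant_table()].
#' @param proband Proband sample id.
#' @param params A [filter_params()].
#' @return A [variant_table()] subset.
#' @export
candidate_homozygous <- function(vt, proband, params = filter_params()) {
  if (!proband %in% vt_samples(vt)) stop("proband '", proband, "' not in variant table")
  keep <- rare_deleterious(vt, params) &
    !vt$variants$chrom %in% c("X", "Y") &
    vt$geno[, proband] == "hom_alt"
  vt[keep]
}

#' Candidate compound-heterozygous genes for a proband
#'
#' Genes carrying at least two distinct rare deleterious heterozygous
#' variants in the proband.  Genes already in the homozygous stream are
#' excluded (the streams are disjoint).
#'
#' @inheritParams candidate_homozygous
#' @return Named list (gene -> [variant_table()] of its het variants).
#' @export
candidate_compound_het <- function(vt, proband, params = filter_params()) {
  if (!proband %in% vt_samples(vt)) stop("proband '", proband, "' not in variant table")
  rd <- rare_deleterious(vt, params) & !vt$variants$chrom %in% c("X", "Y")
  het <- rd & vt$geno[, proband] == "het"
  hom_genes <- unique(vt$variants$gene[rd & vt$geno[, proband] == "hom_alt"])
  genes <- table(vt$variants$gene[het])
  genes <- setdiff(names(genes)[genes >= 2], hom_genes)
  setNames(lapply(genes, function(g) vt[het & vt$variants$gene == g]), genes)
}

#' Candidate hemizygous X-linked variants for a male proband
#'
#' @inheritParams candidate_homozygous
#' @param sex Proband sex; a female proband yields an empty result with a
#'   warning.
#' @return A [variant_table()] subset.
#' @export
candidate_hemizygous_x <- function(vt, proband, sex, params = filter_params()) {
  if (!proband %in% vt_samples(vt)) stop("proband '", proband, "' not in variant table")
  if (!identical(sex, "male")) {
    warning("hemizygous X candidate stream requires a male proband; returning empty set")
    return(vt[integer(0)])
  }
  keep <- rare_deleterious(vt, params) & vt$variants$chrom == "X" &
    vt$geno[, proband] == "hemi_alt"
  vt[keep]
}
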