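# Readers/writers: PLINK-text PED/MAP, variant TSV, minimal VCF, ROH BED.
# PED phenotype coding follows the PLINK dialect (2 = affected,
# 1 = unaffected, 0/-9 = unknown); missing genotype is "0 0"; the
# missing-data symbol in TSVs is ".".

#' Read PLINK-style PED/MAP files
#'
#' Builds the per-marker allele dictionary from the observed alleles
#' (sorted; the alphabetically first allele is the reference).  Markers with
#' more than two observed alleles are dropped with a warning.  Heterozygous
#' calls on the male X are set to missing with a warning.
#'
#' @param ped_path Path to the PED file (>= 6 columns, then genotype pairs).
#' @param map_path Path to the MAP file (chrom, marker id, cM, bp).
#' @return List with `pedigree` (a [pedigree()], or a plain data frame if
#'   multiple families are present) and `genotypes` (a [genotype_matrix()]).
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_raw <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map_raw) != 4) stop("MAP format error: expected 4 columns (chrom, id, cM, bp)")
  map <- data.frame(marker_id = as.character(map_raw[[2]]),
                    chrom = as.character(map_raw[[1]]),
                    bp = as.integer(map_raw[[4]]), cM = as.numeric(map_raw[[3]]),
                    stringsAsFactors = FALSE)
  ped_raw <- read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  n_mark <- nrow(map)
  if (ncol(ped_raw) != 6 + 2 * n_mark)
    stop("PED format error: expected ", 6 + 2 * n_mark, " columns, found ", ncol(ped_raw))
  fam <- data.frame(
    family_id = ped_raw[[1]], id = ped_raw[[2]],
    father = ifelse(ped_raw[[3]] == "0", NA, ped_raw[[3]]),
    mother = ifelse(ped_raw[[4]] == "0", NA, ped_raw[[4]]),
    sex = c("male", "female")[match(ped_raw[[5]], c("1", "2"))],
    affection = ifelse(ped_raw[[6]] == "2", "affected",
                       ifelse(ped_raw[[6]] == "1", "unaffected", "unknown")),
    stringsAsFactors = FALSE)
  n_samp <- nrow(fam)
  a1 <- as.matrix(ped_raw[, 6 + 2 * seq_len(n_mark) - 1, drop = FALSE])
  a2 <- as.matrix(ped_raw[, 6 + 2 * seq_len(n_mark), drop = FALSE])
  calls <- matrix(NA_integer_, n_mark, n_samp)
  drop_marker <- logical(n_mark)
  for (m in seq_len(n_mark)) {
    obs <- c(a1[, m], a2[, m])
    alleles <- sort(setdiff(unique(obs), "0"))
    if (length(alleles) > 2) {
      warning("marker ", map$marker_id[m], " has >2 observed alleles; dropped")
      drop_marker[m] <- TRUE
      next
    }
    if (!all(obs %in% c("0", alleles)))
      stop("unknown allele symbol at marker ", map$marker_id[m])
    i1 <- match(a1[, m], alleles); i2 <- match(a2[, m], alleles)
    ok <- a1[, m] != "0" & a2[, m] != "0"
    calls[m, ok] <- (i1[ok] - 1L) + (i2[ok] - 1L)
  }
  if (any(drop_marker)) {
    map <- map[!drop_marker, , drop = FALSE]
    calls <- calls[!drop_marker, , drop = FALSE]
  }
  sex <- setNames(fam$sex, fam$id)
  xr <- which(map$chrom == "X")
  males <- fam$id[!is.na(fam$sex) & fam$sex == "male"]
  if (length(xr) && length(males)) {
    colnames(calls) <- fam$id
    bad <- calls[xr, males, drop = FALSE] == 1L
    if (any(bad, na.rm = TRUE)) {
      warning("heterozygous male X call(s) set to missing")
      sub <- calls[xr, males, drop = FALSE]
      sub[which(bad)] <- NA_integer_
      calls[xr, males] <- sub
    }
  }
  gm <- genotype_matrix(calls, map, sample_ids = fam$id, sex = sex)
  ped <- if (length(unique(fam$family_id)) == 1)
    pedigree(fam$family_id[1], fam$id, fam$father, fam$mother, fam$sex, fam$affection)
  else fam
  list(pedigree = ped, genotypes = gm)
}

#' Write PLINK-style PED/MAP files
#'
#' @param gm A [genotype_matrix()].
#' @param ped A [pedigree()] (or compatible data frame) covering the samples.
#' @param ped_path,map_path Output paths.
#' @param alleles Two allele symbols for coding hom_ref/het/hom_alt.
#' @export
write_ped_map <- function(gm, ped, ped_path, map_path, alleles = c("A", "G")) {
  stopifnot(length(alleles) == 2, all(gm$sample_ids %in% ped$id))
  map <- gm$map
  write.table(data.frame(map$chrom, map$marker_id, map$cM, map$bp),
              map_path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  gcode <- c(paste(alleles[1], alleles[1]), paste(alleles[1], alleles[2]),
             paste(alleles[2], alleles[2]))
  lines <- vapply(gm$sample_ids, function(s) {
    i <- match(s, ped$id)
    g <- gm$calls[, s]
    gt <- ifelse(is.na(g), "0 0", gcode[g + 1L])
    paste(c(ped$family_id[i], s,
            ifelse(is.na(ped$father[i]), "0", ped$father[i]),
            ifelse(is.na(ped$mother[i]), "0", ped$mother[i]),
            match(ped$sex[i], c("male", "female"), nomatch = 0),
            c(unaffected = 1, affected = 2, unknown = 0)[ped$affection[i]],
            gt), collapse = " ")
  }, character(1))
  writeLines(lines, ped_path)
  invisible(NULL)
}

.vt_fixed_cols <- c("id", "chrom", "pos", "ref", "alt", "gene", "consequence",
                    "variant_class", "mapping_quality", "known_variant")
.vt_opt_cols <- c("brain_expressed", "known_disorder_gene", "noncanonical_splice",
                  "score", "control_alt", "control_total", "control_hom")

#' Read a variant table
#'
#' TSV dialect: a header with the documented fixed columns (see
#' [variant_table()]), optional annotation/control columns, and one column
#' per sample holding genotype states; `"."` denotes missing throughout.
#' VCF dialect: a minimal VCF 4.2 subset; genotype states are derived from
#' GT (a haploid GT of `"1"` on the male X becomes `hemi_alt`),
#' `known_variant` from a non-missing ID (e.g. an rs identifier),
#' `mapping_quality` from INFO `MQ=`, `gene`/`consequence` from INFO
#' `GENE=`/`CSQ=` when present.
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param ped Optional [pedigree()]; samples absent from it trigger a
#'   warning but are kept.
#' @param sex Optional named sex vector for X-genotype interpretation (VCF).
#' @return A [variant_table()].
#' @export
read_variants <- function(path, dialect = c("tsv", "vcf"), ped = NULL, sex = NULL) {
  dialect <- match.arg(dialect)
  vt <- if (dialect == "tsv") read_variants_tsv(path) else read_variants_vcf(path, sex)
  if (!is.null(ped)) {
    extra <- setdiff(vt_samples(vt), ped$id)
    if (length(extra))
      warning("sample(s) not in pedigree (kept): ", paste(extra, collapse = ", "))
  }
  vt
}

read_variants_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = ".", check.names = FALSE)
  miss <- setdiff(.vt_fixed_cols, names(df))
  if (length(miss)) stop("variant TSV missing required column(s): ",
                         paste(miss, collapse = ", "))
  sample_cols <- setdiff(names(df), c(.vt_fixed_cols, .vt_opt_cols))
  variants <- df[, intersect(c(.vt_fixed_cols, .vt_opt_cols), names(df)), drop = FALSE]
  variants$pos <- as.integer(variants$pos)
  variants$known_variant <- as.logical(variants$known_variant)
  for (cc in intersect(c("brain_expressed", "known_disorder_gene", "noncanonical_splice"),
                       names(variants)))
    variants[[cc]] <- as.logical(variants[[cc]])
  geno <- as.matrix(df[, sample_cols, drop = FALSE])
  geno[is.na(geno)] <- "missing"
  variant_table(variants, geno)
}

read_variants_vcf <- function(path, sex = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_field <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0("(^|;)", key, "=[^;]*"), fix$INFO))
    out <- rep(NA_character_, nrow(fix))
    hit <- grepl(paste0(key, "="), fix$INFO)
    out[hit] <- sub(paste0(".*", key, "="), "",
                    regmatches(fix$INFO, regexpr(paste0(key, "=[^;]*"), fix$INFO)))
    out
  }
  gt <- vcfR::extract.gt(v)
  samples <- colnames(gt)
  chrom <- sub("^chr", "", fix$CHROM)
  state <- function(g, s, ch) {
    g <- sub("\\|", "/", g)
    male <- !is.null(sex) && identical(unname(sex[s]), "male")
    if (is.na(g) || g %in% c(".", "./.")) return("missing")
    if (g == "0") return(if (ch == "X" && male) "hemi_ref" else "hom_ref")
    if (g == "1") return(if (ch == "X" && male) "hemi_alt" else "hom_alt")
    if (g == "0/0") return("hom_ref")
    if (g %in% c("0/1", "1/0")) {
      if (ch == "X" && male) { warning("male X diploid het set to missing"); return("missing") }
      return("het")
    }
    if (g == "1/1") return("hom_alt")
    "missing"
  }
  geno <- matrix("missing", nrow(fix), length(samples),
                 dimnames = list(NULL, samples))
  for (s in samples)
    geno[, s] <- mapply(state, gt[, s], s, chrom)
  mq <- suppressWarnings(as.numeric(info_field("MQ")))
  cons <- info_field("CSQ")
  variants <- data.frame(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(chrom, ":", fix$POS, "_", fix$REF, ">", fix$ALT), fix$ID),
    chrom = chrom, pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    gene = info_field("GENE"),
    consequence = ifelse(is.na(cons), "noncoding", cons),
    variant_class = ifelse(nchar(fix$REF) == 1 & nchar(fix$ALT) == 1, "snp", "indel"),
    mapping_quality = mq, known_variant = !is.na(fix$ID) & fix$ID != ".",
    stringsAsFactors = FALSE)
  variant_table(variants, geno)
}

#' Write a variant table as TSV
#'
#' Inverse of the TSV dialect of [read_variants()]; missing values are
#' written as `"."`.
#'
#' @param vt A [variant_table()].
#' @param path Output path.
#' @export
write_variants_tsv <- function(vt, path) {
  df <- vt$variants
  geno <- vt$geno
  geno[geno == "missing"] <- NA
  out <- cbind(df, as.data.frame(geno, stringsAsFactors = FALSE))
  write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE, na = ".")
  invisible(NULL)
}

#' Read a common-variant sites catalog
#'
#' Accepts a headerless 4-column TSV (chrom, pos, ref, alt) or a sites-only
#' VCF; used by [remove_known()].
#'
#' @param path Input file.
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
read_sites_catalog <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "##fileformat=VCF")) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    return(data.frame(chrom = sub("^chr", "", fix$CHROM), pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE))
  }
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("sites catalog needs 4 columns: chrom, pos, ref, alt")
  data.frame(chrom = as.character(df[[1]]), pos = as.integer(df[[2]]),
             ref = df[[3]], alt = df[[4]], stringsAsFactors = FALSE)
}

#' Write ROH segments as BED
#'
#' BED intervals are 0-based half-open; the segment name is the sample id
#' and the score column carries the marker count.
#'
#' @param segments Output of [detect_roh()].
#' @param path Output path.
#' @export
write_roh_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom,
                    start = segments$start_bp - 1L, end = segments$end_bp,
                    name = segments$sample_id, score = segments$n_markers)
  write.table(bed, path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Read ROH segments from BED
#'
#' @param path BED file written by [write_roh_bed()].
#' @return Data frame with 1-based inclusive `start_bp`/`end_bp`.
#' @export
read_roh_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = as.character(df[[1]]), start_bp = as.integer(df[[2]]) + 1L,
             end_bp = as.integer(df[[3]]), sample_id = df[[4]],
             n_markers = as.integer(df[[5]]), stringsAsFactors = FALSE)
}

#' Apply Sequenom-style validation genotypes to a variant table
#'
#' Each validation row refers to one (variant, sample) assay with an
#' `assay_status` (`designed`/`design_failed`), a `run_status`
#' (`ran`/`failed`, defined only when designed) and a `genotype_call`
#' (defined only when ran).  Where a call exists it replaces the
#' sequencing genotype.  A variant survives into the candidate stream only
#' when its proband assay was designed, ran, and confirmed the homozygous
#' (or hemizygous) alternate genotype; contradicted variants are flagged
#' `not_validated` and removed.  Discordant validation calls in other
#' family members replace the genotype but are only logged.
#'
#' @param vt A [variant_table()].
#' @param validation Data frame with columns `variant_id`, `sample`,
#'   `assay_status`, `run_status`, `genotype_call`.
#' @param proband Proband sample id.
#' @return List with `variants` (surviving [variant_table()]), `status`
#'   (per-variant status: `validated`, `not_validated`, `not_run`,
#'   `not_designed`, `no_assay`), and `removed` (ids).
#' @export
apply_validation <- function(vt, validation, proband) {
  stopifnot(all(c("variant_id", "sample", "assay_status", "run_status",
                  "genotype_call") %in% names(validation)))
  unknown <- setdiff(validation$variant_id, vt$variants$id)
  if (length(unknown))
    warning("validation call(s) for unknown variant(s): ",
            paste(unique(unknown), collapse = ", "))
  geno <- vt$geno
  has_call <- !is.na(validation$genotype_call) & validation$run_status %in% "ran" &
    validation$assay_status == "designed" & validation$variant_id %in% rownames(geno)
  for (k in which(has_call)) {
    vid <- validation$variant_id[k]; s <- validation$sample[k]
    if (!s %in% colnames(geno)) next
    old <- geno[vid, s]
    new <- validation$genotype_call[k]
    if (old != new && s != proband)
      message("validation call for ", vid, " in ", s, " replaces ", old, " with ", new)
    geno[vid, s] <- new
  }
  status <- setNames(rep("no_assay", nrow(vt$variants)), vt$variants$id)
  pv <- validation[validation$sample == proband &
                     validation$variant_id %in% vt$variants$id, , drop = FALSE]
  for (k in seq_len(nrow(pv))) {
    vid <- pv$variant_id[k]
    status[vid] <- if (pv$assay_status[k] != "designed") "not_designed"
      else if (!identical(pv$run_status[k], "ran")) "not_run"
      else if (pv$genotype_call[k] %in% c("hom_alt", "hemi_alt")) "validated"
      else "not_validated"
  }
  keep <- names(status)[status == "validated"]
  out <- variant_table(vt$variants, geno)
  list(variants = out[out$variants$id %in% keep],
       status = data.frame(id = names(status), status = unname(status),
                           stringsAsFactors = FALSE),
       removed = setdiff(vt$variants$id, keep))
}
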