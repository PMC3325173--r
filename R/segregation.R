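# Per-family Mendelian segregation tests.  Verdicts:
#   segregates            every member condition holds
#   segregates_incomplete consistent, but an informative genotype is missing
#   fails                 a member condition is violated
#   unphaseable           compound het whose parental origin cannot be fixed
#   mendel_error          transmission-impossible genotype configuration

new_verdict <- function(model, verdict, detail, variants = NULL) {
  structure(list(model = model, verdict = verdict, detail = detail,
                 variants = variants),
            class = "segregation_verdict")
}

#' @export
print.segregation_verdict <- function(x, ...) {
  cat(sprintf("[%s] %s: %s\n", x$model, x$verdict, x$detail))
  invisible(x)
}

carries_alt <- function(g) g %in% c("het", "hom_alt", "hemi_alt")

# collapse monozygotic twin groups to one informative genotype each
collapse_mz <- function(ids, mz_twins) {
  if (is.null(mz_twins)) return(ids)
  for (grp in mz_twins) {
    present <- intersect(grp, ids)
    if (length(present) > 1) ids <- setdiff(ids, present[-1])
  }
  ids
}

#' Homozygous-recessive segregation test
#'
#' Segregates when every affected child is homozygous alternate, both
#' parents are heterozygous, and no unaffected sibling is homozygous
#' alternate.  A parent homozygous reference with a homozygous-alternate
#' affected child is a Mendelian error.  Missing genotypes in informative
#' members downgrade the verdict to `segregates_incomplete`.
#'
#' @param genotypes Named genotype-state vector for one variant (sample ->
#'   state, see [variant_table()]).
#' @param ped A [pedigree()] containing the nuclear family.
#' @param mz_twins Optional list of character vectors, each a group of
#'   monozygotic siblings counted as one informative genotype.
#' @return A `segregation_verdict`.
#' @export
segregate_hom_recessive <- function(genotypes, ped, mz_twins = NULL) {
  roles <- family_roles(ped)
  aff <- collapse_mz(roles$affected, mz_twins)
  una <- roles$unaffected
  g <- function(s) if (s %in% names(genotypes)) genotypes[[s]] else "missing"
  gf <- g(roles$father); gmo <- g(roles$mother)
  ga <- vapply(aff, g, character(1))
  gu <- vapply(una, g, character(1))

  if (any(ga == "hom_alt") && (gf == "hom_ref" || gmo == "hom_ref"))
    return(new_verdict("hom_recessive", "mendel_error",
                       "a hom_ref parent cannot transmit to a hom_alt child"))
  if (any(ga %in% c("hom_ref", "het")))
    return(new_verdict("hom_recessive", "fails",
                       "an affected child is not homozygous alternate"))
  if (any(gu == "hom_alt"))
    return(new_verdict("hom_recessive", "fails",
                       "an unaffected sibling is homozygous alternate"))
  if (gf %in% c("hom_alt") || gmo %in% c("hom_alt"))
    return(new_verdict("hom_recessive", "fails", "a parent is homozygous alternate"))
  incomplete <- any(ga == "missing") || gf == "missing" || gmo == "missing"
  if (!incomplete && gf == "het" && gmo == "het")
    return(new_verdict("hom_recessive", "segregates",
                       "affected hom_alt, parents het, no unaffected hom_alt"))
  if (incomplete && all(ga %in% c("hom_alt", "missing")) &&
      gf %in% c("het", "missing") && gmo %in% c("het", "missing"))
    return(new_verdict("hom_recessive", "segregates_incomplete",
                       "consistent, but informative genotype(s) missing"))
  new_verdict("hom_recessive", "fails", "parental genotypes inconsistent with carrier status")
}

#' Compound-heterozygote phasing and segregation test
#'
#' For every pair of heterozygous proband variants in one gene, parental
#' origin is assigned by carrier status (a variant carried by exactly one
#' parent is phased to that parent).  The gene segregates when at least one
#' pair is in trans (one variant from each parent), every affected sibling
#' carries both variants of that pair, and no unaffected sibling carries
#' both.  Pairs with both variants from the same parent are cis (fail);
#' pairs with an untransmitted or ambiguous variant are unphaseable.
#'
#' @param gene_vt A [variant_table()] holding the proband-heterozygous
#'   variants of one gene (>= 2 rows).
#' @param ped A [pedigree()].
#' @param mz_twins See [segregate_hom_recessive()].
#' @return A `segregation_verdict`; `$variants` names the passing trans pair.
#' @export
phase_compound_het <- function(gene_vt, ped, mz_twins = NULL) {
  stopifnot(n_variants(gene_vt) >= 2)
  roles <- family_roles(ped)
  aff <- collapse_mz(roles$affected, mz_twins)
  ids <- gene_vt$variants$id
  g <- function(vid, s) {
    if (!s %in% colnames(gene_vt$geno)) return("missing")
    gene_vt$geno[vid, s]
  }
  origin <- vapply(ids, function(vid) {
    fa <- carries_alt(g(vid, roles$father)); mo <- carries_alt(g(vid, roles$mother))
    fam <- g(vid, roles$father) == "missing"; mom <- g(vid, roles$mother) == "missing"
    if (fam && mom) return("unknown")
    if (fa && !mo) return("paternal")
    if (mo && !fa) return("maternal")
    if (fa && mo) return("ambiguous")
    "untransmitted"
  }, character(1))

  pairs <- utils::combn(ids, 2)
  any_cis <- FALSE; any_unphaseable <- FALSE; any_incomplete_pair <- NULL
  for (k in seq_len(ncol(pairs))) {
    v1 <- pairs[1, k]; v2 <- pairs[2, k]
    o1 <- origin[v1]; o2 <- origin[v2]
    if (any(c(o1, o2) %in% c("ambiguous", "untransmitted", "unknown"))) {
      any_unphaseable <- TRUE; next
    }
    if (o1 == o2) { any_cis <- TRUE; next }
    ga1 <- vapply(aff, function(s) g(v1, s), character(1))
    ga2 <- vapply(aff, function(s) g(v2, s), character(1))
    if (any(ga1 %in% c("hom_ref", "hom_alt")) || any(ga2 %in% c("hom_ref", "hom_alt")))
      next  # an affected sibling does not carry the het pair
    blocked <- FALSE
    for (u in roles$unaffected) {
      if (carries_alt(g(v1, u)) && carries_alt(g(v2, u))) { blocked <- TRUE; break }
    }
    if (blocked) next
    if (any(ga1 == "missing") || any(ga2 == "missing")) {
      any_incomplete_pair <- c(v1, v2); next
    }
    return(new_verdict("compound_het", "segregates",
                       sprintf("trans pair %s (paternal) / %s (maternal)",
                               if (o1 == "paternal") v1 else v2,
                               if (o1 == "maternal") v1 else v2),
                       variants = c(v1, v2)))
  }
  if (!is.null(any_incomplete_pair))
    return(new_verdict("compound_het", "segregates_incomplete",
                       "trans pair consistent but affected genotype(s) missing",
                       variants = any_incomplete_pair))
  if (any_cis && !any_unphaseable)
    return(new_verdict("compound_het", "fails", "variant pair(s) in cis"))
  if (any_unphaseable)
    return(new_verdict("compound_het", "unphaseable",
                       "parental origin ambiguous or untransmitted"))
  new_verdict("compound_het", "fails",
              "no trans pair shared by affected and absent from unaffected siblings")
}

#' X-linked hemizygous segregation test
#'
#' Segregates when all affected males are hemizygous alternate, the mother
#' is heterozygous, the father is hemizygous reference (or missing), and no
#' unaffected brother is hemizygous alternate.  A homozygous-reference
#' mother with a hemizygous-alternate son is a Mendelian error (possible
#' de novo or cell-line artifact).
#'
#' @inheritParams segregate_hom_recessive
#' @return A `segregation_verdict`.
#' @export
segregate_x_linked <- function(genotypes, ped, mz_twins = NULL) {
  roles <- family_roles(ped)
  aff_m <- collapse_mz(roles$affected[roles$sex[roles$affected] == "male"], mz_twins)
  if (!length(aff_m))
    return(new_verdict("x_linked", "fails", "no affected male in sibship"))
  g <- function(s) if (s %in% names(genotypes)) genotypes[[s]] else "missing"
  ga <- vapply(aff_m, g, character(1))
  gmo <- g(roles$mother); gfa <- g(roles$father)
  if (gmo == "hom_ref" && any(ga == "hemi_alt"))
    return(new_verdict("x_linked", "mendel_error",
                       "hom_ref mother with hemi_alt son (possible de novo/artifact)"))
  if (any(ga == "hemi_ref"))
    return(new_verdict("x_linked", "fails", "an affected male is hemizygous reference"))
  una_m <- roles$unaffected[roles$sex[roles$unaffected] == "male"]
  if (any(vapply(una_m, g, character(1)) == "hemi_alt"))
    return(new_verdict("x_linked", "fails", "an unaffected brother is hemizygous alternate"))
  if (gfa == "hemi_alt")
    return(new_verdict("x_linked", "fails", "father carries the variant"))
  if (gmo %in% c("hom_alt"))
    return(new_verdict("x_linked", "fails", "mother is homozygous alternate"))
  incomplete <- any(ga == "missing") || gmo == "missing"
  if (!incomplete && gmo == "het")
    return(new_verdict("x_linked", "segregates",
                       "affected males hemi_alt, inherited from heterozygous mother"))
  if (incomplete && all(ga %in% c("hemi_alt", "missing")) && gmo %in% c("het", "missing"))
    return(new_verdict("x_linked", "segregates_incomplete",
                       "consistent, but informative genotype(s) missing"))
  new_verdict("x_linked", "fails", "maternal genotype inconsistent with carrier status")
}

#' Run a segregation model over a candidate stream
#'
#' @param candidates A [variant_table()] (hom-recessive or X-linked
#'   stream), or a named list of per-gene tables (compound-het stream from
#'   [candidate_compound_het()]).
#' @param ped A [pedigree()].
#' @param model `"hom_recessive"`, `"compound_het"` or `"x_linked"`.
#' @param mz_twins See [segregate_hom_recessive()].
#' @return Data frame of verdicts (per variant, or per gene for the
#'   compound-het model).
#' @export
segregate_variants <- function(candidates, ped,
                               model = c("hom_recessive", "compound_het", "x_linked"),
                               mz_twins = NULL) {
  model <- match.arg(model)
  if (model == "compound_het") {
    rows <- lapply(names(candidates), function(g) {
      v <- phase_compound_het(candidates[[g]], ped, mz_twins)
      data.frame(gene = g, model = v$model, verdict = v$verdict, detail = v$detail,
                 variants = paste(v$variants, collapse = ","),
                 stringsAsFactors = FALSE)
    })
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(gene = character(0), model = character(0), verdict = character(0),
                 detail = character(0), variants = character(0))
    return(out)
  }
  fun <- if (model == "hom_recessive") segregate_hom_recessive else segregate_x_linked
  rows <- lapply(candidates$variants$id, function(vid) {
    v <- fun(vt_geno(candidates, vid), ped, mz_twins)
    data.frame(variant_id = vid, gene = candidates$variants$gene[
                 match(vid, candidates$variants$id)],
               chrom = candidates$variants$chrom[match(vid, candidates$variants$id)],
               pos = candidates$variants$pos[match(vid, candidates$variants$id)],
               model = v$model, verdict = v$verdict, detail = v$detail,
               stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(0), gene = character(0), chrom = character(0),
               pos = integer(0), model = character(0), verdict = character(0),
               detail = character(0))
}
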