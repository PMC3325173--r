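#' Construct a pedigree
#'
#' A pedigree is a data frame with one row per individual.  Founders have
#' `NA` parent entries; all parent references must resolve to members of the
#' same family, the parent graph must be acyclic, and fathers must be male
#' (mothers female) wherever sex is recorded.
#'
#' @param family_id Single family label.
#' @param id Character vector of unique individual identifiers.
#' @param father,mother Parent identifiers (`NA` for founders).
#' @param sex `"male"`, `"female"` or `NA`.
#' @param affection `"affected"`, `"unaffected"` or `"unknown"`.
#' @return A `data.frame` of class `"pedigree"`.
#' @export
pedigree <- function(family_id, id, father = NA_character_, mother = NA_character_,
                     sex = NA_character_, affection = "unknown") {
  n <- length(id)
  ped <- data.frame(
    family_id = rep_len(as.character(family_id), n),
    id        = as.character(id),
    father    = rep_len(as.character(father), n),
    mother    = rep_len(as.character(mother), n),
    sex       = rep_len(as.character(sex), n),
    affection = rep_len(as.character(affection), n),
    stringsAsFactors = FALSE
  )
  validate_pedigree(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) stop("duplicate individual ids in pedigree")
  resolves <- function(p) all(is.na(p) | p %in% ped$id)
  if (!resolves(ped$father) || !resolves(ped$mother))
    stop("parent references must be NA or resolve to pedigree members")
  if (!all(is.na(ped$sex) | ped$sex %in% c("male", "female")))
    stop("sex must be 'male', 'female' or NA")
  if (!all(ped$affection %in% c("affected", "unaffected", "unknown")))
    stop("affection must be 'affected', 'unaffected' or 'unknown'")
  fsex <- ped$sex[match(ped$father, ped$id)]
  msex <- ped$sex[match(ped$mother, ped$id)]
  if (any(!is.na(fsex) & fsex == "female"))
    stop("a father is recorded as female")
  if (any(!is.na(msex) & msex == "male"))
    stop("a mother is recorded as male")
  ped_depth(ped)  # errors on cycles
  invisible(ped)
}

# Generation depth (founders = 0); errors if the parent graph has a cycle.
ped_depth <- function(ped) {
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  depth <- rep(NA_real_, n)
  for (pass in seq_len(n + 1L)) {
    progressed <- FALSE
    for (i in seq_len(n)) {
      if (!is.na(depth[i])) next
      df <- if (is.na(fa[i])) 0 else depth[fa[i]]
      dm <- if (is.na(mo[i])) 0 else depth[mo[i]]
      if (is.na(df) || is.na(dm)) next
      depth[i] <- if (is.na(fa[i]) && is.na(mo[i])) 0 else 1 + max(df, dm)
      progressed <- TRUE
    }
    if (!anyNA(depth)) break
    if (!progressed) stop("pedigree contains a cycle (an individual is its own ancestor)")
  }
  setNames(depth, ped$id)
}

#' Kinship coefficient between two pedigree members
#'
#' Recursive kinship: phi(a, a) = (1 + F(a)) / 2 where F(a) is a's
#' inbreeding coefficient, and phi(a, b) = (phi(father_a, b) +
#' phi(mother_a, b)) / 2, recursing through whichever of the pair lies
#' deeper in the pedigree (which therefore cannot be an ancestor of the
#' other).  Missing parent links contribute 0.
#'
#' @param ped A [pedigree()].
#' @param a,b Individual ids.
#' @return The kinship coefficient, a probability in \[0, 1\].
#' @export
kinship_coef <- function(ped, a, b) {
  stopifnot(a %in% ped$id, b %in% ped$id)
  depth <- ped_depth(ped)
  fa <- setNames(ped$father, ped$id)
  mo <- setNames(ped$mother, ped$id)
  memo <- new.env(parent = emptyenv())
  phi <- function(x, y) {
    if (is.na(x) || is.na(y)) return(0)
    key <- paste(sort(c(x, y)), collapse = "\r")
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    if (x == y) {
      v <- 0.5 * (1 + phi(fa[[x]], mo[[x]]))
    } else {
      if (depth[[x]] < depth[[y]]) { tmp <- x; x <- y; y <- tmp }
      v <- 0.5 * (phi(fa[[x]], y) + phi(mo[[x]], y))
    }
    memo[[key]] <- v
    v
  }
  phi(a, b)
}

#' Pedigree inbreeding coefficient
#'
#' F of an individual is the kinship coefficient of its parents: the
#' probability that its two alleles at a locus are identical by descent.
#' Offspring of first cousins have F = 1/16 (6.25% expected genome-wide
#' autozygosity); offspring of second cousins F = 1/64 (~1.6%).
#'
#' @param ped A [pedigree()].
#' @param individual Individual id.
#' @return F, a real in \[0, 1\]; 0 if either parent link is missing.
#' @export
inbreeding_coefficient <- function(ped, individual) {
  i <- match(individual, ped$id)
  if (is.na(i)) stop("individual '", individual, "' not in pedigree")
  fa <- ped$father[i]; mo <- ped$mother[i]
  if (is.na(fa) || is.na(mo)) return(0)
  kinship_coef(ped, fa, mo)
}

#' Nuclear-family pedigree with a cousin loop between the parents
#'
#' Builds a family in which the two parents are `degree`-th cousins
#' (degree 1 = first cousins sharing a grandparental couple, degree 2 =
#' second cousins sharing a great-grandparental couple), with a sibship of
#' affected and unaffected children.
#'
#' @param degree Cousin degree of the parental pair (>= 1).
#' @param n_affected,n_unaffected Numbers of affected / unaffected children.
#' @param family_id Family label.
#' @param child_sex Optional character vector of child sexes; defaults to
#'   male for affected and alternating female/male for unaffected children.
#' @return A [pedigree()].  The children are named `CH1`, `CH2`, ...;
#'   the parents are `L1_<degree>` (father) and `L2_<degree>` (mother).
#' @export
make_cousin_pedigree <- function(degree = 1, n_affected = 2, n_unaffected = 1,
                                 family_id = "FAM1", child_sex = NULL) {
  stopifnot(degree >= 1, n_affected >= 1, n_unaffected >= 0)
  id <- c("ANC_M", "ANC_F"); father <- c(NA, NA); mother <- c(NA, NA)
  sex <- c("male", "female"); aff <- c("unaffected", "unaffected")
  add <- function(i, f, m, s) {
    id <<- c(id, i); father <<- c(father, f); mother <<- c(mother, m)
    sex <<- c(sex, s); aff <<- c(aff, "unaffected")
  }
  add("L1_0", "ANC_M", "ANC_F", "male")
  add("L2_0", "ANC_M", "ANC_F", "female")
  cur <- c("L1_0", "L2_0")
  for (g in seq_len(degree)) {
    for (k in 1:2) {
      s_ch <- if (k == 1) "male" else "female"
      s_sp <- if (s_ch == "male") "female" else "male"
      sp <- sprintf("L%d_%d_SP", k, g)
      ch <- sprintf("L%d_%d", k, g)
      add(sp, NA, NA, s_sp)
      if (s_ch == "male") add(ch, cur[k], sp, s_ch) else add(ch, sp, cur[k], s_ch)
    }
    cur <- c(sprintf("L1_%d", g), sprintf("L2_%d", g))
  }
  n_ch <- n_affected + n_unaffected
  if (is.null(child_sex)) {
    child_sex <- c(rep("male", n_affected),
                   rep_len(c("female", "male"), n_unaffected))
  }
  stopifnot(length(child_sex) == n_ch)
  for (j in seq_len(n_ch)) {
    add(sprintf("CH%d", j), cur[1], cur[2], child_sex[j])
    aff[length(aff)] <- if (j <= n_affected) "affected" else "unaffected"
  }
  pedigree(family_id, id, father, mother, sex, aff)
}

#' Outbred nuclear-family pedigree
#'
#' @inheritParams make_cousin_pedigree
#' @return A [pedigree()] with founder parents `FA` and `MO`.
#' @export
make_outbred_pedigree <- function(n_affected = 2, n_unaffected = 1,
                                  family_id = "FAM1", child_sex = NULL) {
  n_ch <- n_affected + n_unaffected
  if (is.null(child_sex)) {
    child_sex <- c(rep("male", n_affected),
                   rep_len(c("female", "male"), n_unaffected))
  }
  stopifnot(length(child_sex) == n_ch)
  pedigree(family_id,
           id        = c("FA", "MO", sprintf("CH%d", seq_len(n_ch))),
           father    = c(NA, NA, rep("FA", n_ch)),
           mother    = c(NA, NA, rep("MO", n_ch)),
           sex       = c("male", "female", child_sex),
           affection = c("unaffected", "unaffected",
                         rep(c("affected", "unaffected"),
                             c(n_affected, n_unaffected))))
}

# Children of the focal sibship and their parents; assumes one nuclear
# sibship of interest (the affected children and their full siblings).
family_roles <- function(ped) {
  aff <- ped$id[ped$affection == "affected" & !is.na(ped$father) & !is.na(ped$mother)]
  if (length(aff) == 0) stop("pedigree has no affected non-founder individual")
  i <- match(aff[1], ped$id)
  fa <- ped$father[i]; mo <- ped$mother[i]
  sibs <- ped$id[!is.na(ped$father) & !is.na(ped$mother) &
                   ped$father == fa & ped$mother == mo]
  list(father = fa, mother = mo,
       affected = sibs[ped$affection[match(sibs, ped$id)] == "affected"],
       unaffected = sibs[ped$affection[match(sibs, ped$id)] == "unaffected"],
       sex = setNames(ped$sex, ped$id)[sibs])
}

pedigree_founders <- function(ped) ped$id[is.na(ped$father) & is.na(ped$mother)]
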