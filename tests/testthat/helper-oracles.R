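# Independent oracles and fixture builders shared across the suite.

# --- small genotype-matrix fixture ---------------------------------------

make_gm <- function(calls, spacing = 0.5, chrom = NULL, sex = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  if (is.null(chrom)) chrom <- rep("1", n)
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("S", seq_len(ncol(calls)))
  cM <- stats::ave(seq_len(n), chrom, FUN = function(i) (seq_along(i) - 1) * spacing)
  bp <- stats::ave(seq_len(n), chrom, FUN = function(i) seq_along(i) * 1000L)
  map <- data.frame(marker_id = paste0("m", seq_len(n)), chrom = chrom,
                    bp = as.integer(bp), cM = cM, stringsAsFactors = FALSE)
  genotype_matrix(calls, map, sex = sex)
}

# --- brute-force ROH oracle ----------------------------------------------
# Enumerates every hom-bounded interval, tests the tolerance rules
# directly, keeps maximal intervals, then applies the length/marker floors.

roh_oracle <- function(g, cM, p) {
  n <- length(g)
  hom <- !is.na(g) & g != 1L
  het <- !is.na(g) & g == 1L
  cs <- c(0L, cumsum(het))
  w <- p$window_size
  valid <- function(i, j) {
    h <- het[i:j]
    r <- rle(h)
    if (any(r$values & r$lengths > p$max_consecutive_het)) return(FALSE)
    len <- j - i + 1L
    if (len >= w) {
      k <- i:(j - w + 1L)
      if (any(cs[k + w] - cs[k] > p$max_het_per_window)) return(FALSE)
    }
    TRUE
  }
  homs <- which(hom)
  if (!length(homs)) return(NULL)
  # furthest valid end for each start, by direct checking
  best <- integer(0); starts <- integer(0)
  for (i in homs) {
    jmax <- NA_integer_
    for (j in rev(homs[homs >= i])) {
      if (valid(i, j)) { jmax <- j; break }
    }
    if (!is.na(jmax)) { starts <- c(starts, i); best <- c(best, jmax) }
  }
  keep <- logical(length(starts))
  for (k in seq_along(starts))
    keep[k] <- !any(starts < starts[k] & best >= best[k])
  m <- cbind(starts[keep], best[keep])
  m <- m[!duplicated(m[, 2]), , drop = FALSE]
  m <- m[cM[m[, 2]] - cM[m[, 1]] > p$min_length_cM &
           (m[, 2] - m[, 1] + 1L) >= p$min_markers, , drop = FALSE]
  if (!nrow(m)) return(NULL)
  m[order(m[, 1]), , drop = FALSE]
}

expect_roh_matches_oracle <- function(gm, sample, p) {
  segs <- detect_roh(gm, sample, p)
  imp <- if (nrow(segs))
    unname(cbind(segs$first_marker_index, segs$last_marker_index)) else NULL
  o <- roh_oracle(gm$calls[, sample], gm$map$cM, p)
  if (is.null(o)) {
    expect_true(is.null(imp) || nrow(imp) == 0)
  } else {
    expect_equal(imp, unname(o))
  }
}

# --- hand-rolled translation oracle --------------------------------------
# Standard nuclear genetic code written out directly (TCAG nesting order),
# independent of the Biostrings table used by the implementation.

.codon_bases <- c("T", "C", "A", "G")
.codon_aas <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")[[1]]
.codon_table <- stats::setNames(.codon_aas, paste0(
  rep(.codon_bases, each = 16), rep(rep(.codon_bases, each = 4), 4),
  rep(.codon_bases, 16)))

oracle_translate <- function(seq) {
  n <- nchar(seq) %/% 3
  codons <- substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
  paste(.codon_table[codons], collapse = "")
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Full-CDS classification oracle: splice window check, then indel frame
# arithmetic, then whole-protein translation before/after the edit.
oracle_classify <- function(pos, ref, alt, model, w = 2) {
  ex <- model$exons
  if (pos < min(ex$start) || pos > max(ex$end)) return("noncoding")
  if (nrow(ex) > 1 && w > 0) {
    for (i in seq_len(nrow(ex) - 1)) {
      is_ <- ex$end[i] + 1; ie <- ex$start[i + 1] - 1
      if ((pos >= is_ && pos <= min(is_ + w - 1, ie)) ||
          (pos <= ie && pos >= max(ie - w + 1, is_))) return("splice_site")
    }
  }
  in_exon <- any(pos >= ex$start & pos <= ex$end)
  if (!in_exon) return("noncoding")
  if (pos < model$cds_start || pos > model$cds_end) return("noncoding")
  if (nchar(ref) != nchar(alt)) {
    d <- nchar(alt) - nchar(ref)
    return(if (d %% 3 != 0) "frameshift" else "coding_nonsynonymous")
  }
  cdsp <- unlist(lapply(seq_len(nrow(ex)), function(i) {
    lo <- max(ex$start[i], model$cds_start); hi <- min(ex$end[i], model$cds_end)
    if (lo > hi) integer(0) else lo:hi
  }))
  cdsp <- sort(cdsp)
  if (!pos %in% cdsp) return("noncoding")
  base <- function(p) substr(model$seq, p - model$seq_start + 1, p - model$seq_start + 1)
  cds_old <- paste(vapply(cdsp, base, character(1)), collapse = "")
  cds_new <- paste(vapply(cdsp, function(p) if (p == pos) alt else base(p),
                          character(1)), collapse = "")
  if (model$strand == "-") {
    cds_old <- oracle_revcomp(cds_old); cds_new <- oracle_revcomp(cds_new)
  }
  if (identical(oracle_translate(cds_old), oracle_translate(cds_new)))
    "coding_synonymous" else "coding_nonsynonymous"
}

random_transcript <- function() {
  L <- 240L
  sq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  n_ex <- sample(1:3, 1)
  cuts <- sort(sample(10:(L - 10), 2 * n_ex))
  exons <- data.frame(start = cuts[seq(1, 2 * n_ex, 2)],
                      end = cuts[seq(2, 2 * n_ex, 2)])
  # widen intron gaps so splice windows are well defined
  exonic <- unlist(mapply(seq, exons$start, exons$end, SIMPLIFY = FALSE))
  cds_lo <- sample(exonic[exonic <= stats::quantile(exonic, 0.4)], 1)
  cds_hi <- sample(exonic[exonic >= stats::quantile(exonic, 0.6)], 1)
  n_cds <- sum(exonic >= cds_lo & exonic <= cds_hi)
  while (n_cds %% 3 != 0 && cds_hi > cds_lo) {
    cds_hi <- max(exonic[exonic < cds_hi])
    n_cds <- sum(exonic >= cds_lo & exonic <= cds_hi)
  }
  if (n_cds < 3) return(NULL)
  transcript_model("GENE", "1", sample(c("+", "-"), 1), exons, cds_lo, cds_hi,
                   sq, seq_start = 1)
}

random_variant_for <- function(model) {
  span <- range(model$exons$start, model$exons$end)
  pos <- sample(max(1, span[1] - 5):(span[2] + 5), 1)
  if (stats::runif(1) < 0.7) {
    ref <- substr(model$seq, pos - model$seq_start + 1, pos - model$seq_start + 1)
    if (ref == "" || is.na(ref)) ref <- "A"
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  } else {
    k <- sample(1:4, 1)
    ref <- substr(model$seq, pos - model$seq_start + 1, pos - model$seq_start + k + 1)
    if (nchar(ref) < 2) ref <- "AC"
    alt <- substr(ref, 1, 1)
  }
  list(pos = pos, ref = ref, alt = alt)
}

# --- exact hypergeometric enumeration oracle for the one-tailed test ------

fisher_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c; n <- a + b
  ks <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= a])
}

# --- tiny variant-table builder ------------------------------------------

make_vt <- function(df, geno) {
  defaults <- list(ref = "C", alt = "T", gene = "GENE1",
                   consequence = "coding_nonsynonymous", variant_class = "snp",
                   mapping_quality = 60, known_variant = FALSE)
  for (col in names(defaults))
    if (is.null(df[[col]])) df[[col]] <- defaults[[col]]
  if (is.null(df$chrom)) df$chrom <- "1"
  if (is.null(df$pos)) df$pos <- seq_len(nrow(df)) * 100L
  if (is.null(df$id)) df$id <- paste0("v", seq_len(nrow(df)))
  variant_table(df, geno)
}
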