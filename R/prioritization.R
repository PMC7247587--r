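#' Compute FPKM from fragment counts
#'
#' `fpkm[i, j] = counts[i, j] * 1e9 / (colsum(counts)[j] * length[i])`,
#' with the exonic length being the union of exon intervals per locus.
#'
#' @param counts integer matrix (loci x samples).
#' @param exonic_length_bp named vector of exonic lengths (bp) covering all
#'   rows of `counts`.
#' @return Numeric FPKM matrix with the same dimnames.
#' @export
compute_fpkm <- function(counts, exonic_length_bp) {
  if (is.null(rownames(counts))) stopf("counts must have locus ids as rownames")
  len <- exonic_length_bp[rownames(counts)]
  if (anyNA(len)) stopf("missing exonic length for some loci")
  if (any(len <= 0)) stopf("exonic lengths must be positive")
  cs <- colSums(counts)
  if (any(cs == 0)) stopf("sample with zero total counts")
  sweep(counts, 2, cs, "/") * 1e9 / len
}

#' Minimal-expression filter
#'
#' A locus is retained if it exceeds `threshold` FPKM (strictly) in at least
#' `min_animals` samples of at least one group.
#'
#' @param fpkm FPKM matrix.
#' @param design design data.frame (`sample`, `group`).
#' @param threshold FPKM threshold (default 0.1).
#' @param min_animals minimum samples above threshold within one group
#'   (default 6).
#' @return Character vector of retained locus ids.
#' @export
minimal_expression_filter <- function(fpkm, design, threshold = 0.1,
                                      min_animals = 6) {
  groups <- unique(design$group)
  keep <- rep(FALSE, nrow(fpkm))
  for (g in groups) {
    cols <- design$sample[design$group == g]
    if (length(cols) < min_animals)
      stopf("group %s has fewer than %d samples", g, min_animals)
    keep <- keep | rowSums(fpkm[, cols, drop = FALSE] > threshold) >= min_animals
  }
  rownames(fpkm)[keep]
}

#' Remove loci with excluded biotypes
#'
#' @param ann an `annotation_set`.
#' @param excluded_biotypes biotype labels to discard (ribosomal,
#'   spliceosomal, SRP-class and Y RNAs by default).
#' @return A filtered `annotation_set`.
#' @export
biotype_exclusion <- function(ann,
                              excluded_biotypes = c("rRNA",
                                                    "snRNA-spliceosomal",
                                                    "SRP-RNA", "Y-RNA")) {
  drop <- ann$loci$biotype %in% excluded_biotypes
  if (!any(drop)) return(ann)
  keep_loc <- ann$loci$locus_id[!drop]
  t2 <- ann$transcripts[ann$transcripts$locus_id %in% keep_loc, , drop = FALSE]
  e2 <- ann$exons[ann$exons$transcript_id %in% t2$transcript_id, , drop = FALSE]
  out <- annotation_set(ann$loci[!drop, , drop = FALSE], t2, e2)
  attr(out, "extra_attributes") <- attr(ann, "extra_attributes")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control; order preserving.
#'
#' @param p vector of raw p-values.
#' @return Vector of BH-adjusted p-values (q-values).
#' @export
benjamini_hochberg <- function(p) {
  p.adjust(p, method = "BH")
}

#' Differential expression between two groups (NB Wald test)
#'
#' Per-locus negative-binomial Wald test: median-of-ratios size factors,
#' method-of-moments dispersion (floored at 1e-8, no shrinkage), Wald
#' statistic on the log ratio of normalised group means with model-based
#' standard errors, BH correction. This is a deliberately simple,
#' self-contained test whose downstream contract is only `(log2fc, q)`;
#' positive `log2fc` means higher abundance in the first (high) group.
#'
#' @param counts integer matrix (loci x samples).
#' @param design design data.frame; the group ordered first in
#'   `levels = c("high", "low")` convention is taken from `high_group`.
#' @param alpha_q significance threshold on q (default 0.1).
#' @param high_group label of the numerator group (default `"high"`).
#' @return data.frame: `locus_id`, `log2fc`, `p`, `q`, `significant`.
#' @export
differential_expression <- function(counts, design, alpha_q = 0.1,
                                    high_group = "high") {
  groups <- unique(design$group)
  if (length(groups) != 2) stopf("exactly two groups required")
  if (!high_group %in% groups) high_group <- groups[1]
  low_group <- setdiff(groups, high_group)
  counts <- counts[, design$sample, drop = FALSE]
  g1 <- design$group == high_group
  g2 <- design$group == low_group
  n1 <- sum(g1); n2 <- sum(g2)

  # median-of-ratios size factors (pseudo-count for zero robustness)
  lgm <- rowMeans(log(counts + 0.5))
  sf <- apply(counts, 2, function(col) exp(median(log(col + 0.5) - lgm)))
  sf <- sf / exp(mean(log(sf)))
  k <- sweep(counts, 2, sf, "/")

  m1 <- rowMeans(k[, g1, drop = FALSE])
  m2 <- rowMeans(k[, g2, drop = FALSE])
  v1 <- apply(k[, g1, drop = FALSE], 1, var)
  v2 <- apply(k[, g2, drop = FALSE], 1, var)
  # pooled method-of-moments dispersion: Var = mu + alpha mu^2 within group
  alpha <- ((n1 - 1) * (v1 - m1) + (n2 - 1) * (v2 - m2)) /
    ((n1 - 1) * m1^2 + (n2 - 1) * m2^2)
  alpha[!is.finite(alpha)] <- 0
  alpha <- pmax(alpha, 1e-8)

  ps <- 0.5
  lfc <- log2((m1 + ps) / (m2 + ps))
  V1 <- (m1 * sum(1 / sf[g1]) + alpha * m1^2 * n1) / n1^2
  V2 <- (m2 * sum(1 / sf[g2]) + alpha * m2^2 * n2) / n2^2
  W <- (log(m1 + ps) - log(m2 + ps)) /
    sqrt(V1 / (m1 + ps)^2 + V2 / (m2 + ps)^2)
  # t reference with n - 2 df: small-sample correction of the Wald normal
  p <- 2 * pt(-abs(W), df = n1 + n2 - 2)
  zero <- rowSums(counts) == 0
  p[zero] <- 1; lfc[zero] <- 0
  q <- benjamini_hochberg(p)
  data.frame(locus_id = rownames(counts), log2fc = lfc, p = p, q = q,
             significant = q <= alpha_q, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' QTL proximity category
#'
#' Loci overlapping or within `max_distance_bp` (gap distance, boundary
#' inclusive) of a QTL interval on the same chromosome.
#'
#' @param ann an `annotation_set`.
#' @param qtl QTL data.frame ([read_qtl_bed()] format, 1-based inclusive).
#' @param max_distance_bp proximity rule (default 3 Mb).
#' @return list with `linked` (character vector of locus ids) and
#'   `direct_overlap` (subset with distance 0).
#' @export
qtl_category <- function(ann, qtl, max_distance_bp = 3e6) {
  gl <- loci_granges(ann)
  gq <- GenomicRanges::GRanges(qtl$chrom, IRanges::IRanges(qtl$start, qtl$end))
  # expand QTL by the proximity rule; coordinate-difference distance means
  # a locus whose edge is exactly max_distance_bp away still qualifies
  gq_ext <- suppressWarnings(GenomicRanges::resize(
    gq, GenomicRanges::width(gq) + 2 * max_distance_bp, fix = "center"))
  ov <- GenomicRanges::findOverlaps(gl, gq_ext, ignore.strand = TRUE)
  linked <- unique(gl$locus_id[S4Vectors::queryHits(ov)])
  ov0 <- GenomicRanges::findOverlaps(gl, gq, ignore.strand = TRUE)
  direct <- unique(gl$locus_id[S4Vectors::queryHits(ov0)])
  list(linked = linked, direct_overlap = direct)
}

#' Partner-gene category
#'
#' Loci predicted as the best positional interaction partner (`is_best = 1`)
#' of any lncRNA.
#'
#' @param classification classification data.frame
#'   ([read_feelnc_table()] format).
#' @return Character vector of partner locus ids (unique).
#' @export
partner_category <- function(classification) {
  unique(classification$partner_locus_id[classification$is_best == 1])
}

#' lncRNA category
#'
#' Loci with at least one transcript classified as lncRNA.
#'
#' @param classification classification data.frame.
#' @return Character vector of lncRNA locus ids (unique).
#' @export
lncRNA_category <- function(classification) {
  unique(classification$lncRNA_locus_id)
}

#' Build the prioritized loci set
#'
#' Union of the four categories (lncRNA, partner, QTL, DE) intersected with
#' the minimally expressed loci; a locus can carry several category flags.
#'
#' @param lnc_ids,partner_ids,qtl_ids,de_ids character vectors of category
#'   members (DE ids should already be the significant set).
#' @param min_expressed character vector of loci passing
#'   [minimal_expression_filter()].
#' @return data.frame: `locus_id`, logical `is_lncRNA`, `is_partner`,
#'   `is_qtl`, `is_de`, `is_min_expressed` (all TRUE).
#' @export
build_prioritized_set <- function(lnc_ids, partner_ids, qtl_ids, de_ids,
                                  min_expressed) {
  members <- intersect(unique(c(lnc_ids, partner_ids, qtl_ids, de_ids)),
                       min_expressed)
  out <- data.frame(
    locus_id = members,
    is_lncRNA = members %in% lnc_ids,
    is_partner = members %in% partner_ids,
    is_qtl = members %in% qtl_ids,
    is_de = members %in% de_ids,
    is_min_expressed = TRUE,
    stringsAsFactors = FALSE)
  stopifnot(all(out$is_lncRNA | out$is_partner | out$is_qtl | out$is_de))
  out
}
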