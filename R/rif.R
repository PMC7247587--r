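#' Regulatory impact factor scores
#'
#' Scores each candidate regulator by its wiring to a set of target loci
#' contrasted between two groups. With `e1_j`, `e2_j` the mean FPKM of
#' target `j` in each group, `a_j = (e1_j + e2_j) / 2`, and `r1_ij`,
#' `r2_ij` the within-group Pearson correlations of regulator `i` with
#' target `j`:
#' \deqn{RIF1_i = (1/n_t) \sum_j a_j (r1_{ij} - r2_{ij})^2}
#' \deqn{RIF2_i = (1/n_t) \sum_j [(e1_j r1_{ij})^2 - (e2_j r2_{ij})^2]}
#' RIF1 rewards abundance-weighted differential wiring; RIF2 contrasts the
#' abundance-weighted squared co-expression between conditions. Raw scores
#' are z-standardised over regulators and a regulator is significant when
#' either absolute z-score reaches `z_threshold`. A regulator that is
#' itself a target is excluded from its own sum. Correlations are computed
#' on raw (untransformed) FPKM; zero-variance profiles contribute
#' correlation 0 with a warning.
#'
#' @param fpkm FPKM matrix covering regulators and targets.
#' @param design design data.frame (`sample`, `group`).
#' @param regulators character vector of candidate regulator locus ids.
#' @param targets character vector of target locus ids.
#' @param z_threshold significance threshold on |z| (default 1.96).
#' @param high_group group treated as condition 1 (default `"high"`).
#' @param pif_weight if TRUE, RIF1 uses the differential-abundance weighted
#'   variant `a_j * (e1_j - e2_j)` instead of `a_j` (default FALSE).
#' @return data.frame: `locus_id`, `rif1_raw`, `rif2_raw`, `rif1_z`,
#'   `rif2_z`, `significant`.
#' @export
compute_rif <- function(fpkm, design, regulators, targets,
                        z_threshold = 1.96, high_group = "high",
                        pif_weight = FALSE) {
  regulators <- intersect(regulators, rownames(fpkm))
  targets <- intersect(targets, rownames(fpkm))
  if (!length(regulators)) stopf("no regulators present in the FPKM matrix")
  if (!length(targets)) stopf("no targets present in the FPKM matrix")
  s1 <- design$sample[design$group == high_group]
  s2 <- design$sample[design$group != high_group]
  if (length(s1) < 3 || length(s2) < 3)
    stopf("each group needs at least 3 samples for correlations")
  X1 <- t(fpkm[regulators, s1, drop = FALSE])
  X2 <- t(fpkm[regulators, s2, drop = FALSE])
  Y1 <- t(fpkm[targets, s1, drop = FALSE])
  Y2 <- t(fpkm[targets, s2, drop = FALSE])
  R1 <- safe_cor(X1, Y1)
  R2 <- safe_cor(X2, Y2)
  nz <- attr(R1, "n_zero_var") + attr(R2, "n_zero_var")
  if (nz > 0)
    warnf("%d regulator-target pairs involved a zero-variance profile; their correlations were set to 0", nz)
  e1 <- colMeans(Y1); e2 <- colMeans(Y2)
  abar <- (e1 + e2) / 2
  w1 <- if (pif_weight) abar * (e1 - e2) else abar
  D2 <- (R1 - R2)^2
  S1 <- D2 %*% w1
  S2 <- R1^2 %*% (e1^2) - R2^2 %*% (e2^2)
  nt <- rep(length(targets), length(regulators))
  self <- match(regulators, targets)
  has_self <- !is.na(self)
  if (any(has_self)) {
    ii <- which(has_self)
    S1[ii] <- S1[ii] - D2[cbind(ii, self[ii])] * w1[self[ii]]
    S2[ii] <- S2[ii] - (R1[cbind(ii, self[ii])]^2 * e1[self[ii]]^2 -
                          R2[cbind(ii, self[ii])]^2 * e2[self[ii]]^2)
    nt[ii] <- nt[ii] - 1L
  }
  rif1 <- as.vector(S1) / nt
  rif2 <- as.vector(S2) / nt
  z1 <- as.vector(scale(rif1))
  z2 <- as.vector(scale(rif2))
  if (length(regulators) < 2) z1 <- z2 <- rep(0, length(regulators))
  data.frame(locus_id = regulators, rif1_raw = rif1, rif2_raw = rif2,
             rif1_z = z1, rif2_z = z2,
             significant = abs(z1) >= z_threshold | abs(z2) >= z_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select key lncRNAs from RIF results
#'
#' @param rif data.frame from [compute_rif()].
#' @param z_threshold absolute z threshold (default 1.96, the two-sided
#'   standard-normal critical value at p = 0.05).
#' @return Character vector of significant regulator ids.
#' @export
select_key_lncRNAs <- function(rif, z_threshold = 1.96) {
  if (!nrow(rif)) return(character())
  rif$locus_id[abs(rif$rif1_z) >= z_threshold |
                 abs(rif$rif2_z) >= z_threshold]
}
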