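#' Generalised log2 transform
#'
#' `glog2(x) = log2((x + sqrt(x^2 + c)) / 2)`, a variance-stabilising
#' transform that behaves like `log2(x)` for large `x` and is defined at 0.
#'
#' @param x numeric values.
#' @param c positive stabilisation constant.
#' @return Transformed values.
#' @export
glog2 <- function(x, c) {
  log2((x + sqrt(x^2 + c)) / 2)
}

# k-nearest-neighbour imputation across metabolite rows: Euclidean distance
# on shared observed samples, mean of the k nearest rows observed at the
# missing cell; falls back to the row mean when no neighbour qualifies
knn_impute_rows <- function(m, k = 10) {
  obs <- !is.na(m)
  out <- m
  nr <- nrow(m)
  for (i in which(rowSums(!obs) > 0)) {
    miss_j <- which(!obs[i, ])
    d <- rep(NA_real_, nr)
    for (o in seq_len(nr)) {
      if (o == i) next
      shared <- obs[i, ] & obs[o, ]
      if (sum(shared) < 2) next
      d[o] <- sqrt(sum((m[i, shared] - m[o, shared])^2) / sum(shared))
    }
    for (j in miss_j) {
      cand <- which(!is.na(d) & obs[, j])
      if (!length(cand)) {
        out[i, j] <- mean(m[i, ], na.rm = TRUE)
      } else {
        nb <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
        out[i, j] <- mean(m[nb, j])
      }
    }
  }
  out
}

#' Differential metabolite abundance between two groups
#'
#' Excludes compounds with more than `missing_frac` missing cells, imputes
#' the remainder by k-nearest-neighbour over metabolite profiles, applies a
#' generalised-log variance stabilisation (`glog2` with
#' `c = median(per-metabolite minima)^2`), tests with an equal-variance
#' two-sample t-test and corrects with Benjamini-Hochberg. The fold change
#' is computed on the imputed raw values. A compound is flagged significant
#' when `q <= alpha_q` and `|log2fc| >= min_abs_lfc`.
#'
#' @param metab metabolite x sample matrix (may contain `NA`).
#' @param design design data.frame (`sample`, `group`).
#' @param missing_frac exclusion threshold on the missing fraction
#'   (strictly greater than; default 0.4).
#' @param knn_k neighbours for imputation (default 10).
#' @param alpha_q significance threshold on q (default 0.05).
#' @param min_abs_lfc absolute log2 fold-change threshold (default 1).
#' @param high_group numerator group label (default `"high"`).
#' @return data.frame: `metabolite`, `log2fc`, `p`, `q`, `significant`.
#' @export
differential_abundance <- function(metab, design, missing_frac = 0.4,
                                   knn_k = 10, alpha_q = 0.05,
                                   min_abs_lfc = 1, high_group = "high") {
  metab <- metab[, design$sample, drop = FALSE]
  frac <- rowMeans(is.na(metab))
  keep <- frac <= missing_frac
  m <- metab[keep, , drop = FALSE]
  if (!nrow(m)) stopf("no metabolite passes the missingness filter")
  imp <- knn_impute_rows(m, k = knn_k)
  cst <- median(apply(imp, 1, min))^2
  tr <- glog2(imp, cst)
  g1 <- design$group == high_group
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(tr[, g1, drop = FALSE]); m2 <- rowMeans(tr[, g2, drop = FALSE])
  v1 <- apply(tr[, g1, drop = FALSE], 1, var)
  v2 <- apply(tr[, g2, drop = FALSE], 1, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(tstat), df = n1 + n2 - 2)
  p[sp2 == 0] <- 1
  lfc <- log2(rowMeans(imp[, g1, drop = FALSE]) /
                rowMeans(imp[, g2, drop = FALSE]))
  q <- benjamini_hochberg(p)
  data.frame(metabolite = rownames(m), log2fc = lfc, p = p, q = q,
             significant = q <= alpha_q & abs(lfc) >= min_abs_lfc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Principal component analysis of a metabolite matrix
#'
#' SVD-based PCA on the centred, transformed matrix with samples as
#' observations.
#'
#' @param metab metabolite x sample matrix (imputed and transformed; no
#'   `NA`).
#' @return list with `scores` (samples x components) and
#'   `explained_variance` (fractions summing to 1).
#' @export
metabolite_pca <- function(metab) {
  if (anyNA(metab)) stopf("PCA input must be imputed (no NA)")
  pc <- prcomp(t(metab), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, explained_variance = ev)
}

#' Prepare metabolites for correlation analysis
#'
#' Keeps compounds with fewer than `max_missing_cases` missing cells
#' (strictly), imputes each missing cell with that compound's minimum
#' observed value (below-detection-limit assumption) and scales each row by
#' its root mean square (denominator n - 1, no centring), the behaviour of
#' `scale(x, center = FALSE)`.
#'
#' @param metab metabolite x sample matrix (may contain `NA`).
#' @param max_missing_cases strict upper bound on missing cells (default 5).
#' @return Scaled matrix without missing values.
#' @export
prepare_metabolites_for_correlation <- function(metab, max_missing_cases = 5) {
  nmiss <- rowSums(is.na(metab))
  keep <- nmiss < max_missing_cases & nmiss < ncol(metab)
  m <- metab[keep, , drop = FALSE]
  for (i in seq_len(nrow(m))) {
    mi <- is.na(m[i, ])
    if (any(mi)) m[i, mi] <- min(m[i, !mi])
  }
  rms <- sqrt(rowSums(m^2) / (ncol(m) - 1))
  zero <- rms == 0
  if (any(zero)) {
    m <- m[!zero, , drop = FALSE]
    rms <- rms[!zero]
  }
  m / rms
}
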