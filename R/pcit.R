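#' Pearson correlation matrix over a locus set
#'
#' Correlations across all retained samples (groups pooled) on raw FPKM.
#' Zero-variance loci are dropped with a warning.
#'
#' @param fpkm FPKM matrix (loci x samples), restricted to the loci of
#'   interest.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(fpkm) {
  sds <- apply(fpkm, 1, sd)
  zero <- sds == 0 | is.na(sds)
  if (any(zero)) {
    warnf("dropping %d zero-variance loci from the correlation matrix",
          sum(zero))
    fpkm <- fpkm[!zero, , drop = FALSE]
  }
  r <- cor(t(fpkm))
  diag(r) <- 1
  r
}

#' PCIT edge selection
#'
#' Applies the partial-correlation-and-information-theory procedure: for
#' every unordered trio of loci the first-order partial correlations define
#' a tolerance `eps` (mean ratio of partial to direct correlation), and a
#' pair is eliminated by a third locus when both of its direct correlations
#' through that locus exceed the tolerance-scaled pair correlation
#' (strict inequalities; ties keep the edge). An edge survives iff no third
#' locus eliminates it.
#'
#' With fewer than 3 loci all pairs are kept with a warning.
#'
#' @param corr symmetric correlation matrix with dimnames.
#' @return data.frame of all pairs: `id_a`, `id_b` (canonical order
#'   `id_a < id_b`), `r`, `kept`.
#' @export
pcit_filter <- function(corr) {
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-12)))
    stopf("correlation matrix must be symmetric")
  ids <- rownames(corr) %||% as.character(seq_len(nrow(corr)))
  n <- nrow(corr)
  if (n < 3) {
    warnf("fewer than 3 loci: all pairs kept")
    keep <- matrix(TRUE, n, n)
  } else {
    keep <- .pcit_keep_cpp(corr)
  }
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  a <- ids[ut[, 1]]; b <- ids[ut[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(id_a = a, id_b = b, r = corr[ut],
                    kept = keep[ut], stringsAsFactors = FALSE)
  out[order(out$id_a, out$id_b), , drop = FALSE]
}

#' Filter PCIT edges for the co-expression network
#'
#' Retains kept edges with `|r| >= min_abs_r` (boundary inclusive) and at
#' least one endpoint among the key lncRNAs.
#'
#' @param edges data.frame from [pcit_filter()].
#' @param rif_keys character vector of key lncRNA ids.
#' @param min_abs_r minimal absolute correlation (default 0.65).
#' @return Filtered edge data.frame.
#' @export
filter_network_edges <- function(edges, rif_keys, min_abs_r = 0.65) {
  sel <- edges$kept & abs(edges$r) >= min_abs_r &
    (edges$id_a %in% rif_keys | edges$id_b %in% rif_keys)
  out <- edges[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}
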