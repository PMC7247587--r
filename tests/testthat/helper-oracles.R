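# independent reference implementations used as oracles

# Benjamini-Hochberg step-up, written directly from the definition:
# q_(i) = min_{j >= i} min(1, m p_(j) / j) on the sorted p-values
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, m * ps / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

# cell-by-cell FPKM recomputation
fpkm_oracle <- function(counts, len) {
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (j in seq_len(ncol(counts))) {
    tot <- sum(counts[, j])
    for (i in seq_len(nrow(counts)))
      out[i, j] <- counts[i, j] * 1e9 / (tot * len[rownames(counts)[i]])
  }
  out
}

# naive PCIT: explicit loops over unordered trios, straight from the
# recurrences; returns logical keep matrix
pcit_oracle <- function(r) {
  n <- nrow(r)
  keep <- matrix(TRUE, n, n)
  if (n < 3) return(keep)
  rc <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  for (x in 1:(n - 2)) for (y in (x + 1):(n - 1)) for (z in (y + 1):n) {
    rxy <- rc[x, y]; rxz <- rc[x, z]; ryz <- rc[y, z]
    pxy <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    pxz <- (rxz - rxy * ryz) / sqrt((1 - rxy^2) * (1 - ryz^2))
    pyz <- (ryz - rxy * rxz) / sqrt((1 - rxy^2) * (1 - rxz^2))
    term <- function(pp, rr) if (abs(rr) < 1e-12) 0 else pp / rr
    eps <- (term(pxy, rxy) + term(pxz, rxz) + term(pyz, ryz)) / 3
    ae <- abs(eps)
    if (abs(rxy) < ae * abs(rxz) && abs(rxy) < ae * abs(ryz))
      keep[x, y] <- keep[y, x] <- FALSE
    if (abs(rxz) < ae * abs(rxy) && abs(rxz) < ae * abs(ryz))
      keep[x, z] <- keep[z, x] <- FALSE
    if (abs(ryz) < ae * abs(rxy) && abs(ryz) < ae * abs(rxz))
      keep[y, z] <- keep[z, y] <- FALSE
  }
  keep
}

# oracle keep flags arranged in the same canonical pair order that
# pcit_filter() reports (id_a < id_b, sorted by id_a then id_b)
pcit_oracle_edges <- function(r) {
  keep <- pcit_oracle(r)
  ids <- rownames(r)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  df <- data.frame(id_a = ids[ut[, 1]], id_b = ids[ut[, 2]],
                   kept = keep[ut], stringsAsFactors = FALSE)
  df[order(df$id_a, df$id_b), , drop = FALSE]
}

# brute-force distance scan for interval proximity
qtl_brute_scan <- function(loci, qtl, max_bp) {
  hits <- character()
  for (i in seq_len(nrow(loci))) {
    for (k in seq_len(nrow(qtl))) {
      if (loci$chrom[i] != qtl$chrom[k]) next
      d <- max(0, qtl$start[k] - loci$end[i], loci$start[i] - qtl$end[k])
      if (d <= max_bp) { hits <- c(hits, loci$locus_id[i]); break }
    }
  }
  hits
}

# random correlation matrix from random data
random_corr <- function(n, m = 20, seed = 1) {
  set.seed(seed)
  cor(matrix(rnorm(n * m), m, n))
}
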