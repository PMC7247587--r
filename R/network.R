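#' Correlations between key lncRNAs and metabolites
#'
#' Pearson correlation for every key-lncRNA x metabolite pair over the
#' shared samples; two-sided p-values from
#' `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2 degrees of freedom. A
#' pair is retained when `p <= p_max` and `|r| >= min_abs_r`.
#'
#' @param metab scaled metabolite matrix
#'   ([prepare_metabolites_for_correlation()] output).
#' @param fpkm FPKM matrix restricted to key lncRNAs.
#' @param p_max p-value threshold (default 0.01).
#' @param min_abs_r absolute correlation threshold (default 0.65).
#' @return data.frame: `lncRNA_id`, `metabolite`, `r`, `p`, `significant`.
#' @export
metabolite_locus_correlations <- function(metab, fpkm, p_max = 0.01,
                                          min_abs_r = 0.65) {
  common <- intersect(colnames(metab), colnames(fpkm))
  if (length(common) < 4) stopf("need at least 4 shared samples")
  n <- length(common)
  R <- safe_cor(t(fpkm[, common, drop = FALSE]),
                t(metab[, common, drop = FALSE]))
  r <- as.vector(R)
  rr <- clamp(r, -1 + 1e-15, 1 - 1e-15)
  tt <- rr * sqrt((n - 2) / (1 - rr^2))
  p <- 2 * pt(-abs(tt), df = n - 2)
  out <- data.frame(
    lncRNA_id = rep(rownames(fpkm), times = nrow(metab)),
    metabolite = rep(rownames(metab), each = nrow(fpkm)),
    r = r, p = p,
    significant = p <= p_max & abs(r) >= min_abs_r,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble the co-expression network
#'
#' Combines locus-locus edges (PCIT-kept, filtered) with significant
#' locus-metabolite edges and locus metadata into a `coexpression_network`
#' object. Duplicate edges are removed; node and edge tables are ordered
#' deterministically.
#'
#' @param locus_edges data.frame from [filter_network_edges()].
#' @param metab_edges data.frame from [metabolite_locus_correlations()]
#'   (only rows with `significant = TRUE` are used), or NULL.
#' @param prioritized data.frame from [build_prioritized_set()].
#' @param ann an `annotation_set` (for symbols/biotypes).
#' @param rif_keys character vector of key lncRNA ids.
#' @return `coexpression_network`: list with `nodes` and `edges`
#'   data.frames.
#' @export
assemble_network <- function(locus_edges, metab_edges, prioritized, ann,
                             rif_keys) {
  le <- unique(locus_edges[, c("id_a", "id_b", "r")])
  le$edge_type <- rep("locus-locus", nrow(le))
  if (!is.null(metab_edges) && nrow(metab_edges)) {
    me <- metab_edges[metab_edges$significant, , drop = FALSE]
    if (nrow(me)) {
      me2 <- data.frame(id_a = me$lncRNA_id, id_b = me$metabolite, r = me$r,
                        edge_type = "locus-metabolite",
                        stringsAsFactors = FALSE)
      le <- rbind(le, unique(me2))
    }
  }
  locus_nodes <- unique(c(le$id_a[le$edge_type == "locus-locus"],
                          le$id_b[le$edge_type == "locus-locus"],
                          le$id_a[le$edge_type == "locus-metabolite"]))
  metab_nodes <- unique(le$id_b[le$edge_type == "locus-metabolite"])
  pi <- match(locus_nodes, prioritized$locus_id)
  ai <- match(locus_nodes, ann$loci$locus_id)
  nodes <- data.frame(
    node_id = c(locus_nodes, metab_nodes),
    node_type = rep(c("locus", "metabolite"),
                    c(length(locus_nodes), length(metab_nodes))),
    gene_symbol = c(ann$loci$gene_symbol[ai],
                    rep(NA_character_, length(metab_nodes))),
    is_lncRNA = c(prioritized$is_lncRNA[pi], rep(FALSE, length(metab_nodes))),
    is_partner = c(prioritized$is_partner[pi], rep(FALSE, length(metab_nodes))),
    is_qtl = c(prioritized$is_qtl[pi], rep(FALSE, length(metab_nodes))),
    is_de = c(prioritized$is_de[pi], rep(FALSE, length(metab_nodes))),
    is_key_lncRNA = c(locus_nodes %in% rif_keys,
                      rep(FALSE, length(metab_nodes))),
    stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$node_type, nodes$node_id), , drop = FALSE]
  le <- le[order(le$edge_type, le$id_a, le$id_b), , drop = FALSE]
  rownames(nodes) <- rownames(le) <- NULL
  structure(list(nodes = nodes, edges = le), class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d nodes (%d metabolites), %d edges (%d locus-metabolite)\n",
              nrow(x$nodes), sum(x$nodes$node_type == "metabolite"),
              nrow(x$edges), sum(x$edges$edge_type == "locus-metabolite")))
  invisible(x)
}

#' Verify the structural invariants of a network
#'
#' Independent checker: every locus-locus edge must have `|r| >= min_abs_r`
#' and a key-lncRNA endpoint; every locus-metabolite edge must have a
#' key-lncRNA locus endpoint; all edge endpoints must be nodes.
#'
#' @param net a `coexpression_network`.
#' @param min_abs_r threshold used at assembly (default 0.65).
#' @return TRUE (invisibly) or an error.
#' @export
validate_network <- function(net, min_abs_r = 0.65) {
  nd <- net$nodes; ed <- net$edges
  keys <- nd$node_id[nd$is_key_lncRNA]
  stopifnot(all(ed$id_a %in% nd$node_id), all(ed$id_b %in% nd$node_id))
  ll <- ed$edge_type == "locus-locus"
  stopifnot(all(abs(ed$r[ll]) >= min_abs_r))
  stopifnot(all(ed$id_a[ll] %in% keys | ed$id_b[ll] %in% keys))
  lm <- ed$edge_type == "locus-metabolite"
  stopifnot(all(ed$id_a[lm] %in% keys))
  invisible(TRUE)
}

#' Detect natural antisense transcripts among key lncRNAs
#'
#' NATs are key lncRNAs whose best positional partner lies in antisense
#' orientation at distance 0. Each pair is annotated with the PCIT
#' correlation to the partner when a kept edge exists (regardless of
#' strength) and with the partner/lncRNA mean-FPKM expression ratio over
#' all retained samples.
#'
#' @param rif_keys character vector of key lncRNA ids.
#' @param classification classification data.frame.
#' @param pcit_edges data.frame from [pcit_filter()] (kept flags used).
#' @param fpkm FPKM matrix covering lncRNAs and partners.
#' @return data.frame: `lncRNA_id`, `partner_id`, `r` (NA without a kept
#'   edge), `has_significant_edge`, `expression_ratio`.
#' @export
detect_nats <- function(rif_keys, classification, pcit_edges, fpkm) {
  cl <- classification[classification$is_best == 1 &
                         classification$direction == "antisense" &
                         classification$distance_bp == 0 &
                         classification$lncRNA_locus_id %in% rif_keys, ,
                       drop = FALSE]
  cl <- unique(cl[, c("lncRNA_locus_id", "partner_locus_id")])
  if (!nrow(cl))
    return(data.frame(lncRNA_id = character(), partner_id = character(),
                      r = numeric(), has_significant_edge = logical(),
                      expression_ratio = numeric()))
  kept <- pcit_edges[pcit_edges$kept, , drop = FALSE]
  key <- paste(pmin(kept$id_a, kept$id_b), pmax(kept$id_a, kept$id_b))
  want <- paste(pmin(cl$lncRNA_locus_id, cl$partner_locus_id),
                pmax(cl$lncRNA_locus_id, cl$partner_locus_id))
  mi <- match(want, key)
  ratio <- vapply(seq_len(nrow(cl)), function(k) {
    lm <- mean(fpkm[cl$lncRNA_locus_id[k], ])
    pm <- mean(fpkm[cl$partner_locus_id[k], ])
    pm / lm
  }, numeric(1))
  data.frame(lncRNA_id = cl$lncRNA_locus_id,
             partner_id = cl$partner_locus_id,
             r = ifelse(is.na(mi), NA_real_, kept$r[mi]),
             has_significant_edge = !is.na(mi),
             expression_ratio = ratio,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Detect cis-interactions of hub lncRNAs
#'
#' For each hub lncRNA, loci on the same chromosome within
#' `max_distance_bp` (gap distance, boundary inclusive) whose PCIT-kept
#' correlation with the lncRNA reaches `min_abs_r` in magnitude.
#' Orientation is reported relative to the lncRNA strand.
#'
#' @param hub_ids character vector of hub lncRNA ids.
#' @param ann an `annotation_set`.
#' @param pcit_edges data.frame from [pcit_filter()].
#' @param max_distance_bp distance rule (default 1 Mb).
#' @param min_abs_r correlation magnitude threshold (default 0.65).
#' @return data.frame: `lncRNA_id`, `partner_id`, `r`, `orientation`,
#'   `distance_bp`.
#' @export
detect_cis_interactions <- function(hub_ids, ann, pcit_edges,
                                    max_distance_bp = 1e6,
                                    min_abs_r = 0.65) {
  kept <- pcit_edges[pcit_edges$kept & abs(pcit_edges$r) >= min_abs_r, ,
                     drop = FALSE]
  loci <- ann$loci
  out <- list()
  for (h in intersect(hub_ids, loci$locus_id)) {
    sel <- kept$id_a == h | kept$id_b == h
    if (!any(sel)) next
    other <- ifelse(kept$id_a[sel] == h, kept$id_b[sel], kept$id_a[sel])
    r <- kept$r[sel]
    hi <- match(h, loci$locus_id)
    oi <- match(other, loci$locus_id)
    ok <- !is.na(oi) & loci$chrom[oi] == loci$chrom[hi]
    if (!any(ok)) next
    d <- gap_distance(loci$start[hi], loci$end[hi],
                      loci$start[oi[ok]], loci$end[oi[ok]])
    near <- d <= max_distance_bp
    if (!any(near)) next
    out[[h]] <- data.frame(
      lncRNA_id = h,
      partner_id = other[ok][near],
      r = r[ok][near],
      orientation = ifelse(loci$strand[oi[ok]][near] == loci$strand[hi],
                           "sense", "antisense"),
      distance_bp = d[near],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(lncRNA_id = character(), partner_id = character(),
                      r = numeric(), orientation = character(),
                      distance_bp = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$lncRNA_id, res$partner_id), , drop = FALSE]
}

#' Select hub lncRNAs from the network
#'
#' A hub is a key lncRNA connected to at least `min_gene_partners`
#' annotated genes (network partners carrying an official gene symbol and
#' not themselves lncRNAs) which additionally satisfies at least one of:
#' I) categorisation as a DE or QTL locus; II) correlation with at least
#' `min_metab_partners` metabolites; III) connectivity with more than
#' `high_connectivity` annotated genes.
#'
#' @param net a `coexpression_network`.
#' @param rif_keys character vector of key lncRNA ids.
#' @param prioritized data.frame from [build_prioritized_set()].
#' @param min_gene_partners connectivity gate (default 10).
#' @param min_metab_partners criterion II threshold (default 10).
#' @param high_connectivity criterion III threshold, strict > (default 50).
#' @return data.frame: `lncRNA_id`, `n_annotated_gene_partners`,
#'   `n_metabolite_partners`, `is_de`, `is_qtl`, `criteria` (string like
#'   "I,II"), `is_hub`.
#' @export
select_hubs <- function(net, rif_keys, prioritized,
                        min_gene_partners = 10, min_metab_partners = 10,
                        high_connectivity = 50) {
  nd <- net$nodes; ed <- net$edges
  annotated <- nd$node_id[nd$node_type == "locus" &
                            !is.na(nd$gene_symbol) & !nd$is_lncRNA]
  metabs <- nd$node_id[nd$node_type == "metabolite"]
  keys <- intersect(rif_keys, nd$node_id)
  rows <- lapply(keys, function(k) {
    sel <- ed$id_a == k | ed$id_b == k
    other <- ifelse(ed$id_a[sel] == k, ed$id_b[sel], ed$id_a[sel])
    ngene <- length(intersect(unique(other), annotated))
    nmet <- length(intersect(unique(other), metabs))
    pi <- match(k, prioritized$locus_id)
    isde <- isTRUE(prioritized$is_de[pi])
    isqtl <- isTRUE(prioritized$is_qtl[pi])
    crit <- c("I", "II", "III")[c(isde || isqtl,
                                  nmet >= min_metab_partners,
                                  ngene > high_connectivity)]
    data.frame(lncRNA_id = k, n_annotated_gene_partners = ngene,
               n_metabolite_partners = nmet, is_de = isde, is_qtl = isqtl,
               criteria = paste(crit, collapse = ","),
               is_hub = ngene >= min_gene_partners && length(crit) > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(lncRNA_id = character(),
                      n_annotated_gene_partners = integer(),
                      n_metabolite_partners = integer(), is_de = logical(),
                      is_qtl = logical(), criteria = character(),
                      is_hub = logical())
  rownames(out) <- NULL
  out[order(out$lncRNA_id), , drop = FALSE]
}

#' Export a network to GraphML and TSV
#'
#' Writes `network.graphml` (importable by Cytoscape and igraph),
#' `nodes.tsv` and `edges.tsv` with deterministic ordering.
#'
#' @param net a `coexpression_network`.
#' @param outdir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
export_network <- function(net, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  nodes <- net$nodes
  edges <- net$edges
  paths <- c(graphml = file.path(outdir, "network.graphml"),
             nodes = file.path(outdir, "nodes.tsv"),
             edges = file.path(outdir, "edges.tsv"))
  nd <- nodes
  nd$gene_symbol[is.na(nd$gene_symbol)] <- ""
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(
      edges[, c("id_a", "id_b", "r", "edge_type")],
      directed = FALSE,
      vertices = nd)
  } else {
    g <- igraph::make_empty_graph(directed = FALSE)
    if (nrow(nd)) g <- igraph::add_vertices(g, nrow(nd), name = nd$node_id)
  }
  igraph::write_graph(g, paths["graphml"], format = "graphml")
  write.table(nodes, paths["nodes"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(edges, paths["edges"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Summarise a pipeline run
#'
#' Machine-readable per-stage counts: category sizes, key lncRNAs, edge
#' counts with sign bookkeeping, NAT pairs (both reporting denominators),
#' hubs and cis-interactions, plus the pooled-mean identity check
#' (size-weighted group means against the overall mean).
#'
#' @param prioritized data.frame from [build_prioritized_set()].
#' @param rif data.frame from [compute_rif()].
#' @param net a `coexpression_network`.
#' @param nats data.frame from [detect_nats()].
#' @param hubs data.frame from [select_hubs()].
#' @param cis data.frame from [detect_cis_interactions()].
#' @param fpkm FPKM matrix (pooled-mean identity check).
#' @param design design data.frame.
#' @param metab_diff optional data.frame from [differential_abundance()].
#' @param high_group group treated as high (default `"high"`).
#' @return Nested list (JSON-ready run report).
#' @export
summarize_run <- function(prioritized, rif, net, nats, hubs, cis, fpkm,
                          design, metab_diff = NULL, high_group = "high") {
  ed <- net$edges
  pos <- sum(ed$r > 0); neg <- sum(ed$r < 0)
  s1 <- design$sample[design$group == high_group]
  s2 <- design$sample[design$group != high_group]
  pooled_dev <- max(abs(pooled_group_mean(rowMeans(fpkm[, s1, drop = FALSE]),
                                          rowMeans(fpkm[, s2, drop = FALSE]),
                                          length(s1), length(s2)) -
                          rowMeans(fpkm[, c(s1, s2), drop = FALSE])))
  n_keys <- sum(rif$significant)
  n_nat_sig <- sum(nats$has_significant_edge)
  hub_ids <- hubs$lncRNA_id[hubs$is_hub]
  n_hub_with_cis <- length(unique(cis$lncRNA_id[cis$lncRNA_id %in% hub_ids]))
  report <- list(
    prioritized = list(
      n_total = nrow(prioritized),
      n_lncRNA = sum(prioritized$is_lncRNA),
      n_partner = sum(prioritized$is_partner),
      n_qtl = sum(prioritized$is_qtl),
      n_de = sum(prioritized$is_de)),
    rif = list(n_regulators = nrow(rif), n_significant = n_keys),
    network = list(
      n_nodes = nrow(net$nodes),
      n_metabolite_nodes = sum(net$nodes$node_type == "metabolite"),
      n_edges = nrow(ed),
      n_positive = pos,
      n_negative = neg,
      pct_positive = if (nrow(ed)) 100 * pos / nrow(ed) else NA,
      sign_check = pos + neg == nrow(ed)),
    nats = list(
      n_nat_pairs = nrow(nats),
      n_with_significant_edge = n_nat_sig,
      n_positive_among_significant = sum(nats$r > 0, na.rm = TRUE),
      pct_of_nat_pairs = if (nrow(nats)) 100 * n_nat_sig / nrow(nats) else NA,
      pct_of_key_lncRNAs = if (n_keys) 100 * n_nat_sig / n_keys else NA),
    hubs = list(n_hubs = sum(hubs$is_hub),
                hub_ids = hub_ids),
    cis = list(n_interactions = nrow(cis),
               n_hubs_with_partner = n_hub_with_cis,
               mean_per_hub_with_partner =
                 if (n_hub_with_cis) nrow(cis) / n_hub_with_cis else NA),
    checks = list(max_pooled_mean_deviation = pooled_dev,
                  pooled_mean_ok = pooled_dev < 5e-4))
  if (!is.null(metab_diff))
    report$metabolites <- list(
      n_tested = nrow(metab_diff),
      n_differential = sum(metab_diff$significant))
  report
}
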