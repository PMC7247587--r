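test_that("metabolite correlation p-values follow the t transform", {
  design <- toy_design()
  set.seed(14)
  n <- 25
  fpkm <- matrix(rlnorm(2 * n, log(5), 0.5), 2, n,
                 dimnames = list(c("k1", "k2"), design$sample))
  met <- matrix(rlnorm(3 * n, 0, 0.4), 3, n,
                dimnames = list(c("mA", "mB", "mC"), design$sample))
  met["mA", ] <- fpkm["k1", ] * 2          # perfect correlation
  res <- metabolite_locus_correlations(met, fpkm)
  # closed-form check against cor.test for an arbitrary pair
  ct <- cor.test(fpkm["k2", ], met["mB", ])
  row <- res[res$lncRNA_id == "k2" & res$metabolite == "mB", ]
  expect_equal(row$r, unname(ct$estimate))
  expect_equal(row$p, ct$p.value, tolerance = 1e-12)
  expect_true(res$significant[res$lncRNA_id == "k1" &
                                res$metabolite == "mA"])
  # at n = 25, |r| = 0.65 already has p < 0.01: the magnitude rule dominates
  r0 <- 0.65
  p0 <- 2 * pt(-abs(r0 * sqrt((n - 2) / (1 - r0^2))), n - 2)
  expect_lt(p0, 0.01)
  # an exactly-zero correlation has p = 1
  x <- c(1, 2, 3, 4); y <- c(1, -1, -1, 1)
  expect_equal(cor(x, y), 0)
  f1 <- matrix(x, 1, dimnames = list("k", letters[1:4]))
  m1 <- matrix(y, 1, dimnames = list("m", letters[1:4]))
  expect_equal(metabolite_locus_correlations(m1, f1)$p, 1)
})

test_that("metabolite correlation p matches a permutation null", {
  set.seed(21)
  n <- 25
  x <- rnorm(n); y <- 0.5 * x + rnorm(n, sd = 0.9)
  f <- matrix(x, 1, dimnames = list("k", sprintf("s%02d", 1:n)))
  m <- matrix(y, 1, dimnames = list("m", sprintf("s%02d", 1:n)))
  p_par <- metabolite_locus_correlations(m, f)$p
  robs <- abs(cor(x, y))
  pperm <- mean(replicate(4000, abs(cor(x, sample(y))) >= robs))
  expect_lt(abs(p_par - pperm), 0.02)
})

test_that("network assembly deduplicates, types edges and validates", {
  pri <- data.frame(locus_id = c("k1", "g1", "g2"),
                    is_lncRNA = c(TRUE, FALSE, FALSE),
                    is_partner = c(FALSE, TRUE, TRUE),
                    is_qtl = FALSE, is_de = c(TRUE, FALSE, FALSE),
                    is_min_expressed = TRUE)
  ann <- toy_annotation(3)
  ann$loci$locus_id <- c("k1", "g1", "g2")
  ann$transcripts$locus_id <- c("k1", "g1", "g2")
  ann$loci$gene_symbol <- c(NA, "G1", "G2")
  ed <- data.frame(id_a = c("g1", "g1"), id_b = c("k1", "k1"),
                   r = 0.8, kept = TRUE)
  me <- data.frame(lncRNA_id = "k1", metabolite = "mA", r = 0.7, p = 0.001,
                   significant = TRUE)
  net <- assemble_network(ed, me, pri, ann, rif_keys = "k1")
  expect_equal(nrow(net$edges), 2)   # duplicate locus edge removed
  expect_setequal(net$edges$edge_type, c("locus-locus", "locus-metabolite"))
  expect_equal(sum(net$nodes$node_type == "metabolite"), 1)
  expect_true(validate_network(net))
  # no metabolite edges -> locus nodes only
  net2 <- assemble_network(ed, NULL, pri, ann, rif_keys = "k1")
  expect_true(all(net2$nodes$node_type == "locus"))
})

test_that("NAT detection keeps antisense distance-0 best partners only", {
  cls <- data.frame(
    lncRNA_transcript_id = c("t1", "t2", "t3", "t4"),
    lncRNA_locus_id = c("k1", "k2", "k3", "notkey"),
    partner_locus_id = c("pA", "pB", "pC", "pD"),
    direction = c("antisense", "sense", "antisense", "antisense"),
    type = c("genic", "genic", "intergenic", "genic"),
    subtype = "nested",
    distance_bp = c(0L, 0L, 5000L, 0L),
    is_best = 1L)
  ed <- data.frame(id_a = "k1", id_b = "pA", r = 0.42, kept = TRUE)
  design_samples <- sprintf("s%d", 1:4)
  fpkm <- matrix(1, 6, 4, dimnames = list(c("k1", "k2", "k3", "pA", "pB", "pC"),
                                          design_samples))
  fpkm["pA", ] <- 10; fpkm["k1", ] <- 0.25
  nats <- detect_nats(c("k1", "k2", "k3"), cls, ed, fpkm)
  # sense overlap and intergenic partners excluded; non-key excluded
  expect_equal(nats$lncRNA_id, "k1")
  # kept edge reported regardless of magnitude
  expect_equal(nats$r, 0.42)
  expect_true(nats$has_significant_edge)
  # expression ratio: partner mean 10 over lncRNA mean 0.25 -> 40
  expect_equal(nats$expression_ratio, 40)
})

test_that("cis-interactions respect the 1 Mb inclusive boundary", {
  loci <- data.frame(
    locus_id = c("hub", "at1mb", "past1mb", "other", "near"),
    chrom = c("1", "1", "1", "2", "1"),
    start = c(1000L, 1002000L, 1002001L, 1002000L, 5000L),
    end = c(2000L, 1003000L, 1003001L, 1003000L, 6000L),
    strand = c("+", "-", "+", "+", "+"),
    biotype = "protein_coding", gene_symbol = NA,
    is_reference_annotated = TRUE)
  tx <- data.frame(locus_id = loci$locus_id,
                   transcript_id = paste0(loci$locus_id, ".1"),
                   is_reference_annotated = TRUE)
  ex <- data.frame(transcript_id = tx$transcript_id, start = loci$start,
                   end = loci$end)
  ann <- annotation_set(loci, tx, ex)
  ed <- data.frame(id_a = rep("hub", 4),
                   id_b = c("at1mb", "past1mb", "other", "near"),
                   r = c(0.8, 0.9, 0.9, 0.5), kept = TRUE)
  cis <- detect_cis_interactions("hub", ann, ed)
  # gap to "at1mb" is exactly 1e6 -> included; 1 bp farther excluded;
  # other chromosome excluded; |r| < 0.65 excluded
  expect_equal(cis$partner_id, "at1mb")
  expect_equal(cis$orientation, "antisense")
  expect_equal(cis$distance_bp, 1e6)
  # brute-force scan over all pairs agrees
  brute <- with(loci, {
    ok <- chrom == "1" & locus_id != "hub" &
      gap_distance(1000, 2000, start, end) <= 1e6
    locus_id[ok]
  })
  strong <- ed$id_b[ed$kept & abs(ed$r) >= 0.65]
  expect_setequal(cis$partner_id, intersect(brute, strong))
})

test_that("hub selection applies the gene gate before criteria", {
  mknet <- function(ngene, nmet) {
    genes <- sprintf("g%02d", seq_len(ngene))
    mets <- if (nmet) sprintf("m%02d", seq_len(nmet)) else character()
    nodes <- data.frame(
      node_id = c("k1", genes, mets),
      node_type = rep(c("locus", "locus", "metabolite"),
                      c(1, ngene, length(mets))),
      gene_symbol = c(NA, toupper(genes), rep(NA, length(mets))),
      is_lncRNA = c(TRUE, rep(FALSE, ngene + length(mets))),
      is_partner = FALSE, is_qtl = FALSE,
      is_de = c(TRUE, rep(FALSE, ngene + length(mets))),
      is_key_lncRNA = c(TRUE, rep(FALSE, ngene + length(mets))))
    edges <- data.frame(
      id_a = "k1", id_b = c(genes, mets), r = 0.8,
      edge_type = rep(c("locus-locus", "locus-metabolite"),
                      c(ngene, length(mets))))
    structure(list(nodes = nodes, edges = edges),
              class = "coexpression_network")
  }
  pri <- data.frame(locus_id = "k1", is_lncRNA = TRUE, is_partner = FALSE,
                    is_qtl = FALSE, is_de = TRUE, is_min_expressed = TRUE)
  # 12 annotated gene partners + DE flag -> hub via criterion I
  h1 <- select_hubs(mknet(12, 0), "k1", pri)
  expect_true(h1$is_hub)
  expect_equal(h1$criteria, "I")
  # 9 gene partners and 30 metabolites: fails the >= 10 gene gate
  h2 <- select_hubs(mknet(9, 30), "k1", pri)
  expect_false(h2$is_hub)
  expect_true(grepl("II", h2$criteria))
  # 60 gene partners, not DE/QTL -> criterion III
  pri3 <- pri; pri3$is_de <- FALSE
  h3 <- select_hubs(mknet(60, 0), "k1", pri3)
  expect_true(h3$is_hub)
  expect_equal(h3$criteria, "III")
})

test_that("network export round-trips through igraph", {
  pri <- data.frame(locus_id = c("k1", "g1"), is_lncRNA = c(TRUE, FALSE),
                    is_partner = c(FALSE, TRUE), is_qtl = FALSE,
                    is_de = FALSE, is_min_expressed = TRUE)
  ann <- toy_annotation(2)
  ann$loci$locus_id <- ann$transcripts$locus_id <- c("k1", "g1")
  ed <- data.frame(id_a = "g1", id_b = "k1", r = 0.8, kept = TRUE)
  net <- assemble_network(ed, NULL, pri, ann, "k1")
  d <- withr::local_tempdir()
  paths <- export_network(net, d)
  g <- igraph::read_graph(paths["graphml"], format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  # empty network still exports valid files
  empty <- assemble_network(ed[0, ], NULL, pri[0, ], ann, character())
  p2 <- export_network(empty, file.path(d, "empty"))
  expect_true(all(file.exists(p2)))
  g2 <- igraph::read_graph(p2["graphml"], format = "graphml")
  expect_equal(igraph::vcount(g2), 0)
})

test_that("the run report keeps consistent bookkeeping", {
  st <- default_rif_stage()
  fx <- st$fx
  keys <- select_key_lncRNAs(st$rif)
  corr <- pearson_matrix(st$fpkm[st$pri$locus_id, ])
  ed <- pcit_filter(corr)
  nete <- filter_network_edges(ed, keys)
  net <- assemble_network(nete, NULL, st$pri, fx$annotation, keys)
  nats <- detect_nats(keys, fx$classification, ed, st$fpkm)
  hubs <- select_hubs(net, keys, st$pri)
  cis <- detect_cis_interactions(hubs$lncRNA_id[hubs$is_hub], fx$annotation,
                                 ed)
  rep <- summarize_run(st$pri, st$rif, net, nats, hubs, cis, st$fpkm,
                       fx$design)
  expect_true(rep$network$sign_check)
  expect_equal(rep$network$n_positive + rep$network$n_negative,
               rep$network$n_edges)
  # pooled-mean identity holds to numerical precision
  expect_true(rep$checks$pooled_mean_ok)
  expect_lt(rep$checks$max_pooled_mean_deviation, 5e-4)
  # positive NAT dominance among pairs with a surviving edge
  sig <- nats[nats$has_significant_edge, ]
  expect_gte(mean(sig$r > 0), 0.9)
})
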