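# shared fixtures, memoised per test run

.fixture_cache <- new.env(parent = emptyenv())

# the default study fixture (seed 1); ~5 s to build, reused across files
default_fixture <- function() {
  if (is.null(.fixture_cache$fx))
    .fixture_cache$fx <- generate_fixture(simulation_config(seed = 1))
  .fixture_cache$fx
}

default_fpkm <- function() {
  if (is.null(.fixture_cache$fpkm)) {
    fx <- default_fixture()
    .fixture_cache$fpkm <- compute_fpkm(fx$counts,
                                        exonic_lengths(fx$annotation))
  }
  .fixture_cache$fpkm
}

# prioritisation + RIF on the default fixture (used by several files)
default_rif_stage <- function() {
  if (is.null(.fixture_cache$rif_stage)) {
    fx <- default_fixture()
    fpkm <- default_fpkm()
    minx <- minimal_expression_filter(fpkm, fx$design)
    de <- differential_expression(fx$counts, fx$design)
    de_ids <- intersect(de$locus_id[de$significant], minx)
    qc <- qtl_category(fx$annotation, fx$qtl)
    pri <- build_prioritized_set(lncRNA_category(fx$classification),
                                 partner_category(fx$classification),
                                 qc$linked, de_ids, minx)
    regs <- pri$locus_id[pri$is_lncRNA]
    tgts <- pri$locus_id[pri$is_partner | pri$is_qtl | pri$is_de]
    rif <- suppressWarnings(compute_rif(fpkm, fx$design, regs, tgts))
    .fixture_cache$rif_stage <- list(fx = fx, fpkm = fpkm, pri = pri,
                                     regs = regs, tgts = tgts, rif = rif,
                                     de = de, min_expressed = minx)
  }
  .fixture_cache$rif_stage
}

# small hand-built annotation: n coding loci on one chromosome, fixed layout
toy_annotation <- function(n = 3, spacing = 10000, len = 2000,
                           chrom = "1", strand = NULL) {
  ids <- sprintf("G%02d", seq_len(n))
  start <- 1000 + (seq_len(n) - 1) * spacing
  loci <- data.frame(locus_id = ids, chrom = chrom, start = start,
                     end = start + len,
                     strand = strand %||% rep("+", n),
                     biotype = "protein_coding",
                     gene_symbol = toupper(ids),
                     is_reference_annotated = TRUE,
                     stringsAsFactors = FALSE)
  tx <- data.frame(locus_id = ids, transcript_id = paste0(ids, ".1"),
                   is_reference_annotated = TRUE, stringsAsFactors = FALSE)
  ex <- data.frame(transcript_id = paste0(ids, ".1"), start = start,
                   end = start + len, stringsAsFactors = FALSE)
  annotation_set(loci, tx, ex)
}

# random small annotation for round-trip properties
random_annotation <- function(seed) {
  cfg <- simulation_config(seed = seed, n_coding = 20L, n_lnc = 6L,
                           n_regulators = 2L, n_targets_per_regulator = 3L,
                           n_gate_partners = 4L, n_decoys = 3L,
                           n_filler = 2L, n_excluded_biotype = 1L,
                           n_qtl = 2L, de_fraction = 0.1,
                           n_metabolites = 10L, n_linked_metabolites = 3L,
                           n_da_metabolites = 2L,
                           n_high_missing_metabolites = 1L)
  generate_annotation(cfg)$annotation
}

# compact equality view of an annotation set (order-insensitive)
annotation_signature <- function(ann) {
  l <- ann$loci[order(ann$loci$locus_id), ]
  t <- ann$transcripts[order(ann$transcripts$transcript_id), ]
  e <- ann$exons[order(ann$exons$transcript_id, ann$exons$start), ]
  rownames(l) <- rownames(t) <- rownames(e) <- NULL
  list(l = l[, c("locus_id", "chrom", "start", "end", "strand", "biotype",
                 "gene_symbol")],
       t = t[, c("locus_id", "transcript_id")], e = e)
}

toy_design <- function(n1 = 12, n2 = 13) {
  data.frame(sample = c(sprintf("H%02d", seq_len(n1)),
                        sprintf("L%02d", seq_len(n2))),
             group = rep(c("high", "low"), c(n1, n2)),
             stringsAsFactors = FALSE)
}
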