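small_cfg <- function(seed = 1, ...) {
  args <- list(seed = seed, n_coding = 60L, n_lnc = 20L,
               n_regulators = 4L, n_targets_per_regulator = 6L,
               n_gate_partners = 8L, n_decoys = 6L, n_filler = 10L,
               n_excluded_biotype = 2L, n_qtl = 3L,
               n_metabolites = 12L, n_linked_metabolites = 4L,
               n_da_metabolites = 2L, n_high_missing_metabolites = 1L)
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}

test_that("configuration validation rejects impossible studies", {
  expect_error(simulation_config(n_high = 5), ">= 6")
  expect_error(simulation_config(frac_antisense_overlap = 1.2), "fractions")
  expect_error(simulation_config(n_regulators = 150,
                                 frac_antisense_overlap = 0.5),
               "antisense")
  expect_error(simulation_config(nb_dispersion = 0), "positive")
})

test_that("same seed yields a byte-identical fixture bundle", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture_bundle(small_cfg(seed = 9), d1)
  write_fixture_bundle(small_cfg(seed = 9), d2)
  fls <- list.files(d1)
  expect_true(length(fls) >= 7)
  for (f in fls)
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
})

test_that("generated files re-read cleanly through the io layer", {
  d <- withr::local_tempdir()
  fx <- write_fixture_bundle(small_cfg(seed = 4), d)
  ann <- read_gtf(file.path(d, "annotation.gtf"))
  expect_equal(n_loci(ann), n_loci(fx$annotation))
  counts <- read_counts(file.path(d, "counts.tsv"))
  expect_equal(counts, fx$counts)
  design <- read_design(file.path(d, "design.tsv"), counts)
  expect_equal(design, fx$design)
  cls <- read_feelnc_table(file.path(d, "feelnc.tsv"))
  expect_equal(nrow(cls), nrow(fx$classification))
  qtl <- read_qtl_bed(file.path(d, "qtl.bed"))
  expect_equal(qtl$start, fx$qtl$start)
  met <- read_metabolites(file.path(d, "metabolites.tsv"))
  expect_equal(dim(met), dim(fx$metabolites))
})

test_that("NAT pair geometry is antisense-overlapping by an independent check", {
  g <- generate_annotation(small_cfg(seed = 2))
  loci <- g$annotation$loci
  nat <- g$truth$nat_pairs
  expect_gt(nrow(nat), 0)
  for (k in seq_len(nrow(nat))) {
    li <- match(nat$lncRNA_id[k], loci$locus_id)
    pi <- match(nat$partner_id[k], loci$locus_id)
    # fully nested inside the partner on the opposite strand
    expect_true(loci$start[li] >= loci$start[pi] &&
                  loci$end[li] <= loci$end[pi])
    expect_true(loci$strand[li] != loci$strand[pi])
  }
  # count matches the configured antisense fraction
  expect_equal(nrow(nat), round(0.6 * 20))
})

test_that("degenerate antisense fractions behave as forced", {
  g1 <- generate_annotation(small_cfg(seed = 3, frac_antisense_overlap = 1))
  cls <- g1$classification[g1$classification$is_best == 1, ]
  expect_true(all(cls$direction == "antisense" & cls$distance_bp == 0))
  g0 <- generate_annotation(small_cfg(seed = 3, n_lnc = 0L,
                                      n_regulators = 0L,
                                      frac_antisense_overlap = 1))
  expect_equal(nrow(g0$classification), 0)
})

test_that("QTL linkage is boundary-inclusive at 3 Mb and matches brute force", {
  # constructed boundary cases
  qtl <- data.frame(qtl_id = "q1", chrom = "1", start = 5000000L,
                    end = 6000000L, trait = "RFI")
  loci <- data.frame(
    locus_id = c("at3mb", "beyond", "inside", "otherchrom"),
    chrom = c("1", "1", "1", "2"),
    start = c(1999000L, 1998999L, 5500000L, 5500000L),
    end = c(2000000L, 1999999L, 5500100L, 5500100L),
    strand = "+", biotype = "protein_coding", gene_symbol = NA,
    is_reference_annotated = TRUE)
  tx <- data.frame(locus_id = loci$locus_id,
                   transcript_id = paste0(loci$locus_id, ".1"),
                   is_reference_annotated = TRUE)
  ex <- data.frame(transcript_id = tx$transcript_id, start = loci$start,
                   end = loci$end)
  ann <- annotation_set(loci, tx, ex)
  res <- qtl_category(ann, qtl, 3e6)
  # gap of locus "at3mb": 5000000 - 2000000 = 3000000 exactly -> linked
  expect_true("at3mb" %in% res$linked)
  # one bp farther -> not linked
  expect_false("beyond" %in% res$linked)
  expect_true("inside" %in% res$linked)
  expect_true("inside" %in% res$direct_overlap)
  expect_false("otherchrom" %in% res$linked)
  expect_setequal(res$linked, qtl_brute_scan(loci, qtl, 3e6))
})

test_that("generated QTL geometry agrees with a brute-force distance scan", {
  cfg <- small_cfg(seed = 6)
  g <- generate_annotation(cfg)
  qtl <- generate_qtl(cfg)
  linked <- qtl_category(g$annotation, qtl, 3e6)$linked
  expect_setequal(linked, qtl_brute_scan(g$annotation$loci, qtl, 3e6))
  expect_setequal(linked, g$truth$qtl_linked_ids)
})

test_that("planted wiring correlation is recovered at enlarged sample size", {
  cfg <- simulation_config(seed = 3, n_high = 200, n_low = 200)
  fx <- generate_fixture(cfg)
  fpkm <- compute_fpkm(fx$counts, exonic_lengths(fx$annotation))
  g1 <- fx$design$sample[fx$design$group == "high"]
  g2 <- fx$design$sample[fx$design$group == "low"]
  r1 <- mean(cor(t(fpkm[fx$truth$regulator_ids, g1]),
                 t(fpkm[fx$truth$module_target_ids, g1])))
  r2 <- mean(cor(t(fpkm[fx$truth$regulator_ids, g2]),
                 t(fpkm[fx$truth$module_target_ids, g2])))
  expect_lt(abs(r1 - 0.8), 0.05)
  expect_lt(abs(r2 - 0.0), 0.05)
})

test_that("lncRNA abundance is skewed low", {
  fx <- default_fixture()
  fpkm <- default_fpkm()
  lnc <- grep("^MSTRG", rownames(fpkm), value = TRUE)
  frac_low <- mean(rowMeans(fpkm[lnc, ]) < 1)
  expect_gt(frac_low, 0.45)
  expect_lt(frac_low, 0.8)
  # partner/lncRNA expression ratios span orders of magnitude
  nat <- fx$truth$nat_pairs
  ratio <- fx$truth$base_fpkm[nat$partner_id] /
    fx$truth$base_fpkm[nat$lncRNA_id]
  expect_gt(max(ratio) / min(ratio), 50)
})

test_that("null differential expression yields near-uniform p-values", {
  cfg <- small_cfg(seed = 8, de_fraction = 0, de_log2fc = 0,
                   wiring_r_group1 = 0, wiring_r_group2 = 0,
                   gate_partner_r = 0, backbone_max = 0,
                   nat_r_range = c(0, 0.01))
  fx <- generate_fixture(cfg)
  de <- differential_expression(fx$counts, fx$design)
  expect_lt(sum(de$significant), 3)
  expect_gt(suppressWarnings(
    stats::ks.test(de$p[rowSums(fx$counts) > 50], "punif")$p.value), 1e-4)
})

test_that("zero metabolite missingness produces a complete matrix", {
  cfg <- small_cfg(seed = 5, metab_missing_rate = 0,
                   n_high_missing_metabolites = 0L)
  fx <- generate_fixture(cfg)
  expect_false(anyNA(fx$metabolites))
})
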