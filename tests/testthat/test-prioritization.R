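test_that("FPKM matches the closed form and is scale invariant", {
  counts <- matrix(c(10L, 999990L, 5L, 499995L), 2, 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  len <- c(a = 1000L, b = 50000L)
  f <- compute_fpkm(counts, len)
  # counts 10, library 1e6, length 1 kb -> 10 FPKM
  expect_equal(f["a", "s1"], 10)
  # doubling a sample's counts leaves its FPKM unchanged
  c2 <- counts; c2[, 1] <- c2[, 1] * 2L
  expect_equal(compute_fpkm(c2, len)[, 1], f[, 1])
  expect_error(compute_fpkm(matrix(0L, 1, 1, dimnames = list("a", "s")),
                            c(a = 10L)), "zero")
})

test_that("FPKM equals a cell-by-cell oracle on random matrices", {
  set.seed(42)
  counts <- matrix(rnbinom(100, mu = 50, size = 5), 20, 5,
                   dimnames = list(sprintf("g%02d", 1:20),
                                   sprintf("s%d", 1:5)))
  len <- setNames(sample(500:5000, 20), rownames(counts))
  expect_equal(compute_fpkm(counts, len), fpkm_oracle(counts, len))
})

test_that("minimal expression uses strict > in at least one group", {
  design <- toy_design(6, 6)
  f <- matrix(0, 3, 12, dimnames = list(c("kept", "edge", "low"),
                                        design$sample))
  f["kept", 1:6] <- 0.2          # 6 high-group animals above threshold
  f["edge", ] <- 0.1             # exactly at the threshold: excluded
  f["low", 1:5] <- 5             # only 5 animals: excluded
  expect_equal(minimal_expression_filter(f, design), "kept")
})

test_that("minimal expression agrees with a direct recount on a fixture", {
  fpkm <- default_fpkm()
  fx <- default_fixture()
  kept <- minimal_expression_filter(fpkm, fx$design)
  hi <- fx$design$sample[fx$design$group == "high"]
  lo <- fx$design$sample[fx$design$group == "low"]
  manual <- rownames(fpkm)[rowSums(fpkm[, hi] > 0.1) >= 6 |
                             rowSums(fpkm[, lo] > 0.1) >= 6]
  expect_setequal(kept, manual)
})

test_that("biotype exclusion removes exactly the configured biotypes", {
  ann <- toy_annotation(3)
  ann$loci$biotype <- c("rRNA", "protein_coding", "Y-RNA")
  filt <- biotype_exclusion(ann)
  expect_equal(filt$loci$locus_id, "G02")
  # empty exclusion set is the identity
  expect_equal(n_loci(biotype_exclusion(ann, character())), 3)
})

test_that("Benjamini-Hochberg matches closed forms and the step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(benjamini_hochberg(p), bh_stepup_oracle(p))
  }
})

test_that("the NB Wald test is calibrated under its own null model", {
  set.seed(101)
  design <- toy_design()
  mu <- rlnorm(2000, log(50), 1)
  counts <- matrix(rnbinom(2000 * 25, mu = rep(mu, 25), size = 1 / 0.1),
                   2000, 25,
                   dimnames = list(sprintf("g%04d", 1:2000), design$sample))
  de <- differential_expression(counts, design)
  t1 <- mean(de$p < 0.05)
  expect_gte(t1, 0.03)
  expect_lte(t1, 0.07)
})

test_that("all-zero loci get p = 1 and log2fc = 0", {
  design <- toy_design(6, 6)
  counts <- matrix(0L, 2, 12, dimnames = list(c("z", "x"), design$sample))
  counts["x", ] <- rep(c(40L, 10L), 6)
  de <- differential_expression(counts, design)
  expect_equal(de$p[de$locus_id == "z"], 1)
  expect_equal(de$log2fc[de$locus_id == "z"], 0)
})

test_that("a planted 4-fold shift at moderate expression is well powered", {
  set.seed(55)
  design <- toy_design()
  shift <- ifelse(design$group == "high", 2, 0.5)
  KA <- t(vapply(1:500, function(i)
    rnbinom(25, mu = 400 * shift, size = 1 / 0.1), numeric(25)))
  K0 <- matrix(rnbinom(1500 * 25, mu = 400, size = 1 / 0.1), 1500, 25)
  counts <- rbind(KA, K0)
  dimnames(counts) <- list(sprintf("g%04d", 1:2000), design$sample)
  de <- differential_expression(counts, design)
  expect_gt(mean(de$significant[1:500]), 0.8)
  # direction convention: higher in the high group means positive log2fc
  expect_gt(median(de$log2fc[1:500]), 1.5)
})

test_that("the NB Wald stand-in agrees directionally with DESeq2", {
  skip_if_not_installed("DESeq2")
  set.seed(77)
  design <- toy_design(8, 8)
  shift <- ifelse(design$group == "high", 2, 0.5)
  KA <- t(vapply(1:60, function(i)
    rnbinom(16, mu = rlnorm(1, log(200), 0.8) * shift, size = 1 / 0.1),
    numeric(16)))
  K0 <- matrix(rnbinom(240 * 16, mu = 200, size = 1 / 0.1), 240, 16)
  counts <- rbind(KA, K0)
  dimnames(counts) <- list(sprintf("g%03d", 1:300), design$sample)
  de <- differential_expression(counts, design)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    counts, S4Vectors::DataFrame(group = factor(design$group,
                                                levels = c("low", "high"))),
    ~group)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)
  both <- de$significant & !is.na(res$padj) & res$padj <= 0.1
  expect_gt(sum(both), 30)
  expect_true(all(sign(de$log2fc[both]) == sign(res$log2FoldChange[both])))
})

test_that("partner category honours the best-partner flag", {
  cls <- data.frame(
    lncRNA_transcript_id = c("t1", "t2", "t3"),
    lncRNA_locus_id = c("l1", "l2", "l3"),
    partner_locus_id = c("pA", "pA", "pB"),
    direction = "antisense", type = "genic", subtype = "nested",
    distance_bp = 0L, is_best = c(1L, 1L, 0L))
  expect_equal(partner_category(cls), "pA")
  expect_equal(partner_category(cls[0, ]), character())
})

test_that("the prioritized set is the flagged union within min-expressed", {
  pri <- build_prioritized_set(lnc_ids = c("a", "b"),
                               partner_ids = c("b", "c"),
                               qtl_ids = "d", de_ids = c("a", "e"),
                               min_expressed = c("a", "b", "c", "d", "x"))
  # e is not min-expressed, x is in no category
  expect_setequal(pri$locus_id, c("a", "b", "c", "d"))
  # multi-category membership keeps all flags
  expect_true(pri$is_lncRNA[pri$locus_id == "a"] &&
                pri$is_de[pri$locus_id == "a"])
  # brute-force union size
  cats <- list(c("a", "b"), c("b", "c"), "d", c("a", "e"))
  expect_equal(nrow(pri),
               length(intersect(unique(unlist(cats)),
                                c("a", "b", "c", "d", "x"))))
  expect_true(all(pri$is_min_expressed))
})
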