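#' Simulation configuration for synthetic study fixtures
#'
#' Returns a validated configuration describing a synthetic two-group liver
#' study: a single chromosome carrying protein-coding loci, low-abundance
#' lncRNAs (mostly antisense-nested in coding hosts), a co-regulated module
#' of differential-wiring regulator lncRNAs, QTL intervals, and a metabolite
#' layer tied to the regulator module. Defaults reproduce the study
#' conditions the pipeline targets (n = 12 vs 13 animals, wiring r of 0.8 in
#' the high group vs 0.0 in the low group, lncRNA expression skewed low with
#' roughly 65 percent of loci under 1 FPKM).
#'
#' @param seed integer seed controlling every random draw.
#' @param n_high,n_low group sizes (>= 6 each; the minimal-expression rule
#'   needs six animals).
#' @param n_coding number of background protein-coding loci.
#' @param n_lnc number of lncRNA loci.
#' @param frac_antisense_overlap fraction of lncRNAs fully nested antisense
#'   within a coding host (distance 0, best partner).
#' @param n_regulators planted regulator lncRNAs (all antisense).
#' @param n_targets_per_regulator size of the shared differential-wiring
#'   target set of the regulator module.
#' @param wiring_r_group1,wiring_r_group2 population Pearson correlation
#'   between regulators and module targets within group high / low.
#' @param n_gate_partners coding genes consistently co-expressed with the
#'   regulators in both groups (network/hub substrate); regulator antisense
#'   hosts are drawn from this set.
#' @param gate_partner_r both-group wiring of gate partners.
#' @param n_decoys abundant independent coding loci placed in QTL regions.
#' @param target_fpkm,decoy_fpkm,bg_fpkm_cap abundance scales (FPKM).
#' @param base_fpkm_lognormal,lnc_fpkm_lognormal,regulator_fpkm_lognormal
#'   `(meanlog, sdlog)` pairs for background coding, lncRNA and regulator
#'   base FPKM.
#' @param lnc_expression_ratio_range range of the partner/lncRNA mean
#'   expression ratio for antisense pairs (log-uniform draw).
#' @param nat_r_range,nat_negative_frac planted antisense-pair correlation
#'   range and the fraction of negative pairs.
#' @param backbone_max inert lncRNAs receive a weak loading on the module
#'   factor drawn uniformly from `[0, backbone_max]` (liver co-expression
#'   backbone).
#' @param de_fraction fraction of background coding loci given a group mean
#'   shift of `de_log2fc` (random sign), in addition to the module targets
#'   which are shifted by `+de_log2fc`.
#' @param de_log2fc planted log2 fold change (high vs low).
#' @param signal_cv biological coefficient of variation of the latent
#'   abundance layer.
#' @param nb_dispersion negative-binomial dispersion of counts given the
#'   latent abundance.
#' @param library_size expected sequencing depth (fragments).
#' @param n_filler,filler_cv bulk-transcriptome loci that absorb the
#'   remaining library mass (moderately expressed genes outside all
#'   prioritisation categories), so that FPKM values sit on their natural
#'   absolute scale.
#' @param n_excluded_biotype loci carrying excluded biotypes (rRNA etc.).
#' @param excluded_biotypes biotype labels used for those loci.
#' @param n_metabolites,n_linked_metabolites,metab_r,n_da_metabolites,
#'   da_metab_log2fc,metab_missing_rate,n_high_missing_metabolites
#'   metabolite layer: total compounds, compounds sharing the regulator
#'   module factor (population correlation `metab_r`), differentially
#'   abundant compounds with shift `da_metab_log2fc`, missing-at-random cell
#'   rate, and compounds with elevated (50 percent) missingness.
#' @param n_qtl,qtl_width QTL intervals and their width (bp).
#' @param coding_spacing genomic spacing of coding locus slots (bp).
#' @param chrom chromosome name.
#' @param regulator_loading loading of regulators on their module factor.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_high = 12L, n_low = 13L,
                              n_coding = 1200L, n_lnc = 200L,
                              frac_antisense_overlap = 0.6,
                              n_regulators = 20L,
                              n_targets_per_regulator = 40L,
                              wiring_r_group1 = 0.8,
                              wiring_r_group2 = 0.0,
                              n_gate_partners = 60L,
                              gate_partner_r = 0.85,
                              n_decoys = 300L,
                              target_fpkm = 40,
                              decoy_fpkm = 35,
                              bg_fpkm_cap = 20,
                              base_fpkm_lognormal = c(meanlog = log(5), sdlog = 0.9),
                              lnc_fpkm_lognormal = c(meanlog = log(0.45), sdlog = 1.6),
                              regulator_fpkm_lognormal = c(meanlog = log(5), sdlog = 0.4),
                              lnc_expression_ratio_range = c(0.2, 400),
                              nat_r_range = c(0.3, 0.85),
                              nat_negative_frac = 0.05,
                              backbone_max = 0.4,
                              de_fraction = 0.06,
                              de_log2fc = 2,
                              signal_cv = 0.5,
                              nb_dispersion = 0.02,
                              library_size = 5e7,
                              n_filler = 2000L,
                              filler_cv = 0.3,
                              n_excluded_biotype = 6L,
                              excluded_biotypes = c("rRNA", "snRNA-spliceosomal",
                                                    "SRP-RNA", "Y-RNA"),
                              n_metabolites = 120L,
                              n_linked_metabolites = 30L,
                              metab_r = 0.85,
                              n_da_metabolites = 10L,
                              da_metab_log2fc = 1.5,
                              metab_missing_rate = 0.1,
                              n_high_missing_metabolites = 4L,
                              n_qtl = 12L,
                              qtl_width = 1e6,
                              coding_spacing = 1e5,
                              chrom = "1",
                              regulator_loading = 0.97) {
  cfg <- as.list(environment())
  if (cfg$n_high < 6 || cfg$n_low < 6)
    stopf("group sizes must be >= 6 (minimal-expression rule)")
  fr <- c(frac_antisense_overlap, metab_missing_rate, nat_negative_frac,
          de_fraction)
  if (any(fr < 0 | fr > 1)) stopf("fractions must lie in [0, 1]")
  if (any(abs(c(wiring_r_group1, wiring_r_group2, gate_partner_r)) > 1))
    stopf("wiring correlations must lie in [-1, 1]")
  if (n_regulators > round(frac_antisense_overlap * n_lnc))
    stopf("need at least n_regulators antisense lncRNAs")
  if (n_regulators > n_gate_partners)
    stopf("regulator hosts are drawn from the gate partners")
  if (diff(range(lnc_expression_ratio_range)) <= 0 ||
      any(lnc_expression_ratio_range <= 0))
    stopf("lnc_expression_ratio_range must be an increasing positive pair")
  if (nb_dispersion <= 0) stopf("nb_dispersion must be positive")
  if (n_linked_metabolites + n_da_metabolites + n_high_missing_metabolites >
      n_metabolites)
    stopf("metabolite role counts exceed n_metabolites")
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("simulation_config: %d+%d samples, %d coding, %d lncRNA ",
                     "(%d regulators), seed %d\n"),
              x$n_high, x$n_low, x$n_coding, x$n_lnc, x$n_regulators, x$seed))
  invisible(x)
}

# deterministic QTL window layout: n_qtl windows spread over the first ~60%
# of the coding span so that a contiguous region is within 3 Mb and the far
# end of the chromosome is beyond it
qtl_windows <- function(cfg) {
  span <- cfg$coding_spacing * cfg$n_coding
  centers <- seq(2e6, 0.56 * span, length.out = cfg$n_qtl)
  data.frame(qtl_id = sprintf("QTL%03d", seq_len(cfg$n_qtl)),
             chrom = cfg$chrom,
             start = as.integer(round(centers - cfg$qtl_width / 2)),
             end = as.integer(round(centers + cfg$qtl_width / 2)),
             trait = "RFI", stringsAsFactors = FALSE)
}

# brute-force scan: locus ids within max_bp of any window (gap distance)
brute_qtl_linked <- function(loci, windows, max_bp = 3e6) {
  hit <- vapply(seq_len(nrow(loci)), function(i) {
    same <- windows$chrom == loci$chrom[i]
    if (!any(same)) return(FALSE)
    d <- gap_distance(loci$start[i], loci$end[i],
                      windows$start[same], windows$end[same])
    any(d <= max_bp)
  }, logical(1))
  loci$locus_id[hit]
}

# helper: exon structure for a locus span
sim_exons <- function(tx_id, start, end, n_exons) {
  len <- end - start + 1
  if (n_exons == 1 || len < 4 * n_exons)
    return(data.frame(transcript_id = tx_id, start = start, end = end))
  cuts <- sort(sample(seq(start + 1, end - 1), 2 * n_exons - 2))
  bounds <- matrix(c(start, cuts, end), ncol = 2, byrow = TRUE)
  data.frame(transcript_id = tx_id,
             start = bounds[, 1], end = bounds[, 2])
}

#' Generate the synthetic annotation and lncRNA classification
#'
#' Lays out coding loci on a synthetic chromosome, nests antisense lncRNAs
#' inside coding hosts (distance 0, best partner) and places the remaining
#' lncRNAs intergenically 10-70 kb from a partner gene. Roles (regulator
#' module, gate partners, QTL decoys, housekeeping filler, excluded
#' biotypes) are assigned geometrically so that planted structure lands in
#' the intended prioritisation categories.
#'
#' @param cfg a [simulation_config()].
#' @return list with elements `annotation` (an `annotation_set`),
#'   `classification` (FEELnc-style data.frame) and `truth` (partial ground
#'   truth: regulator ids, role table, NAT pairs, QTL-linked ids).
#' @export
generate_annotation <- function(cfg) {
  with_seed(cfg$seed + 101L, {
    n_cod <- cfg$n_coding
    n_slots <- n_cod + cfg$n_filler + cfg$n_excluded_biotype
    slot_start <- 5e4 + (seq_len(n_slots) - 1) * cfg$coding_spacing
    cod_len <- round(runif(n_slots, 5e3, 2e4))

    windows <- qtl_windows(cfg)
    # coding slots first; filler and excluded-biotype loci occupy the far end
    cod_ids <- sprintf("ENSSYNG%06d", seq_len(n_cod))
    fill_ids <- sprintf("ENSSYNG%06d", n_cod + seq_len(cfg$n_filler))
    excl_ids <- sprintf("ENSSYNG%06d",
                        n_cod + cfg$n_filler + seq_len(cfg$n_excluded_biotype))
    # filler/excluded get the last slots (outside QTL coverage)
    slot_of <- c(seq_len(n_cod),                       # coding: slots 1..n_cod
                 n_cod + seq_len(cfg$n_filler),
                 n_cod + cfg$n_filler + seq_len(cfg$n_excluded_biotype))
    all_ids <- c(cod_ids, fill_ids, excl_ids)
    loci <- data.frame(
      locus_id = all_ids,
      chrom = cfg$chrom,
      start = as.integer(slot_start[slot_of]),
      end = as.integer(slot_start[slot_of] + cod_len[slot_of]),
      strand = sample(c("+", "-"), length(all_ids), replace = TRUE),
      biotype = c(rep("protein_coding", n_cod + cfg$n_filler),
                  sample(cfg$excluded_biotypes, cfg$n_excluded_biotype,
                         replace = TRUE)),
      gene_symbol = c(sprintf("GENE%04d", seq_len(n_cod)),
                      sprintf("HKG%03d", seq_len(cfg$n_filler)),
                      rep(NA_character_, cfg$n_excluded_biotype)),
      is_reference_annotated = TRUE,
      stringsAsFactors = FALSE)

    linked <- brute_qtl_linked(loci, windows)
    linked_cod <- intersect(linked, cod_ids)
    far_cod <- setdiff(cod_ids, linked)
    need <- cfg$n_targets_per_regulator + cfg$n_gate_partners + cfg$n_decoys
    if (length(linked_cod) < need)
      stopf("QTL coverage too small for planted roles (%d < %d)",
            length(linked_cod), need)
    sp <- sample(linked_cod, need)
    module_targets <- sp[seq_len(cfg$n_targets_per_regulator)]
    gate_partners <- sp[cfg$n_targets_per_regulator + seq_len(cfg$n_gate_partners)]
    decoys <- sp[cfg$n_targets_per_regulator + cfg$n_gate_partners +
                   seq_len(cfg$n_decoys)]

    role <- setNames(rep("background", length(all_ids)), all_ids)
    role[fill_ids] <- "filler"
    role[excl_ids] <- "excluded_biotype"
    role[module_targets] <- "module_target"
    role[gate_partners] <- "gate_partner"
    role[decoys] <- "decoy"

    # lncRNAs -------------------------------------------------------------
    n_as <- round(cfg$frac_antisense_overlap * cfg$n_lnc)
    n_ig <- cfg$n_lnc - n_as
    lnc_ids <- sprintf("MSTRG.%d", seq_len(cfg$n_lnc))
    reg_ids <- lnc_ids[seq_len(cfg$n_regulators)]
    # antisense hosts: regulators inside gate partners; remaining antisense
    # lncRNAs inside other coding loci (one host per lncRNA)
    reg_hosts <- sample(gate_partners, cfg$n_regulators)
    other_pool <- setdiff(cod_ids, c(reg_hosts))
    as_hosts <- c(reg_hosts,
                  sample(other_pool, n_as - cfg$n_regulators))
    ig_partners <- sample(setdiff(cod_ids, as_hosts), n_ig)

    li <- match(c(as_hosts, ig_partners), loci$locus_id)
    empty_cls <- data.frame(lncRNA_transcript_id = character(),
                            lncRNA_locus_id = character(),
                            partner_locus_id = character(),
                            direction = character(), type = character(),
                            subtype = character(),
                            distance_bp = integer(), is_best = integer(),
                            stringsAsFactors = FALSE)
    lnc_rows <- vector("list", cfg$n_lnc)
    cls_rows <- vector("list", cfg$n_lnc)
    for (k in seq_len(cfg$n_lnc)) {
      antisense <- k <= n_as
      host_i <- li[k]
      hstart <- loci$start[host_i]; hend <- loci$end[host_i]
      hlen <- hend - hstart + 1
      if (antisense) {
        len <- round(runif(1, 500, min(4000, hlen - 400)))
        off <- round(runif(1, 100, hlen - len - 100))
        s <- hstart + off; e <- s + len
        strand <- if (loci$strand[host_i] == "+") "-" else "+"
        dist <- 0L; type <- "genic"; direction <- "antisense"
        subtype <- "nested"
      } else {
        len <- round(runif(1, 500, 8000))
        gapd <- round(runif(1, 1e4, 7e4))
        s <- hend + gapd; e <- s + len
        direction <- sample(c("sense", "antisense"), 1)
        strand <- if (direction == "sense") loci$strand[host_i] else
          if (loci$strand[host_i] == "+") "-" else "+"
        dist <- as.integer(gapd); type <- "intergenic"
        subtype <- "downstream"
      }
      lnc_rows[[k]] <- data.frame(
        locus_id = lnc_ids[k], chrom = cfg$chrom,
        start = as.integer(s), end = as.integer(e), strand = strand,
        biotype = "novel", gene_symbol = NA_character_,
        is_reference_annotated = FALSE, stringsAsFactors = FALSE)
      cls_rows[[k]] <- data.frame(
        lncRNA_transcript_id = sprintf("%s.1", lnc_ids[k]),
        lncRNA_locus_id = lnc_ids[k],
        partner_locus_id = loci$locus_id[host_i],
        direction = direction, type = type, subtype = subtype,
        distance_bp = dist, is_best = 1L, stringsAsFactors = FALSE)
    }
    lnc_loci <- do.call(rbind, lnc_rows)
    classification <- if (cfg$n_lnc > 0) do.call(rbind, cls_rows) else empty_cls

    # secondary, non-best classification rows for ~20% of lncRNAs
    sec <- if (cfg$n_lnc > 0) sample(cfg$n_lnc, round(0.2 * cfg$n_lnc))
           else integer()
    sec_rows <- lapply(sec, function(k) {
      other <- sample(setdiff(cod_ids, classification$partner_locus_id[k]), 1)
      oi <- match(other, loci$locus_id)
      d <- gap_distance(lnc_loci$start[k], lnc_loci$end[k],
                        loci$start[oi], loci$end[oi])
      if (d == 0) return(NULL)  # overlap by chance: skip, keep invariant
      data.frame(lncRNA_transcript_id = sprintf("%s.1", lnc_loci$locus_id[k]),
                 lncRNA_locus_id = lnc_loci$locus_id[k],
                 partner_locus_id = other,
                 direction = sample(c("sense", "antisense"), 1),
                 type = "intergenic", subtype = "secondary",
                 distance_bp = as.integer(d), is_best = 0L,
                 stringsAsFactors = FALSE)
    })
    classification <- rbind(classification,
                            do.call(rbind, sec_rows))
    rownames(classification) <- NULL

    all_loci <- rbind(loci, lnc_loci)
    # transcripts + exons: 1-2 transcripts for coding, 1 for lncRNA
    tx_rows <- list(); ex_rows <- list()
    for (i in seq_len(nrow(all_loci))) {
      is_lnc <- grepl("^MSTRG", all_loci$locus_id[i])
      ntx <- if (is_lnc) 1L else sample(1:2, 1)
      for (t in seq_len(ntx)) {
        tid <- sprintf("%s.%d", all_loci$locus_id[i], t)
        tx_rows[[length(tx_rows) + 1]] <- data.frame(
          locus_id = all_loci$locus_id[i], transcript_id = tid,
          is_reference_annotated = !is_lnc, stringsAsFactors = FALSE)
        ex_rows[[length(ex_rows) + 1]] <-
          sim_exons(tid, all_loci$start[i], all_loci$end[i],
                    if (is_lnc) sample(1:3, 1) else sample(2:5, 1))
      }
    }
    ann <- annotation_set(all_loci, do.call(rbind, tx_rows),
                          do.call(rbind, ex_rows))

    nat <- classification[classification$direction == "antisense" &
                            classification$distance_bp == 0 &
                            classification$is_best == 1, ]
    truth <- list(
      regulator_ids = reg_ids,
      regulator_targets = setNames(
        rep(list(module_targets), cfg$n_regulators), reg_ids),
      hub_regulator_ids = reg_ids,
      gate_partner_ids = gate_partners,
      decoy_ids = decoys,
      module_target_ids = module_targets,
      filler_ids = fill_ids,
      excluded_ids = excl_ids,
      nat_pairs = data.frame(lncRNA_id = nat$lncRNA_locus_id,
                             partner_id = nat$partner_locus_id,
                             stringsAsFactors = FALSE),
      qtl_linked_ids = brute_qtl_linked(ann$loci, windows),
      role = role)
    list(annotation = ann, classification = classification, truth = truth)
  })
}

#' Generate QTL intervals for a synthetic annotation
#'
#' Deterministic window layout given the configuration; the returned
#' intervals match the geometry used when roles were assigned, so a known
#' subset of loci lies within 3 Mb and the far end of the chromosome beyond
#' it.
#'
#' @param cfg a [simulation_config()].
#' @param annotation unused; accepted for pipeline-stage symmetry.
#' @param truth unused; accepted for pipeline-stage symmetry.
#' @return data.frame of QTL intervals (`qtl_id`, `chrom`, `start`, `end`,
#'   `trait`).
#' @export
generate_qtl <- function(cfg, annotation = NULL, truth = NULL) {
  qtl_windows(cfg)
}

#' Generate the synthetic count matrix and design
#'
#' Latent-factor model: regulators load on a module factor whose target
#' loadings differ between groups (differential wiring); gate partners load
#' equally in both groups; antisense pairs share a pair factor; inert
#' lncRNAs carry a weak backbone loading. Latent abundance is mapped to
#' negative-binomial counts. Loadings are calibrated analytically for the
#' attenuation caused by count noise so that planted population
#' correlations reappear at the FPKM level.
#'
#' @param cfg a [simulation_config()].
#' @param ann annotation from [generate_annotation()].
#' @param truth ground truth from [generate_annotation()] (updated copy is
#'   returned).
#' @param classification classification table from [generate_annotation()].
#' @return list with `counts` (integer matrix), `design` (data.frame) and
#'   the updated `truth` (adds `de_locus_ids`, `base_fpkm`, planted NAT
#'   correlations and the internal factor scores used by the metabolite
#'   stage).
#' @export
generate_expression <- function(cfg, ann, truth, classification) {
  with_seed(cfg$seed + 202L, {
    ids <- ann$loci$locus_id
    n_loci <- length(ids)
    n <- cfg$n_high + cfg$n_low
    design <- data.frame(
      sample = c(sprintf("H%02d", seq_len(cfg$n_high)),
                 sprintf("L%02d", seq_len(cfg$n_low))),
      group = rep(c("high", "low"), c(cfg$n_high, cfg$n_low)),
      stringsAsFactors = FALSE)
    grp <- ifelse(design$group == "high", 1L, 2L)

    role <- truth$role
    is_lnc <- grepl("^MSTRG", ids)
    reg_idx <- match(truth$regulator_ids, ids)
    mt_idx <- match(truth$module_target_ids, ids)
    gp_idx <- match(truth$gate_partner_ids, ids)
    dc_idx <- match(truth$decoy_ids, ids)
    fl_idx <- match(truth$filler_ids, ids)
    ex_idx <- match(truth$excluded_ids, ids)

    L <- exonic_lengths(ann)[ids]

    # base FPKM by role --------------------------------------------------
    b <- numeric(n_loci)
    bg_cod <- which(!is_lnc)
    b[bg_cod] <- pmin(rlnorm(length(bg_cod), cfg$base_fpkm_lognormal[1],
                             cfg$base_fpkm_lognormal[2]), cfg$bg_fpkm_cap)
    b[is_lnc] <- rlnorm(sum(is_lnc), cfg$lnc_fpkm_lognormal[1],
                        cfg$lnc_fpkm_lognormal[2])
    b[mt_idx] <- rlnorm(length(mt_idx), log(cfg$target_fpkm), 0.2)
    b[gp_idx] <- rlnorm(length(gp_idx), log(15), 0.3)
    b[dc_idx] <- rlnorm(length(dc_idx), log(cfg$decoy_fpkm), 0.3)
    b[reg_idx] <- pmax(rlnorm(length(reg_idx),
                              cfg$regulator_fpkm_lognormal[1],
                              cfg$regulator_fpkm_lognormal[2]), 2)

    # antisense pairs: partner/lncRNA mean ratio drawn log-uniformly; the
    # lncRNA base is tied to its host (regulator hosts keep their own base)
    nat <- truth$nat_pairs
    rr <- cfg$lnc_expression_ratio_range
    ratio <- exp(runif(nrow(nat), log(rr[1]), log(rr[2])))
    for (k in seq_len(nrow(nat))) {
      lnc_i <- match(nat$lncRNA_id[k], ids)
      par_i <- match(nat$partner_id[k], ids)
      if (nat$lncRNA_id[k] %in% truth$regulator_ids) next
      b[lnc_i] <- clamp(b[par_i] / ratio[k], 0.02, 50)
    }

    # filler loci absorb the remaining library mass so that sum(b * L)
    # reproduces the FPKM normalisation constant (1e9)
    bf_raw <- rlnorm(length(fl_idx), log(30), 0.2)
    b[ex_idx] <- rlnorm(length(ex_idx), log(1), 0.5)
    rest <- sum((b * L)[-fl_idx])
    b[fl_idx] <- bf_raw * max(1e9 - rest, 0) / sum(bf_raw * L[fl_idx])

    cpf <- L * cfg$library_size / 1e9       # expected counts per FPKM unit
    cvv <- rep(cfg$signal_cv, n_loci)
    cvv[fl_idx] <- cfg$filler_cv
    alpha <- cfg$nb_dispersion
    atten <- sqrt(cvv^2 / (cvv^2 + 1 / (b * cpf) + alpha * (1 + cvv^2)))

    # planted log2 fold changes -------------------------------------------
    lfc <- numeric(n_loci)
    lfc[mt_idx] <- cfg$de_log2fc
    bg_far <- which(!is_lnc & role[ids] == "background" & b < 15)
    n_de <- round(cfg$de_fraction * cfg$n_coding)
    de_extra <- sample(bg_far, min(n_de, length(bg_far)))
    lfc[de_extra] <- sample(c(-1, 1), length(de_extra), TRUE) * cfg$de_log2fc

    # factors and loadings ------------------------------------------------
    n_nat_free <- sum(!nat$lncRNA_id %in% truth$regulator_ids)
    n_factors <- 1L + n_nat_free
    FF <- matrix(rnorm(n_factors * n), n_factors, n)
    W <- array(0, dim = c(n_loci, n_factors, 2))
    W[reg_idx, 1, ] <- cfg$regulator_loading
    a_reg <- mean(atten[reg_idx])
    q1 <- cfg$wiring_r_group1 / (cfg$regulator_loading * a_reg * atten[mt_idx])
    q2 <- cfg$wiring_r_group2 / (cfg$regulator_loading * a_reg * atten[mt_idx])
    W[mt_idx, 1, 1] <- clamp(q1, -0.98, 0.98)
    W[mt_idx, 1, 2] <- clamp(q2, -0.98, 0.98)
    qp <- cfg$gate_partner_r / (cfg$regulator_loading * a_reg * atten[gp_idx])
    W[gp_idx, 1, 1] <- W[gp_idx, 1, 2] <- clamp(qp, -0.98, 0.98)
    # weak backbone loadings for inert lncRNAs
    inert_l <- setdiff(which(is_lnc), reg_idx)
    W[inert_l, 1, 1] <- W[inert_l, 1, 2] <- runif(length(inert_l), 0,
                                                  cfg$backbone_max)
    # shared pair factors for non-regulator antisense pairs
    nat$planted_r <- NA_real_
    fcount <- 1L
    for (k in seq_len(nrow(nat))) {
      if (nat$lncRNA_id[k] %in% truth$regulator_ids) {
        nat$planted_r[k] <- cfg$gate_partner_r
        next
      }
      fcount <- fcount + 1L
      lnc_i <- match(nat$lncRNA_id[k], ids)
      par_i <- match(nat$partner_id[k], ids)
      rho <- runif(1, cfg$nat_r_range[1], cfg$nat_r_range[2]) *
        if (runif(1) < cfg$nat_negative_frac) -1 else 1
      nat$planted_r[k] <- rho
      rho_lat <- clamp(rho / (atten[lnc_i] * atten[par_i]), -0.96, 0.96)
      w <- sqrt(abs(rho_lat))
      W[lnc_i, fcount, ] <- w
      W[par_i, fcount, 1] <- W[par_i, fcount, 2] <- sign(rho_lat) * w
    }

    # latent layer, counts -------------------------------------------------
    U <- matrix(0, n_loci, n)
    eps <- matrix(rnorm(n_loci * n), n_loci, n)
    for (s in seq_len(n)) {
      Wg <- W[, , grp[s], drop = FALSE]
      dim(Wg) <- dim(W)[1:2]
      ssq <- rowSums(Wg^2)
      sc <- ifelse(ssq > 0.95, sqrt(0.95 / ssq), 1)
      U[, s] <- (Wg * sc) %*% FF[, s] + sqrt(1 - pmin(ssq, 0.95)) * eps[, s]
    }
    shift <- outer(lfc, ifelse(grp == 1, 0.5, -0.5), function(l, s) 2^(l * s))
    mu <- b * shift * pmax(1 + cvv * U, 0)
    counts <- matrix(rnbinom(n_loci * n, mu = mu * cpf, size = 1 / alpha),
                     n_loci, n)
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(ids, design$sample)

    truth$de_locus_ids <- c(ids[mt_idx], ids[de_extra])
    truth$planted_log2fc <- setNames(lfc, ids)
    truth$base_fpkm <- setNames(b, ids)
    truth$nat_pairs <- nat
    truth$.factors <- FF[1, , drop = TRUE]   # module factor scores
    truth$.atten_reg <- a_reg
    list(counts = counts, design = design, truth = truth)
  })
}

#' Generate the synthetic metabolite layer
#'
#' A subset of compounds shares the regulator-module factor (population
#' correlation about `metab_r` with the regulators), some compounds are
#' differentially abundant, and cells are masked missing at random; a few
#' compounds get 50 percent missingness to exercise the exclusion rule.
#'
#' @param cfg a [simulation_config()].
#' @param truth truth after [generate_expression()] (needs factor scores).
#' @param expression result of [generate_expression()] (for the design).
#' @return list with `metabolites` (matrix with NAs) and updated `truth`
#'   (adds `metab_linked`, `da_metabolite_ids`).
#' @export
generate_metabolites <- function(cfg, truth, expression) {
  with_seed(cfg$seed + 303L, {
    design <- expression$design
    n <- nrow(design)
    grp <- ifelse(design$group == "high", 1L, 2L)
    m <- cfg$n_metabolites
    met_ids <- sprintf("met_%03d", seq_len(m))
    linked <- met_ids[seq_len(cfg$n_linked_metabolites)]
    da <- met_ids[cfg$n_linked_metabolites + seq_len(cfg$n_da_metabolites)]
    himiss <- met_ids[cfg$n_linked_metabolites + cfg$n_da_metabolites +
                        seq_len(cfg$n_high_missing_metabolites)]
    f <- truth$.factors
    base <- rlnorm(m, 0, 0.5)
    w <- clamp(cfg$metab_r / (cfg$regulator_loading * truth$.atten_reg), 0, 0.98)
    vals <- matrix(0, m, n, dimnames = list(met_ids, design$sample))
    for (i in seq_len(m)) {
      u <- if (met_ids[i] %in% linked)
        w * f + sqrt(1 - w^2) * rnorm(n) else rnorm(n)
      shift <- if (met_ids[i] %in% da)
        2^(cfg$da_metab_log2fc * ifelse(grp == 1, 0.5, -0.5)) else 1
      vals[i, ] <- base[i] * shift * pmax(1 + 0.35 * u, 0.01)
    }
    mask <- matrix(runif(m * n) < cfg$metab_missing_rate, m, n)
    mask[met_ids %in% himiss, ] <- matrix(runif(length(himiss) * n) < 0.5,
                                          length(himiss), n)
    vals[mask] <- NA_real_
    truth$metab_linked <- setNames(rep(list(linked),
                                       length(truth$regulator_ids)),
                                   truth$regulator_ids)
    truth$da_metabolite_ids <- da
    list(metabolites = vals, truth = truth)
  })
}

#' Generate a complete synthetic fixture in memory
#'
#' Runs all generator stages in order and returns every object the pipeline
#' consumes plus the planted ground truth.
#'
#' @param cfg a [simulation_config()].
#' @return list with `annotation`, `classification`, `counts`, `design`,
#'   `metabolites`, `qtl`, `truth` and the `config`.
#' @export
generate_fixture <- function(cfg = simulation_config()) {
  g <- generate_annotation(cfg)
  e <- generate_expression(cfg, g$annotation, g$truth, g$classification)
  mt <- generate_metabolites(cfg, e$truth, e)
  qtl <- generate_qtl(cfg, g$annotation, mt$truth)
  list(annotation = g$annotation, classification = g$classification,
       counts = e$counts, design = e$design,
       metabolites = mt$metabolites, qtl = qtl,
       truth = mt$truth, config = cfg)
}

#' Write a fixture bundle to disk
#'
#' Serialises a generated fixture as the plain-text formats the pipeline
#' reads: `annotation.gtf`, `counts.tsv`, `design.tsv`, `feelnc.tsv`,
#' `qtl.bed`, `metabolites.tsv`, plus `truth.json` (ground truth, internal
#' dot-fields removed) and `config.yaml`. Identical seeds produce
#' byte-identical bundles.
#'
#' @param cfg a [simulation_config()] or a fixture from
#'   [generate_fixture()].
#' @param outdir output directory (created if needed).
#' @return The fixture list, invisibly.
#' @export
write_fixture_bundle <- function(cfg, outdir) {
  fx <- if (inherits(cfg, "simulation_config")) generate_fixture(cfg) else cfg
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_gtf(fx$annotation, file.path(outdir, "annotation.gtf"))
  write_counts(fx$counts, file.path(outdir, "counts.tsv"))
  write_design(fx$design, file.path(outdir, "design.tsv"))
  write_feelnc_table(fx$classification, file.path(outdir, "feelnc.tsv"))
  write_qtl_bed(fx$qtl, file.path(outdir, "qtl.bed"))
  write_metabolites(fx$metabolites, file.path(outdir, "metabolites.tsv"))
  truth <- fx$truth[!startsWith(names(fx$truth), ".")]
  truth$schema_version <- "1.0"
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_out <- unclass(fx$config)
  yaml::write_yaml(cfg_out, file.path(outdir, "config.yaml"))
  invisible(fx)
}
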