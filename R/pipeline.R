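#' Pipeline configuration
#'
#' Thresholds for every stage with the study defaults: minimal expression
#' 0.1 FPKM in at least 6 animals of one group, DE q threshold 0.1,
#' metabolite q threshold 0.05 with |log2FC| >= 1, RIF |z| >= 1.96, network
#' |r| >= 0.65, metabolite correlation p <= 0.01, QTL proximity 3 Mb,
#' cis-interaction radius 1 Mb, hub gates 10 annotated genes / 10
#' metabolites / more than 50 genes.
#'
#' @param min_fpkm,min_animals minimal-expression rule.
#' @param alpha_q_de DE significance threshold on q.
#' @param alpha_q_metab,min_abs_lfc_metab metabolite differential-abundance
#'   thresholds.
#' @param metab_missing_frac,metab_knn_k differential-abundance
#'   missingness/imputation settings.
#' @param metab_max_missing_cases correlation-stage missingness rule.
#' @param rif_z RIF significance threshold.
#' @param min_abs_r network correlation threshold.
#' @param p_metab metabolite correlation p threshold.
#' @param qtl_max_distance_bp QTL proximity rule (bp).
#' @param cis_max_distance_bp cis-interaction radius (bp).
#' @param hub_min_genes,hub_min_metabolites,hub_high_connectivity hub gates.
#' @param max_transcripts,max_exons,exon_whitelist annotation plausibility
#'   filter settings.
#' @param excluded_biotypes biotypes removed before analysis.
#' @param sample_blacklist samples removed before all statistics (outlier
#'   exclusion hook).
#' @param novel_id_pattern regex identifying novel-assembly ids.
#' @param rif_targets `"all"` (DE, QTL and partner categories) or
#'   `"de-only"`.
#' @param seed integer seed recorded in outputs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_fpkm = 0.1, min_animals = 6,
                            alpha_q_de = 0.1,
                            alpha_q_metab = 0.05, min_abs_lfc_metab = 1,
                            metab_missing_frac = 0.4, metab_knn_k = 10,
                            metab_max_missing_cases = 5,
                            rif_z = 1.96,
                            min_abs_r = 0.65,
                            p_metab = 0.01,
                            qtl_max_distance_bp = 3e6,
                            cis_max_distance_bp = 1e6,
                            hub_min_genes = 10, hub_min_metabolites = 10,
                            hub_high_connectivity = 50,
                            max_transcripts = 20, max_exons = 200,
                            exon_whitelist = character(),
                            excluded_biotypes = c("rRNA",
                                                  "snRNA-spliceosomal",
                                                  "SRP-RNA", "Y-RNA"),
                            sample_blacklist = character(),
                            novel_id_pattern = "^MSTRG",
                            rif_targets = c("all", "de-only"),
                            seed = 1L) {
  cfg <- as.list(environment())
  cfg$rif_targets <- match.arg(rif_targets)
  stopifnot(cfg$min_fpkm >= 0, cfg$min_animals >= 1,
            cfg$alpha_q_de > 0, cfg$alpha_q_de <= 1,
            cfg$alpha_q_metab > 0, cfg$alpha_q_metab <= 1,
            cfg$rif_z > 0, cfg$min_abs_r >= 0, cfg$min_abs_r <= 1,
            cfg$p_metab > 0, cfg$p_metab <= 1,
            cfg$qtl_max_distance_bp >= 0, cfg$cis_max_distance_bp >= 0)
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$exon_whitelist <- as.character(vals$exon_whitelist %||% character())
  vals$sample_blacklist <- as.character(vals$sample_blacklist %||% character())
  vals$excluded_biotypes <- as.character(vals$excluded_biotypes)
  do.call(pipeline_config, vals)
}

#' Run the full discovery pipeline
#'
#' Executes all stages in order: annotation plausibility filtering and
#' biotype exclusion, FPKM and minimal expression, differential expression,
#' category construction and loci prioritisation, metabolite differential
#' abundance, RIF regulator scoring, PCIT edge selection, metabolite
#' correlation, network assembly, NAT / hub / cis screening, and export.
#'
#' @param inputs named list of file paths: `gtf`, `counts`, `design`,
#'   `feelnc`, `qtl_bed` and optionally `metabolites`; alternatively a
#'   directory containing a fixture bundle written by
#'   [write_fixture_bundle()].
#' @param config a [pipeline_config()].
#' @param out_dir output directory; stage outputs and `run_report.json` are
#'   written there (created if needed). NULL skips writing.
#' @return A list with every stage result (annotation, fpkm, de, prioritized,
#'   metab_diff, rif, pcit_edges, network, nats, hubs, cis, report),
#'   invisibly.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), out_dir = NULL) {
  if (is.character(inputs) && length(inputs) == 1 && dir.exists(inputs)) {
    d <- inputs
    inputs <- list(gtf = file.path(d, "annotation.gtf"),
                   counts = file.path(d, "counts.tsv"),
                   design = file.path(d, "design.tsv"),
                   feelnc = file.path(d, "feelnc.tsv"),
                   qtl_bed = file.path(d, "qtl.bed"),
                   metabolites = file.path(d, "metabolites.tsv"))
    if (!file.exists(inputs$metabolites)) inputs$metabolites <- NULL
  }
  for (nm in c("gtf", "counts", "design", "feelnc", "qtl_bed")) {
    if (is.null(inputs[[nm]])) stopf("missing required input: %s", nm)
    if (!file.exists(inputs[[nm]]))
      stopf("input file for '%s' does not exist: %s", nm, inputs[[nm]])
  }

  ann <- read_gtf(inputs$gtf, novel_id_pattern = config$novel_id_pattern)
  ann <- filter_merged_annotation(ann, config$max_transcripts,
                                  config$max_exons, config$exon_whitelist)
  ann <- biotype_exclusion(ann, config$excluded_biotypes)
  counts <- read_counts(inputs$counts)
  design <- read_design(inputs$design, counts)
  cls <- read_feelnc_table(inputs$feelnc)
  qtl <- read_qtl_bed(inputs$qtl_bed)
  metab <- if (!is.null(inputs$metabolites))
    read_metabolites(inputs$metabolites) else NULL

  # outlier exclusion hook: applied before all statistics
  if (length(config$sample_blacklist)) {
    design <- design[!design$sample %in% config$sample_blacklist, ,
                     drop = FALSE]
    if (length(unique(design$group)) != 2)
      stopf("sample blacklist removed an entire group")
  }
  counts <- counts[, design$sample, drop = FALSE]
  if (!is.null(metab))
    metab <- metab[, intersect(colnames(metab), design$sample), drop = FALSE]

  common <- intersect(rownames(counts), ann$loci$locus_id)
  counts <- counts[common, , drop = FALSE]

  lens <- exonic_lengths(ann)
  fpkm <- compute_fpkm(counts, lens)
  min_expressed <- minimal_expression_filter(fpkm, design, config$min_fpkm,
                                             config$min_animals)

  de <- differential_expression(counts, design, config$alpha_q_de)
  de_ids <- intersect(de$locus_id[de$significant], min_expressed)

  qcat <- qtl_category(ann, qtl, config$qtl_max_distance_bp)
  lnc_ids <- intersect(lncRNA_category(cls), rownames(counts))
  partner_ids <- intersect(partner_category(cls), rownames(counts))
  prioritized <- build_prioritized_set(lnc_ids, partner_ids, qcat$linked,
                                       de_ids, min_expressed)

  metab_diff <- NULL
  if (!is.null(metab))
    metab_diff <- differential_abundance(
      metab, design, config$metab_missing_frac, config$metab_knn_k,
      config$alpha_q_metab, config$min_abs_lfc_metab)

  regulators <- prioritized$locus_id[prioritized$is_lncRNA]
  targets <- if (config$rif_targets == "de-only")
    prioritized$locus_id[prioritized$is_de]
  else
    prioritized$locus_id[prioritized$is_partner | prioritized$is_qtl |
                           prioritized$is_de]
  rif <- compute_rif(fpkm, design, regulators, targets, config$rif_z)
  keys <- select_key_lncRNAs(rif, config$rif_z)

  corr <- pearson_matrix(fpkm[prioritized$locus_id, , drop = FALSE])
  pcit_edges <- pcit_filter(corr)
  net_edges <- filter_network_edges(pcit_edges, keys, config$min_abs_r)

  metab_edges <- NULL
  if (!is.null(metab) && length(keys)) {
    scaled <- prepare_metabolites_for_correlation(
      metab, config$metab_max_missing_cases)
    metab_edges <- metabolite_locus_correlations(
      scaled, fpkm[intersect(keys, rownames(fpkm)), , drop = FALSE],
      config$p_metab, config$min_abs_r)
  }

  net <- assemble_network(net_edges, metab_edges, prioritized, ann, keys)
  validate_network(net, config$min_abs_r)
  nats <- detect_nats(keys, cls, pcit_edges, fpkm)
  hubs <- select_hubs(net, keys, prioritized, config$hub_min_genes,
                      config$hub_min_metabolites,
                      config$hub_high_connectivity)
  hub_ids <- hubs$lncRNA_id[hubs$is_hub]
  cis <- detect_cis_interactions(hub_ids, ann, pcit_edges,
                                 config$cis_max_distance_bp,
                                 config$min_abs_r)
  report <- summarize_run(prioritized, rif, net, nats, hubs, cis, fpkm,
                          design, metab_diff)
  report$config_hash <- config_hash(config)
  report$seed <- config$seed

  res <- list(annotation = ann, design = design, counts = counts,
              fpkm = fpkm, min_expressed = min_expressed, de = de,
              prioritized = prioritized, metab_diff = metab_diff,
              rif = rif, keys = keys, pcit_edges = pcit_edges,
              network = net, nats = nats, hubs = hubs, cis = cis,
              report = report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, f) write.table(df, file.path(out_dir, f), sep = "\t",
                                      quote = FALSE, row.names = FALSE)
    wt(prioritized, "prioritized.tsv")
    wt(de, "de.tsv")
    wt(rif, "rif.tsv")
    wt(pcit_edges[pcit_edges$kept, ], "pcit_kept_edges.tsv")
    wt(nats, "nats.tsv")
    wt(hubs, "hubs.tsv")
    wt(cis, "cis.tsv")
    if (!is.null(metab_diff)) wt(metab_diff, "metab_diff.tsv")
    export_network(net, out_dir)
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  }
  invisible(res)
}

# stable hash of the configuration embedded in run reports
config_hash <- function(config) {
  s <- paste(vapply(unclass(config), function(v) paste(format(v), collapse = ","),
                    character(1)), collapse = ";")
  # small deterministic polynomial hash (no extra dependencies)
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Generate and write a synthetic fixture bundle
#'
#' Thin wrapper over [simulation_config()] and [write_fixture_bundle()].
#'
#' @param cfg a [simulation_config()].
#' @param outdir output directory.
#' @return The fixture list, invisibly.
#' @export
make_fixture <- function(cfg = simulation_config(), outdir) {
  write_fixture_bundle(cfg, outdir)
}
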