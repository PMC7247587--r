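#' Read a fragment-count matrix
#'
#' Tab-delimited file with a header; first column holds locus ids, remaining
#' columns one sample each. Counts must be non-negative integers.
#'
#' @param path TSV file path.
#' @return Integer matrix (loci x samples) with dimnames.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(is.na(m))) stopf("counts table contains missing values")
  if (any(m < 0)) stopf("counts table contains negative entries")
  if (any(m != round(m))) stopf("counts table contains non-integer entries")
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix as TSV
#' @param counts integer matrix with rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(locus_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-group sample design table
#'
#' TSV with columns `sample` and `group`. Exactly two distinct group labels
#' are required.
#'
#' @param path TSV file path.
#' @param counts optional count matrix; if given, the sample sets must match.
#' @return data.frame with columns `sample`, `group`.
#' @export
read_design <- function(path, counts = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df)))
    stopf("design table needs columns sample, group")
  g <- unique(df$group)
  if (length(g) != 2)
    stopf("design must have exactly two groups, found %d (%s)",
          length(g), toString(g))
  if (anyDuplicated(df$sample)) stopf("duplicated sample in design")
  if (!is.null(counts)) {
    if (!setequal(colnames(counts), df$sample))
      stopf("sample mismatch between counts and design")
  }
  df[, c("sample", "group")]
}

#' Read QTL intervals from a BED file
#'
#' BED6 (0-based half-open) converted to 1-based inclusive coordinates on
#' read. The name field is taken as the QTL id; an optional `id:trait` form
#' splits into id and trait, otherwise the trait defaults to `"RFI"`.
#'
#' @param path BED file path.
#' @return data.frame with columns `qtl_id`, `chrom`, `start`, `end`,
#'   `trait` (1-based inclusive).
#' @export
read_qtl_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stopf("QTL BED needs at least 4 columns")
  start <- df[[2]] + 1L
  end <- df[[3]]
  if (any(start > end)) stopf("QTL BED interval with start > end")
  nm <- as.character(df[[4]])
  has_trait <- grepl(":", nm, fixed = TRUE)
  qtl_id <- ifelse(has_trait, sub(":.*$", "", nm), nm)
  trait <- ifelse(has_trait, sub("^[^:]*:", "", nm), "RFI")
  data.frame(qtl_id = qtl_id, chrom = as.character(df[[1]]),
             start = start, end = end, trait = trait,
             stringsAsFactors = FALSE)
}

#' Write QTL intervals as BED6
#' @param qtl data.frame as returned by [read_qtl_bed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qtl_bed <- function(qtl, path) {
  bed <- data.frame(qtl$chrom, qtl$start - 1L, qtl$end,
                    paste(qtl$qtl_id, qtl$trait, sep = ":"), 0L, ".")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a FEELnc-style lncRNA classification table
#'
#' TSV with header columns `lncRNA_transcript`, `lncRNA_gene`,
#' `partnerRNA_gene`, `direction` (sense/antisense), `type`
#' (genic/intergenic), `subtype`, `distance`, `isBest` (0/1). Genic
#' classifications must have distance 0 and vice versa.
#'
#' @param path TSV file path.
#' @return data.frame with canonical column names `lncRNA_transcript_id`,
#'   `lncRNA_locus_id`, `partner_locus_id`, `direction`, `type`, `subtype`,
#'   `distance_bp`, `is_best`.
#' @export
read_feelnc_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("lncRNA_transcript", "lncRNA_gene", "partnerRNA_gene",
            "direction", "type", "subtype", "distance", "isBest")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("classification table lacks columns: %s",
                          toString(miss))
  if (!all(df$direction %in% c("sense", "antisense")))
    stopf("direction must be sense or antisense")
  if (!all(df$type %in% c("genic", "intergenic")))
    stopf("type must be genic or intergenic")
  if (!all(df$isBest %in% c(0L, 1L))) stopf("isBest must be 0 or 1")
  if (any(df$distance < 0)) stopf("negative partner distance")
  if (any((df$distance == 0) != (df$type == "genic")))
    stopf("distance must be 0 exactly for genic classifications")
  data.frame(lncRNA_transcript_id = df$lncRNA_transcript,
             lncRNA_locus_id = df$lncRNA_gene,
             partner_locus_id = df$partnerRNA_gene,
             direction = df$direction, type = df$type, subtype = df$subtype,
             distance_bp = as.integer(df$distance),
             is_best = as.integer(df$isBest), stringsAsFactors = FALSE)
}

#' Write a FEELnc-style classification table
#' @param cls data.frame as returned by [read_feelnc_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feelnc_table <- function(cls, path) {
  out <- data.frame(lncRNA_transcript = cls$lncRNA_transcript_id,
                    lncRNA_gene = cls$lncRNA_locus_id,
                    partnerRNA_gene = cls$partner_locus_id,
                    direction = cls$direction, type = cls$type,
                    subtype = cls$subtype, distance = cls$distance_bp,
                    isBest = cls$is_best)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a metabolite abundance matrix
#'
#' TSV, first column metabolite ids, remaining columns samples; empty cells
#' or `NA` mark missing measurements.
#'
#' @param path TSV file path.
#' @return Numeric matrix (metabolites x samples), possibly with `NA`s.
#' @export
read_metabolites <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (nrow(m) < 1) stopf("metabolite table is empty")
  m
}

#' Write a metabolite matrix as TSV
#' @param metab numeric matrix with rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metabolites <- function(metab, path) {
  df <- data.frame(metabolite = rownames(metab), metab, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a design table as TSV
#' @param design data.frame with columns `sample`, `group`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
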