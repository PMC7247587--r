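#' Locus annotation sets
#'
#' An `annotation_set` holds a merged transcriptome annotation as three
#' linked data frames:
#' \describe{
#'   \item{loci}{`locus_id`, `chrom`, `start`, `end`, `strand`, `biotype`,
#'     `gene_symbol`, `is_reference_annotated`. Coordinates are 1-based
#'     inclusive.}
#'   \item{transcripts}{`locus_id`, `transcript_id`,
#'     `is_reference_annotated`.}
#'   \item{exons}{`transcript_id`, `start`, `end`; per transcript the exon
#'     intervals are sorted and non-overlapping after normalisation.}
#' }
#'
#' @param loci,transcripts,exons data frames as described above.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(loci, transcripts, exons) {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  need <- c("locus_id", "chrom", "start", "end", "strand", "biotype",
            "gene_symbol", "is_reference_annotated")
  miss <- setdiff(need, names(loci))
  if (length(miss)) stopf("loci table lacks columns: %s", toString(miss))
  if (!all(c("locus_id", "transcript_id") %in% names(transcripts)))
    stopf("transcripts table needs locus_id and transcript_id")
  if (!all(c("transcript_id", "start", "end") %in% names(exons)))
    stopf("exons table needs transcript_id, start, end")
  if (anyDuplicated(loci$locus_id)) stopf("duplicated locus_id in loci table")
  if (any(loci$start > loci$end)) stopf("locus with start > end")
  if (!all(loci$strand %in% c("+", "-"))) stopf("locus strand must be + or -")
  if (!all(transcripts$locus_id %in% loci$locus_id))
    stopf("transcript refers to unknown locus")
  if (!all(exons$transcript_id %in% transcripts$transcript_id))
    stopf("exon refers to unknown transcript")
  if (!all(transcripts$transcript_id %in% exons$transcript_id))
    stopf("transcript without exons")
  if (is.null(transcripts$is_reference_annotated))
    transcripts$is_reference_annotated <- loci$is_reference_annotated[
      match(transcripts$locus_id, loci$locus_id)]
  exons <- normalize_exons(exons)
  # every exon must lie inside its locus interval
  tx2loc <- setNames(transcripts$locus_id, transcripts$transcript_id)
  li <- match(tx2loc[exons$transcript_id], loci$locus_id)
  bad <- exons$start < loci$start[li] | exons$end > loci$end[li]
  if (any(bad))
    stopf("transcript %s has exons outside its locus interval",
          exons$transcript_id[which(bad)[1]])
  structure(list(loci = loci, transcripts = transcripts, exons = exons),
            class = "annotation_set")
}

# sort exons within transcript and merge overlapping/adjacent intervals
normalize_exons <- function(exons) {
  if (!nrow(exons)) return(exons)
  o <- order(exons$transcript_id, exons$start, exons$end)
  exons <- exons[o, , drop = FALSE]
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  keep <- lapply(sp, function(ix) {
    s <- exons$start[ix]; e <- exons$end[ix]
    if (any(s > e)) stopf("exon with start > end in transcript %s",
                          exons$transcript_id[ix[1]])
    ns <- s[1]; ne <- e[1]; os <- c(); oe <- c()
    if (length(ix) > 1) for (k in 2:length(ix)) {
      if (s[k] <= ne + 1) ne <- max(ne, e[k])
      else { os <- c(os, ns); oe <- c(oe, ne); ns <- s[k]; ne <- e[k] }
    }
    data.frame(transcript_id = exons$transcript_id[ix[1]],
               start = c(os, ns), end = c(oe, ne),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out[order(out$transcript_id, out$start), , drop = FALSE]
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d loci, %d transcripts, %d exons\n",
              nrow(x$loci), nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

#' Number of loci in an annotation set
#' @param ann an `annotation_set`.
#' @return integer count.
#' @export
n_loci <- function(ann) nrow(ann$loci)

#' Exonic length per locus
#'
#' Length of the union of all exon intervals across a locus's transcripts,
#' the denominator used for FPKM.
#'
#' @param ann an `annotation_set`.
#' @return Named integer vector (bp) indexed by locus_id.
#' @export
exonic_lengths <- function(ann) {
  tx2loc <- setNames(ann$transcripts$locus_id, ann$transcripts$transcript_id)
  loc <- tx2loc[ann$exons$transcript_id]
  gr <- GenomicRanges::GRanges(loc, IRanges::IRanges(ann$exons$start,
                                                     ann$exons$end))
  red <- GenomicRanges::reduce(GenomicRanges::split(gr,
                                                    GenomicRanges::seqnames(gr)))
  w <- sum(IRanges::width(red))
  out <- setNames(as.integer(w[ann$loci$locus_id]), ann$loci$locus_id)
  out
}

#' Locus-level GRanges view of an annotation set
#' @param ann an `annotation_set`.
#' @return A [GenomicRanges::GRanges] with locus metadata columns.
#' @export
loci_granges <- function(ann) {
  GenomicRanges::GRanges(
    ann$loci$chrom,
    IRanges::IRanges(ann$loci$start, ann$loci$end),
    strand = ann$loci$strand,
    locus_id = ann$loci$locus_id,
    biotype = ann$loci$biotype,
    gene_symbol = ann$loci$gene_symbol)
}

#' Read a GTF annotation into an annotation_set
#'
#' Parses an Ensembl-dialect GTF with `gene`, `transcript` and `exon`
#' features (via \pkg{rtracklayer}) after a light structural pre-scan that
#' reports malformed lines with their line number. Attributes beyond the
#' core set are preserved in the `extra_attributes` attribute of the result.
#'
#' @param path GTF file path.
#' @param novel_id_pattern regular expression identifying ids from a novel
#'   (non-reference) assembly; matching loci/transcripts are flagged
#'   `is_reference_annotated = FALSE`. Default `"^MSTRG"`.
#' @return An `annotation_set`.
#' @export
read_gtf <- function(path, novel_id_pattern = "^MSTRG") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9)
      stopf("malformed GTF line %d: expected 9 tab-separated fields, got %d",
            i, length(f))
    if (!f[3] %in% c("gene", "transcript", "exon")) next
    if (!f[7] %in% c("+", "-"))
      stopf("malformed GTF line %d: missing or invalid strand '%s'", i, f[7])
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e) || s > e)
      stopf("malformed GTF line %d: bad coordinates %s-%s", i, f[4], f[5])
  }
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  gid <- as.character(mc$gene_id)
  if (anyNA(gid[type %in% c("gene", "transcript", "exon")]))
    stopf("GTF feature without gene_id attribute")
  gsel <- type == "gene"
  if (!any(gsel)) stopf("GTF contains no gene features")
  sym <- if ("gene_name" %in% names(mc)) as.character(mc$gene_name) else
    rep(NA_character_, length(gr))
  bt <- if ("gene_biotype" %in% names(mc)) as.character(mc$gene_biotype) else
    rep(NA_character_, length(gr))
  loci <- data.frame(
    locus_id = gid[gsel],
    chrom = as.character(GenomicRanges::seqnames(gr))[gsel],
    start = GenomicRanges::start(gr)[gsel],
    end = GenomicRanges::end(gr)[gsel],
    strand = as.character(GenomicRanges::strand(gr))[gsel],
    biotype = bt[gsel],
    gene_symbol = sym[gsel],
    is_reference_annotated = !grepl(novel_id_pattern, gid[gsel]),
    stringsAsFactors = FALSE)
  tsel <- type == "transcript"
  tid <- as.character(mc$transcript_id)
  transcripts <- data.frame(
    locus_id = gid[tsel],
    transcript_id = tid[tsel],
    is_reference_annotated = !grepl(novel_id_pattern, tid[tsel]),
    stringsAsFactors = FALSE)
  esel <- type == "exon"
  exons <- data.frame(
    transcript_id = tid[esel],
    start = GenomicRanges::start(gr)[esel],
    end = GenomicRanges::end(gr)[esel],
    stringsAsFactors = FALSE)
  core <- c("type", "gene_id", "transcript_id", "gene_name", "gene_biotype",
            "source", "score", "phase")
  extra <- setdiff(names(mc), core)
  ann <- annotation_set(loci, transcripts, exons)
  if (length(extra)) {
    ex <- as.data.frame(mc[gsel, extra, drop = FALSE])
    ex$locus_id <- gid[gsel]
    attr(ann, "extra_attributes") <- ex
  }
  ann
}

#' Write an annotation_set to GTF
#'
#' Emits gene, transcript and exon rows with `gene_id`, `transcript_id`,
#' `gene_biotype` and `gene_name` attributes so that
#' `read_gtf(write_gtf(x))` round-trips.
#'
#' @param ann an `annotation_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  l <- ann$loci; t <- ann$transcripts; e <- ann$exons
  tx2loc <- setNames(t$locus_id, t$transcript_id)
  li_t <- match(t$locus_id, l$locus_id)
  li_e <- match(tx2loc[e$transcript_id], l$locus_id)
  # transcript spans derived from exons
  sp <- tapply(seq_len(nrow(e)), e$transcript_id, identity)
  t_start <- vapply(sp, function(ix) min(e$start[ix]), numeric(1))
  t_end <- vapply(sp, function(ix) max(e$end[ix]), numeric(1))
  ti <- match(t$transcript_id, names(sp))
  rows <- rbind(
    data.frame(chrom = l$chrom, start = l$start, end = l$end,
               strand = l$strand, type = "gene", gene_id = l$locus_id,
               transcript_id = NA_character_, biotype = l$biotype,
               symbol = l$gene_symbol, stringsAsFactors = FALSE),
    data.frame(chrom = l$chrom[li_t], start = t_start[ti], end = t_end[ti],
               strand = l$strand[li_t], type = "transcript",
               gene_id = t$locus_id, transcript_id = t$transcript_id,
               biotype = l$biotype[li_t], symbol = l$gene_symbol[li_t],
               stringsAsFactors = FALSE),
    data.frame(chrom = l$chrom[li_e], start = e$start, end = e$end,
               strand = l$strand[li_e], type = "exon",
               gene_id = tx2loc[e$transcript_id],
               transcript_id = e$transcript_id,
               biotype = l$biotype[li_e],
               symbol = l$gene_symbol[li_e], stringsAsFactors = FALSE))
  o <- order(rows$chrom, rows$start,
             match(rows$type, c("gene", "transcript", "exon")))
  rows <- rows[o, , drop = FALSE]
  gr <- GenomicRanges::GRanges(rows$chrom,
                               IRanges::IRanges(rows$start, rows$end),
                               strand = rows$strand)
  S4Vectors::mcols(gr)$type <- rows$type
  S4Vectors::mcols(gr)$gene_id <- rows$gene_id
  S4Vectors::mcols(gr)$transcript_id <- rows$transcript_id
  S4Vectors::mcols(gr)$gene_biotype <- rows$biotype
  S4Vectors::mcols(gr)$gene_name <- rows$symbol
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Plausibility filtering of a merged annotation
#'
#' Removes loci with implausibly many transcripts and transcripts with
#' implausibly many exons. A locus with more than `max_transcripts`
#' transcripts is dropped entirely unless at least one of its transcripts is
#' reference-annotated, in which case only the reference-annotated
#' transcript(s) are retained. Transcripts with more than `max_exons` exons
#' are dropped unless their locus is whitelisted (the escape hatch used for
#' extreme but genuine genes such as titin).
#'
#' @param ann an `annotation_set`.
#' @param max_transcripts maximum transcripts per locus (default 20).
#' @param max_exons maximum exons per transcript (default 200).
#' @param exon_whitelist character vector of locus_ids exempt from the exon
#'   rule.
#' @return A filtered `annotation_set`. Idempotent.
#' @export
filter_merged_annotation <- function(ann, max_transcripts = 20,
                                     max_exons = 200,
                                     exon_whitelist = character()) {
  t <- ann$transcripts
  e <- ann$exons
  ntx <- table(t$locus_id)
  over <- names(ntx)[ntx > max_transcripts]
  drop_tx <- rep(FALSE, nrow(t))
  drop_loc <- character()
  for (loc in over) {
    ix <- which(t$locus_id == loc)
    ref <- t$is_reference_annotated[ix]
    if (any(ref)) drop_tx[ix[!ref]] <- TRUE else drop_loc <- c(drop_loc, loc)
  }
  nex <- table(e$transcript_id)
  many <- names(nex)[nex > max_exons]
  if (length(many)) {
    loc_of <- setNames(t$locus_id, t$transcript_id)
    many <- many[!loc_of[many] %in% exon_whitelist]
    drop_tx[t$transcript_id %in% many] <- TRUE
  }
  t2 <- t[!drop_tx & !t$locus_id %in% drop_loc, , drop = FALSE]
  keep_loc <- unique(t2$locus_id)
  l2 <- ann$loci[ann$loci$locus_id %in% keep_loc, , drop = FALSE]
  e2 <- e[e$transcript_id %in% t2$transcript_id, , drop = FALSE]
  rownames(l2) <- rownames(t2) <- rownames(e2) <- NULL
  out <- annotation_set(l2, t2, e2)
  attr(out, "extra_attributes") <- attr(ann, "extra_attributes")
  out
}
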