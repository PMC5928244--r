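#' Construct a peak set
#'
#' Container for called 3'-seq peaks: interval table, per-sample counts,
#' optional per-sample read-start multisets (from which the per-sample
#' interquartile range of read starts is computed), and artifact flags.
#' The 3' end coordinate (\code{end3}, 0-based base of the cleavage site)
#' is the interval end - 1 on "+" and the interval start on "-".
#'
#' @param info data.table/data.frame with columns chrom, start, end, strand
#'   (0-based half-open) and optionally peak_id.
#' @param counts integer matrix, peaks x samples (rows match \code{info}).
#' @param starts optional long table (peak_id, sample, pos, n) of read-start
#'   multisets.
#' @return object of class \code{PeakSet}.
#' @export
peak_set <- function(info, counts, starts = NULL) {
  info <- data.table::as.data.table(info)
  stopifnot(nrow(info) == nrow(counts), all(counts >= 0))
  if (is.null(info$peak_id)) info$peak_id <- sprintf("P%05d", seq_len(nrow(info)))
  rownames(counts) <- info$peak_id
  info$end3 <- ifelse(info$strand == "+", info$end - 1L, info$start)
  for (f in c("blacklist", "internal_priming", "antisense", "immunoglobulin",
              "ambiguous_gene", "smallrna", "convergent_3utr_proximal",
              "upstream_gene_proximal"))
    info[[paste0("flag_", f)]] <- FALSE
  iqr <- matrix(NA_real_, nrow(info), ncol(counts),
                dimnames = dimnames(counts))
  if (!is.null(starts)) {
    starts <- data.table::as.data.table(starts)
    pos <- n <- peak_id <- NULL
    agg <- starts[, list(iqr = weighted_iqr(pos, n)), by = c("peak_id", "sample")]
    iqr[cbind(match(agg$peak_id, info$peak_id),
              match(agg$sample, colnames(counts)))] <- agg$iqr
  }
  structure(list(info = info, counts = counts, iqr = iqr, starts = starts,
                 lib = NULL), class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet: %d peaks x %d samples (%d flagged)\n",
              nrow(x$info), ncol(x$counts), sum(peak_flagged(x))))
  invisible(x)
}

#' Logical vector: is each peak flagged by any artifact/context filter?
#' @param peaks a \code{PeakSet}.
#' @export
peak_flagged <- function(peaks) {
  fcols <- grep("^flag_", names(peaks$info), value = TRUE)
  Reduce(`|`, peaks$info[, fcols, with = FALSE])
}

#' Assign peaks to genes and genomic regions
#'
#' A peak is assigned to the gene whose transcription unit it overlaps on
#' the same strand; its region (UTR3 / INTRON / EXON / OUTSIDE) is that of
#' its 3'-end base.  Peaks overlapping a single gene only on the opposite
#' strand keep \code{gene_id = NA} but record the antisense candidate for
#' the artifact filter.
#'
#' @param peaks a \code{PeakSet}.
#' @param ann a \code{GenomeAnnotation}.
#' @return the \code{PeakSet} with columns gene_id, region, intron_tx,
#'   n_sense, n_antisense added to \code{info}.
#' @export
assign_peaks <- function(peaks, ann) {
  info <- peaks$info
  genes <- ann$genes
  gtab <- data.table::data.table(
    gene_id = names(genes),
    chrom = vapply(genes, `[[`, "", "chrom"),
    start = vapply(genes, `[[`, 0L, "start"),
    end = vapply(genes, `[[`, 0L, "end"),
    strand = vapply(genes, `[[`, "", "strand"))
  pk <- GenomicRanges::GRanges(info$chrom,
                               IRanges::IRanges(info$start + 1L, info$end))
  gn <- GenomicRanges::GRanges(gtab$chrom,
                               IRanges::IRanges(gtab$start + 1L, gtab$end))
  hits <- GenomicRanges::findOverlaps(pk, gn, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  same <- info$strand[qh] == gtab$strand[sh]

  info$gene_id <- NA_character_
  info$region <- "OUTSIDE"
  info$intron_tx <- NA_integer_
  info$n_sense <- tabulate(qh[same], nrow(info))
  info$n_antisense <- tabulate(qh[!same], nrow(info))
  info$antisense_gene <- NA_character_
  # first sense gene (sim genes never overlap; real overlaps are handled by
  # the ambiguous-gene filter downstream)
  if (any(same)) {
    first <- !duplicated(qh[same])
    info$gene_id[qh[same][first]] <- gtab$gene_id[sh[same][first]]
  }
  if (any(!same)) {
    first <- !duplicated(qh[!same])
    info$antisense_gene[qh[!same][first]] <- gtab$gene_id[sh[!same][first]]
  }
  for (r in which(!is.na(info$gene_id))) {
    cl <- classify_position(genes[[info$gene_id[r]]], info$end3[r])
    info$region[r] <- cl$region
    info$intron_tx[r] <- if (cl$region == "INTRON") cl$index else NA_integer_
  }
  peaks$info <- info
  peaks
}

#' Write a peak set to plain-text files
#'
#' Emits BED6 intervals (0-based), a per-sample count TSV, and the
#' read-start multiset TSV; the inverse of \code{\link{read_peaks}}.
#'
#' @param peaks a \code{PeakSet}.
#' @param dir output directory.
#' @export
write_peaks <- function(peaks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bed <- peaks$info[, c("chrom", "start", "end", "peak_id", "strand"), with = FALSE]
  bed <- data.table::data.table(bed[, 1:4], score = 0L, strand = bed$strand)
  data.table::fwrite(bed, file.path(dir, "peaks.bed"), sep = "\t",
                     col.names = FALSE)
  cnt <- data.table::data.table(peak_id = peaks$info$peak_id)
  for (s in colnames(peaks$counts)) cnt[[s]] <- peaks$counts[, s]
  data.table::fwrite(cnt, file.path(dir, "peak_counts.tsv"), sep = "\t")
  if (!is.null(peaks$starts))
    data.table::fwrite(peaks$starts, file.path(dir, "read_starts.tsv"), sep = "\t")
  invisible(dir)
}

#' Read a peak set written by \code{\link{write_peaks}}
#'
#' @param bed,counts_tsv,starts_tsv file paths; \code{starts_tsv} optional.
#' @return a \code{PeakSet}.
#' @export
read_peaks <- function(bed, counts_tsv, starts_tsv = NULL) {
  iv <- read_bed(bed)
  data.table::setnames(iv, "name", "peak_id")
  cnt <- data.table::fread(counts_tsv)
  stopifnot(identical(iv$peak_id, cnt$peak_id))
  m <- as.matrix(cnt[, -1L])
  rownames(m) <- cnt$peak_id
  starts <- if (!is.null(starts_tsv)) data.table::fread(starts_tsv) else NULL
  peak_set(iv[, c("chrom", "start", "end", "strand", "peak_id"), with = FALSE],
           m, starts)
}
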