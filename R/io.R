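# File I/O helpers.  Internal coordinates are 0-based half-open; BED and
# bedGraph files are 0-based on disk (rtracklayer converts to 1-based
# GRanges, undone here), GTF is 1-based inclusive.

#' Read a BED file as a 0-based interval table
#' @param path BED3/BED6 path.
#' @return data.table with chrom, start, end and, when present, name,
#'   score, strand.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr))
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  out$score <- gr$score %||% 0L
  st <- as.character(GenomicRanges::strand(gr))
  out$strand <- ifelse(st == "*", NA_character_, st)
  out
}

#' Write a 0-based interval table as BED6
#' @param iv data.table with chrom, start, end, optional name/score/strand.
#' @param path output path.
#' @export
write_bed <- function(iv, path) {
  iv <- data.table::as.data.table(iv)
  bed <- data.table::data.table(
    chrom = iv$chrom, start = iv$start, end = iv$end,
    name = iv$name %||% ".", score = iv$score %||% 0L,
    strand = iv$strand %||% ".")
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph as per-chromosome run-length coverage
#'
#' @param path bedGraph path.
#' @param chrom_len named vector of chromosome lengths (bases beyond the
#'   last record are zero-filled).
#' @return named list of \code{Rle}, one per chromosome.
#' @export
read_bedgraph <- function(path, chrom_len) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomeInfoDb::seqlevels(gr) <- names(chrom_len)
  GenomeInfoDb::seqlengths(gr) <- unname(chrom_len)
  cov <- GenomicRanges::coverage(gr, weight = gr$score)
  as.list(cov)[names(chrom_len)]
}

#' Write per-chromosome run-length coverage as bedGraph
#'
#' @param track named list of \code{Rle} (one per chromosome).
#' @param path output path.
#' @param drop_zero omit zero-valued runs (default TRUE).
#' @export
write_bedgraph <- function(track, path, drop_zero = TRUE) {
  rows <- lapply(names(track), function(ch) {
    v <- track[[ch]]
    ends <- cumsum(S4Vectors::runLength(v))
    starts <- ends - S4Vectors::runLength(v)
    val <- S4Vectors::runValue(v)
    keep <- if (drop_zero) val != 0 else rep(TRUE, length(val))
    data.table::data.table(chrom = ch, start = starts[keep],
                           end = ends[keep], score = val[keep])
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Write the complete synthetic dataset to a directory
#'
#' Emits every input the pipeline consumes: annotation GTF, genome FASTA,
#' 3'-seq peak files, sample sheet, blacklist/immunoglobulin/external-peak
#' BEDs, per-sample coverage bedGraphs, junction TSV, mappability bedGraph,
#' unmapped polyA-read FASTA, and truth tables for ground-truth comparison.
#'
#' @param sim an \code{IpaSim} after \code{\link{simulate_threeprime}} (and
#'   optionally \code{\link{simulate_rnaseq}}).
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gtf(sim$annotation, file.path(dir, "annotation.gtf"))
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_bed(sim$blacklist, file.path(dir, "blacklist.bed"))
  write_bed(sim$ig, file.path(dir, "ig.bed"))
  tp <- sim$threeprime
  if (!is.null(tp)) {
    pk <- peak_set(tp$peaks[, c("chrom", "start", "end", "strand", "peak_id"),
                            with = FALSE], tp$counts, tp$starts)
    write_peaks(pk, dir)
    data.table::fwrite(tp$samples, file.path(dir, "samples.tsv"), sep = "\t")
    data.table::fwrite(tp$peaks, file.path(dir, "truth_peaks.tsv"), sep = "\t")
    write_bed(simulate_external_3p(sim), file.path(dir, "external3p.bed"))
  }
  rn <- sim$rnaseq
  if (!is.null(rn)) {
    for (s in names(rn$coverage))
      write_bedgraph(rn$coverage[[s]],
                     file.path(dir, sprintf("coverage_%s.bedgraph", s)))
    write_bedgraph(rn$mappability, file.path(dir, "mappability.bedgraph"))
    data.table::fwrite(rn$junctions, file.path(dir, "junctions.tsv"), sep = "\t")
    Biostrings::writeXStringSet(rn$polya_reads, file.path(dir, "polya_reads.fa"))
    data.table::fwrite(rn$truth_ir, file.path(dir, "truth_introns.tsv"), sep = "\t")
  }
  invisible(dir)
}
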