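#' Gene model
#'
#' A single gene in internal coordinates (0-based, half-open).  Exon/intron/CDS
#' intervals are stored genomically ascending; transcription order is ascending
#' on "+" and descending on "-".  The CDS is that of the transcript with the
#' longest summed CDS (ties broken by transcript id), per the "longest
#' annotated open reading frame" convention used throughout.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param transcripts named list; each element a list with elements
#'   \code{exons} (two-column start/end matrix) and optionally \code{cds}.
#' @param biotype gene biotype string.
#' @return object of class \code{GeneModel}.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts,
                       biotype = "protein_coding") {
  stopifnot(strand %in% c("+", "-"), length(transcripts) >= 1L)
  ex_all <- do.call(rbind, lapply(transcripts, `[[`, "exons"))
  exons <- iv_union(ex_all)
  start <- min(exons[, 1L]); end <- max(exons[, 2L])
  introns <- iv_complement(exons, start, end)
  introns <- introns[introns[, 2L] > introns[, 1L], , drop = FALSE]

  # longest annotated ORF: maximal summed CDS, ties by transcript id
  cds_len <- vapply(transcripts, function(tr) {
    if (is.null(tr$cds) || nrow(tr$cds) == 0L) 0 else sum(tr$cds[, 2L] - tr$cds[, 1L])
  }, numeric(1))
  cds <- NULL; cds_tx <- NA_character_; utr3 <- NULL
  if (any(cds_len > 0)) {
    cand <- names(transcripts)[cds_len == max(cds_len)]
    cds_tx <- sort(cand)[1L]
    cds <- transcripts[[cds_tx]]$cds
    cds <- cds[order(cds[, 1L]), , drop = FALSE]
    # 3'UTR: exonic part of the ORF transcript downstream of the CDS end
    tex <- transcripts[[cds_tx]]$exons
    tex <- tex[order(tex[, 1L]), , drop = FALSE]
    if (strand == "+") {
      ce <- max(cds[, 2L])
      u <- tex[tex[, 2L] > ce, , drop = FALSE]
      if (nrow(u)) u[, 1L] <- pmax(u[, 1L], ce)
    } else {
      cs <- min(cds[, 1L])
      u <- tex[tex[, 1L] < cs, , drop = FALSE]
      if (nrow(u)) u[, 2L] <- pmin(u[, 2L], cs)
    }
    if (nrow(u)) utr3 <- u
  }
  structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = start, end = end,
    tss = if (strand == "+") start else end - 1L,
    transcripts = transcripts,
    exons = exons, introns = introns,
    cds = cds, cds_transcript = cds_tx, utr3 = utr3,
    biotype = biotype
  ), class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s) %s:%d-%d  %d exon(s), %d intron(s), %s\n",
              x$gene_id, x$strand, x$chrom, x$start, x$end,
              nrow(x$exons), nrow(x$introns), x$biotype))
  invisible(x)
}

#' Number of introns in transcription order
#' @export
n_introns <- function(gene) nrow(gene$introns)

# intron index (1-based, transcription order) for genomic intron row i
.intron_tx_index <- function(gene, i) {
  if (gene$strand == "+") i else nrow(gene$introns) - i + 1L
}

# genomic row of intron with transcription-order index k
.intron_row <- function(gene, k) {
  if (gene$strand == "+") k else nrow(gene$introns) - k + 1L
}

#' Intron interval by transcription-order index
#' @export
intron_interval <- function(gene, k) {
  gene$introns[.intron_row(gene, k), , drop = TRUE]
}

#' Load a genome annotation from GTF
#'
#' Reads gene/transcript/exon/CDS features, converts the 1-based inclusive
#' GTF coordinates to internal 0-based half-open intervals, derives introns,
#' and flags genes whose transcription units overlap any other gene on either
#' strand (a single shared nucleotide suffices).  Intronic small-RNA loci may
#' be supplied as an interval table for downstream ambiguity filtering.
#'
#' @param gtf_path path to a GTF file.
#' @param smallrna optional data.frame (chrom, start, end) of miRNA/snoRNA/
#'   retrotransposon loci, 0-based half-open.
#' @return object of class \code{GenomeAnnotation}: list with \code{genes}
#'   (named list of \code{GeneModel}), \code{overlap_flags} (character vector
#'   of gene ids), \code{smallrna}.
#' @export
load_annotation <- function(gtf_path, smallrna = NULL) {
  .validate_gtf_lines(gtf_path)
  gr <- tryCatch(
    rtracklayer::import(gtf_path, format = "gtf"),
    error = function(e) stop("GTF parse error in ", gtf_path, ": ",
                             conditionMessage(e), call. = FALSE))
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  ex <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (!nrow(ex)) stop("no exon/CDS features in ", gtf_path)

  genes <- list()
  for (gid in unique(ex$gene_id)) {
    sub <- ex[ex$gene_id == gid, , drop = FALSE]
    biotype <- sub$gene_biotype[1L] %||% "protein_coding"
    if (is.null(sub$gene_biotype)) biotype <- "protein_coding"
    trs <- list()
    for (tid in unique(sub$transcript_id)) {
      tsub <- sub[sub$transcript_id == tid, , drop = FALSE]
      exr <- tsub[tsub$type == "exon", , drop = FALSE]
      if (!nrow(exr)) {
        warning("transcript ", tid, " has no exons; skipped")
        next
      }
      cdr <- tsub[tsub$type == "CDS", , drop = FALSE]
      trs[[tid]] <- list(
        exons = .df_iv(exr),
        cds = if (nrow(cdr)) .df_iv(cdr) else NULL)
    }
    if (!length(trs)) next
    genes[[gid]] <- gene_model(gid, sub$seqnames[1L], sub$strand[1L], trs,
                               biotype = ifelse(is.na(biotype), "protein_coding", biotype))
  }
  ann <- structure(list(genes = genes,
                        overlap_flags = character(0),
                        smallrna = smallrna),
                   class = "GenomeAnnotation")
  ann$overlap_flags <- .flag_overlapping_genes(ann)
  ann
}

.df_iv <- function(d) {
  m <- matrix(c(d$start - 1L, d$end), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  m[order(m[, 1L]), , drop = FALSE]
}

.validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L)) {
    bad <- which(body)[which(nf < 8L)[1L]]
    stop("malformed GTF record at line ", bad, " of ", path, call. = FALSE)
  }
  pos_ok <- vapply(fields, function(f)
    !is.na(suppressWarnings(as.integer(f[4L]))) &&
    !is.na(suppressWarnings(as.integer(f[5L]))), logical(1))
  if (any(!pos_ok)) {
    bad <- which(body)[which(!pos_ok)[1L]]
    stop("malformed GTF coordinates at line ", bad, " of ", path, call. = FALSE)
  }
  invisible(TRUE)
}

.flag_overlapping_genes <- function(ann) {
  g <- ann$genes
  if (length(g) < 2L) return(character(0))
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(g, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(start = vapply(g, `[[`, 0L, "start") + 1L,
                              end = vapply(g, `[[`, 0L, "end")))
  hits <- GenomicRanges::findOverlaps(gr, ignore.strand = TRUE,
                                      drop.self = TRUE, drop.redundant = FALSE)
  sort(unique(names(g)[S4Vectors::queryHits(hits)]))
}

#' Classify a genomic position within a gene
#'
#' Region precedence: positions in the annotated 3'UTR report \code{UTR3};
#' otherwise introns, then exons, with indices counted in transcription order.
#'
#' @param gene a \code{GeneModel}.
#' @param pos 0-based genomic position.
#' @return list with \code{region} in \{"UTR3","INTRON","EXON","OUTSIDE"\}
#'   and \code{index} (1-based transcription-order index, NA for UTR3/OUTSIDE).
#' @export
classify_position <- function(gene, pos) {
  if (pos < gene$start || pos >= gene$end)
    return(list(region = "OUTSIDE", index = NA_integer_))
  if (!is.null(gene$utr3) &&
      any(pos >= gene$utr3[, 1L] & pos < gene$utr3[, 2L]))
    return(list(region = "UTR3", index = NA_integer_))
  if (nrow(gene$introns)) {
    hit <- which(pos >= gene$introns[, 1L] & pos < gene$introns[, 2L])
    if (length(hit))
      return(list(region = "INTRON", index = .intron_tx_index(gene, hit)))
  }
  hit <- which(pos >= gene$exons[, 1L] & pos < gene$exons[, 2L])
  if (length(hit)) {
    idx <- if (gene$strand == "+") hit else nrow(gene$exons) - hit + 1L
    return(list(region = "EXON", index = idx))
  }
  list(region = "OUTSIDE", index = NA_integer_)
}

#' Coding nucleotides upstream of an intronic position
#'
#' Counts coding nucleotides from the start codon through the end of the last
#' coding exon 5' of \code{pos} (which must lie in an intron).  Returns 0 when
#' the position precedes the start codon.
#'
#' @inheritParams classify_position
#' @return nucleotide count.
#' @export
upstream_cds_length <- function(gene, pos) {
  cl <- classify_position(gene, pos)
  if (cl$region != "INTRON")
    stop("position ", pos, " is not intronic in gene ", gene$gene_id)
  if (is.null(gene$cds)) return(NA_integer_)
  cds <- gene$cds
  if (gene$strand == "+") {
    keep <- cds[, 2L] <= pos
  } else {
    keep <- cds[, 1L] > pos
  }
  as.integer(sum(cds[keep, 2L] - cds[keep, 1L]))
}

#' Total CDS length of the longest annotated ORF
#' @export
cds_length <- function(gene) {
  if (is.null(gene$cds)) return(NA_integer_)
  as.integer(sum(gene$cds[, 2L] - gene$cds[, 1L]))
}

# 3'-most coordinate of the gene's 3'UTR in transcription orientation
# (the annotated transcript end of the ORF transcript), 0-based position of
# the last transcribed base + orientation handled by caller.
.utr3_end <- function(gene) {
  if (is.null(gene$utr3)) return(NA_integer_)
  if (gene$strand == "+") max(gene$utr3[, 2L]) else min(gene$utr3[, 1L])
}

#' Last exons of every transcript
#'
#' @param ann a \code{GenomeAnnotation}.
#' @return data.table with chrom, start, end, strand, gene_id, transcript_id
#'   of each transcript's 3'-most exon (0-based half-open).
#' @export
last_exons <- function(ann) {
  rows <- lapply(ann$genes, function(g) {
    lapply(names(g$transcripts), function(tid) {
      ex <- g$transcripts[[tid]]$exons
      le <- if (g$strand == "+") ex[which.max(ex[, 2L]), ] else ex[which.min(ex[, 1L]), ]
      data.table::data.table(chrom = g$chrom, start = le[1L], end = le[2L],
                             strand = g$strand, gene_id = g$gene_id,
                             transcript_id = tid)
    })
  })
  data.table::rbindlist(unlist(rows, recursive = FALSE))
}

#' Write derived introns as BED
#'
#' @param ann a \code{GenomeAnnotation}.
#' @param path output BED path (0-based, BED6; name = gene:intron index).
#' @export
write_introns_bed <- function(ann, path) {
  rows <- lapply(ann$genes, function(g) {
    if (!nrow(g$introns)) return(NULL)
    idx <- vapply(seq_len(nrow(g$introns)), function(i) .intron_tx_index(g, i), 1L)
    data.table::data.table(chrom = g$chrom, start = g$introns[, 1L],
                           end = g$introns[, 2L],
                           name = paste0(g$gene_id, ":I", idx),
                           score = 0L, strand = g$strand)
  })
  bed <- data.table::rbindlist(rows)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a GenomeAnnotation to GTF (1-based inclusive)
#' @param ann a \code{GenomeAnnotation}.
#' @param path output path.
#' @export
write_gtf <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(chrom, feat, s, e, strand, attr)
    sprintf("%s\tipaAtlas\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, feat, s, e, strand, attr)
  out <- character(0)
  for (g in ann$genes) {
    ga <- sprintf('gene_id "%s"; gene_biotype "%s";', g$gene_id, g$biotype)
    out <- c(out, fmt(g$chrom, "gene", g$start + 1L, g$end, g$strand, ga))
    for (tid in names(g$transcripts)) {
      ta <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                    g$gene_id, tid, g$biotype)
      tr <- g$transcripts[[tid]]
      out <- c(out,
               fmt(g$chrom, "transcript", min(tr$exons[, 1L]) + 1L,
                   max(tr$exons[, 2L]), g$strand, ta),
               fmt(g$chrom, "exon", tr$exons[, 1L] + 1L, tr$exons[, 2L],
                   g$strand, ta))
      if (!is.null(tr$cds))
        out <- c(out, fmt(g$chrom, "CDS", tr$cds[, 1L] + 1L, tr$cds[, 2L],
                          g$strand, ta))
    }
  }
  writeLines(out, con)
  invisible(path)
}
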