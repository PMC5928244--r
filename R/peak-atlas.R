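# Filter cascade -> clustering -> quantification.  Flags are monotone: each
# filter only sets flags, depending solely on the raw peak, the genome and
# the annotation, so the cascade is order-insensitive.

#' Flag artifact peaks: blacklist overlap, internal priming, antisense
#'
#' Blacklist: >= 1 nt overlap with a blacklisted interval.  Internal
#' priming: the genomic sequence immediately downstream of the 3' end
#' (transcription orientation) contains a run of >= \code{ip_run}
#' consecutive A, or >= \code{ip_count} A within \code{ip_window} nt.
#' Antisense: the peak overlaps at least one gene, all on the opposite
#' strand only.
#'
#' @param peaks a \code{PeakSet} after \code{\link{assign_peaks}}.
#' @param blacklist interval table (chrom, start, end), 0-based; may be
#'   empty or NULL.
#' @param genome a \code{DNAStringSet}.
#' @param ip_run,ip_count,ip_window internal-priming thresholds.
#' @return the \code{PeakSet} with flags set.
#' @export
filter_artifact_peaks <- function(peaks, blacklist, genome,
                                  ip_run = 6L, ip_count = 7L, ip_window = 10L) {
  info <- peaks$info
  if (!is.null(blacklist) && nrow(blacklist)) {
    pk <- GenomicRanges::GRanges(info$chrom,
                                 IRanges::IRanges(info$start + 1L, info$end))
    bl <- GenomicRanges::GRanges(blacklist$chrom,
                                 IRanges::IRanges(blacklist$start + 1L,
                                                  blacklist$end))
    hit <- GenomicRanges::countOverlaps(pk, bl) > 0L
    info$flag_blacklist <- info$flag_blacklist | hit
  }
  chrom_len <- setNames(Biostrings::width(genome), names(genome))
  run_pat <- strrep("A", ip_run)
  for (r in seq_len(nrow(info))) {
    if (info$end[r] > chrom_len[[info$chrom[r]]][1] ||
        info$start[r] < 0)
      stop("peak ", info$peak_id[r], " beyond chromosome end")
    p <- info$end3[r]
    down <- if (info$strand[r] == "+") {
      genome_seq(genome, info$chrom[r], p + 1L,
                 min(p + 1L + ip_window, chrom_len[[info$chrom[r]]]))
    } else {
      genome_seq(genome, info$chrom[r], max(0L, p - ip_window), p, strand = "-")
    }
    n_a <- sum(strsplit(down, "")[[1L]] == "A")
    if (grepl(run_pat, down, fixed = TRUE) || n_a >= ip_count)
      info$flag_internal_priming[r] <- TRUE
  }
  info$flag_antisense <- info$flag_antisense |
    (info$n_sense == 0L & info$n_antisense > 0L)
  peaks$info <- info
  peaks
}

#' Mask immunoglobulin loci and adjust library sizes
#'
#' Peaks overlapping immunoglobulin intervals are flagged; the adjusted
#' library size of every sample is its raw size minus the counts of all
#' flagged peaks (artifacts and immunoglobulin), since those reads stem
#' from artifacts or skewed expression of specific regions.
#'
#' @param peaks a \code{PeakSet}.
#' @param ig_intervals interval table (chrom, start, end) or NULL/empty.
#' @return the \code{PeakSet} with flags set and \code{lib} (data.table:
#'   sample, raw, adjusted) attached.
#' @export
mask_ig_adjust_library <- function(peaks, ig_intervals = NULL) {
  info <- peaks$info
  if (!is.null(ig_intervals) && nrow(ig_intervals)) {
    pk <- GenomicRanges::GRanges(info$chrom,
                                 IRanges::IRanges(info$start + 1L, info$end))
    ig <- GenomicRanges::GRanges(ig_intervals$chrom,
                                 IRanges::IRanges(ig_intervals$start + 1L,
                                                  ig_intervals$end))
    info$flag_immunoglobulin <- info$flag_immunoglobulin |
      (GenomicRanges::countOverlaps(pk, ig) > 0L)
  }
  peaks$info <- info
  raw <- colSums(peaks$counts)
  flagged <- peak_flagged(peaks)
  removed <- if (any(flagged)) colSums(peaks$counts[flagged, , drop = FALSE]) else 0
  adjusted <- raw - removed
  if (any(adjusted <= 0)) stop("adjusted library size non-positive")
  peaks$lib <- data.table::data.table(sample = colnames(peaks$counts),
                                      raw = raw, adjusted = adjusted)
  peaks
}

#' Flag peaks with an ambiguous or misleading gene context
#'
#' Four rules: (1) peaks of genes whose transcription units overlap another
#' gene on either strand; (2) intronic peaks overlapping small-RNA loci
#' (miRNA/snoRNA/retrotransposon); (3) intronic peaks whose 3' end lies
#' within \code{convergent_nt} of the annotated 3'UTR end of an
#' opposite-strand gene; (4) intronic peaks within \code{upstream_nt}
#' downstream of the 3'UTR end of the upstream same-strand gene.
#'
#' @param peaks a \code{PeakSet} after \code{\link{assign_peaks}}.
#' @param ann a \code{GenomeAnnotation}.
#' @param convergent_nt,upstream_nt rule distances (nt).
#' @return the \code{PeakSet} with flags set.
#' @export
filter_gene_context <- function(peaks, ann, convergent_nt = 100L,
                                upstream_nt = 5000L) {
  info <- peaks$info
  info$flag_ambiguous_gene <- info$flag_ambiguous_gene |
    (!is.na(info$gene_id) & info$gene_id %in% ann$overlap_flags) |
    (info$n_sense > 1L)
  intronic <- !is.na(info$gene_id) & info$region == "INTRON"
  if (!is.null(ann$smallrna) && nrow(ann$smallrna) && any(intronic)) {
    pk <- GenomicRanges::GRanges(info$chrom,
                                 IRanges::IRanges(info$start + 1L, info$end))
    sr <- GenomicRanges::GRanges(ann$smallrna$chrom,
                                 IRanges::IRanges(ann$smallrna$start + 1L,
                                                  ann$smallrna$end))
    info$flag_smallrna <- info$flag_smallrna |
      (intronic & GenomicRanges::countOverlaps(pk, sr) > 0L)
  }
  ends <- data.table::data.table(
    gene_id = names(ann$genes),
    chrom = vapply(ann$genes, `[[`, "", "chrom"),
    strand = vapply(ann$genes, `[[`, "", "strand"),
    utr_end = vapply(ann$genes, function(g) {
      e <- .utr3_end(g)
      # genomic base of the terminal transcribed nt
      if (is.na(e)) NA_real_ else if (g$strand == "+") e - 1 else e
    }, numeric(1)))
  ends <- ends[!is.na(ends$utr_end), ]
  for (r in which(intronic)) {
    p <- info$end3[r]
    other <- ends[ends$gene_id != info$gene_id[r] & ends$chrom == info$chrom[r], ]
    conv <- other[other$strand != info$strand[r] &
                    abs(other$utr_end - p) <= convergent_nt, ]
    if (nrow(conv)) info$flag_convergent_3utr_proximal[r] <- TRUE
    same <- other[other$strand == info$strand[r], ]
    d <- if (info$strand[r] == "+") p - same$utr_end else same$utr_end - p
    if (any(d >= 0 & d <= upstream_nt))
      info$flag_upstream_gene_proximal[r] <- TRUE
  }
  peaks$info <- info
  peaks
}

#' Per-sample TPM (tags per million of the adjusted library)
#'
#' @param peaks a \code{PeakSet} with \code{lib} attached
#'   (\code{\link{mask_ig_adjust_library}}).
#' @return numeric matrix, peaks x samples.
#' @export
quantify_tpm <- function(peaks) {
  if (is.null(peaks$lib)) stop("library sizes not computed; run mask_ig_adjust_library")
  if (any(peaks$lib$adjusted <= 0)) stop("zero adjusted library size")
  sweep(peaks$counts, 2L, peaks$lib$adjusted / 1e6, "/")
}

#' Cluster peaks into cleavage events
#'
#' Single-linkage chaining of surviving (unflagged, gene-assigned) peaks
#' whose 3' ends lie within \code{gap} nt of each other, within gene and
#' region class (intronic peaks cluster as IPA, 3'UTR peaks as UTR3; peaks
#' in exons or outside genes are dropped).  Cluster counts are member sums;
#' read-start multisets are pooled before the IQR is recomputed; the
#' representative 3'-end position is the member with the highest pooled
#' count, ties resolved to the most distal member in transcription
#' orientation.
#'
#' @param peaks a \code{PeakSet} after assignment, filtering, and
#'   \code{\link{mask_ig_adjust_library}}.
#' @param gap maximum 3'-end distance chained into one event (nt).
#' @return an \code{IpaAtlas}: list with \code{events} (table), matrices
#'   \code{counts}, \code{tpm}, \code{iqr}, and \code{lib}.
#' @export
cluster_peaks <- function(peaks, gap = 200L) {
  info <- peaks$info
  keep <- !peak_flagged(peaks) & !is.na(info$gene_id) &
    info$region %in% c("INTRON", "UTR3")
  info <- info[keep, ]
  counts <- peaks$counts[keep, , drop = FALSE]
  iqr <- peaks$iqr[keep, , drop = FALSE]
  info$class <- ifelse(info$region == "INTRON", "IPA", "UTR3")

  info$.row <- seq_len(nrow(info))
  ev_rows <- list(); memb <- list()
  data.table::setorderv(info, c("gene_id", "class", "end3"))
  grp <- paste(info$gene_id, info$class)
  for (g in unique(grp)) {
    sub <- info[grp == g, ]
    brk <- c(0L, which(diff(sub$end3) > gap), nrow(sub))
    for (k in seq_len(length(brk) - 1L)) {
      mem <- sub[(brk[k] + 1L):brk[k + 1L], ]
      pooled <- rowSums(counts[mem$.row, , drop = FALSE])
      best <- which(pooled == max(pooled))
      if (length(best) > 1L) {  # ties -> most distal 3' end
        best <- if (mem$strand[1L] == "+") best[which.max(mem$end3[best])]
                else best[which.min(mem$end3[best])]
      }
      ev_rows[[length(ev_rows) + 1L]] <- data.table::data.table(
        gene_id = mem$gene_id[1L], class = mem$class[1L],
        chrom = mem$chrom[1L], start = min(mem$start), end = max(mem$end),
        strand = mem$strand[1L], rep_pos = mem$end3[best],
        intron_tx = mem$intron_tx[best],
        n_peaks = nrow(mem))
      memb[[length(memb) + 1L]] <- mem$.row
    }
  }
  events <- data.table::rbindlist(ev_rows)

  na_max <- function(x) { x <- x[!is.na(x)]; if (length(x)) max(x) else NA_real_ }
  agg_counts <- do.call(rbind, lapply(memb, function(m)
    colSums(counts[m, , drop = FALSE])))
  agg_iqr <- do.call(rbind, lapply(memb, function(m)
    apply(iqr[m, , drop = FALSE], 2L, na_max)))
  # pooled multiset IQR when read starts are available
  if (!is.null(peaks$starts)) {
    for (e in seq_along(memb)) {
      mids <- info$peak_id[match(memb[[e]], info$.row)]
      st <- peaks$starts[peaks$starts$peak_id %in% mids, ]
      if (!nrow(st)) next
      pos <- n <- NULL
      a <- st[, list(iqr = weighted_iqr(pos, n)), by = "sample"]
      agg_iqr[e, match(a$sample, colnames(iqr))] <- a$iqr
    }
  }
  events$event_id <- sprintf("EV%05d", seq_len(nrow(events)))
  dimnames(agg_counts) <- list(events$event_id, colnames(counts))
  dimnames(agg_iqr) <- dimnames(agg_counts)
  atlas <- structure(list(events = events, counts = agg_counts,
                          iqr = agg_iqr, lib = peaks$lib),
                     class = "IpaAtlas")
  atlas$tpm <- if (!is.null(peaks$lib)) {
    sweep(agg_counts, 2L, peaks$lib$adjusted / 1e6, "/")
  } else NULL
  atlas
}

#' @export
print.IpaAtlas <- function(x, ...) {
  cat(sprintf("IpaAtlas: %d events (%d IPA, %d UTR3) x %d samples\n",
              nrow(x$events), sum(x$events$class == "IPA"),
              sum(x$events$class == "UTR3"), ncol(x$counts)))
  invisible(x)
}

#' Isoform usage per event and sample
#'
#' IpA usage is the event's TPM over the summed TPM of all IpA and 3'UTR
#' events of its gene; 3'UTR usage is relative to the gene's 3'UTR events
#' only (3'UTR length does not change the encoded protein).  A zero
#' denominator (gene silent in a sample) yields NA, not 0.
#'
#' @param atlas an \code{IpaAtlas}.
#' @return numeric matrix of usage in [0,1] (events x samples), with the
#'   atlas attached as attribute \code{"atlas"}.
#' @export
compute_usage <- function(atlas) {
  ev <- atlas$events
  tpm <- atlas$tpm
  usage <- matrix(NA_real_, nrow(tpm), ncol(tpm), dimnames = dimnames(tpm))
  for (g in unique(ev$gene_id)) {
    rows <- which(ev$gene_id == g)
    utr <- rows[ev$class[rows] == "UTR3"]
    denom_all <- colSums(tpm[rows, , drop = FALSE])
    denom_utr <- colSums(tpm[utr, , drop = FALSE])
    for (r in rows) {
      den <- if (ev$class[r] == "IPA") denom_all else denom_utr
      usage[r, ] <- ifelse(den > 0, tpm[r, ] / den, NA_real_)
    }
  }
  usage
}

#' Robust-expression filter on clustered events
#'
#' 3'UTR events are kept when TPM >= \code{utr_tpm} and usage >=
#' \code{min_usage} co-occur in at least one sample; IpA events when TPM >=
#' \code{ipa_tpm}, usage >= \code{min_usage}, and read-start IQR >=
#' \code{min_iqr} co-occur in at least one sample (the IQR rule removes
#' PCR-duplicate-driven peaks).
#'
#' @param atlas an \code{IpaAtlas}.
#' @param usage usage matrix from \code{\link{compute_usage}}.
#' @param utr_tpm,ipa_tpm,min_usage,min_iqr thresholds.
#' @return the filtered \code{IpaAtlas}.
#' @export
apply_robustness_filters <- function(atlas, usage, utr_tpm = 3, ipa_tpm = 5,
                                     min_usage = 0.1, min_iqr = 5) {
  ev <- atlas$events
  tpm <- atlas$tpm
  keep <- logical(nrow(ev))
  for (r in seq_len(nrow(ev))) {
    u <- usage[r, ]; t <- tpm[r, ]; q <- atlas$iqr[r, ]
    ok <- if (ev$class[r] == "UTR3") {
      t >= utr_tpm & !is.na(u) & u >= min_usage
    } else {
      t >= ipa_tpm & !is.na(u) & u >= min_usage & !is.na(q) & q >= min_iqr
    }
    keep[r] <- any(ok, na.rm = TRUE)
  }
  subset_atlas(atlas, keep)
}

#' Subset an atlas by a logical or index vector
#' @param atlas an \code{IpaAtlas}.
#' @param idx logical or integer index over events.
#' @export
subset_atlas <- function(atlas, idx) {
  atlas$events <- atlas$events[idx, ]
  atlas$counts <- atlas$counts[idx, , drop = FALSE]
  atlas$tpm <- atlas$tpm[idx, , drop = FALSE]
  atlas$iqr <- atlas$iqr[idx, , drop = FALSE]
  atlas
}

#' Per-gene, per-cell-type expression calls and IpA prevalence
#'
#' A gene is IPA_EXPRESSED in a cell type when any of its IpA events
#' reaches \code{ipa_tpm} TPM in at least \code{prop} of the cell type's
#' samples (ceiling rule); FL_ONLY when only the full-length rule (summed
#' 3'UTR TPM >= \code{fl_tpm}) holds; NOT_EXPRESSED otherwise.  Prevalence
#' is the fraction of expressed genes that generate IpA isoforms.
#'
#' @param atlas an \code{IpaAtlas}.
#' @param samples sample sheet with columns sample, cell_type.
#' @param ipa_tpm,fl_tpm,prop thresholds.
#' @return list with \code{calls} (gene x cell type table) and
#'   \code{prevalence} (named numeric per cell type).
#' @export
expression_calls <- function(atlas, samples, ipa_tpm = 5, fl_tpm = 5.5,
                             prop = 0.75) {
  ev <- atlas$events
  tpm <- atlas$tpm
  cts <- unique(samples$cell_type)
  genes <- unique(ev$gene_id)
  calls <- matrix("NOT_EXPRESSED", length(genes), length(cts),
                  dimnames = list(genes, cts))
  for (ct in cts) {
    cols <- samples$sample[samples$cell_type == ct]
    need <- ceiling(prop * length(cols))
    for (g in genes) {
      rows <- which(ev$gene_id == g)
      ipa_rows <- rows[ev$class[rows] == "IPA"]
      utr_rows <- rows[ev$class[rows] == "UTR3"]
      ipa_ok <- length(ipa_rows) > 0 &&
        any(vapply(ipa_rows, function(r)
          sum(tpm[r, cols] >= ipa_tpm) >= need, logical(1)))
      fl <- if (length(utr_rows)) colSums(tpm[utr_rows, cols, drop = FALSE]) else 0
      fl_ok <- sum(fl >= fl_tpm) >= need
      calls[g, ct] <- if (ipa_ok) "IPA_EXPRESSED"
                      else if (fl_ok) "FL_ONLY" else "NOT_EXPRESSED"
    }
  }
  prev <- apply(calls, 2L, function(x) {
    expressed <- sum(x != "NOT_EXPRESSED")
    if (expressed == 0) NA_real_ else sum(x == "IPA_EXPRESSED") / expressed
  })
  list(calls = data.table::as.data.table(calls, keep.rownames = "gene_id"),
       prevalence = prev)
}

#' Distal 3'UTR site usage per gene and sample
#'
#' Usage of the gene's 3'-most UTR3 event relative to all of its UTR3
#' events; genes without a UTR3 event are absent.
#'
#' @param atlas an \code{IpaAtlas}.
#' @param usage usage matrix from \code{\link{compute_usage}}.
#' @return numeric matrix, genes x samples.
#' @export
distal_utr_usage <- function(atlas, usage) {
  ev <- atlas$events
  out <- list()
  for (g in unique(ev$gene_id)) {
    rows <- which(ev$gene_id == g & ev$class == "UTR3")
    if (!length(rows)) next
    distal <- if (ev$strand[rows[1L]] == "+") rows[which.max(ev$rep_pos[rows])]
              else rows[which.min(ev$rep_pos[rows])]
    out[[g]] <- usage[distal, ]
  }
  do.call(rbind, out)
}
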