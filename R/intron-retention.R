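# Intron retention calling from coverage + junction evidence, per sample,
# aggregated per cell type, and the IpA-IR co-occurrence statistic.

#' Call retained introns in one sample
#'
#' An intron is RETAINED when all four criteria hold: (i) at least
#' \code{min_junction} reads span both exon-intron junctions; (ii) at
#' least \code{min_cov_frac} of its (uniquely mappable) length is covered
#' by \code{min_cov} or more reads; (iii) the median coverage over the
#' pooled flanking exons is at least \code{min_exon_median}; (iv) the
#' intron/exon median coverage ratio is at least \code{min_ratio}.
#' Introns with less than \code{min_map_frac} uniquely mappable sequence
#' are UNTESTABLE; a missing junction record fails criterion (i).
#'
#' @param gene a \code{GeneModel} (must not be overlap-flagged upstream).
#' @param coverage per-chromosome list of \code{Rle} for one sample.
#' @param junctions junction table for this sample (gene_id, intron_tx,
#'   up_reads, down_reads) or NULL.
#' @param mappability per-chromosome list of \code{Rle} in \{0,1\}, or
#'   NULL for fully mappable.
#' @param min_junction,min_cov,min_cov_frac,min_exon_median,min_ratio,min_map_frac
#'   criterion thresholds.
#' @return data.table: gene_id, intron_tx, status in
#'   \{RETAINED, NOT_RETAINED, UNTESTABLE\}, plus the measured quantities.
#' @export
call_retained_introns_sample <- function(gene, coverage, junctions = NULL,
                                         mappability = NULL,
                                         min_junction = 3L, min_cov = 3L,
                                         min_cov_frac = 0.5,
                                         min_exon_median = 10,
                                         min_ratio = 0.1,
                                         min_map_frac = 0.5) {
  nk <- n_introns(gene)
  if (nk == 0L) return(data.table::data.table())
  cov <- coverage[[gene$chrom]]
  map <- if (!is.null(mappability)) mappability[[gene$chrom]] else NULL
  rows <- vector("list", nk)
  for (k in seq_len(nk)) {
    iv <- intron_interval(gene, k)
    ivec <- as.numeric(cov[(iv[1L] + 1L):iv[2L]])
    mvec <- if (!is.null(map)) as.numeric(map[(iv[1L] + 1L):iv[2L]]) > 0
            else rep(TRUE, length(ivec))
    map_frac <- mean(mvec)
    # flanking exons: the two exons adjacent to this intron, pooled
    gi <- .intron_row(gene, k)
    ex_up <- gene$exons[gi, ]; ex_dn <- gene$exons[gi + 1L, ]
    evec <- c(as.numeric(cov[(ex_up[1L] + 1L):ex_up[2L]]),
              as.numeric(cov[(ex_dn[1L] + 1L):ex_dn[2L]]))
    exon_med <- median(evec)
    if (map_frac < min_map_frac) {
      rows[[k]] <- data.table::data.table(
        gene_id = gene$gene_id, intron_tx = k, status = "UNTESTABLE",
        map_frac = map_frac, cov_frac = NA_real_, intron_median = NA_real_,
        exon_median = exon_med, junc_up = NA_integer_, junc_dn = NA_integer_)
      next
    }
    jr <- if (!is.null(junctions)) {
      j <- junctions[junctions$gene_id == gene$gene_id &
                       junctions$intron_tx == k, ]
      if (nrow(j)) c(j$up_reads[1L], j$down_reads[1L]) else c(0L, 0L)
    } else c(0L, 0L)
    usable <- ivec[mvec]
    cov_frac <- mean(usable >= min_cov)
    intron_med <- median(usable)
    ok <- all(jr >= min_junction) &&
      cov_frac >= min_cov_frac &&
      exon_med >= min_exon_median &&
      (exon_med > 0 && intron_med / exon_med >= min_ratio)
    rows[[k]] <- data.table::data.table(
      gene_id = gene$gene_id, intron_tx = k,
      status = if (ok) "RETAINED" else "NOT_RETAINED",
      map_frac = map_frac, cov_frac = cov_frac, intron_median = intron_med,
      exon_median = exon_med, junc_up = jr[1L], junc_dn = jr[2L])
  }
  data.table::rbindlist(rows)
}

#' Aggregate per-sample retention calls per cell type
#'
#' An intron is RETAINED when it fulfils all criteria in at least
#' \code{hi} of the testable samples of the cell type, NOT_RETAINED at
#' \code{lo} or fewer, and AMBIGUOUS (removed) in between.  Introns must
#' contain a PAS to belong to the IpA-relevant universe, and genes whose
#' overall intron/exon median-coverage ratio reaches \code{gene_ratio}
#' are flagged and their introns removed.
#'
#' @param calls rbind of per-sample call tables with a \code{sample}
#'   column.
#' @param samples sample sheet (sample, cell_type).
#' @param ann a \code{GenomeAnnotation}.
#' @param genome a \code{DNAStringSet} (PAS scan; NULL skips the scan and
#'   marks every intron as PAS-bearing).
#' @param motifs a \code{\link{motif_config}}.
#' @param hi,lo aggregation fractions (>= hi retained, <= lo not).
#' @param gene_ratio gene-level intron/exon ratio flag threshold.
#' @return data.table: gene_id, intron_tx, cell_type, n_retained,
#'   n_testable, aggregate in \{RETAINED, NOT_RETAINED, AMBIGUOUS\},
#'   has_pas, gene_flagged.
#' @export
aggregate_retention <- function(calls, samples, ann, genome = NULL,
                                motifs = motif_config(), hi = 0.66,
                                lo = 0.33, gene_ratio = 0.2) {
  calls <- data.table::as.data.table(calls)
  calls$cell_type <- samples$cell_type[match(calls$sample, samples$sample)]
  status <- cell_type <- gene_id <- intron_tx <- intron_median <- exon_median <- NULL

  agg <- calls[status != "UNTESTABLE",
               list(n_retained = sum(status == "RETAINED"),
                    n_testable = .N),
               by = c("gene_id", "intron_tx", "cell_type")]
  frac <- agg$n_retained / agg$n_testable
  agg$aggregate <- ifelse(frac >= hi, "RETAINED",
                          ifelse(frac <= lo, "NOT_RETAINED", "AMBIGUOUS"))

  # gene flag: median over samples of (intron median / exon median) pooled
  gstat <- calls[status != "UNTESTABLE",
                 list(ratio = median(intron_median, na.rm = TRUE) /
                        max(median(exon_median, na.rm = TRUE), 1e-9)),
                 by = "gene_id"]
  flagged <- gstat$gene_id[gstat$ratio >= gene_ratio]
  agg$gene_flagged <- agg$gene_id %in% flagged

  agg$has_pas <- TRUE
  if (!is.null(genome)) {
    key <- unique(agg[, c("gene_id", "intron_tx"), with = FALSE])
    key$has_pas <- vapply(seq_len(nrow(key)), function(r) {
      g <- ann$genes[[key$gene_id[r]]]
      iv <- intron_interval(g, key$intron_tx[r])
      s <- genome_seq(genome, g$chrom, iv[1L], iv[2L], strand = g$strand)
      length(scan_motifs(s, motifs)$pas) > 0L
    }, logical(1))
    agg$has_pas <- key$has_pas[match(paste(agg$gene_id, agg$intron_tx),
                                     paste(key$gene_id, key$intron_tx))]
  }
  agg
}

#' IpA-IR co-occurrence against the independence expectation
#'
#' Over a universe of expressed, PAS-bearing introns: expected co-occurring
#' introns = P(IpA) x P(IR) x N; the observed count is compared with a
#' two-sided binomial test at success probability P(IpA) x P(IR), and IpA
#' usage is compared between retained and non-retained introns with a
#' one-sided rank-sum test (non-retained higher).
#'
#' @param ipa_introns character keys ("gene:intron") with an IpA event.
#' @param ir_introns character keys with aggregate retention.
#' @param universe character keys of all expressed PAS-bearing introns.
#' @param ipa_usage optional named vector (keys as above) of IpA usage for
#'   the usage comparison.
#' @return list with observed, expected, p_ipa, p_ir, n, binomial test
#'   p-value, and optional usage comparison.
#' @export
ipa_ir_overlap <- function(ipa_introns, ir_introns, universe,
                           ipa_usage = NULL) {
  if (!length(universe)) stop("empty intron universe")
  ipa_introns <- intersect(ipa_introns, universe)
  ir_introns <- intersect(ir_introns, universe)
  n <- length(universe)
  p_ipa <- length(ipa_introns) / n
  p_ir <- length(ir_introns) / n
  both <- intersect(ipa_introns, ir_introns)
  expected <- p_ipa * p_ir * n
  bt <- if (p_ipa * p_ir > 0 && p_ipa * p_ir < 1)
    binom.test(length(both), n, p_ipa * p_ir)$p.value else NA_real_
  usage_test <- NULL
  if (!is.null(ipa_usage)) {
    u_ir <- ipa_usage[intersect(names(ipa_usage), both)]
    u_no <- ipa_usage[setdiff(intersect(names(ipa_usage), ipa_introns), both)]
    if (length(u_ir) >= 2L && length(u_no) >= 2L)
      usage_test <- suppressWarnings(
        wilcox.test(u_no, u_ir, alternative = "greater"))
  }
  list(observed = length(both), expected = expected, p_ipa = p_ipa,
       p_ir = p_ir, n = n, binom_p = bt, usage_test = usage_test)
}
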