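# Five-tier independent-evidence validation of candidate IpA events.
# Precedence: ANNOTATED > RNASEQ_GLM > EXTERNAL_3P > POLYA_READS >
# HIGH_EXPRESSION; events matching no tier are UNVALIDATED and dropped
# from the confident atlas.

#' Tier 1: overlap with annotated last exons
#'
#' An event matches when its representative 3' end falls inside any
#' transcript's last exon extended \code{ext_nt} downstream of the
#' annotated end (transcription orientation).
#'
#' @param atlas an \code{IpaAtlas}.
#' @param annotations a \code{GenomeAnnotation} or list of them (several
#'   annotation sources may be combined).
#' @param ext_nt downstream extension (nt).
#' @return character vector of matching event ids.
#' @export
evidence_annotation <- function(atlas, annotations, ext_nt = 100L) {
  if (inherits(annotations, "GenomeAnnotation")) annotations <- list(annotations)
  le <- data.table::rbindlist(lapply(annotations, last_exons))
  ext_start <- ifelse(le$strand == "+", le$start, le$start - ext_nt)
  ext_end <- ifelse(le$strand == "+", le$end + ext_nt, le$end)
  ev <- atlas$events[atlas$events$class == "IPA", ]
  hit <- vapply(seq_len(nrow(ev)), function(r) {
    any(le$chrom == ev$chrom[r] & le$strand == ev$strand[r] &
          ev$rep_pos[r] >= ext_start & ev$rep_pos[r] < ext_end)
  }, logical(1))
  ev$event_id[hit]
}

# method-of-moments NB dispersion from the replicate windows, estimated
# within each side and averaged (between-side variation is the signal
# being tested, not dispersion)
.window_dispersion <- function(up, down, floor = 0.01) {
  est <- vapply(list(up, down), function(v) {
    m <- mean(v)
    if (m <= 0) return(NA_real_)
    (var(v) - m) / m^2
  }, numeric(1))
  est <- est[is.finite(est)]
  if (!length(est)) return(floor)
  max(floor, mean(est))
}

#' Exact NB conditional test of upstream > downstream window counts
#'
#' Two replicate counts per side; each side's sum is NB with size
#' 2/dispersion, and conditional on the total the upstream sum follows a
#' beta-binomial-type law.  The one-sided mid-P value
#' P(U > u) + P(U = u)/2 is returned: the mid-P variant keeps the null
#' distribution close to uniform despite the discreteness of counts.
#'
#' @param up,down integer vectors of window counts (upstream, downstream).
#' @param dispersion NB dispersion; estimated by pooled method of moments
#'   (floored at \code{disp_floor}) when NULL.
#' @param disp_floor dispersion floor.
#' @return one-sided mid-P value (upstream greater).
#' @export
coverage_window_test <- function(up, down, dispersion = NULL,
                                 disp_floor = 0.01) {
  u <- sum(up); d <- sum(down); tot <- u + d
  if (tot == 0L) return(NA_real_)
  if (is.null(dispersion))
    dispersion <- .window_dispersion(up, down, disp_floor)
  r <- length(up) / dispersion
  k <- 0:tot
  lw <- dnbinom(k, size = r, mu = tot / 2, log = TRUE) +
    dnbinom(tot - k, size = length(down) / dispersion, mu = tot / 2, log = TRUE)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  sum(w[k > u]) + 0.5 * w[u + 1L]
}

# window intervals (0-based half-open) for an event 3' end, transcription
# orientation; returns 4 x 2 matrix rows: up_distal, up_prox, down_prox,
# down_distal
.glm_windows <- function(rep_pos, strand, width = 100L, sep = 51L) {
  if (strand == "+") {
    e <- rep_pos + 1L
    rbind(up_distal = c(e - 2L * width - sep, e - width - sep),
          up_prox = c(e - width, e),
          down_prox = c(e, e + width),
          down_distal = c(e + width + sep, e + 2L * width + sep))
  } else {
    e <- rep_pos
    rbind(up_distal = c(e + width + sep + 1L, e + 2L * width + sep + 1L),
          up_prox = c(e + 1L, e + width + 1L),
          down_prox = c(e - width + 1L, e + 1L),
          down_distal = c(e - 2L * width - sep + 1L, e - width - sep + 1L))
  }
}

#' Tier 2: RNA-seq coverage drop test at the cleavage site
#'
#' Within each sample, two replicate 100-nt windows separated by 51 nt are
#' placed on each side of the event's 3' end; window counts are the summed
#' per-base coverage divided by the read length (no library-size
#' normalization: both sides come from the same sample), and upstream >
#' downstream is tested one-sidedly.  Events whose windows overlap an
#' annotated exon, run off the chromosome, or fall below
#' \code{min_window_mean} reads per window are untestable.  P-values are
#' BH-adjusted per sample across tested events; an event is validated when
#' any sample reaches \code{fdr}.
#'
#' Method "pooled" (default) mirrors the pooled-dispersion philosophy of
#' genome-wide NB testing: the window mean-variance relation
#' Var(w) = c1*mu + c2*mu^2 is estimated once per sample from the
#' within-side replicate differences of all tested events, and each event
#' gets the continuous statistic
#' z = (U - D) / sqrt(4 (c1 mu + c2 mu^2)); under exchangeability U - D is
#' symmetric, so the p-values are uniform without the discreteness atoms
#' that any per-event exact conditional test carries (see the methods
#' vignette).  Method "exact" instead applies
#' \code{\link{coverage_window_test}} per event on rounded counts.
#'
#' @param atlas an \code{IpaAtlas}.
#' @param coverage named list (per sample) of per-chromosome \code{Rle}.
#' @param ann a \code{GenomeAnnotation}.
#' @param read_length read length used to convert coverage to counts.
#' @param width,sep window geometry (nt).
#' @param fdr validation threshold on the per-sample BH-adjusted p.
#' @param min_window_mean minimum mean reads per window for testability.
#' @param method "pooled" or "exact".
#' @param disp_floor dispersion floor (exact method).
#' @return list with \code{pvals} (events x samples; NA = untestable in
#'   that sample), \code{fdr} (same shape), \code{testable} (geometry
#'   testability), \code{validated} (event ids), \code{var_trend}
#'   (per-sample c1, c2).
#' @export
evidence_rnaseq_glm <- function(atlas, coverage, ann, read_length = 50L,
                                width = 100L, sep = 51L, fdr = 0.1,
                                min_window_mean = 3,
                                method = c("pooled", "exact"),
                                disp_floor = 0.01) {
  method <- match.arg(method)
  ev <- atlas$events[atlas$events$class == "IPA", ]
  samples <- names(coverage)
  exon_iv <- data.table::rbindlist(lapply(ann$genes, function(g)
    data.table::data.table(chrom = g$chrom, start = g$exons[, 1L],
                           end = g$exons[, 2L])))
  ex_gr <- GenomicRanges::GRanges(exon_iv$chrom,
                                  IRanges::IRanges(exon_iv$start + 1L,
                                                   exon_iv$end))
  chrom_len <- vapply(coverage[[1L]], length, 0L)

  pv <- matrix(NA_real_, nrow(ev), length(samples),
               dimnames = list(ev$event_id, samples))
  testable <- logical(nrow(ev))
  wins <- vector("list", nrow(ev))
  for (r in seq_len(nrow(ev))) {
    w <- .glm_windows(ev$rep_pos[r], ev$strand[r], width, sep)
    if (any(w[, 1L] < 0) || any(w[, 2L] > chrom_len[[ev$chrom[r]]])) next
    wg <- GenomicRanges::GRanges(ev$chrom[r],
                                 IRanges::IRanges(w[, 1L] + 1L, w[, 2L]))
    if (any(GenomicRanges::countOverlaps(wg, ex_gr) > 0L)) next
    testable[r] <- TRUE
    wins[[r]] <- w
  }
  var_trend <- list()
  for (s in samples) {
    cov <- coverage[[s]]
    idx <- which(testable)
    if (!length(idx)) next
    cnts <- matrix(NA_real_, length(idx), 4L)
    for (k in seq_along(idx)) {
      w <- wins[[idx[k]]]
      v <- cov[[ev$chrom[idx[k]]]]
      cnts[k, ] <- vapply(seq_len(4L), function(i)
        sum(as.numeric(v[(w[i, 1L] + 1L):w[i, 2L]])), numeric(1)) / read_length
    }
    mu <- rowMeans(cnts)
    deep <- mu >= min_window_mean
    if (method == "exact") {
      for (k in which(deep))
        pv[idx[k], s] <- coverage_window_test(round(cnts[k, 1:2]),
                                              round(cnts[k, 3:4]),
                                              disp_floor = disp_floor)
      next
    }
    # pooled mean-variance trend from within-side replicate differences:
    # regress s2/mu on mu with equal event weights (an unweighted fit of
    # s2 on (mu, mu^2) lets the deepest events dominate and miscalibrates
    # the bulk)
    s2 <- ((cnts[, 1L] - cnts[, 2L])^2 + (cnts[, 3L] - cnts[, 4L])^2) / 4
    use <- deep & is.finite(s2) & mu > 0
    if (sum(use) >= 10L) {
      fit <- tryCatch(stats::lm.fit(cbind(1, mu[use]), s2[use] / mu[use]),
                      error = function(e) NULL)
      cc <- if (is.null(fit)) c(1, 0) else pmax(fit$coefficients, 0)
    } else if (sum(use) >= 1L) {
      cc <- c(max(0.05, sum(s2[use]) / sum(mu[use])), 0)
    } else cc <- c(1, 0)
    if (cc[1L] < 0.05 && cc[2L] == 0) cc[1L] <- 0.05
    var_trend[[s]] <- cc
    vv <- 4 * (cc[1L] * mu + cc[2L] * mu^2)
    z <- (cnts[, 1L] + cnts[, 2L] - cnts[, 3L] - cnts[, 4L]) / sqrt(vv)
    p <- stats::pnorm(z, lower.tail = FALSE)
    p[!deep] <- NA_real_
    pv[idx, s] <- p
  }
  fdr_m <- apply(pv, 2L, bh_adjust)
  if (is.null(dim(fdr_m))) fdr_m <- matrix(fdr_m, nrow = nrow(pv),
                                           dimnames = dimnames(pv))
  validated <- ev$event_id[testable &
                             apply(fdr_m < fdr, 1L, any, na.rm = TRUE)]
  list(pvals = pv, fdr = fdr_m, testable = setNames(testable, ev$event_id),
       validated = validated, var_trend = var_trend)
}

#' Tier 3: overlap with an external 3'-end peak set
#'
#' External peaks are resized to 75 nt (25 nt upstream and 50 nt
#' downstream of the original start); an event matches when its
#' representative 3' end falls inside a resized peak on the same strand.
#'
#' @param atlas an \code{IpaAtlas}.
#' @param external interval table (chrom, start, end, strand), 0-based.
#' @return character vector of matching event ids.
#' @export
evidence_external_3p <- function(atlas, external) {
  ev <- atlas$events[atlas$events$class == "IPA", ]
  if (is.null(external) || nrow(external) == 0L) return(character(0))
  a <- external$start - 25L
  b <- external$start + 50L
  hit <- vapply(seq_len(nrow(ev)), function(r) {
    any(external$chrom == ev$chrom[r] & external$strand == ev$strand[r] &
          ev$rep_pos[r] >= a & ev$rep_pos[r] < b)
  }, logical(1))
  ev$event_id[hit]
}

#' Tier 4: untemplated-A (polyA-tail) read support
#'
#' Unmapped reads ending in >= \code{min_a} adenosines are trimmed of the
#' terminal A-run, kept when longer than \code{min_len} nt, aligned by
#' exact match to the genome (unique hits only), deduplicated on identical
#' mapped coordinates, and counted when the mapped 3' end falls within the
#' event peak extended \code{ext_nt} on both sides.  Validation requires
#' \code{min_reads} supporting reads and a PAS within \code{pas_nt}
#' upstream of the representative 3' end.
#'
#' @param atlas an \code{IpaAtlas}.
#' @param reads a \code{DNAStringSet} of unmapped reads.
#' @param genome a \code{DNAStringSet}.
#' @param motifs a \code{\link{motif_config}}.
#' @param min_a,min_len,min_reads,ext_nt,pas_nt rule parameters.
#' @return list with \code{counts} (named per event), \code{validated}
#'   (event ids), \code{alignments} (table of deduplicated read hits).
#' @export
evidence_polya_reads <- function(atlas, reads, genome,
                                 motifs = motif_config(), min_a = 4L,
                                 min_len = 21L, min_reads = 4L,
                                 ext_nt = 20L, pas_nt = 50L) {
  ev <- atlas$events[atlas$events$class == "IPA", ]
  aln <- list()
  for (i in seq_along(reads)) {
    s <- as.character(reads[[i]])
    m <- regexpr(sprintf("A{%d,}$", min_a), s)
    if (m == -1L) next
    trimmed <- substr(s, 1L, m - 1L)
    if (nchar(trimmed) <= min_len) next
    hits <- list()
    for (ch in names(genome)) {
      fw <- Biostrings::matchPattern(trimmed, genome[[ch]])
      for (st in Biostrings::start(fw))
        hits[[length(hits) + 1L]] <- data.table::data.table(
          chrom = ch, start = st - 1L, end = st - 1L + nchar(trimmed),
          strand = "+", end3 = st - 2L + nchar(trimmed))
      rv <- Biostrings::matchPattern(rev_comp(trimmed), genome[[ch]])
      for (st in Biostrings::start(rv))
        hits[[length(hits) + 1L]] <- data.table::data.table(
          chrom = ch, start = st - 1L, end = st - 1L + nchar(trimmed),
          strand = "-", end3 = st - 1L)
    }
    if (length(hits) != 1L) next  # unaligned or multi-mapping
    aln[[length(aln) + 1L]] <- hits[[1L]]
  }
  counts <- setNames(integer(nrow(ev)), ev$event_id)
  aln_tab <- data.table::data.table()
  if (length(aln)) {
    aln_tab <- unique(data.table::rbindlist(aln))  # PCR-duplicate collapse
    for (r in seq_len(nrow(ev))) {
      counts[r] <- sum(aln_tab$chrom == ev$chrom[r] &
                         aln_tab$strand == ev$strand[r] &
                         aln_tab$end3 >= ev$start[r] - ext_nt &
                         aln_tab$end3 < ev$end[r] + ext_nt)
    }
  }
  pas <- vapply(seq_len(nrow(ev)), function(r)
    pas_upstream(genome, ev$chrom[r], ev$strand[r], ev$rep_pos[r],
                 width = pas_nt, motifs = motifs), logical(1))
  list(counts = counts,
       validated = ev$event_id[counts >= min_reads & pas],
       alignments = aln_tab)
}

#' Tier 5: stringent expression with an upstream PAS
#'
#' Validated when TPM >= \code{min_tpm} and usage >= \code{min_usage}
#' co-occur in at least one sample and a PAS lies within \code{pas_nt}
#' upstream of the representative 3' end.
#'
#' @param atlas an \code{IpaAtlas}.
#' @param usage usage matrix from \code{\link{compute_usage}}.
#' @param genome a \code{DNAStringSet}.
#' @param motifs a \code{\link{motif_config}}.
#' @param min_tpm,min_usage,pas_nt rule parameters.
#' @return character vector of validated event ids.
#' @export
evidence_high_expression <- function(atlas, usage, genome,
                                     motifs = motif_config(), min_tpm = 10,
                                     min_usage = 0.1, pas_nt = 50L) {
  ev <- atlas$events
  ipa <- which(ev$class == "IPA")
  ok <- vapply(ipa, function(r) {
    expr <- any(atlas$tpm[r, ] >= min_tpm & !is.na(usage[r, ]) &
                  usage[r, ] >= min_usage)
    expr && pas_upstream(genome, ev$chrom[r], ev$strand[r], ev$rep_pos[r],
                         width = pas_nt, motifs = motifs)
  }, logical(1))
  ev$event_id[ipa][ok]
}

#' Assemble the confident atlas from the five evidence tiers
#'
#' Each IpA event receives the first matching tier in precedence order;
#' unvalidated IpA events are dropped.  3'UTR events are retained
#' unconditionally (they anchor usage denominators).
#'
#' @param atlas an \code{IpaAtlas}.
#' @param annotated,glm_validated,external,polya,high_expr character
#'   vectors of event ids validated by each tier (see the per-tier
#'   functions).
#' @param glm_result optional full result of
#'   \code{\link{evidence_rnaseq_glm}} whose p-values are copied into the
#'   evidence table.
#' @return list with \code{atlas} (confident \code{IpaAtlas}) and
#'   \code{evidence} (per-candidate table: event_id, tier, annotated flag,
#'   glm p/FDR, polyA read count).
#' @export
build_confident_atlas <- function(atlas, annotated = character(0),
                                  glm_validated = character(0),
                                  external = character(0),
                                  polya = character(0),
                                  high_expr = character(0),
                                  glm_result = NULL) {
  ev <- atlas$events
  ipa_ids <- ev$event_id[ev$class == "IPA"]
  tier <- setNames(rep("UNVALIDATED", length(ipa_ids)), ipa_ids)
  tier[ipa_ids %in% high_expr] <- "HIGH_EXPRESSION"
  tier[ipa_ids %in% polya] <- "POLYA_READS"
  tier[ipa_ids %in% external] <- "EXTERNAL_3P"
  tier[ipa_ids %in% glm_validated] <- "RNASEQ_GLM"
  tier[ipa_ids %in% annotated] <- "ANNOTATED"
  evidence <- data.table::data.table(
    event_id = ipa_ids, tier = unname(tier),
    annotated = ipa_ids %in% annotated)
  if (!is.null(glm_result)) {
    evidence$glm_p <- apply(glm_result$pvals, 1L, function(x)
      if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))[ipa_ids]
    evidence$glm_fdr <- apply(glm_result$fdr, 1L, function(x)
      if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))[ipa_ids]
  }
  keep <- ev$class == "UTR3" |
    (ev$event_id %in% ipa_ids[tier != "UNVALIDATED"])
  list(atlas = subset_atlas(atlas, keep), evidence = evidence)
}
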