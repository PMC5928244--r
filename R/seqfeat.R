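#' Motif configuration
#'
#' Polyadenylation-signal hexamers (canonical AATAAA, ATTAAA, and the
#' common single-substitution variant set) and a 5' splice-site consensus
#' list standing in for U1 snRNP binding signals.  Both lists are
#' configurable; motifs are defined on the sense strand in DNA alphabet.
#'
#' @param pas_variants character vector of PAS hexamers.
#' @param u1_motifs character vector of U1/5'ss motifs.
#' @return list of class \code{MotifConfig}.
#' @export
motif_config <- function(pas_variants = c("AATAAA", "ATTAAA", "TATAAA",
                                          "AGTAAA", "AAGAAA", "AATATA",
                                          "AATACA", "CATAAA", "GATAAA",
                                          "AATGAA", "TTTAAA", "ACTAAA",
                                          "AATAGA"),
                         u1_motifs = c("GTAAGT", "GTGAGT", "GTAAGG")) {
  motifs <- c(pas_variants, u1_motifs)
  if (any(nchar(motifs) < 5L) || any(grepl("[^ACGT]", motifs)))
    stop("motifs must be uppercase DNA of length >= 5")
  structure(list(pas = pas_variants, u1 = u1_motifs), class = "MotifConfig")
}

#' Scan a sequence for PAS and U1 motifs
#'
#' Exact matching of every configured motif, overlapping occurrences
#' included; positions are 0-based match starts on the given (sense)
#' sequence.
#'
#' @param sequence DNA string (sense strand).
#' @param motifs a \code{\link{motif_config}}.
#' @return list with integer vectors \code{pas} and \code{u1}.
#' @export
scan_motifs <- function(sequence, motifs = motif_config()) {
  if (grepl("[^ACGTN]", sequence)) stop("sequence contains non-ACGTN characters")
  if (!nzchar(sequence)) return(list(pas = integer(0), u1 = integer(0)))
  subj <- Biostrings::DNAString(sequence)
  hit <- function(ms) {
    pos <- unlist(lapply(ms, function(m)
      Biostrings::start(Biostrings::matchPattern(m, subj))))
    sort(unique(as.integer(pos))) - 1L
  }
  list(pas = hit(motifs$pas), u1 = hit(motifs$u1))
}

# any PAS on the sense strand within `width` nt upstream of cleavage base p
#' @keywords internal
pas_upstream <- function(genome, chrom, strand, p, width = 50L,
                         motifs = motif_config()) {
  if (strand == "+") {
    a <- max(0L, p - width + 1L); b <- p + 1L
    s <- genome_seq(genome, chrom, a, b)
  } else {
    len <- Biostrings::width(genome)[match(chrom, names(genome))]
    s <- genome_seq(genome, chrom, p, min(len, p + width), strand = "-")
  }
  length(scan_motifs(s, motifs)$pas) > 0L
}

#' A+T fraction of a sequence
#'
#' @param sequence non-empty DNA string; N is excluded from the denominator.
#' @return real in [0, 1] (NaN if only N).
#' @export
at_content <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  ch <- strsplit(toupper(sequence), "")[[1L]]
  at <- sum(ch %in% c("A", "T"))
  acgt <- sum(ch %in% c("A", "C", "G", "T"))
  at / acgt
}

#' Per-gene PAS and U1 signal densities with AT stratification
#'
#' Counts motifs on the sense strand from the TSS to the start of the
#' 3'UTR and reports signals per kb per gene, the gene-body AT content,
#' and one-sided rank-sum comparisons of IpA versus non-IpA genes overall
#' and within high-AT (> \code{at_split}) and low-AT strata.
#'
#' @param ann a \code{GenomeAnnotation}.
#' @param genome a \code{DNAStringSet}.
#' @param ipa_genes character vector of gene ids with IpA events.
#' @param motifs a \code{\link{motif_config}}.
#' @param at_split AT-content stratification threshold.
#' @return list with \code{density} (per-gene table) and \code{tests}
#'   (stratum x motif-class table of one-sided Wilcoxon rank-sum p-values,
#'   alternative: IpA genes have higher density).
#' @export
signal_density <- function(ann, genome, ipa_genes, motifs = motif_config(),
                           at_split = 0.5) {
  rows <- lapply(ann$genes, function(g) {
    if (is.null(g$utr3)) return(NULL)
    # region TSS -> 3'UTR start, in transcription orientation
    if (g$strand == "+") { a <- g$start; b <- min(g$utr3[, 1L]) }
    else { a <- max(g$utr3[, 2L]); b <- g$end }
    if (b <= a) return(NULL)
    s <- genome_seq(genome, g$chrom, min(a, b), max(a, b), strand = g$strand)
    hits <- scan_motifs(s, motifs)
    kb <- nchar(s) / 1000
    data.table::data.table(gene_id = g$gene_id,
                           pas_per_kb = length(hits$pas) / kb,
                           u1_per_kb = length(hits$u1) / kb,
                           at = at_content(s),
                           is_ipa = g$gene_id %in% ipa_genes)
  })
  dens <- data.table::rbindlist(rows)
  strata <- list(all = rep(TRUE, nrow(dens)),
                 high_at = dens$at > at_split,
                 low_at = dens$at <= at_split)
  tests <- data.table::rbindlist(lapply(names(strata), function(st) {
    d <- dens[strata[[st]], ]
    pv <- function(col) {
      x <- d[[col]][d$is_ipa]; y <- d[[col]][!d$is_ipa]
      if (length(x) < 2L || length(y) < 2L) return(NA_real_)
      suppressWarnings(wilcox.test(x, y, alternative = "greater")$p.value)
    }
    data.table::data.table(stratum = st, pas_p = pv("pas_per_kb"),
                           u1_p = pv("u1_per_kb"),
                           n_ipa = sum(d$is_ipa), n_other = sum(!d$is_ipa))
  }))
  list(density = dens, tests = tests)
}

#' Mean conservation profile around cleavage sites
#'
#' Per-offset mean conservation over [-flank, +flank] nt around each
#' event's 3' end in transcription orientation, for 5'IpA, 3'IpA, and a
#' random-intronic-PAS control: introns of IpA genes without IpA events
#' but containing a canonical AATAAA, one randomly chosen signal per
#' intron, profiled the same way.
#'
#' @param atlas an \code{IpaAtlas} (IPA events used).
#' @param track named list of per-chromosome \code{Rle} scores.
#' @param ann a \code{GenomeAnnotation}.
#' @param genome a \code{DNAStringSet} (for the control's PAS scan).
#' @param consequences optional table (event_id, class5p3p) used to split
#'   events; all events fall in one group when absent.
#' @param flank window half-width (nt).
#' @param n_control number of control introns sampled.
#' @param seed RNG seed for the control draw.
#' @return list with \code{profile} (offset x group matrix of means),
#'   \code{n} (events per group), \code{skipped} (events with windows off
#'   chromosome).
#' @export
conservation_profile <- function(atlas, track, ann, genome,
                                 consequences = NULL, flank = 200L,
                                 n_control = 200L, seed = 1L) {
  set.seed(seed)
  ev <- atlas$events[atlas$events$class == "IPA", ]
  grp <- rep("IPA", nrow(ev))
  if (!is.null(consequences)) {
    m <- match(ev$event_id, consequences$event_id)
    grp <- ifelse(is.na(m), "IPA", consequences$class5p3p[m])
  }
  offs <- seq(-flank, flank)
  pull <- function(chrom, p, strand) {
    v <- track[[chrom]]
    if (is.null(v) || p - flank < 0 || p + flank >= length(v)) return(NULL)
    x <- as.numeric(v[(p - flank + 1L):(p + flank + 1L)])
    if (strand == "-") rev(x) else x
  }
  groups <- unique(grp)
  skipped <- 0L
  prof <- sapply(groups, function(g) {
    rows <- which(grp == g)
    xs <- lapply(rows, function(r) pull(ev$chrom[r], ev$rep_pos[r], ev$strand[r]))
    skipped <<- skipped + sum(vapply(xs, is.null, logical(1)))
    xs <- xs[!vapply(xs, is.null, logical(1))]
    if (!length(xs)) return(rep(NA_real_, length(offs)))
    colMeans(do.call(rbind, xs))
  })
  # control: random PAS in IpA-gene introns lacking IpA events
  ipa_key <- paste(ev$gene_id, ev$intron_tx)
  ctl_pos <- list()
  for (g in ann$genes[unique(ev$gene_id)]) {
    if (is.null(g) || !nrow(g$introns)) next
    for (i in seq_len(nrow(g$introns))) {
      k <- .intron_tx_index(g, i)
      if (paste(g$gene_id, k) %in% ipa_key) next
      s <- genome_seq(genome, g$chrom, g$introns[i, 1L], g$introns[i, 2L],
                      strand = g$strand)
      hits <- Biostrings::start(Biostrings::matchPattern("AATAAA",
                                                         Biostrings::DNAString(s))) - 1L
      if (!length(hits)) next
      h <- hits[sample.int(length(hits), 1L)]
      p <- if (g$strand == "+") g$introns[i, 1L] + h else g$introns[i, 2L] - 1L - h
      ctl_pos[[length(ctl_pos) + 1L]] <- list(p = unname(p), chrom = g$chrom,
                                              strand = g$strand)
    }
  }
  if (length(ctl_pos)) {
    if (length(ctl_pos) > n_control)
      ctl_pos <- ctl_pos[sample.int(length(ctl_pos), n_control)]
    xs <- lapply(ctl_pos, function(cp)
      pull(cp$chrom, as.integer(cp$p), cp$strand))
    xs <- xs[!vapply(xs, is.null, logical(1))]
    if (length(xs))
      prof <- cbind(prof, control = colMeans(do.call(rbind, xs)))
  }
  rownames(prof) <- offs
  list(profile = prof,
       n = table(grp), skipped = skipped)
}

#' CLIP binding-site enrichment in exonized introns
#'
#' For each RNA-binding protein and background region class, computes the
#' expected number of binding sites in the pooled exonized introns under a
#' per-nucleotide binomial placement model (p = background sites /
#' background length) and the closed-form Z-score
#' (obs - exp) / sqrt(exp * (1 - p)).  Exonized introns of 50 nt or less
#' are excluded.
#'
#' @param exonized interval table (chrom, start, end) of exonized introns,
#'   0-based.
#' @param clip_peaks named list (per RBP) of interval tables of CLIP sites.
#' @param backgrounds named list (per region class) of interval tables.
#' @param min_len minimum exonized-intron length retained (strictly
#'   greater).
#' @return data.table with rbp, background, observed, expected, p, z.
#' @export
clip_enrichment <- function(exonized, clip_peaks, backgrounds, min_len = 50L) {
  exonized <- data.table::as.data.table(exonized)
  exonized <- exonized[(exonized$end - exonized$start) > min_len, ]
  ex_len <- sum(exonized$end - exonized$start)
  ex_gr <- GenomicRanges::GRanges(exonized$chrom,
                                  IRanges::IRanges(exonized$start + 1L,
                                                   exonized$end))
  count_in <- function(sites, region_gr) {
    s_gr <- GenomicRanges::GRanges(sites$chrom,
                                   IRanges::IRanges(sites$start + 1L, sites$end))
    sum(GenomicRanges::countOverlaps(s_gr, region_gr) > 0L)
  }
  rows <- list()
  for (rbp in names(clip_peaks)) {
    obs <- count_in(clip_peaks[[rbp]], ex_gr)
    for (bg in names(backgrounds)) {
      bgt <- data.table::as.data.table(backgrounds[[bg]])
      bg_len <- sum(bgt$end - bgt$start)
      if (bg_len == 0) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          rbp = rbp, background = bg, observed = obs, expected = NA_real_,
          p = NA_real_, z = NA_real_)
        next
      }
      bg_gr <- GenomicRanges::GRanges(bgt$chrom,
                                      IRanges::IRanges(bgt$start + 1L, bgt$end))
      bg_sites <- count_in(clip_peaks[[rbp]], bg_gr)
      p <- bg_sites / bg_len
      expected <- p * ex_len
      z <- if (expected > 0 && p < 1) (obs - expected) / sqrt(expected * (1 - p))
           else NA_real_
      rows[[length(rows) + 1L]] <- data.table::data.table(
        rbp = rbp, background = bg, observed = obs, expected = expected,
        p = p, z = z)
    }
  }
  data.table::rbindlist(rows)
}
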