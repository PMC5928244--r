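# Molecular consequences of IpA events: retained coding fraction, 5'/3'
# class, terminal-exon type, transcript assignment, coding-potential call,
# and protein-domain / TMD retention.

#' Retained coding fraction and 5'/3' IpA class
#'
#' Fraction of the longest annotated ORF retained by an intronic cleavage
#' event: coding nucleotides from the start codon to the end of the exon
#' upstream of the event, over the total CDS length.  Events retaining
#' less than \code{cut} are 5'IpA, the remainder 3'IpA (the boundary
#' itself is 3'IpA: "less than" is strict).
#'
#' @param gene a \code{GeneModel}.
#' @param pos 0-based intronic position of the cleavage site.
#' @param cut 5' / 3' class boundary on the retained fraction.
#' @return list with \code{fraction} (NA for non-coding genes) and
#'   \code{class5p3p} in \{"IPA_5P","IPA_3P"\}.
#' @export
retained_cdr_fraction <- function(gene, pos, cut = 0.25) {
  tot <- cds_length(gene)
  if (is.na(tot) || tot == 0L)
    return(list(fraction = NA_real_, class5p3p = NA_character_))
  up <- upstream_cds_length(gene, pos)
  fr <- up / tot
  list(fraction = fr,
       class5p3p = if (fr < cut) "IPA_5P" else "IPA_3P")
}

#' Assign an assembled transcript to an IpA event
#'
#' Candidates are transcripts overlapping the gene; multi-exon transcripts
#' are preferred, single-exon candidates are admitted only when an
#' endpoint lies within \code{tss_nt} of the TSS (their orientation is
#' uncertain).  Match order: (1) transcripts ending within \code{near_nt}
#' of the event end, ties broken by maximal exon count then TSS proximity;
#' (2) the nearest-ending transcript if within \code{mid_nt}; (3) any
#' overlapping transcript ending within \code{far_nt}.  The assigned
#' transcript's 3' end is replaced by the 3'-seq position, which is the
#' more accurate end.
#'
#' @param event_end3 0-based cleavage base of the event.
#' @param gene a \code{GeneModel}.
#' @param assembled list of transcript models: each a list with
#'   \code{exons} (start/end matrix), \code{chrom}, \code{strand}.
#' @param near_nt,mid_nt,far_nt,tss_nt rule distances (nt).
#' @return list with \code{transcript} (name or NA) and \code{model} (the
#'   chosen transcript, 3' end clipped to the event) or NULL fields.
#' @export
assign_transcript <- function(event_end3, gene, assembled, near_nt = 50L,
                              mid_nt = 500L, far_nt = 5000L, tss_nt = 100L) {
  if (!length(assembled)) return(list(transcript = NA_character_, model = NULL))
  tx_end3 <- function(tr) if (gene$strand == "+") max(tr$exons[, 2L]) - 1L
                          else min(tr$exons[, 1L])
  tx_start <- function(tr) if (gene$strand == "+") min(tr$exons[, 1L])
                           else max(tr$exons[, 2L]) - 1L
  overlaps_gene <- vapply(assembled, function(tr) {
    tr$chrom == gene$chrom && min(tr$exons[, 1L]) < gene$end &&
      max(tr$exons[, 2L]) > gene$start
  }, logical(1))
  cand <- assembled[overlaps_gene]
  if (!length(cand)) return(list(transcript = NA_character_, model = NULL))
  nex <- vapply(cand, function(tr) nrow(tr$exons), 0L)
  single_ok <- vapply(cand, function(tr)
    min(abs(c(min(tr$exons[, 1L]), max(tr$exons[, 2L]) - 1L) - gene$tss)) <= tss_nt,
    logical(1))
  keep <- nex > 1L | single_ok
  if (any(nex > 1L)) keep <- keep & (nex > 1L)  # multi-exon preferred
  cand <- cand[keep]; nex <- nex[keep]
  if (!length(cand)) return(list(transcript = NA_character_, model = NULL))
  ends <- vapply(cand, tx_end3, numeric(1))
  d_end <- abs(ends - event_end3)
  tssd <- abs(vapply(cand, tx_start, numeric(1)) - gene$tss)

  pick <- NA_integer_
  near <- which(d_end <= near_nt)
  if (length(near)) {
    near <- near[order(-nex[near], tssd[near])]
    pick <- near[1L]
  } else if (min(d_end) <= mid_nt) {
    pick <- which.min(d_end)
  } else {
    far <- which(d_end <= far_nt)
    if (length(far)) pick <- far[which.min(d_end[far])]
  }
  if (is.na(pick)) return(list(transcript = NA_character_, model = NULL))
  model <- cand[[pick]]
  # 3'-seq end supersedes the assembled end
  ex <- model$exons
  if (gene$strand == "+") {
    le <- which.max(ex[, 2L]); ex[le, 2L] <- event_end3 + 1L
  } else {
    le <- which.min(ex[, 1L]); ex[le, 1L] <- event_end3
  }
  model$exons <- ex
  list(transcript = names(assembled[overlaps_gene])[keep][pick] %||%
         NA_character_, model = model)
}

#' Terminal-exon classification: composite vs skipped
#'
#' COMPOSITE: the IpA transcript's last exon starts at an annotated
#' internal exon's start (within \code{tol} nt) and reads through that
#' exon's donor site into the intron -- the donor is not recognized.
#' SKIPPED: the last exon starts strictly inside the intron (a novel
#' acceptor creates a new small terminal exon).  Anything else is
#' UNRESOLVED.
#'
#' @param model assigned transcript model (from
#'   \code{\link{assign_transcript}}), or NULL.
#' @param gene a \code{GeneModel}.
#' @param tol exon-start matching tolerance absorbing assembler
#'   imprecision (nt).
#' @return one of "COMPOSITE", "SKIPPED", "UNRESOLVED".
#' @export
classify_terminal_exon <- function(model, gene, tol = 5L) {
  if (is.null(model)) return("UNRESOLVED")
  ex <- model$exons
  if (gene$strand == "+") {
    le <- ex[which.max(ex[, 2L]), ]
    le_start <- le[1L]; le_end <- le[2L]
    ann_starts <- gene$exons[, 1L]
    ann_match <- which(abs(ann_starts - le_start) <= tol)
    if (length(ann_match)) {
      donor <- gene$exons[ann_match[1L], 2L]
      if (le_end > donor) return("COMPOSITE")
      return("UNRESOLVED")
    }
  } else {
    le <- ex[which.min(ex[, 1L]), ]
    le_start <- le[2L]  # transcription-orientation start boundary
    ann_starts <- gene$exons[, 2L]
    ann_match <- which(abs(ann_starts - le_start) <= tol)
    if (length(ann_match)) {
      donor <- gene$exons[ann_match[1L], 1L]
      if (le[1L] < donor) return("COMPOSITE")
      return("UNRESOLVED")
    }
  }
  # novel last exon: strictly inside an intron?
  a <- if (gene$strand == "+") le[1L] else le[2L] - 1L
  inside <- any(a >= gene$introns[, 1L] & a < gene$introns[, 2L])
  if (inside) "SKIPPED" else "UNRESOLVED"
}

#' Longest open reading frame in a transcript sequence
#'
#' Scans all three frames of the given (sense) sequence for ATG..stop;
#' the length includes the stop codon.  ORFs without an in-frame stop are
#' counted to the sequence end (open 3' end).
#'
#' @param sequence sense-strand transcript sequence.
#' @return longest ORF length in nt (0 when no ATG).
#' @export
longest_orf <- function(sequence) {
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < 3L) return(0L)
  codons <- function(off) {
    ks <- seq(off + 1L, n - 2L, by = 3L)
    substring(s, ks, ks + 2L)
  }
  best <- 0L
  for (off in 0:2) {
    if (n - off < 3L) next
    cd <- codons(off)
    open_at <- NA_integer_
    for (i in seq_along(cd)) {
      if (is.na(open_at) && cd[i] == "ATG") open_at <- i
      if (!is.na(open_at) && cd[i] %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, (i - open_at + 1L) * 3L)
        open_at <- NA_integer_
      }
    }
    if (!is.na(open_at)) best <- max(best, (length(cd) - open_at + 1L) * 3L)
  }
  as.integer(best)
}

#' Non-coding call for an IpA isoform
#'
#' Non-coding iff the externally supplied coding-potential probability is
#' below \code{prob_cut}, the retained coding fraction is below
#' \code{cdr_cut}, and the longest ORF of the isoform sequence is at most
#' \code{orf_cut} nt.
#'
#' @param coding_prob coding-potential probability (external predictor
#'   column; NA defers the call).
#' @param retained_fraction retained CDR fraction of the event.
#' @param sequence isoform (sense) sequence used for the ORF scan.
#' @param prob_cut,cdr_cut,orf_cut rule thresholds.
#' @return list with \code{noncoding} (logical, NA when deferred) and
#'   \code{orf_nt}.
#' @export
call_noncoding <- function(coding_prob, retained_fraction, sequence,
                           prob_cut = 0.3, cdr_cut = 0.25, orf_cut = 300L) {
  orf <- longest_orf(sequence)
  if (is.na(coding_prob))
    return(list(noncoding = NA, orf_nt = orf, deferred = TRUE))
  list(noncoding = coding_prob < prob_cut &&
         !is.na(retained_fraction) && retained_fraction < cdr_cut &&
         orf <= orf_cut,
       orf_nt = orf, deferred = FALSE)
}

#' Logistic coding-potential stub on ORF length
#'
#' Stand-in for an external coding-potential predictor in synthetic tests:
#' a logistic curve on the longest-ORF length, centred at
#' \code{midpoint} nt.
#'
#' @param sequence transcript sequence.
#' @param midpoint,scale logistic parameters (nt).
#' @return probability in (0, 1).
#' @export
coding_potential_stub <- function(sequence, midpoint = 300, scale = 60) {
  1 / (1 + exp(-(longest_orf(sequence) - midpoint) / scale))
}

#' Domain retention under an IpA truncation
#'
#' The truncated protein spans \code{floor(upstream CDS nt / 3)} amino
#' acids; domains wholly within the truncation are retained, all others
#' (including partially overlapped ones) are lost.
#'
#' @param domains data.table (domain, category, aa_start, aa_end),
#'   1-based inclusive amino-acid intervals on the longest protein
#'   isoform.
#' @param upstream_cds_nt coding nucleotides retained by the event.
#' @return list with \code{retained}, \code{lost} (subsets of
#'   \code{domains}), \code{truncation_aa}, and repeat counts.
#' @export
domain_retention <- function(domains, upstream_cds_nt) {
  trunc_aa <- floor(upstream_cds_nt / 3)
  if (is.null(domains) || nrow(domains) == 0L)
    return(list(retained = NULL, lost = NULL, truncation_aa = trunc_aa,
                n_retained = 0L, n_lost = 0L, flag_missing = TRUE))
  domains <- data.table::as.data.table(domains)
  keep <- domains$aa_end <= trunc_aa
  list(retained = domains[keep, ], lost = domains[!keep, ],
       truncation_aa = trunc_aa,
       n_retained = sum(keep), n_lost = sum(!keep), flag_missing = FALSE)
}

#' TMD retention status and distance of the truncation from the first TMD
#'
#' NONE when the protein has no transmembrane domain; RETAINED when every
#' TMD lies within the truncation; LOST otherwise (with a flag when the
#' truncation cuts into a TMD).  For lost TMDs the distance in amino
#' acids is (upstream CDS at the IpA - upstream CDS at the intron
#' preceding the first TMD) / 3; negative values mean the truncation ends
#' upstream of the TMD.
#'
#' @param gene a \code{GeneModel}.
#' @param pos intronic cleavage position of the event.
#' @param domains domain table including rows with category "TMD".
#' @return list with \code{status}, \code{distance_aa}, \code{flag_partial}.
#' @export
tmd_analysis <- function(gene, pos, domains) {
  tmds <- if (is.null(domains)) NULL else {
    d <- data.table::as.data.table(domains)
    d[d$category == "TMD", ]
  }
  if (is.null(tmds) || nrow(tmds) == 0L)
    return(list(status = "NONE", distance_aa = NA_real_, flag_partial = FALSE))
  up_nt <- upstream_cds_length(gene, pos)
  trunc_aa <- floor(up_nt / 3)
  first <- tmds[which.min(tmds$aa_start), ]
  if (all(tmds$aa_end <= trunc_aa))
    return(list(status = "RETAINED", distance_aa = NA_real_,
                flag_partial = FALSE))
  partial <- any(tmds$aa_start <= trunc_aa & tmds$aa_end > trunc_aa)
  # intron preceding the first TMD: last intron whose upstream CDS does
  # not reach the TMD start codon
  tmd_start_nt <- (first$aa_start - 1L) * 3L
  nk <- n_introns(gene)
  up_by_intron <- vapply(seq_len(nk), function(k) {
    iv <- intron_interval(gene, k)
    p <- if (gene$strand == "+") iv[1L] else iv[2L] - 1L
    upstream_cds_length(gene, p)
  }, integer(1))
  before <- which(up_by_intron <= tmd_start_nt)
  ref_nt <- if (length(before)) up_by_intron[max(before)] else 0L
  list(status = "LOST",
       distance_aa = (up_nt - ref_nt) / 3,
       flag_partial = partial)
}

#' Protein size and domain-content contrast between gene sets
#'
#' One-sided Wilcoxon rank-sum tests (alternative: IpA genes larger) on
#' protein length and domain count, plus per-category 2x2 Fisher odds
#' ratios of domain presence.
#'
#' @param protein_tab data.table (gene_id, length_aa, is_ipa).
#' @param domain_tab data.table (gene_id, domain, category).
#' @return list with \code{length_test}, \code{count_test} (wilcox
#'   results), \code{medians}, and \code{categories} (per-category table).
#' @export
size_and_domain_contrast <- function(protein_tab, domain_tab) {
  protein_tab <- data.table::as.data.table(protein_tab)
  if (!any(protein_tab$is_ipa) || !any(!protein_tab$is_ipa))
    stop("both gene partitions must be non-empty")
  x <- protein_tab$length_aa[protein_tab$is_ipa]
  y <- protein_tab$length_aa[!protein_tab$is_ipa]
  lt <- suppressWarnings(wilcox.test(x, y, alternative = "greater"))
  domain_tab <- data.table::as.data.table(domain_tab)
  cnt <- domain_tab[, list(n = .N), by = "gene_id"]
  protein_tab$n_domains <- cnt$n[match(protein_tab$gene_id, cnt$gene_id)]
  protein_tab$n_domains[is.na(protein_tab$n_domains)] <- 0L
  ct <- suppressWarnings(
    wilcox.test(protein_tab$n_domains[protein_tab$is_ipa],
                protein_tab$n_domains[!protein_tab$is_ipa],
                alternative = "greater"))
  cats <- data.table::rbindlist(lapply(unique(domain_tab$category), function(cg) {
    has <- unique(domain_tab$gene_id[domain_tab$category == cg])
    a <- sum(protein_tab$is_ipa & protein_tab$gene_id %in% has)
    b <- sum(protein_tab$is_ipa) - a
    c <- sum(!protein_tab$is_ipa & protein_tab$gene_id %in% has)
    d <- sum(!protein_tab$is_ipa) - c
    if ((a + c) == 0L)
      return(data.table::data.table(category = cg, odds_ratio = NA_real_,
                                    p = NA_real_))
    ft <- fisher.test(matrix(c(a, b, c, d), 2L))
    data.table::data.table(category = cg, odds_ratio = unname(ft$estimate),
                           p = ft$p.value)
  }))
  list(length_test = lt, count_test = ct,
       medians = c(ipa_aa = median(x), other_aa = median(y),
                   ipa_domains = median(protein_tab$n_domains[protein_tab$is_ipa]),
                   other_domains = median(protein_tab$n_domains[!protein_tab$is_ipa])),
       categories = cats)
}
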