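#' Simulate assembled transcript models for planted IpA events
#'
#' For each planted IpA event, emits a transcript whose terminal exon is
#' either COMPOSITE (the exon upstream of the IpA intron reads through its
#' donor site up to the cleavage position) or SKIPPED (a novel small
#' terminal exon inside the intron ending at the cleavage position), with
#' the planted label recorded; a few decoy transcripts far from any event
#' are added.
#'
#' @param sim an \code{IpaSim} after \code{\link{simulate_threeprime}}.
#' @param seed stage seed.
#' @param p_composite probability of the composite architecture.
#' @param skipped_exon_len length of the novel skipped terminal exon (nt).
#' @return list with \code{models} (named list: chrom, strand, exons) and
#'   \code{truth} (peak_id, transcript, terminal_class).
#' @export
simulate_assembled_transcripts <- function(sim, seed = sim$cfg$seed + 5L,
                                           p_composite = 0.6,
                                           skipped_exon_len = 120L) {
  set.seed(seed)
  ipa <- sim$threeprime$peaks[sim$threeprime$peaks$type == "ipa", ]
  models <- list(); truth <- list()
  for (r in seq_len(nrow(ipa))) {
    g <- sim$annotation$genes[[ipa$gene_id[r]]]
    k <- ipa$intron_tx[r]
    p <- ipa$end3[r]
    composite <- runif(1L) < p_composite
    # exons 1..k in transcription order, genomic coordinates
    n_ex <- nrow(g$exons)
    rows <- if (g$strand == "+") seq_len(k) else seq(n_ex - k + 1L, n_ex)
    ex <- g$exons[rows, , drop = FALSE]
    if (composite) {
      if (g$strand == "+") ex[nrow(ex), 2L] <- p + 1L
      else ex[1L, 1L] <- p
    } else {
      nov <- if (g$strand == "+") c(p + 1L - skipped_exon_len, p + 1L)
             else c(p, p + skipped_exon_len)
      ex <- rbind(ex, nov)
      ex <- ex[order(ex[, 1L]), , drop = FALSE]
    }
    tid <- sprintf("ASM_%s", ipa$peak_id[r])
    models[[tid]] <- list(chrom = g$chrom, strand = g$strand,
                          exons = ex)
    truth[[length(truth) + 1L]] <- data.table::data.table(
      peak_id = ipa$peak_id[r], transcript = tid,
      terminal_class = if (composite) "COMPOSITE" else "SKIPPED")
  }
  # decoys: single-exon fragments in intergenic space
  for (q in 1:3) {
    a <- 200L + q * 137L
    models[[sprintf("ASM_decoy%d", q)]] <-
      list(chrom = "chrS1", strand = "+",
           exons = matrix(c(a, a + 400L), 1L,
                          dimnames = list(NULL, c("start", "end"))))
  }
  list(models = models, truth = data.table::rbindlist(truth))
}

#' Write transcript models as GTF
#' @param models named list (chrom, strand, exons).
#' @param path output path (1-based inclusive records).
#' @export
write_transcripts_gtf <- function(models, path) {
  out <- character(0)
  for (tid in names(models)) {
    m <- models[[tid]]
    attr <- sprintf('gene_id "%s"; transcript_id "%s";', tid, tid)
    out <- c(out,
             sprintf("%s\tipaAtlas\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                     m$chrom, min(m$exons[, 1L]) + 1L, max(m$exons[, 2L]),
                     m$strand, attr),
             sprintf("%s\tipaAtlas\texon\t%d\t%d\t.\t%s\t.\t%s",
                     m$chrom, m$exons[, 1L] + 1L, m$exons[, 2L],
                     m$strand, attr))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read transcript models from GTF
#' @param path GTF with exon features carrying transcript_id.
#' @return named list of models (chrom, strand, exons), 0-based.
#' @export
read_transcripts_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   tid = gr$transcript_id)
  models <- lapply(split(df, df$tid), function(d) {
    d <- d[order(d$start), ]
    list(chrom = d$chrom[1L], strand = d$strand[1L],
         exons = cbind(start = d$start, end = d$end))
  })
  models
}

#' Simulate a protein-domain table
#'
#' For every coding gene: non-overlapping domains along the protein of the
#' longest ORF, categories drawn from the broad classes, a subset of
#' proteins carrying transmembrane domains, and occasional repeated
#' domains (same name multiple times).
#'
#' @param sim an \code{IpaSim}.
#' @param seed stage seed.
#' @param tmd_fraction fraction of proteins given TMDs.
#' @return data.table (gene_id, domain, category, aa_start, aa_end).
#' @export
simulate_domains <- function(sim, seed = sim$cfg$seed + 6L,
                             tmd_fraction = 0.25) {
  set.seed(seed)
  cats <- c("ACTIVE_SITE", "DNA_BINDING", "PPI", "RNA_BINDING", "OTHER")
  rows <- list()
  for (g in sim$annotation$genes) {
    plen <- cds_length(g)
    if (is.na(plen)) next
    plen <- plen %/% 3L
    if (plen < 60L) next
    n_dom <- sample(2:6, 1L)
    width <- sample(20:40, n_dom, replace = TRUE)
    starts <- sort(sample.int(max(1L, plen - 45L), n_dom))
    repeated <- runif(1L) < 0.2
    for (i in seq_len(n_dom)) {
      nm <- if (repeated) "REP_domain" else sprintf("dom%d", i)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        gene_id = g$gene_id, domain = nm,
        category = if (repeated) "REPEATED" else sample(cats, 1L),
        aa_start = starts[i],
        aa_end = min(plen, starts[i] + width[i] - 1L))
    }
    if (runif(1L) < tmd_fraction) {
      ts <- sample.int(max(1L, plen - 25L), 1L)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        gene_id = g$gene_id, domain = "TM1", category = "TMD",
        aa_start = ts, aa_end = min(plen, ts + 20L))
    }
  }
  data.table::rbindlist(rows)
}

#' Simulate CLIP peak sets with planted enrichment in exonized introns
#'
#' @param sim an \code{IpaSim} after \code{\link{simulate_threeprime}}.
#' @param rbps RBP names; the first half are enriched, the rest background.
#' @param seed stage seed.
#' @param bg_per_kb background site density; enriched RBPs get
#'   \code{enrich_factor}-fold more sites in the exonized intron prefixes.
#' @param enrich_factor planted fold enrichment.
#' @return named list (per RBP) of site interval tables.
#' @export
simulate_clip <- function(sim, rbps = c("RBP1", "RBP2", "RBP3", "RBP4"),
                          seed = sim$cfg$seed + 7L, bg_per_kb = 0.5,
                          enrich_factor = 8) {
  set.seed(seed)
  ipa <- sim$threeprime$peaks[sim$threeprime$peaks$type == "ipa", ]
  exonized <- exonized_introns(sim$annotation, ipa)
  L <- sim$chrom_len[["chrS1"]]
  out <- list()
  for (i in seq_along(rbps)) {
    n_bg <- rpois(1L, bg_per_kb * L / 1000)
    pos <- sample.int(L - 30L, n_bg)
    tabs <- list(data.table::data.table(chrom = "chrS1", start = pos,
                                        end = pos + 20L))
    if (i <= length(rbps) / 2) {
      for (r in seq_len(nrow(exonized))) {
        w <- exonized$end[r] - exonized$start[r]
        n_e <- rpois(1L, (enrich_factor - 1) * bg_per_kb * w / 1000)
        if (n_e == 0L) next
        p2 <- exonized$start[r] + sample.int(max(1L, w - 20L), n_e,
                                             replace = TRUE)
        tabs[[length(tabs) + 1L]] <- data.table::data.table(
          chrom = "chrS1", start = p2, end = p2 + 20L)
      }
    }
    out[[rbps[i]]] <- data.table::rbindlist(tabs)
  }
  out
}

#' Exonized intron intervals of IpA events
#'
#' The intron prefix transcribed into the IpA isoform: from the intron's
#' 5' boundary (transcription orientation) to the cleavage base.
#'
#' @param ann a \code{GenomeAnnotation}.
#' @param events table with gene_id, intron_tx, end3 (e.g. truth peaks or
#'   atlas events with \code{rep_pos} renamed).
#' @return data.table (gene_id, chrom, start, end, strand), 0-based.
#' @export
exonized_introns <- function(ann, events) {
  rows <- lapply(seq_len(nrow(events)), function(r) {
    g <- ann$genes[[events$gene_id[r]]]
    if (is.null(g) || is.na(events$intron_tx[r])) return(NULL)
    iv <- intron_interval(g, events$intron_tx[r])
    p <- events$end3[r]
    if (g$strand == "+") {
      data.table::data.table(gene_id = g$gene_id, chrom = g$chrom,
                             start = iv[1L], end = p + 1L, strand = "+")
    } else {
      data.table::data.table(gene_id = g$gene_id, chrom = g$chrom,
                             start = p, end = iv[2L], strand = "-")
    }
  })
  data.table::rbindlist(rows)
}
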