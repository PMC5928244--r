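# Transcript-space <-> genome-space mapping helpers.  Transcript coordinate
# t (0-based) indexes transcribed bases 5'->3'; exons are genomic-ascending.

.tx_cum <- function(exons) cumsum(exons[, 2L] - exons[, 1L])

# genomic coordinate of transcript position t
tx2gen <- function(exons, strand, t) {
  lens <- exons[, 2L] - exons[, 1L]
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  lens <- exons[, 2L] - exons[, 1L]
  cum <- c(0L, cumsum(lens))
  vapply(t, function(ti) {
    k <- findInterval(ti, cum, rightmost.closed = FALSE)
    off <- ti - cum[k]
    if (strand == "+") exons[k, 1L] + off else exons[k, 2L] - 1L - off
  }, numeric(1))
}

# intersect transcript-space interval [a, b) with exons -> genomic intervals
tx_interval_to_genomic <- function(exons, strand, a, b) {
  ord <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  ex <- exons[ord, , drop = FALSE]
  lens <- ex[, 2L] - ex[, 1L]
  cum <- c(0, cumsum(lens))
  out <- NULL
  for (k in seq_len(nrow(ex))) {
    lo <- max(a, cum[k]); hi <- min(b, cum[k + 1L])
    if (hi <= lo) next
    if (strand == "+") {
      g <- c(ex[k, 1L] + (lo - cum[k]), ex[k, 1L] + (hi - cum[k]))
    } else {
      g <- c(ex[k, 2L] - (hi - cum[k]), ex[k, 2L] - (lo - cum[k]))
    }
    out <- rbind(out, g)
  }
  out <- matrix(as.numeric(out), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
  out[order(out[, 1L]), , drop = FALSE]
}

# stamp of `motif` (sense strand) whose sense-coordinate start is `up` nt
# upstream of cleavage base p: sense positions [-up, -up+len).  Stamps are
# collected and applied in one pass (per-call vector copies are ruinous).
.stamp_sense <- function(strand, p, up, motif) {
  m <- strsplit(motif, "")[[1L]]
  L <- length(m)
  if (strand == "+") {
    list(idx = (p - up):(p - up + L - 1L) + 1L, vals = m)
  } else {
    list(idx = (p + up - L + 1L):(p + up) + 1L,
         vals = strsplit(rev_comp(motif), "")[[1L]])
  }
}

.apply_stamps <- function(chars, stamps) {
  for (s in stamps) chars[s$idx] <- s$vals
  chars
}

#' Simulate a genome annotation with planted IpA architecture
#'
#' Builds \code{cfg$n_genes} multi-exon genes laid head-to-tail (random
#' strand) on artificial chromosomes, with CDS, 3'UTR, and one planted
#' intronic cleavage site in each IpA-designated gene.  IpA genes draw their
#' introns \code{cfg$ipa_intron_factor}-fold longer, mirroring the enrichment
#' of intronic cleavage in long introns and long transcription units.  The
#' genome sequence carries a PAS hexamer upstream of every planted cleavage
#' site (IpA and 3'UTR) and a fixed A-poor stamp downstream, so only the
#' deliberately planted internal-priming artifacts are A-rich downstream.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list of class \code{IpaSim} with elements \code{annotation}
#'   (\code{GenomeAnnotation}), \code{genome} (\code{DNAStringSet}),
#'   \code{truth} (gene/event tables), \code{blacklist}, \code{ig}
#'   (interval data.tables), \code{cfg}.
#' @export
simulate_annotation <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_genes
  n_ipa <- round(cfg$ipa_fraction * n)
  ipa_genes <- sort(sample.int(n, n_ipa))
  is_ipa <- seq_len(n) %in% ipa_genes

  genes <- vector("list", n)
  gene_rows <- vector("list", n)
  event_rows <- list()
  cursor <- 2000
  chrom <- "chrS1"

  for (i in seq_len(n)) {
    gid <- sprintf("G%04d", i)
    strand <- sample(c("+", "-"), 1L)
    k <- sample(seq(cfg$n_exons_range[1L], cfg$n_exons_range[2L]), 1L)
    exon_len <- pmax(60L, pmin(600L, round(rlnorm(k, cfg$exon_len_meanlog, cfg$len_sdlog))))
    exon_len[k] <- max(exon_len[k], 450L)  # room for stop + 3'UTR
    mlog <- cfg$intron_len_meanlog + if (is_ipa[i]) log(cfg$ipa_intron_factor) else 0
    intron_len <- pmax(250L, pmin(9000L, round(rlnorm(k - 1L, mlog, cfg$len_sdlog))))

    ipa_intron <- NA_integer_
    if (is_ipa[i]) {
      ipa_intron <- sample(seq_len(k - 1L), 1L)
      intron_len[ipa_intron] <- max(intron_len[ipa_intron], 1600L)
    }

    # genomic layout left->right; transcription order depends on strand
    lens_tx_ex <- exon_len; lens_tx_in <- intron_len
    if (strand == "-") { lens_gen_ex <- rev(exon_len); lens_gen_in <- rev(intron_len) }
    else { lens_gen_ex <- exon_len; lens_gen_in <- intron_len }
    starts <- cursor + cumsum(c(0L, head(as.integer(rbind(lens_gen_ex, c(lens_gen_in, 0L))), -1L)))
    ex_starts <- starts[seq(1L, by = 2L, length.out = k)]
    exons <- cbind(start = ex_starts, end = ex_starts + lens_gen_ex)
    gend <- max(exons[, 2L])

    # CDS in transcript space: 5'UTR offset, 3'UTR tail, length % 3 == 0
    total_ex <- sum(exon_len)
    u5 <- sample(20:60, 1L)
    u3 <- sample(250:400, 1L)
    cds_len_nt <- total_ex - u5 - u3
    cds_len_nt <- cds_len_nt - (cds_len_nt %% 3L)
    cds <- tx_interval_to_genomic(exons, strand, u5, u5 + cds_len_nt)

    tr <- list(exons = exons, cds = cds)
    genes[[i]] <- gene_model(gid, chrom, strand, setNames(list(tr), paste0(gid, ".t1")))

    # planted cleavage ends (0-based base of the last transcribed nt)
    distal_end3 <- tx2gen(exons, strand, total_ex - 1L)
    utr3_tx_start <- u5 + cds_len_nt
    prox_off <- utr3_tx_start + round(0.45 * (total_ex - utr3_tx_start))
    prox_end3 <- tx2gen(exons, strand, prox_off)

    ev <- data.table::data.table(
      gene_id = gid, type = c("utr_distal", "utr_proximal"),
      chrom = chrom, strand = strand, end3 = c(distal_end3, prox_end3),
      intron_tx = NA_integer_)
    if (is_ipa[i]) {
      g <- genes[[i]]
      iv <- intron_interval(g, ipa_intron)
      ilen <- iv[2L] - iv[1L]
      d <- sample(300:(ilen - 300L), 1L)
      p <- if (strand == "+") iv[1L] + d else iv[2L] - 1L - d
      ev <- rbind(ev, data.table::data.table(
        gene_id = gid, type = "ipa", chrom = chrom, strand = strand,
        end3 = p, intron_tx = ipa_intron))
    }
    event_rows[[i]] <- ev
    gene_rows[[i]] <- data.table::data.table(
      gene_id = gid, chrom = chrom, strand = strand, start = cursor,
      end = gend, n_exons = k, is_ipa = is_ipa[i],
      median_intron = median(intron_len))
    # gaps exceed the 5000 nt upstream-gene proximity rule so that planted
    # true events never sit in the context filters' ambiguity zones
    cursor <- gend + sample(5200:12000, 1L)
  }

  chrom_len <- cursor + 5000L
  events <- data.table::rbindlist(event_rows)
  gene_tab <- data.table::rbindlist(gene_rows)

  # genome sequence with planted motifs
  pA <- cfg$at_content / 2; pG <- (1 - cfg$at_content) / 2
  chars <- sample(c("A", "T", "G", "C"), chrom_len, replace = TRUE,
                  prob = c(pA, pA, pG, pG))
  down_stamp <- "GTCGTGCTCGTG"
  stamps <- vector("list", 2L * nrow(events))
  for (r in seq_len(nrow(events))) {
    st <- events$strand[r]; p <- events$end3[r]
    stamps[[2L * r - 1L]] <- .stamp_sense(st, p, cfg$pas_offset, "AATAAA")
    stamps[[2L * r]] <- .stamp_sense(st, p, -1L, down_stamp)
  }
  chars <- .apply_stamps(chars, stamps)

  ann <- structure(list(genes = setNames(genes, vapply(genes, `[[`, "", "gene_id")),
                        overlap_flags = character(0), smallrna = NULL),
                   class = "GenomeAnnotation")
  ann$overlap_flags <- .flag_overlapping_genes(ann)

  sim <- structure(list(annotation = ann, genome = NULL,
                        truth = list(genes = gene_tab, events = events),
                        cfg = cfg, chrom_len = c(chrS1 = chrom_len)),
                   class = "IpaSim")
  sim <- .plant_artifacts(sim, chars)
  sim
}

# Plant artifact peaks and finalize the genome sequence.  Internal-priming
# artifacts get >= 6 genomic As immediately downstream; antisense peaks sit
# in an intron on the opposite strand; blacklist peaks get a covering
# interval in the emitted blacklist; one immunoglobulin-like locus carries
# an ultra-high-count peak.
.plant_artifacts <- function(sim, chars) {
  cfg <- sim$cfg
  stamps <- list()
  tg <- sim$truth$genes
  ev <- sim$truth$events
  ipa_used <- unique(ev[ev$type == "ipa", ]$gene_id)
  host_pool <- tg[!tg$gene_id %in% ipa_used & tg$n_exons >= 4L, ]

  pick_intron_pos <- function(gid, min_margin = 300L) {
    g <- sim$annotation$genes[[gid]]
    ok <- which(g$introns[, 2L] - g$introns[, 1L] >= 2L * min_margin + 100L)
    if (!length(ok)) {
      min_margin <- 60L
      ok <- which(g$introns[, 2L] - g$introns[, 1L] >= 2L * min_margin + 100L)
    }
    row <- sample(rep(ok, 2L), 1L)
    iv <- g$introns[row, ]
    d <- sample(min_margin:(iv[2L] - iv[1L] - min_margin), 1L)
    list(pos = iv[1L] + d, strand = g$strand)
  }

  art <- list()
  n_art <- c(ip = cfg$n_artifact_ip, anti = cfg$n_artifact_antisense,
             bl = cfg$n_artifact_blacklist)
  n_hosts <- sum(n_art) + cfg$n_subthreshold
  hosts <- sample(rep(host_pool$gene_id, ceiling(n_hosts / nrow(host_pool)) + 1L),
                  n_hosts)
  j <- 0L
  for (typ in names(n_art)) {
    for (q in seq_len(n_art[[typ]])) {
      j <- j + 1L
      pp <- pick_intron_pos(hosts[j])
      strand <- if (typ == "anti") setdiff(c("+", "-"), pp$strand) else pp$strand
      lab <- c(ip = "artifact_ip", anti = "artifact_antisense",
               bl = "artifact_blacklist")[[typ]]
      art[[length(art) + 1L]] <- data.table::data.table(
        gene_id = hosts[j], type = lab, chrom = "chrS1", strand = strand,
        end3 = pp$pos, intron_tx = NA_integer_)
      stamps[[length(stamps) + 1L]] <- .stamp_sense(
        strand, pp$pos, -1L, if (typ == "ip") "AAAAAAAA" else "GTCGTGCTCGTG")
      stamps[[length(stamps) + 1L]] <- .stamp_sense(strand, pp$pos,
                                                    cfg$pas_offset, "AATAAA")
    }
  }
  # sub-threshold (low-usage) and PCR-duplicate-like intronic peaks
  for (q in seq_len(cfg$n_subthreshold)) {
    j <- j + 1L
    pp <- pick_intron_pos(hosts[j])
    art[[length(art) + 1L]] <- data.table::data.table(
      gene_id = hosts[j], type = "subthreshold", chrom = "chrS1",
      strand = pp$strand, end3 = pp$pos, intron_tx = NA_integer_)
    stamps[[length(stamps) + 1L]] <- .stamp_sense(pp$strand, pp$pos, -1L,
                                                  "GTCGTGCTCGTG")
    stamps[[length(stamps) + 1L]] <- .stamp_sense(pp$strand, pp$pos,
                                                  cfg$pas_offset, "AATAAA")
  }
  dup_hosts <- setdiff(host_pool$gene_id, hosts)
  if (length(dup_hosts) < cfg$n_pcr_dup) dup_hosts <- host_pool$gene_id
  for (q in seq_len(cfg$n_pcr_dup)) {
    gid <- dup_hosts[q]
    pp <- pick_intron_pos(gid)
    art[[length(art) + 1L]] <- data.table::data.table(
      gene_id = gid, type = "pcr_dup", chrom = "chrS1", strand = pp$strand,
      end3 = pp$pos, intron_tx = NA_integer_)
    stamps[[length(stamps) + 1L]] <- .stamp_sense(pp$strand, pp$pos, -1L,
                                                  "GTCGTGCTCGTG")
    stamps[[length(stamps) + 1L]] <- .stamp_sense(pp$strand, pp$pos,
                                                  cfg$pas_offset, "AATAAA")
  }

  # immunoglobulin-like locus: intergenic ultra-high-count peak
  ig_pos <- sim$chrom_len[["chrS1"]] - 2500L
  art[[length(art) + 1L]] <- data.table::data.table(
    gene_id = NA_character_, type = "ig", chrom = "chrS1", strand = "+",
    end3 = ig_pos, intron_tx = NA_integer_)
  stamps[[length(stamps) + 1L]] <- .stamp_sense("+", ig_pos, -1L,
                                                "GTCGTGCTCGTG")
  chars <- .apply_stamps(chars, stamps)

  ev <- rbind(sim$truth$events, data.table::rbindlist(art))
  ev$peak_id <- sprintf("P%05d", seq_len(nrow(ev)))

  bl <- ev[ev$type == "artifact_blacklist", ]
  sim$blacklist <- data.table::data.table(
    chrom = bl$chrom, start = bl$end3 - 60L, end = bl$end3 + 60L)
  sim$ig <- data.table::data.table(chrom = "chrS1", start = ig_pos - 200L,
                                   end = ig_pos + 200L)
  sim$truth$events <- ev
  sim$genome <- Biostrings::DNAStringSet(setNames(paste(chars, collapse = ""), "chrS1"))
  sim
}
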