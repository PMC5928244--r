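# Read-placement coverage simulator.  Reads are discrete read_length-nt
# intervals (Poisson counts, uniform starts) so that window counts derived
# as sum(coverage)/read_length keep Poisson/NB mean-variance structure --
# independent per-base noise would be ~read_length-fold underdispersed
# after that division and would break the null calibration of the coverage
# GLM.

# accumulate read start positions for a component: rate c reads/base over
# [a, b), reads constrained to start in [lo, hi]
.reads_for <- function(c_rate, a, b, rl, lo = a, hi = b - rl) {
  hi <- max(hi, lo)
  n <- rpois(1L, c_rate * (b - a) / rl)
  if (n == 0L) return(integer(0))
  as.integer(lo + floor(runif(n) * (hi - lo + 1L)))
}

#' Simulate RNA-seq coverage, splice-junction counts, and polyA-tail reads
#'
#' Per sample: exonic coverage proportional to the gene's 3'-seq expression;
#' intronic coverage upstream of each planted IpA end proportional to its
#' true usage in that sample's condition, with background-level coverage
#' downstream; uniform low background over all introns; planted retained
#' introns covered at a fixed fraction of the exonic level with
#' junction-spanning reads at both boundaries.  Also emits a mappability
#' track (planted low-mappability introns), and an unmapped-read FASTA in
#' which a subset of planted IpA ends is supported by reads carrying
#' untemplated terminal adenosines.
#'
#' @param sim an \code{IpaSim} after \code{\link{simulate_threeprime}}.
#' @param seed stage seed (defaults to \code{cfg$seed + 2}).
#' @return the \code{IpaSim} with element \code{rnaseq}: \code{coverage}
#'   (per sample: list of per-chromosome \code{Rle}), \code{junctions}
#'   (long table), \code{mappability} (per-chromosome \code{Rle}),
#'   \code{polya_reads} (\code{DNAStringSet}), \code{truth_ir},
#'   \code{truth_lowmap}.
#' @export
simulate_rnaseq <- function(sim, seed = sim$cfg$seed + 2L) {
  stopifnot(!is.null(sim$threeprime))
  cfg <- sim$cfg
  set.seed(seed)
  tp <- sim$threeprime
  rl <- cfg$read_length
  genes <- sim$annotation$genes
  expr <- tp$gene_expr
  c_ex_gene <- cfg$coverage_depth * expr / exp(cfg$gene_expr_meanlog)

  ev <- tp$peaks
  ipa <- ev[ev$type == "ipa", ]

  # plant retained introns and low-mappability introns
  all_introns <- data.table::rbindlist(lapply(genes, function(g) {
    if (!nrow(g$introns)) return(NULL)
    k <- vapply(seq_len(nrow(g$introns)), function(i) .intron_tx_index(g, i), 1L)
    data.table::data.table(gene_id = g$gene_id, intron_tx = k,
                           chrom = g$chrom, start = g$introns[, 1L],
                           end = g$introns[, 2L], strand = g$strand)
  }))
  ipa_key <- paste(ipa$gene_id, ipa$intron_tx)
  all_introns$has_ipa <- paste(all_introns$gene_id, all_introns$intron_tx) %in% ipa_key
  all_introns$is_ir <- runif(nrow(all_introns)) < cfg$ir_fraction
  all_introns$ir_ratio <- ifelse(all_introns$is_ir,
                                 runif(nrow(all_introns), cfg$ir_ratio_range[1L],
                                       cfg$ir_ratio_range[2L]), 0)
  elig_lowmap <- which(!all_introns$is_ir & !all_introns$has_ipa &
                         (all_introns$end - all_introns$start) >= 600L)
  lowmap <- sample(elig_lowmap, min(5L, length(elig_lowmap)))
  all_introns$is_lowmap <- seq_len(nrow(all_introns)) %in% lowmap

  chrom_len <- sim$chrom_len
  mappab <- lapply(chrom_len, function(L) S4Vectors::Rle(1, L))
  for (r in lowmap) {
    a <- all_introns$start[r]; b <- all_introns$end[r]
    w <- b - a
    lo <- a + round(0.2 * w); hi <- a + round(0.8 * w)
    v <- mappab[[all_introns$chrom[r]]]
    v[(lo + 1L):hi] <- 0
    mappab[[all_introns$chrom[r]]] <- v
  }

  coverage <- list()
  junc_rows <- list()
  for (s in seq_len(nrow(tp$samples))) {
    sname <- tp$samples$sample[s]
    cond <- tp$samples$condition[s]
    starts_acc <- list()
    add <- function(x) if (length(x)) starts_acc[[length(starts_acc) + 1L]] <<- x
    for (g in genes) {
      gid <- g$gene_id
      c_ex <- c_ex_gene[[gid]]
      c_bg <- c_ex * cfg$intron_background
      u <- 0
      gev <- ipa[ipa$gene_id == gid, ]
      if (nrow(gev)) u <- tp$truth_usage[gev$peak_id, cond]
      # exons: full coverage 5' of the IpA intron, (1-u) downstream
      for (i in seq_len(nrow(g$exons))) {
        a <- g$exons[i, 1L]; b <- g$exons[i, 2L]
        exon_tx <- if (g$strand == "+") i else nrow(g$exons) - i + 1L
        cc <- if (nrow(gev) && exon_tx > gev$intron_tx[1L]) c_ex * (1 - u) else c_ex
        add(.reads_for(cc, a, b, rl))
      }
      # introns: background + IR + IpA prefix
      gint <- all_introns[all_introns$gene_id == gid, ]
      for (i in seq_len(nrow(gint))) {
        a <- gint$start[i]; b <- gint$end[i]
        cc <- c_bg + c_ex * gint$ir_ratio[i]
        add(.reads_for(cc, a, b, rl))
        if (gint$has_ipa[i] && nrow(gev)) {
          p <- gev$end3[1L]
          if (g$strand == "+") {
            add(.reads_for(c_ex * u, a, p + 1L, rl, a, p + 1L - rl))
          } else {
            add(.reads_for(c_ex * u, p, b, rl, p, b - rl))
          }
        }
        # junction-spanning read counts at both exon-intron boundaries
        junc_rows[[length(junc_rows) + 1L]] <- data.table::data.table(
          gene_id = gid, intron_tx = gint$intron_tx[i], chrom = gint$chrom[i],
          start = a, end = b, strand = gint$strand[i], sample = sname,
          up_reads = rpois(1L, cc), down_reads = rpois(1L, cc))
      }
    }
    starts_all <- unlist(starts_acc, use.names = FALSE) %||% integer(0)
    ir <- IRanges::IRanges(start = starts_all + 1L, width = rl)
    cov <- IRanges::coverage(ir, width = chrom_len[["chrS1"]])
    coverage[[sname]] <- list(chrS1 = cov)
  }

  # untemplated-A reads supporting a subset of planted IpA ends
  reads <- character(0); rnames <- character(0)
  supported <- ipa$peak_id[runif(nrow(ipa)) < cfg$polya_fraction]
  for (r in seq_len(nrow(ipa))) {
    if (!ipa$peak_id[r] %in% supported) next
    p <- ipa$end3[r]; st <- ipa$strand[r]
    for (j in seq_len(cfg$polya_reads_per_event)) {
      L <- 28L + j   # distinct alignment coordinates defeat dedup collapse
      body <- if (st == "+") genome_seq(sim$genome, ipa$chrom[r], p - L + 1L, p + 1L)
              else genome_seq(sim$genome, ipa$chrom[r], p, p + L, strand = "-")
      reads <- c(reads, paste0(body, strrep("A", 4L + j %% 3L)))
      rnames <- c(rnames, sprintf("%s_read%d", ipa$peak_id[r], j))
    }
  }
  # decoys: too short after trimming, no terminal A-run, unalignable
  reads <- c(reads, paste0(strrep("G", 21L), "AAAAA"),
             strrep("C", 40L),
             paste0(strrep("TGCA", 10L), "AAAAAA"))
  rnames <- c(rnames, "decoy_short", "decoy_noA", "decoy_unmapped")
  polya <- Biostrings::DNAStringSet(setNames(reads, rnames))

  sim$rnaseq <- list(coverage = coverage,
                     junctions = data.table::rbindlist(junc_rows),
                     mappability = mappab,
                     polya_reads = polya,
                     truth_ir = all_introns)
  sim
}

#' Simulate a per-base conservation track
#'
#' Low background with a conserved block centred on every planted IpA
#' cleavage site, emulating purifying selection on functional 3' ends.
#'
#' @param sim an \code{IpaSim} after \code{\link{simulate_threeprime}}.
#' @param background,peak_score background and planted block score.
#' @param half_width half-width (nt) of the conserved block.
#' @return named list of per-chromosome \code{Rle} scores.
#' @export
simulate_conservation <- function(sim, background = 0.1, peak_score = 0.6,
                                  half_width = 25L) {
  tr <- lapply(sim$chrom_len, function(L) S4Vectors::Rle(background, L))
  ipa <- sim$threeprime$peaks[sim$threeprime$peaks$type == "ipa", ]
  for (r in seq_len(nrow(ipa))) {
    p <- ipa$end3[r]
    v <- tr[[ipa$chrom[r]]]
    v[(p - half_width + 1L):(p + half_width + 1L)] <- peak_score
    tr[[ipa$chrom[r]]] <- v
  }
  tr
}

#' Simulate an external 3'-end peak set
#'
#' A fraction of planted IpA ends (plus all 3'UTR distal ends) appears in an
#' external BED-like peak table, as another 3'-end protocol would report.
#'
#' @param sim an \code{IpaSim} after \code{\link{simulate_threeprime}}.
#' @param seed stage seed.
#' @return data.table (chrom, start, end, name, score, strand), 0-based.
#' @export
simulate_external_3p <- function(sim, seed = sim$cfg$seed + 3L) {
  set.seed(seed)
  ev <- sim$threeprime$peaks
  ipa <- ev[ev$type == "ipa", ]
  keep <- ipa[runif(nrow(ipa)) < sim$cfg$external_fraction, ]
  ext <- rbind(keep, ev[ev$type == "utr_distal", ])
  # external peak "start" is the reported cleavage region start
  data.table::data.table(chrom = ext$chrom,
                         start = ext$end3 - 10L, end = ext$end3 + 10L,
                         name = paste0("ext_", ext$peak_id), score = 0L,
                         strand = ext$strand,
                         peak_id = ext$peak_id)
}
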