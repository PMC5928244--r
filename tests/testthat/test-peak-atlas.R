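# Filter cascade, clustering, TPM/usage quantification, robustness
# filters, expression calls.

library(data.table)

.two_gene_ann <- function() {
  # plus-strand gene [0,520) and a far-away minus-strand gene
  gp <- toy_gene_plus()
  gm <- toy_gene("FARM", "-",
                 cbind(start = c(8000L, 8400L), end = c(8200L, 8600L)),
                 cds = cbind(start = c(8420L, NA)[1], end = 8540L))
  toy_annotation(list(gp, gm))
}

test_that("artifact flags: blacklist, internal priming, antisense", {
  ann <- .two_gene_ann()
  # peak 1: intronic, clean; peak 2: in blacklist; peak 3: A-rich downstream;
  # peak 4: antisense inside FARM (overlaps only that gene, wrong strand)
  genome <- toy_genome(10000L, plant = list(AAAAAAAA = 376L), seed = 3L)
  counts <- matrix(10L, 4L, 2L)
  pk <- toy_peakset("chrT", starts = c(110L, 130L, 351L, 8450L),
                    ends = c(135L, 155L, 376L, 8475L),
                    strands = c("+", "+", "+", "+"), counts = counts)
  pk <- assign_peaks(pk, ann)
  pk <- filter_artifact_peaks(pk, blacklist = data.table(
    chrom = "chrT", start = 150L, end = 160L), genome = genome)
  expect_equal(pk$info$flag_blacklist, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(pk$info$flag_internal_priming, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(pk$info$flag_antisense, c(FALSE, FALSE, FALSE, TRUE))
  # >= 7 A scattered in the 10 nt downstream also triggers the flag
  g2 <- toy_genome(1000L, plant = list(AAGAAAGAAA = 526L), seed = 4L)
  pk2 <- toy_peakset("chrT", 501L, 526L, "+", matrix(5L, 1L, 1L))
  pk2 <- assign_peaks(pk2, ann)
  pk2 <- filter_artifact_peaks(pk2, NULL, g2)
  expect_true(pk2$info$flag_internal_priming)
  # peak beyond chromosome end errors
  pk3 <- toy_peakset("chrT", 990L, 1015L, "+", matrix(1L, 1L, 1L))
  pk3 <- assign_peaks(pk3, ann)
  expect_error(filter_artifact_peaks(pk3, NULL, g2), "beyond chromosome")
})

test_that("immunoglobulin masking adjusts library sizes", {
  ann <- .two_gene_ann()
  counts <- matrix(c(1e6, 1e6, 1e6, 1e6), 2L, 2L, byrow = TRUE)
  pk <- toy_peakset("chrT", c(110L, 300L), c(135L, 325L), c("+", "+"),
                    counts)
  pk <- assign_peaks(pk, ann)
  pk <- mask_ig_adjust_library(pk, data.table(chrom = "chrT", start = 290L,
                                              end = 330L))
  expect_true(pk$info$flag_immunoglobulin[2L])
  expect_equal(pk$lib$raw, c(2e6, 2e6), ignore_attr = TRUE)
  expect_equal(pk$lib$adjusted, c(1e6, 1e6), ignore_attr = TRUE)
  # empty intervals: adjusted equals raw when nothing else is flagged
  pk2 <- toy_peakset("chrT", 110L, 135L, "+", matrix(100L, 1L, 1L))
  pk2 <- assign_peaks(pk2, ann)
  pk2 <- mask_ig_adjust_library(pk2, NULL)
  expect_equal(pk2$lib$adjusted, pk2$lib$raw)
})

test_that("gene-context filters: overlap flag, convergent and upstream rules", {
  # gene X [0,520)+; convergent gene CONV on '-' whose 3' terminus (left
  # end) sits at 180, i.e. inside X's intron 1; upstream gene UP on '+'
  # ending at 90 -> X intronic peaks within 5000 nt are context-flagged.
  gX <- toy_gene_plus()
  gConv <- toy_gene("CONV", "-", cbind(start = 180L, end = 290L),
                    cds = cbind(start = 200L, end = 260L))
  gUp <- toy_gene("UPG", "+", cbind(start = c(3000L, 3300L),
                                    end = c(3100L, 3400L)),
                  cds = cbind(start = 3010L, end = 3340L))
  gY <- toy_gene("YY", "+", cbind(start = c(6000L, 7800L),
                                  end = c(6200L, 8000L)),
                 cds = cbind(start = 6020L, end = 7900L))
  ann <- toy_annotation(list(gX, gConv, gUp, gY))
  expect_setequal(ann$overlap_flags, c("TOYP", "CONV"))

  # intronic peak in X at 3' end 170 (within 100 nt of CONV end 180);
  # intronic peak in Y at 6500 (within 5000 of UPG 3'UTR end 3399);
  # intronic peak in Y at 7500: still within 5000 -> also flagged
  pk <- toy_peakset("chrT", c(146L, 6476L, 7476L), c(171L, 6501L, 7501L),
                    c("+", "+", "+"), matrix(10L, 3L, 1L))
  pk <- assign_peaks(pk, ann)
  pk <- filter_gene_context(pk, ann)
  expect_true(pk$info$flag_ambiguous_gene[1L])        # TOYP overlaps CONV
  expect_true(pk$info$flag_convergent_3utr_proximal[1L])
  expect_true(pk$info$flag_upstream_gene_proximal[2L])
  expect_true(pk$info$flag_upstream_gene_proximal[3L])

  # 6000+ nt away from the upstream gene end -> kept
  gZ <- toy_gene("ZZ", "+", cbind(start = c(9000L, 12000L),
                                  end = c(9200L, 12200L)),
                 cds = cbind(start = 9020L, end = 12100L))
  ann2 <- toy_annotation(list(gUp, gZ))
  pk2 <- toy_peakset("chrT", 9451L, 9476L, "+", matrix(10L, 1L, 1L))
  pk2 <- assign_peaks(pk2, ann2)
  pk2 <- filter_gene_context(pk2, ann2)  # 9475 - 3399 = 6076 > 5000
  expect_false(pk2$info$flag_upstream_gene_proximal[1L])

  # intronic peak overlapping a small-RNA locus is removed
  ann2$smallrna <- data.table(chrom = "chrT", start = 9460L, end = 9470L)
  pk3 <- assign_peaks(toy_peakset("chrT", 9451L, 9476L, "+",
                                  matrix(10L, 1L, 1L)), ann2)
  pk3 <- filter_gene_context(pk3, ann2)
  expect_true(pk3$info$flag_smallrna[1L])
})

test_that("TPM is count per million of the adjusted library", {
  ann <- .two_gene_ann()
  pk <- toy_peakset("chrT", c(110L, 300L), c(135L, 325L), c("+", "+"),
                    matrix(c(50L, 9999950L, 0L, 10L), 2L, 2L))
  pk <- assign_peaks(pk, ann)
  pk <- mask_ig_adjust_library(pk, NULL)
  tpm <- quantify_tpm(pk)
  expect_equal(tpm[1L, 1L], 50 / (1e7 / 1e6))  # 5 TPM
  expect_equal(tpm[1L, 2L], 0)
  expect_true(all(colSums(tpm) <= 1e6 + 1e-6))
})

test_that("single-linkage clustering chains 3' ends within 200 nt", {
  ann <- toy_annotation(list(toy_gene(
    "BIG", "+", cbind(start = c(0L, 2000L), end = c(100L, 2400L)),
    cds = cbind(start = 10L, end = 2200L))))
  # intronic 3' ends at 300, 450, 660 chain into one event (150, 210? no:
  # 450->660 is 210 > 200) -> two events; plus 1000 separate
  ends3 <- c(300L, 450L, 640L, 1000L)
  counts <- matrix(c(5L, 9L, 7L, 4L), 4L, 1L)
  pk <- toy_peakset("chrT", ends3 - 24L, ends3 + 1L, rep("+", 4L), counts)
  pk <- assign_peaks(pk, ann)
  pk <- mask_ig_adjust_library(pk, NULL)
  atl <- cluster_peaks(pk)
  expect_equal(nrow(atl$events), 2L)
  chain <- atl$events[atl$events$n_peaks == 3L, ]
  expect_equal(chain$rep_pos, 450L)          # highest pooled count member
  expect_equal(as.vector(atl$counts[chain$event_id, ]), 21)
  # exhaustive single-linkage oracle over all orderings
  sl_oracle <- function(e) {
    e <- sort(e); split(e, cumsum(c(1, diff(e) > 200)))
  }
  expect_equal(length(sl_oracle(ends3)), 2L)
  expect_equal(vapply(sl_oracle(ends3), length, 1L), c(`1` = 3L, `2` = 1L))

  # idempotence: reclustering the clustered events is the identity
  ev <- atl$events
  pk2 <- toy_peakset(ev$chrom, ev$start, ev$end, ev$strand,
                     atl$counts + 0L)
  pk2 <- assign_peaks(pk2, ann)
  pk2 <- mask_ig_adjust_library(pk2, NULL)
  atl2 <- cluster_peaks(pk2)
  expect_equal(nrow(atl2$events), nrow(atl$events))
  expect_equal(unname(atl2$counts), unname(atl$counts))
})

test_that("cluster representative ties resolve to the most distal end", {
  ann <- toy_annotation(list(toy_gene(
    "BIG", "+", cbind(start = c(0L, 2000L), end = c(100L, 2400L)),
    cds = cbind(start = 10L, end = 2200L))))
  ends3 <- c(300L, 400L)
  pk <- toy_peakset("chrT", ends3 - 24L, ends3 + 1L, c("+", "+"),
                    matrix(c(5L, 5L), 2L, 1L))
  pk <- assign_peaks(pk, ann)
  pk <- mask_ig_adjust_library(pk, NULL)
  expect_equal(cluster_peaks(pk)$events$rep_pos, 400L)
})

test_that("usage: IpA over all events, 3'UTR over UTR events only", {
  ann <- toy_annotation(list(toy_gene_plus()))
  # IpA at intron 1 (end 150), proximal UTR 465, distal UTR 510
  ends3 <- c(150L, 465L, 510L)
  counts <- matrix(c(50L, 100L, 50L), 3L, 1L)  # lib 200
  pk <- toy_peakset("chrT", ends3 - 24L, ends3 + 1L, rep("+", 3L), counts)
  pk <- assign_peaks(pk, ann)
  pk <- mask_ig_adjust_library(pk, NULL)
  atl <- cluster_peaks(pk, gap = 40L)
  u <- compute_usage(atl)
  ev <- atl$events
  expect_equal(u[ev$class == "IPA", 1L], 50 / 200)          # 0.25
  expect_equal(u[ev$class == "UTR3" & ev$rep_pos == 465L, 1L], 100 / 150)
  expect_equal(sum(u[ev$class == "UTR3", 1L]), 1)            # UTR sums to 1
  expect_true(sum(u[, 1L][ev$class == "IPA"]) +
                max(u[ev$class == "UTR3", 1L]) <= 1 + 1e-12)
  du <- distal_utr_usage(atl, u)
  expect_equal(du["TOYP", 1L], 50 / 150, ignore_attr = TRUE)
})

test_that("single-isoform gene has usage 1", {
  ann <- toy_annotation(list(toy_gene_plus()))
  pk <- toy_peakset("chrT", 486L, 511L, "+", matrix(80L, 1L, 1L))
  pk <- assign_peaks(pk, ann)
  pk <- mask_ig_adjust_library(pk, NULL)
  atl <- cluster_peaks(pk)
  expect_equal(as.vector(compute_usage(atl)), 1)
  expect_equal(as.vector(distal_utr_usage(atl, compute_usage(atl))), 1)
})

test_that("robustness filters enforce TPM, usage and IQR jointly per sample", {
  ann <- toy_annotation(list(toy_gene_plus()))
  ends3 <- c(150L, 510L)
  # lib chosen so the IpA peak hits exactly 6 TPM in sample 1
  counts <- matrix(c(60L, 240L,    # sample 1: lib 1e7 scaled below
                     10L, 990L), 2L, 2L)
  starts_tab <- data.table::CJ(peak_id = c("P00001", "P00002"),
                               sample = c("S1", "S2"),
                               off = c(0L, 15L, 30L))
  starts_tab$pos <- ifelse(starts_tab$peak_id == "P00001", 100L, 460L) +
    starts_tab$off
  starts_tab$n <- 10L
  starts_tab$off <- NULL
  pk <- toy_peakset("chrT", ends3 - 24L, ends3 + 1L, c("+", "+"), counts,
                    starts_tab = starts_tab)
  pk$counts <- pk$counts * 1L
  pk <- assign_peaks(pk, ann)
  pk <- mask_ig_adjust_library(pk, NULL)
  # scale library to 1e7 by hand to make TPM arithmetic transparent
  pk$lib$adjusted <- c(1e4, 1e5)
  atl <- cluster_peaks(pk)
  u <- compute_usage(atl)
  ipa_row <- which(atl$events$class == "IPA")
  expect_equal(atl$tpm[ipa_row, "S1"], 6000)
  expect_gte(atl$iqr[ipa_row, "S1"], 5)
  kept <- apply_robustness_filters(atl, u)
  expect_equal(nrow(kept$events), 2L)
  # degenerate read starts (IQR 0 everywhere) remove the IpA event
  pk2 <- peak_set(pk$info[, c("chrom", "start", "end", "strand", "peak_id"),
                          with = FALSE], pk$counts,
                  starts_tab[, list(peak_id, sample, pos = 140L, n)])
  pk2 <- assign_peaks(pk2, ann)
  pk2 <- mask_ig_adjust_library(pk2, NULL)
  pk2$lib$adjusted <- c(1e4, 1e5)
  atl2 <- cluster_peaks(pk2)
  kept2 <- apply_robustness_filters(atl2, compute_usage(atl2))
  expect_equal(kept2$events$class, "UTR3")
  # 3'UTR below 3 TPM everywhere is removed
  pk3 <- toy_peakset("chrT", 486L, 511L, "+", matrix(2L, 1L, 1L))
  pk3 <- assign_peaks(pk3, ann)
  pk3 <- mask_ig_adjust_library(pk3, NULL)
  pk3$lib$adjusted <- 1e6
  atl3 <- cluster_peaks(pk3)
  expect_equal(nrow(apply_robustness_filters(
    atl3, compute_usage(atl3))$events), 0L)
})

test_that("expression calls use the 75% ceiling rule and prevalence", {
  ann <- toy_annotation(list(toy_gene_plus()))
  ends3 <- c(150L, 510L)
  tpm <- rbind(c(6, 6, 6, 1), c(8, 8, 8, 8))
  counts <- matrix(as.integer(tpm), 2L, 4L)
  pk <- toy_peakset("chrT", ends3 - 24L, ends3 + 1L, c("+", "+"), counts,
                    samples = paste0("S", 1:4))
  pk <- assign_peaks(pk, ann)
  pk <- mask_ig_adjust_library(pk, NULL)
  pk$lib$adjusted <- rep(1e6, 4L)
  atl <- cluster_peaks(pk)
  samples <- data.table(sample = paste0("S", 1:4), cell_type = "CT")
  ec <- expression_calls(atl, samples)
  expect_equal(ec$calls$CT, "IPA_EXPRESSED")  # 3 of 4 samples = 75%
  expect_equal(unname(ec$prevalence["CT"]), 1)
  # IpA in only 2 of 4 samples, full-length everywhere -> FL_ONLY
  atl$tpm[atl$events$class == "IPA", ] <- c(6, 6, 1, 1)
  ec2 <- expression_calls(atl, samples)
  expect_equal(ec2$calls$CT, "FL_ONLY")
  expect_equal(unname(ec2$prevalence["CT"]), 0)
})

test_that("atlas is invariant to peak input order and flags are monotone", {
  sim <- shared_sim()
  tp <- sim$threeprime
  info <- tp$peaks[, c("chrom", "start", "end", "strand", "peak_id"),
                   with = FALSE]
  build <- function(ord) {
    pk <- peak_set(info[ord], tp$counts[ord, ], tp$starts)
    b <- build_atlas(pk, sim$annotation, sim$genome, sim$blacklist, sim$ig)
    ev <- b$atlas$events
    ev[order(ev$chrom, ev$rep_pos, ev$strand),
       c("gene_id", "class", "rep_pos", "strand")]
  }
  set.seed(1)
  ord <- sample.int(nrow(info))
  expect_equal(build(seq_len(nrow(info))), build(ord), ignore_attr = TRUE)
})
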