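# Isoform consequences: retained CDR, transcript assignment, terminal-exon
# classification, coding potential, domain/TMD retention.

library(data.table)

test_that("retained CDR fraction and the strict 25% boundary", {
  # gene with CDS 900 nt split 90/810 across two exons
  g <- toy_gene("CDR", "+",
                cbind(start = c(0L, 1000L), end = c(200L, 2000L)),
                cds = cbind(start = c(100L, 1000L), end = c(190L, 1810L)))
  r <- retained_cdr_fraction(g, 500L)
  expect_equal(r$fraction, 0.1)
  expect_equal(r$class5p3p, "IPA_5P")
  # fraction exactly 0.25 is 3'IpA ("less than 25%" is strict)
  g2 <- toy_gene("CDR2", "+",
                 cbind(start = c(0L, 1000L), end = c(300L, 2000L)),
                 cds = cbind(start = c(0L, 1000L), end = c(300L, 1900L)))
  r2 <- retained_cdr_fraction(g2, 600L)
  expect_equal(r2$fraction, 0.25)
  expect_equal(r2$class5p3p, "IPA_3P")
  # non-coding gene: missing fraction
  g3 <- toy_gene("NC", "+", cbind(start = c(0L, 500L), end = c(100L, 700L)))
  expect_true(is.na(retained_cdr_fraction(g3, 300L)$fraction))
})

test_that("retained fraction is monotone along transcription order", {
  for (g in list(toy_gene_plus(), toy_gene_minus())) {
    ipos <- apply(g$introns, 1L, function(iv) floor(mean(iv)))
    if (g$strand == "-") ipos <- rev(ipos)
    fr <- vapply(ipos, function(p) retained_cdr_fraction(g, p)$fraction,
                 numeric(1))
    expect_true(all(diff(fr) >= 0))
  }
})

test_that("transcript assignment follows the 50/500/5000 nt rules", {
  g <- toy_gene("ASG", "+",
                cbind(start = c(0L, 2000L, 12000L), end = c(100L, 2100L, 12400L)),
                cds = cbind(start = 10L, end = 12100L))
  ev_end <- 5000L
  mk <- function(end3, n_ex) {
    starts <- seq(0L, by = 900L, length.out = n_ex)
    ex <- cbind(start = starts, end = starts + 300L)
    ex[n_ex, 2L] <- end3 + 1L
    list(chrom = "chrT", strand = "+", exons = ex)
  }
  # rule 1 tie: +30 with 2 exons vs +40 with 4 exons -> the 4-exon one
  asm <- list(t_a = mk(ev_end + 30L, 2L), t_b = mk(ev_end + 40L, 4L))
  a <- assign_transcript(ev_end, g, asm)
  expect_equal(a$transcript, "t_b")
  # assigned end replaced by the 3'-seq position
  expect_equal(max(a$model$exons[, 2L]), ev_end + 1L)
  # rule 2: nearest end within 500
  asm2 <- list(t_c = mk(ev_end + 420L, 3L), t_d = mk(ev_end + 480L, 5L))
  expect_equal(assign_transcript(ev_end, g, asm2)$transcript, "t_c")
  # rule 3: nearest end at +800 but within 5000 -> assigned
  asm3 <- list(t_e = mk(ev_end + 800L, 3L))
  expect_equal(assign_transcript(ev_end, g, asm3)$transcript, "t_e")
  # nothing within 5000 -> none
  asm4 <- list(t_f = mk(ev_end + 6000L, 3L))
  expect_true(is.na(assign_transcript(ev_end, g, asm4)$transcript))
  # single-exon transcripts only admitted near the TSS
  single_far <- list(s1 = list(chrom = "chrT", strand = "+",
                               exons = cbind(start = 4000L, end = ev_end + 10L)))
  expect_true(is.na(assign_transcript(ev_end, g, single_far)$transcript))
  single_tss <- list(s2 = list(chrom = "chrT", strand = "+",
                               exons = cbind(start = 50L, end = ev_end + 10L)))
  expect_equal(assign_transcript(ev_end, g, single_tss)$transcript, "s2")
})

test_that("terminal exon classification: composite, skipped, unresolved", {
  g <- toy_gene_plus()   # exons [0,100) [200,300) [400,520)
  # composite: last exon starts at annotated exon 2 start, reads through
  comp <- list(chrom = "chrT", strand = "+",
               exons = cbind(start = c(0L, 202L), end = c(100L, 370L)))
  expect_equal(classify_terminal_exon(comp, g), "COMPOSITE")
  # skipped: novel exon fully inside intron 2
  skp <- list(chrom = "chrT", strand = "+",
              exons = cbind(start = c(0L, 200L, 330L),
                            end = c(100L, 300L, 380L)))
  expect_equal(classify_terminal_exon(skp, g), "SKIPPED")
  # last exon matching an annotated start but not passing the donor
  unr <- list(chrom = "chrT", strand = "+",
              exons = cbind(start = c(0L, 200L), end = c(100L, 290L)))
  expect_equal(classify_terminal_exon(unr, g), "UNRESOLVED")
  expect_equal(classify_terminal_exon(NULL, g), "UNRESOLVED")
})

test_that("planted composite/skipped labels are reproduced exactly", {
  sim <- shared_sim()
  asm <- simulate_assembled_transcripts(sim)
  ipa <- sim$threeprime$peaks[sim$threeprime$peaks$type == "ipa", ]
  got <- vapply(seq_len(nrow(ipa)), function(r) {
    g <- sim$annotation$genes[[ipa$gene_id[r]]]
    a <- assign_transcript(ipa$end3[r], g, asm$models)
    classify_terminal_exon(a$model, g)
  }, character(1))
  expect_equal(got, asm$truth$terminal_class[match(ipa$peak_id,
                                                   asm$truth$peak_id)])
})

test_that("longest ORF scan over all frames, with and without stop", {
  expect_equal(longest_orf("ATGAAATAA"), 9L)          # ATG AAA TAA
  expect_equal(longest_orf("CCATGAAATAA"), 9L)        # frame 2
  expect_equal(longest_orf("GGGGGG"), 0L)             # no ATG
  expect_equal(longest_orf("ATGAAA"), 6L)             # open-ended ORF
  s <- paste0("ATG", strrep("GCT", 99L), "TAA")       # 303 nt
  expect_equal(longest_orf(s), 303L)
})

test_that("non-coding call combines probability, CDR fraction and ORF", {
  orf150 <- paste0("ATG", strrep("GCA", 48L), "TAA")
  expect_true(call_noncoding(0.1, 0.05, orf150)$noncoding)
  orf303 <- paste0("ATG", strrep("GCA", 99L), "TAA")
  expect_false(call_noncoding(0.1, 0.05, orf303)$noncoding)  # 303 > 300
  expect_false(call_noncoding(0.5, 0.05, orf150)$noncoding)
  expect_false(call_noncoding(0.1, 0.40, orf150)$noncoding)
  expect_true(call_noncoding(0.1, 0.05, "GGCC")$noncoding)   # no ATG
  def <- call_noncoding(NA, 0.05, orf150)
  expect_true(def$deferred)
  # logistic stub rises through 0.5 at the midpoint
  expect_lt(coding_potential_stub(orf150), 0.3)
  expect_gt(coding_potential_stub(orf303), 0.5)
})

test_that("domain retention: whole-domain rule, repeats, totals", {
  dom <- data.table(domain = paste0("zf", 1:7), category = "REPEATED",
                    aa_start = seq(10L, by = 40L, length.out = 7L),
                    aa_end = seq(40L, by = 40L, length.out = 7L))
  # truncation after repeat 4 (aa 170): 4 retained, 3 lost
  dr <- domain_retention(dom, upstream_cds_nt = 3L * 170L)
  expect_equal(dr$n_retained, 4L)
  expect_equal(dr$n_lost, 3L)
  expect_equal(dr$n_retained + dr$n_lost, nrow(dom))
  # domain spanning the truncation point is lost
  dom2 <- data.table(domain = "d", category = "OTHER",
                     aa_start = 290L, aa_end = 310L)
  expect_equal(domain_retention(dom2, 900L)$n_lost, 1L)   # trunc at 300 aa
  expect_equal(domain_retention(dom2, 931L)$n_retained, 1L)
  # missing table flagged
  expect_true(domain_retention(NULL, 900L)$flag_missing)
})

test_that("TMD status and amino-acid distance from the paper formula", {
  # gene: CDS 90 nt in exon1, 810 nt in exon2 (protein 300 aa);
  # TMD at aa 100-110 -> encoded in exon 2; intron 1 precedes it
  g <- toy_gene("TMDG", "+",
                cbind(start = c(0L, 1000L), end = c(200L, 2000L)),
                cds = cbind(start = c(100L, 1000L), end = c(190L, 1810L)))
  tmd <- data.table(domain = "TM1", category = "TMD",
                    aa_start = 100L, aa_end = 110L)
  r <- tmd_analysis(g, 500L, tmd)   # IpA in intron 1: upstream CDS 90 nt
  expect_equal(r$status, "LOST")
  # reference intron = intron 1 itself (upstream CDS 90 <= 297): distance 0
  expect_equal(r$distance_aa, 0)
  expect_false(r$flag_partial)
  # no TMD
  expect_equal(tmd_analysis(g, 500L, tmd[0L])$status, "NONE")
  # all TMDs upstream of the truncation
  tmd2 <- data.table(domain = "TM1", category = "TMD",
                     aa_start = 5L, aa_end = 25L)
  expect_equal(tmd_analysis(g, 500L, tmd2)$status, "RETAINED")
})

test_that("size and domain contrast finds planted differences", {
  set.seed(31)
  prot <- data.table(gene_id = sprintf("g%03d", 1:200),
                     length_aa = c(round(rlnorm(100, log(600), 0.3)),
                                   round(rlnorm(100, log(300), 0.3))),
                     is_ipa = rep(c(TRUE, FALSE), each = 100L))
  dom <- data.table(gene_id = rep(prot$gene_id, times = c(rep(5L, 100L),
                                                          rep(3L, 100L))))
  dom$domain <- "d"; dom$category <- sample(c("PPI", "DNA_BINDING"),
                                            nrow(dom), replace = TRUE)
  out <- size_and_domain_contrast(prot, dom)
  expect_lt(out$length_test$p.value, 0.01)
  expect_lt(out$count_test$p.value, 0.01)
  expect_gt(out$medians[["ipa_aa"]], out$medians[["other_aa"]])
  # identical partitions: no signal
  prot2 <- copy(prot); prot2$length_aa <- rep(400L, 200L)
  dom2 <- data.table(gene_id = prot2$gene_id[c(1:50, 101:150)], domain = "d",
                     category = "PPI")
  out2 <- size_and_domain_contrast(prot2, dom2)
  expect_gt(out2$length_test$p.value, 0.4)
  expect_equal(out2$categories$odds_ratio[out2$categories$category == "PPI"],
               1, tolerance = 0.2)
  expect_error(size_and_domain_contrast(prot[is_ipa == TRUE], dom), "non-empty")
})
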