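# Five evidence tiers and the NB conditional window test.

library(data.table)

toy_atlas <- function(events, tpm = NULL, iqr = NULL) {
  events <- as.data.table(events)
  if (is.null(events$event_id))
    events$event_id <- sprintf("EV%05d", seq_len(nrow(events)))
  if (is.null(tpm))
    tpm <- matrix(20, nrow(events), 1L,
                  dimnames = list(events$event_id, "S1"))
  if (is.null(iqr)) iqr <- tpm * 0 + 10
  structure(list(events = events, counts = tpm, tpm = tpm, iqr = iqr,
                 lib = data.table(sample = colnames(tpm),
                                  raw = 1e6, adjusted = 1e6)),
            class = "IpaAtlas")
}

# independent oracle: conditional law of U given U+D for side sums that are
# NB with size r each, written with explicit gamma-function weights
oracle_midp <- function(up, down, phi) {
  u <- sum(up); tot <- u + sum(down)
  r <- length(up) / phi
  k <- 0:tot
  lw <- lgamma(k + r) - lgamma(k + 1) +
    lgamma(tot - k + r) - lgamma(tot - k + 1)
  w <- exp(lw - max(lw)); w <- w / sum(w)
  sum(w[k > u]) + 0.5 * w[u + 1L]
}

test_that("coverage window test matches the closed-form oracle", {
  cases <- list(list(up = c(200, 190), down = c(5, 6)),
                list(up = c(20, 22), down = c(21, 19)),
                list(up = c(40, 45), down = c(35, 38)),
                list(up = c(0, 1), down = c(2, 0)))
  for (cs in cases) {
    for (phi in c(0.01, 0.05, 0.2)) {
      expect_equal(coverage_window_test(cs$up, cs$down, dispersion = phi),
                   oracle_midp(cs$up, cs$down, phi), tolerance = 1e-10)
    }
  }
  # strong drop is highly significant; exchangeable counts are not
  expect_lt(coverage_window_test(c(200, 190), c(5, 6)), 0.01)
  p_null <- coverage_window_test(c(20, 22), c(21, 19))
  expect_gt(p_null, 0.3)   # near 1/2 under exchangeability
  expect_lt(p_null, 0.6)
  # mid-P complements: up-vs-down and down-vs-up sum to one
  expect_equal(coverage_window_test(c(20, 22), c(21, 19), dispersion = 0.05) +
                 coverage_window_test(c(21, 19), c(20, 22), dispersion = 0.05),
               1, tolerance = 1e-10)
})

test_that("annotation tier matches 100 nt-extended last exons only", {
  # gene with last exon [400,520); candidate ends at 570 (+50), 670 (+150),
  # and one overlapping the internal exon at 250
  ann <- toy_annotation(list(toy_gene_plus()))
  ev <- data.table(gene_id = "TOYP", class = "IPA", chrom = "chrT",
                   start = c(545L, 645L, 225L), end = c(571L, 671L, 251L),
                   strand = "+", rep_pos = c(570L, 670L, 250L),
                   intron_tx = NA_integer_)
  atl <- toy_atlas(ev)
  hits <- evidence_annotation(atl, ann)
  expect_equal(hits, atl$events$event_id[1L])
})

test_that("coverage GLM tier: windows, exon exclusion, FDR validation", {
  # minus-strand gene far from exons; cleavage at p with coverage high
  # upstream (genomically right of p) and background downstream
  g <- toy_gene("GM", "-", cbind(start = c(200L, 5000L), end = c(400L, 5400L)),
                cds = cbind(start = 5050L, end = 5350L))
  ann <- toy_annotation(list(g))
  p <- 2500L
  len <- 8000L
  cov <- S4Vectors::Rle(0, len)
  cov[(p + 1L):(p + 1200L)] <- 40      # upstream of the '-' strand end
  cov[(p - 1200L):p] <- 2              # downstream residue
  track <- list(S1 = list(chrT = cov))
  ev <- data.table(gene_id = "GM", class = "IPA", chrom = "chrT",
                   start = c(p, 380L), end = c(p + 25L, 405L),
                   strand = "-", rep_pos = c(p, 390L),
                   intron_tx = c(1L, 1L))
  atl <- toy_atlas(ev)
  res <- evidence_rnaseq_glm(atl, track, ann)
  expect_true(res$testable[[atl$events$event_id[1L]]])
  # second event's windows overlap the annotated exon [200,400)
  expect_false(res$testable[[atl$events$event_id[2L]]])
  expect_equal(res$validated, atl$events$event_id[1L])
  expect_lt(res$pvals[1L, "S1"], 0.01)
})

test_that("GLM null on exchangeable coverage is not significant", {
  g <- toy_gene("GP", "+", cbind(start = c(0L, 9000L), end = c(100L, 9200L)),
                cds = cbind(start = 10L, end = 9100L))
  ann <- toy_annotation(list(g))
  set.seed(7)
  # flat read-placement coverage across the intron
  starts <- sample.int(8800L, 600L)
  cov <- IRanges::coverage(IRanges::IRanges(starts + 100L, width = 50L),
                           width = 10000L)
  ev <- data.table(gene_id = "GP", class = "IPA", chrom = "chrT",
                   start = 4476L, end = 4501L, strand = "+", rep_pos = 4500L,
                   intron_tx = 1L)
  res <- evidence_rnaseq_glm(toy_atlas(ev), list(S1 = list(chrT = cov)), ann)
  expect_gt(res$pvals[1L, "S1"], 0.05)
})

test_that("external 3'-end tier uses the resized 75 nt window and strand", {
  ev <- data.table(gene_id = "G", class = "IPA", chrom = "chrT",
                   start = c(975L, 975L, 975L), end = c(1001L, 1001L, 1001L),
                   strand = c("+", "+", "-"),
                   rep_pos = c(1000L, 1000L, 1000L), intron_tx = 1L)
  atl <- toy_atlas(ev)
  # external peak start 990: window [965, 1040) captures end 1000, '+' only
  ext <- data.table(chrom = "chrT", start = 990L, end = 1010L, strand = "+")
  hits <- evidence_external_3p(atl, ext)
  expect_setequal(hits, atl$events$event_id[1:2])
  # outside the window
  ext2 <- data.table(chrom = "chrT", start = 1060L, end = 1080L, strand = "+")
  expect_length(evidence_external_3p(atl, ext2), 0L)
  expect_length(evidence_external_3p(atl, ext2[0L]), 0L)
})

test_that("polyA-read tier trims, filters, deduplicates and needs a PAS", {
  # random genome (40-mers unique) with a PAS 37 nt upstream of p = 499 and a
  # non-A block at the cleavage so trimming stops at the read body
  genome <- toy_genome(1600L, plant = list(
    AATAAA = 462L, CGTCGTGCTCGG = 488L), seed = 5L)
  p <- 499L
  body <- function(len, shift = 0L)
    genome_seq(genome, "chrT", p - len + 1L - shift, p + 1L - shift)
  reads <- Biostrings::DNAStringSet(c(
    r1 = paste0(body(30L), "AAAA"),
    r2 = paste0(body(31L), "AAAAA"),
    r3 = paste0(body(32L), "AAAAAA"),
    r4 = paste0(body(33L), "AAAA"),
    r4dup = paste0(body(33L), "AAAAAAA"),   # same mapped coords as r4
    short = paste0(body(21L), "AAAA"),      # 21 nt after trim: discarded
    noA = body(30L),                        # no terminal A-run: ignored
    faraway = paste0(body(30L, shift = 300L), "AAAA")))
  ev <- data.table(gene_id = "G", class = "IPA", chrom = "chrT",
                   start = p - 24L, end = p + 1L, strand = "+",
                   rep_pos = p, intron_tx = 1L)
  atl <- toy_atlas(ev)
  res <- evidence_polya_reads(atl, reads, genome)
  expect_equal(unname(res$counts), 4L)      # r1-r4; dup collapsed; far away
  expect_equal(res$validated, atl$events$event_id)
  # with only 3 distinct mapped reads: not validated
  res3 <- evidence_polya_reads(atl, reads[c(1:3, 6:8)], genome)
  expect_equal(unname(res3$counts), 3L)
  expect_length(res3$validated, 0L)
})

test_that("high-expression tier needs TPM, usage and PAS together", {
  ch <- strsplit(paste(rep("ACGTGTCA", 100L), collapse = ""), "")[[1L]]
  ch[460:465] <- strsplit("AATAAA", "")[[1L]]
  genome <- Biostrings::DNAStringSet(setNames(paste(ch, collapse = ""), "chrT"))
  ev <- data.table(gene_id = "G", class = "IPA", chrom = "chrT",
                   start = 475L, end = 501L, strand = "+", rep_pos = 500L,
                   intron_tx = 1L)
  mk <- function(tpm) toy_atlas(ev, tpm = matrix(tpm, 1L, 1L,
                                                 dimnames = list(NULL, "S1")))
  usage <- matrix(0.15, 1L, 1L)
  expect_length(evidence_high_expression(mk(12), usage, genome), 1L)
  expect_length(evidence_high_expression(mk(9.9), usage, genome), 0L)
  expect_length(evidence_high_expression(mk(12), usage * 0 + 0.05, genome), 0L)
  # PAS absent
  genome2 <- Biostrings::DNAStringSet(setNames(
    paste(rep("ACGTGTCA", 100L), collapse = ""), "chrT"))
  expect_length(evidence_high_expression(mk(12), usage, genome2), 0L)
})

test_that("tier precedence and unvalidated events dropped", {
  ev <- data.table(gene_id = "G", class = c("IPA", "IPA", "IPA", "UTR3"),
                   chrom = "chrT", start = c(100L, 200L, 300L, 400L),
                   end = c(126L, 226L, 326L, 426L), strand = "+",
                   rep_pos = c(125L, 225L, 325L, 425L), intron_tx = 1L)
  atl <- toy_atlas(ev)
  ids <- atl$events$event_id
  conf <- build_confident_atlas(atl,
                                annotated = ids[1L],
                                glm_validated = ids[1:2],
                                polya = ids[2L])
  expect_equal(conf$evidence$tier,
               c("ANNOTATED", "RNASEQ_GLM", "UNVALIDATED"))
  expect_setequal(conf$atlas$events$event_id, c(ids[1:2], ids[4L]))
  # tier counts cover every candidate exactly once
  expect_equal(nrow(conf$evidence), 3L)
})

test_that("shared synthetic dataset validates all true events, no artifacts", {
  sim <- shared_sim()
  conf <- shared_confident()
  ev <- conf$atlas$events[conf$atlas$events$class == "IPA", ]
  tt <- truth_type_of(ev, sim)
  expect_true(all(tt == "ipa"))
  ipa_truth <- sim$truth$events[sim$truth$events$type == "ipa", ]
  expect_gte(nrow(ev) / nrow(ipa_truth), 0.95)
})
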