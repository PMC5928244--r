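# Intron retention caller, brute-force oracle equivalence, aggregation,
# and the IpA-IR co-occurrence expectation.

library(data.table)

# one-intron gene with fully controllable coverage and junctions
.ir_gene <- function() {
  toy_gene("IRG", "+", cbind(start = c(0L, 1100L), end = c(100L, 1200L)),
           cds = cbind(start = 10L, end = 1150L))
}

# coverage track: flanking exons at `exon_cov`, a fraction `frac` of the
# intron at `intron_cov`, the rest at 0
.ir_track <- function(exon_cov, intron_cov, frac, len = 1500L) {
  v <- S4Vectors::Rle(0, len)
  v[1:100] <- exon_cov
  v[1101:1200] <- exon_cov
  k <- round(frac * 1000L)
  if (k > 0L) v[101:(100L + k)] <- intron_cov
  list(chrT = v)
}

.ir_junc <- function(up, down, sample = "S1") {
  data.table(gene_id = "IRG", intron_tx = 1L, chrom = "chrT", start = 100L,
             end = 1100L, strand = "+", sample = sample,
             up_reads = up, down_reads = down)
}

# brute-force reimplementation of the four criteria from their definitions
.ir_oracle <- function(exon_cov, intron_cov, frac, up, down, map_frac = 1) {
  if (map_frac < 0.5) return("UNTESTABLE")
  ivec <- c(rep(intron_cov, round(frac * 1000)),
            rep(0, 1000 - round(frac * 1000)))
  evec <- rep(exon_cov, 200)
  ok <- (up >= 3 && down >= 3) &&
    mean(ivec >= 3) >= 0.5 &&
    median(evec) >= 10 &&
    median(ivec) / median(evec) >= 0.1
  if (ok) "RETAINED" else "NOT_RETAINED"
}

test_that("caller equals the brute-force oracle across criterion boundaries", {
  g <- .ir_gene()
  grid <- expand.grid(exon_cov = c(9, 10, 12),
                      intron_cov = c(1, 2, 3, 5),
                      frac = c(0.49, 0.5, 0.6, 1),
                      up = c(2L, 3L), down = c(2L, 3L, 5L))
  for (i in seq_len(nrow(grid))) {
    gr <- grid[i, ]
    cov <- .ir_track(gr$exon_cov, gr$intron_cov, gr$frac)
    call <- call_retained_introns_sample(g, cov, .ir_junc(gr$up, gr$down))
    expect_equal(call$status,
                 .ir_oracle(gr$exon_cov, gr$intron_cov, gr$frac, gr$up, gr$down),
                 info = paste(unlist(gr), collapse = "/"))
  }
})

test_that("criterion iv boundary: ratio 0.099 fails, 0.1 passes", {
  g <- .ir_gene()
  # intron fully covered at given level, exons at 100
  c1 <- call_retained_introns_sample(g, .ir_track(100, 9.9, 1), .ir_junc(5L, 5L))
  expect_equal(c1$status, "NOT_RETAINED")
  c2 <- call_retained_introns_sample(g, .ir_track(100, 10, 1), .ir_junc(5L, 5L))
  expect_equal(c2$status, "RETAINED")
})

test_that("low mappability makes an intron untestable; missing junctions fail (i)", {
  g <- .ir_gene()
  cov <- .ir_track(50, 20, 1)
  map <- list(chrT = S4Vectors::Rle(1, 1500L))
  map$chrT[101:700] <- 0   # 60% of the intron unmappable
  call <- call_retained_introns_sample(g, cov, .ir_junc(5L, 5L), map)
  expect_equal(call$status, "UNTESTABLE")
  # 40% unmappable: testable, criteria computed on mappable positions only
  map2 <- list(chrT = S4Vectors::Rle(1, 1500L))
  map2$chrT[101:500] <- 0
  call2 <- call_retained_introns_sample(g, cov, .ir_junc(5L, 5L), map2)
  expect_equal(call2$status, "RETAINED")
  # junction table absent: criterion (i) fails, intron is NOT_RETAINED
  call3 <- call_retained_introns_sample(g, cov, NULL)
  expect_equal(call3$status, "NOT_RETAINED")
})

test_that("aggregation follows the 66/33 rule over testable samples", {
  g <- .ir_gene()
  samples <- data.table(sample = paste0("S", 1:4), cell_type = "CT")
  mk_calls <- function(statuses) {
    rbindlist(lapply(seq_along(statuses), function(i) {
      cov <- if (statuses[i] == "RETAINED") .ir_track(50, 20, 1)
             else .ir_track(50, 0, 0)
      cl <- call_retained_introns_sample(g, cov, .ir_junc(5L, 5L,
                                                          paste0("S", i)))
      cl$sample <- paste0("S", i)
      cl
    }))
  }
  agg <- aggregate_retention(mk_calls(rep(c("RETAINED", "NOT"), c(3L, 1L))),
                             samples, toy_annotation(list(g)))
  expect_equal(agg$aggregate, "RETAINED")       # 75% >= 66%
  agg2 <- aggregate_retention(mk_calls(rep(c("RETAINED", "NOT"), c(2L, 2L))),
                              samples, toy_annotation(list(g)))
  expect_equal(agg2$aggregate, "AMBIGUOUS")     # 50%
  agg3 <- aggregate_retention(mk_calls(rep(c("RETAINED", "NOT"), c(1L, 3L))),
                              samples, toy_annotation(list(g)))
  expect_equal(agg3$aggregate, "NOT_RETAINED")  # 25% <= 33%
  # aggregate is invariant to sample order
  cl <- mk_calls(rep(c("RETAINED", "NOT"), c(3L, 1L)))
  expect_equal(aggregate_retention(cl[sample(nrow(cl))], samples,
                                   toy_annotation(list(g)))$aggregate,
               "RETAINED")
})

test_that("gene-level intron/exon ratio >= 0.2 flags the gene", {
  g <- .ir_gene()
  samples <- data.table(sample = "S1", cell_type = "CT")
  cl <- call_retained_introns_sample(g, .ir_track(50, 12.5, 1),
                                     .ir_junc(5L, 5L))
  cl$sample <- "S1"
  agg <- aggregate_retention(cl, samples, toy_annotation(list(g)))
  expect_true(agg$gene_flagged)                  # 12.5/50 = 0.25 >= 0.2
  cl2 <- call_retained_introns_sample(g, .ir_track(50, 5, 1),
                                      .ir_junc(5L, 5L))
  cl2$sample <- "S1"
  expect_false(aggregate_retention(cl2, samples,
                                   toy_annotation(list(g)))$gene_flagged)
})

test_that("PAS requirement restricts the IpA-relevant intron universe", {
  g <- .ir_gene()
  samples <- data.table(sample = "S1", cell_type = "CT")
  cl <- call_retained_introns_sample(g, .ir_track(50, 20, 1), .ir_junc(5L, 5L))
  cl$sample <- "S1"
  with_pas <- toy_genome(1500L, plant = list(AATAAA = 600L), seed = 1L, at = 0)
  no_pas <- toy_genome(1500L, seed = 1L, at = 0)
  a1 <- aggregate_retention(cl, samples, toy_annotation(list(g)),
                            genome = with_pas)
  a2 <- aggregate_retention(cl, samples, toy_annotation(list(g)),
                            genome = no_pas)
  expect_true(a1$has_pas)
  expect_false(a2$has_pas)
})

test_that("co-occurrence expectation formula and independence band", {
  universe <- sprintf("g%04d:1", 1:1000)
  set.seed(13)
  ipa <- sample(universe, 100L)
  ir <- sample(universe, 200L)
  out <- ipa_ir_overlap(ipa, ir, universe)
  expect_equal(out$expected, 0.1 * 0.2 * 1000)
  # independent draws stay inside the central 95% binomial band
  band <- qbinom(c(0.025, 0.975), 1000L, 0.1 * 0.2)
  inside <- replicate(60L, {
    o <- ipa_ir_overlap(sample(universe, 100L), sample(universe, 200L),
                        universe)$observed
    o >= band[1L] && o <= band[2L]
  })
  expect_gte(mean(inside), 0.85)
  expect_error(ipa_ir_overlap(ipa, ir, character(0)), "empty")
  # usage comparison: non-retained higher usage detected
  usage <- setNames(runif(length(ipa), 0.4, 0.8), ipa)
  both <- intersect(ipa, ir)
  usage[both] <- runif(length(both), 0.05, 0.3)
  out2 <- ipa_ir_overlap(ipa, ir, universe, ipa_usage = usage)
  expect_lt(out2$usage_test$p.value, 0.01)
})
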