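#' Simulate per-sample 3'-seq peak tables
#'
#' Draws negative-binomial read counts for every planted peak (true 3'UTR
#' and IpA cleavage events, internal-priming / antisense / blacklisted
#' artifacts, one immunoglobulin-like ultra-high-count locus, sub-threshold
#' and PCR-duplicate-like peaks) in each sample of each condition, together
#' with a read-start position multiset per peak per sample.  A configurable
#' fraction of IpA genes receives a usage shift in the second condition.
#'
#' @param sim an \code{IpaSim} from \code{\link{simulate_annotation}}.
#' @param seed seed for this stage (defaults to \code{cfg$seed + 1}).
#' @return the \code{IpaSim} with element \code{threeprime}: list with
#'   \code{peaks} (info table), \code{counts} (peaks x samples), \code{starts}
#'   (long table: peak_id, sample, pos, n), \code{samples} (sample sheet),
#'   \code{truth_usage} (per-condition true usage of IpA events).
#' @export
simulate_threeprime <- function(sim, seed = sim$cfg$seed + 1L) {
  cfg <- sim$cfg
  set.seed(seed)
  ev <- data.table::copy(sim$truth$events)
  conds <- cfg$conditions
  samples <- data.table::data.table(
    sample = paste0(rep(conds, each = cfg$n_samples), seq_len(cfg$n_samples)),
    condition = rep(conds, each = cfg$n_samples))
  samples$cell_type <- samples$condition

  gene_ids <- sim$truth$genes$gene_id
  gene_expr <- setNames(rlnorm(length(gene_ids), cfg$gene_expr_meanlog,
                               cfg$gene_expr_sdlog), gene_ids)
  # keep every gene comfortably expressed so planted events are testable
  gene_expr <- pmax(gene_expr, 60)

  ipa_ev <- which(ev$type == "ipa")
  n_diff <- round(cfg$diff_fraction * length(ipa_ev))
  diff_ev <- if (n_diff > 0) sample(ipa_ev, n_diff) else integer(0)
  u_base <- runif(nrow(ev), cfg$ipa_usage_range[1L], cfg$ipa_usage_range[2L])
  usage <- matrix(NA_real_, nrow(ev), length(conds),
                  dimnames = list(ev$peak_id, conds))
  usage[ipa_ev, ] <- u_base[ipa_ev]
  if (length(diff_ev)) {
    # half shift up in condition 2, half down; magnitude cfg$diff_delta
    up <- sample(c(TRUE, FALSE), length(diff_ev), replace = TRUE)
    lo <- 0.05
    usage[diff_ev[up], 1L] <- runif(sum(up), lo, 1 - cfg$diff_delta - lo)
    usage[diff_ev[up], -1L] <- usage[diff_ev[up], 1L] + cfg$diff_delta
    usage[diff_ev[!up], 1L] <- runif(sum(!up), cfg$diff_delta + lo, 1 - lo)
    usage[diff_ev[!up], -1L] <- usage[diff_ev[!up], 1L] - cfg$diff_delta
  }
  sub_ev <- which(ev$type == "subthreshold")
  usage[sub_ev, ] <- 0.02
  dup_ev <- which(ev$type == "pcr_dup")
  usage[dup_ev, ] <- 0.2

  # expected count of each peak in each condition
  mu <- matrix(0, nrow(ev), length(conds), dimnames = list(ev$peak_id, conds))
  for (ci in seq_along(conds)) {
    u_g <- setNames(rep(0, length(gene_ids)), gene_ids)
    uevc <- usage[, ci]
    intronic <- ev$type %in% c("ipa", "subthreshold", "pcr_dup")
    u_tot <- tapply(ifelse(intronic, uevc, 0), ev$gene_id, sum, na.rm = TRUE)
    u_g[names(u_tot)] <- u_tot
    for (r in seq_len(nrow(ev))) {
      g <- ev$gene_id[r]
      e <- if (is.na(g)) NA_real_ else gene_expr[[g]]
      mu[r, ci] <- switch(ev$type[r],
        utr_distal = e * (1 - u_g[[g]]) * 0.7,
        utr_proximal = e * (1 - u_g[[g]]) * 0.3,
        ipa = , subthreshold = , pcr_dup = e * uevc[r],
        artifact_ip = , artifact_antisense = , artifact_blacklist = e * 0.3,
        ig = 3e5)
    }
  }

  size <- 1 / cfg$nb_dispersion
  lib_factor <- setNames(rlnorm(nrow(samples), 0, 0.1), samples$sample)
  counts <- matrix(0L, nrow(ev), nrow(samples),
                   dimnames = list(ev$peak_id, samples$sample))
  for (s in seq_len(nrow(samples))) {
    ci <- match(samples$condition[s], conds)
    counts[, s] <- rnbinom(nrow(ev), mu = mu[, ci] * lib_factor[s], size = size)
  }

  # read-start multisets: spread for real peaks, degenerate for PCR dups
  starts <- vector("list", nrow(ev))
  offs <- 10:35
  for (r in seq_len(nrow(ev))) {
    dirn <- if (ev$strand[r] == "+") -1L else 1L
    pos_pool <- ev$end3[r] + dirn * offs
    per_sample <- lapply(seq_len(nrow(samples)), function(s) {
      n <- counts[r, s]
      if (n == 0L) return(NULL)
      if (ev$type[r] == "pcr_dup") {
        data.table::data.table(sample = samples$sample[s],
                               pos = ev$end3[r] + dirn * 20L, n = n)
      } else {
        w <- as.vector(stats::rmultinom(1L, n, rep(1, length(offs))))
        keep <- w > 0L
        data.table::data.table(sample = samples$sample[s],
                               pos = pos_pool[keep], n = w[keep])
      }
    })
    tab <- data.table::rbindlist(per_sample)
    if (nrow(tab)) tab$peak_id <- ev$peak_id[r]
    starts[[r]] <- tab
  }
  starts <- data.table::rbindlist(starts[lengths(starts) > 0L])
  data.table::setcolorder(starts, c("peak_id", "sample", "pos", "n"))

  # peak intervals: 25 nt ending at the cleavage base
  ev$start <- ifelse(ev$strand == "+", ev$end3 - 24L, ev$end3)
  ev$end <- ifelse(ev$strand == "+", ev$end3 + 1L, ev$end3 + 25L)

  sim$threeprime <- list(peaks = ev, counts = counts, starts = starts,
                         samples = samples,
                         truth_usage = usage, gene_expr = gene_expr,
                         lib_factor = lib_factor)
  sim
}

#' Simulate IpA / full-length count pairs for differential-usage tests
#'
#' Lightweight generator used by operating-characteristic simulations:
#' for each event, NB counts of the IpA isoform and the pooled full-length
#' isoform across two conditions, with planted usage and an optional shift.
#'
#' @param n_events number of events.
#' @param n_per_cond samples per condition.
#' @param usage baseline usage (scalar or length \code{n_events}).
#' @param delta usage shift in condition 2 (scalar or vector; 0 = null).
#' @param depth expected total (IpA + full-length) count per event.
#' @param dispersion NB dispersion.
#' @param lib_size nominal per-sample library size (all equal).
#' @param seed RNG seed.
#' @return list with \code{ipa}, \code{fl} (event x sample count matrices),
#'   \code{condition} (factor), \code{lib_sizes}, \code{usage1},
#'   \code{usage2}.
#' @export
simulate_usage_counts <- function(n_events, n_per_cond = 3L, usage = 0.25,
                                  delta = 0, depth = 400,
                                  dispersion = 0.05, lib_size = 1e6,
                                  seed = 1L) {
  set.seed(seed)
  u1 <- rep_len(usage, n_events)
  u2 <- pmin(0.95, pmax(0.02, u1 + rep_len(delta, n_events)))
  cond <- factor(rep(c("A", "B"), each = n_per_cond))
  ns <- 2L * n_per_cond
  size <- 1 / dispersion
  ipa <- fl <- matrix(0L, n_events, ns,
                      dimnames = list(sprintf("E%04d", seq_len(n_events)),
                                      paste0(cond, rep(seq_len(n_per_cond), 2L))))
  for (s in seq_len(ns)) {
    u <- if (cond[s] == "A") u1 else u2
    ipa[, s] <- rnbinom(n_events, mu = depth * u, size = size)
    fl[, s] <- rnbinom(n_events, mu = depth * (1 - u), size = size)
  }
  list(ipa = ipa, fl = fl, condition = cond,
       lib_sizes = rep(lib_size, ns), usage1 = u1, usage2 = u2)
}
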