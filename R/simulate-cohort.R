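#' Simulate a two-group patient cohort with IpA-signature usage and PFS
#'
#' Two latent groups with shifted mean signature usage (group A low, group B
#' high), exponential progression-free survival with hazard ratio
#' \code{cfg$hazard_ratio} for group A over group B, and independent
#' exponential censoring.  A configurable fraction of patients is
#' heterogeneous: each signature event's usage is drawn from the A or the B
#' law by an independent coin flip, emulating subclonal mixtures; their
#' hazard is the geometric mean of the group hazards.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param seed stage seed (defaults to \code{cfg$seed + 4}).
#' @param mean_usage length-2 mean usage of the low and high group.
#' @param usage_sd event-level usage standard deviation.
#' @return list with \code{cohort} (data.table: patient, group_true,
#'   het_true, pfs_days, event), \code{usage} (patients x events matrix in
#'   [0,1]).
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = cfg$seed + 4L,
                            mean_usage = c(0.15, 0.55), usage_sd = 0.08) {
  stopifnot(cfg$signature_size >= 1L)
  set.seed(seed)
  n <- cfg$cohort_n
  n_tot <- sum(n)
  group <- rep(c("A", "B"), times = n)
  het <- runif(n_tot) < cfg$het_fraction
  p_events <- cfg$signature_size

  draw <- function(mu, k) pmin(0.98, pmax(0.01, rnorm(k, mu, usage_sd)))
  usage <- matrix(NA_real_, n_tot, p_events,
                  dimnames = list(sprintf("PT%03d", seq_len(n_tot)),
                                  sprintf("SIG%02d", seq_len(p_events))))
  for (i in seq_len(n_tot)) {
    if (het[i]) {
      pick_high <- runif(p_events) < 0.5
      usage[i, ] <- ifelse(pick_high, draw(mean_usage[2L], p_events),
                           draw(mean_usage[1L], p_events))
    } else {
      mu <- if (group[i] == "A") mean_usage[1L] else mean_usage[2L]
      usage[i, ] <- draw(mu, p_events)
    }
  }

  # group B (high usage) has baseline hazard; group A hazard_ratio-fold lower
  hz <- ifelse(group == "B", cfg$baseline_hazard,
               cfg$baseline_hazard / cfg$hazard_ratio)
  hz[het] <- sqrt(cfg$baseline_hazard^2 / cfg$hazard_ratio)
  t_event <- rexp(n_tot, rate = hz)
  t_cens <- rexp(n_tot, rate = cfg$censor_rate)
  cohort <- data.table::data.table(
    patient = rownames(usage),
    group_true = group, het_true = het,
    pfs_days = round(pmin(t_event, t_cens), 1),
    event = as.integer(t_event <= t_cens))
  list(cohort = cohort, usage = usage)
}
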