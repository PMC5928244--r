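# IpA-signature survival stratification: RNA-seq usage proxy, signature
# selection, Ward clustering with kNN homogeneity filtering, and a
# reimplemented Kaplan-Meier estimator + two-sample log-rank test.

#' RNA-seq proxy of IpA usage for one event
#'
#' IpA expression is the length-normalized read count in the window up to
#' \code{win} bp upstream of the event 3' end, truncated at the nearest
#' upstream exon and requiring at least \code{min_win} bp; full-length
#' expression is the length-normalized count in the \code{win} bp from
#' the start of the last coding exon.  The proxy is IpA/(IpA + FL).
#'
#' @param gene a \code{GeneModel}.
#' @param event_end3 0-based cleavage base (intronic).
#' @param coverage per-chromosome list of \code{Rle} for one sample.
#' @param win,min_win window length and minimum usable length (bp).
#' @return list with \code{usage} (NA when the window is too short),
#'   \code{ipa_expr}, \code{fl_expr}.
#' @export
rnaseq_usage_proxy <- function(gene, event_end3, coverage, win = 500L,
                               min_win = 50L) {
  cov <- coverage[[gene$chrom]]
  dens <- function(a, b) {
    if (b <= a) return(NA_real_)
    sum(as.numeric(cov[(a + 1L):b])) / (b - a)
  }
  if (gene$strand == "+") {
    lim <- gene$exons[gene$exons[, 2L] <= event_end3, 2L]
    lo <- max(c(event_end3 + 1L - win, lim))
    ipa_win <- c(lo, event_end3 + 1L)
  } else {
    lim <- gene$exons[gene$exons[, 1L] > event_end3, 1L]
    hi <- min(c(event_end3 + win, lim))
    ipa_win <- c(event_end3, hi)
  }
  if (diff(ipa_win) < min_win)
    return(list(usage = NA_real_, ipa_expr = NA_real_, fl_expr = NA_real_))
  ipa_expr <- dens(ipa_win[1L], ipa_win[2L])
  # last coding exon start, transcription orientation
  if (is.null(gene$cds))
    return(list(usage = NA_real_, ipa_expr = ipa_expr, fl_expr = NA_real_))
  if (gene$strand == "+") {
    lce <- gene$cds[which.max(gene$cds[, 2L]), ]
    fl_win <- c(lce[1L], min(lce[1L] + win, length(cov)))
  } else {
    lce <- gene$cds[which.min(gene$cds[, 1L]), ]
    fl_win <- c(max(0L, lce[2L] - win), lce[2L])
  }
  fl_expr <- dens(fl_win[1L], fl_win[2L])
  u <- if (is.na(ipa_expr) || is.na(fl_expr) || ipa_expr + fl_expr == 0)
    NA_real_ else ipa_expr / (ipa_expr + fl_expr)
  list(usage = unname(u), ipa_expr = unname(ipa_expr),
       fl_expr = unname(fl_expr))
}

#' Select the survival signature events
#'
#' Events qualify when differentially used (FDR < \code{fdr_cut},
#' |usage shift| > \code{delta_cut}) and their RNA-seq usage proxy tracks
#' the 3'-seq usage across calibration samples (Pearson r >
#' \code{cor_cut}).
#'
#' @param results differential-usage table
#'   (\code{\link{fit_differential_usage}}).
#' @param proxy_usage,threeprime_usage matrices (events x calibration
#'   samples) of proxy and 3'-seq usage; rows matched by name.
#' @param fdr_cut,delta_cut,cor_cut selection thresholds.
#' @return data.table (event_id, fdr, delta_usage, cor) of selected events.
#' @export
select_signature_events <- function(results, proxy_usage, threeprime_usage,
                                    fdr_cut = 0.05, delta_cut = 0.25,
                                    cor_cut = 0.75) {
  if (ncol(proxy_usage) < 3L) stop("need >= 3 calibration samples")
  common <- intersect(rownames(proxy_usage), rownames(threeprime_usage))
  rs <- vapply(common, function(e) {
    x <- proxy_usage[e, ]; y <- threeprime_usage[e, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    cor(x[ok], y[ok])
  }, numeric(1))
  res <- data.table::as.data.table(results)
  res <- res[match(common, res$event_id), ]
  keep <- !is.na(res$fdr) & res$fdr < fdr_cut &
    abs(res$delta_usage) > delta_cut & !is.na(rs) & rs > cor_cut
  data.table::data.table(event_id = common[keep], fdr = res$fdr[keep],
                         delta_usage = res$delta_usage[keep],
                         cor = rs[keep])
}

#' Cluster patients on signature usage and filter heterogeneous ones
#'
#' Agglomerative hierarchical clustering (Euclidean distance, Ward
#' linkage) cut at \code{k}; groups are labelled A, B, ... in order of
#' increasing median signature usage.  A patient is retained when at
#' least \code{ceiling(agreement * knn)} of its \code{knn} nearest
#' neighbours (Euclidean, self excluded) share its group; the filter is
#' applied once, without recomputing neighbourhoods.
#'
#' @param usage patients x events usage matrix (missing values imputed by
#'   the event's cohort median).
#' @param k number of groups.
#' @param knn neighbours examined.
#' @param agreement required fraction of concordant neighbours.
#' @return data.table: patient, group, retained, imputed fraction.
#' @export
cluster_and_filter_patients <- function(usage, k = 2L, knn = 5L,
                                        agreement = 0.8) {
  if (anyDuplicated(rownames(usage))) stop("duplicate patient rows")
  if (nrow(usage) < k + knn) stop("too few patients for k groups + kNN filter")
  imp <- 0
  for (j in seq_len(ncol(usage))) {
    miss <- is.na(usage[, j])
    if (any(miss)) {
      usage[miss, j] <- median(usage[, j], na.rm = TRUE)
      imp <- imp + sum(miss)
    }
  }
  d <- dist(usage)
  cl <- cutree(hclust(d, method = "ward.D2"), k = k)
  med <- tapply(rowMeans(usage), cl, median)
  relab <- setNames(LETTERS[seq_len(k)], names(sort(med)))
  grp <- unname(relab[as.character(cl)])

  dm <- as.matrix(d)
  diag(dm) <- Inf
  need <- ceiling(agreement * knn)
  retained <- vapply(seq_len(nrow(usage)), function(i) {
    nb <- order(dm[i, ])[seq_len(knn)]
    sum(grp[nb] == grp[i]) >= need
  }, logical(1))
  data.table::data.table(patient = rownames(usage), group = grp,
                         retained = retained,
                         imputed_fraction = imp / length(usage))
}

#' Kaplan-Meier estimator (reimplemented)
#'
#' @param time follow-up times.
#' @param event 1 = event, 0 = censored.
#' @return data.table (time, n_risk, n_event, surv): the step function
#'   evaluated at each distinct event time.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event))
  ut <- sort(unique(time[event == 1L]))
  n_risk <- vapply(ut, function(t) sum(time >= t), 0)
  n_event <- vapply(ut, function(t) sum(time == t & event == 1L), 0)
  surv <- cumprod(1 - n_event / n_risk)
  data.table::data.table(time = ut, n_risk = n_risk, n_event = n_event,
                         surv = surv)
}

#' Two-sample log-rank test (reimplemented)
#'
#' Standard Mantel-Haenszel log-rank statistic over the pooled distinct
#' event times; the statistic is referred to chi-square(1).
#'
#' @param time,event follow-up times and event indicators.
#' @param group two-level group labels.
#' @return list with \code{chisq}, \code{p.value}, \code{obs},
#'   \code{exp} (per-group observed and expected events).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("two groups required")
  if (any(tapply(rep(1L, length(group)), group, sum) == 0))
    stop("empty group")
  ut <- sort(unique(time[event == 1L]))
  o1 <- e1 <- v <- 0
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == levels(group)[1L])
    d <- sum(time == t & event == 1L)
    d1 <- sum(time == t & event == 1L & group == levels(group)[1L])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1L) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1L)
  }
  chisq <- if (v > 0) (o1 - e1)^2 / v else NA_real_
  list(chisq = chisq,
       p.value = if (is.na(chisq)) NA_real_ else
         pchisq(chisq, 1L, lower.tail = FALSE),
       obs = c(o1, sum(event) - o1),
       exp = c(e1, sum(event) - e1))
}

#' Kaplan-Meier curves and log-rank comparison of patient groups
#'
#' @param cohort data.table with pfs_days, event, and a \code{group}
#'   column (e.g. merged output of
#'   \code{\link{cluster_and_filter_patients}}); only retained patients
#'   should be passed.
#' @return list with \code{curves} (per-group KM tables) and \code{test}
#'   (\code{\link{logrank_test}} result).
#' @export
km_logrank <- function(cohort) {
  cohort <- data.table::as.data.table(cohort)
  groups <- sort(unique(cohort$group))
  if (any(table(cohort$group) == 0L)) stop("empty group")
  curves <- lapply(setNames(groups, groups), function(g) {
    sub <- cohort[cohort$group == g, ]
    km_estimate(sub$pfs_days, sub$event)
  })
  test <- logrank_test(cohort$pfs_days, cohort$event, cohort$group)
  list(curves = curves, test = test)
}
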