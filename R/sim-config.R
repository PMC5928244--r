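#' Simulation configuration
#'
#' Parameters of the synthetic world used by all generators.  Defaults
#' describe a small but realistic bulk 3'-seq + RNA-seq experiment: 200
#' multi-exon genes on artificial chromosomes, two conditions with three
#' samples each, 30% of genes carrying one intronic cleavage event with
#' usage drawn from [0.15, 0.7], negative-binomial peak counts, 50x exonic
#' read coverage, and a two-group patient cohort with hazard ratio 2.5.
#'
#' @param n_genes number of simulated genes.
#' @param n_samples samples per condition.
#' @param conditions condition labels (also used as cell types).
#' @param seed master seed; every downstream draw derives from it.
#' @param ipa_fraction fraction of genes given one planted IpA event.
#' @param ipa_usage_range range of true IpA usage (uniform draw).
#' @param diff_fraction fraction of IpA genes with condition-shifted usage.
#' @param diff_delta usage shift added in the second condition.
#' @param n_artifact_ip,n_artifact_antisense,n_artifact_blacklist planted
#'   artifact peak counts (internal priming / antisense / blacklisted).
#' @param n_subthreshold planted real-looking but sub-threshold IpA peaks.
#' @param n_pcr_dup planted peaks whose read starts are all identical.
#' @param nb_dispersion NB dispersion of 3'-seq peak counts.
#' @param gene_expr_meanlog,gene_expr_sdlog log-normal law of per-gene
#'   expected 3'-seq counts per sample.
#' @param coverage_depth mean exonic RNA-seq coverage (reads/base) of an
#'   average-expression gene.
#' @param read_length RNA-seq read length (nt).
#' @param intron_background intronic background coverage as a fraction of
#'   the gene's exonic coverage.
#' @param ir_fraction fraction of eligible introns planted as retained.
#' @param ir_ratio_range intron/exon coverage ratio range of retained introns.
#' @param n_exons_range exons per gene (uniform integer draw).
#' @param exon_len_meanlog,intron_len_meanlog,len_sdlog log-normal exon and
#'   intron length parameters.
#' @param ipa_intron_factor multiplicative intron-length separation of IpA
#'   genes over the rest.
#' @param at_content genomic background A+T fraction.
#' @param pas_offset planted PAS start, nt upstream of the cleavage base.
#' @param external_fraction fraction of planted IpA ends present in the
#'   simulated external 3'-end peak set.
#' @param polya_fraction fraction of planted IpA ends with untemplated-A
#'   reads in the unmapped FASTA.
#' @param polya_reads_per_event untemplated-A reads emitted per such end.
#' @param cohort_n patients per cohort group, length 2.
#' @param hazard_ratio group A vs group B hazard ratio of PFS.
#' @param het_fraction fraction of heterogeneous (mixed-usage) patients.
#' @param censor_rate independent exponential censoring rate (per day).
#' @param baseline_hazard group B (high-usage) hazard per day.
#' @param signature_size number of signature events in the cohort usage
#'   matrix.
#' @return list of class \code{SimConfig}.
#' @export
sim_config <- function(n_genes = 200L,
                       n_samples = 3L,
                       conditions = c("A", "B"),
                       seed = 1L,
                       ipa_fraction = 0.3,
                       ipa_usage_range = c(0.15, 0.7),
                       diff_fraction = 0.25,
                       diff_delta = 0.4,
                       n_artifact_ip = 15L,
                       n_artifact_antisense = 10L,
                       n_artifact_blacklist = 10L,
                       n_subthreshold = 3L,
                       n_pcr_dup = 2L,
                       nb_dispersion = 0.05,
                       gene_expr_meanlog = log(300),
                       gene_expr_sdlog = 0.8,
                       coverage_depth = 50,
                       read_length = 50L,
                       intron_background = 0.05,
                       ir_fraction = 0.1,
                       ir_ratio_range = c(0.15, 0.5),
                       n_exons_range = c(4L, 8L),
                       exon_len_meanlog = log(160),
                       intron_len_meanlog = log(1000),
                       len_sdlog = 0.5,
                       ipa_intron_factor = 2,
                       at_content = 0.55,
                       pas_offset = 21L,
                       external_fraction = 0.6,
                       polya_fraction = 0.7,
                       polya_reads_per_event = 6L,
                       cohort_n = c(100L, 100L),
                       hazard_ratio = 2.5,
                       het_fraction = 0.1,
                       censor_rate = 1 / 3000,
                       baseline_hazard = 1 / 900,
                       signature_size = 20L) {
  cfg <- as.list(environment())
  rates <- c(cfg$ipa_fraction, cfg$diff_fraction, cfg$het_fraction,
             cfg$intron_background, cfg$ir_fraction, cfg$external_fraction,
             cfg$polya_fraction, cfg$at_content)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (diff(range(cfg$ipa_usage_range)) < 0 || any(cfg$ipa_usage_range < 0) ||
      any(cfg$ipa_usage_range > 1)) stop("ipa_usage_range must be within [0,1]")
  structure(cfg, class = "SimConfig")
}
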