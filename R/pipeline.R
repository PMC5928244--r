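# End-to-end orchestration: filter cascade -> clustering -> usage ->
# robustness -> five-tier validation, from in-memory objects or from a
# dataset directory (the formats written by write_sim_dataset).

#' Build a quantified cleavage-event atlas from called peaks
#'
#' Runs the full filter cascade (artifact flags, immunoglobulin masking
#' with library adjustment, gene-context filters), clusters surviving
#' peaks into events, quantifies TPM and usage, and applies the
#' robust-expression filters.
#'
#' @param peaks a \code{PeakSet}.
#' @param ann a \code{GenomeAnnotation}.
#' @param genome a \code{DNAStringSet}.
#' @param blacklist,ig optional interval tables (0-based).
#' @return list with \code{atlas} (robust events), \code{usage} (usage of
#'   the robust events, computed before the robustness filter),
#'   \code{peaks} (flagged \code{PeakSet}), \code{raw_atlas} (pre-filter
#'   events), \code{raw_usage}.
#' @export
build_atlas <- function(peaks, ann, genome, blacklist = NULL, ig = NULL) {
  peaks <- assign_peaks(peaks, ann)
  peaks <- filter_artifact_peaks(peaks, blacklist, genome)
  peaks <- mask_ig_adjust_library(peaks, ig)
  peaks <- filter_gene_context(peaks, ann)
  raw_atlas <- cluster_peaks(peaks)
  raw_usage <- compute_usage(raw_atlas)
  atlas <- apply_robustness_filters(raw_atlas, raw_usage)
  usage <- raw_usage[match(atlas$events$event_id, raw_atlas$events$event_id), ,
                     drop = FALSE]
  list(atlas = atlas, usage = usage, peaks = peaks,
       raw_atlas = raw_atlas, raw_usage = raw_usage)
}

#' Validate IpA events through the five evidence tiers
#'
#' @param built result of \code{\link{build_atlas}}.
#' @param ann a \code{GenomeAnnotation} (or list of annotation sources).
#' @param genome a \code{DNAStringSet}.
#' @param coverage per-sample coverage tracks (may be NULL to skip the
#'   GLM tier).
#' @param external external 3'-end peak table or NULL.
#' @param polya_reads \code{DNAStringSet} of unmapped reads or NULL.
#' @param motifs a \code{\link{motif_config}}.
#' @param ... tier parameters passed through.
#' @return list with \code{atlas} (confident atlas), \code{evidence}
#'   (tier table), \code{usage} (usage rows of the confident atlas),
#'   \code{glm} (full GLM result or NULL).
#' @export
validate_atlas <- function(built, ann, genome, coverage = NULL,
                           external = NULL, polya_reads = NULL,
                           motifs = motif_config(), ...) {
  atlas <- built$atlas
  usage <- built$usage
  annotated <- evidence_annotation(atlas,
                                   if (inherits(ann, "GenomeAnnotation"))
                                     list(ann) else ann)
  glm_res <- NULL; glm_ok <- character(0)
  if (!is.null(coverage)) {
    ann1 <- if (inherits(ann, "GenomeAnnotation")) ann else ann[[1L]]
    glm_res <- evidence_rnaseq_glm(atlas, coverage, ann1, ...)
    glm_ok <- glm_res$validated
  }
  ext_ok <- evidence_external_3p(atlas, external)
  pol_ok <- character(0)
  if (!is.null(polya_reads))
    pol_ok <- evidence_polya_reads(atlas, polya_reads, genome,
                                   motifs = motifs)$validated
  hx_ok <- evidence_high_expression(atlas, usage, genome, motifs = motifs)
  conf <- build_confident_atlas(atlas, annotated, glm_ok, ext_ok, pol_ok,
                                hx_ok, glm_result = glm_res)
  conf$usage <- usage[match(conf$atlas$events$event_id,
                            atlas$events$event_id), , drop = FALSE]
  conf$glm <- glm_res
  conf
}

#' Run the atlas pipeline from a dataset directory
#'
#' Reads the plain-text inputs written by \code{\link{write_sim_dataset}}
#' (or equivalently formatted real data), builds the robust atlas, runs
#' the evidence tiers for which inputs are present, and optionally writes
#' \code{atlas.tsv} / \code{evidence.tsv}.
#'
#' @param dir dataset directory.
#' @param out optional output directory for the atlas/evidence TSVs.
#' @return list: \code{confident} (validated atlas + evidence),
#'   \code{built} (pre-validation stages), \code{ann}, \code{genome},
#'   \code{samples}.
#' @export
run_atlas_pipeline <- function(dir, out = NULL) {
  ann <- load_annotation(file.path(dir, "annotation.gtf"))
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrom_len <- setNames(Biostrings::width(genome), names(genome))
  peaks <- read_peaks(file.path(dir, "peaks.bed"),
                      file.path(dir, "peak_counts.tsv"),
                      if (file.exists(file.path(dir, "read_starts.tsv")))
                        file.path(dir, "read_starts.tsv") else NULL)
  rd <- function(f) if (file.exists(file.path(dir, f)))
    read_bed(file.path(dir, f)) else NULL
  samples <- data.table::fread(file.path(dir, "samples.tsv"))
  built <- build_atlas(peaks, ann, genome, rd("blacklist.bed"), rd("ig.bed"))
  cov_files <- list.files(dir, pattern = "^coverage_.*\\.bedgraph$")
  coverage <- NULL
  if (length(cov_files)) {
    coverage <- lapply(cov_files, function(f)
      read_bedgraph(file.path(dir, f), chrom_len))
    names(coverage) <- sub("^coverage_(.*)\\.bedgraph$", "\\1", cov_files)
  }
  polya <- if (file.exists(file.path(dir, "polya_reads.fa")))
    Biostrings::readDNAStringSet(file.path(dir, "polya_reads.fa")) else NULL
  confident <- validate_atlas(built, ann, genome, coverage,
                              rd("external3p.bed"), polya)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_atlas_tsv(confident$atlas, confident$usage, confident$evidence,
                    file.path(out, "atlas.tsv"))
    data.table::fwrite(confident$evidence, file.path(out, "evidence.tsv"),
                       sep = "\t")
  }
  list(confident = confident, built = built, ann = ann, genome = genome,
       samples = samples)
}

#' Write an atlas (with usage and evidence tier) as TSV
#' @param atlas an \code{IpaAtlas}.
#' @param usage usage matrix aligned to the atlas events.
#' @param evidence evidence table or NULL (tier column left empty).
#' @param path output path.
#' @export
write_atlas_tsv <- function(atlas, usage, evidence = NULL, path) {
  ev <- data.table::copy(atlas$events)
  ev$tier <- if (!is.null(evidence))
    evidence$tier[match(ev$event_id, evidence$event_id)] else NA_character_
  tpm <- atlas$tpm; colnames(tpm) <- paste0("tpm_", colnames(tpm))
  usg <- usage; colnames(usg) <- paste0("usage_", colnames(usg))
  out <- cbind(ev, data.table::as.data.table(tpm),
               data.table::as.data.table(usg))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
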