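# One moderately sized synthetic dataset shared across test files
# (built lazily, once per test run).

.fixture_env <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(n_genes = 50L, seed = 42L,
                      n_artifact_ip = 6L, n_artifact_antisense = 4L,
                      n_artifact_blacklist = 4L, n_subthreshold = 2L,
                      n_pcr_dup = 2L)
    sim <- simulate_annotation(cfg)
    sim <- simulate_threeprime(sim)
    sim <- simulate_rnaseq(sim)
    .fixture_env$sim <- sim
  }
  .fixture_env$sim
}

shared_built <- function() {
  if (is.null(.fixture_env$built)) {
    sim <- shared_sim()
    tp <- sim$threeprime
    pk <- peak_set(tp$peaks[, c("chrom", "start", "end", "strand", "peak_id"),
                            with = FALSE], tp$counts, tp$starts)
    .fixture_env$built <- build_atlas(pk, sim$annotation, sim$genome,
                                      sim$blacklist, sim$ig)
  }
  .fixture_env$built
}

shared_confident <- function() {
  if (is.null(.fixture_env$confident)) {
    sim <- shared_sim()
    .fixture_env$confident <- validate_atlas(
      shared_built(), sim$annotation, sim$genome,
      coverage = sim$rnaseq$coverage,
      external = simulate_external_3p(sim),
      polya_reads = sim$rnaseq$polya_reads)
  }
  .fixture_env$confident
}

# map atlas events back to planted truth by representative position
truth_type_of <- function(events, sim, tol = 5L) {
  tt <- sim$truth$events
  vapply(seq_len(nrow(events)), function(r) {
    d <- abs(tt$end3 - events$rep_pos[r])
    hit <- which(d <= tol & tt$strand == events$strand[r])
    if (length(hit)) tt$type[hit[1L]] else NA_character_
  }, character(1))
}
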