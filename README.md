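# ipaAtlas

Intronic polyadenylation (IpA) occurs when the cleavage/polyadenylation
machinery fires inside an intron instead of the annotated 3'UTR, producing
truncated mRNAs that encode shortened proteins — often dropping
transmembrane domains or DNA-binding fingers — or non-coding fragments.
`ipaAtlas` is an R package for building a confident atlas of IpA events
from 3'-end sequencing (3'-seq) peak tables and interrogating their
regulation and consequences. It is aimed at transcriptomics groups with
called 3'-seq peaks, matched RNA-seq, and (optionally) patient cohorts.

The pipeline:

1. **Peak atlas** (`build_atlas`) — artifact removal (ENCODE-style
   blacklist overlap; internal priming, flagged when the genomic sequence
   just downstream of the cleavage site is A-rich: ≥6 consecutive A or ≥7 A
   in 10 nt; antisense peaks), immunoglobulin-locus masking with
   library-size adjustment, ambiguous gene-context filters (overlapping
   genes, small-RNA loci, convergent-gene 3'UTR ends within 100 nt,
   upstream-gene 3'UTR ends within 5000 nt), single-linkage clustering of
   3' ends within 200 nt into cleavage events, TPM quantification against
   the adjusted library, isoform **usage**
   `u(e,s) = TPM(e,s) / Σ TPM(gene events)` (IpA events against all IpA +
   3'UTR events; 3'UTR events against 3'UTR events only), and robustness
   filters (3'UTR: ≥3 TPM & usage ≥0.1; IpA: ≥5 TPM & usage ≥0.1 &
   read-start IQR ≥5, co-occurring in one sample).
2. **Five evidence tiers** (`validate_atlas`) — annotated last exons
   (+100 nt), an RNA-seq coverage-drop test at the cleavage site (two
   100-nt windows per side separated by 51 nt; one-sided upstream >
   downstream with a pooled mean–variance trend, BH FDR < 0.1), external
   3'-end peak sets (75-nt resized), untemplated-A reads (terminal A-run
   ≥4 trimmed, >21 nt, uniquely mapped, deduplicated, ≥4 reads + upstream
   PAS), and stringent expression (≥10 TPM, usage ≥0.1, upstream PAS).
   Unvalidated events are dropped.
3. **Differential usage** (`fit_differential_usage`) — per event, a
   negative-binomial GLM of the IpA and pooled full-length counts with an
   isoform × condition interaction (log link, library-size offsets,
   Cox–Reid dispersion, LRT referred to F(1, 2n−4)), BH FDR < 0.05.
4. **Consequences** (`retained_cdr_fraction`, `assign_transcript`,
   `classify_terminal_exon`, `call_noncoding`, `domain_retention`,
   `tmd_analysis`) — retained coding fraction (5'IpA < 25% ≤ 3'IpA),
   composite vs skipped terminal exons, coding-potential calls, and
   protein-domain / transmembrane-domain retention.
5. **Sequence features** (`scan_motifs`, `signal_density`,
   `conservation_profile`, `clip_enrichment`) — PAS and U1-motif
   densities with AT stratification, conservation around cleavage sites
   with a random-intronic-PAS control, and CLIP binding-site enrichment
   in exonized introns via a binomial Z-score.
6. **Intron retention** (`call_retained_introns_sample`,
   `aggregate_retention`, `ipa_ir_overlap`) — junction + coverage
   criteria per sample, 66%/33% aggregation per cell type, and the
   co-occurrence expectation `P(IpA) × P(IR) × N`.
7. **Survival** (`rnaseq_usage_proxy`, `select_signature_events`,
   `cluster_and_filter_patients`, `km_logrank`) — an RNA-seq usage proxy,
   signature selection (FDR < 0.05, |Δusage| > 0.25, r > 0.75), Ward
   clustering with a 5-nearest-neighbour 80%-agreement homogeneity
   filter, and a reimplemented Kaplan–Meier / log-rank comparison.

A seeded synthetic-data generator (`sim_config`, `simulate_annotation`,
`simulate_threeprime`, `simulate_rnaseq`, `simulate_cohort`, plus
assembled-transcript/domain/CLIP/conservation generators and
`write_sim_dataset`) emits every input format — GTF, FASTA, BED,
bedGraph, TSV — with planted ground truth, so the whole pipeline is
testable without downloads.

## Worked example

```r
library(ipaAtlas)

cfg <- sim_config(n_genes = 60, seed = 7, n_artifact_ip = 5,
                  n_artifact_antisense = 3, n_artifact_blacklist = 3,
                  n_subthreshold = 2, n_pcr_dup = 1)
sim <- simulate_rnaseq(simulate_threeprime(simulate_annotation(cfg)))
tp  <- sim$threeprime
pk  <- peak_set(tp$peaks[, c("chrom","start","end","strand","peak_id")],
                tp$counts, tp$starts)
built <- build_atlas(pk, sim$annotation, sim$genome, sim$blacklist, sim$ig)
conf  <- validate_atlas(built, sim$annotation, sim$genome,
                        coverage = sim$rnaseq$coverage,
                        external = simulate_external_3p(sim),
                        polya_reads = sim$rnaseq$polya_reads)
conf$atlas
#> IpaAtlas: 88 events (18 IPA, 70 UTR3) x 6 samples
table(conf$evidence$tier)
#>
#> RNASEQ_GLM
#>         18

res <- differential_usage_atlas(built$atlas, tp$samples, c("A", "B"))
res[res$fdr < 0.05, c("event_id", "delta_usage", "fdr")]
#>    event_id delta_usage          fdr
#>      <char>       <num>        <num>
#> 1:  EV00003  -0.3885820 0.0003975064
#> 2:  EV00014  -0.4183491 0.0001531892
#> 3:  EV00025   0.3649382 0.0011194956
#> 4:  EV00062   0.3954191 0.0001409875
```

All 18 planted IpA events pass the robustness filters and are validated
by the coverage-drop tier (RNASEQ_GLM has precedence over the other
tiers that also support them); none of the 14 planted artifact or
sub-threshold peaks enters the atlas. The four events called
differentially used are exactly the four planted with a usage shift of
0.4 (sign and magnitude recovered in `delta_usage`).

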