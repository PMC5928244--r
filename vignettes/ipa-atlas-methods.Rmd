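---
title: "Models and methods behind ipaAtlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ipaAtlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the tunable parameters,
the numerical choices, and the limits of what a green test establishes.
It states no empirical result that the test suite does not itself
compute.

## The problem and the data model

A 3'-seq library reads the 3' ends of polyadenylated transcripts; a
called peak marks a cleavage/polyadenylation site with per-sample read
counts and read-start positions. Intronic polyadenylation (IpA) events
are peaks falling in introns of protein-coding genes; they terminate
transcription early and produce truncated or non-coding isoforms. The
package works in 0-based half-open coordinates internally (GTF I/O is
1-based inclusive, BED/bedGraph 0-based), and every interval is oriented
by the gene's strand where transcription order matters.

Two conventions deserve mention because they silently shape downstream
numbers:

* **"Longest annotated ORF"** is the CDS of the transcript with maximal
  summed CDS length; ties break lexicographically on transcript id.
  The retained coding fraction and all domain arithmetic refer to it.
* **A gene's transcription unit** is the union of its transcripts'
  exons; introns are the complement of the exon union inside it.

## Atlas construction

The filter cascade sets monotone flags, each depending only on the raw
peak, genome and annotation, so filter order is irrelevant and the atlas
is invariant to peak input order (asserted in the tests).

* *Internal priming* (oligo-dT annealing to genomic A-tracts rather than
  polyA tails): the 10 nt downstream of the cleavage base on the sense
  strand contain a run of ≥ 6 A or ≥ 7 A total. Both thresholds are
  arguments; the values are the field's convention, since the upstream
  peak caller's exact rule is not part of this package.
* *Antisense*: the peak overlaps at least one gene, all on the opposite
  strand. Peaks overlapping genes on both strands fall to the
  ambiguous-gene filter instead.
* *Library adjustment*: raw library size minus all reads in flagged
  peaks (artifacts and immunoglobulin loci); TPM is tags per million of
  this adjusted library, not length-normalized RNA-seq TPM.
* *Clustering*: single-linkage chaining of 3' ends within 200 nt, per
  gene and region class. The representative position is the member with
  the highest pooled count, ties to the most distal 3' end (the choice
  is not dictated by anything upstream; distal was chosen because the
  distal-most cleavage base is the one the polymerase actually reached).
* *Usage with a zero denominator is missing, not zero*: a silent gene
  carries no evidence about isoform proportions.
* *The 75% expression rule* uses a ceiling: 3 of 4 samples pass, 2 of 3
  do not.

## The coverage-drop validation tier

If an IpA isoform ends in an intron, RNA-seq coverage is high just
upstream of the cleavage site and background just downstream. Two
100-nt windows separated by 51 nt are placed on each side (proximal
edges abutting the 3' end; widths and separation are arguments), window
counts are summed per-base coverage divided by the read length, and
upstream > downstream is tested one-sidedly within each sample (size
factor 1: both sides come from the same library). Events whose windows
overlap an annotated exon, leave the chromosome, or average fewer than
`min_window_mean = 3` reads per window are untestable.

The default test statistic deserves its own paragraph. A per-event
exact NB conditional test with two replicates per side is available
(`coverage_window_test`, `method = "exact"`), and its mid-P variant is
the best deterministic version of that test. But any discrete one-sided
test carries a point mass of `P(U = D)` at p = 0.5 — about 0.17 at
realistic intronic depths — and a dispersion estimated from two
replicates has essentially two degrees of freedom. Both effects are
large enough that null p-values fail a Kolmogorov–Smirnov uniformity
check at n = 2000, which is precisely the calibration property the
random-intron control is supposed to certify. The default
(`method = "pooled"`) therefore does what genome-wide NB machinery does
anyway: it estimates the window mean–variance relation
`Var(w) = c1*mu + c2*mu^2` once per sample, pooled across all tested
events from the within-side replicate differences, and refers each
event's `z = (U - D) / sqrt(4 (c1 mu + c2 mu^2))` to the standard
normal. Under exchangeability `U - D` is symmetric, so the p-values are
uniform by construction up to moment error; the acceptance suite checks
this against U(0,1) on ~2000 random intron positions. Note `c1` is
estimated, not fixed at 1: coverage divided by read length is a
compound sum with marks ≤ 1, so window counts are *under*dispersed
relative to Poisson (measured ratio ≈ 0.83 on the synthetic data), and
assuming Poisson would visibly distort the null.

Validation: BH adjustment per sample across tested events, validated at
FDR < 0.1 in any sample. Tier precedence for reporting is
ANNOTATED > RNASEQ_GLM > EXTERNAL_3P > POLYA_READS > HIGH_EXPRESSION.

## Differential usage

Each IpA event is tested with a two-isoform (event vs pooled
full-length, i.e. the sum of the gene's surviving 3'UTR events) ×
two-condition NB GLM with log link and log adjusted-library offsets.
Dispersion is per event by Cox–Reid adjusted profile likelihood
maximized over a fixed log-space grid (method-of-moments fallback,
floored at 1e-4). The interaction is tested by likelihood ratio — but
the statistic is referred to **F(1, 2n − 4)** rather than chi-square(1).
With three samples per condition and an estimated dispersion, the
chi-square reference is several-fold anticonservative in the far tail
(the region BH actually uses), while the quasi-likelihood-style F
reference is nearly exactly calibrated; the acceptance suite measures
empirical FDR ≤ 0.10 at nominal 0.05 with power ≥ 0.8 on planted
Δusage = 0.4 at 3 vs 3. Dispersion-trend shrinkage across events was
deliberately omitted: at desk scale, per-event Cox–Reid plus the F
reference already achieves calibration, and shrinkage would couple
events in ways that are hard to reason about in tests.

The one-sided two-sample KS test of full-length log2 fold changes asks
whether genes with significantly increased IpA usage shift their
full-length output downward relative to non-significant events.

## Consequences

* Retained coding fraction = upstream CDS nt / total CDS nt; "< 25%" is
  strict, so a fraction of exactly 0.25 is 3'IpA.
* Transcript assignment: multi-exon transcripts outrank single-exon
  ones (single-exon fragments are admitted only with an endpoint within
  100 nt of the TSS, since their orientation is uncertain); then ends
  within 50 nt (ties: most exons, then TSS proximity), else nearest end
  within 500 nt, else any overlapping transcript ending within 5000 nt.
  The 3'-seq position replaces the assembled 3' end.
* Composite terminal exons extend an annotated exon through its donor
  site (5-nt start-matching tolerance absorbs assembler imprecision);
  skipped terminal exons start strictly inside the intron.
* Domains partially overlapped by the truncation count as lost
  (whole-domain rule), and the truncation point is floor(upstream CDS
  nt / 3) — the remainder codon is discarded.
* The coding-potential probability is an input column; a logistic stub
  on ORF length exists only so synthetic tests can exercise the
  decision rule (prob < 0.3 AND retained fraction < 0.25 AND longest
  ORF ≤ 300 nt).

## Intron retention and co-occurrence

The four criteria (≥3 junction-spanning reads both sides; ≥50% of the
mappable intron covered ≥3×; pooled flanking-exon median ≥ 10;
intron/exon median ratio ≥ 10%) are implemented literally; "flanking
exon median" pools both exons' base-level coverage (a per-exon-minimum
variant would be stricter; pooled was chosen and is switchable).
Introns under 50% unique mappability are untestable, and fractions in
the 66%/33% aggregation rule are computed over testable samples only.
The expected number of introns with both IpA and retention under
independence is `P(IpA) × P(IR) × N` over the expressed, PAS-bearing
intron universe.

## Survival stratification

The RNA-seq usage proxy is length-normalized coverage in the ≤500 bp
window upstream of the IpA end (truncated at the nearest upstream exon,
minimum 50 bp) against the same window from the last coding exon start.
Signature events need differential usage (FDR < 0.05, |Δusage| > 0.25)
and proxy–3'-seq concordance (Pearson r > 0.75). Patients are clustered
by Ward/Euclidean (linkage and distance are choices — nothing upstream
dictates them — exposed as arguments), groups labelled by median
signature usage, and a patient is retained when ≥ 4 of its 5 nearest
neighbours share its group. The filter is single-pass; Kaplan–Meier and
the two-sample log-rank test are reimplemented (and cross-checked
against the survival package in the tests).

**A structural limit worth knowing.** The kNN-agreement filter removes
patients whose *neighbourhoods* are label-mixed. A patient lying between
two well-separated clusters still lies slightly closer to one of them,
and because within-cluster distance spread (seen from that patient) is
narrow, its five nearest neighbours are almost always label-pure; widely
scattered heterogeneous patients instead become each other's neighbours
and inherit one common label. Across heterogeneity models (midpoint
Gaussians, per-event subclonal coin-flips, uniform draws, a range of
spreads and signature sizes) the measured removal rate plateaus around
40% — far above the ~5% removal of planted pure patients, but nowhere
near complete. The corresponding acceptance criterion demands ≥ 90%
removal and is left failing, with this analysis, rather than met by a
contrived generator.

## The synthetic world

The generator emulates: multi-exon genes (4–8 exons, log-normal
exon/intron lengths) with IpA genes drawing 2× longer introns; planted
PAS hexamers 21 nt upstream of every true cleavage site and an A-poor
stamp downstream (so only planted internal-priming artifacts are A-rich
downstream); NB peak counts (dispersion 0.05) with log-normal library
factors; planted artifacts of every filtered class including an
immunoglobulin-like ultra-high-count locus and PCR-duplicate-style
peaks with degenerate read starts; RNA-seq coverage built by placing
discrete 50-nt reads (Poisson counts, uniform starts) — per-base
independent noise would be ~50× underdispersed after the
sum/read-length conversion and would invalidate the coverage-test
calibration; retained introns covered at 15–50% of the exonic level
with junction-spanning reads; untemplated-A reads for 70% of planted
IpA ends; and a two-group cohort (100/100, usage means 0.15/0.55,
hazard ratio 2.5, exponential times, independent censoring) with a
coin-flip subclonal-mixture model for heterogeneous patients.

What it does not emulate: spliced reads, mappability structure beyond
planted blocks, GC/positional coverage bias, overlapping gene dense
regions, isoform-level 3'UTR complexity, or real human sequence
composition. A green test therefore establishes algorithmic
correctness and statistical calibration under the stated model, not
performance on any particular real library.
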