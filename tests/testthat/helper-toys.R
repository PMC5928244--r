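# Hand-built toy genes and genomes used across test files.

# 3-exon plus-strand gene: exons [0,100) [200,300) [400,520);
# CDS [30,100)+[200,300)+[400,458) = 228 nt -> 3'UTR [458,520).
toy_gene_plus <- function() {
  exons <- cbind(start = c(0L, 200L, 400L), end = c(100L, 300L, 520L))
  cds <- cbind(start = c(30L, 200L, 400L), end = c(100L, 300L, 458L))
  gene_model("TOYP", "chrT", "+", list(t1 = list(exons = exons, cds = cds)))
}

# mirror of toy_gene_plus on the minus strand of a 1000 nt chromosome:
# genomic coordinates are 1000 - plus-strand coordinates, reversed
toy_gene_minus <- function(L = 1000L) {
  exons <- cbind(start = L - c(520L, 300L, 100L), end = L - c(400L, 200L, 0L))
  cds <- cbind(start = L - c(458L, 300L, 100L), end = L - c(400L, 200L, 30L))
  gene_model("TOYM", "chrT", "-", list(t1 = list(exons = exons, cds = cds)))
}

# single-transcript gene from explicit exon/cds matrices
toy_gene <- function(id, strand, exons, cds = NULL, chrom = "chrT") {
  gene_model(id, chrom, strand,
             setNames(list(list(exons = exons, cds = cds)), paste0(id, ".t1")))
}

toy_annotation <- function(genes) {
  ann <- structure(list(genes = setNames(genes,
                                         vapply(genes, `[[`, "", "gene_id")),
                        overlap_flags = character(0), smallrna = NULL),
                   class = "GenomeAnnotation")
  ann$overlap_flags <- ipaAtlas:::.flag_overlapping_genes(ann)
  ann
}

# random toy genome with a given sequence planted at 0-based position
toy_genome <- function(len = 2000L, plant = NULL, at = 0.5, seed = 99L,
                       chrom = "chrT") {
  set.seed(seed)
  ch <- sample(c("A", "T", "G", "C"), len, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2))
  if (!is.null(plant)) {
    for (nm in names(plant)) {
      p <- plant[[nm]]
      ch[(p + 1L):(p + nchar(nm))] <- strsplit(nm, "")[[1L]]
    }
  }
  Biostrings::DNAStringSet(setNames(paste(ch, collapse = ""), chrom))
}

# PeakSet with one peak per row of `ends` on a toy gene layout
toy_peakset <- function(chrom, starts, ends, strands, counts,
                        samples = paste0("S", seq_len(ncol(counts))),
                        starts_tab = NULL) {
  info <- data.table::data.table(chrom = chrom, start = starts, end = ends,
                                 strand = strands)
  colnames(counts) <- samples
  peak_set(info, counts, starts_tab)
}

# per-chromosome constant Rle coverage
flat_track <- function(value, len, chrom = "chrT") {
  setNames(list(S4Vectors::Rle(value, len)), chrom)
}
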