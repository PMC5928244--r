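#' @import data.table
#' @importFrom stats quantile median rnbinom rpois rbinom runif rnorm rexp
#'   rlnorm rbeta pchisq pnbinom dnbinom ks.test wilcox.test fisher.test
#'   binom.test ecdf optimize setNames aggregate cutree hclust dist sd var
#'   p.adjust cor
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Interval complement within [lo, hi)
#'
#' Given disjoint sorted half-open intervals, return the gaps inside
#' \code{[lo, hi)}.  Used to derive introns from exon unions.
#'
#' @param ivs two-column matrix (start, end), 0-based half-open.
#' @param lo,hi bounds of the enclosing interval.
#' @return two-column matrix of gap intervals.
#' @keywords internal
iv_complement <- function(ivs, lo, hi) {
  if (is.null(ivs) || nrow(ivs) == 0L) {
    return(matrix(c(lo, hi), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  ivs <- ivs[order(ivs[, 1L]), , drop = FALSE]
  starts <- c(lo, ivs[, 2L])
  ends <- c(ivs[, 1L], hi)
  keep <- ends > starts
  matrix(c(starts[keep], ends[keep]), ncol = 2L,
         dimnames = list(NULL, c("start", "end")))
}

#' Union of possibly-overlapping intervals
#' @keywords internal
iv_union <- function(ivs) {
  if (nrow(ivs) == 0L) return(ivs)
  ir <- IRanges::reduce(IRanges::IRanges(start = ivs[, 1L] + 1L, end = ivs[, 2L]))
  matrix(c(IRanges::start(ir) - 1L, IRanges::end(ir)), ncol = 2L,
         dimnames = list(NULL, c("start", "end")))
}

#' Quartile spread of a weighted position multiset
#'
#' IQR of read-start positions where each distinct position carries a
#' multiplicity.  Expands when the multiset is small, falls back to a
#' weighted type-7 quantile otherwise.
#' @keywords internal
weighted_iqr <- function(pos, n) {
  stopifnot(length(pos) == length(n))
  if (length(pos) == 0L || sum(n) == 0L) return(NA_real_)
  total <- sum(n)
  if (total <= 1e5) {
    q <- quantile(rep(pos, n), c(0.25, 0.75), names = FALSE, type = 7)
  } else {
    o <- order(pos)
    pos <- pos[o]; n <- n[o]
    cum <- cumsum(n)
    qf <- function(p) {
      h <- (total - 1) * p + 1
      lo <- pos[which(cum >= floor(h))[1L]]
      hi <- pos[which(cum >= ceiling(h))[1L]]
      lo + (h - floor(h)) * (hi - lo)
    }
    q <- c(qf(0.25), qf(0.75))
  }
  q[2L] - q[1L]
}

#' Reverse complement of a DNA string
#' @keywords internal
rev_comp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract a genome subsequence
#'
#' Returns the sequence of \code{[start, end)} (0-based half-open) on
#' chromosome \code{chrom}; strand "-" returns the reverse complement
#' (i.e. the sense-strand sequence of a minus-strand feature).
#' @param genome a \code{DNAStringSet}.
#' @param chrom,start,end,strand coordinates.
#' @export
genome_seq <- function(genome, chrom, start, end, strand = "+") {
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (is.na(len)) stop("unknown chromosome: ", chrom)
  if (start < 0 || end > len) stop("interval beyond chromosome end: ",
                                   chrom, ":", start, "-", end)
  if (end <= start) return("")
  s <- as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
  if (strand == "-") rev_comp(s) else s
}

#' Benjamini-Hochberg adjustment that tolerates NAs
#' @keywords internal
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}
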