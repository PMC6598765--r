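# Interval algebra. Intervals live in GRanges (1-based closed); all text IO
# converts to/from BED convention (0-based half-open). Strand is ignored
# throughout: fragment processing is strand-agnostic.

# BED (0-based half-open) columns -> GRanges (1-based closed)
granges_from_bed <- function(chrom, start0, end0, ...) {
  chrom <- unname(chrom); start0 <- unname(start0); end0 <- unname(end0)
  if (any(start0 >= end0)) {
    i <- which(start0 >= end0)[1L]
    stop(sprintf("empty or inverted interval: %s:%d-%d",
                 chrom[i], start0[i], end0[i]), call. = FALSE)
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1, end = end0), ...)
}

granges_to_bed <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Merge genomic intervals
#'
#' Collapses a set of intervals into the minimal sorted, disjoint set covering
#' the same bases. Overlapping and book-ended (abutting) intervals are merged,
#' matching `bedtools merge` defaults.
#'
#' @param intervals a `GRanges`.
#' @return A sorted, disjoint, non-adjacent `GRanges` with the same union.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 6), c(10, 15)))
#' merge_intervals(gr)
#' @export
merge_intervals <- function(intervals) {
  stopifnot(is(intervals, "GRanges"))
  GenomicRanges::reduce(GenomicRanges::sort(intervals), ignore.strand = TRUE)
}

# put two GRanges on the union of their seqlevels so overlap queries do not
# warn about disjoint seqinfo
harmonize_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a = a, b = b)
}

#' Pairwise interval overlap test
#'
#' True where intervals share at least one base pair on the same chromosome
#' (half-open BED semantics: adjacency is not overlap). `a` and `b` are
#' compared element-wise and must have equal length or length one.
#'
#' @param a,b `GRanges` objects.
#' @return Logical vector.
#' @export
overlaps <- function(a, b) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"))
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  as.character(GenomicRanges::seqnames(a)) == as.character(GenomicRanges::seqnames(b)) &
    GenomicRanges::start(a) <= GenomicRanges::end(b) &
    GenomicRanges::start(b) <= GenomicRanges::end(a)
}
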