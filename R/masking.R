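#' Mask regions
#'
#' Container for low-complexity mask intervals (sorted, disjoint,
#' non-adjacent) on one genome.
#'
#' @param regions a `GRanges`; merged with [merge_intervals()].
#' @param genome genome name the regions belong to (or `NA`).
#' @param min_run_length minimal alternating-run length the scan used, bp.
#' @return An object of class `MaskRegions`.
#' @export
mask_regions <- function(regions, genome = NA_character_,
                         min_run_length = NA_real_) {
  stopifnot(is(regions, "GRanges"))
  structure(list(genome = genome, regions = merge_intervals(regions),
                 min_run_length = min_run_length),
            class = "MaskRegions")
}

#' @export
print.MaskRegions <- function(x, ...) {
  cat(sprintf("MaskRegions: %d region(s) on genome '%s' (min run %s bp)\n",
              length(x$regions), x$genome, format(x$min_run_length)))
  invisible(x)
}

#' Scan a genome for (TA)n low-complexity runs
#'
#' Finds all maximal runs of strictly alternating T/A (either phase, starting
#' with either base, case-insensitive) of at least `min_run_length` bp.
#' Sequencing libraries can carry (TA)n contamination of undetermined origin
#' that cross-maps into these regions, so fragments overlapping them are
#' excluded before downstream scoring. `N` and any base other than T/A
#' terminate a run. The default threshold of 25 bp corresponds to a
#' TATATATATATATATATATATATAT 25-mer query.
#'
#' @param sequences a `DNAStringSet` or named character vector of chromosome
#'   sequences.
#' @param min_run_length minimal run length in bp (>= 2).
#' @param genome genome name to record on the result.
#' @return A [mask_regions()] object; region coordinates follow the input
#'   sequence names.
#' @examples
#' scan_ta_repeats(c(chr1 = "GGTATATATATATATATATATATATATCC"), min_run_length = 25)
#' @export
scan_ta_repeats <- function(sequences, min_run_length = 25, genome = NA_character_) {
  if (is(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  stopifnot(is.character(sequences))
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be named by chromosome", call. = FALSE)
  if (!is.numeric(min_run_length) || length(min_run_length) != 1L ||
      min_run_length < 2)
    stop("min_run_length must be >= 2", call. = FALSE)

  per_chrom <- lapply(sequences, function(s) {
    b <- charToRaw(toupper(s))
    n <- length(b)
    if (n < 2L) return(NULL)
    ta <- b == as.raw(84L) | b == as.raw(65L)  # T or A
    # link[i]: positions i and i+1 are both T/A and differ (strict alternation)
    link <- ta[-n] & ta[-1L] & (b[-n] != b[-1L])
    r <- rle(link)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & (r$lengths + 1L >= min_run_length)
    if (!any(keep)) return(NULL)
    # a block of k consecutive links spans positions [start, start + k], 1-based
    data.frame(start = starts[keep], end = ends[keep] + 1L)
  })
  hits <- Filter(Negate(is.null), per_chrom)
  if (length(hits) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    df <- do.call(rbind, Map(cbind, chrom = names(hits), hits))
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  }
  mask_regions(gr, genome = genome, min_run_length = min_run_length)
}

#' Exclude fragments overlapping mask regions
#'
#' Keeps exactly the fragments with zero base-pair overlap with every mask
#' region (the `bedtools intersect -v` operation); order is preserved.
#'
#' @param fs a [fragment_set()].
#' @param mask a [mask_regions()] object on the same genome.
#' @return A [fragment_set()] containing the retained fragments.
#' @export
exclude_fragments <- function(fs, mask) {
  stopifnot(inherits(fs, "FragmentSet"), inherits(mask, "MaskRegions"))
  gf <- genome_name(fs)
  if (!is.na(gf) && !is.na(mask$genome) && gf != mask$genome)
    stop(sprintf("genome mismatch in exclude_fragments: '%s' vs '%s'",
                 gf, mask$genome), call. = FALSE)
  if (length(mask$regions) == 0L || length(fs) == 0L) return(fs)
  h <- harmonize_seqlevels(fs$fragments, mask$regions)
  hits <- GenomicRanges::countOverlaps(h$a, h$b, ignore.strand = TRUE)
  fragment_set(fs$fragments[hits == 0L], sample_id = fs$sample_id,
               genome = fs$genome)
}

#' Read mask regions from a BED3 file
#' @param path BED file path.
#' @param genome genome name to record.
#' @return A [mask_regions()] object.
#' @export
read_mask_bed <- function(path, genome = NA_character_) {
  fs <- read_fragments_bed(path)
  mask_regions(fs$fragments, genome = genome)
}

#' Write mask regions to a BED3 file
#' @param mask a [mask_regions()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_bed <- function(mask, path) {
  stopifnot(inherits(mask, "MaskRegions"))
  bed <- granges_to_bed(mask$regions)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
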