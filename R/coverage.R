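#' Coverage tracks
#'
#' A `CoverageTrack` stores a per-base-pair value over a whole genome as one
#' run-length-encoded vector per chromosome (bedGraph semantics: bases not
#' covered by an explicit interval are zero).
#'
#' @param cov an `RleList` with one numeric `Rle` per chromosome, each of
#'   length equal to the chromosome size.
#' @param genome the [genome_spec()] the track lives on.
#' @return An object of class `CoverageTrack` with fields `genome` and `cov`.
#' @export
coverage_track <- function(cov, genome) {
  stopifnot(inherits(genome, "GenomeSpec"), is(cov, "RleList"))
  if (!setequal(names(cov), names(genome$chrom_sizes)))
    stop("coverage chromosomes do not match the genome", call. = FALSE)
  cov <- cov[names(genome$chrom_sizes)]
  lens <- lengths(cov)
  if (any(lens != genome$chrom_sizes))
    stop("coverage vector lengths do not match chromosome sizes", call. = FALSE)
  structure(list(genome = genome, cov = cov), class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack on '%s': total %s, bp-weighted mean %.6g\n",
              x$genome$name, format(track_total(x), scientific = FALSE),
              track_total(x) / x$genome$total_size))
  invisible(x)
}

#' Sum of track values over all base pairs
#' @param track a [coverage_track()].
#' @return A single number.
#' @export
track_total <- function(track) {
  stopifnot(inherits(track, "CoverageTrack"))
  sum(vapply(track$cov, function(r) sum(as.numeric(runValue(r)) *
                                          as.numeric(runLength(r))), numeric(1L)))
}

#' Fragment depth coverage
#'
#' Value at each base pair x is the number of fragments whose interval
#' contains x.
#'
#' @param fs a [fragment_set()].
#' @param genome a [genome_spec()]; defaults to the set's own genome.
#' @return A [coverage_track()].
#' @export
fragment_depth <- function(fs, genome = NULL) {
  stopifnot(inherits(fs, "FragmentSet"))
  genome <- genome %||% fs$genome
  if (is.null(genome))
    stop("fragment_depth requires a genome (chrom sizes)", call. = FALSE)
  gr <- fs$fragments
  check_in_bounds(gr, genome, what = "fragment")
  GenomeInfoDb::seqlevels(gr) <- names(genome$chrom_sizes)
  cov <- GenomicRanges::coverage(gr,
                                 width = stats::setNames(as.integer(genome$chrom_sizes),
                                                         names(genome$chrom_sizes)))
  coverage_track(cov, genome)
}

#' Scaled fractional-count normalization
#'
#' Rescales a depth track so that the value at each base pair is the fraction
#' of total counts at that base times the genome size: if counts were
#' uniformly distributed the value would be one at every bp. Equivalently,
#' `value(x) = depth(x) * total_size / sum(depth)`, so the base-pair-weighted
#' mean of the output is exactly 1. This puts samples of different depths on a
#' common per-genome scale before calibration factors are applied.
#'
#' @param depth a [coverage_track()] of fragment depth with at least one
#'   nonzero base.
#' @return A [coverage_track()].
#' @export
fractional_count_track <- function(depth) {
  stopifnot(inherits(depth, "CoverageTrack"))
  total <- track_total(depth)
  if (total <= 0) stop("all-zero depth track cannot be normalized", call. = FALSE)
  scale_track(depth, depth$genome$total_size / total)
}

#' Multiply a track by a scalar
#' @param track a [coverage_track()].
#' @param factor positive finite scale factor (e.g. a calibration factor).
#' @return A [coverage_track()] with every value multiplied by `factor`.
#' @export
scale_track <- function(track, factor) {
  stopifnot(inherits(track, "CoverageTrack"), is.numeric(factor),
            length(factor) == 1L, is.finite(factor), factor > 0)
  cov <- methods::as(lapply(track$cov, function(r) r * factor), "RleList")
  coverage_track(cov, track$genome)
}

#' Write a track as bedGraph
#'
#' Four-column bedGraph (chrom, start, end, value), 0-based half-open,
#' zero-valued runs omitted, values formatted to 5 significant digits with
#' trailing ".0" dropped for integers.
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "CoverageTrack"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(track$cov)) {
    r <- track$cov[[chrom]]
    ends <- cumsum(as.numeric(runLength(r)))
    starts <- ends - as.numeric(runLength(r))  # 0-based starts
    vals <- as.numeric(runValue(r))
    keep <- vals != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom,
                       as.integer(starts[keep]), as.integer(ends[keep]),
                       format_track_value(vals[keep])), con)
  }
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' @param path bedGraph path (4 columns, 0-based half-open). Intervals must
#'   not overlap; unspecified bases are zero.
#' @param genome the [genome_spec()] the track lives on.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, genome) {
  stopifnot(inherits(genome, "GenomeSpec"))
  fields <- read_tsv_lines(path, 4L, "bedGraph")
  cov <- methods::as(lapply(genome$chrom_sizes, function(len)
    S4Vectors::Rle(0, len)), "RleList")
  if (!is.null(fields)) {
    lines <- seq_along(fields)
    chrom <- vapply(fields, `[[`, character(1L), 1L)
    start0 <- parse_coord(vapply(fields, `[[`, character(1L), 2L), "start", lines)
    end0 <- parse_coord(vapply(fields, `[[`, character(1L), 3L), "end", lines)
    val <- as.numeric(vapply(fields, `[[`, character(1L), 4L))
    if (any(is.na(val)))
      stop(sprintf("non-numeric value at line %d", which(is.na(val))[1L]),
           call. = FALSE)
    gr <- granges_from_bed(chrom, start0, end0)
    check_in_bounds(gr, genome, lines, "bedGraph interval")
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      o <- order(start0[sel])
      s <- start0[sel][o]; e <- end0[sel][o]; v <- val[sel][o]
      if (any(s[-1L] < e[-length(e)]))
        stop(sprintf("overlapping bedGraph intervals on %s", ch), call. = FALSE)
      r <- cov[[ch]]
      r[unlist(Map(seq.int, s + 1, e))] <- rep.int(v, e - s)
      cov[[ch]] <- r
    }
  }
  coverage_track(cov, genome)
}
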