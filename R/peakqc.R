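#' Peak records
#'
#' Peaks are a `GRanges` with a `summit` metadata column holding the 0-based
#' absolute position of maximal signal within each peak, and an optional
#' `score` column. The summit must lie within the peak interval.
#'
#' @param gr a `GRanges` of peak intervals.
#' @param summit 0-based absolute summit positions; defaults to the peak
#'   midpoints.
#' @param score optional numeric scores.
#' @param name optional peak names; defaults to `peak_<i>`.
#' @return A `GRanges` with `name`, `summit` and `score` metadata columns.
#' @export
peak_records <- function(gr, summit = NULL, score = NULL, name = NULL) {
  stopifnot(is(gr, "GRanges"))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  summit <- summit %||% (start0 + (end0 - start0 - 1L) %/% 2L)
  if (any(summit < start0 | summit >= end0)) {
    i <- which(summit < start0 | summit >= end0)[1L]
    stop(sprintf("summit %d outside peak %s:%d-%d", summit[i],
                 as.character(GenomicRanges::seqnames(gr))[i], start0[i], end0[i]),
         call. = FALSE)
  }
  S4Vectors::mcols(gr)$name <- name %||% sprintf("peak_%d", seq_along(gr))
  S4Vectors::mcols(gr)$summit <- as.numeric(summit)
  S4Vectors::mcols(gr)$score <- if (is.null(score)) NA_real_ else as.numeric(score)
  gr
}

#' Read peaks with summits
#'
#' Reads either ENCODE narrowPeak (10 columns; the summit is `start` plus the
#' column-10 offset, falling back to the midpoint when the offset is -1) or
#' BED3+ (summit taken as the peak midpoint; 1-bp records are summit records).
#'
#' @param path peak file path.
#' @return Peaks as returned by [peak_records()].
#' @export
read_peaks <- function(path) {
  fields <- read_tsv_lines(path, 3L, "peak file")
  if (is.null(fields)) return(peak_records(GenomicRanges::GRanges()))
  lines <- seq_along(fields)
  chrom <- vapply(fields, `[[`, character(1L), 1L)
  start0 <- parse_coord(vapply(fields, `[[`, character(1L), 2L), "start", lines)
  end0 <- parse_coord(vapply(fields, `[[`, character(1L), 3L), "end", lines)
  gr <- granges_from_bed(chrom, start0, end0)
  nc <- lengths(fields)
  name <- if (all(nc >= 4L)) vapply(fields, `[[`, character(1L), 4L) else NULL
  score <- if (all(nc >= 5L))
    suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 5L))) else NULL
  summit <- NULL
  if (all(nc >= 10L)) {
    off <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 10L)))
    if (any(is.na(off)))
      stop(sprintf("non-numeric summit offset at line %d", which(is.na(off))[1L]),
           call. = FALSE)
    mid <- start0 + (end0 - start0 - 1) %/% 2
    summit <- ifelse(off >= 0, start0 + off, mid)
  }
  peak_records(gr, summit = summit, score = score, name = name)
}

#' Mean track signal around peak summits
#'
#' For each peak, the arithmetic mean of the track over the window
#' `[summit - flank, summit + flank]` inclusive (2*flank + 1 bp, truncated at
#' chromosome ends). Bases without explicit coverage count as zero.
#'
#' @param track a [coverage_track()].
#' @param peaks peaks from [peak_records()] / [read_peaks()].
#' @param flank window half-width in bp (default 150).
#' @return Numeric vector of per-peak means, named by peak name.
#' @export
peak_summit_scores <- function(track, peaks, flank = 150) {
  stopifnot(inherits(track, "CoverageTrack"), is(peaks, "GRanges"),
            is.numeric(flank), length(flank) == 1L, flank > 0)
  if (length(peaks) == 0L) return(stats::setNames(numeric(0L), character(0L)))
  summit <- S4Vectors::mcols(peaks)$summit
  if (is.null(summit)) stop("peaks lack a summit column", call. = FALSE)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  nm <- S4Vectors::mcols(peaks)$name %||% sprintf("peak_%d", seq_along(peaks))
  sizes <- track$genome$chrom_sizes
  bad <- !(chrom %in% names(sizes)) | summit < 0 | summit >= sizes[chrom]
  if (any(bad, na.rm = TRUE) || anyNA(bad)) {
    i <- which(bad | is.na(bad))[1L]
    stop(sprintf("summit of peak '%s' (%s:%s) is off the genome",
                 nm[i], chrom[i], format(summit[i])), call. = FALSE)
  }
  pos1 <- summit + 1  # 1-based summit position
  out <- numeric(length(peaks))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    s <- pmax(1, pos1[sel] - flank)
    e <- pmin(as.numeric(sizes[ch]), pos1[sel] + flank)
    v <- IRanges::Views(track$cov[[ch]], start = as.integer(s), end = as.integer(e))
    out[sel] <- IRanges::viewMeans(v)
  }
  stats::setNames(out, nm)
}

#' IgG percentile peak filter
#'
#' Retains the peaks whose IgG-control summit score is less than or equal to
#' the given percentile of all IgG scores (peaks strictly greater are removed
#' as artifactual outliers). The percentile is computed by linear
#' interpolation between order statistics.
#'
#' @param scores_igg per-peak IgG mean scores.
#' @param percentile percentile in (0, 100), default 99.
#' @return Integer indices of retained peaks.
#' @export
igg_peak_filter <- function(scores_igg, percentile = 99) {
  if (length(scores_igg) == 0L) stop("empty score list", call. = FALSE)
  stopifnot(is.numeric(scores_igg), !anyNA(scores_igg),
            is.numeric(percentile), length(percentile) == 1L,
            percentile > 0, percentile < 100)
  thr <- stats::quantile(scores_igg, percentile / 100, names = FALSE, type = 7L)
  which(scores_igg <= thr)
}

#' Peak-by-sample score matrix
#'
#' Summit-window mean scores for every peak in every sample's coverage track.
#'
#' @param tracks named list of [coverage_track()] objects (one per sample),
#'   all on the same genome.
#' @param peaks peaks from [peak_records()] (after any IgG filtering).
#' @param flank window half-width in bp.
#' @return Numeric matrix, one row per peak (named), one column per sample.
#' @export
build_score_matrix <- function(tracks, peaks, flank = 150) {
  stopifnot(is.list(tracks), length(tracks) >= 1L, !is.null(names(tracks)),
            all(vapply(tracks, inherits, logical(1L), "CoverageTrack")))
  gname <- unique(vapply(tracks, function(t) t$genome$name, character(1L)))
  if (length(gname) != 1L)
    stop(sprintf("tracks on different genomes: %s",
                 paste(gname, collapse = ", ")), call. = FALSE)
  cols <- lapply(tracks, peak_summit_scores, peaks = peaks, flank = flank)
  m <- do.call(cbind, cols)
  colnames(m) <- names(tracks)
  m
}

#' Sample-by-sample peak-vector correlation matrix
#'
#' Pearson correlations between the columns of a peak score matrix, reported
#' as R squared by default. Rows containing any missing entry are dropped
#' first (complete-observation policy), so every pairwise correlation uses the
#' same peak set.
#'
#' @param m peak-by-sample score matrix from [build_score_matrix()].
#' @param use_complete_rows drop rows with any `NA` before correlating.
#' @param squared return R squared rather than r.
#' @return Symmetric samples-by-samples matrix; columns with zero variance
#'   yield `NA` entries with a warning.
#' @export
correlation_matrix <- function(m, use_complete_rows = TRUE, squared = TRUE) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (use_complete_rows) m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2L)
    stop("need at least 2 complete peak rows to correlate", call. = FALSE)
  r <- suppressWarnings(stats::cor(m))
  if (anyNA(r)) warning("zero-variance column(s): correlation undefined",
                        call. = FALSE)
  if (squared) r <- r^2
  r
}

#' Fraction of fragments in peaks (FRiP)
#'
#' Fraction of fragments overlapping at least one peak by at least one base
#' pair; the counting unit is the fragment (read pair), not the read.
#'
#' @param fs a non-empty [fragment_set()].
#' @param peaks peak `GRanges`.
#' @return A fraction in \[0, 1\].
#' @export
frip <- function(fs, peaks) {
  stopifnot(inherits(fs, "FragmentSet"), is(peaks, "GRanges"))
  if (length(fs) == 0L) stop("empty fragment set", call. = FALSE)
  if (length(peaks) == 0L) return(0)
  h <- harmonize_seqlevels(fs$fragments, peaks)
  mean(GenomicRanges::countOverlaps(h$a, h$b, ignore.strand = TRUE) > 0L)
}

#' FRiP down-sampling series
#'
#' FRiP recomputed on independent seeded subsamples at a series of depths
#' (halving by default, mirroring sequencing-depth titration). Depths
#' exceeding the available fragment count are skipped with a warning. Each
#' depth draws independently from the full set; set `nested = TRUE` to make
#' each depth a subset of the previous one.
#'
#' @param fs a [fragment_set()].
#' @param peaks peak `GRanges`.
#' @param depths strictly decreasing fragment counts, default
#'   `c(5e6, 2.5e6, 1.25e6, 625e3, 312500)`.
#' @param seed integer seed.
#' @param nested draw each depth from the previous subsample instead of the
#'   full set.
#' @return Named numeric vector of FRiP values (`NA` for skipped depths),
#'   names are the depths.
#' @export
frip_series <- function(fs, peaks, depths = c(5e6, 2.5e6, 1.25e6, 625e3, 312500),
                        seed, nested = FALSE) {
  stopifnot(inherits(fs, "FragmentSet"), length(depths) >= 1L,
            all(diff(depths) < 0) || length(depths) == 1L)
  out <- stats::setNames(rep(NA_real_, length(depths)),
                         format(depths, scientific = FALSE, trim = TRUE))
  current <- fs
  for (i in seq_along(depths)) {
    d <- depths[i]
    pool_i <- if (nested) current else fs
    if (d > length(pool_i)) {
      warning(sprintf("depth %s exceeds available %d fragments; skipped",
                      format(d, scientific = FALSE), length(pool_i)),
              call. = FALSE)
      next
    }
    sub <- sample_fragments(pool_i, d, seed = seed + i)
    if (nested) current <- sub
    out[i] <- frip(sub, peaks)
  }
  out
}
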