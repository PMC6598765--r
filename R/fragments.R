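#' Fragment sets
#'
#' A `FragmentSet` holds the sequenced fragments of one sample mapped to one
#' genome, as coordinate-sorted intervals. Each properly paired read pair
#' contributes one fragment; duplicates are kept (no deduplication step is
#' exposed).
#'
#' @param fragments a `GRanges` of fragment intervals.
#' @param sample_id sample label.
#' @param genome optional [genome_spec()]; when given, fragments outside its
#'   bounds are an error.
#' @return An object of class `FragmentSet` with fields `sample_id`, `genome`
#'   and `fragments` (sorted `GRanges`).
#' @export
fragment_set <- function(fragments, sample_id = "sample", genome = NULL) {
  stopifnot(is(fragments, "GRanges"),
            is.character(sample_id), length(sample_id) == 1L)
  GenomicRanges::strand(fragments) <- "*"
  if (!is.null(genome)) {
    stopifnot(inherits(genome, "GenomeSpec"))
    check_in_bounds(fragments, genome, what = "fragment")
    GenomeInfoDb::seqlevels(fragments) <- names(genome$chrom_sizes)
    GenomeInfoDb::seqinfo(fragments) <- as_seqinfo(genome)
  }
  structure(list(sample_id = sample_id, genome = genome,
                 fragments = GenomicRanges::sort(fragments)),
            class = "FragmentSet")
}

#' @export
length.FragmentSet <- function(x) length(x$fragments)

#' @export
print.FragmentSet <- function(x, ...) {
  cat(sprintf("FragmentSet '%s': %d fragment(s) on genome '%s'\n",
              x$sample_id, length(x),
              if (is.null(x$genome)) "<unspecified>" else x$genome$name))
  invisible(x)
}

genome_name <- function(fs) if (is.null(fs$genome)) NA_character_ else fs$genome$name

check_same_genome <- function(a, b, what) {
  ga <- genome_name(a); gb <- genome_name(b)
  if (!is.na(ga) && !is.na(gb) && ga != gb)
    stop(sprintf("genome mismatch in %s: '%s' vs '%s'", what, ga, gb),
         call. = FALSE)
  invisible(TRUE)
}

#' Read fragments from a BED file
#'
#' Reads BED3+ (0-based half-open) fragment intervals. Column 4, when present,
#' is kept as the fragment name. Records with `start >= end`, non-integer
#' coordinates, or (when `genome` is given) coordinates outside the genome are
#' errors naming the offending line.
#'
#' @param path BED file path.
#' @param genome optional [genome_spec()] used for bounds checking.
#' @param sample_id sample label; defaults to the file name without extension.
#' @return A [fragment_set()].
#' @export
read_fragments_bed <- function(path, genome = NULL, sample_id = NULL) {
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  fields <- read_tsv_lines(path, 3L, "BED")
  if (is.null(fields)) {
    gr <- GenomicRanges::GRanges()
    return(fragment_set(gr, sample_id = sample_id, genome = genome))
  }
  lines <- seq_along(fields)
  chrom <- vapply(fields, `[[`, character(1L), 1L)
  start0 <- parse_coord(vapply(fields, `[[`, character(1L), 2L), "start", lines)
  end0 <- parse_coord(vapply(fields, `[[`, character(1L), 3L), "end", lines)
  bad <- start0 >= end0
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("empty or inverted interval at line %d: %s:%d-%d",
                 i, chrom[i], start0[i], end0[i]), call. = FALSE)
  }
  gr <- granges_from_bed(chrom, start0, end0)
  if (any(lengths(fields) >= 4L))
    S4Vectors::mcols(gr)$name <- vapply(fields, function(f)
      if (length(f) >= 4L) f[[4L]] else NA_character_, character(1L))
  if (!is.null(genome)) check_in_bounds(gr, genome, lines, "fragment")
  fragment_set(gr, sample_id = sample_id, genome = genome)
}

#' Write fragments to a BED file
#' @param fs a [fragment_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fs, path) {
  stopifnot(inherits(fs, "FragmentSet"))
  bed <- granges_to_bed(fs$fragments)
  nm <- S4Vectors::mcols(fs$fragments)$name
  if (!is.null(nm) && !all(is.na(nm))) bed$name <- ifelse(is.na(nm), ".", nm)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Down-sample a fragment set
#'
#' Draws a uniform sample of `n` fragments without replacement, deterministic
#' for a given `seed`. The sample is drawn by seeded index sampling over the
#' sorted fragment list and returned coordinate-sorted. The caller's RNG state
#' is left untouched.
#'
#' @param fs a [fragment_set()].
#' @param n number of fragments to keep; must not exceed `length(fs)`.
#' @param seed integer seed (required; no hidden global state).
#' @return A [fragment_set()] with `n` fragments.
#' @export
sample_fragments <- function(fs, n, seed) {
  stopifnot(inherits(fs, "FragmentSet"), is.numeric(n), length(n) == 1L,
            n == round(n), n >= 0)
  total <- length(fs)
  if (n > total)
    stop(sprintf("cannot sample %d fragments from a set of %d", n, total),
         call. = FALSE)
  idx <- sort(with_seed(seed, sample.int(total, size = n)))
  fragment_set(fs$fragments[idx], sample_id = fs$sample_id, genome = fs$genome)
}

#' Pool fragment sets
#'
#' Multiset union of fragment sets on the same genome: duplicates are kept and
#' the pooled set is re-sorted. Used to pool samples before peak calling.
#'
#' @param sets list of [fragment_set()] objects on the same genome.
#' @param sample_id label for the pooled set.
#' @return A [fragment_set()] whose size is the sum of the input sizes.
#' @export
pool_fragments <- function(sets, sample_id = "pooled") {
  stopifnot(is.list(sets), length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1L), "FragmentSet")))
  for (s in sets[-1L]) check_same_genome(sets[[1L]], s, "pool_fragments")
  genome <- Filter(Negate(is.null), lapply(sets, `[[`, "genome"))
  genome <- if (length(genome)) genome[[1L]] else NULL
  grl <- lapply(sets, function(s) {
    gr <- s$fragments
    S4Vectors::mcols(gr) <- NULL
    if (!is.null(genome)) GenomeInfoDb::seqlevels(gr) <- names(genome$chrom_sizes)
    gr
  })
  fragment_set(do.call(c, grl), sample_id = sample_id, genome = genome)
}
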