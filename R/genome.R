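#' Genome specification
#'
#' A `GenomeSpec` names a genome and records its chromosome sizes; its
#' `total_size` is the denominator of the fractional-count coverage
#' normalization (the "size of the genome" in bp).
#'
#' @param name single character label (e.g. `"hg19"`, `"ecoli"`).
#' @param chrom_sizes named numeric vector of chromosome lengths in bp;
#'   names are chromosome names, all lengths must be positive integers.
#' @return An object of class `GenomeSpec` with fields `name`, `chrom_sizes`
#'   and `total_size`.
#' @examples
#' genome_spec("toy", c(chr1 = 100, chr2 = 50))
#' @export
genome_spec <- function(name, chrom_sizes) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(chrom_sizes) == 0L) stop("no chromosomes", call. = FALSE)
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be named", call. = FALSE)
  if (anyDuplicated(names(chrom_sizes)))
    stop(sprintf("duplicate chromosome name: '%s'",
                 names(chrom_sizes)[duplicated(names(chrom_sizes))][1L]),
         call. = FALSE)
  chrom_sizes <- stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0) ||
      any(chrom_sizes != round(chrom_sizes)))
    stop("all chromosome lengths must be positive integers", call. = FALSE)
  structure(list(name = name, chrom_sizes = chrom_sizes,
                 total_size = sum(chrom_sizes)),
            class = "GenomeSpec")
}

#' @export
print.GenomeSpec <- function(x, ...) {
  cat(sprintf("GenomeSpec '%s': %d chromosome(s), %s bp total\n",
              x$name, length(x$chrom_sizes),
              format(x$total_size, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Read a chrom.sizes file
#'
#' Parses the standard two-column (chromosome name, length) whitespace-
#' delimited format into a [genome_spec()].
#'
#' @param path path to a chrom.sizes file.
#' @param name genome label; defaults to the file name without extension.
#' @return A `GenomeSpec`.
#' @export
read_chrom_sizes <- function(path, name = NULL) {
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  fields <- read_tsv_lines(path, 2L, "chrom.sizes")
  if (is.null(fields)) stop("no chromosomes", call. = FALSE)
  chroms <- vapply(fields, `[[`, character(1L), 1L)
  lens <- parse_coord(vapply(fields, `[[`, character(1L), 2L),
                      "chromosome length", seq_along(fields))
  if (any(lens <= 0)) {
    i <- which(lens <= 0)[1L]
    stop(sprintf("non-positive length for chromosome '%s' at line %d",
                 chroms[i], i), call. = FALSE)
  }
  genome_spec(name, stats::setNames(lens, chroms))
}

#' Write a chrom.sizes file
#' @param genome a `GenomeSpec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  stopifnot(inherits(genome, "GenomeSpec"))
  writeLines(sprintf("%s\t%d", names(genome$chrom_sizes),
                     as.integer(genome$chrom_sizes)), path)
  invisible(path)
}

# Seqinfo for attaching bounds to GRanges
as_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = names(genome$chrom_sizes),
                        seqlengths = as.integer(genome$chrom_sizes),
                        genome = genome$name)
}

# validate that a GRanges lies within genome bounds; `lines` improves reader
# error messages when available
check_in_bounds <- function(gr, genome, lines = NULL, what = "record") {
  chroms <- as.character(GenomicRanges::seqnames(gr))
  unknown <- !(chroms %in% names(genome$chrom_sizes))
  if (any(unknown)) {
    i <- which(unknown)[1L]
    loc <- if (!is.null(lines)) sprintf(" at line %d", lines[i]) else ""
    stop(sprintf("%s%s on unknown chromosome '%s' for genome '%s'",
                 what, loc, chroms[i], genome$name), call. = FALSE)
  }
  lens <- genome$chrom_sizes[chroms]
  over <- GenomicRanges::end(gr) > lens | GenomicRanges::start(gr) < 1L
  if (any(over)) {
    i <- which(over)[1L]
    loc <- if (!is.null(lines)) sprintf(" at line %d", lines[i]) else ""
    stop(sprintf("%s%s out of bounds: %s:%d-%d exceeds length %d",
                 what, loc, chroms[i],
                 GenomicRanges::start(gr)[i] - 1L, GenomicRanges::end(gr)[i],
                 as.integer(lens[i])), call. = FALSE)
  }
  invisible(TRUE)
}
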