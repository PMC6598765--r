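# Brute-force oracles, independent of the package's interval machinery:
# everything here works on plain data.frames of 0-based half-open intervals
# and per-bp arrays.

rand_intervals0 <- function(n, max_pos = 200L, max_w = 30L) {
  start <- sample.int(max_pos - 1L, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  data.frame(start = start, end = pmin(start + w, max_pos))
}

# per-bp boolean union -> merged runs (book-ended runs coalesce by construction)
oracle_merge0 <- function(df, max_pos) {
  occ <- logical(max_pos)
  for (i in seq_len(nrow(df))) occ[(df$start[i] + 1L):df$end[i]] <- TRUE
  r <- rle(occ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

oracle_depth0 <- function(df, max_pos) {
  d <- numeric(max_pos)
  for (i in seq_len(nrow(df))) {
    idx <- (df$start[i] + 1L):df$end[i]
    d[idx] <- d[idx] + 1
  }
  d
}

# 0-based half-open overlap of one interval against a table
oracle_overlap_any0 <- function(s, e, tab) {
  any(s < tab$end & tab$start < e)
}

oracle_frip0 <- function(frags, peaks) {
  hit <- vapply(seq_len(nrow(frags)), function(i)
    oracle_overlap_any0(frags$start[i], frags$end[i], peaks), logical(1L))
  mean(hit)
}

oracle_pearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# maximal alternating T/A runs by PCRE regex; returns merged 0-based intervals
oracle_ta_runs0 <- function(s, min_len) {
  m <- gregexpr("(?:TA)+T?|(?:AT)+A?", toupper(s), perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(data.frame(start = integer(0L), end = integer(0L)))
  len <- attr(m, "match.length")
  keep <- len >= min_len
  df <- data.frame(start = as.integer(m[keep]) - 1L,
                   end = as.integer(m[keep]) + len[keep] - 1L)
  if (nrow(df) < 2L) return(df)
  df <- df[order(df$start), ]
  out <- df[1L, ]
  for (i in 2L:nrow(df)) {
    if (df$start[i] <= out$end[nrow(out)]) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], df$end[i])
    } else out <- rbind(out, df[i, ])
  }
  out
}

# convenience builders around the package API
toy_genome <- function(size = 1000, name = "toy", chrom = "chr1") {
  sizes <- stats::setNames(size, if (length(size) == length(chrom)) chrom
                           else paste0("chr", seq_along(size)))
  genome_spec(name, sizes)
}

fs_from_df <- function(df, genome = NULL, chrom = "chr1", sample_id = "s") {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  fragment_set(gr, sample_id = sample_id, genome = genome)
}

gr_from_df <- function(df, chrom = "chr1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(df$start + 1L, df$end))
}

granges_to_df <- function(x) {
  gr <- if (inherits(x, "FragmentSet")) x$fragments else x
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

track_values <- function(track, chrom = "chr1") {
  as.numeric(track$cov[[chrom]])
}
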