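test_that("fragment depth counts per-bp fragment containment", {
  g <- toy_genome(10)
  fs <- fs_from_df(data.frame(start = c(0, 3), end = c(5, 8)), genome = g)
  expect_equal(track_values(fragment_depth(fs)),
               c(1, 1, 1, 2, 2, 1, 1, 1, 0, 0))
  empty <- fragment_set(GenomicRanges::GRanges(), genome = g)
  expect_equal(track_total(fragment_depth(empty)), 0)
})

test_that("fragment depth matches the array-accumulation oracle and is additive", {
  set.seed(61)
  n_instances <- 1000L
  size <- 300L
  dfs <- lapply(seq_len(n_instances), function(i)
    rand_intervals0(sample.int(15L, 1L), max_pos = size))
  chroms <- sprintf("inst%04d", seq_len(n_instances))
  g <- genome_spec("batch", stats::setNames(rep(size, n_instances), chroms))
  all_df <- do.call(rbind, dfs)
  gr <- GenomicRanges::GRanges(rep(chroms, vapply(dfs, nrow, integer(1L))),
                               IRanges::IRanges(all_df$start + 1L, all_df$end))
  track <- fragment_depth(fragment_set(gr, genome = g))
  ok <- vapply(seq_len(n_instances), function(i)
    isTRUE(all.equal(as.numeric(track$cov[[chroms[i]]]),
                     oracle_depth0(dfs[[i]], size))), logical(1L))
  expect_true(all(ok))

  # depth(pool(A, B)) = depth(A) + depth(B) pointwise
  g1 <- toy_genome(200)
  a <- fs_from_df(rand_intervals0(30, 200), genome = g1, sample_id = "a")
  b <- fs_from_df(rand_intervals0(40, 200), genome = g1, sample_id = "b")
  expect_equal(track_values(fragment_depth(pool_fragments(list(a, b)))),
               track_values(fragment_depth(a)) + track_values(fragment_depth(b)))
})

test_that("fractional counts give 1 for uniform coverage and conserve mass", {
  g <- toy_genome(10)
  fs <- fs_from_df(data.frame(start = c(0, 5), end = c(5, 10)), genome = g)
  expect_equal(track_values(fractional_count_track(fragment_depth(fs))),
               rep(1, 10))
  single <- fs_from_df(data.frame(start = 0, end = 5), genome = g)
  expect_equal(track_values(fractional_count_track(fragment_depth(single))),
               c(rep(2, 5), rep(0, 5)))
  empty <- fragment_set(GenomicRanges::GRanges(), genome = g)
  expect_error(fractional_count_track(fragment_depth(empty)), "all-zero")

  # conservation and duplication invariance on random sets
  set.seed(71)
  g2 <- toy_genome(5000)
  for (i in 1:100) {
    fs <- fs_from_df(rand_intervals0(sample.int(80L, 1L), 5000, max_w = 200L),
                     genome = g2)
    fr <- fractional_count_track(fragment_depth(fs))
    expect_equal(track_total(fr) / g2$total_size, 1, tolerance = 1e-9)
    doubled <- pool_fragments(list(fs, fs))
    expect_equal(track_values(fractional_count_track(fragment_depth(doubled))),
                 track_values(fr), tolerance = 1e-12)
  }
})

test_that("track scaling multiplies values and inverts cleanly", {
  g <- toy_genome(50)
  fs <- fs_from_df(rand_intervals0(10, 50), genome = g)
  tr <- fragment_depth(fs)
  expect_equal(track_values(scale_track(tr, 1)), track_values(tr))
  expect_equal(track_values(scale_track(scale_track(tr, 2), 0.5)),
               track_values(tr), tolerance = 1e-15)
  expect_equal(track_total(scale_track(tr, 3)), 3 * track_total(tr))
  expect_error(scale_track(tr, 0))
})

test_that("bedGraph output format and round trip", {
  g <- toy_genome(20)
  fs <- fs_from_df(data.frame(start = 0, end = 10), genome = g)
  tr <- fragment_depth(fs)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, path)
  expect_equal(readLines(path), "chr1\t0\t10\t1")  # integer prints without .0

  tr2 <- scale_track(tr, 1 / 3)
  write_bedgraph(tr2, path)
  expect_equal(readLines(path), "chr1\t0\t10\t0.33333")  # 5 significant digits

  # zero intervals omitted; empty track gives an empty file
  empty <- fragment_set(GenomicRanges::GRanges(), genome = g)
  write_bedgraph(fragment_depth(empty), path)
  expect_length(readLines(path), 0L)

  # read/write round trip within formatting precision
  set.seed(81)
  g3 <- genome_spec("toy2", c(chr1 = 400, chr2 = 300))
  fs3 <- fragment_set(GenomicRanges::GRanges(
    rep(c("chr1", "chr2"), c(25, 15)),
    IRanges::IRanges(c(sample(300, 25), sample(200, 15)), width = 50)),
    genome = g3)
  tr3 <- fractional_count_track(fragment_depth(fs3))
  write_bedgraph(tr3, path)
  back <- read_bedgraph(path, g3)
  expect_equal(as.numeric(back$cov$chr1), as.numeric(tr3$cov$chr1),
               tolerance = 1e-4)
  write_bedgraph(back, paste0(path, "2"))
  expect_equal(readLines(paste0(path, "2")), readLines(path))  # idempotent

  writeLines(c("chr1\t0\t10\t1", "chr1\t5\t15\t2"), path)
  expect_error(read_bedgraph(path, g3), "overlapping")
})
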