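make_track <- function(values, genome) {
  coverage_track(methods::as(list(chr1 = S4Vectors::Rle(values)), "RleList"),
                 genome)
}

test_that("summit-window means are exact per-bp averages with end truncation", {
  g <- toy_genome(1000)
  # constant value over the window
  tr <- make_track(rep(2.5, 1000), g)
  pk <- peak_records(gr_from_df(data.frame(start = 400, end = 600)),
                     summit = 500)
  expect_equal(unname(peak_summit_scores(tr, pk, flank = 150)), 2.5)

  # value 3 on part of the window, zero elsewhere: brute-force per-bp mean
  vals <- numeric(1000); vals[401:500] <- 3  # bp 400..499 (0-based)
  tr2 <- make_track(vals, g)
  s <- 450
  win <- (s - 150):(s + 150)  # 0-based, inclusive
  expect_equal(unname(peak_summit_scores(tr2, peak_records(
    gr_from_df(data.frame(start = 400, end = 600)), summit = s), 150)),
    mean(vals[win + 1]))

  # summit at bp 0: window truncated to [0, 150], width 151
  vals0 <- numeric(1000); vals0[1:151] <- 1
  tr3 <- make_track(vals0, g)
  pk0 <- peak_records(gr_from_df(data.frame(start = 0, end = 10)), summit = 0)
  expect_equal(unname(peak_summit_scores(tr3, pk0, 150)), 1)
  vals0[1] <- 152  # mean over 151 bp = (152 + 150)/151
  expect_equal(unname(peak_summit_scores(make_track(vals0, g), pk0, 150)),
               (152 + 150) / 151)

  bad <- peak_records(gr_from_df(data.frame(start = 990, end = 1000)),
                      summit = 995)
  g_small <- toy_genome(900)
  tr4 <- make_track(numeric(900), g_small)
  expect_error(peak_summit_scores(tr4, bad, 150), "off the genome")
})

test_that("window means match a per-bp oracle on many random instances", {
  set.seed(91)
  n_instances <- 1000L
  size <- 500L
  chroms <- sprintf("inst%04d", seq_len(n_instances))
  g <- genome_spec("batch", stats::setNames(rep(size, n_instances), chroms))
  dfs <- lapply(seq_len(n_instances), function(i)
    rand_intervals0(sample.int(10L, 1L), max_pos = size, max_w = 80L))
  all_df <- do.call(rbind, dfs)
  gr <- GenomicRanges::GRanges(rep(chroms, vapply(dfs, nrow, integer(1L))),
                               IRanges::IRanges(all_df$start + 1L, all_df$end))
  track <- fragment_depth(fragment_set(gr, genome = g))
  summits <- sample.int(size, n_instances, replace = TRUE) - 1L
  peaks <- peak_records(GenomicRanges::GRanges(
    chroms, IRanges::IRanges(pmax(1L, summits), pmin(size, summits + 10L))),
    summit = summits)
  flank <- 40
  got <- peak_summit_scores(track, peaks, flank = flank)
  exp <- vapply(seq_len(n_instances), function(i) {
    d <- oracle_depth0(dfs[[i]], size)
    win <- max(0, summits[i] - flank):min(size - 1, summits[i] + flank)
    mean(d[win + 1])
  }, numeric(1L))
  expect_equal(unname(got), exp, tolerance = 1e-12)
})

test_that("IgG percentile filter uses interpolated quantile, strictly-greater removal", {
  idx <- igg_peak_filter(1:100, percentile = 99)
  expect_equal(setdiff(1:100, idx), 100L)  # only the maximum removed
  expect_true(99L %in% idx)

  # all scores equal: nothing is strictly greater
  expect_equal(igg_peak_filter(rep(3.3, 50)), 1:50)
  expect_error(igg_peak_filter(numeric(0)), "empty")

  # quantile property: retains at least floor(p * n)
  set.seed(101)
  for (i in 1:25) {
    x <- rexp(sample(5:300, 1))
    p <- runif(1, 1, 99)
    expect_gte(length(igg_peak_filter(x, p)), floor(p / 100 * length(x)))
  }
  # sort+interpolation oracle on random scores
  for (i in 1:25) {
    x <- rnorm(37)
    xs <- sort(x)
    h <- (37 - 1) * 0.99 + 1
    thr <- xs[floor(h)] + (h - floor(h)) * (xs[ceiling(h)] - xs[floor(h)])
    expect_equal(sort(igg_peak_filter(x, 99)), which(x <= thr))
  }
})

test_that("score matrix stacks per-sample summit scores", {
  g <- toy_genome(2000)
  set.seed(111)
  fs1 <- fs_from_df(rand_intervals0(200, 2000, max_w = 100), genome = g, sample_id = "s1")
  fs2 <- fs_from_df(rand_intervals0(300, 2000, max_w = 100), genome = g, sample_id = "s2")
  t1 <- fractional_count_track(fragment_depth(fs1))
  t2 <- fractional_count_track(fragment_depth(fs2))
  peaks <- peak_records(gr_from_df(data.frame(start = c(100, 900, 1500),
                                              end = c(300, 1100, 1700))))
  m <- build_score_matrix(list(s1 = t1, s2 = t2, s1dup = t1), peaks, flank = 50)
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(m[, "s1"], peak_summit_scores(t1, peaks, 50))
  expect_equal(m[, "s2"], peak_summit_scores(t2, peaks, 50))
  expect_equal(unname(m[, "s1"]), unname(m[, "s1dup"]))  # duplicated sample
})

test_that("correlation matrix matches the direct covariance formula", {
  set.seed(121)
  for (i in 1:250) {
    m <- matrix(rnorm(100 * 4), ncol = 4,
                dimnames = list(NULL, paste0("s", 1:4)))
    cm <- correlation_matrix(m, squared = FALSE)
    cm2 <- correlation_matrix(m, squared = TRUE)
    for (a in 1:3) for (b in (a + 1):4) {
      r <- oracle_pearson(m[, a], m[, b])
      expect_equal(cm[a, b], r, tolerance = 1e-12)
      expect_equal(cm2[a, b], r^2, tolerance = 1e-12)
    }
    expect_equal(unname(diag(cm)), rep(1, 4))
    expect_equal(cm, t(cm))
  }
})

test_that("correlation matrix: affine invariance, complete rows, degenerate columns", {
  set.seed(131)
  x <- rnorm(50)
  m <- cbind(a = x, b = 2 * x + 3)
  expect_equal(correlation_matrix(m)["a", "b"], 1.0)

  # complete-row policy: an NA row is dropped for all pairs
  m3 <- cbind(a = x, b = 2 * x + 3, c = rnorm(50))
  m3[7, "c"] <- NA
  cm <- correlation_matrix(m3, squared = FALSE)
  expect_equal(cm["a", "b"], oracle_pearson(x[-7], (2 * x + 3)[-7]),
               tolerance = 1e-12)

  # positive per-column rescaling cannot change R^2 (calibration-proof)
  scaled <- sweep(m3, 2, c(10, 0.2, 7), `*`)
  expect_equal(correlation_matrix(scaled), correlation_matrix(m3),
               tolerance = 1e-12)

  mz <- cbind(a = x, z = rep(1, 50))
  expect_warning(cmz <- correlation_matrix(mz), "zero-variance")
  expect_true(is.na(cmz["a", "z"]))
  expect_error(correlation_matrix(matrix(1, 1, 2)), "at least 2")
})

test_that("FRiP counts fragment-in-peak fractions exactly", {
  g <- toy_genome(1000)
  peaks <- peak_records(gr_from_df(data.frame(start = 100, end = 200)))
  inside <- fs_from_df(data.frame(start = rep(120, 4), end = rep(150, 4)), genome = g)
  expect_equal(frip(inside, peaks), 1.0)
  outside <- fs_from_df(data.frame(start = c(300, 400), end = c(350, 450)), genome = g)
  expect_equal(frip(outside, peaks), 0.0)
  ten <- fs_from_df(data.frame(start = c(rep(150, 4), seq(300, 800, length.out = 6)),
                               end = c(rep(180, 4), seq(300, 800, length.out = 6) + 20)),
                    genome = g)
  expect_equal(frip(ten, peaks), 0.4)
  expect_error(frip(fragment_set(GenomicRanges::GRanges(), genome = g), peaks),
               "empty")
})

test_that("FRiP matches the all-pairs oracle and is invariant to peak merging/order", {
  set.seed(141)
  for (i in 1:1000) {
    frags <- rand_intervals0(sample(2:12, 1), max_pos = 150L)
    pks <- rand_intervals0(sample.int(4L, 1L), max_pos = 150L)
    fs <- fs_from_df(frags)
    pk_gr <- peak_records(gr_from_df(pks))
    got <- frip(fs, pk_gr)
    expect_equal(got, oracle_frip0(frags, pks))
    expect_equal(frip(fs, rev(pk_gr)), got)
    expect_equal(frip(fs, merge_intervals(pk_gr)), got)
  }
})

test_that("FRiP down-sampling series is deterministic and tracks the truth", {
  g <- toy_genome(10000)
  set.seed(151)
  in_pk <- data.frame(start = round(runif(600, 1000, 1900)), end = NA)
  in_pk$end <- in_pk$start + 100
  out_pk <- data.frame(start = round(runif(400, 3000, 9800)), end = NA)
  out_pk$end <- out_pk$start + 100
  fs <- fs_from_df(rbind(in_pk, out_pk), genome = g)
  peaks <- peak_records(gr_from_df(data.frame(start = 1000, end = 2000)))
  p_true <- frip(fs, peaks)

  s1 <- frip_series(fs, peaks, depths = c(1000, 500, 250), seed = 4)
  s2 <- frip_series(fs, peaks, depths = c(1000, 500, 250), seed = 4)
  expect_identical(s1, s2)
  expect_equal(unname(s1[1]), p_true)  # full-depth equals plain FRiP
  for (k in 2:3) {
    se <- sqrt(p_true * (1 - p_true) / c(1000, 500, 250)[k])
    expect_lt(abs(s1[k] - p_true), 3 * se)
  }
  expect_warning(frip_series(fs, peaks, depths = c(2000, 100), seed = 1),
                 "exceeds")
  # nested mode draws each depth from the previous one
  sn <- frip_series(fs, peaks, depths = c(800, 400), seed = 6, nested = TRUE)
  expect_false(anyNA(sn))
})
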