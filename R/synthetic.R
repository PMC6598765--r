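#' Synthetic experiment configuration
#'
#' Fully specifies a synthetic multi-species CUT&RUN experiment on toy
#' genomes: per-sample expected primary-genome fragment counts, constant
#' expected spike-in and carry-over counts (carry-over is bead-proportional,
#' hence sample-independent in expectation, which is exactly what makes it a
#' valid calibrant), peak-enriched primary fragments over a uniform
#' background, an optional contamination term redirecting fragments to
#' accessible background (emulating premature release of the nuclease-bound
#' complex under standard digestion), and an optional time course of
#' increasing yield.
#'
#' A shared per-sample lognormal recovery factor (mean 1, coefficient of
#' variation `recovery_cv`) multiplies the expected counts of all three
#' genomes. It models sample-to-sample variation in material recovery and
#' library representation, which moves spike-in and carry-over counts
#' together; with independent Poisson noise alone their concordance would be
#' nil.
#'
#' @param seed integer master seed; every draw derives from it.
#' @param primary_size,spikein_size,carryover_size toy genome sizes in bp.
#' @param n_samples number of samples in the series.
#' @param primary_depths per-sample expected primary fragment counts; default
#'   spans 100-fold (1e3 to 1e5, log-spaced), emulating input varying over two
#'   orders of magnitude.
#' @param spike_rate expected spike-in fragments per sample (constant).
#' @param carryover_rate expected carry-over fragments per sample (constant).
#' @param n_peaks,peak_width number and width (bp) of enriched sites on the
#'   primary genome, evenly spaced.
#' @param peak_enrichment per-peak enrichment fold (>= 1); default a geometric
#'   ladder from 4 to 64 so peak vectors have realistic dynamic range.
#' @param background_rate fraction of non-contaminant primary fragments placed
#'   uniformly rather than in peaks.
#' @param fragment_length_mean,fragment_length_sd fragment length in bp
#'   (truncated normal, nucleosomal scale).
#' @param contamination_rate fraction of primary fragments redirected to
#'   uniform accessible background, in \[0, 1\].
#' @param recovery_cv coefficient of variation of the shared per-sample
#'   recovery factor; 0 disables it.
#' @param timecourse_yields optional per-sample yield multipliers on the
#'   primary depth (increasing digestion time gives increasing yield).
#' @param no_spike_samples indices of samples with the spike-in omitted.
#' @return An object of class `SimConfig`; `$genomes` holds the three
#'   [genome_spec()]s and `$peaks` the enriched sites (a `GRanges` with an
#'   `enrichment` column).
#' @export
sim_config <- function(seed,
                       primary_size = 1e6,
                       spikein_size = 1e5,
                       carryover_size = 1e5,
                       n_samples = 20L,
                       primary_depths = NULL,
                       spike_rate = 1000,
                       carryover_rate = 5000,
                       n_peaks = 50L,
                       peak_width = 1000L,
                       peak_enrichment = NULL,
                       background_rate = 0.1,
                       fragment_length_mean = 150,
                       fragment_length_sd = 30,
                       contamination_rate = 0,
                       recovery_cv = 0.5,
                       timecourse_yields = NULL,
                       no_spike_samples = integer(0L)) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            primary_size > 0, spikein_size > 0, carryover_size > 0,
            n_samples >= 1L, spike_rate >= 0, carryover_rate >= 0,
            n_peaks >= 0L, peak_width >= 1L,
            background_rate >= 0, background_rate <= 1,
            contamination_rate >= 0, contamination_rate <= 1,
            recovery_cv >= 0, fragment_length_mean > 0, fragment_length_sd >= 0)
  primary_depths <- primary_depths %||%
    round(10^seq(3, 5, length.out = n_samples))
  stopifnot(length(primary_depths) == n_samples, all(primary_depths > 0))
  if (!is.null(timecourse_yields))
    stopifnot(length(timecourse_yields) == n_samples, all(timecourse_yields > 0))
  peak_enrichment <- peak_enrichment %||%
    (if (n_peaks > 0L) exp(seq(log(4), log(64), length.out = n_peaks)) else numeric(0L))
  stopifnot(length(peak_enrichment) == n_peaks, all(peak_enrichment >= 1))

  genomes <- list(
    primary = genome_spec("simPrimary", c(chrP = primary_size)),
    spikein = genome_spec("simSpike", c(chrS = spikein_size)),
    carryover = genome_spec("simEcoli", c(chrE = carryover_size)))

  peaks <- if (n_peaks > 0L) {
    spacing <- primary_size / (n_peaks + 1)
    start0 <- pmax(0, pmin(round(spacing * seq_len(n_peaks) - peak_width / 2),
                           primary_size - peak_width))
    gr <- peak_records(granges_from_bed(rep("chrP", n_peaks), start0,
                                        start0 + peak_width))
    S4Vectors::mcols(gr)$enrichment <- peak_enrichment
    gr
  } else peak_records(GenomicRanges::GRanges())

  structure(list(seed = as.integer(seed), genomes = genomes,
                 n_samples = as.integer(n_samples),
                 primary_depths = primary_depths, spike_rate = spike_rate,
                 carryover_rate = carryover_rate, peaks = peaks,
                 background_rate = background_rate,
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 contamination_rate = contamination_rate,
                 recovery_cv = recovery_cv,
                 timecourse_yields = timecourse_yields,
                 no_spike_samples = as.integer(no_spike_samples)),
            class = "SimConfig")
}

# truncated-normal fragment lengths on the nucleosomal scale
rfrag_len <- function(n, mean, sd, max_len) {
  pmin(max_len, pmax(20, round(rnorm(n, mean, sd))))
}

# n fragments with uniform midpoints over a genome (chromosome chosen
# proportional to size), lengths truncated normal, clipped to bounds
uniform_fragments_gr <- function(n, genome, len_mean, len_sd) {
  if (n == 0L) return(GenomicRanges::GRanges())
  sizes <- genome$chrom_sizes
  chrom <- names(sizes)[sample.int(length(sizes), n, replace = TRUE,
                                   prob = sizes / sum(sizes))]
  len <- rfrag_len(n, len_mean, len_sd, min(sizes))
  mid <- runif(n) * sizes[chrom]
  start0 <- pmin(pmax(round(mid - len / 2), 0), sizes[chrom] - len)
  granges_from_bed(chrom, start0, start0 + len)
}

#' Simulate one sample of a synthetic experiment
#'
#' Draws the three per-genome fragment sets of sample `sample_index`. Primary
#' fragments are a mixture of peak-enriched, uniform background, and
#' contamination classes; all counts are Poisson around the configured
#' expectations times the sample's recovery factor. Fully reproducible from
#' `(cfg$seed, sample_index)`.
#'
#' @param cfg a [sim_config()].
#' @param sample_index sample number in `1:cfg$n_samples`.
#' @return A list with elements `primary`, `spikein`, `carryover`
#'   ([fragment_set()]s) and `truth`, a one-row `data.frame` of the latent
#'   values (expected depth, yield, recovery factor, realized class counts).
#' @export
simulate_sample <- function(cfg, sample_index) {
  stopifnot(inherits(cfg, "SimConfig"),
            sample_index >= 1L, sample_index <= cfg$n_samples)
  i <- as.integer(sample_index)
  sid <- sprintf("S%02d", i)
  depth <- cfg$primary_depths[i]
  yield <- if (is.null(cfg$timecourse_yields)) 1 else cfg$timecourse_yields[i]
  spike_rate <- if (i %in% cfg$no_spike_samples) 0 else cfg$spike_rate

  with_seed(cfg$seed + 7919L * i, {
    recovery <- if (cfg$recovery_cv > 0) {
      sdlog <- sqrt(log(1 + cfg$recovery_cv^2))
      rlnorm(1L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else 1
    n_pri <- rpois(1L, depth * yield * recovery)
    n_spk <- rpois(1L, spike_rate * recovery)
    n_car <- rpois(1L, cfg$carryover_rate * recovery)

    # Every fragment is first generated as signal (peak-enriched or uniform
    # background); premature release then redirects a `contamination_rate`
    # fraction to accessible (uniform) background. The release indicator is
    # drawn independently of all signal draws, so series simulated from the
    # same seed at different contamination rates are matched fragment for
    # fragment.
    gpri <- cfg$genomes$primary
    sizes <- gpri$chrom_sizes
    released <- runif(n_pri) < cfg$contamination_rate
    is_bg <- if (length(cfg$peaks) == 0L) rep(TRUE, n_pri)
             else runif(n_pri) < cfg$background_rate
    len <- rfrag_len(n_pri, cfg$fragment_length_mean,
                     cfg$fragment_length_sd, min(sizes))
    chrom <- character(n_pri)
    mid <- numeric(n_pri)
    n_pk <- sum(!is_bg)
    if (n_pk > 0L) {
      w <- GenomicRanges::width(cfg$peaks)
      fold <- S4Vectors::mcols(cfg$peaks)$enrichment
      j <- sample.int(length(cfg$peaks), n_pk, replace = TRUE, prob = w * fold)
      chrom[!is_bg] <- as.character(GenomicRanges::seqnames(cfg$peaks))[j]
      mid[!is_bg] <- (GenomicRanges::start(cfg$peaks)[j] - 1) +
        runif(n_pk) * GenomicRanges::width(cfg$peaks)[j]
    }
    n_bg <- sum(is_bg)
    if (n_bg > 0L) {
      chrom[is_bg] <- names(sizes)[sample.int(length(sizes), n_bg,
                                              replace = TRUE,
                                              prob = sizes / sum(sizes))]
      mid[is_bg] <- runif(n_bg) * sizes[chrom[is_bg]]
    }
    chrom_red <- names(sizes)[sample.int(length(sizes), n_pri, replace = TRUE,
                                         prob = sizes / sum(sizes))]
    mid_red <- runif(n_pri) * sizes[chrom_red]
    chrom[released] <- chrom_red[released]
    mid[released] <- mid_red[released]
    start0 <- pmin(pmax(round(mid - len / 2), 0), sizes[chrom] - len)
    primary_gr <- if (n_pri > 0L) granges_from_bed(chrom, start0, start0 + len)
                  else GenomicRanges::GRanges()
    primary <- fragment_set(primary_gr, sample_id = sid, genome = gpri)
    spikein <- fragment_set(
      uniform_fragments_gr(n_spk, cfg$genomes$spikein,
                           cfg$fragment_length_mean, cfg$fragment_length_sd),
      sample_id = sid, genome = cfg$genomes$spikein)
    carryover <- fragment_set(
      uniform_fragments_gr(n_car, cfg$genomes$carryover,
                           cfg$fragment_length_mean, cfg$fragment_length_sd),
      sample_id = sid, genome = cfg$genomes$carryover)

    truth <- data.frame(sample_id = sid, index = i, depth = depth,
                        yield = yield, recovery = recovery,
                        n_primary = n_pri, n_contam = sum(released),
                        n_background = sum(is_bg & !released),
                        n_peak = sum(!is_bg & !released),
                        n_spikein = n_spk, n_carryover = n_car,
                        p_peak_class = if (length(cfg$peaks) == 0L) 0 else
                          (1 - cfg$contamination_rate) *
                          (1 - cfg$background_rate),
                        stringsAsFactors = FALSE)
    list(primary = primary, spikein = spikein, carryover = carryover,
         truth = truth)
  })
}

#' Simulate a full synthetic series
#'
#' Runs [simulate_sample()] for every sample of the configuration: a
#' depth-titration series when `primary_depths` vary (spike-in and carry-over
#' constant in expectation), or a protocol time course when
#' `timecourse_yields` is set (`contamination_rate` then distinguishes the
#' standard arm from the high-calcium/low-salt arm).
#'
#' @param cfg a [sim_config()].
#' @return A list with `samples` (per-sample output of [simulate_sample()]),
#'   `counts` (species count table across samples) and `truth` (latent-value
#'   table).
#' @export
simulate_series <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  samples <- lapply(seq_len(cfg$n_samples), function(i) simulate_sample(cfg, i))
  counts <- do.call(rbind, lapply(samples, function(s)
    tally_species(s$primary, s$spikein, s$carryover)))
  truth <- do.call(rbind, lapply(samples, `[[`, "truth"))
  list(samples = samples, counts = counts, truth = truth)
}

#' Generate a toy genome sequence
#'
#' Random uniform A/C/G/T sequence for every chromosome of a genome, with
#' optional implanted strictly alternating (TA)n runs so the low-complexity
#' scanner can be exercised end to end.
#'
#' @param genome a [genome_spec()].
#' @param seed integer seed.
#' @param ta_runs optional `data.frame` with columns `chrom`, `start` (0-based)
#'   and `length`, giving runs to implant.
#' @return A `DNAStringSet`, one entry per chromosome.
#' @export
simulate_genome_sequence <- function(genome, seed, ta_runs = NULL) {
  stopifnot(inherits(genome, "GenomeSpec"))
  with_seed(seed, {
    seqs <- vapply(names(genome$chrom_sizes), function(ch) {
      n <- as.integer(genome$chrom_sizes[ch])
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, character(1L))
  })
  if (!is.null(ta_runs)) {
    stopifnot(all(c("chrom", "start", "length") %in% names(ta_runs)))
    for (k in seq_len(nrow(ta_runs))) {
      ch <- ta_runs$chrom[k]; s0 <- ta_runs$start[k]; len <- ta_runs$length[k]
      stopifnot(ch %in% names(seqs), s0 >= 0,
                s0 + len <= genome$chrom_sizes[ch])
      run <- substr(strrep("TA", ceiling(len / 2)), 1L, len)
      substr(seqs[ch], s0 + 1L, s0 + len) <- run
    }
  }
  Biostrings::DNAStringSet(seqs)
}
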