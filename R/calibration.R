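#' Tally fragments by source genome
#'
#' Builds one row of a species count table from the three per-genome fragment
#' sets of a sample (primary/experimental genome, heterologous spike-in, and
#' carry-over E. coli). Fragments, not reads, are the counting unit.
#'
#' @param primary,spikein,carryover [fragment_set()] objects (any may be
#'   empty).
#' @param sample_id sample label; defaults to the primary set's id.
#' @param conditions optional named list of condition labels (e.g.
#'   `list(protocol = "pA_std")`) stored as extra columns.
#' @return A one-row `data.frame` with columns `sample_id`, any condition
#'   columns, `primary`, `spikein`, `carryover`.
#' @export
tally_species <- function(primary, spikein, carryover, sample_id = NULL,
                          conditions = list()) {
  stopifnot(inherits(primary, "FragmentSet"), inherits(spikein, "FragmentSet"),
            inherits(carryover, "FragmentSet"))
  row <- data.frame(sample_id = sample_id %||% primary$sample_id,
                    stringsAsFactors = FALSE)
  for (k in names(conditions)) row[[k]] <- conditions[[k]]
  row$primary <- length(primary)
  row$spikein <- length(spikein)
  row$carryover <- length(carryover)
  row
}

#' Calibration configuration
#'
#' @param mode which calibration genome to count: carry-over E. coli
#'   (`"carryover"`, usable post hoc on any experiment) or the heterologous
#'   spike-in (`"spikein"`).
#' @param multiplier positive scale constant; the factor for a sample is
#'   `multiplier / calibration count`. Only sets the global display scale.
#' @return An object of class `CalibrationConfig`.
#' @export
calibration_config <- function(mode = c("carryover", "spikein"),
                               multiplier = 10000) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(multiplier), length(multiplier) == 1L,
            is.finite(multiplier), multiplier > 0)
  structure(list(mode = mode, multiplier = multiplier),
            class = "CalibrationConfig")
}

#' Calibration scale factor from a calibration-genome count
#'
#' `factor = multiplier / calib_count`. Because the calibration genome is
#' present in constant amount per sample, dividing by its fragment count puts
#' samples of a series on a common material scale.
#'
#' @param calib_count fragment count(s) on the calibration genome; must be
#'   positive.
#' @param config a [calibration_config()].
#' @return Numeric scale factor(s).
#' @export
scale_factor <- function(calib_count, config = calibration_config()) {
  stopifnot(inherits(config, "CalibrationConfig"), is.numeric(calib_count))
  if (any(calib_count == 0))
    stop("cannot calibrate: zero calibration-genome fragments", call. = FALSE)
  if (any(calib_count < 0)) stop("negative calibration count", call. = FALSE)
  config$multiplier / calib_count
}

#' Per-sample scale factors from a species count table
#'
#' @param table a species count table ([tally_species()] rows or
#'   [read_species_counts()]).
#' @param config a [calibration_config()]; `mode` selects the `spikein` or
#'   `carryover` column.
#' @return A `data.frame` with columns `sample_id` and `factor`.
#' @export
scale_factors <- function(table, config = calibration_config()) {
  stopifnot(is.data.frame(table),
            all(c("sample_id", "spikein", "carryover") %in% names(table)))
  counts <- table[[config$mode]]
  data.frame(sample_id = table$sample_id,
             factor = scale_factor(counts, config),
             stringsAsFactors = FALSE)
}

#' Apply a calibration factor to a raw count
#' @param raw raw fragment count(s).
#' @param factor positive calibration factor(s).
#' @return `raw * factor`.
#' @export
calibrated_count <- function(raw, factor) {
  stopifnot(is.numeric(raw), is.numeric(factor), all(factor > 0))
  raw * factor
}

#' Spike-in vs carry-over concordance
#'
#' Pearson correlation between spike-in and carry-over fragment counts across
#' the samples of each condition group, on raw (untransformed) counts. High
#' concordance indicates both genomes track the same per-sample recovery, so
#' the carry-over DNA can stand in for the spike-in as calibrant.
#'
#' @param table species count table with `spikein` and `carryover` columns.
#' @param group_by optional name of a condition column; correlations are
#'   computed within each group. `NULL` treats the table as one group.
#' @return A `data.frame` with columns `group`, `n`, `r` (full precision) and
#'   `r_display` (rounded to 2 decimals). Groups with fewer than 3 samples or
#'   zero variance in either count get `NA` with a warning.
#' @export
spike_carryover_correlation <- function(table, group_by = NULL) {
  stopifnot(is.data.frame(table),
            all(c("spikein", "carryover") %in% names(table)))
  groups <- if (is.null(group_by)) rep("all", nrow(table)) else {
    if (!group_by %in% names(table))
      stop(sprintf("no such condition column: '%s'", group_by), call. = FALSE)
    as.character(table[[group_by]])
  }
  out <- lapply(unique(groups), function(g) {
    sub <- table[groups == g, , drop = FALSE]
    r <- if (nrow(sub) < 3L) {
      warning(sprintf("group '%s': fewer than 3 samples, correlation undefined", g),
              call. = FALSE)
      NA_real_
    } else if (stats::var(sub$spikein) == 0 || stats::var(sub$carryover) == 0) {
      warning(sprintf("group '%s': zero variance, correlation undefined", g),
              call. = FALSE)
      NA_real_
    } else {
      stats::cor(sub$spikein, sub$carryover)
    }
    data.frame(group = g, n = nrow(sub), r = r, r_display = round(r, 2L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a species count table from TSV
#'
#' Expects a header row with at least `sample_id`, `primary`, `spikein`,
#' `carryover`; any other columns are kept as condition labels.
#'
#' @param path TSV path.
#' @return A `data.frame`.
#' @export
read_species_counts <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "primary", "spikein", "carryover")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop(sprintf("species count table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  for (k in c("primary", "spikein", "carryover")) {
    if (any(!is.finite(tab[[k]])) || any(tab[[k]] < 0) ||
        any(tab[[k]] != round(tab[[k]])))
      stop(sprintf("column '%s' must hold non-negative integer counts", k),
           call. = FALSE)
  }
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in species count table", call. = FALSE)
  tab
}

#' Write a species count table as TSV
#' @param table species count table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_species_counts <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged H3K27me3 batch-comparison count table
#'
#' Per-sample fragment counts for human (primary), S. cerevisiae spike-in and
#' carry-over E. coli from an H3K27me3 experiment run in parallel under four
#' protocol conditions (pA/pAG fusion protein crossed with low-salt/high-
#' calcium vs standard digestion), each with and without antibody-first
#' incubation and BSA. Ships with the package as a desk-scale concordance
#' fixture.
#'
#' @return A `data.frame` with columns `sample_id`, `protocol`, `ab_first`,
#'   `bsa`, `primary`, `spikein`, `carryover`.
#' @export
h3k27me3_batch_counts <- function() {
  read_species_counts(system.file("extdata", "h3k27me3_batch.tsv", package = "carrycal",
                                  mustWork = TRUE))
}
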