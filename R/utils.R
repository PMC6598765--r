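# internal helpers shared across modules

# Evaluate `code` under a fixed seed, restoring the caller's RNG state so no
# hidden global state leaks out of seeded operations.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# bedGraph value formatting: 5 significant digits, no scientific notation,
# trailing ".0" dropped for integer values.
format_track_value <- function(x) {
  vapply(signif(x, 5L), function(v) {
    format(v, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  }, character(1L))
}

# strict non-negative integer coordinate parser; `what` and line numbers feed
# error messages for malformed BED-family input
parse_coord <- function(x, what, lines) {
  bad <- !grepl("^[0-9]+$", x)
  if (any(bad)) {
    stop(sprintf("non-integer %s at line %d: '%s'",
                 what, lines[which(bad)[1L]], x[which(bad)[1L]]), call. = FALSE)
  }
  as.numeric(x)
}

read_tsv_lines <- function(path, n_min_cols, what) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0L) return(NULL)
  fields <- strsplit(raw, "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols < n_min_cols)) {
    i <- which(ncols < n_min_cols)[1L]
    stop(sprintf("malformed %s at line %d: expected >= %d fields, got %d",
                 what, i, n_min_cols, ncols[i]), call. = FALSE)
  }
  fields
}

`%||%` <- function(a, b) if (is.null(a)) b else a
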