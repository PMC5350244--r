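#' Read traces from a delimited text file
#'
#' Accepts the standard trace dialect: comma- or tab-separated values with a
#' header row, first column time, subsequent columns one neuron each (a
#' two-column file yields a single trace). The time column may be a 0- or
#' 1-based sample index (unit increments) or seconds; it must be strictly
#' increasing and uniformly spaced. Missing or non-numeric cells are parse
#' errors naming the offending line.
#'
#' @param path path to the trace file.
#' @param sampling_interval ms per sample. If `NULL` (default) it is taken
#'   from the time column when that column is in seconds, and defaults to
#'   1.5 ms when the time column is a plain sample index.
#' @return named list of [trace()] objects.
#' @export
read_traces <- function(path, sampling_interval = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, strip.white = TRUE,
                      colClasses = "character", check.names = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  if (ncol(tab) < 2L)
    stop("trace file needs a time column plus at least one neuron column",
         call. = FALSE)
  num <- lapply(tab, function(col) suppressWarnings(as.numeric(col)))
  for (j in seq_along(num)) {
    bad <- which(!is.finite(num[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric or missing value in column '%s' at line %d of %s",
                   names(tab)[j], bad[1] + 1L, path), call. = FALSE)
  }
  tv <- num[[1L]]
  if (length(tv) > 1L && any(diff(tv) <= 0))
    stop(sprintf("time column not strictly increasing at line %d of %s",
                 which(diff(tv) <= 0)[1] + 2L, path), call. = FALSE)
  dt <- sampling_interval
  if (is.null(dt)) {
    step <- if (length(tv) > 1L) stats::median(diff(tv)) else 1
    dt <- if (isTRUE(all.equal(step, 1))) 1.5 else step * 1000  # s -> ms
  }
  ids <- names(tab)[-1L]
  out <- lapply(seq_along(ids), function(k)
    trace(num[[k + 1L]], sampling_interval = dt, neuron_id = ids[k]))
  names(out) <- ids
  out
}

#' Write traces to a delimited text file
#'
#' Inverse of [read_traces()]: one wide comma-separated file with a `time`
#' column holding the 0-based sample index.
#'
#' @param traces a named list of [trace()] objects sharing one time base.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  traces <- as_trace_list(traces)
  n <- unique(vapply(traces, length, integer(1)))
  if (length(n) != 1L)
    stop("all traces must have the same length", call. = FALSE)
  df <- data.frame(time = seq_len(n) - 1L)
  for (id in names(traces)) df[[id]] <- traces[[id]]$values
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_keys <- c(
  "smoothing.window", "smoothing.alignment", "slope.tau",
  "detect.fraction", "detect.epsilon", "detect.max_band", "detect.min_band",
  "detect.zero_range", "match.max_lag", "alpha", "units", "seed",
  "eta.cycles_per_window")

#' Read a key-value configuration file
#'
#' Parses a plain-text configuration of `key = value` (or `key: value`)
#' lines; blank lines and `#` comments are ignored. Values are converted to
#' numeric or logical where possible; a comma-separated value becomes a
#' numeric vector (used for explicit band intervals). Unknown keys are an
#' error — the pipeline never silently substitutes defaults for malformed
#' configuration.
#'
#' Recognised keys: `smoothing.window`, `smoothing.alignment`, `slope.tau`,
#' `detect.fraction`, `detect.epsilon`, `detect.max_band`,
#' `detect.min_band`, `detect.zero_range`, `match.max_lag`, `alpha`,
#' `units`, `seed`, `eta.cycles_per_window`.
#'
#' @param path path to the configuration file.
#' @return named list of configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^([^=:]+)[=:](.*)$", lines[i]))[[1]]
    if (length(m) != 3L)
      stop("cannot parse config line: '", lines[i], "'", call. = FALSE)
    key <- trimws(m[2]); val <- trimws(m[3])
    if (!key %in% config_keys)
      stop("unknown config key: '", key, "'", call. = FALSE)
    out[[key]] <- parse_config_value(val)
  }
  out
}

parse_config_value <- function(val) {
  if (grepl(",", val)) {
    parts <- trimws(strsplit(val, ",")[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    if (!any(is.na(nums))) return(nums)
    return(parts)
  }
  n <- suppressWarnings(as.numeric(val))
  if (!is.na(n)) return(n)
  if (toupper(val) %in% c("TRUE", "FALSE")) return(as.logical(val))
  val
}
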