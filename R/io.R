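# Data ingestion, seasonal splitting and tabular output for the CLI and for
# scripted analyses of hourly exposure records.

#' Read a delimited dataset of equally spaced time series
#'
#' Parses a delimited text file (comma, semicolon or tab; sniffed from the
#' header unless `delimiter` is given) with a header row, optionally one
#' ISO-8601 timestamp column and one numeric column per site. Rows with a
#' non-numeric or missing payload value are rejected with the row number,
#' unless `interpolate = TRUE`, in which case interior gaps of at most
#' `max_gap` consecutive rows are filled linearly.
#'
#' @param path Path to the file.
#' @param timestamp_column Optional name of the timestamp column. Timestamps
#'   must parse as ISO-8601 (timezone-naive, read as UTC) and be strictly
#'   increasing; unequal spacing is reported as a warning.
#' @param delimiter Optional field delimiter; default sniffed.
#' @param interpolate Fill missing payload values by linear interpolation
#'   (default `FALSE`: strict rejection).
#' @param max_gap Largest run of consecutive missing values that may be
#'   interpolated (default 6).
#' @return Object of class `"dataset"`: list with `timestamps` (POSIXct or
#'   `NULL`), `data` (data.frame of numeric columns) and `source`.
#' @export
read_dataset <- function(path, timestamp_column = NULL, delimiter = NULL,
                         interpolate = FALSE, max_gap = 6L) {
  if (!file.exists(path)) stop_input("input file not found: %s", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop_input("empty input file: %s", path)
  if (is.null(delimiter)) {
    counts <- vapply(c(",", ";", "\t"), function(d) {
      length(gregexpr(d, header, fixed = TRUE)[[1L]])
    }, numeric(1))
    delimiter <- if (max(counts) == 0) "," else names(which.max(counts))
  }
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delimiter,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character", blank.lines.skip = FALSE),
    error = function(e) stop_input("malformed input %s: %s", path,
                                   conditionMessage(e)))
  timestamps <- NULL
  if (!is.null(timestamp_column)) {
    if (!timestamp_column %in% names(df)) {
      stop_input("timestamp column '%s' not found", timestamp_column)
    }
    timestamps <- parse_iso8601(df[[timestamp_column]])
    df[[timestamp_column]] <- NULL
    if (anyNA(timestamps)) {
      stop_input("unparseable timestamp at row %d", which(is.na(timestamps))[1L])
    }
    d <- diff(as.numeric(timestamps))
    if (any(d <= 0)) {
      stop_input("timestamps not strictly increasing at row %d",
                 which(d <= 0)[1L] + 1L)
    }
    if (length(unique(d)) > 1L) {
      warning("timestamps are not equally spaced", call. = FALSE)
    }
  }
  if (ncol(df) == 0L) stop_input("no payload columns in %s", path)
  data <- as.data.frame(lapply(df, function(col) {
    suppressWarnings(as.numeric(col))
  }))
  names(data) <- names(df)
  for (nm in names(data)) {
    bad <- which(is.na(data[[nm]]))
    if (length(bad) == 0L) next
    if (!interpolate) {
      stop_input("non-numeric or missing value in column '%s' at row %d",
                 nm, bad[1L])
    }
    runs <- split(bad, cumsum(c(1L, diff(bad) != 1L)))
    if (any(lengths(runs) > max_gap)) {
      stop_input("gap longer than max_gap = %d in column '%s'", max_gap, nm)
    }
    if (bad[1L] == 1L || bad[length(bad)] == nrow(data)) {
      stop_input("cannot interpolate at the edge of column '%s'", nm)
    }
    ok <- which(!is.na(data[[nm]]))
    data[[nm]][bad] <- stats::approx(ok, data[[nm]][ok], xout = bad)$y
  }
  structure(list(timestamps = timestamps, data = data, source = path),
            class = "dataset")
}

parse_iso8601 <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")
  # pick the format from the first entry, then hold every row to it
  for (fmt in fmts) {
    if (length(x) > 0L && !is.na(as.POSIXct(x[1L], format = fmt, tz = "UTC"))) {
      return(as.POSIXct(x, format = fmt, tz = "UTC"))
    }
  }
  as.POSIXct(rep(NA_character_, length(x)), tz = "UTC")
}

#' @export
print.dataset <- function(x, ...) {
  cat(sprintf("Dataset: %d rows, %d column(s)%s [%s]\n",
              nrow(x$data), ncol(x$data),
              if (is.null(x$timestamps)) "" else ", timestamped",
              x$source))
  invisible(x)
}

#' Season of a calendar month or timestamp
#'
#' December–February is winter, March–May spring, June–August summer,
#' September–November fall. Rows are labeled by the calendar month of
#' their timestamp; no re-dating is applied.
#'
#' @param x Integer months (1-12) or POSIXct/Date timestamps.
#' @return Character vector over `c("winter", "spring", "summer", "fall")`.
#' @export
season_of <- function(x) {
  if (inherits(x, "POSIXt") || inherits(x, "Date")) {
    x <- as.integer(format(x, "%m"))
  }
  if (!all(x %in% 1:12)) stop_input("months must lie in 1..12")
  c("winter", "winter", rep("spring", 3), rep("summer", 3),
    rep("fall", 3), "winter")[x]
}

#' Split a timestamped dataset by meteorological season
#'
#' Partitions the rows of a dataset into four datasets by the calendar
#' month of each timestamp. The concatenation of the four outputs is a
#' permutation of the input: no row is lost or duplicated.
#'
#' @param ds A [read_dataset()] result with timestamps.
#' @return Named list of four `"dataset"` objects
#'   (`winter`, `spring`, `summer`, `fall`), possibly with zero rows.
#' @export
split_by_season <- function(ds) {
  if (!inherits(ds, "dataset")) stop_input("ds must be a dataset object")
  if (is.null(ds$timestamps)) {
    stop_input("seasonal split requires timestamps")
  }
  lab <- season_of(ds$timestamps)
  out <- lapply(c(winter = "winter", spring = "spring",
                  summer = "summer", fall = "fall"), function(s) {
    keep <- lab == s
    structure(list(timestamps = ds$timestamps[keep],
                   data = ds$data[keep, , drop = FALSE],
                   source = ds$source),
              class = "dataset")
  })
  out
}

#' Write named per-scale result tables to CSV files
#'
#' One CSV per table, written as `<prefix>_<name>.csv` with a header row,
#' the scale as first column and full double precision (values round-trip
#' to at least 12 significant digits). All tables must share the same
#' scale grid.
#'
#' @param tables Named list of data.frames whose first column is `scale`.
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of files written. An empty table set
#'   writes nothing and warns.
#' @export
write_results <- function(tables, prefix) {
  if (length(tables) == 0L) {
    warning("no result tables to write", call. = FALSE)
    return(invisible(character(0)))
  }
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop_input("tables must be a named list")
  }
  grids <- lapply(tables, function(tb) tb[[1L]])
  if (length(unique(grids)) != 1L) {
    stop_input("tables are not defined on a common scale grid")
  }
  files <- character(length(tables))
  for (i in seq_along(tables)) {
    files[i] <- paste0(prefix, "_", names(tables)[i], ".csv")
    tb <- tables[[i]]
    num <- vapply(tb, is.numeric, logical(1))
    tb[num] <- lapply(tb[num], function(col) {
      ifelse(is.na(col), NA_character_, format(col, digits = 17, trim = TRUE))
    })
    utils::write.table(tb, files[i], sep = ",", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(files)
}

#' Default parameters of the analysis pipeline
#'
#' Single place holding the tunable defaults used across the package and
#' printed by the CLI `config` subcommand.
#'
#' @return Named list of defaults.
#' @export
dfareg_defaults <- function() {
  list(order = 2L, n_min = 10L, n_max = 1000L, n_scales = 30L,
       alpha = 0.01, n_shuffles = 10000L,
       removal_threshold = 1e-5, noise_sd = 1e-4,
       interpolate = FALSE, max_gap = 6L)
}

#' Read a flat key/value configuration file
#'
#' Parses lines of the form `key = value` (blank lines and `#` comments
#' ignored), coercing values that parse as numbers or logicals. Unknown keys
#' are rejected against [dfareg_defaults()]. The CLI merges the result over
#' the defaults, with command-line flags taking final precedence.
#'
#' @param path Path to the configuration file.
#' @return Named list of settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  known <- names(dfareg_defaults())
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop_input("malformed config line: '%s'", ln)
    key <- trimws(parts[1L]); val <- trimws(parts[2L])
    if (!key %in% known) {
      stop_input("unknown config key '%s' (known: %s)", key,
                 paste(known, collapse = ", "))
    }
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(val)
      else val
  }
  out
}

#' Emit a reproducibility log line for a pipeline run
#'
#' Writes one message recording the input file hash (MD5), the parameters,
#' the seed and the package version; every CLI subcommand calls this.
#'
#' @param input Optional input file path (hashed when it exists).
#' @param params Named list of parameters to record.
#' @param seed Seed in use (or `NULL`).
#' @return Invisibly, the log line.
#' @export
log_run <- function(input = NULL, params = list(), seed = NULL) {
  hash <- if (!is.null(input) && file.exists(input)) {
    unname(tools::md5sum(input))
  } else "-"
  line <- sprintf("dfareg %s | input=%s md5=%s | %s | seed=%s",
                  as.character(utils::packageVersion("dfareg")),
                  if (is.null(input)) "-" else input, hash,
                  paste(names(params), unlist(lapply(params, format)),
                        sep = "=", collapse = " "),
                  if (is.null(seed)) "-" else format(seed))
  message(line)
  invisible(line)
}
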