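# Numbers are written with 15 significant digits so that read(write(x))
# round-trips to well under 1e-9 relative error.
fmt_num <- function(x) formatC(x, digits = 15, format = "g")

#' Write / read a respirometry trace
#'
#' Plain UTF-8 comma-separated files with a small `#`-prefixed metadata block
#' (units, sampling rate, seed, config hash) before the header.
#'
#' @param trace A [respirometry_trace()].
#' @param path Output file.
#' @param seed,cfg_hash Optional provenance stamped into the metadata block.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, seed = attr(trace, "seed"),
                        cfg_hash = NULL) {
  hz <- attr(trace, "hz"); if (is.null(hz)) hz <- 2
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# squirreltherm trace v1",
               paste0("# hz: ", hz),
               "# units: time=s fractions=dimensionless flow=ml/min temps=degC",
               paste0("# seed: ", if (is.null(seed)) "NA" else seed),
               paste0("# config: ", if (is.null(cfg_hash)) "NA" else
                 cfg_hash)), con)
  df <- as.data.frame(trace)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param hz Sampling rate to assume if the metadata block is absent.
#' @return `read_trace`: a validated [respirometry_trace()].
#' @export
read_trace <- function(path, hz = 2) {
  head_lines <- readLines(path, n = 50, warn = FALSE)
  meta <- grep("^#", head_lines, value = TRUE)
  hzl <- grep("^# hz:", meta, value = TRUE)
  if (length(hzl)) hz <- as.numeric(sub("^# hz:\\s*", "", hzl[1]))
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  if (!"marker" %in% names(df)) df$marker <- NA_character_
  respirometry_trace(df, hz = hz)
}

#' Read a temperature-logger CSV
#'
#' Accepts either a plain two-column CSV (`timestamp`, `temperature`) or an
#' iButton-style export whose preamble lines precede a `Date/Time,...,Value`
#' header; the preamble is auto-skipped by scanning for the header row.
#' Duplicate timestamps are collapsed to the first occurrence with a
#' warning.
#'
#' @param path CSV file.
#' @param kind `"body"` or `"ambient"`; body records outside the 0-45 degC
#'   sensor range raise an integrity error.
#' @param tz Timezone applied to the parsed timestamps.
#' @return Data frame `timestamp` (POSIXct), `temperature`.
#' @export
read_logger <- function(path, kind = c("body", "ambient"),
                        tz = "America/New_York") {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*(\"?)(timestamp|Date/Time)", lines, ignore.case = TRUE)
  if (!length(hdr))
    stop("format error: no header row with a timestamp column found in ",
         path, call. = FALSE)
  df <- utils::read.csv(text = paste(lines[hdr[1]:length(lines)],
                                     collapse = "\n"),
                        stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  tcol <- intersect(c("timestamp", "date.time", "date_time"), names(df))[1]
  vcol <- intersect(c("temperature", "value"), names(df))[1]
  if (is.na(tcol) || is.na(vcol))
    stop("format error: need timestamp and temperature/value columns",
         call. = FALSE)
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%d %H:%M", "%d/%m/%y %H:%M:%OS",
            "%m/%d/%y %I:%M:%S %p")
  raw <- as.character(df[[tcol]])
  ts <- as.POSIXct(rep(NA_character_, length(raw)), tz = tz)
  for (fmt in fmts) {
    miss <- is.na(ts)
    if (!any(miss)) break
    ts[miss] <- as.POSIXct(strptime(raw[miss], fmt, tz = tz), tz = tz)
  }
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop("format error: unparseable timestamp at data line ", bad, " ('",
         df[[tcol]][bad], "')", call. = FALSE)
  }
  temp <- as.numeric(df[[vcol]])
  if (kind == "body" && any(temp < 0 | temp > 45, na.rm = TRUE))
    stop("integrity error: body temperature outside the 0-45 degC sensor ",
         "range", call. = FALSE)
  dup <- duplicated(ts)
  if (any(dup)) {
    warning(sum(dup), " duplicate timestamp(s) collapsed to first occurrence",
            call. = FALSE)
    ts <- ts[!dup]; temp <- temp[!dup]
  }
  o <- order(ts)
  data.frame(timestamp = ts[o], temperature = temp[o])
}

#' Write a logger series
#'
#' @param records Data frame `timestamp`, `temperature`.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_logger <- function(records, path) {
  df <- data.frame(
    timestamp = strftime(records$timestamp, "%Y-%m-%dT%H:%M:%S",
                         tz = attr(records$timestamp, "tzone")),
    temperature = fmt_num(records$temperature))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial events file
#'
#' CSV with columns `time` (seconds since trial start), `kind` (one of
#' trial_start, disruption, visual_activity_start, visual_activity_end,
#' temperature_step) and `note`.
#'
#' @param path CSV file.
#' @return Validated events data frame.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("numeric", "character", "character"))
  kinds <- c("trial_start", "disruption", "visual_activity_start",
             "visual_activity_end", "temperature_step")
  bad <- setdiff(unique(df$kind), kinds)
  if (length(bad))
    stop("format error: unknown event kind(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  df
}

#' Write pipeline result tables and fit reports
#'
#' Tabular results (bout tables, phase summaries, model comparisons) are
#' written as CSV with a deterministic column order; breakpoint fits are
#' written as JSON reports carrying `psi`, `ci_low`, `ci_high`, slopes, n,
#' the seed and the configuration hash. Identical inputs and configuration
#' produce byte-identical files.
#'
#' @param tables Named list; data frames become `<prefix>_<name>.csv`,
#'   `piecewise_fit` objects become `<prefix>_<name>.json`.
#' @param path_prefix Path prefix for the output files.
#' @param config A [run_config()] whose hash and seed are embedded.
#' @return Character vector of the files written.
#' @export
write_results <- function(tables, path_prefix, config = run_config()) {
  h <- config_hash(config)
  written <- character(0)
  for (nm in names(tables)) {
    x <- tables[[nm]]
    if (inherits(x, "piecewise_fit")) {
      f <- paste0(path_prefix, "_", nm, ".json")
      rep <- list(psi = x$psi, ci_low = x$ci[1], ci_high = x$ci[2],
                  slope_left = x$slope_left, slope_right = x$slope_right,
                  intercept = x$intercept, n = x$n, sigma = x$sigma,
                  method = x$method, converged = x$converged,
                  seed = config$seed, config_hash = h)
      jsonlite::write_json(rep, f, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    } else {
      f <- paste0(path_prefix, "_", nm, ".csv")
      df <- as.data.frame(x)
      df <- df[, order(match(names(df), names(df))), drop = FALSE]
      con <- file(f, "w", encoding = "UTF-8")
      writeLines(paste0("# seed: ", config$seed, " config: ", h), con)
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], fmt_num)
      utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
      close(con)
    }
    written <- c(written, f)
  }
  if (anyNA(written) || any(!file.exists(written)))
    stop("I/O error writing results under prefix ", path_prefix,
         call. = FALSE)
  written
}
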