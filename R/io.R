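# Readers and writers for the package's delimited formats. Spike tables are
# tab-separated with columns (channel, time); traces are tab-separated with
# two numeric columns (time, value-like). Strict parsing: malformed rows are
# reported with their line number.

.read_delim_checked <- function(path, expected, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) {
    warning("empty file: ", path)
    out <- stats::setNames(rep(list(character(0)), length(expected)), expected)
    out[numeric_cols] <- lapply(out[numeric_cols], as.numeric)
    return(as.data.frame(out))
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, expected)) {
    stop(path, ": expected header '", paste(expected, collapse = "\t"),
         "', found '", lines[1], "'")
  }
  if (length(lines) == 1) {
    warning("no data rows in ", path)
    out <- stats::setNames(rep(list(character(0)), length(expected)), expected)
    out[numeric_cols] <- lapply(out[numeric_cols], as.numeric)
    return(as.data.frame(out))
  }
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(expected))
  if (length(bad)) {
    stop(path, ": malformed row at line ", bad[1] + 1, ": '",
         lines[bad[1] + 1], "'")
  }
  m <- do.call(rbind, parts)
  out <- stats::setNames(as.data.frame(m, stringsAsFactors = FALSE), expected)
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(out[[cc]]))
    if (anyNA(v)) {
      stop(path, ": non-numeric '", cc, "' at line ",
           which(is.na(v))[1] + 1)
    }
    out[[cc]] <- v
  }
  out
}

#' Read and write spike-time tables
#'
#' Spike tables are tab-separated text with header `channel<TAB>time`,
#' times in seconds. On reading, times must be strictly increasing within
#' each channel; violations are rejected. An empty file yields an empty
#' table with a warning.
#'
#' @param path file path.
#' @return data frame with columns `channel` and `time`.
#' @export
read_spike_table <- function(path) {
  out <- .read_delim_checked(path, c("channel", "time"), "time")
  for (ch in unique(out$channel)) {
    tt <- out$time[out$channel == ch]
    if (length(tt) > 1 && any(diff(tt) <= 0)) {
      i <- which(diff(tt) <= 0)[1]
      stop(path, ": spike times out of order in channel ", ch,
           " near t = ", tt[i + 1])
    }
  }
  out
}

#' @rdname read_spike_table
#' @param spikes data frame with columns `channel` and `time`.
#' @export
write_spike_table <- function(spikes, path) {
  stopifnot(all(c("channel", "time") %in% names(spikes)))
  out <- data.frame(channel = spikes$channel,
                    time = sprintf("%.17g", spikes$time))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write two-column sampled traces
#'
#' Traces are tab-separated text with a two-column header (first column
#' `time` in seconds, second the sampled value, e.g. `value` or `current`).
#' Time must be strictly increasing.
#'
#' @param path file path.
#' @param value_name name of the value column expected/written (default
#'   "value").
#' @return data frame with columns `time` and `value_name`.
#' @export
read_trace <- function(path, value_name = "value") {
  out <- .read_delim_checked(path, c("time", value_name),
                             c("time", value_name))
  if (nrow(out) > 1 && any(diff(out$time) <= 0)) {
    stop(path, ": trace times must be strictly increasing")
  }
  out
}

#' @rdname read_trace
#' @param trace data frame with a `time` column and one value column.
#' @export
write_trace <- function(trace, path, value_name = "value") {
  stopifnot("time" %in% names(trace), value_name %in% names(trace))
  out <- data.frame(time = sprintf("%.17g", trace$time),
                    value = sprintf("%.17g", trace[[value_name]]))
  names(out)[2] <- value_name
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tidy report table
#'
#' Tab-separated, unquoted, fixed column order as given; byte-identical
#' output for identical input.
#'
#' @param df data frame.
#' @param path file path.
#' @export
write_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
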