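# VelocityTrace container and its CSV dialect.
#
# External files store speeds in mm/s (column `speed_mm_s`); the in-memory
# tibble is strict SI (m/s). Metadata travel as '#'-prefixed key=value
# comment lines ahead of the header.

#' Velocity trace
#'
#' A tibble of (time, speed) samples from a tracked bubble, as extracted
#' from sequential imaging frames or generated synthetically. Internally SI
#' (seconds, m/s); see [read_velocity_trace()] / [write_velocity_trace()]
#' for the external mm/s CSV dialect.
#'
#' @param time Sample times (s), strictly increasing.
#' @param speed Speeds (m/s), same length as `time`.
#' @param power_fraction Transmit power fraction the trace was recorded at
#'   (NA if unknown).
#' @param frame_rate Sampling rate (1/s). Defaults to the reciprocal median
#'   time step; if supplied it must agree with that within 1%.
#' @param label Free-text label.
#' @return A tibble of class `onb_trace` with attributes `power_fraction`,
#'   `frame_rate` and `label`.
#' @export
velocity_trace <- function(time, speed, power_fraction = NA_real_,
                           frame_rate = NULL, label = "") {
  if (length(time) != length(speed)) {
    validation_abort("`time` and `speed` must have equal length.")
  }
  if (length(time) < 2L || any(!is.finite(time)) || any(diff(time) <= 0)) {
    validation_abort("`time` must be strictly increasing with >= 2 samples.")
  }
  if (any(!is.finite(speed))) {
    validation_abort("`speed` must be finite.")
  }
  implied <- 1 / median(diff(time))
  if (is.null(frame_rate)) {
    frame_rate <- implied
  } else if (abs(frame_rate - implied) > 0.01 * implied) {
    validation_abort(
      "`frame_rate` (%g 1/s) is inconsistent with the median time step (implies %g 1/s).",
      frame_rate, implied)
  }
  out <- tibble(time = as.numeric(time), speed = as.numeric(speed))
  attr(out, "power_fraction") <- as.numeric(power_fraction)
  attr(out, "frame_rate") <- frame_rate
  attr(out, "label") <- as.character(label)
  class(out) <- c("onb_trace", class(out))
  out
}

#' @export
print.onb_trace <- function(x, ...) {
  cat(sprintf(
    "<onb_trace> %d samples @ %.4g 1/s, power = %s, label = \"%s\"\n",
    nrow(x), attr(x, "frame_rate"),
    ifelse(is.na(attr(x, "power_fraction")), "?",
           format(attr(x, "power_fraction"))),
    attr(x, "label")))
  NextMethod()
}

#' Write a velocity trace to CSV
#'
#' Columns `time_s` and `speed_mm_s` ('.' decimal separator), preceded by
#' '#'-prefixed key=value metadata lines (`power_fraction`, `frame_rate_hz`,
#' `label`). Formatting is fixed so that identical traces produce
#' byte-identical files.
#'
#' @param trace An [velocity_trace()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_velocity_trace <- function(trace, path) {
  lines <- c(
    sprintf("# power_fraction=%s",
            format_num(attr(trace, "power_fraction"))),
    sprintf("# frame_rate_hz=%s", format_num(attr(trace, "frame_rate"))),
    sprintf("# label=%s", attr(trace, "label")),
    "time_s,speed_mm_s",
    sprintf("%s,%s", format_num(trace$time),
            format_num(trace$speed * 1e3))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a velocity trace from CSV
#'
#' @param path File written by [write_velocity_trace()] (or any CSV with a
#'   `time_s,speed_mm_s` header and optional '#' metadata lines).
#' @return A [velocity_trace()] object.
#' @export
read_velocity_trace <- function(path) {
  if (!file.exists(path)) {
    validation_abort("trace file '%s' does not exist.", path)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    validation_abort("trace file '%s' is empty.", path)
  }
  meta_lines <- grep("^#", lines)
  meta <- parse_metadata(lines[meta_lines])
  body <- if (length(meta_lines)) lines[-meta_lines] else lines
  if (length(body) < 2L || !grepl("^time_s\\s*,\\s*speed_mm_s", body[1])) {
    validation_abort(
      "trace file '%s' must have a 'time_s,speed_mm_s' header row.", path)
  }
  df <- read.csv(text = body, header = TRUE, stringsAsFactors = FALSE)
  time <- suppressWarnings(as.numeric(df$time_s))
  speed <- suppressWarnings(as.numeric(df$speed_mm_s))
  bad <- which(!is.finite(time) | !is.finite(speed))
  if (length(bad)) {
    validation_abort("trace file '%s' has non-numeric values at data row(s) %s.",
                     path, paste(bad, collapse = ", "))
  }
  velocity_trace(
    time = time, speed = speed / 1e3,
    power_fraction = as.numeric(meta[["power_fraction"]] %||% NA_real_),
    frame_rate = if (is.null(meta[["frame_rate_hz"]])) NULL
                 else as.numeric(meta[["frame_rate_hz"]]),
    label = meta[["label"]] %||% ""
  )
}

parse_metadata <- function(lines) {
  lines <- sub("^#\\s*", "", lines)
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  kv <- kv[lengths(kv) == 3L]
  setNames(lapply(kv, function(m) trimws(m[3])),
           vapply(kv, function(m) trimws(m[2]), character(1)))
}

# fixed "%.12g" rendering: deterministic and round-trip safe for doubles
# at the precision these measurements carry
format_num <- function(x) {
  out <- sprintf("%.12g", x)
  out[is.na(x)] <- "NA"
  out
}
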