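#' Construct a DOT trace
#'
#' A `dot_trace` is the basic container for a dissolved-oxygen-tension time
#' series of one reactor run: a data frame with columns `time` (seconds from
#' run start, strictly increasing) and `dot` (% air saturation), plus
#' metadata attributes.  Values below 0 or above the saturation value
#' `dotstar` are kept (they are measurement noise, and clipping would bias
#' slope estimates) but counted in the `n_out_of_range` attribute.
#'
#' @param time numeric vector, seconds from run start; strictly increasing,
#'   at least two points.
#' @param dot numeric vector, % air saturation; same length as `time`.
#' @param dotstar saturation value DOT* in % air saturation (default 100).
#' @param reactor_id optional reactor identifier.
#' @param note optional free-text sampling note.
#' @return An object of class `dot_trace` (a data frame with columns
#'   `time`, `dot`).
#' @export
dot_trace <- function(time, dot, dotstar = 100, reactor_id = NA_character_,
                      note = NA_character_) {
  time <- as.numeric(time)
  dot <- as.numeric(dot)
  if (length(time) != length(dot))
    stop("`time` and `dot` must have the same length", call. = FALSE)
  if (length(time) < 2L)
    stop("a dot_trace needs at least 2 points", call. = FALSE)
  if (anyNA(time) || any(!is.finite(time)))
    stop("`time` must be finite", call. = FALSE)
  if (anyNA(dot) || any(!is.finite(dot)))
    stop("`dot` must be finite; drop non-finite rows before construction",
         call. = FALSE)
  if (any(diff(time) <= 0))
    stop("`time` must be strictly increasing", call. = FALSE)
  if (any(time < 0))
    stop("`time` must be non-negative", call. = FALSE)
  if (!is.numeric(dotstar) || length(dotstar) != 1L || dotstar <= 0)
    stop("`dotstar` must be a single positive number", call. = FALSE)
  x <- data.frame(time = time, dot = dot)
  attr(x, "dotstar") <- dotstar
  attr(x, "reactor_id") <- reactor_id
  attr(x, "note") <- note
  attr(x, "n_out_of_range") <- sum(dot < 0 | dot > dotstar)
  class(x) <- c("dot_trace", "data.frame")
  x
}

#' @export
print.dot_trace <- function(x, ...) {
  dt <- diff(x$time)
  cat(sprintf(
    "<dot_trace> %d points, %.1f-%.1f s, DOT* = %g%%%s\n",
    nrow(x), x$time[1L], x$time[nrow(x)], dotstar(x),
    if (is_uniform(x)) sprintf(", uniform dt = %g s", dt[1L]) else ""))
  oor <- attr(x, "n_out_of_range")
  if (isTRUE(oor > 0)) cat(sprintf("  %d value(s) outside [0, DOT*]\n", oor))
  invisible(x)
}

#' Saturation value of a trace
#' @param trace a `dot_trace`.
#' @return DOT* in % air saturation.
#' @export
dotstar <- function(trace) {
  ds <- attr(trace, "dotstar")
  if (is.null(ds)) 100 else ds
}

#' Is a trace uniformly sampled?
#' @param trace a `dot_trace`.
#' @param tol relative tolerance on the sampling interval.
#' @return `TRUE` if all sampling intervals agree within `tol`.
#' @export
is_uniform <- function(trace, tol = 1e-6) {
  dt <- diff(trace$time)
  diff(range(dt)) <= tol * max(mean(dt), .Machine$double.eps)
}

#' Sampling interval of a uniform trace
#' @param trace a uniformly sampled `dot_trace`.
#' @return dt in seconds.
#' @export
trace_dt <- function(trace) {
  if (!is_uniform(trace))
    stop("trace is not uniformly sampled; call resample_uniform() first",
         call. = FALSE)
  mean(diff(trace$time))
}

#' Construct a feed schedule
#'
#' Ordered bolus feed events.  Times are seconds from run start
#' (non-decreasing), volumes in microlitres, the feed glucose concentration
#' in mg/mL (600 mg/mL by default, the usual concentrated glucose feed).
#'
#' @param time event times in seconds, non-decreasing.
#' @param volume bolus volumes in uL, all positive.
#' @param concentration feed concentration(s) in mg/mL, positive; recycled.
#' @return An object of class `feed_schedule` (data frame with columns
#'   `time`, `volume`, `concentration`).
#' @export
feed_schedule <- function(time, volume, concentration = 600) {
  time <- as.numeric(time)
  volume <- as.numeric(volume)
  if (length(volume) == 1L) volume <- rep_len(volume, length(time))
  concentration <- rep_len(as.numeric(concentration), length(time))
  if (length(time) != length(volume))
    stop("`time` and `volume` must have the same length", call. = FALSE)
  if (length(time) && any(diff(time) < 0))
    stop("feed event times must be non-decreasing", call. = FALSE)
  if (any(volume <= 0)) stop("feed volumes must be positive", call. = FALSE)
  if (any(concentration <= 0))
    stop("feed concentrations must be positive", call. = FALSE)
  x <- data.frame(time = time, volume = volume, concentration = concentration)
  class(x) <- c("feed_schedule", "data.frame")
  x
}

#' Construct an at-line sample table
#'
#' @param time sample times in seconds.
#' @param cx biomass dry weight in mg/mL (optional, `NA` allowed).
#' @param cs glucose concentration in mg/mL (optional).
#' @param ca acetate concentration in mg/mL (optional).
#' @return An object of class `sample_table`.
#' @export
sample_table <- function(time, cx = NA_real_, cs = NA_real_, ca = NA_real_) {
  n <- length(time)
  x <- data.frame(time = as.numeric(time),
                  cx = rep_len(as.numeric(cx), n),
                  cs = rep_len(as.numeric(cs), n),
                  ca = rep_len(as.numeric(ca), n))
  for (col in c("cx", "cs", "ca"))
    if (any(x[[col]] < 0, na.rm = TRUE))
      stop("concentrations must be non-negative when present", call. = FALSE)
  class(x) <- c("sample_table", "data.frame")
  x
}

#' First-order DOT sensor model
#'
#' Optical DO probes respond with a first-order lag; `tau` is the time
#' constant in seconds (36 s for the probes emulated here).
#'
#' @param tau time constant in seconds, >= 0.
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(tau = 36) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stop("`tau` must be a single non-negative number", call. = FALSE)
  structure(list(tau = tau), class = "sensor_model")
}

time_unit_factor <- function(unit = c("s", "min", "h")) {
  switch(match.arg(unit), s = 1, min = 60, h = 3600)
}

#' Read a DOT trace from a delimited text file
#'
#' Expects a header row.  Duplicate timestamps are collapsed by their mean;
#' rows with non-finite time or DOT values are dropped with a warning giving
#' the count.
#'
#' @param path file path.
#' @param time_col,dot_col column names for time and DOT
#'   (defaults `"time_s"`, `"dot_pct"`).
#' @param sep field delimiter (default comma).
#' @param time_unit unit of the time column; converted to seconds.
#' @param dotstar saturation value passed to [dot_trace()].
#' @param reactor_id optional reactor identifier.
#' @return A [dot_trace()].
#' @export
read_dot_trace <- function(path, time_col = "time_s", dot_col = "dot_pct",
                           sep = ",", time_unit = "s", dotstar = 100,
                           reactor_id = NA_character_) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  for (col in c(time_col, dot_col))
    if (!col %in% names(raw))
      stop(sprintf("column '%s' not found in '%s'", col, path), call. = FALSE)
  time <- as.numeric(raw[[time_col]]) * time_unit_factor(time_unit)
  dot <- as.numeric(raw[[dot_col]])
  ok <- is.finite(time) & is.finite(dot)
  n_bad <- sum(!ok)
  if (n_bad > 0)
    warning(sprintf("dropped %d row(s) with non-finite values", n_bad),
            call. = FALSE)
  time <- time[ok]; dot <- dot[ok]
  if (anyDuplicated(time)) {
    dot <- as.numeric(tapply(dot, time, mean))
    time <- sort(unique(time))
  } else {
    o <- order(time)
    time <- time[o]; dot <- dot[o]
  }
  if (length(time) < 2L)
    stop(sprintf("'%s' has fewer than 2 valid rows", path), call. = FALSE)
  dot_trace(time, dot, dotstar = dotstar, reactor_id = reactor_id)
}

#' Read a feed schedule from a delimited text file
#'
#' @param path file path.
#' @param time_col,volume_col,conc_col column names
#'   (defaults `"time_s"`, `"volume_ul"`, `"conc_mg_ml"`).
#' @param sep field delimiter.
#' @param time_unit unit of the time column; converted to seconds.
#' @return A [feed_schedule()].
#' @export
read_feed_schedule <- function(path, time_col = "time_s",
                               volume_col = "volume_ul",
                               conc_col = "conc_mg_ml",
                               sep = ",", time_unit = "s") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  for (col in c(time_col, volume_col, conc_col))
    if (!col %in% names(raw))
      stop(sprintf("column '%s' not found in '%s'", col, path), call. = FALSE)
  feed_schedule(as.numeric(raw[[time_col]]) * time_unit_factor(time_unit),
                as.numeric(raw[[volume_col]]),
                as.numeric(raw[[conc_col]]))
}

#' Read an at-line sample table from a delimited text file
#'
#' Optional concentration columns may be blank (`NA`).
#'
#' @param path file path.
#' @param time_col,cx_col,cs_col,ca_col column names (defaults `"time_s"`,
#'   `"cx_mg_ml"`, `"cs_mg_ml"`, `"ca_mg_ml"`).
#' @param sep field delimiter.
#' @param time_unit unit of the time column; converted to seconds.
#' @return A [sample_table()].
#' @export
read_sample_table <- function(path, time_col = "time_s", cx_col = "cx_mg_ml",
                              cs_col = "cs_mg_ml", ca_col = "ca_mg_ml",
                              sep = ",", time_unit = "s") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!time_col %in% names(raw))
    stop(sprintf("column '%s' not found in '%s'", time_col, path),
         call. = FALSE)
  grab <- function(col) if (col %in% names(raw)) as.numeric(raw[[col]]) else NA_real_
  sample_table(as.numeric(raw[[time_col]]) * time_unit_factor(time_unit),
               cx = grab(cx_col), cs = grab(cs_col), ca = grab(ca_col))
}

#' Write a DOT trace to CSV
#' @param trace a `dot_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dot_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time, dot_pct = trace$dot),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a feed schedule to CSV
#' @param feeds a `feed_schedule`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feed_schedule <- function(feeds, path) {
  utils::write.csv(data.frame(time_s = feeds$time, volume_ul = feeds$volume,
                              conc_mg_ml = feeds$concentration),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a sample table to CSV
#' @param samples a `sample_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.csv(data.frame(time_s = samples$time, cx_mg_ml = samples$cx,
                              cs_mg_ml = samples$cs, ca_mg_ml = samples$ca),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a trace onto a uniform grid
#'
#' Linear interpolation from the first to the last timestamp.  The original
#' endpoints are preserved; if the span is not an integer multiple of `dt`
#' the last interval is shorter (the final point is the original endpoint).
#'
#' @param trace a `dot_trace`.
#' @param dt target sampling interval in seconds, > 0.
#' @return A uniformly sampled `dot_trace`.
#' @export
resample_uniform <- function(trace, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a single positive number", call. = FALSE)
  span <- trace$time[nrow(trace)] - trace$time[1L]
  if (dt > span)
    stop("`dt` is larger than the trace span", call. = FALSE)
  grid <- seq(trace$time[1L], trace$time[nrow(trace)], by = dt)
  # keep the original right endpoint so no signal is discarded
  if (grid[length(grid)] < trace$time[nrow(trace)] - 1e-9 * dt)
    grid <- c(grid, trace$time[nrow(trace)])
  y <- stats::approx(trace$time, trace$dot, xout = grid)$y
  out <- dot_trace(grid, y, dotstar = dotstar(trace),
                   reactor_id = attr(trace, "reactor_id"),
                   note = attr(trace, "note"))
  out
}

#' Smoothed first derivative of a DOT trace
#'
#' Local-polynomial (Savitzky-Golay) smoothed first derivative in % per
#' second.  The signal must be uniformly sampled.  Endpoints are handled by
#' the filter's one-sided startup/shutdown fits, so the result has the same
#' length as the input.
#'
#' @param trace a uniformly sampled `dot_trace`.
#' @param window filter window length in samples; odd, `3 <= window <= n`.
#' @param polyorder polynomial order, `< window`.
#' @return Numeric vector of dDOT/dt in %/s, same length as the trace.
#' @export
smooth_derivative <- function(trace, window = 11, polyorder = 2) {
  if (!is_uniform(trace))
    stop("trace is not uniformly sampled; call resample_uniform() first",
         call. = FALSE)
  n <- nrow(trace)
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L || window > n)
    stop("`window` must be odd and within [3, n]", call. = FALSE)
  if (polyorder >= window)
    stop("`polyorder` must be smaller than `window`", call. = FALSE)
  dt <- trace_dt(trace)
  signal::sgolayfilt(trace$dot, p = polyorder, n = window, m = 1, ts = dt)
}

#' Invert the first-order sensor lag
#'
#' Reconstructs the actual dissolved oxygen signal from the measured one via
#' `DOT = tau * dDOTm/dt + DOTm`, the algebraic inversion of the first-order
#' probe model `dDOTm/dt = (DOT - DOTm)/tau`.  The derivative is the
#' Savitzky-Golay estimate of [smooth_derivative()], so noise amplification
#' by the `tau *` term is controlled by the smoothing window.
#'
#' @param measured a uniformly sampled `dot_trace` of the probe signal.
#' @param sensor a [sensor_model()]; `tau = 0` returns the input unchanged.
#' @param window,polyorder passed to [smooth_derivative()].
#' @return A `dot_trace` with the delay-corrected signal.
#' @export
invert_sensor_delay <- function(measured, sensor = sensor_model(),
                                window = 11, polyorder = 2) {
  stopifnot(inherits(sensor, "sensor_model"))
  if (sensor$tau == 0) return(measured)
  deriv <- smooth_derivative(measured, window = window, polyorder = polyorder)
  dot_trace(measured$time, sensor$tau * deriv + measured$dot,
            dotstar = dotstar(measured),
            reactor_id = attr(measured, "reactor_id"),
            note = attr(measured, "note"))
}

#' Convert a per-hour rate constant to per-second
#' @param x rate in 1/h.
#' @return rate in 1/s.
#' @export
per_hour_to_per_second <- function(x) x / 3600

#' Convert a per-second rate constant to per-hour
#' @param x rate in 1/s.
#' @return rate in 1/h.
#' @export
per_second_to_per_hour <- function(x) x * 3600
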