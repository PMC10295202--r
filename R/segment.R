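#' Segmentation configuration
#'
#' Thresholds for the slope-classification state machine that labels the
#' pulse segments.  The steep-slope reference is estimated per run
#' ("training"): each feed-response window contributes its steepest smoothed
#' decline, `steep_slope_quantile` picks a reference slope from that
#' distribution, and `steep_fraction` of it becomes the steep/moderate
#' boundary `theta_steep`.  The flat band is symmetric around zero at
#' `flat_band_fraction * |theta_steep|`, so a slightly negative plateau
#' still counts as "flat" (second segments drift from slightly positive to
#' slightly negative slopes over a cultivation).
#'
#' @param steep_slope_quantile quantile of the per-pulse steepest-decline
#'   distribution used as the reference slope (default 0.5, the median).
#' @param steep_fraction fraction of the reference slope defining
#'   `theta_steep` (default 0.5).
#' @param flat_band_fraction half-width of the flat band as a fraction of
#'   `|theta_steep|` (default 0.15).
#' @param min_segment_duration minimum run duration in seconds; shorter
#'   slope runs are merged into their longer neighbour (default 4).
#' @param baseline_return_fraction fraction of the pre-pulse DOT at which
#'   the pulse is considered recovered (default 0.95).
#' @param window,polyorder Savitzky-Golay settings for the smoothed
#'   derivative (defaults 11 samples, order 2 at 1 s sampling).
#' @param response_horizon seconds after a feed within which a decline must
#'   start, otherwise the feed is flagged "no-response" (default 60).
#' @param refine sharpen segment boundaries by intersecting line fits to
#'   the adjacent segments (default `TRUE`; the raw class-transition
#'   boundaries are smeared by half the smoothing window).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(steep_slope_quantile = 0.5,
                                steep_fraction = 0.5,
                                flat_band_fraction = 0.15,
                                min_segment_duration = 4,
                                baseline_return_fraction = 0.95,
                                window = 11, polyorder = 2,
                                response_horizon = 60, refine = TRUE) {
  fr <- c(steep_slope_quantile, steep_fraction, flat_band_fraction,
          baseline_return_fraction)
  if (any(fr <= 0) || any(fr >= 1))
    stop("quantiles and fractions must lie strictly between 0 and 1",
         call. = FALSE)
  if (min_segment_duration <= 0)
    stop("`min_segment_duration` must be positive", call. = FALSE)
  structure(list(steep_slope_quantile = steep_slope_quantile,
                 steep_fraction = steep_fraction,
                 flat_band_fraction = flat_band_fraction,
                 min_segment_duration = min_segment_duration,
                 baseline_return_fraction = baseline_return_fraction,
                 window = window, polyorder = polyorder,
                 response_horizon = response_horizon, refine = refine),
            class = "segmentation_config")
}

#' Dilution ratio of a bolus
#'
#' @param volume_ul bolus volume in uL, > 0.
#' @param working_volume_ml reactor working volume in mL, > 0.
#' @return Dilution ratio in uL/mL.
#' @examples
#' dilution_ratio(5, 8)    # 0.625
#' dilution_ratio(7.5, 8)  # 0.9375
#' @export
dilution_ratio <- function(volume_ul, working_volume_ml) {
  if (any(volume_ul <= 0) || any(working_volume_ml <= 0))
    stop("volumes must be positive", call. = FALSE)
  volume_ul / working_volume_ml
}

# Slope thresholds trained on the whole run: one steepest decline per
# feed-response horizon, a quantile of those as reference.
train_thresholds <- function(trace, feeds, config, deriv) {
  dt <- trace_dt(trace)
  steepest <- vapply(seq_len(nrow(feeds)), function(i) {
    lo <- feeds$time[i]
    hi <- if (i < nrow(feeds)) min(feeds$time[i + 1L],
                                   lo + config$response_horizon)
          else lo + config$response_horizon
    idx <- which(trace$time >= lo & trace$time <= hi)
    if (!length(idx)) NA_real_ else min(deriv[idx])
  }, numeric(1))
  s_ref <- stats::quantile(steepest, probs = config$steep_slope_quantile,
                           na.rm = TRUE, names = FALSE)
  theta_steep <- config$steep_fraction * s_ref        # negative
  theta_flat <- config$flat_band_fraction * abs(theta_steep)
  list(steepest = steepest, theta_steep = theta_steep,
       theta_flat = theta_flat)
}

#' Detect feed-response pulse windows in a DOT trace
#'
#' One candidate window per feed event.  A window starts at the last sample
#' before the post-feed decline onset (the first sample whose smoothed
#' derivative drops below the flat band) and ends at baseline recovery --
#' the start of the final period in which DOT stays at or above
#' `baseline_return_fraction` times the pre-pulse value -- or at the next
#' feed event, whichever comes first (the window is then flagged
#' truncated).  Feeds with no detectable decline within
#' `response_horizon` are flagged "no-response".
#'
#' @param trace a uniformly sampled [dot_trace()].
#' @param feeds a [feed_schedule()] whose times lie within the trace span.
#' @param config a [segmentation_config()].
#' @return A list with `windows` (data frame: feed index, times, start/end
#'   sample indices, baseline, flags) and the trained `thresholds`.
#' @export
detect_pulses <- function(trace, feeds, config = segmentation_config()) {
  if (!is_uniform(trace))
    stop("trace must be uniformly sampled; call resample_uniform() first",
         call. = FALSE)
  if (!nrow(feeds)) stop("feed schedule is empty", call. = FALSE)
  if (min(feeds$time) < trace$time[1L] ||
      max(feeds$time) > trace$time[nrow(trace)])
    stop("feed times must lie within the trace span", call. = FALSE)
  deriv <- smooth_derivative(trace, config$window, config$polyorder)
  th <- train_thresholds(trace, feeds, config, deriv)
  n <- nrow(trace)
  # baseline and recovery decisions use a smoothed copy so that single
  # noise dips in the recovered plateau cannot stretch a window
  smooth <- signal::sgolayfilt(trace$dot, p = config$polyorder,
                               n = min(config$window, n - (1 - n %% 2L)),
                               m = 0)
  windows <- lapply(seq_len(nrow(feeds)), function(i) {
    t_feed <- feeds$time[i]
    t_limit <- if (i < nrow(feeds)) feeds$time[i + 1L]
               else trace$time[n]
    i_feed <- which(trace$time >= t_feed)[1L]
    i_horiz <- max(which(trace$time <= min(t_feed + config$response_horizon,
                                           t_limit)))
    onset_rel <- which(deriv[i_feed:i_horiz] < -th$theta_flat)
    if (!length(onset_rel))
      return(data.frame(feed = i, t_feed = t_feed, t_start = NA_real_,
                        t_end = NA_real_, i_start = NA_integer_,
                        i_end = NA_integer_, baseline = NA_real_,
                        no_response = TRUE, truncated = FALSE))
    i_onset <- i_feed + onset_rel[1L] - 1L
    i_start <- max(i_onset - 1L, 1L)
    baseline <- smooth[i_start]
    i_limit <- max(which(trace$time < t_limit - 1e-9), i_start + 1L)
    if (i == nrow(feeds)) i_limit <- n
    seg <- smooth[i_start:i_limit]
    thresh <- config$baseline_return_fraction * baseline
    below <- which(seg < thresh)
    if (!length(below) || max(below) == length(seg)) {
      # never recovered inside the window -> truncated by feed or trace end
      i_end <- i_limit
      truncated <- TRUE
    } else {
      i_end <- i_start + max(below)  # first sample of the final recovery
      truncated <- FALSE
    }
    data.frame(feed = i, t_feed = t_feed, t_start = trace$time[i_start],
               t_end = trace$time[i_end], i_start = i_start, i_end = i_end,
               baseline = baseline, no_response = FALSE,
               truncated = truncated)
  })
  list(windows = do.call(rbind, windows), thresholds = th, deriv = deriv)
}

# Run-length encode slope classes and merge runs shorter than the minimum
# segment duration into their longer neighbour.
merge_short_runs <- function(classes, min_len) {
  r <- rle(classes)
  repeat {
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_len)
    # never merge away the first or last run if it is the only DOWN/UP anchor
    if (!length(short)) break
    k <- short[which.min(r$lengths[short])]
    left <- if (k > 1L) r$lengths[k - 1L] else -1L
    right <- if (k < length(r$lengths)) r$lengths[k + 1L] else -1L
    r$values[k] <- if (left >= right) r$values[k - 1L] else r$values[k + 1L]
    cls <- inverse.rle(r)
    r <- rle(cls)
  }
  r
}

#' Segment one pulse window
#'
#' Classifies every sample of the window by its smoothed slope (steep
#' decline, moderate decline, flat, rise), run-length encodes the classes,
#' merges runs shorter than the minimum segment duration, and maps the
#' resulting down/neutral block structure onto the canonical segments:
#' the leading decline block is S1; if a flat/rising block followed by
#' another decline block precedes the final recovery, those become S2 and
#' S3; the final rising block is S4.  Pulses without an S2/S3 pair report
#' two segments.
#'
#' @param trace the full uniform [dot_trace()].
#' @param window one row of `detect_pulses()$windows`.
#' @param thresholds trained thresholds from [detect_pulses()].
#' @param deriv smoothed derivative of the whole trace.
#' @param config a [segmentation_config()].
#' @return An object of class `dot_pulse`: list with `segments` (data
#'   frame with per-segment metrics), `n_segments`, `dot_min`, window
#'   times and flags.  Degenerate windows yield `flag = "degenerate"`.
#' @export
segment_pulse <- function(trace, window, thresholds, deriv,
                          config = segmentation_config()) {
  dt <- trace_dt(trace)
  min_len <- max(2L, as.integer(ceiling(config$min_segment_duration / dt)))
  out <- list(feed = window$feed, t_feed = window$t_feed,
              t_start = window$t_start, t_end = window$t_end,
              baseline = window$baseline, truncated = window$truncated,
              no_response = isTRUE(window$no_response),
              flag = NA_character_, n_segments = 0L,
              dot_min = NA_real_, segments = NULL)
  class(out) <- "dot_pulse"
  if (out$no_response) { out$flag <- "no-response"; return(out) }
  idx <- window$i_start:window$i_end
  if (length(idx) < 2L * min_len) { out$flag <- "degenerate"; return(out) }
  d <- deriv[idx]
  cls <- ifelse(d > thresholds$theta_flat, "U",
                ifelse(d >= -thresholds$theta_flat, "F",
                       ifelse(d < thresholds$theta_steep, "D", "d")))
  # direction is what matters for the block structure; keep steep/moderate
  # distinction only implicitly (both are "down")
  dir <- ifelse(cls %in% c("D", "d"), "down", "neutral")
  r <- merge_short_runs(dir, min_len)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  blocks <- data.frame(dir = r$values, start = starts, end = ends)
  down <- which(blocks$dir == "down")
  if (!length(down)) { out$flag <- "degenerate"; return(out) }
  first_down <- down[1L]
  last_down <- down[length(down)]
  # boundaries in window-local sample indices
  if (last_down == nrow(blocks)) {
    # no recovery inside the window
    out$flag <- if (out$truncated) "truncated" else "degenerate"
    if (!out$truncated) return(out)
  }
  s1_end <- blocks$end[first_down]
  bounds <- if (last_down > first_down) {
    s2_end <- blocks$start[down[2L]] - 1L
    c(1L, s1_end, s2_end, blocks$end[last_down], length(idx))
  } else {
    c(1L, s1_end, length(idx))
  }
  labels <- if (length(bounds) == 5L) c("S1", "S2", "S3", "S4")
            else c("S1", "S4")
  if (isTRUE(config$refine))
    bounds <- refine_boundaries(trace, idx, bounds, config)
  segs <- lapply(seq_along(labels), function(k) {
    a <- idx[bounds[k]]; b <- idx[bounds[k + 1L]]
    segment_metrics(trace, a, b, labels[k])
  })
  out$segments <- do.call(rbind, segs)
  out$n_segments <- length(labels)
  out$dot_min <- min(trace$dot[idx])
  if (out$truncated && is.na(out$flag)) out$flag <- "truncated"
  out
}

# Sharpen segment boundaries: the slope-class transitions are smeared by
# half the smoothing window, so each boundary is moved to the intersection
# of straight lines fitted to the interiors of the two adjacent segments
# (for the pulse onset, to the pre-window baseline).  Movement is capped at
# the smoothing half-window; degenerate fits leave the boundary unchanged.
refine_boundaries <- function(trace, idx, bounds, config) {
  cap <- 3L
  dt <- trace_dt(trace)
  fit_line <- function(i_a, i_b) {
    # central portion of the segment, away from both smeared boundaries
    len <- i_b - i_a + 1L
    tr <- max(1L, ceiling(len * 0.3))
    a <- i_a + tr; b <- i_b - tr
    if (b - a < 2L) { a <- i_a + 1L; b <- i_b - 1L }
    if (b - a < 1L) return(NULL)
    sel <- idx[a:b]
    d <- data.frame(t = trace$time[sel], y = trace$dot[sel])
    stats::lm(y ~ t, data = d)
  }
  baseline_fit <- function() {
    i0 <- idx[1L]
    sel <- max(1L, i0 - 10L):i0
    if (length(sel) < 3L) return(NULL)
    d <- data.frame(t = trace$time[sel], y = trace$dot[sel])
    stats::lm(y ~ t, data = d)
  }
  segs <- cbind(utils::head(bounds, -1L), utils::tail(bounds, -1L))
  new <- bounds
  for (k in seq_len(nrow(segs))) {
    left <- if (k == 1L) baseline_fit()
            else fit_line(segs[k - 1L, 1L], segs[k - 1L, 2L])
    right <- fit_line(segs[k, 1L], segs[k, 2L])
    if (is.null(left) || is.null(right)) next
    cl <- stats::coef(left); cr <- stats::coef(right)
    dm <- cl[2L] - cr[2L]
    if (!is.finite(dm) || abs(dm) < 1e-12) next
    t_star <- (cr[1L] - cl[1L]) / dm
    b0 <- bounds[k]
    t0 <- trace$time[idx[b0]]
    # uncertainty of the intersection: prediction noise of both lines at the
    # boundary divided by the slope contrast; skip noisy intersections
    se <- sqrt(sum(vapply(list(left, right), function(f)
      stats::predict(f, newdata = data.frame(t = t0),
                     se.fit = TRUE)$se.fit^2, numeric(1))))
    if (!is.finite(se) || se / abs(dm) > 1.5 * dt) next
    shift <- round((t_star - t0) / dt)
    if (is.finite(shift) && abs(shift) <= cap) {
      cand <- b0 + shift
      lo <- if (k == 1L) 1L else new[k - 1L] + 1L
      hi <- bounds[k + 1L] - 1L
      new[k] <- min(max(cand, lo), hi)
    }
  }
  new
}

# Metrics of one labelled segment: duration, endpoint slope, area under the
# curve and the complementary depression area (trapezoidal rule).
segment_metrics <- function(trace, i_a, i_b, label) {
  tt <- trace$time[i_a:i_b]
  yy <- trace$dot[i_a:i_b]
  ds <- dotstar(trace)
  dur <- tt[length(tt)] - tt[1L]
  area <- trapz(tt, yy)
  data.frame(label = label, t_start = tt[1L], t_end = tt[length(tt)],
             dot_start = yy[1L], dot_end = yy[length(yy)],
             duration = dur,
             slope = (yy[length(yy)] - yy[1L]) / dur,
             area_under = area,
             area_depression = ds * dur - area)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1L) +
                                         utils::tail(y, -1L)) / 2)

#' @export
print.dot_pulse <- function(x, ...) {
  cat(sprintf("<dot_pulse> feed #%d at %.0f s: %d segment(s)%s\n",
              x$feed, x$t_feed, x$n_segments,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  if (!is.null(x$segments)) print(x$segments, digits = 4)
  invisible(x)
}

#' Detect and segment all pulses of a run
#'
#' Convenience wrapper: trains the slope thresholds, detects the
#' feed-response windows and segments each one.
#'
#' @param trace a uniformly sampled [dot_trace()].
#' @param feeds a [feed_schedule()].
#' @param config a [segmentation_config()].
#' @return An object of class `pulse_set`: list with `pulses` (list of
#'   [segment_pulse()] results), `windows`, `thresholds`.
#' @export
segment_trace <- function(trace, feeds, config = segmentation_config()) {
  det <- detect_pulses(trace, feeds, config)
  pulses <- lapply(seq_len(nrow(det$windows)), function(i)
    segment_pulse(trace, det$windows[i, ], det$thresholds, det$deriv,
                  config))
  structure(list(pulses = pulses, windows = det$windows,
                 thresholds = det$thresholds, config = config,
                 dotstar = dotstar(trace)),
            class = "pulse_set")
}

#' @export
print.pulse_set <- function(x, ...) {
  n_seg <- vapply(x$pulses, function(p) p$n_segments, integer(1))
  cat(sprintf(
    "<pulse_set> %d feed(s): %d four-segment, %d two-segment, %d flagged\n",
    length(x$pulses), sum(n_seg == 4L), sum(n_seg == 2L),
    sum(vapply(x$pulses, function(p) !is.na(p$flag) &&
                 p$flag != "truncated", logical(1)))))
  invisible(x)
}

#' Per-segment metrics of a pulse set as a data frame
#'
#' @param pulses a `pulse_set` from [segment_trace()].
#' @return Data frame with one row per segment (pulse id, label, times,
#'   duration in s, slope in %/s, areas in %*s) plus pulse-level flags.
#' @export
segments_df <- function(pulses) {
  rows <- lapply(pulses$pulses, function(p) {
    if (is.null(p$segments)) return(NULL)
    cbind(pulse = p$feed, p$segments,
          n_segments = p$n_segments,
          truncated = p$truncated,
          flag = if (is.na(p$flag)) "" else p$flag)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pulse = integer(), label = character(),
                      t_start = numeric(), t_end = numeric(),
                      dot_start = numeric(), dot_end = numeric(),
                      duration = numeric(), slope = numeric(),
                      area_under = numeric(), area_depression = numeric(),
                      n_segments = integer(), truncated = logical(),
                      flag = character())
  rownames(out) <- NULL
  out
}

#' Whole-pulse area metrics
#'
#' Area under the DOT curve and the complementary depression area over the
#' full pulse window; the depression area integrates `DOT* - DOT`, the
#' driving force of the oxygen transfer, and so measures the oxygen
#' deposited into the medium over the pulse.
#'
#' @param trace the uniform [dot_trace()] the pulse was segmented from.
#' @param pulse a `dot_pulse`.
#' @return A one-row data frame with `duration`, `area_under`,
#'   `area_depression`.
#' @export
pulse_area <- function(trace, pulse) {
  if (is.null(pulse$segments)) return(NULL)
  i_a <- which(trace$time >= pulse$t_start)[1L]
  i_b <- utils::tail(which(trace$time <= pulse$t_end), 1L)
  m <- segment_metrics(trace, i_a, i_b, "pulse")
  m[, c("duration", "area_under", "area_depression")]
}

#' Correlate a segment metric with a process covariate
#'
#' Ordinary least-squares line plus the Pearson correlation coefficient and
#' the coefficient of determination.
#'
#' @param metric numeric vector (e.g. third-segment durations).
#' @param covariate numeric vector of equal length (e.g. dilution ratio per
#'   biomass unit).
#' @return A list with `r`, `r_squared`, `slope`, `intercept`, `n`, and
#'   `flag` (`"zero-variance-metric"` with `r = 0` when the metric does not
#'   vary).  A zero-variance covariate is an error.
#' @export
correlate_metrics <- function(metric, covariate) {
  ok <- is.finite(metric) & is.finite(covariate)
  x <- covariate[ok]; y <- metric[ok]
  if (length(x) < 3L)
    stop("need at least 3 paired finite observations", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("covariate has zero variance; correlation undefined", call. = FALSE)
  if (stats::sd(y) == 0) {
    fit <- stats::lm(y ~ x)
    return(list(r = 0, r_squared = 0,
                slope = 0, intercept = mean(y), n = length(x),
                flag = "zero-variance-metric"))
  }
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  list(r = r, r_squared = r^2,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       n = length(x), flag = NA_character_)
}
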