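#' Closed-form KLa from a recovery segment
#'
#' Analytical solution of the pure-transfer balance
#' `dDOT/dt = (DOT* - DOT) * KLa` between two points of the recovery:
#' `KLa = -log((DOT* - DOT_end) / (DOT* - DOT_min)) / dT`.
#'
#' @param dot_min DOT at the lower (earlier) point, %.
#' @param dot_end DOT at the upper (later) point, %; must satisfy
#'   `dot_min < dot_end < dotstar`.
#' @param dt4 time between the two points, seconds.
#' @param dotstar saturation value, %.
#' @return KLa in 1/h.
#' @examples
#' kla_closed_form(20, 90, 36)  # ~207.9 1/h
#' @export
kla_closed_form <- function(dot_min, dot_end, dt4, dotstar = 100) {
  if (any(dot_end >= dotstar))
    stop("DOT_end must be strictly below saturation (singular recovery)",
         call. = FALSE)
  if (any(dot_min >= dot_end))
    stop("DOT_min must be below DOT_end", call. = FALSE)
  -log((dotstar - dot_end) / (dotstar - dot_min)) / (dt4 / 3600)
}

#' Estimate KLa from the fourth segment of a pulse
#'
#' Both methods solve the pure-transfer balance of the recovery,
#' `DOT(t) = DOT* - A exp(-KLa t)`.  `method = "endpoints"` evaluates the
#' closed form [kla_closed_form()] between two points: the segment start
#' (or the first sample at or above `lower_fraction * DOT*`) and the first
#' sample reaching `end_fraction * DOT*` (stopping short of saturation
#' avoids the logarithmic singularity).  `method = "fit"` (default)
#' least-squares fits the same exponential over the recovery, anchored
#' where a smoothed copy of the signal first climbs past
#' `anchor_fraction * DOT*` -- above that level residual acetate oxidation
#' no longer disturbs the balance -- and extending `span_factor` time
#' constants into the post-pulse tail (`t_limit` caps the window at the
#' next feed).  The closed form supplies the initial rate for the fit.
#'
#' @param trace the (delay-corrected) uniform [dot_trace()] the pulse was
#'   segmented from.
#' @param pulse a `dot_pulse` with an untruncated S4 segment.
#' @param end_fraction upper closed-form point as a fraction of DOT*
#'   (default 0.95).
#' @param lower_fraction optional lower closed-form point as a fraction of
#'   DOT*.
#' @param method `"fit"` (exponential least squares; default) or
#'   `"endpoints"` (two-point closed form).
#' @param t_limit latest time the fit may use, seconds (set this to just
#'   before the next feed; the acausal smoothing filter corrupts the
#'   corrected signal during the last filter window before a feed).
#' @param anchor_fraction fit anchor as a fraction of DOT* (default 0.87).
#' @param span_factor fit window length in recovery time constants
#'   (default 5).
#' @return KLa in 1/h, or `NA` with a warning when the segment is unusable.
#' @export
estimate_kla <- function(trace, pulse, end_fraction = 0.95,
                         lower_fraction = NULL,
                         method = c("fit", "endpoints"), t_limit = Inf,
                         anchor_fraction = 0.87, span_factor = 5) {
  method <- match.arg(method)
  if (is.null(pulse$segments) || !"S4" %in% pulse$segments$label)
    return(NA_real_)
  if (isTRUE(pulse$truncated)) {
    warning("pulse is truncated by the next feed; KLa not estimated",
            call. = FALSE)
    return(NA_real_)
  }
  ds <- dotstar(trace)
  s4 <- pulse$segments[pulse$segments$label == "S4", ]
  idx <- which(trace$time >= s4$t_start &
                 trace$time <= min(t_limit, max(trace$time)))
  y <- trace$dot[idx]; tt <- trace$time[idx]
  n <- length(y)
  if (n < 5L) return(NA_real_)
  # closed form between the raw crossings of the two fractions
  in_seg <- tt <= s4$t_end
  i_lo <- 1L
  if (!is.null(lower_fraction)) {
    cand <- which(y >= lower_fraction * ds & in_seg)
    if (length(cand) && cand[1L] < sum(in_seg)) i_lo <- cand[1L]
  }
  i_hi <- which(y >= end_fraction * ds & y < ds & in_seg)
  i_hi <- if (length(i_hi)) i_hi[1L] else sum(in_seg)
  valid <- i_hi > i_lo && y[i_hi] < ds && y[i_lo] < y[i_hi]
  k0 <- if (valid) kla_closed_form(y[i_lo], y[i_hi], tt[i_hi] - tt[i_lo], ds)
        else 100   # neutral initial rate when the crossings are unusable
  if (method == "endpoints") return(if (valid) k0 else NA_real_)
  # smoothed copy gives a noise-robust anchor for the fit window
  w <- min(21L, if (n %% 2L) n else n - 1L)
  ys <- if (w >= 5L) signal::sgolayfilt(y, p = 2, n = w, m = 0) else y
  imin <- which.min(ys)
  i0 <- which(seq_len(n) > imin & ys >= anchor_fraction * ds)[1L]
  if (is.na(i0)) return(NA_real_)
  span_s <- min(max(span_factor / k0 * 3600, 60), 400)
  sel <- which(tt >= tt[i0] & tt <= tt[i0] + span_s)
  if (length(sel) < 8L) return(NA_real_)
  dep <- ds - y[sel]
  ts <- tt[sel] - tt[sel[1L]]
  fit <- tryCatch(
    stats::nls(dep ~ A * exp(-k * ts),
               start = list(A = max(dep[1L], 0.5), k = k0 / 3600),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(k0)
  k <- unname(stats::coef(fit)["k"]) * 3600
  if (k <= 0) k0 else k
}

#' Estimate the specific oxygen uptake rate from a decline segment
#'
#' Rearranged oxygen balance over the first (or third) segment:
#' `qO2 = ((DOT* - DOT) * KLa - dDOT/dt) / (H * Cx)` -- the transfer into
#' the medium minus the accumulation, per unit biomass.  The segment-mean
#' DOT and mean slope are used (the mean is less noise-sensitive than the
#' printed endpoint form; set `use = "endpoint"` for the latter).  A
#' fraction of samples at each segment boundary can be trimmed, because
#' the metabolic transition is not resolved exactly by the segmentation.
#'
#' @param trace delay-corrected uniform [dot_trace()].
#' @param pulse a `dot_pulse`.
#' @param cx biomass concentration near the pulse, mg/mL (g/L).
#' @param reactor a [reactor_params()] (fields `kla`, `h`, `dotstar`).
#' @param kla KLa in 1/h (default: the reactor value; pass a per-run
#'   estimate from [estimate_kla()]).
#' @param segment `"S1"` (default) or `"S3"`.
#' @param use `"mean"` (segment-mean DOT) or `"endpoint"` (DOT at the
#'   segment end).
#' @param trim fraction of the segment trimmed at each boundary
#'   (default 0.1).
#' @return A list with `qo2` (g O2/(g DCW h)) and `our` (g O2/(L h)), or
#'   `NA`s when the segment is absent.
#' @export
estimate_qo2 <- function(trace, pulse, cx, reactor, kla = reactor$kla,
                         segment = c("S1", "S3"), use = c("mean", "endpoint"),
                         trim = 0.1) {
  segment <- match.arg(segment); use <- match.arg(use)
  if (is.null(pulse$segments) || !segment %in% pulse$segments$label ||
      !is.finite(cx))
    return(list(qo2 = NA_real_, our = NA_real_))
  if (cx <= 0) stop("`cx` must be positive", call. = FALSE)
  ds <- dotstar(trace)
  sg <- pulse$segments[pulse$segments$label == segment, ]
  idx <- which(trace$time >= sg$t_start & trace$time <= sg$t_end)
  if (length(idx) >= 5L && trim > 0) {
    k <- floor(length(idx) * trim)
    if (2L * k < length(idx) - 2L) idx <- idx[(1L + k):(length(idx) - k)]
  }
  tt <- trace$time[idx]; y <- trace$dot[idx]
  dur_h <- (tt[length(tt)] - tt[1L]) / 3600
  slope_h <- (y[length(y)] - y[1L]) / dur_h          # %/h
  dot_ref <- if (use == "mean") mean(y) else y[length(y)]
  qo2 <- ((ds - dot_ref) * kla - slope_h) / (reactor$h * cx)
  list(qo2 = max(qo2, 0), our = max(qo2, 0) * cx)
}

#' Maximum specific oxygen uptake rate
#'
#' The instantaneous glucose excess after a bolus drives the cell to its
#' maximum oxygen uptake, so the maximum over the per-pulse first-segment
#' estimates is taken as qO2max.
#'
#' @param qo2 numeric vector of per-pulse qO2 estimates, g/(g h).
#' @return A list with `qo2max`, `mean`, `sd`, `n`.
#' @export
estimate_qo2max <- function(qo2) {
  qo2 <- qo2[is.finite(qo2)]
  if (!length(qo2)) stop("no finite qO2 estimates", call. = FALSE)
  list(qo2max = max(qo2), mean = mean(qo2),
       sd = if (length(qo2) > 1L) stats::sd(qo2) else 0, n = length(qo2))
}

#' Oxygen-on-glucose yield from a two-segment pulse
#'
#' For a pulse with only a decline and a recovery (no adaptation, no
#' separate acetate-oxidation segment) and equal start and end values, the
#' oxygen delivered over the pulse equals the oxygen consumed, so
#' `YO2/S = V * KLa * integral(DOT* - DOT) dt / H / (Fs * Cs_in)`.
#' The estimator assumes equal start and end values; the pulse window ends
#' at the configured recovery fraction (typically 95% of baseline), so the
#' analytic completion term `V * (DOT_start - DOT_end)/H` -- the transfer
#' integral of the remaining pure-transfer recovery -- closes the balance
#' exactly.  `tol` therefore only rejects windows that end far below the
#' pre-pulse level (e.g. interrupted recoveries).
#'
#' @param trace delay-corrected uniform [dot_trace()].
#' @param pulse a two-segment `dot_pulse`.
#' @param feed_volume bolus volume, uL.
#' @param feed_conc feed glucose concentration, mg/mL.
#' @param reactor a [reactor_params()].
#' @param kla KLa in 1/h.
#' @param tol maximum allowed |start - end| DOT difference, % (default 8).
#' @return YO2/S in g/g, or `NA` when the pulse start/end differ by more
#'   than `tol`.
#' @export
estimate_yo2s <- function(trace, pulse, feed_volume, feed_conc = 600,
                          reactor, kla = reactor$kla, tol = 8) {
  if (is.null(pulse$segments)) return(NA_real_)
  if (pulse$n_segments != 2L)
    stop("YO2/S estimation applies to two-segment pulses only; ",
         "use estimate_yo2a() for four-segment pulses", call. = FALSE)
  idx <- which(trace$time >= pulse$t_start & trace$time <= pulse$t_end)
  tt <- trace$time[idx]; y <- trace$dot[idx]
  if (abs(y[1L] - y[length(y)]) > tol) return(NA_real_)
  ds <- dotstar(trace)
  area_h <- trapz(tt / 3600, ds - y)                 # %*h
  v_l <- reactor$v / 1000
  o2_g <- v_l * (kla * area_h + (y[1L] - y[length(y)])) / reactor$h
  feed_g <- feed_volume * feed_conc / 1e6            # uL * mg/mL -> g
  max(o2_g, 0) / feed_g
}

#' Oxygen-on-acetate yield from a four-segment pulse
#'
#' The oxygen spent on acetate is the transfer integral from the start of
#' the third segment until the signal first returns to its value at that
#' start (following the recovery into the fourth segment; the remainder is
#' completed analytically if the window ends first).  The acetate mass is
#' the glucose fed minus the oxidatively consumed glucose, converted with
#' the acetate-on-glucose yield `YA/S`.  Two routes to the oxidized
#' glucose are offered: `method = "balance"` (default) takes it from the
#' oxygen book-keeping of the pulse itself,
#' `(O2_total - O2_acetate) / YO2S`, which remains valid when oxygen
#' limitation throttles the uptake during deep pulses;
#' `method = "kinetic"` evaluates the critical-rate product
#' `qs_ox_max * Cx * V * dT1` over the measured first-segment duration.
#'
#' @param trace delay-corrected uniform [dot_trace()].
#' @param pulse a four-segment `dot_pulse`.
#' @param feed_volume bolus volume, uL.
#' @param feed_conc feed concentration, mg/mL.
#' @param reactor a [reactor_params()].
#' @param kla KLa in 1/h.
#' @param yo2s oxygen-on-glucose yield used by the balance route, g/g.
#' @param qs_ox_max critical oxidative glucose uptake rate, g/(g h), used
#'   by the kinetic route.
#' @param cx biomass concentration near the pulse, mg/mL (kinetic route).
#' @param yas acetate-on-glucose yield, g/g (default 0.667).
#' @param method `"balance"` or `"kinetic"` (see above).
#' @return YO2/A in g/g.  Non-positive computed acetate mass is an error
#'   (such a pulse should not have developed four segments).
#' @export
estimate_yo2a <- function(trace, pulse, feed_volume, feed_conc = 600,
                          reactor, kla = reactor$kla, yo2s = NULL,
                          qs_ox_max = NULL, cx = NULL, yas = 0.667,
                          method = c("balance", "kinetic")) {
  method <- match.arg(method)
  if (is.null(pulse$segments) || pulse$n_segments != 4L)
    stop("YO2/A estimation needs a four-segment pulse", call. = FALSE)
  ds <- dotstar(trace)
  s3 <- pulse$segments[pulse$segments$label == "S3", ]
  idx <- which(trace$time >= s3$t_start & trace$time <= pulse$t_end)
  tt <- trace$time[idx]; y <- trace$dot[idx]
  ref <- y[1L]                                       # DOT at t3_start
  after_min <- seq_along(y) > which.min(y)
  back <- which(after_min & y >= ref)
  if (length(back)) {
    i_ext <- back[1L]
    area_h <- trapz(tt[1:i_ext] / 3600, ds - y[1:i_ext])
    completion <- 0
  } else {
    # window ends before the signal regains the S3 start level: finish the
    # pure-transfer part analytically
    area_h <- trapz(tt / 3600, ds - y)
    completion <- ref - y[length(y)]
  }
  v_l <- reactor$v / 1000
  o2_ace_g <- max(v_l * (kla * area_h + completion) / reactor$h, 0)
  feed_g <- feed_volume * feed_conc / 1e6
  oxidized_g <- if (method == "balance") {
    if (is.null(yo2s) || !is.finite(yo2s) || yo2s <= 0)
      stop("the balance route needs a positive `yo2s`", call. = FALSE)
    jdx <- which(trace$time >= pulse$t_start & trace$time <= pulse$t_end)
    ta <- trace$time[jdx]; ya <- trace$dot[jdx]
    o2_tot_g <- v_l * (kla * trapz(ta / 3600, ds - ya) +
                         (ya[1L] - ya[length(ya)])) / reactor$h
    (o2_tot_g - o2_ace_g) / yo2s
  } else {
    if (is.null(qs_ox_max) || is.null(cx) || !is.finite(cx) || cx <= 0)
      stop("the kinetic route needs `qs_ox_max` and a positive `cx`",
           call. = FALSE)
    s1 <- pulse$segments[pulse$segments$label == "S1", ]
    qs_ox_max * cx * v_l * (s1$duration / 3600)
  }
  acetate_g <- (feed_g - oxidized_g) * yas
  if (acetate_g <= 0)
    stop("computed acetate mass is non-positive; pulse is inconsistent ",
         "with four segments", call. = FALSE)
  o2_ace_g / acetate_g
}

# Nearest at-line sample (by time) with a finite biomass value, or NA when
# none lies within the pairing window.
nearest_cx <- function(t, samples, window) {
  if (is.null(samples) || !nrow(samples)) return(NA_real_)
  ok <- is.finite(samples$cx)
  if (!any(ok)) return(NA_real_)
  dt <- abs(samples$time[ok] - t)
  if (min(dt) > window) return(NA_real_)
  samples$cx[ok][which.min(dt)]
}

#' Retrieve reactor and cell-physiological parameters from a DOT run
#'
#' The full retrieval workflow: sensor-lag inversion, pulse detection and
#' segmentation, then per-pulse parameter estimation -- KLa from the
#' recovery segments of untruncated pulses, qO2 (and OUR) from first
#' segments of pulses near a biomass sample, qO2max as their maximum,
#' YO2/S from two-segment pulses, and YO2/A from four-segment pulses near
#' a biomass sample.  Stage-level failures are recorded per pulse and the
#' workflow continues.
#'
#' @param trace a [dot_trace()] of the measured signal (resampled to a
#'   uniform grid if it is not already uniform).
#' @param feeds a [feed_schedule()].
#' @param samples an optional [sample_table()] with biomass values.
#' @param reactor a [reactor_params()].
#' @param config a [segmentation_config()].
#' @param sample_window pairing half-window between pulses and biomass
#'   samples, seconds (default 900 s = 15 min).
#' @param kla_lower_fraction lower fit point for [estimate_kla()]
#'   (default 0.8).
#' @param yas acetate-on-glucose yield used by the YO2/A stage.
#' @param dt resampling interval when the trace is not uniform, seconds.
#' @return An object of class `physio_estimate`: list with `summary` (one
#'   row per parameter: estimate, mean, sd, n), `per_pulse` (data frame of
#'   per-pulse values), `pulses` (the `pulse_set`), and `qs_ox_critical`
#'   (qO2max/YO2S, the overflow switching condition).
#' @export
run_workflow <- function(trace, feeds, samples = NULL,
                         reactor = reactor_params(),
                         config = segmentation_config(),
                         sample_window = 900, kla_lower_fraction = 0.8,
                         yas = 0.667, dt = 1) {
  if (!is_uniform(trace)) trace <- resample_uniform(trace, dt)
  corrected <- invert_sensor_delay(trace, sensor_model(reactor$tau),
                                   window = config$window,
                                   polyorder = config$polyorder)
  pulses <- segment_trace(corrected, feeds, config)
  n <- length(pulses$pulses)
  per <- data.frame(pulse = seq_len(n), n_segments = NA_integer_,
                    kla = NA_real_, cx = NA_real_, qo2 = NA_real_,
                    our = NA_real_, yo2s = NA_real_, yo2a = NA_real_,
                    note = "")
  guard <- config$window * trace_dt(corrected) + 4
  for (i in seq_len(n)) {
    p <- pulses$pulses[[i]]
    per$n_segments[i] <- p$n_segments
    if (!is.na(p$flag) && p$flag %in% c("no-response", "degenerate")) {
      per$note[i] <- p$flag
      next
    }
    if (!p$truncated) {
      t_lim <- if (p$feed < nrow(feeds)) feeds$time[p$feed + 1L] - guard
               else max(corrected$time)
      per$kla[i] <- suppressWarnings(
        estimate_kla(corrected, p, lower_fraction = kla_lower_fraction,
                     method = "fit", t_limit = t_lim))
    }
    per$cx[i] <- nearest_cx(p$t_feed, samples, sample_window)
  }
  kla_vals <- per$kla[is.finite(per$kla)]
  kla_run <- if (length(kla_vals)) mean(kla_vals) else reactor$kla
  # plausibility envelope for stirred minibioreactor systems
  if (kla_run < 20 || kla_run > 1440)
    warning(sprintf("estimated KLa (%.0f 1/h) is outside the plausible ",
                    kla_run), "range [20, 1440] 1/h for these reactors",
            call. = FALSE)
  for (i in seq_len(n)) {
    p <- pulses$pulses[[i]]
    if (!is.na(p$flag) && p$flag %in% c("no-response", "degenerate")) next
    if (is.finite(per$cx[i])) {
      q <- estimate_qo2(corrected, p, per$cx[i], reactor, kla = kla_run)
      per$qo2[i] <- q$qo2; per$our[i] <- q$our
    }
    if (p$n_segments == 2L && !p$truncated)
      per$yo2s[i] <- tryCatch(
        estimate_yo2s(corrected, p, feeds$volume[p$feed],
                      feeds$concentration[p$feed], reactor, kla = kla_run),
        error = function(e) NA_real_)
  }
  qo2_vals <- per$qo2[is.finite(per$qo2)]
  qo2max <- if (length(qo2_vals)) estimate_qo2max(qo2_vals) else NULL
  yo2s_vals <- per$yo2s[is.finite(per$yo2s)]
  yo2s_mean <- if (length(yo2s_vals)) mean(yo2s_vals) else NA_real_
  qs_ox_max <- if (!is.null(qo2max) && is.finite(yo2s_mean))
    qo2max$qo2max / yo2s_mean else NA_real_
  if (is.finite(yo2s_mean)) {
    for (i in seq_len(n)) {
      p <- pulses$pulses[[i]]
      if (p$n_segments == 4L && !p$truncated)
        per$yo2a[i] <- tryCatch(
          estimate_yo2a(corrected, p, feeds$volume[p$feed],
                        feeds$concentration[p$feed], reactor, kla = kla_run,
                        yo2s = yo2s_mean, yas = yas),
          error = function(e) NA_real_)
    }
  }
  agg <- function(x, est = NULL) {
    x <- x[is.finite(x)]
    data.frame(estimate = if (!is.null(est)) est else
                 if (length(x)) mean(x) else NA_real_,
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
               n = length(x))
  }
  summary <- rbind(
    kla = agg(per$kla),
    qo2max = agg(per$qo2, est = if (is.null(qo2max)) NA_real_ else
      qo2max$qo2max),
    yo2s = agg(per$yo2s),
    yo2a = agg(per$yo2a),
    our = agg(per$our),
    qo2 = agg(per$qo2))
  summary <- cbind(parameter = rownames(summary), summary)
  rownames(summary) <- NULL
  structure(list(summary = summary, per_pulse = per, pulses = pulses,
                 qs_ox_critical = qs_ox_max, kla_run = kla_run,
                 corrected = corrected),
            class = "physio_estimate")
}

#' @export
print.physio_estimate <- function(x, ...) {
  cat("<physio_estimate>\n")
  s <- x$summary
  s$lo <- s$mean - s$sd; s$hi <- s$mean + s$sd
  print(s[, c("parameter", "estimate", "lo", "hi", "n")], digits = 3,
        row.names = FALSE)
  if (is.finite(x$qs_ox_critical))
    cat(sprintf("overflow switching condition qs_ox_critical = %.3f g/(g h)\n",
                x$qs_ox_critical))
  invisible(x)
}
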