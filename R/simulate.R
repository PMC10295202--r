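#' Cell-physiological parameters for the overflow-metabolism model
#'
#' Defaults correspond to the mid-range estimates retrieved from the
#' reference reactor run (qO2max = 0.16 g/(g h), YO2/S = 0.075 g/g,
#' YO2/A = 0.15 g/g) together with kinetic constants chosen so that a
#' single-bolus volume sweep at 10 mg/mL biomass in 8 mL working volume
#' develops the second and third pulse segments at feed volumes above 5 uL.
#' `qs_max` is the calibration knob for that threshold: it controls the
#' overflow fraction of the glucose flux, because the oxidative share is
#' capped at `qo2max / yo2s`.
#'
#' @param qo2max maximum biomass-specific oxygen uptake rate, g O2/(g DCW h).
#' @param qs_max maximum total glucose uptake capacity, g S/(g h); must
#'   exceed `qo2max / yo2s` so overflow is possible.
#' @param ks glucose Monod constant, g/L.  Small by design: bolus feeding
#'   keeps glucose far above `ks` for nearly the whole first segment, and a
#'   small `ks` gives the abrupt glucose exhaustion that the event-driven
#'   state switch assumes.
#' @param ka acetate Monod constant, g/L.
#' @param ko oxygen-limitation Monod constant in % DOT applied to the
#'   oxidative fluxes; set to 0 to disable the oxygen factor.
#' @param qa_max maximum specific acetate uptake rate, g A/(g h).
#' @param yo2s oxygen-on-glucose yield, g/g.
#' @param yo2a oxygen-on-acetate yield, g/g.
#' @param yas acetate-on-overflowed-glucose yield, g/g.
#' @param yxs biomass yield on oxidized glucose, g/g.
#' @param yxa biomass yield on acetate, g/g.
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(qo2max = 0.16, qs_max = 3.95, ks = 0.01, ka = 0.01,
                        ko = 1, qa_max = 0.7, yo2s = 0.075, yo2a = 0.15,
                        yas = 0.667, yxs = 0.5, yxa = 0.4) {
  p <- list(qo2max = qo2max, qs_max = qs_max, ks = ks, ka = ka, ko = ko,
            qa_max = qa_max, yo2s = yo2s, yo2a = yo2a, yas = yas,
            yxs = yxs, yxa = yxa)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L, logical(1))
  if (!all(num)) stop("all cell parameters must be single numbers",
                      call. = FALSE)
  if (any(unlist(p[setdiff(names(p), "ko")]) <= 0) || ko < 0)
    stop("cell parameters must be positive (`ko` may be 0)", call. = FALSE)
  if (qs_max <= qo2max / yo2s)
    stop("`qs_max` must exceed the critical oxidative capacity qo2max/yo2s ",
         "(no overflow would ever occur)", call. = FALSE)
  structure(p, class = "cell_params")
}

#' Critical (maximum oxidative) glucose uptake rate
#'
#' The overflow switching condition: glucose uptake beyond
#' `qo2max / yo2s` g/(g h) is shunted to acetate.
#'
#' @param cell a [cell_params()].
#' @return qs_ox_critical in g/(g h).
#' @export
qs_ox_critical <- function(cell) cell$qo2max / cell$yo2s

#' Adaptation-state parameters
#'
#' The adaptation state is the transient pause of metabolic activity
#' between glucose exhaustion and full-capacity acetate oxidation.  Its
#' duration is either a constant (`mode = "constant"`) or scales with the
#' accumulated acetate and inversely with biomass
#' (`mode = "variable"`, see [adaptation_time()]).  `mode = "none"`
#' disables the state entirely.
#'
#' @param mode one of `"variable"`, `"constant"`, `"none"`.
#' @param dt_const adaptation duration in seconds for `mode = "constant"`.
#' @param rt reduction factor in \[0, 1\]; 1 means all uptake rates are
#'   fully paused during adaptation.
#' @param t_adap_max maximum adaptation time in seconds (reached at
#'   `ca_max` acetate and `cx_max` biomass).
#' @param ca_max reference maximum acetate concentration, mg/mL.
#' @param cx_max reference maximum biomass concentration, mg/mL.
#' @param ca_threshold acetate concentration above which the adaptation
#'   state is entered at glucose exhaustion, mg/mL.
#' @return An object of class `adaptation_params`.
#' @export
adaptation_params <- function(mode = c("variable", "constant", "none"),
                              dt_const = 30, rt = 1, t_adap_max = 60,
                              ca_max = 0.5, cx_max = 25, ca_threshold = 0.1) {
  mode <- match.arg(mode)
  if (rt < 0 || rt > 1) stop("`rt` must lie in [0, 1]", call. = FALSE)
  if (any(c(dt_const, t_adap_max, ca_max, cx_max, ca_threshold) < 0))
    stop("adaptation parameters must be non-negative", call. = FALSE)
  structure(list(mode = mode, dt_const = dt_const, rt = rt,
                 t_adap_max = t_adap_max, ca_max = ca_max, cx_max = cx_max,
                 ca_threshold = ca_threshold),
            class = "adaptation_params")
}

#' Reactor and oxygen-transfer parameters
#'
#' `h` is the Henry-derived conversion between dissolved-oxygen mass
#' concentration and % air saturation: `h = dotstar / c_o2_sat`
#' (% per g O2/L), with `c_o2_sat` the dissolved O2 concentration at air
#' saturation (about 0.007 g/L for warm cultivation media).
#'
#' @param v working volume in mL.
#' @param dotstar saturation value DOT* in %.
#' @param kla volumetric oxygen transfer coefficient in 1/h.
#' @param tau sensor time constant in seconds.
#' @param c_o2_sat dissolved O2 concentration at air saturation, g/L.
#' @return An object of class `reactor_params` with derived field `h`.
#' @export
reactor_params <- function(v = 8, dotstar = 100, kla = 250, tau = 36,
                           c_o2_sat = 0.007) {
  if (any(c(v, dotstar, kla, c_o2_sat) <= 0) || tau < 0)
    stop("reactor parameters must be positive (`tau` may be 0)",
         call. = FALSE)
  structure(list(v = v, dotstar = dotstar, kla = kla, tau = tau,
                 c_o2_sat = c_o2_sat, h = dotstar / c_o2_sat),
            class = "reactor_params")
}

#' Adaptation-state duration
#'
#' Variable adaptation time: `dt = t_adap_max * (CA/ca_max) * (cx_max/Cx)`
#' seconds.  More accumulated acetate prolongs the pause; more biomass
#' shortens it.
#'
#' @param ca acetate concentration at glucose exhaustion, mg/mL.
#' @param cx biomass concentration, mg/mL, > 0.
#' @param adapt an [adaptation_params()] (fields `t_adap_max`, `ca_max`,
#'   `cx_max` are used).
#' @return Duration in seconds.
#' @examples
#' adaptation_time(0.5, 25, adaptation_params())   # 60 s
#' adaptation_time(0.25, 12.5, adaptation_params())  # also 60 s
#' @export
adaptation_time <- function(ca, cx, adapt = adaptation_params()) {
  if (any(cx <= 0)) stop("`cx` must be positive", call. = FALSE)
  if (any(ca < 0)) stop("`ca` must be non-negative", call. = FALSE)
  adapt$t_adap_max * (ca / adapt$ca_max) * (adapt$cx_max / cx)
}

#' Specific uptake and growth rates in a given metabolic state
#'
#' State I (glucose oxidation with overflow): total uptake follows Monod
#' kinetics in glucose, the oxidative share is capped at the critical rate
#' `qo2max/yo2s` (times the optional oxygen factor `DOT/(DOT+ko)`), and the
#' excess is overflowed to acetate.  State II (adaptation): the acetate
#' pathway rates scaled by `1 - rt` (with the default `rt = 1`, a complete
#' pause).  State III (acetate oxidation): acetate is consumed at
#' `qa_max * CA/(CA+ka)`, capped at the oxygen-equivalent `qo2max/yo2a`.
#' State IV (static): all rates are zero.
#'
#' @param state one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param cs,ca,cx glucose, acetate, biomass concentrations in mg/mL.
#' @param dot dissolved oxygen in %, used by the oxygen factor.
#' @param cell a [cell_params()].
#' @param adapt an [adaptation_params()] (used for `rt` in state II).
#' @param growth if `FALSE` the growth rate is reported as 0 (biomass
#'   change is negligible on single-pulse time scales).
#' @return A list with `qs_ox`, `qs_of`, `qa_ox` (g/(g h)), `qo2`
#'   (g O2/(g h)) and `mu` (1/h).
#' @export
metabolic_rates <- function(state, cs, ca, cx, dot, cell = cell_params(),
                            adapt = adaptation_params(), growth = FALSE) {
  fo <- if (cell$ko > 0) max(dot, 0) / (max(dot, 0) + cell$ko) else 1
  qs_ox <- qs_of <- qa_ox <- 0
  if (state == "I") {
    qs <- cell$qs_max * max(cs, 0) / (max(cs, 0) + cell$ks)
    qs_ox <- min(qs, qs_ox_critical(cell)) * fo
    qs_of <- max(qs - qs_ox, 0)
  } else if (state %in% c("II", "III")) {
    qa <- cell$qa_max * max(ca, 0) / (max(ca, 0) + cell$ka)
    qa_ox <- min(qa, cell$qo2max / cell$yo2a) * fo
    if (state == "II") qa_ox <- qa_ox * (1 - adapt$rt)
  }
  qo2 <- cell$yo2s * qs_ox + cell$yo2a * qa_ox
  mu <- if (growth) cell$yxs * qs_ox + cell$yxa * qa_ox else 0
  list(qs_ox = qs_ox, qs_of = qs_of, qa_ox = qa_ox, qo2 = qo2, mu = mu)
}

# State vector layout for the internal ODE (time unit: hours):
# 1 cs, 2 ca, 3 cx [mg/mL]; 4 dot, 5 dotm [%];
# 6 cum_s_ox, 7 cum_s_of, 8 cum_a_ox, 9 cum_o2 [g/L, cumulative].
sim_deriv <- function(t, y, p) {
  r <- metabolic_rates(p$state, y[1L], y[2L], y[3L], y[4L],
                       cell = p$cell, adapt = p$adapt, growth = p$growth)
  cx <- y[3L]
  ddot <- (p$reactor$dotstar - y[4L]) * p$reactor$kla -
    r$qo2 * p$reactor$h * cx
  ddotm <- if (p$tau_h > 0) (y[4L] - y[5L]) / p$tau_h else ddot
  list(c(-(r$qs_ox + r$qs_of) * cx,
         (r$qs_of * p$cell$yas - r$qa_ox) * cx,
         r$mu * cx,
         ddot,
         ddotm,
         r$qs_ox * cx, r$qs_of * cx, r$qa_ox * cx, r$qo2 * cx))
}

sim_root <- function(t, y, p) {
  switch(p$state,
         I = y[1L] - p$cs_event,
         II = t - p$deadline,
         III = y[2L] - p$ca_event,
         IV = 1)  # no internal events in the static state
}

#' Initial simulator state
#'
#' @param cs,ca,cx initial glucose, acetate, biomass in mg/mL.
#' @param v working volume in mL.
#' @param dot,dotm initial actual and measured DOT in % (default: start at
#'   saturation).
#' @param state initial metabolic state label.
#' @param t start time in seconds.
#' @return A list describing the state, used by [simulate_experiment()].
#' @export
sim_state <- function(cs = 0, ca = 0, cx = 10, v = 8, dot = 100, dotm = dot,
                      state = "IV", t = 0) {
  list(t = t / 3600, cs = cs, ca = ca, cx = cx, v = v, dot = dot,
       dotm = dotm, state = state, deadline = NA_real_)
}

# Integrate one continuous leg (no feeds inside), chaining metabolic-state
# switches located by lsodar root finding.  Returns raw output rows (time in
# hours), the event log, and the updated state.
step_events <- function(state, cell, adapt, reactor, t_until, dt_out = 1,
                        growth = FALSE, cs_event = 1e-6, ca_event = 1e-6,
                        rtol = 1e-8, atol = 1e-10) {
  tau_h <- reactor$tau / 3600
  dt_h <- dt_out / 3600
  rows <- list()
  events <- list()
  res_s <- res_a <- 0   # substrate zeroed at switches, charged to totals
  guard <- 0L
  while (state$t < t_until - 1e-12) {
    guard <- guard + 1L
    if (guard > 200L)
      stop("event iteration limit exceeded; inconsistent simulator state",
           call. = FALSE)
    p <- list(state = state$state, cell = cell, adapt = adapt,
              reactor = reactor, growth = growth, tau_h = tau_h,
              cs_event = cs_event, ca_event = ca_event,
              deadline = state$deadline)
    y0 <- c(state$cs, state$ca, state$cx, state$dot, state$dotm, 0, 0, 0, 0)
    # output grid: global multiples of dt_out inside the leg + exact ends
    grid <- seq(ceiling(state$t / dt_h) * dt_h, t_until, by = dt_h)
    times <- sort(unique(c(state$t, grid, t_until)))
    times <- times[times >= state$t - 1e-15 & times <= t_until + 1e-15]
    if (length(times) < 2L) times <- c(state$t, t_until)
    out <- deSolve::lsodar(y = y0, times = times, func = sim_deriv,
                           parms = p, rootfunc = sim_root,
                           rtol = rtol, atol = atol, maxsteps = 100000)
    troot <- attr(out, "troot")
    m <- as.data.frame(unclass(out))
    names(m) <- c("time", "cs", "ca", "cx", "dot", "dotm",
                  "cum_s_ox", "cum_s_of", "cum_a_ox", "cum_o2")
    m$state <- state$state
    m$v <- state$v
    rows[[length(rows) + 1L]] <- m
    last <- m[nrow(m), ]
    state$t <- last$time
    state$cs <- last$cs; state$ca <- last$ca; state$cx <- last$cx
    state$dot <- last$dot; state$dotm <- last$dotm
    if (length(troot) && state$t < t_until - 1e-12) {
      # a metabolic switch fired before the leg end
      sw <- switch_state(state, cell, adapt, ca_event)
      events[[length(events) + 1L]] <-
        data.frame(time = state$t, from = state$state, to = sw$to,
                   trigger = sw$trigger)
      state$state <- sw$to
      state$deadline <- sw$deadline
      if (sw$trigger == "glucose_depleted") { res_s <- res_s + state$cs; state$cs <- 0 }
      if (sw$trigger == "acetate_depleted") { res_a <- res_a + state$ca; state$ca <- 0 }
    } else {
      state$t <- t_until
      break
    }
  }
  list(rows = rows, events = events, state = state,
       residual = c(s = res_s, a = res_a))
}

# Decide the target state after an event in the current state.
switch_state <- function(state, cell, adapt, ca_event) {
  if (state$state == "I") {
    if (adapt$mode != "none" && state$ca > adapt$ca_threshold) {
      dt_s <- if (adapt$mode == "constant") adapt$dt_const
              else adaptation_time(state$ca, state$cx, adapt)
      list(to = "II", trigger = "glucose_depleted",
           deadline = state$t + dt_s / 3600)
    } else if (state$ca > ca_event) {
      list(to = "III", trigger = "glucose_depleted", deadline = NA_real_)
    } else {
      list(to = "IV", trigger = "glucose_depleted", deadline = NA_real_)
    }
  } else if (state$state == "II") {
    to <- if (state$ca > ca_event) "III" else "IV"
    list(to = to, trigger = "adaptation_elapsed", deadline = NA_real_)
  } else if (state$state == "III") {
    list(to = "IV", trigger = "acetate_depleted", deadline = NA_real_)
  } else {
    stop("no events can fire in state IV", call. = FALSE)
  }
}

#' Simulate a bolus-fed cultivation
#'
#' Event-driven piecewise-continuous simulation of the four metabolic
#' states.  Each feed is an instantaneous jump: glucose is mixed in at the
#' feed concentration, all other concentrations are diluted by
#' `V/(V + Fs)`, the volume grows by the bolus, and the culture re-enters
#' state I.  Between events the ODE system (glucose, acetate, biomass,
#' actual DOT, measured DOT) is integrated with a stiff-capable solver and
#' the state switches (glucose exhaustion, adaptation deadline, acetate
#' exhaustion) are located by root finding.
#'
#' @param schedule a [feed_schedule()]; times in seconds.
#' @param init a [sim_state()].
#' @param cell a [cell_params()].
#' @param adapt an [adaptation_params()].
#' @param reactor a [reactor_params()].
#' @param horizon total simulated time in seconds (default: 30 min past the
#'   last feed).
#' @param dt_out dense-output sampling interval in seconds.
#' @param growth include biomass growth (`TRUE` for whole-run synthetic
#'   experiments; `FALSE` for single-pulse studies where biomass change is
#'   negligible).
#' @return An object of class `sim_result`: list with `trajectory` (data
#'   frame, time in seconds, concentrations, `dot`, `dotm`, `v`, `state`),
#'   `events` (time in seconds, from, to, trigger), `totals` (cumulative
#'   oxidized/overflowed masses in mg) and the parameter objects.
#' @export
simulate_experiment <- function(schedule, init = sim_state(),
                                cell = cell_params(),
                                adapt = adaptation_params(),
                                reactor = reactor_params(),
                                horizon = NULL, dt_out = 1, growth = FALSE) {
  stopifnot(inherits(schedule, "feed_schedule") || nrow(schedule) == 0)
  if (is.null(horizon))
    horizon <- if (nrow(schedule)) max(schedule$time) + 1800 else 1800
  horizon_h <- horizon / 3600
  feed_t <- schedule$time / 3600
  if (nrow(schedule) && (min(feed_t) < init$t || max(feed_t) > horizon_h))
    stop("feed times must lie within [start, horizon]", call. = FALSE)
  state <- init
  rows <- list(); events <- list()
  totals <- c(s_ox = 0, s_of = 0, a_ox = 0, o2 = 0)  # mg, volume-weighted
  breakpoints <- c(feed_t, horizon_h)
  feed_idx <- seq_len(nrow(schedule))
  for (k in seq_along(breakpoints)) {
    t_next <- breakpoints[k]
    if (t_next > state$t + 1e-12) {
      leg <- step_events(state, cell, adapt, reactor, t_next,
                         dt_out = dt_out, growth = growth)
      for (m in leg$rows) {
        # cumulative columns restart at 0 each lsodar call; weight by volume
        totals <- totals + state$v * unlist(m[nrow(m), c("cum_s_ox",
                          "cum_s_of", "cum_a_ox", "cum_o2")])
        rows[[length(rows) + 1L]] <- m
      }
      events <- c(events, leg$events)
      # residuals zeroed at state switches count as oxidized substrate
      totals <- totals + state$v *
        c(s_ox = unname(leg$residual["s"]), s_of = 0,
          a_ox = unname(leg$residual["a"]),
          o2 = unname(cell$yo2s * leg$residual["s"] +
                        cell$yo2a * leg$residual["a"]))
      state <- leg$state
    }
    if (k <= nrow(schedule)) {
      fs_ml <- schedule$volume[k] / 1000
      v_new <- state$v + fs_ml
      events[[length(events) + 1L]] <-
        data.frame(time = state$t, from = state$state, to = "I",
                   trigger = "feed")
      state$cs <- (state$cs * state$v +
                     fs_ml * schedule$concentration[k]) / v_new
      state$ca <- state$ca * state$v / v_new
      state$cx <- state$cx * state$v / v_new
      state$v <- v_new
      state$state <- "I"
      state$deadline <- NA_real_
    }
  }
  traj <- do.call(rbind, rows)
  traj <- traj[!duplicated(traj$time), , drop = FALSE]
  traj <- traj[order(traj$time), , drop = FALSE]
  traj$time <- traj$time * 3600  # seconds at the API boundary
  rownames(traj) <- NULL
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(time = numeric(), from = character(), to = character(),
               trigger = character())
  ev$time <- ev$time * 3600
  structure(list(trajectory = traj[, c("time", "cs", "ca", "cx", "v",
                                       "dot", "dotm", "state")],
                 events = ev,
                 totals = totals,  # mg of glucose oxidized/overflowed,
                                   # acetate oxidized, O2 consumed
                 cell = cell, adapt = adapt, reactor = reactor,
                 final = state),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d trajectory points over %.1f s, %d events\n",
              nrow(x$trajectory), max(x$trajectory$time), nrow(x$events)))
  invisible(x)
}

#' Extract a DOT trace from a simulation result
#'
#' @param sim a `sim_result`.
#' @param signal `"dotm"` (the measured, sensor-lagged signal; default) or
#'   `"dot"` (the actual dissolved oxygen).
#' @param dt resample the trace onto this uniform grid in seconds
#'   (`NULL` keeps the simulator output grid).
#' @return A [dot_trace()].
#' @export
sim_dot_trace <- function(sim, signal = c("dotm", "dot"), dt = NULL) {
  signal <- match.arg(signal)
  tr <- dot_trace(sim$trajectory$time, sim$trajectory[[signal]],
                  dotstar = sim$reactor$dotstar)
  if (!is.null(dt)) tr <- resample_uniform(tr, dt) else
    if (!is_uniform(tr)) tr <- resample_uniform(tr, stats::median(diff(tr$time)))
  tr
}

#' Feed volume at which the simulated pulse gains its second and third
#' segments
#'
#' Simulates single-bolus pulses across a volume sweep at fixed biomass,
#' segments each simulated measured-DOT pulse, and returns the smallest
#' volume whose pulse is detected with four segments.
#'
#' @param volumes sweep of bolus volumes in uL.
#' @param cx biomass concentration in mg/mL.
#' @param cell,adapt,reactor model parameter objects.
#' @param concentration feed glucose concentration in mg/mL.
#' @param config a [segmentation_config()].
#' @param lead pre-feed baseline in seconds included in each simulation.
#' @param horizon post-feed simulated time in seconds.
#' @return A list with `threshold` (uL, or `NA` if no four-segment pulse is
#'   found in the sweep) and `n_segments` (named by volume).
#' @export
find_segment_threshold <- function(volumes = seq(1, 10, by = 0.5), cx = 10,
                                   cell = cell_params(),
                                   adapt = adaptation_params(),
                                   reactor = reactor_params(),
                                   concentration = 600,
                                   config = segmentation_config(),
                                   lead = 60, horizon = 900) {
  n_seg <- vapply(volumes, function(v) {
    sim <- simulate_experiment(feed_schedule(lead, v, concentration),
                               init = sim_state(cx = cx, v = reactor$v,
                                                dot = reactor$dotstar),
                               cell = cell, adapt = adapt, reactor = reactor,
                               horizon = lead + horizon, dt_out = 1)
    count_pulse_segments(sim_dot_trace(sim), feed_schedule(lead, v,
                                                           concentration),
                         config)
  }, numeric(1))
  names(n_seg) <- volumes
  hit <- which(n_seg >= 4)
  list(threshold = if (length(hit)) volumes[min(hit)] else NA_real_,
       n_segments = n_seg)
}

# Segment the (single) pulse of a trace and return its segment count
# (0 when no pulse is detected).
count_pulse_segments <- function(trace, feeds, config) {
  pulses <- tryCatch(
    segment_trace(trace, feeds, config),
    error = function(e) NULL)
  if (is.null(pulses) || !length(pulses$pulses)) return(0)
  pulses$pulses[[1L]]$n_segments
}
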