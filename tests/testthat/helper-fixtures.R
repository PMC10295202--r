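# Piecewise-linear pulse fixture: a flat lead-in at `start`, consecutive
# linear segments with the given slopes (%/s) and durations (s), then a
# flat tail.  Optional additive Gaussian noise.
make_piecewise_trace <- function(slopes, durations, start = 100, noise = 0,
                                 seed = 1, lead = 30, tail = 60, dt = 1) {
  set.seed(seed)
  t_all <- seq(0, lead - dt, by = dt)
  y_all <- rep(start, length(t_all))
  y <- start
  t0 <- lead
  for (k in seq_along(slopes)) {
    tt <- seq(t0, t0 + durations[k] - dt, by = dt)
    y_all <- c(y_all, y + slopes[k] * (tt - t0))
    t_all <- c(t_all, tt)
    y <- y + slopes[k] * durations[k]
    t0 <- t0 + durations[k]
  }
  tt <- seq(t0, t0 + tail, by = dt)
  y_all <- c(y_all, rep(y, length(tt)))
  t_all <- c(t_all, tt)
  dot_trace(t_all, y_all + stats::rnorm(length(t_all), 0, noise))
}

# Analytic measured signal of a first-order sensor watching an exponential
# recovery DOT(t) = ds - a0 * exp(-k t); dotm(0) = dot(0).
analytic_lagged_recovery <- function(tt, k, tau, a0 = 80, ds = 100) {
  a <- k * tau
  ds - a0 / (1 - a) * (exp(-k * tt) - a * exp(-tt / tau))
}

# Standard small simulation: one bolus into 8 mL at the given biomass.
single_pulse_sim <- function(volume, cx = 10, lead = 60, horizon = 1200,
                             cell = cell_params(),
                             adapt = adaptation_params(),
                             reactor = reactor_params(), dt_out = 1) {
  simulate_experiment(feed_schedule(lead, volume),
                      init = sim_state(cx = cx, v = reactor$v,
                                       dot = reactor$dotstar),
                      cell = cell, adapt = adapt, reactor = reactor,
                      horizon = lead + horizon, dt_out = dt_out)
}

# Count detected segments of a single simulated pulse.
segments_of_single_pulse <- function(volume, cx = 10, ...) {
  sim <- single_pulse_sim(volume, cx = cx, ...)
  ps <- segment_trace(sim_dot_trace(sim), feed_schedule(60, volume))
  ps$pulses[[1L]]
}
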