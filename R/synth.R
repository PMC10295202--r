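#' Bolus feeding plans of the eight-minibioreactor design
#'
#' Per-reactor bolus volume (uL) and feeding interval (min) of the
#' systematic feeding-frequency/amplitude variation across reactors A-H;
#' the feed is 600 mg/mL glucose in all plans.
#'
#' @return Data frame with columns `plan`, `volume`, `interval_min`,
#'   `concentration`, `dilution_ratio` (uL per mL of the 8 mL working
#'   volume).
#' @export
feeding_plans <- function() {
  p <- data.frame(
    plan = LETTERS[1:8],
    volume = c(5, 5.5, 6.5, 6.5, 6.5, 8.5, 6, 7.5),
    interval_min = c(30, 20, 12, 9, 9, 9, 4, 4),
    concentration = 600)
  p$dilution_ratio <- dilution_ratio(p$volume, 8)
  p
}

#' Specification of a synthetic bolus-fed experiment
#'
#' Describes one synthetic cultivation: the feeding plan (one of the
#' standard plans A-H or custom volume/interval), the initial state, the
#' sampling grid, the sensor noise, and the random seed.  The defaults
#' emulate the reference cultivation: 8 mL initial volume, 600 mg/mL
#' glucose feed, ~1 s DOT sampling, additive Gaussian sensor noise, and a
#' production phase of 11.85 h (79 pulses at the 9-min reference
#' interval).  Real schedules deviate from the plan because feeding
#' competes with sampling and titration tasks; `volume_jitter_sd` emulates
#' that amplitude deviation (relative standard deviation) and is the
#' reason a run contains both two- and four-segment pulses.
#'
#' @param plan plan letter A-H, or `NA` to use `volume`/`interval_min`
#'   directly.
#' @param volume,interval_min,concentration bolus volume (uL), feeding
#'   interval (min), feed concentration (mg/mL); taken from the plan when
#'   `plan` is given.
#' @param horizon total duration in seconds (default 11.85 h).
#' @param v0 initial working volume, mL.
#' @param cx0,cs0,ca0 initial biomass, glucose, acetate, mg/mL.
#' @param noise_sd DOT sensor noise standard deviation, % (default 0.3).
#' @param dt DOT sampling interval, seconds.
#' @param seed integer random seed.
#' @param volume_jitter_sd relative s.d. of the per-bolus volume deviation
#'   (default 0.15; set 0 for a perfectly regular schedule).
#' @param interval_jitter_sd s.d. of the event-time deviation in seconds
#'   (default 0).
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(plan = "E", volume = NULL, interval_min = NULL,
                            concentration = 600, horizon = 11.85 * 3600,
                            v0 = 8, cx0 = 8, cs0 = 0, ca0 = 0,
                            noise_sd = 0.3, dt = 1, seed = 1L,
                            volume_jitter_sd = 0.15,
                            interval_jitter_sd = 0) {
  if (!is.null(plan) && !is.na(plan)) {
    plans <- feeding_plans()
    if (!plan %in% plans$plan)
      stop("unknown plan '", plan, "'; use one of A-H or give ",
           "`volume` and `interval_min`", call. = FALSE)
    row <- plans[plans$plan == plan, ]
    volume <- row$volume; interval_min <- row$interval_min
    concentration <- row$concentration
  }
  if (is.null(volume) || is.null(interval_min))
    stop("either `plan` or both `volume` and `interval_min` are required",
         call. = FALSE)
  if (interval_min <= 0) stop("`interval_min` must be positive",
                              call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(list(plan = plan, volume = volume, interval_min = interval_min,
                 concentration = concentration, horizon = horizon, v0 = v0,
                 cx0 = cx0, cs0 = cs0, ca0 = ca0, noise_sd = noise_sd,
                 dt = dt, seed = as.integer(seed),
                 volume_jitter_sd = volume_jitter_sd,
                 interval_jitter_sd = interval_jitter_sd),
            class = "experiment_spec")
}

#' Build the bolus schedule of an experiment spec
#'
#' Equidistant events at the plan interval and volume from t = 0 up to the
#' horizon.  Jitter is off by default; when the spec carries jitter and
#' `jitter = TRUE`, volumes (relative Gaussian, truncated at +-2.5 s.d.
#' and at 1 uL minimum) and event times deviate from the plan, drawn from
#' the current RNG state.
#'
#' @param spec an [experiment_spec()].
#' @param jitter apply the spec's jitter settings (default `FALSE`:
#'   a perfectly regular schedule).
#' @return A [feed_schedule()].
#' @export
build_schedule <- function(spec, jitter = FALSE) {
  times <- seq(0, spec$horizon, by = spec$interval_min * 60)
  vols <- rep(spec$volume, length(times))
  if (jitter && spec$volume_jitter_sd > 0) {
    z <- pmin(pmax(stats::rnorm(length(vols)), -2.5), 2.5)
    vols <- pmax(vols * (1 + spec$volume_jitter_sd * z), 1)
  }
  if (jitter && spec$interval_jitter_sd > 0) {
    times <- times + c(0, stats::rnorm(length(times) - 1L,
                                       sd = spec$interval_jitter_sd))
    times <- pmin(pmax(sort(times), 0), spec$horizon)
  }
  feed_schedule(times, vols, spec$concentration)
}

#' Generate a synthetic bolus-fed DOT experiment
#'
#' Runs the mechanistic simulator (growth enabled) over the spec's
#' schedule, samples the sensor-lagged DOT on the sampling grid, adds
#' i.i.d. Gaussian sensor noise, and emits five at-line
#' biomass/glucose/acetate samples spread over the horizon.  The
#' ground-truth parameters are returned alongside so recovery studies
#' never have to reverse-engineer them from the outputs.
#'
#' @param spec an [experiment_spec()].
#' @param cell a [cell_params()].
#' @param adapt an [adaptation_params()].
#' @param reactor a [reactor_params()].
#' @param n_samples number of at-line samples (default 5).
#' @return A list with `trace` (noisy measured [dot_trace()]), `feeds`
#'   (the realized [feed_schedule()]), `samples` (a [sample_table()]),
#'   `truth` (list of generating parameters) and `sim` (the full
#'   [simulate_experiment()] result).
#' @export
generate_experiment <- function(spec = experiment_spec(),
                                cell = cell_params(),
                                adapt = adaptation_params(),
                                reactor = reactor_params(),
                                n_samples = 5) {
  set.seed(spec$seed)
  feeds <- build_schedule(spec, jitter = spec$volume_jitter_sd > 0 ||
                            spec$interval_jitter_sd > 0)
  init <- sim_state(cs = spec$cs0, ca = spec$ca0, cx = spec$cx0,
                    v = spec$v0, dot = reactor$dotstar)
  sim <- simulate_experiment(feeds, init = init, cell = cell,
                             adapt = adapt, reactor = reactor,
                             horizon = spec$horizon, dt_out = spec$dt,
                             growth = TRUE)
  clean <- sim_dot_trace(sim, "dotm", dt = spec$dt)
  noisy <- dot_trace(clean$time,
                     clean$dot + stats::rnorm(nrow(clean), 0, spec$noise_sd),
                     dotstar = reactor$dotstar,
                     reactor_id = if (is.na(spec$plan)) "custom" else
                       spec$plan,
                     note = sprintf("synthetic, seed %d", spec$seed))
  t_samp <- spec$horizon * seq(0.1, 0.9, length.out = n_samples)
  traj <- sim$trajectory
  at <- function(col) stats::approx(traj$time, traj[[col]], t_samp)$y
  samples <- sample_table(t_samp, cx = at("cx"), cs = at("cs"),
                          ca = at("ca"))
  truth <- list(kla = reactor$kla, qo2max = cell$qo2max, yo2s = cell$yo2s,
                yo2a = cell$yo2a, yas = cell$yas, qs_max = cell$qs_max,
                qs_ox_critical = qs_ox_critical(cell),
                tau = reactor$tau, seed = spec$seed)
  list(trace = noisy, feeds = feeds, samples = samples, truth = truth,
       sim = sim)
}
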