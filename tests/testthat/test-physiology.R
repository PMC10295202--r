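test_that("closed-form KLa matches hand-computed values", {
  # -ln((100-90)/(100-20)) / (36/3600 h) = ln(8) * 100
  expect_equal(kla_closed_form(20, 90, 36), log(8) * 100, tolerance = 1e-9)
  expect_equal(kla_closed_form(20, 90, 36), 207.944, tolerance = 1e-4)
  # a ratio of e^-1 over one hour is 1 1/h
  dot_min <- 100 - 80
  dot_end <- 100 - 80 * exp(-1)
  expect_equal(kla_closed_form(dot_min, dot_end, 3600), 1)
  expect_error(kla_closed_form(20, 100, 36), "singular")
  expect_error(kla_closed_form(90, 80, 36), "below")
})

test_that("KLa is recovered from a simulated recovery segment", {
  for (kla_true in c(200, 250)) {
    re <- reactor_params(kla = kla_true)
    sim <- single_pulse_sim(6.5, reactor = re, horizon = 1200)
    tr <- invert_sensor_delay(sim_dot_trace(sim), sensor_model(re$tau))
    p <- segment_trace(tr, feed_schedule(60, 6.5))$pulses[[1]]
    est <- estimate_kla(tr, p, method = "fit")
    expect_equal(est, kla_true, tolerance = 0.02)
  }

  # two-point closed form on a metabolism-free reoxygenation (sensor lag
  # inverted): the exact setting of the analytic solution
  re <- reactor_params(kla = 250)
  sim <- simulate_experiment(feed_schedule(numeric(0), numeric(0)),
                             init = sim_state(cx = 10, dot = 20,
                                              state = "IV"),
                             reactor = re, horizon = 200)
  tr <- invert_sensor_delay(sim_dot_trace(sim), sensor_model(re$tau))
  rec <- structure(list(
    segments = data.frame(label = "S4", t_start = 2, t_end = 200,
                          dot_start = tr$dot[3], dot_end = tr$dot[201],
                          duration = 198, slope = 0.4, area_under = 0,
                          area_depression = 0),
    n_segments = 2L, truncated = FALSE, flag = NA_character_,
    t_start = 0, t_end = 200, feed = 1L, t_feed = 0),
    class = "dot_pulse")
  est2 <- estimate_kla(tr, rec, method = "endpoints", lower_fraction = 0.8)
  expect_equal(est2, 250, tolerance = 0.02)
})

test_that("KLa estimation is robust to moderate sensor noise", {
  re <- reactor_params(kla = 250)
  sim <- single_pulse_sim(6.5, reactor = re, horizon = 1200)
  clean <- sim_dot_trace(sim)
  ests <- vapply(1:8, function(s) {
    set.seed(s)
    noisy <- dot_trace(clean$time, clean$dot + rnorm(nrow(clean), 0, 0.5))
    tr <- invert_sensor_delay(noisy, sensor_model(re$tau))
    p <- segment_trace(tr, feed_schedule(60, 6.5))$pulses[[1]]
    suppressWarnings(estimate_kla(tr, p, method = "fit"))
  }, numeric(1))
  ests <- ests[is.finite(ests)]
  expect_gte(length(ests), 6)
  expect_equal(mean(ests), 250, tolerance = 0.05)
})

test_that("a truncated recovery yields no KLa estimate", {
  fe <- feed_schedule(c(60, 180), 6.5)
  sim <- simulate_experiment(fe, init = sim_state(cx = 10, v = 8),
                             horizon = 900)
  tr <- sim_dot_trace(sim)
  p <- segment_trace(tr, fe)$pulses[[1]]
  expect_true(p$truncated)
  expect_warning(est <- estimate_kla(tr, p), "truncated")
  expect_true(is.na(est))
})

test_that("qO2 follows the oxygen balance closed form", {
  # steady depression at 80%: qO2 = 20 * KLa / (H * Cx)
  tt <- 0:100
  tr <- dot_trace(tt, rep(80, 101))
  pulse <- structure(list(
    segments = data.frame(label = "S1", t_start = 10, t_end = 90,
                          dot_start = 80, dot_end = 80, duration = 80,
                          slope = 0, area_under = 80 * 80,
                          area_depression = 20 * 80),
    n_segments = 2L, truncated = FALSE, flag = NA_character_,
    t_start = 0, t_end = 100, feed = 1L, t_feed = 5), class = "dot_pulse")
  re <- reactor_params(kla = 200)             # H = 100/0.007 = 14285.7
  q <- estimate_qo2(tr, pulse, cx = 10, re, kla = 200, trim = 0)
  expect_equal(q$qo2, 20 * 200 / (re$h * 10), tolerance = 1e-9)
  expect_equal(q$qo2, 0.028, tolerance = 1e-3)
  expect_equal(q$our, 0.28, tolerance = 1e-3)

  # no depression, no slope -> zero uptake
  tr0 <- dot_trace(tt, rep(100, 101))
  q0 <- estimate_qo2(tr0, pulse, cx = 10, re, kla = 200, trim = 0)
  expect_equal(q0$qo2, 0)
})

test_that("qO2max recovery from simulated first segments is within 15%", {
  cell <- cell_params()                       # qO2max = 0.16
  ests <- vapply(c(6.5, 8, 9), function(v) {
    sim <- single_pulse_sim(v, cell = cell, horizon = 1200)
    tr <- invert_sensor_delay(sim_dot_trace(sim), sensor_model(36))
    p <- segment_trace(tr, feed_schedule(60, v))$pulses[[1]]
    estimate_qo2(tr, p, cx = 10, reactor_params(), kla = 250)$qo2
  }, numeric(1))
  q <- estimate_qo2max(ests)
  expect_equal(q$qo2max, cell$qo2max, tolerance = 0.15)
})

test_that("qO2max aggregation takes the maximum and reports spread", {
  q <- estimate_qo2max(c(0.10, 0.16, 0.12))
  expect_equal(q$qo2max, 0.16)
  expect_equal(q$mean, mean(c(0.10, 0.16, 0.12)))
  expect_equal(q$n, 3)
  expect_equal(estimate_qo2max(0.11)$qo2max, 0.11)
  expect_error(estimate_qo2max(NA_real_), "no finite")
})

test_that("YO2/S follows the transfer-area closed form", {
  # rectangular 20% depression for 180 s (0.05 h), KLa = 200, V = 8 mL,
  # feed 5 uL x 600 mg/mL = 3 mg
  tt <- 0:200
  y <- rep(100, 201)
  y[11:190] <- 80
  tr <- dot_trace(tt, y)
  pulse <- structure(list(
    segments = data.frame(label = c("S1", "S4"), t_start = c(0, 100),
                          t_end = c(100, 200), dot_start = c(100, 80),
                          dot_end = c(80, 100), duration = c(100, 100),
                          slope = c(-0.2, 0.2), area_under = c(0, 0),
                          area_depression = c(0, 0)),
    n_segments = 2L, truncated = FALSE, flag = NA_character_,
    t_start = 0, t_end = 200, feed = 1L, t_feed = 5), class = "dot_pulse")
  re <- reactor_params(kla = 200)
  est <- estimate_yo2s(tr, pulse, feed_volume = 5, feed_conc = 600, re,
                       kla = 200)
  # independent arithmetic: V[L] * KLa * area[%h] / H / feed[g]
  area_h <- sum(diff(tt / 3600) * (utils::head(100 - y, -1) +
                                     utils::tail(100 - y, -1)) / 2)
  expect_equal(est, 0.008 * 200 * area_h / re$h / 0.003, tolerance = 1e-9)
  expect_equal(est, 0.0373, tolerance = 0.02)

  # zero depression gives zero yield
  trf <- dot_trace(tt, rep(100, 201))
  expect_equal(estimate_yo2s(trf, pulse, 5, 600, re, kla = 200), 0)

  # four-segment pulses are rejected
  pulse4 <- pulse; pulse4$n_segments <- 4L
  expect_error(estimate_yo2s(tr, pulse4, 5, 600, re), "two-segment")
})

test_that("YO2/S is recovered from a simulated two-segment pulse", {
  cell <- cell_params()                       # yo2s = 0.075
  sim <- single_pulse_sim(3, cell = cell, horizon = 1200)
  tr <- invert_sensor_delay(sim_dot_trace(sim), sensor_model(36))
  p <- segment_trace(tr, feed_schedule(60, 3))$pulses[[1]]
  expect_equal(p$n_segments, 2L)
  est <- estimate_yo2s(tr, p, 3, 600, reactor_params(), kla = 250)
  expect_equal(est, cell$yo2s, tolerance = 0.10)
})

test_that("YO2/A is recovered from a simulated four-segment pulse", {
  cell <- cell_params()                       # yo2a = 0.15
  sim <- single_pulse_sim(9, cell = cell, horizon = 1500)
  tr <- invert_sensor_delay(sim_dot_trace(sim), sensor_model(36))
  p <- segment_trace(tr, feed_schedule(60, 9))$pulses[[1]]
  expect_equal(p$n_segments, 4L)
  est <- estimate_yo2a(tr, p, 9, 600, reactor_params(), kla = 250,
                       yo2s = cell$yo2s)
  expect_equal(est, cell$yo2a, tolerance = 0.20)
  # kinetic route stays in the physical ballpark
  est_k <- estimate_yo2a(tr, p, 9, 600, reactor_params(), kla = 250,
                         qs_ox_max = qs_ox_critical(cell), cx = 10,
                         method = "kinetic")
  expect_gt(est_k, 0.05)
  expect_lt(est_k, 0.4)
  expect_error(
    estimate_yo2a(tr, structure(list(segments = p$segments,
                                     n_segments = 2L), class = "dot_pulse"),
                  9, 600, reactor_params(), yo2s = 0.075),
    "four-segment")
})

test_that("the workflow degrades gracefully without samples or recoveries", {
  g <- generate_experiment(experiment_spec(plan = "E", seed = 6,
                                           horizon = 3600))
  # no biomass samples: KLa available, biomass-dependent parameters absent
  wf <- run_workflow(g$trace, g$feeds, samples = NULL)
  s <- wf$summary
  expect_gt(s$n[s$parameter == "kla"], 0)
  expect_equal(s$n[s$parameter == "qo2max"], 0)
  expect_true(is.na(s$estimate[s$parameter == "qo2max"]))

  # all pulses truncated (second feed mid-pulse, trace ends mid-pulse):
  # no KLa estimates, diagnostics intact
  fe <- feed_schedule(c(60, 200), 6.5)
  simt <- simulate_experiment(fe, init = sim_state(cx = 20, v = 8),
                              horizon = 300)
  trt <- sim_dot_trace(simt)
  wft <- run_workflow(trt, fe)
  expect_equal(wft$summary$n[wft$summary$parameter == "kla"], 0)
  expect_true(all(vapply(wft$pulses$pulses, function(p)
    isTRUE(p$truncated) || !is.na(p$flag), logical(1))))
})

test_that("the overflow switching condition is reported consistently", {
  g <- generate_experiment(experiment_spec(plan = "E", seed = 1))
  wf <- run_workflow(g$trace, g$feeds, g$samples)
  s <- wf$summary
  qs_crit <- s$estimate[s$parameter == "qo2max"] /
    s$estimate[s$parameter == "yo2s"]
  expect_equal(wf$qs_ox_critical, qs_crit)
  # matches the simulator's overflow switch within the estimator errors
  expect_equal(qs_crit, qs_ox_critical(cell_params()), tolerance = 0.2)
})
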