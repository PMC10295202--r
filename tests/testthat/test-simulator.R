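test_that("adaptation time follows the acetate/biomass scaling", {
  ad <- adaptation_params()
  expect_equal(adaptation_time(0.5, 25, ad), 60)
  expect_equal(adaptation_time(0.25, 12.5, ad), 60)   # 60 * 0.5 * 2
  expect_equal(adaptation_time(0, 10, ad), 0)
  expect_error(adaptation_time(0.2, 0, ad), "positive")
})

test_that("state-wise rates implement overflow partitioning and the pause", {
  cell <- cell_params(qs_max = 2.5, ko = 0)   # oxygen factor disabled
  r <- metabolic_rates("I", cs = 10, ca = 0, cx = 10, dot = 100, cell)
  expect_equal(r$qs_ox, 0.16 / 0.075, tolerance = 1e-3)  # capped at critical
  expect_equal(r$qs_of, 2.5 * 10 / 10.01 - 0.16 / 0.075, tolerance = 1e-3)
  expect_equal(r$qo2, cell$qo2max, tolerance = 1e-3)

  r4 <- metabolic_rates("IV", 10, 10, 10, 100, cell)
  expect_true(all(unlist(r4) == 0))

  # full pause: all rates zero regardless of substrate availability
  r2 <- metabolic_rates("II", 10, 10, 10, 100, cell,
                        adaptation_params(rt = 1))
  expect_true(all(unlist(r2) == 0))

  # acetate oxidation capped by the oxygen-equivalent capacity
  r3 <- metabolic_rates("III", 0, 5, 10, 100,
                        cell_params(qa_max = 5, ko = 0))
  expect_equal(r3$qa_ox, 0.16 / 0.15, tolerance = 1e-3)
  expect_equal(r3$qo2, 0.16, tolerance = 1e-3)

  expect_error(cell_params(qs_max = 1), "overflow")
})

test_that("pure reoxygenation relaxes exponentially at KLa", {
  re <- reactor_params(kla = 250, tau = 0)
  sim <- simulate_experiment(feed_schedule(numeric(0), numeric(0)),
                             init = sim_state(cx = 10, dot = 50,
                                              state = "IV"),
                             reactor = re, horizon = 120)
  tr <- sim$trajectory
  expect_equal(tr$cs, rep(0, nrow(tr)))
  expect_equal(tr$ca, rep(0, nrow(tr)))
  expected <- 100 - 50 * exp(-250 / 3600 * tr$time)
  expect_equal(tr$dot, expected, tolerance = 1e-5)
})

test_that("feed size selects the metabolic route through the states", {
  # large bolus: overflow acetate above threshold -> adaptation pause
  sim9 <- single_pulse_sim(9)
  expect_equal(sim9$events$to, c("I", "II", "III", "IV"))
  # small bolus: acetate below threshold -> no pause
  sim3 <- single_pulse_sim(3)
  expect_equal(sim3$events$to, c("I", "III", "IV"))
  expect_equal(segments_of_single_pulse(9)$n_segments, 4L)
  expect_equal(segments_of_single_pulse(3)$n_segments, 2L)
})

test_that("mass is conserved over a complete pulse cycle", {
  for (v in c(3, 6.5, 9)) {
    sim <- single_pulse_sim(v, horizon = 1500)
    fed_mg <- v * 600 / 1000
    tot <- sim$totals
    # all fed glucose is consumed (oxidized + overflowed)
    expect_equal(unname(tot["s_ox"] + tot["s_of"]), fed_mg,
                 tolerance = 1e-6)
    # all produced acetate (YAS x overflow) is consumed by the cycle end
    expect_equal(unname(tot["a_ox"]), unname(tot["s_of"]) * 0.667,
                 tolerance = 1e-6)
    final <- utils::tail(sim$trajectory, 1)
    expect_lt(final$cs + final$ca, 1e-5)
  }
})

test_that("oxygen book-keeping closes through yields and the DOT balance", {
  sim <- single_pulse_sim(6.5, horizon = 1500)
  tot <- sim$totals
  cell <- sim$cell
  # consumed oxygen equals the yield-weighted substrate oxidations
  expect_equal(unname(tot["o2"]),
               unname(cell$yo2s * tot["s_ox"] + cell$yo2a * tot["a_ox"]),
               tolerance = 1e-6)
  # independent route: transfer integral minus DOT accumulation (trapezoid
  # on the 1 s grid limits the agreement)
  tr <- sim$trajectory
  re <- sim$reactor
  area_h <- sum(diff(tr$time / 3600) *
                  (utils::head(100 - tr$dot, -1) +
                     utils::tail(100 - tr$dot, -1)) / 2)
  o2_dot_route <- re$v / 1000 / re$h *
    (re$kla * area_h - (tr$dot[nrow(tr)] - tr$dot[1])) * 1000  # mg
  expect_equal(unname(tot["o2"]), o2_dot_route, tolerance = 1e-3)
})

test_that("state variables stay in their physical ranges", {
  g <- generate_experiment(experiment_spec(plan = "F", seed = 1,
                                           horizon = 2 * 3600, cx0 = 15))
  tr <- g$sim$trajectory
  expect_true(all(tr$cs > -1e-9))
  expect_true(all(tr$ca > -1e-9))
  expect_true(all(tr$cx > 0))
  expect_true(all(tr$dot >= -1e-6 & tr$dot <= 100 + 1e-6))
  expect_true(all(tr$dotm >= -1e-6 & tr$dotm <= 100 + 1e-6))
  expect_true(all(diff(g$sim$events$time) >= 0))
})

test_that("the measured signal lags the actual one by about the sensor constant", {
  sim <- single_pulse_sim(6.5)
  tr <- sim$trajectory
  lags <- 0:100
  cc <- vapply(lags, function(L) {
    n <- nrow(tr)
    stats::cor(tr$dot[1:(n - L)], tr$dotm[(1 + L):n])
  }, numeric(1))
  peak <- lags[which.max(cc)]
  expect_gt(peak, 10)
  expect_lt(peak, 80)   # tau = 36 s, pulse shape broadens the peak
})

test_that("event-driven trajectories match a fine fixed-step oracle", {
  sim <- single_pulse_sim(6.5, horizon = 420)
  oracle <- fixed_step_oracle(feed_time = 60, feed_vol_ul = 6.5,
                              horizon = 480, dt = 0.01)
  tr <- sim$trajectory
  tr$time <- round(tr$time, 4)
  oracle$time <- round(oracle$time, 4)
  m <- merge(tr, oracle, by = "time", suffixes = c("", "_o"))
  expect_gt(nrow(m), 400)
  rel_rms <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))
  expect_lt(rel_rms(m$dot, m$dot_o), 1e-3)
  expect_lt(rel_rms(m$dotm, m$dotm_o), 1e-3)
  expect_lt(sqrt(mean((m$ca - m$ca_o)^2)), 1e-3)   # mg/mL scale
})

test_that("disabling the pause removes the second segment", {
  # constant adaptation time of zero
  p0 <- segments_of_single_pulse(9, adapt = adaptation_params(
    mode = "constant", dt_const = 0))
  expect_equal(p0$n_segments, 2L)
  # no reduction of rates during the pause
  pr <- segments_of_single_pulse(9, adapt = adaptation_params(rt = 0))
  expect_equal(pr$n_segments, 2L)
  # unreachable acetate threshold: no four-segment pulse in the sweep
  th <- find_segment_threshold(volumes = seq(2, 9, by = 1),
                               adapt = adaptation_params(
                                 ca_threshold = Inf))
  expect_true(is.na(th$threshold))
})

test_that("identical inputs give bit-identical event logs", {
  s1 <- single_pulse_sim(6.5)
  s2 <- single_pulse_sim(6.5)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$trajectory, s2$trajectory)
})

test_that("empty schedule at saturation stays constant", {
  sim <- simulate_experiment(feed_schedule(numeric(0), numeric(0)),
                             init = sim_state(cx = 10), horizon = 300)
  expect_equal(range(sim$trajectory$dot), c(100, 100))
  expect_equal(nrow(sim$events), 0L)
})

test_that("S2 duration grows with feed volume and shrinks with biomass", {
  d_vol <- vapply(c(6, 7.5, 9), function(v) {
    p <- segments_of_single_pulse(v)
    p$segments$duration[2]
  }, numeric(1))
  expect_true(all(diff(d_vol) > 0))
  d_cx <- vapply(c(8, 10, 12), function(cx) {
    p <- segments_of_single_pulse(9, cx = cx)
    p$segments$duration[2]
  }, numeric(1))
  expect_true(all(diff(d_cx) < 0))
})
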