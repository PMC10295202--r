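# Independent fixed-step oracle for the metabolic model: a plain RK4
# integrator with if/else rate laws and grid-located state switches,
# written without any of the package's simulator machinery.  Time unit:
# seconds.  Used to cross-check the event-driven implementation.
fixed_step_oracle <- function(feed_time, feed_vol_ul, horizon,
                              cx0 = 10, v0 = 8, dt = 0.01,
                              qo2max = 0.16, qs_max = 3.95, ks = 0.01,
                              ka = 0.01, ko = 1, qa_max = 0.7,
                              yo2s = 0.075, yo2a = 0.15, yas = 0.667,
                              kla = 250, tau = 36, ds = 100,
                              c_o2_sat = 0.007, t_adap_max = 60,
                              ca_max = 0.5, cx_max = 25,
                              ca_threshold = 0.1, out_dt = 1) {
  h_const <- ds / c_o2_sat
  kla_s <- kla / 3600
  crit_s <- qo2max / yo2s
  crit_a <- qo2max / yo2a
  deriv <- function(y, state) {
    cs <- y[1]; ca <- y[2]; dot <- y[3]; dotm <- y[4]
    fo <- if (ko > 0) max(dot, 0) / (max(dot, 0) + ko) else 1
    qs_ox <- qs_of <- qa_ox <- 0
    if (state == 1) {
      qs <- qs_max * max(cs, 0) / (max(cs, 0) + ks)
      qs_ox <- min(qs, crit_s) * fo
      qs_of <- qs - qs_ox
    } else if (state == 3) {
      qa_ox <- min(qa_max * max(ca, 0) / (max(ca, 0) + ka), crit_a) * fo
    }                                      # state 2 (pause) and 4: all zero
    qo2 <- yo2s * qs_ox + yo2a * qa_ox
    c(-(qs_ox + qs_of) * cx0 / 3600,
      (qs_of * yas - qa_ox) * cx0 / 3600,
      (ds - dot) * kla_s - qo2 * h_const * cx0 / 3600,
      (dot - dotm) / tau)
  }
  n_steps <- ceiling(horizon / dt)
  y <- c(0, 0, ds, ds)
  state <- 4L
  deadline <- NA_real_
  fed <- FALSE
  v <- v0
  keep <- seq(0, horizon, by = out_dt)
  out <- matrix(NA_real_, length(keep), 6)
  ki <- 1L
  t <- 0
  for (s in seq_len(n_steps)) {
    if (ki <= length(keep) && t >= keep[ki] - dt / 2) {
      out[ki, ] <- c(t, y, state)
      ki <- ki + 1L
    }
    if (!fed && t >= feed_time - dt / 2) {
      fs <- feed_vol_ul / 1000
      y[1] <- (y[1] * v + fs * 600) / (v + fs)
      y[2] <- y[2] * v / (v + fs)
      v <- v + fs
      state <- 1L
      fed <- TRUE
    }
    k1 <- deriv(y, state)
    k2 <- deriv(y + dt / 2 * k1, state)
    k3 <- deriv(y + dt / 2 * k2, state)
    k4 <- deriv(y + dt * k3, state)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
    if (state == 1L && y[1] <= 1e-6) {
      y[1] <- 0
      if (y[2] > ca_threshold) {
        state <- 2L
        deadline <- t + t_adap_max * (y[2] / ca_max) * (cx_max / cx0)
      } else if (y[2] > 1e-6) state <- 3L else state <- 4L
    } else if (state == 2L && t >= deadline) {
      state <- if (y[2] > 1e-6) 3L else 4L
    } else if (state == 3L && y[2] <= 1e-6) {
      y[2] <- 0
      state <- 4L
    }
  }
  colnames(out) <- c("time", "cs", "ca", "dot", "dotm", "state")
  as.data.frame(out[stats::complete.cases(out), ])
}
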