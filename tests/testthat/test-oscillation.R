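sine_trace <- function(period = 2.5, amplitude = 1, phase = 0,
                       duration = 12, dt = 0.01, offset = 0) {
  t <- seq(0, duration, by = dt)
  list(t = t, v = offset + amplitude * sin(2 * pi * t / period + phase))
}

test_that("max_voltage takes the full-run maximum and rejects bad traces", {
  expect_equal(max_voltage(rep(-35, 100)), -35)
  s <- sine_trace()
  expect_equal(max_voltage(s$v), 1, tolerance = 1e-4)
  expect_error(max_voltage(c(1, NA, 2)), "non-finite")
  expect_error(max_voltage(numeric()), "empty")
})

test_that("period estimation recovers known signals and refuses non-oscillations", {
  s <- sine_trace(period = 2.5)
  expect_equal(estimate_period(s$v, s$t, c(0, 12)), 2.5, tolerance = 0.01 / 2.5)
  mono <- exp(-seq(0, 12, by = 0.01))
  expect_true(is.na(estimate_period(mono, s$t, c(0, 12))))
  expect_error(estimate_period(s$v, s$t, c(20, 30)), "window")
})

test_that("period estimation is invariant to offset and positive rescaling", {
  s <- sine_trace(period = 3.1, amplitude = 4)
  p0 <- estimate_period(s$v, s$t, c(0, 12))
  expect_equal(estimate_period(s$v + 120, s$t, c(0, 12)), p0,
               tolerance = 1e-3)
  expect_equal(estimate_period(s$v * 37, s$t, c(0, 12)), p0,
               tolerance = 1e-3)
})

test_that("noisy period recovery agrees with an autocorrelation oracle", {
  ts <- make_surrogate_traces(c(a = 0), period = 2.5, amplitude = 10,
                              noise_sd = 0.5, seed = 7)
  v <- get_trace(ts, "a")
  est <- estimate_period(v, ts$time, c(3, 12))
  # oracle: first local maximum of the autocorrelation of the same signal
  idx <- ts$time >= 3
  ac <- stats::acf(v[idx] - mean(v[idx]), lag.max = 400, plot = FALSE)$acf[, 1, 1]
  first_pk <- which(diff(sign(diff(ac))) < 0)[1] + 1
  oracle <- (first_pk - 1) * 0.01
  expect_equal(est, oracle, tolerance = 0.02 * 2.5)
  expect_equal(est, 2.5, tolerance = 0.02 * 2.5)
})

test_that("prominence filtering keeps major peaks and drops riders", {
  # two large crests with a small ripple riding on the second
  t <- seq(0, 10, by = 0.01)
  v <- sin(2 * pi * t / 5)
  v[680:700] <- v[680:700] + 0.05
  pk <- find_peaks(v, min_prominence = 0.2 * diff(range(v)))
  expect_length(pk, 2)
  # plateaus resolve to their earliest sample
  flat <- c(0, 1, 1, 1, 0)
  expect_equal(find_peaks(flat), 2L)
})

test_that("phase classification handles the canonical sign cases", {
  a <- sine_trace(); b <- sine_trace(phase = pi); q <- sine_trace(phase = pi / 2)
  ip <- classify_phase(a$v, a$v, a$t, c(0, 12))
  expect_equal(ip$relation, "in_phase")
  expect_gt(ip$correlation, 0.99)
  ap <- classify_phase(a$v, b$v, a$t, c(0, 12))
  expect_equal(ap$relation, "anti_phase")
  expect_lt(ap$correlation, -0.99)
  un <- classify_phase(a$v, q$v, a$t, c(0, 12))
  expect_equal(un$relation, "undetermined")
  expect_lt(abs(un$correlation), 0.1)
})

test_that("phase classification is symmetric and guards degenerate traces", {
  a <- sine_trace(); b <- sine_trace(phase = 2.7, amplitude = 3)
  ab <- classify_phase(a$v, b$v, a$t, c(0, 12))
  ba <- classify_phase(b$v, a$v, a$t, c(0, 12))
  expect_identical(ab$relation, ba$relation)
  expect_equal(ab$correlation, ba$correlation)
  flat <- classify_phase(a$v, rep(5, length(a$v)), a$t, c(0, 12))
  expect_equal(flat, list(relation = "undetermined", correlation = 0))
  # non-oscillating partner (below amplitude floor) -> undetermined
  weak <- sine_trace(amplitude = 0.01)
  expect_equal(classify_phase(a$v, weak$v, a$t, c(0, 12))$relation,
               "undetermined")
})

surrogate_classes <- list(
  list(group_name = "VAx", members = c("VAx1", "VAx2")),
  list(group_name = "DAx", members = "DAx1"),
  list(group_name = "VDx", members = c("VDx1", "VDx2")))

test_that("report on constructed in/anti-phase traces gives the known verdicts", {
  ts <- make_surrogate_traces(
    c(VAx1 = 0, VAx2 = 0, DAx1 = 0, VDx1 = pi, VDx2 = pi),
    period = 2.5, amplitude = 10, noise_sd = 0)
  rep <- build_report(ts, surrogate_classes)
  expect_equal(rep$circuit_verdict, "oscillatory")
  pp <- rep$phase_pairs
  pick <- function(a, b) pp$relation[(pp$neuron_a == a & pp$neuron_b == b) |
                                     (pp$neuron_a == b & pp$neuron_b == a)]
  expect_equal(pick("VAx1", "DAx1"), "in_phase")
  expect_equal(pick("VAx1", "VAx2"), "in_phase")
  expect_equal(pick("VAx1", "VDx1"), "anti_phase")
  expect_equal(pick("DAx1", "VDx2"), "anti_phase")
  expect_equal(rep$per_class$oscillating_fraction, c(1, 1, 1))
  expect_equal(rep$per_class$median_period, rep(2.5, 3), tolerance = 0.01)
})

test_that("an all-constant trace set is silent with no periods", {
  t <- seq(0, 12, by = 0.01)
  volt <- matrix(-35, 5, length(t),
                 dimnames = list(c("VAx1", "VAx2", "DAx1", "VDx1", "VDx2")))
  ts <- trace_set(t, volt)
  rep <- build_report(ts, surrogate_classes)
  expect_equal(rep$circuit_verdict, "silent")
  expect_true(all(is.na(rep$per_neuron$period)))
  expect_equal(nrow(rep$phase_pairs), 0)
})

test_that("zeroing an oscillating trace never promotes the verdict", {
  ts <- make_surrogate_traces(
    c(VAx1 = 0, VAx2 = 0, DAx1 = 0, VDx1 = pi, VDx2 = pi),
    period = 2.5, amplitude = 10, noise_sd = 0.5, seed = 3)
  rank <- c(silent = 0, weak = 1, oscillatory = 2)
  prev <- build_report(ts, surrogate_classes)$circuit_verdict
  for (nm in rownames(ts$voltage)) {
    ts$voltage[nm, ] <- 0
    cur <- build_report(ts, surrogate_classes)$circuit_verdict
    expect_lte(rank[[cur]], rank[[prev]])
    prev <- cur
  }
  expect_equal(prev, "silent")
})

test_that("reports persist to JSON and CSV", {
  ts <- make_surrogate_traces(c(VAx1 = 0, VAx2 = 0, DAx1 = 0,
                                VDx1 = pi, VDx2 = pi))
  rep <- build_report(ts, surrogate_classes)
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  write_report(rep, jp, cp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$circuit_verdict, "oscillatory")
  expect_equal(nrow(back$per_neuron), 5)
  expect_equal(read.csv(cp)$neuron, rep$per_neuron$neuron)
})
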