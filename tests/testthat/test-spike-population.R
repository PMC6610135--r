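test_that("kernel rate places unit-area Gaussian bumps at spike times", {
  kr <- kernel_rate(1, sigma = 0.005, fs = 1000, interval = c(0, 2))
  expect_equal(max(kr$rate), 1 / (sqrt(2 * pi) * 0.005), tolerance = 1e-3)
  expect_equal(kr$time[which.max(kr$rate)], 1, tolerance = 2e-3)
  # trapezoid integral equals the spike count for interior spikes
  spikes <- c(0.4, 0.9, 1.3, 1.31, 1.7)
  kr2 <- kernel_rate(spikes, sigma = 0.005, fs = 1000, interval = c(0, 2))
  integral <- sum(kr2$rate) / 1000
  expect_lt(abs(integral - length(spikes)) / length(spikes), 0.001)
  # empty train is a zero trace, not an error
  kr0 <- kernel_rate(numeric(0), sigma = 0.005, fs = 1000, interval = c(0, 1))
  expect_true(all(kr0$rate == 0))
})

test_that("kernel rate recovers a Poisson rate and is linear in spike trains", {
  set.seed(1)
  spikes <- sort(runif(3000, 0, 100)) # 30 spikes/s
  kr <- kernel_rate(spikes, sigma = 0.15, fs = 500, interval = c(0, 100))
  inner <- kr$time > 2 & kr$time < 98
  expect_lt(abs(mean(kr$rate[inner]) - 30), 3 * sqrt(3000) / 100)

  a <- spikes[1:1000]; b <- spikes[1001:3000]
  ra <- kernel_rate(a, 0.15, 500, c(0, 100))$rate
  rb <- kernel_rate(b, 0.15, 500, c(0, 100))$rate
  expect_equal(ra + rb, kr$rate, tolerance = 1e-10)
})

test_that("rate correlation matrices are symmetric with unit diagonal", {
  set.seed(2)
  pop <- make_tuned_population(n_units = 6, kappa = 2, base_rate = 25,
                               duration = 30, seed = 2)
  suppressWarnings(mats <- rate_correlation_matrices(pop$spikes, fs = 500))
  for (m in list(mats$slow, mats$fast)) {
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(1, nrow(m)))
    expect_true(all(m >= -1 & m <= 1))
  }
})

test_that("duplicated units correlate at one; independent units near zero", {
  set.seed(3)
  tt <- sort(runif(600, 0, 30))
  st <- cpgnet:::new_spike_trains(
    unit = c(rep(1, 600), rep(2, 600), rep(3, 500)),
    time = c(tt, tt, runif(500, 0, 30)),
    interval = c(0, 30))
  mats <- rate_correlation_matrices(st, fs = 500)
  expect_equal(mats$fast["1", "2"], 1, tolerance = 1e-6)
  expect_equal(mats$slow["1", "2"], 1, tolerance = 1e-6)
  expect_lt(abs(mats$fast["1", "3"]), 0.05)
})

test_that("zero-spike units are excluded with a warning", {
  st <- cpgnet:::new_spike_trains(
    unit = c(rep(1, 50), rep(2, 50)),
    time = runif(100, 0, 10), interval = c(0, 10), units = 1:3)
  expect_warning(mats <- rate_correlation_matrices(st, fs = 500), "zero spikes")
  expect_equal(mats$excluded, 3)
  expect_equal(dim(mats$slow), c(2, 2))
})

test_that("phase-comodulated units with independent spiking decouple timescales", {
  # same tuning, independent realizations: slow correlation high, fast near zero
  pop <- make_tuned_population(n_units = 2, preferred_phase = c(0, 0),
                               kappa = 3, base_rate = 40, duration = 60,
                               seed = 4)
  mats <- rate_correlation_matrices(pop$spikes, fs = 500)
  expect_gt(mats$slow[1, 2], 0.5)
  expect_lt(abs(mats$fast[1, 2]), 0.1)
  expect_gt(mats$slow[1, 2], abs(mats$fast[1, 2]) + 0.4)
})

test_that("Rayleigh statistic and p-value follow the closed form", {
  rt <- rayleigh_test(rep(pi / 3, 10))
  expect_equal(rt$r, 1, tolerance = 1e-12)
  expect_equal(rt$z, 10, tolerance = 1e-12)
  expect_equal(rt$preferred_phase_deg, 60, tolerance = 1e-9)
  expect_true(rt$significant)

  # perfectly balanced phases: resultant zero, p = 1
  rt0 <- rayleigh_test(seq(0, 2 * pi, length.out = 101)[-101])
  expect_lt(rt0$r, 1e-10)
  expect_equal(rt0$p_value, 1, tolerance = 1e-6)
  expect_error(rayleigh_test(numeric(0)), "at least one")
})

test_that("Rayleigh p decreases monotonically in R at fixed N", {
  for (n in c(10, 50, 500)) {
    r <- seq(0.01, 0.99, by = 0.01)
    rn <- r * n
    log_p <- sqrt(1 + 4 * n + 4 * (n^2 - rn^2)) - (1 + 2 * n)
    expect_true(all(diff(log_p) < 0))
    # and the function agrees with the direct formula
    phases <- c(rep(0, 30), runif(20, 0, 2 * pi))
    rt <- rayleigh_test(phases)
    expect_equal(rt$p_value,
                 min(1, exp(sqrt(1 + 4 * rt$n + 4 * (rt$n^2 - rt$r_n^2)) -
                              (1 + 2 * rt$n))))
  }
})

test_that("instantaneous phase tracks the analytic signal", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  x <- sin(2 * pi * 2 * t)
  ph <- instantaneous_phase(x, fs, smooth_sigma = 0)
  slope <- coef(lm(cumsum(c(0, pmin(abs(diff(ph)), 2 * pi - abs(diff(ph))))) ~ t))[2]
  expect_lt(abs(slope - 2 * pi * 2) / (2 * pi * 2), 0.01)

  # envelope and offset invariance
  am <- (1.5 + sin(2 * pi * 0.2 * t)) * sin(2 * pi * 2 * t) + 3
  ph2 <- instantaneous_phase(am, fs, smooth_sigma = 0)
  mid <- t > 2 & t < 8
  dphi <- atan2(sin(ph2 - ph), cos(ph2 - ph))
  expect_lt(median(abs(dphi[mid])), 0.15)

  expect_error(instantaneous_phase(x, fs, mask = rep(FALSE, length(x))),
               "masked")
})

test_that("spike-triggered phase histograms find the preferred phase", {
  fs <- 1000
  t <- seq(0, 20, by = 1 / fs)
  phase <- (2 * pi * t) %% (2 * pi)
  phase <- atan2(sin(phase), cos(phase)) # wrap to (-pi, pi]
  # spikes exactly at phase pi/2 (t = 0.25 mod 1)
  sh <- spike_triggered_phase_hist(seq(0.25, 19.25, by = 1), phase, fs)
  expect_equal(sh$preferred_phase_deg, 90, tolerance = 1)
  expect_equal(max(sh$counts), sum(sh$counts))

  set.seed(5)
  sh_unif <- spike_triggered_phase_hist(runif(2000, 0, 20), phase, fs)
  expect_lt(sh_unif$r, 0.08)
  expect_error(spike_triggered_phase_hist(numeric(0), phase, fs), "No spikes")
})

test_that("von Mises tuned units are recovered within a few degrees", {
  mu_true <- 2 * pi * 130 / 360
  pop <- make_tuned_population(n_units = 1, preferred_phase = mu_true,
                               kappa = 4, base_rate = 60, duration = 30,
                               fs = 1000, seed = 6)
  ph <- instantaneous_phase(pop$reference$signal, 1000, smooth_sigma = 0)
  sh <- spike_triggered_phase_hist(pop$spikes$time, ph, 1000)
  expect_gt(sh$n, 300)
  delta <- abs(sh$preferred_phase_deg - 130)
  expect_lt(min(delta, 360 - delta), 5)
})

test_that("rhythmicity screening separates tuned from untuned units", {
  n_each <- 12
  pop <- make_tuned_population(
    n_units = 2 * n_each,
    preferred_phase = rep(seq(0, 2 * pi, length.out = n_each + 1)[-1], 2),
    kappa = c(rep(2, n_each), rep(0, n_each)),
    base_rate = 30, duration = 25, fs = 500, seed = 7)
  # mask out filter/Hilbert edge transients ("ongoing activity" only)
  tgrid <- pop$reference$time
  ph <- instantaneous_phase(pop$reference$signal, 500, smooth_sigma = 0,
                            mask = tgrid > 2 & tgrid < 23)
  screen <- screen_rhythmic_units(pop$spikes, ph, 500)
  tuned <- screen$included[1:n_each]
  untuned <- screen$included[(n_each + 1):(2 * n_each)]
  expect_gte(mean(tuned), 0.9)   # power: kappa = 2 at ~500 spikes
  expect_lte(mean(untuned), 0.25) # type-I at alpha = 0.05

  # zero-spike unit excluded with its reason
  st <- cpgnet:::new_spike_trains(unit = rep(1, 20),
                                  time = runif(20, 0, 5),
                                  interval = c(0, 5), units = 1:2)
  sc2 <- screen_rhythmic_units(st, ph[1:2501], 500)
  expect_false(sc2$included[sc2$unit == 2])
  expect_equal(sc2$reason[sc2$unit == 2], "no spikes")
})
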