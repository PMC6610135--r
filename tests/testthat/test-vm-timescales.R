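fs <- 1000

test_that("band decomposition isolates in-band and out-of-band tones", {
  t <- seq(0, 20, by = 1 / fs)
  slow_tone <- sin(2 * pi * 1 * t)
  sp <- decompose_vm(slow_tone, fs)
  expect_lt(sd(sp$fast), 0.01 * sd(slow_tone))
  expect_gt(cor(sp$slow, slow_tone), 0.999)

  fast_tone <- sin(2 * pi * 50 * t)
  sp2 <- decompose_vm(fast_tone, fs)
  expect_lt(sd(sp2$slow), 0.01 * sd(fast_tone))
  expect_gt(cor(sp2$fast, fast_tone), 0.999)
})

test_that("white-noise component power matches the filter transfer function", {
  set.seed(1)
  n <- 2^16
  x <- rnorm(n)
  sp <- decompose_vm(x, fs)
  # oracle: FFT evaluation of the digital filters' transfer functions,
  # |H|^4 because each section is applied forward and backward
  gain <- function(flt, f) {
    z <- exp(-2i * pi * f / fs)
    Mod(outer(z, seq_along(flt$b) - 1, `^`) %*% flt$b) /
      Mod(outer(z, seq_along(flt$a) - 1, `^`) %*% flt$a)
  }
  f <- seq(0, fs / 2, length.out = 2^12)
  hp5 <- signal::butter(3, 5 / (fs / 2), "high")
  hp02 <- signal::butter(3, 0.2 / (fs / 2), "high")
  lp5 <- signal::butter(3, 5 / (fs / 2), "low")
  frac_fast <- mean(gain(hp5, f)^4)
  frac_slow <- mean((gain(hp02, f) * gain(lp5, f))^4)
  # compare on the interior: reflect padding of a white-noise (non-smooth)
  # input leaves edge transients that are not part of the transfer function
  mid <- 4000:(n - 4000)
  expect_lt(abs(var(sp$fast[mid]) / var(x[mid]) - frac_fast) / frac_fast, 0.05)
  expect_lt(abs(var(sp$slow[mid]) / var(x[mid]) - frac_slow) / frac_slow, 0.15)
})

test_that("decomposition is linear and validates its inputs", {
  set.seed(2)
  x <- rnorm(8000)
  a <- -3.7
  s1 <- decompose_vm(x, fs)
  s2 <- decompose_vm(a * x, fs)
  expect_equal(s2$slow, a * s1$slow, tolerance = 1e-6)
  expect_equal(s2$fast, a * s1$fast, tolerance = 1e-6)
  expect_error(decompose_vm(x, fs = 8), "Nyquist|too low")
  expect_error(decompose_vm(rnorm(100), fs), "too short")
})

test_that("spike clipping removes large excursions before filtering", {
  set.seed(3)
  x <- rnorm(6000)
  spikes_at <- c(1000, 3000, 5000)
  x[spikes_at] <- 40
  cleaned <- cpgnet:::clip_action_potentials(x, 5)
  expect_true(all(cleaned[spikes_at] < 5))
  expect_equal(cleaned[-spikes_at], x[-spikes_at])
})

test_that("pearson matches hand-computed values and validates", {
  expect_equal(pearson(1:10, 1:10), 1)
  expect_equal(pearson(1:10, -(1:10)), -1)
  expect_equal(pearson(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(pearson(1:5, 1:4), "equal length")
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
})

test_that("sliding correlation recovers identity, lag ridges and noise floor", {
  set.seed(4)
  x <- rnorm(8000)
  sc <- sliding_correlation(x, x, fs, window = 0.4, step = 0.05)
  expect_true(all(abs(sc$zero_lag$r - 1) < 1e-10))

  delay <- 30 # samples
  y <- c(rep(0, delay), x[1:(length(x) - delay)])
  sc2 <- sliding_correlation(x, y, fs, window = 0.4, step = 0.05,
                             max_lag = 0.1)
  ridge <- sc2$lag[apply(sc2$correlogram, 2, which.max)]
  expect_equal(median(ridge), delay / fs, tolerance = 1e-9)

  y_ind <- rnorm(8000)
  sc3 <- sliding_correlation(x, y_ind, fs, window = 0.4, step = 0.05)
  expect_lt(abs(mean(sc3$zero_lag$r)), 0.05)
  # Fisher variance approximation: sd ~ 1/sqrt(window samples)
  expect_lt(sd(sc3$zero_lag$r), 2.5 / sqrt(400))
  expect_gt(sd(sc3$zero_lag$r), 0.4 / sqrt(400))
  expect_error(sliding_correlation(x, y_ind, fs, window = 0.005),
               "degenerate")
})

test_that("shuffle null separates shared input from chance", {
  set.seed(5)
  pair <- raw_noise_pair(6000, c_shared = 0.6, seed = 5)
  sn <- shuffle_null(pair$x, pair$y, fs, n_shuffles = 200, seed = 1)
  expect_gt(sn$observed, sn$upper) # construction: strongly shared
  expect_equal(sn$upper, sn$null_mean + 1.96 * sn$null_sd)
  expect_lt(abs(sn$null_mean), 0.05)
  expect_error(shuffle_null(pair$x[1:1000], pair$y[1:1000], fs,
                            shift_range = c(0.5, 2)), "exceeds")
})

test_that("shuffle limits cover independent pairs at roughly the nominal rate", {
  hits <- vapply(1:150, function(s) {
    pair <- raw_noise_pair(3000, c_shared = 0, seed = 1000 + s)
    sn <- shuffle_null(pair$x, pair$y, fs, n_shuffles = 100, seed = s)
    sn$observed >= sn$lower && sn$observed <= sn$upper
  }, logical(1))
  expect_gt(mean(hits), 0.88)
})

test_that("pair phase resolves offsets in degrees of the dominant period", {
  t <- seq(0, 20, by = 1 / fs)
  a <- sin(2 * pi * t)
  expect_equal(pair_phase(a, a, fs)$phase_deg, 0, tolerance = 1)
  expect_equal(pair_phase(a, -a, fs)$phase_deg, 180, tolerance = 1)
  quarter <- sin(2 * pi * (t - 0.25))
  ph <- pair_phase(a, quarter, fs)
  expect_equal(ph$phase_deg, 90, tolerance = 2)
  expect_equal(ph$period, 1, tolerance = 0.05)
  set.seed(6)
  expect_error(pair_phase(rnorm(5000), a[1:5000], fs), "not rhythmic")
})

test_that("quiescence mask flags silent epochs and changes fast summaries", {
  t <- seq(0, 20, by = 1 / fs)
  active <- sin(2 * pi * t)
  expect_true(!any(quiescence_mask(active, fs)))

  half_silent <- active
  half_silent[t > 10] <- 0
  mask <- quiescence_mask(half_silent, fs)
  expect_gt(mean(mask[t > 11]), 0.9)
  expect_lt(mean(mask[t < 9]), 0.1)
  expect_warning(quiescence_mask(rep(0, 5000), fs), "quiescent")

  # shared fast input only during the active half: masking changes fast R
  set.seed(7)
  n <- length(t)
  common <- rnorm(n)
  on <- t <= 10
  x <- 5 * half_silent + ifelse(on, common, rnorm(n))
  y <- 5 * half_silent + ifelse(on, common, rnorm(n))
  vm <- cbind(x, y)
  r_all <- vm_pair_correlations(vm, fs)$fast_r
  r_masked <- vm_pair_correlations(vm, fs, mask_quiescence = TRUE)$fast_r
  expect_gt(r_masked, r_all + 0.05)
})

test_that("same-cell control gives unit correlation on both timescales", {
  top <- build_fixed_indegree(20, 2, 10, seed = 8)
  sim <- simulate_network(top, drive_params(12, 10, 1, 10),
                          synapses = synapse_params(g_exc = 10), seed = 8)
  vm <- cbind(sim$vm$vm[, 1], sim$vm$vm[, 1])
  pc <- vm_pair_correlations(vm, sim$vm$fs)
  expect_equal(pc$slow_r, 1, tolerance = 1e-12)
  expect_equal(pc$fast_r, 1, tolerance = 1e-12)
})

test_that("planted anti-phase modulation yields a negative rate dependence", {
  set.seed(9)
  dur <- 60
  t <- seq(0, dur, by = 1 / fs)
  n <- length(t)
  envelope <- sin(2 * pi * 0.5 * t)           # "Vm" rhythm
  w <- (1 - envelope) / 2                      # shared fraction, anti-phase
  common <- rnorm(n); e1 <- rnorm(n); e2 <- rnorm(n)
  x <- sqrt(w) * common + sqrt(1 - w) * e1
  y <- sqrt(w) * common + sqrt(1 - w) * e2
  sc <- sliding_correlation(x, y, fs, window = 0.4, step = 0.02, max_lag = 0)
  dep <- fastcorr_rate_dependence(sc$zero_lag, envelope, fs,
                                  n_shuffles = 50, seed = 2)
  expect_lt(dep$r, -0.15)
  expect_lt(dep$r, quantile(dep$null_r, 0.05))
})
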