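test_that("homogeneous Poisson counts match the rate", {
  st <- sample_inhomogeneous_poisson(
    drive_params(12, 0, 1, 100), n_units = 8, seed = 1)
  counts <- table(factor(st$unit, levels = 1:8))
  # each count ~ Poisson(1200)
  expect_true(all(abs(counts - 1200) < 4 * sqrt(1200)))
  expect_true(all(st$time >= 0 & st$time <= 100))
  expect_false(is.unsorted(st$time[st$unit == 1]))
})

test_that("sinusoidal rate modulation is recovered from sampled trains", {
  drive <- drive_params(12, 10, 1, 30)
  st <- sample_inhomogeneous_poisson(drive, n_units = 40, seed = 2)
  # pooled kernel rate, sigma = 150 ms; fit a 1 Hz quadrature pair
  kr <- kernel_rate(st$time, sigma = 0.15, fs = 200, interval = c(0, 30))
  pooled <- kr$rate / 40
  co <- cos(2 * pi * kr$time); si <- sin(2 * pi * kr$time)
  fit <- lm(pooled ~ si + co)
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  # the 150 ms Gaussian kernel attenuates a 1 Hz sinusoid by exp(-(2 pi f sigma)^2 / 2)
  expect_lt(abs(amp - 10 * exp(-(2 * pi * 0.15)^2 / 2)), 1.5)
  expect_lt(abs(mean(pooled) - 12), 1)
})

test_that("thinning reproduces the rate profile over phase", {
  drive <- drive_params(20, 15, 1, 200)
  st <- sample_inhomogeneous_poisson(drive, n_units = 1, seed = 3)
  phase_bin <- floor((st$time %% 1) * 20) + 1
  counts <- tabulate(phase_bin, nbins = 20)
  centers <- (seq_len(20) - 0.5) / 20
  expected <- pmax(0, 20 + 15 * sin(2 * pi * centers)) * 200 / 20
  # chi-square-style agreement, 3 sigma per bin
  expect_true(all(abs(counts - expected) < 3 * sqrt(pmax(expected, 1)) + 3))
  expect_error(sample_inhomogeneous_poisson(drive_params(5, 0, 1, -1), 1),
               "duration")
})

test_that("zero drive leaves receivers at the leak equilibrium", {
  top <- build_fixed_indegree(5, 3, 2, seed = 1)
  sim <- simulate_network(top, drive_params(0, 0, 1, 1), seed = 1)
  expect_true(all(sim$vm$vm == -60))
  expect_equal(nrow(sim$source_spikes), 0)
})

test_that("high-rate drive settles at the conductance fixed point", {
  # k * g * tau * rate = 10 * 1 nS * 1 ms * 2000/s = 20 nS mean excitation
  top <- build_fixed_indegree(10, 2, 10, seed = 1)
  sim <- simulate_network(top, drive_params(2000, 0, 1, 4),
                          synapses = synapse_params(g_exc = 1), seed = 1)
  v_inf <- (16.67 * -60 + 20 * 0) / (16.67 + 20)
  late <- sim$vm$vm[2000:4000, ]
  expect_lt(abs(mean(late) - v_inf), 1)
})

test_that("compiled integrator matches the plain-R reference network", {
  spec <- motif_spec("recurrent_inh", rho_drive = 0.4, rho_inh = 0.6,
                     rho_rec = 0.6, n_source = 6, n_inh = 5, n_receiver = 4)
  net <- build_motif(spec, seed = 7)
  drive <- drive_params(300, 200, 2, 1.5)
  sim <- simulate_network(net, drive, synapses = synapse_params(g_exc = 5, g_inh = 15),
                          seed = 7, record_fs = 10000)
  src <- sample_inhomogeneous_poisson(drive, 6, seed = cpgnet:::derive_seed(7, 101L))
  ref <- ref_lif_sim(src, net, n_source = 6, n_rec = 4, n_inh = 5,
                     duration = 1.5, record_every = 1L,
                     g_exc = 5, g_inh = 15)
  expect_lt(max(abs(sim$vm$vm - ref$vm)), 1e-9)
  ref_sp <- data.frame(unit = ref$inh_unit, time = ref$inh_time)
  ref_sp <- ref_sp[order(ref_sp$unit, ref_sp$time), ]
  expect_equal(sim$inh_spikes$unit, ref_sp$unit)
  expect_equal(sim$inh_spikes$time, ref_sp$time, tolerance = 1e-12)
})

test_that("simulation is deterministic for a fixed seed and config", {
  net <- build_motif(motif_spec("ff_inh", n_source = 20, n_inh = 10,
                                n_receiver = 5), seed = 3)
  s1 <- simulate_network(net, drive_params(80, 70, 1, 3),
                         synapses = synapse_params(g_exc = 5), seed = 11)
  s2 <- simulate_network(net, drive_params(80, 70, 1, 3),
                         synapses = synapse_params(g_exc = 5), seed = 11)
  expect_identical(s1$vm$vm, s2$vm$vm)
  expect_identical(s1$inh_spikes$time, s2$inh_spikes$time)
})

test_that("membrane potentials stay within the reversal-potential bounds", {
  for (m in c("ff_exc", "recurrent_inh")) {
    net <- build_motif(motif_spec(m, n_source = 50, n_inh = 30,
                                  n_receiver = 10), seed = 1)
    sim <- simulate_network(net, drive_params(150, 100, 1, 4),
                            synapses = synapse_params(g_exc = 5, g_inh = 15),
                            seed = 1)
    expect_true(all(sim$vm$vm >= -80 & sim$vm$vm <= 0))
  }
})

test_that("halving the integration step barely changes the trajectories", {
  top <- build_fixed_indegree(20, 5, 10, seed = 5)
  s1 <- simulate_network(top, drive_params(12, 10, 1, 4),
                         synapses = synapse_params(g_exc = 10),
                         dt = 0.1, seed = 5)
  s2 <- simulate_network(top, drive_params(12, 10, 1, 4),
                         synapses = synapse_params(g_exc = 10),
                         dt = 0.05, seed = 5)
  rms <- sqrt(mean((s1$vm$vm - s2$vm$vm)^2))
  expect_lt(rms, 0.1)
})

test_that("invalid simulation configurations error", {
  top <- build_fixed_indegree(5, 3, 2, seed = 1)
  expect_error(simulate_network(top, drive_params(10, 0, 1, 1), dt = 0.5),
               "too coarse")
  # mismatched motif populations
  bad <- structure(list(
    drive_receiver = build_fixed_indegree(5, 3, 2, seed = 1),
    drive_inh = build_fixed_indegree(6, 4, 2, seed = 1),
    inh_receiver = build_fixed_indegree(4, 3, 2, seed = 1)),
    class = "cpg_motif")
  expect_error(simulate_network(bad, drive_params(10, 0, 1, 1)), "drive")
})

test_that("receiver fast correlation tracks the analytic shared-input fraction", {
  # oracle equivalence with predicted_correlation at two sparseness levels
  for (cfg in list(c(n = 20, exp = 0.5), c(n = 100, exp = 0.1))) {
    top <- build_fixed_indegree(cfg[["n"]], 12, 10, seed = cfg[["n"]])
    sim <- simulate_network(top, drive_params(12, 10, 1, 30),
                            synapses = synapse_params(g_exc = 10),
                            seed = cfg[["n"]])
    pc <- vm_pair_correlations(sim$vm)
    expect_lt(abs(mean(pc$fast_r) - cfg[["exp"]]),
              max(3 * sd(pc$fast_r) / sqrt(nrow(pc)), 0.03))
  }
})
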