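# Shared helpers: an independent plain-R reference integrator for the
# conductance-based LIF network (oracle for the compiled path), and small
# fixture builders.

# Reference network integrator, written independently of the compiled code:
# same model definition (exponential-Euler voltage and conductance decay,
# delayed delivery, threshold/reset interneurons), direct dense-matrix
# bookkeeping. Only usable for tiny problems.
ref_lif_sim <- function(src_spikes, graphs, n_source, n_rec, n_inh,
                        duration, dt = 0.1, record_every = 1L,
                        C = 250, gL = 16.67, EL = -60,
                        V_th = -50, V_reset = -60, t_ref = 2,
                        tau = 1, E_exc = 0, E_inh = -80,
                        g_exc = 10, g_inh = 15, delay = 1) {
  n_steps <- round(duration * 1000 / dt)
  D <- max(1L, round(delay / dt))
  adj <- function(top, n_pre, n_post) {
    A <- matrix(0, n_post, n_pre)
    if (!is.null(top)) for (r in seq_len(nrow(top))) {
      A[top$target[r], top$source[r]] <- A[top$target[r], top$source[r]] + 1
    }
    A
  }
  A_dr <- adj(graphs$drive_receiver, n_source, n_rec)
  A_di <- adj(graphs$drive_inh, n_source, max(n_inh, 1))
  A_ir <- adj(graphs$inh_receiver, max(n_inh, 1), n_rec)
  A_ii <- adj(graphs$inh_inh, max(n_inh, 1), max(n_inh, 1))
  # off-grid spikes land on the next grid point with a pre-decayed weight
  step_exact <- src_spikes$time * 1000 / dt
  drive_step <- ceiling(step_exact) + D
  drive_w <- exp(-(ceiling(step_exact) - step_exact) * dt / tau)
  V_r <- rep(EL, n_rec); gE_r <- numeric(n_rec); gI_r <- numeric(n_rec)
  V_i <- rep(EL, n_inh); gE_i <- numeric(n_inh); gI_i <- numeric(n_inh)
  refr <- integer(n_inh)
  dec <- exp(-dt / tau)
  ref_steps <- round(t_ref / dt)
  pending_inh <- vector("list", n_steps + D + 1L)
  vm <- matrix(NA_real_, ceiling(n_steps / record_every), n_rec)
  inh_sp_unit <- integer(0); inh_sp_time <- numeric(0)
  samp <- 0L
  for (t in seq_len(n_steps) - 1L) {
    if (t %% record_every == 0L) {
      samp <- samp + 1L
      vm[samp, ] <- V_r
    }
    here <- which(drive_step == t)
    if (length(here)) {
      cnt <- numeric(n_source)
      for (h in here) {
        u <- src_spikes$unit[h]
        cnt[u] <- cnt[u] + drive_w[h]
      }
      gE_r <- gE_r + g_exc * as.numeric(A_dr %*% cnt)
      if (n_inh > 0) gE_i <- gE_i + g_exc * as.numeric(A_di %*% cnt)
    }
    if (n_inh > 0 && !is.null(pending_inh[[t + 1L]])) {
      cnt <- tabulate(pending_inh[[t + 1L]], nbins = n_inh)
      gI_r <- gI_r + g_inh * as.numeric(A_ir %*% cnt)
      gI_i <- gI_i + g_inh * as.numeric(A_ii %*% cnt)
    }
    gtot_r <- gL + gE_r + gI_r
    veq_r <- (gL * EL + gE_r * E_exc + gI_r * E_inh) / gtot_r
    V_r <- veq_r + (V_r - veq_r) * exp(-gtot_r * dt / C)
    gE_r <- gE_r * dec; gI_r <- gI_r * dec
    if (n_inh > 0) {
      active <- refr <= 0L
      gtot_i <- gL + gE_i + gI_i
      veq_i <- (gL * EL + gE_i * E_exc + gI_i * E_inh) / gtot_i
      V_new <- veq_i + (V_i - veq_i) * exp(-gtot_i * dt / C)
      V_i[active] <- V_new[active]
      V_i[!active] <- V_reset
      refr[!active] <- refr[!active] - 1L
      sp <- which(active & V_i >= V_th)
      if (length(sp)) {
        inh_sp_unit <- c(inh_sp_unit, sp)
        inh_sp_time <- c(inh_sp_time, rep((t + 1) * dt * 1e-3, length(sp)))
        V_i[sp] <- V_reset
        refr[sp] <- ref_steps
        slot <- t + D + 1L
        pending_inh[[slot]] <- c(pending_inh[[slot]], sp)
      }
      gE_i <- gE_i * dec; gI_i <- gI_i * dec
    }
  }
  list(vm = vm, inh_unit = inh_sp_unit, inh_time = inh_sp_time)
}

# band-limited white-noise pair with known fast correlation, built without
# the package's own generator (for cross-checks)
raw_noise_pair <- function(n, c_shared, seed) {
  set.seed(seed)
  z0 <- rnorm(n); z1 <- rnorm(n); z2 <- rnorm(n)
  list(x = sqrt(c_shared) * z0 + sqrt(1 - c_shared) * z1,
       y = sqrt(c_shared) * z0 + sqrt(1 - c_shared) * z2)
}
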