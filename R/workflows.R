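# High-level workflows chaining topology construction, simulation and
# correlation analysis into the study's standard computations.

mean_pair_correlations <- function(sim) {
  pc <- vm_pair_correlations(sim$vm)
  c(fast = mean(pc$fast_r), slow = mean(pc$slow_r))
}

#' Source-population size sweep
#'
#' Simulates the feedforward common-drive configuration across a range of
#' source-population sizes at fixed in-degree, and summarizes the mean
#' pairwise fast- and slow-component correlations per size. With the
#' in-degree held at `k`, the fast correlation is predicted to decay as
#' `k / n` while sparseness `1 - k / n` climbs toward one.
#'
#' @param sizes Source-population sizes (each >= `k`).
#' @param k In-degree per receiver.
#' @param n_receiver Receiver population size.
#' @param seeds Integer seeds; each (size, seed) pair is one simulation.
#' @param drive A [drive_params()] (default: 12 +/- 10 spikes/s at 1 Hz).
#' @param synapses A [synapse_params()] (default 10 nS excitation).
#' @param duration Simulated duration, s (overrides `drive$duration`).
#' @return A tibble with one row per size: `n_source`, `rho`, `predicted_r`,
#'   `mean_fast_r`, `sd_fast_r`, `mean_slow_r`, `n_pairs`; per-run values
#'   in the `runs` attribute.
#' @export
run_size_sweep <- function(sizes = c(10, 20, 50, 100, 200, 500), k = 10,
                           n_receiver = 30, seeds = 1:3,
                           drive = drive_params(12, 10, 1, 60),
                           synapses = synapse_params(g_exc = 10),
                           duration = NULL) {
  if (any(sizes < k)) abort("All sizes must be at least the in-degree k.")
  if (!is.null(duration)) drive$duration <- duration
  runs <- purrr::map(sizes, function(n) {
    purrr::map(seeds, function(s) {
      top <- build_fixed_indegree(n, n_receiver, k, seed = derive_seed(s, n))
      sim <- simulate_network(top, drive, synapses = synapses, seed = s)
      m <- mean_pair_correlations(sim)
      tibble(n_source = n, seed = s, fast_r = m[["fast"]],
             slow_r = m[["slow"]])
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  out <- runs |>
    dplyr::group_by(.data$n_source) |>
    dplyr::summarise(mean_fast_r = mean(.data$fast_r),
                     sd_fast_r = sd(.data$fast_r),
                     mean_slow_r = mean(.data$slow_r), .groups = "drop") |>
    dplyr::mutate(rho = 1 - k / .data$n_source,
                  predicted_r = k / .data$n_source,
                  n_pairs = choose(n_receiver, 2) * length(seeds),
                  .after = "n_source")
  attr(out, "runs") <- runs
  attr(out, "k") <- k
  out
}

#' Log-log decay exponent of correlation vs network size
#'
#' Least-squares slope of `log(mean fast R)` against `log(n_source)`; a
#' value near -1 is the `1/n` decay signature of fixed in-degree shared
#' input.
#'
#' @param sweep Output of [run_size_sweep()].
#' @return The fitted slope.
#' @export
sweep_decay_exponent <- function(sweep) {
  unname(coef(lm(log(mean_fast_r) ~ log(n_source), data = sweep))[2])
}

#' Compare the three connectivity motifs
#'
#' Runs the feedforward-excitation, feedforward-inhibition and recurrent-
#' inhibition motifs under identical drive and tabulates the receiver-pair
#' fast correlations. Active decorrelation shows up as the recurrent
#' motif's correlations falling below the two feedforward motifs.
#'
#' @param motifs Which motifs to run.
#' @param seeds Integer seeds (one full motif set per seed).
#' @param drive A [drive_params()] (default 80 +/- 70 spikes/s at 1 Hz).
#' @param synapses A [synapse_params()] (default 5 nS exc / 15 nS inh).
#' @param rho_drive,rho_inh,rho_rec Motif sparseness values.
#' @param n_source,n_inh,n_receiver Population sizes.
#' @param duration Simulated duration, s.
#' @return A `motif_comparison` list: `pairs` (tibble motif x seed x pair
#'   fast/slow correlations) and `summary` (mean fast R per motif).
#' @export
run_motif_comparison <- function(motifs = c("ff_exc", "ff_inh", "recurrent_inh"),
                                 seeds = 1:3,
                                 drive = drive_params(80, 70, 1, 30),
                                 synapses = synapse_params(g_exc = 5, g_inh = 15),
                                 rho_drive = 0.5, rho_inh = 0.9, rho_rec = 0.9,
                                 n_source = 100, n_inh = 100, n_receiver = 100,
                                 duration = NULL) {
  if (!is.null(duration)) drive$duration <- duration
  pairs <- purrr::map(motifs, function(m) {
    purrr::map(seeds, function(s) {
      spec <- motif_spec(m, rho_drive, rho_inh, rho_rec,
                         n_source, n_inh, n_receiver)
      net <- build_motif(spec, seed = derive_seed(s, match(m, motifs)))
      sim <- simulate_network(net, drive, synapses = synapses, seed = s)
      pc <- vm_pair_correlations(sim$vm)
      dplyr::mutate(pc, motif = m, seed = s, .before = 1)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  summary <- pairs |>
    dplyr::group_by(.data$motif) |>
    dplyr::summarise(mean_fast_r = mean(.data$fast_r),
                     sd_fast_r = sd(.data$fast_r),
                     mean_slow_r = mean(.data$slow_r), .groups = "drop")
  structure(list(pairs = pairs, summary = summary),
            class = "motif_comparison")
}

#' @export
print.motif_comparison <- function(x, ...) {
  cat("<motif_comparison>\n")
  print(x$summary)
  invisible(x)
}

#' Rate dependence of decorrelation across a receiver population
#'
#' Simulates the recurrent-inhibition motif, computes the sliding fast
#' correlation for a set of receiver pairs, and correlates each pair's
#' zero-lag trace with its low-pass filtered Vm. Under active
#' decorrelation these dependence correlations are shifted negative
#' relative to circularly shifted surrogates (two-sample Kolmogorov-
#' Smirnov test).
#'
#' @param sim A `cpg_sim` from a recurrent-motif run, or `NULL` to
#'   simulate one with the motif defaults.
#' @param n_pairs Number of receiver pairs analysed.
#' @param seed Integer seed (simulation + surrogates).
#' @param duration Simulated duration when `sim` is `NULL`, s.
#' @param n_shuffles Surrogate alignments per pair.
#' @param window,step Sliding-correlation window and step, s.
#' @return A `rate_dependence` list: `dependence` (tibble pair x observed
#'   `r`), `null_r` (pooled surrogate sample), `ks` (the `ks.test` result).
#' @export
run_rate_dependence <- function(sim = NULL, n_pairs = 55, seed = 1,
                                duration = 60, n_shuffles = 10,
                                window = 0.4, step = 0.01) {
  if (is.null(sim)) {
    spec <- motif_spec("recurrent_inh")
    net <- build_motif(spec, seed = derive_seed(seed, 11L))
    sim <- simulate_network(net, drive_params(80, 70, 1, duration),
                            synapses = synapse_params(g_exc = 5, g_inh = 15),
                            seed = seed)
  }
  fs <- sim$vm$fs
  comp <- decompose_vm(sim$vm)
  lowpass <- apply(sim$vm$vm, 2, butter_filtfilt, fs = fs, cutoff = 5,
                   type = "low")
  all_pairs <- pair_index(ncol(sim$vm$vm))
  if (n_pairs < nrow(all_pairs)) {
    set_seed_if(derive_seed(seed, 12L))
    all_pairs <- all_pairs[sample(nrow(all_pairs), n_pairs), , drop = FALSE]
  }
  rows <- purrr::map(seq_len(nrow(all_pairs)), function(p) {
    i <- all_pairs[p, 1]
    j <- all_pairs[p, 2]
    sc <- sliding_correlation(comp$fast[, i], comp$fast[, j], fs,
                              window = window, step = step, max_lag = 0)
    dep <- fastcorr_rate_dependence(
      sc$zero_lag, (lowpass[, i] + lowpass[, j]) / 2, fs,
      n_shuffles = n_shuffles, seed = derive_seed(seed, 100L + p))
    list(obs = tibble(cell_x = i, cell_y = j, r = dep$r), null = dep$null_r)
  })
  dependence <- dplyr::bind_rows(purrr::map(rows, "obs"))
  null_r <- unlist(purrr::map(rows, "null"))
  ks <- suppressWarnings(ks.test(dependence$r, null_r,
                                 alternative = "greater"))
  structure(list(dependence = dependence, null_r = null_r, ks = ks),
            class = "rate_dependence")
}

#' @export
print.rate_dependence <- function(x, ...) {
  cat(sprintf("<rate_dependence> %d pairs: mean dependence R = %.3f (null %.3f); KS D = %.3f, p = %.3g\n",
              nrow(x$dependence), mean(x$dependence$r), mean(x$null_r),
              x$ks$statistic, x$ks$p.value))
  invisible(x)
}

#' Run a standard reproduction workflow
#'
#' One-call orchestration of the package's three headline computations:
#' `"size_sweep"` (mean fast correlation vs source-population size at fixed
#' in-degree), `"motif_comparison"` (feedforward vs recurrent-inhibition
#' motifs), and `"rate_dependence"` (anti-phase relation between fast
#' correlation and low-pass Vm in the recurrent motif). The `scale` factor
#' multiplies the simulated durations (validity floor 5 s) for quick
#' desk-scale runs.
#'
#' @param workflow Which workflow to run.
#' @param scale Duration scale factor.
#' @param seed Master integer seed.
#' @param out Optional directory; when given, summary tables and a run
#'   manifest are written there.
#' @return The workflow result object.
#' @export
reproduce <- function(workflow = c("size_sweep", "motif_comparison",
                                   "rate_dependence"),
                      scale = 1, seed = 1, out = NULL) {
  workflow <- match.arg(workflow)
  check_scalar_number(scale, "scale", min = 1e-9)
  base_dur <- switch(workflow, size_sweep = 60, motif_comparison = 30,
                     rate_dependence = 60)
  dur <- base_dur * scale
  if (dur < 5) abort(sprintf("scale = %g gives a %g s run; need at least 5 s.", scale, dur))
  res <- switch(
    workflow,
    size_sweep = run_size_sweep(seeds = derive_seed(seed, 1:3) %% 100000L,
                                duration = dur),
    motif_comparison = run_motif_comparison(
      seeds = derive_seed(seed, 1:5) %% 100000L, duration = dur),
    rate_dependence = run_rate_dependence(seed = seed, duration = dur))
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    tab <- switch(workflow, size_sweep = res,
                  motif_comparison = res$summary,
                  rate_dependence = res$dependence)
    f <- file.path(out, paste0(workflow, ".tsv"))
    utils::write.table(as.data.frame(tab), f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    write_run_manifest(file.path(out, paste0(workflow, "_manifest.json")),
                       config = list(workflow = workflow, scale = scale),
                       seed = seed, files = basename(f))
  }
  res
}
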