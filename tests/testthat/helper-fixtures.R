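# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# small, fast generator configuration
quick_config <- function(..., n_animals = 3, cycles_per_episode = c(15, 20),
                         seed = 42) {
  generator_config(n_animals = n_animals,
                   cycles_per_episode = cycles_per_episode, seed = seed, ...)
}

# a noise-free configuration whose phases are exactly the stated means
noiseless_config <- function(dphi_peri = 0.2, dphi_sync = 0.05, ...,
                             seed = 7) {
  generator_config(
    var_population = 0, var_bilateral = 0, var_repetition = 0, var_cycle = 0,
    period_cv = 0,
    dphi_mean = list(cpg = c(peristaltic = dphi_peri, synchronous = dphi_sync),
                     motor = c(peristaltic = dphi_peri, synchronous = dphi_sync),
                     beat = c(peristaltic = dphi_peri, synchronous = dphi_sync)),
    seed = seed, ...)
}

# a bare phase_series for segmentation tests (bypasses spike plumbing)
make_phase_series <- function(dphi, cycle = seq_along(dphi)) {
  out <- data.frame(cycle = cycle, t_ref = cycle * 8, period = 8,
                    n_target = 1L, phi = dphi %% 1, dphi = wrap_phase(dphi))
  class(out) <- c("phase_series", class(out))
  out
}

# regular burst-like trigger times: n_bursts bursts of n_spikes, spaced so
# that alpha-function kernels never overlap
regular_triggers <- function(n_bursts = 20, n_spikes = 5, isi = 0.3,
                             burst_period = 10, t0 = 2) {
  as.numeric(vapply(seq_len(n_bursts) - 1,
                    function(b) t0 + b * burst_period + (seq_len(n_spikes) - 1) * isi,
                    numeric(n_spikes)))
}

# wrapped-normal sigma (phase units) for a target angular variance
sigma_for <- function(v) sqrt(-2 * log(1 - 2 * pi^2 * v)) / (2 * pi)
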