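# Small cohort presets used across tests; kept deliberately small so the
# whole suite runs in minutes.

tiny_config <- function(seed = 1, n_sub = 3L, n_spec = 4L, ...) {
  cohort_config(n_subjects_per_group = n_sub, spectra_per_subject = n_spec,
                seed = seed, ...)
}

# noise-free-ish, deterministic cohort: no jitter, no subject effects, no
# spikes; the only variation left is noise (if any) and the random baseline
quiet_config <- function(seed = 1, n_sub = 2L, n_spec = 3L, noise_sd = 0,
                         subject_effect_sd = 0, amplitude_jitter_sd = 0,
                         spike_rate = 0, ...) {
  tiny_config(seed = seed, n_sub = n_sub, n_spec = n_spec,
              noise_sd = noise_sd, subject_effect_sd = subject_effect_sd,
              amplitude_jitter_sd = amplitude_jitter_sd,
              spike_rate = spike_rate, ...)
}

flat_axis <- function(n = 200L, start = 400, step = 0.8) {
  start + (seq_len(n) - 1L) * step
}

gaussian_band <- function(x, center, hwhm, amp = 1) {
  amp * exp(-(x - center)^2 / (2 * (hwhm / sqrt(2 * log(2)))^2))
}

# difference_spectrum object built directly for attribution tests
fake_difference <- function(grid, delta, error = rep(0.001, length(grid))) {
  structure(list(grid = grid, delta = delta, error = error,
                 groups = c("COPD", "CTRL")),
            class = "difference_spectrum")
}
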