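# Small fixtures built in code.

# Archetype-mean amplitudes for the two movement patterns.
amp_arch1 <- c(unload = 0.50, seatoff = 1.16, stab = 0.39, stand = 1.04)
amp_arch2 <- c(unload = 0.55, seatoff = 1.15, stab = 0.69, stand = 1.01)

# A tiny two-group set of noisy near-constant series for clustering tests.
two_group_series <- function(n_per = 10, len = 20, levels = c(2, 8),
                             sd = 0.1, seed = 1) {
  set.seed(seed)
  series <- c(
    lapply(seq_len(n_per), function(i) levels[1] + rnorm(len, 0, sd)),
    lapply(seq_len(n_per), function(i) levels[2] + rnorm(len, 0, sd)))
  list(series = series, truth = rep(1:2, each = n_per))
}

# Quick synthetic participant with fixed settings.
quick_participant <- function(arch_id = 1, seed = 1, noise_sd = 0.008,
                              n_cycles = 5L, within = 0.3, rest_pad_s = 1) {
  cfg <- cohort_config(noise_sd = noise_sd, rest_pad_s = rest_pad_s,
                       within_participant_sd_scale = within)
  set.seed(seed)
  synth_participant(default_archetypes()[[arch_id]], cfg,
                    participant_id = sprintf("T%d", seed),
                    n_cycles = n_cycles)
}
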