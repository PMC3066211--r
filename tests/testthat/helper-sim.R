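# Small simulated screens for unit tests: 40 genes x 3 siRNA on 2 plates of
# 60 sample wells, full-size model otherwise. Full-geometry screens are used
# only where a test is about the screen-scale behaviour.

small_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_genes = 40, samples_per_plate = 60)
  user <- list(...)
  args[names(user)] <- user
  do.call(simulation_config, args)
}

small_screen <- function(seed = 1, ...) {
  simulate_screen(small_config(seed, ...))
}

score_small <- function(sim, config = screen_config()) {
  score_screen(sim$screen, sim$layout, sim$library, config)
}

# independent brute-force robust z (reduction-positive)
oracle_robust_z <- function(sample, x, kappa = 1.4826) {
  s <- sort(sample)
  n <- length(s)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  dev <- sort(abs(sample - med))
  mad <- if (n %% 2 == 1) dev[(n + 1) / 2] else (dev[n / 2] + dev[n / 2 + 1]) / 2
  (med - x) / (kappa * mad)
}
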