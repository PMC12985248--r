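# Shared fixtures, built in code at test time.

# small clean window set (no noise, known peaks)
tiny_windows <- function(n_records = 2L, seed = 11L, duration_s = 12,
                         noise_sd = 0, baseline_wander_amp = 0) {
  cfg <- sim_config(duration_s = duration_s, noise_sd = noise_sd,
                    baseline_wander_amp = baseline_wander_amp, seed = seed)
  recs <- generate_dataset(n_records, cfg, seed = seed,
                          hr_range = c(60, 90), ptt_range = c(0.2, 0.3))
  make_windows(recs)
}

# central finite-difference gradient of f at params[[name]][i]
fd_grad <- function(f, params, name, i, h = 1e-5) {
  pp <- params; pp[[name]][i] <- pp[[name]][i] + h
  pm <- params; pm[[name]][i] <- pm[[name]][i] - h
  (f(pp) - f(pm)) / (2 * h)
}

# one shared tiny trained/untrained model pair for the expensive
# end-to-end checks; built on first use, reused across test files
.shared <- new.env(parent = emptyenv())

shared_e2e <- function() {
  if (is.null(.shared$runs)) {
    runs <- list()
    passes <- 0L
    for (s in 1:3) {
      r <- e2e_smoke(seed = s)
      ok <- is.finite(r$metrics$hr_mae) && r$metrics$hr_mae < 5 &&
        r$metrics$rmse < r$rmse_untrained
      runs[[s]] <- r
      passes <- passes + ok
      if (passes >= 2L) break
    }
    .shared$runs <- runs
  }
  .shared$runs
}
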