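# shared fixtures: reduced MCMC settings keep unit tests quick while the
# sampler still mixes on these small posteriors

small_mcmc <- function(seed = 1L, n_steps = 4000L) {
  mcmc_config(n_chains = 3L, n_steps = n_steps, thin = 2L, seed = seed)
}

tiny_mcmc <- function(seed = 1L) {
  mcmc_config(n_chains = 2L, n_steps = 2500L, thin = 2L, seed = seed)
}

# a clean noiseless cohort config for closed-form checks
noiseless_growth <- function(...) {
  growth_sim_config(initial_volume_log_sd = 0, noise_log_sd = 0,
                    detection_floor = 0.5, ...)
}

# brute-force grid oracle for the IC50 least-squares problem
grid_ic50_oracle <- function(plate, lo, hi, n_grid = 2000L) {
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  ss <- vapply(grid, function(g) {
    sum((plate$viability_pct - 100 * (1 - plate$concentration /
                                        (plate$concentration + g)))^2)
  }, numeric(1))
  grid[which.min(ss)]
}

# per-mouse OLS slopes of ln V on day: the independent frequentist oracle
ols_slopes <- function(cohort) {
  vapply(split(cohort, cohort$mouse_id), function(d) {
    unname(coef(lm(log(volume_mm3) ~ day, data = d))[2])
  }, numeric(1))
}
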