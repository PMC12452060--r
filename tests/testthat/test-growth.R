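test_that("caliper volume follows pi/6 * length * width^2", {
  expect_equal(caliper_volume(0, 0), 0)
  expect_equal(caliper_volume(10, 8), pi / 6 * 10 * 64)
  expect_equal(caliper_volume(10, 8), 335.1032, tolerance = 1e-6)
  # cubic scaling identity
  expect_equal(caliper_volume(10, 8), 8 * caliper_volume(5, 4))
  # longer diameter is length: swapped inputs warn but give the same volume
  expect_warning(v <- caliper_volume(8, 10), "swapped")
  expect_equal(v, caliper_volume(10, 8))
  expect_error(caliper_volume(-1, 0), "non-negative")
})

test_that("predict_volume and time_to_volume invert each other", {
  expect_equal(predict_volume(2.5, 0.7, 0), 2.5)
  expect_equal(predict_volume(2.5, 0, 100), 2.5)
  # doubling time and the printed forward prediction
  expect_equal(time_to_volume(1, log(2), 2), 1)
  expect_equal(time_to_volume(0.3, 0.65, 1000), 12.48, tolerance = 1e-3)
  expect_equal(time_to_volume(0.3, 0.65, 1000), log(1000 / 0.3) / 0.65)
  expect_equal(predict_volume(0.3, 0.65, time_to_volume(0.3, 0.65, 1000)),
               1000)
  # round trip across a grid of parameters
  for (k in c(0.2, 0.65, 1.1)) {
    for (v in c(10, 500, 1500)) {
      expect_equal(predict_volume(0.4, k, time_to_volume(0.4, k, v)), v)
    }
  }
  expect_error(time_to_volume(1, -0.1, 10), "k must be positive")
  expect_error(time_to_volume(10, 0.5, 5), "v_target")
  expect_error(predict_volume(0, 0.5, 1), "c_t0")
})

test_that("growth log-likelihood matches the Gaussian closed form", {
  # residual-free curve with sigma = 1: n * ln(1/sqrt(2*pi))
  curve <- data.frame(day = c(0, 2, 4),
                      volume_mm3 = 2 * exp(0.5 * c(0, 2, 4)))
  expect_equal(growth_log_likelihood(curve, c_t0 = 2, k = 0.5, sigma = 1),
               3 * log(1 / sqrt(2 * pi)))
  # brute-force term-by-term summation oracle at several sigmas
  set.seed(4)
  noisy <- data.frame(day = c(1, 3, 5, 7),
                      volume_mm3 = exp(log(1.5) + 0.4 * c(1, 3, 5, 7) +
                                         rnorm(4, 0, 0.3)))
  for (s in c(0.25, 0.5, 1)) {
    manual <- sum(vapply(seq_len(4), function(i) {
      r <- log(noisy$volume_mm3[i]) - (log(1.5) + 0.4 * noisy$day[i])
      -0.5 * log(2 * pi) - log(s) - r^2 / (2 * s^2)
    }, numeric(1)))
    expect_equal(growth_log_likelihood(noisy, 1.5, 0.4, s), manual)
  }
  # doubling sigma strictly changes the value when residuals are nonzero
  expect_false(growth_log_likelihood(noisy, 1.5, 0.4, 0.5) ==
                 growth_log_likelihood(noisy, 1.5, 0.4, 1))
  # time-translation identity: shift days by +c, rescale c_t0 by exp(-k c)
  shifted <- transform(noisy, day = day + 3)
  expect_equal(growth_log_likelihood(noisy, 1.5, 0.4, 0.5),
               growth_log_likelihood(shifted, 1.5 * exp(-0.4 * 3), 0.4, 0.5))
  expect_error(
    growth_log_likelihood(data.frame(day = 1, volume_mm3 = 0), 1, 0.5, 1),
    "exclude")
})

test_that("cohort fit recovers the rate exactly in the low-noise limit", {
  cohort <- simulate_growth_cohort(growth_sim_config(
    n_mice = 3, true_rate = 0.5, initial_volume_median = 2,
    initial_volume_log_sd = 0.3, noise_log_sd = 1e-6,
    schedule = seq(4, 16, 2), seed = 5))
  fit <- fit_cohort(cohort, small_mcmc(seed = 2))
  expect_lt(abs(median(fit$samples$k) - 0.5), 1e-3)
  expect_true(all(c("chain", "draw", "k", "sigma") %in% names(fit$samples)))
  expect_equal(sort(unique(fit$samples$chain)), 1:3)
})

test_that("single-mouse flat-prior fit matches the OLS oracle", {
  cohort <- simulate_growth_cohort(growth_sim_config(
    n_mice = 1, true_rate = 0.45, initial_volume_median = 2,
    noise_log_sd = 0.15, schedule = seq(4, 24, 2), seed = 17))
  ols <- unname(coef(lm(log(volume_mm3) ~ day, data = cohort)))
  fit <- fit_cohort(cohort, small_mcmc(seed = 3, n_steps = 8000L))
  expect_true(fit$converged)
  expect_lt(abs(mean(fit$samples$k) - ols[2]), 0.01)
  expect_lt(abs(mean(log(fit$samples[[grep("^c_t0_",
                                           names(fit$samples))]])) - ols[1]),
            0.06)
})

test_that("cohort fit validates its inputs", {
  short <- data.frame(mouse_id = "m1", day = c(4, 6), volume_mm3 = c(10, 20))
  expect_error(fit_cohort(short, tiny_mcmc()), "fewer than 3")
  bad <- data.frame(mouse_id = "m1", day = c(4, 6, 8),
                    volume_mm3 = c(10, -1, 20))
  expect_error(fit_cohort(bad, tiny_mcmc()), "non-positive")
  nonmono <- data.frame(mouse_id = "m1", day = c(4, 8, 6),
                        volume_mm3 = c(10, 20, 30))
  expect_error(fit_cohort(nonmono, tiny_mcmc()), "strictly increasing")
})

test_that("posterior rate error shrinks as measurement noise vanishes", {
  err_at <- function(noise, seed) {
    cohort <- simulate_growth_cohort(growth_sim_config(
      n_mice = 3, true_rate = 0.5, initial_volume_median = 2,
      noise_log_sd = noise, schedule = seq(4, 16, 2), seed = seed))
    fit <- fit_cohort(cohort, tiny_mcmc(seed = seed))
    abs(median(fit$samples$k) - 0.5)
  }
  seeds <- 1:20
  lo <- vapply(seeds, function(s) err_at(0.001, s), numeric(1))
  hi <- vapply(seeds, function(s) err_at(0.3, s), numeric(1))
  expect_lt(mean(lo), mean(hi))
  expect_lt(mean(lo), 0.005)
})

test_that("log-ratio of degenerate posteriors is the exact log rate ratio", {
  lr <- log_ratio(rep(0.65, 200), rep(0.535, 200), seed = 1)
  expect_equal(lr$median, log(0.65 / 0.535))
  expect_equal(lr$median, 0.195, tolerance = 0.002)
  expect_true(all(lr$log_ratio_samples == lr$log_ratio_samples[1]))
  kd <- immune_death_rate(rep(0.65, 200), rep(0.535, 200), seed = 1)
  expect_equal(kd$median, 0.115)
})

test_that("log-ratio of a posterior against an independent copy is ~zero", {
  set.seed(31)
  draws <- rnorm(5000, 0.5, 0.05)
  lr <- log_ratio(draws, draws, seed = 2)
  # pairing against an independent permutation of itself: symmetric about 0
  expect_lt(abs(lr$median), 3 * (0.05 / 0.5) * sqrt(2) / sqrt(5000) * 5)
  expect_lt(lr$credible_interval_95[1], 0)
  expect_gt(lr$credible_interval_95[2], 0)
  expect_true(lr$credible_interval_95[1] <= lr$median &&
                lr$median <= lr$credible_interval_95[2])
})

test_that("non-positive immunocompetent rates are rejected with a record", {
  set.seed(7)
  kn <- rnorm(1000, 0.5, 0.02)
  kc <- c(rnorm(900, 0.2, 0.02), rep(-0.1, 100))
  lr <- log_ratio(kn, kc, seed = 3)
  expect_equal(lr$rejection_fraction, 0.1, tolerance = 0.05)
  expect_equal(lr$n, length(lr$log_ratio_samples))
  expect_error(log_ratio(kn, rep(-0.1, 100), seed = 1), "undefined")
  # immune death rate is not clipped: negative draws survive
  kd <- immune_death_rate(rep(0.3, 100), rep(0.5, 100), seed = 1)
  expect_true(all(kd$samples < 0))
  expect_equal(kd$median, -0.2)
})

test_that("refitting the same cohort twice gives a ~zero log-ratio", {
  cohort <- simulate_growth_cohort(growth_sim_config(
    n_mice = 3, true_rate = 0.5, initial_volume_median = 2,
    noise_log_sd = 0.15, schedule = seq(4, 16, 2), seed = 23))
  f1 <- fit_cohort(cohort, tiny_mcmc(seed = 101))
  f2 <- fit_cohort(cohort, tiny_mcmc(seed = 202))
  lr <- log_ratio(f1, f2, seed = 5)
  expect_lt(abs(lr$median), 0.02)
})
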