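# controls with a prescribed noise law, for direct envelope checks
make_controls <- function(n, sd_fun, seed, lo = 10, hi = 10000) {
  set.seed(seed)
  ma <- exp(seq(log(lo), log(hi), length.out = n))
  data.frame(probe = sprintf("ctl_%02d", seq_len(n)),
             role = rep(c("neg_control", "pos_control"), length.out = n),
             mean_abundance = ma,
             difference = rnorm(n, 0, sd_fun(ma)))
}

test_that("array normalization recovers injected scale and background", {
  base <- simulate_cytokine_arrays(array_sim_config(seed = 3))
  # already matched arrays: scale factor 1
  norm0 <- normalize_arrays(base, background = FALSE)
  expect_equal(attr(norm0, "scale_factor"), 1, tolerance = 0.05)
  # condition B globally twice as bright
  bright <- base
  idx <- bright$condition == "B"
  bright$spot1[idx] <- bright$spot1[idx] * 2
  bright$spot2[idx] <- bright$spot2[idx] * 2
  expect_equal(attr(normalize_arrays(bright, background = FALSE),
                    "scale_factor"), 0.5, tolerance = 0.05)
  # known scale 1.3 and additive background 50 on both arrays
  sf <- bg <- numeric(5)
  for (s in 1:5) {
    sp <- simulate_cytokine_arrays(array_sim_config(seed = s))
    neg <- sp$role == "neg_control"
    sp$spot1[neg] <- 0  # negatives carry pure background
    sp$spot2[neg] <- 0
    sp$spot1 <- sp$spot1 + 50
    sp$spot2 <- sp$spot2 + 50
    idx <- sp$condition == "B"
    sp$spot1[idx] <- sp$spot1[idx] * 1.3
    sp$spot2[idx] <- sp$spot2[idx] * 1.3
    norm <- normalize_arrays(sp)
    sf[s] <- attr(norm, "scale_factor")
    bg[s] <- attr(norm, "background")[["A"]]
  }
  expect_equal(mean(sf), 1 / 1.3, tolerance = 0.05)
  expect_equal(mean(bg), 50, tolerance = 0.05 * 50)
  expect_error(normalize_arrays(base[base$role == "analyte", ]),
               "positive-control")
})

test_that("duplicate collapsing returns means and discordance", {
  spots <- data.frame(probe = c("a", "b"), role = "analyte",
                      condition = "A", spot1 = c(100, 90),
                      spot2 = c(100, 110))
  col <- collapse_duplicates(spots)
  expect_equal(col$intensity, c(100, 100))
  expect_equal(col$discordance, c(0, 0.2))
  expect_error(collapse_duplicates(transform(spots, spot2 = c(NA, 110))),
               "missing duplicate")
  expect_error(collapse_duplicates(rbind(spots, spots[1, ])),
               "more than two")
})

test_that("duplicate discordance matches the folded-normal oracle", {
  # spots = M(1 + delta), delta ~ N(0, js^2): discordance ~ |N(0, 2 js^2)|
  # whose mean is 2*js/sqrt(pi)
  js <- 0.05
  disc <- unlist(lapply(1:10, function(s) {
    sp <- simulate_cytokine_arrays(array_sim_config(
      noise_c = 0, duplicate_jitter_sd = js, seed = s))
    collapse_duplicates(sp)$discordance
  }))
  expect_equal(mean(disc), 2 * js / sqrt(pi), tolerance = 0.05)
})

test_that("envelope fit tracks homoscedastic and proportional noise laws", {
  # constant SD: exponent clamps to ~0 and half-width ~ 2s everywhere
  s <- 40
  env <- build_null_envelope(make_controls(48, function(ma) s, seed = 1))
  expect_lt(env$fit_coefficients[["b"]], 0.25)
  for (x in c(20, 200, 2000)) {
    expect_equal(env$half_width(x), 2 * s, tolerance = 0.35)
  }
  # SD proportional to abundance: exponent near 1 on average over seeds
  bs <- vapply(1:20, function(sd) {
    e <- build_null_envelope(make_controls(48, function(ma) 0.1 * ma,
                                           seed = sd))
    e$fit_coefficients[["b"]]
  }, numeric(1))
  expect_lt(abs(mean(bs) - 1), 0.15)
  # doubling every control difference doubles the half-width pointwise
  ctl <- make_controls(24, function(ma) 0.1 * ma, seed = 3)
  e1 <- build_null_envelope(ctl)
  ctl2 <- transform(ctl, difference = 2 * difference)
  e2 <- build_null_envelope(ctl2)
  for (x in c(50, 500, 5000)) {
    expect_equal(e2$half_width(x), 2 * e1$half_width(x), tolerance = 1e-8)
  }
  # stored bin table reproduces the fit inputs
  expect_true(all(c("mean_abundance", "two_sd", "n") %in%
                    names(e1$bin_table)))
  expect_gte(min(e1$bin_table$n), 3)
})

test_that("envelope preconditions are enforced", {
  expect_error(build_null_envelope(make_controls(5, function(ma) 1, 1)),
               "insufficient controls")
  narrow <- make_controls(12, function(ma) 1, 1, lo = 100, hi = 500)
  expect_error(build_null_envelope(narrow), "10-fold")
})

test_that("z-scores place the 95% band at |z| = 2", {
  env <- build_null_envelope(make_controls(48, function(ma) 0.1 * ma, 2))
  expect_equal(z_score(0, 1000, env), 0)
  hw <- env$half_width(1000)
  expect_equal(z_score(hw, 1000, env), 2)
  expect_equal(z_score(-hw / 2, 1000, env), -1)
})

test_that("null z-scores are calibrated against the Gaussian oracle", {
  # control count chosen high enough that envelope-estimation error is
  # secondary to the tail probability being checked
  zs <- unlist(lapply(1:50, function(s) {
    sp <- simulate_cytokine_arrays(array_sim_config(
      n_pos_controls = 24, n_neg_controls = 24, seed = s))
    res <- analyze_arrays(sp)
    res$comparisons$z[res$comparisons$role == "analyte"]
  }))
  expect_lt(abs(sd(zs) - 1), 0.2)
  rate196 <- mean(abs(zs) > 1.96)
  expect_gt(rate196, 0.03)
  expect_lt(rate196, 0.08)
  expect_lte(mean(abs(zs) > 3), 0.01)
})

test_that("z-scores are antisymmetric under condition swap and scale-free", {
  sp <- simulate_cytokine_arrays(array_sim_config(
    seed = 12, differential_probes = c(analyte_004 = 5)))
  res <- analyze_arrays(sp)
  swapped <- sp
  swapped$condition <- ifelse(sp$condition == "A", "B", "A")
  res_sw <- analyze_arrays(swapped)
  ix <- match(res$comparisons$probe, res_sw$comparisons$probe)
  expect_equal(res_sw$comparisons$z[ix], -res$comparisons$z,
               tolerance = 1e-10)
  expect_equal(res_sw$comparisons$difference[ix],
               -res$comparisons$difference, tolerance = 1e-10)
  # multiplying all intensities on both arrays leaves every z unchanged
  scaled <- sp
  scaled$spot1 <- scaled$spot1 * 7
  scaled$spot2 <- scaled$spot2 * 7
  res_sc <- analyze_arrays(scaled)
  expect_equal(res_sc$comparisons$z, res$comparisons$z, tolerance = 1e-8)
})

test_that("injected differential probes are called with their direction", {
  hits <- lapply(1:30, function(s) {
    sp <- simulate_cytokine_arrays(array_sim_config(
      seed = s, differential_probes = c(analyte_007 = 10)))
    analyze_arrays(sp)$hits
  })
  flagged <- vapply(hits, function(h) {
    any(h$probe == "analyte_007" & h$direction == "higher_in_B")
  }, logical(1))
  expect_gte(mean(flagged), 0.95)
  # threshold = Inf flags nothing
  sp <- simulate_cytokine_arrays(array_sim_config(
    seed = 1, differential_probes = c(analyte_007 = 10)))
  cmp <- probe_comparisons(collapse_duplicates(sp))
  env <- build_null_envelope(cmp)
  expect_equal(nrow(call_differential(cmp, env, threshold = Inf)), 0)
  # significance flag is exactly |z| >= threshold
  scored <- score_probes(cmp, env, threshold = 3)
  expect_identical(scored$significant, abs(scored$z) >= 3)
})
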