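#' Tumor volume from perpendicular caliper diameters
#'
#' Converts two perpendicular caliper diameters to an ellipsoid volume using
#' \eqn{\pi/6 \times length \times width^2}. By convention the longer
#' diameter is the length; arguments violating `length >= width` are swapped
#' with a warning.
#'
#' @param length longer diameter, mm (vectorised).
#' @param width shorter diameter, mm.
#' @return tumor volume in mm^3.
#' @examples
#' caliper_volume(10, 8)  # 335.1 mm^3
#' @export
caliper_volume <- function(length, width) {
  if (any(length < 0) || any(width < 0))
    stop("caliper diameters must be non-negative")
  swap <- width > length
  if (any(swap)) {
    warning("width exceeded length for ", sum(swap),
            " measurement(s); diameters swapped so the longer one is length")
    tmp <- length[swap]
    length[swap] <- width[swap]
    width[swap] <- tmp
  }
  pi / 6 * length * width^2
}

#' Expected tumor volume under exponential growth
#'
#' \eqn{V(t) = C_{T0} e^{kt}}: the initial bolus size grown at net rate
#' \eqn{k = k_P - k_D} (proliferation minus immune-mediated death).
#'
#' @param c_t0 initial tumor bolus volume, mm^3 (> 0).
#' @param k net growth rate, day^-1 (any real).
#' @param t days post-inoculation.
#' @return expected volume in mm^3.
#' @export
predict_volume <- function(c_t0, k, t) {
  if (any(c_t0 <= 0)) stop("c_t0 must be positive")
  c_t0 * exp(k * t)
}

#' Time for an exponentially growing tumor to reach a target volume
#'
#' Inverse of [predict_volume()]: \eqn{t = \ln(V_{target}/C_{T0}) / k}.
#'
#' @inheritParams predict_volume
#' @param v_target target volume, mm^3 (must exceed `c_t0`).
#' @return days until the target volume is reached.
#' @export
time_to_volume <- function(c_t0, k, v_target) {
  if (any(c_t0 <= 0)) stop("c_t0 must be positive")
  if (any(k <= 0)) stop("k must be positive: the target volume is never reached")
  if (any(v_target <= c_t0))
    stop("v_target must exceed c_t0 (already at or beyond the target)")
  log(v_target / c_t0) / k
}

#' Log-likelihood of one growth curve under the log-linear model
#'
#' Gaussian log-density of \eqn{\ln V_{obs}(t)} with mean
#' \eqn{\ln C_{T0} + k t} and standard deviation `sigma`, summed over the
#' curve's measurements.
#'
#' @param curve data frame with columns `day` and `volume_mm3` (all volumes
#'   strictly positive; exclude sub-detection points upstream).
#' @param c_t0 initial bolus volume, mm^3 (> 0).
#' @param k net growth rate, day^-1.
#' @param sigma residual sd on the natural-log-volume scale (> 0).
#' @return scalar log-likelihood.
#' @export
growth_log_likelihood <- function(curve, c_t0, k, sigma) {
  if (any(curve$volume_mm3 <= 0))
    stop("non-positive volume in curve: exclude sub-detection points ",
         "before computing the likelihood")
  if (c_t0 <= 0 || sigma <= 0) stop("c_t0 and sigma must be positive")
  sum(dnorm(log(curve$volume_mm3), log(c_t0) + k * curve$day, sigma,
            log = TRUE))
}

# Uniform prior bounds: k (day^-1), ln c_t0 (ln mm^3), sigma (ln-volume sd).
# Weakly informative; chosen to keep plausible murine-tumor values interior.
.k_bounds <- c(-1, 3)
.lc0_bounds <- log(c(1e-3, 1e2))
.sigma_bounds <- c(0.01, 2)

# per-mouse OLS of ln V on t; used for inits and as an independent oracle
.ols_curve <- function(day, volume) {
  fit <- lm(log(volume) ~ day)
  c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
    sd = sqrt(mean(fit$residuals^2)))
}

#' Fit a cohort growth model by MCMC
#'
#' Fits the log-linear exponential growth model to every mouse in a cohort:
#' one net growth rate `k` shared by the cohort, one initial bolus size
#' `c_t0` per mouse, and one residual sd `sigma` on the natural-log-volume
#' scale shared by the cohort. Posterior sampling uses adaptive random-walk
#' Metropolis ([run_chains()]) with uniform priors: k in (-1, 3) day^-1,
#' ln c_t0 in (ln 1e-3, ln 1e2), sigma in (0.01, 2). Chains are initialised
#' at jittered per-mouse ordinary-least-squares estimates.
#'
#' @param cohort data frame with columns `mouse_id`, `day`, `volume_mm3`
#'   (extra columns such as `cell_line`/`host` are carried in the result
#'   metadata); every mouse needs >= 3 usable points on strictly increasing
#'   days.
#' @param config an [mcmc_config()].
#' @param detection_floor volumes at or below this (mm^3) are excluded
#'   before fitting (ln V is unstable near zero); exclusions are counted in
#'   the result.
#' @return an object of class `cohort_posterior`: `samples` (data frame of
#'   retained draws with columns `chain`, `draw`, `k`, one `c_t0_<id>` per
#'   mouse, `sigma`), `diagnostics` ([chain_diagnostics()]), `converged`,
#'   `mouse_ids`, `n_excluded`, and metadata. Convergence failure is
#'   reported via `converged = FALSE`, never silently ignored.
#' @seealso [log_ratio()], [immune_death_rate()], [posterior_summary()]
#' @export
fit_cohort <- function(cohort, config = mcmc_config(), detection_floor = 1) {
  req <- c("mouse_id", "day", "volume_mm3")
  if (!all(req %in% names(cohort)))
    stop("cohort must contain columns ", paste(req, collapse = ", "))
  if (any(cohort$volume_mm3 <= 0))
    stop("non-positive volumes in cohort: remove or correct before fitting")
  keep <- cohort$volume_mm3 > detection_floor
  n_excluded <- sum(!keep)
  cohort <- cohort[keep, , drop = FALSE]
  mice <- unique(as.character(cohort$mouse_id))
  n_m <- length(mice)
  if (n_m < 1L) stop("no usable curves after detection-floor exclusion")
  per <- split(cohort, factor(as.character(cohort$mouse_id), levels = mice))
  for (m in mice) {
    if (nrow(per[[m]]) < 3L)
      stop("mouse ", m, " has fewer than 3 usable points; the log-linear ",
           "model needs >= 3 measurements per curve")
    if (any(diff(per[[m]]$day) <= 0))
      stop("mouse ", m, ": measurement days must be strictly increasing")
  }

  # flatten once; the likelihood is a single vectorised Gaussian evaluation
  midx <- match(as.character(cohort$mouse_id), mice)
  tt <- cohort$day
  lv <- log(cohort$volume_mm3)

  ols <- t(vapply(per, function(d) .ols_curve(d$day, d$volume_mm3),
                  numeric(3)))
  k0 <- mean(ols[, "slope"])
  lc0_0 <- ols[, "intercept"]
  sig0 <- max(mean(ols[, "sd"]), 0.05)
  clamp <- function(x, b) pmin(pmax(x, b[1] + 1e-6), b[2] - 1e-6)

  d <- 1L + n_m + 1L
  param_names <- c("k", paste0("c_t0_", mice), "sigma")
  lp <- function(theta) {
    k <- theta[1]
    lc0 <- theta[2:(1 + n_m)]
    sigma <- theta[d]
    if (k < .k_bounds[1] || k > .k_bounds[2] ||
        any(lc0 < .lc0_bounds[1]) || any(lc0 > .lc0_bounds[2]) ||
        sigma < .sigma_bounds[1] || sigma > .sigma_bounds[2]) return(-Inf)
    sum(dnorm(lv, lc0[midx] + k * tt, sigma, log = TRUE))
  }

  init <- withr::with_seed(.chain_seed(config$seed, 0), {
    t(vapply(seq_len(config$n_chains), function(ch) {
      spread <- (ch - (config$n_chains + 1) / 2) / config$n_chains
      c(clamp(k0 + 0.2 * spread + rnorm(1, 0, 0.01), .k_bounds),
        clamp(lc0_0 + 0.3 * spread + rnorm(n_m, 0, 0.02), .lc0_bounds),
        clamp(sig0 * exp(0.5 * spread + rnorm(1, 0, 0.02)), .sigma_bounds))
    }, numeric(d)))
  })

  raw <- run_chains(lp, init, config, param_names = param_names)
  diag <- chain_diagnostics(raw)

  samples <- do.call(rbind, lapply(seq_along(raw$chains), function(ch) {
    m <- raw$chains[[ch]]
    out <- as.data.frame(m)
    # c_t0 is sampled on the log scale; report on the natural scale
    for (j in grep("^c_t0_", names(out))) out[[j]] <- exp(out[[j]])
    cbind(chain = ch, draw = seq_len(nrow(m)), out)
  }))

  meta <- list(
    cell_line = if ("cell_line" %in% names(cohort))
      unique(as.character(cohort$cell_line)) else NA_character_,
    host = if ("host" %in% names(cohort))
      unique(as.character(cohort$host)) else NA_character_)

  structure(list(samples = samples, diagnostics = diag,
                 converged = diag$converged, mouse_ids = mice,
                 n_excluded = n_excluded, burn_in_discarded = TRUE,
                 config = config, meta = meta),
            class = "cohort_posterior")
}

#' @export
print.cohort_posterior <- function(x, ...) {
  s <- posterior_summary(x$samples$k)
  cat("Cohort growth-model posterior (", length(x$mouse_ids), " mice, ",
      nrow(x$samples), " retained draws, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  cat(sprintf("  k = %.3f day^-1 [%.3f, %.3f] (median, 95%% CrI)\n",
              s["median"], s["ci_low"], s["ci_high"]))
  s2 <- posterior_summary(x$samples$sigma)
  cat(sprintf("  sigma = %.3f [%.3f, %.3f]\n",
              s2["median"], s2["ci_low"], s2["ci_high"]))
  if (x$n_excluded > 0)
    cat("  ", x$n_excluded, "point(s) excluded below the detection floor\n")
  invisible(x)
}

#' Posterior summary table for a fitted cohort
#'
#' @param posterior a `cohort_posterior` from [fit_cohort()].
#' @return data frame with one row per parameter: `parameter`, `median`,
#'   `ci_low`, `ci_high`, `psrf`, `ess`.
#' @export
cohort_summary <- function(posterior) {
  stopifnot(inherits(posterior, "cohort_posterior"))
  pn <- setdiff(names(posterior$samples), c("chain", "draw"))
  rows <- lapply(pn, function(p) {
    s <- posterior_summary(posterior$samples[[p]])
    data.frame(parameter = p, median = s["median"], ci_low = s["ci_low"],
               ci_high = s["ci_high"],
               psrf = unname(posterior$diagnostics$psrf[p]),
               ess = unname(posterior$diagnostics$ess[p]),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

# accept a cohort_posterior or a bare vector of rate draws
.rate_draws <- function(x, arg) {
  if (inherits(x, "cohort_posterior")) return(x$samples$k)
  if (is.numeric(x) && length(x) >= 1L) return(as.numeric(x))
  stop(arg, " must be a cohort_posterior or a numeric vector of rate draws")
}

# evenly thin a vector to length m, then pair via a seeded permutation
.paired_rates <- function(post_a, post_b, seed) {
  ka <- .rate_draws(post_a, "posterior_nsg")
  kb <- .rate_draws(post_b, "posterior_c57")
  m <- min(length(ka), length(kb))
  ka <- ka[round(seq(1, length(ka), length.out = m))]
  kb <- kb[round(seq(1, length(kb), length.out = m))]
  withr::with_seed(abs(seed) %% 2147483647, {
    list(a = ka[sample.int(m)], b = kb[sample.int(m)])
  })
}

#' Immune-pressure log-ratio of growth rates
#'
#' Forms posterior draws of \eqn{\ln(k_{NSG} / k_{C57})}, the natural-log
#' ratio of the growth rate in immunodeficient hosts (the intrinsic
#' proliferation rate \eqn{k_P}) to the net rate in immunocompetent hosts
#' (\eqn{k_P - k_D}). Zero means host immunity exerts no detectable
#' selective pressure; positive values mean tumors grow faster without
#' immunity. Draws are randomly paired from the two independent posteriors
#' after thinning both to a common length; pairs with a non-positive
#' immunocompetent rate are rejected and the rejection fraction recorded.
#'
#' @param posterior_nsg,posterior_c57 `cohort_posterior` objects from
#'   [fit_cohort()] (or bare numeric vectors of rate draws).
#' @param seed integer seed for the pairing permutation.
#' @return an object of class `immune_pressure`: `log_ratio_samples`,
#'   `median`, `credible_interval_95`, `rejection_fraction`, `n`.
#' @export
log_ratio <- function(posterior_nsg, posterior_c57, seed = 1L) {
  pr <- .paired_rates(posterior_nsg, posterior_c57, seed)
  ok <- pr$b > 0
  if (!any(ok))
    stop("all immunocompetent-host rate draws are <= 0: log-ratio undefined")
  lr <- log(pr$a[ok] / pr$b[ok])
  s <- posterior_summary(lr)
  structure(list(log_ratio_samples = lr, median = unname(s["median"]),
                 credible_interval_95 = unname(s[c("ci_low", "ci_high")]),
                 rejection_fraction = mean(!ok), n = sum(ok), seed = seed),
            class = "immune_pressure")
}

#' @export
print.immune_pressure <- function(x, ...) {
  cat(sprintf(paste0("Immune pressure ln(k_NSG/k_C57): %.3f ",
                     "[%.3f, %.3f] (median, 95%% CrI; n = %d draws)\n"),
              x$median, x$credible_interval_95[1], x$credible_interval_95[2],
              x$n))
  if (x$rejection_fraction > 0)
    cat(sprintf("  %.1f%% of pairs rejected (non-positive C57 rate)\n",
                100 * x$rejection_fraction))
  invisible(x)
}

#' Posterior draws of the immune-mediated death rate
#'
#' Pairs draws from the two independent posteriors (same pairing rule as
#' [log_ratio()]) and returns \eqn{k_D = k_P - k_{net}}, the single rate
#' parameter absorbing all anti-tumor immunity present in the
#' immunocompetent host but absent in the immunodeficient one. Draws may be
#' negative (immune enhancement) and are not clipped.
#'
#' @inheritParams log_ratio
#' @return list with `samples` (k_D draws, day^-1), `median`,
#'   `credible_interval_95`.
#' @export
immune_death_rate <- function(posterior_nsg, posterior_c57, seed = 1L) {
  pr <- .paired_rates(posterior_nsg, posterior_c57, seed)
  kd <- pr$a - pr$b
  s <- posterior_summary(kd)
  list(samples = kd, median = unname(s["median"]),
       credible_interval_95 = unname(s[c("ci_low", "ci_high")]))
}
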