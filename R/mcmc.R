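#' MCMC sampler configuration
#'
#' Settings for the adaptive random-walk Metropolis sampler used by
#' [run_chains()] and [fit_cohort()]. Proposal scales adapt toward the
#' target acceptance rate only during burn-in; retained draws therefore come
#' from a fixed transition kernel.
#'
#' @param n_chains number of independent chains (>= 2, so the Gelman-Rubin
#'   diagnostic is defined).
#' @param n_steps total Metropolis sweeps per chain (each sweep updates every
#'   coordinate once).
#' @param burn_in_fraction fraction of `n_steps` discarded as burn-in,
#'   strictly in (0, 1).
#' @param target_acceptance per-coordinate acceptance rate the adaptation
#'   steers toward; 0.25 is a standard choice for random-walk proposals.
#' @param adaptation_window number of sweeps between proposal-scale updates
#'   during burn-in.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param psrf_threshold convergence gate on the potential scale reduction
#'   factor (all parameters must satisfy psrf <= threshold).
#' @param seed integer seed; chain c uses a seed derived from `seed` and `c`.
#' @return an object of class `mcmc_config` (a validated list).
#' @seealso [run_chains()], [chain_diagnostics()]
#' @export
mcmc_config <- function(n_chains = 3L, n_steps = 20000L,
                        burn_in_fraction = 0.5, target_acceptance = 0.25,
                        adaptation_window = 100L, thin = 5L,
                        psrf_threshold = 1.1, seed = 1L) {
  cfg <- list(n_chains = as.integer(n_chains), n_steps = as.integer(n_steps),
              burn_in_fraction = burn_in_fraction,
              target_acceptance = target_acceptance,
              adaptation_window = as.integer(adaptation_window),
              thin = as.integer(thin), psrf_threshold = psrf_threshold,
              seed = as.integer(seed))
  if (cfg$n_chains < 2L) stop("n_chains must be >= 2")
  if (cfg$burn_in_fraction <= 0 || cfg$burn_in_fraction >= 1)
    stop("burn_in_fraction must lie strictly in (0, 1)")
  if (cfg$n_steps < 2L || floor(cfg$n_steps * cfg$burn_in_fraction) >= cfg$n_steps)
    stop("burn-in must be strictly less than n_steps")
  if (cfg$thin < 1L) stop("thin must be >= 1")
  if (cfg$target_acceptance <= 0 || cfg$target_acceptance >= 1)
    stop("target_acceptance must lie in (0, 1)")
  if (cfg$adaptation_window < 1L) stop("adaptation_window must be >= 1")
  class(cfg) <- "mcmc_config"
  cfg
}

# deterministic per-chain seed below 2^31
.chain_seed <- function(seed, chain) {
  (abs(as.numeric(seed)) + 104729 * chain) %% 2147483647
}

#' Run adaptive random-walk Metropolis chains
#'
#' Samples from an unnormalised log target density using coordinatewise
#' Gaussian random-walk proposals. Each proposal scale is multiplicatively
#' adapted every `adaptation_window` sweeps during burn-in so that the
#' per-coordinate acceptance rate approaches `target_acceptance`; adaptation
#' is frozen at the end of burn-in.
#'
#' @param log_posterior function mapping a numeric parameter vector to the
#'   log target density (may return `-Inf` outside the support; `NaN` aborts
#'   with the offending parameter vector).
#' @param init numeric matrix of starting points, one row per chain
#'   (overdispersed, distinct rows; `log_posterior` must be finite at each).
#' @param config an [mcmc_config()].
#' @param param_names optional character vector of parameter names.
#' @return an object of class `mcmc_chains`: a list with elements
#'   `chains` (list of retained draw matrices, one per chain),
#'   `acceptance` (post-burn-in acceptance rate per chain),
#'   `scale_history` (per chain, matrix of proposal scales recorded at the
#'   end of every adaptation window, burn-in and after), `param_names`,
#'   and `config`.
#' @examples
#' cfg <- mcmc_config(n_chains = 2, n_steps = 2000, seed = 1)
#' fit <- run_chains(function(p) dnorm(p, log = TRUE),
#'                   init = matrix(c(-1, 1), ncol = 1), config = cfg)
#' posterior_summary(do.call(rbind, fit$chains)[, 1])
#' @export
run_chains <- function(log_posterior, init, config = mcmc_config(),
                       param_names = NULL) {
  if (!inherits(config, "mcmc_config")) stop("config must be an mcmc_config")
  if (is.list(init) && !is.matrix(init)) init <- do.call(rbind, init)
  init <- as.matrix(init)
  if (nrow(init) != config$n_chains)
    stop("init must supply one starting point per chain")
  if (anyDuplicated(init) > 0L)
    stop("init points must be distinct (overdispersed starts)")
  d <- ncol(init)
  if (is.null(param_names)) param_names <- paste0("par", seq_len(d))

  eval_lp <- function(theta) {
    lp <- log_posterior(theta)
    if (is.nan(lp))
      stop("log_posterior returned NaN at parameter vector [",
           paste(signif(theta, 6), collapse = ", "), "]")
    lp
  }

  n_burn <- floor(config$n_steps * config$burn_in_fraction)
  keep_idx <- seq.int(n_burn + 1L, config$n_steps, by = config$thin)

  chains <- vector("list", config$n_chains)
  acceptance <- numeric(config$n_chains)
  scale_history <- vector("list", config$n_chains)

  for (ch in seq_len(config$n_chains)) {
    withr::with_seed(.chain_seed(config$seed, ch), {
      theta <- init[ch, ]
      lp <- eval_lp(theta)
      if (!is.finite(lp))
        stop("log_posterior not finite at init point for chain ", ch)
      scale <- 0.1 * pmax(abs(theta), 1)
      draws <- matrix(NA_real_, length(keep_idx), d,
                      dimnames = list(NULL, param_names))
      win_prop <- win_acc <- numeric(d)
      post_prop <- post_acc <- 0
      scales <- list()
      k_out <- 1L
      for (step in seq_len(config$n_steps)) {
        for (j in seq_len(d)) {
          prop <- theta
          prop[j] <- theta[j] + scale[j] * rnorm(1)
          lp_prop <- eval_lp(prop)
          win_prop[j] <- win_prop[j] + 1
          if (step > n_burn) post_prop <- post_prop + 1
          if (log(runif(1)) < lp_prop - lp) {
            theta <- prop
            lp <- lp_prop
            win_acc[j] <- win_acc[j] + 1
            if (step > n_burn) post_acc <- post_acc + 1
          }
        }
        if (step %% config$adaptation_window == 0L) {
          if (step <= n_burn) {
            # multiplicative Robbins-Monro-style update toward the target rate
            acc <- ifelse(win_prop > 0, win_acc / win_prop,
                          config$target_acceptance)
            scale <- scale * exp(acc - config$target_acceptance)
            win_prop[] <- 0
            win_acc[] <- 0
          }
          scales[[length(scales) + 1L]] <- scale
        }
        if (step > n_burn && (step - n_burn - 1L) %% config$thin == 0L) {
          draws[k_out, ] <- theta
          k_out <- k_out + 1L
        }
      }
      chains[[ch]] <- draws
      acceptance[ch] <- if (post_prop > 0) post_acc / post_prop else NA_real_
      scale_history[[ch]] <- do.call(rbind, scales)
    })
  }

  structure(list(chains = chains, acceptance = acceptance,
                 scale_history = scale_history, param_names = param_names,
                 config = config, n_burn = n_burn),
            class = "mcmc_chains")
}

#' @export
print.mcmc_chains <- function(x, ...) {
  cat("Random-walk Metropolis run:", length(x$chains), "chains x",
      nrow(x$chains[[1]]), "retained draws of", length(x$param_names),
      "parameters\n")
  cat("Post-burn-in acceptance:",
      paste(sprintf("%.2f", x$acceptance), collapse = ", "), "\n")
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classical PSRF \eqn{\sqrt{((n-1)/n \cdot W + B/n) / W}} computed from the
#' within-chain variance W (mean of per-chain variances) and between-chain
#' variance B (n times the variance of the chain means). Values near 1
#' indicate that the chains have mixed.
#'
#' @param chains list of equal-length numeric vectors (>= 2 chains), or a
#'   matrix with one chain per column.
#' @return the scalar PSRF. When every chain is constant and identical the
#'   statistic is defined as 1; constant chains at different values are an
#'   error (zero within-chain variance with disagreement between chains).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  m <- length(chains)
  if (m < 2L) stop("gelman_rubin needs at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal retained lengths")
  if (n < 2L) stop("chains must contain at least 2 draws")
  W <- mean(vapply(chains, var, numeric(1)))
  mu <- vapply(chains, mean, numeric(1))
  B <- n * var(mu)
  if (W == 0) {
    if (B == 0) return(1)
    stop("zero within-chain variance with differing chains: PSRF undefined")
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of a single chain
#'
#' Initial-positive-sequence estimator: \eqn{n / (1 + 2\sum_t \rho_t)} with
#' the autocorrelation sum truncated at the first non-positive paired sum
#' \eqn{\rho_{2m} + \rho_{2m+1}}, and the result capped at `n`.
#'
#' @param chain numeric vector of retained draws (length >= 10).
#' @return estimated effective sample size. A constant (degenerate) chain is
#'   reported as `n` with a warning.
#' @export
effective_sample_size <- function(chain) {
  n <- length(chain)
  if (n < 10L) stop("effective_sample_size needs a retained length >= 10")
  if (var(chain) == 0) {
    warning("constant chain: effective sample size is degenerate, reporting n")
    return(n)
  }
  rho <- drop(acf(chain, lag.max = min(n - 1L, 2000L), plot = FALSE,
                  demean = TRUE)$acf)[-1]
  # pad to even length so lags pair as (1,2), (3,4), ...
  if (length(rho) %% 2L == 1L) rho <- c(rho, 0)
  s <- 0
  for (m in seq.int(1L, length(rho), by = 2L)) {
    pair <- rho[m] + rho[m + 1L]
    if (pair <= 0) break
    s <- s + pair
  }
  max(1, min(n, n / (1 + 2 * s)))
}

#' Median and central 95% credible interval of posterior draws
#'
#' @param samples numeric vector of retained draws (>= 1).
#' @return named numeric vector with elements `median`, `ci_low`, `ci_high`
#'   (2.5 and 97.5 percentiles).
#' @export
posterior_summary <- function(samples) {
  if (length(samples) < 1L) stop("posterior_summary needs at least one draw")
  q <- quantile(samples, c(0.025, 0.975), names = FALSE)
  c(median = median(samples), ci_low = q[1], ci_high = q[2])
}

#' Convergence diagnostics for a multi-chain run
#'
#' @param chains an `mcmc_chains` object from [run_chains()].
#' @return an object of class `chain_diagnostics`: per-parameter `psrf` and
#'   `ess` (summed over chains), per-chain `acceptance_rate`, and a
#'   `converged` flag (all psrf <= the configured threshold).
#' @export
chain_diagnostics <- function(chains) {
  stopifnot(inherits(chains, "mcmc_chains"))
  pn <- chains$param_names
  psrf <- vapply(seq_along(pn), function(j) {
    gelman_rubin(lapply(chains$chains, function(m) m[, j]))
  }, numeric(1))
  ess <- vapply(seq_along(pn), function(j) {
    sum(vapply(chains$chains, function(m) {
      suppressWarnings(effective_sample_size(m[, j]))
    }, numeric(1)))
  }, numeric(1))
  names(psrf) <- names(ess) <- pn
  structure(list(psrf = psrf, ess = ess,
                 acceptance_rate = chains$acceptance,
                 converged = all(psrf <= chains$config$psrf_threshold)),
            class = "chain_diagnostics")
}

#' @export
print.chain_diagnostics <- function(x, ...) {
  cat("Chain diagnostics (", if (x$converged) "converged" else "NOT converged",
      ")\n", sep = "")
  print(data.frame(psrf = round(x$psrf, 4), ess = round(x$ess, 1)))
  invisible(x)
}
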