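#' Predicted viability under the two-parameter dose-response model
#'
#' \eqn{100 (1 - x/(x + IC_{50}))}: 100% at zero dose, 50% at the
#' half-maximal concentration, strictly decreasing in dose. The model has no
#' Hill slope and no floor/ceiling parameters.
#'
#' @param x drug concentration (>= 0, vectorised), in any consistent unit.
#' @param ic50 half-maximal concentration (> 0), same unit as `x`.
#' @return predicted viability in percent, in (0, 100].
#' @export
predict_viability <- function(x, ic50) {
  if (any(ic50 <= 0)) stop("ic50 must be positive")
  if (any(x < 0)) stop("concentrations must be non-negative")
  100 * (1 - x / (x + ic50))
}

.ic50_ss <- function(ic50, conc, viab) sum((viab - predict_viability(conc, ic50))^2)

#' Fit the half-maximal concentration to a viability plate
#'
#' Least-squares fit of [predict_viability()] over the log-transformed IC50
#' (enforcing positivity). The search starts at the dose whose mean
#' viability is nearest 50% (falling back to the geometric mean of positive
#' doses), optimises `log(ic50)` over a factor-of-1000 window around the
#' start by golden-section search, and cross-checks the optimum against a
#' dense 1-D grid over the same window; the `converged` flag requires the
#' two to agree.
#'
#' @param plate data frame with columns `concentration` and `viability_pct`
#'   (>= 4 distinct doses, at least one positive; zero-dose wells are
#'   included, where the model predicts exactly 100). Optional `drug`,
#'   `cell_line`, `concentration_unit` columns are carried into the result.
#' @return an object of class `ic50_fit`: `ic50`, `residual_sd`
#'   (percentage points), `n_points`, `converged`, and a `diagnosis` string
#'   when unconverged (e.g. `"insufficient inhibition"` when no dose drops
#'   viability below 90%).
#' @examples
#' plate <- simulate_viability_plate(
#'   plate_sim_config(true_ic50 = 5, concentrations = c(0, 1, 2.5, 5, 10, 20),
#'                    noise_sd = 0))
#' fit_ic50(plate)
#' @export
fit_ic50 <- function(plate) {
  req <- c("concentration", "viability_pct")
  if (!all(req %in% names(plate)))
    stop("plate must contain columns ", paste(req, collapse = ", "))
  conc <- plate$concentration
  viab <- plate$viability_pct
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (any(viab < 0)) stop("viability_pct must be non-negative")
  if (length(unique(conc)) < 4L)
    stop("need at least 4 distinct concentrations")
  if (!any(conc > 0)) stop("need at least one positive concentration")

  lab <- function(col, default) if (col %in% names(plate))
    as.character(plate[[col]][1]) else default
  meta <- list(drug = lab("drug", NA_character_),
               cell_line = lab("cell_line", NA_character_),
               concentration_unit = lab("concentration_unit", NA_character_))

  mean_v <- tapply(viab, conc, mean)
  doses <- as.numeric(names(mean_v))
  if (all(mean_v > 90)) {
    return(structure(list(ic50 = NA_real_, residual_sd = NA_real_,
                          n_points = length(viab), converged = FALSE,
                          diagnosis = "insufficient inhibition",
                          meta = meta),
                     class = "ic50_fit"))
  }
  pos <- doses > 0
  start <- doses[pos][which.min(abs(mean_v[pos] - 50))]
  if (!length(start) || !is.finite(start))
    start <- exp(mean(log(doses[pos])))

  window <- log(start) + c(-1, 1) * log(1000)
  opt <- optimize(function(th) .ic50_ss(exp(th), conc, viab),
                  interval = window, tol = 1e-10)
  # grid cross-check over the same factor-of-1000 window
  grid <- seq(window[1], window[2], length.out = 400L)
  gss <- vapply(grid, function(th) .ic50_ss(exp(th), conc, viab), numeric(1))
  th_grid <- grid[which.min(gss)]
  agree <- abs(opt$minimum - th_grid) < 2 * diff(window) / 399 ||
    opt$objective <= min(gss) + 1e-8
  at_edge <- min(abs(opt$minimum - window)) < 1e-3

  ic50 <- exp(opt$minimum)
  n <- length(viab)
  structure(list(ic50 = ic50,
                 residual_sd = sqrt(opt$objective / max(n - 1, 1)),
                 n_points = n, converged = agree && !at_edge,
                 diagnosis = if (agree && !at_edge) NA_character_
                             else "optimizer/grid disagreement or boundary",
                 meta = meta),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  if (!x$converged) {
    cat("IC50 fit did not converge:", x$diagnosis, "\n")
  } else {
    unit <- if (is.na(x$meta$concentration_unit)) ""
            else paste0(" ", x$meta$concentration_unit)
    cat(sprintf("IC50 = %.4g%s (residual sd %.2f%%, n = %d)\n",
                x$ic50, unit, x$residual_sd, x$n_points))
  }
  invisible(x)
}

#' Fold difference between two fitted IC50s
#'
#' @param fit_a,fit_b converged [fit_ic50()] results in the same
#'   concentration unit.
#' @return list with `ratio` (max/min, >= 1) and `more_sensitive`
#'   (`"first"`, `"second"`, or `"equal"`; the more sensitive line is the
#'   one with the lower IC50).
#' @export
ic50_fold_difference <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "ic50_fit"), inherits(fit_b, "ic50_fit"))
  if (!fit_a$converged || !fit_b$converged)
    stop("both IC50 fits must have converged")
  a <- fit_a$ic50
  b <- fit_b$ic50
  list(ratio = max(a, b) / min(a, b),
       more_sensitive = if (a < b) "first" else if (b < a) "second" else "equal")
}
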