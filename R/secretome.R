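#' Normalize two antibody arrays to each other
#'
#' Optional pre-processing for the two-condition comparison: condition B is
#' rescaled so the mean of its positive controls matches condition A's
#' (`scale`), and the per-condition negative-control mean is subtracted as
#' background (`background`). Results are floored at 0.
#'
#' @param spots data frame with columns `probe`, `role`
#'   (`analyte`/`pos_control`/`neg_control`), `condition` (`A`/`B`),
#'   `spot1`, `spot2`; >= 3 positive controls per condition.
#' @param scale,background logical switches for the two steps.
#' @return the normalized spot table, with attributes `scale_factor` (the
#'   multiplier applied to condition B) and `background` (named per-condition
#'   negative-control means subtracted).
#' @export
normalize_arrays <- function(spots, scale = TRUE, background = TRUE) {
  .check_spots(spots)
  vals <- function(cond, rl) {
    d <- spots[spots$condition == cond & spots$role == rl, ]
    c(d$spot1, d$spot2)
  }
  for (cond in c("A", "B"))
    if (length(vals(cond, "pos_control")) < 6L)  # 3 probes x 2 spots
      stop("need >= 3 positive-control probes in condition ", cond)

  scale_factor <- 1
  if (scale) {
    mA <- mean(vals("A", "pos_control"))
    mB <- mean(vals("B", "pos_control"))
    if (mA <= 0 || mB <= 0)
      stop("positive-control mean must be positive to rescale arrays")
    scale_factor <- mA / mB
    idx <- spots$condition == "B"
    spots$spot1[idx] <- spots$spot1[idx] * scale_factor
    spots$spot2[idx] <- spots$spot2[idx] * scale_factor
  }
  bg <- c(A = 0, B = 0)
  if (background) {
    for (cond in c("A", "B")) {
      bg[cond] <- mean(vals(cond, "neg_control"))
      idx <- spots$condition == cond
      spots$spot1[idx] <- pmax(spots$spot1[idx] - bg[cond], 0)
      spots$spot2[idx] <- pmax(spots$spot2[idx] - bg[cond], 0)
    }
  }
  attr(spots, "scale_factor") <- scale_factor
  attr(spots, "background") <- bg
  spots
}

.check_spots <- function(spots) {
  req <- c("probe", "role", "condition", "spot1", "spot2")
  if (!all(req %in% names(spots)))
    stop("spot table must contain columns ", paste(req, collapse = ", "))
  if (isTRUE(any(spots$spot1 < 0, na.rm = TRUE)) ||
      isTRUE(any(spots$spot2 < 0, na.rm = TRUE)))
    stop("spot intensities must be non-negative")
  invisible(TRUE)
}

#' Collapse duplicate spots to per-probe intensities
#'
#' Each probe is spotted in duplicate on each array; the pair is collapsed
#' to its mean, and the duplicate discordance |spot1 - spot2| / mean is
#' recorded for quality control.
#'
#' @param spots spot table as in [normalize_arrays()].
#' @return data frame with columns `probe`, `role`, `condition`,
#'   `intensity` (duplicate mean), `discordance` (0 where the mean is 0).
#' @export
collapse_duplicates <- function(spots) {
  .check_spots(spots)
  key <- paste(spots$probe, spots$condition)
  dup <- key[duplicated(key)]
  if (length(dup))
    stop("more than two spots for probe/condition: ",
         paste(unique(dup), collapse = ", "))
  if (anyNA(spots$spot1) || anyNA(spots$spot2))
    stop("missing duplicate spot for probe ",
         paste(spots$probe[is.na(spots$spot1) | is.na(spots$spot2)],
               collapse = ", "))
  m <- (spots$spot1 + spots$spot2) / 2
  disc <- ifelse(m > 0, abs(spots$spot1 - spots$spot2) / m, 0)
  data.frame(probe = spots$probe, role = spots$role,
             condition = spots$condition, intensity = m, discordance = disc)
}

#' Per-probe two-condition comparison (MA-style coordinates)
#'
#' Pairs the duplicate-collapsed intensities of the two conditions:
#' `mean_abundance` is the average of the two conditions' intensities (the
#' x-axis of the comparison plot) and `difference` is condition A minus
#' condition B (the vertical distance from the x-axis).
#'
#' @param collapsed output of [collapse_duplicates()] containing both
#'   conditions for every probe.
#' @return data frame with columns `probe`, `role`, `mean_abundance`,
#'   `difference`.
#' @export
probe_comparisons <- function(collapsed) {
  a <- collapsed[collapsed$condition == "A", ]
  b <- collapsed[collapsed$condition == "B", ]
  ix <- match(a$probe, b$probe)
  if (anyNA(ix) || nrow(a) != nrow(b))
    stop("every probe must appear in both conditions")
  b <- b[ix, ]
  data.frame(probe = a$probe, role = a$role,
             mean_abundance = (a$intensity + b$intensity) / 2,
             difference = a$intensity - b$intensity)
}

#' Fit the control-based null envelope
#'
#' Estimates how the spread of null between-condition differences grows
#' with abundance, using only control probes (positive and negative;
#' analytes never feed the null). Controls are sorted by `mean_abundance`
#' and grouped into equal-count bins (4-8 bins, >= 3 members each,
#' adaptive); per bin, the standard deviation of the differences (with a
#' small-sample log-scale bias correction) and the bin's mean abundance are
#' computed; the envelope half-width
#' \eqn{h(x) = a x^b} (twice the local SD, i.e. the ~95% band) is fitted to
#' (bin mean, 2 SD) by least squares on the log-log scale, with the
#' exponent clamped to `b >= 0` so the envelope widens monotonely.
#'
#' @param control_comparisons rows of [probe_comparisons()] (analyte rows
#'   are dropped automatically); needs >= 6 controls spanning at least a
#'   10-fold abundance range.
#' @return an object of class `null_envelope`: `half_width` (function of
#'   mean abundance returning 2 SD), `fit_coefficients` (`a`, `b`), and
#'   `bin_table` (bin mean abundance, bin 2 SD, n).
#' @export
build_null_envelope <- function(control_comparisons) {
  ctl <- control_comparisons[
    control_comparisons$role %in% c("pos_control", "neg_control"), ]
  n <- nrow(ctl)
  if (n < 6L) stop("insufficient controls for envelope: need >= 6, got ", n)
  rng <- range(ctl$mean_abundance)
  if (rng[1] <= 0 || rng[2] / rng[1] < 10)
    stop("controls must span at least a 10-fold abundance range")
  ctl <- ctl[order(ctl$mean_abundance), ]
  n_bins <- max(2L, min(8L, n %/% 3L))
  bin <- ceiling(seq_len(n) / (n / n_bins))
  bt <- do.call(rbind, lapply(split(ctl, bin), function(d) {
    m <- nrow(d)
    # small-sample correction: E[log s] underestimates log sigma by
    # (log((m-1)/2) - digamma((m-1)/2))/2 for Gaussian data, which would
    # bias the log-log regression toward a too-narrow envelope
    corr <- exp((log((m - 1) / 2) - digamma((m - 1) / 2)) / 2)
    data.frame(mean_abundance = mean(d$mean_abundance),
               two_sd = 2 * sd(d$difference) * corr, n = m)
  }))
  rownames(bt) <- NULL
  usable <- bt$mean_abundance > 0 & bt$two_sd > 0
  if (sum(usable) < 2L)
    stop("insufficient controls for envelope: fewer than 2 usable bins")
  fit <- lm(log(two_sd) ~ log(mean_abundance), data = bt[usable, ])
  b <- unname(coef(fit)[2])
  if (b < 0) {
    # homoscedastic fallback: flat envelope at the geometric-mean width
    b <- 0
    a <- exp(mean(log(bt$two_sd[usable])))
  } else {
    a <- exp(unname(coef(fit)[1]))
  }
  hw <- function(x) a * x^b
  structure(list(half_width = hw, fit_coefficients = c(a = a, b = b),
                 bin_table = bt),
            class = "null_envelope")
}

#' @export
print.null_envelope <- function(x, ...) {
  cat(sprintf(
    "Null envelope half-width (2 SD): %.4g * abundance^%.3f (%d bins)\n",
    x$fit_coefficients["a"], x$fit_coefficients["b"], nrow(x$bin_table)))
  invisible(x)
}

#' Z-score of a probe difference against the null envelope
#'
#' The envelope half-width at a probe's abundance is twice the local null
#' SD, so \eqn{z = 2\,d / h(x)} expresses the difference `d` in SD units:
#' a probe sitting exactly on the 95% band scores |z| = 2.
#'
#' @param difference condition A minus B duplicate-collapsed intensity
#'   (vectorised).
#' @param mean_abundance the probe's mean abundance (x-axis value).
#' @param envelope a [build_null_envelope()] result.
#' @return z-scores, carrying the sign of the difference.
#' @export
z_score <- function(difference, mean_abundance, envelope) {
  stopifnot(inherits(envelope, "null_envelope"))
  hw <- envelope$half_width(mean_abundance)
  if (any(hw <= 0))
    stop("null envelope half-width is zero at the requested abundance")
  2 * difference / hw
}

#' Score all probes against the null envelope
#'
#' @param comparisons output of [probe_comparisons()].
#' @param envelope a [build_null_envelope()] result.
#' @param threshold |z| at or above which a probe is flagged significant.
#' @return `comparisons` with added columns `z`, `significant`, and
#'   `direction` (`"higher_in_A"` / `"higher_in_B"` / `"equal"`).
#' @export
score_probes <- function(comparisons, envelope, threshold = 3) {
  z <- z_score(comparisons$difference, comparisons$mean_abundance, envelope)
  comparisons$z <- z
  comparisons$significant <- abs(z) >= threshold
  comparisons$direction <- ifelse(comparisons$difference > 0, "higher_in_A",
                                  ifelse(comparisons$difference < 0,
                                         "higher_in_B", "equal"))
  comparisons
}

#' Call differentially secreted probes
#'
#' Flags analyte probes whose |z| meets the significance threshold (3 by
#' default, i.e. three null SDs from no difference), sorted by decreasing
#' |z|, with the direction of the change.
#'
#' @inheritParams score_probes
#' @return data frame of flagged analyte probes: `probe`, `mean_abundance`,
#'   `difference`, `z`, `direction`.
#' @export
call_differential <- function(comparisons, envelope, threshold = 3) {
  scored <- score_probes(comparisons, envelope, threshold)
  hits <- scored[scored$role == "analyte" & scored$significant, ]
  hits <- hits[order(-abs(hits$z)),
               c("probe", "mean_abundance", "difference", "z", "direction")]
  rownames(hits) <- NULL
  hits
}

#' End-to-end two-array differential secretome analysis
#'
#' Convenience wrapper: optional normalization, duplicate collapsing,
#' comparison coordinates, control-based envelope, and differential calls.
#'
#' @param spots raw spot table (see [normalize_arrays()]).
#' @param normalize logical; rescale/background-subtract first.
#' @param threshold significance threshold on |z|.
#' @return list with `comparisons` (scored probe table), `envelope`, and
#'   `hits` (the [call_differential()] output).
#' @export
analyze_arrays <- function(spots, normalize = FALSE, threshold = 3) {
  if (normalize) spots <- normalize_arrays(spots)
  cmp <- probe_comparisons(collapse_duplicates(spots))
  env <- build_null_envelope(cmp)
  list(comparisons = score_probes(cmp, env, threshold), envelope = env,
       hits = call_differential(cmp, env, threshold))
}
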