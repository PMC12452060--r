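#' Configuration for simulating a tumor growth cohort
#'
#' Describes the generative law the growth fitter assumes: per-mouse initial
#' bolus sizes drawn lognormally around `initial_volume_median`, exponential
#' growth at a cohort-shared net rate, and multiplicative lognormal
#' measurement noise (Gaussian on ln volume). Measurements on an
#' every-two-days schedule are right-truncated at the humane-endpoint
#' ceiling (no volume above `ceiling_volume` is emitted) and points below
#' the caliper detection floor are dropped.
#'
#' @param n_mice number of mice in the cohort.
#' @param true_rate net growth rate k, day^-1 (k = k_P in immunodeficient
#'   hosts, k_P - k_D in immunocompetent hosts).
#' @param initial_volume_median median initial bolus volume C_T0, mm^3.
#' @param initial_volume_log_sd lognormal spread of per-mouse C_T0
#'   (sd of ln C_T0).
#' @param noise_log_sd sd of Gaussian measurement noise on ln volume
#'   (0.15 corresponds to roughly 15% caliper coefficient of variation).
#' @param schedule strictly increasing measurement days; default every two
#'   days from day 4 (approximate palpability) to day 30.
#' @param ceiling_volume humane-endpoint volume, mm^3; the series is
#'   truncated before the first measurement exceeding it.
#' @param detection_floor volumes below this (mm^3) are dropped.
#' @param min_points minimum retained points per curve.
#' @param on_short_curve what to do when truncation leaves a curve with
#'   fewer than `min_points` points: `"error"` (default) or `"resimulate"`
#'   (redraw that mouse's noise, up to 25 attempts).
#' @param cell_line,host labels copied into the output table.
#' @param seed integer seed; the whole table is reproducible under it.
#' @return an object of class `growth_sim_config`.
#' @export
growth_sim_config <- function(n_mice = 5L, true_rate = 0.5,
                              initial_volume_median = 1,
                              initial_volume_log_sd = 0.5,
                              noise_log_sd = 0.15,
                              schedule = seq(4, 30, by = 2),
                              ceiling_volume = 1500, detection_floor = 1,
                              min_points = 3L,
                              on_short_curve = c("error", "resimulate"),
                              cell_line = "other", host = "other",
                              seed = 1L) {
  cfg <- list(n_mice = as.integer(n_mice), true_rate = true_rate,
              initial_volume_median = initial_volume_median,
              initial_volume_log_sd = initial_volume_log_sd,
              noise_log_sd = noise_log_sd, schedule = schedule,
              ceiling_volume = ceiling_volume,
              detection_floor = detection_floor,
              min_points = as.integer(min_points),
              on_short_curve = match.arg(on_short_curve),
              cell_line = cell_line, host = host, seed = as.integer(seed))
  if (cfg$n_mice < 1L) stop("n_mice must be >= 1")
  if (cfg$initial_volume_median <= 0 || cfg$ceiling_volume <= 0 ||
      cfg$detection_floor <= 0)
    stop("all volumes must be positive")
  if (cfg$initial_volume_log_sd < 0 || cfg$noise_log_sd < 0)
    stop("log-sd parameters must be non-negative")
  if (any(diff(cfg$schedule) <= 0) || length(cfg$schedule) < 1L)
    stop("schedule must be strictly increasing")
  if (any(cfg$schedule < 0)) stop("schedule days must be non-negative")
  if (cfg$ceiling_volume <= cfg$detection_floor)
    stop("ceiling_volume must exceed detection_floor")
  class(cfg) <- "growth_sim_config"
  cfg
}

# one mouse's retained (day, volume) series under the config's censoring
.simulate_curve <- function(config, c0) {
  v <- c0 * exp(config$true_rate * config$schedule) *
    exp(rnorm(length(config$schedule), 0, config$noise_log_sd))
  over <- which(v > config$ceiling_volume)
  keep <- if (length(over)) seq_len(over[1] - 1L) else seq_along(v)
  keep <- keep[v[keep] >= config$detection_floor]
  data.frame(day = config$schedule[keep], volume_mm3 = v[keep])
}

#' Simulate a longitudinal tumor growth cohort
#'
#' Generates one growth table per the generative law described in
#' [growth_sim_config()]: \eqn{V_i(t) = C_{T0,i} e^{kt} e^{\epsilon}},
#' \eqn{\epsilon \sim N(0, \sigma_{ln}^2)}, with detection-floor and
#' humane-endpoint censoring applied.
#'
#' @param config a [growth_sim_config()].
#' @return data frame with columns `mouse_id`, `cell_line`, `host`, `day`,
#'   `volume_mm3`; attribute `true_c_t0` holds the simulated per-mouse
#'   initial volumes.
#' @examples
#' cohort <- simulate_growth_cohort(growth_sim_config(n_mice = 3, seed = 7))
#' head(cohort)
#' @export
simulate_growth_cohort <- function(config) {
  stopifnot(inherits(config, "growth_sim_config"))
  # fail fast when even a noiseless curve cannot retain min_points
  clean <- config$initial_volume_median *
    exp(config$true_rate * config$schedule)
  n_clean <- sum(clean >= config$detection_floor &
                   cumsum(clean > config$ceiling_volume) == 0)
  if (n_clean < config$min_points)
    stop("schedule too short at this rate: a typical curve retains ",
         n_clean, " point(s) between the detection floor and the humane ",
         "ceiling, but min_points = ", config$min_points)
  withr::with_seed(config$seed, {
    c0 <- config$initial_volume_median *
      exp(rnorm(config$n_mice, 0, config$initial_volume_log_sd))
    rows <- lapply(seq_len(config$n_mice), function(i) {
      cur <- .simulate_curve(config, c0[i])
      attempts <- 0L
      while (nrow(cur) < config$min_points) {
        if (config$on_short_curve == "error")
          stop("mouse ", i, " retained ", nrow(cur), " point(s) < min_points ",
               "= ", config$min_points, " after floor/ceiling truncation; ",
               "lengthen the schedule or set on_short_curve = 'resimulate'")
        attempts <- attempts + 1L
        if (attempts > 25L)
          stop("mouse ", i, ": resimulation failed to reach min_points = ",
               config$min_points, " in 25 attempts; the schedule is too ",
               "short at this growth rate")
        cur <- .simulate_curve(config, c0[i])
      }
      data.frame(mouse_id = sprintf("m%02d", i), cell_line = config$cell_line,
                 host = config$host, day = cur$day,
                 volume_mm3 = cur$volume_mm3)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "true_c_t0") <- setNames(c0, sprintf("m%02d", seq_along(c0)))
    out
  })
}

#' Simulate paired cohorts in immunodeficient and immunocompetent hosts
#'
#' Two cohorts of the same cell line differing only in true net rate (and
#' seed): an NSG-like cohort growing at the intrinsic proliferation rate
#' `k_p`, and a C57-like cohort at the net rate `k_p - k_d`.
#'
#' @param k_p intrinsic proliferation rate, day^-1 (> 0).
#' @param k_d immune-mediated death rate, day^-1 (any real; `k_p - k_d` may
#'   be negative, in which case the immunocompetent cohort shrinks).
#' @param config a [growth_sim_config()]; its `true_rate` is overridden and
#'   the C57-like cohort uses `seed + 1`.
#' @return named list of two growth tables, `nsg` and `c57`, with `host`
#'   labels `"NSG"` and `"C57BL/6"`.
#' @export
simulate_paired_cohorts <- function(k_p, k_d, config = growth_sim_config()) {
  if (k_p <= 0) stop("k_p must be positive")
  cfg_nsg <- config
  cfg_nsg$true_rate <- k_p
  cfg_nsg$host <- "NSG"
  cfg_c57 <- config
  cfg_c57$true_rate <- k_p - k_d
  cfg_c57$host <- "C57BL/6"
  cfg_c57$seed <- config$seed + 1L
  list(nsg = simulate_growth_cohort(cfg_nsg),
       c57 = simulate_growth_cohort(cfg_c57))
}

#' Configuration for simulating a viability plate
#'
#' @param true_ic50 generating half-maximal concentration (> 0), in the
#'   plate's concentration unit.
#' @param concentrations >= 4 distinct non-negative doses, including 0.
#' @param n_replicates biological replicates per dose (default 4).
#' @param noise_sd additive Gaussian noise on viability, percentage points.
#' @param drug,cell_line,concentration_unit labels copied into the table.
#' @param seed integer seed.
#' @return an object of class `plate_sim_config`.
#' @export
plate_sim_config <- function(true_ic50, concentrations, n_replicates = 4L,
                             noise_sd = 5, drug = "drug",
                             cell_line = "line", concentration_unit = "uM",
                             seed = 1L) {
  cfg <- list(true_ic50 = true_ic50, concentrations = concentrations,
              n_replicates = as.integer(n_replicates), noise_sd = noise_sd,
              drug = drug, cell_line = cell_line,
              concentration_unit = concentration_unit,
              seed = as.integer(seed))
  if (cfg$true_ic50 <= 0) stop("true_ic50 must be positive")
  if (any(cfg$concentrations < 0)) stop("concentrations must be >= 0")
  if (length(unique(cfg$concentrations)) < 4L)
    stop("need at least 4 distinct concentrations (including 0)")
  if (cfg$n_replicates < 1L) stop("n_replicates must be >= 1")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  class(cfg) <- "plate_sim_config"
  cfg
}

#' Simulate a dose-response viability plate
#'
#' Viability is \eqn{100(1 - x/(x + IC_{50}))} plus additive Gaussian noise
#' in percentage points, clipped at 0.
#'
#' @param config a [plate_sim_config()].
#' @return data frame with columns `drug`, `cell_line`, `concentration`,
#'   `concentration_unit`, `replicate`, `viability_pct`.
#' @export
simulate_viability_plate <- function(config) {
  stopifnot(inherits(config, "plate_sim_config"))
  withr::with_seed(config$seed, {
    grid <- expand.grid(replicate = seq_len(config$n_replicates),
                        concentration = config$concentrations)
    v <- predict_viability(grid$concentration, config$true_ic50) +
      rnorm(nrow(grid), 0, config$noise_sd)
    data.frame(drug = config$drug, cell_line = config$cell_line,
               concentration = grid$concentration,
               concentration_unit = config$concentration_unit,
               replicate = grid$replicate,
               viability_pct = pmax(v, 0))
  })
}

#' Configuration for simulating duplicate-spot antibody arrays
#'
#' Two arrays (condition A and B) sharing per-probe latent abundances drawn
#' lognormally. Each condition observes a probe's level once with
#' heteroscedastic noise SD = `noise_c * level^noise_gamma` (SD grows with
#' abundance), then spots it in duplicate with relative within-array jitter.
#' Differential probes have their condition-B level multiplied by a fold
#' change. Control probes sit on a fixed log-spaced abundance ladder
#' (negative controls low, positive controls high) so the null envelope can
#' be estimated across the abundance range.
#'
#' @param n_analytes number of analyte probes (default 111, the size of a
#'   typical mouse XL cytokine membrane).
#' @param abundance_log_mean,abundance_log_sd lognormal parameters of
#'   analyte latent abundances (arbitrary intensity units).
#' @param noise_c,noise_gamma heteroscedastic noise law SD = c * mean^gamma,
#'   `c > 0`, `0 < gamma <= 1`.
#' @param differential_probes named numeric vector of fold changes (> 0)
#'   applied to condition B, names matching probe ids such as
#'   `"analyte_005"`.
#' @param n_pos_controls,n_neg_controls control spot counts (>= 3 each).
#' @param duplicate_jitter_sd relative sd of within-array duplicate jitter
#'   (each spot is the condition-level value times `1 + N(0, sd^2)`).
#' @param seed integer seed.
#' @return an object of class `array_sim_config`.
#' @export
array_sim_config <- function(n_analytes = 111L,
                             abundance_log_mean = log(500),
                             abundance_log_sd = 1.2,
                             noise_c = 0.1, noise_gamma = 0.8,
                             differential_probes = NULL,
                             n_pos_controls = 9L, n_neg_controls = 9L,
                             duplicate_jitter_sd = 0.05, seed = 1L) {
  cfg <- list(n_analytes = as.integer(n_analytes),
              abundance_log_mean = abundance_log_mean,
              abundance_log_sd = abundance_log_sd,
              noise_c = noise_c, noise_gamma = noise_gamma,
              differential_probes = differential_probes,
              n_pos_controls = as.integer(n_pos_controls),
              n_neg_controls = as.integer(n_neg_controls),
              duplicate_jitter_sd = duplicate_jitter_sd,
              seed = as.integer(seed))
  if (cfg$n_analytes < 1L) stop("n_analytes must be >= 1")
  if (cfg$noise_c < 0) stop("noise_c must be non-negative")
  if (cfg$noise_gamma <= 0 || cfg$noise_gamma > 1)
    stop("noise_gamma must lie in (0, 1]")
  if (cfg$n_pos_controls < 3L || cfg$n_neg_controls < 3L)
    stop("need >= 3 positive and >= 3 negative controls to estimate the ",
         "null envelope")
  if (cfg$duplicate_jitter_sd < 0) stop("duplicate_jitter_sd must be >= 0")
  if (!is.null(cfg$differential_probes)) {
    if (is.null(names(cfg$differential_probes)) ||
        any(!nzchar(names(cfg$differential_probes))))
      stop("differential_probes must be a named vector of fold changes")
    if (any(cfg$differential_probes <= 0)) stop("fold changes must be > 0")
  }
  class(cfg) <- "array_sim_config"
  cfg
}

#' Simulate a pair of duplicate-spot antibody arrays
#'
#' @param config an [array_sim_config()].
#' @return data frame (the two arrays stacked) with columns `probe`,
#'   `role` (`analyte`/`pos_control`/`neg_control`), `condition`
#'   (`A`/`B`), `spot1`, `spot2`; all intensities floored at 0.
#' @export
simulate_cytokine_arrays <- function(config) {
  stopifnot(inherits(config, "array_sim_config"))
  withr::with_seed(config$seed, {
    probes <- sprintf("analyte_%03d", seq_len(config$n_analytes))
    if (!is.null(config$differential_probes)) {
      bad <- setdiff(names(config$differential_probes), probes)
      if (length(bad))
        stop("differential probe(s) not on the array: ",
             paste(bad, collapse = ", "))
    }
    abund <- exp(rnorm(config$n_analytes, config$abundance_log_mean,
                       config$abundance_log_sd))
    # fixed control ladders spanning the analyte abundance range:
    # negatives low, positives high, 1000-fold combined span
    neg_ab <- exp(seq(log(10), log(150), length.out = config$n_neg_controls))
    pos_ab <- exp(seq(log(300), log(10000),
                      length.out = config$n_pos_controls))
    probe <- c(probes,
               sprintf("neg_ctrl_%02d", seq_len(config$n_neg_controls)),
               sprintf("pos_ctrl_%02d", seq_len(config$n_pos_controls)))
    role <- c(rep("analyte", config$n_analytes),
              rep("neg_control", config$n_neg_controls),
              rep("pos_control", config$n_pos_controls))
    level <- c(abund, neg_ab, pos_ab)

    one_condition <- function(cond) {
      lv <- level
      if (cond == "B" && !is.null(config$differential_probes)) {
        idx <- match(names(config$differential_probes), probe)
        lv[idx] <- lv[idx] * config$differential_probes
      }
      obs <- lv + rnorm(length(lv), 0, config$noise_c * lv^config$noise_gamma)
      obs <- pmax(obs, 0)
      s1 <- obs * (1 + rnorm(length(obs), 0, config$duplicate_jitter_sd))
      s2 <- obs * (1 + rnorm(length(obs), 0, config$duplicate_jitter_sd))
      data.frame(probe = probe, role = role, condition = cond,
                 spot1 = pmax(s1, 0), spot2 = pmax(s2, 0))
    }
    out <- rbind(one_condition("A"), one_condition("B"))
    rownames(out) <- NULL
    out
  })
}
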