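# Synthetic infection-experiment generator with known ground truth.
#
# A scenario is a factorial set of host_type x strain cells; each cell has
# its own vigour a, slope b, optional quadratic term, and a density
# distribution (normal on the analysis scale, truncated so raw cfu >= 0).
# Continuous health is a + b*d + quad*d^2 + N(0, sigma_health); binary
# survival is Bernoulli with logit-linear predictor a + b*d + quad*d^2
# (a and b are then log-odds parameters).

CELL_COLS <- c("host_type", "strain", "a", "b", "mu_density", "sd_density", "n")

#' Define a simulation scenario
#'
#' @param cells data.frame with one row per host_type x strain cell and
#'   columns `host_type`, `strain`, `a` (vigour), `b` (slope),
#'   `mu_density`, `sd_density` (density mean/sd on the analysis scale),
#'   `n` (hosts per cell) and optionally `quad` (quadratic density
#'   coefficient, default 0).
#' @param sigma_health residual health standard deviation (continuous
#'   outcomes; must be positive).
#' @param outcome_kind `"continuous"` (health score) or `"binary"`
#'   (survival; `a` and `b` are then log-odds parameters).
#' @param seed integer seed; mandatory, fully determines the simulated data.
#' @param analysis_scale scale on which `mu_density`/`sd_density` and the
#'   health model operate: `"log10p1"` (default; densities are lognormal-like
#'   on the raw cfu scale) or `"raw"`.
#' @return object of class `sim_scenario`.
#' @export
simulation_scenario <- function(cells, sigma_health = 1,
                                outcome_kind = c("continuous", "binary"),
                                seed, analysis_scale = c("log10p1", "raw")) {
  outcome_kind <- match.arg(outcome_kind)
  analysis_scale <- match.arg(analysis_scale)
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop_config("scenario field 'seed' is mandatory (an omitted seed is an error)")
  }
  if (!is.data.frame(cells)) stop_config("scenario field 'cells' must be a data.frame")
  missing_cols <- setdiff(CELL_COLS, names(cells))
  if (length(missing_cols)) {
    stop_config("scenario cells missing field(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"quad" %in% names(cells)) cells$quad <- 0
  if (any(cells$n < 1)) stop_config("scenario field 'n' must be >= 1 in every cell")
  if (any(cells$sd_density <= 0)) stop_config("scenario field 'sd_density' must be positive")
  if (outcome_kind == "continuous" && sigma_health <= 0) {
    stop_config("scenario field 'sigma_health' must be positive for continuous outcomes")
  }
  if (any(!is.finite(cells$a)) || any(!is.finite(cells$b)) ||
      any(!is.finite(cells$mu_density))) {
    stop_config("scenario cell parameters 'a', 'b', 'mu_density' must be finite")
  }
  cells$host_type <- as.character(cells$host_type)
  cells$strain <- as.character(cells$strain)
  cells$n <- as.integer(cells$n)
  structure(
    list(cells = cells[, c(CELL_COLS[1:4], "quad", CELL_COLS[5:7])],
         sigma_health = sigma_health, outcome_kind = outcome_kind,
         seed = as.integer(seed), analysis_scale = analysis_scale),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("Simulation scenario: %d cell(s), outcome %s, scale %s, seed %d\n",
              nrow(x$cells), x$outcome_kind, x$analysis_scale, x$seed))
  if (x$outcome_kind == "continuous") {
    cat(sprintf("sigma_health = %g\n", x$sigma_health))
  }
  print(x$cells, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Simulate an infection experiment from a scenario
#'
#' Densities are drawn per cell from a normal distribution on the analysis
#' scale, truncated (by redraw) so raw density is non-negative; the health
#' or survival outcome follows the cell's health-density model. The seed in
#' the scenario fully determines the output. If truncation affects more than
#' 0.1% of draws a message is logged.
#'
#' @param scenario a [simulation_scenario()] (or a preset from
#'   [make_preset()]).
#' @return data.frame of experiment records with columns `host_type`,
#'   `strain`, `density` (raw scale) and `health` or `survived`; the
#'   generating scenario is attached as attribute `"ground_truth"`.
#' @export
simulate_experiment <- function(scenario) {
  if (!inherits(scenario, "sim_scenario")) {
    stop_config("`scenario` must be a simulation_scenario")
  }
  set.seed(scenario$seed)
  cells <- scenario$cells
  n_rejected <- 0L
  n_total <- 0L
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    d <- stats::rnorm(cl$n, cl$mu_density, cl$sd_density)
    n_total <- n_total + cl$n
    # truncate at 0 on the raw scale (d >= 0 on both supported scales)
    for (guard in 1:1000) {
      neg <- d < 0
      if (!any(neg)) break
      n_rejected <- n_rejected + sum(neg)
      n_total <- n_total + sum(neg)
      d[neg] <- stats::rnorm(sum(neg), cl$mu_density, cl$sd_density)
    }
    lp <- cl$a + cl$b * d + cl$quad * d^2
    out <- data.frame(
      host_type = cl$host_type, strain = cl$strain,
      density = from_analysis_scale(d, scenario$analysis_scale),
      stringsAsFactors = FALSE
    )
    if (scenario$outcome_kind == "continuous") {
      out$health <- lp + stats::rnorm(cl$n, 0, scenario$sigma_health)
    } else {
      out$survived <- stats::rbinom(cl$n, 1, stats::plogis(lp))
    }
    rows[[i]] <- out
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (n_rejected / n_total > 0.001) {
    message(sprintf("density truncation at 0 affected %.2f%% of draws",
                    100 * n_rejected / n_total))
  }
  attr(res, "ground_truth") <- scenario
  res
}

PRESETS <- c("fig1_resistance", "fig1_tolerance", "fig2_strains",
             "knockout_pure_benevolence", "knockout_pure_malevolence",
             "knockout_pure_proliferation", "knockout_mixed", "null")

#' Preset simulation scenarios
#'
#' Ready-made scenarios whose ground truth matches their name:
#' \describe{
#'   \item{fig1_resistance}{three host types differing only in mean density
#'     (variation in resistance, none in tolerance).}
#'   \item{fig1_tolerance}{three host types differing only in slope
#'     (variation in tolerance, none in resistance).}
#'   \item{fig2_strains}{three strains with benevolent (b > 0), neutral
#'     (b = 0) and malevolent (b < 0) slopes and distinct mean densities.}
#'   \item{knockout_pure_benevolence}{wild type slope above knockout slope,
#'     identical density distributions.}
#'   \item{knockout_pure_malevolence}{wild type slope below knockout slope,
#'     identical density distributions.}
#'   \item{knockout_pure_proliferation}{identical slopes, wild type mean
#'     density above knockout.}
#'   \item{knockout_mixed}{wild type both raises density (+1 log10) and
#'     lowers the slope (-0.8).}
#'   \item{null}{two strains with identical parameters.}
#' }
#' Defaults emulate a typical rodent/insect infection assay on the
#' log10(cfu+1) scale: vigour 10, residual health sd 1, density sd 1 log
#' unit around a mean of ~4 log10 cfu, n = 50 hosts per cell.
#'
#' @param name preset name (see above).
#' @param seed integer seed (mandatory).
#' @param n hosts per cell (default 50).
#' @param sigma_health residual health standard deviation (default 1).
#' @return a [simulation_scenario()].
#' @export
make_preset <- function(name, seed, n = 50, sigma_health = 1) {
  if (length(name) != 1 || !name %in% PRESETS) {
    stop_config("unknown preset '", paste(name, collapse = ","),
                "'; available presets: ", paste(PRESETS, collapse = ", "))
  }
  cell <- function(host, strain, a, b, mu, quad = 0) {
    data.frame(host_type = host, strain = strain, a = a, b = b, quad = quad,
               mu_density = mu, sd_density = 1, n = n, stringsAsFactors = FALSE)
  }
  cells <- switch(name,
    null = rbind(cell("host", "wt", 10, -1, 4), cell("host", "ko", 10, -1, 4)),
    fig1_resistance = rbind(cell("H1", "microbe", 10, -1, 2),
                            cell("H2", "microbe", 10, -1, 4),
                            cell("H3", "microbe", 10, -1, 6)),
    fig1_tolerance = rbind(cell("H1", "microbe", 10, -0.5, 4),
                           cell("H2", "microbe", 10, -1.0, 4),
                           cell("H3", "microbe", 10, -1.5, 4)),
    fig2_strains = rbind(cell("host", "S_benevolent", 10, 1, 2),
                         cell("host", "S_neutral", 10, 0, 4),
                         cell("host", "S_malevolent", 10, -1, 6)),
    knockout_pure_benevolence = rbind(cell("host", "wt", 10, 0, 4),
                                      cell("host", "ko", 10, -1, 4)),
    knockout_pure_malevolence = rbind(cell("host", "wt", 10, -1, 4),
                                      cell("host", "ko", 10, 0, 4)),
    knockout_pure_proliferation = rbind(cell("host", "wt", 10, -1, 5),
                                        cell("host", "ko", 10, -1, 4)),
    knockout_mixed = rbind(cell("host", "wt", 10, -1.4, 5),
                           cell("host", "ko", 10, -0.6, 4))
  )
  simulation_scenario(cells, sigma_health = sigma_health,
                      outcome_kind = "continuous", seed = seed,
                      analysis_scale = "log10p1")
}

# Apply one varied parameter to a scenario; used by power_sweep.
apply_sweep_parameter <- function(scenario, parameter, value) {
  sc <- scenario
  switch(parameter,
    n = { sc$cells$n <- as.integer(value) },
    sigma_health = { sc$sigma_health <- value },
    sd_density = { sc$cells$sd_density <- value },
    mu_density = { sc$cells$mu_density <- value },
    delta_b = {
      # slope offset of every non-reference cell relative to the first cell
      sc$cells$b <- c(sc$cells$b[1], rep(sc$cells$b[1] + value, nrow(sc$cells) - 1))
    },
    delta_mu = {
      sc$cells$mu_density <- c(sc$cells$mu_density[1],
                               rep(sc$cells$mu_density[1] + value, nrow(sc$cells) - 1))
    },
    stop_config("unknown sweep parameter '", parameter, "'; supported: ",
                "n, sigma_health, sd_density, mu_density, delta_b, delta_mu")
  )
  sc
}

# Pick the grouping with >= 2 levels for a simulated record set.
pick_grouping <- function(records) {
  if (length(unique(records$strain)) > 1) "strain" else "host_type"
}

# Headline p-value of one named test on one record set.
run_named_test <- function(records, test, scale) {
  switch(test,
    benevolence   = test_slope_variation(records, "strain", scale)$interaction_p,
    tolerance     = test_slope_variation(records, "host_type", scale)$interaction_p,
    proliferation = test_density_variation(records, "strain", scale)$p_value,
    resistance    = test_density_variation(records, "host_type", scale)$p_value,
    curvature     = fit_quadratic_extension(records, pick_grouping(records), scale)$curvature_p,
    binary_interaction = fit_binary_outcome(records, pick_grouping(records), scale)$interaction_p,
    stop_config("unknown test '", test, "'")
  )
}

#' Monte-Carlo power sweep for the framework's tests
#'
#' Repeatedly simulates a scenario while varying one parameter over a grid
#' and records the fraction of replicates in which the named test rejects at
#' `alpha`, with Monte-Carlo standard errors. Replicate seeds are derived
#' from the scenario seed, so the sweep is reproducible.
#'
#' @param base_scenario a [simulation_scenario()].
#' @param varied_parameter one of `"n"`, `"sigma_health"`, `"sd_density"`,
#'   `"mu_density"`, `"delta_b"` (slope offset of non-reference cells
#'   relative to the first cell), `"delta_mu"` (density-mean offset).
#' @param grid numeric vector of parameter values (non-empty).
#' @param reps replicates per grid value (>= 100 recommended for stable
#'   estimates; fewer trigger a warning).
#' @param alpha rejection level.
#' @param test which test's rejection rate to measure: `"benevolence"`,
#'   `"tolerance"`, `"proliferation"`, `"resistance"`, `"curvature"` or
#'   `"binary_interaction"`.
#' @return data.frame with one row per grid value: `value`, `reps`,
#'   `rejections`, `power`, `mc_se`.
#' @export
power_sweep <- function(base_scenario, varied_parameter, grid, reps,
                        alpha = 0.05,
                        test = c("benevolence", "tolerance", "proliferation",
                                 "resistance", "curvature", "binary_interaction")) {
  test <- match.arg(test)
  if (!inherits(base_scenario, "sim_scenario")) {
    stop_config("`base_scenario` must be a simulation_scenario")
  }
  if (length(grid) == 0) stop_config("sweep grid must be non-empty")
  if (is.null(reps) || !is.finite(reps) || reps < 1) {
    stop_config("reps must be a positive integer")
  }
  if (reps < 100) {
    warning("reps < 100 gives unstable power estimates", call. = FALSE)
  }
  seeds <- matrix(mc_seeds(base_scenario$seed, length(grid) * reps),
                  nrow = reps)
  out <- data.frame(parameter = varied_parameter, value = grid,
                    reps = as.integer(reps), rejections = NA_integer_,
                    power = NA_real_, mc_se = NA_real_)
  for (g in seq_along(grid)) {
    sc_g <- apply_sweep_parameter(base_scenario, varied_parameter, grid[g])
    rej <- 0L
    for (r in seq_len(reps)) {
      sc_g$seed <- seeds[r, g]
      p <- run_named_test(simulate_experiment(sc_g), test, sc_g$analysis_scale)
      if (!is.na(p) && !is.nan(p) && p < alpha) rej <- rej + 1L
    }
    out$rejections[g] <- rej
    out$power[g] <- rej / reps
    out$mc_se[g] <- sqrt(out$power[g] * (1 - out$power[g]) / reps)
  }
  attr(out, "test") <- test
  attr(out, "alpha") <- alpha
  out
}
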