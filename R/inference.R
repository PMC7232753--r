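# Fit-and-test operations for the framework's study designs.
#
# Each operation fits one of the standard models
#   density = group                         (resistance / proliferation)
#   health  = group + density + group:density   (tolerance / benevolence)
#   density = host_type + strain (+ host_type:strain screen)
#   health  = host_type + strain + density + host_type:density + strain:density
# on the configured density scale and returns a `pb_fit` with per-term tests,
# per-group lines and summaries. Interaction tests use extra-sum-of-squares F
# comparisons of the full vs the additive model.

check_min_levels <- function(df, grouping) {
  lev <- levels(df$group)
  if (length(lev) < 2) {
    stop_design("need at least two ", grouping, " levels; found ",
                length(lev), " (", paste(lev, collapse = ", "), ")")
  }
  lev
}

check_density_varies <- function(df, grouping) {
  flat <- tapply(df$d, df$group, function(x) length(unique(x)) < 2)
  if (any(flat)) {
    stop_design("density is constant within ", grouping, " level(s): ",
                paste(names(flat)[flat], collapse = ", "),
                "; the slope is unidentifiable there")
  }
}

# Internal overlap check used by slope-comparison fits (see density_overlap);
# low pairwise overlap of observed density ranges makes slope comparisons
# unreliable.
overlap_flags <- function(df, threshold) {
  rep <- overlap_pairs(df$d, df$group, threshold)
  if (nrow(rep$flagged)) "low_density_overlap" else character()
}

#' Test for variation in resistance or proliferation (density ~ group)
#'
#' Fits a one-way linear model of microbial density (on the analysis scale)
#' against host type or strain. A significant group effect indicates
#' variation in resistance (grouping by host type) or in proliferation
#' (grouping by strain).
#'
#' @param records experiment data.frame (see [read_records()] for columns).
#' @param grouping `"host_type"` or `"strain"`.
#' @param scale density analysis scale: `"log10p1"` (log10(cfu + 1), default)
#'   or `"raw"`.
#' @param alpha significance level recorded in the result.
#' @param include_uninfected keep density-0 hosts (default `TRUE`).
#' @return a `pb_fit`; `$p_value` is the omnibus group p-value,
#'   `$group_summaries` holds per-group mean densities `c_bar`.
#' @export
test_density_variation <- function(records, grouping = c("host_type", "strain"),
                                   scale = c("log10p1", "raw"), alpha = 0.05,
                                   include_uninfected = TRUE) {
  grouping <- match.arg(grouping)
  scale <- match.arg(scale)
  prep <- pb_prepare(records, grouping, scale, include_uninfected)
  df <- prep$df
  check_min_levels(df, grouping)
  counts <- table(df$group)
  if (any(counts < 2)) {
    stop_design("each ", grouping, " level needs at least 2 records; too few in: ",
                paste(names(counts)[counts < 2], collapse = ", "))
  }
  m1 <- stats::lm(d ~ group, data = df)
  m0 <- stats::lm(d ~ 1, data = df)
  cmp <- model_comparison_p(m0, m1)
  flags <- c(character(), cmp$flag)
  new_pb_fit(
    model_name = paste0("density ~ ", grouping),
    property = if (grouping == "host_type") "resistance" else "proliferation",
    formula_terms = c("(Intercept)", grouping),
    coefficients = coef_table(m1),
    p_value = cmp$p,
    group_summaries = make_group_summaries(df),
    n_obs = nrow(df), n_excluded = prep$n_excluded,
    analysis_scale = scale, alpha = alpha, flags = flags,
    extra = list(statistic = cmp$stat, statistic_df = cmp$df, grouping = grouping)
  )
}

#' Test for variation in tolerance or benevolence (health ~ group * density)
#'
#' Fits the ANCOVA-style model `health = group + density + group:density`.
#' A significant group-by-density interaction means the slope of health on
#' density varies among groups: variation in tolerance (host types) or in
#' benevolence (strains). The interaction is tested by an
#' extra-sum-of-squares F comparison of the full against the additive model.
#'
#' @inheritParams test_density_variation
#' @param overlap_threshold pairwise density-range overlap coefficient below
#'   which the result is flagged `low_density_overlap` (slope comparisons
#'   between groups with barely-overlapping density ranges can be spurious).
#' @return a `pb_fit`; `$interaction_p` is the slope-heterogeneity p-value,
#'   `$group_lines` the per-group intercepts/slopes (equal to independent
#'   per-group least squares), `$group_summaries` the c_bar/b/virulence table.
#' @export
test_slope_variation <- function(records, grouping = c("host_type", "strain"),
                                 scale = c("log10p1", "raw"), alpha = 0.05,
                                 include_uninfected = TRUE,
                                 overlap_threshold = 0.5) {
  grouping <- match.arg(grouping)
  scale <- match.arg(scale)
  prep <- pb_prepare(records, grouping, scale, include_uninfected)
  if (prep$outcome_kind == "binary") {
    stop_design("binary (survival) outcome: use fit_binary_outcome()")
  }
  df <- prep$df
  check_min_levels(df, grouping)
  check_density_varies(df, grouping)
  full <- stats::lm(outcome ~ group + d + group:d, data = df)
  add  <- stats::lm(outcome ~ group + d, data = df)
  cmp <- model_comparison_p(add, full)
  lines <- fit_group_lines(df)
  flags <- c(overlap_flags(df, overlap_threshold), cmp$flag)
  new_pb_fit(
    model_name = paste0("health ~ ", grouping, " + density + ", grouping, ":density"),
    property = if (grouping == "host_type") "tolerance" else "benevolence",
    formula_terms = c("(Intercept)", grouping, "density", paste0(grouping, ":density")),
    coefficients = coef_table(full),
    p_value = cmp$p,
    interaction_p = cmp$p,
    group_lines = lines,
    group_summaries = make_group_summaries(df, lines),
    n_obs = nrow(df), n_excluded = prep$n_excluded,
    analysis_scale = scale, alpha = alpha, flags = flags,
    extra = list(statistic = cmp$stat, statistic_df = cmp$df, grouping = grouping)
  )
}

#' Combined factorial analysis: hosts and microbes varied together
#'
#' For a design with two or more host types each infected by two or more
#' strains, fits (i) the density model `density = host_type + strain`, which
#' tests for variation in resistance and proliferation, and (ii) the health
#' model `health = host_type + strain + density + host_type:density +
#' strain:density`, which tests for variation in tolerance and benevolence.
#'
#' The host_type-by-strain interaction is screened first in the density
#' model: if significant at `alpha` it is retained and the result is flagged
#' (`outcome depends on the specific combination of host type and strain`);
#' otherwise the additive density model is reported. Per-term p-values are
#' Type-II model-comparison tests.
#'
#' @inheritParams test_density_variation
#' @return object of class `pb_factorial` with elements `density` and
#'   `health` (each a `pb_fit`) and `screen` (host-by-strain screen p-value
#'   and whether the term was retained). The health fit carries
#'   `tolerance_p` and `benevolence_p` for the two interaction tests and
#'   per-cell lines/summaries.
#' @export
fit_combined_factorial <- function(records, scale = c("log10p1", "raw"),
                                   alpha = 0.05, include_uninfected = TRUE) {
  scale <- match.arg(scale)
  v <- validate_records(records)
  if (v$outcome_kind == "binary") {
    stop_design("binary (survival) outcome: the combined factorial model is ",
                "defined for continuous health scores")
  }
  df <- v$records
  df$uninfected <- df$density == 0
  n_excluded <- v$n_excluded
  if (!include_uninfected) {
    n_excluded <- n_excluded + sum(df$uninfected)
    df <- df[!df$uninfected, , drop = FALSE]
  }
  df$host_type <- factor(df$host_type)
  df$strain <- factor(df$strain)
  if (nlevels(df$host_type) < 2 || nlevels(df$strain) < 2) {
    stop_design("combined factorial needs >= 2 host types and >= 2 strains; found ",
                nlevels(df$host_type), " host type(s) and ",
                nlevels(df$strain), " strain(s)")
  }
  cells <- table(df$host_type, df$strain)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop_design("empty host_type x strain cell(s): ",
                paste(rownames(cells)[empty[, 1]], "x",
                      colnames(cells)[empty[, 2]], collapse = ", "))
  }
  df$d <- to_analysis_scale(df$density, scale)

  # -- density model with host x strain screen
  dens_full <- stats::lm(d ~ host_type * strain, data = df)
  dens_add  <- stats::lm(d ~ host_type + strain, data = df)
  screen <- model_comparison_p(dens_add, dens_full)
  retained <- identical(screen$flag, "exact_fit") ||
    (is.finite(screen$p) && screen$p < alpha)
  dens_model <- if (retained) dens_full else dens_add
  dens_flags <- c(screen$flag %||% character(),
                  if (retained) "host_strain_interaction_retained")
  dens_terms <- as.data.frame(car::Anova(dens_model, type = 2))
  dens_terms <- data.frame(term = rownames(dens_terms), dens_terms,
                           row.names = NULL, check.names = FALSE)

  density_fit <- new_pb_fit(
    model_name = if (retained) "density ~ host_type * strain"
                 else "density ~ host_type + strain",
    property = "resistance + proliferation",
    formula_terms = attr(stats::terms(dens_model), "term.labels"),
    coefficients = coef_table(dens_model),
    p_value = NA_real_,
    group_summaries = NULL,
    n_obs = nrow(df), n_excluded = n_excluded,
    analysis_scale = scale, alpha = alpha, flags = dens_flags,
    extra = list(
      term_tests = dens_terms,
      resistance_p = dens_terms[dens_terms$term == "host_type", "Pr(>F)"],
      proliferation_p = dens_terms[dens_terms$term == "strain", "Pr(>F)"]
    )
  )

  # -- health model with both density interactions
  h_full <- stats::lm(outcome ~ host_type + strain + d +
                        host_type:d + strain:d, data = df)
  h_no_hd <- stats::lm(outcome ~ host_type + strain + d + strain:d, data = df)
  h_no_sd <- stats::lm(outcome ~ host_type + strain + d + host_type:d, data = df)
  tol_cmp <- model_comparison_p(h_no_hd, h_full)
  ben_cmp <- model_comparison_p(h_no_sd, h_full)
  h_terms <- as.data.frame(car::Anova(h_full, type = 2))
  h_terms <- data.frame(term = rownames(h_terms), h_terms,
                        row.names = NULL, check.names = FALSE)

  cell_df <- df
  cell_df$group <- interaction(df$host_type, df$strain, sep = ":", drop = TRUE)
  lines <- fit_group_lines(cell_df)
  health_fit <- new_pb_fit(
    model_name = "health ~ host_type + strain + density + host_type:density + strain:density",
    property = "tolerance + benevolence",
    formula_terms = attr(stats::terms(h_full), "term.labels"),
    coefficients = coef_table(h_full),
    p_value = NA_real_,
    group_lines = lines,
    group_summaries = make_group_summaries(cell_df, lines),
    n_obs = nrow(df), n_excluded = n_excluded,
    analysis_scale = scale, alpha = alpha,
    flags = c(tol_cmp$flag %||% character(), ben_cmp$flag %||% character()),
    extra = list(term_tests = h_terms,
                 tolerance_p = tol_cmp$p, benevolence_p = ben_cmp$p)
  )

  structure(
    list(density = density_fit, health = health_fit,
         screen = list(p = screen$p, retained = retained),
         analysis_scale = scale, alpha = alpha,
         n_obs = nrow(df), n_excluded = n_excluded,
         flags = if (retained) "cell_specific_outcome" else character()),
    class = "pb_factorial"
  )
}

#' @export
print.pb_factorial <- function(x, ...) {
  cat("Combined factorial analysis (host types x strains)\n")
  cat(sprintf("host_type x strain screen: p = %s -> %s\n",
              format.pval(x$screen$p, digits = 3),
              if (x$screen$retained)
                "retained (outcome depends on the specific host-strain combination)"
              else "removed (additive model reported)"))
  cat(sprintf("Resistance p = %s, proliferation p = %s\n",
              format.pval(x$density$resistance_p, digits = 3),
              format.pval(x$density$proliferation_p, digits = 3)))
  cat(sprintf("Tolerance p  = %s, benevolence p   = %s\n",
              format.pval(x$health$tolerance_p, digits = 3),
              format.pval(x$health$benevolence_p, digits = 3)))
  invisible(x)
}

#' Quadratic extension of the health-density model
#'
#' When the health-density relationship is nonlinear the linear model can be
#' extended with a quadratic density term and its interaction with the
#' grouping: `health = group * density + group * density^2`. The curvature
#' evidence is the extra-sum-of-squares comparison of this model against the
#' linear interaction model.
#'
#' @inheritParams test_density_variation
#' @return a `pb_fit` with `$curvature_p`, per-group quadratic coefficients
#'   in `$quad_by_group`, and the linear-part `$group_lines` from the
#'   quadratic model's per-group parameterisation.
#' @export
fit_quadratic_extension <- function(records, grouping = c("host_type", "strain"),
                                    scale = c("log10p1", "raw"), alpha = 0.05,
                                    include_uninfected = TRUE) {
  grouping <- match.arg(grouping)
  scale <- match.arg(scale)
  prep <- pb_prepare(records, grouping, scale, include_uninfected)
  if (prep$outcome_kind == "binary") {
    stop_design("binary (survival) outcome: use fit_binary_outcome()")
  }
  df <- prep$df
  check_min_levels(df, grouping)
  n_distinct <- tapply(df$d, df$group, function(x) length(unique(x)))
  if (any(n_distinct < 3)) {
    stop_design("the quadratic term needs >= 3 distinct density values per group; ",
                "too few in: ", paste(names(n_distinct)[n_distinct < 3], collapse = ", "))
  }
  df$d2 <- df$d^2
  full <- stats::lm(outcome ~ group + d + d2 + group:d + group:d2, data = df)
  lin  <- stats::lm(outcome ~ group + d + group:d, data = df)
  cmp <- model_comparison_p(lin, full)

  nested <- stats::lm(outcome ~ 0 + group + group:d + group:d2, data = df)
  cf <- stats::coef(nested)
  sm <- suppressWarnings(summary(nested))$coefficients
  lev <- levels(df$group)
  nm_q <- paste0("group", lev, ":d2")
  quad <- data.frame(
    group = lev,
    quad = unname(cf[nm_q]),
    se_quad = ifelse(nm_q %in% rownames(sm),
                     sm[match(nm_q, rownames(sm)), "Std. Error"], NA_real_),
    stringsAsFactors = FALSE
  )
  nm_a <- paste0("group", lev)
  nm_b <- paste0("group", lev, ":d")
  se_of <- function(nm) ifelse(nm %in% rownames(sm),
                               sm[match(nm, rownames(sm)), "Std. Error"], NA_real_)
  lines <- data.frame(
    group = lev, a = unname(cf[nm_a]), b = unname(cf[nm_b]),
    se_a = se_of(nm_a), se_b = se_of(nm_b), df = nested$df.residual,
    stringsAsFactors = FALSE
  )
  new_pb_fit(
    model_name = paste0("health ~ ", grouping, " * density + ", grouping, " * density^2"),
    property = paste0(if (grouping == "host_type") "tolerance" else "benevolence",
                      " (quadratic)"),
    formula_terms = attr(stats::terms(full), "term.labels"),
    coefficients = coef_table(full),
    p_value = cmp$p,
    group_lines = lines,
    group_summaries = make_group_summaries(df, lines),
    n_obs = nrow(df), n_excluded = prep$n_excluded,
    analysis_scale = scale, alpha = alpha,
    flags = c(character(), cmp$flag),
    extra = list(curvature_p = cmp$p, quad_by_group = quad, grouping = grouping)
  )
}
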