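# FitResult container shared by all model-fitting operations, plus the
# model-comparison machinery (extra-sum-of-squares F and its degenerate
# cases) and per-group line extraction.

new_pb_fit <- function(model_name, property, formula_terms, coefficients,
                       p_value, interaction_p = NA_real_, group_lines = NULL,
                       group_summaries = NULL, n_obs, n_excluded = 0L,
                       analysis_scale, alpha, flags = character(),
                       extra = list()) {
  out <- c(list(
    model_name = model_name,
    property = property,
    formula_terms = formula_terms,
    coefficients = coefficients,
    p_value = p_value,
    interaction_p = interaction_p,
    group_lines = group_lines,
    group_summaries = group_summaries,
    n_obs = as.integer(n_obs),
    n_excluded = as.integer(n_excluded),
    analysis_scale = analysis_scale,
    alpha = alpha,
    flags = flags
  ), extra)
  structure(out, class = "pb_fit")
}

#' @export
print.pb_fit <- function(x, ...) {
  cat(sprintf("Model: %s   [property: %s, scale: %s, n = %d (%d excluded)]\n",
              x$model_name, x$property, x$analysis_scale, x$n_obs, x$n_excluded))
  if (is.finite(x$interaction_p) || is.nan(x$interaction_p)) {
    cat(sprintf("Interaction (slope heterogeneity) p = %s\n",
                format.pval(x$interaction_p, digits = 3)))
  } else if (!is.na(x$p_value)) {
    cat(sprintf("Group effect p = %s\n", format.pval(x$p_value, digits = 3)))
  }
  if (!is.null(x$curvature_p)) {
    cat(sprintf("Curvature (quadratic vs linear) p = %s\n",
                format.pval(x$curvature_p, digits = 3)))
  }
  if (!is.null(x$group_summaries)) {
    cat("Per-group summaries:\n")
    print(x$group_summaries, row.names = FALSE, digits = 4)
  }
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Extra-sum-of-squares F comparison of two nested lm fits.
# Degenerate cases: if the full model's residual SS is ~0 relative to the
# total SS the usual F is meaningless; the p-value is then NaN when the extra
# SS is also ~0 (nothing to test), or 0 when the full model alone achieves an
# exact fit that the reduced model does not.
model_comparison_p <- function(reduced, full) {
  rss_r <- sum(stats::residuals(reduced)^2)
  rss_f <- sum(stats::residuals(full)^2)
  df_num <- reduced$df.residual - full$df.residual
  df_den <- full$df.residual
  y <- stats::model.response(stats::model.frame(full))
  tss <- sum((y - mean(y))^2)
  tol <- 1e-10 * max(tss, 1)
  if (df_num <= 0 || df_den <= 0) {
    return(list(p = NaN, stat = NaN, df = c(df_num, df_den), flag = "degenerate_df"))
  }
  if (rss_f < tol) {
    if (rss_r - rss_f < tol) {
      return(list(p = NaN, stat = NaN, df = c(df_num, df_den),
                  flag = "degenerate_zero_residual"))
    }
    return(list(p = 0, stat = Inf, df = c(df_num, df_den), flag = "exact_fit"))
  }
  stat <- ((rss_r - rss_f) / df_num) / (rss_f / df_den)
  list(p = stats::pf(stat, df_num, df_den, lower.tail = FALSE),
       stat = stat, df = c(df_num, df_den), flag = NULL)
}

# Per-group intercepts and slopes from the saturated interaction model,
# parameterised so each group gets its own (a, b) directly. Estimates equal
# independent per-group least squares; standard errors use the pooled
# residual variance.
fit_group_lines <- function(df) {
  m <- stats::lm(outcome ~ 0 + group + group:d, data = df)
  cf <- stats::coef(m)
  sm <- suppressWarnings(summary(m))$coefficients
  lev <- levels(df$group)
  nm_a <- paste0("group", lev)
  nm_b <- paste0("group", lev, ":d")
  se_of <- function(nm) {
    ifelse(nm %in% rownames(sm), sm[match(nm, rownames(sm)), "Std. Error"], NA_real_)
  }
  data.frame(
    group = lev,
    a = unname(cf[nm_a]),
    b = unname(cf[nm_b]),
    se_a = se_of(nm_a),
    se_b = se_of(nm_b),
    df = m$df.residual,
    stringsAsFactors = FALSE
  )
}

# Per-group c_bar / b / virulence summaries on the analysis scale.
make_group_summaries <- function(df, lines = NULL) {
  lev <- levels(df$group)
  c_bar <- tapply(df$d, df$group, mean)[lev]
  n <- as.integer(table(df$group)[lev])
  b <- if (is.null(lines)) rep(NA_real_, length(lev)) else lines$b[match(lev, lines$group)]
  data.frame(
    group = lev,
    c_bar = unname(c_bar),
    b = b,
    virulence = b * unname(c_bar),
    n = n,
    stringsAsFactors = FALSE
  )
}

# Coefficient table from a fitted lm/glm.
coef_table <- function(model) {
  sm <- suppressWarnings(summary(model))$coefficients
  data.frame(
    term = rownames(sm),
    estimate = sm[, 1],
    se = sm[, 2],
    statistic = sm[, 3],
    p = sm[, 4],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
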