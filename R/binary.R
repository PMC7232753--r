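# Binomial-GLM analysis for survival (0/1) outcomes, with a Firth
# penalized-likelihood fallback under complete separation.

# Firth bias-reduced logistic regression by modified-score Newton iteration.
# Returns penalized log-likelihood so nested models can be compared by a
# penalized likelihood-ratio statistic.
firth_logit <- function(X, y, maxit = 200, tol = 1e-9) {
  beta <- numeric(ncol(X))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- pmax(p * (1 - p), 1e-12)
    XW <- X * W
    I <- crossprod(X, XW)
    Iinv <- tryCatch(solve(I), error = function(e) solve(I + diag(1e-8, ncol(X))))
    h <- rowSums((X %*% Iinv) * XW) # leverages of the weighted fit
    U <- crossprod(X, y - p + h * (0.5 - p))
    delta <- drop(Iinv %*% U)
    if (max(abs(delta)) > 5) delta <- delta * 5 / max(abs(delta)) # step cap
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  p <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  I <- crossprod(X, X * pmax(p * (1 - p), 1e-12))
  ll <- sum(y * log(p) + (1 - y) * log(1 - p))
  pll <- ll + 0.5 * as.numeric(determinant(I, logarithm = TRUE)$modulus)
  Iinv <- tryCatch(solve(I), error = function(e) solve(I + diag(1e-8, ncol(X))))
  list(coef = stats::setNames(drop(beta), colnames(X)),
       se = stats::setNames(sqrt(diag(Iinv)), colnames(X)),
       logLik_pen = pll, converged = converged)
}

#' Test for variation in tolerance or benevolence with a survival outcome
#'
#' For binary (0/1 survival) outcomes the ANCOVA is replaced by a binomial
#' generalized linear model with logit link and the same term structure:
#' `survived = group + density + group:density`. Per-group slopes are on the
#' log-odds scale and labelled as such. The interaction is tested by a
#' likelihood-ratio comparison of the full against the additive model.
#'
#' Complete separation (monotone likelihood) is detected from glm warnings
#' and runaway coefficients; the fit is then repeated with Firth
#' penalized-likelihood logistic regression, the interaction tested by a
#' penalized likelihood ratio, and the result flagged.
#'
#' @inheritParams test_density_variation
#' @return a `pb_fit`; `$interaction_p` is the likelihood-ratio interaction
#'   p-value, `$group_lines` holds per-group log-odds intercepts/slopes.
#' @export
fit_binary_outcome <- function(records, grouping = c("host_type", "strain"),
                               scale = c("log10p1", "raw"), alpha = 0.05,
                               include_uninfected = TRUE) {
  grouping <- match.arg(grouping)
  scale <- match.arg(scale)
  prep <- pb_prepare(records, grouping, scale, include_uninfected)
  if (prep$outcome_kind != "binary") {
    stop_design("continuous outcome: use test_slope_variation() (binomial GLM ",
                "applies to 0/1 survival outcomes)")
  }
  df <- prep$df
  check_min_levels(df, grouping)
  check_density_varies(df, grouping)
  if (length(unique(df$outcome)) < 2) {
    stop_design("degenerate outcome: every host has the same survival status")
  }

  separation <- FALSE
  fit_one <- function(formula) {
    withCallingHandlers(
      stats::glm(formula, family = stats::binomial(), data = df),
      warning = function(w) {
        msg <- conditionMessage(w)
        if (grepl("fitted probabilities numerically 0 or 1", msg) ||
            grepl("algorithm did not converge", msg)) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
  }
  full <- fit_one(outcome ~ group + d + group:d)
  add  <- fit_one(outcome ~ group + d)
  nested <- fit_one(outcome ~ 0 + group + group:d)
  if (!separation) {
    separation <- any(abs(stats::coef(full)) > 15, na.rm = TRUE)
  }

  lev <- levels(df$group)
  flags <- "slopes_log_odds"
  if (!separation) {
    df_diff <- add$df.residual - full$df.residual
    lrt <- add$deviance - full$deviance
    interaction_p <- stats::pchisq(lrt, df_diff, lower.tail = FALSE)
    cf <- stats::coef(nested)
    sm <- suppressWarnings(summary(nested))$coefficients
    coefs <- coef_table(full)
  } else {
    flags <- c(flags, "separation", "firth_penalized")
    Xf <- stats::model.matrix(~ group + d + group:d, df)
    Xa <- stats::model.matrix(~ group + d, df)
    Xn <- stats::model.matrix(~ 0 + group + group:d, df)
    ff <- firth_logit(Xf, df$outcome)
    fa <- firth_logit(Xa, df$outcome)
    fn <- firth_logit(Xn, df$outcome)
    df_diff <- ncol(Xf) - ncol(Xa)
    interaction_p <- stats::pchisq(2 * (ff$logLik_pen - fa$logLik_pen),
                                   df_diff, lower.tail = FALSE)
    cf <- fn$coef
    sm <- cbind(`Std. Error` = fn$se)
    rownames(sm) <- names(fn$coef)
    coefs <- data.frame(term = names(ff$coef), estimate = unname(ff$coef),
                        se = unname(ff$se), statistic = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE)
  }

  nm_a <- paste0("group", lev)
  nm_b <- paste0("group", lev, ":d")
  se_of <- function(nm) ifelse(nm %in% rownames(sm),
                               sm[match(nm, rownames(sm)), "Std. Error"], NA_real_)
  lines <- data.frame(
    group = lev, a = unname(cf[nm_a]), b = unname(cf[nm_b]),
    se_a = se_of(nm_a), se_b = se_of(nm_b), df = Inf,
    stringsAsFactors = FALSE
  )
  new_pb_fit(
    model_name = paste0("survived ~ ", grouping, " + density + ", grouping,
                        ":density (binomial, logit link)"),
    property = if (grouping == "host_type") "tolerance" else "benevolence",
    formula_terms = c("(Intercept)", grouping, "density", paste0(grouping, ":density")),
    coefficients = coefs,
    p_value = interaction_p,
    interaction_p = interaction_p,
    group_lines = lines,
    group_summaries = make_group_summaries(df, lines),
    n_obs = nrow(df), n_excluded = prep$n_excluded,
    analysis_scale = scale, alpha = alpha, flags = flags,
    extra = list(grouping = grouping, link = "logit")
  )
}
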