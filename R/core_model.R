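# Core algebra of the framework: the linear health-density model
# health = a + b * density, its per-group parameters, and the virulence
# identity v = b * c_bar.
#
# Interpretation of the parameters:
#   a      baseline health of uninfected hosts ("vigour"; intercept)
#   b      change in health per unit density; for a host type this is
#          (inverse) tolerance, for a microbial strain it is benevolence
#          (b > 0) or malevolence (b < 0)
#   c_bar  mean microbial density on the analysis scale; (inverse)
#          resistance for a host type, proliferation for a strain

#' Construct a fitted health-density line for one group
#'
#' @param group group label (a host type or a microbial strain).
#' @param a intercept: baseline health of uninfected hosts (vigour).
#' @param b slope: change in health per unit microbial density on the
#'   analysis scale.
#' @param se_a,se_b standard errors (non-negative; `NA` if unknown).
#' @param df residual degrees of freedom behind the standard errors
#'   (`Inf` gives normal-theory tests).
#' @return object of class `health_line`.
#' @examples
#' ln <- health_density_line("wt", a = 10, b = -0.5, se_b = 0.1, df = 48)
#' predict_health(ln, 4)
#' @export
health_density_line <- function(group, a, b, se_a = NA_real_, se_b = NA_real_,
                                df = Inf) {
  if (!is.finite(a) || !is.finite(b)) {
    stop_domain("intercept and slope must be finite")
  }
  if ((is.finite(se_a) && se_a < 0) || (is.finite(se_b) && se_b < 0)) {
    stop_domain("standard errors must be non-negative")
  }
  structure(
    list(group = as.character(group), a = a, b = b,
         se_a = se_a, se_b = se_b, df = df),
    class = "health_line"
  )
}

#' @export
print.health_line <- function(x, ...) {
  cat(sprintf("health ~ density line for group '%s'\n", x$group))
  cat(sprintf("  vigour a = %.4g (se %.3g), slope b = %.4g (se %.3g)\n",
              x$a, x$se_a, x$b, x$se_b))
  invisible(x)
}

#' Predicted health at a given microbial density
#'
#' Evaluates `a + b * density` for a fitted line. The density must be on the
#' same scale as the fit and non-negative.
#'
#' @param line a [health_density_line()].
#' @param density non-negative density (same scale as the fit).
#' @return predicted health (numeric, vectorised over `density`).
#' @export
predict_health <- function(line, density) {
  stopifnot(inherits(line, "health_line"))
  if (any(!is.finite(density))) stop_domain("density must be finite")
  if (any(density < 0)) stop_domain("density must be non-negative")
  line$a + line$b * density
}

#' Virulence as the product of malevolence and proliferation
#'
#' Virulence is `b * c_bar`: the per-density health effect of a microbe times
#' the mean density it attains. The value is signed; negative values indicate
#' net harm (`b < 0`), positive values net benefit.
#'
#' @param b slope of health on density (benevolence/malevolence).
#' @param c_bar mean microbial density on the analysis scale (>= 0).
#' @return signed virulence `b * c_bar`.
#' @examples
#' virulence(-0.5, 4) # -2: a harmful microbe at moderate density
#' @export
virulence <- function(b, c_bar) {
  if (any(!is.finite(b)) || any(!is.finite(c_bar))) {
    stop_domain("b and c_bar must be finite")
  }
  if (any(c_bar < 0)) stop_domain("c_bar must be non-negative")
  b * c_bar
}

#' Per-group summary: mean density, slope and virulence
#'
#' @param group group label.
#' @param c_bar mean density on the analysis scale.
#' @param b slope of health on density (`NA` when the summary comes from a
#'   density-only model).
#' @param n number of observations in the group.
#' @return object of class `group_summary` (also a one-row list); the
#'   `virulence` element is always `b * c_bar`.
#' @export
group_summary <- function(group, c_bar, b = NA_real_, n) {
  if (is.finite(c_bar) && c_bar < 0) stop_domain("c_bar must be non-negative")
  if (n < 1) stop_domain("n must be a positive integer")
  structure(
    list(group = as.character(group), c_bar = c_bar, b = b,
         virulence = b * c_bar, n = as.integer(n)),
    class = "group_summary"
  )
}

#' Classify the direction of a microbe's health effect
#'
#' A microbe is benevolent if it benefits the host (`b > 0`) within the
#' relevant range of densities, malevolent if detrimental (`b < 0`), and
#' neutral otherwise. By default the call requires a two-sided test of
#' `b != 0` at level `alpha`; with `point_estimate = TRUE` the sign of the
#' estimate alone decides.
#'
#' @param line a [health_density_line()] with a standard error for the slope
#'   (unless `point_estimate = TRUE`).
#' @param density_range numeric length-2: observed density span of the group.
#'   A zero-width range makes the slope unidentifiable and is an error.
#' @param alpha two-sided significance level (default 0.05).
#' @param point_estimate if `TRUE`, classify by the sign of `b` alone.
#' @return one of `"benevolent"`, `"neutral"`, `"malevolent"`.
#' @export
classify_direction <- function(line, density_range, alpha = 0.05,
                               point_estimate = FALSE) {
  stopifnot(inherits(line, "health_line"))
  density_range <- range(density_range)
  if (diff(density_range) <= 0) {
    stop_design("zero-width density range for group '", line$group,
                "': slope is unidentifiable")
  }
  if (line$b == 0) return("neutral")
  if (point_estimate) return(if (line$b > 0) "benevolent" else "malevolent")
  if (!is.finite(line$se_b)) {
    stop_domain("slope standard error needed for a significance-based call; ",
                "use point_estimate = TRUE otherwise")
  }
  if (line$se_b == 0) {
    p <- 0 # exact fit with a non-zero slope
  } else {
    df <- if (is.finite(line$df)) line$df else Inf
    p <- 2 * stats::pt(-abs(line$b / line$se_b), df = df)
  }
  if (p < alpha) {
    if (line$b > 0) "benevolent" else "malevolent"
  } else {
    "neutral"
  }
}
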