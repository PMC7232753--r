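# Pre-fit diagnostics: density-range overlap between groups and linearity
# of the health-density relationship.

# Pairwise range-overlap coefficients on an already-transformed density
# vector. Shared by density_overlap() and the slope-fit overlap flag.
overlap_pairs <- function(d, group, threshold) {
  lev <- levels(group)
  lo <- tapply(d, group, min)[lev]
  hi <- tapply(d, group, max)[lev]
  combs <- utils::combn(lev, 2)
  n_pairs <- ncol(combs)
  out <- data.frame(
    group_i = combs[1, ], group_j = combs[2, ],
    overlap = NA_real_, degenerate = FALSE,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(n_pairs)) {
    i <- combs[1, k]; j <- combs[2, k]
    inter <- min(hi[i], hi[j]) - max(lo[i], lo[j])
    degen <- (hi[i] - lo[i]) == 0 || (hi[j] - lo[j]) == 0
    if (inter < 0) {
      ov <- 0
    } else {
      uni <- max(hi[i], hi[j]) - min(lo[i], lo[j])
      ov <- if (uni == 0) 1 else inter / uni # two identical point ranges
    }
    out$overlap[k] <- ov
    out$degenerate[k] <- degen
  }
  list(pairs = out, flagged = out[out$overlap < threshold | out$degenerate, , drop = FALSE])
}

#' Density-range overlap between groups
#'
#' Slope (tolerance/benevolence) comparisons between groups whose observed
#' density ranges barely overlap can be spurious: each group's slope is then
#' estimated over a different stretch of the density axis. For every pair of
#' groups this reports the overlap coefficient
#' `length(intersection of observed ranges) / length(union)`, in `[0, 1]`,
#' and flags pairs below `threshold`. Single-point (zero-width) ranges are
#' flagged as degenerate.
#'
#' @inheritParams test_density_variation
#' @param threshold flagging threshold for the overlap coefficient
#'   (default 0.5).
#' @return object of class `overlap_report`: `$pairs` (one row per group
#'   pair with the symmetric overlap coefficient), `$flagged_pairs`, and
#'   `$threshold`.
#' @export
density_overlap <- function(records, grouping = c("host_type", "strain"),
                            threshold = 0.5, scale = c("log10p1", "raw"),
                            include_uninfected = TRUE) {
  grouping <- match.arg(grouping)
  scale <- match.arg(scale)
  if (threshold < 0 || threshold > 1) stop_config("threshold must be in [0, 1]")
  prep <- pb_prepare(records, grouping, scale, include_uninfected)
  df <- prep$df
  check_min_levels(df, grouping)
  rep <- overlap_pairs(df$d, df$group, threshold)
  structure(
    list(pairs = rep$pairs, flagged_pairs = rep$flagged,
         threshold = threshold, grouping = grouping, analysis_scale = scale),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("Density-range overlap by %s (scale: %s, threshold %.2f)\n",
              x$grouping, x$analysis_scale, x$threshold))
  print(x$pairs, row.names = FALSE, digits = 3)
  if (nrow(x$flagged_pairs)) {
    cat("Flagged pairs (slope comparisons unreliable):\n")
    print(x$flagged_pairs[, c("group_i", "group_j", "overlap")],
          row.names = FALSE, digits = 3)
  } else {
    cat("No pairs flagged.\n")
  }
  invisible(x)
}

#' Check linearity of the health-density relationship
#'
#' The framework's slope-based quantities assume health is linear in density
#' over the observed range. This wraps [fit_quadratic_extension()] and
#' reports the likelihood-ratio (extra-sum-of-squares) evidence for
#' curvature together with per-group quadratic coefficients, plus an
#' advisory message when curvature is detected.
#'
#' @inheritParams fit_quadratic_extension
#' @return object of class `linearity_report` with `$curvature_p`,
#'   `$quad_by_group`, `$advisory` and the underlying `$fit`.
#' @export
linearity_check <- function(records, grouping = c("host_type", "strain"),
                            scale = c("log10p1", "raw"), alpha = 0.05,
                            include_uninfected = TRUE) {
  fit <- fit_quadratic_extension(records, grouping, scale, alpha,
                                 include_uninfected)
  curved <- !is.na(fit$curvature_p) && !is.nan(fit$curvature_p) &&
    fit$curvature_p < alpha
  advisory <- if (curved) {
    paste0("curvature detected (p = ", format.pval(fit$curvature_p, digits = 3),
           "): the linear health-density model is inadequate; report the ",
           "quadratic extension instead")
  } else {
    "no evidence against linearity at the configured alpha"
  }
  structure(
    list(curvature_p = fit$curvature_p, quad_by_group = fit$quad_by_group,
         advisory = advisory, alpha = alpha, fit = fit),
    class = "linearity_report"
  )
}

#' @export
print.linearity_report <- function(x, ...) {
  cat("Linearity check (quadratic vs linear health-density model)\n")
  cat(sprintf("Curvature p = %s\n", format.pval(x$curvature_p, digits = 3)))
  print(x$quad_by_group, row.names = FALSE, digits = 4)
  cat(x$advisory, "\n")
  invisible(x)
}
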