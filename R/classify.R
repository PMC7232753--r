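# Classification of molecular factors from wild-type vs isogenic-knockout
# contrasts.
#
# A microbial factor is a benevolence factor if the wild type has the more
# positive (or less negative) slope of health on density (b_wt > b_ko), a
# malevolence factor if b_wt < b_ko, and a proliferation factor if the wild
# type attains higher mean density (c_bar_wt > c_bar_ko). Host-side factors
# mirror this: a resistance factor lowers microbial density in the wild-type
# host (c_bar_wt < c_bar_ko); a tolerance factor gives the wild-type host the
# shallower slope toward harm (b_wt > b_ko). "Pure" factors move only one of
# {slope, mean density}.

factor_call <- function(side, labels, pure, b_wt, b_ko, c_bar_wt, c_bar_ko,
                        p_slope, p_density, alpha, flags = character(),
                        mde_slope = NA_real_, mde_density = NA_real_) {
  structure(
    list(side = side, labels = labels, pure = pure,
         b_wt = b_wt, b_ko = b_ko, c_bar_wt = c_bar_wt, c_bar_ko = c_bar_ko,
         p_slope = p_slope, p_density = p_density, alpha = alpha,
         flags = flags, mde_slope = mde_slope, mde_density = mde_density),
    class = "factor_call"
  )
}

#' @export
print.factor_call <- function(x, ...) {
  verdict <- if (length(x$labels)) paste(x$labels, collapse = " + ") else "no factor effect detected"
  cat(sprintf("Verdict: %s%s\n", verdict,
              if (isTRUE(x$pure)) " (pure)" else ""))
  ev <- data.frame(
    quantity = c("slope b", "mean density c_bar"),
    wild_type = c(x$b_wt, x$c_bar_wt),
    knockout = c(x$b_ko, x$c_bar_ko),
    p = c(x$p_slope, x$p_density),
    min_detectable = c(x$mde_slope, x$mde_density)
  )
  print(ev, row.names = FALSE, digits = 4)
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# significance helper tolerant of NaN (degenerate) p-values
is_sig <- function(p, alpha) !is.na(p) && !is.nan(p) && p < alpha

# Minimum detectable difference at ~80% power for a two-sided alpha-level
# test, from the standard error of the contrast.
mde_from_se <- function(se, alpha) {
  (stats::qnorm(1 - alpha / 2) + stats::qnorm(0.8)) * se
}

classify_contrast <- function(wt_records, ko_records, grouping, alpha, scale,
                              bonferroni, point_estimate, overlap_threshold) {
  wt <- as.data.frame(wt_records)
  ko <- as.data.frame(ko_records)
  wt[[grouping]] <- "wt"
  ko[[grouping]] <- "ko"
  combined <- rbind(
    wt[, intersect(names(wt), c("host_type", "strain", "density", "health", "survived")), drop = FALSE],
    ko[, intersect(names(ko), c("host_type", "strain", "density", "health", "survived")), drop = FALSE]
  )
  if (grouping == "strain") combined$host_type <- "host"
  if (grouping == "host_type") combined$strain <- "microbe"

  slope_fit <- test_slope_variation(combined, grouping = grouping, scale = scale,
                                    alpha = alpha,
                                    overlap_threshold = overlap_threshold)
  dens_fit <- test_density_variation(combined, grouping = grouping,
                                     scale = scale, alpha = alpha)
  gl <- slope_fit$group_lines
  gs <- dens_fit$group_summaries
  b_wt <- gl$b[gl$group == "wt"]
  b_ko <- gl$b[gl$group == "ko"]
  c_wt <- gs$c_bar[gs$group == "wt"]
  c_ko <- gs$c_bar[gs$group == "ko"]
  alpha_eff <- if (bonferroni) alpha / 2 else alpha
  p_slope <- slope_fit$interaction_p
  p_density <- dens_fit$p_value
  sig_slope <- if (point_estimate) b_wt != b_ko else is_sig(p_slope, alpha_eff)
  sig_density <- if (point_estimate) c_wt != c_ko else is_sig(p_density, alpha_eff)

  se_db <- sqrt(sum(gl$se_b^2)) # nested parameterisation: independent SEs
  sd_pool <- sqrt(sum(stats::residuals(stats::lm(d ~ group,
    data = pb_prepare(combined, grouping, scale)$df))^2) / (nrow(combined) - 2))
  se_dc <- sd_pool * sqrt(1 / gs$n[gs$group == "wt"] + 1 / gs$n[gs$group == "ko"])

  flags <- character()
  if ("low_density_overlap" %in% slope_fit$flags) flags <- c(flags, "low_density_overlap_unreliable")
  if (is.nan(p_slope)) flags <- c(flags, "slope_test_degenerate")

  list(b_wt = b_wt, b_ko = b_ko, c_wt = c_wt, c_ko = c_ko,
       p_slope = p_slope, p_density = p_density,
       sig_slope = sig_slope, sig_density = sig_density,
       alpha_eff = alpha_eff, flags = flags,
       mde_slope = mde_from_se(se_db, alpha_eff),
       mde_density = mde_from_se(se_dc, alpha_eff))
}

#' Classify a microbial effector molecule from a wild-type vs knockout contrast
#'
#' Compares infections with a wild-type microbe against its isogenic
#' factor-negative knockout. If the slope of health on density differs
#' significantly and the wild type's slope is more positive (`b_wt > b_ko`),
#' the molecule is a benevolence factor; if less positive (`b_wt < b_ko`), a
#' malevolence factor. If mean density differs significantly and the wild
#' type attains the higher density (`c_bar_wt > c_bar_ko`), it is (also) a
#' proliferation factor. A factor is "pure" when exactly one of the two tests
#' is significant; purity is reported together with the non-significant
#' test's p-value and a minimum-detectable-effect estimate (~80% power).
#'
#' @param wt_records,ko_records experiment data.frames for the wild-type and
#'   knockout strain (same outcome column and density scale).
#' @param alpha significance level for each of the two tests.
#' @param scale density analysis scale (`"log10p1"` or `"raw"`).
#' @param bonferroni if `TRUE`, test each hypothesis at `alpha/2`.
#' @param point_estimate if `TRUE`, classify from point estimates without
#'   significance requirements.
#' @param overlap_threshold density-overlap threshold; classifications on
#'   barely-overlapping density ranges are flagged unreliable.
#' @return object of class `factor_call`.
#' @export
classify_microbial_factor <- function(wt_records, ko_records, alpha = 0.05,
                                      scale = c("log10p1", "raw"),
                                      bonferroni = FALSE, point_estimate = FALSE,
                                      overlap_threshold = 0.5) {
  scale <- match.arg(scale)
  cc <- classify_contrast(wt_records, ko_records, "strain", alpha, scale,
                          bonferroni, point_estimate, overlap_threshold)
  labels <- character()
  flags <- cc$flags
  if (cc$sig_slope) {
    labels <- c(labels, if (cc$b_wt > cc$b_ko) "benevolence_factor" else "malevolence_factor")
  }
  if (cc$sig_density) {
    if (cc$c_wt > cc$c_ko) {
      labels <- c(labels, "proliferation_factor")
    } else {
      flags <- c(flags, "density_effect_reversed")
    }
  }
  pure <- xor(isTRUE(cc$sig_slope), isTRUE(cc$sig_density))
  factor_call("microbe", labels, pure, cc$b_wt, cc$b_ko, cc$c_wt, cc$c_ko,
              cc$p_slope, cc$p_density, cc$alpha_eff, flags,
              cc$mde_slope, cc$mde_density)
}

#' Classify a host molecule from a wild-type vs knockout host contrast
#'
#' Mirror of [classify_microbial_factor()] for host-encoded molecules: a
#' wild-type host with significantly lower microbial density than its
#' isogenic knockout (`c_bar_wt < c_bar_ko`) carries a resistance factor; a
#' wild-type host with a significantly shallower slope of health on density
#' toward harm (`b_wt > b_ko` for harmful infections) carries a tolerance
#' factor. When the two slopes straddle zero, "shallower toward harm" is
#' ambiguous and the call is flagged rather than made.
#'
#' @inheritParams classify_microbial_factor
#' @param wt_host_records,ko_host_records experiment data.frames for the
#'   wild-type and knockout host.
#' @return object of class `factor_call`.
#' @export
classify_host_factor <- function(wt_host_records, ko_host_records, alpha = 0.05,
                                 scale = c("log10p1", "raw"),
                                 bonferroni = FALSE, point_estimate = FALSE,
                                 overlap_threshold = 0.5) {
  scale <- match.arg(scale)
  cc <- classify_contrast(wt_host_records, ko_host_records, "host_type", alpha,
                          scale, bonferroni, point_estimate, overlap_threshold)
  labels <- character()
  flags <- cc$flags
  if (cc$sig_slope) {
    straddle <- (cc$b_wt > 0 && cc$b_ko < 0) || (cc$b_wt < 0 && cc$b_ko > 0)
    if (straddle) {
      flags <- c(flags, "ambiguous_slope_signs")
    } else if (cc$b_wt > cc$b_ko) {
      labels <- c(labels, "tolerance_factor")
    } else {
      flags <- c(flags, "tolerance_effect_reversed")
    }
  }
  if (cc$sig_density) {
    if (cc$c_wt < cc$c_ko) {
      labels <- c(labels, "resistance_factor")
    } else {
      flags <- c(flags, "resistance_effect_reversed")
    }
  }
  pure <- xor(isTRUE(cc$sig_slope), isTRUE(cc$sig_density))
  factor_call("host", labels, pure, cc$b_wt, cc$b_ko, cc$c_wt, cc$c_ko,
              cc$p_slope, cc$p_density, cc$alpha_eff, flags,
              cc$mde_slope, cc$mde_density)
}
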