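# Validation of infection-experiment records.
#
# A record set is an ordinary data.frame with one row per infected host and
# columns host_type, strain, density (raw cfu, >= 0) and exactly one of
# health (continuous score) or survived (0/1).

#' Validate a set of infection-experiment records
#'
#' Checks column structure and row-level validity of an experiment table.
#' Malformed rows (non-finite or negative density, missing outcome, empty
#' labels, non-0/1 survival) are dropped and counted; structural problems
#' (missing columns, no or ambiguous outcome column) raise a format error.
#'
#' @param records data.frame with columns `host_type`, `strain`, `density`
#'   and exactly one of `health` or `survived`.
#' @return list with elements `records` (cleaned data.frame with standardised
#'   columns `host_type`, `strain`, `density`, `outcome`), `outcome_kind`
#'   (`"continuous"` or `"binary"`), `n_excluded` and `excluded_rows`.
#' @keywords internal
validate_records <- function(records) {
  if (!is.data.frame(records)) {
    stop_format("`records` must be a data.frame, got ", class(records)[1])
  }
  outcome_col <- intersect(c("health", "survived"), names(records))
  if (length(outcome_col) == 0) {
    stop_format("records need an outcome column: one of 'health' or 'survived'")
  }
  if (length(outcome_col) > 1) {
    stop_format("records must have exactly one of 'health' or 'survived', found both")
  }
  missing_cols <- setdiff(c("host_type", "strain", "density"), names(records))
  if (length(missing_cols) > 0) {
    stop_format("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  outcome_kind <- if (outcome_col == "health") "continuous" else "binary"

  out <- data.frame(
    host_type = as.character(records$host_type),
    strain    = as.character(records$strain),
    density   = suppressWarnings(as.numeric(records$density)),
    outcome   = suppressWarnings(as.numeric(records[[outcome_col]])),
    stringsAsFactors = FALSE
  )
  bad_label   <- is.na(out$host_type) | is.na(out$strain) |
    !nzchar(trimws(out$host_type)) | !nzchar(trimws(out$strain))
  bad_density <- !is.finite(out$density) | out$density < 0
  bad_outcome <- !is.finite(out$outcome) |
    (outcome_kind == "binary" & !(out$outcome %in% c(0, 1)))
  bad <- bad_label | bad_density | bad_outcome
  reasons <- character(sum(bad))
  if (any(bad)) {
    reasons <- ifelse(bad_density[bad], "invalid density",
               ifelse(bad_outcome[bad], "invalid outcome", "empty label"))
  }
  list(
    records = out[!bad, , drop = FALSE],
    outcome_kind = outcome_kind,
    n_excluded = sum(bad),
    excluded_rows = which(bad),
    excluded_reasons = reasons
  )
}

# Shared preparation for model fits: validate, optionally drop uninfected
# hosts, build the grouping factor and the analysis-scale density.
pb_prepare <- function(records, grouping, scale, include_uninfected = TRUE) {
  if (!grouping %in% c("host_type", "strain")) {
    stop_config("grouping must be 'host_type' or 'strain', got '", grouping, "'")
  }
  v <- validate_records(records)
  df <- v$records
  n_excluded <- v$n_excluded
  if (nrow(df) == 0) stop_design("no usable records after validation")
  df$uninfected <- df$density == 0
  if (!include_uninfected) {
    n_excluded <- n_excluded + sum(df$uninfected)
    df <- df[!df$uninfected, , drop = FALSE]
    if (nrow(df) == 0) stop_design("no infected hosts left after dropping density-0 records")
  }
  # alphabetical level order => treatment contrasts use the first level as reference
  df$group <- factor(df[[grouping]])
  df$d <- to_analysis_scale(df$density, scale)
  list(df = df, outcome_kind = v$outcome_kind, n_excluded = n_excluded)
}
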