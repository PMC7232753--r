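# Readers and writers: record CSV/TSV, scenario YAML/JSON, result JSON/TSV.

JSON_SCHEMA_VERSION <- "1.0"

sep_for <- function(path) {
  if (tolower(tools::file_ext(path)) %in% c("tsv", "tab", "txt")) "\t" else ","
}

#' Read infection-experiment records from CSV or TSV
#'
#' Expects header columns `host_type`, `strain`, `density` and exactly one
#' of `health` (continuous score) or `survived` (0/1). Malformed rows
#' (negative or non-finite density, survival outside \{0, 1\}, empty labels)
#' are rejected with a warning naming the offending rows, or an error when
#' `strict = TRUE`.
#'
#' @param path file path; `.tsv`/`.tab`/`.txt` are read tab-separated,
#'   anything else comma-separated.
#' @param map optional named character vector aliasing non-standard column
#'   names, e.g. `c(host_type = "mouse_line", density = "cfu")`.
#' @param strict error (rather than warn and drop) on malformed rows.
#' @return data.frame of records with attributes `outcome_kind` and
#'   `n_excluded`.
#' @export
read_records <- function(path, map = NULL, strict = FALSE) {
  if (!file.exists(path)) stop_format("input file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep_for(path),
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(map)) {
    for (std in names(map)) {
      idx <- match(map[[std]], names(raw))
      if (!is.na(idx)) names(raw)[idx] <- std
    }
  }
  v <- validate_records(raw)
  if (v$n_excluded > 0) {
    detail <- paste0("row ", v$excluded_rows, " (", v$excluded_reasons, ")",
                     collapse = ", ")
    msg <- paste0("rejected ", v$n_excluded, " malformed row(s): ", detail)
    if (strict) stop_format(msg) else warning(msg, call. = FALSE)
  }
  out <- v$records
  if (v$outcome_kind == "binary") {
    names(out)[names(out) == "outcome"] <- "survived"
  } else {
    names(out)[names(out) == "outcome"] <- "health"
  }
  attr(out, "outcome_kind") <- v$outcome_kind
  attr(out, "n_excluded") <- v$n_excluded
  out
}

# Full-precision, locale-independent numeric formatting so that a written
# record set reads back bit-identically and identical inputs give
# byte-identical files.
fmt_full <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write infection-experiment records to CSV or TSV
#'
#' Numeric columns are written with full (round-trip-exact) precision so
#' that [read_records()] recovers the values bit-identically, and the same
#' records always produce byte-identical files.
#'
#' @param records data.frame with the standard record columns.
#' @param path output path; extension selects comma or tab separation.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  v <- validate_records(records)
  outcome_name <- if (v$outcome_kind == "binary") "survived" else "health"
  df <- v$records
  sep <- sep_for(path)
  header <- paste(c("host_type", "strain", "density", outcome_name),
                  collapse = sep)
  body <- paste(df$host_type, df$strain, fmt_full(df$density),
                fmt_full(df$outcome), sep = sep)
  writeLines(c(header, body), path, sep = "\n")
  invisible(path)
}

#' Read a simulation scenario from YAML or JSON
#'
#' The file must contain `cells` (list/table of per-cell parameters),
#' `seed` (mandatory), and optionally `sigma_health`, `outcome_kind`,
#' `analysis_scale`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a [simulation_scenario()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop_format("scenario file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    stop_format("scenario file must be YAML or JSON, got .", ext)
  }
  if (is.null(obj$seed)) {
    stop_config("scenario field 'seed' is mandatory (an omitted seed is an error)")
  }
  cells <- obj$cells
  if (is.list(cells) && !is.data.frame(cells)) {
    atomic_cols <- all(vapply(cells, is.atomic, logical(1))) &&
      length(unique(lengths(cells))) == 1 && !is.null(names(cells))
    cells <- if (atomic_cols) {
      as.data.frame(cells, stringsAsFactors = FALSE) # column-major (YAML default)
    } else {
      do.call(rbind, lapply(cells, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
    }
  }
  simulation_scenario(
    cells = cells,
    sigma_health = obj$sigma_health %||% 1,
    outcome_kind = obj$outcome_kind %||% "continuous",
    seed = obj$seed,
    analysis_scale = obj$analysis_scale %||% "log10p1"
  )
}

scenario_as_list <- function(scenario) {
  list(
    schema_version = JSON_SCHEMA_VERSION,
    cells = scenario$cells,
    sigma_health = scenario$sigma_health,
    outcome_kind = scenario$outcome_kind,
    seed = scenario$seed,
    analysis_scale = scenario$analysis_scale
  )
}

#' Write a ground-truth manifest for a simulated dataset
#'
#' @param scenario the generating [simulation_scenario()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(scenario, path) {
  jsonlite::write_json(scenario_as_list(scenario), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(path)
}

fit_as_list <- function(fit) {
  if (inherits(fit, "pb_factorial")) {
    return(list(
      schema_version = JSON_SCHEMA_VERSION,
      model = "combined_factorial",
      screen = fit$screen,
      density = fit_as_list(fit$density),
      health = fit_as_list(fit$health),
      n_obs = fit$n_obs, n_excluded = fit$n_excluded,
      analysis_scale = fit$analysis_scale, alpha = fit$alpha,
      flags = as.list(fit$flags)
    ))
  }
  keep <- c("model_name", "property", "formula_terms", "coefficients",
            "p_value", "interaction_p", "group_lines", "group_summaries",
            "n_obs", "n_excluded", "analysis_scale", "alpha", "flags",
            "curvature_p", "quad_by_group", "tolerance_p", "benevolence_p",
            "resistance_p", "proliferation_p", "term_tests")
  out <- fit[intersect(keep, names(fit))]
  c(list(schema_version = JSON_SCHEMA_VERSION), out)
}

#' Serialize a fit result to JSON
#'
#' @param fit a `pb_fit` or `pb_factorial`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(fit_as_list(fit), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a flat TSV coefficient table for a fit result
#'
#' @param fit a `pb_fit` or `pb_factorial`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fit_tsv <- function(fit, path) {
  tab <- if (inherits(fit, "pb_factorial")) {
    rbind(
      cbind(model = "density", fit$density$coefficients),
      cbind(model = "health", fit$health$coefficients)
    )
  } else {
    cbind(model = fit$model_name, fit$coefficients)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

factor_call_as_list <- function(call) {
  c(list(schema_version = JSON_SCHEMA_VERSION),
    call[c("side", "labels", "pure", "b_wt", "b_ko", "c_bar_wt", "c_bar_ko",
           "p_slope", "p_density", "alpha", "flags", "mde_slope", "mde_density")])
}

#' Serialize a factor classification to JSON
#'
#' @param call a `factor_call`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_factor_call_json <- function(call, path) {
  obj <- factor_call_as_list(call)
  obj$labels <- as.list(obj$labels)
  obj$flags <- as.list(obj$flags)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
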