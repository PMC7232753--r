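# Internal helpers: classed conditions, density-scale transforms, seed streams.

pb_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "probene_error", "error")))
}

stop_design <- function(...) pb_abort(paste0(...), "probene_design_error")
stop_config <- function(...) pb_abort(paste0(...), "probene_config_error")
stop_format <- function(...) pb_abort(paste0(...), "probene_format_error")
stop_domain <- function(...) pb_abort(paste0(...), "probene_domain_error")

ANALYSIS_SCALES <- c("log10p1", "raw")

# raw cfu -> analysis scale
to_analysis_scale <- function(density, scale) {
  switch(scale,
    log10p1 = log10(density + 1),
    raw = density,
    stop_config("unknown analysis scale '", scale, "'; use one of: ",
                paste(ANALYSIS_SCALES, collapse = ", "))
  )
}

# analysis scale -> raw cfu
from_analysis_scale <- function(d, scale) {
  switch(scale,
    log10p1 = 10^d - 1,
    raw = d,
    stop_config("unknown analysis scale '", scale, "'")
  )
}

# Independent per-replicate seeds derived from one master seed; kept < 2^31.
mc_seeds <- function(seed, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
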