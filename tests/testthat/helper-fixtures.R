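# Shared fixtures and independent oracles. All oracles are closed-form or
# sums-of-squares arithmetic, independent of the lm/glm code paths they check.

# Closed-form simple least squares for one group.
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  list(a = a, b = b)
}

# One-way ANOVA from hand-rolled between/within sums of squares.
oracle_oneway <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ss_within <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  f <- (ss_between / df1) / (ss_within / df2)
  list(F = f, p = pf(f, df1, df2, lower.tail = FALSE))
}

# Two-group slope-difference test: separate per-group OLS, pooled residual
# variance, t contrast. For two groups t^2 equals the interaction F.
oracle_slope_contrast <- function(x1, y1, x2, y2) {
  f1 <- oracle_ols(x1, y1); f2 <- oracle_ols(x2, y2)
  rss <- sum((y1 - f1$a - f1$b * x1)^2) + sum((y2 - f2$a - f2$b * x2)^2)
  df <- length(y1) + length(y2) - 4
  s2 <- rss / df
  se <- sqrt(s2 * (1 / sum((x1 - mean(x1))^2) + 1 / sum((x2 - mean(x2))^2)))
  t <- (f1$b - f2$b) / se
  list(delta_b = f1$b - f2$b, t = t, p = 2 * pt(-abs(t), df))
}

# Brute-force interval overlap coefficient.
oracle_overlap <- function(r1, r2) {
  inter <- min(r1[2], r2[2]) - max(r1[1], r2[1])
  if (inter < 0) return(0)
  inter / (max(r1[2], r2[2]) - min(r1[1], r2[1]))
}

# Zero-residual two-strain fixture: strain A has slope -1, strain B slope 0.
exact_two_strain_fixture <- function() {
  data.frame(
    host_type = "host",
    strain = rep(c("A", "B"), each = 4),
    density = rep(1:4, 2),
    health = c(9, 8, 7, 6, 10, 10, 10, 10),
    stringsAsFactors = FALSE
  )
}

# Zero-noise quadratic fixture: strain P is the exact parabola
# h = 10 - (c - 3)^2, strain L the exact line h = 10 - c.
exact_parabola_fixture <- function() {
  d <- 1:5
  data.frame(
    host_type = "host",
    strain = rep(c("P", "L"), each = 5),
    density = rep(d, 2),
    health = c(10 - (d - 3)^2, 10 - d),
    stringsAsFactors = FALSE
  )
}

# Null scenario over host types (identical cells), for type-I checks of the
# host-side (resistance / tolerance) tests.
null_host_scenario <- function(seed, n = 50) {
  cells <- data.frame(
    host_type = c("H1", "H2"), strain = "microbe",
    a = 10, b = -1, quad = 0, mu_density = 4, sd_density = 1, n = n,
    stringsAsFactors = FALSE
  )
  simulation_scenario(cells, sigma_health = 1, outcome_kind = "continuous",
                      seed = seed)
}

# Null binary-outcome scenario: identical logistic cells, n chosen larger
# because 0/1 outcomes carry less information per host.
null_binary_scenario <- function(seed, n = 100) {
  cells <- data.frame(
    host_type = "host", strain = c("ko", "wt"),
    a = 2, b = -0.5, quad = 0, mu_density = 4, sd_density = 1, n = n,
    stringsAsFactors = FALSE
  )
  simulation_scenario(cells, outcome_kind = "binary", seed = seed)
}

split_wt_ko <- function(records) {
  list(wt = records[records$strain == "wt", , drop = FALSE],
       ko = records[records$strain == "ko", , drop = FALSE])
}

# Monte-Carlo rejection rate of one named test under a scenario.
mc_rejection_rate <- function(scenario, test, reps, alpha = 0.05) {
  seeds <- probene:::mc_seeds(scenario$seed, reps)
  rej <- 0L
  for (r in seq_len(reps)) {
    scenario$seed <- seeds[r]
    p <- probene:::run_named_test(simulate_experiment(scenario), test,
                                  scenario$analysis_scale)
    if (!is.na(p) && !is.nan(p) && p < alpha) rej <- rej + 1L
  }
  rej / reps
}

binom_ci99 <- function(p0, n) {
  p0 + c(-1, 1) * qnorm(0.995) * sqrt(p0 * (1 - p0) / n)
}
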