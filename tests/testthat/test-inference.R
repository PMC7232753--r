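# Fit-and-test operations on continuous outcomes.

test_that("density model detects variation in proliferation and matches a
           hand-rolled one-way decomposition", {
  # identical density vectors: no variation, p = 1
  same <- data.frame(host_type = "h", strain = rep(c("A", "B"), each = 4),
                     density = rep(c(2, 3, 4, 5), 2), health = rnorm(8))
  f0 <- test_density_variation(same, "strain", scale = "raw")
  expect_equal(f0$p_value, 1)
  expect_identical(f0$property, "proliferation")

  # clearly separated strains: significant variation in proliferation
  set.seed(11)
  apart <- data.frame(host_type = "h", strain = rep(c("A", "B"), each = 4),
                      density = c(2, 2, 2, 2, 6, 6, 6, 6) + rnorm(8, 0, 0.01),
                      health = rnorm(8))
  f1 <- test_density_variation(apart, "strain", scale = "raw")
  expect_lt(f1$p_value, 1e-6)

  # 3 host types x n = 10 against the sums-of-squares oracle
  set.seed(21)
  d <- c(rnorm(10, 2, 0.5), rnorm(10, 4, 0.5), rnorm(10, 8, 0.5))
  rec <- data.frame(host_type = rep(c("X", "Y", "Z"), each = 10),
                    strain = "s", density = d, health = 0)
  fit <- test_density_variation(rec, "host_type", scale = "raw")
  orc <- oracle_oneway(d, rec$host_type)
  expect_equal(fit$statistic, orc$F, tolerance = 1e-10)
  expect_equal(fit$p_value, orc$p, tolerance = 1e-10)
  expect_identical(fit$property, "resistance")
  expect_equal(fit$group_summaries$c_bar,
               as.numeric(tapply(d, rec$host_type, mean)), tolerance = 1e-12)
})

test_that("density model preconditions and degenerate cases", {
  one_level <- data.frame(host_type = "h", strain = "A",
                          density = 1:4, health = 1:4)
  expect_error(test_density_variation(one_level, "strain"),
               class = "probene_design_error")
  # zero within-group variance with distinct means: exact-fit flag
  flat <- data.frame(host_type = "h", strain = rep(c("A", "B"), each = 3),
                     density = rep(c(2, 6), each = 3), health = 0)
  ff <- test_density_variation(flat, "strain", scale = "raw")
  expect_true("exact_fit" %in% ff$flags)
  # zero variance everywhere: degenerate NaN
  allsame <- data.frame(host_type = "h", strain = rep(c("A", "B"), each = 3),
                        density = 4, health = 0)
  fd <- test_density_variation(allsame, "strain", scale = "raw")
  expect_true(is.nan(fd$p_value))
  expect_true("degenerate_zero_residual" %in% fd$flags)
})

test_that("saturated interaction model reproduces per-group least squares", {
  fix <- exact_two_strain_fixture()
  fit <- test_slope_variation(fix, "strain", scale = "raw")
  gl <- fit$group_lines
  oa <- oracle_ols(fix$density[fix$strain == "A"], fix$health[fix$strain == "A"])
  ob <- oracle_ols(fix$density[fix$strain == "B"], fix$health[fix$strain == "B"])
  expect_equal(gl$b[gl$group == "A"], oa$b, tolerance = 1e-12)  # -1
  expect_equal(gl$b[gl$group == "B"], ob$b, tolerance = 1e-12)  # 0
  expect_equal(gl$a[gl$group == "A"], oa$a, tolerance = 1e-12)  # 10
  expect_equal(gl$a[gl$group == "B"], ob$a, tolerance = 1e-12)  # 10
  # zero residuals, real slope difference: exact-fit interaction call
  expect_true("exact_fit" %in% fit$flags)
  expect_equal(fit$interaction_p, 0)
  expect_identical(fit$property, "benevolence")

  # noisy case: interaction F equals the independent slope-contrast oracle
  set.seed(33)
  n <- 50
  dA <- rnorm(n, 4, 1); dB <- rnorm(n, 4, 1)
  hA <- 10 - 1 * dA + rnorm(n); hB <- 10 - 0 * dB + rnorm(n)
  rec <- data.frame(host_type = "h", strain = rep(c("A", "B"), each = n),
                    density = c(dA, dB), health = c(hA, hB))
  fit2 <- test_slope_variation(rec, "strain", scale = "raw")
  orc <- oracle_slope_contrast(dA, hA, dB, hB)
  expect_equal(fit2$statistic, orc$t^2, tolerance = 1e-10)
  expect_equal(fit2$interaction_p, orc$p, tolerance = 1e-10)
  gl2 <- fit2$group_lines
  expect_equal(gl2$b, c(oracle_ols(dA, hA)$b, oracle_ols(dB, hB)$b),
               tolerance = 1e-12)
})

test_that("equal-slope zero-noise groups give an exactly null interaction", {
  d <- 1:6
  rec <- data.frame(host_type = "h", strain = rep(c("A", "B"), each = 6),
                    density = rep(d, 2),
                    health = c(12 - d, 9 - d)) # same slope, different vigour
  fit <- test_slope_variation(rec, "strain", scale = "raw")
  gl <- fit$group_lines
  expect_equal(diff(gl$b), 0, tolerance = 1e-12)
  expect_true(is.nan(fit$interaction_p)) # nothing left to test: flagged
  expect_true("degenerate_zero_residual" %in% fit$flags)
})

test_that("slope model refuses constant density within a group, naming it", {
  rec <- data.frame(host_type = "h", strain = rep(c("A", "B"), each = 3),
                    density = c(1, 2, 3, 5, 5, 5), health = rnorm(6))
  err <- tryCatch(test_slope_variation(rec, "strain", scale = "raw"),
                  probene_design_error = function(e) conditionMessage(e))
  expect_match(err, "B")
})

test_that("p-values are invariant to group relabelling and record order", {
  set.seed(44)
  rec <- simulate_experiment(make_preset("knockout_mixed", seed = 9, n = 25))
  f1 <- test_slope_variation(rec, "strain")
  perm <- rec[sample(nrow(rec)), ]
  f2 <- test_slope_variation(perm, "strain")
  relab <- rec
  relab$strain <- c(wt = "zzz", ko = "aaa")[relab$strain]
  f3 <- test_slope_variation(relab, "strain")
  expect_equal(f1$interaction_p, f2$interaction_p, tolerance = 1e-12)
  expect_equal(f1$interaction_p, f3$interaction_p, tolerance = 1e-12)
  d1 <- test_density_variation(rec, "strain")
  d3 <- test_density_variation(relab, "strain")
  expect_equal(d1$p_value, d3$p_value, tolerance = 1e-12)
})

test_that("shifting all health values moves intercepts only", {
  set.seed(55)
  rec <- simulate_experiment(make_preset("fig2_strains", seed = 5, n = 20))
  f1 <- test_slope_variation(rec, "strain")
  shifted <- rec
  shifted$health <- shifted$health + 7
  f2 <- test_slope_variation(shifted, "strain")
  expect_equal(f2$group_lines$a, f1$group_lines$a + 7, tolerance = 1e-10)
  expect_equal(f2$group_lines$b, f1$group_lines$b, tolerance = 1e-12)
  expect_equal(f2$interaction_p, f1$interaction_p, tolerance = 1e-10)
  expect_equal(f2$group_summaries$c_bar, f1$group_summaries$c_bar,
               tolerance = 1e-12)
})

test_that("combined factorial screens the host x strain interaction", {
  make_factorial <- function(seed, interaction_shift = 0, n = 30) {
    cells <- expand.grid(host_type = c("H1", "H2"), strain = c("A", "B"),
                         stringsAsFactors = FALSE)
    cells$a <- 10
    cells$b <- -1
    cells$quad <- 0
    cells$mu_density <- 4 + 0.5 * (cells$host_type == "H2") +
      0.5 * (cells$strain == "B") +
      interaction_shift * (cells$host_type == "H2" & cells$strain == "B")
    cells$sd_density <- 1
    cells$n <- n
    simulation_scenario(cells, seed = seed)
  }
  # additive generating model: the screen removes the interaction ~ (1 - alpha)
  seeds <- probene:::mc_seeds(101, 300)
  removed <- vapply(seeds, function(s) {
    !fit_combined_factorial(simulate_experiment(make_factorial(s)))$screen$retained
  }, logical(1))
  expect_gte(mean(removed), 0.95 - qnorm(0.995) * sqrt(0.05 * 0.95 / 300))

  # a 2-sd-unit host x strain density interaction: retained with high power
  seeds2 <- probene:::mc_seeds(202, 200)
  retained <- vapply(seeds2, function(s) {
    fit_combined_factorial(simulate_experiment(make_factorial(s, 2)))$screen$retained
  }, logical(1))
  expect_gte(mean(retained), 0.9)

  # the factorial fit reports all four property tests
  ff <- fit_combined_factorial(simulate_experiment(make_factorial(7)))
  expect_true(all(is.finite(c(ff$density$resistance_p, ff$density$proliferation_p,
                              ff$health$tolerance_p, ff$health$benevolence_p))))
  # single strain violates the factorial precondition
  rec <- simulate_experiment(make_preset("fig1_resistance", seed = 3, n = 10))
  expect_error(fit_combined_factorial(rec), class = "probene_design_error")
})

test_that("quadratic extension recovers an exact parabola and detects curvature", {
  fix <- exact_parabola_fixture()
  fit <- fit_quadratic_extension(fix, "strain", scale = "raw")
  q <- fit$quad_by_group
  expect_equal(q$quad[q$group == "P"], -1, tolerance = 1e-10)
  expect_equal(q$quad[q$group == "L"], 0, tolerance = 1e-10)
  expect_equal(fit$curvature_p, 0) # exact fit of the quadratic, not the line
  expect_true("exact_fit" %in% fit$flags)

  # curvature power on noisy quadratic data (coefficient -0.5, sigma = 1, n = 60)
  cells <- data.frame(host_type = "h", strain = c("A", "B"), a = 10, b = -1,
                      quad = -0.5, mu_density = 4, sd_density = 1, n = 30)
  seeds <- probene:::mc_seeds(303, 150)
  rej <- vapply(seeds, function(s) {
    sc <- simulation_scenario(cells, seed = s)
    fit_quadratic_extension(simulate_experiment(sc), "strain")$curvature_p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)

  # too few distinct densities per group
  rec <- data.frame(host_type = "h", strain = rep(c("A", "B"), each = 4),
                    density = rep(c(1, 2), 4), health = rnorm(8))
  expect_error(fit_quadratic_extension(rec, "strain", scale = "raw"),
               class = "probene_design_error")
})
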