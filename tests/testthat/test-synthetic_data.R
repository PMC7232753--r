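# Synthetic-data generator: determinism, distributional targets, presets,
# recovery of generating parameters, power machinery.

test_that("the seed fully determines the simulated dataset", {
  sc <- make_preset("fig2_strains", seed = 314, n = 20)
  r1 <- simulate_experiment(sc)
  r2 <- simulate_experiment(sc)
  expect_identical(r1, r2)
  r3 <- simulate_experiment(make_preset("fig2_strains", seed = 315, n = 20))
  expect_false(identical(r1$density, r3$density))
})

test_that("a noise-free neutral microbe leaves health exactly at vigour", {
  cells <- data.frame(host_type = "h", strain = "s", a = 7.5, b = 0, quad = 0,
                      mu_density = 4, sd_density = 1, n = 25)
  sc <- simulation_scenario(cells, sigma_health = 1e-12, seed = 2)
  rec <- simulate_experiment(sc)
  expect_equal(rec$health, rep(7.5, 25), tolerance = 1e-9)
})

test_that("sample mean density honours the configured mean (n = 1e4)", {
  cells <- data.frame(host_type = "h", strain = "s", a = 10, b = -1, quad = 0,
                      mu_density = 4, sd_density = 1, n = 10000)
  rec <- simulate_experiment(simulation_scenario(cells, seed = 99))
  d <- log10(rec$density + 1)
  expect_lt(abs(mean(d) - 4), 3 * 1 / sqrt(10000))
  expect_lt(abs(sd(d) - 1), 0.05)
})

test_that("presets encode their advertised ground truth", {
  pp <- make_preset("knockout_pure_proliferation", seed = 1)
  expect_equal(length(unique(pp$cells$b)), 1)
  expect_gt(pp$cells$mu_density[pp$cells$strain == "wt"],
            pp$cells$mu_density[pp$cells$strain == "ko"])
  fr <- make_preset("fig1_resistance", seed = 1)
  expect_equal(length(unique(fr$cells$b)), 1)
  expect_equal(length(unique(fr$cells$mu_density)), 3)
  ft <- make_preset("fig1_tolerance", seed = 1)
  expect_equal(length(unique(ft$cells$mu_density)), 1)
  expect_equal(length(unique(ft$cells$b)), 3)
  nn <- make_preset("null", seed = 1)
  expect_equal(nrow(unique(nn$cells[, c("a", "b", "quad", "mu_density",
                                        "sd_density", "n")])), 1)
  expect_error(make_preset("not_a_preset", seed = 1),
               class = "probene_config_error")
})

test_that("scenario validation names the offending field", {
  cells <- data.frame(host_type = "h", strain = "s", a = 10, b = -1,
                      mu_density = 4, sd_density = 1, n = 10)
  expect_error(simulation_scenario(cells), class = "probene_config_error")
  bad_sd <- transform(cells, sd_density = 0)
  err <- tryCatch(simulation_scenario(bad_sd, seed = 1),
                  probene_config_error = function(e) conditionMessage(e))
  expect_match(err, "sd_density")
  bad_n <- transform(cells, n = 0)
  err2 <- tryCatch(simulation_scenario(bad_n, seed = 1),
                   probene_config_error = function(e) conditionMessage(e))
  expect_match(err2, "n")
})

test_that("inference on generated data recovers a, b, c_bar with vanishing bias", {
  errs <- vapply(c(20, 200, 2000), function(n) {
    sc <- make_preset("fig2_strains", seed = 11, n = n)
    seeds <- probene:::mc_seeds(1000 + n, 30)
    est <- vapply(seeds, function(s) {
      sc$seed <- s
      fit <- test_slope_variation(suppressMessages(simulate_experiment(sc)), "strain")
      gl <- fit$group_lines
      gs <- fit$group_summaries
      c(gl$b[gl$group == "S_malevolent"], gs$c_bar[gs$group == "S_neutral"],
        gl$a[gl$group == "S_benevolent"])
    }, numeric(3))
    mean(abs(rowMeans(est) - c(-1, 4, 10)))
  }, numeric(1))
  expect_lt(errs[3], errs[1] + 0.05)
  expect_lt(errs[3], 0.05)
})

test_that("fig2 regime: per-strain slope signs and density ordering recovered", {
  sc0 <- make_preset("fig2_strains", seed = 17)
  seeds <- probene:::mc_seeds(17, 400)
  ok <- vapply(seeds, function(s) {
    sc0$seed <- s
    fit <- test_slope_variation(suppressMessages(simulate_experiment(sc0)), "strain")
    gl <- fit$group_lines
    gs <- fit$group_summaries
    dir_of <- function(g) {
      classify_direction(
        health_density_line(g, gl$a[gl$group == g], gl$b[gl$group == g],
                            gl$se_a[gl$group == g], gl$se_b[gl$group == g],
                            gl$df[gl$group == g]),
        density_range = c(0, 8))
    }
    dir_of("S_benevolent") == "benevolent" &&
      dir_of("S_neutral") == "neutral" &&
      dir_of("S_malevolent") == "malevolent" &&
      gs$c_bar[gs$group == "S_benevolent"] < gs$c_bar[gs$group == "S_neutral"] &&
      gs$c_bar[gs$group == "S_neutral"] < gs$c_bar[gs$group == "S_malevolent"]
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("power_sweep validates its configuration and reports MC error", {
  sc <- make_preset("null", seed = 1, n = 10)
  expect_error(power_sweep(sc, "delta_b", numeric(0), reps = 100),
               class = "probene_config_error")
  expect_error(power_sweep(sc, "delta_b", 1, reps = 0),
               class = "probene_config_error")
  expect_error(power_sweep(sc, "no_such_field", 1, reps = 100),
               class = "probene_config_error")
  tab <- suppressWarnings(power_sweep(sc, "delta_b", c(0, 2), reps = 30,
                                      test = "benevolence"))
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$power >= 0 & tab$power <= 1))
  expect_true(all(tab$mc_se >= 0))
  expect_gt(tab$power[2], tab$power[1]) # 2-unit slope gap at n=10 is obvious
})

test_that("density truncation at zero is rare for default parameters and logged
           when common", {
  cells <- data.frame(host_type = "h", strain = "s", a = 10, b = -1, quad = 0,
                      mu_density = 0.5, sd_density = 1, n = 2000)
  expect_message(simulate_experiment(simulation_scenario(cells, seed = 4)),
                 "truncation")
  expect_silent(simulate_experiment(make_preset("null", seed = 4, n = 2000)))
})
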