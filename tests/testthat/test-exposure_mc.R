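# Probabilistic dietary-exposure simulation.

point_pop <- function(bw = 58, dir = 58) {
  population_model(list(list(label = "fixed", proportion = 1,
                             bw_dist = dist_spec("point", value = bw),
                             dir_dist = dist_spec("point", value = dir))))
}

test_that("distribution specs validate family parameters and truncation", {
  expect_error(dist_spec("lognormal", meanlog = 0, sdlog = -1),
               class = "vegrisk_config_error")
  expect_error(dist_spec("normal", mean = 0), class = "vegrisk_config_error")
  expect_error(dist_spec("triangular", min = 2, mode = 1, max = 3),
               class = "vegrisk_config_error")
  expect_error(dist_spec("normal", mean = 0, sd = 1, lower = 2, upper = 1),
               class = "vegrisk_config_error")
  expect_s3_class(dist_spec("empirical", values = 1:3), "dist_spec")
})

test_that("truncated draws respect their bounds; point masses are exact", {
  spec <- dist_spec("normal", mean = 0, sd = 5, lower = -1, upper = 2)
  x <- vegrisk:::with_seed(4, vegrisk:::draw_dist(spec, 5000))
  expect_true(all(x > -1 & x < 2))
  tri <- dist_spec("triangular", min = 1, mode = 2, max = 4)
  y <- vegrisk:::with_seed(4, vegrisk:::draw_dist(tri, 5000))
  expect_true(all(y >= 1 & y <= 4))
  expect_equal(mean(y), (1 + 2 + 4) / 3, tolerance = 0.05)
  expect_equal(vegrisk:::with_seed(4, vegrisk:::draw_dist(
    dist_spec("point", value = 7), 3)), rep(7, 3))
})

test_that("lognormal fitting recomputes log-moments and applies the LOD/2 rule", {
  tab <- table1_fixture()
  fits <- fit_concentration_dists(tab)
  # direct recomputation oracle for a metal with no zeros
  expect_equal(fits$Fe$pars$meanlog, mean(log(tab$Fe)))
  expect_equal(fits$Fe$pars$sdlog, sd(log(tab$Fe)))
  # Se has zeros and LOD 0.063: zeros replaced by LOD/2 before fitting
  se_fit <- fit_concentration_dists(tab, metals = "Se")
  se_obs <- tab$Se
  se_obs[se_obs == 0] <- 0.063 / 2
  expect_equal(se_fit$Se$pars$meanlog, mean(log(se_obs)))
  # identical observations degenerate to a point mass
  const <- concentration_table(paste0("S", 1:4), "X", data.frame(Cd = rep(2, 4)))
  expect_equal(fit_concentration_dists(const, metals = "Cd")$Cd$family, "point")
  # all-zero metal without an LOD is skipped with a warning, not an error
  zero <- concentration_table(paste0("S", 1:4), "X",
                              data.frame(Cd = rep(2, 4), Ag = rep(0, 4)))
  expect_warning(f <- fit_concentration_dists(zero, metals = c("Cd", "Ag")),
                 "Ag")
  expect_named(f, "Cd")
})

test_that("point-mass configurations give exact 0/1 exceedance", {
  below <- mc_config(conc_dist = list(Cd = dist_spec("point", value = 0.5)),
                     limits = c(Cd = 1), population = point_pop(),
                     n_iter = 500, seed = 1)
  above <- mc_config(conc_dist = list(Cd = dist_spec("point", value = 2)),
                     limits = c(Cd = 1), population = point_pop(),
                     n_iter = 500, seed = 1)
  expect_equal(run_simulation(below)$summary$exceedance_prob, 0)
  expect_equal(run_simulation(above)$summary$exceedance_prob, 1)
})

test_that("lognormal exceedance matches the analytic tail within 3 MC standard errors", {
  # bw = dir = 58 makes EDI numerically equal to the concentration draw
  settings <- list(list(mu = 0, sigma = 1, limit = 1),
                   list(mu = 0, sigma = 1, limit = exp(1)),
                   list(mu = 1, sigma = 0.5, limit = exp(1)))
  for (s in settings) {
    cfg <- mc_config(conc_dist = list(Cd = dist_spec("lognormal",
                                                     meanlog = s$mu,
                                                     sdlog = s$sigma)),
                     limits = c(Cd = s$limit), population = point_pop(),
                     n_iter = 10000, seed = 20)
    res <- run_simulation(cfg)$summary
    p_true <- 1 - pnorm((log(s$limit) - s$mu) / s$sigma)
    se <- sqrt(p_true * (1 - p_true) / 10000)
    expect_lt(abs(res$exceedance_prob - p_true), 3 * se)
    expect_equal(res$mc_se,
                 sqrt(res$exceedance_prob * (1 - res$exceedance_prob) / 10000))
  }
})

test_that("identical configs give bit-identical results", {
  cfg <- mc_config(conc_dist = fit_concentration_dists(table1_fixture(),
                                                       metals = c("Cd", "Pb")),
                   limits = c(Cd = 1, Pb = 3.6), n_iter = 2000, seed = 77)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$edi, r2$edi)
  r3 <- run_simulation(mc_config(conc_dist = cfg$conc_dist,
                                 limits = cfg$limits, n_iter = 2000, seed = 78))
  expect_false(identical(r1$summary$exceedance_prob,
                         r3$summary$exceedance_prob))
})

test_that("exceedance is monotone in the limit and in concentration scale", {
  base <- fit_concentration_dists(table1_fixture(), metals = "Cd")$Cd
  p_at <- function(limit, shift = 0) {
    spec <- dist_spec("lognormal", meanlog = base$pars$meanlog + shift,
                      sdlog = base$pars$sdlog)
    cfg <- mc_config(conc_dist = list(Cd = spec), limits = c(Cd = limit),
                     population = point_pop(), n_iter = 4000, seed = 3)
    run_simulation(cfg)$summary$exceedance_prob
  }
  limits <- c(0.1, 0.5, 1, 5)
  probs <- vapply(limits, p_at, numeric(1))
  expect_true(all(diff(probs) <= 0))
  # scaling all concentrations up (log-shift) never decreases exceedance
  expect_gte(p_at(1, shift = log(2)), p_at(1))
})

test_that("MC standard error shrinks as the square root of the iteration count", {
  se_at <- function(n) {
    cfg <- mc_config(conc_dist = list(Cd = dist_spec("lognormal",
                                                     meanlog = 0, sdlog = 1)),
                     limits = c(Cd = 1), population = point_pop(),
                     n_iter = n, seed = 15)
    run_simulation(cfg)$summary$mc_se
  }
  ratio <- se_at(100) / se_at(10000)
  expect_gt(ratio, 10 / 1.5)
  expect_lt(ratio, 10 * 1.5)
})

test_that("exceedance table formats percentages in reporting order", {
  cfg <- mc_config(conc_dist = list(Pb = dist_spec("point", value = 10),
                                    Mn = dist_spec("point", value = 10)),
                   limits = c(Pb = 1, Mn = 700), population = point_pop(),
                   n_iter = 100, seed = 1)
  tabout <- exceedance_table(run_simulation(cfg))
  expect_equal(tabout$metal, c("Mn", "Pb")) # Mn before Pb, per convention
  expect_equal(tabout$probability_pct, c(0, 100))
  expect_equal(tabout$probability_label, c("0 %", "100 %"))
})

test_that("config validation fails before any sampling", {
  expect_error(mc_config(conc_dist = list(Cd = dist_spec("point", value = 1)),
                         limits = c(Pb = 1)),
               class = "vegrisk_config_error")
  expect_error(mc_config(conc_dist = list(), limits = c(Cd = 1)),
               class = "vegrisk_config_error")
  expect_error(population_model(list(list(label = "a", proportion = 0.4))),
               class = "vegrisk_config_error")
})

test_that("YAML round trip builds an equivalent simulation config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_iter: 500", "seed: 5",
    "limits:", "  Cd: 1.0",
    "distributions:",
    "  Cd: {family: lognormal, meanlog: 0.0, sdlog: 1.0}",
    "strata:",
    "  - label: fixed", "    proportion: 1.0",
    "    bw: {family: point, value: 58}",
    "    dir: {family: point, value: 58}"), path)
  cfg <- read_mc_config(path)
  expect_equal(cfg$n_iter, 500L)
  res <- run_simulation(cfg)
  direct <- run_simulation(mc_config(
    conc_dist = list(Cd = dist_spec("lognormal", meanlog = 0, sdlog = 1)),
    limits = c(Cd = 1), population = point_pop(), n_iter = 500, seed = 5))
  expect_equal(res$summary, direct$summary)
})
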