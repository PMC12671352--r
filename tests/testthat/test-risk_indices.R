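# Deterministic risk pipeline: EDI, THQ, HI, limit screening, site summaries.

scen <- exposure_scenario() # DIR 60 g/day, BW 58 kg, EF 365, ED 70, AT 25550

test_that("EDI reproduces the published spot values", {
  expect_equal(round(estimated_daily_intake(519.24, scen), 2), 537.14)
  expect_equal(round(estimated_daily_intake(844.94, scen), 2), 874.08)
  expect_equal(estimated_daily_intake(0, scen), 0)
  expect_error(estimated_daily_intake(-1, scen), class = "vegrisk_domain_error")
})

test_that("EDI scales linearly in concentration and intake, inversely in body weight", {
  set.seed(5)
  for (i in 1:20) {
    c0 <- runif(1, 0, 100); k <- runif(1, 0.1, 10)
    s0 <- exposure_scenario(dir = runif(1, 10, 200), bw = runif(1, 20, 100))
    sk_dir <- exposure_scenario(dir = k * s0$dir, bw = s0$bw)
    sk_bw <- exposure_scenario(dir = s0$dir, bw = k * s0$bw)
    expect_equal(estimated_daily_intake(k * c0, s0),
                 k * estimated_daily_intake(c0, s0))
    expect_equal(estimated_daily_intake(c0, sk_dir),
                 k * estimated_daily_intake(c0, s0))
    expect_equal(estimated_daily_intake(c0, sk_bw),
                 estimated_daily_intake(c0, s0) / k)
  }
})

test_that("THQ applies the hazard-quotient formula with its time terms", {
  expect_equal(round(target_hazard_quotient(88.36, 0.04, scen), 3), 2.209)
  expect_equal(target_hazard_quotient(0, 0.04, scen), 0)
  # halving the exposed fraction of the averaging time halves the quotient
  half <- exposure_scenario(ef = 365, ed = 35, at = 25550)
  expect_equal(target_hazard_quotient(1, 0.001, half), 0.5)
  err <- expect_error(target_hazard_quotient(1, NA, scen, metal = "Ti"),
                      class = "vegrisk_missing_rfd_error")
  expect_match(conditionMessage(err), "Ti")
})

test_that("scenario identity: with ef*ed = at, THQ * rfd * 1e3 equals EDI", {
  set.seed(9)
  for (i in 1:20) {
    edi <- runif(1, 0, 2000); rfd <- runif(1, 1e-4, 1)
    ef <- runif(1, 100, 366); ed <- runif(1, 1, 80)
    s <- exposure_scenario(ef = ef, ed = ed, at = ef * ed)
    expect_equal(target_hazard_quotient(edi, rfd, s) * rfd * 1e3, edi)
  }
})

test_that("hazard index is the THQ sum, permutation-invariant and additive", {
  thqs <- c(Mn = 1.2, Cd = 0.3, Pb = 2.5)
  h <- hazard_index(thqs)
  expect_equal(h$hi, 4)
  expect_true(h$exceeds)
  expect_equal(hazard_index(rev(thqs))$hi, h$hi)
  expect_equal(hazard_index(thqs[1:2])$hi + hazard_index(thqs[3])$hi, h$hi)
  expect_equal(hazard_index(c(Pb = 0.4))$hi, 0.4)
  expect_false(hazard_index(c(Mn = 0, Cd = 0))$exceeds)
  expect_error(hazard_index(numeric(0)), class = "vegrisk_domain_error")
})

test_that("risk table on the survey data reproduces the published indices", {
  risk <- compute_risk_table(table1_fixture())
  expect_equal(risk$metals, c("Mn", "Fe", "Cu", "Zn", "As", "Cd", "Pb"))
  expect_equal(round(risk$edi["CS1A", "Fe"], 2), 537.14)
  expect_equal(round(risk$thq["CS1A", "Cu"], 3), 2.209)
  expect_equal(risk$hi[["LS4A"]], 12.15, tolerance = 0.02 / 12.15)
  # full-precision values where the published table summed rounded cells
  expect_equal(round(risk$hi[["CS4M"]], 2), 2.99)
  expect_equal(round(risk$hi[["CS4P"]], 2), 16.12)
  # HI equals its own THQ row sums
  expect_equal(risk$hi, rowSums(risk$thq))
  expect_true(all(risk$edi >= 0) && all(risk$thq >= 0))
  # all-zero table gives all-zero indices
  z <- concentration_table(paste0("Z", 1:2), "X",
                           as.data.frame(matrix(0, 2, 7,
                             dimnames = list(NULL, risk$metals))))
  rz <- compute_risk_table(z)
  expect_true(all(rz$edi == 0) && all(rz$hi == 0))
  expect_error(compute_risk_table(table1_fixture(), metals = c("Mn", "Xx")),
               class = "vegrisk_missing_metal_error")
})

test_that("rounded-intermediate convention reproduces the published HI extrema", {
  risk <- compute_risk_table(table1_fixture(), round_thq = 2)
  cec <- risk$hi[risk$site == "Cecomaf"]
  expect_equal(round(min(cec), 2), 2.98)
  expect_equal(max(cec), 16.11, tolerance = 0.02 / 16.11)
})

test_that("exceedance screening matches the published fold ratios", {
  rep <- exceedance_report(table1_fixture())
  folds <- setNames(rep$fold, rep$metal)
  expect_equal(folds[["Cd"]], 29.5)
  expect_equal(folds[["Hg"]], 58)
  expect_equal(folds[["Cr"]], 3.5)
  expect_equal(folds[["Cu"]], 115.39 / 40)
  # Pb fold is emitted as computed from the data (30.94 / 0.3)
  expect_equal(folds[["Pb"]], 30.94 / 0.3)
  expect_true(all(rep$exceeds))
  expect_setequal(rep$metal, c("Cr", "Cu", "Cd", "Pb", "Hg"))
})

test_that("exceedance is a strict >1 test, monotone in concentration", {
  reg <- metal_registry(metal_descriptor("Cd", food_limit = 0.1))
  at_limit <- concentration_table("S1", "X", data.frame(Cd = 0.1))
  r <- exceedance_report(at_limit, reg)
  expect_equal(r$fold, 1)
  expect_false(r$exceeds)
  set.seed(21)
  for (i in 1:20) {
    lo <- runif(1, 0, 0.3); hi <- lo + runif(1, 0, 0.3)
    rlo <- exceedance_report(concentration_table("S1", "X", data.frame(Cd = lo)), reg)
    rhi <- exceedance_report(concentration_table("S1", "X", data.frame(Cd = hi)), reg)
    expect_true(rhi$exceeds >= rlo$exceeds)
  }
  expect_error(exceedance_report(table1_fixture(), site = "Nowhere"),
               class = "vegrisk_domain_error")
})

test_that("site summaries reproduce the published HI ranges", {
  risk <- compute_risk_table(table1_fixture())
  cec <- site_summary(risk, "Cecomaf")
  lut <- site_summary(risk, "Lutendele")
  expect_equal(cec$max, 16.11, tolerance = 0.02 / 16.11)
  expect_equal(cec$min, 2.98, tolerance = 0.02 / 2.98)
  expect_equal(lut$max, 12.15, tolerance = 0.02 / 12.15)
  expect_equal(lut$min, 4.85, tolerance = 0.02 / 4.85)
  expect_equal(cec$n, 11)
  expect_equal(lut$n, 8)
  expect_error(site_summary(risk, "Nowhere"),
               class = "vegrisk_unknown_site_error")
  # degenerate one-sample site
  one <- concentration_table("S1", "Solo",
                             data.frame(Mn = 1, Fe = 1, Cu = 1, Zn = 1,
                                        As = 1, Cd = 1, Pb = 1))
  s1 <- site_summary(compute_risk_table(one), "Solo")
  expect_equal(s1$min, s1$max)
  expect_equal(s1$mean, s1$max)
})

test_that("long-format export mirrors the published table layout", {
  risk <- compute_risk_table(table1_fixture())
  df <- as.data.frame(risk)
  expect_equal(nrow(df), 19 * 7)
  expect_named(df, c("sample", "site", "metal", "edi", "thq", "hi"))
  expect_equal(df$edi[df$sample == "CS1A" & df$metal == "Fe"], 537.14)
})
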