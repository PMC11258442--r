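test_that("perfect interocular correlation with no residual gives identical eyes", {
  cfg <- cohort_config(n_animals = 8, interocular_correlation = 1,
                       diameter_sd = 0, seed = 5)
  gen <- generate_cohort(cfg, traces = FALSE)
  t <- gen$truth
  od <- t[t$eye == "OD", ]
  os <- t[t$eye == "OS", ]
  expect_equal(od$Cr_true, os$Cr_true)
  expect_equal(od$beta_true, os$beta_true)
  expect_equal(od$phir_true, os$phir_true)
  expect_equal(od$diameter_mm, os$diameter_mm)
})

test_that("a null beta trend generates a null OLS slope", {
  cfg <- cohort_config(n_animals = 500, beta_age_slope = 0, seed = 7)
  gen <- generate_cohort(cfg, traces = FALSE)
  r <- regress_on_age(gen$truth$age_months, gen$truth$beta_true)
  expect_true(r$CI_slope[1] < 0 && r$CI_slope[2] > 0)
  expect_lt(abs(r$slope), 0.005)
})

test_that("the configured beta age trend is recovered from the truth table", {
  cfg <- cohort_config(n_animals = 60, seed = 11)
  gen <- generate_cohort(cfg, traces = FALSE)
  per_animal <- aggregate(cbind(beta_true, age_months) ~ animal_id,
                          gen$truth, mean)
  r <- regress_on_age(per_animal$age_months, per_animal$beta_true)
  expect_true(r$CI_slope[1] <= -0.027 && -0.027 <= r$CI_slope[2])
})

test_that("generator output is reproducible and respects the truth schema", {
  cfg <- cohort_config(n_animals = 3, seed = 2)
  g1 <- generate_cohort(cfg, quick_protocol(), traces = TRUE)
  g2 <- generate_cohort(cfg, quick_protocol(), traces = TRUE)
  expect_identical(g1$truth, g2$truth)
  expect_identical(g1$traces[[1]]$flow_nl_min, g2$traces[[1]]$flow_nl_min)
  expect_equal(nrow(g1$truth), 6)   # two eyes per animal
  expect_true(all(g1$truth$Cr_true > 0))
  expect_true(all(g1$truth$phir_true > 0))
  expect_error(cohort_config(n_animals = 0), "at least 1")
})

test_that("configured interocular correlation appears in the truth table", {
  cfg <- cohort_config(n_animals = 500, interocular_correlation = 0.7,
                       seed = 13)
  gen <- generate_cohort(cfg, traces = FALSE)
  t <- gen$truth
  od <- t[t$eye == "OD", ]
  os <- t[t$eye == "OS", ]
  # correlation of the age-detrended log compliance between fellow eyes
  res_od <- residuals(lm(log(od$phir_true) ~ od$age_months))
  res_os <- residuals(lm(log(os$phir_true) ~ os$age_months))
  r <- interocular_correlation(res_od, res_os)
  expect_equal(r$r, 0.7, tolerance = 0.15)
})

test_that("morphometry tables follow their configured trends", {
  # noiseless generator: every age regression is exact with R^2 = 1
  cfg0 <- cohort_config(n_animals = 12, cell_density_sd = 0, pigment_sd = 0,
                        p21_sd = 0, iris_angle_sd = 0, zeta_sd = 0,
                        sc_slope_sd = 0, seed = 3)
  tab <- generate_morphometry_tables(cfg0)
  r <- regress_on_age(tab$summary$age_months, tab$summary$cell_density_mm2)
  expect_equal(r$slope, -2.0, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)

  # linear trend arithmetic: 400 cells/mm2 at 2 months, -2/month -> 380 at 12
  pred <- 400 + (-2.0) * (12 - 2)
  expect_equal(pred, 380)
  i <- which.min(abs(tab$summary$age_months - 12))

  # SC areas derive exactly from the per-eye slope through 100% at 10 mmHg
  ser <- tab$pressure_series[tab$pressure_series$eye_id == "E001", ]
  sl <- fixed_intercept_slope(ser$iop_mmHg, ser$sc_area_rel_pct)
  expect_equal(sl$slope, tab$summary$sc_slope_true[1], tolerance = 1e-10)

  # zero slope config gives 100% everywhere
  cfg_flat <- cohort_config(n_animals = 4, sc_slope_ref = 0,
                            sc_slope_age_slope = 0, sc_slope_sd = 0, seed = 3)
  flat <- generate_morphometry_tables(cfg_flat)
  expect_true(all(flat$pressure_series$sc_area_rel_pct == 100))

  # iris angles follow the log law exactly
  ser2 <- tab$pressure_series[tab$pressure_series$eye_id == "E002", ]
  above <- ser2$iop_mmHg > 10
  fz <- fit_iris_sensitivity(ser2$iop_mmHg[above], ser2$iris_angle_deg[above],
                             theta0 = ser2$iris_angle_deg[!above][1])
  expect_equal(fz$zeta, tab$summary$zeta_true[2], tolerance = 1e-10)
})
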