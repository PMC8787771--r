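test_that("empty and invalid configurations are handled", {
  ds <- generate_trial(generator_config(n_patients = 0))
  expect_s3_class(ds, "trial_dataset")
  expect_equal(nrow(ds$records), 0)
  expect_setequal(names(ds$records),
                  c("patient_id", "site_id", "copd", "haem", "open_system",
                    "sofa", "pf_ratio", "lactate", "norepi_dose",
                    "allocation", "dead_90d"))

  expect_error(generator_config(prob_copd = 1.2), "prob_copd")
  expect_error(generator_config(lactate_dist = list(meanlog = 0, sdlog = 0)),
               "lactate_dist")
  expect_error(generator_config(n_patients = 5, n_sites = 10), "n_sites")
  expect_error(generator_config(missing_rates = c(norepi_dose = 0.1)),
               "missing_rates")
})

test_that("generation is deterministic given the configuration seed", {
  cfg <- generator_config(n_patients = 500, seed = 77)
  d1 <- generate_trial(cfg)
  d2 <- generate_trial(cfg)
  expect_identical(d1$records, d2$records)
  d3 <- generate_trial(generator_config(n_patients = 500, seed = 78))
  expect_false(identical(d1$records, d3$records))
})

test_that("stratified allocation balances every stratum to within one", {
  rec2 <- make_records(2)
  al2 <- stratified_allocate(rec2, "site_id", seed = 1)
  expect_setequal(al2, c("lower", "higher"))

  rec101 <- make_records(101)
  al101 <- stratified_allocate(rec101, "site_id", seed = 2)
  expect_true(sort(table(al101))[1] == 50 && sort(table(al101))[2] == 51)

  expect_identical(stratified_allocate(make_records(0)[0, ], "site_id", seed = 1),
                   character(0))

  # 1000 patients over site x copd x haem strata: exhaustive balance check
  set.seed(11)
  rec <- make_records(1000, site_id = sample.int(35, 1000, TRUE),
                      copd = rbinom(1000, 1, 0.2),
                      haem = rbinom(1000, 1, 0.06))
  al <- stratified_allocate(rec, c("site_id", "copd", "haem"), seed = 3)
  st <- interaction(rec$site_id, rec$copd, rec$haem, drop = TRUE)
  imb <- tapply(al == "lower", st, function(x) abs(sum(x) - sum(!x)))
  expect_true(all(imb <= 1))

  expect_error(stratified_allocate(rec, "not_a_column"), "not_a_column")
})

test_that("null treatment effect yields near-identical arm mortality and logit recovery", {
  cfg <- generator_config(n_patients = 50000, treatment_log_or = 0,
                          covariate_log_ors = numeric(0),
                          missing_rates = numeric(0), seed = 5)
  rec <- generate_trial(cfg)$records
  p <- tapply(rec$dead_90d, rec$allocation, mean)
  expect_lt(abs(p[["lower"]] - p[["higher"]]), 0.01)

  # logistic consistency: with a non-null effect and no covariates, the
  # empirical log-OR recovers the generating value
  cfg2 <- generator_config(n_patients = 50000, treatment_log_or = 0.4,
                           covariate_log_ors = numeric(0),
                           site_intercept_sd = 0,
                           missing_rates = numeric(0), seed = 6)
  rec2 <- generate_trial(cfg2)$records
  est <- coef(glm(dead_90d ~ I(allocation == "lower"), binomial, rec2))[2]
  expect_lt(abs(est - 0.4), 0.05)
})

test_that("default configuration reproduces the target baseline table", {
  rec <- generate_trial(generator_config(seed = 4))$records
  expect_equal(nrow(rec), 2888)
  expect_lt(abs(median(rec$sofa, na.rm = TRUE) - 8) / 8, 0.15)
  expect_lt(abs(median(rec$lactate, na.rm = TRUE) - 1.8) / 1.8, 0.15)
  expect_lt(abs(median(rec$pf_ratio, na.rm = TRUE) - 15.8) / 15.8, 0.15)
  frac_vaso <- mean(rec$norepi_dose > 0)
  expect_gt(frac_vaso, 0.50); expect_lt(frac_vaso, 0.60)
  # exact point mass at zero for non-users
  expect_true(all(rec$norepi_dose >= 0))
  expect_true(any(rec$norepi_dose == 0))
  expect_true(all(rec$sofa >= 0 & rec$sofa <= 24, na.rm = TRUE))
  # mortality in the 42-43% neighbourhood
  expect_gt(mean(rec$dead_90d), 0.37); expect_lt(mean(rec$dead_90d), 0.48)
})

test_that("norepinephrine zero mass matches the non-user probability", {
  cfg <- generator_config(n_patients = 20000, missing_rates = numeric(0),
                          seed = 9)
  rec <- generate_trial(cfg)$records
  p0 <- mean(rec$norepi_dose == 0)
  expected <- 1 - cfg$prob_any_vasopressor
  se <- sqrt(expected * (1 - expected) / 20000)
  expect_lt(abs(p0 - expected), 4 * se)
})

test_that("missingness injection respects rates, identity and saturation", {
  ds <- generate_trial(generator_config(n_patients = 800,
                                        missing_rates = numeric(0), seed = 2))
  same <- inject_missingness(ds, numeric(0))
  expect_identical(same$records, ds$records)

  all_gone <- inject_missingness(ds, c(lactate = 1), seed = 3)
  expect_true(all(is.na(all_gone$records$lactate)))
  expect_false(anyNA(all_gone$records$allocation))
  expect_false(anyNA(all_gone$records$dead_90d))

  expect_error(inject_missingness(ds, c(allocation = 0.5)), "configuration")

  # default rates on n = 2888: counts within 3 SD of binomial expectation
  rates <- c(sofa = 89 / 2888, pf_ratio = 12 / 2888, lactate = 19 / 2888)
  big <- generate_trial(generator_config(seed = 21))
  for (v in names(rates)) {
    k <- sum(is.na(big$records[[v]]))
    mu <- 2888 * rates[[v]]
    expect_lt(abs(k - mu), 3 * sqrt(mu * (1 - rates[[v]])) + 1e-9)
  }
})

test_that("trial CSV round-trips with empty-field missing encoding", {
  ds <- generate_trial(generator_config(n_patients = 300, seed = 8))
  ds$records$lactate[5] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(ds, path)
  back <- read_trial_csv(path)
  expect_equal(back$records, ds$records, tolerance = 1e-12)
  expect_identical(back$config, "external")
  expect_true(is.na(back$records$lactate[5]))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,site_id\n1,1", bad)
  expect_error(read_trial_csv(bad), "missing required columns")
})
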