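# a hand-built posterior_draws object with known parameter columns
fake_fit <- function(alpha = 0, beta = 0, gamma_copd = 0, gamma_haem = 0,
                     kind = "primary", n_draws = 4) {
  len <- max(lengths(list(alpha, beta, gamma_copd, gamma_haem)), n_draws)
  mat <- cbind(alpha = rep_len(alpha, len), beta = rep_len(beta, len),
               gamma_copd = rep_len(gamma_copd, len),
               gamma_haem = rep_len(gamma_haem, len))
  f <- as_posterior_draws(mat, chains = 2)
  f$kind <- kind
  f
}
null_profile <- structure(list(copd = 0L, haem = 0L, site_id = 1L),
                          class = "covariate_profile")

test_that("modal covariate profile follows the tie-break rules", {
  rec <- make_records(10, copd = c(rep(1, 8), 0, 0),
                      haem = c(rep(1, 5), rep(0, 5)),       # 50/50 tie -> 0
                      open_system = c(rep(0, 7), rep(1, 3)),
                      site_id = c(rep(2L, 4), rep(7L, 4), 1L, 3L))
  prof <- most_common_profile(rec)
  expect_equal(prof$copd, 1L)
  expect_equal(prof$haem, 0L)          # tie broken toward reference
  expect_equal(prof$open_system, 0L)
  expect_equal(prof$site_id, 2)        # 4-4 tie broken toward smallest ID
  expect_error(most_common_profile(rec[0, ]), "empty")
})

test_that("standardized event probabilities follow inverse-logit arithmetic", {
  # alpha = 0, all coefficients 0 -> both arms at 0.5
  p_null <- standardized_event_probs(fake_fit(), null_profile)
  expect_true(all(p_null$p0 == 0.5) && all(p_null$p1 == 0.5))

  # alpha = 0, beta = log 2 -> p0 = 0.5, p1 = 2/3
  p2 <- standardized_event_probs(fake_fit(beta = log(2)), null_profile)
  expect_equal(unique(p2$p0), 0.5)
  expect_equal(unique(p2$p1), 2 / 3, tolerance = 1e-12)

  # monotonicity: every draw with beta > 0 has p1 > p0
  set.seed(10)
  f <- fake_fit(alpha = rnorm(200), beta = abs(rnorm(200)) + 1e-6,
                n_draws = 200)
  pp <- standardized_event_probs(f, null_profile)
  expect_true(all(pp$p1 > pp$p0))

  # missing profile term is a contract error naming the term
  expect_error(standardized_event_probs(fake_fit(),
                                        structure(list(copd = 0L),
                                                  class = "covariate_profile")),
               "haem")
})

test_that("effect summaries match a four-draw hand enumeration", {
  probs <- data.frame(p0 = c(0.4, 0.4, 0.5, 0.2), p1 = c(0.4, 0.5, 0.4, 0.4))
  es <- effect_summary(probs)
  # RDs are {0, 0.1, -0.1, 0.2}: median 0.05; exactly one draw has RR < 1
  expect_equal(unname(es$rd["median"]), 0.05)
  expect_equal(unname(es$prob_rr_below[["1.00"]]), 0.25)
  expect_equal(es$n_draws, 4L)
  # per-draw identities hold exactly
  expect_identical(es$draws$rd, probs$p1 - probs$p0)
  expect_identical(es$draws$rr, probs$p1 / probs$p0)
  expect_identical(es$draws$or, (probs$p1 / (1 - probs$p1)) /
                     (probs$p0 / (1 - probs$p0)))
})

test_that("identity draws and permutation invariance", {
  same <- data.frame(p0 = runif(50, 0.2, 0.6))
  same$p1 <- same$p0
  es <- effect_summary(same)
  expect_equal(unname(es$rr["median"]), 1)
  expect_equal(unname(es$rd["median"]), 0)
  expect_equal(unname(es$prob_rr_below[["0.80"]]), 0)

  set.seed(20)
  probs <- data.frame(p0 = runif(500, 0.3, 0.5), p1 = runif(500, 0.3, 0.5))
  e1 <- effect_summary(probs)
  e2 <- effect_summary(probs[sample.int(500), ])
  for (f in c("p0", "p1", "rr", "rd", "or"))
    expect_equal(e1[[f]], e2[[f]], tolerance = 1e-12)
  expect_equal(e1$prob_rr_below, e2$prob_rr_below)
})

test_that("threshold probability maps are monotone and complementary", {
  set.seed(21)
  probs <- data.frame(p0 = plogis(rnorm(2000, 0, 0.3)),
                      p1 = plogis(rnorm(2000, 0.1, 0.3)))
  es <- effect_summary(probs)
  expect_true(all(diff(es$prob_rr_below) >= 0))
  expect_true(all(diff(es$prob_rd_below) >= 0))
  rr <- es$draws$rr
  expect_equal(mean(rr < 1) + mean(rr >= 1), 1)
  expect_error(effect_summary(data.frame(p0 = c(0.4, 0), p1 = c(0.5, 0.5))),
               "p0")
})

test_that("threshold probabilities converge to the normal CDF", {
  # draws generated from a known normal log-OR at fixed p0 = 0.5
  set.seed(22)
  m <- -0.1; s <- 0.25
  lor <- rnorm(40000, m, s)
  probs <- data.frame(p0 = 0.5, p1 = plogis(qlogis(0.5) + lor))
  es <- effect_summary(probs)
  for (c_ in c(0.8, 1, 1.25)) {
    emp <- mean(es$draws$or < c_)
    expect_lt(abs(emp - pnorm((log(c_) - m) / s)), 0.01)
  }
})

test_that("interaction summaries report directional probabilities and curves", {
  set.seed(23)
  n <- 2000
  mat <- cbind(alpha = rnorm(n, 0, 0.05), beta = rnorm(n, 0, 0.05),
               gamma_copd = 0, gamma_haem = 0,
               delta = rnorm(n, 0, 0.02), eta = rnorm(n, 0, 0.1))
  f <- as_posterior_draws(mat, chains = 2)
  f$kind <- "interaction"
  f$meta <- list(variable = "lactate", x_mean = 2, x_sd = 1, x_range = c(0, 8))
  s <- interaction_summary(f, null_profile)
  expect_equal(s$prob_or_gt1 + s$prob_or_lt1 + s$prob_or_eq1, 1)
  expect_lt(abs(s$prob_or_gt1 - 0.5), 0.05)   # symmetric around zero
  expect_true(all(s$curve$median > 0 & s$curve$median < 1))
  expect_true(all(s$curve$lower <= s$curve$median &
                    s$curve$median <= s$curve$upper))
  expect_warning(interaction_summary(f, null_profile, grid = c(-5, 2)),
                 "outside")

  # degenerate point mass at zero interaction is reported separately
  mat0 <- mat; mat0[, "eta"] <- 0
  f0 <- as_posterior_draws(mat0, chains = 2)
  f0$kind <- "interaction"; f0$meta <- f$meta
  s0 <- interaction_summary(f0, null_profile)
  expect_equal(s0$prob_or_gt1, 0)
  expect_equal(s0$prob_or_lt1, 0)
  expect_equal(s0$prob_or_eq1, 1)

  # null point: zero draws everywhere -> both arms at 0.5 along the curve
  matn <- mat * 0
  fn <- as_posterior_draws(matn, chains = 2)
  fn$kind <- "interaction"; fn$meta <- f$meta
  sn <- interaction_summary(fn, null_profile)
  expect_true(all(sn$curve$median == 0.5))
})

test_that("subgroup summaries assemble a five-row effect table", {
  rec <- make_subgroup_data(1500, beta_g = c(-0.3, 0, 0.1, 0.3, 0.5), seed = 30)
  scheme <- quintile_subgroups(rec$xvar, variable = "xvar")
  fit <- fit_subgroup_hte(rec, scheme, quick_spec("subgroup", warmup = 200,
                                                  draws = 250, seed = 12))
  prof <- most_common_profile(rec, fit)
  ss <- summarize_subgroups(fit, prof)
  expect_equal(nrow(ss$table), 5)
  expect_equal(sum(ss$table$n), nrow(rec))
  expect_length(ss$summaries, 5)
  # per-subgroup identities inherited from effect_summary
  s1 <- ss$summaries[[1]]
  expect_identical(s1$draws$rd, s1$draws$p1 - s1$draws$p0)
  # CrI ordering for every reported quantity
  with(ss$table, {
    expect_true(all(rr_lo <= rr_med & rr_med <= rr_hi))
    expect_true(all(rd_lo <= rd_med & rd_med <= rd_hi))
  })
})
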