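test_that("model_spec validates its invariants", {
  expect_error(model_spec("primary", chains = 1), "chains")
  expect_error(model_spec("primary", draws = 0), "draw")
  expect_error(fit_continuous_interaction(make_toy_trial(), variable = NULL),
               "interaction variable")
  s <- model_spec("interaction", interaction_variable = "lactate")
  expect_identical(s$interaction_variable, "lactate")
})

test_that("with no data the posterior reproduces the treatment prior", {
  empty <- make_records(0)[0, ]
  spec <- model_spec("primary", prior = sceptic_prior(), chains = 4,
                     warmup = 300, draws = 5000, seed = 2)
  fit <- fit_primary(empty, spec)
  expect_equal(nrow(fit$draws), 20000)
  b <- fit$draws[, "beta"]
  expect_lt(abs(mean(b) - 0), 0.02)
  expect_lt(abs(sd(b) / 0.355 - 1), 0.05)
})

test_that("sampling is deterministic given dataset, spec and seed", {
  rec <- make_toy_trial()
  f1 <- fit_primary(rec, quick_spec("primary", warmup = 150, draws = 100,
                                    seed = 5))
  f2 <- fit_primary(rec, quick_spec("primary", warmup = 150, draws = 100,
                                    seed = 5))
  f3 <- fit_primary(rec, quick_spec("primary", warmup = 150, draws = 100,
                                    seed = 6))
  expect_identical(f1$draws, f2$draws)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("posterior concentrates near the MLE with weak priors", {
  set.seed(31)
  rec <- make_records(3000, site_id = sample.int(10, 3000, TRUE),
                      copd = rbinom(3000, 1, 0.2),
                      haem = rbinom(3000, 1, 0.06))
  lp <- -0.4 + 0.3 * (rec$allocation == "lower") + 0.2 * rec$copd
  rec$dead_90d <- rbinom(3000, 1, plogis(lp))
  fit <- fit_primary(rec, quick_spec("primary", seed = 3))
  est <- coef(glm(dead_90d ~ I(allocation == "lower") + copd + haem,
                  binomial, rec))[2]
  expect_lt(abs(median(fit$draws[, "beta"]) - est), 0.05)
  expect_true(all(c("sigma_site", "u_site[1]") %in% colnames(fit$draws)))
})

test_that("the primary posterior is invariant to site relabelling", {
  set.seed(41)
  rec <- make_records(2500, site_id = sample.int(8, 2500, TRUE),
                      copd = rbinom(2500, 1, 0.2))
  rec$dead_90d <- rbinom(2500, 1, plogis(-0.3 + 0.25 * (rec$allocation == "lower")))
  f1 <- fit_primary(rec, quick_spec("primary", seed = 4))
  rec2 <- rec
  rec2$site_id <- 9L - rec2$site_id  # reverse the labels
  f2 <- fit_primary(rec2, quick_spec("primary", seed = 4))
  expect_lt(abs(median(f1$draws[, "beta"]) - median(f2$draws[, "beta"])), 0.04)
})

test_that("HMC posterior matches JAGS on a small hierarchical model", {
  set.seed(51)
  rec <- make_records(600, site_id = sample.int(6, 600, TRUE),
                      copd = rbinom(600, 1, 0.25),
                      haem = rbinom(600, 1, 0.1))
  rec$dead_90d <- rbinom(600, 1, plogis(-0.2 + 0.4 * (rec$allocation == "lower") +
                                          0.3 * rec$copd))
  fit <- fit_primary(rec, quick_spec("primary", warmup = 500, draws = 2000,
                                     seed = 7))

  model_str <- "
  model {
    for (i in 1:n) {
      y[i] ~ dbern(p[i])
      logit(p[i]) <- alpha + beta*tr[i] + g1*copd[i] + g2*haem[i] + u[site[i]]
    }
    for (s in 1:S) { u[s] ~ dnorm(0, tau_u) }
    tau_u <- pow(sd_u, -2)
    sd_u ~ dnorm(0, 1) T(0,)
    alpha ~ dnorm(0, 0.16)
    beta ~ dnorm(0, 1)
    g1 ~ dnorm(0, 1)
    g2 ~ dnorm(0, 1)
  }"
  jm <- rjags::jags.model(textConnection(model_str),
                          data = list(y = rec$dead_90d,
                                      tr = as.integer(rec$allocation == "lower"),
                                      copd = rec$copd, haem = rec$haem,
                                      site = rec$site_id, n = 600, S = 6),
                          n.chains = 2, n.adapt = 500, quiet = TRUE,
                          inits = list(
                            list(.RNG.name = "base::Mersenne-Twister",
                                 .RNG.seed = 1),
                            list(.RNG.name = "base::Mersenne-Twister",
                                 .RNG.seed = 2)))
  update(jm, 500, progress.bar = "none")
  sm <- rjags::coda.samples(jm, "beta", n.iter = 3000, progress.bar = "none")
  jags_beta <- unlist(sm)
  expect_lt(abs(mean(fit$draws[, "beta"]) - mean(jags_beta)), 0.05)
  expect_lt(abs(sd(fit$draws[, "beta"]) - sd(jags_beta)), 0.03)
})

test_that("subgroup fits expose partial pooling structure and edge warnings", {
  rec <- make_subgroup_data(1500, beta_g = rep(0.2, 5), seed = 61)
  scheme <- quintile_subgroups(rec$xvar, variable = "xvar")
  fit <- fit_subgroup_hte(rec, scheme, quick_spec("subgroup", draws = 300,
                                                  seed = 8))
  expect_identical(fit$kind, "subgroup")
  expect_true(all(c("sigma_a", "sigma_b", "a_sub[1]", "b_sub[5]") %in%
                    colnames(fit$draws)))
  # complete-pooling limit: forcing sigma_b ~ 0 collapses subgroup effects
  fit0 <- fit_subgroup_hte(rec, scheme,
                           quick_spec("subgroup", draws = 300, seed = 9,
                                      subgroup_effect_scale = 1e-3))
  bspread <- max(abs(vapply(1:5, function(g)
    median(fit0$draws[, paste0("b_sub[", g, "]")]), numeric(1))))
  expect_lt(bspread, 0.005)

  # a subgroup absent from one arm triggers a warning, not an error
  rec_bad <- rec[!(rec$xvar == 5 & rec$allocation == "lower"), ]
  expect_warning(fit_subgroup_hte(rec_bad, scheme,
                                  quick_spec("subgroup", warmup = 100,
                                             draws = 50, seed = 10)),
                 "zero patients")
})

test_that("interaction fits adjust for the oxygen system only for PF ratio", {
  set.seed(71)
  rec <- make_records(1200, copd = rbinom(1200, 1, 0.2),
                      open_system = rbinom(1200, 1, 0.3),
                      lactate = rlnorm(1200, 0.5, 0.7),
                      pf_ratio = rlnorm(1200, log(15), 0.4))
  rec$dead_90d <- rbinom(1200, 1, plogis(-0.3 + 0.1 * rec$lactate))
  sp <- quick_spec("interaction", warmup = 200, draws = 200, seed = 11)
  f_lac <- fit_continuous_interaction(rec, "lactate", sp)
  f_pf <- fit_continuous_interaction(rec, "pf_ratio", sp)
  expect_false("gamma_open" %in% colnames(f_lac$draws))
  expect_true("gamma_open" %in% colnames(f_pf$draws))
  expect_true(all(c("delta", "eta") %in% colnames(f_lac$draws)))

  rec$sofa <- 8L
  expect_error(fit_continuous_interaction(rec, "sofa", sp), "constant")
})

test_that("non-binary outcomes are rejected", {
  rec <- make_toy_trial()
  rec$dead_90d[1] <- 2L
  expect_error(fit_primary(rec, quick_spec("primary")), "non-binary")
})
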