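#' Declarative specification of a Bayesian logistic analysis model
#'
#' Describes one of the three analysis models and its sampler settings:
#'
#' * `primary`: `logit P(death) = alpha + beta T + gamma_copd COPD +
#'   gamma_haem HAEM + u_site`, with partially pooled site intercepts
#'   `u_s ~ Normal(0, sigma_site)`.
#' * `subgroup`: adds partially pooled subgroup intercepts `a_g` and
#'   subgroup treatment effects `b_g`, so the per-subgroup treatment
#'   log-OR is `beta + b_g`.
#' * `interaction`: adds a continuous covariate slope `delta` and a
#'   treatment-by-covariate interaction `eta` (linear on the log-OR
#'   scale); the covariate is standardized internally and effects are
#'   reported per original unit.
#'
#' The treatment prior is a [prior_spec()] on the log-OR. Nuisance priors
#' are weakly informative: Normal(0, `intercept_scale`) for the intercept,
#' Normal(0, `coef_scale`) for binary/continuous adjustment coefficients,
#' half-Normal scales for the pooled standard deviations. Default sampler
#' settings are 4 chains with 5000 warm-up and 5000 post-warm-up draws per
#' chain (20 000 recorded draws); tests and quick runs should reduce them.
#'
#' @param kind `"primary"`, `"subgroup"` or `"interaction"`.
#' @param prior treatment-effect prior, a [prior_spec()].
#' @param chains number of chains (>= 2).
#' @param warmup,draws warm-up and post-warm-up iterations per chain.
#' @param seed integer seed for the sampler.
#' @param target_accept dual-averaging target acceptance statistic.
#' @param max_leapfrog maximum leapfrog steps per trajectory (the actual
#'   number is jittered uniformly on 1..`max_leapfrog`).
#' @param intercept_scale,coef_scale,site_scale,subgroup_intercept_scale,subgroup_effect_scale
#'   prior scales (log-odds units) for the intercept, adjustment/slope
#'   coefficients, and the half-normal hyperpriors on `sigma_site`,
#'   `sigma_a`, `sigma_b`.
#' @param subgroup_intercepts include the pooled subgroup intercepts `a_g`
#'   in subgroup models (set `FALSE` to model subgroup-varying treatment
#'   effects only).
#' @param interaction_variable covariate for `interaction` models (one of
#'   `sofa`, `pf_ratio`, `lactate`, `norepi_dose`).
#' @param adjust_open_system adjust for the oxygen-system type; default
#'   (`NULL`) adds it exactly when the interaction variable is `pf_ratio`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("primary", "subgroup", "interaction"),
                       prior = weakly_informative_prior(),
                       chains = 4L, warmup = 5000L, draws = 5000L,
                       seed = 1L, target_accept = 0.8, max_leapfrog = 20L,
                       intercept_scale = 2.5, coef_scale = 1,
                       site_scale = 1,
                       subgroup_intercept_scale = 0.5,
                       subgroup_effect_scale = 0.5,
                       subgroup_intercepts = TRUE,
                       interaction_variable = NULL,
                       adjust_open_system = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(prior, "prior_spec"))
  if (chains < 2) stop("at least 2 chains are required", call. = FALSE)
  if (draws < 1) stop("at least 1 post-warm-up draw is required", call. = FALSE)
  if (warmup < 0) stop("warmup must be >= 0", call. = FALSE)
  if (!is.null(interaction_variable))
    interaction_variable <- match.arg(interaction_variable,
                                      c("sofa", "pf_ratio", "lactate",
                                        "norepi_dose"))
  structure(list(kind = kind, prior = prior, chains = as.integer(chains),
                 warmup = as.integer(warmup), draws = as.integer(draws),
                 seed = as.integer(seed), target_accept = target_accept,
                 max_leapfrog = as.integer(max_leapfrog),
                 intercept_scale = intercept_scale, coef_scale = coef_scale,
                 site_scale = site_scale,
                 subgroup_intercept_scale = subgroup_intercept_scale,
                 subgroup_effect_scale = subgroup_effect_scale,
                 subgroup_intercepts = isTRUE(subgroup_intercepts),
                 interaction_variable = interaction_variable,
                 adjust_open_system = adjust_open_system),
            class = "model_spec")
}

# ---- internal: data preparation -------------------------------------------

check_outcome <- function(rec) {
  if (!all(rec$dead_90d %in% c(0L, 1L)))
    stop("non-binary outcome: `dead_90d` must be 0/1", call. = FALSE)
  bad <- setdiff(unique(rec$allocation), c("lower", "higher"))
  if (length(bad))
    stop("allocation must be 'lower' or 'higher'", call. = FALSE)
}

# complete cases over `vars`; returns records plus treatment indicator
prep_records <- function(dataset, vars) {
  rec <- trial_records(dataset)
  if (nrow(rec)) {
    rec <- rec[complete.cases(rec[, intersect(vars, names(rec)), drop = FALSE]), ,
               drop = FALSE]
    check_outcome(rec)
  }
  rec$treat <- as.integer(rec$allocation == "lower")
  rec
}

site_block <- function(rec, spec) {
  levels <- sort(unique(rec$site_id))
  if (length(levels) < 2) return(list(block = NULL, levels = levels))
  list(block = list(g = match(rec$site_id, levels),
                    mult = rep(1, nrow(rec)),
                    m = length(levels), scale = spec$site_scale),
       levels = levels)
}

# ---- internal: sampler driver ---------------------------------------------

run_sampler <- function(y, X, prior_mean, prior_sd, blocks, spec) {
  dim_ <- ncol(X) + sum(vapply(blocks, function(b) b$m + 1L, integer(1)))
  with_seed(spec$seed, {
    chains <- vector("list", spec$chains)
    for (ch in seq_len(spec$chains)) {
      init <- c(prior_mean + 0.1 * rnorm(ncol(X)),
                unlist(lapply(blocks, function(b)
                  c(0.1 * rnorm(b$m), log(b$scale / 2) + 0.1 * rnorm(1)))))
      if (length(init) == 0) init <- numeric(0)
      chains[[ch]] <- hmc_chain(X, y, prior_mean, prior_sd, blocks,
                                spec$warmup, spec$draws, spec$target_accept,
                                spec$max_leapfrog, init)
    }
    chains
  })
}

# Transform raw sampler output into a named draw matrix. `fixed_names` names
# the columns of X; each element of `block_names` is list(effects=..,
# sigma=..) naming the transformed random effects (sigma * z) and the scale.
assemble_draws <- function(chains, fixed_names, blocks, block_names) {
  raw <- do.call(rbind, lapply(chains, `[[`, "draws"))
  d <- length(fixed_names)
  cols <- list()
  for (j in seq_len(d)) cols[[fixed_names[j]]] <- raw[, j, drop = TRUE]
  off <- d
  for (k in seq_along(blocks)) {
    m <- blocks[[k]]$m
    sigma <- exp(raw[, off + m + 1, drop = TRUE])
    for (j in seq_len(m))
      cols[[block_names[[k]]$effects[j]]] <- sigma * raw[, off + j, drop = TRUE]
    cols[[block_names[[k]]$sigma]] <- sigma
    off <- off + m + 1
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(cols)
  mat
}

new_posterior_draws <- function(draws, spec, divergences, accept_rate,
                                step_size, meta) {
  structure(list(draws = draws, chains = spec$chains,
                 warmup = spec$warmup, draws_per_chain = spec$draws,
                 kind = spec$kind, prior = spec$prior,
                 divergences = divergences, accept_rate = accept_rate,
                 step_size = step_size, meta = meta, spec = spec),
            class = "posterior_draws")
}

#' Construct a posterior_draws object from a plain draw matrix
#'
#' Mainly for diagnostics of externally produced draws and for tests. Rows
#' must be ordered chain-major (all draws of chain 1, then chain 2, ...).
#'
#' @param draws numeric matrix with named columns.
#' @param chains number of chains the rows represent.
#' @param divergences divergence count.
#' @return A `posterior_draws` object.
#' @export
as_posterior_draws <- function(draws, chains, divergences = 0L) {
  draws <- as.matrix(draws)
  if (nrow(draws) %% chains != 0)
    stop("number of rows must be a multiple of `chains`", call. = FALSE)
  structure(list(draws = draws, chains = as.integer(chains),
                 warmup = NA_integer_, draws_per_chain = nrow(draws) %/% chains,
                 kind = "external", prior = NULL,
                 divergences = as.integer(divergences), accept_rate = NA_real_,
                 step_size = NA_real_, meta = list(), spec = NULL),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws '%s'> %d draws (%d chains x %d), %d parameters, %d divergence(s)\n",
              x$kind, nrow(x$draws), x$chains, x$draws_per_chain,
              ncol(x$draws), x$divergences))
  invisible(x)
}

finish_fit <- function(chains, spec, fixed_names, blocks, block_names, meta) {
  draws <- assemble_draws(chains, fixed_names, blocks, block_names)
  new_posterior_draws(draws, spec,
                      divergences = sum(vapply(chains, `[[`, numeric(1),
                                               "divergences")),
                      accept_rate = mean(vapply(chains, `[[`, numeric(1),
                                                "accept_rate")),
                      step_size = vapply(chains, `[[`, numeric(1), "step_size"),
                      meta = meta)
}

# ---- fits ------------------------------------------------------------------

#' Fit the primary adjusted Bayesian logistic regression model
#'
#' Samples from `logit P(death_i) = alpha + beta T_i + gamma_copd COPD_i +
#' gamma_haem HAEM_i + u_site(i)`, `u_s ~ Normal(0, sigma_site)`, with the
#' supplied prior on the treatment log-OR `beta`. Complete cases over the
#' model variables are used. With a single site (or none, for an empty
#' dataset) the site term is dropped; with an empty dataset the posterior
#' reproduces the priors.
#'
#' @param dataset a `trial_dataset` or records data.frame.
#' @param spec a [model_spec()] of kind `primary`.
#' @return A `posterior_draws` object.
#' @export
fit_primary <- function(dataset, spec = model_spec("primary")) {
  stopifnot(inherits(spec, "model_spec"))
  rec <- prep_records(dataset, c("dead_90d", "allocation", "copd", "haem",
                                 "site_id"))
  n <- nrow(rec)
  X <- cbind(alpha = rep(1, n), beta = rec$treat, gamma_copd = rec$copd,
             gamma_haem = rec$haem)
  if (n == 0) X <- matrix(numeric(0), nrow = 0, ncol = 4)
  pm <- c(0, spec$prior$mean, 0, 0)
  ps <- c(spec$intercept_scale, spec$prior$sd, spec$coef_scale, spec$coef_scale)
  sb <- site_block(rec, spec)
  blocks <- if (is.null(sb$block)) list() else list(sb$block)
  block_names <- if (is.null(sb$block)) list() else
    list(list(effects = paste0("u_site[", sb$levels, "]"),
              sigma = "sigma_site"))
  chains <- run_sampler(rec$dead_90d, X, pm, ps, blocks, spec)
  finish_fit(chains, spec, c("alpha", "beta", "gamma_copd", "gamma_haem"),
             blocks, block_names,
             meta = list(n = n, site_levels = sb$levels,
                         arm_n = c(lower = sum(rec$treat == 1L),
                                   higher = sum(rec$treat == 0L))))
}

#' Fit the hierarchical subgroup heterogeneity model
#'
#' Samples from `logit P = alpha + a_g(i) + (beta + b_g(i)) T_i +
#' gamma_copd COPD + gamma_haem HAEM + u_site`, with partial pooling
#' `a_g ~ Normal(0, sigma_a)`, `b_g ~ Normal(0, sigma_b)`. The per-subgroup
#' treatment log-OR is `beta + b_g`; shrinkage pulls noisy subgroup
#' estimates toward the overall effect.
#'
#' @param dataset a `trial_dataset` or records data.frame.
#' @param scheme a [quintile_subgroups()] scheme over one of the dataset's
#'   baseline variables.
#' @param spec a [model_spec()]; its `kind` is coerced to `subgroup`.
#' @return A `posterior_draws` object; `meta$scheme` keeps the scheme and
#'   `meta$subgroup_n` the per-subgroup arm counts.
#' @export
fit_subgroup_hte <- function(dataset, scheme, spec = model_spec("subgroup")) {
  stopifnot(inherits(spec, "model_spec"), inherits(scheme, "subgroup_scheme"))
  spec$kind <- "subgroup"
  v <- scheme$variable
  rec <- prep_records(dataset, c("dead_90d", "allocation", "copd", "haem",
                                 "site_id", v))
  if (!v %in% names(rec))
    stop("subgroup variable `", v, "` not found in dataset", call. = FALSE)
  n <- nrow(rec)
  grp <- assign_subgroup(scheme, rec[[v]], warn = FALSE)
  G <- length(scheme$labels)

  cross <- table(factor(grp, levels = seq_len(G)),
                 factor(rec$treat, levels = 0:1))
  if (any(cross == 0))
    warning("subgroup(s) with zero patients in an arm: ",
            paste(scheme$labels[rowSums(cross == 0) > 0], collapse = ", "),
            "; their effects are informed by pooling alone")

  X <- cbind(alpha = rep(1, n), beta = rec$treat, gamma_copd = rec$copd,
             gamma_haem = rec$haem)
  pm <- c(0, spec$prior$mean, 0, 0)
  ps <- c(spec$intercept_scale, spec$prior$sd, spec$coef_scale, spec$coef_scale)

  sb <- site_block(rec, spec)
  blocks <- list()
  block_names <- list()
  if (!is.null(sb$block)) {
    blocks <- c(blocks, list(sb$block))
    block_names <- c(block_names,
                     list(list(effects = paste0("u_site[", sb$levels, "]"),
                               sigma = "sigma_site")))
  }
  if (spec$subgroup_intercepts) {
    blocks <- c(blocks, list(list(g = grp, mult = rep(1, n), m = G,
                                  scale = spec$subgroup_intercept_scale)))
    block_names <- c(block_names,
                     list(list(effects = paste0("a_sub[", seq_len(G), "]"),
                               sigma = "sigma_a")))
  }
  blocks <- c(blocks, list(list(g = grp, mult = as.numeric(rec$treat), m = G,
                                scale = spec$subgroup_effect_scale)))
  block_names <- c(block_names,
                   list(list(effects = paste0("b_sub[", seq_len(G), "]"),
                             sigma = "sigma_b")))

  chains <- run_sampler(rec$dead_90d, X, pm, ps, blocks, spec)
  finish_fit(chains, spec, c("alpha", "beta", "gamma_copd", "gamma_haem"),
             blocks, block_names,
             meta = list(n = n, site_levels = sb$levels, scheme = scheme,
                         subgroup_n = cross))
}

#' Fit the continuous treatment-covariate interaction model
#'
#' Samples from `logit P = alpha + beta T + delta x + eta (T x) +
#' gamma_copd COPD + gamma_haem HAEM + u_site`, linear on the log-OR scale,
#' with additional adjustment for the oxygen-supplementation system
#' (`gamma_open`) exactly when the covariate is the PaO2:FiO2 ratio. The
#' covariate is standardized internally for sampler geometry; `delta`,
#' `eta`, `alpha` and `beta` in the returned draws are back-transformed so
#' the linear predictor reads directly in original units of `x` (and `beta`
#' is the treatment log-OR at `x = 0`).
#'
#' @param dataset a `trial_dataset` or records data.frame.
#' @param variable one of `sofa`, `pf_ratio`, `lactate`, `norepi_dose`.
#' @param spec a [model_spec()]; its `kind` is coerced to `interaction`.
#' @return A `posterior_draws` object; `meta` records the covariate's mean,
#'   SD and observed range.
#' @export
fit_continuous_interaction <- function(dataset, variable = spec$interaction_variable,
                                       spec = model_spec("interaction")) {
  stopifnot(inherits(spec, "model_spec"))
  spec$kind <- "interaction"
  if (is.null(variable))
    stop("interaction models require an interaction variable", call. = FALSE)
  variable <- match.arg(variable, c("sofa", "pf_ratio", "lactate",
                                    "norepi_dose"))
  spec$interaction_variable <- variable
  add_open <- spec$adjust_open_system %||% (variable == "pf_ratio")
  vars <- c("dead_90d", "allocation", "copd", "haem", "site_id", variable,
            if (add_open) "open_system")
  rec <- prep_records(dataset, vars)
  n <- nrow(rec)
  if (n == 0) stop("no complete cases for the interaction model", call. = FALSE)
  x <- rec[[variable]]
  m <- mean(x); s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("interaction variable `", variable,
         "` is constant; the interaction is unidentifiable", call. = FALSE)
  xs <- (x - m) / s

  fixed_names <- c("alpha", "beta", "gamma_copd", "gamma_haem",
                   if (add_open) "gamma_open", "delta", "eta")
  X <- cbind(rep(1, n), rec$treat, rec$copd, rec$haem,
             if (add_open) rec$open_system, xs, rec$treat * xs)
  colnames(X) <- fixed_names
  pm <- c(0, spec$prior$mean, 0, 0, if (add_open) 0, 0, 0)
  ps <- c(spec$intercept_scale, spec$prior$sd, spec$coef_scale,
          spec$coef_scale, if (add_open) spec$coef_scale,
          spec$coef_scale, spec$coef_scale)

  sb <- site_block(rec, spec)
  blocks <- if (is.null(sb$block)) list() else list(sb$block)
  block_names <- if (is.null(sb$block)) list() else
    list(list(effects = paste0("u_site[", sb$levels, "]"),
              sigma = "sigma_site"))

  chains <- run_sampler(rec$dead_90d, X, pm, ps, blocks, spec)
  fit <- finish_fit(chains, spec, fixed_names, blocks, block_names,
                    meta = list(n = n, site_levels = sb$levels,
                                variable = variable, x_mean = m, x_sd = s,
                                x_range = range(x), has_open = add_open))

  # back-transform standardized-scale draws to original units of x
  dr <- fit$draws
  delta_s <- dr[, "delta"]; eta_s <- dr[, "eta"]
  dr[, "alpha"] <- dr[, "alpha"] - delta_s * m / s
  dr[, "beta"] <- dr[, "beta"] - eta_s * m / s
  dr[, "delta"] <- delta_s / s
  dr[, "eta"] <- eta_s / s
  fit$draws <- dr
  fit
}

# ---- persistence -----------------------------------------------------------

#' Persist posterior draws and diagnostics as CSV
#'
#' `write_draws` writes one row per post-warm-up draw and one column per
#' parameter (plus a `chain` column); `write_diagnostics` writes the
#' per-parameter diagnostics table with the divergence count and verdict in
#' comment-free extra columns.
#'
#' @param fit a `posterior_draws` object.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "posterior_draws"))
  df <- data.frame(chain = rep(seq_len(fit$chains), each = fit$draws_per_chain),
                   fit$draws, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_draws
#' @param diag an `mcmc_diagnostics` object from [diagnostics()].
#' @export
write_diagnostics <- function(diag, path) {
  stopifnot(inherits(diag, "mcmc_diagnostics"))
  df <- diag$parameters
  df$divergences <- diag$divergences
  df$acceptable <- diag$acceptable
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
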