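#' Most common covariate profile for posterior standardization
#'
#' Adjusted event probabilities are reported at the modal level of every
#' adjustment variable (the "most common value" convention): COPD and
#' haematological malignancy at their modal 0/1 level (ties broken toward
#' 0), the site at the most frequent site ID (ties toward the smallest ID),
#' and, where the model adjusts for it, the oxygen-system type at its modal
#' level.
#'
#' @param dataset a `trial_dataset` or records data.frame (the data the
#'   model was fitted to).
#' @param fit optionally, the fitted `posterior_draws`; used to decide
#'   whether an `open_system` level is needed.
#' @return An object of class `covariate_profile` (named list).
#' @export
most_common_profile <- function(dataset, fit = NULL) {
  rec <- trial_records(dataset)
  if (nrow(rec) == 0) stop("cannot take modes of an empty dataset", call. = FALSE)
  mode_binary <- function(x) {
    x <- x[!is.na(x)]
    if (sum(x == 1) > sum(x == 0)) 1L else 0L  # ties toward reference 0
  }
  mode_site <- function(s) {
    tab <- table(s)
    ids <- names(tab)[tab == max(tab)]
    v <- sort(ids)[1]
    if (is.numeric(s)) as.numeric(v) else v
  }
  prof <- list(copd = mode_binary(rec$copd), haem = mode_binary(rec$haem),
               site_id = mode_site(rec$site_id))
  need_open <- if (!is.null(fit)) isTRUE(fit$meta$has_open) ||
    "gamma_open" %in% colnames(fit$draws) else TRUE
  if (need_open && "open_system" %in% names(rec))
    prof$open_system <- mode_binary(rec$open_system)
  structure(prof, class = "covariate_profile")
}

#' Per-draw standardized event probabilities
#'
#' For every posterior draw, evaluates the model's event probability at the
#' fixed covariate profile under both arms: `p0` (higher-oxygenation,
#' control) and `p1` (lower-oxygenation, treated). For subgroup models the
#' probabilities are computed within a subgroup using `(beta + b_g, a_g)`;
#' for interaction models the covariate is fixed at `x` (its fitted mean by
#' default).
#'
#' @param fit a `posterior_draws` object from one of the fit functions.
#' @param profile a [most_common_profile()] (or compatible named list).
#' @param subgroup integer subgroup index for subgroup fits; `NULL` gives
#'   the overall (pooled mean) effect.
#' @param x covariate value for interaction fits.
#' @return data.frame with one row per draw and columns `p0`, `p1`.
#' @export
standardized_event_probs <- function(fit, profile, subgroup = NULL, x = NULL) {
  stopifnot(inherits(fit, "posterior_draws"))
  dr <- fit$draws
  need <- function(term) {
    if (is.null(profile[[term]]))
      stop("profile is missing required term `", term, "`", call. = FALSE)
    profile[[term]]
  }
  lp0 <- dr[, "alpha"] + dr[, "gamma_copd"] * need("copd") +
    dr[, "gamma_haem"] * need("haem")
  if ("gamma_open" %in% colnames(dr))
    lp0 <- lp0 + dr[, "gamma_open"] * need("open_system")
  if ("sigma_site" %in% colnames(dr)) {
    site <- need("site_id")
    ucol <- paste0("u_site[", site, "]")
    if (!ucol %in% colnames(dr))
      stop("profile site `", site, "` was not among the fitted sites",
           call. = FALSE)
    lp0 <- lp0 + dr[, ucol]
  }
  beta_eff <- dr[, "beta"]
  if (fit$kind == "subgroup" && !is.null(subgroup)) {
    g <- as.integer(subgroup)
    acol <- paste0("a_sub[", g, "]"); bcol <- paste0("b_sub[", g, "]")
    if (!bcol %in% colnames(dr))
      stop("subgroup index ", g, " not present in the fit", call. = FALSE)
    if (acol %in% colnames(dr)) lp0 <- lp0 + dr[, acol]
    beta_eff <- beta_eff + dr[, bcol]
  }
  if (fit$kind == "interaction") {
    xv <- x %||% fit$meta$x_mean
    lp0 <- lp0 + dr[, "delta"] * xv
    beta_eff <- beta_eff + dr[, "eta"] * xv
  }
  data.frame(p0 = plogis(lp0), p1 = plogis(lp0 + beta_eff))
}

default_rr_thresholds <- c(0.67, 0.80, 0.90, 1.00, 1.11, 1.25, 1.50)
default_rd_thresholds <- c(-0.05, -0.02, 0, 0.02, 0.05)

#' Summarize per-draw event probabilities into effect measures
#'
#' Computes, per draw, RD = p1 - p0, RR = p1/p0 and OR =
#' (p1/(1-p1))/(p0/(1-p0)) — exact identities for every retained draw —
#' then reports medians with percentile-based 95% credible intervals and
#' the posterior probabilities of lying below each threshold (equality,
#' which has measure zero for continuous posteriors, counts with the lower
#' side: probabilities are P(RR < c), P(RD < c)).
#'
#' @param probs data.frame/matrix with per-draw columns `p0`, `p1` (from
#'   [standardized_event_probs()]).
#' @param rr_thresholds,rd_thresholds threshold vectors (RD thresholds on
#'   the probability scale, e.g. `-0.02` for -2 percentage points).
#' @return An object of class `effect_summary`.
#' @export
effect_summary <- function(probs, rr_thresholds = default_rr_thresholds,
                           rd_thresholds = default_rd_thresholds) {
  probs <- as.data.frame(probs)
  if (nrow(probs) < 1) stop("at least one draw is required", call. = FALSE)
  p0 <- probs$p0; p1 <- probs$p1
  if (any(p0 == 0))
    stop("RR undefined: some draws have p0 = 0", call. = FALSE)
  rr <- p1 / p0
  rd <- p1 - p0
  or <- (p1 / (1 - p1)) / (p0 / (1 - p0))
  qfun <- function(x) {
    q <- quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
    c(median = q[1], lower = q[2], upper = q[3])
  }
  structure(list(p0 = qfun(p0), p1 = qfun(p1), rr = qfun(rr), rd = qfun(rd),
                 or = qfun(or),
                 prob_rr_below = setNames(vapply(rr_thresholds,
                                                 function(c_) mean(rr < c_),
                                                 numeric(1)),
                                          format(rr_thresholds)),
                 prob_rd_below = setNames(vapply(rd_thresholds,
                                                 function(c_) mean(rd < c_),
                                                 numeric(1)),
                                          format(rd_thresholds)),
                 n_draws = length(rr),
                 draws = list(p0 = p0, p1 = p1, rr = rr, rd = rd, or = or)),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  f <- function(v, d = 2) sprintf(paste0("%.", d, "f (95%% CrI: %.", d,
                                         "f-%.", d, "f)"),
                                  v[1], v[2], v[3])
  cat("<effect_summary> ", x$n_draws, " draws\n", sep = "")
  cat("  P(event | lower):  ", f(100 * x$p1, 1), "%\n", sep = "")
  cat("  P(event | higher): ", f(100 * x$p0, 1), "%\n", sep = "")
  cat("  RR: ", f(x$rr), "   RD: ", f(100 * x$rd, 1), " pp   OR: ",
      f(x$or), "\n", sep = "")
  cat("  P(RR < 1.00) = ", sprintf("%.3f", mean(x$draws$rr < 1)), "\n",
      sep = "")
  invisible(x)
}

#' Subgroup effect table
#'
#' Applies [standardized_event_probs()] and [effect_summary()] within every
#' subgroup of a hierarchical subgroup fit, returning a per-subgroup table
#' mirroring the trial-report layout (group label, n, per-arm event
#' probabilities, RR, RD, OR, each with 95% CrI).
#'
#' @param fit a subgroup `posterior_draws` from [fit_subgroup_hte()].
#' @param profile a [most_common_profile()].
#' @param rr_thresholds,rd_thresholds passed to [effect_summary()].
#' @return list with `table` (data.frame) and `summaries` (per-subgroup
#'   `effect_summary` objects, named by group label).
#' @export
summarize_subgroups <- function(fit, profile,
                                rr_thresholds = default_rr_thresholds,
                                rd_thresholds = default_rd_thresholds) {
  stopifnot(inherits(fit, "posterior_draws"), fit$kind == "subgroup")
  scheme <- fit$meta$scheme
  G <- length(scheme$labels)
  n_g <- rowSums(fit$meta$subgroup_n)
  sums <- lapply(seq_len(G), function(g)
    effect_summary(standardized_event_probs(fit, profile, subgroup = g),
                   rr_thresholds, rd_thresholds))
  names(sums) <- scheme$labels
  row <- function(g) {
    s <- sums[[g]]
    data.frame(group = g, label = scheme$labels[g], n = n_g[g],
               p_lower_med = s$p1[1], p_lower_lo = s$p1[2], p_lower_hi = s$p1[3],
               p_higher_med = s$p0[1], p_higher_lo = s$p0[2], p_higher_hi = s$p0[3],
               rr_med = s$rr[1], rr_lo = s$rr[2], rr_hi = s$rr[3],
               rd_med = s$rd[1], rd_lo = s$rd[2], rd_hi = s$rd[3],
               or_med = s$or[1], or_lo = s$or[2], or_hi = s$or[3],
               stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, lapply(seq_len(G), row)), summaries = sums)
}

#' Summarize a continuous treatment-covariate interaction
#'
#' Reports the interaction OR per original unit of the covariate (median,
#' 95% CrI), the directional posterior probabilities P(interaction OR < 1)
#' and P(interaction OR > 1) (any point mass at exactly 1 is reported
#' separately as `prob_or_eq1`), and the conditional-effect curve: the
#' event probability per arm over a grid of covariate values at the fixed
#' covariate profile.
#'
#' @param fit an interaction `posterior_draws` from
#'   [fit_continuous_interaction()].
#' @param profile a [most_common_profile()].
#' @param grid covariate grid; default 50 points over the observed range.
#'   Values outside the observed range are allowed with a warning.
#' @return An object of class `interaction_summary`.
#' @export
interaction_summary <- function(fit, profile, grid = NULL) {
  stopifnot(inherits(fit, "posterior_draws"), fit$kind == "interaction")
  eta <- fit$draws[, "eta"]
  if (is.null(grid))
    grid <- seq(fit$meta$x_range[1], fit$meta$x_range[2], length.out = 50)
  else if (any(grid < fit$meta$x_range[1] | grid > fit$meta$x_range[2]))
    warning("grid extends outside the observed range of `",
            fit$meta$variable, "`")
  orq <- quantile(exp(eta), c(0.5, 0.025, 0.975), names = FALSE)
  curve <- do.call(rbind, lapply(grid, function(xv) {
    pr <- standardized_event_probs(fit, profile, x = xv)
    q0 <- quantile(pr$p0, c(0.5, 0.025, 0.975), names = FALSE)
    q1 <- quantile(pr$p1, c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(x = xv, arm = c("higher", "lower"),
               median = c(q0[1], q1[1]), lower = c(q0[2], q1[2]),
               upper = c(q0[3], q1[3]))
  }))
  structure(list(variable = fit$meta$variable,
                 or_unit = c(median = orq[1], lower = orq[2], upper = orq[3]),
                 prob_or_gt1 = mean(eta > 0), prob_or_lt1 = mean(eta < 0),
                 prob_or_eq1 = mean(eta == 0),
                 curve = curve, n_draws = length(eta),
                 draws = list(eta = eta)),
            class = "interaction_summary")
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat(sprintf("<interaction_summary '%s'> OR per unit %.3f (95%% CrI: %.3f-%.3f)\n",
              x$variable, x$or_unit[1], x$or_unit[2], x$or_unit[3]))
  cat(sprintf("  P(OR < 1) = %.3f   P(OR > 1) = %.3f\n",
              x$prob_or_lt1, x$prob_or_gt1))
  invisible(x)
}
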