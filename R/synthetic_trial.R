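#' Configuration for the synthetic trial generator
#'
#' Builds the full parameter set controlling [generate_trial()]. Defaults
#' emulate the baseline table of a large two-arm ICU oxygenation trial
#' (n = 2888, 35 sites, 1:1 allocation stratified by site, COPD and
#' haematological malignancy): median SOFA 8 (IQR 5-10), median lactate
#' 1.8 mM (1.1-3.2), median PaO2:FiO2 15.8 kPa (11.8-21.0), ~55% of patients
#' on vasopressors with median highest norepinephrine dose 0.20 ug/kg/min
#' (0.10-0.40) among users, ~71% on a closed oxygen system, and ~42-43%
#' 90-day mortality. Continuous positive variables are log-normal
#' (moment-matched to the printed medians/IQRs); SOFA is a beta-binomial on
#' 0..24 matched to the printed median and IQR; covariates are mutually
#' independent.
#'
#' The outcome model is
#' \deqn{\mathrm{logit}\,P(\mathrm{death}_i) = \alpha_0 + \beta T_i +
#'   \sum_v \gamma_v x_{vi} + \sum_v \eta_v T_i x_{vi} + u_{s(i)}}
#' with treatment indicator \eqn{T_i = 1} for the lower-oxygenation arm and
#' site intercepts \eqn{u_s \sim N(0, \sigma_{site}^2)}.
#'
#' @param n_patients number of patients to generate.
#' @param n_sites number of trial sites.
#' @param prob_copd,prob_haem,prob_open_system,prob_any_vasopressor marginal
#'   probabilities of the binary baseline variables.
#' @param sofa_dist list `(size, mu, rho)`: beta-binomial size (24), mean
#'   fraction and intraclass dispersion for the SOFA score.
#' @param lactate_dist,pf_dist,norepi_dist lists `(meanlog, sdlog)` of
#'   log-normal distributions for lactate (mM), PaO2:FiO2 ratio (kPa) and
#'   norepinephrine dose among users (ug/kg/min).
#' @param site_intercept_sd SD of site intercepts, log-odds units.
#' @param baseline_logit log-odds of death at zero covariates, control arm.
#' @param treatment_log_or true treatment log odds ratio (lower vs higher).
#' @param covariate_log_ors named vector of per-unit log-OR covariate effects;
#'   names among `copd, haem, open_system, sofa, lactate, norepi_dose,
#'   pf_ratio`.
#' @param interaction_log_ors named vector of per-unit
#'   treatment-by-covariate interaction log-ORs (same names).
#' @param missing_rates named vector of missingness probabilities; only
#'   `sofa`, `pf_ratio` and `lactate` may be masked.
#' @param seed integer seed; the generated dataset is a pure function of the
#'   configuration including this seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 2888,
                             n_sites = 35,
                             prob_copd = 0.195,
                             prob_haem = 0.058,
                             prob_open_system = 0.286,
                             prob_any_vasopressor = 0.547,
                             sofa_dist = list(size = 24, mu = 1 / 3, rho = 0.068),
                             lactate_dist = list(meanlog = log(1.8), sdlog = 0.79),
                             pf_dist = list(meanlog = log(15.8), sdlog = 0.43),
                             norepi_dist = list(meanlog = log(0.20), sdlog = 1.03),
                             site_intercept_sd = 0.3,
                             baseline_logit = -1.36,
                             treatment_log_or = 0,
                             covariate_log_ors = c(copd = 0.2, haem = 0.6,
                                                   sofa = 0.12, lactate = 0.15,
                                                   norepi_dose = 0.8,
                                                   pf_ratio = -0.03),
                             interaction_log_ors = numeric(0),
                             missing_rates = c(sofa = 89 / 2888,
                                               pf_ratio = 12 / 2888,
                                               lactate = 19 / 2888),
                             seed = 1L) {
  cfg <- list(n_patients = n_patients, n_sites = n_sites,
              prob_copd = prob_copd, prob_haem = prob_haem,
              prob_open_system = prob_open_system,
              prob_any_vasopressor = prob_any_vasopressor,
              sofa_dist = sofa_dist, lactate_dist = lactate_dist,
              pf_dist = pf_dist, norepi_dist = norepi_dist,
              site_intercept_sd = site_intercept_sd,
              baseline_logit = baseline_logit,
              treatment_log_or = treatment_log_or,
              covariate_log_ors = covariate_log_ors,
              interaction_log_ors = interaction_log_ors,
              missing_rates = missing_rates, seed = seed)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

covariate_names <- c("copd", "haem", "open_system", "sofa", "lactate",
                     "norepi_dose", "pf_ratio")
maskable_names <- c("sofa", "pf_ratio", "lactate")

validate_generator_config <- function(cfg) {
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop("configuration error: `", field, "` must be a probability in [0, 1]",
           call. = FALSE)
  }
  for (f in c("prob_copd", "prob_haem", "prob_open_system",
              "prob_any_vasopressor")) chk_prob(f)
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      is.na(cfg$n_patients) || cfg$n_patients < 0 ||
      cfg$n_patients != round(cfg$n_patients))
    stop("configuration error: `n_patients` must be a non-negative integer",
         call. = FALSE)
  if (!is.numeric(cfg$n_sites) || cfg$n_sites < 1 ||
      cfg$n_sites != round(cfg$n_sites))
    stop("configuration error: `n_sites` must be a positive integer",
         call. = FALSE)
  if (cfg$n_patients > 0 && cfg$n_sites > cfg$n_patients)
    stop("configuration error: `n_sites` must not exceed `n_patients`",
         call. = FALSE)
  for (f in c("lactate_dist", "pf_dist", "norepi_dist")) {
    d <- cfg[[f]]
    if (!is.list(d) || !is.numeric(d$meanlog) || !is.numeric(d$sdlog) ||
        d$sdlog <= 0)
      stop("configuration error: `", f,
           "` needs numeric meanlog and positive sdlog", call. = FALSE)
  }
  sd <- cfg$sofa_dist
  if (!is.list(sd) || is.null(sd$size) || is.null(sd$mu) || is.null(sd$rho) ||
      sd$size < 1 || sd$mu <= 0 || sd$mu >= 1 || sd$rho <= 0 || sd$rho >= 1)
    stop("configuration error: `sofa_dist` needs size >= 1, mu in (0,1), rho in (0,1)",
         call. = FALSE)
  if (!is.numeric(cfg$site_intercept_sd) || cfg$site_intercept_sd < 0)
    stop("configuration error: `site_intercept_sd` must be >= 0", call. = FALSE)
  for (f in c("covariate_log_ors", "interaction_log_ors")) {
    v <- cfg[[f]]
    if (length(v) && (is.null(names(v)) ||
                      !all(names(v) %in% covariate_names)))
      stop("configuration error: `", f, "` names must be among: ",
           paste(covariate_names, collapse = ", "), call. = FALSE)
  }
  mr <- cfg$missing_rates
  if (length(mr)) {
    if (is.null(names(mr)) || !all(names(mr) %in% maskable_names))
      stop("configuration error: `missing_rates` may only name ",
           paste(maskable_names, collapse = ", "), call. = FALSE)
    if (any(mr < 0 | mr > 1))
      stop("configuration error: `missing_rates` must lie in [0, 1]",
           call. = FALSE)
  }
  invisible(cfg)
}

#' Generate a synthetic two-arm trial dataset
#'
#' Draws baseline covariates, allocates patients 1:1 by stratified permuted
#' blocks within site x COPD x haematological-malignancy strata, draws the
#' 90-day mortality outcome from the configured logistic model, and applies
#' the configured missingness. The result is byte-identical for identical
#' configurations (including the seed).
#'
#' @param config a [generator_config()].
#' @return An object of class `trial_dataset`: a list with `records` (one
#'   data.frame row per patient), the generating `config`, and creation
#'   metadata (`seed`, `created`).
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  n <- as.integer(config$n_patients)

  records <- with_seed(config$seed, {
    if (n == 0) {
      empty_records()
    } else {
      site_id <- sample.int(config$n_sites, n, replace = TRUE)
      copd <- rbinom(n, 1, config$prob_copd)
      haem <- rbinom(n, 1, config$prob_haem)
      open_system <- rbinom(n, 1, config$prob_open_system)

      sd_ <- config$sofa_dist
      ab <- (1 - sd_$rho) / sd_$rho
      p_sofa <- rbeta(n, sd_$mu * ab, (1 - sd_$mu) * ab)
      sofa <- rbinom(n, sd_$size, p_sofa)

      lactate <- rlnorm(n, config$lactate_dist$meanlog, config$lactate_dist$sdlog)
      pf_ratio <- rlnorm(n, config$pf_dist$meanlog, config$pf_dist$sdlog)
      user <- rbinom(n, 1, config$prob_any_vasopressor)
      norepi_dose <- ifelse(user == 1L,
                            rlnorm(n, config$norepi_dist$meanlog,
                                   config$norepi_dist$sdlog),
                            0)

      rec <- data.frame(patient_id = seq_len(n), site_id = site_id,
                        copd = copd, haem = haem, open_system = open_system,
                        sofa = sofa, pf_ratio = pf_ratio, lactate = lactate,
                        norepi_dose = norepi_dose,
                        stringsAsFactors = FALSE)

      rec$allocation <- stratified_allocate(rec,
                                            c("site_id", "copd", "haem"))
      tr <- as.integer(rec$allocation == "lower")

      u <- rnorm(config$n_sites, 0, config$site_intercept_sd)
      lp <- config$baseline_logit + config$treatment_log_or * tr + u[site_id]
      for (v in names(config$covariate_log_ors))
        lp <- lp + config$covariate_log_ors[[v]] * rec[[v]]
      for (v in names(config$interaction_log_ors))
        lp <- lp + config$interaction_log_ors[[v]] * tr * rec[[v]]
      rec$dead_90d <- rbinom(n, 1, plogis(lp))
      rec
    }
  })

  ds <- new_trial_dataset(records, config)
  if (n > 0 && length(config$missing_rates))
    ds <- inject_missingness(ds, config$missing_rates,
                             seed = config$seed + 1L)
  ds
}

empty_records <- function() {
  data.frame(patient_id = integer(0), site_id = integer(0), copd = integer(0),
             haem = integer(0), open_system = integer(0), sofa = integer(0),
             pf_ratio = numeric(0), lactate = numeric(0),
             norepi_dose = numeric(0), allocation = character(0),
             dead_90d = integer(0), stringsAsFactors = FALSE)
}

new_trial_dataset <- function(records, config) {
  structure(list(records = records, config = config,
                 seed = if (is.list(config)) config$seed else NA_integer_,
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  rec <- x$records
  cat("<trial_dataset> ", nrow(rec), " patients",
      if (nrow(rec)) paste0(", ", length(unique(rec$site_id)), " sites"),
      "\n", sep = "")
  if (nrow(rec)) {
    cat("  arms: ", sum(rec$allocation == "lower"), " lower / ",
        sum(rec$allocation == "higher"), " higher; deaths: ",
        sum(rec$dead_90d), " (", round(100 * mean(rec$dead_90d), 1), "%)\n",
        sep = "")
  }
  invisible(x)
}

# Coerce trial_dataset or data.frame to the records data.frame.
trial_records <- function(dataset) {
  if (inherits(dataset, "trial_dataset")) dataset$records
  else if (is.data.frame(dataset)) dataset
  else stop("expected a `trial_dataset` or a data.frame of patient records",
            call. = FALSE)
}

#' Stratified 1:1 permuted-block allocation
#'
#' Allocates records 1:1 to the `lower` / `higher` oxygenation-target arms
#' using permuted blocks of four within each stratum defined by the
#' combination of `strata_variables`; a final partial block is balanced so
#' arm counts within every stratum differ by at most one.
#'
#' @param records data.frame of patient records (or a `trial_dataset`).
#' @param strata_variables character vector of stratification column names.
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (as inside [generate_trial()]).
#' @return Character vector of `"lower"` / `"higher"` labels, one per record.
#' @export
stratified_allocate <- function(records, strata_variables, seed = NULL) {
  rec <- trial_records(records)
  if (nrow(rec) == 0) return(character(0))
  missing_vars <- setdiff(strata_variables, names(rec))
  if (length(missing_vars))
    stop("strata variables absent from records: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  if (any(!complete.cases(rec[strata_variables])))
    stop("strata variables must be present (non-missing) for all records",
         call. = FALSE)

  do_alloc <- function() {
    stratum <- interaction(rec[strata_variables], drop = TRUE)
    out <- character(nrow(rec))
    for (s in levels(stratum)) {
      idx <- which(stratum == s)
      m <- length(idx)
      n_blocks <- m %/% 4L
      labs <- character(0)
      if (n_blocks > 0)
        labs <- unlist(lapply(seq_len(n_blocks), function(i)
          sample(c("lower", "lower", "higher", "higher"))))
      r <- m - 4L * n_blocks
      if (r > 0) {
        part <- switch(as.character(r),
                       "1" = sample(c("lower", "higher"), 1),
                       "2" = sample(c("lower", "higher")),
                       "3" = sample(c("lower", "higher",
                                      sample(c("lower", "higher"), 1))))
        labs <- c(labs, part)
      }
      out[idx] <- labs
    }
    out
  }
  if (is.null(seed)) do_alloc() else with_seed(seed, do_alloc())
}

#' Inject missing values into maskable baseline variables
#'
#' Masks `sofa`, `pf_ratio` and/or `lactate` independently with the given
#' per-variable rates, emulating the sporadic baseline missingness of real
#' trial data. Allocation and outcome are never masked.
#'
#' @param dataset a `trial_dataset` or records data.frame.
#' @param missing_rates named vector of probabilities; names must be among
#'   `sofa`, `pf_ratio`, `lactate`.
#' @param seed integer seed.
#' @return Object of the same type as `dataset` with values masked.
#' @export
inject_missingness <- function(dataset, missing_rates, seed = 1L) {
  rec <- trial_records(dataset)
  if (length(missing_rates) == 0) return(dataset)
  if (is.null(names(missing_rates)) ||
      !all(names(missing_rates) %in% maskable_names))
    stop("configuration error: missingness may only be injected into ",
         paste(maskable_names, collapse = ", "), call. = FALSE)
  if (any(missing_rates < 0 | missing_rates > 1))
    stop("configuration error: missing rates must lie in [0, 1]", call. = FALSE)
  if (nrow(rec)) {
    rec <- with_seed(seed, {
      for (v in names(missing_rates)) {
        hit <- runif(nrow(rec)) < missing_rates[[v]]
        rec[[v]][hit] <- NA
      }
      rec
    })
  }
  if (inherits(dataset, "trial_dataset")) {
    dataset$records <- rec
    dataset
  } else rec
}

trial_csv_columns <- c("patient_id", "site_id", "copd", "haem", "open_system",
                       "sofa", "pf_ratio", "lactate", "norepi_dose",
                       "allocation", "dead_90d")

#' Read / write the patient-level trial table
#'
#' The on-disk format is a plain CSV with the fixed header
#' `patient_id, site_id, copd, haem, open_system, sofa, pf_ratio, lactate,
#' norepi_dose, allocation, dead_90d`; missing values are empty fields.
#'
#' @param dataset a `trial_dataset` or records data.frame.
#' @param path file path.
#' @return `write_trial_csv` returns `path` invisibly; `read_trial_csv`
#'   returns a `trial_dataset` with config `"external"`.
#' @export
write_trial_csv <- function(dataset, path) {
  rec <- trial_records(dataset)
  write.csv(rec[, trial_csv_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_csv_columns, names(rec))
  if (length(missing_cols))
    stop("trial CSV is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  rec$allocation <- as.character(rec$allocation)
  bad <- setdiff(unique(rec$allocation), c("lower", "higher"))
  if (length(bad))
    stop("allocation must be 'lower' or 'higher'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  ds <- new_trial_dataset(rec[, trial_csv_columns], "external")
  ds$seed <- NA_integer_
  ds
}
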