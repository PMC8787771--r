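# MCMC convergence diagnostics: rank-normalized split R-hat, bulk and tail
# effective sample sizes (FFT autocovariance + Geyer initial monotone
# sequence), and the divergence count from the HMC backend.

# biased autocovariance (divide by n) via FFT
autocovariance <- function(x) {
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  xc <- x - mean(x)
  f <- fft(c(xc, rep(0, nfft - n)))
  Re(fft(Mod(f)^2, inverse = TRUE))[seq_len(n)] / (nfft * n)
}

rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

# split each chain into halves; returns n2 x (2m) matrix
split_chain_matrix <- function(x, chains) {
  n <- length(x) %/% chains
  n2 <- n %/% 2
  if (n2 < 1) return(NULL)
  cols <- lapply(seq_len(chains), function(ch) {
    v <- x[((ch - 1) * n + 1):(ch * n)]
    cbind(v[seq_len(n2)], v[(n - n2 + 1):n])
  })
  do.call(cbind, cols)
}

# basic (split) R-hat on an n x m matrix of chains
rhat_core <- function(sims) {
  n <- nrow(sims); m <- ncol(sims)
  if (n < 2 || m < 2) return(NA_real_)
  W <- mean(apply(sims, 2, var))
  B <- n * var(colMeans(sims))
  if (!is.finite(W) || W == 0) return(if (B == 0) 1 else NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size of an n x m matrix of chains (Vehtari et al. 2021)
ess_core <- function(sims) {
  n <- nrow(sims); m <- ncol(sims)
  if (n < 3) return(NA_real_)
  if (all(sims == sims[1])) return(NA_real_)
  acov <- apply(sims, 2, autocovariance)
  chain_means <- colMeans(sims)
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n + (if (m > 1) var(chain_means) else 0)
  if (!is.finite(var_plus) || var_plus == 0) return(NA_real_)

  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus  # rho[1] == 1 at lag 0
  # Geyer initial positive sequence over pairs, then monotone enforcement
  max_t <- n - 2
  tau <- 0
  prev_pair <- Inf
  t <- 1
  while (t + 1 <= max_t + 1) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    prev_pair <- pair
    tau <- tau + pair
    t <- t + 2
  }
  ess <- m * n / max(2 * tau - 1, 1e-12)
  min(ess, m * n * 10)  # guard against pathological anticorrelation blowup
}

#' MCMC diagnostics for posterior draws
#'
#' Computes per-parameter rank-normalized split R-hat (the larger of the
#' bulk and folded versions), bulk and tail effective sample sizes, and
#' carries the sampler's divergence count. The overall verdict is
#' `acceptable` exactly when the maximum R-hat is below 1.01 and no
#' divergences occurred. With a single chain, R-hat is undefined and is
#' reported as `NA` with a note; the verdict is then `NA`.
#'
#' @param fit a `posterior_draws` object (from a fit or
#'   [as_posterior_draws()]).
#' @return An object of class `mcmc_diagnostics`: `parameters` data.frame
#'   (`parameter`, `rhat`, `ess_bulk`, `ess_tail`), `divergences`,
#'   `max_rhat`, `acceptable`, `note`.
#' @export
diagnostics <- function(fit) {
  stopifnot(inherits(fit, "posterior_draws"))
  draws <- fit$draws
  chains <- fit$chains
  params <- colnames(draws)
  note <- NULL

  one <- function(x) {
    # rank-normalize jointly across all draws, then split into half-chains
    z <- split_chain_matrix(rank_normalize(x), chains)
    zf <- split_chain_matrix(rank_normalize(abs(x - median(x))), chains)
    if (is.null(z)) return(c(rhat = NA_real_, ess_bulk = NA_real_,
                             ess_tail = NA_real_))
    c(rhat = if (chains < 2) NA_real_ else max(rhat_core(z), rhat_core(zf)),
      ess_bulk = ess_core(z),
      ess_tail = tail_ess(x, chains))
  }

  tail_ess <- function(x, chains) {
    qs <- quantile(x, c(0.05, 0.95), names = FALSE)
    ess_q <- function(q) {
      sm <- split_chain_matrix(as.numeric(x <= q), chains)
      if (is.null(sm)) NA_real_ else ess_core(sm)
    }
    vals <- c(ess_q(qs[1]), ess_q(qs[2]))
    if (all(is.na(vals))) NA_real_ else min(vals, na.rm = TRUE)
  }

  res <- t(vapply(params, function(p) one(draws[, p]), numeric(3)))
  tab <- data.frame(parameter = params, rhat = res[, 1],
                    ess_bulk = res[, 2], ess_tail = res[, 3],
                    row.names = NULL, stringsAsFactors = FALSE)
  max_rhat <- suppressWarnings(max(tab$rhat, na.rm = TRUE))
  if (!is.finite(max_rhat)) max_rhat <- NA_real_
  if (chains < 2) {
    note <- "single chain: R-hat undefined"
    acceptable <- NA
  } else {
    acceptable <- !is.na(max_rhat) && max_rhat < 1.01 && fit$divergences == 0
  }
  structure(list(parameters = tab, divergences = fit$divergences,
                 max_rhat = max_rhat, acceptable = acceptable, note = note),
            class = "mcmc_diagnostics")
}

#' @export
print.mcmc_diagnostics <- function(x, ...) {
  cat("<mcmc_diagnostics> max R-hat:",
      if (is.na(x$max_rhat)) "NA" else sprintf("%.4f", x$max_rhat),
      "| divergences:", x$divergences,
      "| verdict:", if (is.na(x$acceptable)) "undetermined"
      else if (x$acceptable) "acceptable" else "NOT acceptable", "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  worst <- x$parameters[order(-x$parameters$rhat), ][seq_len(min(5, nrow(x$parameters))), ]
  print(worst, row.names = FALSE, digits = 4)
  invisible(x)
}
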