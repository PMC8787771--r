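# Shared fixtures and small oracles, all built in code at test time.

# minimal records data.frame with every trial column, overridable
make_records <- function(n, site_id = 1L, copd = 0L, haem = 0L,
                         open_system = 0L, sofa = 8L, pf_ratio = 15,
                         lactate = 2, norepi_dose = 0, allocation = NULL,
                         dead_90d = 0L, seed = 1) {
  set.seed(seed)
  if (is.null(allocation))
    allocation <- sample(rep(c("lower", "higher"), length.out = max(n, 1)))
  r <- function(x) rep_len(x, n)
  data.frame(patient_id = seq_len(n), site_id = r(site_id), copd = r(copd),
             haem = r(haem), open_system = r(open_system), sofa = r(sofa),
             pf_ratio = r(pf_ratio), lactate = r(lactate),
             norepi_dose = r(norepi_dose), allocation = r(allocation),
             dead_90d = r(dead_90d), stringsAsFactors = FALSE)
}

# subgroup-structured simulation: G equal groups of a synthetic baseline
# variable `xvar`, group-specific baselines and treatment log-ORs
make_subgroup_data <- function(n, beta_g, base_g = rep(qlogis(0.35),
                                                       length(beta_g)),
                               seed = 1) {
  set.seed(seed)
  G <- length(beta_g)
  x <- rep(seq_len(G), each = n %/% G)
  tr <- as.integer(runif(length(x)) < 0.5)
  lp <- base_g[x] + beta_g[x] * tr
  rec <- make_records(length(x), allocation = ifelse(tr == 1, "lower", "higher"))
  rec$xvar <- x
  rec$dead_90d <- rbinom(length(x), 1, plogis(lp))
  rec
}

# reduced-draw sampler settings for tests
quick_spec <- function(kind, ...) {
  defaults <- list(kind = kind, chains = 2L, warmup = 300L, draws = 400L,
                   seed = 1L, max_leapfrog = 16L)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_spec, args)
}

# 40-patient toy trial used by the quadrature-oracle checks
make_toy_trial <- function(seed = 42) {
  set.seed(seed)
  n <- 40
  rec <- make_records(n, copd = rbinom(n, 1, 0.3), haem = rbinom(n, 1, 0.2),
                      allocation = sample(rep(c("lower", "higher"), n / 2)))
  lp <- -0.3 + 0.5 * (rec$allocation == "lower") + 0.4 * rec$copd +
    0.6 * rec$haem
  rec$dead_90d <- rbinom(n, 1, plogis(lp))
  rec
}

# Dense-grid quadrature for the single-site toy model: posterior moments of
# the treatment log-OR under logit P = a + b T + c1 copd + c2 haem with
# priors N(0, 2.5) on a and N(0, 1) on b, c1, c2. Independent of the HMC
# path: direct summation over a 4-D grid centered on the MLE.
grid_posterior_beta <- function(rec, points = 41, half_width = 5) {
  tr <- as.integer(rec$allocation == "lower")
  dat <- data.frame(y = rec$dead_90d, tr = tr, copd = rec$copd,
                    haem = rec$haem)
  patt <- aggregate(cbind(deaths = y, n = 1) ~ tr + copd + haem, dat, sum)
  g <- glm(y ~ tr + copd + haem, binomial, dat)
  ctr <- coef(g); se <- sqrt(diag(vcov(g)))
  gr <- lapply(1:4, function(j)
    seq(ctr[j] - half_width * se[j], ctr[j] + half_width * se[j],
        length.out = points))
  G <- as.matrix(expand.grid(gr[[1]], gr[[2]], gr[[3]], gr[[4]]))
  lp <- rep(0, nrow(G))
  for (k in seq_len(nrow(patt))) {
    eta <- G[, 1] + G[, 2] * patt$tr[k] + G[, 3] * patt$copd[k] +
      G[, 4] * patt$haem[k]
    lp <- lp + patt$deaths[k] * eta - patt$n[k] * log1p(exp(eta))
  }
  lp <- lp + dnorm(G[, 1], 0, 2.5, log = TRUE) + dnorm(G[, 2], 0, 1, log = TRUE) +
    dnorm(G[, 3], 0, 1, log = TRUE) + dnorm(G[, 4], 0, 1, log = TRUE)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  m <- sum(w * G[, 2])
  list(mean = m, sd = sqrt(sum(w * (G[, 2] - m)^2)))
}

# Brute-force oracle for tie-respecting balanced partitions: enumerate all
# placements of G-1 boundaries between the distinct-value blocks, score
# with the integer cost sum((G*n_g - N)^2), break ties by lexicographically
# smallest boundary vector. Independent of the package's DP.
brute_force_partition <- function(values, G) {
  d <- sort(unique(values))
  cnt <- as.integer(table(factor(values, levels = d)))
  B <- length(d)
  G <- min(G, B)
  N <- sum(cnt)
  if (G == 1) return(rep(1L, length(values)))
  # combn enumerates boundary vectors in lexicographic order, so keeping the
  # first strict minimum realizes the lexicographic tie-break
  best_cost <- Inf; best_ends <- NULL
  for (cmb in asplit(utils::combn(B - 1, G - 1), 2)) {
    ends <- c(cmb, B)
    starts <- c(1L, head(ends, -1L) + 1L)
    sizes <- vapply(seq_len(G), function(g) sum(cnt[starts[g]:ends[g]]),
                    integer(1))
    cost <- sum((G * sizes - N)^2)
    if (cost < best_cost) { best_cost <- cost; best_ends <- ends }
  }
  grp_of_block <- rep(seq_len(G),
                      times = diff(c(0, best_ends)))
  grp_of_block[match(values, d)]
}
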