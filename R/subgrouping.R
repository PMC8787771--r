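#' Quintile-based, tie-respecting subgroups of a baseline variable
#'
#' Partitions the non-missing values into (by default) five ordered groups
#' targeting the 20/40/60/80th percentiles while guaranteeing that patients
#' sharing an identical value always land in the same group. Because heavy
#' ties can make naive percentile cuts produce empty or grossly unequal
#' groups, the partition is chosen as the tie-respecting ordered partition
#' whose group sizes are nearest to equal: among partitions of the distinct
#' values into `n_groups` consecutive runs, the one minimizing
#' \eqn{\sum_g (G n_g - N)^2} (an integer-exact rescaling of the squared
#' deviation from \eqn{N/G}) is selected by dynamic programming, with ties
#' broken toward the lexicographically smallest group boundaries.
#'
#' With `zero_mass_group = TRUE` (for zero-inflated exposures such as
#' norepinephrine dose) all exact zeros form the first group and the
#' positive values are split into `n_groups - 1` balanced groups, so the
#' total number of groups is unchanged.
#'
#' @param values numeric vector; may contain `NA` (left unassigned).
#' @param zero_mass_group if `TRUE`, exact zeros form their own first group.
#' @param n_groups target number of groups (default 5). If fewer distinct
#'   values exist, fewer groups are formed, with a warning.
#' @param variable variable name recorded in the scheme.
#' @return An object of class `subgroup_scheme`: ordered group `labels` and
#'   inclusive `lower`/`upper` value ranges, per-patient `assignment`
#'   (integer, `NA` for missing input), per-group `counts`, and the
#'   percentile targets used.
#' @export
quintile_subgroups <- function(values, zero_mass_group = FALSE, n_groups = 5,
                               variable = deparse(substitute(values))) {
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  obs <- values[!is.na(values)]
  if (length(obs) == 0)
    stop("all values are missing; cannot build subgroups", call. = FALSE)
  if (n_groups < 1) stop("`n_groups` must be >= 1", call. = FALSE)

  assignment <- rep(NA_integer_, length(values))

  if (zero_mass_group) {
    if (any(obs < 0))
      stop("zero-mass grouping requires non-negative values", call. = FALSE)
    pos <- obs[obs > 0]
    if (length(pos) == 0) {
      warning("no positive values; single zero-mass group formed")
      scheme <- make_scheme(variable, lower = 0, upper = 0,
                            counts = length(obs), targets = numeric(0))
      assignment[!is.na(values)] <- 1L
      scheme$assignment <- assignment
      return(scheme)
    }
    part <- balanced_tie_partition(pos, n_groups - 1L)
    lower <- c(0, part$lower)
    upper <- c(0, part$upper)
    counts <- c(sum(obs == 0), part$counts)
    scheme <- make_scheme(variable, lower, upper, counts, part$targets,
                          zero_mass = TRUE)
  } else {
    part <- balanced_tie_partition(obs, n_groups)
    scheme <- make_scheme(variable, part$lower, part$upper, part$counts,
                          part$targets)
  }
  scheme$assignment <- assign_subgroup(scheme, values, warn = FALSE)
  scheme
}

# Balanced tie-respecting ordered partition of `obs` into up to G groups.
# Returns per-group inclusive ranges and counts plus the percentile targets.
balanced_tie_partition <- function(obs, G) {
  d <- sort(unique(obs))          # distinct-value blocks
  cnt <- as.integer(table(factor(obs, levels = d)))
  B <- length(d)
  if (B < G) {
    warning(sprintf("only %d distinct value(s); forming %d group(s) instead of %d",
                    B, B, G))
    G <- B
  }
  targets <- if (G > 1) quantile(obs, probs = seq_len(G - 1) / G,
                                 type = 7, names = FALSE) else numeric(0)
  ends <- partition_blocks(cnt, G)     # last block index of each group
  starts <- c(1L, head(ends, -1L) + 1L)
  list(lower = d[starts], upper = d[ends],
       counts = vapply(seq_len(G), function(g)
         sum(cnt[starts[g]:ends[g]]), integer(1)),
       targets = targets)
}

# Exact DP: partition blocks with counts `cnt` into G consecutive nonempty
# groups minimizing sum((G*n_g - N)^2) (integer arithmetic), tie-broken to
# the lexicographically smallest vector of group end indices. `best[j, g]`
# is the optimal cost of partitioning blocks j..B into g groups; greedy
# left-to-right reconstruction over optimal choices yields the
# lexicographically smallest boundaries.
partition_blocks <- function(cnt, G) {
  B <- length(cnt)
  N <- sum(cnt)
  cum <- c(0, cumsum(cnt))
  segcost <- function(i, j) (G * (cum[j + 1] - cum[i]) - N)^2

  best <- matrix(Inf, nrow = B + 2, ncol = G + 1)
  best[B + 1, 1] <- 0   # no blocks left, zero groups
  for (g in 1:G) for (j in B:1) {
    # group starting at block j may end at e = j..B-(g-1)
    e_max <- B - (g - 1L)
    if (e_max < j) next
    costs <- vapply(j:e_max, function(e) segcost(j, e) + best[e + 2 - 1, g - 1 + 1],
                    numeric(1))
    best[j, g + 1] <- min(costs)
  }

  ends <- integer(G)
  j <- 1L
  for (g in G:1) {
    e_max <- B - (g - 1L)
    for (e in j:e_max) {
      if (segcost(j, e) + best[e + 1, g] == best[j, g + 1]) {
        ends[G - g + 1L] <- e
        j <- e + 1L
        break
      }
    }
  }
  ends
}

make_scheme <- function(variable, lower, upper, counts, targets,
                        zero_mass = FALSE) {
  G <- length(lower)
  labels <- vapply(seq_len(G), function(g) {
    if (lower[g] == upper[g]) format(lower[g])
    else paste0(format(lower[g]), "-", format(upper[g]))
  }, character(1))
  structure(list(variable = variable, labels = labels, lower = lower,
                 upper = upper, counts = as.integer(counts),
                 quantile_targets = targets, zero_mass = zero_mass,
                 assignment = NULL),
            class = "subgroup_scheme")
}

#' @export
print.subgroup_scheme <- function(x, ...) {
  cat("<subgroup_scheme> variable '", x$variable, "', ",
      length(x$labels), " groups", if (x$zero_mass) " (zero-mass first)",
      "\n", sep = "")
  print(data.frame(group = seq_along(x$labels), label = x$labels,
                   lower = x$lower, upper = x$upper, n = x$counts))
  invisible(x)
}

#' Assign values to the groups of an existing subgroup scheme
#'
#' Deterministic assignment by comparison against the inclusive group upper
#' bounds: a value equal to a group's upper bound falls in that (lower)
#' group, so tied values are never split. Values outside the scheme's
#' overall range (possible at prediction time) are assigned to the nearest
#' boundary group with a warning.
#'
#' @param scheme a [quintile_subgroups()] scheme.
#' @param value numeric vector; `NA` yields `NA`.
#' @param warn warn on out-of-range values (default `TRUE`).
#' @return Integer vector of group indices.
#' @export
assign_subgroup <- function(scheme, value, warn = TRUE) {
  stopifnot(inherits(scheme, "subgroup_scheme"))
  G <- length(scheme$upper)
  out <- rep(NA_integer_, length(value))
  ok <- !is.na(value)
  if (any(ok)) {
    v <- value[ok]
    idx <- 1L + rowSums(outer(v, scheme$upper[-G], `>`))
    if (G == 1) idx <- rep(1L, length(v))
    out[ok] <- as.integer(idx)
    if (warn && any(v < scheme$lower[1] | v > scheme$upper[G]))
      warning("value(s) outside the scheme's range assigned to the nearest boundary group")
  }
  out
}

#' Serialize / read a subgroup scheme as CSV
#'
#' Writes one row per group: `group, label, lower, upper, n`.
#'
#' @param scheme a `subgroup_scheme`.
#' @param path CSV path.
#' @return `write_subgroup_scheme` returns `path` invisibly;
#'   `read_subgroup_scheme` returns a `subgroup_scheme` without per-patient
#'   assignments.
#' @export
write_subgroup_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "subgroup_scheme"))
  df <- data.frame(group = seq_along(scheme$labels), label = scheme$labels,
                   lower = scheme$lower, upper = scheme$upper,
                   n = scheme$counts, variable = scheme$variable,
                   zero_mass = scheme$zero_mass)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subgroup_scheme
#' @export
read_subgroup_scheme <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  make_scheme(df$variable[1], df$lower, df$upper, df$n, numeric(0),
              zero_mass = isTRUE(df$zero_mass[1]))
}
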