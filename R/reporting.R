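# Figure and table analogues of the trial report: posterior distribution
# plots, per-subgroup density overlays, conditional-effects panels, and CSV
# effect tables. Display convention: RR/OR to two decimals, percentages to
# one decimal.

#' Posterior distribution plot for the adjusted relative risk
#'
#' Two stacked panels: the cumulative posterior probability P(RR <= x), and
#' the posterior density with the median marked and the central 95% CrI
#' shaded.
#'
#' @param rr_draws numeric vector of per-draw RRs (an [effect_summary()]'s
#'   `draws$rr`), at least 100 draws.
#' @param file output file (png or svg, by extension).
#' @param measure axis label for the effect measure.
#' @return Invisibly, `list(file, plot, cri)`; `cri` holds the shaded 2.5,
#'   50 and 97.5 percentiles.
#' @export
render_posterior_plot <- function(rr_draws, file, measure = "Relative risk") {
  if (inherits(rr_draws, "effect_summary")) rr_draws <- rr_draws$draws$rr
  if (length(rr_draws) < 100)
    stop("at least 100 draws are required for a posterior plot", call. = FALSE)
  q <- quantile(rr_draws, c(0.025, 0.5, 0.975), names = FALSE)
  sorted <- sort(rr_draws)
  cum <- data.frame(x = sorted, p = seq_along(sorted) / length(sorted))
  p_top <- ggplot2::ggplot(cum, ggplot2::aes(x = .data$x, y = .data$p)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = measure, y = paste0("P(", measure, " ≤ x)")) +
    ggplot2::theme_minimal()
  if (length(unique(rr_draws)) > 1) {
    d <- stats::density(rr_draws)
    dd <- data.frame(x = d$x, y = d$y)
    p_bot <- ggplot2::ggplot(dd, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_area(data = dd[dd$x >= q[1] & dd$x <= q[3], ],
                         fill = "steelblue", alpha = 0.4) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = q[2]) +
      ggplot2::labs(x = measure, y = "Posterior density") +
      ggplot2::theme_minimal()
  } else {
    p_bot <- ggplot2::ggplot(data.frame(x = q[2]), ggplot2::aes(x = .data$x)) +
      ggplot2::geom_vline(xintercept = q[2]) +
      ggplot2::labs(x = measure, y = "Posterior mass (degenerate)") +
      ggplot2::theme_minimal()
  }
  pl <- patchwork::wrap_plots(p_top, p_bot, ncol = 1)
  ggplot2::ggsave(file, pl, width = 7, height = 6, dpi = 120)
  invisible(list(file = file, plot = pl,
                 cri = c(lower = q[1], median = q[2], upper = q[3])))
}

#' Per-subgroup posterior densities with the overall posterior overlaid
#'
#' One panel per subgrouping scheme; each panel shows the posterior RR
#' density of every subgroup together with the overall-cohort posterior
#' from the corresponding non-subgroup analysis.
#'
#' @param subgroup_draws named list (one element per scheme) of named lists
#'   of per-subgroup RR draw vectors.
#' @param overall_draws per-draw RRs of the overall analysis.
#' @param file output file.
#' @return Invisibly, `list(file, plot, n_panels)`.
#' @export
render_subgroup_densities <- function(subgroup_draws, overall_draws, file) {
  long <- do.call(rbind, lapply(names(subgroup_draws), function(sch) {
    grp <- subgroup_draws[[sch]]
    do.call(rbind, lapply(names(grp), function(g)
      data.frame(scheme = sch, group = g, rr = grp[[g]],
                 stringsAsFactors = FALSE)))
  }))
  overall <- do.call(rbind, lapply(names(subgroup_draws), function(sch)
    data.frame(scheme = sch, rr = overall_draws)))
  pl <- ggplot2::ggplot(long, ggplot2::aes(x = .data$rr, colour = .data$group)) +
    ggplot2::geom_density() +
    ggplot2::geom_density(data = overall, colour = "black", linetype = "dashed",
                          inherit.aes = FALSE, ggplot2::aes(x = .data$rr)) +
    ggplot2::facet_wrap(~scheme, scales = "free") +
    ggplot2::labs(x = "Relative risk", y = "Posterior density",
                  colour = "Subgroup") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file, pl, width = 9, height = 7, dpi = 120)
  invisible(list(file = file, plot = pl, n_panels = length(subgroup_draws)))
}

#' Conditional-effects panels for continuous interactions
#'
#' One panel per interaction summary: predicted mortality probability by
#' arm over the covariate grid with 95% CrI ribbons, annotated with the
#' interaction OR (95% CrI) and the directional probabilities P(OR < 1) /
#' P(OR > 1). The plotted x-range can be truncated (e.g. to the 95th
#' percentile of a long-tailed covariate) via `x_max`.
#'
#' @param summaries list of [interaction_summary()] objects.
#' @param file output file.
#' @param x_max optional named vector of per-variable x-axis truncation
#'   points.
#' @return Invisibly, `list(file, plot, annotations)` where `annotations`
#'   is the data.frame of printed numbers.
#' @export
render_conditional_effects <- function(summaries, file, x_max = NULL) {
  if (inherits(summaries, "interaction_summary")) summaries <- list(summaries)
  curves <- do.call(rbind, lapply(summaries, function(s) {
    cv <- s$curve
    cv$variable <- s$variable
    if (!is.null(x_max) && s$variable %in% names(x_max))
      cv <- cv[cv$x <= x_max[[s$variable]], ]
    cv
  }))
  ann <- do.call(rbind, lapply(summaries, function(s)
    data.frame(variable = s$variable,
               label = sprintf("interaction OR %.2f (%.2f-%.2f)\nP(OR<1)=%.0f%%  P(OR>1)=%.0f%%",
                               s$or_unit[1], s$or_unit[2], s$or_unit[3],
                               100 * s$prob_or_lt1, 100 * s$prob_or_gt1),
               or_median = unname(s$or_unit[1]),
               prob_lt1 = s$prob_or_lt1, prob_gt1 = s$prob_or_gt1,
               stringsAsFactors = FALSE)))
  pl <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$x, y = .data$median,
                                             colour = .data$arm,
                                             fill = .data$arm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_text(data = ann, inherit.aes = FALSE, size = 2.8,
                       ggplot2::aes(label = .data$label),
                       x = Inf, y = Inf, hjust = 1.05, vjust = 1.2) +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::labs(x = "Baseline value", y = "P(90-day mortality)",
                  colour = "Target", fill = "Target") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file, pl, width = 9, height = 7, dpi = 120)
  invisible(list(file = file, plot = pl, annotations = ann))
}

#' Write an effect table as CSV
#'
#' For an [effect_summary()], writes a one-row table (plus threshold
#' probabilities); for a [summarize_subgroups()] result, writes the
#' per-subgroup table.
#'
#' @param x an `effect_summary` or the result of [summarize_subgroups()].
#' @param path CSV path.
#' @param label row label for a single summary.
#' @return `path`, invisibly.
#' @export
write_effect_csv <- function(x, path, label = "all_patients") {
  if (inherits(x, "effect_summary")) {
    df <- data.frame(group = label, n_draws = x$n_draws,
                     p_lower_med = x$p1[1], p_lower_lo = x$p1[2],
                     p_lower_hi = x$p1[3],
                     p_higher_med = x$p0[1], p_higher_lo = x$p0[2],
                     p_higher_hi = x$p0[3],
                     rr_med = x$rr[1], rr_lo = x$rr[2], rr_hi = x$rr[3],
                     rd_med = x$rd[1], rd_lo = x$rd[2], rd_hi = x$rd[3],
                     or_med = x$or[1], or_lo = x$or[2], or_hi = x$or[3])
    thr <- data.frame(t(c(x$prob_rr_below, x$prob_rd_below)))
    names(thr) <- c(paste0("p_rr_lt_", names(x$prob_rr_below)),
                    paste0("p_rd_lt_", names(x$prob_rd_below)))
    df <- cbind(df, thr)
  } else if (is.list(x) && !is.null(x$table)) {
    df <- x$table
  } else stop("unsupported object for write_effect_csv", call. = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
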