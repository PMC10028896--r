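#' Tidy a free energy result
#'
#' One row per alchemical state with its dimensionless free energy.
#'
#' @param x An `fe_result`.
#' @param ... Unused.
#' @return Tibble with `state`, `f` (kT) and `n_samples`.
#' @export
tidy.fe_result <- function(x, ...) {
  if (is.null(x$f_k)) {
    return(tibble::tibble(state = integer(0), f = numeric(0),
                          n_samples = integer(0)))
  }
  tibble::tibble(state = seq_along(x$f_k), f = x$f_k,
                 n_samples = x$N_k %||% rep(NA_integer_, length(x$f_k)))
}

#' One-row summary of a free energy result
#'
#' @param x An `fe_result`.
#' @param ... Unused.
#' @return Tibble with `delta_g`, `sigma`, `error_bar_2sd`, `ci_lo`,
#'   `ci_hi`, `n_bootstrap` (energies in kcal/mol).
#' @export
glance.fe_result <- function(x, ...) {
  tibble::tibble(delta_g = x$delta_g, sigma = x$sigma,
                 error_bar_2sd = 2 * x$sigma,
                 ci_lo = x$ci95[1], ci_hi = x$ci95[2],
                 n_bootstrap = x$n_bootstrap)
}

#' Tidy a replica mixing report
#'
#' @param x A `mixing_report`.
#' @param ... Unused.
#' @return The per-replica summary tibble (states visited, round trips,
#'   chi-square uniformity p-value).
#' @export
tidy.mixing_report <- function(x, ...) x$replica_summary

#' One-row summary of a mixing report
#'
#' @param x A `mixing_report`.
#' @param ... Unused.
#' @return Tibble with `subdominant_eigenvalue`, `mean_round_trips`,
#'   `bottleneck`.
#' @export
glance.mixing_report <- function(x, ...) {
  tibble::tibble(subdominant_eigenvalue = x$subdominant_eigenvalue,
                 mean_round_trips = x$mean_round_trips,
                 bottleneck = x$bottleneck)
}

#' One-row summary of a convergence verdict
#'
#' @param x A `convergence_verdict`.
#' @param ... Unused.
#' @return Tibble with `slope`, `slope_2sd`, `window`, `threshold`,
#'   `converged`.
#' @export
glance.convergence_verdict <- function(x, ...) {
  tibble::tibble(slope = x$slope, slope_2sd = x$slope_2sd,
                 window = x$window, threshold = x$threshold,
                 converged = x$converged)
}

#' Plot a free energy time series
#'
#' dG(t) with a 2-SD ribbon, the standard convergence picture: a flat tail
#' indicates a converged estimate.
#'
#' @param object A `dg_series` from [dg_time_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dg_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_ns, y = .data$delta_g)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$delta_g - 2 * .data$sigma,
                   ymax = .data$delta_g + 2 * .data$sigma),
      fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::labs(x = "simulation time (ns)",
                  y = expression(Delta * G ~ "(kcal/mol)"),
                  title = "Free energy time series (ribbon: 2 SD)") +
    ggplot2::theme_minimal()
}

#' Plot replica state occupancies
#'
#' Heatmap of the fraction of iterations each replica spent in each
#' alchemical state; a uniform map indicates a healthy random walk through
#' the states.
#'
#' @param object A `mixing_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mixing_report <- function(object, ...) {
  occ <- object$occupancy
  df <- tidyr::expand_grid(replica = seq_len(nrow(occ)),
                           state = seq_len(ncol(occ)))
  df$fraction <- occ[cbind(df$replica, df$state)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$replica,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, max(df$fraction))) +
    ggplot2::labs(x = "alchemical state", y = "replica",
                  fill = "occupancy",
                  title = "Replica state occupancy") +
    ggplot2::theme_minimal()
}

#' Plot a dU/dlambda correlation table
#'
#' Dot-and-interval plot of the replica-averaged Pearson correlation of
#' each catalogued degree of freedom with dU/dlambda.
#'
#' @param object A `correlation_table` from [dudl_dof_correlation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_table <- function(object, ...) {
  df <- dplyr::filter(object, !.data$flagged)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pcc,
                                   y = stats::reorder(.data$dof_id,
                                                      abs(.data$pcc)),
                                   color = .data$category)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi), height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::xlim(-1, 1) +
    ggplot2::labs(x = "Pearson correlation with dU/dlambda",
                  y = NULL, color = "category") +
    ggplot2::theme_minimal()
}
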