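#' Convergence test on a free energy time series
#'
#' Ordinary least-squares slope of the trailing window of a dG(t) series.
#' The series is considered converged if the slope is close to zero:
#' either |slope| <= `threshold` (default 0.1 kcal/mol/ns) or zero lies
#' within slope +/- 2 standard errors.
#'
#' @param series A `dg_series` (from [dg_time_series()]) or any data frame
#'   with columns `t_ns` and `delta_g`.
#' @param window Trailing window length in ns; default half the series span.
#' @param threshold Convergence threshold, kcal/mol/ns.
#' @return List of class `convergence_verdict`: `slope`, `slope_2sd`,
#'   `window`, `n_points`, `converged`, `threshold`.
#' @export
convergence_slope_test <- function(series, window = NULL, threshold = 0.1) {
  stopifnot(all(c("t_ns", "delta_g") %in% names(series)))
  t <- series$t_ns; y <- series$delta_g
  span <- max(t) - min(t)
  if (is.null(window)) window <- span / 2
  if (window > span + 1e-12) stop("window longer than the series span")
  keep <- t >= max(t) - window - 1e-12
  if (sum(keep) < 3) stop("need at least 3 points in the trailing window")
  fit <- lm(y[keep] ~ t[keep])
  slope <- unname(coef(fit)[2])
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  if (!is.finite(se)) se <- 0  # exactly collinear points
  converged <- abs(slope) <= threshold ||
    (0 >= slope - 2 * se && 0 <= slope + 2 * se)
  structure(list(slope = slope, slope_2sd = 2 * se, window = window,
                 n_points = sum(keep), converged = converged,
                 threshold = threshold),
            class = "convergence_verdict")
}

#' @export
print.convergence_verdict <- function(x, ...) {
  cat(sprintf(
    "<convergence_verdict> slope %.4f +/- %.4f kcal/mol/ns over last %.3g ns: %s\n",
    x$slope, x$slope_2sd, x$window,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Replica mixing report
#'
#' Summarises how well replicas random-walk through the alchemical states:
#' per-replica state-occupancy histograms, the empirical state-transition
#' matrix and its subdominant eigenvalue, round-trip counts (state 1 to K
#' and back), a per-replica chi-square uniformity test (computed on the
#' state sequence thinned at its statistical inefficiency, since the raw
#' sequence is autocorrelated), and a bottleneck flag raised if any replica
#' fails to visit all states or the subdominant eigenvalue indicates slow
#' state-space mixing.
#'
#' @param record A `run_record`.
#' @param eigen_threshold Subdominant-eigenvalue threshold for the
#'   bottleneck flag.
#' @return List of class `mixing_report`: `occupancy` (K×K replica × state
#'   fractions), `replica_summary` (tibble: states visited, round trips,
#'   chi-square p), `transition_matrix`, `subdominant_eigenvalue`,
#'   `mean_round_trips`, `bottleneck`.
#' @export
replica_mixing_report <- function(record, eigen_threshold = 0.995) {
  stopifnot(inherits(record, "run_record"))
  S <- record$state_history
  K <- record$K
  n_iter <- nrow(S)
  occupancy <- t(apply(S, 2, function(s) tabulate(s, nbins = K))) / n_iter

  trans <- matrix(0, K, K)
  if (n_iter >= 2) {
    for (r in seq_len(K)) {
      from <- S[-n_iter, r]; to <- S[-1, r]
      for (i in seq_along(from)) trans[from[i], to[i]] <- trans[from[i], to[i]] + 1
    }
  }
  rs <- rowSums(trans)
  P <- trans
  P[rs > 0, ] <- P[rs > 0, ] / rs[rs > 0]
  sub_eig <- if (K >= 2 && all(rs > 0)) {
    ev <- sort(Mod(eigen(P, only.values = TRUE)$values), decreasing = TRUE)
    ev[2]
  } else if (K == 1) 0 else 1

  round_trips <- integer(K)
  visited <- integer(K)
  chisq_p <- numeric(K)
  for (r in seq_len(K)) {
    s <- S[, r]
    visited[r] <- length(unique(s))
    # completed 1 -> K -> 1 excursions
    phase <- 0L; n_rt <- 0L
    for (v in s) {
      if (phase == 0L && v == 1L) phase <- 1L
      else if (phase == 1L && v == K) phase <- 2L
      else if (phase == 2L && v == 1L) { n_rt <- n_rt + 1L; phase <- 1L }
    }
    round_trips[r] <- if (K == 1) n_iter else n_rt
    if (K >= 2 && var(s) > 0 && n_iter >= 10) {
      g <- statistical_inefficiency(s)$g
      thin <- s[seq(1, n_iter, by = ceiling(g))]
      counts <- tabulate(thin, nbins = K)
      chisq_p[r] <- suppressWarnings(
        stats::chisq.test(counts, p = rep(1 / K, K))$p.value)
    } else {
      chisq_p[r] <- if (K == 1) 1 else 0
    }
  }
  bottleneck <- any(visited < K) || sub_eig > eigen_threshold
  structure(list(
    occupancy = occupancy,
    replica_summary = tibble::tibble(
      replica = seq_len(K), states_visited = visited,
      round_trips = round_trips, chisq_p = chisq_p),
    transition_matrix = P,
    subdominant_eigenvalue = sub_eig,
    mean_round_trips = mean(round_trips),
    bottleneck = bottleneck
  ), class = "mixing_report")
}

#' @export
print.mixing_report <- function(x, ...) {
  cat(sprintf(
    "<mixing_report> subdominant eigenvalue %.3f | mean round trips %.1f | %s\n",
    x$subdominant_eigenvalue, x$mean_round_trips,
    if (x$bottleneck) "BOTTLENECK flagged" else "no bottleneck"))
  invisible(x)
}

#' Catalogue of conformational degrees of freedom
#'
#' Resolves the observable series used by the correlation diagnostics, one
#' series per registered degree of freedom per replica: torsion angles for
#' registered quadruples (degrees, degenerate frames `NA`), pair distances
#' for registered contacts, neighbour counts within a radius of the
#' mutating particles, and raw tagged coordinates. Uses the series recorded
#' during the run when available, otherwise recomputes them from stored
#' configurations.
#'
#' @param record A `run_record`.
#' @param hybrid The hybrid system (defaults to the one stored in the
#'   record).
#' @param spec Observable registration table (defaults to the fixture's).
#' @return List of class `dof_catalog`: `series` (named list of
#'   iteration × replica matrices) and `spec`.
#' @export
dof_catalog <- function(record, hybrid = record$hybrid,
                        spec = hybrid$observables) {
  stopifnot(inherits(record, "run_record"))
  if (is.null(spec)) stop("no observables registered for this fixture")
  have <- names(record$observables)
  series <- list()
  need_configs <- setdiff(spec$id, have)
  if (length(need_configs) && is.null(record$configurations)) {
    stop(sprintf("observables not recorded and no configurations stored: %s",
                 paste(need_configs, collapse = ", ")))
  }
  attr(spec, "mutating_idx") <- which(hybrid$tags == "mutating")
  for (row in seq_len(nrow(spec))) {
    id <- spec$id[row]
    if (id %in% have) {
      series[[id]] <- record$observables[[id]]
    } else {
      K <- record$K; n_iter <- record$n_iterations
      m <- matrix(NA_real_, n_iter, K)
      for (it in seq_len(n_iter)) {
        for (r in seq_len(K)) {
          m[it, r] <- eval_observables(spec[row, , drop = FALSE],
                                       record$configurations[, , r, it])[[1]]
        }
      }
      series[[id]] <- m
    }
  }
  structure(list(series = series, spec = spec), class = "dof_catalog")
}

#' Correlation of dU/dlambda with conformational degrees of freedom
#'
#' For each catalogued degree of freedom, the Pearson correlation
#' coefficient between the per-replica dU/dlambda series and the observable
#' series, averaged over replicas; the 95% CI is obtained by bootstrapping
#' over replicas. Degrees of freedom tightly coupled to dU/dlambda (large
#' |PCC|) are the candidates for causing slow free energy convergence. The
#' statistical inefficiency of dU/dlambda itself is reported in time units
#' alongside.
#'
#' @param record A `run_record`.
#' @param observables A [dof_catalog()]; computed from the record if
#'   missing.
#' @param n_bootstrap Bootstrap resamples over replicas for the CI.
#' @param seed Bootstrap seed.
#' @return A tibble of class `correlation_table`: `dof_id`, `category`,
#'   `pcc` (replica mean), `ci_lo`, `ci_hi`, `n_replicas`, `flagged`
#'   (zero-variance), `dudl_g_ns`. Per-replica PCCs are kept in the
#'   `"per_replica"` attribute.
#' @export
dudl_dof_correlation <- function(record, observables = dof_catalog(record),
                                 n_bootstrap = 1000, seed = 1) {
  stopifnot(inherits(record, "run_record"))
  K <- record$K
  dudl_g <- max(vapply(seq_len(K), function(r) {
    s <- record$dudl[, r]
    if (var(s) == 0) 1 else
      statistical_inefficiency(s, record$sampling_interval_ns)$g
  }, numeric(1)))
  dudl_g_ns <- dudl_g * record$sampling_interval_ns

  local_seed(seed)
  ids <- names(observables$series)
  per_replica <- matrix(NA_real_, length(ids), K, dimnames = list(ids, NULL))
  rows <- list()
  for (id in ids) {
    obs <- observables$series[[id]]
    pccs <- vapply(seq_len(K), function(r) {
      o <- obs[, r]; d <- record$dudl[, r]
      ok <- is.finite(o) & is.finite(d)
      if (sum(ok) < 3 || var(o[ok]) == 0 || var(d[ok]) == 0) return(NA_real_)
      cor(d[ok], o[ok])
    }, numeric(1))
    per_replica[id, ] <- pccs
    good <- pccs[is.finite(pccs)]
    flagged <- length(good) == 0
    if (!flagged) {
      boots <- vapply(seq_len(n_bootstrap), function(b) {
        mean(good[sample.int(length(good), length(good), replace = TRUE)])
      }, numeric(1))
      ci <- unname(quantile(boots, c(0.025, 0.975)))
    } else ci <- c(NA_real_, NA_real_)
    cat_row <- observables$spec$category[observables$spec$id == id][1]
    rows[[length(rows) + 1]] <- tibble::tibble(
      dof_id = id, category = cat_row,
      pcc = if (flagged) NA_real_ else mean(good),
      ci_lo = ci[1], ci_hi = ci[2],
      n_replicas = sum(is.finite(pccs)), flagged = flagged,
      dudl_g_ns = dudl_g_ns)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "per_replica") <- per_replica
  class(out) <- c("correlation_table", class(out))
  out
}

#' Per-category summary of a correlation table
#'
#' For each degree-of-freedom category, picks the entry with the largest
#' |PCC| (sign preserved), the machine-readable analogue of a per-mutation
#' heatmap row; rows are ordered by the statistical inefficiency of
#' dU/dlambda, descending, so the slowest mutations come first.
#'
#' @param table A `correlation_table` (rows from one or more mutations).
#' @return Tibble: `category`, `dof_id`, `pcc`, `ci_lo`, `ci_hi`,
#'   `dudl_g_ns`.
#' @export
correlation_summary <- function(table) {
  stopifnot(nrow(table) > 0)
  usable <- dplyr::filter(table, !.data$flagged & is.finite(.data$pcc))
  dropped <- setdiff(unique(table$category), unique(usable$category))
  if (length(dropped)) {
    message("categories omitted (no usable entries): ",
            paste(dropped, collapse = ", "))
  }
  usable |>
    dplyr::group_by(.data$dudl_g_ns, .data$category) |>
    dplyr::slice_max(abs(.data$pcc), n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$dudl_g_ns), dplyr::desc(abs(.data$pcc))) |>
    dplyr::select("category", "dof_id", "pcc", "ci_lo", "ci_hi", "dudl_g_ns")
}

#' Forward/reverse internal consistency
#'
#' A transformation estimated in both directions is internally consistent
#' if the forward free energy agrees with the negated reverse one within
#' statistical error: inconsistency is declared only when neither the
#' forward value is within `margin` (default 1 kcal/mol) of the negated
#' reverse 95% CI, nor the negated reverse value within `margin` of the
#' forward 95% CI. The rule is symmetric in the two directions.
#'
#' @param forward,reverse `fe_result` objects for the two directions.
#' @param margin CI proximity margin, kcal/mol.
#' @return List of class `consistency_report`: `discrepancy`
#'   (forward + reverse, kcal/mol), `sigma`, `consistent`.
#' @export
internal_consistency <- function(forward, reverse, margin = 1) {
  stopifnot(inherits(forward, "fe_result"), inherits(reverse, "fe_result"))
  disc <- forward$delta_g + reverse$delta_g  # fwd - (-rev)
  neg_rev <- -reverse$delta_g
  neg_rev_ci <- sort(-reverse$ci95)
  dist_to <- function(x, ci) max(0, ci[1] - x, x - ci[2])
  fail_fwd <- dist_to(forward$delta_g, neg_rev_ci) > margin
  fail_rev <- dist_to(neg_rev, forward$ci95) > margin
  structure(list(
    discrepancy = disc,
    sigma = sqrt(forward$sigma^2 + reverse$sigma^2),
    forward = forward$delta_g, reverse = reverse$delta_g,
    consistent = !(fail_fwd && fail_rev), margin = margin
  ), class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "<consistency_report> fwd %.3f, rev %.3f, discrepancy %.3f +/- %.3f: %s\n",
    x$forward, x$reverse, x$discrepancy, 2 * x$sigma,
    if (x$consistent) "consistent" else "INCONSISTENT"))
  invisible(x)
}

#' Accuracy metrics for a set of discrepancies
#'
#' Root-mean-square error and mean unsigned error of a set of values
#' (e.g. forward/reverse discrepancies or deviations from a reference),
#' with 95% CIs from bootstrapping the set.
#'
#' @param values Numeric vector.
#' @param n_bootstrap Bootstrap resamples (default 1000).
#' @param seed Bootstrap seed.
#' @return Tibble with `metric` (`rmse`, `mue`), `value`, `ci_lo`, `ci_hi`.
#' @export
consistency_metrics <- function(values, n_bootstrap = 1000, seed = 1) {
  values <- values[is.finite(values)]
  stopifnot(length(values) >= 1)
  local_seed(seed)
  rmse <- function(v) sqrt(mean(v^2))
  mue <- function(v) mean(abs(v))
  bt <- vapply(seq_len(n_bootstrap), function(b) {
    v <- values[sample.int(length(values), length(values), replace = TRUE)]
    c(rmse(v), mue(v))
  }, numeric(2))
  tibble::tibble(
    metric = c("rmse", "mue"),
    value = c(rmse(values), mue(values)),
    ci_lo = unname(c(quantile(bt[1, ], 0.025), quantile(bt[2, ], 0.025))),
    ci_hi = unname(c(quantile(bt[1, ], 0.975), quantile(bt[2, ], 0.975))))
}

#' Restrained-vs-unrestrained convergence comparison
#'
#' Diagnostic for whether slow convergence is caused by conformational
#' sampling: if positional restraints make the dG time series converge
#' while the unrestrained series does not, the sampling problem is
#' conformational; if both converge, no problem is detected; otherwise the
#' problem is not solely conformational.
#'
#' @param unrestrained,restrained `dg_series` objects (see
#'   [dg_time_series()]) from matched runs without and with restraints.
#' @param threshold Slope threshold, kcal/mol/ns.
#' @param window Trailing window, ns (default half-span).
#' @return List of class `restrained_verdict`: `verdict` (one of
#'   `"conformational-sampling problem"`, `"no detected problem"`,
#'   `"not solely conformational"`) plus both `convergence_verdict`s.
#' @export
restrained_comparison <- function(unrestrained, restrained, threshold = 0.1,
                                  window = NULL) {
  vu <- convergence_slope_test(unrestrained, window = window,
                               threshold = threshold)
  vr <- convergence_slope_test(restrained, window = window,
                               threshold = threshold)
  verdict <- if (!vu$converged && vr$converged) {
    "conformational-sampling problem"
  } else if (vu$converged && vr$converged) {
    "no detected problem"
  } else {
    "not solely conformational"
  }
  structure(list(verdict = verdict, unrestrained = vu, restrained = vr),
            class = "restrained_verdict")
}

#' @export
print.restrained_verdict <- function(x, ...) {
  cat(sprintf("<restrained_verdict> %s (unrestrained %s, restrained %s)\n",
              x$verdict,
              if (x$unrestrained$converged) "converged" else "drifting",
              if (x$restrained$converged) "converged" else "drifting"))
  invisible(x)
}
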