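#' Statistical inefficiency of a time series
#'
#' `g = 1 + 2 * sum_t C(t)` (equivalently `2 tau + 1` with `tau` the
#' integrated autocorrelation time), where the normalised autocorrelation
#' `C(t)` is summed up to its first crossing below zero (initial-positive
#' truncation). `g` is the subsampling stride that yields effectively
#' independent samples; multiplied by the sampling interval it is the value
#' reported in time units.
#'
#' @param series Numeric time series (length >= 10, finite).
#' @param sampling_interval_ns Nominal time per sample for the time-unit
#'   report (default 0.1 ns).
#' @return List with `g` (samples, >= 1), `g_ns` (time units), `tau`
#'   (integrated autocorrelation time, samples), `truncation_lag`, and
#'   `degenerate` (`TRUE` for a constant series, where `g` is defined as 1).
#' @export
#' @examples
#' set.seed(1)
#' statistical_inefficiency(rnorm(1000))$g  # close to 1
statistical_inefficiency <- function(series, sampling_interval_ns = 0.1) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 10) stop("series must have length >= 10")
  if (any(!is.finite(series))) stop("series must be finite")
  if (var(series) == 0) {
    return(list(g = 1, g_ns = sampling_interval_ns, tau = 0,
                truncation_lag = 0L, degenerate = TRUE))
  }
  x <- series - mean(series)
  np <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(x, rep(0, np - n)))
  s <- Re(stats::fft(Mod(f)^2, inverse = TRUE)) / np
  C <- s[seq_len(n)] / s[1]
  neg <- which(C[-1] <= 0)
  t_max <- if (length(neg)) neg[1] - 1L else n - 1L
  tau <- if (t_max >= 1) sum(C[2:(t_max + 1)]) else 0
  g <- max(1, 1 + 2 * tau)
  list(g = g, g_ns = g * sampling_interval_ns, tau = tau,
       truncation_lag = t_max, degenerate = FALSE)
}

#' Decorrelate a run record into a reduced potential matrix
#'
#' Discards a burn-in fraction, estimates the statistical inefficiency `g`
#' of a driver series (by default the per-replica dU/dlambda, taking the
#' maximum `g` over replicas, since slowly varying dU/dlambda is the
#' convergence-limiting quantity), subsamples iterations at stride
#' `ceiling(g)`, and assembles the decorrelated reduced potential matrix
#' `u[k, n]` grouped by the state each sample was generated at.
#'
#' @param record A `run_record` from [run_arex()] / [run_arest()].
#' @param burn_in Fraction of iterations to discard (default 0.1).
#' @param driver Driver series for `g`: `"dudl"` (default) or the name of a
#'   recorded observable.
#' @param min_per_state Minimum average samples per state required
#'   (default 5).
#' @return A `reduced_potential_matrix`: list with `u` (K × N, kT), `N_k`,
#'   `state_of_sample`, `g`, retained iteration `indices`, `lambdas` and
#'   `temperature`.
#' @export
decorrelate <- function(record, burn_in = 0.1, driver = "dudl",
                        min_per_state = 5) {
  stopifnot(inherits(record, "run_record"))
  n_iter <- record$n_iterations
  K <- record$K
  start <- floor(burn_in * n_iter) + 1
  if (start > n_iter - 2) stop("burn-in leaves too few iterations")
  kept <- start:n_iter

  series_mat <- if (identical(driver, "dudl")) {
    record$dudl
  } else if (driver %in% names(record$observables)) {
    record$observables[[driver]]
  } else stop(sprintf("unknown driver series '%s'", driver))
  g <- 1
  if (length(kept) >= 10) {
    g <- max(vapply(seq_len(K), function(r) {
      s <- series_mat[kept, r]
      if (var(s) == 0) 1 else statistical_inefficiency(s)$g
    }, numeric(1)))
  }
  stride <- ceiling(g)
  sub <- kept[seq(1, length(kept), by = stride)]

  n_total <- length(sub) * K
  u <- matrix(NA_real_, K, n_total)
  state_of_sample <- integer(n_total)
  col <- 0
  for (it in sub) {
    for (r in seq_len(K)) {
      col <- col + 1
      u[, col] <- record$u[, r, it]
      state_of_sample[col] <- record$state_history[it, r]
    }
  }
  ord <- order(state_of_sample)
  u <- u[, ord, drop = FALSE]
  state_of_sample <- state_of_sample[ord]
  N_k <- tabulate(state_of_sample, nbins = K)
  if (sum(N_k) < K * min_per_state) {
    stop(sprintf(
      "only %d decorrelated samples for %d states; run longer or reduce burn-in",
      sum(N_k), K))
  }
  structure(list(
    u = u, N_k = N_k, state_of_sample = state_of_sample, g = g,
    burn_in = burn_in, indices = sub, lambdas = record$lambdas,
    temperature = record$temperature,
    provenance = list(method = record$method, seed = record$seed,
                      driver = driver)
  ), class = "reduced_potential_matrix")
}

#' @export
print.reduced_potential_matrix <- function(x, ...) {
  cat(sprintf("<reduced_potential_matrix> K=%d states, N=%d samples (g=%.2f)\n",
              nrow(x$u), ncol(x$u), x$g))
  invisible(x)
}

log_sum_exp_cols <- function(A) {
  K <- nrow(A)
  m <- A[1, ]
  if (K > 1) for (k in 2:K) m <- pmax(m, A[k, ])
  m + log(colSums(exp(A - rep(m, each = K))))
}

#' Solve the MBAR equations
#'
#' Estimates the dimensionless free energies `f_k` of all states from the
#' reduced potential matrix by the multistate Bennett acceptance ratio:
#' self-consistent iteration to approach the solution, then Newton-Raphson
#' on the states with samples for quadratic convergence. States with zero
#' samples are treated as perturbation states and evaluated from the final
#' mixture distribution. Gauge `f_1 = 0`.
#'
#' @param matrix A `reduced_potential_matrix` (or a plain list with `u` and
#'   `N_k`).
#' @param tolerance Convergence tolerance on the free energy increment.
#' @param max_iterations Iteration cap.
#' @param f_init Optional warm start.
#' @return List of class `mbar_fit`: `f_k` (dimensionless, `f_k[1] = 0`),
#'   `N_k`, `converged`, `iterations`.
#' @export
mbar_solve <- function(matrix, tolerance = 1e-8, max_iterations = 2000,
                       f_init = NULL) {
  u <- matrix$u
  N_k <- matrix$N_k
  K <- nrow(u); N <- ncol(u)
  stopifnot(length(N_k) == K, sum(N_k) == N)
  sampled <- which(N_k > 0)
  f <- if (is.null(f_init)) numeric(K) else as.numeric(f_init)
  logN <- rep(-Inf, K); logN[sampled] <- log(N_k[sampled])

  denom <- function(f) {
    # log sum_l N_l exp(f_l - u_ln), per sample
    log_sum_exp_cols((f[sampled] + logN[sampled]) - u[sampled, , drop = FALSE])
  }
  update_f <- function(f) {
    d <- denom(f)
    fk <- vapply(seq_len(K), function(k) {
      -log_sum_exp_scalar(-u[k, ] - d)
    }, numeric(1))
    fk - fk[1]
  }

  converged <- FALSE
  it <- 0
  # a few self-consistent sweeps to reach the Newton basin (none when warm)
  n_sc <- if (is.null(f_init)) 5L else 0L
  for (s in seq_len(min(n_sc, max_iterations))) {
    it <- it + 1
    f_new <- update_f(f)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tolerance) { converged <- TRUE; break }
  }
  # Newton-Raphson on the sampled states (gauge: first sampled state fixed).
  # Boltzmann factors are precomputed with a per-sample shift (free energies
  # are invariant to per-sample constants) so the loop is pure linear algebra.
  if (!converged && length(sampled) > 1) {
    E_s <- boltzmann_factors(u[sampled, , drop = FALSE])
    core <- mbar_newton(E_s, N_k[sampled], f[sampled], tolerance,
                        max_iterations - it)
    it <- it + core$iterations
    converged <- core$converged
    f[sampled] <- core$f
    f <- f - f[sampled[1]]
  } else if (!converged) {
    while (it < max_iterations) {
      it <- it + 1
      f_new <- update_f(f)
      delta <- max(abs(f_new - f))
      f <- f_new
      if (delta < tolerance) { converged <- TRUE; break }
    }
  }
  if (!converged) {
    d <- denom(f)
    res <- max(abs(update_f(f) - f))
    stop(sprintf("MBAR failed to converge in %d iterations (residual %.3g)",
                 max_iterations, res))
  }
  # final pass so zero-sample (perturbation) states are consistent
  if (any(N_k == 0)) f <- update_f(f)
  structure(list(f_k = f, N_k = N_k, converged = converged, iterations = it),
            class = "mbar_fit")
}

log_sum_exp_scalar <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

# exp(-(u - per-sample min)): per-sample shifts leave free energy
# differences invariant and keep the factors in [0, 1]
boltzmann_factors <- function(us) {
  Ks <- nrow(us)
  shift <- us[1, ]
  if (Ks > 1) for (k in 2:Ks) shift <- pmin(shift, us[k, ])
  exp(-(us - rep(shift, each = Ks)))
}

# Newton solve of the MBAR equations on precomputed Boltzmann factors;
# all states assumed sampled (Ns > 0). Returns f relative to state 1.
mbar_newton <- function(E_s, Ns, f_init, tolerance, max_iterations) {
  Ks <- nrow(E_s)
  f <- f_init - f_init[1]
  free_i <- seq_len(Ks)[-1]
  it <- 0
  converged <- FALSE
  while (it < max_iterations) {
    it <- it + 1
    Nf <- Ns * exp(f)
    dn <- as.vector(Nf %*% E_s)
    W <- (E_s * Nf) / rep(dn, each = Ks)
    rs <- rowSums(W)
    grad <- rs - Ns
    H <- -tcrossprod(W)
    diag(H) <- diag(H) + rs
    Hf <- H[free_i, free_i, drop = FALSE]
    gf <- grad[free_i]
    step <- tryCatch(solve(Hf + diag(1e-10, nrow(Hf)), gf),
                     error = function(e) gf / (diag(Hf) + 1e-10))
    if (!all(is.finite(step))) stop("MBAR iteration diverged")
    # damp overshooting steps
    while (max(abs(step)) > 2) step <- step / 2
    f[free_i] <- f[free_i] - step
    if (!all(is.finite(f))) stop("MBAR iteration diverged")
    if (max(abs(step)) < tolerance) { converged <- TRUE; break }
  }
  list(f = f, converged = converged, iterations = it)
}

#' Free energy difference with bootstrap uncertainty
#'
#' Solves MBAR on the decorrelated reduced potential matrix, then resamples
#' samples with replacement within each state `n_bootstrap` times (the
#' default 200 matches common practice) and re-solves MBAR per resample
#' (warm-started). The headline uncertainty is the bootstrap standard
#' deviation; error bars in reports are 2 SD; `ci95` is the percentile
#' interval.
#'
#' @param matrix A `reduced_potential_matrix`.
#' @param n_bootstrap Number of bootstrap resamples.
#' @param seed Integer seed for resampling.
#' @param resample_tolerance MBAR tolerance for the (warm-started) resample
#'   solves; looser than the point-estimate solve since bootstrap noise
#'   dominates.
#' @return Object of class `fe_result`: `f_k`, `delta_g` (kcal/mol, last
#'   state minus first), `sigma` (kcal/mol, bootstrap SD), `ci95`,
#'   `n_bootstrap`, `N_k`, `temperature`.
#' @export
bootstrap_delta_g <- function(matrix, n_bootstrap = 200, seed = 1,
                              resample_tolerance = 1e-6) {
  fit <- mbar_solve(matrix)
  kT <- kt_kcal(matrix$temperature)
  K <- nrow(matrix$u)
  dg <- (fit$f_k[K] - fit$f_k[1]) * kT
  local_seed(seed)
  by_state <- split(seq_len(ncol(matrix$u)), matrix$state_of_sample)
  boots <- numeric(n_bootstrap)
  max_redraw <- 5L
  all_sampled <- all(matrix$N_k > 0)
  E_full <- if (all_sampled) boltzmann_factors(matrix$u) else NULL
  for (b in seq_len(n_bootstrap)) {
    ok <- FALSE
    for (att in seq_len(max_redraw)) {
      idx <- unlist(lapply(by_state, function(ix) {
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }), use.names = FALSE)
      fit_b <- tryCatch({
        if (all_sampled) {
          mbar_newton(E_full[, idx, drop = FALSE], matrix$N_k, fit$f_k,
                      resample_tolerance, 500)$f
        } else {
          mbar_solve(list(u = matrix$u[, idx, drop = FALSE],
                          N_k = matrix$N_k),
                     tolerance = resample_tolerance, f_init = fit$f_k)$f_k
        }
      }, error = function(e) NULL)
      if (!is.null(fit_b)) {
        boots[b] <- (fit_b[K] - fit_b[1]) * kT
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      warning("bootstrap resample failed to converge repeatedly; using point estimate")
      boots[b] <- dg
    }
  }
  sigma <- sd(boots)
  ci <- unname(quantile(boots, c(0.025, 0.975)))
  ci[1] <- min(ci[1], dg); ci[2] <- max(ci[2], dg)
  structure(list(
    f_k = fit$f_k, delta_g = dg, sigma = sigma, ci95 = ci,
    n_bootstrap = n_bootstrap, N_k = matrix$N_k, bootstrap_samples = boots,
    temperature = matrix$temperature
  ), class = "fe_result")
}

#' @export
print.fe_result <- function(x, ...) {
  cat(sprintf(
    "<fe_result> dG = %.4f +/- %.4f kcal/mol (2 SD; 95%% CI [%.4f, %.4f], %d bootstraps)\n",
    x$delta_g, 2 * x$sigma, x$ci95[1], x$ci95[2], x$n_bootstrap))
  invisible(x)
}

#' Relative free energy between two phases
#'
#' `ddG = dG_phase2 - dG_phase1`, with the bootstrap standard deviations
#' combined in quadrature (the two phases are independent calculations).
#'
#' @param phase1,phase2 `fe_result` objects (e.g. apo and complex).
#' @return An `fe_result` holding the difference.
#' @export
delta_delta_g <- function(phase1, phase2) {
  stopifnot(inherits(phase1, "fe_result"), inherits(phase2, "fe_result"))
  if (!isTRUE(all.equal(phase1$temperature, phase2$temperature))) {
    stop("phases must be at the same temperature")
  }
  d <- phase2$delta_g - phase1$delta_g
  s <- sqrt(phase1$sigma^2 + phase2$sigma^2)
  structure(list(
    f_k = NULL, delta_g = d, sigma = s,
    ci95 = c(d - 1.96 * s, d + 1.96 * s),
    n_bootstrap = min(phase1$n_bootstrap, phase2$n_bootstrap),
    N_k = NULL, temperature = phase1$temperature
  ), class = "fe_result")
}

#' Free energy estimate as a function of simulation time
#'
#' For each truncation time (evenly spaced over the record) the record is
#' decorrelated and MBAR + bootstrap are run on the data up to that time.
#' The trailing slope of this series is the convergence criterion (see
#' [convergence_slope_test()]).
#'
#' @param record A `run_record`.
#' @param n_points Number of truncation points (>= 3).
#' @param burn_in Burn-in fraction applied at each truncation.
#' @param n_bootstrap Bootstrap resamples per point.
#' @param seed Bootstrap seed.
#' @param min_per_state Decorrelation sample floor per truncation; the
#'   default (1) is laxer than [decorrelate()]'s because early truncations
#'   of strongly correlated runs are informative even when sparse.
#' @return Tibble of class `dg_series` with columns `t_iter`, `t_ns`,
#'   `delta_g`, `sigma`, `n_samples`.
#' @export
dg_time_series <- function(record, n_points = 10, burn_in = 0.1,
                           n_bootstrap = 200, seed = 1, min_per_state = 1) {
  stopifnot(inherits(record, "run_record"), n_points >= 3)
  n_iter <- record$n_iterations
  cuts <- unique(round(seq(max(10, n_iter / n_points), n_iter,
                           length.out = n_points)))
  rows <- list()
  for (tc in cuts) {
    rec_t <- truncate_record(record, tc)
    m <- tryCatch(decorrelate(rec_t, burn_in = burn_in,
                              min_per_state = min_per_state),
                  error = function(e) NULL)
    if (is.null(m)) {
      message(sprintf("truncation at %d iterations skipped (too few samples)", tc))
      next
    }
    fe <- bootstrap_delta_g(m, n_bootstrap = n_bootstrap, seed = seed)
    rows[[length(rows) + 1]] <- tibble::tibble(
      t_iter = tc, t_ns = tc * record$sampling_interval_ns,
      delta_g = fe$delta_g, sigma = fe$sigma, n_samples = sum(m$N_k))
  }
  if (length(rows) < 3) stop("fewer than 3 usable truncation points")
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dg_series", class(out))
  out
}

#' Truncate a run record to its first iterations
#'
#' @param record A `run_record`.
#' @param n_keep Number of leading iterations to keep.
#' @return The truncated `run_record`.
#' @export
truncate_record <- function(record, n_keep) {
  stopifnot(inherits(record, "run_record"), n_keep >= 1,
            n_keep <= record$n_iterations)
  record$u <- record$u[, , seq_len(n_keep), drop = FALSE]
  record$state_history <- record$state_history[seq_len(n_keep), , drop = FALSE]
  record$dudl <- record$dudl[seq_len(n_keep), , drop = FALSE]
  record$observables <- lapply(record$observables,
                               function(m) m[seq_len(n_keep), , drop = FALSE])
  if (!is.null(record$configurations)) {
    record$configurations <-
      record$configurations[, , , seq_len(n_keep), drop = FALSE]
  }
  record$n_iterations <- n_keep
  record
}
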