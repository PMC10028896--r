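## Brute-force oracles used by the test suite: numerical quadrature of toy
## configurational integrals, exact enumeration of small discrete
## replica-exchange models, and long-budget reference runs. These are kept
## independent of the compiled alchemical path on purpose.

#' Free energy difference by numerical quadrature
#'
#' Directly integrates the configurational integrals of both endstates for
#' fixtures whose old/new difference is confined to separable blocks of at
#' most one coordinate: the harmonic ladder (per-axis Gaussian integrals),
#' the two-particle LJ cluster (1-D radial integral over the pair
#' separation) and the double-well fixture (1-D integral over the slow
#' coordinate). The reported tolerance combines the integrator's error
#' estimates.
#'
#' @param pair A [mutation_pair()].
#' @param temperature Temperature, K.
#' @return List of class `oracle_result`: `value` (kcal/mol), `method`,
#'   `tolerance`, `provenance`.
#' @export
quadrature_delta_g <- function(pair, temperature = pair$temperature) {
  stopifnot(inherits(pair, "mutation_pair"))
  kT <- kt_kcal(temperature)
  beta <- 1 / kT
  old <- pair$old_system; new <- pair$new_system

  ratio_1d <- function(v_old, v_new, lower, upper) {
    # returns list(log_ratio, tol) for ln(Z_new/Z_old) of a 1-D block
    zo <- integrate(function(s) exp(-beta * v_old(s)), lower, upper,
                    rel.tol = 1e-11, abs.tol = 0)
    zn <- integrate(function(s) exp(-beta * v_new(s)), lower, upper,
                    rel.tol = 1e-11, abs.tol = 0)
    list(log_ratio = log(zn$value) - log(zo$value),
         tol = kT * (zo$abs.error / zo$value + zn$abs.error / zn$value))
  }

  if (pair$kind == "harmonic_ladder") {
    ro <- old$restraints; rn <- new$restraints
    dg <- 0; tol <- 0
    for (t in seq_len(nrow(ro))) {
      ko <- ro$k_spring[t]; kn <- rn$k_spring[t]
      if (ko == kn) next
      span <- 12 / sqrt(beta * min(ko, kn))
      r1 <- ratio_1d(function(s) 0.5 * ko * s^2,
                     function(s) 0.5 * kn * s^2, -span, span)
      dg <- dg - 3 * kT * r1$log_ratio  # three identical axes
      tol <- tol + 3 * r1$tol
    }
    return(oracle_result(dg, "quadrature", max(tol, 1e-12),
                         list(kind = pair$kind, temperature = temperature)))
  }

  if (pair$kind == "lj_cluster" && old$n_particles == 2 &&
      !is.null(old$bonds) && nrow(old$bonds) == 1) {
    pairpot <- function(sys) {
      b <- sys$bonds
      q12 <- sys$charges[1] * sys$charges[2]
      eps <- sqrt(sys$lj_epsilon[1] * sys$lj_epsilon[2])
      sig <- (sys$lj_sigma[1] + sys$lj_sigma[2]) / 2
      function(r) {
        e <- 0.5 * b$k_spring * (r - b$r0)^2
        if (q12 != 0) e <- e + alchrex_constants$coulomb * q12 / r
        if (eps > 0) {
          x6 <- (sig / r)^6
          e <- e + 4 * eps * x6 * (x6 - 1)
        }
        e
      }
    }
    vo <- pairpot(old); vn <- pairpot(new)
    # radial configurational integral, weight r^2; COM and angles cancel
    zo <- integrate(function(r) r^2 * exp(-beta * vapply(r, vo, 1)),
                    1e-3, 2.5, rel.tol = 1e-11, abs.tol = 0)
    zn <- integrate(function(r) r^2 * exp(-beta * vapply(r, vn, 1)),
                    1e-3, 2.5, rel.tol = 1e-11, abs.tol = 0)
    dg <- -kT * (log(zn$value) - log(zo$value))
    tol <- kT * (zo$abs.error / zo$value + zn$abs.error / zn$value)
    return(oracle_result(dg, "quadrature", max(tol, 1e-12),
                         list(kind = pair$kind, temperature = temperature)))
  }

  if (pair$kind == "double_well") {
    mk <- function(dw, anchor) {
      force(dw); force(anchor)
      function(xs) {
        s <- (xs - dw$center) / dw$s0
        dw$barrier * (s^2 - 1)^2 + dw$tilt * s +
          0.5 * anchor$k_spring * (xs - anchor$x0)^2
      }
    }
    dg <- 0; tol <- 0
    for (t in seq_len(nrow(old$doublewells))) {
      i <- old$doublewells$i[t]
      dwo <- old$doublewells[t, ]
      dwn <- new$doublewells[new$doublewells$i == i, ]
      ro <- old$restraints[old$restraints$i == i, ]
      span <- c(dwo$center - 6 * dwo$s0, dwo$center + 6 * dwo$s0)
      r1 <- ratio_1d(mk(dwo, ro), mk(dwn, ro), span[1], span[2])
      dg <- dg - kT * r1$log_ratio
      tol <- tol + r1$tol
    }
    return(oracle_result(dg, "quadrature", max(tol, 1e-12),
                         list(kind = pair$kind, temperature = temperature)))
  }

  stop(sprintf(
    "no separable quadrature for fixture kind '%s'; use long_reference_delta_g",
    pair$kind))
}

oracle_result <- function(value, method, tolerance, provenance = list()) {
  stopifnot(tolerance > 0)
  structure(list(value = value, method = method, tolerance = tolerance,
                 provenance = provenance), class = "oracle_result")
}

#' @export
print.oracle_result <- function(x, ...) {
  cat(sprintf("<oracle_result> %s: %.8f kcal/mol (tol %.2g)\n",
              x$method, x$value, x$tolerance))
  invisible(x)
}

#' Discrete replica-exchange model
#'
#' A fully enumerable model: each replica occupies one of `n_configs`
#' discrete configurations with reduced energies `u[k, c]` at state `k`.
#' Used as the exact oracle for the swap kernel's stationary distribution.
#'
#' @param u K × n_configs matrix of reduced energies.
#' @return List of class `discrete_model`.
#' @export
discrete_exchange_model <- function(u) {
  u <- as.matrix(u)
  structure(list(u = u, K = nrow(u), n_configs = ncol(u)),
            class = "discrete_model")
}

#' Exact joint density of configurations and state permutation
#'
#' Enumerates `P(X, S) = (1/K!) prod_k p(x_k | s_k)` over all configuration
#' assignments and state permutations of a [discrete_exchange_model()].
#'
#' @param model A `discrete_exchange_model`.
#' @param max_outcomes Safety cap on the joint space size.
#' @return Tibble: one row per joint outcome with the replica configuration
#'   columns `x1..xK`, the permutation columns `s1..sK` and `prob`.
#' @export
enumerate_joint_density <- function(model, max_outcomes = 1e4) {
  stopifnot(inherits(model, "discrete_model"))
  K <- model$K; nc <- model$n_configs
  perms <- all_permutations(K)
  n_out <- nrow(perms) * nc^K
  if (n_out > max_outcomes) stop("joint outcome space too large to enumerate")
  p_xs <- exp(-model$u)                      # unnormalised p(x | state)
  p_xs <- sweep(p_xs, 1, rowSums(p_xs), "/") # normalise per state
  configs <- as.matrix(expand.grid(rep(list(seq_len(nc)), K)))
  rows <- vector("list", n_out)
  idx <- 0
  for (pi in seq_len(nrow(perms))) {
    s <- perms[pi, ]
    for (ci in seq_len(nrow(configs))) {
      xc <- configs[ci, ]
      pr <- prod(p_xs[cbind(s, xc)]) / nrow(perms)
      idx <- idx + 1
      rows[[idx]] <- c(xc, s, pr)
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c(paste0("x", seq_len(K)), paste0("s", seq_len(K)), "prob")
  tibble::as_tibble(out)
}

all_permutations <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(K - 1)
  blocks <- lapply(seq_len(K), function(pos) {
    left <- if (pos > 1) sub[, 1:(pos - 1), drop = FALSE] else NULL
    right <- if (pos <= K - 1) sub[, pos:(K - 1), drop = FALSE] else NULL
    cbind(left, K, right)
  })
  unname(do.call(rbind, blocks))
}

#' Gibbs sampling of the discrete replica-exchange model
#'
#' Alternates exact conditional draws of each replica's configuration given
#' its state with Metropolis swap sweeps of the state permutation — the
#' discrete analogue of the replica-exchange loop — and tallies the
#' empirical joint distribution of `(X, S)`.
#'
#' @param model A [discrete_exchange_model()].
#' @param n_sweeps Number of Gibbs sweeps.
#' @param seed Integer seed.
#' @param n_attempts Swap attempts per sweep (default `K^3`).
#' @return Tibble like [enumerate_joint_density()] with empirical `prob`.
#' @export
run_discrete_exchange <- function(model, n_sweeps, seed = 1,
                                  n_attempts = model$K^3) {
  stopifnot(inherits(model, "discrete_model"))
  K <- model$K; nc <- model$n_configs
  local_seed(seed)
  p_xs <- exp(-model$u)
  p_xs <- sweep(p_xs, 1, rowSums(p_xs), "/")
  cum <- t(apply(p_xs, 1, cumsum))
  perm <- seq_len(K)
  x <- rep(1L, K)
  counts <- new.env(hash = TRUE)
  for (sw in seq_len(n_sweeps)) {
    for (r in seq_len(K)) {
      x[r] <- findInterval(runif(1), cum[perm[r], ]) + 1L
    }
    u_kr <- model$u[, x, drop = FALSE]  # u[k, r]: replica r's config at state k
    res <- cpp_swap_sweep(u_kr, as.integer(perm), as.integer(n_attempts))
    perm <- res$perm
    key <- paste(c(x, perm), collapse = ",")
    counts[[key]] <- (counts[[key]] %||% 0) + 1
  }
  keys <- ls(counts)
  mat <- do.call(rbind, lapply(keys, function(k) {
    as.integer(strsplit(k, ",")[[1]])
  }))
  out <- as.data.frame(mat)
  names(out) <- c(paste0("x", seq_len(K)), paste0("s", seq_len(K)))
  out$prob <- vapply(keys, function(k) counts[[k]], 1) / n_sweeps
  tibble::as_tibble(out)
}

#' Total variation distance between two joint distributions
#'
#' @param p,q Tibbles as returned by [enumerate_joint_density()] /
#'   [run_discrete_exchange()] (matched on the outcome columns).
#' @return Total variation distance in \[0, 1\].
#' @export
total_variation <- function(p, q) {
  keycols <- setdiff(names(p), "prob")
  kp <- do.call(paste, c(p[keycols], sep = ","))
  kq <- do.call(paste, c(q[keycols], sep = ","))
  keys <- union(kp, kq)
  pv <- setNames(rep(0, length(keys)), keys); pv[kp] <- p$prob
  qv <- setNames(rep(0, length(keys)), keys); qv[kq] <- q$prob
  sum(abs(pv - qv)) / 2
}

#' Bennett acceptance ratio for two states (cross-check oracle)
#'
#' Classic two-state BAR estimate from a K = 2 reduced potential matrix,
#' solved by root finding. Used as an independent cross-check of the MBAR
#' solver, never as the production estimator.
#'
#' @param matrix A `reduced_potential_matrix` with exactly 2 states.
#' @return Dimensionless free energy difference `f_2 - f_1`.
#' @export
bar_delta_f <- function(matrix) {
  u <- matrix$u; N_k <- matrix$N_k
  stopifnot(nrow(u) == 2, all(N_k > 0))
  s1 <- matrix$state_of_sample == 1
  w_f <- u[2, s1] - u[1, s1]    # forward work, samples from state 1
  w_r <- u[1, !s1] - u[2, !s1]  # reverse work, samples from state 2
  M <- log(N_k[1] / N_k[2])
  fn <- function(df) {
    sum(1 / (1 + exp(M + w_f - df))) - sum(1 / (1 + exp(-M + w_r + df)))
  }
  lo <- -50; hi <- 50
  uniroot(fn, c(lo, hi), tol = 1e-12)$root
}

#' Long-budget reference free energy
#'
#' Runs a high-budget AREX calculation to serve as the reference for
#' short-run convergence experiments, and flags itself if its own dG time
#' series fails the convergence slope test.
#'
#' @param pair A [mutation_pair()].
#' @param budget Number of replica-exchange iterations.
#' @param seed Integer seed.
#' @param protocol,params,n_bootstrap,... Passed to [run_arex()] /
#'   [bootstrap_delta_g()].
#' @return An `oracle_result` with `converged` in its provenance and the
#'   `fe_result` attached.
#' @export
long_reference_delta_g <- function(pair, budget = 2000, seed = 1,
                                   protocol = lambda_protocol(),
                                   params = alchemical_params(),
                                   n_bootstrap = 100, ...) {
  hybrid <- build_hybrid(pair)
  rec <- run_arex(hybrid, protocol, params, n_iterations = budget,
                  seed = seed, store_configurations = FALSE, ...)
  fe <- bootstrap_delta_g(decorrelate(rec), n_bootstrap = n_bootstrap,
                          seed = seed)
  ser <- dg_time_series(rec, n_points = 8, n_bootstrap = 30, seed = seed)
  verdict <- convergence_slope_test(ser)
  res <- oracle_result(fe$delta_g, "long_reference",
                       max(2 * fe$sigma, 1e-6),
                       list(kind = pair$kind, seed = seed, budget = budget,
                            converged = verdict$converged))
  res$fe <- fe
  res
}
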