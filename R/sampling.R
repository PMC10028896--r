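#' Suggest a stable integration timestep
#'
#' Estimates the stiffest local curvature of the potential by a numerical
#' second difference along each coordinate at a reference configuration and
#' returns a timestep targeting `target` radians of the fastest oscillation
#' per step (default 0.15, about 1/40 of a period, where the integrator's
#' configurational sampling bias is negligible for the toy fixtures).
#'
#' @param hybrid A `hybrid_system`.
#' @param x Reference configuration (defaults to stored positions).
#' @param lambda Lambdas at which to probe the potential; the stiffest wins
#'   (alchemical states can differ in stiffness).
#' @param params [alchemical_params()].
#' @param target Radians of the fastest mode per step.
#' @return Timestep in ps.
#' @export
suggest_timestep <- function(hybrid, x = hybrid$positions,
                             lambda = c(0, 0.5, 1),
                             params = alchemical_params(), target = 0.12) {
  comp <- compile_hybrid(hybrid, params)
  x <- as.matrix(x)
  delta <- 1e-4
  omega_max <- 0
  for (lam in lambda) {
    u0 <- cpp_energy(comp, x, lam, 1, 1)[["total"]]
    for (i in seq_len(hybrid$n_atoms)) {
      for (d in 1:3) {
        xp <- x; xp[i, d] <- xp[i, d] + delta
        xm <- x; xm[i, d] <- xm[i, d] - delta
        up <- cpp_energy(comp, xp, lam, 1, 1)[["total"]]
        um <- cpp_energy(comp, xm, lam, 1, 1)[["total"]]
        curv <- (up + um - 2 * u0) / delta^2
        if (is.finite(curv) && curv > 0) {
          omega <- sqrt(curv * alchrex_constants$kcal_to_kj / hybrid$masses[i])
          omega_max <- max(omega_max, omega)
        }
      }
    }
  }
  if (omega_max == 0) return(0.01)
  target / omega_max
}

#' Langevin (BAOAB) propagation of one replica
#'
#' Propagates a configuration with the BAOAB splitting of Langevin dynamics
#' at thermostat temperature `temperature`; REST effective-temperature
#' effects enter only through the scaled potential, never the thermostat.
#' Uses R's RNG, so results are reproducible under `set.seed()`.
#'
#' @param hybrid A `hybrid_system`.
#' @param x n×3 starting configuration, nm.
#' @param n_steps Number of integration steps.
#' @param dt Timestep, ps (see [suggest_timestep()]).
#' @param friction Langevin friction, 1/ps.
#' @param temperature Thermostat temperature, K.
#' @param lambda Alchemical state.
#' @param params [alchemical_params()].
#' @param rest Optional [rest_params()].
#' @param v Optional n×3 starting velocities, nm/ps; drawn from the
#'   Maxwell-Boltzmann distribution if `NULL`.
#' @return List with updated `x` and `v`.
#' @export
langevin_propagate <- function(hybrid, x, n_steps, dt, friction = 5,
                               temperature = 300, lambda = 0,
                               params = alchemical_params(), rest = NULL,
                               v = NULL) {
  comp <- compile_hybrid(hybrid, params)
  x <- as.matrix(x)
  if (is.null(v)) v <- draw_velocities(hybrid$masses, temperature)
  sc <- rest_scales(rest, lambda)
  cpp_baoab(comp, x, as.matrix(v), as.integer(n_steps), dt, friction,
            kt_kcal(temperature), lambda, sc$srest, sc$sinter)
}

draw_velocities <- function(masses, temperature) {
  kT_md <- kt_kcal(temperature) * alchrex_constants$kcal_to_kj
  n <- length(masses)
  matrix(rnorm(n * 3), n, 3) * sqrt(kT_md / masses)
}

#' Metropolis sweep of replica-state swap attempts
#'
#' Attempts `n_attempts` swaps of the alchemical state labels of random
#' replica pairs, each accepted with probability `min(1, exp(-delta))`,
#' where `delta` compares the two replicas' reduced potentials at the two
#' states. Many attempts per sweep approximate drawing an independent state
#' permutation, which enhances mixing relative to neighbour-only exchanges.
#'
#' @param u_matrix K×K matrix of reduced potentials, `u_matrix[k, r]` =
#'   reduced potential of replica `r`'s configuration at state `k`.
#' @param permutation Integer vector: current state (1-based) of each
#'   replica; a permutation of `1:K`.
#' @param n_attempts Number of attempts (default `K^3`).
#' @return List with the updated `permutation` and the `accepted` count.
#' @export
metropolis_swap_sweep <- function(u_matrix, permutation,
                                  n_attempts = length(permutation)^3) {
  u_matrix <- as.matrix(u_matrix)
  K <- length(permutation)
  stopifnot(nrow(u_matrix) == K, ncol(u_matrix) == K,
            sort(permutation) == seq_len(K))
  res <- cpp_swap_sweep(u_matrix, as.integer(permutation),
                        as.integer(n_attempts))
  list(permutation = res$perm, accepted = res$accepted)
}

#' Run alchemical replica exchange (AREX)
#'
#' Gibbs sampling over configurations and state labels: each iteration
#' propagates every replica with Langevin dynamics at its current alchemical
#' state, evaluates every replica's reduced potential at every state, records
#' dU/dlambda and registered observables, then performs a Metropolis swap
#' sweep of the state permutation. The result contains everything the
#' estimation and diagnostics modules need.
#'
#' @param hybrid A `hybrid_system`.
#' @param protocol A [lambda_protocol()].
#' @param params [alchemical_params()].
#' @param n_iterations Number of replica-exchange iterations.
#' @param steps_per_iteration MD steps between exchange attempts.
#' @param temperature Thermostat temperature, K.
#' @param seed Integer seed (fully determines the run).
#' @param dt Timestep in ps; `NULL` uses [suggest_timestep()].
#' @param friction Langevin friction, 1/ps.
#' @param rest Optional [rest_params()] (used by [run_arest()]).
#' @param store_configurations Keep per-iteration configurations (needed by
#'   [dof_catalog()]); on by default at toy sizes.
#' @param sampling_interval_ns Nominal time label per recorded iteration,
#'   used when diagnostics report statistical inefficiencies in time units
#'   (default 0.1 ns per iteration).
#' @return A `run_record`: list with reduced potential array `u`
#'   (state × replica × iteration, kT), `state_history`
#'   (iteration × replica, the state each replica was propagated at),
#'   `dudl` (iteration × replica, kcal/mol), `observables` (named list of
#'   iteration × replica matrices), acceptance statistics and run metadata.
#' @export
run_arex <- function(hybrid, protocol = lambda_protocol(),
                     params = alchemical_params(), n_iterations = 500,
                     steps_per_iteration = 40, temperature = 300, seed = 1,
                     dt = NULL, friction = 5, rest = NULL,
                     store_configurations = TRUE,
                     sampling_interval_ns = 0.1) {
  stopifnot(inherits(hybrid, "hybrid_system"),
            inherits(protocol, "lambda_protocol"))
  lambdas <- protocol$lambdas
  K <- protocol$K
  kT <- kt_kcal(temperature)
  comp <- compile_hybrid(hybrid, params)
  sc <- rest_scales(rest, lambdas)
  if (is.null(dt)) dt <- suggest_timestep(hybrid, params = params)
  local_seed(seed)

  n <- hybrid$n_atoms
  h <- 1e-4
  lam_lo <- pmax(0, lambdas - h); lam_hi <- pmin(1, lambdas + h)
  sc_lo <- rest_scales(rest, lam_lo); sc_hi <- rest_scales(rest, lam_hi)

  res <- cpp_rex_run(comp, hybrid$positions, lambdas, sc$srest, sc$sinter,
                     lam_lo, lam_hi, sc_lo$srest, sc_lo$sinter,
                     sc_hi$srest, sc_hi$sinter,
                     as.integer(n_iterations),
                     as.integer(steps_per_iteration), dt, friction, kT,
                     as.integer(K^3), isTRUE(store_configurations))
  u <- array(res$u, c(K, K, n_iterations))
  state_history <- res$states
  dudl <- res$dudl
  configs <- if (store_configurations) {
    array(res$configs, c(n, 3, K, n_iterations))
  } else NULL
  accepted <- res$accepted
  attempted <- as.numeric(n_iterations) * K^3

  obs_spec <- hybrid$observables
  observables <- list()
  if (!is.null(obs_spec)) {
    if (!store_configurations) {
      stop("recording observables requires store_configurations = TRUE")
    }
    attr(obs_spec, "mutating_idx") <- which(hybrid$tags == "mutating")
    observables <- setNames(
      lapply(seq_len(nrow(obs_spec)),
             function(i) matrix(NA_real_, n_iterations, K)),
      obs_spec$id)
    for (it in seq_len(n_iterations)) {
      for (r in seq_len(K)) {
        vals <- eval_observables(obs_spec, configs[, , r, it])
        for (nm in names(vals)) observables[[nm]][it, r] <- vals[[nm]]
      }
    }
  }

  structure(list(
    u = u, state_history = state_history, dudl = dudl,
    observables = observables, configurations = configs,
    lambdas = lambdas, K = K, temperature = temperature,
    rest = rest, params = params, seed = seed,
    n_iterations = n_iterations, steps_per_iteration = steps_per_iteration,
    dt = dt, friction = friction,
    sampling_interval_ns = sampling_interval_ns,
    swap_acceptance = if (attempted > 0) accepted / attempted else NA_real_,
    hybrid = hybrid,
    method = if (is.null(rest)) "arex" else "arest"
  ), class = "run_record")
}

#' Run alchemical replica exchange with solute tempering (AREST)
#'
#' AREX with a REST region: the potential of each intermediate state is
#' scaled so the REST region's effective temperature rises to `rest$Tmax`
#' at lambda = 1/2 and returns to `rest$T0` at both endstates, which are
#' identical to AREX's. Assign the region first with [assign_rest_region()].
#'
#' @inheritParams run_arex
#' @param rest A [rest_params()] (required).
#' @return A `run_record` (see [run_arex()]).
#' @export
run_arest <- function(hybrid, protocol = lambda_protocol(),
                      params = alchemical_params(), rest = rest_params(),
                      n_iterations = 500, steps_per_iteration = 40,
                      temperature = 300, seed = 1, dt = NULL, friction = 5,
                      store_configurations = TRUE, sampling_interval_ns = 0.1) {
  stopifnot(inherits(rest, "rest_params"))
  run_arex(hybrid, protocol, params, n_iterations, steps_per_iteration,
           temperature, seed, dt, friction, rest = rest,
           store_configurations = store_configurations,
           sampling_interval_ns = sampling_interval_ns)
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf(
    "<run_record> %s | K=%d states, %d iterations, %d steps/iter, T=%g K\n",
    toupper(x$method), x$K, x$n_iterations, x$steps_per_iteration,
    x$temperature))
  cat(sprintf("  swap acceptance %.1f%% | dt %.4g ps | seed %d\n",
              100 * x$swap_acceptance, x$dt, x$seed))
  invisible(x)
}

# evaluate registered observables at one configuration
eval_observables <- function(spec, x) {
  out <- setNames(numeric(nrow(spec)), spec$id)
  for (row in seq_len(nrow(spec))) {
    type <- spec$type[row]
    out[row] <- switch(
      type,
      coordinate = x[spec$i[row], spec$axis[row]],
      distance = vec_norm(x[spec$i[row], ] - x[spec$j[row], ]),
      torsion = {
        phi <- dihedral_angle(x[spec$i[row], ], x[spec$j[row], ],
                              x[spec$k[row], ], x[spec$l[row], ])
        if (is.na(phi)) NA_real_ else phi * 180 / pi
      },
      neighbors = NA_real_,  # filled below (needs the mutating atom set)
      NA_real_)
  }
  # neighbor counts need the mutating atom set, resolved lazily via attr
  nb <- which(spec$type == "neighbors")
  if (length(nb)) {
    mut <- attr(spec, "mutating_idx")
    for (row in nb) {
      if (length(mut) == 0) { out[row] <- 0; next }
      rad <- spec$radius[row]
      others <- setdiff(seq_len(nrow(x)), mut)
      cnt <- 0
      for (o in others) {
        d2 <- min(colSums((t(x[mut, , drop = FALSE]) - x[o, ])^2))
        if (d2 <= rad^2) cnt <- cnt + 1
      }
      out[row] <- cnt
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
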