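#' Alchemical nonbonded parameters
#'
#' @param w_lifting Maximal softcore lifting distance, nm (default 0.4, of
#'   the order of a Lennard-Jones diameter: large enough to regularise
#'   overlaps of decoupling atoms without collapsing overlap between
#'   neighbouring states).
#' @param screening_alpha Direct-space Coulomb screening parameter, 1/nm;
#'   0 (default) gives plain Coulomb, matching non-periodic toy systems.
#' @param coulomb_constant Coulomb constant, kcal·nm/(mol·e²).
#' @param cutoff Nonbonded cutoff, nm, or `NULL` for none (toy systems use
#'   full O(N²) pair sums).
#' @return List of class `alchemical_params`.
#' @export
alchemical_params <- function(w_lifting = 0.4, screening_alpha = 0,
                              coulomb_constant = alchrex_constants$coulomb,
                              cutoff = NULL) {
  stopifnot(w_lifting >= 0, screening_alpha >= 0, coulomb_constant > 0)
  structure(list(w_lifting = w_lifting, screening_alpha = screening_alpha,
                 coulomb_constant = coulomb_constant, cutoff = cutoff),
            class = "alchemical_params")
}

#' Alchemical lambda protocol
#'
#' Evenly spaced lambda values on \[0, 1\]. The default number of states is
#' 12 for charge-preserving mutations and 24 for charge-changing ones
#' (doubling the states for charge mutations mirrors standard practice for
#' the larger thermodynamic length of those paths).
#'
#' @param K Number of alchemical states (>= 2), or `NULL` to choose from
#'   `charge_changing`.
#' @param charge_changing Logical used when `K` is `NULL`.
#' @param lambdas Explicit lambda vector overriding `K` (must be strictly
#'   increasing with endpoints 0 and 1).
#' @return List of class `lambda_protocol` with `lambdas` and `K`.
#' @export
lambda_protocol <- function(K = NULL, charge_changing = FALSE, lambdas = NULL) {
  if (is.null(lambdas)) {
    if (is.null(K)) K <- if (charge_changing) 24L else 12L
    stopifnot(K >= 2)
    lambdas <- seq(0, 1, length.out = K)
  }
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) == 1) {
    # single-state protocol: replica exchange degenerates to plain MD
    if (lambdas < 0 || lambdas > 1) stop("lambda must be in [0, 1]")
  } else if (lambdas[1] != 0 || lambdas[length(lambdas)] != 1 ||
             any(diff(lambdas) <= 0)) {
    stop("lambdas must be strictly increasing from 0 to 1")
  }
  structure(list(lambdas = lambdas, K = length(lambdas)),
            class = "lambda_protocol")
}

#' REST (solute tempering) parameters
#'
#' The REST scale factor alpha(lambda) is piecewise linear: 1 at both
#' endstates (so they are unscaled) and a minimum of `T0/Tmax` at
#' lambda = 1/2, where the effective temperature of the REST region peaks at
#' `Tmax`. Interactions straddling the REST boundary are scaled by
#' `alpha^inter_exponent` (default 0.5, the solute-tempering convention that
#' preserves detailed balance across the boundary; settable to 1).
#'
#' @param T0 Simulation temperature, K.
#' @param Tmax Maximum effective temperature of the REST region, K
#'   (>= `T0`).
#' @param inter_exponent Exponent applied to alpha for `inter` interactions,
#'   0.5 or 1.
#' @return List of class `rest_params` with an `alpha_of_lambda` function.
#' @export
#' @examples
#' rp <- rest_params(300, 600)
#' rp$alpha_of_lambda(c(0, 0.5, 1))  # 1, 0.5, 1
rest_params <- function(T0 = 300, Tmax = 600, inter_exponent = 0.5) {
  stopifnot(Tmax >= T0, T0 > 0, inter_exponent %in% c(0.5, 1))
  ratio <- T0 / Tmax
  alpha_of_lambda <- function(lambda) {
    1 - 2 * (1 - ratio) * pmin(lambda, 1 - lambda)
  }
  structure(list(T0 = T0, Tmax = Tmax, inter_exponent = inter_exponent,
                 alpha_of_lambda = alpha_of_lambda),
            class = "rest_params")
}

# REST scale factors (rest-class, inter-class) at given lambdas
rest_scales <- function(rest, lambdas) {
  if (is.null(rest)) {
    return(list(srest = rep(1, length(lambdas)),
                sinter = rep(1, length(lambdas))))
  }
  a <- rest$alpha_of_lambda(lambdas)
  list(srest = a, sinter = a^rest$inter_exponent)
}

#' Interpolated per-atom charge
#'
#' Charge of a hybrid atom at coupling `lambda`: environment atoms keep
#' their old charge; core atoms interpolate linearly; unique-old atoms scale
#' as (1-lambda) and unique-new atoms as lambda, so each unique side is
#' fully decoupled at the opposite endstate.
#'
#' @param atom_index Hybrid atom index (1-based); may be a vector.
#' @param hybrid A `hybrid_system`.
#' @param lambda Coupling parameter in \[0, 1\].
#' @return Charge(s) in e.
#' @export
interpolated_charge <- function(atom_index, hybrid, lambda) {
  stopifnot(inherits(hybrid, "hybrid_system"))
  if (any(lambda < 0 | lambda > 1)) stop("lambda must be in [0, 1]")
  cls <- hybrid$class_code[atom_index]
  qo <- hybrid$q_old[atom_index]; qn <- hybrid$q_new[atom_index]
  ifelse(cls == 0L, qo,
  ifelse(cls == 1L, (1 - lambda) * qo + lambda * qn,
  ifelse(cls == 2L, (1 - lambda) * qo, lambda * qn)))
}

#' Softcore effective inter-atomic distance
#'
#' Lifts the distance of pairs involving unique atoms into a fourth
#' dimension: `r_eff = sqrt(r^2 + w(lambda)^2)` with
#' `w(lambda) = w_lifting * (chi_old * lambda + chi_new * (1 - lambda))`,
#' so a decoupling pair is maximally lifted exactly when it is most nearly
#' non-interacting and unlifted at its own endstate.
#'
#' @param r Inter-particle distance, nm (vectorised).
#' @param lambda Coupling parameter in \[0, 1\].
#' @param pair_class Length-2 0/1 vector `(chi_ij_old, chi_ij_new)`: whether
#'   the pair involves a unique-old and/or unique-new atom.
#' @param params [alchemical_params()].
#' @return Effective distance(s), nm.
#' @export
#' @examples
#' effective_distance(0.3, 0.5, c(1, 0), alchemical_params(w_lifting = 0.8))
effective_distance <- function(r, lambda, pair_class,
                               params = alchemical_params()) {
  stopifnot(all(r >= 0), all(lambda >= 0 & lambda <= 1))
  w <- params$w_lifting * (pair_class[1] * lambda + pair_class[2] * (1 - lambda))
  sqrt(r^2 + w^2)
}

## ---- compiled representation for the C++ kernels ----

compile_hybrid <- function(hybrid, params = alchemical_params()) {
  n <- hybrid$n_atoms
  member <- hybrid$rest_membership
  # pair list: all i<j except excluded
  if (n >= 2) {
    pr <- t(utils::combn(n, 2))
  } else {
    pr <- matrix(integer(0), 0, 2)
  }
  if (nrow(hybrid$excluded_pairs) > 0 && nrow(pr) > 0) {
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    drop <- key(pr[, 1], pr[, 2]) %in%
      key(hybrid$excluded_pairs[, 1], hybrid$excluded_pairs[, 2])
    pr <- pr[!drop, , drop = FALSE]
  }
  cc <- hybrid$class_code
  rest_class_pair <- function(i, j) {
    m <- member[i] + member[j]
    ifelse(m == 2L, 2L, ifelse(m == 0L, 0L, 1L))
  }
  rest_class_atoms <- function(idx_list) {
    vapply(idx_list, function(at) {
      at <- at[!is.na(at)]
      m <- sum(member[at])
      if (m == length(at)) 2L else if (m == 0L) 0L else 1L
    }, integer(1))
  }

  vt <- hybrid$valence
  tab_or_empty <- function(tab, cols) {
    if (is.null(tab)) {
      as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    } else tab
  }
  b <- tab_or_empty(vt$bonds, c("at1", "at2", "k_spring_old", "r0_old",
                                "k_spring_new", "r0_new", "mode"))
  a <- tab_or_empty(vt$angles, c("at1", "at2", "at3", "k_angle_old",
                                 "theta0_old", "k_angle_new", "theta0_new",
                                 "mode"))
  tt <- tab_or_empty(vt$torsions, c("at1", "at2", "at3", "at4", "barrier_old",
                                    "periodicity_old", "phase_old",
                                    "barrier_new", "periodicity_new",
                                    "phase_new", "mode"))
  r <- tab_or_empty(vt$restraints, c("at1", "k_spring_old", "x0_old", "y0_old",
                                     "z0_old", "k_spring_new", "x0_new",
                                     "y0_new", "z0_new", "mode", "rest_exempt"))
  d <- tab_or_empty(vt$doublewells, c("at1", "axis_old", "barrier_old",
                                      "s0_old", "center_old", "tilt_old",
                                      "axis_new", "barrier_new", "s0_new",
                                      "center_new", "tilt_new", "mode"))
  nr <- nrow(r)
  r_rest <- if (nr) rest_class_atoms(split(r$at1, seq_len(nr))) else integer(0)
  if (nr && !is.null(r$rest_exempt)) r_rest[r$rest_exempt] <- 0L

  list(
    n = n,
    class = as.integer(cc),
    q_old = hybrid$q_old, q_new = hybrid$q_new,
    sigma_old = hybrid$sigma_old, sigma_new = hybrid$sigma_new,
    eps_old = hybrid$eps_old, eps_new = hybrid$eps_new,
    mass = hybrid$masses,
    pair_i = as.integer(pr[, 1] - 1L), pair_j = as.integer(pr[, 2] - 1L),
    pair_lift_old = as.integer(cc[pr[, 1]] == 2L | cc[pr[, 2]] == 2L),
    pair_lift_new = as.integer(cc[pr[, 1]] == 3L | cc[pr[, 2]] == 3L),
    pair_rest = as.integer(rest_class_pair(pr[, 1], pr[, 2])),
    b_i = as.integer(b$at1 - 1L), b_j = as.integer(b$at2 - 1L),
    b_mode = as.integer(b$mode),
    b_rest = rest_class_atoms(asplit_idx(b, 2)),
    b_k0 = as.numeric(b$k_spring_old), b_k1 = as.numeric(b$k_spring_new),
    b_r0 = as.numeric(b$r0_old), b_r1 = as.numeric(b$r0_new),
    a_i = as.integer(a$at1 - 1L), a_j = as.integer(a$at2 - 1L),
    a_k = as.integer(a$at3 - 1L), a_mode = as.integer(a$mode),
    a_rest = rest_class_atoms(asplit_idx(a, 3)),
    a_k0 = as.numeric(a$k_angle_old), a_k1 = as.numeric(a$k_angle_new),
    a_t0 = as.numeric(a$theta0_old), a_t1 = as.numeric(a$theta0_new),
    t_i = as.integer(tt$at1 - 1L), t_j = as.integer(tt$at2 - 1L),
    t_k = as.integer(tt$at3 - 1L), t_l = as.integer(tt$at4 - 1L),
    t_mode = as.integer(tt$mode),
    t_rest = rest_class_atoms(asplit_idx(tt, 4)),
    t_b0 = as.numeric(tt$barrier_old), t_b1 = as.numeric(tt$barrier_new),
    t_p0 = as.numeric(tt$periodicity_old), t_p1 = as.numeric(tt$periodicity_new),
    t_f0 = as.numeric(tt$phase_old), t_f1 = as.numeric(tt$phase_new),
    r_i = as.integer(r$at1 - 1L), r_mode = as.integer(r$mode),
    r_rest = as.integer(r_rest),
    r_k0 = as.numeric(r$k_spring_old), r_k1 = as.numeric(r$k_spring_new),
    r_x0 = as.numeric(r$x0_old), r_y0 = as.numeric(r$y0_old),
    r_z0 = as.numeric(r$z0_old),
    r_x1 = as.numeric(r$x0_new), r_y1 = as.numeric(r$y0_new),
    r_z1 = as.numeric(r$z0_new),
    d_i = as.integer(d$at1 - 1L),
    d_axis = as.integer(d$axis_old - 1L),
    d_mode = as.integer(d$mode),
    d_rest = rest_class_atoms(asplit_idx(d, 1)),
    d_b0 = as.numeric(d$barrier_old), d_b1 = as.numeric(d$barrier_new),
    d_s0 = as.numeric(d$s0_old), d_s1 = as.numeric(d$s0_new),
    d_c0 = as.numeric(d$center_old), d_c1 = as.numeric(d$center_new),
    d_t0 = as.numeric(d$tilt_old), d_t1 = as.numeric(d$tilt_new),
    w_lifting = params$w_lifting,
    screening_alpha = params$screening_alpha,
    coulomb_constant = params$coulomb_constant
  )
}

# list of atom-index vectors for the first k index columns (at1..atk)
asplit_idx <- function(tab, k) {
  if (nrow(tab) == 0) return(list())
  cols <- paste0("at", seq_len(k))
  lapply(seq_len(nrow(tab)), function(r) as.integer(unlist(tab[r, cols])))
}

## ---- user-facing energy functions ----

energy_components <- function(hybrid, x, lambda, params = alchemical_params(),
                              rest = NULL) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  comp <- attr(hybrid, "compiled")
  if (is.null(comp) || !identical(attr(hybrid, "compiled_params"), params)) {
    comp <- compile_hybrid(hybrid, params)
  }
  sc <- rest_scales(rest, lambda)
  cpp_energy(comp, as.matrix(x), lambda, sc$srest, sc$sinter)
}

#' Alchemical electrostatics energy
#'
#' Screened direct-space Coulomb energy over all non-excluded pairs with
#' linearly interpolated charges and softcore-lifted effective distances.
#'
#' @param hybrid A `hybrid_system`.
#' @param x n×3 configuration, nm.
#' @param lambda Coupling parameter in \[0, 1\].
#' @param params [alchemical_params()].
#' @param rest Optional [rest_params()]; scales each pair by its REST class.
#' @return Energy in kcal/mol.
#' @export
electrostatics_energy <- function(hybrid, x, lambda,
                                  params = alchemical_params(), rest = NULL) {
  unname(energy_components(hybrid, x, lambda, params, rest)["electrostatics"])
}

#' Alchemical Lennard-Jones (sterics) energy
#'
#' 12-6 Lennard-Jones energy with per-atom linearly interpolated sigma and
#' epsilon (Lorentz-Berthelot combination) over softcore-lifted distances.
#' Environment atoms keep their unmodified parameters at all lambda.
#'
#' @inheritParams electrostatics_energy
#' @return Energy in kcal/mol.
#' @export
sterics_energy <- function(hybrid, x, lambda, params = alchemical_params(),
                           rest = NULL) {
  unname(energy_components(hybrid, x, lambda, params, rest)["sterics"])
}

#' Valence energy of a hybrid system
#'
#' Bond, angle, torsion, restraint and double-well energy. Terms involving
#' dummy (unique) atoms are always fully present with their own endstate
#' parameters; matched terms whose parameters differ between endstates
#' interpolate linearly in lambda.
#'
#' @inheritParams electrostatics_energy
#' @param lambda Coupling parameter (needed because core valence parameters
#'   may interpolate; dummy-atom terms are lambda-independent).
#' @return Energy in kcal/mol.
#' @export
valence_energy <- function(hybrid, x, lambda = 0,
                           params = alchemical_params(), rest = NULL) {
  unname(energy_components(hybrid, x, lambda, params, rest)["valence"])
}

#' Total alchemical potential
#'
#' `U(x; lambda)` = electrostatics + sterics + valence. With `rest` given,
#' each interaction's contribution is multiplied by alpha(lambda),
#' alpha^inter_exponent or 1 according to whether all, some or none of its
#' atoms belong to the REST region, so the REST region's effective
#' temperature is raised at intermediate lambda while both endstates remain
#' exactly unscaled.
#'
#' @inheritParams electrostatics_energy
#' @return Energy in kcal/mol.
#' @export
total_potential <- function(hybrid, x, lambda, params = alchemical_params(),
                            rest = NULL) {
  unname(energy_components(hybrid, x, lambda, params, rest)["total"])
}

#' Derivative of the potential with respect to lambda
#'
#' Central finite difference (one-sided at the endpoints) of the full
#' alchemical potential, including the REST scale factor's lambda
#' dependence. The default step gives second-order accuracy, verified by
#' Richardson extrapolation in the test suite.
#'
#' @inheritParams electrostatics_energy
#' @param h Finite-difference step.
#' @return dU/dlambda in kcal/mol.
#' @export
du_dlambda <- function(hybrid, x, lambda, params = alchemical_params(),
                       rest = NULL, h = 1e-4) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  lo <- max(0, lambda - h); hi <- min(1, lambda + h)
  u_lo <- total_potential(hybrid, x, lo, params, rest)
  u_hi <- total_potential(hybrid, x, hi, params, rest)
  if (!is.finite(u_lo) || !is.finite(u_hi)) {
    stop("non-finite potential at lambda +/- h; cannot differentiate")
  }
  (u_hi - u_lo) / (hi - lo)
}

#' Reduced (dimensionless) potential
#'
#' @param U Potential energy, kcal/mol.
#' @param temperature Temperature, K.
#' @return `U / kT`, dimensionless, as consumed by multistate estimators.
#' @export
reduced_potential <- function(U, temperature) {
  U / kt_kcal(temperature)
}
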