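#' Construct a toy mutation pair
#'
#' Bundles an "old" (wild-type analog) and "new" (mutant analog) particle
#' system together with the atom mapping that identifies which atoms share
#' coordinates in the hybrid topology. Most users will call one of the
#' fixture generators ([make_harmonic_ladder()], [make_lj_mutation()],
#' [make_double_well_mutation()]) rather than this constructor.
#'
#' @param old_system,new_system [particle_system()] objects.
#' @param atom_map Two-column integer matrix of (old_index, new_index) pairs,
#'   1-based, one-to-one.
#' @param analytic_delta_g Analytic free energy difference in kcal/mol if a
#'   closed form exists, else `NA`.
#' @param kind Fixture kind label used by oracles for dispatch.
#' @param temperature Reference temperature (K) the analytic value refers to.
#' @param observables Optional data frame registering conformational degrees
#'   of freedom for diagnostics (see [dof_catalog()]): columns `id`,
#'   `category`, `type` (`"torsion"`, `"distance"`, `"neighbors"`,
#'   `"coordinate"`), `i, j, k, l` (old-system indices, `NA` where unused),
#'   `axis`, `radius`.
#' @return An object of class `mutation_pair` with fields `old_system`,
#'   `new_system`, `atom_map`, `net_charge_change` (integer, counter
#'   particles excluded), `analytic_delta_g`, `analytic_valid`.
#' @export
mutation_pair <- function(old_system, new_system, atom_map,
                          analytic_delta_g = NA_real_, kind = "custom",
                          temperature = 300, observables = NULL) {
  stopifnot(inherits(old_system, "particle_system"),
            inherits(new_system, "particle_system"))
  atom_map <- matrix(as.integer(atom_map), ncol = 2)
  if (nrow(atom_map) > 0) {
    if (any(atom_map[, 1] < 1) || any(atom_map[, 1] > old_system$n_particles) ||
        any(atom_map[, 2] < 1) || any(atom_map[, 2] > new_system$n_particles)) {
      stop("atom_map indices out of range")
    }
    if (anyDuplicated(atom_map[, 1]) || anyDuplicated(atom_map[, 2])) {
      stop("atom_map must be one-to-one")
    }
  }
  non_counter_old <- old_system$tags != "counter"
  non_counter_new <- new_system$tags != "counter"
  dq <- sum(new_system$charges[non_counter_new]) -
    sum(old_system$charges[non_counter_old])
  structure(list(
    old_system = old_system, new_system = new_system, atom_map = atom_map,
    net_charge_change = as.integer(round(dq)),
    analytic_delta_g = analytic_delta_g,
    analytic_valid = is.finite(analytic_delta_g),
    kind = kind, temperature = temperature,
    observables = observables
  ), class = "mutation_pair")
}

#' @export
print.mutation_pair <- function(x, ...) {
  cat(sprintf(
    "<mutation_pair> kind=%s | old %d atoms, new %d atoms, %d mapped | dq=%+d e\n",
    x$kind, x$old_system$n_particles, x$new_system$n_particles,
    nrow(x$atom_map), x$net_charge_change))
  if (x$analytic_valid) {
    cat(sprintf("  analytic dG = %.6f kcal/mol at %g K\n",
                x$analytic_delta_g, x$temperature))
  }
  invisible(x)
}

#' Reverse the direction of a mutation
#'
#' Swaps old and new systems (and the atom map columns); the analytic free
#' energy, if present, changes sign. Used for forward/reverse internal
#' consistency checks.
#'
#' @param pair A [mutation_pair()].
#' @return The reversed `mutation_pair`.
#' @export
reverse_mutation <- function(pair) {
  stopifnot(inherits(pair, "mutation_pair"))
  mutation_pair(
    old_system = pair$new_system, new_system = pair$old_system,
    atom_map = pair$atom_map[, c(2, 1), drop = FALSE],
    analytic_delta_g = if (pair$analytic_valid) -pair$analytic_delta_g else NA_real_,
    kind = pair$kind, temperature = pair$temperature,
    observables = pair$observables
  )
}

#' Harmonic-oscillator ladder fixture (analytic oracle)
#'
#' A set of independent 3-D harmonic oscillators anchored to fixed centers.
#' The first `n_mutating` particles change their anchor spring constant from
#' `k_old` to `k_new` between endstates; the rest are unmodified environment
#' oscillators. The free energy difference has the closed form
#' `(3 n_mutating / 2) kT log(k_new / k_old)`, making this the primary
#' fixture for validating the whole sampling + MBAR stack.
#'
#' @param n_particles Total number of oscillators (>= 1).
#' @param k_old,k_new Anchor spring constants, kcal/mol/nm², > 0.
#' @param temperature Temperature in K for the analytic reference.
#' @param seed Integer seed controlling the (small) positional jitter.
#' @param n_mutating Number of mutating oscillators (default 1).
#' @param mass Particle mass, amu.
#' @return A [mutation_pair()] with `analytic_delta_g` set and flagged valid.
#' @export
#' @examples
#' pair <- make_harmonic_ladder(2, k_old = 100, k_new = 100 * exp(2),
#'                              temperature = 300, seed = 1)
#' pair$analytic_delta_g  # 3 kT
make_harmonic_ladder <- function(n_particles, k_old, k_new, temperature = 300,
                                 seed = 1, n_mutating = 1, mass = 10) {
  if (k_old <= 0 || k_new <= 0) stop("spring constants must be positive")
  stopifnot(n_particles >= 1, n_mutating >= 1, n_mutating <= n_particles)
  rng <- local_seed(seed)
  centers <- cbind(seq_len(n_particles) - 1, 0, 0)  # 1 nm spacing, no interactions
  pos <- centers + matrix(rnorm(n_particles * 3, sd = 0.02), ncol = 3)
  tags <- c(rep("mutating", n_mutating), rep("", n_particles - n_mutating))
  base <- function(k_mut) {
    particle_system(
      positions = pos,
      charges = rep(0, n_particles),
      lj_sigma = rep(0.3, n_particles),
      lj_epsilon = rep(0, n_particles),
      masses = rep(mass, n_particles),
      restraints = data.frame(
        i = seq_len(n_particles),
        k_spring = c(rep(k_mut, n_mutating), rep(k_old, n_particles - n_mutating)),
        x0 = centers[, 1], y0 = centers[, 2], z0 = centers[, 3]),
      tags = tags
    )
  }
  kT <- kt_kcal(temperature)
  mutation_pair(
    old_system = base(k_old), new_system = base(k_new),
    atom_map = cbind(seq_len(n_particles), seq_len(n_particles)),
    analytic_delta_g = (3 * n_mutating / 2) * kT * log(k_new / k_old),
    kind = "harmonic_ladder", temperature = temperature
  )
}

#' Lennard-Jones cluster mutation fixture
#'
#' A small LJ cluster in which one tagged particle changes its sigma, epsilon
#' and/or charge between endstates. For `cluster_size = 2` the two particles
#' are joined by a harmonic bond so the configurational integral reduces to a
#' 1-D radial integral, giving a quadrature oracle ([quadrature_delta_g()]).
#' A nonzero integer `delta_charge` triggers the counter-particle toggle (see
#' [make_charge_change_mutation()]) so total charge is constant in lambda.
#'
#' @param cluster_size Number of cluster particles (>= 2).
#' @param delta_sigma Change of sigma on the mutating particle, nm.
#' @param delta_epsilon Change of epsilon, kcal/mol.
#' @param delta_charge Change of charge, e.
#' @param seed Integer seed for cluster geometry.
#' @param sigma,epsilon Base LJ parameters.
#' @return A [mutation_pair()] (analytic value not set; use oracles).
#' @export
make_lj_mutation <- function(cluster_size, delta_sigma = 0, delta_epsilon = 0,
                             delta_charge = 0, seed = 1,
                             sigma = 0.3, epsilon = 0.2) {
  stopifnot(cluster_size >= 2)
  if (sigma + delta_sigma <= 0) stop("delta_sigma would produce sigma <= 0")
  if (epsilon + delta_epsilon < 0) stop("delta_epsilon would produce epsilon < 0")
  rng <- local_seed(seed)
  n <- cluster_size
  if (n == 2) {
    pos <- rbind(c(0, 0, 0), c(0.35, 0, 0))
    bonds <- data.frame(i = 1, j = 2, k_spring = 500, r0 = 0.35)
    restr <- NULL
  } else {
    # jittered grid, light anchors keep the cluster bounded
    grid <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2))[seq_len(n), ] * 0.4
    pos <- grid + matrix(rnorm(n * 3, sd = 0.03), ncol = 3)
    bonds <- NULL
    restr <- data.frame(i = seq_len(n), k_spring = 20,
                        x0 = pos[, 1], y0 = pos[, 2], z0 = pos[, 3])
  }
  tags <- c("mutating", rep("", n - 1))
  mk <- function(ds, de, dq) {
    particle_system(
      positions = pos,
      charges = c(dq, rep(0, n - 1)),
      lj_sigma = c(sigma + ds, rep(sigma, n - 1)),
      lj_epsilon = c(epsilon + de, rep(epsilon, n - 1)),
      masses = rep(12, n),
      bonds = bonds, restraints = restr, tags = tags
    )
  }
  pair <- mutation_pair(
    old_system = mk(0, 0, 0),
    new_system = mk(delta_sigma, delta_epsilon, delta_charge),
    atom_map = cbind(seq_len(n), seq_len(n)),
    analytic_delta_g = if (delta_sigma == 0 && delta_epsilon == 0 &&
                           delta_charge == 0) 0 else NA_real_,
    kind = "lj_cluster"
  )
  if (pair$net_charge_change != 0) {
    pair <- make_charge_change_mutation(pair, -pair$net_charge_change)
  }
  pair
}

#' Double-well fixture with a planted slow degree of freedom
#'
#' One particle (tagged `"slow_dof"`) moves on a symmetric quartic double
#' well of height `barrier` along x; the well asymmetry (tilt) interpolates
#' between endstates with coupling strength `well_offset_coupling`, so the
#' coordinate's equilibrium population shifts as the mutation is switched
#' on. A mutating anchor particle and a four-particle decoy chain (with a
#' registered torsion and contact distances that are *not* coupled to the
#' alchemical coordinate) complete the system, so correlation diagnostics
#' have both true and null degrees of freedom to rank.
#'
#' The default barrier of 4 kcal/mol (about 6.7 kT at 300 K) keeps
#' symmetric-well crossing slow; the per-well coupling of 2.5 kcal/mol tilts
#' each well by 2.5 kcal/mol at the endstates (a rotamer-flip-like population
#' inversion) while leaving a downhill barrier of roughly 2-3 kcal/mol, so a
#' run started in the wrong wells relaxes over tens of exchange iterations.
#' Several independent slow coordinates (`n_slow`, default 4) are planted so
#' the ensemble relaxation is the average of several rare-event clocks — the
#' regime where a short run's free energy series shows a measurable drift —
#' but only the first is registered as a monitored observable, emulating the
#' realistic situation where the monitored set does not exhaust the slow
#' modes.
#'
#' @param barrier Double-well barrier height, kcal/mol, > 0 (0 allowed for
#'   the barrierless control).
#' @param well_offset_coupling Endstate-to-endstate tilt change per slow
#'   coordinate, kcal/mol.
#' @param temperature Temperature (K); stored for oracles.
#' @param seed Integer seed for decoy geometry.
#' @param n_slow Number of independent slow double-well coordinates.
#' @return A [mutation_pair()] with registered diagnostics observables.
#' @export
make_double_well_mutation <- function(barrier = 4, well_offset_coupling = 2.5,
                                      temperature = 300, seed = 1,
                                      n_slow = 4) {
  if (barrier < 0) stop("barrier must be non-negative")
  stopifnot(n_slow >= 1)
  rng <- local_seed(seed)
  s0 <- 0.25      # nm, half-separation of the wells
  well_x <- 0.4   # nm, well center distance from the mutating particle
  # particles: 1 = mutating anchor, 2:(1+n_slow) = slow dofs, then 4 decoys
  n <- 1 + n_slow + 4
  slow_idx <- 1 + seq_len(n_slow)
  decoy_idx <- 1 + n_slow + 1:4
  chain <- cbind(1.0 + 0.15 * (0:3), 0.8, 0) +
    matrix(rnorm(12, sd = 0.01), ncol = 3)
  slow_pos <- cbind(well_x - s0, 0.45 * (seq_len(n_slow) - 1), 0)
  pos <- rbind(c(0, 0, 0), slow_pos, chain)
  tags <- c("mutating", "slow_dof", rep("slow", n_slow - 1), rep("", 4))
  mk <- function(tilt) {
    particle_system(
      positions = pos,
      charges = rep(0, n),
      lj_sigma = rep(0.3, n),
      lj_epsilon = rep(0, n),
      masses = rep(10, n),
      bonds = data.frame(i = decoy_idx[1:3], j = decoy_idx[2:4],
                         k_spring = 300, r0 = 0.15),
      angles = data.frame(i = decoy_idx[1:2], j = decoy_idx[2:3],
                          k = decoy_idx[3:4], k_angle = 20,
                          theta0 = 2 * pi / 3),
      torsions = data.frame(i = decoy_idx[1], j = decoy_idx[2],
                            k = decoy_idx[3], l = decoy_idx[4],
                            barrier = 0.5, periodicity = 1, phase = 0),
      restraints = data.frame(
        i = c(1, slow_idx, decoy_idx),
        k_spring = c(100, rep(5, n_slow), rep(20, 4)),
        x0 = c(0, slow_pos[, 1] + s0, chain[, 1]),
        y0 = c(0, slow_pos[, 2], chain[, 2]),
        z0 = c(0, slow_pos[, 3], chain[, 3])),
      doublewells = data.frame(i = slow_idx, axis = 1, barrier = barrier,
                               s0 = s0, center = well_x, tilt = tilt),
      tags = tags
    )
  }
  obs <- data.frame(
    id = c("slow_dof", "slow_mut_distance", "decoy_torsion",
           "decoy_contact", "neighbors_mutating"),
    category = c("sidechain_torsion", "inter_contact", "backbone_torsion",
                 "intra_contact", "neighbor_waters"),
    type = c("coordinate", "distance", "torsion", "distance", "neighbors"),
    i = c(2, 1, decoy_idx[1], decoy_idx[1], NA),
    j = c(NA, 2, decoy_idx[2], 1, NA),
    k = c(NA, NA, decoy_idx[3], NA, NA),
    l = c(NA, NA, decoy_idx[4], NA, NA),
    axis = c(1, NA, NA, NA, NA),
    radius = c(NA, NA, NA, NA, 0.5)
  )
  # old endstate favors the well nearer the anchor (positive tilt penalises
  # +s); the new endstate favors the far well
  mutation_pair(
    old_system = mk(+well_offset_coupling / 2),
    new_system = mk(-well_offset_coupling / 2),
    atom_map = cbind(seq_len(n), seq_len(n)),
    kind = "double_well", temperature = temperature,
    observables = obs
  )
}

#' Add a neutralising counter-particle to a charge-changing mutation
#'
#' Appends a tagged counter-particle whose charge interpolates from 0 (old
#' endstate) to `counter_charge` (new endstate), so the total system charge
#' is constant along the alchemical path. This abstracts the practice of
#' transforming a solvent molecule into a counterion for charge-changing
#' mutations.
#'
#' @param base A [mutation_pair()] with nonzero `net_charge_change`.
#' @param counter_charge Charge of the counter-particle at the new endstate;
#'   must neutralise the remaining imbalance exactly.
#' @return A new [mutation_pair()] with the counter-particle appended to
#'   both systems (mapped, charge 0 in the old system).
#' @export
make_charge_change_mutation <- function(base, counter_charge) {
  stopifnot(inherits(base, "mutation_pair"))
  existing <- sum(base$new_system$charges[base$new_system$tags == "counter"])
  imbalance <- base$net_charge_change + existing
  if (imbalance == 0) stop("base has no remaining net charge change to neutralise")
  if (abs(counter_charge + imbalance) > 1e-12) {
    stop(sprintf("counter_charge must be %+g to neutralise the mutation", -imbalance))
  }
  place <- colMeans(base$old_system$positions) + c(0, 0, 1.5)
  add_counter <- function(sys, q) {
    n <- sys$n_particles + 1
    particle_system(
      positions = rbind(sys$positions, place),
      charges = c(sys$charges, q),
      lj_sigma = c(sys$lj_sigma, 0.3),
      lj_epsilon = c(sys$lj_epsilon, 0.05),
      masses = c(sys$masses, 20),
      bonds = sys$bonds, angles = sys$angles, torsions = sys$torsions,
      restraints = rbind(
        if (is.null(sys$restraints)) NULL else sys$restraints,
        data.frame(i = n, k_spring = 50,
                   x0 = place[1], y0 = place[2], z0 = place[3])),
      doublewells = sys$doublewells,
      tags = c(sys$tags, "counter")
    )
  }
  old2 <- add_counter(base$old_system, 0)
  new2 <- add_counter(base$new_system, counter_charge)
  pair <- mutation_pair(
    old_system = old2, new_system = new2,
    atom_map = rbind(base$atom_map,
                     c(old2$n_particles, new2$n_particles)),
    analytic_delta_g = NA_real_, kind = base$kind,
    temperature = base$temperature, observables = base$observables
  )
  pair
}

#' Randomised mutation fixture for property tests
#'
#' Generates a small random system pair: a few mapped atoms (some with
#' perturbed nonbonded parameters, hence core), optional unmapped atoms on
#' either side with their own valence terms, random bonds, and random
#' charges. Used to exercise partition, endstate-equivalence and
#' serialisation properties across many seeds.
#'
#' @param seed Integer seed.
#' @param charge_change If `TRUE`, plant an integer net charge change and
#'   counter-balance it.
#' @return A [mutation_pair()].
#' @export
make_random_mutation <- function(seed, charge_change = FALSE) {
  rng <- local_seed(seed)
  n_map <- sample(2:4, 1)
  n_uold <- sample(0:2, 1)
  n_unew <- sample(0:2, 1)
  n_old <- n_map + n_uold
  n_new <- n_map + n_unew

  # rejection-sample positions with a physical minimum separation so random
  # configurations cannot produce astronomically large overlap energies
  scatter <- function(n, existing = NULL) {
    out <- matrix(numeric(0), 0, 3)
    while (nrow(out) < n) {
      cand <- runif(3, 0, 1.2)
      all_pts <- rbind(existing, out)
      if (nrow(all_pts) == 0 ||
          min(sqrt(colSums((t(all_pts) - cand)^2))) > 0.3) {
        out <- rbind(out, cand)
      }
    }
    unname(out)
  }
  pos_map <- scatter(n_map)
  mass_map <- runif(n_map, 5, 20)
  mk <- function(n_total, pos_extra, q, sig, eps, tags) {
    pos <- rbind(pos_map, pos_extra)
    particle_system(
      positions = pos, charges = q, lj_sigma = sig, lj_epsilon = eps,
      masses = c(mass_map, runif(n_total - n_map, 5, 20)),
      bonds = if (n_total >= 2) {
        data.frame(i = 1, j = 2, k_spring = runif(1, 100, 400),
                   r0 = runif(1, 0.2, 0.4))
      } else NULL,
      restraints = data.frame(i = seq_len(n_total), k_spring = 15,
                              x0 = pos[, 1], y0 = pos[, 2], z0 = pos[, 3]),
      tags = tags
    )
  }
  q_map_old <- round(runif(n_map, -0.5, 0.5), 2)
  q_map_new <- q_map_old
  q_map_new[1] <- q_map_old[1] + round(runif(1, -0.4, 0.4), 2)
  # an exact integer charge change keeps the counter-balance exact; the
  # unique atoms are then kept neutral so no fractional residue remains
  q_uold <- round(runif(n_uold, -0.3, 0.3), 2)
  q_unew <- round(runif(n_unew, -0.3, 0.3), 2)
  if (charge_change) {
    q_map_new[1] <- q_map_old[1] + sample(c(-1, 1), 1)
    q_uold <- rep(0, n_uold)
    q_unew <- rep(0, n_unew)
  }
  sig_map_old <- runif(n_map, 0.25, 0.35)
  sig_map_new <- sig_map_old
  sig_map_new[1] <- sig_map_old[1] + runif(1, -0.03, 0.03)
  eps_map <- runif(n_map, 0.05, 0.3)
  tags_map <- c("mutating", rep("", n_map - 1))

  old_sys <- mk(n_old, scatter(n_uold, pos_map),
                c(q_map_old, q_uold),
                c(sig_map_old, runif(n_uold, 0.25, 0.35)),
                c(eps_map, runif(n_uold, 0.05, 0.3)),
                c(tags_map, rep("", n_uold)))
  new_sys <- mk(n_new, scatter(n_unew, pos_map),
                c(q_map_new, q_unew),
                c(sig_map_new, runif(n_unew, 0.25, 0.35)),
                c(eps_map, runif(n_unew, 0.05, 0.3)),
                c(tags_map, rep("", n_unew)))
  pair <- mutation_pair(
    old_system = old_sys, new_system = new_sys,
    atom_map = cbind(seq_len(n_map), seq_len(n_map)),
    kind = "random"
  )
  if (charge_change && pair$net_charge_change != 0) {
    pair <- make_charge_change_mutation(pair, -pair$net_charge_change)
  }
  pair
}

# seed the RNG for the calling function's lifetime, then restore caller state
local_seed <- function(seed) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    expr <- bquote(assign(".Random.seed", .(old), envir = globalenv()))
    do.call(on.exit, list(expr, TRUE), envir = parent.frame())
  }
  set.seed(as.integer(seed))
  invisible(NULL)
}
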