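test_that("interpolated charges follow the atom-class rules", {
  old <- particle_system(rbind(c(0, 0, 0), c(0.4, 0, 0), c(1, 0, 0)),
                         charges = c(-1, 0.4, 0.25), lj_sigma = rep(0.3, 3),
                         lj_epsilon = rep(0, 3), masses = rep(10, 3),
                         tags = c("mutating", "", ""))
  new <- particle_system(rbind(c(0, 0, 0), c(1, 0, 0)),
                         charges = c(0, 0.25), lj_sigma = rep(0.3, 2),
                         lj_epsilon = rep(0, 2), masses = rep(10, 2),
                         tags = c("mutating", ""))
  pair <- mutation_pair(old, new, rbind(c(1, 1), c(3, 2)))
  hs <- build_hybrid(pair)  # atom 2 of old is unique_old, hybrid index 3
  # core atom: linear midpoint
  expect_equal(interpolated_charge(1, hs, 0.5), -0.5)
  # environment atom unchanged at any lambda
  expect_equal(interpolated_charge(2, hs, 0.73), 0.25)
  # unique-old atom fully decoupled at lambda = 1
  expect_equal(interpolated_charge(3, hs, 1), 0)
  expect_equal(interpolated_charge(3, hs, 0), 0.4)
  expect_error(interpolated_charge(1, hs, 1.2), "lambda")
})

test_that("effective distance lifts only unique pairs", {
  p <- alchemical_params(w_lifting = 0.4)
  # non-unique pair: never lifted
  expect_equal(effective_distance(0.27, 0.6, c(0, 0), p), 0.27)
  # fully interacting old pair unlifted at its own endstate
  expect_equal(effective_distance(0.27, 0, c(1, 0), p), 0.27)
  # Pythagorean identity at full lift
  expect_equal(effective_distance(0.3, 1, c(1, 0), p), 0.5)
  expect_equal(effective_distance(0.3, 0, c(0, 1), p), 0.5)
})

test_that("electrostatics energy matches the Coulomb hand value", {
  pos <- rbind(c(0, 0, 0), c(0.3, 0, 0))
  sys <- particle_system(pos, charges = c(1, -1), lj_sigma = rep(0.3, 2),
                         lj_epsilon = rep(0, 2), masses = rep(10, 2))
  pair <- mutation_pair(sys, sys, cbind(1:2, 1:2))
  hs <- build_hybrid(pair)
  e <- electrostatics_energy(hs, pos, 0.5)
  expect_equal(e, alchrex_constants$coulomb * (1) * (-1) / 0.3,
               tolerance = 1e-12)
  expect_equal(e, -110.688, tolerance = 1e-4)
  # all charges zero
  sys0 <- particle_system(pos, charges = c(0, 0), lj_sigma = rep(0.3, 2),
                          lj_epsilon = rep(0, 2), masses = rep(10, 2))
  pair0 <- mutation_pair(sys0, sys0, cbind(1:2, 1:2))
  expect_equal(electrostatics_energy(build_hybrid(pair0), pos, 0.2), 0)
})

test_that("screened electrostatics matches an independent erfc evaluation", {
  pos <- rbind(c(0, 0, 0), c(0.3, 0, 0))
  sys <- particle_system(pos, charges = c(0.5, -0.8), lj_sigma = rep(0.3, 2),
                         lj_epsilon = rep(0, 2), masses = rep(10, 2))
  pair <- mutation_pair(sys, sys, cbind(1:2, 1:2))
  hs <- build_hybrid(pair)
  alpha <- 2.5
  e <- electrostatics_energy(hs, pos, 0, alchemical_params(screening_alpha = alpha))
  erfc <- function(z) 2 * pnorm(z * sqrt(2), lower.tail = FALSE)
  expect_equal(e, alchrex_constants$coulomb * 0.5 * (-0.8) / 0.3 *
                 erfc(alpha * 0.3), tolerance = 1e-9)
})

test_that("Lennard-Jones energy has its zero crossing and minimum", {
  mk <- function(r) {
    pos <- rbind(c(0, 0, 0), c(r, 0, 0))
    sys <- particle_system(pos, charges = c(0, 0), lj_sigma = c(0.3, 0.34),
                           lj_epsilon = c(0.2, 0.45), masses = rep(10, 2))
    pair <- mutation_pair(sys, sys, cbind(1:2, 1:2))
    sterics_energy(build_hybrid(pair), pos, 0.5)
  }
  sig <- (0.3 + 0.34) / 2
  eps <- sqrt(0.2 * 0.45)
  expect_equal(mk(sig), 0, tolerance = 1e-12)
  expect_equal(mk(2^(1 / 6) * sig), -eps, tolerance = 1e-12)
})

test_that("softcore lifting keeps coincident unique atoms finite", {
  # one unique-old and one unique-new atom placed on top of an environment atom
  old <- particle_system(rbind(c(0, 0, 0), c(0, 0, 0)),
                         charges = c(0.3, 0.5), lj_sigma = rep(0.3, 2),
                         lj_epsilon = rep(0.2, 2), masses = rep(10, 2))
  new <- particle_system(rbind(c(0, 0, 0), c(0, 0, 0)),
                         charges = c(0.3, -0.5), lj_sigma = rep(0.3, 2),
                         lj_epsilon = rep(0.2, 2), masses = rep(10, 2))
  pair <- mutation_pair(old, new, rbind(c(1, 1)))  # atom 2 unmapped both sides
  hs <- build_hybrid(pair)
  x <- hs$positions  # all three hybrid atoms coincident
  for (lam in c(0.001, 0.25, 0.5, 0.75, 0.999)) {
    expect_true(is.finite(total_potential(hs, x, lam)))
  }
  # at lambda = 0 the unique-old pair is unlifted and coincident: singular
  expect_false(is.finite(total_potential(hs, x, 0)))
})

test_that("hybrid endstates reproduce the plain endpoint systems", {
  # the defining property: U(x; 0) = U_old(x) + dummy-new valence, and
  # symmetrically at lambda = 1 (checked against the pure-R reference path)
  for (seed in 1:8) {
    pair <- make_random_mutation(seed, charge_change = seed %% 3 == 0)
    hs <- build_hybrid(pair)
    cls <- classify_atoms(pair)
    set.seed(seed + 100)
    for (rep in 1:3) {
      x <- hs$positions + matrix(rnorm(hs$n_atoms * 3, sd = 0.03), ncol = 3)
      x_old <- x[cls$old_to_hybrid, , drop = FALSE]
      x_new <- x[cls$new_to_hybrid, , drop = FALSE]
      u0 <- total_potential(hs, x, 0)
      u1 <- total_potential(hs, x, 1)
      ref0 <- system_energy(pair$old_system, x_old) +
        dummy_valence_energy(pair$new_system, x_new, pair$atom_map[, 2])
      ref1 <- system_energy(pair$new_system, x_new) +
        dummy_valence_energy(pair$old_system, x_old, pair$atom_map[, 1])
      expect_lt(abs(u0 - ref0), 1e-9)
      expect_lt(abs(u1 - ref1), 1e-9)
    }
  }
})

test_that("valence energy of the identity mutation equals the plain system", {
  sys <- chain_system(jitter_seed = 1)
  pair <- mutation_pair(sys, sys, cbind(1:4, 1:4))
  hs <- build_hybrid(pair)
  set.seed(2)
  x <- sys$positions + matrix(rnorm(12, sd = 0.02), ncol = 3)
  expect_equal(valence_energy(hs, x),
               alchrex:::valence_terms_energy(sys, x), tolerance = 1e-9)
  # harmonic bond at its rest length contributes nothing
  b <- particle_system(rbind(c(0, 0, 0), c(0.15, 0, 0)), c(0, 0),
                       rep(0.3, 2), rep(0, 2), rep(10, 2),
                       bonds = data.frame(i = 1, j = 2, k_spring = 300,
                                          r0 = 0.15))
  pb <- mutation_pair(b, b, cbind(1:2, 1:2))
  expect_equal(valence_energy(build_hybrid(pb), b$positions), 0)
})

test_that("total interpolated charge is linear, constant when balanced", {
  lams <- seq(0, 1, by = 0.1)
  for (seed in 1:6) {
    pair <- make_random_mutation(seed, charge_change = seed %% 2 == 0)
    hs <- build_hybrid(pair)
    qtot <- vapply(lams, function(l) {
      sum(interpolated_charge(seq_len(hs$n_atoms), hs, l))
    }, numeric(1))
    # linearity: second differences vanish
    expect_lt(max(abs(diff(diff(qtot)))), 1e-12)
    if (seed %% 2 == 0) {
      # counter-balanced: constant to machine precision
      expect_lt(max(qtot) - min(qtot), 1e-12)
    }
  }
})

test_that("potential is continuous in lambda", {
  pair <- make_random_mutation(5)
  hs <- build_hybrid(pair)
  set.seed(6)
  x <- hs$positions + matrix(rnorm(hs$n_atoms * 3, sd = 0.02), ncol = 3)
  lams <- seq(0, 1, length.out = 201)
  u <- vapply(lams, function(l) total_potential(hs, x, l), numeric(1))
  expect_true(all(is.finite(u)))
  expect_lt(max(abs(diff(u))), 0.05 * (max(u) - min(u)) + 1e-6)
})

test_that("REST scaling halves a pure-REST contribution at the midpoint", {
  rp <- rest_params(300, 600)
  expect_equal(rp$alpha_of_lambda(c(0, 0.5, 1)), c(1, 0.5, 1))
  pair <- make_double_well_mutation(seed = 7)
  hs <- assign_rest_region(build_hybrid(pair), radius = 0.5)
  x <- hs$positions
  slow <- which(hs$tags == "slow_dof")[1]
  x2 <- x; x2[slow, 1] <- x2[slow, 1] + 0.1
  # the double-well term is pure REST: its contribution halves at lambda 0.5
  d_plain <- total_potential(hs, x2, 0.5) - total_potential(hs, x, 0.5)
  d_rest <- total_potential(hs, x2, 0.5, rest = rp) -
    total_potential(hs, x, 0.5, rest = rp)
  # displacement also touches the (REST) anchor restraint; both scale by 0.5
  expect_equal(d_rest, 0.5 * d_plain, tolerance = 1e-9)
  # endstates unscaled; Tmax = T0 is a no-op everywhere
  for (lam in c(0, 1)) {
    expect_identical(total_potential(hs, x2, lam, rest = rp),
                     total_potential(hs, x2, lam))
  }
  rp0 <- rest_params(300, 300)
  expect_identical(total_potential(hs, x2, 0.37, rest = rp0),
                   total_potential(hs, x2, 0.37))
})

test_that("dU/dlambda matches analytic derivatives and converges at order 2", {
  # identity mutation: zero everywhere
  sys <- chain_system()
  pid <- mutation_pair(sys, sys, cbind(1:4, 1:4))
  hid <- build_hybrid(pid)
  expect_equal(du_dlambda(hid, sys$positions, 0.3), 0, tolerance = 1e-8)
  # single core charge (0 -> 1) against a fixed unit environment charge:
  # dU/dlambda = C * q_env / r, constant in lambda
  r <- 0.42
  mkq <- function(q1) particle_system(rbind(c(0, 0, 0), c(r, 0, 0)),
                                      c(q1, 1), rep(0.3, 2), rep(0, 2),
                                      rep(10, 2), tags = c("mutating", ""))
  pq <- mutation_pair(mkq(0), mkq(1), cbind(1:2, 1:2))
  hq <- build_hybrid(pq)
  expected <- alchrex_constants$coulomb / r
  for (lam in c(0.2, 0.5, 0.8)) {
    expect_equal(du_dlambda(hq, hq$positions, lam), expected,
                 tolerance = 1e-6)
  }
  # Richardson: halving h reduces the error about fourfold on a smooth fixture
  pair <- make_random_mutation(9)
  hs <- build_hybrid(pair)
  x <- hs$positions
  d_exact <- du_dlambda(hs, x, 0.37, h = 1e-7)
  e1 <- abs(du_dlambda(hs, x, 0.37, h = 2e-2) - d_exact)
  e2 <- abs(du_dlambda(hs, x, 0.37, h = 1e-2) - d_exact)
  if (e1 > 1e-10) expect_lt(e2, e1 / 2.5)
})

test_that("reduced potential is U / kT", {
  expect_equal(reduced_potential(0, 300), 0)
  expect_equal(reduced_potential(kt_kcal(300), 300), 1)
  expect_equal(reduced_potential(0.5961, 300), 1, tolerance = 2e-4)
})

test_that("compiled forces agree with numerical gradients of the potential", {
  p <- alchemical_params()
  for (seed in c(1, 4, 8)) {
    pair <- make_random_mutation(seed)
    hs <- assign_rest_region(build_hybrid(pair), radius = 0.6)
    comp <- alchrex:::compile_hybrid(hs, p)
    set.seed(seed)
    x <- hs$positions + matrix(rnorm(hs$n_atoms * 3, sd = 0.03), ncol = 3)
    lam <- runif(1)
    sr <- 0.7; si <- sqrt(0.7)
    F <- alchrex:::cpp_forces(comp, x, lam, sr, si)
    h <- 1e-6
    for (i in seq_len(hs$n_atoms)) {
      for (d in 1:3) {
        xp <- x; xp[i, d] <- xp[i, d] + h
        xm <- x; xm[i, d] <- xm[i, d] - h
        fn <- -(alchrex:::cpp_energy(comp, xp, lam, sr, si)[["total"]] -
                  alchrex:::cpp_energy(comp, xm, lam, sr, si)[["total"]]) /
          (2 * h)
        expect_lt(abs(fn - F[i, d]), 1e-5 + 1e-5 * abs(F[i, d]))
      }
    }
  }
})
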