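test_that("suggest_timestep scales with the stiffest state", {
  pair <- ladder_e2(1)
  hs <- build_hybrid(pair)
  dt <- suggest_timestep(hs)
  # stiffest state is lambda = 1 (k = 100 e^2); dt = target / omega_max
  omega_max <- sqrt(100 * exp(2) * alchrex_constants$kcal_to_kj / 10)
  expect_equal(dt, 0.12 / omega_max, tolerance = 0.05)
})

test_that("Langevin sampling satisfies equipartition on a harmonic well", {
  pair <- make_harmonic_ladder(1, 100, 100, seed = 1)
  hs <- build_hybrid(pair)
  dt <- suggest_timestep(hs)
  set.seed(2)
  st <- langevin_propagate(hs, hs$positions, 500, dt, friction = 10,
                           temperature = 300)
  n <- 3000
  xs <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    st <- langevin_propagate(hs, st$x, 15, dt, friction = 10,
                             temperature = 300, v = st$v)
    xs[i, ] <- st$x[1, ] - c(0, 0, 0)
  }
  target <- kt_kcal(300) / 100  # kT / k per axis, nm^2
  # effective sample size per axis is about n / (2 tau + 1)
  g <- mean(apply(xs, 2, function(s) statistical_inefficiency(s)$g))
  se <- target * sqrt(2 / (3 * n / g))
  expect_lt(abs(mean(apply(xs, 2, var)) - target), 3 * se)
})

test_that("zero-temperature dynamics descends in energy", {
  pair <- make_harmonic_ladder(1, 100, 100, seed = 3)
  hs <- build_hybrid(pair)
  x0 <- hs$positions + 0.3
  u0 <- total_potential(hs, x0, 0)
  set.seed(1)
  st <- langevin_propagate(hs, x0, 800, 0.005, friction = 5,
                           temperature = 1e-12,
                           v = matrix(0, hs$n_atoms, 3))
  expect_lt(total_potential(hs, st$x, 0), u0 * 0.01)
})

test_that("free diffusion matches the Langevin mean squared displacement", {
  # single particle, no potential: per-axis MSD(t) for Langevin dynamics is
  # (2 kT / m gamma) * (t - (1 - exp(-gamma t)) / gamma)
  sys <- particle_system(matrix(0, 1, 3), 0, 0.3, 0, 10)
  pair <- mutation_pair(sys, sys, cbind(1, 1))
  hs <- build_hybrid(pair)
  gamma <- 20; dt <- 0.002; n <- 20000
  set.seed(4)
  st <- langevin_propagate(hs, hs$positions, 200, dt, friction = gamma,
                           temperature = 300)
  xs <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    st <- langevin_propagate(hs, st$x, 1, dt, friction = gamma,
                             temperature = 300, v = st$v)
    xs[i, ] <- st$x[1, ]
  }
  lag <- 50
  t_lag <- lag * dt
  d <- xs[(1 + lag):n, ] - xs[1:(n - lag), ]
  msd_axis <- mean(d^2)
  kT_md <- kt_kcal(300) * alchrex_constants$kcal_to_kj
  expected <- 2 * (kT_md / (10 * gamma)) *
    (t_lag - (1 - exp(-gamma * t_lag)) / gamma)
  expect_lt(abs(msd_axis - expected) / expected, 0.15)
})

test_that("swap sweep follows the Metropolis acceptance probability", {
  # a single forced proposal with Delta = 2 kT accepts with prob e^-2
  u <- matrix(c(0, 2, 0, 0), 2, 2)  # u[state, replica]
  set.seed(5)
  acc <- vapply(seq_len(4000), function(i) {
    metropolis_swap_sweep(u, 1:2, n_attempts = 1)$accepted
  }, numeric(1))
  p <- mean(acc)
  se <- sqrt(exp(-2) * (1 - exp(-2)) / 4000)
  expect_lt(abs(p - exp(-2)), 4 * se)
})

test_that("degenerate energies make all proposals accepted and permutations uniform", {
  K <- 3
  u <- matrix(0, K, K)
  set.seed(6)
  perms <- character(2000)
  perm <- 1:K
  for (i in seq_along(perms)) {
    res <- metropolis_swap_sweep(u, perm, n_attempts = K^3)
    perm <- res$permutation
    expect_identical(sort(perm), 1:K)  # always a valid permutation
    perms[i] <- paste(perm, collapse = "")
  }
  counts <- table(perms)
  expect_equal(length(counts), 6L)  # all 3! permutations visited
  p <- suppressWarnings(chisq.test(as.vector(counts))$p.value)
  expect_gt(p, 0.001)
})

test_that("run_arex with one state is plain molecular dynamics", {
  pair <- make_harmonic_ladder(1, 100, 100, seed = 1)
  hs <- build_hybrid(pair)
  rec <- run_arex(hs, lambda_protocol(lambdas = 0), n_iterations = 20,
                  seed = 1, store_configurations = FALSE)
  expect_true(all(rec$state_history == 1L))  # state history constant
  expect_equal(rec$K, 1L)
})

test_that("replica exchange runs are bitwise seed-deterministic", {
  pair <- make_double_well_mutation(seed = 2)
  hs <- build_hybrid(pair)
  r1 <- run_dw(hs, n_iterations = 30, seed = 7)
  r2 <- run_dw(hs, n_iterations = 30, seed = 7)
  expect_identical(r1$u, r2$u)
  expect_identical(r1$state_history, r2$state_history)
  expect_identical(r1$dudl, r2$dudl)
  expect_identical(r1$observables$slow_dof, r2$observables$slow_dof)
  r3 <- run_dw(hs, n_iterations = 30, seed = 8)
  expect_false(identical(r1$u, r3$u))
})

test_that("state history rows are always permutations", {
  pair <- ladder_e2(1)
  rec <- run_ladder(pair, n_iterations = 50, seed = 3, K = 6)
  for (it in seq_len(nrow(rec$state_history))) {
    expect_identical(sort(rec$state_history[it, ]), 1:6)
  }
})

test_that("AREST equals AREX bitwise when Tmax = T0, and differs when hotter", {
  pair <- make_double_well_mutation(seed = 3)
  hs <- assign_rest_region(build_hybrid(pair), radius = 0.5)
  rx <- run_arex(hs, lambda_protocol(6), n_iterations = 25, seed = 11)
  r0 <- run_arest(hs, lambda_protocol(6), rest = rest_params(300, 300),
                  n_iterations = 25, seed = 11)
  expect_identical(rx$u, r0$u)
  expect_identical(rx$state_history, r0$state_history)
  rh <- run_arest(hs, lambda_protocol(6), rest = rest_params(300, 600),
                  n_iterations = 25, seed = 11)
  expect_false(identical(rx$u, rh$u))
  # endstate replicas (alpha = 1) follow identical trajectories, so their
  # endstate reduced potentials agree exactly
  expect_identical(rh$u[1, 1, 1], rx$u[1, 1, 1])
  expect_identical(rh$u[6, 6, 1], rx$u[6, 6, 1])
})

test_that("identity mutation gives zero free energy within noise", {
  pair <- make_harmonic_ladder(2, 80, 80, seed = 4)
  rec <- run_ladder(pair, n_iterations = 600, seed = 9, K = 6)
  fe <- bootstrap_delta_g(decorrelate(rec), n_bootstrap = 100, seed = 1)
  expect_lt(abs(fe$delta_g), 3 * max(fe$sigma, 1e-6))
})
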