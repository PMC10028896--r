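# Shared builders for small test systems.

# the flagship analytic fixture: dG = 3 kT exactly
ladder_e2 <- function(n = 1, seed = 1) {
  make_harmonic_ladder(n, k_old = 100, k_new = 100 * exp(2),
                       temperature = 300, seed = seed)
}

# a quick AREX run on the ladder with settings that decorrelate well
run_ladder <- function(pair, n_iterations, seed, K = 12) {
  run_arex(build_hybrid(pair), lambda_protocol(K),
           n_iterations = n_iterations, steps_per_iteration = 60,
           friction = 10, seed = seed, store_configurations = FALSE)
}

# diagnostic-length double-well run (see vignette for the regime choice)
run_dw <- function(hybrid, n_iterations = 100, seed = 1, rest = NULL) {
  run_arex(hybrid, lambda_protocol(12), n_iterations = n_iterations,
           steps_per_iteration = 150, seed = seed, rest = rest)
}

# four-particle chain exercising every valence term type
chain_system <- function(jitter_seed = NULL) {
  pos <- matrix(c(0, 0, 0, 0.15, 0.05, 0, 0.3, 0, 0.08, 0.42, 0.12, 0.02),
                4, 3, byrow = TRUE)
  if (!is.null(jitter_seed)) {
    set.seed(jitter_seed)
    pos <- pos + matrix(rnorm(12, sd = 0.02), ncol = 3)
  }
  particle_system(
    pos, charges = c(0.2, -0.1, 0, -0.1), lj_sigma = rep(0.3, 4),
    lj_epsilon = rep(0.1, 4), masses = rep(10, 4),
    bonds = data.frame(i = 1:3, j = 2:4, k_spring = 300, r0 = 0.15),
    angles = data.frame(i = 1:2, j = 2:3, k = 3:4, k_angle = 20,
                        theta0 = 2 * pi / 3),
    torsions = data.frame(i = 1, j = 2, k = 3, l = 4, barrier = 0.5,
                          periodicity = 2, phase = 0.3)
  )
}

# exact Gaussian samples for a two-state 1-D harmonic-oscillator MBAR
# problem (analytic f2 - f1 = 0.5 * log(k2 / k1) per dimension)
gaussian_two_state <- function(k1, k2, n_per_state, temperature = 300,
                               seed = 1) {
  set.seed(seed)
  kT <- kt_kcal(temperature)
  x1 <- rnorm(n_per_state, sd = sqrt(kT / k1))
  x2 <- rnorm(n_per_state, sd = sqrt(kT / k2))
  x <- c(x1, x2)
  u <- rbind(0.5 * k1 * x^2, 0.5 * k2 * x^2) / kT
  structure(list(u = u, N_k = c(n_per_state, n_per_state),
                 state_of_sample = rep(1:2, each = n_per_state),
                 temperature = temperature, g = 1,
                 lambdas = c(0, 1)),
            class = "reduced_potential_matrix")
}

# valence energy of the terms that involve unmapped (dummy) atoms of a
# system, evaluated by the pure-R reference path
dummy_valence_energy <- function(sys, x, mapped) {
  unmapped <- setdiff(seq_len(sys$n_particles), mapped)
  if (!length(unmapped)) return(0)
  keep <- function(df, idx_cols) {
    if (is.null(df)) return(NULL)
    touch <- apply(df[idx_cols], 1, function(r) any(r %in% unmapped))
    if (!any(touch)) return(NULL)
    df[touch, , drop = FALSE]
  }
  sub <- sys
  sub$bonds <- keep(sys$bonds, c("i", "j"))
  sub$angles <- keep(sys$angles, c("i", "j", "k"))
  sub$torsions <- keep(sys$torsions, c("i", "j", "k", "l"))
  sub$restraints <- keep(sys$restraints, "i")
  sub$doublewells <- keep(sys$doublewells, "i")
  alchrex:::valence_terms_energy(sub, x)
}
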