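test_that("statistical inefficiency calibrates on known processes", {
  set.seed(1)
  # iid series: g near 1
  expect_lt(abs(statistical_inefficiency(rnorm(1e5))$g - 1), 0.2)
  # AR(1), phi = 0.9: g = (1 + phi) / (1 - phi) = 19
  phi <- 0.9; n <- 1e5
  x <- as.numeric(stats::arima.sim(list(ar = phi), n))
  g <- statistical_inefficiency(x)$g
  expect_lt(abs(g - 19) / 19, 0.2)
  # duplicating every point approximately doubles g
  set.seed(2)
  y <- rnorm(5e4)
  y2 <- rep(y, each = 2)
  g1 <- statistical_inefficiency(y)$g
  g2 <- statistical_inefficiency(y2)$g
  expect_lt(abs(g2 - 2 * g1) / (2 * g1), 0.15)
  # time-unit report and degenerate/edge handling
  si <- statistical_inefficiency(rnorm(100), sampling_interval_ns = 0.1)
  expect_equal(si$g_ns, si$g * 0.1)
  const <- statistical_inefficiency(rep(1, 100))
  expect_equal(const$g, 1)
  expect_true(const$degenerate)
  expect_error(statistical_inefficiency(rnorm(5)), "length")
  expect_error(statistical_inefficiency(c(rnorm(20), NA)), "finite")
})

test_that("decorrelate discards burn-in and subsamples at the stride", {
  pair <- ladder_e2(1)
  rec <- run_ladder(pair, n_iterations = 100, seed = 2, K = 6)
  m <- decorrelate(rec, burn_in = 0.5)
  # at most 50 retained iterations per replica
  expect_lte(length(m$indices), 50)
  expect_gte(min(m$indices), 51)
  expect_equal(sum(m$N_k), ncol(m$u))
  expect_equal(length(m$indices) * rec$K, ncol(m$u))
  # stride equals ceiling(g)
  expect_equal(diff(m$indices)[1], ceiling(m$g))
  # too-short records are rejected with advice
  short <- truncate_record(rec, 12)
  expect_error(decorrelate(short, burn_in = 0.1, min_per_state = 10),
               "run longer")
})

test_that("MBAR recovers the analytic two-state harmonic free energy", {
  # exact Gaussian samples, analytic df = (1/2) log(k2 / k1)
  m <- gaussian_two_state(100, 100 * exp(2), 5e4, seed = 3)
  fit <- mbar_solve(m)
  analytic <- 0.5 * log(exp(2))
  fe <- bootstrap_delta_g(m, n_bootstrap = 100, seed = 4)
  sigma_f <- fe$sigma / kt_kcal(300)
  expect_lt(abs(fit$f_k[2] - analytic), 3 * sigma_f)
  # two identical states give exactly zero
  m0 <- gaussian_two_state(100, 100, 1000, seed = 5)
  expect_equal(mbar_solve(m0)$f_k[2], 0, tolerance = 1e-6)
})

test_that("MBAR agrees with BAR for two states", {
  m <- gaussian_two_state(100, 350, 4000, seed = 6)
  fit <- mbar_solve(m, tolerance = 1e-12)
  expect_lt(abs(fit$f_k[2] - bar_delta_f(m)), 1e-6)
})

test_that("MBAR is gauge invariant under per-sample shifts", {
  m <- gaussian_two_state(100, 300, 2000, seed = 7)
  f1 <- mbar_solve(m)$f_k
  m2 <- m
  shift <- rnorm(ncol(m2$u))
  m2$u <- sweep(m2$u, 2, shift, "+")
  f2 <- mbar_solve(m2)$f_k
  expect_equal(f1[2] - f1[1], f2[2] - f2[1], tolerance = 1e-7)
})

test_that("zero-sample states are consistent perturbation estimates", {
  pair <- ladder_e2(1)
  rec <- run_ladder(pair, n_iterations = 400, seed = 8, K = 6)
  m <- decorrelate(rec)
  f_full <- mbar_solve(m)$f_k
  # drop all samples from the middle state and mark it zero-sample
  drop <- m$state_of_sample == 3
  m2 <- list(u = m$u[, !drop, drop = FALSE],
             N_k = replace(tabulate(m$state_of_sample[!drop], 6), 3, 0))
  f_pert <- mbar_solve(m2)$f_k
  expect_equal(f_pert[6], f_full[6], tolerance = 0.15)
  expect_equal(f_pert[3], f_full[3], tolerance = 0.15)
})

test_that("MBAR bias on the harmonic fixture shrinks with sample size", {
  analytic <- 0.5 * log(exp(2))
  errs <- sapply(c(1e3, 1e4, 5e4), function(n) {
    dev <- sapply(1:4, function(s) {
      abs(mbar_solve(gaussian_two_state(100, 100 * exp(2), n,
                                        seed = 10 * n + s))$f_k[2] - analytic)
    })
    mean(dev)
  })
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.02)
})

test_that("bootstrap uncertainty tracks the repeated-experiment spread", {
  # spread of the point estimate over independent replications vs the
  # bootstrap sigma of one of them
  reps <- sapply(1:25, function(s) {
    mbar_solve(gaussian_two_state(100, 500, 800, seed = 100 + s))$f_k[2]
  })
  fe <- bootstrap_delta_g(gaussian_two_state(100, 500, 800, seed = 101),
                          n_bootstrap = 200, seed = 1)
  sigma_f <- fe$sigma / kt_kcal(300)
  ratio <- sigma_f / sd(reps)
  expect_gt(ratio, 1 / 1.8)
  expect_lt(ratio, 1.8)
})

test_that("bootstrap is deterministic in its seed and degenerate on constants", {
  m <- gaussian_two_state(100, 300, 500, seed = 8)
  fe1 <- bootstrap_delta_g(m, n_bootstrap = 50, seed = 9)
  fe2 <- bootstrap_delta_g(m, n_bootstrap = 50, seed = 9)
  expect_identical(fe1$delta_g, fe2$delta_g)
  expect_identical(fe1$sigma, fe2$sigma)
  expect_true(fe1$ci95[1] <= fe1$delta_g && fe1$delta_g <= fe1$ci95[2])
  # zero-variance degenerate matrix: all resamples identical, sigma = 0
  mdeg <- list(u = matrix(c(0, 1), 2, 10), N_k = c(5L, 5L),
               state_of_sample = rep(1:2, each = 5), temperature = 300)
  class(mdeg) <- "reduced_potential_matrix"
  fed <- bootstrap_delta_g(mdeg, n_bootstrap = 20, seed = 1)
  expect_equal(fed$sigma, 0)
})

test_that("phase differences combine in quadrature and antisymmetrically", {
  mk_fe <- function(dg, sigma) {
    structure(list(delta_g = dg, sigma = sigma,
                   ci95 = c(dg - 1.96 * sigma, dg + 1.96 * sigma),
                   n_bootstrap = 200, f_k = NULL, N_k = NULL,
                   temperature = 300), class = "fe_result")
  }
  a <- mk_fe(1, 0.1); b <- mk_fe(3, 0.1)
  dd <- delta_delta_g(a, b)
  expect_equal(dd$delta_g, 2)
  expect_equal(dd$sigma, sqrt(0.02), tolerance = 1e-12)
  expect_equal(delta_delta_g(b, a)$delta_g, -2)
  same <- delta_delta_g(a, a)
  expect_equal(same$delta_g, 0)
  expect_equal(same$sigma, sqrt(2) * 0.1, tolerance = 1e-12)
})

test_that("dG time series is consistent with the whole-record estimate", {
  pair <- ladder_e2(1)
  rec <- run_ladder(pair, n_iterations = 300, seed = 10, K = 6)
  ser <- dg_time_series(rec, n_points = 6, n_bootstrap = 60, seed = 3)
  expect_gte(nrow(ser), 3)
  expect_true(all(diff(ser$t_iter) > 0))
  # the final point equals the whole-record bootstrap estimate
  fe <- bootstrap_delta_g(decorrelate(rec, min_per_state = 1),
                          n_bootstrap = 60, seed = 3)
  last <- ser[nrow(ser), ]
  expect_equal(last$delta_g, fe$delta_g, tolerance = 1e-10)
  # stationary fixture: final value within noise of the analytic answer
  expect_lt(abs(last$delta_g - pair$analytic_delta_g), 3 * last$sigma)
})

test_that("tidy and glance methods expose the fit as tibbles", {
  m <- gaussian_two_state(100, 300, 500, seed = 12)
  fe <- bootstrap_delta_g(m, n_bootstrap = 30, seed = 2)
  td <- tidy(fe)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  expect_equal(td$f[1], 0)
  gl <- glance(fe)
  expect_equal(gl$error_bar_2sd, 2 * gl$sigma)
})
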