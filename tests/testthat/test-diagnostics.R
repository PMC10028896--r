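mk_series <- function(t_ns, delta_g, sigma = 0.05) {
  tibble::tibble(t_ns = t_ns, delta_g = delta_g, sigma = sigma)
}

test_that("convergence slope test handles exact flat and drifting series", {
  t <- seq(1, 10)
  flat <- mk_series(t, rep(2, 10))
  v <- convergence_slope_test(flat)
  expect_equal(v$slope, 0)
  expect_true(v$converged)
  # noiseless linear drift of 0.3 per ns: not converged at threshold 0.1
  drift <- mk_series(t, 1 + 0.3 * t)
  vd <- convergence_slope_test(drift)
  expect_equal(vd$slope, 0.3, tolerance = 1e-10)
  expect_false(vd$converged)
  # window longer than the series span is rejected
  expect_error(convergence_slope_test(flat, window = 100), "window")
  expect_error(convergence_slope_test(flat[1:2, ]), "3 points")
})

test_that("slope test false-alarm rate is near nominal on flat noise", {
  # white noise around a constant with SE(slope) ~ 0.05: the two-sided 2-SE
  # rule plus the absolute threshold should reject rarely
  t <- seq_len(50)
  resid_sd <- 0.05 * sqrt(sum((t[26:50] - mean(t[26:50]))^2))
  set.seed(31)
  fails <- vapply(seq_len(400), function(i) {
    s <- mk_series(t, 3 + rnorm(50, sd = resid_sd))
    !convergence_slope_test(s)$converged
  }, logical(1))
  expect_lt(mean(fails), 0.10)
})

test_that("mixing report flags a pinned replica deterministically", {
  K <- 4
  hist_ok <- t(replicate(200, sample(1:K)))
  hist_bad <- hist_ok
  hist_bad[, 1] <- 1L  # replica 1 pinned to state 1
  # rebuild rows as permutations with replica 1 pinned
  for (i in seq_len(nrow(hist_bad))) {
    hist_bad[i, 2:K] <- sample(2:K)
  }
  mk_rec <- function(h) {
    structure(list(state_history = h, K = K, n_iterations = nrow(h),
                   dudl = matrix(rnorm(length(h)), nrow(h), K),
                   observables = list(), sampling_interval_ns = 0.1),
              class = "run_record")
  }
  set.seed(40)
  rep_bad <- replica_mixing_report(mk_rec(hist_bad))
  expect_true(rep_bad$bottleneck)
  expect_equal(rep_bad$replica_summary$states_visited[1], 1L)
  rep_ok <- replica_mixing_report(mk_rec(hist_ok))
  expect_false(rep_ok$bottleneck)
  # uniform-permutation history mixes almost instantly: tiny second eigenvalue
  expect_lt(rep_ok$subdominant_eigenvalue, 0.3)
  expect_true(all(rep_ok$replica_summary$round_trips >= 1))
})

test_that("mixing report is trivial for a single state", {
  rec1 <- structure(list(state_history = matrix(1L, 50, 1), K = 1L,
                         n_iterations = 50L,
                         dudl = matrix(rnorm(50), 50, 1),
                         observables = list(), sampling_interval_ns = 0.1),
                    class = "run_record")
  mix <- replica_mixing_report(rec1)
  expect_false(mix$bottleneck)
  expect_equal(unname(mix$occupancy[1, 1]), 1)
})

test_that("dof catalog computes torsions, contacts and neighbor counts", {
  pair <- make_double_well_mutation(seed = 11)
  hs <- build_hybrid(pair)
  rec <- run_dw(hs, n_iterations = 15, seed = 12)
  cat_ <- dof_catalog(rec)
  expect_setequal(names(cat_$series),
                  c("slow_dof", "slow_mut_distance", "decoy_torsion",
                    "decoy_contact", "neighbors_mutating"))
  # torsions are reported in degrees within (-180, 180]
  tor <- cat_$series$decoy_torsion
  expect_true(all(tor > -180 & tor <= 180, na.rm = TRUE))
  # neighbor counts are non-negative integers
  nb <- cat_$series$neighbors_mutating
  expect_true(all(nb == round(nb)))
  # recomputation from configurations matches the recorded series
  rec2 <- rec
  rec2$observables <- list()
  cat2 <- dof_catalog(rec2)
  expect_equal(cat2$series$slow_dof, cat_$series$slow_dof, tolerance = 1e-12)
  expect_equal(cat2$series$decoy_torsion, cat_$series$decoy_torsion,
               tolerance = 1e-9)
})

test_that("degenerate geometry and zero radius behave as documented", {
  # collinear quadruple: torsion undefined -> NA
  x <- cbind(0:3, 0, 0)
  spec <- data.frame(id = "t", category = "backbone_torsion",
                     type = "torsion", i = 1, j = 2, k = 3, l = 4,
                     axis = NA, radius = NA)
  v <- alchrex:::eval_observables(spec, x)
  expect_true(is.na(v[["t"]]))
  # neighbor count with radius 0 counts nothing
  spec2 <- data.frame(id = "n", category = "neighbor_waters",
                      type = "neighbors", i = NA, j = NA, k = NA, l = NA,
                      axis = NA, radius = 0)
  attr(spec2, "mutating_idx") <- 1L
  expect_equal(unname(alchrex:::eval_observables(spec2, x)), 0)
})

test_that("dU/dlambda correlations recover planted relationships", {
  pair <- make_double_well_mutation(seed = 13)
  hs <- build_hybrid(pair)
  rec <- run_dw(hs, n_iterations = 60, seed = 14)
  # the slow coordinate is one of several equal contributors to dU/dlambda:
  # strongly coupled, and the top-ranked registered observable
  ct <- dudl_dof_correlation(rec)
  slow <- ct[ct$dof_id == "slow_dof", ]
  expect_gt(abs(slow$pcc), 0.3)
  expect_equal(ct$dof_id[which.max(abs(ct$pcc))], "slow_dof")
  # an observable identical to dudl has PCC exactly 1
  rec2 <- rec
  rec2$observables$self <- rec$dudl
  rec2$hybrid$observables <- rbind(
    rec2$hybrid$observables,
    data.frame(id = "self", category = "intra_contact", type = "coordinate",
               i = 1, j = NA, k = NA, l = NA, axis = 1, radius = NA))
  ct2 <- dudl_dof_correlation(rec2)
  expect_equal(ct2$pcc[ct2$dof_id == "self"], 1, tolerance = 1e-12)
  # independent decoys: CI straddles zero
  decoy <- ct[ct$dof_id == "decoy_torsion", ]
  expect_true(decoy$ci_lo < 0.3 && decoy$ci_hi > -0.3)
})

test_that("planted bivariate correlation is recovered within the CI", {
  K <- 4; n <- 5000; rho <- 0.7
  dudl <- matrix(rnorm(n * K), n, K)
  set.seed(21)
  obs <- rho * dudl + sqrt(1 - rho^2) * matrix(rnorm(n * K), n, K)
  rec <- structure(list(dudl = dudl, observables = list(planted = obs),
                        K = K, n_iterations = n,
                        state_history = matrix(rep(1:K, each = n), n, K),
                        sampling_interval_ns = 0.1,
                        hybrid = list(observables = data.frame(
                          id = "planted", category = "inter_contact",
                          type = "coordinate", i = 1, j = NA, k = NA, l = NA,
                          axis = 1, radius = NA), tags = character(0)),
                        configurations = NULL),
                   class = "run_record")
  ct <- dudl_dof_correlation(rec, dof_catalog(rec))
  expect_lt(abs(ct$pcc[1] - rho), 0.05)
})

test_that("zero-variance observables are flagged, not propagated", {
  K <- 2; n <- 50
  rec <- structure(list(dudl = matrix(rnorm(n * K), n, K),
                        observables = list(const = matrix(1, n, K)),
                        K = K, n_iterations = n,
                        state_history = matrix(rep(1:K, each = n), n, K),
                        sampling_interval_ns = 0.1,
                        hybrid = list(observables = data.frame(
                          id = "const", category = "intra_contact",
                          type = "coordinate", i = 1, j = NA, k = NA, l = NA,
                          axis = 1, radius = NA), tags = character(0)),
                        configurations = NULL),
                   class = "run_record")
  ct <- dudl_dof_correlation(rec, dof_catalog(rec))
  expect_true(ct$flagged[1])
  expect_true(is.na(ct$pcc[1]))
})

test_that("correlation summary picks max-|PCC| per category, ordered by g", {
  tab <- tibble::tibble(
    dof_id = c("a", "b", "c", "d"),
    category = c("x", "x", "y", "y"),
    pcc = c(0.3, -0.8, 0.1, NA),
    ci_lo = c(0.1, -0.9, -0.1, NA), ci_hi = c(0.5, -0.7, 0.3, NA),
    n_replicas = 4L, flagged = c(FALSE, FALSE, FALSE, TRUE),
    dudl_g_ns = c(5, 5, 5, 5))
  class(tab) <- c("correlation_table", class(tab))
  s <- correlation_summary(tab)
  expect_equal(s$dof_id[s$category == "x"], "b")  # sign preserved
  expect_equal(s$pcc[s$category == "x"], -0.8)
  # two mutations stacked: rows in non-increasing dudl_g order
  tab2 <- dplyr::bind_rows(tab, dplyr::mutate(tab, dudl_g_ns = 9))
  s2 <- correlation_summary(tab2)
  expect_true(all(diff(s2$dudl_g_ns) <= 0))
})

test_that("internal consistency follows the mutual-CI rule and is symmetric", {
  mk_fe <- function(dg, half) {
    structure(list(delta_g = dg, sigma = half / 2,
                   ci95 = c(dg - half, dg + half), n_bootstrap = 200,
                   temperature = 300), class = "fe_result")
  }
  ok <- internal_consistency(mk_fe(2, 0.2), mk_fe(-2, 0.2))
  expect_equal(ok$discrepancy, 0)
  expect_true(ok$consistent)
  bad <- internal_consistency(mk_fe(2, 0.2), mk_fe(-4, 0.2))
  expect_false(bad$consistent)
  # symmetry under exchanging forward and reverse
  bad2 <- internal_consistency(mk_fe(-4, 0.2), mk_fe(2, 0.2))
  expect_equal(bad$consistent, bad2$consistent)
  expect_equal(bad$discrepancy, bad2$discrepancy)
  # within 1 kcal/mol of the other's CI in one direction suffices
  edge <- internal_consistency(mk_fe(2, 0.2), mk_fe(-3.0, 0.2))
  expect_true(edge$consistent)
})

test_that("consistency metrics bootstrap RMSE and MUE", {
  z <- consistency_metrics(c(0, 0, 0), seed = 1)
  expect_equal(z$value, c(0, 0))
  expect_equal(z$ci_lo, c(0, 0))
  m <- consistency_metrics(c(1, -1, 2, -2), n_bootstrap = 500, seed = 2)
  expect_equal(m$value[m$metric == "rmse"], sqrt(mean(c(1, 1, 4, 4))))
  expect_equal(m$value[m$metric == "mue"], 1.5)
  expect_true(all(m$ci_lo <= m$value & m$value <= m$ci_hi))
})

test_that("restrained comparison applies the verdict rules", {
  t <- 1:10
  flat <- mk_series(t, rep(1, 10))
  drift <- mk_series(t, 0.5 * t)
  expect_equal(restrained_comparison(drift, flat)$verdict,
               "conformational-sampling problem")
  expect_equal(restrained_comparison(flat, flat)$verdict,
               "no detected problem")
  expect_equal(restrained_comparison(drift, drift)$verdict,
               "not solely conformational")
})

test_that("autoplot methods return ggplot objects", {
  pair <- ladder_e2(1)
  rec <- run_ladder(pair, n_iterations = 120, seed = 15, K = 6)
  ser <- dg_time_series(rec, n_points = 5, n_bootstrap = 20, seed = 1)
  expect_s3_class(autoplot(ser), "ggplot")
  mix <- replica_mixing_report(rec)
  expect_s3_class(autoplot(mix), "ggplot")
  expect_s3_class(tidy(mix), "tbl_df")
  expect_s3_class(glance(mix), "tbl_df")
})
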