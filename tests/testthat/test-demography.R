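# Demographic models, expected spectra, composite likelihood and the AIC
# machinery (cheap checks; the stochastic recovery studies live in the
# acceptance suite).

test_that("model definitions carry the declared structure", {
  ks <- vapply(1:6, function(i) demographic_model(i)$k, numeric(1))
  expect_equal(ks, c(2, 5, 4, 7, 7, 9))
  expect_true("T0" %in% demographic_model(2)$par_names)   # free divergence
  expect_false("T1" %in% demographic_model(3)$par_names)  # single epoch
  expect_error(demographic_model(7), "1..6")
  m <- demographic_model(4)
  expect_error(expected_sfs(m, c(N_C1 = 100, N_A1 = 100), 4, 4),
               "out of bounds or missing")
})

test_that("expected spectra are normalized and hit analytic limits", {
  # all samples on one side: folded margin follows the constant-size form
  m1 <- demographic_model(1)
  e <- expected_sfs(m1, c(N_C = 2000, N_A = 2000), 12, 0,
                    n_genealogies = 40000, seed = 3)
  expect_equal(sum(e$counts), 1, tolerance = 1e-12)
  margin <- e$counts[2:7, 1]
  expect_lt(max(abs(margin / sum(margin) - oracle_folded_1d(12))), 0.01)

  # deep isolation concentrates mass near the fixed-difference fold cells
  m1b <- demographic_model(1, T0 = 3e5)
  e2 <- expected_sfs(m1b, c(N_C = 500, N_A = 500), 6, 6,
                     n_genealogies = 4000, seed = 4)
  # the (0, j)+(i, 0) private margins dominated by the corner (0,6)/(6,0) fold
  corner <- e2$counts[7, 1] + e2$counts[1, 7]
  expect_gt(corner, 0.5)
})

test_that("composite log-likelihood follows its definition and guards", {
  mk <- function(mat, n1, n2) {
    x <- petrelpop:::new_folded_2dsfs(mat, n1, n2, sum(mat))
    x
  }
  # obs (2,1,1) on cells with expected (0.5, 0.25, 0.25):
  # lnCL = 2 ln 0.5 + 2 ln 0.25
  obs <- matrix(0, 3, 3); exp_ <- matrix(0, 3, 3)
  obs[2, 1] <- 2; obs[1, 2] <- 1; obs[2, 2] <- 1
  exp_[2, 1] <- 0.5; exp_[1, 2] <- 0.25; exp_[2, 2] <- 0.25
  expect_equal(composite_loglik(mk(obs, 2, 2), mk(exp_, 2, 2)),
               2 * log(0.5) + 2 * log(0.25), tolerance = 1e-9)
  expect_equal(2 * log(0.5) + 2 * log(0.25), -4.158883, tolerance = 1e-6)

  # all-zero observed errors; zero expected cell with observations stays finite
  expect_error(composite_loglik(mk(matrix(0, 3, 3), 2, 2), mk(exp_, 2, 2)),
               "all zero")
  exp0 <- exp_; exp0[2, 2] <- 0
  v <- composite_loglik(mk(obs, 2, 2), mk(exp0, 2, 2), eps = 1e-8)
  expect_true(is.finite(v))

  # scaling identity: lnCL(c * obs) = c * lnCL(obs)
  v1 <- composite_loglik(mk(obs, 2, 2), mk(exp_, 2, 2))
  v3 <- composite_loglik(mk(obs * 3, 2, 2), mk(exp_, 2, 2))
  expect_equal(v3, 3 * v1, tolerance = 1e-12)

  # information inequality: the matching expectation maximizes lnCL
  set.seed(6)
  for (i in 1:10) {
    pert <- exp_
    nz <- which(pert > 0)
    pert[nz] <- pert[nz] * exp(stats::rnorm(length(nz), 0, 0.3))
    pert <- pert / sum(pert)
    expect_lte(composite_loglik(mk(obs, 2, 2), mk(pert, 2, 2)), v1 + 1e-9)
  }
})

test_that("degenerate fitting budgets and AIC bookkeeping work", {
  m3 <- demographic_model(3, size_bounds = c(100, 5000),
                          mig_bounds = c(1e-6, 1e-2))
  truth <- c(N_C = 1500, N_A = 400, M_AC = 1e-3, M_CA = 1e-4)
  e <- expected_sfs(m3, truth, 8, 8, n_genealogies = 8000, seed = 7)
  obs <- e; obs$counts <- e$counts * 2000

  # n_runs = 1, max_cycles = 0: the initialization point is evaluated as-is
  f0 <- fit_model(obs, m3, n_runs = 1, max_cycles = 0, n_genealogies = 2000,
                  seed = 5)
  expect_s3_class(f0, "sfs_fit")
  expect_equal(f0$AIC, 2 * m3$k - 2 * f0$loglik, tolerance = 1e-12)
  expect_false(f0$converged)

  # init values override the random draw
  f1 <- fit_model(obs, m3, n_runs = 1, max_cycles = 0, n_genealogies = 2000,
                  seed = 5, init = truth)
  expect_equal(unname(f1$par[names(truth)]), unname(truth))

  # compare_models: equal lnCL prefers smaller k, weights sum to one
  fa <- f0; fa$model_id <- 1L; fa$k <- 2; fa$AIC <- 2 * 2 - 2 * fa$loglik
  fb <- f0; fb$model_id <- 2L; fb$k <- 4; fb$AIC <- 2 * 4 - 2 * fb$loglik
  tab <- compare_models(list(fb, fa))
  expect_equal(tab$model[1], 1)
  expect_equal(tab$delta_AIC[1], 0)
  expect_equal(sum(tab$akaike_weight), 1, tolerance = 1e-12)

  # fits on different observed spectra cannot be compared
  obs2 <- obs; obs2$counts <- obs$counts * 2
  f2 <- fit_model(obs2, m3, n_runs = 1, max_cycles = 0,
                  n_genealogies = 1000, seed = 6)
  expect_error(compare_models(list(f0, f2)), "same observed")
})

test_that("bootstrap CIs degenerate to zero width on identical replicates", {
  m1 <- demographic_model(1, size_bounds = c(100, 5000))
  e <- expected_sfs(m1, c(N_C = 1200, N_A = 600), 6, 6,
                    n_genealogies = 6000, seed = 8)
  obs <- e; obs$counts <- e$counts * 500
  reps <- list(obs, obs, obs)
  ci <- bootstrap_cis(reps, m1, n_runs = 1, max_cycles = 2,
                      n_genealogies = 800, seed = 3)
  expect_equal(ci$ci_lower, ci$ci_upper, tolerance = 1e-9)
  expect_true(all(ci$ci_lower <= ci$median & ci$median <= ci$ci_upper))
  expect_error(bootstrap_cis(list(obs), m1), "at least two")
})
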