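# Priors, proposal covariance, importance-sampled evidence, model selection.

test_that("log prior matches the closed form and its support", {
  pr <- prior_config()
  m <- fp_model(tau = pr$Z_tau, L = pr$Z_L)
  expect_equal(log_prior(m, pr), -2 - log(pr$Z_tau) - log(pr$Z_L),
               tolerance = 1e-12)
  over <- fp_model(tau = c(1, 1), L = c(1, 1), x = pr$Z_x * 1.01)
  expect_identical(log_prior(over, pr), -Inf)
  # M = 1 prior integrates to one (coarse log-grid quadrature)
  lt <- seq(log(1e-4), log(500), length.out = 400)
  g <- exp(lt)
  w <- c(diff(lt)[1] / 2, (diff(lt)[-1] + diff(lt)[-399]) / 2, diff(lt)[398] / 2)
  one_d <- sum(w * g * exp(-g / pr$Z_tau) / pr$Z_tau)
  expect_equal(one_d^2, 1, tolerance = 1e-3)  # tau and L factors are identical
})

test_that("the finite-difference Hessian machinery inverts a known quadratic", {
  A <- matrix(c(2.0, 0.3, 0.1,
                0.3, 1.5, -0.2,
                0.1, -0.2, 0.8), 3, 3)
  f <- function(th) -0.5 * as.numeric(t(th - 1) %*% A %*% (th - 1))
  H <- fpinfer:::num_hessian(f, c(1, 1, 1), hess_step = 1e-3)
  expect_equal(H, -A, tolerance = 1e-4)
  Sigma <- fpinfer:::invert_neg_hessian(H, 1e-10)
  expect_equal(Sigma, solve(A), tolerance = 1e-3)
})

test_that("interior proposal curvature reaches the Fisher-information limit", {
  tau <- 10
  n <- 1e4
  s <- generate_dataset(exp_model(tau), n, dt = 0.5, seed = 31)
  d <- bin_isi(s, 0.5)
  fit <- fit_mle(d, 1, config = fit_config(n_starts = 2))
  occ <- fpinfer:::occupied_bins(d)
  H <- fpinfer:::num_hessian(
    function(th) fpinfer:::log_f_theta(th, 1L, occ, fit$priors),
    fpinfer:::theta_from_model(fit$model), hess_step = 1e-4)
  # conditional variance of tau-hat at fixed L: 1 / (-H)_tautau ~ tau^2 / n
  expect_lt(abs(1 / (-H[1, 1]) - tau^2 / n) / (tau^2 / n), 0.2)
})

test_that("boundary fits get the block-diagonal proposal covariance", {
  s <- generate_dataset(exp_model(8), 2000, dt = 0.5, seed = 32)
  d <- bin_isi(s, 0.5)
  f1 <- fit_mle(d, 1, config = fit_config(n_starts = 2))
  # a two-path model whose second path carries (essentially) zero flux
  m2 <- fp_model(tau = c(f1$model$tau, 5), L = c(f1$model$L, 3), x = 1e-9)
  cfg <- fit_config()
  fit2 <- structure(
    list(model = m2, M = 2L,
         log_f = log_likelihood(d, m2) + log_prior(m2),
         log_lik = log_likelihood(d, m2), log_prior = log_prior(m2),
         at_boundary = fpinfer:::boundary_flags(m2, prior_config(), cfg),
         priors = prior_config(), config = cfg,
         data_info = list(dt = d$dt, n_total = d$n_total)),
    class = "fp_fit")
  expect_identical(fit2$at_boundary, c(FALSE, TRUE))
  icfg <- is_config(n_samples = 1000)
  S <- proposal_covariance(fit2, d, icfg)
  expect_identical(attr(S, "trivial_paths"), 2L)
  # trivial path coordinates (x2, tau2, L2) = theta indices 3:5 decouple
  expect_true(all(S[3:5, 1:2] == 0))
  expect_true(all(S[1:2, 3:5] == 0))
  expect_equal(diag(S)[3:5], c(icfg$alpha_x^2, icfg$alpha_tau_sq,
                               icfg$alpha_L_sq), ignore_attr = TRUE)
  expect_true(all(S[3:5, 3:5][upper.tri(diag(3))] == 0))
})

test_that("importance-sampled evidence agrees with dense quadrature on tiny data", {
  s <- c(3.2, 5.1, 6.8, 9.4, 12.3)
  d <- bin_isi(s, dt = 1)
  fit <- fit_mle(d, 1, config = fit_config(n_starts = 2))
  ev <- log_marginal_likelihood(d, fit, is_config(n_samples = 2e4, seed = 41))
  quad <- quadrature_evidence_m1(d, n_grid = 150)
  quad_fine <- quadrature_evidence_m1(d, n_grid = 280)
  quad_err <- abs(quad_fine - quad)
  combined <- sqrt(max(ev$err_lo, ev$err_hi)^2 + quad_err^2)
  expect_lt(abs(ev$log_evidence - quad_fine), 2 * combined + 0.02)
})

test_that("reported error bars are consistent with seed-to-seed scatter", {
  s <- generate_dataset(exp_model(6), 200, dt = 0.5, seed = 33)
  d <- bin_isi(s, 0.5)
  fit <- fit_mle(d, 1, config = fit_config(n_starts = 2))
  S <- proposal_covariance(fit, d, is_config(n_samples = 2000))
  evs <- vapply(1:12, function(k) {
    log_marginal_likelihood(d, fit, is_config(n_samples = 2000, seed = k),
                            S)$log_evidence
  }, numeric(1))
  reported <- log_marginal_likelihood(
    d, fit, is_config(n_samples = 2000, seed = 99), S)
  ratio <- sd(evs) / max(reported$err_lo, reported$err_hi)
  expect_gt(ratio, 0.2)
  expect_lt(ratio, 4)
})

test_that("evidence totals add across conditions", {
  s1 <- generate_dataset(exp_model(5), 300, dt = 0.5, seed = 34)
  s2 <- generate_dataset(exp_model(9), 300, dt = 0.5, seed = 35)
  fcfg <- fit_config(n_starts = 2)
  icfg <- is_config(n_samples = 2000)
  multi <- select_model_multi(list(a = s1, b = s2), dt = 0.5, M_max = 2,
                              fit_cfg = fcfg, is_cfg = icfg)
  # joint-product oracle: per-condition selections with the same derived seeds
  singles <- lapply(seq_along(multi$per_condition), function(j) {
    multi$per_condition[[j]]$per_M$log_evidence
  })
  expect_equal(multi$totals$log_evidence, singles[[1]] + singles[[2]],
               tolerance = 1e-12)
  # s = 1 reduces to plain select_model
  one <- select_model_multi(list(a = s1), dt = 0.5, M_max = 2,
                            fit_cfg = fcfg, is_cfg = icfg)
  expect_equal(one$totals$log_evidence,
               one$per_condition[[1]]$per_M$log_evidence)
  expect_identical(one$best_M, one$per_condition[[1]]$best_M)
})

test_that("two identical datasets double the evidence within combined error", {
  s <- generate_dataset(exp_model(5), 400, dt = 0.5, seed = 36)
  icfg <- is_config(n_samples = 4000)
  multi <- select_model_multi(list(a = s, b = s), dt = 0.5, M_max = 1,
                              fit_cfg = fit_config(n_starts = 2),
                              is_cfg = icfg)
  per <- vapply(multi$per_condition, function(x) x$per_M$log_evidence[1],
                numeric(1))
  errs <- vapply(multi$per_condition, function(x)
    max(x$per_M$err_lo[1], x$per_M$err_hi[1]), numeric(1))
  expect_lt(abs(per[1] - per[2]), 2 * sqrt(sum(errs^2)) + 0.02)
  expect_equal(multi$totals$log_evidence[1], sum(per), tolerance = 1e-12)
})

test_that("an extra path is penalized on single-path data (Occam factor)", {
  s <- generate_dataset(exp_model(10), 1500, dt = 0.5, seed = 37)
  sel <- select_model(s, 0.5, 2, fit_cfg = fit_config(n_starts = 2),
                      is_cfg = is_config(n_samples = 4000))
  e1 <- sel$per_M[1, ]
  e2 <- sel$per_M[2, ]
  combined <- sqrt(max(e1$err_lo, e1$err_hi)^2 + max(e2$err_lo, e2$err_hi)^2)
  expect_lte(e2$log_evidence, e1$log_evidence + combined + 0.1)
  expect_identical(sel$best_M, 1L)
})

test_that("selection recovers the order of a two-path generator", {
  m <- two_path_model()
  hits <- vapply(1:4, function(r) {
    s <- generate_dataset(m, 5000, dt = 0.2, seed = 700 + r)
    sel <- select_model(s, 0.2, 3,
                        fit_cfg = fit_config(n_starts = 2, seed = r),
                        is_cfg = is_config(n_samples = 2000, seed = r))
    sel$best_M
  }, integer(1))
  expect_gte(sum(hits == 2L), 3L)
})
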