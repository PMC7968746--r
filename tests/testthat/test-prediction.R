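# Cross-condition path matching, interpolation, and JSD validation.

linear_gen <- function(n_per = 5000, conditions = c(0.5, 1, 1.5, 2, 2.5, 3)) {
  condition_generator(
    base_summaries = tibble::tibble(mean_completion = c(8, 60),
                                    cv = c(0.55, 0.25),
                                    weight = c(0.7, 0.3)),
    slopes = tibble::tibble(mean_completion = c(2, -8),
                            cv = c(-0.05, 0.02),
                            weight = c(-0.06, 0.06)),
    conditions = conditions, dt = 0.2, n_per_condition = n_per, seed = 61
  )
}

test_that("path matching orders by completion time and survives permutation", {
  m <- fp_model(tau = c(3.2, 2.5), L = c(25, 4), x = 0.6 / 0.4)  # slow first
  p <- mixture_weights(m$x)
  m_perm <- fp_model(tau = rev(m$tau), L = rev(m$L), x = p[1] / p[2])
  series <- match_paths(list(m, m_perm), conditions = c(1, 2))
  s1 <- series[series$condition == 1, c("mean_completion", "cv", "weight")]
  s2 <- series[series$condition == 2, c("mean_completion", "cv", "weight")]
  expect_equal(as.data.frame(s1), as.data.frame(s2), tolerance = 1e-12)
  expect_true(all(diff(s1$mean_completion) > 0))
  # single condition: identity correspondence
  one <- match_paths(list(m), conditions = 1)
  expect_equal(one$mean_completion, sort(path_summaries(m)$mean_completion))
  expect_error(match_paths(list(m, exp_model()), c(1, 2)), "same number")
})

test_that("key ties are broken by the fixed summary cycle", {
  # equal mean completion times, different CVs
  m <- fp_model(tau = c(5, 2.5), L = c(2, 4), x = 1)  # T = 10 for both
  series <- match_paths(list(m), conditions = 1)
  expect_equal(series$cv, sort(1 / sqrt(c(2, 4))))
  # cv key: order by cv first
  series_cv <- match_paths(list(m), conditions = 1, key = "cv")
  expect_equal(series_cv$cv, sort(1 / sqrt(c(2, 4))))
})

test_that("interpolation is exact at observed conditions and for constant series", {
  gen <- linear_gen()
  models <- lapply(c(1, 2, 3), function(cc) condition_model(gen, cc))
  series <- match_paths(models, conditions = c(1, 2, 3))
  at2 <- interpolate_model(series, 2)
  expect_equal(at2$mode, "interpolated")
  truth <- condition_summaries(gen, 2)
  expect_equal(sort(at2$summaries$mean_completion),
               sort(truth$mean_completion), tolerance = 1e-9)
  # constant series predicts itself anywhere
  m <- two_path_model()
  const <- match_paths(list(m, m), conditions = c(1, 2))
  far <- interpolate_model(const, 7.5)
  expect_equal(far$mode, "extrapolated")
  expect_equal(sort(far$summaries$mean_completion),
               sort(path_summaries(m)$mean_completion), tolerance = 1e-9)
})

test_that("linear generators are recovered exactly at held-out conditions", {
  gen <- linear_gen()
  conds <- gen$conditions
  models <- lapply(conds, function(cc) condition_model(gen, cc))
  series <- match_paths(models, conditions = conds)
  # interpolation at a held-out interior point
  pred_in <- interpolate_model(match_paths(models[-3], conds[-3]), conds[3])
  truth_in <- condition_model(gen, conds[3])
  expect_equal(sort(pred_in$model$tau), sort(truth_in$tau), tolerance = 1e-8)
  expect_equal(sort(pred_in$model$L), sort(truth_in$L), tolerance = 1e-8)
  # extrapolation beyond the range
  pred_out <- interpolate_model(series, 3.5)
  truth_out <- condition_model(gen, 3.5)
  expect_equal(sort(pred_out$model$tau * pred_out$model$L),
               sort(truth_out$tau * truth_out$L), tolerance = 1e-8)
  expect_identical(pred_out$source_conditions, conds[5:6])
  # weights always form a probability vector
  expect_equal(sum(mixture_weights(pred_out$model$x)), 1, tolerance = 1e-12)
})

test_that("summary back-transform round-trips to machine precision", {
  for (k in 1:10) {
    s <- withr::with_seed(k, tibble::tibble(
      mean_completion = runif(3, 1, 100),
      cv = runif(3, 0.1, 1.2),
      weight = {
        w <- runif(3)
        w / sum(w)
      }
    ))
    m <- fp_model_from_summaries(s)
    back <- path_summaries(m)[c("mean_completion", "cv", "weight")]
    expect_equal(as.data.frame(back), as.data.frame(s), tolerance = 1e-10)
  }
})

test_that("JSD has its closed-form limits and symmetry", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(jsd(p, p), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), log(2), tolerance = 1e-12)
  for (k in 1:5) {
    q1 <- withr::with_seed(k, {
      a <- runif(6)
      a / sum(a)
    })
    q2 <- withr::with_seed(k + 100, {
      a <- runif(6)
      a / sum(a)
    })
    expect_equal(jsd(q1, q2), jsd(q2, q1), tolerance = 1e-12)
    expect_gte(jsd(q1, q2), 0)
    expect_lte(jsd(q1, q2), log(2))
  }
  expect_error(jsd(c(0.5, 0.5), c(1, 0, 0)), "length")
})

test_that("held-out prediction of a linear family has tiny JSD vs truth", {
  gen <- linear_gen()
  conds <- gen$conditions
  models <- lapply(conds, function(cc) condition_model(gen, cc))
  hold <- 4L
  series <- match_paths(models[-hold], conds[-hold])
  pred <- interpolate_model(series, conds[hold])
  truth <- condition_model(gen, conds[hold])
  edges <- fpinfer:::common_bins(0.2, 150)
  d <- jsd(fpinfer:::model_probs(pred$model, edges),
           fpinfer:::model_probs(truth, edges))
  expect_lt(d, 1e-3)
})

test_that("bootstrap JSD streams concentrate near zero in the degenerate setup", {
  truth <- exp_model(8)
  val <- generate_dataset(truth, 1500, dt = 1, seed = 62)
  res <- evaluate_prediction(test = val, validation = val, predicted = truth,
                             dt = 1, n_boot = 15, seed = 63)
  med <- tapply(res$jsd, res$stream, stats::median)
  expect_true(all(med < 0.05))
  expect_setequal(unique(res$stream),
                  c("test_vs_boot", "fit_vs_boot", "prediction_vs_boot"))
  # determinism
  res2 <- evaluate_prediction(test = val, validation = val, predicted = truth,
                              dt = 1, n_boot = 15, seed = 63)
  expect_identical(res$jsd, res2$jsd)
})

test_that("prediction JSD degrades with extrapolation distance", {
  # a family with curvature in the condition: linear extrapolation from the
  # last two fitted conditions errs increasingly far outside the range
  summaries_at <- function(cc) {
    tibble::tibble(
      mean_completion = c(8 + 2 * cc + 1.5 * cc^2, 60 - 4 * cc),
      cv = c(0.5, 0.25),
      weight = c(0.6, 0.4)
    )
  }
  conds <- c(1, 1.5, 2, 2.5, 3)
  models <- lapply(conds, function(cc) fp_model_from_summaries(summaries_at(cc)))
  series <- match_paths(models, conds)
  meds <- vapply(c(3.2, 4.0, 4.8), function(cc) {
    pred <- interpolate_model(series, cc)
    truth <- fp_model_from_summaries(summaries_at(cc))
    val <- generate_dataset(truth, 3000, dt = 0.2, seed = round(100 * cc))
    test <- generate_dataset(truth, 3000, dt = 0.2, seed = round(100 * cc) + 1L)
    res <- evaluate_prediction(test, val, pred, dt = 0.2, n_boot = 8, seed = 64)
    stats::median(res$jsd[res$stream == "prediction_vs_boot"])
  }, numeric(1))
  expect_true(meds[3] > meds[1])
})
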