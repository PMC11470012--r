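# Maximum-likelihood fitting, AIC/Akaike-weight model comparison, pooling.

fast_settings <- function(seed = 1) fit_settings(n_starts = 16, seed = seed)

test_that("individual fit recovers scout parameters and respects the support", {
  truth <- scout_params(0.2, 2, 0.5)
  gen <- mixture_params(1, truth, recruit_params(0.2, 2, 0.5))
  rel_a <- rel_b <- c()
  for (s in 1:10) {
    d <- waggle_dataset("t", rmixture(2000, gen, seed = 400 + s))
    fit <- fit_individual(d, fast_settings(s))
    expect_true(fit$params$scout$a_s * max(d$durations) < 1)
    rel_a <- c(rel_a, fit$params$scout$a_s / truth$a_s - 1)
    rel_b <- c(rel_b, fit$params$scout$b_s / truth$b_s - 1)
  }
  expect_lt(median(abs(rel_a)), 0.10)
  expect_lt(median(abs(rel_b)), 0.20)
})

test_that("fitted log-likelihood is at least the likelihood at the truth", {
  truth <- study_mixture(0.3)
  for (s in 1:3) {
    d <- waggle_dataset("t", rmixture(800, truth, seed = 500 + s))
    at_truth <- log_likelihood(d, study_mixture(0.3, m = d$m))
    expect_gte(fit_collective(d, fast_settings(s))$loglik, at_truth)
  }
})

test_that("collective fit recovers the scout fraction", {
  truth <- study_mixture(0.3)
  errs <- sapply(1:5, function(s) {
    d <- waggle_dataset("t", rmixture(2000, truth, seed = 600 + s))
    fit_collective(d, fast_settings(s))$params$p - 0.3
  })
  expect_lt(median(abs(errs)), 0.05)
})

test_that("the nested collective model never fits worse than the individual one", {
  for (s in 1:4) {
    p <- c(0.2, 0.6, 1, 1)[s]
    d <- waggle_dataset("t", rmixture(300, study_mixture(p), seed = 700 + s))
    ind <- fit_individual(d, fast_settings(s))
    col <- fit_collective(d, fast_settings(s))
    expect_gte(col$loglik, ind$loglik - 1e-6)
  }
})

test_that("AIC identity and free-parameter counts hold for every fit", {
  d <- waggle_dataset("t", rmixture(200, ref_mixture(), seed = 42))
  ind <- fit_individual(d, fast_settings())
  col <- fit_collective(d, fast_settings())
  expect_identical(ind$n_free_params, 2L)
  expect_identical(col$n_free_params, 5L)
  expect_equal(ind$aic, 2 * 2 - 2 * ind$loglik)
  expect_equal(col$aic, 2 * 5 - 2 * col$loglik)
  expect_identical(ind$params$p, 1)
})

test_that("model comparison arithmetic: penalty, weights, tie-breaking", {
  mk <- function(kind, loglik, k, hive = "h") {
    structure(list(model_kind = kind, params = ref_mixture(if (kind == "individual") 1 else 0.5),
                   loglik = loglik, n_free_params = k, aic = 2 * k - 2 * loglik,
                   converged = TRUE, n_restarts_used = 1L, hive_id = hive),
              class = "waggle_fit")
  }
  # equal log-likelihoods: the 3 extra parameters cost exactly 6 AIC units
  cmp <- compare_models(mk("individual", -100, 2), mk("collective", -100, 5))
  expect_equal(cmp$delta_aic, -6)
  expect_identical(cmp$selected, "individual")
  expect_equal(sum(cmp$akaike_weights), 1, tolerance = 1e-12)
  # collective must gain > 3 nats to win
  cmp2 <- compare_models(mk("individual", -100, 2), mk("collective", -96.9, 5))
  expect_identical(cmp2$selected, "collective")
  expect_equal(sum(cmp2$akaike_weights), 1, tolerance = 1e-12)
  # exact tie in AIC goes to the simpler model
  cmp3 <- compare_models(mk("individual", -100, 2), mk("collective", -97, 5))
  expect_identical(cmp3$selected, "individual")
  expect_error(compare_models(mk("individual", -1, 2, "a"),
                              mk("collective", -1, 5, "b")),
               class = "wagglefit_input_error")
})

test_that("waggle dance use is one minus the collective scout fraction", {
  d <- waggle_dataset("t", rmixture(400, study_mixture(0.25), seed = 77))
  cmp <- compare_models(fit_individual(d, fast_settings()),
                        fit_collective(d, fast_settings()))
  expect_equal(cmp$waggle_dance_use, 1 - cmp$fits$collective$params$p)
  expect_gte(cmp$waggle_dance_use, 0)
  expect_lte(cmp$waggle_dance_use, 1)
})

test_that("fitting refuses datasets below the observation floor", {
  expect_error(fit_individual(waggle_dataset("t", c(1, 2, 3))),
               class = "wagglefit_input_error")
})

test_that("pooling a dataset with itself reproduces the single fit", {
  d <- waggle_dataset("t", rmixture(500, study_mixture(0.3), seed = 31))
  single <- fit_collective(d, fast_settings())
  pooled <- fit_pooled(list(d, d), fast_settings())
  expect_equal(pooled$fits$collective$params$p, single$params$p, tolerance = 0.02)
})

test_that("heterogeneous hives: summed per-hive AIC beats pooled AIC", {
  wins <- sapply(1:3, function(s) {
    d1 <- waggle_dataset("h1", rmixture(400, study_mixture(0.1), seed = 800 + s))
    d2 <- waggle_dataset("h2", rmixture(400, study_mixture(0.9), seed = 900 + s))
    ps <- pooled_summary(list(d1, d2), fast_settings(s))
    ps$sum_best_aic < ps$pooled_best_aic
  })
  expect_gte(sum(wins), 2)
})
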