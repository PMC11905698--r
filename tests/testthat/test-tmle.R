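# hand-built nuisance object with known constant probabilities
fake_nuisance <- function(p_a, p_cens, levels = c(0, 1), lookback = Inf) {
  structure(list(
    exposure = structure(list(
      levels = levels,
      predict = function(newdf, a) rep(if (a == 1) p_a else 1 - p_a,
                                       nrow(newdf))), class = "exposure_fit"),
    censoring = lapply(1:4, function(t) structure(
      list(predict = function(newdf) rep(p_cens, nrow(newdf))),
      class = "prob_fit")),
    lookback = lookback), class = "nuisance_fits")
}

test_that("clever weights follow the closed form", {
  d <- simulate_survival_data(500, seed = 31,
                              params = params_no_censoring())
  nu <- fake_nuisance(p_a = 0.5, p_cens = 0)
  h <- clever_weights(d, a = 1, j = 1, nuisance = nu)
  expect_true(all(h[d$exposure != 1] == 0))
  expect_true(all(h[d$exposure == 1 & d$censor[, 1] == 0] == 2))
  # gbound domain
  expect_error(clever_weights(d, 1, 1, nu, gbound = 0.7), "gbound")
  expect_error(clever_weights(d, 1, 1, nu, gbound = 0), "gbound")

  # under correctly specified models the weights average to ~1
  d <- simulate_survival_data(5000, seed = 32)
  nu <- fit_nuisance(d)
  for (j in c(1, 4)) {
    h <- clever_weights(d, a = 1, j = j, nuisance = nu)
    expect_lt(abs(mean(h) - 1), 0.1)
  }
})

test_that("the fluctuation step solves its weighted score equation", {
  n <- 50
  Q <- runif(n, 0.2, 0.8)

  # zero weights: nothing to update
  upd <- target_step(Q, response = rep(1, n), weights = rep(0, n),
                     riskset = rep(TRUE, n))
  expect_equal(upd$epsilon, 0)
  expect_equal(upd$Q_updated, Q)

  # fixed point: response equal to the predictions gives epsilon 0
  upd <- target_step(Q, response = Q, weights = runif(n),
                     riskset = rep(TRUE, n))
  expect_lt(abs(upd$epsilon), 1e-8)

  # closed form: offset logit(0.5) = 0, so epsilon = logit(weighted mean)
  set.seed(41)
  y <- rep(c(1, 0), times = c(40, 10))
  upd <- target_step(rep(0.5, n), response = y, weights = rep(1, n),
                     riskset = rep(TRUE, n))
  expect_equal(upd$epsilon, qlogis(0.8), tolerance = 1e-8)
  expect_equal(unique(round(upd$Q_updated, 10)), 0.8)

  # generic case: the score is numerically zero at the solution
  w <- rexp(n)
  y <- rbinom(n, 1, 0.4)
  upd <- target_step(Q, y, w, riskset = rep(TRUE, n))
  expect_lt(abs(sum(w * (y - upd$Q_updated))), 1e-8)
})

test_that("targeting zeroes the score at every backward step (n = 2000)", {
  d <- simulate_survival_data(2000, seed = 52)
  nu <- fit_nuisance(d)
  for (a in c(0, 1)) {
    r <- tmle_survival(d, a = a, t = 4, nuisance = nu)
    expect_true(all(abs(r$score_residuals) < 1e-6))
    expect_lt(abs(mean(r$influence_curve)), 1e-6)
    expect_true(r$estimate >= 0 && r$estimate <= 1)
    expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
  }
})

test_that("TMLE reproduces the nonparametric standardized estimate exactly
           under saturated models without censoring", {
  d <- simulate_survival_data(800, seed = 53,
                              params = params_no_censoring())
  # saturated outcome model for binary (A, L): main effects + interaction
  saturated <- learner_spec("stacked",
                            library = list(learner_glm_interactions()),
                            folds = 5)
  suppressWarnings({  # zero-censoring strata are expected here
    nu <- fit_nuisance(d)
    for (a in c(0, 1)) {
      r <- tmle_survival(d, a = a, t = 1, nuisance = nu,
                         learner_outcome = saturated)
      expect_equal(r$estimate, standardized_t1(d, a), tolerance = 1e-10)
    }
  })
})

test_that("a null exposure effect yields matching survival arms", {
  p_null <- dgp_params(beta_a = 0)
  d <- simulate_survival_data(4000, seed = 54, params = p_null)
  nu <- fit_nuisance(d)
  r1 <- tmle_survival(d, a = 1, t = 2, nuisance = nu)
  r0 <- tmle_survival(d, a = 0, t = 2, nuisance = nu)
  ate <- tmle_ate(r1, r0)
  expect_lt(abs(ate$estimate), 3 * ate$se + 0.01)
})

test_that("ATE combines estimates and influence curves", {
  d <- simulate_survival_data(1000, seed = 55)
  nu <- fit_nuisance(d)
  r1 <- tmle_survival(d, a = 1, t = 2, nuisance = nu)
  r0 <- tmle_survival(d, a = 0, t = 2, nuisance = nu)
  ate <- tmle_ate(r1, r0)
  expect_equal(ate$estimate, r1$estimate - r0$estimate)
  expect_equal(ate$influence_curve,
               r1$influence_curve - r0$influence_curve)

  # identical inputs: zero effect with identically zero influence curve
  ate0 <- tmle_ate(r1, r1)
  expect_equal(ate0$estimate, 0)
  expect_equal(ate0$se, 0)

  r3 <- tmle_survival(d, a = 1, t = 3, nuisance = nu)
  expect_error(tmle_ate(r3, r0), "different times")

  expect_error(tmle_survival(d, a = 1, t = 9, nuisance = nu), "1..K")
  expect_error(tmle_survival(d, a = 7, t = 1, nuisance = nu), "not present")
})

test_that("the survival-curve wrapper aligns estimates with influence curves", {
  d <- simulate_survival_data(800, seed = 56)
  cv <- tmle_survival_curve(d)
  expect_identical(nrow(cv$estimates), 8L)
  expect_identical(dim(cv$ic), c(800L, 8L))
  for (r in seq_len(nrow(cv$estimates))) {
    expect_equal(mean(cv$ic[, r]), 0, tolerance = 1e-6)
    expect_equal(sqrt(var(cv$ic[, r]) / 800), cv$estimates$se[r])
  }
})
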