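test_that("parametric nuisance fits recover the generating probabilities", {
  n <- 200000
  d <- simulate_survival_data(n, seed = 303)

  # exposure model: predicted P(A=1|L) at both covariate values
  ef <- fit_exposure(d)
  newdf <- data.frame(L = c(0, 1))
  p_hat <- ef$predict(newdf, 1)
  p_true <- plogis(c(-3, -2.4))
  # 3 SEs of the stratum-specific empirical proportions (n/2 per stratum)
  se <- sqrt(p_true * (1 - p_true) / (n / 2))
  expect_true(all(abs(p_hat - p_true) < 3 * se))
  expect_equal(ef$predict(newdf, 0), 1 - p_hat)

  # censoring model at t = 1: rare outcome, wider relative error
  cf <- fit_censoring(d, t = 1)
  grid <- expand.grid(L = c(0, 1), A = c(0, 1))
  p_hat <- cf$predict(grid)
  p_true <- plogis(-5 + 0.2 * grid$A + 0.2 * grid$L)
  se <- sqrt(p_true * (1 - p_true) / (n / 4))
  expect_true(all(abs(p_hat - p_true) < 3.5 * se))

  # event model at j = 1 with the observed binary response
  of <- fit_outcome_step(d, j = 1, response = as.numeric(d$event[, 1]))
  p_hat <- of$predict(grid)
  p_true <- plogis(-2 - 1 * grid$A + 0.25 * grid$L)
  se <- sqrt(p_true * (1 - p_true) / (n / 4))
  expect_true(all(abs(p_hat - p_true) < 3.5 * se))
})

test_that("exposure model handles degenerate and multilevel codes", {
  d <- simulate_survival_data(200, seed = 5)
  d$exposure <- rep(1L, d$n)
  expect_error(fit_exposure(d), "degenerate")

  set.seed(6)
  d3 <- simulate_survival_data(600, seed = 6)
  d3$exposure <- sample(0:2, d3$n, replace = TRUE,
                        prob = c(0.5, 0.3, 0.2))
  ef <- fit_exposure(d3)
  probs <- sapply(0:2, function(a) ef$predict(d3$baseline, a))
  expect_true(all(abs(rowSums(probs) - 1) < 1e-8))
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("degenerate strata yield constant-probability models", {
  d <- simulate_survival_data(400, seed = 7, params = params_no_censoring())
  expect_warning(cf <- fit_censoring(d, t = 2), "no censoring")
  expect_equal(cf$predict(data.frame(L = c(0, 1), A = c(0, 1))), c(0, 0))

  # fractional response constant at c: intercept-only fit predicts c
  of <- fit_outcome_step(d, j = 1, response = rep(0.37, d$n),
                         learner = learner_spec("intercept"))
  expect_equal(of$predict(data.frame(L = 0, A = 1)), 0.37, tolerance = 1e-10)
})

test_that("lookback controls which covariate history enters the models", {
  set.seed(8)
  d <- simulate_survival_data(300, seed = 8)
  tv <- lapply(1:4, function(t) if (t >= 2) data.frame(W = rnorm(d$n)))
  d$tv_covariates <- tv
  f0 <- tmlesurv:::covariate_frame(d, j = 3, lookback = 0)
  expect_named(f0, c("L", "A"))
  f1 <- tmlesurv:::covariate_frame(d, j = 3, lookback = 1)
  expect_named(f1, c("L", "A", "W.3"))
  fall <- tmlesurv:::covariate_frame(d, j = 3, lookback = Inf)
  expect_named(fall, c("L", "A", "W.2", "W.3"))
  # the fit accepts a restricted history
  expect_s3_class(fit_censoring(d, t = 3, lookback = 0), "prob_fit")
})

test_that("stacking weights form a convex combination favouring the truth", {
  # single learner: weight 1
  set.seed(21)
  n <- 300
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(2 * x))
  df <- data.frame(x = x)
  s1 <- stack_learners(df, y, library = list(learner_glm()), folds = 5)
  expect_equal(unname(s1$weights), 1)

  # two identical learners: weights sum to 1 and the combined predictor
  # equals either one
  s2 <- stack_learners(df, y, library = list(learner_glm(), learner_glm()),
                       folds = 5)
  expect_equal(sum(s2$weights), 1)
  single <- learner_glm()$fit(df, y, rep(1, n))
  expect_equal(s2$predict(df), single(df), tolerance = 1e-8)

  # strong signal: nearly all weight on the correct model over the mean
  set.seed(22)
  n <- 2000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(3 * x))
  df <- data.frame(x = x)
  s3 <- stack_learners(df, y, library = list(learner_glm(), learner_mean()),
                       folds = 5)
  expect_gte(s3$weights[["glm"]], 0.9)

  # predictions stay inside [0, 1] for fractional responses
  yfrac <- plogis(3 * x + rnorm(n))
  s4 <- stack_learners(df, yfrac, library = default_learner_library(),
                       folds = 2)
  p <- s4$predict(df)
  expect_true(all(p >= 0 & p <= 1))

  # adaptive fold rule: too small errors out; thresholds are monotone
  expect_error(adaptive_folds(20), "effective sample size")
  expect_identical(c(adaptive_folds(30), adaptive_folds(500),
                     adaptive_folds(501), adaptive_folds(5001)),
                   c(10L, 10L, 5L, 2L))
})
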