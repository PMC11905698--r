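#' @include learners.R
NULL

# Build the covariate frame used by censoring/outcome regressions at
# interval j: exposure (numeric for binary codes, factor for multilevel),
# baseline covariates, and the time-varying covariate blocks of the last
# `lookback` intervals up to j.  lookback = 0 keeps exposure + baseline only.
covariate_frame <- function(data, j, lookback = Inf, include_exposure = TRUE,
                            exposure_value = NULL) {
  df <- data$baseline
  if (include_exposure) {
    if (is.null(data$exposure) && is.null(exposure_value))
      stop("data carry no exposure", call. = FALSE)
    a <- exposure_value %||% data$exposure
    if (length(a) == 1L) a <- rep(a, data$n)
    levels_a <- sort(unique(data$exposure %||% a))
    df$A <- if (length(levels_a) > 2L)
      factor(a, levels = levels_a) else as.numeric(a)
  }
  if (!is.null(data$tv_covariates) && lookback > 0) {
    first <- max(2L, j - as.integer(min(lookback, j)) + 1L)
    for (t in seq(first, j)) {
      if (t > length(data$tv_covariates)) next
      blk <- data$tv_covariates[[t]]
      if (is.null(blk)) next
      names(blk) <- paste0(names(blk), ".", t)
      df <- cbind(df, blk)
    }
  }
  df
}

# Risk-set mask at interval j: uncensored at j-1 and event-free at j-1
# (C_0 = Y_0 = 0 by convention).
at_risk <- function(data, j) {
  if (j == 1L) rep(TRUE, data$n)
  else data$censor[, j - 1L] == 0L &
    !is.na(data$event[, j - 1L]) & data$event[, j - 1L] == 0L
}

#' Fit the exposure model
#'
#' Estimates `P(A = a | L1)` from the baseline covariates.  A binary
#' exposure uses a probability regression of `I(A = 1)` per the supplied
#' learner; a multilevel exposure (3+ codes) always uses multinomial
#' logistic regression ([nnet::multinom()]), with per-level probabilities
#' summing to one for every subject.
#'
#' @param data a [wide_survival_data] object with a non-degenerate exposure.
#' @param learner a [learner_spec()].
#' @return An object of class `"exposure_fit"` with elements `levels` and
#'   `predict(baseline_df, a)` giving `P(A = a | L1)`.
#' @export
fit_exposure <- function(data, learner = learner_spec()) {
  if (is.null(data$exposure)) stop("data carry no exposure", call. = FALSE)
  a_obs <- data$exposure
  levels_a <- sort(unique(a_obs))
  if (length(levels_a) < 2L)
    stop("degenerate exposure: only level ", levels_a[1L],
         " observed", call. = FALSE)
  df <- data$baseline
  if (length(levels_a) == 2L) {
    hi <- levels_a[2L]
    fit <- fit_prob_model(df, as.numeric(a_obs == hi), learner = learner)
    pred <- function(newdf, a) {
      p_hi <- fit$predict(newdf)
      if (a == hi) p_hi else 1 - p_hi
    }
    info <- fit$info
  } else {
    mdf <- df
    mdf$.A <- factor(a_obs, levels = levels_a)
    mfit <- nnet::multinom(
      if (ncol(df) > 0L) .A ~ . else .A ~ 1,
      data = mdf, trace = FALSE, maxit = 500)
    pred <- function(newdf, a) {
      if (nrow(newdf) == 0L) return(numeric(0))
      pr <- predict(mfit, newdata = newdf, type = "probs")
      if (!is.matrix(pr))  # single row: named probability vector
        pr <- matrix(pr, nrow = 1L, dimnames = list(NULL, names(pr)))
      unname(pr[, as.character(a)])
    }
    info <- list(kind = "multinomial")
  }
  structure(list(levels = levels_a, predict = pred, info = info),
            class = "exposure_fit")
}

#' Fit a per-interval censoring model
#'
#' Models `P(C_t = 1 | A, Lbar_t, C_{t-1} = 0, Y_{t-1} = 0)` on the risk set
#' at interval `t`, conditioning on exposure, baseline covariates, and the
#' last `lookback` time-varying covariate blocks.  If no censoring occurs in
#' the risk set, a degenerate zero-probability model is returned with a
#' warning.
#'
#' @inheritParams fit_exposure
#' @param t interval in `1..K`.
#' @param lookback number of time-varying covariate blocks to condition on
#'   (`Inf` for the full history; 0 for exposure and baseline only).
#' @return A `"prob_fit"` whose `predict(newdf)` gives censoring
#'   probabilities.
#' @export
fit_censoring <- function(data, t, lookback = Inf, learner = learner_spec()) {
  rs <- at_risk(data, t)
  if (!any(rs)) stop("empty risk set at interval ", t, call. = FALSE)
  y <- data$censor[rs, t]
  df <- covariate_frame(data, t, lookback)[rs, , drop = FALSE]
  if (all(y == 0L)) {
    warning("no censoring events in the risk set at interval ", t,
            "; using a zero-probability model", call. = FALSE)
    return(structure(list(predict = function(newdf) rep(0, nrow(newdf)),
                          info = list(degenerate = TRUE, value = 0)),
                     class = "prob_fit"))
  }
  fit_prob_model(df, as.numeric(y), learner = learner)
}

#' Fit an event or iterated-expectation regression at one backward step
#'
#' Fits the response (the observed event indicator when the step equals the
#' target horizon; otherwise the previous backward step's updated
#' prediction, a fractional value in `[0, 1]`) on exposure and covariate
#' history, restricted to the risk set `{C_j = 0, Y_{j-1} = 0}`.
#'
#' @inheritParams fit_censoring
#' @param j interval of the backward step.
#' @param response per-subject values in `[0, 1]`; only risk-set entries are
#'   used.
#' @return A `"prob_fit"` accepting counterfactual covariate rows (exposure
#'   set to a level of interest) for prediction.
#' @export
fit_outcome_step <- function(data, j, response, lookback = Inf,
                             learner = learner_spec()) {
  rs <- at_risk(data, j) & data$censor[, j] == 0L
  if (!any(rs)) stop("empty risk set at interval ", j, call. = FALSE)
  y <- response[rs]
  if (anyNA(y))
    stop("missing response values inside the risk set at interval ", j,
         call. = FALSE)
  if (all(y == 0))
    warning("all-zero response in the risk set at interval ", j,
            "; using a zero-probability model", call. = FALSE)
  df <- covariate_frame(data, j, lookback)[rs, , drop = FALSE]
  fit_prob_model(df, as.numeric(y), learner = learner)
}

#' Fit all exposure and censoring models once
#'
#' Convenience wrapper caching the exposure model and the `K` per-interval
#' censoring models; these do not depend on the target time or exposure
#' level and are reused across every survival target.
#'
#' @inheritParams fit_censoring
#' @param learner_exposure,learner_censoring [learner_spec()]s for the two
#'   processes.
#' @return An object of class `"nuisance_fits"`.
#' @export
fit_nuisance <- function(data, learner_exposure = learner_spec(),
                         learner_censoring = learner_spec(),
                         lookback = Inf) {
  structure(list(
    exposure = fit_exposure(data, learner_exposure),
    censoring = lapply(seq_len(data$K), function(t)
      fit_censoring(data, t, lookback, learner_censoring)),
    lookback = lookback), class = "nuisance_fits")
}

# Per-subject cumulative probability of remaining uncensored through
# interval j, with exposure set to a and each per-interval probability of
# remaining uncensored floored at gbound.  Returns the vector with a
# truncation count attribute.
cumulative_uncensored <- function(nuisance, data, a, j, gbound = 0.005) {
  cum <- rep(1, data$n)
  n_trunc <- 0L
  for (k in seq_len(j)) {
    df <- covariate_frame(data, k, nuisance$lookback, exposure_value = a)
    p_unc <- 1 - nuisance$censoring[[k]]$predict(df)
    p_unc <- gbound_floor(p_unc, gbound)
    n_trunc <- n_trunc + attr(p_unc, "n_truncated")
    cum <- cum * as.numeric(p_unc)
  }
  attr(cum, "n_truncated") <- n_trunc
  cum
}
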