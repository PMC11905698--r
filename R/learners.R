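#' Candidate learners for nuisance regressions
#'
#' Each learner fits a probability regression of a response in `[0, 1]`
#' (binary events or fractional iterated-expectation responses) on a
#' covariate frame, with observation weights, and predicts probabilities for
#' new rows.  Fractional responses are handled throughout with
#' quasi-binomial iteratively reweighted least squares (logit link), which
#' solves the same score equations as logistic regression but tolerates
#' non-integer outcomes.
#'
#' Available learners:
#' * `learner_mean()` — weighted-mean (intercept-only) model;
#' * `learner_glm()` — main-terms logistic regression;
#' * `learner_glm_interactions()` — logistic regression with all two-way
#'   interactions plus squared terms for continuous covariates;
#' * `learner_gam()` — spline-based additive model ([mgcv::gam()]) with
#'   smooth terms for continuous covariates.
#'
#' @return An object of class `"tmlesurv_learner"` wrapping `fit(df, y, w)`,
#'   which returns a fitted model whose `predict(newdf)` gives probabilities.
#' @name learners
NULL

new_learner <- function(name, fit) {
  structure(list(name = name, fit = fit), class = "tmlesurv_learner")
}

glm_ctrl <- function() stats::glm.control(epsilon = 1e-10, maxit = 100)

# Fit a quasibinomial glm, returning a probability predictor.  Falls back to
# the weighted mean if the design is degenerate.
.fit_quasibinom <- function(formula, df, y, w) {
  df$.y <- y
  fit <- suppressWarnings(
    stats::glm(formula, data = df, family = quasibinomial(),
               weights = w, control = glm_ctrl()))
  function(newdf) clamp(unname(predict(fit, newdata = newdf, type = "response")))
}

#' @rdname learners
#' @export
learner_mean <- function() {
  new_learner("mean", function(df, y, w) {
    m <- stats::weighted.mean(y, w)
    function(newdf) rep(m, nrow(newdf))
  })
}

#' @rdname learners
#' @export
learner_glm <- function() {
  new_learner("glm", function(df, y, w) {
    if (ncol(df) == 0L) return(learner_mean()$fit(df, y, w))
    .fit_quasibinom(.y ~ ., df, y, w)
  })
}

# numeric columns with more than two distinct values are treated as continuous
.continuous_cols <- function(df) {
  names(df)[vapply(df, function(x)
    is.numeric(x) && length(unique(x)) > 2L, logical(1))]
}

#' @rdname learners
#' @export
learner_glm_interactions <- function() {
  new_learner("glm_interactions", function(df, y, w) {
    if (ncol(df) == 0L) return(learner_mean()$fit(df, y, w))
    rhs <- if (ncol(df) > 1L) "(.)^2" else "."
    sq <- .continuous_cols(df)
    if (length(sq) > 0L)
      rhs <- paste(c(rhs, sprintf("I(%s^2)", sq)), collapse = " + ")
    .fit_quasibinom(stats::as.formula(paste(".y ~", rhs)), df, y, w)
  })
}

#' @rdname learners
#' @export
learner_gam <- function() {
  new_learner("gam", function(df, y, w) {
    cont <- .continuous_cols(df)
    cont <- cont[vapply(df[cont], function(x) length(unique(x)) >= 10L,
                        logical(1))]
    other <- setdiff(names(df), cont)
    if (length(cont) == 0L) return(learner_glm()$fit(df, y, w))
    rhs <- paste(c(sprintf("s(%s)", cont), other), collapse = " + ")
    df$.y <- y
    df$.w <- w
    fit <- suppressWarnings(
      mgcv::gam(stats::as.formula(paste(".y ~", rhs)), data = df,
                family = quasibinomial(), weights = .w))
    function(newdf) clamp(unname(predict(fit, newdata = newdf,
                                         type = "response")))
  })
}

#' Default stacking library
#'
#' Learners of graded flexibility: an intercept-only mean, a main-terms
#' logistic regression, a logistic regression with two-way interactions and
#' squared continuous terms, and a spline-based additive model.  Highly
#' flexible tree-based methods are deliberately excluded: without sample
#' splitting they can break the conditions under which influence-curve
#' inference is valid.
#'
#' @return List of [learners].
#' @export
default_learner_library <- function() {
  list(learner_mean(), learner_glm(), learner_glm_interactions(),
       learner_gam())
}

#' Specify how a nuisance regression is fitted
#'
#' @param kind `"parametric"` for a single main-terms logistic regression,
#'   `"stacked"` for a cross-validated stacking ensemble over `library`, or
#'   `"intercept"` for an intercept-only (weighted mean) model — useful as a
#'   deliberately misspecified arm in double-robustness simulations.
#' @param library list of candidate [learners] (stacking only).
#' @param folds number of cross-validation folds, or `"adaptive"` to map the
#'   effective sample size to a fold count (see [adaptive_folds()]).
#' @return An object of class `"learner_spec"`.
#' @export
learner_spec <- function(kind = c("parametric", "stacked", "intercept"),
                         library = default_learner_library(),
                         folds = "adaptive") {
  kind <- match.arg(kind)
  if (kind == "stacked" && length(library) < 1L)
    stop("stacking requires at least one learner", call. = FALSE)
  structure(list(kind = kind, library = library, folds = folds),
            class = "learner_spec")
}

#' Adaptive cross-validation fold count
#'
#' Monotone rule mapping effective sample size to a number of folds: fewer
#' than 30 observations is an error; 30-500 uses 10 folds; 501-5000 uses 5;
#' above 5000 uses 2.  The effective sample size of a binary response is
#' `min(n, 5 * n_rare)` where `n_rare` is the count of the rarer outcome
#' class; fractional responses use `n` directly.
#'
#' @param n_eff effective sample size.
#' @return Integer fold count.
#' @export
adaptive_folds <- function(n_eff) {
  if (n_eff < 30) stop("effective sample size below 30: too small for ",
                       "cross-validated stacking", call. = FALSE)
  if (n_eff <= 500) 10L else if (n_eff <= 5000) 5L else 2L
}

effective_n <- function(y, w) {
  n <- sum(w > 0)
  if (all(y %in% c(0, 1))) {
    n_rare <- min(sum(y == 1 & w > 0), sum(y == 0 & w > 0))
    min(n, 5 * n_rare)
  } else n
}

#' Cross-validated stacking of probability learners
#'
#' Fits every learner in `library` on `folds` training splits, collects
#' out-of-fold predictions, and finds convex combination weights minimizing
#' the weighted cross-validated squared-error loss over the simplex
#' (non-negative least squares followed by normalization).  Learners that
#' fail on any fold are dropped with a warning; if all fail, the ensemble
#' falls back to the intercept-only mean.
#'
#' @param df covariate frame.
#' @param y response in `[0, 1]`.
#' @param w observation weights (default 1).
#' @param library list of [learners].
#' @param folds fold count or `"adaptive"`.
#' @return An object of class `"stack_fit"` with elements `weights` (named,
#'   non-negative, summing to 1), `folds`, `cv_risk`, and `predict(newdf)`.
#' @export
stack_learners <- function(df, y, w = rep(1, length(y)),
                           library = default_learner_library(),
                           folds = "adaptive") {
  n <- length(y)
  if (identical(folds, "adaptive")) folds <- adaptive_folds(effective_n(y, w))
  folds <- as.integer(folds)
  if (folds < 2L) stop("need at least 2 folds", call. = FALSE)
  fold_id <- sample(rep_len(seq_len(folds), n))
  p <- length(library)
  Z <- matrix(NA_real_, n, p)
  ok <- rep(TRUE, p)
  for (k in seq_len(p)) {
    for (v in seq_len(folds)) {
      test <- fold_id == v
      pred <- tryCatch({
        f <- library[[k]]$fit(df[!test, , drop = FALSE], y[!test], w[!test])
        f(df[test, , drop = FALSE])
      }, error = function(e) NULL)
      if (is.null(pred)) { ok[k] <- FALSE; break }
      Z[test, k] <- pred
    }
    if (!ok[k])
      warning("learner '", library[[k]]$name,
              "' failed during cross-validation and was dropped",
              call. = FALSE)
  }
  if (!any(ok)) {
    warning("all learners failed; falling back to intercept-only mean",
            call. = FALSE)
    library <- list(learner_mean())
    ok <- TRUE
    Z <- matrix(stats::weighted.mean(y, w), n, 1L)
  }
  Z <- Z[, ok, drop = FALSE]
  library <- library[ok]
  cv_risk <- colSums(w * (Z - y)^2) / sum(w)
  sw <- sqrt(w)
  alpha <- tryCatch(pracma::lsqnonneg(sw * Z, sw * y)$x,
                    error = function(e) NULL)
  if (is.null(alpha) || sum(alpha) <= 0) {
    alpha <- as.numeric(seq_along(library) == which.min(cv_risk))
  }
  alpha <- alpha / sum(alpha)
  fits <- lapply(library, function(l) l$fit(df, y, w))
  names(alpha) <- vapply(library, `[[`, character(1), "name")
  structure(list(
    weights = alpha, folds = folds, cv_risk = cv_risk,
    predict = function(newdf) {
      preds <- vapply(fits, function(f) f(newdf), numeric(nrow(newdf)))
      if (nrow(newdf) == 1L) preds <- matrix(preds, nrow = 1L)
      clamp(as.numeric(preds %*% alpha))
    }), class = "stack_fit")
}

# Fit a probability regression according to a learner_spec.  Returns a
# "prob_fit": list(predict = function(newdf) probs, info = list(...)).
fit_prob_model <- function(df, y, w = rep(1, length(y)),
                           learner = learner_spec()) {
  stopifnot(inherits(learner, "learner_spec"))
  if (all(y == y[1])) {
    # degenerate response: constant-probability model
    const <- as.numeric(y[1])
    return(structure(list(predict = function(newdf) rep(const, nrow(newdf)),
                          info = list(degenerate = TRUE, value = const)),
                     class = "prob_fit"))
  }
  if (learner$kind == "parametric") {
    f <- learner_glm()$fit(df, y, w)
    structure(list(predict = f, info = list(kind = "parametric")),
              class = "prob_fit")
  } else if (learner$kind == "intercept") {
    f <- learner_mean()$fit(df, y, w)
    structure(list(predict = f, info = list(kind = "intercept")),
              class = "prob_fit")
  } else {
    sf <- stack_learners(df, y, w, library = learner$library,
                         folds = learner$folds)
    structure(list(predict = sf$predict,
                   info = list(kind = "stacked", weights = sf$weights,
                               folds = sf$folds, cv_risk = sf$cv_risk)),
              class = "prob_fit")
  }
}
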