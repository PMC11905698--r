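#' Discrete-time hazards from a survival table
#'
#' `lambda_a(t) = (S_a(t-1) - S_a(t)) / S_a(t-1)` with `S_a(0) = 1`.  A
#' negative raw hazard (possible when finite-sample survival estimates are
#' non-monotone in `t`) is clamped to 0 with a warning.
#'
#' @param S_table `data.frame` with columns `a`, `t`, `estimate` holding
#'   `S_a(t)` for every level and `t = 1..K`, or a [tmle_survival_curve()]
#'   result.
#' @return `data.frame` with columns `a`, `t`, `surv_prev`, `surv`,
#'   `hazard`.
#' @export
hazards_from_survival <- function(S_table) {
  if (inherits(S_table, "tmle_curve")) S_table <- S_table$estimates
  S_table <- S_table[order(S_table$a, S_table$t), , drop = FALSE]
  out <- do.call(rbind, lapply(split(S_table, S_table$a), function(d) {
    if (!identical(as.integer(d$t), seq_len(nrow(d))))
      stop("survival table must cover t = 1..K for every level", call. = FALSE)
    s_prev <- c(1, d$estimate[-nrow(d)])
    if (any(s_prev <= 0))
      stop("zero survival in a hazard denominator", call. = FALSE)
    data.frame(a = d$a, t = d$t, surv_prev = s_prev, surv = d$estimate,
               hazard = (s_prev - d$estimate) / s_prev)
  }))
  rownames(out) <- NULL
  if (any(out$hazard < 0 | out$hazard > 1)) {
    warning("non-monotone survival estimates produced hazards outside ",
            "[0, 1]; clamping", call. = FALSE)
    out$hazard <- clamp(out$hazard)
  }
  out
}

#' Design matrix of a working hazard MSM
#'
#' Builds the design rows `X_{a,t}` of a marginal structural model
#' `logit[lambda_a(t)] = X_{a,t}^T gamma` over all combinations of exposure
#' level and interval.  The formula is a right-hand side in `a` and `t`
#' (e.g. the default `~ a + factor(t)`, which expands time into indicators
#' `I(t = 2), ..., I(t = K)`; or `~ a * t` for a linear-time interaction
#' model).
#'
#' @param formula right-hand-side formula in `a` and `t`.
#' @param K number of intervals.
#' @param levels exposure levels.
#' @return An object of class `"msm_design"`: list with the model matrix
#'   `X` (full column rank enforced) and `cells`, a `data.frame` of the
#'   `(a, t)` combination of each row (ordered `t`-major, levels within
#'   `t`).
#' @export
msm_design <- function(formula = ~ a + factor(t), K, levels = c(0, 1)) {
  cells <- expand.grid(a = levels, t = seq_len(K))
  X <- stats::model.matrix(formula, data = cells)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient MSM design", call. = FALSE)
  structure(list(X = X, cells = cells, formula = formula, K = K,
                 levels = levels), class = "msm_design")
}

#' Weighted logistic fit of the hazard MSM
#'
#' Fits `logit[lambda_a(t)] = X_{a,t}^T gamma` by weighted quasi-binomial
#' regression on the `m*K` pseudo-observations (one per exposure level and
#' interval), with weights `S_a(t-1)` (so the pseudo-observations at `t = 1`
#' carry weight 1).  Hazards exactly at 0 or 1 are clamped to
#' `[1e-10, 1 - 1e-10]` to avoid separation.
#'
#' @param hazard hazards aligned with the design rows (`design$cells`).
#' @param design an [msm_design()].
#' @param weights `S_a(t-1)` aligned with the design rows; must be positive.
#' @return List of class `"msm_fit"` with `gamma`, `fitted` (fitted
#'   hazards), `design`, `weights`.
#' @export
fit_msm <- function(hazard, design, weights) {
  stopifnot(inherits(design, "msm_design"))
  if (length(hazard) != nrow(design$X) || length(weights) != nrow(design$X))
    stop("hazards/weights not aligned with the design rows", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  y <- clamp(hazard, 1e-10, 1 - 1e-10)
  fit <- suppressWarnings(
    stats::glm.fit(x = design$X, y = y, weights = weights,
                   family = quasibinomial(), control = glm_ctrl()))
  gamma <- fit$coefficients
  structure(list(gamma = gamma, fitted = as.numeric(fit$fitted.values),
                 design = design, weights = weights),
            class = "msm_fit")
}

#' Delta-method covariance of the MSM coefficients
#'
#' Propagates the efficient-influence-curve uncertainty of the survival
#' estimates through the survival-to-hazard map and the weighted logistic
#' projection.  Writing `p_{a,t} = expit(X_{a,t}^T gamma)`, the bread is the
#' weighted logistic information matrix
#' `M = sum_{a,t} S_a(t-1) p_{a,t} (1 - p_{a,t}) X_{a,t} X_{a,t}^T`
#' and each subject's influence-curve row is
#' `IC_gamma_i = M^{-1} sum_{a,t} [-X_{a,t} + X_{a,t+1} (1 + exp(X_{a,t+1}^T
#' gamma))^{-1}] IC_{a,t,i}`,
#' where `IC_{a,t,i}` is the subject's efficient influence curve for
#' `S_a(t)`.  At `t = K` the `X_{a,t+1}` term does not exist and is dropped,
#' consistent with the telescoping structure of the survival-to-hazard map.
#' The covariance of `gamma` is the sample covariance of the `IC_gamma` rows
#' divided by `n`.
#'
#' @param msm a [fit_msm()] result whose `weights` are the estimated
#'   `S_a(t-1)`.
#' @param IC_matrix `n x (m*K)` matrix of per-subject influence curves for
#'   `S_a(t)`, columns aligned with `msm$design$cells`.
#' @return List with `vcov` (covariance matrix of `gamma`) and `ic` (the
#'   `n x q` per-subject influence-curve matrix for `gamma`).
#' @export
msm_variance <- function(msm, IC_matrix) {
  stopifnot(inherits(msm, "msm_fit"))
  X <- msm$design$X
  cells <- msm$design$cells
  if (ncol(IC_matrix) != nrow(X))
    stop("influence-curve columns not aligned with the design cells",
         call. = FALSE)
  p <- expit(as.numeric(X %*% msm$gamma))
  M <- crossprod(X, X * (msm$weights * p * (1 - p)))
  Minv <- tryCatch(solve(M), error = function(e)
    stop("singular MSM information matrix", call. = FALSE))
  # derivative of the score w.r.t. each S_a(t): -X_{a,t} + X_{a,t+1}(1-p_{a,t+1})
  D <- matrix(0, nrow(X), ncol(X))
  for (r in seq_len(nrow(X))) {
    term <- -X[r, ]
    nxt <- which(cells$a == cells$a[r] & cells$t == cells$t[r] + 1L)
    if (length(nxt) == 1L)
      term <- term + X[nxt, ] * (1 - p[nxt])
    D[r, ] <- term
  }
  ic_gamma <- IC_matrix %*% D %*% Minv
  colnames(ic_gamma) <- colnames(X)
  list(vcov = stats::var(ic_gamma) / nrow(ic_gamma), ic = ic_gamma)
}

#' Marginal structural model for the counterfactual hazards
#'
#' End-to-end wrapper: converts TMLE survival estimates to discrete-time
#' hazards, fits the weighted logistic MSM, and computes influence-curve
#' Wald inference for the coefficients.  `exp(gamma)` for exposure terms is
#' an odds ratio in general; it approximates a hazard ratio only when the
#' hazards are small (below about 0.1).
#'
#' @param curve a [tmle_survival_curve()] result covering `t = 1..K` for
#'   every level.
#' @param formula right-hand-side MSM formula in `a` and `t`.
#' @return An object of class `"tmle_msm"`: list with `gamma`, `vcov`,
#'   `table` (`data.frame`: coefficient, estimate, se, ci_low, ci_high,
#'   exp_estimate), `hazards`, `fit`, `ic`.
#' @export
tmle_msm <- function(curve, formula = ~ a + factor(t)) {
  stopifnot(inherits(curve, "tmle_curve"))
  if (!identical(sort(unique(curve$estimates$t)), seq_len(curve$K)))
    stop("the MSM needs survival estimates at every t = 1..K", call. = FALSE)
  design <- msm_design(formula, K = curve$K, levels = curve$levels)
  haz <- hazards_from_survival(curve)
  key <- function(a, t) paste(a, t)
  idx <- match(key(design$cells$a, design$cells$t), key(haz$a, haz$t))
  msm <- fit_msm(hazard = haz$hazard[idx], design = design,
                 weights = haz$surv_prev[idx])
  ic_idx <- match(key(design$cells$a, design$cells$t),
                  key(curve$estimates$a, curve$estimates$t))
  v <- msm_variance(msm, curve$ic[, ic_idx, drop = FALSE])
  se <- sqrt(diag(v$vcov))
  tab <- data.frame(coefficient = names(msm$gamma) %||% colnames(design$X),
                    estimate = unname(msm$gamma), se = se,
                    ci_low = unname(msm$gamma) - 1.96 * se,
                    ci_high = unname(msm$gamma) + 1.96 * se,
                    exp_estimate = exp(unname(msm$gamma)))
  rownames(tab) <- NULL
  structure(list(gamma = msm$gamma, vcov = v$vcov, table = tab,
                 hazards = haz, fit = msm, ic = v$ic),
            class = "tmle_msm")
}

#' @export
print.tmle_msm <- function(x, ...) {
  cat("Marginal structural model for the discrete-time hazard\n")
  cat("(exp(estimate) is an odds ratio; ~ hazard ratio only for small",
      "hazards)\n")
  print(format(x$table, digits = 4), row.names = FALSE)
  invisible(x)
}
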