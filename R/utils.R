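#' @importFrom stats plogis qlogis glm predict coef binomial quasibinomial
#'   glm.control model.matrix as.formula var uniroot rbinom runif terms
NULL

# Inverse logit / logit, named as in the survival-TMLE literature.
expit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

# Clamp a probability vector into [lo, hi]; NA passes through.
clamp <- function(p, lo = 0, hi = 1) pmin(pmax(p, lo), hi)

# Floor probabilities at gbound (lower truncation only; only denominators of
# inverse-probability weights are truncated, so no symmetric ceiling).
# Returns the floored vector with the number of affected entries as an attribute.
gbound_floor <- function(p, gbound) {
  if (!is.numeric(gbound) || length(gbound) != 1L || gbound <= 0 || gbound >= 0.5)
    stop("'gbound' must be a single number in (0, 0.5)", call. = FALSE)
  n_trunc <- sum(p < gbound, na.rm = TRUE)
  out <- pmax(p, gbound)
  attr(out, "n_truncated") <- n_trunc
  out
}

# Machine-safe clamp applied to initial event-probability predictions before
# taking logits for the fluctuation offset.
QBOUND <- 1e-6

`%||%` <- function(a, b) if (is.null(a)) b else a
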