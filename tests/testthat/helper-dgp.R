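# Shared simulation shortcuts for the test suite.

# benchmark process with essentially no censoring (per-interval censoring
# probability ~2e-9), used for oracle comparisons that assume full follow-up
params_no_censoring <- function(...) {
  dgp_params(delta = c(-20, 0, 0), ...)
}

# stratified nonparametric standardized survival estimate at t = 1 for
# binary L and no censoring: sum_l phat(l) * (1 - mean(Y1 | A = a, L = l))
standardized_t1 <- function(data, a) {
  L <- data$baseline$L
  y1 <- data$event[, 1]
  s <- 0
  for (l in unique(L)) {
    ybar <- mean(y1[data$exposure == a & L == l])
    s <- s + mean(L == l) * (1 - ybar)
  }
  s
}

# closed-form survival table of a dgp as a data.frame matching
# tmle_survival_curve()$estimates columns
true_surv_table <- function(params = dgp_params()) {
  grid <- expand.grid(a = c(0, 1), t = seq_len(params$K))
  data.frame(a = grid$a, t = grid$t,
             estimate = true_survival(grid$a, grid$t, params))
}
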