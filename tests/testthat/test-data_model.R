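test_that("discretization maps terminal status to absorbing indicator rows", {
  spec <- discretization_spec(0:4)

  d <- discretize_followup(1.0, 1, spec)
  expect_equal(d$event[1, ], c(1L, 1L, 1L, 1L))
  expect_equal(d$censor[1, ], c(0L, 0L, 0L, 0L))

  d <- discretize_followup(2.5, 0, spec)
  expect_equal(d$censor[1, ], c(0L, 0L, 1L, 1L))
  expect_equal(d$event[1, ], c(0L, 0L, NA_integer_, NA_integer_))

  # boundary time belongs to the earlier interval (half-open (b_{j-1}, b_j])
  d <- discretize_followup(2.0, 1, spec)
  expect_equal(d$event[1, ], c(0L, 1L, 1L, 1L))

  # event-free at the end of study: complete follow-up by default,
  # administrative censoring at K on request
  d <- discretize_followup(4.0, 0, spec)
  expect_equal(d$event[1, ], c(0L, 0L, 0L, 0L))
  expect_equal(d$censor[1, ], c(0L, 0L, 0L, 0L))
  d <- discretize_followup(4.0, 0, spec, admin_censor_at_end = TRUE)
  expect_equal(d$censor[1, ], c(0L, 0L, 0L, 1L))
  expect_true(is.na(d$event[1, 4]))
})

test_that("discretization rejects inadmissible input", {
  expect_error(discretization_spec(c(0, 2, 1)), "increasing")
  expect_error(discretization_spec(c(1, 2)), "b_0")
  spec <- discretization_spec(0:4)
  expect_error(discretize_followup(-1, 0, spec), "non-negative")
  expect_error(discretize_followup(5, 1, spec), "exceed")
})

test_that("discretized output always satisfies the invariants (property)", {
  set.seed(11)
  for (rep in 1:20) {
    K <- sample(1:6, 1)
    b <- c(0, sort(runif(K, 0.1, 10)))
    n <- 100
    time <- runif(n, 0, b[K + 1])
    status <- rbinom(n, 1, 0.5)
    d <- discretize_followup(time, status, discretization_spec(b),
                             admin_censor_at_end = rep %% 2 == 0)
    expect_identical(nrow(validate_wide_survival(d)), 0L)
    # round trip: every event lands in exactly one subject row
    expect_equal(sum(d$event[, K] == 1L, na.rm = TRUE), sum(status == 1))
  }
})

test_that("validate enumerates each violated rule with its location", {
  ok <- matrix(0L, 1, 4)
  # event reverts 1 -> 0: absorbing-event violation at t = 3
  d <- wide_survival_data(censor = ok, event = rbind(c(0L, 1L, 0L, 1L)),
                          check = FALSE)
  v <- validate_wide_survival(d)
  expect_true(any(v$rule == "absorbing_event" & v$interval == 3))

  # censored at 1 but event observed: missingness violation
  d <- wide_survival_data(censor = rbind(c(1L, 1L, 1L, 1L)),
                          event = rbind(c(0L, NA, NA, NA)), check = FALSE)
  v <- validate_wide_survival(d)
  expect_true(any(v$rule == "event_not_missing_after_censor" & v$interval == 1))

  # censoring reverts 1 -> 0
  d <- wide_survival_data(censor = rbind(c(1L, 0L, 1L, 1L)),
                          event = rbind(c(NA, 0L, NA, NA)), check = FALSE)
  v <- validate_wide_survival(d)
  expect_true(any(v$rule == "absorbing_censor" & v$interval == 2))

  # uncensored but missing event
  d <- wide_survival_data(censor = ok, event = rbind(c(0L, NA, 0L, 0L)),
                          check = FALSE)
  v <- validate_wide_survival(d)
  expect_true(any(v$rule == "event_missing_while_uncensored" & v$interval == 2))

  # the constructor refuses invalid data outright
  expect_error(wide_survival_data(censor = ok,
                                  event = rbind(c(0L, 1L, 0L, 1L))),
               "absorbing_event")
})

test_that("CSV round trip preserves the data", {
  set.seed(3)
  d <- simulate_survival_data(80)
  path <- withr::local_tempfile(fileext = ".csv")
  write_wide_survival(d, path)
  d2 <- read_wide_survival(path, Yvar = paste0("Y", 1:4),
                           Cvar = paste0("C", 1:4), Avar = "A", L0var = "L")
  expect_equal(d2$event, d$event)
  expect_equal(d2$censor, d$censor)
  expect_equal(d2$exposure, d$exposure)
  expect_equal(d2$baseline$L, d$baseline$L)
  expect_error(read_wide_survival(path, Yvar = paste0("Y", 1:4),
                                  Cvar = paste0("C", 1:4), Avar = "Arm"),
               "Arm")
})
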