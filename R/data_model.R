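#' Wide-format discrete-time survival data
#'
#' Container for subject-level survival data discretized into `K` intervals:
#' one row per subject, with baseline covariates `L1`, a point exposure `A`
#' (integer codes `0..m-1`), per-interval censoring indicators `C_1..C_K` and
#' event indicators `Y_1..Y_K`, and optional time-varying covariate blocks
#' `L_2..L_K`.  The assumed temporal ordering within the follow-up is
#' `{L1, A, C1, Y1, L2, C2, Y2, ..., LK, CK, YK}`: in interval `t` the
#' censoring indicator precedes the event indicator, so a subject censored in
#' interval `t` has a missing `Y_t`.
#'
#' The object enforces (via [validate_wide_survival()]) the absorbing-state
#' structure of discrete-time survival data:
#' * absorbing event: once `Y_t = 1`, every later non-missing `Y` is 1;
#' * absorbing censoring: once `C_t = 1`, every later `C` is 1;
#' * missingness: if `C_t = 1` then `Y_t, ..., Y_K` are all missing, and `Y_t`
#'   is non-missing wherever `C_t = 0`.
#'
#' @param censor integer/numeric matrix (`n x K`) with entries 0/1; censoring
#'   at or before interval `t`.  Must not contain missing values (censoring is
#'   absorbing and always observed).
#' @param event integer/numeric matrix (`n x K`) with entries 0/1/`NA`; event
#'   at or before interval `t`, missing after censoring.
#' @param exposure optional integer vector of exposure codes `0..m-1`.  May be
#'   `NULL` for outcome-only data (e.g. the output of
#'   [discretize_followup()]).
#' @param baseline optional `data.frame` of baseline covariates (houses `L1`).
#' @param tv_covariates optional list of length `K` of per-interval
#'   `data.frame` blocks of time-varying covariates (`L_t`); element `t = 1`
#'   is conventionally `NULL` because `L1` lives in `baseline`.
#' @param check if `TRUE` (default), run [validate_wide_survival()] and abort
#'   on any violation.
#'
#' @return An object of class `"wide_survival_data"`: a list with elements
#'   `n`, `K`, `baseline`, `exposure`, `censor`, `event`, `tv_covariates`.
#' @seealso [validate_wide_survival()], [discretize_followup()],
#'   [read_wide_survival()]
#' @export
wide_survival_data <- function(censor, event, exposure = NULL, baseline = NULL,
                               tv_covariates = NULL, check = TRUE) {
  censor <- as.matrix(censor)
  event <- as.matrix(event)
  storage.mode(censor) <- "integer"
  storage.mode(event) <- "integer"
  dimnames(censor) <- NULL
  dimnames(event) <- NULL
  if (!identical(dim(censor), dim(event)))
    stop("'censor' and 'event' must have identical dimensions", call. = FALSE)
  n <- nrow(censor)
  K <- ncol(censor)
  if (K < 1L) stop("need at least one time interval (K >= 1)", call. = FALSE)
  if (!is.null(exposure)) {
    if (length(exposure) != n)
      stop("'exposure' must have one entry per subject", call. = FALSE)
    exposure <- as.integer(exposure)
    if (n > 0 && (anyNA(exposure) || any(exposure < 0L)))
      stop("'exposure' must be non-missing integer codes 0..m-1", call. = FALSE)
  }
  if (is.null(baseline)) {
    baseline <- as.data.frame(matrix(nrow = n, ncol = 0))
  } else {
    baseline <- as.data.frame(baseline)
    if (nrow(baseline) != n)
      stop("'baseline' must have one row per subject", call. = FALSE)
  }
  if (!is.null(tv_covariates)) {
    if (!is.list(tv_covariates) || length(tv_covariates) != K)
      stop("'tv_covariates' must be a list of length K", call. = FALSE)
    tv_covariates <- lapply(tv_covariates, function(b) {
      if (is.null(b)) return(NULL)
      b <- as.data.frame(b)
      if (nrow(b) != n)
        stop("each time-varying covariate block needs one row per subject",
             call. = FALSE)
      b
    })
  }
  x <- structure(
    list(n = n, K = K, baseline = baseline, exposure = exposure,
         censor = censor, event = event, tv_covariates = tv_covariates),
    class = "wide_survival_data")
  if (check) {
    viol <- validate_wide_survival(x)
    if (nrow(viol) > 0L)
      stop("invalid wide survival data; first violation: rule '",
           viol$rule[1L], "' for subject ", viol$subject[1L],
           " at interval ", viol$interval[1L],
           " (", nrow(viol), " violation(s) in total; run",
           " validate_wide_survival() for the full report)", call. = FALSE)
  }
  x
}

#' @export
print.wide_survival_data <- function(x, ...) {
  m <- if (is.null(x$exposure)) "none" else length(unique(x$exposure))
  cat("Wide-format survival data: ", x$n, " subjects, K = ", x$K,
      " intervals\n", sep = "")
  cat("  exposure levels: ", paste(m, collapse = " "),
      "; baseline covariates: ", ncol(x$baseline), "\n", sep = "")
  if (x$n > 0L) {
    cat("  events by interval:   ",
        paste(colSums(x$event == 1L, na.rm = TRUE), collapse = " "), "\n")
    cat("  censored by interval: ",
        paste(colSums(x$censor == 1L, na.rm = TRUE), collapse = " "), "\n")
  }
  invisible(x)
}

#' Check the absorbing-state and missingness invariants
#'
#' Enumerates every violation of the wide-format invariants: absorbing event,
#' absorbing censoring, events missing exactly where the subject is censored,
#' and indicator values restricted to 0/1.
#'
#' @param data a [wide_survival_data] object (or a bare list with `censor` and
#'   `event` matrices).
#' @return A `data.frame` with columns `rule`, `subject`, `interval`; zero
#'   rows when the data are valid.
#' @export
validate_wide_survival <- function(data) {
  cens <- data$censor
  ev <- data$event
  n <- nrow(cens)
  K <- ncol(cens)
  rule <- character(0)
  subj <- integer(0)
  intv <- integer(0)
  add <- function(r, subject, interval) {
    if (length(subject) == 0L) return(invisible())
    rule <<- c(rule, rep(r, length(subject)))
    subj <<- c(subj, subject)
    intv <<- c(intv, interval)
  }
  # linear index of an n x k matrix -> (subject, column)
  ij <- function(idx, k) list(i = ((idx - 1L) %% n) + 1L,
                              j = ((idx - 1L) %/% n) + 1L)
  # domain checks
  bad <- which(is.na(cens) | !(cens %in% c(0L, 1L)))
  p <- ij(bad, K); add("censor_not_binary", p$i, p$j)
  bad <- which(!is.na(ev) & !(ev %in% c(0L, 1L)))
  p <- ij(bad, K); add("event_not_binary", p$i, p$j)
  if (K > 1L) {
    prev_c <- cens[, -K, drop = FALSE]
    next_c <- cens[, -1L, drop = FALSE]
    bad <- which(!is.na(prev_c) & !is.na(next_c) & prev_c == 1L & next_c == 0L)
    p <- ij(bad, K - 1L); add("absorbing_censor", p$i, p$j + 1L)
    prev_y <- ev[, -K, drop = FALSE]
    next_y <- ev[, -1L, drop = FALSE]
    bad <- which(!is.na(prev_y) & !is.na(next_y) & prev_y == 1L & next_y == 0L)
    p <- ij(bad, K - 1L); add("absorbing_event", p$i, p$j + 1L)
  }
  # missingness rule: Y_t missing iff censored at t
  bad <- which(!is.na(cens) & cens == 1L & !is.na(ev))
  p <- ij(bad, K); add("event_not_missing_after_censor", p$i, p$j)
  bad <- which(!is.na(cens) & cens == 0L & is.na(ev))
  p <- ij(bad, K); add("event_missing_while_uncensored", p$i, p$j)
  out <- data.frame(rule = as.character(rule), subject = subj, interval = intv,
                    stringsAsFactors = FALSE)
  out[order(out$subject, out$interval, out$rule), , drop = FALSE]
}

#' Interval boundaries for discretizing continuous follow-up
#'
#' @param boundaries strictly increasing numeric vector `b_0 < b_1 < ... <
#'   b_K`; `b_0` must be 0.  Intervals are half-open `(b_{j-1}, b_j]`, so an
#'   event exactly at a boundary `b_j` belongs to interval `j`.
#' @return An object of class `"discretization_spec"`.
#' @export
discretization_spec <- function(boundaries) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2L)
    stop("need at least two boundaries (b_0 = 0 and b_K)", call. = FALSE)
  if (boundaries[1L] != 0)
    stop("the first boundary b_0 must be 0", call. = FALSE)
  if (any(diff(boundaries) <= 0))
    stop("boundaries must be strictly increasing", call. = FALSE)
  structure(list(boundaries = boundaries, K = length(boundaries) - 1L),
            class = "discretization_spec")
}

#' Discretize continuous follow-up times into interval indicators
#'
#' Converts per-subject follow-up time and terminal status into the wide
#' censoring/event matrices.  A subject whose event falls in interval `j`
#' gets `Y_j = ... = Y_K = 1` and is never censored; a subject whose
#' follow-up ends without the event in interval `j < K` is censored there
#' (`C_j = ... = C_K = 1`, `Y_j ... Y_K` missing).  A subject reaching the
#' final boundary event-free is administratively censored at `K` only if
#' `admin_censor_at_end = TRUE`; by default such subjects are treated as
#' completely followed with `Y = 0` throughout (the estimand at `t <= K` is
#' unaffected by this convention).
#'
#' @param followup_time non-negative follow-up times, at most `b_K`.
#' @param event_indicator 0/1 per subject; 1 if follow-up ended with the
#'   event, 0 if it ended by censoring.
#' @param spec a [discretization_spec()].
#' @param admin_censor_at_end how to code subjects who are event-free at the
#'   final boundary; see Details above.
#' @inheritParams wide_survival_data
#' @return A [wide_survival_data] object.
#' @export
discretize_followup <- function(followup_time, event_indicator, spec,
                                admin_censor_at_end = FALSE,
                                exposure = NULL, baseline = NULL) {
  if (!inherits(spec, "discretization_spec"))
    spec <- discretization_spec(spec)
  time <- as.numeric(followup_time)
  status <- as.integer(event_indicator)
  if (length(status) != length(time))
    stop("'followup_time' and 'event_indicator' must have equal length",
         call. = FALSE)
  if (anyNA(time) || any(time < 0))
    stop("follow-up times must be non-negative and non-missing", call. = FALSE)
  b <- spec$boundaries
  K <- spec$K
  if (any(time > b[K + 1L]))
    stop("follow-up times exceed the last boundary b_K", call. = FALSE)
  if (anyNA(status) || !all(status %in% c(0L, 1L)))
    stop("'event_indicator' must be 0/1", call. = FALSE)
  n <- length(time)
  # interval j such that time in (b_{j-1}, b_j]; time 0 falls in interval 1
  j <- findInterval(time, b, left.open = TRUE)
  j[time == 0] <- 1L
  cens <- matrix(0L, n, K)
  ev <- matrix(0L, n, K)
  at_end <- status == 0L & time >= b[K + 1L]
  for (t in seq_len(K)) {
    ev[status == 1L & j <= t, t] <- 1L
    cens_here <- status == 0L & j <= t & (!at_end | admin_censor_at_end)
    cens[cens_here, t] <- 1L
    ev[cens_here, t] <- NA_integer_
  }
  wide_survival_data(censor = cens, event = ev, exposure = exposure,
                     baseline = baseline)
}

#' Read or write wide-format survival data as CSV
#'
#' Columns are named by the usual wide-format arguments: `Yvar` (event
#' indicators `Y_1..Y_K`), `Cvar` (censoring indicators), `Avar` (exposure),
#' `L0var` (baseline covariates) and `Lvar` (time-varying covariates, a list
#' of character vectors grouped per interval).  Missing cells are encoded as
#' empty strings or the `NA` token.
#'
#' @param path file path of a delimited text file with a header row.
#' @param Yvar,Cvar character vectors of length `K` naming the event and
#'   censoring columns, in time order.
#' @param Avar optional name of the exposure column.
#' @param L0var optional character vector naming baseline covariate columns.
#' @param Lvar optional list of length `K` of character vectors naming the
#'   time-varying covariate columns of each interval (element 1 may be
#'   omitted/`NULL`).
#' @return [read_wide_survival()] returns a [wide_survival_data] object;
#'   [write_wide_survival()] invisibly returns `path`.
#' @export
read_wide_survival <- function(path, Yvar, Cvar, Avar = NULL, L0var = NULL,
                               Lvar = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(Yvar, Cvar, Avar, L0var, unlist(Lvar))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (length(Yvar) != length(Cvar))
    stop("'Yvar' and 'Cvar' must name the same number of intervals",
         call. = FALSE)
  K <- length(Yvar)
  tv <- NULL
  if (!is.null(Lvar)) {
    if (length(Lvar) > K) stop("'Lvar' longer than K", call. = FALSE)
    tv <- vector("list", K)
    for (t in seq_along(Lvar))
      if (!is.null(Lvar[[t]]) && length(Lvar[[t]]) > 0L)
        tv[[t]] <- df[, Lvar[[t]], drop = FALSE]
  }
  wide_survival_data(
    censor = as.matrix(df[, Cvar, drop = FALSE]),
    event = as.matrix(df[, Yvar, drop = FALSE]),
    exposure = if (!is.null(Avar)) df[[Avar]],
    baseline = if (!is.null(L0var)) df[, L0var, drop = FALSE],
    tv_covariates = tv)
}

#' @rdname read_wide_survival
#' @param data a [wide_survival_data] object.
#' @export
write_wide_survival <- function(data, path) {
  df <- as.data.frame(data)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
as.data.frame.wide_survival_data <- function(x, ...) {
  K <- x$K
  out <- x$baseline
  if (!is.null(x$exposure)) out$A <- x$exposure
  for (t in seq_len(K)) {
    if (!is.null(x$tv_covariates) && !is.null(x$tv_covariates[[t]])) {
      blk <- x$tv_covariates[[t]]
      names(blk) <- paste0(names(blk), ".", t)
      out <- cbind(out, blk)
    }
    out[[paste0("C", t)]] <- x$censor[, t]
    out[[paste0("Y", t)]] <- x$event[, t]
  }
  out
}
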