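#' Fit the first-order loss coefficient from post-vaping decay
#'
#' After vaping stops, a well-mixed chamber concentration decays as
#' `C(t) = C0 * exp(-beta * t)`, where `beta` combines deposition and (in the
#' ventilated scenario) air exchange. `fit_decay` estimates `beta` as minus the
#' slope of an ordinary-least-squares regression of `ln C` on `t` within the
#' chosen window. A nonlinear exponential fit is available behind
#' `method = "nls"` for decays where log-linear weighting is a concern.
#'
#' @param x A [conc_series()] (fitted on the total concentration, or per bin
#'   with `on = "bin"`) or a data frame with columns `time_s` and `conc`.
#' @param window Numeric `c(t_begin, t_end)` in seconds; samples with
#'   `t_begin <= t <= t_end` are used. Defaults to the full series.
#' @param on `"total"` fits the summed concentration; `"bin"` returns one fit
#'   per diameter bin (a list of `decay_fit`s).
#' @param method `"loglinear"` (default, closed form) or `"nls"` (nonlinear
#'   least squares on the exponential itself).
#' @return An object of class `decay_fit`: `beta_per_s`, `window`,
#'   `r_squared` (`NA` for a constant trace), `n_points`, and
#'   `negative_flagged` (`TRUE` when the estimated rate is negative, i.e. the
#'   concentration rose over the window).
#' @examples
#' tr <- data.frame(time_s = seq(0, 7200, 60),
#'                  conc = 5000 * exp(-2.2e-4 * seq(0, 7200, 60)))
#' fit_decay(tr)$beta_per_s
#' @export
fit_decay <- function(x, window = NULL, on = c("total", "bin"),
                      method = c("loglinear", "nls")) {
  on <- match.arg(on)
  method <- match.arg(method)
  if (inherits(x, "conc_series")) {
    if (on == "bin") {
      fits <- lapply(seq_len(ncol(x$conc)), function(b) {
        fit_decay(data.frame(time_s = x$times, conc = x$conc[, b]),
                  window = window, method = method)
      })
      names(fits) <- sprintf("bin_%d", seq_along(fits))
      return(fits)
    }
    x <- total_concentration(x)
  }
  if (!is.data.frame(x) || !all(c("time_s", "conc") %in% names(x))) {
    stop("`x` must be a conc_series or a data frame with `time_s` and `conc`",
         call. = FALSE)
  }
  if (is.null(window)) window <- range(x$time_s)
  if (length(window) != 2L || window[2] <= window[1]) {
    stop("`window` must be an increasing c(t_begin, t_end)", call. = FALSE)
  }
  keep <- x$time_s >= window[1] & x$time_s <= window[2]
  t <- x$time_s[keep]
  c_ <- x$conc[keep]
  if (length(t) < 3L) stop("fewer than 3 samples in the decay window", call. = FALSE)
  if (any(c_ <= 0)) {
    stop("non-positive concentrations in the decay window; shrink the window",
         call. = FALSE)
  }

  if (method == "loglinear") {
    fit <- stats::lm(y ~ t, data = data.frame(t = t, y = log(c_)))
    beta <- -unname(stats::coef(fit)["t"])
    r2 <- if (stats::var(log(c_)) == 0) NA_real_ else
      suppressWarnings(summary(fit)$r.squared)
    if (stats::var(log(c_)) == 0) beta <- 0
  } else {
    start <- list(c0 = max(c_), b = max(1e-6, (log(c_[1]) - log(c_[length(c_)])) /
                                          max(t[length(t)] - t[1], 1)))
    fit <- minpack.lm::nlsLM(y ~ c0 * exp(-b * t),
                             data = data.frame(t = t - t[1], y = c_),
                             start = start)
    beta <- unname(stats::coef(fit)["b"])
    ss_res <- sum(stats::resid(fit)^2)
    ss_tot <- sum((c_ - mean(c_))^2)
    r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
    if (ss_tot == 0) beta <- 0
  }

  structure(
    list(beta_per_s = beta, window = c(t[1], t[length(t)]), r_squared = r2,
         n_points = length(t), method = method,
         negative_flagged = beta < 0),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit: beta = %.4g /s over [%g, %g] s (n = %d, R2 = %.4f)%s>\n",
              x$beta_per_s, x$window[1], x$window[2], x$n_points,
              if (is.na(x$r_squared)) NA else x$r_squared,
              if (x$negative_flagged) " [NEGATIVE RATE FLAGGED]" else ""))
  invisible(x)
}

#' Choose the decay window after the last puff
#'
#' Returns `[last_puff_time + lag_s, end_of_series]`, truncated just before
#' the first saturated sample inside that range, so the decay fit only sees
#' quantitative post-vaping data. The lag allows the chamber to mix after the
#' final puff.
#'
#' @param series A [conc_series()].
#' @param schedule A [puff_schedule()] with at least one puff.
#' @param lag_s Mixing lag in seconds after the final puff.
#' @return Numeric `c(t_begin, t_end)`.
#' @export
pick_decay_window <- function(series, schedule, lag_s = 120) {
  stopifnot(inherits(series, "conc_series"), inherits(schedule, "puff_schedule"))
  if (!length(schedule$puff_times_s)) {
    stop("schedule has no puffs; there is no post-vaping decay", call. = FALSE)
  }
  t_begin <- max(schedule$puff_times_s) + lag_s
  t_end <- max(series$times)
  in_win <- series$times >= t_begin
  if (!any(in_win)) stop("series ends before the decay window starts", call. = FALSE)
  sat_rows <- rowSums(series$saturated_flags) > 0
  sat_in <- which(in_win & sat_rows)
  if (length(sat_in)) {
    first_sat <- min(sat_in)
    if (first_sat == which(in_win)[1]) {
      stop("decay window starts saturated; no usable post-vaping data", call. = FALSE)
    }
    t_end <- series$times[first_sat - 1L]
  }
  if (sum(series$times >= t_begin & series$times <= t_end) < 3L) {
    stop("fewer than 3 usable samples after the last puff", call. = FALSE)
  }
  c(t_begin, t_end)
}
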