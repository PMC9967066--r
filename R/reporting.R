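#' Summarize replicate experiments
#'
#' One replicate is one vaping experiment (one emission result); replicates
#' are reported as mean plus/minus standard error, `SE = sd / sqrt(n)`. For a
#' single replicate the SE is undefined and flagged `NA`.
#'
#' @param values Numeric vector of replicate values, length >= 1.
#' @param label Optional group label.
#' @return An object of class `group_summary` with `label`, `n_replicates`,
#'   `mean`, `standard_error`, and the raw `values`.
#' @export
summarize_group <- function(values, label = NA_character_) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("`values` must not be empty", call. = FALSE)
  if (any(!is.finite(values))) stop("`values` must be finite", call. = FALSE)
  n <- length(values)
  se <- if (n >= 2L) stats::sd(values) / sqrt(n) else NA_real_
  structure(
    list(label = label, n_replicates = n, mean = mean(values),
         standard_error = se, values = values),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary '%s': %.4g +/- %.4g (n = %d)>\n",
              x$label, x$mean, x$standard_error, x$n_replicates))
  invisible(x)
}

#' Two-group comparison by t-test
#'
#' Two-sided unpaired t-test between replicate groups at `alpha = 0.05`.
#' Welch's unequal-variance form is the default (device types are unlikely to
#' share a variance); Student's pooled form is available by flag. Groups with
#' zero variance in both arms are degenerate for the t statistic and are
#' flagged rather than silently reported.
#'
#' @param a,b [summarize_group()] results (their raw `values` are used), or
#'   numeric vectors.
#' @param variant `"welch"` or `"student"`.
#' @param alpha Significance level.
#' @return An object of class `comparison_result` with `t_statistic`,
#'   `p_value`, `alpha`, `significant` (`p < alpha`), and `degenerate`.
#' @export
compare_groups <- function(a, b, variant = c("welch", "student"),
                           alpha = 0.05) {
  variant <- match.arg(variant)
  va <- if (inherits(a, "group_summary")) a$values else as.numeric(a)
  vb <- if (inherits(b, "group_summary")) b$values else as.numeric(b)
  if (length(va) < 2L || length(vb) < 2L) {
    stop("both groups need at least 2 replicates", call. = FALSE)
  }
  la <- if (inherits(a, "group_summary")) a$label else "a"
  lb <- if (inherits(b, "group_summary")) b$label else "b"
  degenerate <- stats::sd(va) == 0 && stats::sd(vb) == 0
  if (degenerate) {
    same <- isTRUE(all.equal(mean(va), mean(vb)))
    tt <- list(statistic = if (same) 0 else Inf * sign(mean(va) - mean(vb)),
               p.value = if (same) 1 else 0)
  } else {
    tt <- stats::t.test(va, vb, var.equal = (variant == "student"))
  }
  structure(
    list(group_a = la, group_b = lb,
         t_statistic = unname(tt$statistic), p_value = tt$p.value,
         alpha = alpha, significant = tt$p.value < alpha,
         variant = variant, degenerate = degenerate),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison '%s' vs '%s' (%s): t = %.4g, p = %.4g%s%s>\n",
              x$group_a, x$group_b, x$variant, x$t_statistic, x$p_value,
              if (x$significant) " *" else "",
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}
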