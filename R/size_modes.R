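#' Normalized number size distributions
#'
#' Converts per-bin particle counts (or concentrations) to the standard
#' log-normalized form `dN/dlogDp`, dividing each bin by its decadal width
#' `log10(hi/lo)` so that distributions from instruments with different bin
#' resolutions are directly comparable.
#'
#' @param counts Per-bin counts or concentrations, >= 0, one per grid bin; or
#'   a [conc_series()], in which case the time-averaged per-bin concentration
#'   is used (the averaged distribution over the run).
#' @param grid The matching [size_grid()]; taken from the series when `counts`
#'   is a [conc_series()].
#' @return An object of class `size_distribution`: a data frame with columns
#'   `d_mid_nm` and `dN_dlogDp`, with the grid and total as attributes.
#' @export
normalize_distribution <- function(counts, grid = NULL) {
  if (inherits(counts, "conc_series")) {
    grid <- counts$grid
    counts <- colMeans(counts$conc)
  }
  stopifnot(inherits(grid, "size_grid"))
  counts <- as.numeric(counts)
  if (length(counts) != length(grid$bin_mids)) {
    stop("`counts` length must match the grid bin count", call. = FALSE)
  }
  if (any(counts < 0)) stop("`counts` must be non-negative", call. = FALSE)
  w <- dlog10(grid)
  if (any(w <= 0)) stop("zero-width bins in the grid", call. = FALSE)
  out <- data.frame(d_mid_nm = grid$bin_mids, dN_dlogDp = counts / w)
  structure(out, grid = grid, total_n = sum(counts),
            class = c("size_distribution", "data.frame"))
}

#' @rdname normalize_distribution
#' @param dist A `size_distribution`.
#' @return `denormalize_distribution` returns the per-bin counts, inverting
#'   the normalization exactly.
#' @export
denormalize_distribution <- function(dist) {
  stopifnot(inherits(dist, "size_distribution"))
  dist$dN_dlogDp * dlog10(attr(dist, "grid"))
}

#' Geometric mean diameter and geometric standard deviation
#'
#' Moment estimates on log-diameter using the bin midpoints: with weights
#' `w_i = N_i / sum(N)`, `GMD = exp(sum(w * ln d))` and `GSD = exp(sd_w(ln d))`
#' (the weighted standard deviation of `ln d`). A monodisperse distribution
#' has GSD 1.
#'
#' @param dist A [normalize_distribution()] result.
#' @return Named list with `gmd_nm` and `gsd`.
#' @export
gmd_gsd <- function(dist) {
  stopifnot(inherits(dist, "size_distribution"))
  n <- denormalize_distribution(dist)
  if (sum(n) <= 0) stop("empty distribution", call. = FALSE)
  w <- n / sum(n)
  ld <- log(dist$d_mid_nm)
  mu <- sum(w * ld)
  sg <- sqrt(sum(w * (ld - mu)^2))
  list(gmd_nm = exp(mu), gsd = exp(sg))
}

#' Per-scan GMD trajectory
#'
#' GMD of each instrument scan (each row of the series), exposing the drift of
#' the mean size over a run — e.g. the growth from coagulation/condensation as
#' puffs accumulate. This is distinct from the GMD of the time-averaged
#' distribution returned by [gmd_gsd()] on [normalize_distribution()] of the
#' series; both conventions are provided.
#'
#' @param series A [conc_series()].
#' @return Data frame with `time_s` and `gmd_nm` (`NA` for empty scans).
#' @export
gmd_trajectory <- function(series) {
  stopifnot(inherits(series, "conc_series"))
  ld <- log(series$grid$bin_mids)
  tot <- rowSums(series$conc)
  gmd <- ifelse(tot > 0, exp(as.vector(series$conc %*% ld) / tot), NA_real_)
  data.frame(time_s = series$times, gmd_nm = gmd)
}

# dN/dlogDp of a lognormal mode at diameters d (nm)
mode_density <- function(d, n_total, gmd_nm, gsd) {
  s <- log10(gsd)
  n_total / (sqrt(2 * pi) * s) * exp(-(log10(d) - log10(gmd_nm))^2 / (2 * s^2))
}

#' Fit a lognormal mixture to a number size distribution
#'
#' Least-squares fit of a 1- or 2-mode lognormal mixture to `dN/dlogDp`,
#' the standard deconvolution used to report mode locations (e.g. a single
#' ~100 nm mode for pod-type emissions versus Aitken + accumulation modes for
#' mod-type emissions). Each mode contributes
#' `N / (sqrt(2*pi) * log10(gsd)) * exp(-(log10 d - log10 gmd)^2 / (2 log10(gsd)^2))`.
#' Fitting is Levenberg--Marquardt in linear concentration space by default
#' (`objective = "log"` fits `log(dN/dlogDp + eps)` instead, useful when the
#' coarse tail spans decades). `n_modes = "auto"` fits both and selects by
#' BIC under a multinomial likelihood: the per-bin integrated counts are
#' treated as a size-`N` multinomial sample of the fitted bin fractions, so
#' `BIC = -2 * sum(n_i log p_i) + 3k * log(N)` — the natural model for
#' counting statistics, and far more selective than an equal-variance
#' Gaussian criterion on spectra whose noise scales with the bin count.
#' Unimodal starts come from the moment estimates; bimodal starts split
#' the distribution at the deepest internal minimum of its smoothed form,
#' falling back to quantile-based seeds — both deterministic.
#'
#' @param dist A [normalize_distribution()] result with at least
#'   `6 * n_modes` informative (positive) bins.
#' @param n_modes `1`, `2`, or `"auto"`.
#' @param objective `"linear"` or `"log"`.
#' @return List of [lognormal_mode()]s sorted by GMD, with attributes
#'   `converged`, `bic`, `r_squared`, and `n_modes_selected`.
#' @export
fit_modes <- function(dist, n_modes = c("auto", "1", "2"),
                      objective = c("linear", "log")) {
  stopifnot(inherits(dist, "size_distribution"))
  objective <- match.arg(objective)
  n_modes <- as.character(n_modes)
  n_modes <- match.arg(n_modes)
  y <- dist$dN_dlogDp
  if (all(y <= 0)) stop("all-zero distribution; nothing to fit", call. = FALSE)

  if (n_modes == "auto") {
    f1 <- try(fit_modes(dist, 1, objective), silent = TRUE)
    f2 <- try(fit_modes(dist, 2, objective), silent = TRUE)
    ok1 <- !inherits(f1, "try-error")
    ok2 <- !inherits(f2, "try-error")
    if (!ok1 && !ok2) stop("neither a 1- nor a 2-mode fit converged", call. = FALSE)
    if (!ok2) return(f1)
    if (!ok1) return(f2)
    return(if (attr(f1, "bic") <= attr(f2, "bic")) f1 else f2)
  }
  k <- as.integer(n_modes)
  if (sum(y > 0) < 6L * k) {
    stop(sprintf("need at least %d informative bins for a %d-mode fit", 6L * k, k),
         call. = FALSE)
  }
  start <- mode_start(dist, k)
  d <- dist$d_mid_nm
  eps <- max(y) * 1e-6
  yy <- if (objective == "log") log(y + eps) else y

  model_fun <- function(par) {
    # par: per mode (log N, log10 gmd, log10(gsd - 1) unconstrained via exp)
    pred <- 0
    for (j in seq_len(k)) {
      p <- par[(3 * j - 2):(3 * j)]
      pred <- pred + mode_density(d, exp(p[1]), 10^p[2], 1 + exp(p[3]))
    }
    pred
  }
  resid_fun <- function(par) {
    pred <- model_fun(par)
    if (objective == "log") log(pred + eps) - yy else pred - yy
  }
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  conv <- fit$info %in% 1:4
  if (!conv) {
    stop(sprintf("mode fit did not converge (nls.lm info %d: %s)",
                 fit$info, fit$message), call. = FALSE)
  }
  par <- fit$par
  modes <- lapply(seq_len(k), function(j) {
    p <- par[(3 * j - 2):(3 * j)]
    lognormal_mode(exp(p[1]), 10^p[2], 1 + exp(p[3]))
  })
  modes <- modes[order(vapply(modes, `[[`, numeric(1), "gmd_nm"))]
  rss <- sum((model_fun(par) - y)^2)
  n <- length(y)
  ss_tot <- sum((y - mean(y))^2)
  # multinomial BIC regardless of objective, so model selection compares
  # like with like; counts are the denormalized per-bin integrals
  counts <- denormalize_distribution(dist)
  pred_counts <- pmax(model_fun(par) * dlog10(attr(dist, "grid")), 1e-300)
  p <- pred_counts / sum(pred_counts)
  n_tot <- sum(counts)
  loglik <- sum(counts * log(p))
  bic <- -2 * loglik + (3 * k) * log(n_tot)
  structure(modes, converged = conv, bic = bic,
            r_squared = if (ss_tot > 0) 1 - rss / ss_tot else NA_real_,
            n_modes_selected = k, class = "mode_fit")
}

#' @export
print.mode_fit <- function(x, ...) {
  cat(sprintf("<mode_fit: %d mode(s), R2 = %.4f, BIC = %.1f>\n",
              attr(x, "n_modes_selected"), attr(x, "r_squared"), attr(x, "bic")))
  for (m in x) {
    cat(sprintf("  N = %.4g, GMD = %.4g nm, GSD = %.3f\n",
                m$n_total, m$gmd_nm, m$gsd))
  }
  invisible(x)
}

# deterministic starting values: moments for k = 1; split at the deepest
# internal minimum of the 3-point smoothed distribution for k = 2, with a
# quantile fall-back when no internal minimum exists
mode_start <- function(dist, k) {
  par_of <- function(n, gmd, gsd) c(log(max(n, 1e-12)), log10(gmd),
                                    log(max(gsd, 1.05) - 1))
  counts <- denormalize_distribution(dist)
  if (k == 1L) {
    g <- gmd_gsd(dist)
    return(par_of(sum(counts), g$gmd_nm, max(g$gsd, 1.2)))
  }
  y <- dist$dN_dlogDp
  ys <- stats::filter(y, rep(1 / 3, 3), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  ys <- as.numeric(ys)
  n <- length(ys)
  split <- NA_integer_
  if (n >= 5L) {
    interior <- 2:(n - 1L)
    is_min <- ys[interior] <= ys[interior - 1L] & ys[interior] <= ys[interior + 1L] &
      (ys[interior] < ys[interior - 1L] | ys[interior] < ys[interior + 1L])
    cand <- interior[is_min]
    # require substantial aerosol on both sides, so noise dips in the sparse
    # tails cannot masquerade as the inter-mode valley
    cand <- cand[vapply(cand, function(i) {
      min(sum(counts[1:i]), sum(counts[(i + 1L):n])) >= 0.05 * sum(counts)
    }, logical(1))]
    if (length(cand)) split <- cand[which.min(ys[cand])]
  }
  if (is.na(split)) {
    # quantile fall-back: split at the median of the count distribution
    cum <- cumsum(counts) / sum(counts)
    split <- max(2L, min(n - 2L, which(cum >= 0.5)[1]))
  }
  sub_dist <- function(idx) {
    g <- attr(dist, "grid")
    sg <- size_grid(g$bin_edges[min(idx):(max(idx) + 1L)], g$instrument_label)
    normalize_distribution(counts[idx], sg)
  }
  gl <- gmd_gsd(sub_dist(1:split))
  gr <- gmd_gsd(sub_dist((split + 1L):n))
  c(par_of(sum(counts[1:split]), gl$gmd_nm, max(gl$gsd, 1.2)),
    par_of(sum(counts[(split + 1L):n]), gr$gmd_nm, max(gr$gsd, 1.2)))
}

#' Evaluate a fitted mixture on a diameter axis
#'
#' @param modes A [fit_modes()] result or list of [lognormal_mode()]s.
#' @param d_nm Diameters in nm.
#' @return `dN/dlogDp` of the mixture at `d_nm`.
#' @export
mixture_density <- function(modes, d_nm) {
  Reduce(`+`, lapply(modes, function(m) {
    mode_density(d_nm, m$n_total, m$gmd_nm, m$gsd)
  }))
}
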