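#' Read and write concentration series as CSV
#'
#' The series is stored with one row per timestamp and a header
#' `time_s,bin_<lo>nm_<hi>nm,...`; the size grid round-trips exactly from the
#' column names. Saturation flags go to a sidecar CSV of the same shape with
#' 0/1 entries.
#'
#' @param series A [conc_series()].
#' @param path Output CSV path.
#' @param flags_path Optional sidecar path for the saturation flags; defaults
#'   to `<path minus .csv>_flags.csv` when any sample is flagged.
#' @return `write_conc_csv` returns `path` invisibly; `read_conc_csv` returns
#'   a [conc_series()].
#' @export
write_conc_csv <- function(series, path, flags_path = NULL) {
  stopifnot(inherits(series, "conc_series"))
  g <- series$grid
  lo <- g$bin_edges[-length(g$bin_edges)]
  hi <- g$bin_edges[-1L]
  cols <- sprintf("bin_%snm_%snm", format_edge(lo), format_edge(hi))
  df <- data.frame(time_s = series$times, series$conc, check.names = FALSE)
  names(df) <- c("time_s", cols)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (is.null(flags_path) && any(series$saturated_flags)) {
    flags_path <- sub("\\.csv$", "_flags.csv", path)
  }
  if (!is.null(flags_path)) {
    fdf <- data.frame(time_s = series$times, series$saturated_flags * 1L,
                      check.names = FALSE)
    names(fdf) <- c("time_s", cols)
    utils::write.csv(fdf, flags_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# edges are printed with 15 significant digits so the grid round-trips to
# double precision
format_edge <- function(x) {
  formatC(x, format = "g", digits = 15, width = 1)
}

#' @rdname write_conc_csv
#' @param instrument_label Grid label for the reconstructed series.
#' @export
read_conc_csv <- function(path, flags_path = NULL,
                          instrument_label = c("composite", "smps", "ops")) {
  instrument_label <- match.arg(instrument_label)
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_s") stop("first column must be `time_s`", call. = FALSE)
  cols <- names(df)[-1L]
  m <- regmatches(cols, regexec("^bin_([0-9.eE+-]+)nm_([0-9.eE+-]+)nm$", cols))
  if (any(vapply(m, length, integer(1)) != 3L)) {
    stop("malformed bin column names; expected bin_<lo>nm_<hi>nm", call. = FALSE)
  }
  lo <- vapply(m, function(x) as.numeric(x[2]), numeric(1))
  hi <- vapply(m, function(x) as.numeric(x[3]), numeric(1))
  if (any(abs(lo[-1L] - hi[-length(hi)]) > 1e-9 * hi[-length(hi)])) {
    stop("bin columns are not contiguous", call. = FALSE)
  }
  grid <- size_grid(c(lo, hi[length(hi)]), instrument_label)
  sat <- NULL
  if (is.null(flags_path)) {
    cand <- sub("\\.csv$", "_flags.csv", path)
    if (file.exists(cand)) flags_path <- cand
  }
  if (!is.null(flags_path) && file.exists(flags_path)) {
    fdf <- utils::read.csv(flags_path, check.names = FALSE)
    sat <- as.matrix(fdf[, -1L, drop = FALSE]) > 0
  }
  conc_series(df$time_s, grid, as.matrix(df[, -1L, drop = FALSE]), sat)
}

#' Serialize fit and emission results
#'
#' Flat CSV writers/readers for [fit_decay()] results, [emission_factor()]
#' results, fitted modes, and normalized distributions. All writers round-trip
#' through their readers losslessly to double precision.
#'
#' @param x The object to write.
#' @param path CSV path.
#' @return The reader returns the reconstructed object; writers return `path`
#'   invisibly.
#' @name result_io
NULL

#' @rdname result_io
#' @export
write_decay_csv <- function(x, path) {
  stopifnot(inherits(x, "decay_fit"))
  df <- data.frame(beta_per_s = x$beta_per_s, window_begin_s = x$window[1],
                   window_end_s = x$window[2], r_squared = x$r_squared,
                   n_points = x$n_points)
  write_precise_csv(df, path)
}

#' @rdname result_io
#' @export
read_decay_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(
    list(beta_per_s = df$beta_per_s,
         window = c(df$window_begin_s, df$window_end_s),
         r_squared = df$r_squared, n_points = df$n_points,
         method = "loglinear", negative_flagged = df$beta_per_s < 0),
    class = "decay_fit"
  )
}

#' @rdname result_io
#' @param scenario,device Labels recorded in the emission CSV.
#' @export
write_emission_csv <- function(x, path, scenario = x$scenario_label,
                               device = NA_character_) {
  stopifnot(inherits(x, "emission_result"))
  df <- data.frame(
    scenario = scenario, device = device,
    metric = c("number", "mass"),
    tp = c(x$tp_number, x$tp_mass_ug),
    ef_per_puff = c(x$ef_number_per_puff, x$ef_mass_ug_per_puff),
    puff_number = x$puff_number, dilution_factor = x$dilution_factor,
    beta_per_s = x$beta_used_per_s
  )
  write_precise_csv(df, path)
}

#' @rdname result_io
#' @export
read_emission_csv <- function(path) {
  df <- utils::read.csv(path)
  num <- df[df$metric == "number", ]
  mas <- df[df$metric == "mass", ]
  emission_factor(num$tp, num$puff_number, num$dilution_factor,
                  tp_mass_ug = if (nrow(mas)) mas$tp else NA_real_,
                  beta_per_s = num$beta_per_s,
                  scenario_label = as.character(num$scenario))
}

#' @rdname result_io
#' @export
write_modes_csv <- function(x, path) {
  df <- data.frame(
    mode = seq_along(x),
    n_total = vapply(x, `[[`, numeric(1), "n_total"),
    gmd_nm = vapply(x, `[[`, numeric(1), "gmd_nm"),
    gsd = vapply(x, `[[`, numeric(1), "gsd"),
    converged = isTRUE(attr(x, "converged"))
  )
  write_precise_csv(df, path)
}

#' @rdname result_io
#' @export
read_modes_csv <- function(path) {
  df <- utils::read.csv(path)
  modes <- lapply(seq_len(nrow(df)), function(i) {
    lognormal_mode(df$n_total[i], df$gmd_nm[i], df$gsd[i])
  })
  structure(modes, converged = all(df$converged), class = "mode_fit",
            n_modes_selected = nrow(df))
}

#' @rdname result_io
#' @param dist A [normalize_distribution()] result.
#' @export
write_distribution_csv <- function(dist, path) {
  stopifnot(inherits(dist, "size_distribution"))
  g <- attr(dist, "grid")
  df <- data.frame(d_lo_nm = g$bin_edges[-length(g$bin_edges)],
                   d_mid_nm = dist$d_mid_nm,
                   d_hi_nm = g$bin_edges[-1L],
                   dN_dlogDp = dist$dN_dlogDp)
  write_precise_csv(df, path)
}

#' @rdname result_io
#' @export
read_distribution_csv <- function(path) {
  df <- utils::read.csv(path)
  grid <- size_grid(c(df$d_lo_nm, df$d_hi_nm[nrow(df)]))
  normalize_distribution(df$dN_dlogDp * dlog10(grid), grid)
}

#' @rdname result_io
#' @param schedule A [puff_schedule()].
#' @param power Optional numeric vector of per-puff power (W).
#' @export
write_schedule_csv <- function(schedule, path, power = NA_real_) {
  stopifnot(inherits(schedule, "puff_schedule"))
  df <- data.frame(puff_index = seq_along(schedule$puff_times_s),
                   puff_time_s = schedule$puff_times_s,
                   power_W = rep_len(power, length(schedule$puff_times_s)))
  write_precise_csv(df, path)
}

#' @rdname result_io
#' @param profile Puff profile to attach to the read schedule.
#' @export
read_schedule_csv <- function(path, profile = puff_profile()) {
  df <- utils::read.csv(path)
  sched <- puff_schedule(df$puff_time_s, profile)
  if ("power_W" %in% names(df) && !all(is.na(df$power_W))) {
    attr(sched, "power_W") <- df$power_W
  }
  sched
}

# write.csv with full double precision (signif 17), so numeric round-trips
write_precise_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], formatC, format = "g", digits = 17)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
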