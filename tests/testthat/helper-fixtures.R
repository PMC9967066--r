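# shared fixture builders; everything is generated in code at test time

static_chamber <- function() chamber_scenario(6, 0, "static")
dynamic_chamber <- function() {
  chamber_scenario(6, 3, "dynamic",
                   dilution_flow_eags_lpm = 2, dilution_flow_chamber_lpm = 2)
}

# noiseless static run: n puffs at a regular interval into the default grid
sim_static <- function(n_puffs = 20, interval_s = 300, source = pod_source(),
                       beta_dep = 1.34e-4, dt_s = 10, ...) {
  schedule <- regular_schedule(n_puffs, interval_s)
  list(schedule = schedule,
       series = simulate_chamber(static_chamber(), schedule, source,
                                 beta_dep = beta_dep, dt_s = dt_s, ...))
}

# discretized lognormal mixture: per-bin counts of `modes` on `grid`
lognormal_counts <- function(modes, grid, n_total = 1) {
  le <- log(grid$bin_edges)
  frac <- numeric(length(grid$bin_mids))
  for (m in modes) {
    p <- pnorm(le, log(m$gmd_nm), log(m$gsd))
    frac <- frac + m$n_total * diff(p)
  }
  n_total * frac
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
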