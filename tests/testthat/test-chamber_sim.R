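test_that("empty schedule and zero initial concentration give an identically zero series", {
  sim <- simulate_chamber(static_chamber(), empty_schedule(), pod_source(),
                          beta_dep = 0, dt_s = 60, horizon_s = 600)
  expect_true(all(sim$conc == 0))
})

test_that("a single puff with no losses steps to N/V_c and is conserved forever", {
  src <- pod_source(number_per_puff = 6e9)
  sch <- puff_schedule(60)
  sim <- simulate_chamber(static_chamber(), sch, src, beta_dep = 0,
                          dt_s = 30, horizon_s = 600)
  vc_cm3 <- 6e6
  tot <- rowSums(sim$conc)
  expect_equal(tot[sim$times < 60], rep(0, sum(sim$times < 60)))
  injected <- sum(attr(sim, "injected_per_puff"))
  expect_equal(tot[sim$times >= 60], rep(injected / vc_cm3, sum(sim$times >= 60)),
               tolerance = 1e-12)
})

test_that("decay between puffs matches the analytic exponential solution", {
  # one puff, ach = 3/h, no deposition: C(t) = C(0+) exp(-t/1200)
  sch <- puff_schedule(0)
  sim <- simulate_chamber(dynamic_chamber(), sch, pod_source(), beta_dep = 0,
                          dt_s = 60, horizon_s = 2400)
  tot <- rowSums(sim$conc)
  c0 <- tot[1]
  expect_gt(c0, 0)
  expect_equal(tot, c0 * exp(-sim$times / 1200), tolerance = 1e-9)
  expect_equal(tot[sim$times == 1200], c0 / exp(1), tolerance = 1e-9)

  # combined rate: per-sample match at 1e-9 relative for lambda + beta_dep
  sim2 <- simulate_chamber(dynamic_chamber(), sch, pod_source(),
                           beta_dep = 2.2e-4, dt_s = 60, horizon_s = 2400)
  tot2 <- rowSums(sim2$conc)
  r <- 3 / 3600 + 2.2e-4
  expect_lt(max(abs(tot2 / (tot2[1] * exp(-r * sim2$times)) - 1)), 1e-9)
})

test_that("simulation agrees with an independent ODE integration", {
  # oracle integrates the same mass balance with lsoda from the post-impulse
  # state to the horizon
  sch <- puff_schedule(0)
  r <- 3 / 3600 + 1.5e-4
  sim <- simulate_chamber(
    chamber_scenario(6, 3, "dynamic"), sch, pod_source(1e10),
    beta_dep = 1.5e-4, dt_s = 120, horizon_s = 3600)
  tot <- rowSums(sim$conc)
  ode <- deSolve::lsoda(
    y = c(C = tot[1]), times = sim$times,
    func = function(t, y, p) list(-p$r * y), parms = list(r = r),
    rtol = 1e-10, atol = 1e-12)
  expect_equal(tot, unname(ode[, "C"]), tolerance = 1e-7)
})

test_that("number is conserved with zero losses across many puffs", {
  sch <- regular_schedule(20, 300)
  sim <- simulate_chamber(static_chamber(), sch, pod_source(), beta_dep = 0,
                          dt_s = 10)
  vc_cm3 <- 6e6
  per_puff <- sum(attr(sim, "injected_per_puff"))
  for (tq in c(70, 1500, 5900, max(sim$times))) {
    n_in <- per_puff * sum(sch$puff_times_s <= tq)
    airborne <- vc_cm3 * sum(sim$conc[which.min(abs(sim$times - tq)), ])
    expect_lt(abs(airborne / n_in - 1), 1e-9)
  }
})

test_that("identical seeds give bit-identical noisy output, different seeds differ", {
  args <- list(static_chamber(), regular_schedule(5, 300), pod_source(),
               beta_dep = 1e-4, dt_s = 30, noise = noise_spec(gsd = 1.05))
  a <- do.call(simulate_chamber, c(args, seed = 7))
  b <- do.call(simulate_chamber, c(args, seed = 7))
  c_ <- do.call(simulate_chamber, c(args, seed = 8))
  expect_identical(a$conc, b$conc)
  expect_false(identical(a$conc, c_$conc))
})

test_that("noiseless static staircase rises at every puff", {
  run <- sim_static(10, 300)
  tot <- rowSums(run$series$conc)
  after <- vapply(run$schedule$puff_times_s,
                  function(t0) tot[which(run$series$times >= t0)[1]], numeric(1))
  expect_true(all(diff(after) > 0))
})

test_that("invalid simulation inputs are rejected with messages", {
  expect_error(simulate_chamber(static_chamber(), regular_schedule(2, 300),
                                pod_source(), beta_dep = -1e-4),
               "beta_dep")
  expect_error(simulate_chamber(static_chamber(), regular_schedule(2, 300),
                                pod_source(), dt_s = 0),
               "dt_s")
  expect_error(simulate_chamber(static_chamber(), puff_schedule(5000),
                                pod_source(), horizon_s = 600),
               "horizon")
  expect_error(chamber_scenario(6, 3, "static"), "static")
  expect_error(chamber_scenario(6, 0, "dynamic"), "dynamic")
})

test_that("instrument ceiling clips and flags exactly the saturated samples", {
  g <- size_grid(c(100, 200))
  s <- conc_series(c(0, 10, 20), g, matrix(c(1000, 5000, 2999), ncol = 1))
  out <- apply_instrument(s, 3000)
  expect_equal(out$conc[, 1], c(1000, 3000, 2999))
  expect_equal(out$saturated_flags[, 1], c(FALSE, TRUE, FALSE))
  # infinite ceiling is the identity
  out2 <- apply_instrument(s, Inf)
  expect_identical(out2$conc, s$conc)
  expect_false(any(out2$saturated_flags))
  # untouched values unchanged
  expect_equal(out$conc[c(1, 3), 1], s$conc[c(1, 3), 1])
})

test_that("stitching abutting SMPS and OPS series conserves bins and totals", {
  times <- seq(0, 300, 60)
  gs <- smps_grid(8)
  go <- ops_grid(4)
  cs <- conc_series(times, gs, matrix(runif(length(times) * 8), ncol = 8))
  co <- conc_series(times, go, matrix(runif(length(times) * 4), ncol = 4))
  st <- stitch_grids(cs, co)
  expect_equal(ncol(st$conc), 12)
  expect_equal(st$grid$instrument_label, "composite")
  expect_equal(rowSums(st$conc), rowSums(cs$conc) + rowSums(co$conc))
  # misaligned timestamps rejected
  co2 <- conc_series(times + 1, go, co$conc)
  expect_error(stitch_grids(cs, co2), "misaligned")
  # gapped grids rejected
  gg <- size_grid(c(400, 600, 900, 2000, 10000), "ops")
  cg <- conc_series(times, gg, matrix(1, length(times), 4))
  expect_error(stitch_grids(cs, cg), "abut")
})

test_that("size grids validate edges and use geometric midpoints", {
  g <- size_grid(c(10, 40, 160))
  expect_equal(g$bin_mids, c(20, 80))
  expect_equal(range(smps_grid()$bin_edges), c(7, 300))
  expect_equal(range(ops_grid()$bin_edges), c(300, 10000))
  expect_error(size_grid(c(10, 10, 20)), "increasing")
  expect_error(size_grid(c(-1, 10)), "positive")
})
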