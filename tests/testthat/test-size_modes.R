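test_that("dN/dlogDp normalization divides by the decadal bin width and round-trips", {
  # one bin of width 0.1 decades holding 10 particles: dN/dlogDp = 100
  g <- size_grid(c(100, 100 * 10^0.1))
  d <- normalize_distribution(10, g)
  expect_equal(d$dN_dlogDp, 100)
  expect_equal(denormalize_distribution(d), 10)

  # uniform dN/dlogDp over one decade: per-bin N proportional to log width
  g2 <- size_grid(c(10, 20, 50, 100))
  w <- diff(log10(g2$bin_edges))
  counts <- 100 * w / sum(w) # total 100, split by log width
  d2 <- normalize_distribution(counts, g2)
  expect_equal(d2$dN_dlogDp, rep(100 / sum(w), 3), tolerance = 1e-12)

  # exact round-trip for arbitrary counts
  withr::with_seed(2, counts3 <- runif(47))
  g3 <- composite_grid(31, 16)
  expect_equal(denormalize_distribution(normalize_distribution(counts3, g3)),
               counts3, tolerance = 1e-14)
  expect_error(normalize_distribution(c(-1, 1, 1), g2), "non-negative")
})

test_that("GMD/GSD moment estimates are exact for degenerate cases", {
  # monodisperse: GMD at the bin midpoint, GSD exactly 1
  g <- size_grid(c(50, 200))
  gg <- gmd_gsd(normalize_distribution(1000, g))
  expect_equal(gg$gmd_nm, 100)
  expect_equal(gg$gsd, 1)

  # two equal monodisperse bins: GMD is the geometric mean of the midpoints
  g2 <- size_grid(c(20, 45, 245.0))
  d1 <- g2$bin_mids[1]; d2 <- g2$bin_mids[2]
  gg2 <- gmd_gsd(normalize_distribution(c(7, 7), g2))
  expect_equal(gg2$gmd_nm, sqrt(d1 * d2), tolerance = 1e-12)

  expect_error(gmd_gsd(normalize_distribution(c(0, 0), g2)), "empty")
})

test_that("GMD/GSD recover generating parameters of a discretized lognormal", {
  g <- size_grid(exp(seq(log(7), log(2000), length.out = 65)))
  counts <- lognormal_counts(list(lognormal_mode(1, 100, 1.8)), g, 1e4)
  gg <- gmd_gsd(normalize_distribution(counts, g))
  expect_rel_equal(gg$gmd_nm, 100, 0.02)
  expect_rel_equal(gg$gsd, 1.8, 0.03)
  # discretization bias shrinks with bin refinement
  g2 <- size_grid(exp(seq(log(7), log(2000), length.out = 257)))
  counts2 <- lognormal_counts(list(lognormal_mode(1, 100, 1.8)), g2, 1e4)
  gg2 <- gmd_gsd(normalize_distribution(counts2, g2))
  expect_lt(abs(gg2$gmd_nm - 100), abs(gg$gmd_nm - 100) + 1e-9)
  expect_lt(abs(gg2$gsd - 1.8), abs(gg$gsd - 1.8))
})

test_that("GMD/GSD are invariant to rescaling concentrations", {
  g <- composite_grid()
  counts <- lognormal_counts(list(lognormal_mode(1, 120, 1.6)), g, 1e4)
  a <- gmd_gsd(normalize_distribution(counts, g))
  b <- gmd_gsd(normalize_distribution(counts * 1e6, g))
  expect_equal(a$gmd_nm, b$gmd_nm, tolerance = 1e-12)
  expect_equal(a$gsd, b$gsd, tolerance = 1e-12)
})

test_that("unimodal fit recovers generating parameters within 1%", {
  g <- composite_grid()
  counts <- lognormal_counts(list(lognormal_mode(1, 100, 1.7)), g, 5e4)
  fit <- fit_modes(normalize_distribution(counts, g), 1)
  expect_length(fit, 1)
  expect_rel_equal(fit[[1]]$gmd_nm, 100, 0.01)
  expect_rel_equal(fit[[1]]$gsd, 1.7, 0.01)
  expect_rel_equal(fit[[1]]$n_total, 5e4, 0.01)
  expect_true(attr(fit, "converged"))
})

test_that("bimodal fit resolves the Aitken and accumulation modes within 5%", {
  g <- composite_grid()
  truth <- list(lognormal_mode(0.5, 58.2, 1.6), lognormal_mode(0.5, 794, 1.6))
  counts <- lognormal_counts(truth, g, 2e4)
  fit <- fit_modes(normalize_distribution(counts, g), 2)
  expect_length(fit, 2)
  expect_rel_equal(fit[[1]]$gmd_nm, 58.2, 0.05)
  expect_rel_equal(fit[[2]]$gmd_nm, 794, 0.05)
  expect_rel_equal(fit[[1]]$n_total + fit[[2]]$n_total, 2e4, 0.05)
})

test_that("all-zero distributions are rejected", {
  g <- composite_grid()
  expect_error(fit_modes(normalize_distribution(numeric(48), g)), "all-zero")
})

test_that("BIC selects the true number of modes on sampled spectra", {
  g <- composite_grid()
  uni <- lognormal_counts(list(lognormal_mode(1, 100, 1.7)), g)
  bi <- lognormal_counts(list(lognormal_mode(0.5, 58.2, 1.6),
                              lognormal_mode(0.5, 794, 1.6)), g)
  n_rep <- 50
  correct <- c(uni = 0L, bi = 0L)
  withr::with_seed(99, {
    for (i in seq_len(n_rep)) {
      cu <- as.numeric(rmultinom(1, 1e4, uni))
      fu <- try(fit_modes(normalize_distribution(cu, g), "auto"), silent = TRUE)
      if (!inherits(fu, "try-error") && attr(fu, "n_modes_selected") == 1L) {
        correct["uni"] <- correct["uni"] + 1L
      }
      cb <- as.numeric(rmultinom(1, 1e4, bi))
      fb <- try(fit_modes(normalize_distribution(cb, g), "auto"), silent = TRUE)
      if (!inherits(fb, "try-error") && attr(fb, "n_modes_selected") == 2L) {
        correct["bi"] <- correct["bi"] + 1L
      }
    }
  })
  expect_gte(correct[["uni"]] / n_rep, 0.95)
  expect_gte(correct[["bi"]] / n_rep, 0.95)
})

test_that("per-scan GMD trajectory tracks a drifting mixture", {
  # growing share of a coarse mode raises the scan GMD monotonically
  g <- composite_grid()
  fine <- lognormal_counts(list(lognormal_mode(1, 67.9, 1.6)), g, 1e4)
  coarse <- lognormal_counts(list(lognormal_mode(1, 96.8, 1.6)), g, 1e4)
  mix <- t(sapply(seq(0, 1, 0.25), function(a) (1 - a) * fine + a * coarse))
  s <- conc_series(seq(0, 240, 60), g, mix)
  traj <- gmd_trajectory(s)
  expect_true(all(diff(traj$gmd_nm) > 0))
  expect_rel_equal(traj$gmd_nm[1], 67.9, 0.02)
  expect_rel_equal(traj$gmd_nm[5], 96.8, 0.02)
})
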