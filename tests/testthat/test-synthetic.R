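test_that("simulated traces conserve mass and respect the uninhibited limit", {
  sc <- atpdf_scheme(); mm <- default_mm()
  d <- assay_design("kobs", inhibitor_grid = c(0, 1e-7), replicates = 1,
                    duration_s = 200, seed = 1)
  sim <- simulate_assay(sc, mm, d, noise = FALSE)
  for (el in sim) {
    tr <- el$trace
    expect_lt(max(abs(tr$E + tr$EI + tr$EIs - d$enzyme_total)),
              1e-6 * d$enzyme_total + 1e-11)
    expect_lt(max(abs(tr$S + tr$P - d$substrate0)),
              1e-6 * d$substrate0 + 1e-11)
  }
  # no inhibitor: product accumulates linearly at the Michaelis-Menten rate
  cv0 <- sim[[1]]$curve
  v_expect <- michaelis_velocity(mm, d$enzyme_total, d$substrate0)
  fit <- stats::lm(signal ~ time_s, data = cv0)
  expect_equal(unname(stats::coef(fit)[2]), v_expect, tolerance = 1e-4)
  expect_lt(max(sim[[1]]$trace$P) / d$substrate0, 0.01)
})

test_that("simulation is deterministic in the seed, noiseless independent of it", {
  sc <- atpdf_scheme(); mm <- default_mm()
  d1 <- assay_design("kobs", inhibitor_grid = c(3e-8, 3e-7), replicates = 2,
                     n_points = 40, seed = 5)
  d2 <- assay_design("kobs", inhibitor_grid = c(3e-8, 3e-7), replicates = 2,
                     n_points = 40, seed = 5)
  d3 <- assay_design("kobs", inhibitor_grid = c(3e-8, 3e-7), replicates = 2,
                     n_points = 40, seed = 6)
  expect_identical(assay_curves(simulate_assay(sc, mm, d1)),
                   assay_curves(simulate_assay(sc, mm, d2)))
  expect_false(identical(assay_curves(simulate_assay(sc, mm, d1)),
                         assay_curves(simulate_assay(sc, mm, d3))))
  expect_identical(assay_curves(simulate_assay(sc, mm, d1, noise = FALSE)),
                   assay_curves(simulate_assay(sc, mm, d3, noise = FALSE)))
  # replicates within one assay differ only in noise
  s <- simulate_assay(sc, mm, d1)
  expect_false(identical(s[[1]]$curve$signal, s[[2]]$curve$signal))
  expect_identical(s[[1]]$trace, s[[2]]$trace)
})

test_that("ODE-derived k_obs approaches the closed form as [I]/[E] grows", {
  sc <- atpdf_scheme(); mm <- default_mm()
  I <- 100e-9
  ratios <- c(5, 50, 500)
  errs <- vapply(ratios, function(r) {
    d <- assay_design("kobs", enzyme_total = I / r, inhibitor_grid = I,
                      replicates = 1, seed = 1)
    f <- fit_progress_curve(simulate_assay(sc, mm, d, noise = FALSE)[[1]]$curve)
    abs(f$kobs - kobs_induced_fit(sc, I)) / kobs_induced_fit(sc, I)
  }, 0)
  expect_true(all(diff(errs) < 0))       # depletion bias shrinks monotonically
  expect_lt(errs[3], 0.002)
})

test_that("preincubated assays start at the inhibited steady-state velocity", {
  sc <- atpdf_scheme(); mm <- default_mm()
  base <- list(inhibitor_grid = 1e-6, replicates = 1, seed = 1)
  dpre <- do.call(assay_design, c(list("kobs", preincubation_s = 900), base))
  dnon <- do.call(assay_design, c(list("kobs"), base))
  fpre <- fit_progress_curve(simulate_assay(sc, mm, dpre, noise = FALSE)[[1]]$curve)
  fnon <- fit_progress_curve(simulate_assay(sc, mm, dnon, noise = FALSE)[[1]]$curve)
  expect_equal(fpre$v0, fnon$vs, tolerance = 0.05)
})

test_that("direct k_obs series generation matches the requested mechanism", {
  sc <- atpdf_scheme()
  grid <- c(1e-8, 1e-7, 1e-6)
  s0 <- simulate_kobs_series(sc, grid, "induced_fit", noise_cv = 0)
  expect_equal(s0$kobs, kobs_induced_fit(sc, grid))
  s1 <- simulate_kobs_series(sc, grid, "conformational_selection", noise_cv = 0)
  expect_equal(s1$kobs, kobs_conformational_selection(sc, grid))
  expect_identical(simulate_kobs_series(sc, grid, seed = 4),
                   simulate_kobs_series(sc, grid, seed = 4))
})
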