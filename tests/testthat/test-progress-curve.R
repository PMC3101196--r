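test_that("noiseless burst curves are recovered essentially exactly", {
  times <- seq(0, 5 / 0.02, length.out = 60)
  cv <- burst_curve(v0 = 3.7e-9, vs = 0.4e-9, kobs = 0.02, times = times)
  f <- fit_progress_curve(cv)
  expect_false(f$degenerate)
  expect_equal(f$v0, 3.7e-9, tolerance = 1e-3)
  expect_equal(f$vs, 0.4e-9, tolerance = 1e-3)
  expect_equal(f$kobs, 0.02, tolerance = 1e-3)
})

test_that("noisy burst fit agrees with a dense grid-search oracle", {
  times <- seq(0, 5 / 0.02, length.out = 60)
  cv <- burst_curve(v0 = 3.7e-9, vs = 0.4e-9, kobs = 0.02, times = times)
  set.seed(1)
  cv$signal <- cv$signal * (1 + stats::rnorm(60, 0, 0.02))
  f <- fit_progress_curve(cv)
  # independent oracle: exhaustive grid over (v0, vs, kobs), refined once
  rss <- function(p) sum((cv$signal - burst_curve(p[1], p[2], p[3], times)$signal)^2)
  grid <- expand.grid(v0 = seq(2e-9, 6e-9, length.out = 40),
                      vs = seq(0, 1e-9, length.out = 40),
                      k = seq(0.005, 0.05, length.out = 40))
  vals <- apply(grid, 1, rss)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(best, rss, control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(f$v0, opt$par[1], tolerance = 0.02)
  expect_equal(f$kobs, opt$par[3], tolerance = 0.02)
  # both land within 5% of the generating parameters at this noise level
  expect_equal(f$v0, 3.7e-9, tolerance = 0.05)
  expect_equal(f$vs, 0.4e-9, tolerance = 0.05)
  expect_equal(f$kobs, 0.02, tolerance = 0.05)
})

test_that("uninhibited (linear) curves are flagged degenerate with slope v0", {
  times <- seq(0, 300, length.out = 50)
  cv <- data.frame(time_s = times, signal = 2.5e-9 * times)
  f <- fit_progress_curve(cv)
  expect_true(f$degenerate)
  expect_true(is.na(f$kobs))
  expect_equal(f$v0, 2.5e-9, tolerance = 1e-6)
})

test_that("invalid curves are rejected with informative errors", {
  expect_error(fit_progress_curve(data.frame(time_s = c(3, 2, 1, 4, 5, 6, 7, 8),
                                             signal = 1:8)),
               "strictly increasing")
  expect_error(fit_progress_curve(data.frame(time_s = 1:5, signal = 1:5)),
               "at least 8")
})

test_that("tight vs preincubated velocity ordering is reflected in the fits", {
  sc <- atpdf_scheme(); mm <- default_mm()
  d <- assay_design("kobs", inhibitor_grid = 1e-6, replicates = 1, seed = 3)
  f <- fit_progress_curve(simulate_assay(sc, mm, d, noise = FALSE)[[1]]$curve)
  expect_lt(f$vs, f$v0)  # slow tightening always decelerates the assay
})
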