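kobs_grid <- c(10, 30, 100, 300, 1000, 3000) * 1e-9

test_that("saturation fit is exact on a noiseless series", {
  sc <- atpdf_scheme()
  ser <- data.frame(inhibitor_M = kobs_grid,
                    kobs = kobs_induced_fit(sc, kobs_grid))
  f <- fit_kobs_saturation(ser)
  expect_equal(f$k5, sc$k5, tolerance = 1e-6)
  expect_equal(f$k6, sc$k6, tolerance = 1e-6)
  expect_equal(f$KI, ki_initial(sc), tolerance = 1e-6)
  expect_false(f$decreasing)
})

test_that("saturation fit tolerates noise at replicate-calibrated accuracy", {
  sc <- atpdf_scheme()
  ser <- do.call(rbind, lapply(1:3, function(r)
    simulate_kobs_series(sc, kobs_grid, "induced_fit", noise_cv = 0.05,
                         seed = 7 + r)))
  f <- fit_kobs_saturation(ser)
  expect_equal(f$k5, sc$k5, tolerance = 0.10)
  expect_equal(f$k6, sc$k6, tolerance = 0.25)
})

test_that("a decreasing series is fitted but flagged inconsistent", {
  sc <- atpdf_scheme()
  ser <- simulate_kobs_series(sc, kobs_grid, "conformational_selection",
                              noise_cv = 0, seed = 1)
  f <- fit_kobs_saturation(ser)
  expect_true(f$decreasing)
})

test_that("double-reciprocal line is exact without noise and near-perfect with 2%", {
  sc <- atpdf_scheme()
  ser <- data.frame(inhibitor_M = kobs_grid,
                    kobs = kobs_induced_fit(sc, kobs_grid))
  rec <- fit_double_reciprocal(ser, k6 = sc$k6)
  expect_equal(rec$r_squared, 1, tolerance = 1e-9)
  expect_equal(rec$intercept, 1 / sc$k5, tolerance = 1e-9)
  expect_equal(rec$KI, ki_initial(sc), tolerance = 1e-9)
  ser2 <- simulate_kobs_series(sc, kobs_grid, "induced_fit",
                               noise_cv = 0.02, seed = 3)
  rec2 <- fit_double_reciprocal(ser2, k6 = sc$k6)
  expect_gte(rec2$r_squared, 0.99)
  expect_error(fit_double_reciprocal(ser[1:2, ], k6 = sc$k6), "3 points")
})

test_that("reciprocal slope agrees with the saturation fit on shared data", {
  sc <- atpdf_scheme()
  ser <- simulate_kobs_series(sc, kobs_grid, "induced_fit",
                              noise_cv = 0.02, seed = 9)
  f <- fit_kobs_saturation(ser)
  rec <- fit_double_reciprocal(ser, k6 = f$k6)
  expect_equal(rec$k5, f$k5, tolerance = 3 * f$se[["k5"]] / f$k5 + 0.02)
})

test_that("mechanism classification separates the two limiting models", {
  sc <- atpdf_scheme()
  v_if <- classify_mechanism(
    simulate_kobs_series(sc, kobs_grid, "induced_fit", seed = 2))
  expect_identical(v_if$label, "induced_fit")
  v_cs <- classify_mechanism(
    simulate_kobs_series(sc, kobs_grid, "conformational_selection", seed = 2))
  expect_identical(v_cs$label, "conformational_selection")
  flat <- kinetic_scheme(k4 = 140, k5 = 0, k6 = 4e-4)
  v_fl <- classify_mechanism(
    simulate_kobs_series(flat, kobs_grid, "induced_fit", seed = 2))
  expect_identical(v_fl$label, "ambiguous")
  # narrow span cannot support a verdict
  narrow <- simulate_kobs_series(sc, c(1, 1.5, 2, 2.5, 3) * 1e-7, "induced_fit",
                                 seed = 2)
  expect_identical(classify_mechanism(narrow)$label, "ambiguous")
})

test_that("Michaelis-Menten fitting recovers parameters", {
  mm <- default_mm(); E <- 100e-9
  S <- c(0.1, 0.3, 1, 3, 10) * 1e-3
  v <- michaelis_velocity(mm, E, S)
  f <- fit_michaelis(S, v, E)
  expect_equal(f$kcat, mm$kcat, tolerance = 1e-6)
  expect_equal(f$Km, mm$Km, tolerance = 1e-6)
  set.seed(11)
  vn <- v * (1 + stats::rnorm(length(v), 0, 0.03))
  fn <- fit_michaelis(S, vn, E)
  expect_equal(fn$kcat, mm$kcat, tolerance = 0.10)
  expect_equal(fn$Km, mm$Km, tolerance = 0.10)
  expect_warning(fit_michaelis(c(1, 2, 3, 4, 5) * 1e-5,
                               michaelis_velocity(mm, E, c(1, 2, 3, 4, 5) * 1e-5),
                               E),
                 "saturation")
})
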