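test_that("observed-rate laws obey their closed-form limits and midpoints", {
  sc <- atpdf_scheme()
  KI <- ki_initial(sc)
  expect_equal(kobs_induced_fit(sc, 0), sc$k6)
  expect_equal(kobs_induced_fit(sc, KI), sc$k6 + sc$k5 / 2)
  # saturation limit of the rising hyperbola
  expect_equal(kobs_induced_fit(sc, 1), sc$k5 + sc$k6, tolerance = 1e-6)
  expect_equal(sc$k5 + sc$k6, 0.0634)
  expect_equal(kobs_conformational_selection(sc, 0), sc$k5 + sc$k6)
  expect_equal(kobs_conformational_selection(sc, KI), sc$k6 + sc$k5 / 2)
  expect_equal(kobs_conformational_selection(sc, 1), sc$k6, tolerance = 1e-3)
  expect_error(kobs_induced_fit(sc, -1e-9), "inhibitor_conc")
  expect_error(kinetic_scheme(k4 = -1, k5 = 1, k6 = 1), "invalid scheme")
})

test_that("monotonicity of the two rate laws holds over random schemes", {
  set.seed(11)
  Igrid <- 10^seq(-9, -4, length.out = 25)
  for (i in 1:25) {
    sc <- random_scheme()
    kif <- kobs_induced_fit(sc, Igrid)
    kcs <- kobs_conformational_selection(sc, Igrid)
    expect_true(all(diff(kif) >= 0))
    expect_true(all(diff(kcs) <= 0))
    expect_true(all(kif >= sc$k6 - 1e-15) && all(kif <= sc$k5 + sc$k6 + 1e-15))
  }
})

test_that("overall dissociation constant follows from the rate constants", {
  sc <- atpdf_scheme()
  expect_equal(ki_star(sc) * 1e9, 0.883, tolerance = 1e-3)
  # identity K_I* = K_I k6/(k5+k6)
  expect_equal(ki_star(sc), ki_initial(sc) * sc$k6 / (sc$k5 + sc$k6))
  # no tightening: K_I* = K_I; equal rates: K_I/2
  expect_equal(ki_star(kinetic_scheme(k4 = 140, k5 = 0, k6 = 4e-4)),
               140e-9)
  expect_equal(ki_star(kinetic_scheme(k4 = 140, k5 = 4e-4, k6 = 4e-4)),
               70e-9)
  expect_error(ki_star(kinetic_scheme(k4 = 140, k5 = 1e-2, k6 = 0)),
               "irreversible")
})

test_that("k6 recovery from the tightening ratio round-trips", {
  expect_equal(k6_from_ratio(63e-3, 140e-9, 0.9e-9), 4.08e-4,
               tolerance = 1e-3)
  expect_equal(k6_from_ratio(1, 2e-9, 1e-9), 1)  # KI = 2 KI* -> k6 = k5
  expect_lt(k6_from_ratio(1, 1e-3, 1e-9), 1.1e-6)  # ratio -> Inf: k6 -> 0
  expect_error(k6_from_ratio(63e-3, 1e-9, 2e-9), "tightening")
  set.seed(21)
  for (i in 1:25) {
    sc <- random_scheme()
    expect_equal(k6_from_ratio(sc$k5, ki_initial(sc), ki_star(sc)), sc$k6,
                 tolerance = 1e-12)
    expect_lt(ki_star(sc), ki_initial(sc))
  }
})

test_that("complex half-life matches the residence-time formula and its limit", {
  expect_equal(complex_half_life(atpdf_scheme()) / 60, 28.9, tolerance = 1e-3)
  expect_equal(complex_half_life(ecpdf_scheme()) / 60, 6.09, tolerance = 1e-3)
  # k6 << k5 << k4 limit: t1/2 ~ 0.693/k6
  sc <- atpdf_scheme()
  expect_equal(complex_half_life(sc), 0.693 / sc$k6,
               tolerance = 1.01 * (sc$k5 + sc$k6) / sc$k4)
  expect_equal(complex_half_life(sc, exact_ln2 = TRUE) / complex_half_life(sc),
               log(2) / 0.693, tolerance = 1e-12)
  expect_warning(out <- complex_half_life(kinetic_scheme(k4 = 1, k5 = 1, k6 = 0)),
                 "half-life")
  expect_identical(out, Inf)
})

test_that("diffusion-limited k4 and the free-energy relation reproduce known values", {
  expect_equal(k4_from_KI(140e-9), 140)
  expect_equal(k4_from_KI(185e-9), 185)
  expect_error(k4_from_KI(0), "positive")
  ctx <- thermo_context()
  expect_equal(ctx$RT, 0.616, tolerance = 1e-3)
  expect_equal(ddg_from_ratio(155), 3.11, tolerance = 1e-2)
  expect_equal(ddg_from_ratio(1), 0)
  expect_equal(ddg_from_ratio(exp(1)), ctx$RT)
  expect_error(ddg_from_ratio(0), "positive")
  # additivity over composed ratios
  set.seed(5)
  for (i in 1:10) {
    a <- stats::runif(1, 0.1, 100); b <- stats::runif(1, 0.1, 100)
    expect_equal(ddg_from_ratio(a * b),
                 ddg_from_ratio(a) + ddg_from_ratio(b), tolerance = 1e-12)
  }
})

test_that("Michaelis-Menten velocity reduces correctly at limits", {
  mm <- default_mm()
  E <- 100e-9
  expect_equal(michaelis_velocity(mm, E, 1), mm$kcat * E, tolerance = 1e-3)
  expect_equal(michaelis_velocity(mm, E, mm$Km), mm$kcat * E / 2)
  expect_equal(michaelis_velocity(mm, E, 1, competitive_I = 1e-6,
                                  Ki_eff = Inf),
               michaelis_velocity(mm, E, 1))
  # competitive inhibition raises the apparent Km only
  v_i <- michaelis_velocity(mm, E, mm$Km, competitive_I = 1e-6, Ki_eff = 1e-6)
  expect_equal(v_i, mm$kcat * E * mm$Km / (2 * mm$Km + mm$Km))
  expect_equal(michaelis_velocity(mm, E, 1), 3.7e-6, tolerance = 1e-3)
})

test_that("scheme serialization round-trips through JSON and YAML", {
  sc <- ecpdf_scheme()
  for (fmt in c("json", "yaml")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_scheme(sc, path, format = fmt)
    back <- read_scheme(path)
    expect_equal(back[c("k3", "k4", "k5", "k6")],
                 sc[c("k3", "k4", "k5", "k6")])
  }
})

test_that("tabulated report converts to conventional units", {
  rep <- scheme_report(atpdf_scheme())
  expect_equal(rep$KI_nM, 140)
  expect_equal(rep$k5_1e3_per_s, 63)
  expect_equal(rep$k6_1e4_per_s, 4)
  expect_equal(rep$ratio, 158.5, tolerance = 1e-3)
  expect_equal(rep$t_half_min, 28.9, tolerance = 1e-3)
})
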