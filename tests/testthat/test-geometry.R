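test_that("PDB parsing resolves chains, altlocs and round-trips coordinates", {
  m <- read_structure(two_chain_pdb())
  expect_equal(nrow(m$ca), 4)
  # highest-occupancy altloc retained
  kept <- m$ca[m$ca$chain == "A" & m$ca$resno == 2, ]
  expect_equal(kept$x, 4.0)
  expect_setequal(unique(m$atoms$chain), c("A", "B"))
  # single-residue file
  m1 <- read_structure(two_chain_pdb()[1:2])
  expect_equal(nrow(m1$ca), 1)
  # write/read round trip preserves coordinates to PDB precision
  conf <- generate_conformer(target_delta_ap = 97)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(conf, path)
  back <- read_structure(path)
  expect_equal(as.matrix(back$ca[, c("x", "y", "z")]),
               as.matrix(conf$ca[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("Kabsch superposition is exact for rigid copies and proper only", {
  m <- generate_conformer(target_delta_ap = 95)
  expect_equal(kabsch_superpose(m, m)$rmsd, 0, tolerance = 1e-12)
  moved <- rigid_move(m, angles = c(0.4, -1.2, 2.2), translation = c(10, -4, 7))
  sup <- kabsch_superpose(moved, m)
  expect_equal(sup$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  # applying the transform and recomputing reproduces the rmsd
  aligned <- apply_superposition(moved, sup)
  expect_equal(kabsch_superpose(aligned, m)$rmsd, sup$rmsd, tolerance = 1e-9)
  expect_error(kabsch_superpose(m, m, residue_selection = 1:2), "at least 3")
})

test_that("Kabsch rmsd matches the brute-force rotation oracle on 4-point toys", {
  set.seed(31)
  for (i in 1:5) {
    X <- matrix(stats::rnorm(12, sd = 3), 4, 3)
    Y <- matrix(stats::rnorm(12, sd = 3), 4, 3)
    mk <- function(M) structure_model(data.frame(
      chain = "A", resno = 1:4, resid = "ALA", elety = "CA",
      x = M[, 1], y = M[, 2], z = M[, 3]))
    sup <- kabsch_superpose(mk(X), mk(Y))
    expect_equal(sup$rmsd, bruteforce_rmsd(X, Y), tolerance = 1e-3)
    # optimal superposition never exceeds the unsuperposed rmsd
    expect_lte(sup$rmsd, sqrt(mean(rowSums((X - Y)^2))) + 1e-12)
  }
})

test_that("aperture angle measures the vertex angle and ignores pose", {
  pts <- data.frame(chain = "A", resno = 1:3, resid = "ALA", elety = "CA",
                    x = c(0, 1, 1), y = c(0, 0, 1), z = 0)
  m <- structure_model(pts)
  mk <- marker_triple(1, 2, 3, vertex = 2)
  expect_equal(aperture_angle(m, mk), 90)
  lin <- structure_model(transform(pts, x = c(0, 1, 2), y = 0))
  expect_equal(aperture_angle(lin, mk), 180)
  coin <- structure_model(transform(pts, x = c(1, 1, 2), y = c(0, 0, 1)))
  expect_error(aperture_angle(coin, mk), "coincident")
  conf <- generate_conformer(target_delta_ap = 83.5)
  moved <- rigid_move(conf, angles = c(1, 2, 3), translation = c(-4, 8, 1))
  expect_equal(aperture_angle(moved), aperture_angle(conf), tolerance = 1e-9)
})

test_that("rigid-motion invariance holds across many random poses", {
  conf <- generate_conformer(target_delta_ap = 92)
  ref <- generate_conformer(target_delta_ap = 95)
  d0 <- aperture_angle(conf)
  r0 <- kabsch_superpose(conf, ref)$rmsd
  set.seed(7)
  for (i in 1:100) {
    moved <- rigid_move(conf, angles = stats::runif(3, -pi, pi),
                        translation = stats::runif(3, -50, 50))
    expect_lt(abs(aperture_angle(moved) - d0), 1e-6)
    expect_lt(abs(kabsch_superpose(moved, ref)$rmsd - r0), 1e-6)
  }
})

test_that("per-residue displacement localizes an engineered 4 A shift", {
  ref <- generate_conformer(target_delta_ap = 95)
  at <- ref$atoms
  at[at$resno == 60, c("x", "y", "z")] <-
    at[at$resno == 60, c("x", "y", "z")] + c(4, 0, 0)
  shifted <- structure_model(at)
  sup <- kabsch_superpose(shifted, ref, residue_selection = setdiff(1:150, 60))
  disp <- residue_displacement(shifted, ref, sup)
  expect_equal(disp$max, 4, tolerance = 1e-9)
  expect_equal(disp$argmax, 60)
  expect_gte(disp$max, kabsch_superpose(shifted, ref)$rmsd)
  # identical structures: all displacements vanish
  d0 <- residue_displacement(ref, ref, kabsch_superpose(ref, ref))
  expect_lt(d0$max, 1e-12)
})

test_that("atom distances answer hydrogen-bond-scale queries", {
  at <- data.frame(chain = "A", resno = c(42, 42, 200), resid = "ALA",
                   elety = c("N", "CA", "O"),
                   x = c(0, 1.5, 2.8), y = 0, z = 0)
  m <- structure_model(at)
  expect_equal(atom_distance(m, list(resno = 42, elety = "N"),
                             list(resno = 200, elety = "O")), 2.8)
  expect_equal(atom_distance(m, list(resno = 42, elety = "N"),
                             list(resno = 42, elety = "N")), 0)
  expect_error(atom_distance(m, list(resno = 42, elety = "N"),
                             list(resno = 99, elety = "O")), "not found")
})

test_that("state zones validate, tie-break by order, classify generated pairs", {
  expect_error(state_zones(list(A = c(0, 10, 0, 1), B = c(5, 15, 0.5, 2))),
               "overlap")
  zones <- state_zones(list(O = c(90, 100, 0, 1), C = c(75, 90, 1, 5)))
  expect_identical(classify_state(95, 0.5, zones), "O")
  expect_identical(classify_state(60, 0.2, zones), "unassigned")
  # boundary point shared between closed rectangles goes to the first zone
  zb <- state_zones(list(O = c(90, 100, 0, 1), I = c(80, 90, 0, 1)))
  expect_identical(classify_state(90, 0.5, zb), "O")
  open <- generate_conformer(target_delta_ap = 95)
  closed <- generate_conformer(target_delta_ap = 80)
  zw <- state_zones(list(O = c(90, 100, 0, 1), C = c(70, 85, 1, 5)))
  expect_identical(aperture_result(open, open, zones = zw)$state, "O")
  expect_identical(aperture_result(closed, open, zones = zw)$state, "C")
})
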