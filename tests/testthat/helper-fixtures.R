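# shared fixtures: the three enzyme-inhibitor schemes and assay shortcuts

atpdf_scheme <- function() kinetic_scheme(k4 = 140, k5 = 63e-3, k6 = 4e-4)
ecpdf_scheme <- function() kinetic_scheme(k4 = 112, k5 = 170e-3, k6 = 19e-4)
bspdf2_scheme <- function() kinetic_scheme(k4 = 185, k5 = 72e-3, k6 = 11e-4)

default_mm <- function() michaelis_params(kcat = 37, Km = 1e-3)

# log-uniform random scheme for property tests
random_scheme <- function() {
  kinetic_scheme(k3 = 10^stats::runif(1, 8, 10),
                 k4 = 10^stats::runif(1, 0, 3),
                 k5 = 10^stats::runif(1, -3, 0),
                 k6 = 10^stats::runif(1, -5, -2))
}

# closed-form burst progress curve (independent of the ODE simulator)
burst_curve <- function(v0, vs, kobs, times, P0 = 0) {
  data.frame(time_s = times,
             signal = P0 + vs * times + (v0 - vs) * (1 - exp(-kobs * times)) / kobs)
}

# brute-force rigid-superposition oracle: minimise rmsd over rotations
# (Euler-angle grid + Nelder-Mead refinement), centroids aligned per rotation
bruteforce_rmsd <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  rmsd_of <- function(ang) {
    R <- euler_rotation(ang)
    sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- c(0, 0, 0); best_val <- Inf
  for (a in grid) for (b in seq(0, pi, length.out = 7)) for (g in grid) {
    v <- rmsd_of(c(a, b, g))
    if (v < best_val) { best_val <- v; best <- c(a, b, g) }
  }
  opt <- stats::optim(best, rmsd_of, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# minimal PDB text with altloc A/B on one atom and two chains
two_chain_pdb <- function() {
  c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA AVAL A   2       4.000   1.000   0.000  0.60  0.00           C",
    "ATOM      4  CA BVAL A   2       4.200   1.200   0.000  0.40  0.00           C",
    "ATOM      5  CA  GLY B   1       0.000   5.000   2.000  1.00  0.00           C",
    "ATOM      6  CA  SER B   2       3.000   5.500   2.500  1.00  0.00           C",
    "END")
}
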