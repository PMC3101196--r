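#' Simulated assay design
#'
#' Describes one simulated coupled deformylation assay: concentrations,
#' preincubation, sampling, and the noise model.  Two presets are provided.
#' \code{mode = "kobs"} emulates the non-preincubated progress-curve assay
#' used to extract the observed binding rate at each inhibitor concentration;
#' it defaults to trace enzyme (0.2 nM), 2 mM substrate and an inhibitor
#' grid of 10 nM - 3 uM so that the pseudo-first-order condition
#' \eqn{[I] \gg [E]} holds everywhere and free-inhibitor depletion is
#' negligible even at the lowest inhibitor concentration.  \code{mode = "henderson"} emulates
#' the preincubated initial-velocity titration used for tight-binding
#' analysis; it defaults to 100 nM enzyme and 2 mM substrate.
#'
#' The noise model is multiplicative Gaussian (coefficient of variation
#' \code{noise_cv}) plus additive Gaussian (\code{noise_sd}, molar), applied
#' to the product signal.  One master \code{seed} drives every curve through
#' deterministic per-curve substreams.
#'
#' @param mode \code{"kobs"} or \code{"henderson"}.
#' @param enzyme_total total enzyme (molar).
#' @param substrate0 initial substrate (molar); for \code{"henderson"} a
#'   vector of substrate levels is allowed.
#' @param inhibitor_grid inhibitor concentrations (molar).
#' @param preincubation_s enzyme-inhibitor preincubation before substrate
#'   addition (seconds; 0 disables).
#' @param duration_s duration of each recorded curve (seconds); \code{NULL}
#'   lets the simulator pick ~5 relaxation times per curve.
#' @param n_points samples per curve.
#' @param replicates independent noise replicates per inhibitor
#'   concentration (default 3 for \code{"kobs"}, 1 for \code{"henderson"}).
#' @param noise_cv multiplicative noise CV (default 1\%).
#' @param noise_sd additive noise SD in molar (default 2 nM).
#' @param seed master seed (integer).
#' @return Object of class \code{"assay_design"}.
#' @export
assay_design <- function(mode = c("kobs", "henderson"),
                         enzyme_total = NULL,
                         substrate0 = NULL,
                         inhibitor_grid = NULL,
                         preincubation_s = NULL,
                         duration_s = NULL,
                         n_points = 200,
                         replicates = NULL,
                         noise_cv = 0.01,
                         noise_sd = 2e-9,
                         seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(enzyme_total))
    enzyme_total <- if (mode == "kobs") 0.2e-9 else 100e-9
  if (is.null(substrate0)) substrate0 <- 2e-3
  if (is.null(inhibitor_grid))
    inhibitor_grid <- if (mode == "kobs")
      c(10, 30, 100, 300, 1000, 3000) * 1e-9
    else
      c(25, 50, 100, 150, 200, 300) * 1e-9
  if (is.null(preincubation_s))
    preincubation_s <- if (mode == "kobs") 0 else 600
  if (any(c(enzyme_total, substrate0, inhibitor_grid) < 0))
    stop("concentrations must be >= 0")
  if (enzyme_total <= 0) stop("enzyme_total must be positive")
  if (n_points < 8) stop("need at least 8 samples per curve")
  if (is.null(replicates)) replicates <- if (mode == "kobs") 3L else 1L
  if (replicates < 1) stop("replicates must be >= 1")
  structure(list(mode = mode, enzyme_total = enzyme_total,
                 substrate0 = substrate0, inhibitor_grid = inhibitor_grid,
                 preincubation_s = preincubation_s, duration_s = duration_s,
                 n_points = as.integer(n_points),
                 replicates = as.integer(replicates), noise_cv = noise_cv,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "assay_design")
}

#' @export
print.assay_design <- function(x, ...) {
  cat(sprintf("Assay design (%s mode): E = %.3g nM, S0 = %s\n", x$mode,
              1e9 * x$enzyme_total,
              paste(sprintf("%.3g", 1e6 * x$substrate0), collapse = "/")), sep = "")
  cat(sprintf("  [I]: %s nM; preincubation %g s; %d pts/curve; noise %g%% + %.3g nM; seed %d\n",
              paste(sprintf("%.3g", 1e9 * x$inhibitor_grid), collapse = ", "),
              x$preincubation_s, x$n_points, 100 * x$noise_cv,
              1e9 * x$noise_sd, x$seed))
  invisible(x)
}

# deterministic per-curve noise substreams from the master seed
curve_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# right-hand side of the two-step inhibition mechanism under rapid-equilibrium
# Michaelis-Menten competition; y = (E, EI, EIs, S, P); free I by conservation
mechanism_rhs <- function(t, y, p) {
  E <- y[1]; EI <- y[2]; EIs <- y[3]; S <- y[4]
  I_free <- max(p$I_total - EI - EIs, 0)
  v <- if (p$with_substrate) p$kcat * E * S / (p$Km + S) else 0
  dE   <- -p$k3 * E * I_free + p$k4 * EI
  dEI  <-  p$k3 * E * I_free - (p$k4 + p$k5) * EI + p$k6 * EIs
  dEIs <-  p$k5 * EI - p$k6 * EIs
  list(c(dE, dEI, dEIs, -v, v))
}

integrate_mechanism <- function(y0, times, pars, rtol = 1e-8, atol = 1e-12) {
  out <- deSolve::lsoda(y = y0, times = times, func = mechanism_rhs,
                        parms = pars, rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("ODE solver failed (istate = ", attr(out, "istate")[1], ") at [I] = ",
         signif(pars$I_total, 3), " M")
  out
}

#' Simulate slow-binding progress curves by ODE integration
#'
#' Integrates the full two-step inhibition mechanism coupled to substrate
#' turnover,
#' \deqn{dE/dt = -k_3 E I + k_4 EI,\quad
#'       dEI/dt = k_3 E I - (k_4+k_5) EI + k_6 EI^*,\quad
#'       dEI^*/dt = k_5 EI - k_6 EI^*,}
#' with \eqn{dP/dt = k_{cat} E S/(K_m + S)}, \eqn{dS/dt = -dP/dt}, and free
#' inhibitor tracked by conservation \eqn{I = I_{tot} - EI - EI^*}.  Substrate
#' binding is treated as a rapid equilibrium on the free enzyme (no explicit
#' ES species), matching the competitive analysis applied downstream.  When
#' the design requests preincubation the same system is first integrated
#' without substrate, then substrate is introduced.
#'
#' A stiff-capable solver (\code{deSolve::lsoda}) is used with relative
#' tolerance 1e-8 and absolute tolerance 1e-12 M, since the rate constants
#' span ~6 decades.  The detection signal is taken as the product
#' concentration itself (the downstream dehydrogenase coupling is treated as
#' instantaneous and stoichiometric).
#'
#' @param scheme a [kinetic_scheme()].
#' @param mm a [michaelis_params()].
#' @param design an [assay_design()].
#' @param noise apply the design's noise model (\code{FALSE} gives the
#'   noiseless signal, independent of the seed).
#' @return A list of class \code{"simulated_assay"}: one element per
#'   (inhibitor concentration, replicate), each a list with \code{curve}
#'   (data.frame \code{time_s}, \code{signal}, \code{inhibitor_M},
#'   \code{substrate_M}, \code{replicate}, \code{preincubated}) and
#'   \code{trace} (species trajectories including the noiseless signal;
#'   shared across replicates, which differ only in noise).
#' @examples
#' sc <- kinetic_scheme(k4 = 140, k5 = 63e-3, k6 = 4e-4)
#' mm <- michaelis_params(kcat = 37, Km = 1e-3)
#' sim <- simulate_assay(sc, mm, assay_design("kobs", seed = 1))
#' head(sim[[3]]$curve)
#' @export
simulate_assay <- function(scheme, mm, design, noise = TRUE) {
  stop_if_not_scheme(scheme)
  if (!inherits(mm, "michaelis_params")) stop("mm must be michaelis_params()")
  if (!inherits(design, "assay_design")) stop("design must be assay_design()")
  n <- length(design$inhibitor_grid)
  nrep <- design$replicates
  seeds <- matrix(curve_seeds(design$seed, max(n * nrep, 1L)), nrow = n)
  Et <- design$enzyme_total
  S0 <- design$substrate0[1]
  out <- vector("list", n * nrep)
  for (i in seq_len(n)) {
    I_tot <- design$inhibitor_grid[i]
    pars <- list(k3 = scheme$k3, k4 = scheme$k4, k5 = scheme$k5,
                 k6 = scheme$k6, kcat = mm$kcat, Km = mm$Km,
                 I_total = I_tot, with_substrate = TRUE)
    y0 <- c(E = Et, EI = 0, EIs = 0, S = S0, P = 0)
    if (design$preincubation_s > 0) {
      pre_pars <- pars; pre_pars$with_substrate <- FALSE
      pre <- integrate_mechanism(c(E = Et, EI = 0, EIs = 0, S = 0, P = 0),
                                 c(0, design$preincubation_s), pre_pars)
      eq <- pre[nrow(pre), ]
      y0 <- c(E = unname(eq["E"]), EI = unname(eq["EI"]),
              EIs = unname(eq["EIs"]), S = S0, P = 0)
    }
    dur <- design$duration_s
    if (is.null(dur)) {
      ko <- kobs_induced_fit(scheme, I_tot)
      dur <- if (I_tot > 0 && ko > 0) min(5 / ko, 7200) else 300
    }
    times <- seq(0, dur, length.out = design$n_points)
    sol <- integrate_mechanism(y0, times, pars)
    trace <- as.data.frame(sol)
    names(trace)[1] <- "time_s"
    # conservation must hold to solver tolerance
    etot_dev <- max(abs(trace$E + trace$EI + trace$EIs - Et))
    stot_dev <- max(abs(trace$S + trace$P - S0))
    if (etot_dev > 1e-6 * Et + 1e-11 || stot_dev > 1e-6 * S0 + 1e-11)
      stop("mass conservation violated beyond solver tolerance")
    signal <- trace$P
    trace$signal_noiseless <- signal
    for (r in seq_len(nrep)) {
      noisy <- signal
      if (noise && (design$noise_cv > 0 || design$noise_sd > 0)) {
        old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
        set.seed(seeds[i, r])
        noisy <- signal * (1 + stats::rnorm(length(signal), 0, design$noise_cv)) +
          stats::rnorm(length(signal), 0, design$noise_sd)
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      }
      curve <- data.frame(time_s = times, signal = noisy,
                          inhibitor_M = I_tot, substrate_M = S0,
                          replicate = r,
                          preincubated = design$preincubation_s > 0)
      out[[(i - 1) * nrep + r]] <- list(curve = curve, trace = trace,
                                        replicate = r)
    }
  }
  structure(out, class = "simulated_assay", design = design)
}

#' Bind the curves of a simulated assay into one long data frame
#'
#' Produces the CSV dialect the inference functions read:
#' \code{time_s, signal, inhibitor_M, substrate_M, replicate, preincubated}.
#'
#' @param sim a [simulate_assay()] result.
#' @param replicate optional offset added to the stored replicate labels
#'   (useful when pooling several simulated assays).
#' @return data.frame.
#' @export
assay_curves <- function(sim, replicate = NULL) {
  stopifnot(inherits(sim, "simulated_assay"))
  df <- do.call(rbind, lapply(sim, `[[`, "curve"))
  if (is.null(df$replicate)) df$replicate <- 1L
  if (!is.null(replicate)) df$replicate <- df$replicate + (replicate - 1L)
  df[, c("time_s", "signal", "inhibitor_M", "substrate_M",
         "replicate", "preincubated")]
}

#' Equilibrium fractional velocity of a tight-binding competitive inhibitor
#'
#' Solves the tight-binding (Morrison) quadratic for the free-enzyme fraction
#' \eqn{a = v_i/v_0} at total enzyme \eqn{E_t}, total inhibitor \eqn{I_t} and
#' effective dissociation constant \eqn{K_{eff}}:
#' \deqn{a = \frac{(E_t - I_t - K_{eff}) + \sqrt{(I_t + K_{eff} - E_t)^2 + 4 K_{eff} E_t}}{2 E_t}.}
#'
#' @param I_total total inhibitor (molar), vectorized.
#' @param E_total total enzyme (molar).
#' @param K_eff effective dissociation constant (molar).
#' @return fractional velocity in (0, 1].
#' @export
morrison_fraction <- function(I_total, E_total, K_eff) {
  if (E_total <= 0) stop("E_total must be positive")
  if (K_eff < 0 || any(I_total < 0)) stop("concentrations must be >= 0")
  disc <- sqrt((I_total + K_eff - E_total)^2 + 4 * K_eff * E_total)
  pmin(pmax(((E_total - I_total - K_eff) + disc) / (2 * E_total), 0), 1)
}

#' Generate a Henderson initial-velocity table
#'
#' Emulates the preincubated tight-binding titration: at each combination of
#' inhibitor and substrate the equilibrated fractional velocity
#' \eqn{v_i/v_0} is computed from the Morrison quadratic with
#' \eqn{K_{eff} = K_I^* (1 + S/K_m)}, optionally with the design's noise.
#'
#' @param scheme a [kinetic_scheme()].
#' @param mm a [michaelis_params()].
#' @param design an [assay_design()] (\code{"henderson"} mode; its
#'   \code{substrate0} may hold several substrate levels).
#' @param noise apply multiplicative noise (CV \code{design$noise_cv}) to the
#'   fractional velocities.
#' @return data.frame of class \code{"henderson_table"} with columns
#'   \code{inhibitor_M}, \code{substrate_M}, \code{fraction} (= vi/v0).
#' @export
generate_henderson_table <- function(scheme, mm, design, noise = FALSE) {
  stop_if_not_scheme(scheme)
  KIs <- ki_star(scheme)
  grid <- expand.grid(inhibitor_M = design$inhibitor_grid,
                      substrate_M = design$substrate0)
  K_eff <- KIs * (1 + grid$substrate_M / mm$Km)
  frac <- mapply(morrison_fraction, grid$inhibitor_M,
                 MoreArgs = list(E_total = design$enzyme_total), K_eff = K_eff)
  if (noise && design$noise_cv > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(design$seed)
    frac <- pmin(pmax(frac * (1 + stats::rnorm(length(frac), 0, design$noise_cv)), 1e-12), 1)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  structure(data.frame(grid, fraction = frac),
            class = c("henderson_table", "data.frame"))
}

#' Simulate a k_obs series directly from a limiting mechanism
#'
#' Draws (inhibitor concentration, k_obs) pairs from the closed-form rate law
#' of either limiting mechanism and perturbs them with multiplicative
#' Gaussian noise.  Useful for generating the decreasing-rate alternative
#' (conformational selection), which has no progress-curve simulator here.
#'
#' @param scheme a [kinetic_scheme()].
#' @param inhibitor_grid molar concentrations.
#' @param mechanism \code{"induced_fit"} or \code{"conformational_selection"}.
#' @param noise_cv multiplicative noise CV.
#' @param seed integer seed.
#' @param KI_eff optional effective K_I (substrate competition).
#' @return data.frame with \code{inhibitor_M}, \code{kobs}, \code{se}.
#' @export
simulate_kobs_series <- function(scheme, inhibitor_grid,
                                 mechanism = c("induced_fit",
                                               "conformational_selection"),
                                 noise_cv = 0.05, seed = 1L,
                                 KI_eff = ki_initial(scheme)) {
  mechanism <- match.arg(mechanism)
  k <- if (mechanism == "induced_fit")
    kobs_induced_fit(scheme, inhibitor_grid, KI_eff)
  else
    kobs_conformational_selection(scheme, inhibitor_grid, KI_eff)
  if (noise_cv > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    k <- k * (1 + stats::rnorm(length(k), 0, noise_cv))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  data.frame(inhibitor_M = inhibitor_grid, kobs = pmax(k, 1e-12),
             se = abs(k) * max(noise_cv, 1e-3))
}
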