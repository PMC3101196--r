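#' Two-step slow, tight-binding kinetic scheme
#'
#' Constructs the kinetic scheme of two-step slow, tight-binding inhibition,
#'
#' \deqn{E + I \rightleftharpoons E{:}I \rightleftharpoons E{:}I^*}
#'
#' where the encounter complex E:I forms rapidly (association \code{k3},
#' dissociation \code{k4}) and then tightens slowly into the final complex
#' E:I* (forward isomerization \code{k5}, reverse \code{k6}).  The initial
#' dissociation constant is \eqn{K_I = k_4/k_3}; the overall (final)
#' dissociation constant \eqn{K_I^*} follows from [ki_star()].
#'
#' All rates are in SI units: \code{k3} in M^-1 s^-1, the others in s^-1.
#'
#' @param k3 association rate of the encounter complex (M^-1 s^-1).
#'   Defaults to the diffusion limit 1e9.
#' @param k4 dissociation rate of the encounter complex (s^-1).
#' @param k5 forward isomerization rate E:I -> E:I* (s^-1).
#' @param k6 reverse isomerization rate E:I* -> E:I (s^-1).
#' @return An object of class \code{"kinetic_scheme"}: a list with the four
#'   rate constants.
#' @examples
#' sc <- kinetic_scheme(k4 = 140, k5 = 63e-3, k6 = 4e-4)
#' ki_initial(sc) * 1e9   # K_I in nM
#' ki_star(sc) * 1e9      # K_I* in nM
#' @export
kinetic_scheme <- function(k4, k5, k6, k3 = 1e9) {
  for (nm in c("k3", "k4", "k5", "k6")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("invalid scheme: '", nm, "' must be a single finite number")
    if (v < 0) stop("invalid scheme: '", nm, "' must be nonnegative")
  }
  if (k3 <= 0 || k4 <= 0)
    stop("invalid scheme: k3 and k4 must be strictly positive")
  structure(list(k3 = k3, k4 = k4, k5 = k5, k6 = k6),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Two-step slow, tight-binding scheme (E + I <-> E:I <-> E:I*)\n")
  cat(sprintf("  k3 = %.3g M^-1 s^-1   k4 = %.3g s^-1\n", x$k3, x$k4))
  cat(sprintf("  k5 = %.3g s^-1        k6 = %.3g s^-1\n", x$k5, x$k6))
  cat(sprintf("  K_I  = %.3g nM   K_I* = %s\n",
              1e9 * ki_initial(x),
              if (x$k6 > 0) sprintf("%.3g nM", 1e9 * ki_star(x)) else "0 (k6 = 0)"))
  invisible(x)
}

stop_if_not_scheme <- function(scheme) {
  if (!inherits(scheme, "kinetic_scheme"))
    stop("expected a 'kinetic_scheme' object; see kinetic_scheme()")
}

#' Initial (encounter-complex) dissociation constant K_I
#'
#' @param scheme a [kinetic_scheme()].
#' @return \eqn{K_I = k_4/k_3} in molar.
#' @export
ki_initial <- function(scheme) {
  stop_if_not_scheme(scheme)
  scheme$k4 / scheme$k3
}

#' Overall dissociation constant K_I* of the tightened complex
#'
#' The final complex E:I* dissociates with overall constant
#' \deqn{K_I^* = \frac{k_4}{k_3 + k_3 k_5 / k_6} = K_I \frac{k_6}{k_5 + k_6},}
#' always at most \eqn{K_I}, with equality only when there is no tightening
#' (\eqn{k_5 = 0}).
#'
#' @param scheme a [kinetic_scheme()].
#' @return K_I* in molar.
#' @examples
#' # AtPDF-actinonin: ~0.88 nM
#' ki_star(kinetic_scheme(k4 = 140, k5 = 63e-3, k6 = 4e-4)) * 1e9
#' @export
ki_star <- function(scheme) {
  stop_if_not_scheme(scheme)
  if (scheme$k6 == 0)
    stop("k6 = 0: isomerization is irreversible and K_I* -> 0 ",
         "(division by zero in k4/(k3 + k3*k5/k6))")
  scheme$k4 / (scheme$k3 * (1 + scheme$k5 / scheme$k6))
}

#' Reverse isomerization rate from the tightening ratio
#'
#' Rearranges the K_I* relation to recover the reverse isomerization rate:
#' \deqn{k_6 = \frac{k_5}{K_I/K_I^* - 1}.}
#'
#' @param k5 forward isomerization rate (s^-1).
#' @param KI initial dissociation constant (molar).
#' @param KIstar overall dissociation constant (molar); must be < \code{KI}.
#' @return k6 in s^-1.
#' @examples
#' k6_from_ratio(63e-3, 140e-9, 0.9e-9)   # ~4.1e-4 s^-1
#' @export
k6_from_ratio <- function(k5, KI, KIstar) {
  if (KIstar <= 0 || KI <= 0) stop("KI and KIstar must be positive")
  if (KI <= KIstar)
    stop("KI must exceed KIstar: no slow-binding tightening when KI/KIstar <= 1")
  k5 / (KI / KIstar - 1)
}

#' Observed rate of approach to the inhibited steady state (induced fit)
#'
#' Under the rapid-equilibrium treatment of the two-step scheme the observed
#' pseudo-first-order rate is the saturating hyperbola
#' \deqn{k_{obs} = k_6 + \frac{k_5 [I]}{K_I + [I]},}
#' increasing from \eqn{k_6} at \eqn{[I] = 0} towards \eqn{k_5 + k_6}.  A
#' rising, saturable \eqn{k_{obs}} is the kinetic signature of induced fit.
#'
#' When inhibition is assayed in the presence of a competing substrate the
#' encounter step is weakened: pass \code{KI_eff = KI * (1 + S/Km)} to use the
#' apparent constant.
#'
#' @param scheme a [kinetic_scheme()].
#' @param inhibitor_conc inhibitor concentration(s), molar (>= 0).
#' @param KI_eff effective encounter dissociation constant (molar); defaults
#'   to \code{ki_initial(scheme)}.
#' @return k_obs in s^-1 (vectorized over \code{inhibitor_conc}).
#' @export
kobs_induced_fit <- function(scheme, inhibitor_conc,
                             KI_eff = ki_initial(scheme)) {
  stop_if_not_scheme(scheme)
  if (any(inhibitor_conc < 0)) stop("inhibitor_conc must be >= 0")
  scheme$k6 + scheme$k5 * inhibitor_conc / (KI_eff + inhibitor_conc)
}

#' Observed rate under conformational selection (reference model)
#'
#' The contrasting limiting mechanism, in which the ligand captures a
#' pre-existing minor conformer, predicts an observed rate that decreases
#' with ligand concentration:
#' \deqn{k_{obs} = k_6 + \frac{k_5}{1 + [I]/K_I},}
#' falling from \eqn{k_5 + k_6} towards \eqn{k_6}.  Used as the alternative
#' hypothesis when classifying the mechanism from a k_obs series.
#'
#' @inheritParams kobs_induced_fit
#' @return k_obs in s^-1.
#' @export
kobs_conformational_selection <- function(scheme, inhibitor_conc,
                                          KI_eff = ki_initial(scheme)) {
  stop_if_not_scheme(scheme)
  if (any(inhibitor_conc < 0)) stop("inhibitor_conc must be >= 0")
  scheme$k6 + scheme$k5 / (1 + inhibitor_conc / KI_eff)
}

#' Half-life of the final tightened complex
#'
#' Residence half-life of E:I* for the two-step induced-fit scheme:
#' \deqn{t_{1/2} = \frac{0.693\,(k_4 + k_5 + k_6)}{k_4 k_6},}
#' which reduces to \eqn{0.693/k_6} when \eqn{k_6 \ll k_5 \ll k_4}.  The
#' leading factor is the literal 0.693 used in tabulated residence times by
#' default; set \code{exact_ln2 = TRUE} for \eqn{\ln 2} at full precision.
#'
#' @param scheme a [kinetic_scheme()].
#' @param exact_ln2 use \code{log(2)} instead of the literal 0.693.
#' @return half-life in seconds (\code{Inf} with a warning when k6 = 0).
#' @examples
#' complex_half_life(kinetic_scheme(k4 = 140, k5 = 63e-3, k6 = 4e-4)) / 60 # ~29 min
#' @export
complex_half_life <- function(scheme, exact_ln2 = FALSE) {
  stop_if_not_scheme(scheme)
  ln2 <- if (exact_ln2) log(2) else 0.693
  if (scheme$k6 == 0) {
    warning("k6 = 0: the tightened complex never dissociates (infinite half-life)")
    return(Inf)
  }
  ln2 * (scheme$k4 + scheme$k5 + scheme$k6) / (scheme$k4 * scheme$k6)
}

#' Encounter-complex dissociation rate from K_I at the diffusion limit
#'
#' With association assumed diffusion-limited (\code{k3} = 1e9 M^-1 s^-1 by
#' default), the dissociation rate of the encounter complex follows directly
#' from the measured initial constant: \eqn{k_4 = k_3 K_I}.
#'
#' @param KI initial dissociation constant (molar), > 0.
#' @param k3 association rate (M^-1 s^-1), > 0.
#' @return k4 in s^-1.
#' @export
k4_from_KI <- function(KI, k3 = 1e9) {
  if (any(KI <= 0)) stop("KI must be strictly positive")
  if (any(k3 <= 0)) stop("k3 must be strictly positive")
  k3 * KI
}

#' Thermodynamic context (temperature and gas constant)
#'
#' @param temperature absolute temperature in kelvin (default 310.15 K, 37 C).
#' @param gas_constant in kcal mol^-1 K^-1; the default 1.987e-3 gives
#'   RT = 0.616 kcal/mol at 37 C.
#' @return Object of class \code{"thermo_context"} with fields
#'   \code{temperature}, \code{gas_constant} and \code{RT}.
#' @export
thermo_context <- function(temperature = 310.15, gas_constant = 1.987e-3) {
  if (temperature <= 0 || gas_constant <= 0)
    stop("temperature and gas_constant must be positive")
  structure(list(temperature = temperature, gas_constant = gas_constant,
                 RT = temperature * gas_constant),
            class = "thermo_context")
}

#' @export
print.thermo_context <- function(x, ...) {
  cat(sprintf("T = %.2f K, R = %.4g kcal/mol/K, RT = %.3f kcal/mol\n",
              x$temperature, x$gas_constant, x$RT))
  invisible(x)
}

#' Binding free-energy difference from a ratio of dissociation constants
#'
#' \deqn{\Delta\Delta G = RT \ln(\mathrm{ratio}).}
#' For the tightening of a slow-binding complex the natural ratio is
#' \eqn{K_I/K_I^*}, giving the free-energy gain of isomerization; additive
#' over composed ratios.
#'
#' @param ratio dimensionless positive ratio of dissociation constants.
#' @param ctx a [thermo_context()].
#' @return kcal/mol.
#' @examples
#' ddg_from_ratio(155)   # ~3.1 kcal/mol at 37 C
#' @export
ddg_from_ratio <- function(ratio, ctx = thermo_context()) {
  if (any(ratio <= 0)) stop("ratio must be strictly positive")
  ctx$RT * log(ratio)
}

#' Michaelis-Menten parameters
#'
#' @param kcat turnover number (s^-1), > 0.
#' @param Km Michaelis constant (molar), > 0.
#' @return Object of class \code{"michaelis_params"}.
#' @export
michaelis_params <- function(kcat, Km) {
  if (kcat <= 0 || Km <= 0) stop("kcat and Km must be strictly positive")
  structure(list(kcat = kcat, Km = Km), class = "michaelis_params")
}

#' @export
print.michaelis_params <- function(x, ...) {
  cat(sprintf("Michaelis-Menten: kcat = %.3g s^-1, Km = %.3g M\n", x$kcat, x$Km))
  invisible(x)
}

#' Michaelis-Menten velocity with optional competitive inhibition
#'
#' \deqn{v = \frac{k_{cat} [E] [S]}{K_m (1 + [I]/K_{i,\mathrm{eff}}) + [S]}.}
#' Reduces to the uninhibited Michaelis-Menten rate at \code{competitive_I = 0}.
#'
#' @param mm a [michaelis_params()].
#' @param E free-enzyme concentration (molar).
#' @param S substrate concentration (molar).
#' @param competitive_I competitive inhibitor concentration (molar).
#' @param Ki_eff effective inhibition constant (molar); \code{Inf} disables.
#' @return velocity in molar per second.
#' @export
michaelis_velocity <- function(mm, E, S, competitive_I = 0, Ki_eff = Inf) {
  if (!inherits(mm, "michaelis_params")) stop("mm must be michaelis_params()")
  if (any(E < 0) || any(S < 0) || any(competitive_I < 0))
    stop("concentrations must be >= 0")
  alpha <- if (is.infinite(Ki_eff)) 1 else 1 + competitive_I / Ki_eff
  mm$kcat * E * S / (mm$Km * alpha + S)
}

#' Tabulated report of a kinetic scheme in conventional units
#'
#' Collects every derived quantity of the two-step scheme on the scales in
#' which such parameters are conventionally printed: nM for dissociation
#' constants, 1e-3 / 1e-4 s^-1 scaling for the isomerization rates, minutes
#' for the complex half-life and kcal/mol for the tightening free energy.
#'
#' @param scheme a [kinetic_scheme()].
#' @param ctx a [thermo_context()].
#' @param exact_ln2 passed to [complex_half_life()].
#' @return A named list of class \code{"scheme_report"}.
#' @export
scheme_report <- function(scheme, ctx = thermo_context(), exact_ln2 = FALSE) {
  KI <- ki_initial(scheme)
  KIs <- ki_star(scheme)
  structure(list(
    KI_nM        = 1e9 * KI,
    KIstar_nM    = 1e9 * KIs,
    ratio        = KI / KIs,
    k5_1e3_per_s = 1e3 * scheme$k5,
    k6_1e4_per_s = 1e4 * scheme$k6,
    k4_per_s     = scheme$k4,
    k3_per_M_s   = scheme$k3,
    t_half_min   = complex_half_life(scheme, exact_ln2 = exact_ln2) / 60,
    ddG_kcal_mol = ddg_from_ratio(KI / KIs, ctx),
    temperature_K = ctx$temperature
  ), class = "scheme_report")
}

#' @export
print.scheme_report <- function(x, ...) {
  cat("Derived slow, tight-binding parameters\n")
  cat(sprintf("  K_I        %8.3g nM\n", x$KI_nM))
  cat(sprintf("  K_I*       %8.3g nM\n", x$KIstar_nM))
  cat(sprintf("  K_I/K_I*   %8.3g\n", x$ratio))
  cat(sprintf("  k5         %8.3g x1e-3 s^-1\n", x$k5_1e3_per_s))
  cat(sprintf("  k6         %8.3g x1e-4 s^-1\n", x$k6_1e4_per_s))
  cat(sprintf("  k4         %8.3g s^-1\n", x$k4_per_s))
  cat(sprintf("  t1/2       %8.3g min\n", x$t_half_min))
  cat(sprintf("  ddG(tight) %8.3g kcal/mol at %.2f K\n",
              x$ddG_kcal_mol, x$temperature_K))
  invisible(x)
}

#' Serialize a kinetic scheme (with units) to JSON or YAML
#'
#' @param scheme a [kinetic_scheme()].
#' @param path optional file path; when given the text is also written there.
#' @param format \code{"json"} or \code{"yaml"}.
#' @return The serialized text, invisibly when written to a file.
#' @export
write_scheme <- function(scheme, path = NULL, format = c("json", "yaml")) {
  stop_if_not_scheme(scheme)
  format <- match.arg(format)
  payload <- list(
    kinetic_scheme = list(
      k3 = list(value = scheme$k3, units = "M^-1 s^-1"),
      k4 = list(value = scheme$k4, units = "s^-1"),
      k5 = list(value = scheme$k5, units = "s^-1"),
      k6 = list(value = scheme$k6, units = "s^-1")
    )
  )
  txt <- if (format == "json") {
    as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE))
  } else {
    yaml::as.yaml(payload)
  }
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a kinetic scheme from JSON or YAML written by [write_scheme()]
#'
#' @param path file path.
#' @return a [kinetic_scheme()].
#' @export
read_scheme <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  obj <- if (grepl("^\\s*\\{", txt)) jsonlite::fromJSON(txt) else yaml::yaml.load(txt)
  ks <- obj$kinetic_scheme
  if (is.null(ks)) stop("file does not contain a 'kinetic_scheme' entry")
  val <- function(x) if (is.list(x)) x$value else x
  kinetic_scheme(k3 = val(ks$k3), k4 = val(ks$k4),
                 k5 = val(ks$k5), k6 = val(ks$k6))
}
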