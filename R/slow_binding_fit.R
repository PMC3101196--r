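#' Fit the two-step slow, tight-binding model to progress-curve data
#'
#' The central fitting function of the package.  Takes a long-format table
#' of progress curves recorded at several inhibitor concentrations (the
#' dialect of [read_progress_csv()] / [assay_curves()]) and runs the staged
#' analysis used for slow, tight-binding inhibitors:
#' \enumerate{
#'   \item each curve is fitted with the integrated exponential-burst form
#'     ([fit_progress_curve()]) to extract \eqn{(v_0, v_s, k_{obs})};
#'   \item the \eqn{(I, k_{obs})} series is fitted with the induced-fit
#'     saturation hyperbola ([fit_kobs_saturation()]) for
#'     \eqn{(k_5, k_6, K_{I,\mathrm{app}})}, and the mechanism is classified
#'     against the conformational-selection alternative
#'     ([classify_mechanism()]);
#'   \item optionally (\code{correct_competition = TRUE}) the apparent
#'     encounter constant is corrected for substrate competition,
#'     \eqn{K_I = K_{I,\mathrm{app}}/(1 + S/K_m)}.  Apply this to data from
#'     real competitive assays; the bundled simulator treats substrate
#'     turnover and inhibitor binding as independent (no explicit ES
#'     species), so its output needs no correction;
#'   \item the derived constants follow: \eqn{k_4 = k_3 K_I} at the
#'     diffusion limit, \eqn{K_I^*}, the tightening ratio, the complex
#'     half-life and \eqn{\Delta\Delta G}.
#' }
#'
#' @param data data.frame with columns \code{time_s}, \code{signal},
#'   \code{inhibitor_M}, \code{substrate_M} and optionally
#'   \code{replicate}, \code{preincubated}.
#' @param Km Michaelis constant of the competing substrate (molar); required
#'   when \code{correct_competition} is TRUE.
#' @param correct_competition divide the apparent \eqn{K_I} by
#'   \eqn{1 + S/K_m} (for data from a genuinely competitive assay).
#' @param k3 assumed association rate (M^-1 s^-1), diffusion limit by default.
#' @param alpha significance level for the mechanism trend test.
#' @param ctx a [thermo_context()] for the free-energy report.
#' @return Object of class \code{"slow_binding_fit"} with components
#'   \code{progress_fits}, \code{kobs_series}, \code{saturation},
#'   \code{verdict}, \code{scheme} (a [kinetic_scheme()] when k6 > 0),
#'   \code{report} (a [scheme_report()]) and the call.  Supports
#'   \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{residuals}, \code{plot} and \code{simulate}.
#' @examples
#' sc <- kinetic_scheme(k4 = 140, k5 = 63e-3, k6 = 4e-4)
#' mm <- michaelis_params(kcat = 37, Km = 1e-3)
#' sim <- simulate_assay(sc, mm, assay_design("kobs", seed = 42))
#' fit <- fit_slow_binding(assay_curves(sim), Km = mm$Km)
#' coef(fit)
#' @export
fit_slow_binding <- function(data, Km = NULL, correct_competition = FALSE,
                             k3 = 1e9, alpha = 0.05,
                             ctx = thermo_context()) {
  need <- c("time_s", "signal", "inhibitor_M", "substrate_M")
  if (!all(need %in% names(data)))
    stop("data needs columns ", paste(need, collapse = ", "))
  if (!nrow(data)) stop("data is empty")
  if (is.null(data$replicate)) data$replicate <- 1L
  key <- interaction(data$inhibitor_M, data$replicate, drop = TRUE)
  groups <- split(data, key)
  fits <- lapply(groups, function(g)
    fit_progress_curve(g[order(g$time_s), , drop = FALSE]))
  series <- kobs_series(fits)
  if (nrow(series) < 2) {
    out <- structure(list(progress_fits = fits, kobs_series = series,
                          saturation = NULL, verdict = NULL, scheme = NULL,
                          report = NULL, Km = Km, k3 = k3,
                          note = "single usable inhibitor concentration: saturation analysis skipped",
                          call = match.call()),
                     class = "slow_binding_fit")
    return(out)
  }
  sat <- fit_kobs_saturation(series)
  verdict <- classify_mechanism(series, alpha = alpha)
  S_med <- stats::median(data$substrate_M)
  KI <- sat$KI
  if (correct_competition) {
    if (is.null(Km)) stop("correct_competition = TRUE requires Km")
    KI <- sat$KI / (1 + S_med / Km)
  }
  scheme <- NULL; report <- NULL
  if (sat$k6 > 0 && sat$k5 > 0) {
    scheme <- kinetic_scheme(k3 = k3, k4 = k4_from_KI(KI, k3),
                             k5 = sat$k5, k6 = sat$k6)
    report <- scheme_report(scheme, ctx = ctx)
  }
  structure(list(progress_fits = fits, kobs_series = series,
                 saturation = sat, verdict = verdict, scheme = scheme,
                 report = report, Km = Km, k3 = k3, KI = KI,
                 substrate_M = S_med, note = NULL, call = match.call()),
            class = "slow_binding_fit")
}

#' @export
print.slow_binding_fit <- function(x, ...) {
  cat("Slow, tight-binding kinetic analysis\n")
  cat(sprintf("  %d progress curve(s), %d usable k_obs point(s)\n",
              length(x$progress_fits), nrow(x$kobs_series)))
  if (!is.null(x$note)) {
    cat("  note:", x$note, "\n")
    return(invisible(x))
  }
  print(x$saturation)
  if (!is.null(x$verdict)) cat("  mechanism:", x$verdict$label, "\n")
  if (!is.null(x$report))
    cat(sprintf("  K_I = %.3g nM, K_I* = %.3g nM, t1/2 = %.3g min\n",
                x$report$KI_nM, x$report$KIstar_nM, x$report$t_half_min))
  invisible(x)
}

#' @export
summary.slow_binding_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.slow_binding_fit")
}

#' @export
print.summary.slow_binding_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (!is.null(f$report)) {
    cat("\n")
    print(f$report)
  }
  if (!is.null(f$verdict)) {
    cat("\n")
    print(f$verdict)
  }
  invisible(x)
}

#' @export
coef.slow_binding_fit <- function(object, ...) {
  if (is.null(object$saturation))
    return(c(k5 = NA_real_, k6 = NA_real_, KI = NA_real_))
  out <- c(k5 = object$saturation$k5, k6 = object$saturation$k6,
           KI = object$KI, KI_app = object$saturation$KI)
  if (!is.null(object$scheme))
    out <- c(out, k4 = object$scheme$k4, KIstar = ki_star(object$scheme))
  out
}

#' Predicted k_obs values from a fitted slow-binding model
#'
#' @param object a [fit_slow_binding()] result.
#' @param newdata optional data.frame with \code{inhibitor_M}; defaults to
#'   the observed series.
#' @param ... unused.
#' @return numeric vector of predicted k_obs (s^-1) under the fitted
#'   induced-fit hyperbola (apparent K_I scale, as observed).
#' @export
predict.slow_binding_fit <- function(object, newdata = NULL, ...) {
  if (is.null(object$saturation)) stop("no saturation fit available")
  I <- if (is.null(newdata)) object$kobs_series$inhibitor_M
  else newdata$inhibitor_M
  s <- object$saturation
  s$k6 + s$k5 * I / (s$KI + I)
}

#' @export
residuals.slow_binding_fit <- function(object, ...) {
  if (is.null(object$saturation)) stop("no saturation fit available")
  object$kobs_series$kobs - predict(object)
}

#' Diagnostic plots for a fitted slow-binding model
#'
#' Draws the k_obs saturation plot with the fitted induced-fit hyperbola
#' (and, for comparison, the conformational-selection alternative when
#' available) and the double-reciprocal line.
#'
#' @param x a [fit_slow_binding()] result.
#' @param which \code{"saturation"}, \code{"reciprocal"} or both.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, \code{x}.
#' @export
plot.slow_binding_fit <- function(x, which = c("saturation", "reciprocal"),
                                  ...) {
  if (is.null(x$saturation)) stop("no saturation fit available")
  which <- match.arg(which, several.ok = TRUE)
  s <- x$kobs_series
  if ("saturation" %in% which) {
    graphics::plot(s$inhibitor_M * 1e9, s$kobs, xlab = "[I] (nM)",
                   ylab = expression(k[obs] ~ (s^-1)),
                   main = "k_obs saturation", ...)
    Igrid <- seq(0, max(s$inhibitor_M), length.out = 200)
    graphics::lines(Igrid * 1e9,
                    predict(x, data.frame(inhibitor_M = Igrid)))
  }
  if ("reciprocal" %in% which && is.finite(x$saturation$k6)) {
    rec <- tryCatch(fit_double_reciprocal(s, x$saturation$k6),
                    error = function(e) NULL)
    if (!is.null(rec)) {
      keep <- s$kobs > 10 * x$saturation$k6 & s$inhibitor_M > 0
      graphics::plot(1 / s$inhibitor_M[keep], 1 / s$kobs[keep],
                     xlab = "1/[I] (M^-1)", ylab = "1/kobs (s)",
                     main = "Double-reciprocal")
      graphics::abline(rec$intercept, rec$slope)
    }
  }
  invisible(x)
}

#' Simulate new assays from a fitted slow-binding model
#'
#' Re-simulates progress curves from the fitted kinetic scheme through the
#' ODE assay simulator, enabling parametric-bootstrap style checks.
#'
#' @param object a [fit_slow_binding()] result with a complete scheme.
#' @param nsim number of simulated assays.
#' @param seed master seed for the first simulation (incremented per assay).
#' @param mm a [michaelis_params()]; defaults to kcat 37 s^-1 and the Km
#'   used in fitting (or 1 mM).
#' @param design an [assay_design()]; defaults to the k_obs preset.
#' @param ... unused.
#' @return list of data.frames in the input dialect of [fit_slow_binding()].
#' @export
simulate.slow_binding_fit <- function(object, nsim = 1, seed = 1L,
                                      mm = NULL, design = NULL, ...) {
  if (is.null(object$scheme))
    stop("fitted object has no complete kinetic scheme to simulate from")
  if (is.null(mm))
    mm <- michaelis_params(kcat = 37, Km = object$Km %||% 1e-3)
  lapply(seq_len(nsim), function(i) {
    d <- if (is.null(design)) assay_design("kobs", seed = seed + i - 1L)
    else { design$seed <- as.integer(seed + i - 1L); design }
    assay_curves(simulate_assay(object$scheme, mm, d), replicate = i)
  })
}
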