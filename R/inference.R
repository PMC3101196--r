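#' Read progress curves from CSV
#'
#' Reads the long-format dialect written by the simulator:
#' \code{time_s, signal, inhibitor_M, substrate_M, replicate, preincubated}.
#' Missing \code{replicate}/\code{preincubated} columns are filled with
#' defaults (1, FALSE).
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_progress_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "signal", "inhibitor_M", "substrate_M")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("progress CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(df)) stop("progress CSV is empty")
  if (is.null(df$replicate)) df$replicate <- 1L
  if (is.null(df$preincubated)) df$preincubated <- FALSE
  df
}

#' Fit one slow-binding progress curve
#'
#' Fits the integrated exponential-burst form of a slow-binding progress
#' curve.  The instantaneous velocity
#' \eqn{v_I = v_s + (v_0 - v_s) e^{-k_{obs} t}} integrates to the recorded
#' product signal
#' \deqn{P(t) = P_0 + v_s t + \frac{(v_0 - v_s)(1 - e^{-k_{obs} t})}{k_{obs}},}
#' which is fitted by nonlinear least squares (Levenberg-Marquardt) for the
#' initial velocity \eqn{v_0}, steady-state velocity \eqn{v_s} and observed
#' rate \eqn{k_{obs}}.  Starting values come from the slopes of the first and
#' last deciles of the data and a log-linear transform.  If the curvature is
#' below tolerance (near-linear curve, e.g. no inhibitor) the fit falls back
#' to a straight line and the result is flagged degenerate with
#' \code{kobs = NA} and \code{v0} equal to the slope.
#'
#' @param curve data.frame with strictly increasing \code{time_s} and
#'   nonnegative \code{signal} (>= 8 points); extra columns
#'   (\code{inhibitor_M}, \code{substrate_M}, \code{preincubated}) are
#'   carried through if present.
#' @param curvature_tol relative residual-variance improvement of the burst
#'   model over the straight line below which the curve is declared linear.
#' @return Object of class \code{"progress_fit"}: estimates \code{v0},
#'   \code{vs}, \code{kobs} with standard errors, \code{converged} and
#'   \code{degenerate} flags, the data and fitted values.
#' @export
fit_progress_curve <- function(curve, curvature_tol = 1e-3) {
  if (!all(c("time_s", "signal") %in% names(curve)))
    stop("curve needs columns 'time_s' and 'signal'")
  t <- curve$time_s; y <- curve$signal
  if (length(t) < 8) stop("need at least 8 points per progress curve")
  if (any(diff(t) <= 0)) stop("time_s must be strictly increasing")
  n <- length(t)
  dec <- max(3L, ceiling(n / 10))
  lin <- stats::lm(y ~ t)
  rss_lin <- sum(stats::resid(lin)^2)
  # starting values: early slope, late slope, rate from the mid-velocity time
  v0_0 <- unname(stats::coef(stats::lm(y[1:dec] ~ t[1:dec]))[2])
  vs_0 <- unname(stats::coef(stats::lm(y[(n - dec + 1):n] ~ t[(n - dec + 1):n]))[2])
  if (!is.finite(v0_0)) v0_0 <- unname(stats::coef(lin)[2])
  if (!is.finite(vs_0)) vs_0 <- unname(stats::coef(lin)[2])
  # profiled start for k: the model is linear in (P0, vs, v0 - vs) at fixed
  # k, so scan a log-grid of rates and keep the linear-LS minimiser
  T_obs <- max(t) - min(t)
  kgrid <- 10^seq(log10(0.1 / T_obs), log10(100 / T_obs), length.out = 40)
  rss_k <- vapply(kgrid, function(k) {
    b <- (1 - exp(-k * t)) / k
    sum(stats::resid(stats::lm(y ~ t + b))^2)
  }, 0)
  k_0 <- kgrid[which.min(rss_k)]
  b0 <- (1 - exp(-k_0 * t)) / k_0
  cf0 <- stats::coef(stats::lm(y ~ t + b0))
  if (all(is.finite(cf0))) {
    vs_0 <- unname(cf0[2])
    v0_0 <- unname(cf0[2] + cf0[3])
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ P0 + vs * t + (v0 - vs) * (1 - exp(-k * t)) / k,
      start = list(P0 = y[1], v0 = v0_0, vs = max(vs_0, 0), k = k_0),
      lower = c(-Inf, -Inf, -Inf, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  meta <- list(inhibitor_M = curve$inhibitor_M[1] %||% NA_real_,
               substrate_M = curve$substrate_M[1] %||% NA_real_,
               preincubated = isTRUE(curve$preincubated[1]))
  make <- function(est, se, converged, degenerate, fitted, note = NULL) {
    structure(c(list(v0 = est[["v0"]], vs = est[["vs"]], kobs = est[["kobs"]],
                     se = se, converged = converged, degenerate = degenerate,
                     fitted = fitted, data = curve, note = note), meta),
              class = "progress_fit")
  }
  if (is.null(fit)) {
    se <- c(v0 = suppressWarnings(summary(lin))$coefficients[2, 2],
            vs = NA_real_, kobs = NA_real_)
    return(make(c(v0 = unname(stats::coef(lin)[2]), vs = NA_real_, kobs = NA_real_),
                se, converged = FALSE, degenerate = TRUE,
                fitted = stats::fitted(lin),
                note = "nonlinear fit failed; linear fallback"))
  }
  rss_nl <- sum(stats::resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  # near-linear curve: burst model adds nothing over the straight line
  if (tss > 0 && (rss_lin - rss_nl) / tss < curvature_tol) {
    se <- c(v0 = suppressWarnings(summary(lin))$coefficients[2, 2],
            vs = NA_real_, kobs = NA_real_)
    return(make(c(v0 = unname(stats::coef(lin)[2]), vs = NA_real_, kobs = NA_real_),
                se, converged = TRUE, degenerate = TRUE,
                fitted = stats::fitted(lin),
                note = "curvature below tolerance; kobs not identifiable"))
  }
  cf <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  make(c(v0 = unname(cf["v0"]), vs = unname(cf["vs"]), kobs = unname(cf["k"])),
       c(v0 = sm["v0", 2], vs = sm["vs", 2], kobs = sm["k", 2]),
       converged = TRUE, degenerate = FALSE, fitted = stats::fitted(fit))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.progress_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Progress-curve fit (degenerate/linear): v0 = %.4g M/s", x$v0))
    if (!is.null(x$note)) cat("  [", x$note, "]", sep = "")
    cat("\n")
  } else {
    cat(sprintf("Progress-curve fit: v0 = %.4g, vs = %.4g M/s, kobs = %.4g s^-1 (SE %.2g)\n",
                x$v0, x$vs, x$kobs, x$se[["kobs"]]))
  }
  invisible(x)
}

#' @export
coef.progress_fit <- function(object, ...) {
  c(v0 = object$v0, vs = object$vs, kobs = object$kobs)
}

#' Extract a k_obs series from a set of progress-curve fits
#'
#' @param fits list of [fit_progress_curve()] results.
#' @param drop_degenerate drop curves whose k_obs was unidentifiable.
#' @return data.frame with \code{inhibitor_M}, \code{kobs}, \code{se}.
#' @export
kobs_series <- function(fits, drop_degenerate = TRUE) {
  df <- data.frame(
    inhibitor_M = vapply(fits, function(f) f$inhibitor_M, 0),
    kobs = vapply(fits, function(f) f$kobs, 0),
    se = vapply(fits, function(f) unname(f$se[["kobs"]]), 0))
  if (drop_degenerate) df <- df[is.finite(df$kobs), , drop = FALSE]
  df[order(df$inhibitor_M), , drop = FALSE]
}

check_series <- function(series) {
  if (!all(c("inhibitor_M", "kobs") %in% names(series)))
    stop("series needs columns 'inhibitor_M' and 'kobs'")
  if (any(series$inhibitor_M < 0) || any(series$kobs <= 0))
    stop("series concentrations must be >= 0 and kobs > 0")
}

series_weights <- function(series) {
  if (!is.null(series$se) && all(is.finite(series$se)) && all(series$se > 0))
    1 / series$se^2 else rep(1, nrow(series))
}

#' Fit the induced-fit saturation hyperbola to a k_obs series
#'
#' Weighted nonlinear least squares of
#' \eqn{k_{obs} = k_6 + k_5 [I]/(K_I + [I])}: the intercept estimates the
#' reverse isomerization rate \eqn{k_6}, the asymptote is \eqn{k_5 + k_6}
#' and the midpoint is the (apparent) encounter constant \eqn{K_I}.  Weights
#' are inverse variances from the per-point standard errors when available,
#' else unity.  A series whose overall trend decreases is still fitted but
#' flagged inconsistent with the model.
#'
#' @param series data.frame with \code{inhibitor_M}, \code{kobs} and
#'   optionally \code{se}.
#' @return Object of class \code{"kobs_fit"} with elements \code{k5},
#'   \code{k6}, \code{KI}, their standard errors, \code{decreasing} flag and
#'   the underlying \code{nls} fit.
#' @export
fit_kobs_saturation <- function(series) {
  check_series(series)
  if (nrow(series) < 3) stop("need at least 3 (inhibitor, kobs) points")
  I <- series$inhibitor_M; k <- series$kobs
  w <- series_weights(series)
  decreasing <- stats::cor(I, k, method = "kendall") < 0
  # profiled start: at fixed KI the hyperbola is linear in (k6, k5)
  Ipos <- I[I > 0]
  KIgrid <- 10^seq(log10(min(Ipos) / 30), log10(max(Ipos) * 30),
                   length.out = 60)
  prof <- vapply(KIgrid, function(KI) {
    x <- I / (KI + I)
    fit <- stats::lm(k ~ x, weights = w)
    c(sum(w * stats::resid(fit)^2), stats::coef(fit))
  }, numeric(3))
  best <- which.min(prof[1, ])
  start <- list(k6 = max(prof[2, best], 1e-9),
                k5 = max(prof[3, best], 1e-9), KI = KIgrid[best])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      k ~ k6 + k5 * I / (KI + I), start = start,
      lower = c(0, 1e-12, 1e-12), weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # rank-deficient at the optimum (e.g. unidentifiable KI); keep the
    # constrained profiled solution
    pr <- profile_hyperbola(I, k, w, decreasing = FALSE)
    return(structure(list(k5 = pr$k5, k6 = pr$k6, KI = pr$KI,
                          se = c(k5 = NA_real_, k6 = NA_real_, KI = NA_real_),
                          asymptote = pr$k5 + pr$k6,
                          decreasing = decreasing, series = series,
                          fit = NULL, profiled = TRUE),
                     class = "kobs_fit"))
  }
  cf <- stats::coef(fit); sm <- summary(fit)$coefficients
  structure(list(k5 = unname(cf["k5"]), k6 = unname(cf["k6"]),
                 KI = unname(cf["KI"]),
                 se = c(k5 = sm["k5", 2], k6 = sm["k6", 2], KI = sm["KI", 2]),
                 asymptote = unname(cf["k5"] + cf["k6"]),
                 decreasing = decreasing, series = series, fit = fit),
            class = "kobs_fit")
}

#' @export
print.kobs_fit <- function(x, ...) {
  cat(sprintf("k_obs saturation fit: k5 = %.4g s^-1, k6 = %.4g s^-1, K_I(app) = %.4g M\n",
              x$k5, x$k6, x$KI))
  if (x$decreasing)
    cat("  warning: series decreases with [I] - inconsistent with induced fit\n")
  invisible(x)
}

#' @export
coef.kobs_fit <- function(object, ...) {
  c(k5 = object$k5, k6 = object$k6, KI = object$KI)
}

#' Double-reciprocal diagnostic line for induced-fit kinetics
#'
#' For points with \eqn{k_{obs} \gg k_6} the induced-fit hyperbola
#' linearizes to
#' \deqn{1/k_{obs} = \frac{K_I}{k_5}\frac{1}{[I]} + \frac{1}{k_5},}
#' a straight line in \eqn{1/[I]} whose intercept is \eqn{1/k_5} and whose
#' slope/intercept ratio is \eqn{K_I}.  Only points with
#' \code{kobs > cutoff * k6} enter the regression (default cutoff 10).
#' By default the known intercept rate is subtracted before inverting
#' (\eqn{1/(k_{obs} - k_6)}), which makes the line exact rather than
#' asymptotic; set \code{subtract_k6 = FALSE} for the classical plot of raw
#' reciprocals.
#'
#' @param series data.frame with \code{inhibitor_M} (> 0) and \code{kobs}.
#' @param k6 reverse isomerization rate used for the inclusion cutoff (and
#'   subtracted when \code{subtract_k6}).
#' @param cutoff inclusion multiplier.
#' @param subtract_k6 subtract \code{k6} from \code{kobs} before inverting.
#' @return list of class \code{"reciprocal_fit"}: \code{slope},
#'   \code{intercept}, \code{r_squared}, implied \code{k5} and \code{KI},
#'   points used.
#' @export
fit_double_reciprocal <- function(series, k6, cutoff = 10,
                                  subtract_k6 = TRUE) {
  check_series(series)
  keep <- series$kobs > cutoff * k6 & series$inhibitor_M > 0
  if (sum(keep) < 3)
    stop("fewer than 3 points satisfy kobs > ", cutoff, " * k6")
  x <- 1 / series$inhibitor_M[keep]
  y <- 1 / (series$kobs[keep] - if (subtract_k6) k6 else 0)
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 k5 = 1 / unname(cf[1]), KI = unname(cf[2] / cf[1]),
                 n_used = sum(keep), fit = fit),
            class = "reciprocal_fit")
}

#' @export
print.reciprocal_fit <- function(x, ...) {
  cat(sprintf("1/kobs vs 1/[I]: slope = %.4g, intercept = %.4g (k5 = %.4g s^-1), r^2 = %.4f (n = %d)\n",
              x$slope, x$intercept, x$k5, x$r_squared, x$n_used))
  invisible(x)
}

# Weighted fit of a monotone hyperbolic rate law by profiling: at fixed KI
# the model k6 + k5*x (x = I/(KI+I) rising, or 1/(1+I/KI) falling) is linear
# in (k6, k5); both are constrained nonnegative.  A bounded LM refinement is
# attempted from the best grid point.
profile_hyperbola <- function(I, k, w, decreasing = FALSE) {
  Ipos <- I[I > 0]
  KIgrid <- 10^seq(log10(min(Ipos) / 30), log10(max(Ipos) * 30),
                   length.out = 60)
  eval_at <- function(KI) {
    x <- if (decreasing) 1 / (1 + I / KI) else I / (KI + I)
    fit <- stats::lm(k ~ x, weights = w)
    cf <- stats::coef(fit)
    if (anyNA(cf)) {  # rank-deficient design (x ~ constant at extreme KI)
      k6c <- sum(w * k) / sum(w)
      return(list(rss = sum(w * (k - k6c)^2), k6 = k6c, k5 = 0))
    }
    if (cf[2] < 0 || cf[1] < 0) {
      # clamp to the boundary: nonnegative slope and intercept
      k5c <- max(cf[2], 0)
      k6c <- if (cf[2] < 0) sum(w * k) / sum(w) else max(cf[1], 0)
      if (cf[1] < 0 && cf[2] >= 0) {
        k6c <- 0
        k5c <- max(sum(w * k * x) / sum(w * x^2), 0)
      }
      pred <- k6c + k5c * x
      list(rss = sum(w * (k - pred)^2), k6 = k6c, k5 = k5c)
    } else {
      list(rss = sum(w * stats::resid(fit)^2),
           k6 = unname(cf[1]), k5 = unname(cf[2]))
    }
  }
  prof <- lapply(KIgrid, eval_at)
  best <- which.min(vapply(prof, `[[`, 0, "rss"))
  out <- list(k5 = prof[[best]]$k5, k6 = prof[[best]]$k6, KI = KIgrid[best],
              rss_w = prof[[best]]$rss, decreasing = decreasing)
  refined <- tryCatch({
    form <- if (decreasing) k ~ k6 + k5 / (1 + I / KI)
    else k ~ k6 + k5 * I / (KI + I)
    f <- minpack.lm::nlsLM(form,
                           start = list(k6 = max(out$k6, 1e-9),
                                        k5 = max(out$k5, 1e-9), KI = out$KI),
                           lower = c(0, 0, 1e-12), weights = w,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(f)
    list(k5 = unname(cf["k5"]), k6 = unname(cf["k6"]), KI = unname(cf["KI"]),
         rss_w = sum(w * stats::resid(f)^2), decreasing = decreasing, fit = f)
  }, error = function(e) NULL)
  if (!is.null(refined) && refined$rss_w <= out$rss_w) refined else out
}

#' Classify the binding mechanism from a k_obs series
#'
#' Discriminates the two limiting mechanisms by their opposite k_obs
#' concentration dependence: induced fit predicts a rising saturable
#' hyperbola, conformational selection a falling one.  Both rate laws are
#' fitted, compared by AIC, and the monotone trend is tested by a one-sided
#' Kendall rank correlation in the direction the AIC winner predicts.  The
#' verdict is \code{"ambiguous"} when the two criteria disagree, the trend
#' is not significant at \code{alpha}, or the series spans less than a
#' 10-fold concentration range over at least 5 distinct concentrations.
#'
#' @param series data.frame with \code{inhibitor_M}, \code{kobs},
#'   optional \code{se}.
#' @param alpha significance level for the trend test.
#' @return Object of class \code{"mechanism_verdict"}: \code{label}
#'   (\code{induced_fit}, \code{conformational_selection} or
#'   \code{ambiguous}), trend statistic and p-value, both fits and their
#'   AICs, and a \code{reason} string.
#' @export
classify_mechanism <- function(series, alpha = 0.05) {
  check_series(series)
  I <- series$inhibitor_M; k <- series$kobs
  pos <- I > 0
  distinct <- length(unique(I[pos]))
  span_ok <- distinct >= 5 && max(I[pos]) / min(I[pos]) >= 10
  w <- series_weights(series)
  fit_if <- profile_hyperbola(I, k, w, decreasing = FALSE)
  fit_cs <- profile_hyperbola(I, k, w, decreasing = TRUE)
  # both monotone rate laws have 3 parameters and are fitted under the same
  # weights, so the AIC comparison reduces to the weighted RSS
  n <- length(k)
  aic_if <- n * log(fit_if$rss_w / n) + 6
  aic_cs <- n * log(fit_cs$rss_w / n) + 6
  tau <- suppressWarnings(stats::cor(I, k, method = "kendall"))
  preferred <- if (aic_if <= aic_cs) "induced_fit" else "conformational_selection"
  p_trend <- tryCatch(
    suppressWarnings(stats::cor.test(I, k, method = "kendall",
                                     alternative = "two.sided")$p.value),
    error = function(e) NA_real_)
  trend_sign <- sign(tau)
  agrees <- (preferred == "induced_fit" && trend_sign > 0) ||
    (preferred == "conformational_selection" && trend_sign < 0)
  label <- "ambiguous"
  reason <- NULL
  if (!span_ok) {
    reason <- "inhibitor span too narrow (< 10-fold or < 5 distinct concentrations)"
  } else if (!is.finite(p_trend) || p_trend >= alpha) {
    reason <- "monotone trend not significant"
  } else if (!agrees) {
    reason <- "model comparison and trend sign disagree"
  } else {
    label <- preferred
  }
  winner <- if (label == "induced_fit") fit_if else if
  (label == "conformational_selection") fit_cs else NULL
  structure(list(label = label, tau = tau, p_trend = p_trend,
                 aic = c(induced_fit = aic_if, conformational_selection = aic_cs),
                 fit_induced = fit_if, fit_selection = fit_cs,
                 parameters = if (!is.null(winner))
                   c(k5 = winner$k5, k6 = winner$k6, KI = winner$KI) else NULL,
                 reason = reason, alpha = alpha),
            class = "mechanism_verdict")
}

#' @export
print.mechanism_verdict <- function(x, ...) {
  cat("Mechanism verdict:", x$label, "\n")
  cat(sprintf("  Kendall tau = %.3f (p = %.3g), AIC induced-fit = %.1f vs selection = %.1f\n",
              x$tau, x$p_trend, x$aic[1], x$aic[2]))
  if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Henderson regression for a tight-binding competitive inhibitor
#'
#' Linearizes the equilibrated fractional velocities of a tight-binding
#' titration,
#' \deqn{\frac{[I]}{1 - v_i/v_0} = E_t + K_{I^*\mathrm{app}} \frac{v_0}{v_i},}
#' so that at each substrate level the slope is the apparent dissociation
#' constant and the intercept is the total active enzyme.  The competitive
#' correction \eqn{K_I^* = K_{I^*\mathrm{app}}/(1 + S/K_m)} is applied per
#' substrate level and the corrected values pooled (mean).
#'
#' @param table data.frame with \code{inhibitor_M}, \code{substrate_M} and
#'   \code{fraction} (= vi/v0 in (0, 1]).
#' @param Km Michaelis constant (molar) for the competitive correction.
#' @return Object of class \code{"henderson_fit"}: pooled \code{KIstar} and
#'   \code{Et}, per-level table (slope = KIstar_app, intercept, r^2), rows
#'   used.
#' @export
henderson_fit <- function(table, Km) {
  need <- c("inhibitor_M", "substrate_M", "fraction")
  if (!all(need %in% names(table)))
    stop("table needs columns ", paste(need, collapse = ", "))
  if (any(table$fraction <= 0)) stop("fractional velocities must be positive")
  bad <- table$fraction >= 1 & table$inhibitor_M > 0
  if (any(bad))
    warning(sum(bad), " row(s) with vi >= v0 at [I] > 0 excluded")
  use <- table$inhibitor_M > 0 & table$fraction < 1
  if (!any(use))
    stop("no usable rows: all have [I] = 0 or vi >= v0")
  tab <- table[use, , drop = FALSE]
  levels <- sort(unique(tab$substrate_M))
  per <- do.call(rbind, lapply(levels, function(S) {
    d <- tab[tab$substrate_M == S, , drop = FALSE]
    if (nrow(d) < 2) return(NULL)
    y <- d$inhibitor_M / (1 - d$fraction)
    x <- 1 / d$fraction
    fit <- stats::lm(y ~ x)
    cf <- stats::coef(fit)
    data.frame(substrate_M = S, KIstar_app = unname(cf[2]),
               Et = unname(cf[1]),
               KIstar = unname(cf[2]) / (1 + S / Km),
               r_squared = suppressWarnings(summary(fit)$r.squared), n = nrow(d))
  }))
  if (is.null(per) || !nrow(per))
    stop("no substrate level has >= 2 usable inhibitor points")
  structure(list(KIstar = mean(per$KIstar), Et = mean(per$Et),
                 per_level = per, Km = Km, n_used = nrow(tab)),
            class = "henderson_fit")
}

#' @export
print.henderson_fit <- function(x, ...) {
  cat(sprintf("Henderson tight-binding fit: K_I* = %.4g M, E_t = %.4g M (%d rows, %d substrate level(s))\n",
              x$KIstar, x$Et, x$n_used, nrow(x$per_level)))
  invisible(x)
}

#' Fit Michaelis-Menten parameters from an initial-velocity curve
#'
#' Nonlinear least squares of \eqn{v = V_{max} S/(K_m + S)};
#' \eqn{k_{cat} = V_{max}/[E]}.  Emits a warning when the substrate range
#' does not reach saturation (max S < 2 Km), in which case the confidence
#' intervals are wide.
#'
#' @param S substrate concentrations (molar), >= 5 levels.
#' @param v initial velocities (molar/s).
#' @param E enzyme concentration (molar).
#' @return a [michaelis_params()] with attributes \code{Vmax}, \code{se}
#'   and the \code{nls} fit.
#' @export
fit_michaelis <- function(S, v, E) {
  if (length(S) != length(v)) stop("S and v must have equal length")
  if (length(unique(S)) < 5) stop("need at least 5 substrate levels")
  if (E <= 0) stop("E must be positive")
  fit <- minpack.lm::nlsLM(v ~ Vmax * S / (Km + S),
                           start = list(Vmax = max(v), Km = stats::median(S)),
                           lower = c(1e-30, 1e-30),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit); sm <- summary(fit)$coefficients
  if (max(S) < 2 * cf[["Km"]])
    warning("substrate range does not reach saturation (max S < 2 Km); ",
            "estimates have wide confidence intervals")
  out <- michaelis_params(kcat = cf[["Vmax"]] / E, Km = cf[["Km"]])
  attr(out, "Vmax") <- cf[["Vmax"]]
  attr(out, "se") <- c(Vmax = sm["Vmax", 2], Km = sm["Km", 2])
  attr(out, "fit") <- fit
  out
}
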