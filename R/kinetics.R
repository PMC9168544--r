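# Ferrozine-assay processing and Michaelis-Menten fitting.

#' Molar extinction coefficient of the Fe2+-ferrozine complex at 560 nm
#' (M^-1 cm^-1).
#' @export
FERROZINE_EPSILON_560 <- 25400

#' Convert ferrozine absorbance to Fe2+ concentration
#'
#' Beer-Lambert inversion with the ferrozine complex extinction coefficient
#' (25,400 M^-1 cm^-1 at 560 nm): c(uM) = A560 / (25400 * path) * 1e6.
#' Negative absorbances are flagged and returned as 0 with a warning.
#'
#' @param a560 absorbance at 560 nm (vectorized).
#' @param path_cm cuvette path length in cm (> 0, default 1).
#' @return Fe2+ concentration(s) in uM.
#' @export
fe2_from_absorbance <- function(a560, path_cm = 1) {
  if (any(path_cm <= 0)) stop("path_cm must be > 0")
  neg <- a560 < 0
  if (any(neg)) {
    warning(sum(neg), " negative absorbance value(s) clamped to 0")
    a560[neg] <- 0
  }
  a560 / (FERROZINE_EPSILON_560 * path_cm) * 1e6
}

#' Fe2+ oxidation rate from paired absorbances
#'
#' The enzyme removes Fe2+, so the ferrozine signal drops relative to the
#' no-enzyme control: v = (c_control - c_sample) / time. A sample reading
#' above its control gives a (flagged) rate of 0.
#'
#' @param a560_no_enzyme control absorbance.
#' @param a560_with_enzyme sample absorbance.
#' @param time_min reaction time in minutes (> 0).
#' @param path_cm path length in cm.
#' @return rate(s) in uM min^-1 with logical attribute `"clamped"`.
#' @export
oxidation_rate <- function(a560_no_enzyme, a560_with_enzyme, time_min,
                           path_cm = 1) {
  if (any(time_min <= 0)) stop("time_min must be > 0")
  v <- (fe2_from_absorbance(a560_no_enzyme, path_cm) -
          fe2_from_absorbance(a560_with_enzyme, path_cm)) / time_min
  clamped <- v < 0
  v[clamped] <- 0
  attr(v, "clamped") <- clamped
  v
}

#' Build a rate series
#'
#' @param S substrate concentrations (uM, >= 0).
#' @param v velocities (same length; uM min^-1 or specific activity).
#' @param replicate optional replicate ids.
#' @return data.frame of class `rate_series` with columns S, v, replicate.
#' @export
rate_series <- function(S, v, replicate = 1L) {
  if (length(S) != length(v)) stop("S and v must have equal length")
  if (any(S < 0)) stop("substrate concentrations must be >= 0")
  out <- data.frame(S = as.numeric(S), v = as.numeric(v),
                    replicate = rep_len(replicate, length(S)))
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Subtract background activity, pointwise on a matching substrate grid
#'
#' Controls (e.g. extracts without the enzyme) are subtracted point by
#' point; negative differences are clamped to 0 and flagged.
#'
#' @param v_sample,v_control `rate_series` on identical (S, replicate) grids.
#' @return `rate_series` of differences with attribute `"clamped"`.
#' @export
subtract_background <- function(v_sample, v_control) {
  if (nrow(v_sample) != nrow(v_control) ||
      any(v_sample$S != v_control$S))
    stop("sample and control series must share the same substrate grid")
  diff <- v_sample$v - v_control$v
  clamped <- diff < 0
  diff[clamped] <- 0
  out <- rate_series(v_sample$S, diff, v_sample$replicate)
  attr(out, "clamped") <- clamped
  out
}

# Hanes-Woolf linearization S/v = S/Vmax + Km/Vmax for starting values.
hanes_woolf_start <- function(S, v) {
  use <- S > 0 & v > 0
  if (sum(use) >= 2L) {
    fitlm <- stats::lm(I(S[use] / v[use]) ~ S[use])
    slope <- stats::coef(fitlm)[2]
    intercept <- stats::coef(fitlm)[1]
    vmax0 <- 1 / slope
    km0 <- intercept * vmax0
    if (is.finite(vmax0) && vmax0 > 0 && is.finite(km0) && km0 > 0)
      return(list(km = unname(km0), vmax = unname(vmax0)))
  }
  list(km = max(stats::median(S[S > 0]), 1e-6), vmax = max(v) * 1.2 + 1e-9)
}

#' Fit the Michaelis-Menten equation to a rate series
#'
#' Unweighted nonlinear least squares of v = Vmax * S / (Km + S), pooled
#' over replicates, initialized from a Hanes-Woolf regression and solved by
#' Levenberg-Marquardt with convergence tolerance 1e-8 on the relative
#' parameter change. Standard errors come from the Jacobian at the optimum.
#'
#' @param series a `rate_series` (or data.frame with columns S, v); at
#'   least 3 distinct substrate levels are required, >= 4 spanning the
#'   eventual Km recommended.
#' @return object of class `mm_fit`: list(km_uM, vmax, km_se, vmax_se, rss,
#'   converged, n_points, start).
#' @export
fit_mm <- function(series) {
  S <- series$S
  v <- series$v
  if (length(unique(S)) < 3L)
    stop("need at least 3 distinct substrate levels")
  if (all(v == 0)) stop("all velocities are zero; nothing to fit")
  start <- hanes_woolf_start(S, v)
  dat <- data.frame(S = S, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = dat,
                      start = list(Km = start$km, Vmax = start$vmax),
                      lower = c(Km = 1e-12, Vmax = 1e-12),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ptol = 1e-8, ftol = 1e-12)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(km_uM = NA_real_, vmax = NA_real_,
                          km_se = NA_real_, vmax_se = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          n_points = length(S), start = start,
                          message = conditionMessage(fit)),
                     class = "mm_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Km = NA_real_, Vmax = NA_real_))
  structure(list(km_uM = unname(cf["Km"]), vmax = unname(cf["Vmax"]),
                 km_se = unname(se["Km"]), vmax_se = unname(se["Vmax"]),
                 rss = sum(stats::residuals(fit)^2),
                 converged = fit$convInfo$isConv,
                 n_points = length(S), start = start),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> Km = %.4g uM (SE %.2g), Vmax = %.4g (SE %.2g), RSS %.3g, %s\n",
              x$km_uM, x$km_se, x$vmax, x$vmax_se, x$rss,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Predict Michaelis-Menten velocities from a fit
#'
#' @param object an `mm_fit`.
#' @param newdata optional data.frame with column S (defaults to fitted S
#'   not stored; supply explicitly).
#' @param ... ignored.
#' @return numeric velocities Vmax * S / (Km + S).
#' @export
predict.mm_fit <- function(object, newdata, ...) {
  object$vmax * newdata$S / (object$km_uM + newdata$S)
}

#' Convert an agar trace-element content to medium molarity
#'
#' An element present at `content_ug_per_g` micrograms per gram of dry agar
#' contributes, in a medium of `agar_percent_wv` % w/v (i.e.
#' 10 * agar_percent grams agar per litre),
#' uM = content * (agar_percent * 10) / molar_mass.
#'
#' @param content_ug_per_g element content of the dry agar (ug/g).
#' @param agar_percent_wv agar concentration, % w/v (default 1).
#' @param molar_mass_g_mol element molar mass (g/mol).
#' @return list(uM, uM_2sf): full precision and 2-significant-figure value.
#' @export
medium_micromolar <- function(content_ug_per_g, agar_percent_wv = 1,
                              molar_mass_g_mol) {
  if (molar_mass_g_mol <= 0) stop("molar mass must be > 0")
  if (content_ug_per_g < 0 || agar_percent_wv <= 0)
    stop("content must be >= 0 and agar percentage > 0")
  uM <- content_ug_per_g * (agar_percent_wv * 10) / molar_mass_g_mol
  list(uM = uM, uM_2sf = signif(uM, 2))
}
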