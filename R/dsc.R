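#' Two-state (van't Hoff) excess heat capacity
#'
#' Baseline-subtracted excess heat capacity of a two-state unfolding
#' transition, `Cp_ex(T) = dH_vH^2 / (R T^2) * K / (1 + K)^2` with
#' `K = exp(-dG/RT)` and `dG = dH_vH * (1 - T/Tm)`. The curve is
#' non-negative, peaks at the midpoint, and integrates to the van't
#' Hoff enthalpy. For a sequential three-state transition the package
#' models the trace as the sum of two such independent terms.
#'
#' @param p for `model_kind = "two_state"`: named list with `Tm_C`
#'   (degrees Celsius) and `dH_vH` (kcal mol^-1); for
#'   `"sequential_three_state"`: `Tm1_C`, `dH1`, `Tm2_C`, `dH2`.
#' @param T_C temperature(s) in degrees Celsius.
#' @param model_kind `"two_state"` or `"sequential_three_state"`.
#' @return excess heat capacity in kcal mol^-1 K^-1.
#' @export
dsc_excess_cp <- function(p, T_C, model_kind = c("two_state",
                                                 "sequential_three_state")) {
  model_kind <- match.arg(model_kind)
  p <- as.list(p)
  one <- function(Tm_C, dH) {
    if (dH <= 0) stop("enthalpies must be positive")
    TK <- celsius_to_kelvin(T_C)
    TmK <- celsius_to_kelvin(Tm_C)
    dG <- dH * (1 - TK / TmK)
    K <- exp(-dG / (.R_KCAL * TK))
    dH^2 / (.R_KCAL * TK^2) * K / (1 + K)^2
  }
  switch(model_kind,
    two_state = one(p$Tm_C, p$dH_vH),
    sequential_three_state = one(p$Tm1_C, p$dH1) + one(p$Tm2_C, p$dH2))
}

#' Calorimetric enthalpy by trapezoidal integration
#'
#' @param T_C temperatures, degrees Celsius.
#' @param cp excess heat capacity, kcal mol^-1 K^-1.
#' @return integral of `cp` over `T_C`, kcal mol^-1.
#' @export
dh_calorimetric <- function(T_C, cp) {
  o <- order(T_C)
  T_C <- T_C[o]; cp <- cp[o]
  sum(diff(T_C) * (head(cp, -1) + tail(cp, -1)) / 2)
}

#' Fit a DSC endotherm
#'
#' Fits a baseline-subtracted excess-heat-capacity trace to a two-state
#' or sequential three-state van't Hoff model. Reports per-transition
#' midpoints and van't Hoff enthalpies, the calorimetric enthalpy
#' (trapezoidal integral of the trace), the temperature of the
#' excess-heat-capacity maximum (`Tmax`), and the ratio
#' `dH_vH / dH_cal`, whose closeness to 1 diagnoses a two-state
#' transition.
#'
#' @param trace a [denaturation_curve()] with `probe = "DSC"` and
#'   `axis_kind = "temperature"`: x in degrees Celsius, y the excess
#'   heat capacity in kcal mol^-1 K^-1 after baseline subtraction.
#' @param model_kind `"two_state"` or `"sequential_three_state"`.
#' @param seed seed for jittered restarts.
#' @return a [fit_result()]; `meta` carries `dH_cal`, `Tmax_C` and
#'   `vH_cal_ratio` (total van't Hoff over calorimetric enthalpy).
#' @export
fit_dsc <- function(trace, model_kind = c("two_state",
                                          "sequential_three_state"),
                    seed = 101L) {
  stopifnot(inherits(trace, "denaturation_curve"))
  model_kind <- match.arg(model_kind)
  if (attr(trace, "probe") != "DSC") stop("fit_dsc needs a DSC trace")
  x <- trace$x; y <- trace$y
  peak <- max(y)
  # a systematic negative lobe (integrated undershoot beyond 5% of the
  # positive area) indicates a bad chemical-baseline subtraction;
  # point-wise noise excursions are tolerated
  neg_area <- -dh_calorimetric(x, pmin(y, 0))
  pos_area <- dh_calorimetric(x, pmax(y, 0))
  if (neg_area > 0.05 * pos_area) {
    stop("negative lobe exceeds 5% of the endotherm area: ",
         "check the chemical baseline subtraction")
  }
  dH_cal <- dh_calorimetric(x, y)
  Tmax <- x[which.max(y)]
  # peak height of one transition: dH^2/(4 R Tm^2)
  dH_from_peak <- function(Tm_C, h) {
    2 * celsius_to_kelvin(Tm_C) * sqrt(.R_KCAL * max(h, 1e-12))
  }
  if (model_kind == "two_state") {
    init <- c(Tm_C = Tmax, dH_vH = dH_from_peak(Tmax, peak))
    resid_fn <- function(p) y - dsc_excess_cp(as.list(p), x, "two_state")
    fit <- ls_fit(resid_fn, init, lower = c(Tm_C = -200, dH_vH = 1),
                  seed = seed)
    dH_tot <- fit$par[["dH_vH"]]
  } else {
    # split the trace at the maximum and seed one transition per side
    lo <- x <= Tmax; hi <- x > Tmax
    Tm1 <- if (sum(lo) > 2) sum(x[lo] * y[lo]) / sum(y[lo]) else Tmax - 3
    Tm2 <- if (sum(hi) > 2) sum(x[hi] * y[hi]) / sum(y[hi]) else Tmax + 3
    init <- c(Tm1_C = Tm1, dH1 = dH_from_peak(Tm1, peak / 2),
              Tm2_C = Tm2, dH2 = dH_from_peak(Tm2, peak / 2))
    resid_fn <- function(p) {
      y - dsc_excess_cp(as.list(p), x, "sequential_three_state")
    }
    fit <- ls_fit(resid_fn, init,
                  lower = c(Tm1_C = -200, dH1 = 1, Tm2_C = -200, dH2 = 1),
                  seed = seed)
    if (fit$par[["Tm1_C"]] > fit$par[["Tm2_C"]]) {
      pr <- fit$par
      fit$par[c("Tm1_C", "dH1")] <- pr[c("Tm2_C", "dH2")]
      fit$par[c("Tm2_C", "dH2")] <- pr[c("Tm1_C", "dH1")]
    }
    dH_tot <- fit$par[["dH1"]] + fit$par[["dH2"]]
  }
  se <- rep(NA_real_, length(fit$par)); names(se) <- names(fit$par)
  se[names(fit$stderr)] <- fit$stderr
  fit_result(paste0("dsc_", model_kind), fit$par, se, fit$residuals,
             converged = fit$converged, niter = fit$niter,
             meta = list(dH_cal = dH_cal, Tmax_C = Tmax,
                         dH_vH_total = dH_tot,
                         vH_cal_ratio = dH_tot / dH_cal))
}
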