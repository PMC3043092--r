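#' Gibbs-Helmholtz unfolding free energy
#'
#' Temperature dependence of the unfolding free energy,
#' `dG(T) = dH(Tm) * (1 - T/Tm) + dCp * ((T - Tm) - T * log(T/Tm))`,
#' zero at the midpoint by construction and reducing to the van't Hoff
#' form when the heat-capacity change is zero.
#'
#' @param dH unfolding enthalpy at the midpoint, kcal mol^-1.
#' @param Tm midpoint temperature, K.
#' @param dCp heat-capacity change, kcal mol^-1 K^-1.
#' @param T temperature(s), K.
#' @return free energy in kcal mol^-1 (vectorized over `T`).
#' @export
#' @examples
#' gibbs_helmholtz(100, 350, 0, 340)    # 2.857
#' gibbs_helmholtz(100, 350, 1.2, 340)  # 2.684
gibbs_helmholtz <- function(dH, Tm, dCp, T) {
  if (Tm <= 0 || any(T <= 0)) stop("absolute temperatures must be positive")
  dH * (1 - T / Tm) + dCp * ((T - Tm) - T * log(T / Tm))
}

#' Two-state thermal denaturation signal
#'
#' Observable of a two-state thermal unfolding versus temperature with
#' linear folded and unfolded baselines; the equilibrium constant comes
#' from [gibbs_helmholtz()]. Temperatures are taken in degrees Celsius
#' (instrument convention) and converted to kelvin internally.
#'
#' @param p named list with `Tm_C` (midpoint, degrees Celsius), `dH`
#'   (kcal mol^-1), `dCp` (kcal mol^-1 K^-1), baselines `alpha_N`,
#'   `beta_N`, `alpha_D`, `beta_D` (slopes per degree Celsius).
#' @param T_C temperature(s) in degrees Celsius.
#' @return signal value(s).
#' @export
thermal_signal <- function(p, T_C) {
  p <- as.list(p)
  TK <- celsius_to_kelvin(T_C)
  TmK <- celsius_to_kelvin(p$Tm_C)
  dG <- gibbs_helmholtz(p$dH, TmK, p$dCp, TK)
  K <- exp(-dG / (.R_KCAL * TK))
  XN <- p$alpha_N + p$beta_N * T_C
  XD <- p$alpha_D + p$beta_D * T_C
  (XN + XD * K) / (1 + K)
}

init_thermal <- function(x, y) {
  bn <- edge_baseline(x, y, "low")
  bd <- edge_baseline(x, y, "high")
  XN <- bn["intercept"] + bn["slope"] * x
  XD <- bd["intercept"] + bd["slope"] * x
  f <- (y - XN) / ifelse(XD - XN == 0, 1, XD - XN)
  tm <- half_crossing(x, f)
  i <- which.min(abs(x - tm))
  i <- min(max(i, 2), length(x) - 1)
  slope <- (f[i + 1] - f[i - 1]) / (x[i + 1] - x[i - 1])
  # df/dT at Tm equals dH / (4 R Tm^2)
  TmK <- celsius_to_kelvin(tm)
  dH0 <- abs(slope) * 4 * .R_KCAL * TmK^2
  if (!is.finite(dH0) || dH0 <= 0) dH0 <- 80
  c(alpha_N = unname(bn["intercept"]), beta_N = unname(bn["slope"]),
    alpha_D = unname(bd["intercept"]), beta_D = unname(bd["slope"]),
    Tm_C = tm, dH = dH0)
}

#' Fit the thermal denaturation model
#'
#' Gibbs-Helmholtz two-state fit of a temperature-axis curve. The
#' heat-capacity change can be fitted freely or fixed (the usual
#' standard value is 1.2 kcal mol^-1 K^-1); on well-sampled data the
#' fitted midpoint is insensitive to that choice. The midpoint is
#' reported in degrees Celsius; the entropy at the midpoint,
#' `dS(Tm) = dH(Tm)/Tm`, is returned in `meta`.
#'
#' @param curve a [denaturation_curve()] with `axis_kind =
#'   "temperature"` (x in degrees Celsius) and at least 8 points.
#' @param dCp_mode `"free"` or `"fixed"`.
#' @param dCp_fixed value used when `dCp_mode = "fixed"`
#'   (kcal mol^-1 K^-1).
#' @param init optional named starting values.
#' @param seed seed for jittered restarts.
#' @return a [fit_result()] with estimates `alpha_N`, `beta_N`,
#'   `alpha_D`, `beta_D`, `Tm_C`, `dH` (and `dCp` when free). A
#'   midpoint outside the scanned range is flagged
#'   `"extrapolated_midpoint"`; a curve with no upper baseline is
#'   flagged `"no_upper_baseline"`.
#' @export
fit_thermal <- function(curve, dCp_mode = c("fixed", "free"),
                        dCp_fixed = 1.2, init = NULL, seed = 101L) {
  stopifnot(inherits(curve, "denaturation_curve"))
  dCp_mode <- match.arg(dCp_mode)
  if (attr(curve, "axis_kind") != "temperature") {
    stop("fit_thermal needs a temperature-axis curve")
  }
  x <- curve$x; y <- curve$y
  if (length(x) < 8) stop("need at least 8 points")
  if (is.null(init)) init <- init_thermal(x, y)
  if (dCp_mode == "free") {
    init <- c(init, dCp = dCp_fixed)
    fixed <- numeric()
  } else {
    fixed <- c(dCp = dCp_fixed)
    init <- c(init, dCp = dCp_fixed)
  }
  resid_fn <- function(p) y - thermal_signal(as.list(p), x)
  lower <- c(Tm_C = -200, dH = 1e-3, dCp = -5)
  fit <- ls_fit(resid_fn, init, fixed = fixed, lower = lower, seed = seed)
  flags <- character()
  tm <- fit$par[["Tm_C"]]
  if (tm < min(x) || tm > max(x)) flags <- c(flags, "extrapolated_midpoint")
  # transition width in degrees: ~ 4RTm^2/dH
  width <- 4 * .R_KCAL * celsius_to_kelvin(tm)^2 / fit$par[["dH"]]
  if (sum(x > tm + width / 2) < 2) {
    flags <- c(flags, "no_upper_baseline")
    warning("no post-transition baseline: fitted Tm/dH unreliable")
  }
  se <- rep(NA_real_, length(fit$par)); names(se) <- names(fit$par)
  se[names(fit$stderr)] <- fit$stderr
  TmK <- celsius_to_kelvin(tm)
  fit_result("thermal_two_state", fit$par, se, fit$residuals,
             converged = fit$converged, niter = fit$niter,
             fixed = fixed, flags = flags,
             meta = list(dCp_mode = dCp_mode,
                         dS_Tm = fit$par[["dH"]] / TmK,
                         equilibrium_model = TRUE,
                         reversibility_caveat = paste(
                           "equilibrium fit; check scan reversibility",
                           "before interpreting dH and dS")))
}
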