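#' Single-transition pH titration signal
#'
#' Henderson-Hasselbalch base-10 sigmoid with an optional Hill
#' coefficient: `y = y_low + (y_high - y_low) / (1 + 10^(n*(pKa - pH)))`.
#' At `pH = pKa` the signal is exactly midway between the plateaus.
#'
#' @param p named list with `pKa`, `y_low`, `y_high`, optional `hill_n`
#'   (default 1; must lie in (0, 4]).
#' @param pH pH value(s).
#' @return signal value(s).
#' @export
#' @examples
#' single_pka_signal(list(pKa = 6.3, y_low = 0, y_high = 1), 7.3) # 0.909
single_pka_signal <- function(p, pH) {
  p <- as.list(p)
  n <- if (is.null(p$hill_n)) 1 else p$hill_n
  if (n <= 0 || n > 4) stop("hill_n must lie in (0, 4]")
  p$y_low + (p$y_high - p$y_low) / (1 + 10^(n * (p$pKa - pH)))
}

#' Bell-shaped double-transition pH signal
#'
#' Sum of two base-10 sigmoids with independent signed amplitudes:
#' `y = y0 + A1/(1 + 10^(pKa1 - pH)) + A2/(1 + 10^(pKa2 - pH))`.
#' Opposite-sign amplitudes produce the "bump" seen in dye-binding
#' titrations; with `A2 = 0` the model reduces exactly to the single
#' transition.
#'
#' @param p named list with `y0`, `A1`, `pKa1`, `A2`, `pKa2`
#'   (convention `pKa1 < pKa2`).
#' @param pH pH value(s).
#' @return signal value(s).
#' @export
bell_signal <- function(p, pH) {
  p <- as.list(p)
  p$y0 + p$A1 / (1 + 10^(p$pKa1 - pH)) + p$A2 / (1 + 10^(p$pKa2 - pH))
}

# plateau support: points beyond +/- 1 pH unit from the midpoint
plateau_support <- function(pH, pKa) {
  c(acid = sum(pH < pKa - 1), base = sum(pH > pKa + 1))
}

#' Fit a single-pKa titration
#'
#' Fits [single_pka_signal()] to a pH-axis curve. Mirroring standard
#' practice of withholding a pKa when a baseline is missing, the fit is
#' marked unreliable when either plateau is supported by fewer than 2
#' points or when a fitted plateau's standard error exceeds half the
#' amplitude; the verdict is recorded in `meta$reliability` as one of
#' `"reliable"`, `"no_acid_baseline"`, `"no_base_baseline"`,
#' `"unidentifiable"`.
#'
#' @param curve a [denaturation_curve()] with `axis_kind = "pH"` and at
#'   least 6 points.
#' @param hill logical: fit a Hill coefficient (default `FALSE`, n
#'   pinned to 1).
#' @param seed seed for jittered restarts.
#' @return a [fit_result()] with `pKa`, `y_low`, `y_high` (and
#'   `hill_n` when `hill = TRUE`).
#' @export
fit_single_pka <- function(curve, hill = FALSE, seed = 101L) {
  stopifnot(inherits(curve, "denaturation_curve"))
  if (attr(curve, "axis_kind") != "pH") stop("fit_single_pka needs a pH axis")
  x <- curve$x; y <- curve$y
  if (length(x) < 6) stop("need at least 6 points")
  ylo <- mean(y[x <= sort(x)[2]])
  yhi <- mean(y[x >= sort(x, decreasing = TRUE)[2]])
  f <- (y - ylo) / ifelse(yhi - ylo == 0, 1, yhi - ylo)
  pka0 <- half_crossing(x, f)
  init <- c(pKa = pka0, y_low = ylo, y_high = yhi)
  fixed <- c(hill_n = 1)
  if (hill) {
    init <- c(init, hill_n = 1)
    fixed <- numeric()
  }
  resid_fn <- function(p) y - single_pka_signal(as.list(p), x)
  fit <- ls_fit(resid_fn, init, fixed = fixed,
                lower = c(pKa = 0.5, hill_n = 0.05),
                upper = c(pKa = 13.5, hill_n = 4), seed = seed)
  par <- fit$par
  se <- rep(NA_real_, length(par)); names(se) <- names(par)
  se[names(fit$stderr)] <- fit$stderr
  sup <- plateau_support(x, par[["pKa"]])
  amp <- abs(par[["y_high"]] - par[["y_low"]])
  verdict <- "reliable"
  flags <- character()
  if (sup["acid"] < 2 ||
      (!is.na(se["y_low"]) && se[["y_low"]] > 0.5 * amp)) {
    verdict <- "no_acid_baseline"; flags <- "missing_baseline"
  } else if (sup["base"] < 2 ||
             (!is.na(se["y_high"]) && se[["y_high"]] > 0.5 * amp)) {
    verdict <- "no_base_baseline"; flags <- "missing_baseline"
  }
  if (!fit$converged) verdict <- "unidentifiable"
  fit_result("single_pka", par, se, fit$residuals,
             converged = fit$converged, niter = fit$niter, fixed = fixed,
             flags = flags, meta = list(reliability = verdict,
                                        plateau_support = sup))
}

#' Fit a bell-shaped double-pKa titration
#'
#' Fits [bell_signal()] to a pH-axis curve with at least 9 points
#' spanning both transitions. Midpoints are reported ordered
#' (`pKa1 < pKa2`); amplitudes keep their sign. Transitions closer
#' than 0.5 pH units trigger an identifiability warning.
#'
#' @param curve a [denaturation_curve()] with `axis_kind = "pH"`.
#' @param init optional named starting values (`y0`, `A1`, `pKa1`,
#'   `A2`, `pKa2`).
#' @param seed seed for jittered restarts.
#' @return a [fit_result()] with `meta$reliability` as in
#'   [fit_single_pka()].
#' @export
fit_double_pka <- function(curve, init = NULL, seed = 101L) {
  stopifnot(inherits(curve, "denaturation_curve"))
  if (attr(curve, "axis_kind") != "pH") stop("fit_double_pka needs a pH axis")
  x <- curve$x; y <- curve$y
  if (length(x) < 9) stop("need at least 9 points")
  if (is.null(init)) {
    # bump heuristics: extremum of the detrended signal locates the
    # region between the two midpoints
    y0 <- y[which.min(x)]
    detr <- y - approx(range(x), y[c(which.min(x), which.max(x))],
                       xout = x)$y
    xb <- x[which.max(abs(detr))]
    amp <- max(abs(detr)) * 2 * sign(detr[which.max(abs(detr))])
    init <- c(y0 = y0, A1 = amp, pKa1 = xb - 1, A2 = (y[which.max(x)] -
              y0) - amp, pKa2 = xb + 1)
  }
  resid_fn <- function(p) y - bell_signal(as.list(p), x)
  fit <- ls_fit(resid_fn, init,
                lower = c(pKa1 = 0.5, pKa2 = 0.5),
                upper = c(pKa1 = 13.5, pKa2 = 13.5), seed = seed)
  par <- fit$par
  if (par[["pKa1"]] > par[["pKa2"]]) {
    pr <- par
    par[c("pKa1", "A1")] <- pr[c("pKa2", "A2")]
    par[c("pKa2", "A2")] <- pr[c("pKa1", "A1")]
  }
  flags <- character()
  verdict <- "reliable"
  if (par[["pKa2"]] - par[["pKa1"]] < 0.5) {
    flags <- c(flags, "close_transitions")
    verdict <- "unidentifiable"
    warning("fitted pKas are closer than 0.5 pH units: ",
            "the two transitions may not be identifiable")
  }
  if (!fit$converged) verdict <- "unidentifiable"
  se <- rep(NA_real_, length(par)); names(se) <- names(par)
  se[names(fit$stderr)] <- fit$stderr
  fit_result("double_pka", par, se, fit$residuals,
             converged = fit$converged, niter = fit$niter,
             flags = flags, meta = list(reliability = verdict))
}
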