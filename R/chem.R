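#' Linear extrapolation model free energy
#'
#' Unfolding free energy under the linear extrapolation model (LEM),
#' `dG = m * (U50 - U)`: linear in denaturant concentration, zero at
#' the transition midpoint, and equal to `m * U50` in water.
#'
#' @param m m-value, kcal mol^-1 M^-1 (> 0).
#' @param U50 midpoint denaturant concentration, M.
#' @param U denaturant concentration(s), M.
#' @return free energy in kcal mol^-1 (vectorized over `U`).
#' @export
#' @examples
#' lem_free_energy(2.3, 3.19, 0)  # 7.337 kcal/mol in water
lem_free_energy <- function(m, U50, U) {
  if (m <= 0) stop("m must be positive")
  m * (U50 - U)
}

#' Two-state chemical denaturation signal
#'
#' Observable of a two-state N <-> U equilibrium versus denaturant,
#' with linear native and denatured baselines:
#' `X(U) = (X_N + X_D * exp(-dG/RT)) / (1 + exp(-dG/RT))`,
#' `X_N = alpha_N + beta_N * U`, `X_D = alpha_D + beta_D * U`,
#' `dG = m * (U50 - U)`. At `U = U50` the unfolded fraction is exactly
#' one half.
#'
#' @param p named list or vector with `alpha_N`, `beta_N`, `alpha_D`,
#'   `beta_D`, `m`, `U50`, and optionally `T` (K, default 298.15).
#' @param U denaturant concentration(s), M.
#' @return signal value(s).
#' @export
#' @examples
#' p <- list(alpha_N = 1, beta_N = 0, alpha_D = 0, beta_D = 0,
#'           m = 2.3, U50 = 3.19)
#' two_state_chem_signal(p, 3.19)  # 0.5
two_state_chem_signal <- function(p, U) {
  p <- as.list(p)
  T <- if (is.null(p$T)) 298.15 else p$T
  dG <- p$m * (p$U50 - U)
  K <- exp(-dG / (.R_KCAL * T))
  XN <- p$alpha_N + p$beta_N * U
  XD <- p$alpha_D + p$beta_D * U
  (XN + XD * K) / (1 + K)
}

#' Apparent unfolded fraction of a two-state chemical transition
#' @inheritParams two_state_chem_signal
#' @return fraction unfolded in `[0, 1]`.
#' @export
two_state_unfolded_fraction <- function(p, U) {
  p <- as.list(p)
  T <- if (is.null(p$T)) 298.15 else p$T
  K <- exp(-p$m * (p$U50 - U) / (.R_KCAL * T))
  K / (1 + K)
}

#' Three-state chemical denaturation signal
#'
#' Sequential N <-> I <-> U model with a constant intermediate signal
#' level `alpha_I`:
#' `X(U) = (X_N + alpha_I*K1 + X_D*K1*K2) / (1 + K1 + K1*K2)`,
#' `K_i = exp(-m_i (U50_i - U) / RT)`. The three Boltzmann population
#' weights sum to one at every concentration.
#'
#' @param p named list with baselines `alpha_N`, `beta_N`, `alpha_D`,
#'   `beta_D`, intermediate level `alpha_I`, and `m1`, `U50_1`, `m2`,
#'   `U50_2` (convention `U50_1 <= U50_2`), optional `T` (K).
#' @param U denaturant concentration(s), M.
#' @return signal value(s).
#' @export
three_state_chem_signal <- function(p, U) {
  p <- as.list(p)
  T <- if (is.null(p$T)) 298.15 else p$T
  RT <- .R_KCAL * T
  K1 <- exp(-p$m1 * (p$U50_1 - U) / RT)
  K2 <- exp(-p$m2 * (p$U50_2 - U) / RT)
  XN <- p$alpha_N + p$beta_N * U
  XD <- p$alpha_D + p$beta_D * U
  (XN + p$alpha_I * K1 + XD * K1 * K2) / (1 + K1 + K1 * K2)
}

#' State populations of the three-state chemical model
#' @inheritParams three_state_chem_signal
#' @return data frame with columns `U`, `N`, `I`, `D` (fractions).
#' @export
three_state_populations <- function(p, U) {
  p <- as.list(p)
  T <- if (is.null(p$T)) 298.15 else p$T
  RT <- .R_KCAL * T
  K1 <- exp(-p$m1 * (p$U50_1 - U) / RT)
  K2 <- exp(-p$m2 * (p$U50_2 - U) / RT)
  Z <- 1 + K1 + K1 * K2
  data.frame(U = U, N = 1 / Z, I = K1 / Z, D = K1 * K2 / Z)
}

# Heuristic starting values for a two-state chemical fit.
init_two_state_chem <- function(x, y, T) {
  bn <- edge_baseline(x, y, "low")
  bd <- edge_baseline(x, y, "high")
  XN <- bn["intercept"] + bn["slope"] * x
  XD <- bd["intercept"] + bd["slope"] * x
  f <- (y - XN) / ifelse(XD - XN == 0, 1, XD - XN)
  u50 <- half_crossing(x, f)
  # df/dU at the midpoint equals m / (4RT)
  i <- which.min(abs(x - u50))
  i <- min(max(i, 2), length(x) - 1)
  slope <- (f[i + 1] - f[i - 1]) / (x[i + 1] - x[i - 1])
  m0 <- abs(slope) * 4 * .R_KCAL * T
  if (!is.finite(m0) || m0 <= 0) m0 <- 1
  c(alpha_N = unname(bn["intercept"]), beta_N = unname(bn["slope"]),
    alpha_D = unname(bd["intercept"]), beta_D = unname(bd["slope"]),
    m = m0, U50 = u50)
}

#' Fit the two-state chemical denaturation model
#'
#' Nonlinear least-squares fit of [two_state_chem_signal()] to a
#' denaturant-axis curve, with self-chosen starting values (baselines
#' from the outer 20% of the concentration range, midpoint from the
#' half-amplitude crossing, m-value from the midpoint slope) and five
#' seeded jittered restarts; the lowest-SSR solution is kept.
#'
#' @param curve a [denaturation_curve()] with `axis_kind = "denaturant"`
#'   and at least 7 points.
#' @param fixed optional named vector of pinned parameters.
#' @param init optional named vector of starting values (as in
#'   [two_state_chem_signal()]).
#' @param T fit temperature in K (default 298.15).
#' @param seed seed for the jittered restarts.
#' @return a [fit_result()] with estimates `alpha_N`, `beta_N`,
#'   `alpha_D`, `beta_D`, `m`, `U50` and, in `meta`, `dG_water = m*U50`.
#'   A curve without points beyond the transition triggers a
#'   `"no_upper_baseline"` flag and warning.
#' @export
fit_two_state_chem <- function(curve, fixed = NULL, init = NULL,
                               T = 298.15, seed = 101L) {
  stopifnot(inherits(curve, "denaturation_curve"))
  if (attr(curve, "axis_kind") != "denaturant") {
    stop("fit_two_state_chem needs a denaturant-axis curve")
  }
  x <- curve$x; y <- curve$y
  if (length(x) < 7) stop("need at least 7 points to fit 6 parameters")
  if (is.null(init)) init <- init_two_state_chem(x, y, T)
  fixed <- if (is.null(fixed)) numeric() else fixed
  resid_fn <- function(p) {
    y - two_state_chem_signal(c(as.list(p), T = T), x)
  }
  lower <- c(alpha_N = -Inf, beta_N = -Inf, alpha_D = -Inf,
             beta_D = -Inf, m = 1e-6, U50 = 0)
  fit <- ls_fit(resid_fn, init, fixed = fixed, lower = lower, seed = seed)
  flags <- character()
  # unreliable denatured baseline: fewer than 2 points past the
  # fitted midpoint plus ~ 1 transition width
  width <- 2 * .R_KCAL * T / fit$par[["m"]]
  if (sum(x > fit$par[["U50"]] + width) < 2) {
    flags <- c(flags, "no_upper_baseline")
    warning("few points beyond the transition: denatured baseline ",
            "(and hence m) may be unreliable")
  }
  se <- rep(NA_real_, length(fit$par)); names(se) <- names(fit$par)
  se[names(fit$stderr)] <- fit$stderr
  fit_result("two_state_chem", fit$par, se, fit$residuals,
             converged = fit$converged, niter = fit$niter,
             fixed = fixed, flags = flags,
             meta = list(T = T,
                         dG_water = fit$par[["m"]] * fit$par[["U50"]],
                         equilibrium_model = TRUE,
                         reversibility_caveat = paste(
                           "equilibrium two-state fit; parameters are",
                           "thermodynamic only if unfolding is reversible")))
}

#' Fit the three-state chemical denaturation model
#'
#' Fits the sequential N <-> I <-> U model to one curve, or jointly to
#' a pair of curves from different probes sharing the thermodynamic
#' parameters (`m1`, `U50_1`, `m2`, `U50_2`) while keeping per-probe
#' baselines and intermediate levels. Midpoints are reported ordered
#' (`U50_1 <= U50_2`). When the fitted intermediate never exceeds 5%
#' population the result is flagged `"low_intermediate_population"`
#' and a two-state description is recommended.
#'
#' @param curves a single [denaturation_curve()] or a list of two
#'   (denaturant axis).
#' @param init optional named starting values for the shared
#'   thermodynamic parameters (`m1`, `U50_1`, `m2`, `U50_2`).
#' @param T fit temperature in K.
#' @param seed seed for the jittered restarts.
#' @return a [fit_result()]; for a joint fit the per-curve parameters
#'   are suffixed `.1`, `.2`.
#' @export
fit_three_state_chem <- function(curves, init = NULL, T = 298.15,
                                 seed = 101L) {
  if (inherits(curves, "denaturation_curve")) curves <- list(curves)
  stopifnot(all(vapply(curves, inherits, logical(1), "denaturation_curve")))
  if (any(vapply(curves, function(cv) attr(cv, "axis_kind"),
                 character(1)) != "denaturant")) {
    stop("fit_three_state_chem needs denaturant-axis curves")
  }
  npts <- sum(vapply(curves, nrow, integer(1)))
  if (npts < 11) stop("need at least 11 points for a three-state fit")

  nc <- length(curves)
  # shared thermodynamics
  if (is.null(init)) {
    i2 <- lapply(curves, function(cv) init_two_state_chem(cv$x, cv$y, T))
    u50s <- sort(vapply(i2, function(p) p[["U50"]], numeric(1)))
    ms <- vapply(i2, function(p) p[["m"]], numeric(1))
    if (nc == 1) {
      u0 <- u50s[1]
      init <- c(m1 = ms[1], U50_1 = max(0.1, u0 * 0.7),
                m2 = ms[1], U50_2 = u0 * 1.3)
    } else {
      init <- c(m1 = ms[1], U50_1 = u50s[1], m2 = ms[nc], U50_2 = u50s[nc])
    }
  }
  per <- list()
  for (i in seq_len(nc)) {
    p0 <- init_two_state_chem(curves[[i]]$x, curves[[i]]$y, T)
    per[[i]] <- c(p0[c("alpha_N", "beta_N", "alpha_D", "beta_D")],
                  alpha_I = unname((p0[["alpha_N"]] + p0[["alpha_D"]]) / 2))
    names(per[[i]]) <- paste0(c("alpha_N", "beta_N", "alpha_D", "beta_D",
                                "alpha_I"), ".", i)
  }
  start <- c(init, unlist(per))

  model_curve <- function(p, i, x) {
    pi <- list(alpha_N = p[[paste0("alpha_N.", i)]],
               beta_N = p[[paste0("beta_N.", i)]],
               alpha_D = p[[paste0("alpha_D.", i)]],
               beta_D = p[[paste0("beta_D.", i)]],
               alpha_I = p[[paste0("alpha_I.", i)]],
               m1 = p[["m1"]], U50_1 = p[["U50_1"]],
               m2 = p[["m2"]], U50_2 = p[["U50_2"]], T = T)
    three_state_chem_signal(pi, x)
  }
  resid_fn <- function(p) {
    p <- as.list(p)
    unlist(lapply(seq_len(nc), function(i) {
      curves[[i]]$y - model_curve(p, i, curves[[i]]$x)
    }))
  }
  lower <- c(m1 = 1e-6, U50_1 = 0, m2 = 1e-6, U50_2 = 0)
  fit <- ls_fit(resid_fn, start, lower = lower, seed = seed)
  par <- fit$par
  # enforce transition ordering by convention
  if (par[["U50_1"]] > par[["U50_2"]]) {
    tmp <- par[c("m1", "U50_1")]
    par[c("m1", "U50_1")] <- par[c("m2", "U50_2")]
    par[c("m2", "U50_2")] <- tmp
  }
  flags <- character()
  grid <- seq(0, 7, by = 0.01)
  pops <- three_state_populations(
    c(as.list(par[c("m1", "U50_1", "m2", "U50_2")]), T = T), grid)
  max_I <- max(pops$I)
  if (max_I < 0.05) {
    flags <- c(flags, "low_intermediate_population")
  }
  # model selection against the nested two-state description: if a
  # plain two-state fit explains a single curve essentially as well,
  # the intermediate is not identifiable from these data
  if (nc == 1 && nrow(curves[[1]]) >= 7) {
    f2 <- try(suppressWarnings(
      fit_two_state_chem(curves[[1]], T = T, seed = seed)), silent = TRUE)
    if (!inherits(f2, "try-error") &&
        f2$ssr <= 1.05 * sum(fit$residuals^2) + 1e-12) {
      flags <- c(flags, "intermediate_not_required")
    }
  }
  recommend_two_state <- max_I < 0.05 ||
    "intermediate_not_required" %in% flags
  se <- rep(NA_real_, length(par)); names(se) <- names(par)
  se[names(fit$stderr)] <- fit$stderr
  fit_result("three_state_chem", par, se, fit$residuals,
             converged = fit$converged, niter = fit$niter,
             flags = flags,
             meta = list(T = T, n_curves = nc, max_intermediate = max_I,
                         recommend_two_state = recommend_two_state))
}

#' Brute-force grid-search fit of the two-state chemical model
#'
#' Independent reference fit: for each candidate `(m, U50)` pair on a
#' refined grid, the unfolded-fraction profile is fixed and the four
#' baseline parameters become a linear least-squares problem, solved
#' exactly; the pair with the lowest SSR wins. A coarse pass (step 0.1)
#' over the full range is refined to an exhaustive local grid at the
#' requested step. Slow but free of nonlinear-optimizer failure modes,
#' so it serves as an oracle for [fit_two_state_chem()].
#'
#' @param curve denaturant-axis [denaturation_curve()].
#' @param m_range,U50_range numeric length-2 search ranges.
#' @param step final grid step for both parameters.
#' @param T temperature in K.
#' @return list with `m`, `U50`, baseline vector, and `ssr`.
#' @export
grid_search_two_state <- function(curve, m_range = c(0.2, 6),
                                  U50_range = NULL, step = 0.01,
                                  T = 298.15) {
  stopifnot(inherits(curve, "denaturation_curve"))
  x <- curve$x; y <- curve$y
  if (is.null(U50_range)) U50_range <- range(x)
  RT <- .R_KCAL * T
  eval_grid <- function(ms, us) {
    best <- list(ssr = Inf)
    for (m in ms) for (u in us) {
      f <- 1 / (1 + exp(m * (u - x) / RT))
      A <- cbind((1 - f), (1 - f) * x, f, f * x)
      ls <- tryCatch(qr.solve(A, y), error = function(e) NULL)
      if (is.null(ls)) next
      r <- y - A %*% ls
      ssr <- sum(r^2)
      if (ssr < best$ssr) {
        best <- list(m = m, U50 = u,
                     baselines = c(alpha_N = ls[1], beta_N = ls[2],
                                   alpha_D = ls[3], beta_D = ls[4]),
                     ssr = ssr)
      }
    }
    best
  }
  coarse <- eval_grid(seq(m_range[1], m_range[2], by = 0.1),
                      seq(U50_range[1], U50_range[2], by = 0.1))
  fine <- eval_grid(
    seq(max(m_range[1], coarse$m - 0.15), min(m_range[2], coarse$m + 0.15),
        by = step),
    seq(max(U50_range[1], coarse$U50 - 0.15),
        min(U50_range[2], coarse$U50 + 0.15), by = step))
  fine
}
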