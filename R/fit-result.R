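#' Fit result container
#'
#' All model-fitting functions in the package return a `fit_result`:
#' parameter estimates with standard errors, the residual vector, the
#' sum of squared residuals, a convergence flag, iteration count, the
#' record of any fixed (pinned) parameters, and qualitative flags such
#' as `"no_upper_baseline"` or `"low_intermediate_population"`.
#'
#' @param model character model identifier.
#' @param estimates named numeric vector of parameter estimates.
#' @param stderr named numeric vector of standard errors (same names).
#' @param residuals numeric residual vector (data minus model).
#' @param converged logical convergence status.
#' @param niter number of iterations used.
#' @param fixed named numeric vector of pinned parameters (may be empty).
#' @param flags character vector of diagnostic flags.
#' @param meta list of extra metadata (derived quantities, reversibility
#'   caveats, reliability verdicts).
#' @return an object of class `fit_result`.
#' @export
fit_result <- function(model, estimates, stderr = NULL, residuals = numeric(),
                       converged = TRUE, niter = NA_integer_,
                       fixed = numeric(), flags = character(),
                       meta = list()) {
  if (is.null(stderr)) {
    stderr <- rep(NA_real_, length(estimates))
    names(stderr) <- names(estimates)
  }
  stopifnot(length(stderr) == length(estimates))
  if (any(!is.na(stderr) & stderr < 0)) {
    stop("standard errors must be non-negative")
  }
  structure(
    list(model = model, estimates = estimates, stderr = stderr,
         residuals = residuals, ssr = sum(residuals^2),
         converged = isTRUE(converged), niter = as.integer(niter),
         fixed = fixed, flags = flags, meta = meta),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> model:", x$model,
      if (!x$converged) "[NOT CONVERGED]" else "", "\n")
  tab <- data.frame(estimate = x$estimates, std.error = x$stderr)
  print(round(tab, 4))
  if (length(x$fixed)) {
    cat("fixed:", paste(names(x$fixed), signif(x$fixed, 4),
                        sep = "=", collapse = ", "), "\n")
  }
  cat("SSR:", format(x$ssr, digits = 6), " n:", length(x$residuals),
      " iter:", x$niter, "\n")
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.fit_result <- function(object, ...) object$estimates

# Numerical Jacobian of a residual function by central differences.
num_jacobian <- function(fn, par, eps = 1e-6) {
  r0 <- fn(par)
  J <- matrix(0, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(1, abs(par[j]))
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    J[, j] <- (fn(up) - fn(dn)) / (2 * h)
  }
  colnames(J) <- names(par)
  J
}

# Damped least squares with jittered restarts.
#
# resid_fn(par) returns the residual vector (data - model). Fixed
# parameters are pinned by name. Convergence follows the package-wide
# contract: relative SSR change below `ftol` or `maxiter` iterations;
# ties broken by lowest SSR over `restarts` seeded jittered starts.
ls_fit <- function(resid_fn, init, fixed = numeric(),
                   lower = NULL, upper = NULL,
                   restarts = 5, jitter_sd = 0.1, seed = 101L,
                   ftol = 1e-10, maxiter = 500) {
  free_names <- setdiff(names(init), names(fixed))
  if (!length(free_names)) stop("no free parameters to fit")
  full <- function(p_free) {
    p <- c(p_free, fixed)
    p[names(init)]
  }
  fn_free <- function(p_free) resid_fn(full(p_free))
  lw <- if (is.null(lower)) rep(-Inf, length(free_names)) else lower[free_names]
  up <- if (is.null(upper)) rep(Inf, length(free_names)) else upper[free_names]
  lw[is.na(lw)] <- -Inf; up[is.na(up)] <- Inf

  starts <- list(init[free_names])
  if (restarts > 1) {
    jit <- with_seed(seed, {
      lapply(seq_len(restarts - 1), function(i) {
        p <- init[free_names] * (1 + rnorm(length(free_names), 0, jitter_sd))
        p + ifelse(p == 0, rnorm(length(free_names), 0, jitter_sd), 0)
      })
    })
    starts <- c(starts, jit)
  }

  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lw), up)
    res <- try(suppressWarnings(
      minpack.lm::nls.lm(par = st, lower = lw, upper = up, fn = fn_free,
                         control = minpack.lm::nls.lm.control(
                           ftol = ftol, maxiter = maxiter))),
      silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) {
    return(list(par = init, stderr = NULL, residuals = resid_fn(init),
                converged = FALSE, niter = NA_integer_))
  }
  p_free <- best$par
  r <- fn_free(p_free)
  n <- length(r); k <- length(p_free)
  se <- rep(NA_real_, k); names(se) <- free_names
  if (n > k) {
    J <- num_jacobian(fn_free, p_free)
    s2 <- sum(r^2) / (n - k)
    ct <- try({
      cv <- solve(crossprod(J)) * s2
      sqrt(pmax(diag(cv), 0))
    }, silent = TRUE)
    if (!inherits(ct, "try-error")) se <- ct
  }
  conv <- best$info %in% 1:4
  list(par = full(p_free), stderr = se, residuals = r,
       converged = conv, niter = best$niter)
}

# Initialization helper: linear baselines from the outer fractions of x.
edge_baseline <- function(x, y, side = c("low", "high"), frac = 0.2) {
  side <- match.arg(side)
  n <- length(x)
  k <- max(2, ceiling(frac * n))
  idx <- order(x)
  sel <- if (side == "low") idx[seq_len(k)] else idx[(n - k + 1):n]
  fit <- lm(y[sel] ~ x[sel])
  c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
}

# x of the half-amplitude crossing of the apparent unfolded fraction.
half_crossing <- function(x, f) {
  o <- order(x); x <- x[o]; f <- f[o]
  s <- which(diff(sign(f - 0.5)) != 0)
  if (!length(s)) return(x[which.min(abs(f - 0.5))])
  i <- s[1]
  x[i] + (0.5 - f[i]) * (x[i + 1] - x[i]) / (f[i + 1] - f[i])
}
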