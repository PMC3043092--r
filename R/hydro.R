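#' Complementary error function and its inverse
#'
#' `erfc(x) = 1 - erf(x)`, evaluated through the normal distribution
#' (`erfc(x) = 2 * pnorm(-x * sqrt(2))`... more precisely
#' `2 * pnorm(x * sqrt(2), lower.tail = FALSE)`), and its inverse on
#' (0, 2). `erfc_inv(1) = 0`.
#'
#' @param x numeric.
#' @return numeric of the same length.
#' @export
#' @examples
#' erfc(erfc_inv(0.3))  # 0.3
erfc <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)

#' @rdname erfc
#' @export
erfc_inv <- function(x) {
  if (any(x <= 0 | x >= 2)) stop("erfc_inv is defined on (0, 2)")
  qnorm(x / 2, lower.tail = FALSE) / sqrt(2)
}

#' Size-exclusion column constants
#'
#' @param Vo void volume, ml.
#' @param Vi internal volume, ml.
#' @return an object of class `sec_column`.
#' @export
#' @examples
#' col <- sec_column(Vo = 7.88, Vi = 18.72)
sec_column <- function(Vo, Vi) {
  if (Vo <= 0 || Vi <= 0) stop("Vo and Vi must be positive")
  structure(list(Vo = Vo, Vi = Vi), class = "sec_column")
}

#' @export
print.sec_column <- function(x, ...) {
  cat(sprintf("<sec_column> Vo = %.2f ml, Vi = %.2f ml (total %.2f ml)\n",
              x$Vo, x$Vi, x$Vo + x$Vi))
  invisible(x)
}

#' Average-weight partition coefficient
#'
#' `sigma = (Ve - Vo) / Vi`: the fraction of the column's internal
#' volume accessible to the analyte. Values above 1 (elution after the
#' total volume) are returned with an `interaction` attribute set, as
#' late elution usually signals analyte-matrix interaction rather than
#' a size effect.
#'
#' @param Ve elution volume(s), ml; must be at least `Vo`.
#' @param column a [sec_column()].
#' @return partition coefficient(s); attribute `interaction` flags
#'   values above 1.
#' @export
#' @examples
#' partition_coefficient(13.3, sec_column(7.88, 18.72))  # 0.2895
partition_coefficient <- function(Ve, column) {
  stopifnot(inherits(column, "sec_column"))
  if (any(Ve < column$Vo)) stop("Ve below the void volume")
  sigma <- (Ve - column$Vo) / column$Vi
  if (any(sigma > 1)) {
    attr(sigma, "interaction") <- sigma > 1
    warning("partition coefficient above 1: possible column interaction")
  }
  sigma
}

#' Fit the inverse-erfc Stokes-radius calibration
#'
#' Linear least-squares fit of `Rs = a + b * erfc_inv(sigma)` for a set
#' of standards of known Stokes radius run on the column. Standards
#' whose partition coefficient falls outside (0, 1) are excluded with a
#' warning.
#'
#' @param standards data frame with columns `name`, `Rs` (angstrom) and
#'   `Ve` (ml).
#' @param column a [sec_column()].
#' @return an object of class `sec_calibration`: intercept `a`, slope
#'   `b` (both angstrom), their standard errors, per-standard
#'   residuals, and the column.
#' @export
fit_sec_calibration <- function(standards, column) {
  stopifnot(inherits(column, "sec_column"),
            all(c("Rs", "Ve") %in% names(standards)))
  sigma <- (standards$Ve - column$Vo) / column$Vi
  ok <- sigma > 0 & sigma < 1
  if (any(!ok)) {
    warning(sprintf("excluding %d standard(s) with sigma outside (0,1)",
                    sum(!ok)))
  }
  if (sum(ok) < 3) {
    stop("need at least 3 standards with sigma in (0, 1); got ", sum(ok))
  }
  z <- erfc_inv(sigma[ok])
  fit <- lm(standards$Rs[ok] ~ z)
  sm <- summary(fit)$coefficients
  structure(list(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
                 a_se = sm[1, 2], b_se = sm[2, 2],
                 residuals = stats::setNames(
                   unname(stats::residuals(fit)),
                   if (!is.null(standards$name)) standards$name[ok]
                   else NULL),
                 n = sum(ok), column = column),
            class = "sec_calibration")
}

#' Construct a calibration from known constants
#' @param a,b calibration intercept and slope, angstrom.
#' @param column a [sec_column()].
#' @return a `sec_calibration` object.
#' @export
sec_calibration <- function(a, b, column) {
  if (b <= 0) stop("a physically sensible column has b > 0")
  structure(list(a = a, b = b, a_se = NA_real_, b_se = NA_real_,
                 residuals = NULL, n = NA_integer_, column = column),
            class = "sec_calibration")
}

#' @export
print.sec_calibration <- function(x, ...) {
  cat(sprintf(
    "<sec_calibration> Rs = %.2f (+/-%.2f) + %.2f (+/-%.2f) * erfc_inv(sigma)\n",
    x$a, x$a_se, x$b, x$b_se))
  invisible(x)
}

#' Stokes radius from a partition coefficient
#'
#' `Rs = a + b * erfc_inv(sigma)`; strictly decreasing in sigma, so
#' earlier-eluting (larger) species get larger radii.
#'
#' @param sigma partition coefficient(s) in (0, 1).
#' @param cal a [sec_calibration()].
#' @return Stokes radius in angstrom.
#' @export
stokes_radius <- function(sigma, cal) {
  stopifnot(inherits(cal, "sec_calibration"))
  if (any(sigma <= 0 | sigma >= 1)) {
    stop("stokes_radius needs sigma strictly inside (0, 1)")
  }
  cal$a + cal$b * erfc_inv(sigma)
}

#' Elution volume from a Stokes radius (calibration inverse)
#'
#' Inverts the calibration and the partition-coefficient definition:
#' `Ve = Vo + Vi * erfc((Rs - a)/b)`. Round-trips with
#' [stokes_radius()] and [partition_coefficient()].
#'
#' @param Rs Stokes radius (angstrom), must exceed the intercept `a`.
#' @param cal a [sec_calibration()] carrying its column.
#' @return elution volume in ml.
#' @export
elution_volume <- function(Rs, cal) {
  stopifnot(inherits(cal, "sec_calibration"))
  if (any(Rs <= cal$a)) {
    stop("Rs must exceed the calibration intercept for a finite Ve")
  }
  cal$column$Vo + cal$column$Vi * erfc((Rs - cal$a) / cal$b)
}

#' Theoretical radius of an anhydrous sphere
#'
#' `r0 = (3 M vbar / (4 pi N_Av))^(1/3)` for a protein of molecular
#' mass `M` and partial specific volume `vbar`; scales as the cube
#' root of the mass.
#'
#' @param M_kDa molecular mass in kDa.
#' @param vbar partial specific volume, cm^3 g^-1 (default 0.73, a
#'   typical protein average).
#' @return radius in angstrom.
#' @export
#' @examples
#' sphere_radius(13.1)  # 15.6 A
sphere_radius <- function(M_kDa, vbar = 0.73) {
  if (any(M_kDa <= 0) || vbar <= 0) stop("M and vbar must be positive")
  r_cm <- (3 * (M_kDa * 1000) * vbar / (4 * pi * .N_AVOGADRO))^(1 / 3)
  r_cm * 1e8
}

#' Chain-length scaling estimate of the Stokes radius
#'
#' Empirical scaling for folded globular proteins,
#' `Rs = 4.75 * N^0.29` angstrom, with `N` the residue count. The
#' literature prefactor carries an uncertainty of about +/-1.11, which
#' propagates to roughly +/-4 angstrom for a ~120-residue protein.
#'
#' @param N residue count (>= 1).
#' @param prefactor,exponent scaling constants.
#' @return Stokes radius in angstrom.
#' @export
#' @examples
#' wilkins_radius(120)  # 19.0 A
wilkins_radius <- function(N, prefactor = 4.75, exponent = 0.29) {
  if (any(N < 1)) stop("N must be at least 1")
  prefactor * N^exponent
}

#' Rotational correlation time from NMR transverse relaxation
#'
#' Empirical estimate `tau_c (ns) = 1 / (5 * T2 (s))` from the
#' transverse relaxation time of slowly relaxing amide/aromatic
#' protons; carries an inherent uncertainty of about 10%, recorded as
#' an attribute.
#'
#' @param T2_ms transverse relaxation time in milliseconds.
#' @return correlation time in ns, with attribute
#'   `relative_uncertainty = 0.1`.
#' @export
#' @examples
#' correlation_time(30.0)  # 6.67 ns
correlation_time <- function(T2_ms) {
  if (any(T2_ms <= 0)) stop("T2 must be positive")
  tau <- 1 / (5 * (T2_ms / 1000))
  attr(tau, "relative_uncertainty") <- 0.1
  tau
}

#' Molecular weight from a rotational correlation time
#'
#' Linear mapping `MW = k * tau_c` between the rotational correlation
#' time and the molecular mass of a compact globular protein at 25 C;
#' the default `k = 2.0` kDa per ns reproduces typical small-protein
#' masses. The 10% uncertainty of the underlying correlation time is
#' propagated as a band.
#'
#' @param tau_c_ns correlation time in ns.
#' @param k mapping constant, kDa per ns.
#' @return estimated mass in kDa with attribute `band` (lower/upper
#'   10% bounds).
#' @export
#' @examples
#' mw_from_correlation_time(6.7)  # 13.4 kDa
mw_from_correlation_time <- function(tau_c_ns, k = 2.0) {
  if (any(tau_c_ns <= 0)) stop("tau_c must be positive")
  mw <- k * as.numeric(tau_c_ns)
  attr(mw, "band") <- cbind(lower = 0.9 * mw, upper = 1.1 * mw)
  mw
}
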