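#' Emission spectrum
#'
#' A fluorescence emission spectrum on a strictly increasing wavelength
#' grid with non-negative intensities, plus condition metadata (the
#' value of the denaturant concentration, temperature or pH at which it
#' was recorded, and the excitation wavelength).
#'
#' @param wavelengths numeric, nm, strictly increasing, length >= 2.
#' @param intensities numeric, arbitrary fluorescence units, same
#'   length, all non-negative.
#' @param condition named list with `axis_kind` (one of `"denaturant"`,
#'   `"temperature"`, `"pH"`), `value` (the condition value) and
#'   optionally `excitation_nm`.
#' @return an object of class `emission_spectrum`.
#' @export
#' @examples
#' sp <- emission_spectrum(300:400, dnorm(300:400, 340, 15),
#'                         condition = list(axis_kind = "pH", value = 7,
#'                                          excitation_nm = 280))
#' avg_emission_wavelength(sp)
emission_spectrum <- function(wavelengths, intensities,
                              condition = list(axis_kind = "denaturant",
                                               value = 0,
                                               excitation_nm = 280)) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) != length(intensities)) {
    stop("wavelengths and intensities must have the same length")
  }
  if (length(wavelengths) < 2) stop("a spectrum needs at least 2 points")
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (is.null(condition$axis_kind) ||
      !condition$axis_kind %in% c("denaturant", "temperature", "pH")) {
    stop("condition$axis_kind must be denaturant, temperature or pH")
  }
  structure(list(wavelengths = wavelengths, intensities = intensities,
                 condition = condition),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum> %d points, %.0f-%.0f nm, %s = %s\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$condition$axis_kind, format(x$condition$value)))
  invisible(x)
}

#' Intensity-weighted average emission wavelength
#'
#' The average emission wavelength of a fluorescence spectrum,
#' `<lambda> = sum(lambda_i * I_i) / sum(I_i)`, the scalar observable
#' commonly used to track tryptophan solvent exposure: it red-shifts on
#' unfolding and is less noisy than the raw band maximum.
#'
#' @param spectrum an [emission_spectrum()].
#' @return the average emission wavelength in nm; always within the
#'   wavelength grid extremes and invariant under rescaling of the
#'   intensities by a positive constant.
#' @export
#' @examples
#' sp <- emission_spectrum(c(320, 360), c(1, 3))
#' avg_emission_wavelength(sp)  # (320 + 3*360)/4 = 350
avg_emission_wavelength <- function(spectrum) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  tot <- sum(spectrum$intensities)
  if (tot <= 0) stop("degenerate spectrum: all intensities are zero")
  sum(spectrum$wavelengths * spectrum$intensities) / tot
}

#' Intensity at a fixed wavelength
#'
#' Reads the intensity at wavelength `at` (nm) off the spectrum grid,
#' snapping to the nearest grid point; a snap larger than 0.5 nm raises
#' a warning.
#'
#' @param spectrum an [emission_spectrum()].
#' @param at wavelength in nm.
#' @return intensity at the nearest grid point.
#' @export
intensity_at <- function(spectrum, at) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  i <- which.min(abs(spectrum$wavelengths - at))
  off <- abs(spectrum$wavelengths[i] - at)
  if (off > 0.5) {
    warning(sprintf(
      "requested %.2f nm is %.2f nm off the grid; using %.2f nm",
      at, off, spectrum$wavelengths[i]))
  }
  spectrum$intensities[i]
}

#' Denaturation curve
#'
#' An ordered set of (condition, signal) observations for one probe
#' along one axis: denaturant concentration (M), temperature (degrees
#' Celsius) or pH. Observations are sorted by `x` on ingest; exact
#' duplicate points are collapsed, while duplicate `x` with differing
#' `y` is an error (fits must be reproducible, so no silent averaging).
#'
#' @param x condition values.
#' @param y signal values (average emission wavelength in nm, intensity
#'   in arbitrary units, ellipticity in mdeg, elution volume in ml, or
#'   excess heat capacity in kcal mol^-1 K^-1).
#' @param axis_kind one of `"denaturant"`, `"temperature"`, `"pH"`.
#' @param probe one of `"fluorescence"`, `"far-UV CD"`, `"ANS"`,
#'   `"SEC"`, `"DSC"`.
#' @param ground_truth optional list of generating parameters (attached
#'   by the synthetic generators).
#' @return a data frame of class `denaturation_curve` with columns `x`
#'   and `y` and attributes `axis_kind`, `probe`, `ground_truth`.
#' @export
denaturation_curve <- function(x, y,
                               axis_kind = c("denaturant", "temperature",
                                             "pH"),
                               probe = c("fluorescence", "far-UV CD",
                                         "ANS", "SEC", "DSC"),
                               ground_truth = NULL) {
  axis_kind <- match.arg(axis_kind)
  probe <- match.arg(probe)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have the same length")
  o <- order(x)
  x <- x[o]; y <- y[o]
  dup <- duplicated(x)
  if (any(dup)) {
    for (xi in unique(x[dup])) {
      ys <- y[x == xi]
      if (length(unique(ys)) > 1) {
        stop(sprintf("duplicate x = %g with differing y values", xi))
      }
    }
    keep <- !dup
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 2) stop("a curve needs at least 2 distinct points")
  out <- data.frame(x = x, y = y)
  attr(out, "axis_kind") <- axis_kind
  attr(out, "probe") <- probe
  attr(out, "ground_truth") <- ground_truth
  class(out) <- c("denaturation_curve", "data.frame")
  out
}

#' @export
print.denaturation_curve <- function(x, ...) {
  cat(sprintf("<denaturation_curve> %s vs %s, %d points [%g, %g]\n",
              attr(x, "probe"), attr(x, "axis_kind"), nrow(x),
              min(x$x), max(x$x)))
  NextMethod()
}

#' Axis kind and probe accessors
#' @param curve a [denaturation_curve()].
#' @return character scalar.
#' @export
axis_kind <- function(curve) attr(curve, "axis_kind")

#' @rdname axis_kind
#' @export
probe <- function(curve) attr(curve, "probe")

#' @rdname axis_kind
#' @export
ground_truth <- function(curve) attr(curve, "ground_truth")

#' Assemble a denaturation curve from a series of spectra
#'
#' Reduces each spectrum of a series to a scalar observable (average
#' emission wavelength or intensity at a fixed wavelength) and collects
#' the results into a [denaturation_curve()] sorted by condition.
#'
#' @param spectra list of [emission_spectrum()] objects sharing the same
#'   `axis_kind` and excitation wavelength.
#' @param observable `"avg_wavelength"` or `"intensity_at"`.
#' @param at wavelength (nm) when `observable = "intensity_at"`.
#' @param probe probe label for the resulting curve.
#' @return a [denaturation_curve()].
#' @export
spectra_to_curve <- function(spectra,
                             observable = c("avg_wavelength",
                                            "intensity_at"),
                             at = NULL, probe = "fluorescence") {
  observable <- match.arg(observable)
  if (length(spectra) < 2) stop("need at least 2 spectra")
  kinds <- vapply(spectra, function(s) s$condition$axis_kind, character(1))
  if (length(unique(kinds)) != 1) {
    stop("mixed axis kinds across spectra")
  }
  exc <- vapply(spectra, function(s) {
    if (is.null(s$condition$excitation_nm)) NA_real_
    else s$condition$excitation_nm
  }, numeric(1))
  if (length(unique(exc[!is.na(exc)])) > 1) {
    stop("mixed excitation wavelengths across spectra")
  }
  xs <- vapply(spectra, function(s) s$condition$value, numeric(1))
  ys <- switch(observable,
    avg_wavelength = vapply(spectra, avg_emission_wavelength, numeric(1)),
    intensity_at = {
      if (is.null(at)) stop("'at' is required for intensity_at")
      vapply(spectra, intensity_at, numeric(1), at = at)
    })
  denaturation_curve(xs, ys, axis_kind = kinds[1], probe = probe)
}

#' Normalize a curve to its lowest-condition value
#'
#' Divides every signal by the signal at the lowest condition value, so
#' different probes can be overlaid on a common scale; the first point
#' becomes exactly 1. Sign-preserving (negative ellipticities stay
#' negative in ratio terms) and idempotent.
#'
#' @param curve a [denaturation_curve()].
#' @return the normalized [denaturation_curve()].
#' @export
normalize_to_lowest_condition <- function(curve) {
  stopifnot(inherits(curve, "denaturation_curve"))
  ref <- curve$y[which.min(curve$x)]
  if (ref == 0) stop("reference signal at the lowest condition is zero")
  denaturation_curve(curve$x, curve$y / ref,
                     axis_kind = attr(curve, "axis_kind"),
                     probe = attr(curve, "probe"),
                     ground_truth = attr(curve, "ground_truth"))
}
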