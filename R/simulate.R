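#' Noise specification for the synthetic-data generators
#'
#' Homoscedastic Gaussian noise, parameterized either as a fraction of
#' the noiseless signal amplitude (`relative = TRUE`, the default, so
#' scenarios transfer across probes with different signal scales) or in
#' absolute signal units. The same seed always produces the same
#' draws.
#'
#' @param sigma standard deviation (fraction of amplitude, or absolute
#'   units when `relative = FALSE`); `sigma >= 0`.
#' @param seed integer RNG seed.
#' @param relative logical; interpret `sigma` as a fraction of the
#'   noiseless amplitude.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0, seed = 1L, relative = TRUE) {
  if (sigma < 0) stop("sigma must be non-negative")
  structure(list(sigma = sigma, seed = as.integer(seed),
                 relative = isTRUE(relative)),
            class = "noise_spec")
}

add_noise <- function(y, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$sigma == 0) return(y)
  sd_abs <- if (noise$relative) {
    amp <- diff(range(y))
    if (amp == 0) amp <- max(abs(y), 1)
    noise$sigma * amp
  } else {
    noise$sigma
  }
  y + with_seed(noise$seed, rnorm(length(y), 0, sd_abs))
}

#' Generate a chemical denaturation curve
#'
#' Forward model of the two- or three-state chemical signal on a
#' denaturant grid (model chosen by the parameter names), plus seeded
#' Gaussian noise. The generating parameters are attached to the curve
#' as ground-truth metadata.
#'
#' @param params parameter list for [two_state_chem_signal()] (fields
#'   `m`, `U50`, baselines) or [three_state_chem_signal()] (fields
#'   `m1`, `U50_1`, ...).
#' @param grid denaturant concentrations, M (within the 0-7 M range of
#'   a standard stock).
#' @param noise a [noise_spec()].
#' @param probe probe label.
#' @return a [denaturation_curve()] with `ground_truth` metadata.
#' @export
#' @examples
#' p <- list(alpha_N = 1, beta_N = -0.01, alpha_D = 0.1, beta_D = 0.005,
#'           m = 2.3, U50 = 3.19)
#' cv <- gen_chem_curve(p, seq(0, 7, 0.25), noise_spec(0.02, seed = 7))
gen_chem_curve <- function(params, grid = seq(0, 7, by = 0.25),
                           noise = noise_spec(0), probe = "fluorescence") {
  if (any(grid < 0 | grid > 7)) stop("grid must lie within 0-7 M")
  params <- as.list(params)
  y <- if (!is.null(params$m1)) three_state_chem_signal(params, grid)
       else two_state_chem_signal(params, grid)
  denaturation_curve(grid, add_noise(y, noise), axis_kind = "denaturant",
                     probe = probe,
                     ground_truth = list(model = if (!is.null(params$m1))
                       "three_state_chem" else "two_state_chem",
                       params = params, noise = unclass(noise)))
}

#' Generate a thermal denaturation curve
#'
#' Forward model of [thermal_signal()] on a temperature grid (degrees
#' Celsius; the default 25-95 C at 0.2 C matches common scan
#' settings), plus seeded Gaussian noise.
#'
#' @param params parameter list for [thermal_signal()].
#' @param grid temperatures, degrees Celsius.
#' @param noise a [noise_spec()].
#' @param probe probe label.
#' @return a [denaturation_curve()] with `ground_truth` metadata.
#' @export
gen_thermal_curve <- function(params, grid = seq(25, 95, by = 0.2),
                              noise = noise_spec(0),
                              probe = "far-UV CD") {
  params <- as.list(params)
  y <- thermal_signal(params, grid)
  denaturation_curve(grid, add_noise(y, noise), axis_kind = "temperature",
                     probe = probe,
                     ground_truth = list(model = "thermal_two_state",
                                         params = params,
                                         noise = unclass(noise)))
}

#' Generate a pH titration curve
#'
#' Forward model of [single_pka_signal()] or [bell_signal()] (chosen by
#' the parameter names) on a pH grid (default pH 2-13 in 0.5 steps,
#' matching a typical buffer series).
#'
#' @param params parameter list (`pKa`, plateaus for single; `pKa1`,
#'   `pKa2`, amplitudes for double).
#' @param grid pH values.
#' @param noise a [noise_spec()].
#' @param probe probe label.
#' @return a [denaturation_curve()] with `ground_truth` metadata.
#' @export
gen_titration <- function(params, grid = seq(2, 13, by = 0.5),
                          noise = noise_spec(0), probe = "fluorescence") {
  params <- as.list(params)
  double <- !is.null(params$pKa2)
  y <- if (double) bell_signal(params, grid)
       else single_pka_signal(params, grid)
  denaturation_curve(grid, add_noise(y, noise), axis_kind = "pH",
                     probe = probe,
                     ground_truth = list(
                       model = if (double) "double_pka" else "single_pka",
                       params = params, noise = unclass(noise)))
}

#' Generate synthetic calibration standards
#'
#' Inverts the Stokes-radius calibration and the partition-coefficient
#' definition to produce elution volumes for standards of known radius,
#' optionally with Gaussian noise on the volumes. With zero noise the
#' calibration fit recovers the generating constants exactly.
#'
#' @param cal a [sec_calibration()] (the generating constants).
#' @param Rs Stokes radii of the standards, angstrom; defaults to the
#'   classic low-molecular-weight kit (ribonuclease A 16.4,
#'   chymotrypsinogen 20.9, ovalbumin 30.5, bovine serum albumin
#'   35.5).
#' @param names optional standard names.
#' @param noise a [noise_spec()] applied to Ve (absolute ml when
#'   `relative = FALSE`).
#' @return data frame with columns `name`, `Rs`, `Ve`.
#' @export
gen_sec_standards <- function(cal,
                              Rs = c(16.4, 20.9, 30.5, 35.5),
                              names = c("ribonuclease A",
                                        "chymotrypsinogen",
                                        "ovalbumin",
                                        "bovine serum albumin"),
                              noise = noise_spec(0)) {
  stopifnot(inherits(cal, "sec_calibration"))
  if (length(names) != length(Rs)) names <- paste0("std", seq_along(Rs))
  Ve <- elution_volume(Rs, cal)
  Ve <- add_noise(Ve, noise)
  data.frame(name = names, Rs = Rs, Ve = Ve)
}

#' Generate a DSC endotherm
#'
#' Forward model of [dsc_excess_cp()] on a temperature grid, plus
#' seeded Gaussian noise. `scale` multiplies the whole trace, which
#' emulates partially irreversible re-heating scans where only a
#' fraction of the protein refolds (the calorimetric enthalpy scales
#' while the peak temperature does not).
#'
#' @param params parameters for [dsc_excess_cp()].
#' @param model_kind `"two_state"` or `"sequential_three_state"`.
#' @param grid temperatures, degrees Celsius.
#' @param noise a [noise_spec()].
#' @param scale amplitude factor (1 = first scan).
#' @return a [denaturation_curve()] with `probe = "DSC"`.
#' @export
gen_dsc_endotherm <- function(params, model_kind = "two_state",
                              grid = seq(35, 95, by = 0.05),
                              noise = noise_spec(0), scale = 1) {
  y <- scale * dsc_excess_cp(params, grid, model_kind)
  denaturation_curve(grid, add_noise(y, noise), axis_kind = "temperature",
                     probe = "DSC",
                     ground_truth = list(model = paste0("dsc_", model_kind),
                                         params = as.list(params),
                                         scale = scale,
                                         noise = unclass(noise)))
}

#' Generate a series of emission spectra with known unfolded fractions
#'
#' Each spectrum is a population-weighted sum of two Gaussian emission
#' bands of equal integrated amplitude, one centred at the folded-state
#' maximum and one at the unfolded-state maximum; the weight follows
#' the supplied unfolded-fraction schedule. With fraction 0 (1) the
#' average emission wavelength equals the folded (unfolded) band
#' centroid on the grid.
#'
#' @param fractions unfolded-fraction schedule in `[0, 1]`, one per
#'   spectrum.
#' @param conditions condition values, one per spectrum (same length).
#' @param axis_kind axis of the condition values.
#' @param folded_max,unfolded_max band centres, nm.
#' @param bandwidth Gaussian band standard deviation, nm.
#' @param grid wavelength grid, nm (default 300-400 at 1 nm).
#' @param amplitude peak amplitude of each band.
#' @param noise a [noise_spec()] applied per spectrum (seed offset by
#'   the spectrum index so spectra differ).
#' @param excitation_nm excitation wavelength metadata.
#' @return list of [emission_spectrum()] objects; each carries its
#'   generating fraction in `condition$fraction_unfolded`.
#' @export
gen_spectrum_series <- function(fractions, conditions,
                                axis_kind = "denaturant",
                                folded_max = 335, unfolded_max = 355,
                                bandwidth = 12, grid = 300:400,
                                amplitude = 1000,
                                noise = noise_spec(0),
                                excitation_nm = 280) {
  stopifnot(length(fractions) == length(conditions),
            all(fractions >= 0 & fractions <= 1))
  lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    I <- amplitude * ((1 - f) * exp(-(grid - folded_max)^2 /
                                      (2 * bandwidth^2)) +
                      f * exp(-(grid - unfolded_max)^2 /
                                (2 * bandwidth^2)))
    ns <- noise
    ns$seed <- noise$seed + i
    I <- pmax(add_noise(I, ns), 0)
    emission_spectrum(grid, I,
                      condition = list(axis_kind = axis_kind,
                                       value = conditions[i],
                                       excitation_nm = excitation_nm,
                                       fraction_unfolded = f))
  })
}
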