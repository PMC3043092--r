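#' Per-protein accessible-surface-area table
#'
#' Folded and extended-state polar and non-polar accessible surface
#' areas for one protein, as produced by structure-analysis servers.
#' The extended-state area must be at least the folded-state area in
#' each polarity class.
#'
#' @param protein protein identifier.
#' @param folded_nonpolar,folded_polar exposed ASA in the folded
#'   state, square angstrom.
#' @param extended_nonpolar,extended_polar ASA in the extended
#'   (fully unfolded) state, square angstrom.
#' @param hbond_count optional main-chain hydrogen-bond count.
#' @return an object of class `asa_table`.
#' @export
#' @examples
#' asa_table("PsTRXh1", 3774.1, 2934.5, 12360.7, 7593.4, 80)
asa_table <- function(protein, folded_nonpolar, folded_polar,
                      extended_nonpolar, extended_polar,
                      hbond_count = NA_integer_) {
  areas <- c(folded_nonpolar, folded_polar,
             extended_nonpolar, extended_polar)
  if (any(areas <= 0)) stop("all areas must be positive")
  if (extended_nonpolar < folded_nonpolar ||
      extended_polar < folded_polar) {
    stop("extended-state ASA must be >= folded-state ASA in each class")
  }
  structure(list(protein = protein,
                 folded_nonpolar = folded_nonpolar,
                 folded_polar = folded_polar,
                 extended_nonpolar = extended_nonpolar,
                 extended_polar = extended_polar,
                 hbond_count = hbond_count),
            class = "asa_table")
}

#' @export
print.asa_table <- function(x, ...) {
  cat(sprintf("<asa_table> %s: folded %.1f/%.1f, extended %.1f/%.1f A^2 (np/p)\n",
              x$protein, x$folded_nonpolar, x$folded_polar,
              x$extended_nonpolar, x$extended_polar))
  invisible(x)
}

#' Change in accessible surface area on unfolding
#'
#' `dASA_class = extended_class - folded_class` for the non-polar and
#' polar classes; the total is their sum.
#'
#' @param table an [asa_table()].
#' @return list with `protein`, `delta_asa_nonpolar`,
#'   `delta_asa_polar`, `delta_asa_total` (square angstrom).
#' @export
#' @examples
#' tab <- asa_table("PsTRXh1", 3774.1, 2934.5, 12360.7, 7593.4)
#' delta_asa(tab)$delta_asa_nonpolar  # 8586.6
delta_asa <- function(table) {
  stopifnot(inherits(table, "asa_table"))
  dn <- table$extended_nonpolar - table$folded_nonpolar
  dp <- table$extended_polar - table$folded_polar
  if (dn < 0 || dp < 0) stop("negative ASA difference")
  list(protein = table$protein,
       delta_asa_nonpolar = dn,
       delta_asa_polar = dp,
       delta_asa_total = dn + dp)
}

#' Theoretical m-value from the change in accessible surface area
#'
#' Empirical regression of guanidinium-chloride m-values on the total
#' surface area newly exposed on unfolding:
#' `m = 0.859 + 2.2e-4 * dASA_total` (kcal mol^-1 M^-1, dASA in square
#' angstrom). Coefficients are configurable.
#'
#' @param delta_asa_total total change in ASA, square angstrom (> 0).
#' @param intercept,slope regression constants.
#' @return theoretical m-value, kcal mol^-1 M^-1.
#' @export
#' @examples
#' myers_m_gdmcl(13245.5)  # 3.77
myers_m_gdmcl <- function(delta_asa_total, intercept = 0.859,
                          slope = 2.2e-4) {
  if (any(delta_asa_total < 0)) stop("delta_asa_total must be non-negative")
  intercept + slope * delta_asa_total
}

#' Consistency of reported free energy with the linear extrapolation model
#'
#' Relative deviation between the product `m * U50` (the LEM free
#' energy in water) and an independently reported free energy:
#' `|m * U50 - dG_reported| / dG_reported`.
#'
#' @param m m-value, kcal mol^-1 M^-1.
#' @param U50 midpoint denaturant concentration, M.
#' @param dG_reported reported free energy, kcal mol^-1.
#' @return relative deviation (dimensionless).
#' @export
#' @examples
#' lem_consistency(2.3, 3.19, 7.3)  # ~0.005
lem_consistency <- function(m, U50, dG_reported) {
  if (any(c(m, U50, dG_reported) <= 0)) stop("all inputs must be positive")
  abs(m * U50 - dG_reported) / dG_reported
}
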