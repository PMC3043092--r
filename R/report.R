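#' Hydrodynamic summary table
#'
#' Assembles the standard per-protein hydrodynamic summary from masses,
#' residue counts and NMR transverse relaxation times: anhydrous sphere
#' radius, chain-length Stokes-radius estimate, rotational correlation
#' time and the correlation-time mass estimate. Output follows the
#' usual reporting precision (radii and times to one decimal).
#'
#' @param proteins data frame with columns `name`, `mw_kda`,
#'   `n_residues`, `t2_ms`.
#' @param vbar partial specific volume for the sphere radius.
#' @param k correlation-time-to-mass constant, kDa per ns.
#' @return data frame with columns `name`, `r0_A`, `rs_chain_A`,
#'   `tau_c_ns`, `mw_est_kda`.
#' @export
#' @examples
#' hydro_summary(data.frame(name = "PsTRXh1", mw_kda = 13.1,
#'                          n_residues = 120, t2_ms = 30.0))
hydro_summary <- function(proteins, vbar = 0.73, k = 2.0) {
  stopifnot(all(c("name", "mw_kda", "n_residues", "t2_ms") %in%
                  names(proteins)))
  tau <- as.numeric(correlation_time(proteins$t2_ms))
  data.frame(name = proteins$name,
             r0_A = round(sphere_radius(proteins$mw_kda, vbar), 1),
             rs_chain_A = round(wilkins_radius(proteins$n_residues)),
             tau_c_ns = round(tau, 1),
             mw_est_kda = round(mw_from_correlation_time(round(tau, 1),
                                                         k), 1))
}

#' Surface-area and theoretical m-value summary
#'
#' Computes the unfolding ASA changes and the theoretical m-value for
#' each protein. Areas are reported to one decimal, m-values to two.
#'
#' @param tables list of [asa_table()] objects.
#' @return data frame with columns `protein`, `dasa_nonpolar_A2`,
#'   `dasa_polar_A2`, `dasa_total_A2`, `m_theory`.
#' @export
asa_m_summary <- function(tables) {
  if (inherits(tables, "asa_table")) tables <- list(tables)
  rows <- lapply(tables, function(tab) {
    d <- delta_asa(tab)
    data.frame(protein = d$protein,
               dasa_nonpolar_A2 = round(d$delta_asa_nonpolar, 1),
               dasa_polar_A2 = round(d$delta_asa_polar, 1),
               dasa_total_A2 = round(d$delta_asa_total, 1),
               m_theory = round(myers_m_gdmcl(d$delta_asa_total), 2))
  })
  do.call(rbind, rows)
}

#' Chemical-denaturation summary table
#'
#' Collects two-state chemical fits into the usual per-probe summary
#' (m-value to one decimal, midpoint to two, LEM free energy in water
#' to one).
#'
#' @param fits named list of [fit_result()] objects from
#'   [fit_two_state_chem()]; names label the rows (e.g. the probe).
#' @return data frame with columns `label`, `m`, `U50_M`,
#'   `dG_water_kcal_mol`.
#' @export
chem_summary <- function(fits) {
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    stopifnot(inherits(f, "fit_result"))
    data.frame(label = if (!is.null(names(fits))) names(fits)[i]
               else as.character(i),
               m = round(f$estimates[["m"]], 1),
               U50_M = round(f$estimates[["U50"]], 2),
               dG_water_kcal_mol = round(
                 f$estimates[["m"]] * f$estimates[["U50"]], 1))
  })
  do.call(rbind, rows)
}
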