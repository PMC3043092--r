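# Published per-protein parameter scenarios used as ground truth for
# the synthetic-data studies (raw instrument data are unavailable, so
# the printed summary values define the simulated conditions).

# chemical denaturation at pH 7.0, 25 C: m (kcal/mol/M) and midpoint (M)
chem_scenarios <- list(
  PsTRXh1_fluor = list(m = 2.3, U50 = 3.19),
  PsTRXh2_fluor = list(m = 2.6, U50 = 2.62),
  PsTRXh2_cd    = list(m = 1.4, U50 = 1.56),
  PsTRXf_fluor  = list(m = 1.9, U50 = 2.00)
)

# hydrodynamics: mass (kDa), residue count, NMR T2 (ms) and the
# corresponding published estimates
hydro_proteins <- data.frame(
  name = c("PsTRXh1", "PsTRXh2", "PsTRXf"),
  mw_kda = c(13.1, 13.0, 12.1),
  n_residues = c(120, 118, 109),
  t2_ms = c(30.0, 30.5, 28.7),
  r0_printed = c(15.6, 15.5, 15.2),
  rs_printed = c(19, 19, 18),
  tau_printed = c(6.7, 6.5, 6.9),
  mw_nmr_printed = c(13.4, 13.1, 13.7)
)

# size-exclusion column and published calibration line
sec_column_ref <- function() sec_column(Vo = 7.88, Vi = 18.72)
sec_cal_ref <- function() sec_calibration(1.69, 26.7, sec_column_ref())
standard_radii <- c(16.4, 20.9, 30.5, 35.5)

# per-protein accessible surface areas (square angstrom) and the
# published unfolding differences
asa_scenarios <- list(
  PsTRXh1 = list(tab = asa_table("PsTRXh1", 3774.1, 2934.5,
                                 12360.7, 7593.4, 80),
                 d_nonpolar = 8586.6, d_polar = 4658.9),
  PsTRXh2 = list(tab = asa_table("PsTRXh2", 3950.6, 2521.9,
                                 12250.1, 7407.6, 81),
                 d_nonpolar = 8299.5, d_polar = 4885.7),
  PsTRXf  = list(tab = asa_table("PsTRXf", 3988.1, 2303.0,
                                 12249.8, 6965.7, 77),
                 d_nonpolar = 8261.7, d_polar = 4662.7)
)

# DSC scenario: single endotherm at 68.5 C with dHcal ~ dHvH ~ 62 kcal/mol
dsc_two_state_scenario <- list(Tm_C = 68.5, dH_vH = 61.6)

# base seed for all seeded studies (fixed once for the whole suite)
BASE_SEED <- 20110222L

# default two-state baseline set used when a scenario only pins (m, U50)
default_chem_baselines <- list(alpha_N = 1, beta_N = -0.02,
                               alpha_D = 0.12, beta_D = 0.01)

make_chem_curve <- function(scn, grid = seq(0, 7, length.out = 30),
                            noise = noise_spec(0)) {
  gen_chem_curve(c(default_chem_baselines, scn), grid = grid,
                 noise = noise)
}
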