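test_that("linear extrapolation free energy is linear with a zero midpoint", {
  expect_equal(lem_free_energy(2.3, 3.19, 0), 7.337)
  expect_equal(lem_free_energy(2.3, 3.19, 3.19), 0)
  expect_equal(lem_free_energy(1.9, 2.00, 1.0), 1.9)
  # linearity in U
  U <- seq(0, 7, 0.5)
  dG <- lem_free_energy(2.0, 3.0, U)
  expect_equal(diff(dG), rep(-1, length(U) - 1))
  expect_error(lem_free_energy(-1, 3, 0), "positive")
})

test_that("two-state chemical signal obeys midpoint and limit behaviour", {
  p <- list(alpha_N = 1, beta_N = 0, alpha_D = 0, beta_D = 0,
            m = 2.3, U50 = 3.19)
  # flat baselines: exactly half-way at the midpoint
  expect_equal(two_state_chem_signal(p, 3.19), 0.5)
  expect_equal(two_state_unfolded_fraction(p, 3.19), 0.5)
  # native limit
  expect_equal(two_state_chem_signal(p, 0), 1, tolerance = 1e-5)
  # closed-form evaluation at U = 4 M, 298.15 K
  RT <- gas_constant_kcal() * 298.15
  fU <- 1 / (1 + exp(2.3 * (3.19 - 4) / RT))
  expect_equal(two_state_chem_signal(p, 4), 1 - fU, tolerance = 1e-12)
  # signal stays between the baselines for sloped baselines
  p2 <- list(alpha_N = 5, beta_N = -0.1, alpha_D = 1, beta_D = 0.2,
             m = 2, U50 = 3)
  U <- seq(0, 7, 0.1)
  sig <- two_state_chem_signal(p2, U)
  XN <- 5 - 0.1 * U; XD <- 1 + 0.2 * U
  expect_true(all(sig <= pmax(XN, XD) + 1e-12 &
                    sig >= pmin(XN, XD) - 1e-12))
})

test_that("three-state populations normalize and nest the two-state model", {
  set.seed(BASE_SEED + 1)
  for (i in 1:10) {
    p <- list(m1 = runif(1, 0.5, 3), U50_1 = runif(1, 0.5, 3),
              m2 = runif(1, 0.5, 3), U50_2 = runif(1, 3, 6))
    pops <- three_state_populations(p, seq(0, 7, 0.25))
    expect_equal(pops$N + pops$I + pops$D, rep(1, nrow(pops)),
                 tolerance = 1e-12)
  }
  # degenerate limit: coincident transitions with alpha_I midway give
  # the two-state signal value at the shared midpoint
  p <- list(alpha_N = 1, beta_N = 0, alpha_D = 0, beta_D = 0,
            alpha_I = 0.5, m1 = 2, U50_1 = 3, m2 = 2, U50_2 = 3)
  expect_equal(three_state_chem_signal(p, 3), 0.5, tolerance = 1e-12)
  # second transition pushed far away: reduces to a two-state between
  # the native level and alpha_I
  p$U50_2 <- 50; p$alpha_I <- 0.3
  p2 <- list(alpha_N = 1, beta_N = 0, alpha_D = 0.3, beta_D = 0,
             m = 2, U50 = 3)
  U <- seq(0, 6, 0.2)
  expect_equal(three_state_chem_signal(p, U),
               two_state_chem_signal(p2, U), tolerance = 1e-10)
})

test_that("two-state chemical fit recovers noiseless scenarios exactly", {
  for (scn in chem_scenarios[c("PsTRXh1_fluor", "PsTRXf_fluor")]) {
    cv <- make_chem_curve(scn)
    fit <- fit_two_state_chem(cv)
    expect_true(fit$converged)
    truth <- c(unlist(default_chem_baselines), m = scn$m, U50 = scn$U50)
    expect_equal(fit$estimates[names(truth)], truth, tolerance = 1e-6)
    expect_equal(fit$meta$dG_water, scn$m * scn$U50, tolerance = 1e-5)
    expect_true(all(is.na(fit$stderr) | fit$stderr >= 0))
  }
})

test_that("two-state chemical fit honours parameter pins", {
  scn <- chem_scenarios$PsTRXh1_fluor
  cv <- make_chem_curve(scn)
  fit <- fit_two_state_chem(cv, fixed = c(m = 2.3))
  expect_identical(unname(fit$estimates["m"]), 2.3)
  expect_identical(fit$fixed, c(m = 2.3))
  expect_equal(fit$estimates[["U50"]], scn$U50, tolerance = 1e-6)
})

test_that("curves without a denatured baseline are flagged", {
  scn <- chem_scenarios$PsTRXh1_fluor
  cv <- make_chem_curve(scn, grid = seq(0, 3.4, length.out = 12))
  expect_warning(fit <- fit_two_state_chem(cv), "baseline")
  expect_true("no_upper_baseline" %in% fit$flags)
  # wrong axis rejected
  tcv <- denaturation_curve(seq(25, 90, 5), rnorm(14),
                            axis_kind = "temperature")
  expect_error(fit_two_state_chem(tcv), "denaturant")
})

test_that("noisy two-state fits recover the midpoint within 2%", {
  scn <- chem_scenarios$PsTRXh1_fluor
  u50 <- vapply(1:40, function(i) {
    cv <- make_chem_curve(scn, noise = noise_spec(0.02,
                                                  seed = BASE_SEED + i))
    fit_two_state_chem(cv)$estimates[["U50"]]
  }, numeric(1))
  expect_lt(abs(mean(u50) - scn$U50) / scn$U50, 0.02)
})

test_that("three-state fit recovers a noiseless intermediate scenario", {
  p3 <- list(alpha_N = 1, beta_N = -0.01, alpha_D = 0, beta_D = 0.005,
             alpha_I = 0.55, m1 = 2.0, U50_1 = 1.5, m2 = 2.5,
             U50_2 = 3.5)
  cv <- gen_chem_curve(p3, grid = seq(0, 7, 0.2))
  fit <- fit_three_state_chem(cv)
  expect_true(fit$converged)
  shared <- c(m1 = 2.0, U50_1 = 1.5, m2 = 2.5, U50_2 = 3.5)
  expect_equal(fit$estimates[names(shared)], shared, tolerance = 1e-4)
  expect_lte(fit$estimates[["U50_1"]], fit$estimates[["U50_2"]])
  expect_false(fit$meta$recommend_two_state)
})

test_that("three-state fit flags data that a two-state model explains", {
  cv <- make_chem_curve(chem_scenarios$PsTRXh1_fluor,
                        grid = seq(0, 7, 0.25))
  fit <- fit_three_state_chem(cv)
  expect_true(fit$meta$recommend_two_state)
  expect_true(length(fit$flags) > 0)
})

test_that("joint two-probe fit shares thermodynamics across baselines", {
  th <- list(m1 = chem_scenarios$PsTRXh2_cd$m,
             U50_1 = chem_scenarios$PsTRXh2_cd$U50,
             m2 = chem_scenarios$PsTRXh2_fluor$m,
             U50_2 = chem_scenarios$PsTRXh2_fluor$U50)
  # CD loses its signal in the first transition; fluorescence only in
  # the second: probe-dependent apparent midpoints, shared energetics
  cd <- gen_chem_curve(c(th, list(alpha_N = -12, beta_N = 0.05,
                                  alpha_D = -1, beta_D = 0.02,
                                  alpha_I = -1.5)),
                       grid = seq(0, 7, 0.2), probe = "far-UV CD")
  fl <- gen_chem_curve(c(th, list(alpha_N = 340, beta_N = 0.1,
                                  alpha_D = 355, beta_D = 0.05,
                                  alpha_I = 341)),
                       grid = seq(0, 7, 0.2), probe = "fluorescence")
  fit <- fit_three_state_chem(list(cd, fl))
  expect_true(fit$converged)
  expect_equal(fit$estimates[["U50_1"]], th$U50_1, tolerance = 1e-4)
  expect_equal(fit$estimates[["U50_2"]], th$U50_2, tolerance = 1e-4)
  expect_equal(fit$estimates[["m1"]], th$m1, tolerance = 1e-3)
  expect_equal(fit$estimates[["m2"]], th$m2, tolerance = 1e-3)
})

test_that("nonlinear fit agrees with the brute-force grid oracle", {
  scn <- chem_scenarios$PsTRXf_fluor
  cv <- make_chem_curve(scn, grid = seq(0, 7, length.out = 15),
                        noise = noise_spec(0.02, seed = BASE_SEED + 99))
  gs <- grid_search_two_state(cv)
  fit <- fit_two_state_chem(cv)
  expect_lte(abs(gs$m - fit$estimates[["m"]]), 0.01 + 1e-9)
  expect_lte(abs(gs$U50 - fit$estimates[["U50"]]), 0.01 + 1e-9)
})
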