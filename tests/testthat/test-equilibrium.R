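test_that("keq reflects the equilibrium free energy", {
  # dG_eq = 0 gives K_eq = 1
  p <- equilibrium_params(dh_eq = 298.15 * 0.1, ds_eq = 0.1, dh_b = 0)
  expect_equal(keq(p, 298.15), 1)
  # ligand 0 at 298.15 K: dG_eq just under 0.3 kcal/mol, K_eq ~ 0.60
  p0 <- ligand_params()$l0
  dg_eq <- p0$dh_eq - 298.15 * p0$ds_eq
  expect_equal(round(dg_eq, 2), 0.30)
  expect_equal(keq(p0, 298.15),
               exp(-dg_eq / (gas_constant_kcal() * 298.15)))
  expect_equal(keq(p0, 298.15), 0.60, tolerance = 0.01)
  # an ever more uphill equilibrium empties the inactive state
  up <- equilibrium_params(1e4, 0.059, 0)
  expect_equal(keq(up, 298.15), 0)
  expect_error(keq(p0, -1), "positive")
})

test_that("apparent_enthalpy interpolates between its two limits", {
  p0 <- ligand_params()$l0
  expect_equal(apparent_enthalpy(p0, 298.15), -6.64, tolerance = 0.05)
  # fully active limit (dG_eq >> RT): dh_b
  cold <- equilibrium_params(30, 0, 2.5)
  expect_equal(apparent_enthalpy(cold, 300), 2.5, tolerance = 1e-8)
  # fully inactive limit (dG_eq << -RT): dh_b - dh_eq
  hot <- equilibrium_params(-30, 0, 2.5)
  expect_equal(apparent_enthalpy(hot, 300), 2.5 - (-30), tolerance = 1e-8)
  # monotone decreasing in T for dh_eq > 0, between the limits
  tt <- seq(250, 400, by = 5)
  h <- apparent_enthalpy(p0, tt)
  expect_true(all(diff(h) < 0))
  expect_true(all(h < p0$dh_b & h > p0$dh_b - p0$dh_eq))
})

test_that("apparent_cp is the analytic derivative of apparent_enthalpy", {
  # symmetric dip at the transition temperature
  ds <- 0.0582
  p <- equilibrium_params(dh_eq = 300 * ds, ds_eq = ds, dh_b = 1)
  expect_equal(apparent_cp(p, 300),
               -p$dh_eq^2 / (4 * gas_constant_kcal() * 300^2))
  # no equilibrium enthalpy, no heat capacity signal
  expect_equal(apparent_cp(equilibrium_params(0, 0.01, 1), 298.15), 0)
  # finite-difference identity at the across-ligand average parameters
  avg <- equilibrium_params(17.57, 0.0582, 0)
  val <- apparent_cp(avg, 298.15)
  h <- 1e-3
  fd <- (apparent_enthalpy(avg, 298.15 + h) -
           apparent_enthalpy(avg, 298.15 - h)) / (2 * h)
  expect_equal(val, fd, tolerance = 1e-6)
  expect_equal(val, -0.42, tolerance = 0.01)
})

test_that("apparent_free_energy adds the equilibrium depletion penalty", {
  pars <- ligand_params()
  expect_equal(apparent_free_energy(pars$l0, 298.15), -12.22,
               tolerance = 0.03)
  expect_equal(apparent_free_energy(pars$l2, 298.15), -11.99,
               tolerance = 0.03)
  # K_eq -> 0 regime leaves the true binding free energy
  p <- equilibrium_params(50, 0, 1, ds_b = 0.04)
  expect_equal(apparent_free_energy(p, 298.15), 1 - 298.15 * 0.04)
  # undefined ds_b is flagged, not silently zeroed
  expect_error(apparent_free_energy(equilibrium_params(17.5, 0.058, 1),
                                    298.15), "ds_b")
})

test_that("alternate_solution is the published transform and an involution", {
  p5 <- ligand_params()$l5
  alt <- alternate_solution(p5)
  expect_equal(alt$dh_eq, -17.50)
  expect_equal(alt$ds_eq, -0.0575)
  expect_equal(alt$dh_b, -16.00)
  expect_equal(alt$ds_b, -0.0098)
  back <- alternate_solution(alt)
  expect_equal(back[c("dh_eq", "ds_eq", "dh_b", "ds_b")],
               p5[c("dh_eq", "ds_eq", "dh_b", "ds_b")])
})

test_that("both solutions predict identical observables", {
  tt <- seq(283, 313, by = 5)
  for (p in ligand_params()) {
    alt <- alternate_solution(p)
    expect_equal(apparent_enthalpy(p, tt), apparent_enthalpy(alt, tt),
                 tolerance = 1e-9)
    expect_equal(apparent_free_energy(p, tt),
                 apparent_free_energy(alt, tt), tolerance = 1e-9)
    expect_equal(apparent_cp(p, tt), apparent_cp(alt, tt),
                 tolerance = 1e-9)
  }
})

test_that("fit_equilibrium recovers noise-free parameters exactly", {
  truth <- equilibrium_params(17.86, 0.0601, 3.69)
  tt <- seq(283, 313, length.out = 7)
  data <- itc_series(tt, apparent_enthalpy(truth, tt))
  fit <- fit_equilibrium(data)
  expect_equal(fit$params$dh_eq, truth$dh_eq, tolerance = 1e-6)
  expect_equal(fit$params$ds_eq, truth$ds_eq, tolerance = 1e-6)
  expect_equal(fit$params$dh_b, truth$dh_b, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_identical(fit$ds_b_source, "undefined")
  expect_true(is.na(fit$params$ds_b))
})

test_that("fit_equilibrium recovers noisy truth and solves ds_b", {
  truth <- equilibrium_params(17.86, 0.0601, 3.69)
  tt <- seq(283, 313, length.out = 9)
  data <- gen_itc_series(truth, tt, noise_sd = 0.1, seed = 3)
  fit <- fit_equilibrium(data, dg_app_ref = c(298.15, -12.54))
  expect_lt(abs(fit$params$dh_eq - truth$dh_eq) / truth$dh_eq, 0.10)
  expect_identical(fit$ds_b_source, "reference")
  # the reference free energy is reproduced by the fitted parameters
  expect_equal(apparent_free_energy(fit$params, 298.15), -12.54,
               tolerance = 1e-9)
  expect_true(all(is.finite(fit$se)))
  # inverting dG_app at the exact generating parameters pins ds_b
  exact <- fit_equilibrium(itc_series(tt, apparent_enthalpy(truth, tt)),
                           dg_app_ref = c(298.15, -12.54))
  expect_equal(round(exact$params$ds_b, 4), 0.0559)
})

test_that("fit_equilibrium honours the branch convention", {
  truth <- equilibrium_params(17.86, 0.0601, 3.69)
  tt <- seq(283, 313, length.out = 7)
  data <- itc_series(tt, apparent_enthalpy(truth, tt))
  pos <- fit_equilibrium(data, branch = "positive")
  neg <- fit_equilibrium(data, branch = "negative")
  expect_gt(pos$params$dh_eq, 0)
  expect_lt(neg$params$dh_eq, 0)
  # the two branches are each other's alternate solution
  alt <- alternate_solution(pos$params)
  expect_equal(alt$dh_eq, neg$params$dh_eq, tolerance = 1e-5)
  expect_equal(alt$dh_b, neg$params$dh_b, tolerance = 1e-5)
})

test_that("fit_equilibrium enforces its data precondition", {
  expect_error(fit_equilibrium(itc_series(c(283, 293), c(1, 2))),
               "insufficient")
})

test_that("summarize_equilibrium reproduces the across-ligand statistics", {
  s <- summarize_equilibrium(ligand_params())
  # the printed 17.57 rounds the exactly-midway mean 17.565 half-up
  expect_lt(abs(s$dh_eq_mean - 17.57), 0.00501)
  expect_lt(abs(s$dh_eq_sem - 0.13), 0.005)
  expect_lt(abs(s$ds_eq_mean - 0.0582), 0.00005)
  expect_equal(nrow(s$table), 6)
  # derived 298.15 K columns agree with direct evaluation for ligand 3
  row <- s$table[s$table$ligand == "l3", ]
  expect_equal(row$dH_app_298,
               apparent_enthalpy(ligand_params()$l3, 298.15))
  expect_equal(row$dG_eq_298, 17.86 - 298.15 * 0.0601)
})

test_that("ITC tables round-trip through delimited text", {
  s <- gen_itc_series(ligand_params()$l3, noise_sd = 0.1, seed = 9)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_itc_table(s, f)
  back <- read_itc_table(f)
  expect_equal(back$temperature, s$temperature)
  expect_equal(back$dh_app, s$dh_app, tolerance = 1e-12)
  expect_equal(back$sd, s$sd)
})
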