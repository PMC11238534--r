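test_that("end_to_end_series computes per-frame distances", {
  coords <- array(0, dim = c(1, 2, 3))
  coords[1, 2, ] <- c(3, 4, 0)
  atoms <- data.frame(name = c("N1", "C9"), resno = 1L, resid = "LIG",
                      chain = "A")
  ens <- coordinate_ensemble(coords, atoms)
  expect_equal(end_to_end_series(ens, list(name = "N1"),
                                 list(name = "C9")), 5)
  # rigid per-frame translation leaves distances unchanged
  co2 <- array(0, dim = c(3, 2, 3))
  for (f in 1:3) {
    co2[f, 1, ] <- c(0, 0, 0) + f * 10
    co2[f, 2, ] <- c(3, 4, 0) + f * 10
  }
  ens2 <- coordinate_ensemble(co2, atoms)
  expect_equal(end_to_end_series(ens2, 1, 2), rep(5, 3))
  expect_error(end_to_end_series(ens, list(resid = "LIG"), 2),
               "selection error")
})

test_that("distance_distribution normalises and tracks overflow", {
  d <- rep(5.2, 100)
  dd <- distance_distribution(d)
  expect_equal(sum(dd$probabilities), 1)
  expect_equal(max(dd$probabilities), 1)
  expect_equal(dd$n_overflow, 0)
  dd2 <- distance_distribution(c(d, 25, 1))
  expect_equal(dd2$n_overflow, 2)
  expect_equal(sum(dd2$probabilities), 1)
  expect_error(distance_distribution(numeric(0)), "insufficient")
  set.seed(2)
  expect_equal(sum(distance_distribution(runif(500, 3, 20))$probabilities),
               1)
})

test_that("two-state trajectories are bimodal at the expected modes", {
  tr <- gen_two_state_trajectory(two_state_spec(inactive_fraction = 0.4),
                                 seed = 5)
  modes <- distribution_modes(distance_distribution(tr$distances))
  expect_length(modes, 2)
  expect_lt(abs(min(modes) - 5.5), 0.75)
  expect_gt(max(modes), 11)
  # the sample mean sits between the two state means
  expect_gt(mean(tr$distances), 5.5)
  expect_lt(mean(tr$distances), 12.5)
})

test_that("state_fractions counts the three classes", {
  expect_equal(state_fractions(rep(5, 10), 8, 11),
               c(f_compact = 1, f_intermediate = 0, f_extended = 0))
  expect_equal(state_fractions(c(7, 9, 12), 8, 11),
               c(f_compact = 1 / 3, f_intermediate = 1 / 3,
                 f_extended = 1 / 3))
  expect_error(state_fractions(1:5, 11, 8), "compact_cut")
  set.seed(3)
  f <- state_fractions(runif(1000, 3, 20))
  expect_equal(sum(f), 1)
})

test_that("generator state fractions match their analytic expectations", {
  spec <- two_state_spec(inactive_fraction = 0.4)
  tr <- gen_two_state_trajectory(spec, seed = 5)
  # latent extended fraction: binomial, MC error ~ 0.005 at 1e4 frames
  expect_equal(mean(tr$states == "extended"), 0.4, tolerance = 0.03)
  # observed d > 11 fraction: mixture of truncated Gaussian tails
  p_expect <- 0.4 * pnorm(11, 12.5, 1.8, lower.tail = FALSE) +
    0.6 * pnorm(11, 5.5, 0.7, lower.tail = FALSE)
  f <- state_fractions(tr$distances)
  expect_equal(f[["f_extended"]], p_expect, tolerance = 0.03)
})

test_that("binned_energy_profile averages energies per distance bin", {
  d <- c(5.1, 5.2, 7.6)
  p0 <- binned_energy_profile(d, c(0, 0, 0))
  occ <- p0$count > 0
  expect_true(all(p0$mean_energy[occ] == 0))
  expect_true(all(is.na(p0$mean_energy[!occ])))  # empty bins are NA
  # identity signal: mean energy per bin equals mean distance per bin
  pid <- binned_energy_profile(d, d)
  expect_equal(pid$mean_energy[pid$count == 2], mean(c(5.1, 5.2)))
  expect_error(binned_energy_profile(1:3, 1:4), "alignment")
})

test_that("energy profiles recover the generator's opposing trends", {
  tr <- gen_two_state_trajectory(two_state_spec(inactive_fraction = 0.5),
                                 seed = 11)
  fit_slope <- function(prof) {
    ok <- prof$count >= 20
    coef(lm(prof$mean_energy[ok] ~ prof$bin_center[ok]))[2]
  }
  intra <- binned_energy_profile(tr$distances, tr$intra_energy)
  solv <- binned_energy_profile(tr$distances, tr$solvent_energy)
  expect_lt(fit_slope(intra), 0)  # intramolecular favours extension
  expect_gt(fit_slope(solv), 0)   # solvation opposes it
})

test_that("superpose_ensemble removes rigid motion and recovers the mean", {
  fx <- make_ca_structure(25)
  # single frame: average is the frame itself
  one <- coordinate_ensemble(array(fx$base, dim = c(1, 25, 3)), fx$atoms)
  s1 <- superpose_ensemble(one)
  expect_equal(s1$average, fx$base, ignore_attr = TRUE)
  # pure rigid motions collapse to zero pairwise RMSD
  co <- array(NA_real_, dim = c(5, 25, 3))
  for (f in 1:5) co[f, , ] <- rotate_translate(fx$base, angle = 0.3 * f,
                                               shift = c(f, -f, 2 * f))
  rig <- superpose_ensemble(coordinate_ensemble(co, fx$atoms))
  for (f in 2:5)
    expect_lt(sqrt(mean(rowSums((rig$ensemble$coords[f, , ] -
                                   rig$ensemble$coords[1, , ])^2))), 1e-6)
  # noisy ensemble: average structure approaches the generating base
  ens <- gen_ensemble(fx$base, fx$atoms, rep(0.3, 25), n_frames = 500,
                      seed = 21, rigid_motion = TRUE)
  sup <- superpose_ensemble(ens)
  expect_true(sup$converged)
  expect_lt(ca_rmsd(sup$average, fx$base), 0.05)
  expect_error(superpose_ensemble(ens, selection = 1:2), "degenerate")
})

test_that("ca_rmsd is zero under rigid motion and bounds perturbations", {
  fx <- make_ca_structure(100)
  expect_equal(ca_rmsd(fx$base, fx$base), 0)
  expect_lt(ca_rmsd(fx$base, rotate_translate(fx$base)), 1e-9)
  moved <- fx$base
  moved[7, ] <- moved[7, ] + c(1, 0, 0)
  r <- ca_rmsd(fx$base, moved)
  expect_gt(r, 0)
  expect_lte(r, sqrt(1 / 100))  # one 1-A displacement among 100 atoms
  expect_error(ca_rmsd(fx$base, fx$base[1:10, ]), "alignment")
})

test_that("rmsf_per_residue matches direct fluctuation formulas", {
  fx <- make_ca_structure(10)
  # static ensemble
  co <- array(rep(fx$base, each = 8), dim = c(8, 10, 3))
  expect_equal(rmsf_per_residue(coordinate_ensemble(co, fx$atoms))$rmsf,
               rep(0, 10))
  # one atom oscillating +/-1 A along x: its RMSF is exactly 1
  co[c(1, 3, 5, 7), 4, 1] <- co[c(1, 3, 5, 7), 4, 1] + 1
  co[c(2, 4, 6, 8), 4, 1] <- co[c(2, 4, 6, 8), 4, 1] - 1
  r <- rmsf_per_residue(coordinate_ensemble(co, fx$atoms))
  expect_equal(r$rmsf[r$resno == 4], 1)
  expect_equal(r$rmsf[r$resno != 4], rep(0, 9))
})

test_that("prescribed per-residue mobility is recovered after alignment", {
  fx <- make_ca_structure(30)
  sds <- seq(0.1, 1, length.out = 30)
  ens <- gen_ensemble(fx$base, fx$atoms, sds, n_frames = 300, seed = 2,
                      rigid_motion = TRUE)
  sup <- superpose_ensemble(ens)
  r <- rmsf_per_residue(sup$ensemble)
  expect_gt(cor(r$rmsf, sds, method = "spearman"), 0.95)
  # and matches the no-rigid-motion ensemble of the same displacement field
  plain <- gen_ensemble(fx$base, fx$atoms, sds, n_frames = 300, seed = 2,
                        rigid_motion = FALSE)
  r0 <- rmsf_per_residue(superpose_ensemble(plain)$ensemble)
  expect_equal(r$rmsf, r0$rmsf, tolerance = 0.02)
  # unaligned input with rigid motion triggers the drift warning
  expect_warning(rmsf_per_residue(ens), "drift")
})

test_that("rmsf_from_bfactors implements the isotropic relation", {
  expect_equal(rmsf_from_bfactors(0), 0)
  expect_equal(rmsf_from_bfactors(8 * pi^2 / 3), 1)
  expect_equal(rmsf_from_bfactors(20), sqrt(60 / (8 * pi^2)))
  expect_equal(rmsf_from_bfactors(20), 0.872, tolerance = 1e-3)
  expect_error(rmsf_from_bfactors(-1), "non-negative")
})

test_that("multi-model PDB files round-trip through bio3d", {
  fx <- make_ca_structure(12)
  ens <- gen_ensemble(fx$base, fx$atoms, rep(0.5, 12), n_frames = 4,
                      seed = 8)
  ens$bfactor <- seq(5, 60, length.out = 12)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(ens, f)
  back <- read_multimodel_pdb(f)
  expect_equal(n_frames(back), 4)
  expect_equal(back$coords, round(ens$coords, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(back$atoms$resno, fx$atoms$resno)
  expect_equal(back$atoms$name, fx$atoms$name)
  expect_equal(back$bfactor, ens$bfactor, tolerance = 0.01)
  # B-factor column flows into the RMSF conversion
  expect_equal(rmsf_from_bfactors(back$bfactor),
               sqrt(3 * back$bfactor / (8 * pi^2)))
})

test_that("distance observables are invariant to global rigid motion", {
  tr <- gen_two_state_trajectory(two_state_spec(inactive_fraction = 0.3,
                                                n_frames = 200),
                                 seed = 4, ensemble = TRUE)
  ens <- tr$ensemble
  co <- ens$coords
  for (f in seq_len(n_frames(ens)))
    co[f, , ] <- rotate_translate(co[f, , ], angle = 1.1,
                                  shift = c(-4, 8, 15))
  moved <- coordinate_ensemble(co, ens$atoms)
  expect_equal(end_to_end_series(moved, 1, 2),
               end_to_end_series(ens, 1, 2), tolerance = 1e-9)
})

test_that("superposition RMSD agrees with the bio3d reference", {
  fx <- make_ca_structure(40)
  set.seed(17)
  moved <- rotate_translate(fx$base + matrix(rnorm(120, sd = 0.4), 40, 3))
  ours <- ca_rmsd(fx$base, moved)
  ref <- bio3d::rmsd(as.vector(t(fx$base)), as.vector(t(moved)),
                     fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})
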