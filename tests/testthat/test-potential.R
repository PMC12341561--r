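test_that("ensemble uncertainty follows the population-std convention", {
  r <- ensemble_uncertainty(c(-1.23, -1.23, -1.23))
  expect_equal(r$uncertainty, 0)
  expect_false(r$uncertain)
  # two members one kcal/mol apart: population std is half the gap
  e <- kcalmol_to_hartree(c(0, 1))
  expect_equal(ensemble_uncertainty(e)$uncertainty, 0.5, tolerance = 1e-12)
  # threshold behaviour around the 0.36 kcal/mol default
  e2 <- kcalmol_to_hartree(c(0, 0.74))
  expect_equal(ensemble_uncertainty(e2)$uncertainty, 0.37, tolerance = 1e-12)
  expect_true(ensemble_uncertainty(e2)$uncertain)
  expect_false(ensemble_uncertainty(kcalmol_to_hartree(c(0, 0.70)))$uncertain)
  expect_error(ensemble_uncertainty(-1.0), "at least 2")
})

test_that("reaction-energy uncertainty forms per-member deltas first", {
  # perfectly correlated spreads cancel in the difference
  a <- c(-10.0, -10.1, -10.2)
  b <- a + 5.0
  r <- relative_energy_uncertainty(list(b, a), c(1, -1))
  expect_equal(r$uncertainty, 0)
  # independent noise: equals brute-force per-member enumeration
  set.seed(3)
  eA <- rnorm(8, -40, 1e-3); eB <- rnorm(8, -39.5, 1e-3)
  r2 <- relative_energy_uncertainty(list(eA, eB), c(-2, 1))
  manual <- hartree_to_kcalmol(deltadyn:::pop_sd(-2 * eA + eB))
  expect_equal(r2$uncertainty, manual, tolerance = 1e-12)
  expect_error(relative_energy_uncertainty(list(1, 1), c(1, -1)), "at least 2")
  expect_error(relative_energy_uncertainty(list(eA, eB[1:3]), c(1, -1)),
               "member counts differ")
})

test_that("bias-only networks add exact constants and identical members have zero spread", {
  ens <- bias_only_ensemble(tiny_ensemble("H", n_members = 3, seed = 2), 0.017)
  h <- dd_structure("H", rbind(c(0, 0, 0)))
  r <- nn_correction(h, ens)
  expect_equal(r$member_energies, rep(0.017, 3), tolerance = 1e-15)
  expect_equal(r$uncertainty, 0)
  # self-energy offsets add on top
  ens$self_energies["H"] <- -0.5
  expect_equal(nn_correction(h, ens)$mean, 0.017 - 0.5, tolerance = 1e-15)
})

test_that("the NN correction is extensive for well-separated fragments", {
  ens <- tiny_ensemble(n_members = 2, seed = 9)
  s <- random_cluster(c("C", "O", "H"), seed = 13)
  far <- dd_structure(c(s$elements, s$elements),
                      rbind(s$coordinates, s$coordinates + 40))
  eA <- nn_correction(s, ens)$member_energies
  eAB <- nn_correction(far, ens)$member_energies
  expect_lt_all(eAB - 2 * eA, 1e-10)
})

test_that("composite energy reduces to the baseline when NN and dispersion vanish", {
  els <- c("C", "O", "H", "H")
  s <- random_cluster(els, seed = 4)
  base <- morse_baseline(els)
  ens0 <- zero_ensemble(tiny_ensemble(n_members = 2))
  disp0 <- dispersion_term(els, c6 = c(H = 0, C = 0, N = 0, O = 0))
  r <- composite_energy(s, base, ens0, disp0)
  rb <- eval_structure(base, s)
  expect_equal(r$energy, rb$energy, tolerance = 1e-14)
  expect_lt_all(r$gradient - rb$gradient, 1e-14)
  expect_equal(r$components[["nn"]], 0)
  expect_equal(r$components[["dispersion"]], 0)
  # constant-shift ensemble moves the energy, not the gradient
  shift <- bias_only_ensemble(tiny_ensemble(n_members = 2), 0.01)
  r2 <- composite_energy(s, base, shift, disp0)
  expect_equal(r2$energy - r$energy, 4 * 0.01, tolerance = 1e-12)
  expect_lt_all(r2$gradient - r$gradient, 1e-10)
})

test_that("composite totals, charges and uncertainty are wired through", {
  els <- c("C", "O", "H", "H")
  s <- random_cluster(els, seed = 4)
  base <- morse_baseline(els)
  ens <- tiny_ensemble(n_members = 3, seed = 5)
  disp <- dispersion_term(els)
  r <- composite_energy(s, base, ens, disp)
  expect_equal(r$energy, sum(r$components), tolerance = 1e-12)
  expect_equal(r$charges, eval_structure(base, s)$charges)
  expect_length(r$dipole, 3L)
  expect_equal(r$uncertainty,
               ensemble_uncertainty(r$member_energies)$uncertainty)
})

test_that("composite gradient matches finite differences on a random cluster", {
  els <- c("C", "O", "H", "H", "N", "H")
  s <- random_cluster(els, seed = 31)
  pot <- composite_potential(morse_baseline(els),
                             tiny_ensemble(n_members = 2, seed = 3),
                             dispersion_term(els))
  x0 <- deltadyn:::flatten_coords(s)
  r <- pot_eval(pot, x0)
  expect_lt_all(r$gradient - fd_gradient(pot, x0), 1e-5)
})

test_that("swapping baselines changes only the baseline component", {
  els <- c("C", "O", "H")
  s <- random_cluster(els, seed = 8)
  ens <- tiny_ensemble(n_members = 2, seed = 1)
  disp <- dispersion_term(els)
  r1 <- composite_energy(s, morse_baseline(els), ens, disp)
  r2 <- composite_energy(s, morse_baseline(els, de_scale = 0.5), ens, disp)
  expect_identical(r1$components[["nn"]], r2$components[["nn"]])
  expect_identical(r1$components[["dispersion"]], r2$components[["dispersion"]])
  expect_false(r1$components[["baseline"]] == r2$components[["baseline"]])
})

test_that("composite Hessian: spring closed form, symmetry, translation sums", {
  # harmonic-spring baseline with known k, NN and dispersion off:
  # the diatomic Hessian has the analytic spring structure
  ref <- dd_structure(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  spr <- spring_model(ref, bonds = rbind(c(1, 2)), angles = NULL, k_bond = 0.4)
  H <- composite_hessian(ref, spr, fd_step = 5e-4)
  k_block <- matrix(0, 3, 3); k_block[1, 1] <- 0.4
  expect_lt_all(H[1:3, 1:3] - k_block, 1e-6)
  expect_lt_all(H[1:3, 4:6] + k_block, 1e-6)
  # full composite on a cluster: symmetric with near-zero row sums
  els <- c("C", "O", "H", "H")
  s <- random_cluster(els, seed = 4)
  ens <- tiny_ensemble(n_members = 2, seed = 3)
  Hc <- composite_hessian(s, morse_baseline(els), ens, dispersion_term(els))
  expect_lt_all(Hc - t(Hc), 1e-8)
  for (ax in 1:3)
    expect_lt_all(rowSums(Hc[, seq(ax, ncol(Hc), by = 3)]), 1e-5)
})

test_that("analytical NN Hessian matches finite differences of NN forces", {
  els <- c("C", "O", "H", "H")
  s <- random_cluster(els, seed = 4)
  ens <- tiny_ensemble(n_members = 2, seed = 3)
  Hnn <- nn_hessian(s, ens)
  x0 <- deltadyn:::flatten_coords(s)
  h <- 1e-5
  worst <- 0
  for (q in seq_along(x0)) {
    xp <- x0; xp[q] <- xp[q] + h
    xm <- x0; xm[q] <- xm[q] - h
    gp <- nn_correction(deltadyn:::set_coords(s, xp), ens, forces = TRUE)$gradient
    gm <- nn_correction(deltadyn:::set_coords(s, xm), ens, forces = TRUE)$gradient
    worst <- max(worst, max(abs(Hnn[, q] - (gp - gm) / (2 * h))))
  }
  expect_lt(worst, 1e-4)
})

test_that("dispersion is damped -C6/r^6 with analytical gradient", {
  els <- c("C", "C")
  d0 <- dispersion_term(els, c6 = c(C = 0, H = 0, N = 0, O = 0))
  s <- dd_structure(els, rbind(c(0, 0, 0), c(2, 0, 0)))
  r0 <- pairwise_dispersion(s, d0)
  expect_equal(r0$energy, 0)
  expect_true(all(r0$gradient == 0))
  # long range: damping -> 1 and the bare -C6/r^6 is recovered within 1%
  dt <- dispersion_term(els)
  far <- dd_structure(els, rbind(c(0, 0, 0), c(12, 0, 0)))
  e <- pairwise_dispersion(far, dt)$energy
  expect_lt(abs(e - (-8 / 12^6)) / (8 / 12^6), 0.01)
  expect_lt(e, 0)
  # analytical gradient vs finite differences
  s2 <- random_cluster(c("C", "O", "H"), seed = 17)
  dt2 <- dispersion_term(s2$elements)
  x0 <- deltadyn:::flatten_coords(s2)
  expect_lt_all(pot_eval(dt2, x0)$gradient - fd_gradient(dt2, x0), 1e-7)
  expect_error(pairwise_dispersion(
    s, dispersion_term(els, c6 = c(H = 1))), "missing")
})

test_that("uncertainty grows monotonically when an outlier member is added", {
  e <- c(-1.000, -1.001, -0.999)
  u0 <- ensemble_uncertainty(e)$uncertainty
  u1 <- ensemble_uncertainty(c(e, -0.990))$uncertainty
  expect_gt(u1, u0)
})
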