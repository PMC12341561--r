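test_that("delta datasets subtract the baseline level exactly", {
  s <- random_cluster(c("C", "O"), seed = 2)
  base <- morse_baseline()
  e_base <- eval_structure(base, s)$energy
  frames <- list(labeled_frame(s, e_base - 0.2))
  ds <- build_delta_dataset(frames, base)
  expect_equal(ds[[1]]$delta_energy, -0.2, tolerance = 1e-12)
  # identical high and baseline levels: all-zero deltas
  ds0 <- build_delta_dataset(list(labeled_frame(s, e_base)), base)
  expect_equal(ds0[[1]]$delta_energy, 0, tolerance = 1e-14)
})

test_that("constructed two-level deltas equal the perturbation", {
  task <- make_two_level_task(5, 30)
  ds <- build_delta_dataset(task$frames_high, task$low)
  for (i in c(1, 10, 30)) {
    bump <- eval_structure(task$perturbation, ds[[i]]$structure)
    expect_lt(abs(ds[[i]]$delta_energy - bump$energy), 1e-12)
    expect_lt_all(ds[[i]]$delta_forces -
                    (-deltadyn:::unflatten_coords(bump$gradient)), 1e-12)
  }
  # zero perturbation: all deltas vanish
  task0 <- make_two_level_task(5, 10, bump = list(amp = 0, r0 = 1.8, width = 0.5))
  ds0 <- build_delta_dataset(task0$frames_high, task0$low)
  expect_lt_all(vapply(ds0, `[[`, 1.0, "delta_energy"), 1e-14)
})

test_that("a constant delta is fitted to well below 1e-3 kcal/mol", {
  s <- random_cluster(c("C", "H", "H"), seed = 6)
  base <- morse_baseline()
  e_base <- eval_structure(base, s)$energy
  cc <- 0.0123
  frames <- replicate(12, labeled_frame(s, e_base + cc), simplify = FALSE)
  ds <- build_delta_dataset(frames, base)
  cfg <- train_config(aev = aev_small(), hidden = c(4), n_members = 2,
                      epochs = 5, w_force = 0, seed = 3, val_fraction = 0.25)
  ens <- train_delta_ensemble(ds, cfg)
  pred <- nn_correction(s, ens)$mean
  expect_lt(hartree_to_kcalmol(abs(pred - cc)), 1e-3)
})

test_that("training is deterministic: same seeds give identical parameters", {
  task <- make_two_level_task(8, 24)
  ds <- build_delta_dataset(task$frames_high, task$low)
  cfg <- train_config(aev = aev_small(), hidden = c(6, 4), n_members = 2,
                      epochs = 4, w_force = 0.1, seed = 17)
  e1 <- train_delta_ensemble(ds, cfg)
  e2 <- train_delta_ensemble(ds, cfg)
  expect_identical(coef(e1), coef(e2))
  expect_identical(e1$history$loss, e2$history$loss)
})

test_that("force-loss training requires delta forces", {
  s <- random_cluster(c("C", "O"), seed = 2)
  base <- morse_baseline()
  frames <- list(labeled_frame(s, eval_structure(base, s)$energy + 0.1))
  ds <- build_delta_dataset(frames, base)   # no forces on the frames
  cfg <- train_config(aev = aev_small(), hidden = c(4), n_members = 2,
                      epochs = 2, w_force = 0.1)
  expect_error(train_delta_ensemble(ds, cfg), "delta_forces")
})

test_that("the trained correction reduces the held-out error of the baseline", {
  task <- make_two_level_task(31, 160)
  ds <- build_delta_dataset(task$frames_high, task$low)
  cfg <- train_config(aev = aev_train(), hidden = c(10, 8), n_members = 2,
                      epochs = 30, patience = 30, lr = 1e-2, w_force = 0.1,
                      seed = 5)
  ens <- train_delta_ensemble(ds[1:120], cfg)
  held <- 121:160
  mae_comp <- mean(abs(residuals(ens, ds[held])))
  mae_base <- mean(hartree_to_kcalmol(
    abs(vapply(ds[held], `[[`, 1.0, "delta_energy"))))
  expect_lt(mae_comp, mae_base)
})

test_that("transfer learning freezes the declared layers exactly", {
  task <- make_two_level_task(12, 60)
  ds <- build_delta_dataset(task$frames_high, task$low)
  cfg <- train_config(aev = aev_small(), hidden = c(8, 6, 5), n_members = 2,
                      epochs = 8, w_force = 0, seed = 2)
  ens <- train_delta_ensemble(ds[1:40], cfg)
  ds2 <- build_delta_dataset(task$frames_transfer, task$low, stage = "transfer")

  # zero-epoch transfer is the identity
  cfg0 <- cfg; cfg0$epochs <- 0L
  expect_identical(transfer_learn(ens, ds2[1:40], cfg0)$members, ens$members)

  frozen <- function(e) lapply(e$members, function(m)
    lapply(m, function(net) net[c(1, 3)]))
  unfrozen <- function(e) lapply(e$members, function(m)
    lapply(m, function(net) net[c(2, 4)]))
  cfg2 <- cfg; cfg2$epochs <- 6L
  ens2 <- transfer_learn(ens, ds2[1:40], cfg2)
  expect_identical(frozen(ens2), frozen(ens))
  expect_false(identical(unfrozen(ens2), unfrozen(ens)))
  expect_equal(ens2$stage, "transfer")
  # frozen index outside the architecture
  cfg_bad <- cfg; cfg_bad$frozen_layers <- c(1L, 9L)
  expect_error(transfer_learn(ens, ds2[1:40], cfg_bad), "outside")
})

test_that("transfer learning reduces the error against the higher level", {
  task <- make_two_level_task(44, 140)
  ds <- build_delta_dataset(task$frames_high, task$low)
  ds2 <- build_delta_dataset(task$frames_transfer, task$low, stage = "transfer")
  cfg <- train_config(aev = aev_train(), hidden = c(10, 8, 6), n_members = 2,
                      epochs = 30, patience = 30, lr = 1e-2, w_force = 0.1,
                      seed = 9)
  ens <- train_delta_ensemble(ds[1:100], cfg)
  held <- 101:140
  pre <- mean(abs(residuals(ens, ds2[held])))
  cfg2 <- cfg; cfg2$epochs <- 25L; cfg2$lr <- 5e-3
  ens2 <- transfer_learn(ens, ds2[1:100], cfg2)
  post <- mean(abs(residuals(ens2, ds2[held])))
  expect_lt(post, pre)
})

test_that("threshold calibration matches a brute-force scan oracle", {
  # perfect predictions: everything is reliable
  r <- threshold_scan(rep(0, 5), c(0.1, 0.2, 0.3, 0.4, 0.5), target_mae = 1)
  expect_identical(r$threshold, Inf)
  expect_false(r$degenerate)
  # errors grow monotonically with the spread: threshold sits at the
  # last point whose inclusion still meets the target
  err <- c(0.1, 0.2, 0.4, 0.8, 1.6)
  unc <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  r2 <- threshold_scan(err, unc, target_mae = 0.4)
  # brute force: try every prefix of the uncertainty-sorted points
  o <- order(unc)
  ok <- which(cumsum(err[o]) / seq_along(err) <= 0.4)
  expect_equal(r2$threshold, unc[o][max(ok)])
  # randomised case against the same independent enumeration
  set.seed(99)
  err3 <- runif(40); unc3 <- runif(40)
  r3 <- threshold_scan(err3, unc3, target_mae = 0.45)
  o3 <- order(unc3)
  cm <- cumsum(err3[o3]) / seq_along(err3)
  ok3 <- which(cm <= 0.45)
  expected <- if (length(ok3) == 0) min(unc3)
              else if (max(ok3) == 40) Inf else unc3[o3][max(ok3)]
  expect_equal(r3$threshold, expected)
  # no subset meets the target: smallest uncertainty, flagged degenerate
  r4 <- threshold_scan(c(5, 6), c(0.2, 0.3), target_mae = 1)
  expect_true(r4$degenerate)
  expect_equal(r4$threshold, 0.2)
  expect_error(threshold_scan(numeric(0), numeric(0), 1), "empty")
})

test_that("calibrate_threshold wires ensemble predictions into the scan", {
  s <- random_cluster(c("C", "H"), seed = 3)
  ens <- bias_only_ensemble(tiny_ensemble(n_members = 2), 0.0)
  holdout <- list(list(structure = s, delta_energy = 0.0))
  r <- calibrate_threshold(ens, holdout, target_mae = 0.1)
  expect_identical(r$threshold, Inf)
  expect_error(calibrate_threshold(ens, list(), 0.1), "empty")
})
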