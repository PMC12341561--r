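test_that("velocity Verlet reproduces the harmonic oscillator and is reversible", {
  u <- dd_units()
  k <- 0.3
  bowl <- harmonic_bowl(0, k = k)
  om <- sqrt(k * u$acc_factor)
  period <- 2 * pi / om
  seg <- propagate(list(coords = 0.5, velocities = 0), bowl,
                   dt = period / 1000, t_end = 10 * period)
  expect_lt_all(seg$coords[, 1] - 0.5 * cos(om * seg$times), 1e-4)
  # zero velocity at an exact minimum stays put
  still <- propagate(list(coords = 0, velocities = 0), bowl, dt = 0.1,
                     t_end = 10)
  expect_true(all(still$coords == 0))
  # symplectic reversibility: negate velocities and integrate back
  seg1 <- propagate(list(coords = 0.5, velocities = 0.01), bowl,
                    dt = 0.05, t_end = 5)
  n <- nrow(seg1$coords)
  seg2 <- propagate(list(coords = seg1$coords[n, ],
                         velocities = -seg1$velocities[n, ]), bowl,
                    dt = 0.05, t_end = 5)
  expect_lt(abs(seg2$coords[nrow(seg2$coords), 1] - 0.5), 1e-8)
})

test_that("sampling gives exact zero-point energies in the T -> 0 limit", {
  surf <- make_bifurcating_surface(asymmetry = 0)
  row <- surf$catalog[surf$catalog$name == "TS_ambimodal", ]
  ts <- characterize_point(surf, c(row$x, row$y))
  spec <- sampling_spec(temperature = 1e-8, n_samples = 25, seed = 4)
  ics <- sample_initial_conditions(ts, ts$modes, spec)
  u <- dd_units()
  lam <- ts$modes$eigenvalues
  hnu <- u$h_hartree_fs * sqrt(lam[lam > 0] * u$acc_factor) / (2 * pi)
  em <- attr(ics, "mode_energies")
  expect_true(all(em == matrix(hnu / 2, nrow(em), ncol(em), byrow = TRUE)))
  # the realised displacement/velocity reproduce the mode energy
  minv <- 1 / sqrt(ts$modes$masses)
  for (i in c(1, 25)) {
    dx <- (ics[[i]]$coords - ts$coords) / minv
    Q <- as.vector(crossprod(ts$modes$modes, dx))
    Qd <- as.vector(crossprod(ts$modes$modes, ics[[i]]$velocities / minv))
    real_mode <- which(lam > 1e-8)
    e_mode <- (0.5 * Qd[real_mode]^2 + 0.5 * lam[real_mode] * u$acc_factor *
                 Q[real_mode]^2) * u$mass_vel2_to_hartree
    expect_lt(abs(e_mode - hnu / 2), 1e-12)
  }
})

test_that("sampling refuses non-saddle input and is seed-reproducible", {
  surf <- make_bifurcating_surface(asymmetry = 0)
  rmin <- surf$catalog[surf$catalog$name == "reactant", ]
  min_pt <- characterize_point(surf, c(rmin$x, rmin$y))
  spec <- sampling_spec(n_samples = 3, seed = 1)
  expect_error(sample_initial_conditions(min_pt, min_pt$modes, spec),
               "order")
  row <- surf$catalog[surf$catalog$name == "TS_ambimodal", ]
  ts <- characterize_point(surf, c(row$x, row$y))
  a <- sample_initial_conditions(ts, ts$modes, spec)
  b <- sample_initial_conditions(ts, ts$modes, spec)
  expect_identical(a[], b[])
  expect_error(sampling_spec(temperature = -5), "positive")
})

test_that("combining enforces shared initial conditions and the signed time axis", {
  bowl <- harmonic_bowl(c(0, 0), k = 0.4)
  ic <- list(coords = c(0.4, -0.1), velocities = c(0.01, 0.02))
  fwd <- propagate(ic, bowl, dt = 0.1, t_end = 0.2)        # 3 frames
  bwd <- propagate(ic, bowl, dt = 0.1, t_end = 0.2, direction = "backward")
  tr <- combine(fwd, bwd)
  expect_length(tr$times, 5L)                               # 3 + 3 - 1
  expect_true(all(diff(tr$times) > 0))
  expect_equal(tr$times, c(-0.2, -0.1, 0, 0.1, 0.2))
  expect_equal(tr$coords[3, ], ic$coords)
  # energy series continuous at t = 0 (same frame kept once)
  expect_equal(tr$etot[3], fwd$etot[1])
  # mismatched initial conditions are rejected
  ic2 <- list(coords = c(0.5, -0.1), velocities = c(0.01, 0.02))
  bwd2 <- propagate(ic2, bowl, dt = 0.1, t_end = 0.2, direction = "backward")
  expect_error(combine(fwd, bwd2), "initial condition")
  # a (dt = 0.1, 500 fs) pair spans [-500, 500] with 10001 frames
  expect_equal(length(seq(0, 500, by = 0.1)) * 2 - 1, 10001L)
})

test_that("bond-event classification follows the reactive-trajectory rule", {
  # constructed 4-atom frames: reactant at early negative times, then
  # bond 1-2 forms, later bond 3-4 forms (product P2)
  times <- seq(-100, 100, by = 1)
  nf <- length(times)
  d12 <- ifelse(times < -20, 3.0, 1.4)
  d34 <- ifelse(times < 40, 3.0, 1.3)
  coords <- t(vapply(seq_len(nf), function(i) {
    c(0, 0, 0, d12[i], 0, 0, 0, 5, 0, d34[i], 5, 0)
  }, numeric(12)))
  traj <- structure(list(times = times, coords = coords,
                         velocities = coords * 0,
                         epot = numeric(nf), etot = numeric(nf),
                         id = 1L, blown_up = FALSE),
                    class = "combined_trajectory")
  reactant <- product_definition("reactant", list(
    list(pair = c(1, 2), type = "broken", threshold = 1.6),
    list(pair = c(3, 4), type = "broken", threshold = 1.6)))
  p1 <- product_definition("P1", list(
    list(pair = c(1, 2), type = "formed", threshold = 1.6),
    list(pair = c(3, 4), type = "broken", threshold = 1.6)))
  p2 <- product_definition("P2", list(
    list(pair = c(1, 2), type = "formed", threshold = 1.6),
    list(pair = c(3, 4), type = "formed", threshold = 1.6)))
  oc <- classify(traj, reactant, list(p2), persistence = 30)
  expect_equal(oc$label, "P2")
  expect_true(oc$reactive)
  expect_equal(unname(oc$bond_times$P2), c(-20, 40))
  # never leaving the reactant state
  coords_r <- coords; coords_r[, 4] <- 3.0; coords_r[, 10] <- 0 + 3.0
  traj_r <- traj; traj_r$coords <- coords_r
  expect_equal(classify(traj_r, reactant, list(p1, p2),
                        persistence = 30)$label, "reactant-only")
})

test_that("the persistence window ignores sub-window spikes", {
  times <- seq(0, 200, by = 1)
  d <- rep(3.0, length(times))
  d[times >= 50 & times < 55] <- 1.4      # 5 fs spike
  d[times >= 120] <- 1.4                  # persistent formation at 120 fs
  coords <- cbind(0, 0, 0, d, 0, 0)
  traj <- structure(list(times = times, coords = coords,
                         velocities = coords * 0,
                         epot = numeric(length(times)),
                         etot = numeric(length(times)),
                         id = 1L, blown_up = FALSE),
                    class = "combined_trajectory")
  p <- product_definition("P", list(
    list(pair = c(1, 2), type = "formed", threshold = 1.6)))
  oc <- classify(traj,
                 product_definition("R", list(
                   list(pair = c(1, 2), type = "broken", threshold = 1.6))),
                 list(p), persistence = 50)
  expect_equal(unname(oc$bond_times$P["1-2"]), 120)
})

test_that("evaluation bookkeeping matches the analytic count", {
  expect_equal(plan_evaluations(1000, 500, 0.1), 1e7)
  expect_equal(plan_evaluations(2, 1, 0.1), 40)
  surf <- make_bifurcating_surface(asymmetry = 0)
  row <- surf$catalog[surf$catalog$name == "TS_ambimodal", ]
  ts <- characterize_point(surf, c(row$x, row$y))
  counted <- counted_potential(surf)
  spec <- sampling_spec(n_samples = 3, seed = 6)
  run <- run_dynamics(ts, ts$modes, counted, spec, dt = 0.1, t_end = 2)
  # per-segment force calls sum to the plan; the one-off shared initial
  # gradient per trajectory is the only extra call on the potential
  expect_equal(run$n_force_evals, plan_evaluations(3, 2, 0.1))
  expect_equal(evaluation_count(counted), run$n_force_evals + 3L)
})
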