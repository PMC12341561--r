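mk_outcome <- function(label, gap = NULL) {
  bt <- list()
  if (!is.null(gap) && label %in% c("P1", "P2"))
    bt[[label]] <- c(a = 0, b = gap)
  structure(list(label = label, reactive = label %in% c("P1", "P2"),
                 present = NULL, bond_times = bt),
            class = "trajectory_outcome")
}

test_that("product ratios are reported in the 1 : x form", {
  expect_equal(format_ratio(c(P1 = 10, P2 = 520)), "1 : 52")
  expect_equal(format_ratio(c(5, 5)), "1 : 1")
  expect_equal(format_ratio(c(3, 0)), "undefined")
  expect_error(format_ratio(c(1, 2, 3)), "two counts")
})

test_that("outcome statistics count, label and bootstrap correctly", {
  outs <- c(replicate(10, mk_outcome("P1"), simplify = FALSE),
            replicate(520, mk_outcome("P2"), simplify = FALSE),
            replicate(5, mk_outcome("reactant-only"), simplify = FALSE))
  st <- outcome_statistics(outs, bootstrap_reps = 200, seed = 3)
  expect_equal(st$product_counts[["P1"]], 10)
  expect_equal(st$product_counts[["P2"]], 520)
  expect_equal(st$ratio, "1 : 52")
  expect_equal(st$ratio_value, 52)
  expect_equal(sum(st$counts), 535)
  expect_true(st$ratio_ci[1] <= 52 && 52 <= st$ratio_ci[2])
  # degenerate ensemble of identical labels: zero-width interval
  same <- replicate(30, mk_outcome("P2"), simplify = FALSE)
  st2 <- outcome_statistics(c(same, list(mk_outcome("P1"))),
                            bootstrap_reps = 50, seed = 1)
  expect_true(all(is.finite(st2$major_fraction_ci)))
  st3 <- outcome_statistics(same, product_names = "P2",
                            bootstrap_reps = 50, seed = 1)
  expect_equal(st3$ratio, "undefined")
})

test_that("inter-bond time gaps average as constructed", {
  outs <- list(mk_outcome("P2", gap = 100), mk_outcome("P2", gap = 200),
               mk_outcome("P2", gap = 300), mk_outcome("reactant-only"))
  st <- outcome_statistics(outs, product_names = c("P1", "P2"),
                           bootstrap_reps = 10, seed = 1)
  expect_equal(st$mean_gap, 200)
  expect_equal(st$median_gap, 200)
  expect_length(st$bond_gaps, 3L)
})

test_that("energy-conservation report uses the population convention", {
  mk_traj <- function(etot) structure(
    list(times = seq_along(etot), coords = matrix(0, length(etot), 2),
         velocities = matrix(0, length(etot), 2),
         epot = etot, etot = etot, id = 1L, blown_up = FALSE),
    class = "combined_trajectory")
  # exactly conserved: zero
  expect_equal(energy_conservation_report(list(mk_traj(rep(-1, 10))))$sd, 0)
  # series {E, E + 2}: population std is 1 (in the reporting unit)
  e2 <- kcalmol_to_hartree(c(5, 7))
  expect_equal(energy_conservation_report(list(mk_traj(e2)))$sd, 1,
               tolerance = 1e-12)
  expect_error(energy_conservation_report(list(mk_traj(1))), "one frame")
  # paired comparison
  r <- energy_conservation_report(list(mk_traj(e2)),
                                  list(mk_traj(kcalmol_to_hartree(c(5, 13)))))
  expect_equal(r$ratio, 4)
  expect_equal(r$fraction_alt_larger, 1)
})

test_that("coarser time steps conserve energy worse at O(dt^2)", {
  surf <- make_bifurcating_surface(asymmetry = 0)
  row <- surf$catalog[surf$catalog$name == "TS_ambimodal", ]
  ts <- characterize_point(surf, c(row$x, row$y))
  spec <- sampling_spec(n_samples = 10, seed = 21)
  ics <- sample_initial_conditions(ts, ts$modes, spec)
  run_at <- function(dt) lapply(ics, function(ic) {
    fwd <- propagate(ic, surf, dt = dt, t_end = 60)
    bwd <- propagate(ic, surf, dt = dt, t_end = 60, direction = "backward")
    combine(fwd, bwd)
  })
  rep_big <- energy_conservation_report(run_at(0.5), run_at(1.0))
  expect_gte(rep_big$fraction_alt_larger, 0.9)
  # halving the step cuts the fluctuation roughly fourfold
  expect_gt(median(rep_big$ratio), 2.5)
  expect_lt(median(rep_big$ratio), 6)
})
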