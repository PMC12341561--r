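test_that("cosine cutoff has the closed-form values and vanishes beyond Rc", {
  expect_equal(cutoff_fn(0, 4), 1.0)
  expect_equal(cutoff_fn(4, 4), 0.0)
  expect_equal(cutoff_fn(2, 4.0), 0.5)  # 0.5 cos(pi/2) + 0.5
  expect_identical(cutoff_fn(4.0001, 4), 0)
  expect_error(cutoff_fn(-0.1, 4), "negative")
})

test_that("descriptor length follows the declared grid layout", {
  p <- aev_params()
  expect_equal(p$n_features, 4 * 16 + 10 * 8 * 4)
  expect_equal(p$rc_angular, 4.0)
  expect_error(aev_params(rc_angular = 6), "rc_angular")
  expect_error(aev_params(rs_radial = c(1, 6)), "below rc_radial")
})

test_that("isolated and beyond-cutoff atoms give all-zero vectors", {
  p <- aev_small()
  one <- dd_structure("C", rbind(c(0, 0, 0)))
  expect_true(all(compute_aev(one, p) == 0))
  two <- dd_structure(c("C", "C"), rbind(c(0, 0, 0), c(6.0, 0, 0)))
  expect_true(all(compute_aev(two, p) == 0))
  expect_error(compute_aev(
    dd_structure("F", rbind(c(0, 0, 0)), supported_elements = "F"), p),
    "outside the descriptor element set")
})

test_that("H-H radial term at a shift centre equals the cutoff value", {
  p <- aev_params(elements = "H", rc_radial = 5.2, eta_r = 16,
                  rs_radial = 1.0, theta_s = pi / 2, rs_angular = 0.9,
                  rc_angular = 4.0)
  s <- dd_structure(c("H", "H"), rbind(c(0, 0, 0), c(1.0, 0, 0)))
  g <- compute_aev(s, p)
  expect_equal(g[1, 1], cutoff_fn(1.0, 5.2), tolerance = 1e-12)
  expect_equal(g[2, 1], g[1, 1])
})

test_that("analytical Jacobian matches central finite differences", {
  s <- random_cluster(c("C", "H", "N", "O", "H"), seed = 42)
  p <- aev_small()
  res <- aev_with_jacobian(s, p)
  x0 <- as.vector(t(s$coordinates))
  h <- 1e-5
  worst <- 0
  for (q in seq_along(x0)) {
    xp <- x0; xp[q] <- xp[q] + h
    xm <- x0; xm[q] <- xm[q] - h
    fd <- (compute_aev(deltadyn:::set_coords(s, xp), p) -
             compute_aev(deltadyn:::set_coords(s, xm), p)) / (2 * h)
    for (a in seq_len(n_atoms(s)))
      worst <- max(worst, max(abs(res$jacobian[[a]][, q] - fd[a, ])))
  }
  expect_lt(worst, 1e-6)
  # isolated atom: zero Jacobian
  ji <- aev_jacobian(dd_structure("C", rbind(c(0, 0, 0))), p)
  expect_true(all(ji[[1]] == 0))
})

test_that("diatomic Jacobian is antisymmetric under swapping displacements", {
  p <- aev_small()
  s <- dd_structure(c("C", "O"), rbind(c(0, 0, 0), c(1.3, 0, 0)))
  jac <- aev_jacobian(s, p)
  expect_lt_all(jac[[1]][, 1:3] + jac[[1]][, 4:6], 1e-14)
  expect_lt_all(jac[[2]][, 1:3] + jac[[2]][, 4:6], 1e-14)
})

test_that("weighted second derivatives match finite differences of the Jacobian", {
  s <- random_cluster(c("C", "O", "H", "H"), seed = 11)
  p <- aev_small()
  set.seed(1)
  W <- matrix(rnorm(n_atoms(s) * p$n_features), n_atoms(s))
  H <- deltadyn:::aev_weighted_hessian(s, p, W)
  expect_lt_all(H - t(H), 1e-12)
  x0 <- as.vector(t(s$coordinates))
  gfun <- function(x) {
    r <- aev_with_jacobian(deltadyn:::set_coords(s, x), p)
    g <- numeric(length(x))
    for (a in seq_len(n_atoms(s)))
      g <- g + as.vector(W[a, ] %*% r$jacobian[[a]])
    g
  }
  h <- 1e-5
  worst <- 0
  for (q in seq_along(x0)) {
    xp <- x0; xp[q] <- xp[q] + h
    xm <- x0; xm[q] <- xm[q] - h
    worst <- max(worst, max(abs(H[, q] - (gfun(xp) - gfun(xm)) / (2 * h))))
  }
  expect_lt(worst, 1e-6)
})

test_that("descriptors are invariant under rigid motions and permutations", {
  s <- random_cluster(c("C", "H", "H", "O", "N"), seed = 7)
  p <- aev_small()
  a0 <- compute_aev(s, p)
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  s2 <- s
  s2$coordinates <- s$coordinates %*% R +
    matrix(rep(c(1.5, -2, 0.7), each = n_atoms(s)), ncol = 3)
  expect_lt_all(compute_aev(s2, p) - a0, 1e-10)
  # swapping the two H atoms permutes rows but leaves values identical
  s3 <- s
  s3$coordinates <- s$coordinates[c(1, 3, 2, 4, 5), ]
  a3 <- compute_aev(s3, p)
  expect_identical(a3[2, ], a0[3, ])
  expect_identical(a3[3, ], a0[2, ])
  expect_identical(a3[1, ], a0[1, ])
})

test_that("perturbing an atom beyond the cutoff leaves a centre's AEV bit-identical", {
  p <- aev_small()
  xyz <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(8, 0, 0))
  s <- dd_structure(c("C", "O", "H"), xyz)
  a0 <- compute_aev(s, p)
  xyz2 <- xyz; xyz2[3, ] <- c(9, 1, -2)
  a1 <- compute_aev(dd_structure(c("C", "O", "H"), xyz2), p)
  expect_identical(a1[1, ], a0[1, ])
  expect_identical(a1[2, ], a0[2, ])
})
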