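test_that("minimisation solves quadratic and Morse problems", {
  bowl <- harmonic_bowl(c(0.3, -0.2, 1.1), k = 0.7)
  sp <- minimize(c(1, 1, 1), bowl, tol_grad = 1e-8, project = FALSE)
  expect_lt_all(sp$coords - bowl$center, 1e-6)
  expect_equal(sp$order, 0L)
  # starting at the exact minimum returns immediately
  sp0 <- minimize(bowl$center, bowl, project = FALSE)
  expect_equal(sp0$n_steps, 0L)
  # Morse diatomic: equilibrium distance equals the covalent-radius sum
  b <- morse_baseline(c("C", "C"))
  spm <- minimize(dd_structure(c("C", "C"), rbind(c(0, 0, 0), c(1.2, 0, 0))),
                  b, tol_grad = 1e-8)
  xyz <- deltadyn:::unflatten_coords(spm$coords)
  expect_lt(abs(sqrt(sum((xyz[2, ] - xyz[1, ])^2)) - 1.54), 1e-5)
  # non-convergence carries the best point
  err <- tryCatch(minimize(c(5, 5, 5), bowl, tol_grad = 1e-10, max_steps = 1L,
                           project = FALSE),
                  nonconvergence_error = function(e) e)
  expect_s3_class(err$point, "stationary_point")
})

test_that("saddle search finds both catalogued saddles of the model surface", {
  surf <- make_bifurcating_surface()
  for (nm in c("TS_ambimodal", "TS_products")) {
    row <- surf$catalog[surf$catalog$name == nm, ]
    start <- c(row$x + 0.25, row$y + 0.2)
    sp <- find_saddle(start, surf, tol_grad = 1e-8)
    expect_lt_all(sp$coords - c(row$x, row$y), 1e-4)
    expect_equal(sp$order, 1L)
    expect_equal(sum(sp$frequencies < 0), 1L)
  }
})

test_that("a quadratic saddle converges immediately; a bowl never succeeds", {
  # z = x^2/2 - y^2/2 has an exact saddle at the origin
  quad <- analytic_surface(function(z)
    list(energy = 0.5 * z[1]^2 - 0.5 * z[2]^2,
         gradient = c(z[1], -z[2])), 2L)
  sp <- find_saddle(c(0, 0), quad, tol_grad = 1e-8)
  expect_equal(sp$n_steps, 0L)
  expect_equal(sp$order, 1L)
  bowl <- harmonic_bowl(c(0, 0), k = 0.5)
  res <- tryCatch(find_saddle(c(0.4, 0.1), bowl, project = FALSE),
                  wrong_order_error = function(e) "wrong_order",
                  nonconvergence_error = function(e) "nonconvergence")
  expect_true(res %in% c("wrong_order", "nonconvergence"))
})

test_that("harmonic diatomic frequency matches sqrt(k/mu)/(2 pi c)", {
  ref <- dd_structure(c("O", "H"), rbind(c(0, 0, 0), c(0.97, 0, 0)))
  k <- 0.5
  spr <- spring_model(ref, bonds = rbind(c(1, 2)), angles = NULL, k_bond = k)
  nm <- normal_modes(ref, spr)
  m <- atomic_masses(c("O", "H"))
  mu <- prod(m) / sum(m)
  expect_equal(max(nm$frequencies), sqrt(k / mu) * dd_units()$freq_to_cm1,
               tolerance = 1e-4)
  # 3N - 5 modes for a linear molecule
  expect_length(nm$frequencies, 1L)
})

test_that("projection removes rigid modes: free atom and bent triatomic", {
  # free atom: everything is projected away
  free <- harmonic_bowl(c(0, 0, 0), k = 0)
  free$elements <- "C"
  nm <- normal_modes(c(0, 0, 0), free, masses = rep(12.011, 3),
                     project = TRUE)
  expect_true(all(abs(nm$frequencies) < 1e-6))
  # water-like spring model: exactly 3N - 6 = 3 genuine modes
  w <- dd_structure(c("O", "H", "H"),
                    rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
  nmw <- normal_modes(w, spring_model(w))
  expect_length(nmw$frequencies, 3L)
  expect_true(all(nmw$frequencies > 100))
  # mode vectors are orthonormal
  G <- crossprod(nmw$modes)
  expect_lt_all(G - diag(ncol(G)), 1e-8)
})

test_that("Kabsch RMSD: identity, rigid-motion invariance, symmetry, triangle", {
  s <- random_cluster(c("C", "O", "H", "H"), seed = 12)
  expect_equal(rmsd_kabsch(s, s), 0)
  th <- 0.9
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  s2 <- s
  s2$coordinates <- s$coordinates %*% R +
    matrix(rep(c(2, -1, 3), each = 4), ncol = 3)
  expect_lt(rmsd_kabsch(s, s2), 1e-8)
  s3 <- s
  s3$coordinates <- s$coordinates + matrix(rnorm(12, sd = 0.2), 4, 3)
  expect_equal(rmsd_kabsch(s, s3), rmsd_kabsch(s3, s), tolerance = 1e-10)
  expect_lte(rmsd_kabsch(s2, s3),
             rmsd_kabsch(s2, s) + rmsd_kabsch(s, s3) + 1e-10)
  expect_error(rmsd_kabsch(s, random_cluster(c("C", "O"), seed = 1)),
               "atom counts")
})

test_that("Kabsch matches a brute-force rotation-grid oracle", {
  set.seed(44)
  a <- matrix(rnorm(12), 4, 3)
  b <- a
  b[2, ] <- b[2, ] + c(0.4, 0, 0)    # one atom displaced 0.4 A
  # rotation-search oracle: Euler-angle grid plus local refinement,
  # fully independent of the SVD route
  ca <- sweep(a, 2, colMeans(a)); cb <- sweep(b, 2, colMeans(b))
  euler_R <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  }
  obj <- function(ang) sqrt(mean(rowSums((ca - cb %*% euler_R(ang))^2)))
  grid <- seq(0, 2 * pi, length.out = 9)[-9]
  best <- Inf; best_ang <- c(0, 0, 0)
  for (az in grid) for (ay in grid) for (ax in grid) {
    v <- obj(c(az, ay, ax))
    if (v < best) { best <- v; best_ang <- c(az, ay, ax) }
  }
  best <- stats::optim(best_ang, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 5000))$value
  expect_lt(abs(rmsd_kabsch(a, b, align_elements = FALSE) - best), 1e-3)
})
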