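# Shared helpers: reduced descriptor grids and tiny ensembles keep the
# unit tests fast while exercising every code path.

aev_small <- function(elements = c("H", "C", "N", "O")) {
  aev_params(elements = elements,
             rs_radial = c(0.9, 1.9, 2.9, 3.9),
             theta_s = pi / 8 + (0:3) * pi / 4,
             rs_angular = c(0.9, 2.0, 3.1),
             zeta = 8)
}

# reduced grid used by the training-based checks
aev_train <- function() {
  aev_params(rs_radial = 0.8 + (0:7) * 0.55,
             theta_s = pi / 8 + (0:3) * pi / 4,
             rs_angular = c(0.9, 1.9, 2.9), zeta = 16)
}

# a random non-clashing cluster with fixed composition
random_cluster <- function(elements, seed = 1, spread = 1.3, min_dist = 0.95) {
  set.seed(seed)
  n <- length(elements)
  repeat {
    xyz <- matrix(stats::runif(3 * n, -spread, spread), n, 3)
    if (n < 2L || min(stats::dist(xyz)) > min_dist) break
  }
  dd_structure(elements, xyz)
}

tiny_ensemble <- function(elements = c("H", "C", "N", "O"), n_members = 3,
                          hidden = c(10, 8, 6), seed = 5) {
  ens <- nn_ensemble(aev = aev_small(elements), hidden = hidden,
                     n_members = n_members, seed = seed)
  # untrained networks carry a zero output layer; give the derivative
  # tests a fully non-trivial function by randomising it
  set.seed(seed + 77)
  L <- length(ens$members[[1]][[1]])
  ens$members <- lapply(ens$members, function(m) lapply(m, function(net) {
    net[[L]]$W[] <- stats::rnorm(length(net[[L]]$W), 0, 0.05)
    net[[L]]$b <- stats::rnorm(length(net[[L]]$b), 0, 0.01)
    net
  }))
  ens
}

# set every weight and bias of every member to zero
zero_ensemble <- function(ens) {
  ens$members <- lapply(ens$members, function(m)
    lapply(m, function(net) lapply(net, function(l)
      list(W = l$W * 0, b = l$b * 0))))
  ens
}

# set all weights to zero and the output bias to `b` for every element
bias_only_ensemble <- function(ens, b) {
  ens <- zero_ensemble(ens)
  L <- length(ens$members[[1]][[1]])
  ens$members <- lapply(ens$members, function(m)
    lapply(m, function(net) { net[[L]]$b <- b; net }))
  ens
}

# central finite-difference gradient of a potential
fd_gradient <- function(pot, x, h = 1e-5) {
  vapply(seq_along(x), function(q) {
    xp <- x; xp[q] <- xp[q] + h
    xm <- x; xm[q] <- xm[q] - h
    (pot_eval(pot, xp)$energy - pot_eval(pot, xm)$energy) / (2 * h)
  }, 1.0)
}

expect_lt_all <- function(x, bound) expect_lt(max(abs(x)), bound)
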