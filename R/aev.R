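#' Atomic environment vector parameters
#'
#' Grid and cutoff parameters of the ANI-style atomic environment vector
#' (AEV): smooth-cutoff radial Gaussian shells per neighbour element, and
#' angular terms per unordered neighbour-element pair.  Defaults follow
#' the ANI-1x layout, except that the angular cutoff is 4.0 Angstrom
#' (increased from the customary 3.5 Angstrom for a better description of
#' longer-range interactions).
#'
#' @param elements supported element symbols (order fixes the descriptor
#'   block layout)
#' @param rc_radial radial cutoff, Angstrom
#' @param rc_angular angular cutoff, Angstrom (must not exceed `rc_radial`)
#' @param eta_r radial Gaussian width, 1/Angstrom^2
#' @param rs_radial radial shift grid, Angstrom (all < `rc_radial`)
#' @param eta_a angular radial width, 1/Angstrom^2
#' @param rs_angular angular radial shift grid, Angstrom (all < `rc_angular`)
#' @param theta_s angular shift grid, radians
#' @param zeta angular sharpness exponent (> 0)
#' @return An object of class `aev_params`; its `n_features` field is the
#'   per-atom descriptor length
#'   `n_el * |rs_radial| + n_el(n_el+1)/2 * |theta_s| * |rs_angular|`.
#' @examples
#' p <- aev_params()
#' p$n_features  # 384 for 4 elements with the default grids
#' @export
aev_params <- function(elements = c("H", "C", "N", "O"),
                       rc_radial = 5.2,
                       rc_angular = 4.0,
                       eta_r = 16.0,
                       rs_radial = 0.9 + (0:15) * (5.2 - 0.9) / 16,
                       eta_a = 8.0,
                       rs_angular = c(0.90, 1.55, 2.20, 2.85),
                       theta_s = pi / 16 + (0:7) * pi / 8,
                       zeta = 32.0) {
  if (rc_angular > rc_radial)
    stop("rc_angular must not exceed rc_radial")
  if (any(rs_radial >= rc_radial))
    stop("all radial shifts must lie below rc_radial")
  if (any(rs_angular >= rc_angular))
    stop("all angular radial shifts must lie below rc_angular")
  if (zeta <= 0) stop("zeta must be positive")
  n_el <- length(elements)
  n_pairs <- n_el * (n_el + 1L) / 2L
  # unordered element-pair block lookup
  pair_index <- matrix(0L, n_el, n_el)
  k <- 0L
  for (a in seq_len(n_el)) for (b in a:n_el) {
    k <- k + 1L
    pair_index[a, b] <- k
    pair_index[b, a] <- k
  }
  p <- list(elements = elements, rc_radial = rc_radial, rc_angular = rc_angular,
            eta_r = eta_r, rs_radial = rs_radial, eta_a = eta_a,
            rs_angular = rs_angular, theta_s = theta_s, zeta = zeta,
            pair_index = pair_index,
            n_radial = n_el * length(rs_radial),
            n_angular = n_pairs * length(theta_s) * length(rs_angular))
  p$n_features <- p$n_radial + p$n_angular
  class(p) <- "aev_params"
  p
}

#' @export
print.aev_params <- function(x, ...) {
  cat(sprintf(paste0("<aev_params> elements [%s], Rc radial %.2f A, ",
                     "angular %.2f A, %d features (%d radial + %d angular)\n"),
              paste(x$elements, collapse = ","), x$rc_radial, x$rc_angular,
              x$n_features, x$n_radial, x$n_angular))
  invisible(x)
}

#' Smooth cosine cutoff function
#'
#' `0.5 cos(pi r / Rc) + 0.5` for `r <= Rc` and exactly 0 beyond; C^1
#' continuous at `r = Rc`.
#'
#' @param r distance(s), Angstrom (non-negative)
#' @param rc cutoff, Angstrom (positive)
#' @return dimensionless value(s) in \[0, 1\]
#' @examples
#' cutoff_fn(0, 4)    # 1
#' cutoff_fn(2, 4)    # 0.5
#' cutoff_fn(4.5, 4)  # 0
#' @export
cutoff_fn <- function(r, rc) {
  if (any(r < 0)) stop("negative distance passed to cutoff_fn")
  if (any(rc <= 0)) stop("cutoff must be positive")
  ifelse(r <= rc, 0.5 * cos(pi * r / rc) + 0.5, 0)
}

# cutoff value + first/second derivatives at scalar r (r <= rc assumed)
.fc123 <- function(r, rc) {
  a <- pi / rc
  list(f = 0.5 * cos(a * r) + 0.5,
       d1 = -0.5 * a * sin(a * r),
       d2 = -0.5 * a * a * cos(a * r))
}

# numerical guard used in the angle: cos(theta) is scaled by this factor
# before acos so derivatives stay finite at collinear geometries (the
# customary regularisation of this descriptor family)
.ANGLE_SCALE <- 0.95

# angular scalar part A(theta_d) and derivatives w.r.t. cos(theta), for
# all theta_s at once.  Returns vectors over theta_s.
.angular_A <- function(cth, theta_s, zeta) {
  u <- .ANGLE_SCALE * cth
  th <- acos(u)
  om <- 1 - u * u
  th1 <- -.ANGLE_SCALE / sqrt(om)                 # dtheta/dc
  th2 <- -.ANGLE_SCALE^2 * u / om^1.5             # d2theta/dc2
  phi <- th - theta_s
  base <- 1 + cos(phi)
  A <- base^zeta
  dA_dth <- -zeta * base^(zeta - 1) * sin(phi)
  d2A_dth2 <- zeta * (zeta - 1) * base^(pmax(zeta - 2, 0)) * sin(phi)^2 -
    zeta * base^(zeta - 1) * cos(phi)
  list(A = A,
       Ac = dA_dth * th1,
       Acc = d2A_dth2 * th1 * th1 + dA_dth * th2)
}

# radial scalar part of the angular term: R(r1,r2) = E(m) f(r1) f(r2),
# m = (r1+r2)/2, for all rs_angular at once.  Returns vectors over rs.
.angular_R <- function(r1, r2, rs, eta_a, rc) {
  f1 <- .fc123(r1, rc); f2 <- .fc123(r2, rc)
  m <- 0.5 * (r1 + r2)
  dm <- m - rs
  E <- exp(-eta_a * dm * dm)
  E1 <- -2 * eta_a * dm * E                       # dE/dm
  E2 <- (-2 * eta_a + 4 * eta_a^2 * dm * dm) * E  # d2E/dm2
  list(R = E * f1$f * f2$f,
       R1 = 0.5 * E1 * f1$f * f2$f + E * f1$d1 * f2$f,
       R2 = 0.5 * E1 * f1$f * f2$f + E * f1$f * f2$d1,
       R11 = 0.25 * E2 * f1$f * f2$f + E1 * f1$d1 * f2$f + E * f1$d2 * f2$f,
       R22 = 0.25 * E2 * f1$f * f2$f + E1 * f1$f * f2$d1 + E * f1$f * f2$d2,
       R12 = 0.25 * E2 * f1$f * f2$f + 0.5 * E1 * (f1$f * f2$d1 + f1$d1 * f2$f) +
         E * f1$d1 * f2$d1)
}

# radial AEV scalar g(r) = exp(-eta (r - rs)^2) fc(r) and derivatives,
# vectors over rs_radial
.radial_g <- function(r, rs, eta_r, rc) {
  fc <- .fc123(r, rc)
  d <- r - rs
  e <- exp(-eta_r * d * d)
  e1 <- -2 * eta_r * d * e
  e2 <- (-2 * eta_r + 4 * eta_r^2 * d * d) * e
  list(g = e * fc$f,
       g1 = e1 * fc$f + e * fc$d1,
       g2 = e2 * fc$f + 2 * e1 * fc$d1 + e * fc$d2)
}

# first and second derivatives of cos(theta) w.r.t. v1 = x_j - x_i and
# v2 = x_k - x_i (each 3-vectors); returns gradient (6) and blocks (3x3)
.cos_derivs <- function(v1, v2, r1, r2) {
  u1 <- v1 / r1; u2 <- v2 / r2
  c0 <- sum(u1 * u2)
  dc1 <- (u2 - c0 * u1) / r1
  dc2 <- (u1 - c0 * u2) / r2
  I3 <- diag(3)
  H11 <- (-(outer(u2, u1) + outer(u1, u2)) + 3 * c0 * outer(u1, u1) -
            c0 * I3) / r1^2
  H22 <- (-(outer(u1, u2) + outer(u2, u1)) + 3 * c0 * outer(u2, u2) -
            c0 * I3) / r2^2
  H12 <- (I3 - outer(u2, u2) - outer(u1, u1) + c0 * outer(u1, u2)) / (r1 * r2)
  list(c = c0, u1 = u1, u2 = u2, dc1 = dc1, dc2 = dc2,
       H11 = H11, H22 = H22, H12 = H12)
}

#' Compute atomic environment vectors
#'
#' Radial terms `sum_j exp(-eta_R (R_ij - Rs)^2) fC(R_ij)` grouped by
#' neighbour element, and angular terms
#' `2^(1-zeta) sum_{j<k} (1 + cos(theta_ijk - theta_s))^zeta
#'  exp(-eta_A ((R_ij+R_ik)/2 - Rs_A)^2) fC(R_ij) fC(R_ik)`
#' grouped by unordered neighbour-element pair.  Atoms beyond the cutoff
#' contribute exactly zero.  The descriptor is invariant under global
#' rotation/translation and under permutation of same-element neighbours.
#'
#' @param structure a [dd_structure()] whose elements are all in
#'   `params$elements`
#' @param params an [aev_params()] object
#' @return numeric matrix, one row per atom, `params$n_features` columns.
#' @export
compute_aev <- function(structure, params) {
  .aev_core(structure, params, want_jacobian = FALSE)$aev
}

#' Atomic environment vectors with analytical Jacobians
#'
#' @param structure a [dd_structure()]
#' @param params an [aev_params()]
#' @return list with `aev` (N x D matrix) and `jacobian`, a list of one
#'   D x 3N matrix per atom: `jacobian[[a]][d, ]` is the derivative of
#'   feature d of atom a with respect to all Cartesian coordinates
#'   (Angstrom^-1).
#' @export
aev_with_jacobian <- function(structure, params) {
  .aev_core(structure, params, want_jacobian = TRUE)
}

#' Jacobian of the atomic environment vectors
#'
#' Convenience wrapper around [aev_with_jacobian()] returning only the
#' per-atom derivative matrices.
#'
#' @inheritParams aev_with_jacobian
#' @return list of D x 3N matrices, one per atom.
#' @export
aev_jacobian <- function(structure, params) {
  .aev_core(structure, params, want_jacobian = TRUE)$jacobian
}

# shared value/Jacobian engine
.aev_core <- function(structure, params, want_jacobian = FALSE) {
  stopifnot(inherits(structure, "dd_structure"), inherits(params, "aev_params"))
  el_idx <- match(structure$elements, params$elements)
  if (anyNA(el_idx))
    stop("structure contains element(s) outside the descriptor element set: ",
         paste(unique(structure$elements[is.na(el_idx)]), collapse = ", "))
  n <- n_atoms(structure)
  D <- params$n_features
  xyz <- structure$coordinates
  n_rs <- length(params$rs_radial)
  n_th <- length(params$theta_s)
  n_ra <- length(params$rs_angular)
  n_ang_feat <- n_th * n_ra
  K <- 2^(1 - params$zeta)
  aev <- matrix(0, n, D)
  jac <- if (want_jacobian) lapply(seq_len(n), function(i) matrix(0, D, 3L * n))
  rmat <- if (n > 1L) as.matrix(stats::dist(xyz)) else matrix(0, 1, 1)

  for (i in seq_len(n)) {
    nb_r <- which(rmat[i, ] <= params$rc_radial & seq_len(n) != i)
    # radial part
    for (j in nb_r) {
      r <- rmat[i, j]
      g <- .radial_g(r, params$rs_radial, params$eta_r, params$rc_radial)
      cols <- (el_idx[j] - 1L) * n_rs + seq_len(n_rs)
      aev[i, cols] <- aev[i, cols] + g$g
      if (want_jacobian) {
        u <- (xyz[j, ] - xyz[i, ]) / r
        ja <- 3L * (j - 1L) + 1:3
        ia <- 3L * (i - 1L) + 1:3
        contrib <- outer(g$g1, u)
        jac[[i]][cols, ja] <- jac[[i]][cols, ja] + contrib
        jac[[i]][cols, ia] <- jac[[i]][cols, ia] - contrib
      }
    }
    # angular part
    nb_a <- nb_r[rmat[i, nb_r] <= params$rc_angular]
    if (length(nb_a) >= 2L) {
      for (jj in seq_len(length(nb_a) - 1L)) for (kk in (jj + 1L):length(nb_a)) {
        j <- nb_a[jj]; k <- nb_a[kk]
        r1 <- rmat[i, j]; r2 <- rmat[i, k]
        v1 <- xyz[j, ] - xyz[i, ]; v2 <- xyz[k, ] - xyz[i, ]
        cd <- .cos_derivs(v1, v2, r1, r2)
        A <- .angular_A(cd$c, params$theta_s, params$zeta)
        R <- .angular_R(r1, r2, params$rs_angular, params$eta_a,
                        params$rc_angular)
        blk <- params$pair_index[el_idx[j], el_idx[k]]
        cols <- params$n_radial + (blk - 1L) * n_ang_feat + seq_len(n_ang_feat)
        # feature vector, theta varying fastest within each rs_angular
        aev[i, cols] <- aev[i, cols] + K * as.vector(outer(A$A, R$R))
        if (want_jacobian) {
          Fc <- K * as.vector(outer(A$Ac, R$R))
          Fr1 <- K * as.vector(outer(A$A, R$R1))
          Fr2 <- K * as.vector(outer(A$A, R$R2))
          dj <- outer(Fr1, cd$u1) + outer(Fc, cd$dc1)
          dk <- outer(Fr2, cd$u2) + outer(Fc, cd$dc2)
          ja <- 3L * (j - 1L) + 1:3; ka <- 3L * (k - 1L) + 1:3
          ia <- 3L * (i - 1L) + 1:3
          jac[[i]][cols, ja] <- jac[[i]][cols, ja] + dj
          jac[[i]][cols, ka] <- jac[[i]][cols, ka] + dk
          jac[[i]][cols, ia] <- jac[[i]][cols, ia] - dj - dk
        }
      }
    }
  }
  list(aev = aev, jacobian = jac)
}

# Weighted sum of AEV second derivatives: given per-atom feature weights
# W (N x D), returns the 3N x 3N matrix sum_a sum_d W[a,d] d2 G_{a,d}/dx2.
# This is the descriptor half of the analytical network Hessian.
aev_weighted_hessian <- function(structure, params, W) {
  el_idx <- match(structure$elements, params$elements)
  n <- n_atoms(structure)
  stopifnot(nrow(W) == n, ncol(W) == params$n_features)
  xyz <- structure$coordinates
  n_rs <- length(params$rs_radial)
  n_th <- length(params$theta_s)
  n_ra <- length(params$rs_angular)
  K <- 2^(1 - params$zeta)
  H <- matrix(0, 3L * n, 3L * n)
  rmat <- if (n > 1L) as.matrix(stats::dist(xyz)) else matrix(0, 1, 1)
  I3 <- diag(3)

  add_block <- function(H, a, b, M) {
    ia <- 3L * (a - 1L) + 1:3; ib <- 3L * (b - 1L) + 1:3
    H[ia, ib] <- H[ia, ib] + M
    H
  }

  for (i in seq_len(n)) {
    w <- W[i, ]
    nb_r <- which(rmat[i, ] <= params$rc_radial & seq_len(n) != i)
    for (j in nb_r) {
      r <- rmat[i, j]
      g <- .radial_g(r, params$rs_radial, params$eta_r, params$rc_radial)
      cols <- (el_idx[j] - 1L) * n_rs + seq_len(n_rs)
      w1 <- sum(w[cols] * g$g1)
      w2 <- sum(w[cols] * g$g2)
      u <- (xyz[j, ] - xyz[i, ]) / r
      M <- w2 * outer(u, u) + w1 * (I3 - outer(u, u)) / r
      H <- add_block(H, j, j, M)
      H <- add_block(H, i, i, M)
      H <- add_block(H, i, j, -M)
      H <- add_block(H, j, i, -M)
    }
    nb_a <- nb_r[rmat[i, nb_r] <= params$rc_angular]
    if (length(nb_a) >= 2L) {
      for (jj in seq_len(length(nb_a) - 1L)) for (kk in (jj + 1L):length(nb_a)) {
        j <- nb_a[jj]; k <- nb_a[kk]
        r1 <- rmat[i, j]; r2 <- rmat[i, k]
        v1 <- xyz[j, ] - xyz[i, ]; v2 <- xyz[k, ] - xyz[i, ]
        cd <- .cos_derivs(v1, v2, r1, r2)
        A <- .angular_A(cd$c, params$theta_s, params$zeta)
        R <- .angular_R(r1, r2, params$rs_angular, params$eta_a,
                        params$rc_angular)
        blk <- params$pair_index[el_idx[j], el_idx[k]]
        cols <- params$n_radial + (blk - 1L) * n_th * n_ra + seq_len(n_th * n_ra)
        Wm <- matrix(w[cols], n_th, n_ra)   # theta fastest
        # weighted partial sums over features: F = K A(theta) R(r1,r2)
        qf <- function(av, rv) K * as.numeric(crossprod(av, Wm %*% rv))
        Fc <- qf(A$Ac, R$R);  Fr1 <- qf(A$A, R$R1);  Fr2 <- qf(A$A, R$R2)
        Fcc <- qf(A$Acc, R$R)
        Fr1r1 <- qf(A$A, R$R11); Fr2r2 <- qf(A$A, R$R22)
        Fr1r2 <- qf(A$A, R$R12)
        Fcr1 <- qf(A$Ac, R$R1);  Fcr2 <- qf(A$Ac, R$R2)
        # gradients of (r1, r2, c) in the 6-dim (v1, v2) space
        G1 <- c(cd$u1, 0, 0, 0)
        G2 <- c(0, 0, 0, cd$u2)
        Gc <- c(cd$dc1, cd$dc2)
        H6 <- Fr1r1 * outer(G1, G1) + Fr2r2 * outer(G2, G2) +
          Fcc * outer(Gc, Gc) +
          Fr1r2 * (outer(G1, G2) + outer(G2, G1)) +
          Fcr1 * (outer(Gc, G1) + outer(G1, Gc)) +
          Fcr2 * (outer(Gc, G2) + outer(G2, Gc))
        # curvature of r1, r2, c themselves
        H6[1:3, 1:3] <- H6[1:3, 1:3] + Fr1 * (I3 - outer(cd$u1, cd$u1)) / r1 +
          Fc * cd$H11
        H6[4:6, 4:6] <- H6[4:6, 4:6] + Fr2 * (I3 - outer(cd$u2, cd$u2)) / r2 +
          Fc * cd$H22
        H6[1:3, 4:6] <- H6[1:3, 4:6] + Fc * cd$H12
        H6[4:6, 1:3] <- H6[4:6, 1:3] + Fc * t(cd$H12)
        # map (v1, v2) blocks onto atoms (i, j, k)
        Hjj <- H6[1:3, 1:3]; Hkk <- H6[4:6, 4:6]
        Hjk <- H6[1:3, 4:6]; Hkj <- H6[4:6, 1:3]
        H <- add_block(H, j, j, Hjj)
        H <- add_block(H, k, k, Hkk)
        H <- add_block(H, j, k, Hjk)
        H <- add_block(H, k, j, Hkj)
        H <- add_block(H, i, j, -(Hjj + Hkj))
        H <- add_block(H, j, i, -(Hjj + Hjk))
        H <- add_block(H, i, k, -(Hkk + Hjk))
        H <- add_block(H, k, i, -(Hkk + Hkj))
        H <- add_block(H, i, i, Hjj + Hjk + Hkj + Hkk)
      }
    }
  }
  H
}
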