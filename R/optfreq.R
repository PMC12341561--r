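# Geometry optimisation, transition-state search and harmonic analysis,
# potential-agnostic: everything operates through pot_eval/pot_hessian
# on flat coordinate vectors (3N Cartesians or analytic-surface
# coordinates).

# resolve a start argument (dd_structure or numeric) to flat coords
.as_coords <- function(start) {
  if (inherits(start, "dd_structure")) flatten_coords(start) else as.numeric(start)
}

#' Characterise a point on a potential
#'
#' Computes energy, gradient norm, the Hessian with its mass-unweighted
#' eigenvalues, the Hessian index (count of negative mass-weighted
#' eigenvalues after projection) and harmonic frequencies.
#'
#' @param potential a potential object
#' @param x flat coordinates (or a `dd_structure`)
#' @param project remove translations/rotations before counting the
#'   index?  Default: TRUE for Cartesian molecular potentials, FALSE for
#'   low-dimensional analytic surfaces.
#' @return object of class `stationary_point` with fields `coords`,
#'   `energy`, `grad_norm` (max absolute gradient component), `hessian`,
#'   `hessian_eigenvalues`, `order`, `frequencies` (cm^-1, imaginary
#'   modes negative), `modes` (the [normal_modes()] result).
#' @export
characterize_point <- function(potential, x, project = NULL) {
  x <- .as_coords(x)
  r <- pot_eval(potential, x)
  H <- pot_hessian(potential, x)
  if (is.null(project)) project <- .is_molecular(potential)
  nm <- normal_modes(x, potential, project = project, hessian = H)
  structure(list(coords = x, energy = r$energy,
                 grad_norm = max(abs(r$gradient)),
                 hessian = H,
                 hessian_eigenvalues = eigen(H, symmetric = TRUE,
                                             only.values = TRUE)$values,
                 order = nm$order, frequencies = nm$frequencies,
                 modes = nm),
            class = "stationary_point")
}

.is_molecular <- function(potential) {
  !is.null(potential$elements) ||
    (inherits(potential, "counted_potential") && .is_molecular(potential$inner))
}

#' @export
print.stationary_point <- function(x, ...) {
  cat(sprintf("<stationary_point> E = %.8f Ha, max|g| = %.2e, order %d\n",
              x$energy, x$grad_norm, x$order))
  fr <- x$frequencies
  if (length(fr) > 0)
    cat("  frequencies (cm^-1):", paste(sprintf("%.1f", fr), collapse = ", "),
        "\n")
  invisible(x)
}

#' Minimise a potential
#'
#' BFGS with backtracking (Armijo) line search: the energy is
#' non-increasing across accepted steps.  Converges when the largest
#' absolute gradient component drops to `tol_grad`; the converged point
#' is characterised (Hessian, index, frequencies).
#'
#' @param start starting geometry (`dd_structure` or flat coordinates)
#' @param potential potential providing energy and gradient
#' @param tol_grad convergence threshold on max |gradient component|,
#'   Hartree/Angstrom
#' @param max_steps iteration cap
#' @param project see [characterize_point()]
#' @return a `stationary_point` with `n_steps`; raises a
#'   `nonconvergence_error` (carrying the best point found in field
#'   `point`) when `max_steps` is exhausted.
#' @export
minimize <- function(start, potential, tol_grad = 4.5e-4, max_steps = 500L,
                     project = NULL) {
  x <- .as_coords(start)
  d <- length(x)
  r <- pot_eval(potential, x)
  if (max(abs(r$gradient)) <= tol_grad) {
    sp <- characterize_point(potential, x, project)
    sp$n_steps <- 0L
    return(sp)
  }
  B <- diag(d)   # inverse-Hessian approximation
  for (it in seq_len(max_steps)) {
    p <- -as.vector(B %*% r$gradient)
    # backtracking line search on the energy
    alpha <- 1
    repeat {
      x_new <- x + alpha * p
      r_new <- pot_eval(potential, x_new)
      if (is.finite(r_new$energy) &&
          r_new$energy <= r$energy + 1e-4 * alpha * sum(r$gradient * p)) break
      alpha <- alpha / 2
      if (alpha < 1e-12) break
    }
    s <- x_new - x
    yv <- r_new$gradient - r$gradient
    sy <- sum(s * yv)
    if (sy > 1e-14) {
      rho <- 1 / sy
      I <- diag(d)
      B <- (I - rho * outer(s, yv)) %*% B %*% (I - rho * outer(yv, s)) +
        rho * outer(s, s)
    }
    x <- x_new; r <- r_new
    if (max(abs(r$gradient)) <= tol_grad) {
      sp <- characterize_point(potential, x, project)
      sp$n_steps <- it
      return(sp)
    }
  }
  best <- characterize_point(potential, x, project)
  best$n_steps <- max_steps
  cond <- structure(
    list(message = sprintf(
           "minimize: not converged after %d steps (max|g| = %.2e)",
           max_steps, max(abs(r$gradient))),
         call = NULL, point = best),
    class = c("nonconvergence_error", "error", "condition"))
  stop(cond)
}

#' Saddle-point (transition-state) optimisation
#'
#' Partitioned rational-function (eigenvector-following) optimisation:
#' the step maximises the energy along the lowest Hessian eigenvector
#' and minimises along all others, within a trust radius.  The Hessian
#' is recomputed every `hessian_every` steps and carried between
#' recomputations by the Bofill update.  The converged point is
#' re-characterised with a fresh Hessian and must have exactly one
#' negative (projected) eigenvalue — the transition-state acceptance
#' rule of one imaginary frequency.
#'
#' @inheritParams minimize
#' @param trust trust radius (maximum step norm), Angstrom
#' @param hessian_every recompute the exact Hessian every this many steps
#' @return a `stationary_point` of order 1 with `n_steps`.  Raises
#'   `wrong_order_error` (with the characterised point in field `point`)
#'   when the converged point is not an index-1 saddle, and
#'   `nonconvergence_error` when `max_steps` is exhausted.
#' @export
find_saddle <- function(start, potential, tol_grad = 4.5e-4, max_steps = 200L,
                        trust = 0.1, hessian_every = 5L, project = NULL) {
  x <- .as_coords(start)
  d <- length(x)
  r <- pot_eval(potential, x)
  H <- pot_hessian(potential, x)
  for (it in seq_len(max_steps)) {
    if (max(abs(r$gradient)) <= tol_grad) {
      sp <- characterize_point(potential, x, project)
      sp$n_steps <- it - 1L
      if (sp$order != 1L) {
        cond <- structure(
          list(message = sprintf(
                 "find_saddle: converged to a stationary point of order %d, not 1",
                 sp$order),
               call = NULL, point = sp),
          class = c("wrong_order_error", "error", "condition"))
        stop(cond)
      }
      return(sp)
    }
    ei <- eigen((H + t(H)) / 2, symmetric = TRUE)
    lam <- ei$values[d:1]; V <- ei$vectors[, d:1, drop = FALSE]  # ascending
    gq <- as.vector(crossprod(V, r$gradient))
    # uphill along the lowest mode
    lam_p <- 0.5 * lam[1] + 0.5 * sqrt(lam[1]^2 + 4 * gq[1]^2)
    p <- (gq[1] / (lam_p - lam[1] + 1e-14)) * V[, 1]
    # downhill along the rest via the RFO shift
    if (d > 1L) {
      Maug <- rbind(cbind(diag(lam[-1], d - 1L), gq[-1]),
                    c(gq[-1], 0))
      lam_n <- min(eigen(Maug, symmetric = TRUE, only.values = TRUE)$values)
      for (i in 2:d) p <- p + gq[i] / (lam_n - lam[i] - 1e-14) * V[, i]
    }
    pn <- sqrt(sum(p * p))
    if (pn > trust) p <- p * trust / pn
    x_new <- x + p
    r_new <- pot_eval(potential, x_new)
    if (!is.finite(r_new$energy))
      stop("find_saddle: non-finite energy encountered")
    if (it %% hessian_every == 0L) {
      H <- pot_hessian(potential, x_new)
    } else {
      H <- bofill_update(H, x_new - x, r_new$gradient - r$gradient)
    }
    x <- x_new; r <- r_new
  }
  best <- characterize_point(potential, x, project)
  best$n_steps <- max_steps
  cond <- structure(
    list(message = sprintf(
           "find_saddle: not converged after %d steps (max|g| = %.2e)",
           max_steps, max(abs(r$gradient))),
         call = NULL, point = best),
    class = c("nonconvergence_error", "error", "condition"))
  stop(cond)
}

# Bofill quasi-Newton Hessian update (SR1/PSB blend), suited to saddles
bofill_update <- function(H, s, y) {
  E <- y - as.vector(H %*% s)
  ss <- sum(s * s); EE <- sum(E * E); sE <- sum(s * E)
  if (ss < 1e-20 || EE < 1e-20) return(H)
  phi <- sE^2 / (ss * EE)
  dH_psb <- (outer(E, s) + outer(s, E)) / ss - sE * outer(s, s) / ss^2
  dH_sr1 <- if (abs(sE) > 1e-12) outer(E, E) / sE else dH_psb
  H + phi * dH_sr1 + (1 - phi) * dH_psb
}

#' Harmonic normal-mode analysis
#'
#' Mass-weights the Hessian, optionally projects out rigid translations
#' and rotations (Eckart projection), diagonalises, and converts
#' eigenvalues to wavenumbers `nu = sign(lambda) sqrt(|lambda|)/(2 pi c)`
#' with imaginary modes reported as negative numbers.
#'
#' @param point geometry (`dd_structure` or flat coordinates)
#' @param potential potential providing the Hessian
#' @param masses per-coordinate masses, amu (default from the potential)
#' @param project project out translations/rotations? (for 3D Cartesian
#'   systems)
#' @param hessian optionally a precomputed Hessian
#' @return object of class `normal_modes`: `frequencies` (cm^-1, sorted
#'   ascending, projected rigid modes removed), `modes` (mass-weighted
#'   orthonormal columns matching `frequencies`), `eigenvalues`
#'   (Hartree/(Angstrom^2 amu)), `order` (count of imaginary physical
#'   modes), `projected` flag, `masses`.
#' @export
normal_modes <- function(point, potential, masses = NULL, project = TRUE,
                         hessian = NULL) {
  x <- .as_coords(point)
  d <- length(x)
  if (is.null(masses)) masses <- pot_masses(potential)
  stopifnot(length(masses) == d)
  H <- if (is.null(hessian)) pot_hessian(potential, x) else hessian
  if (any(!is.finite(H))) stop("non-finite Hessian in normal-mode analysis")
  minv <- 1 / sqrt(masses)
  Hmw <- H * outer(minv, minv)
  n_rigid <- 0L
  if (project && d %% 3L == 0L && d >= 3L) {
    P <- .rigid_projector(x, masses)
    n_rigid <- ncol(P)
    Q <- diag(d) - tcrossprod(P)
    Hmw <- Q %*% Hmw %*% Q
  }
  Hmw <- (Hmw + t(Hmw)) / 2
  ei <- eigen(Hmw, symmetric = TRUE)
  lam <- ei$values[d:1]; V <- ei$vectors[, d:1, drop = FALSE]  # ascending
  if (n_rigid > 0L) {
    # drop the n_rigid eigenvalues closest to zero (the projected modes)
    drop_idx <- order(abs(lam))[seq_len(n_rigid)]
    keep <- setdiff(seq_len(d), drop_idx)
    lam <- lam[keep]; V <- V[, keep, drop = FALSE]
  }
  u <- dd_units()
  freqs <- sign(lam) * sqrt(abs(lam)) * u$freq_to_cm1
  structure(list(frequencies = freqs, modes = V, eigenvalues = lam,
                 order = sum(lam < -1e-8), projected = n_rigid > 0L,
                 masses = masses),
            class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  cat(sprintf("<normal_modes> %d modes%s, order %d\n", length(x$frequencies),
              if (x$projected) " (translations/rotations projected)" else "",
              x$order))
  cat("  frequencies (cm^-1):",
      paste(sprintf("%.1f", x$frequencies), collapse = ", "), "\n")
  invisible(x)
}

# orthonormal basis of mass-weighted rigid translations and rotations
.rigid_projector <- function(x, masses) {
  d <- length(x)
  n <- d %/% 3L
  xyz <- unflatten_coords(x)
  m_at <- masses[seq(1, d, by = 3L)]
  com <- colSums(xyz * m_at) / sum(m_at)
  rel <- sweep(xyz, 2L, com)
  vecs <- list()
  for (ax in 1:3) {
    v <- matrix(0, n, 3L); v[, ax] <- sqrt(m_at)
    vecs[[length(vecs) + 1L]] <- as.vector(t(v))
  }
  for (ax in 1:3) {
    e <- numeric(3); e[ax] <- 1
    v <- t(vapply(seq_len(n), function(a)
      sqrt(m_at[a]) * .cross3(e, rel[a, ]), numeric(3)))
    vecs[[length(vecs) + 1L]] <- as.vector(t(v))
  }
  B <- do.call(cbind, vecs)
  qr_b <- qr(B)
  qr.Q(qr_b)[, seq_len(qr_b$rank), drop = FALSE]
}

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

#' Minimal RMSD after optimal rigid superposition (Kabsch)
#'
#' Centres both structures, finds the optimal rotation by SVD of the
#' cross-covariance (with the determinant correction against improper
#' rotations) and returns the root-mean-square deviation.
#'
#' @param a,b structures ([dd_structure()]) or N x 3 coordinate matrices
#'   with the same atom count
#' @param align_elements require identical element sequences?
#' @return RMSD in Angstrom.
#' @export
rmsd_kabsch <- function(a, b, align_elements = TRUE) {
  xa <- if (inherits(a, "dd_structure")) a$coordinates else as.matrix(a)
  xb <- if (inherits(b, "dd_structure")) b$coordinates else as.matrix(b)
  if (nrow(xa) != nrow(xb))
    stop("structures have different atom counts")
  if (align_elements && inherits(a, "dd_structure") &&
      inherits(b, "dd_structure") && !identical(a$elements, b$elements))
    stop("element sequences differ")
  xa <- sweep(xa, 2L, colMeans(xa))
  xb <- sweep(xb, 2L, colMeans(xb))
  C <- crossprod(xb, xa)
  sv <- svd(C)
  dsign <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, dsign)) %*% t(sv$v)
  diff <- xa - xb %*% R
  sqrt(mean(rowSums(diff^2)))
}
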