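# Synthetic-data generators.  Every fixture ships its own ground truth
# (closed form or a verified stationary-point catalog), so downstream
# tests never need external reference data.  All generators are pure
# functions of (seed, parameters).

#' Smooth pairwise Gaussian perturbation
#'
#' `V = sum_{i<j} amp * exp(-(r_ij - r0)^2 / width^2)`: a bounded, smooth
#' element-agnostic potential used as the "high minus low level"
#' perturbation of the synthetic two-level task.
#'
#' @param amp amplitude, Hartree
#' @param r0 centre of the Gaussian in pair distance, Angstrom
#' @param width width, Angstrom
#' @return potential object of class `pair_bump`.
#' @export
pair_bump <- function(amp = 0.02, r0 = 1.8, width = 0.5) {
  structure(list(amp = amp, r0 = r0, width = width, elements = NULL),
            class = c("pair_bump", "dd_potential"), element_aware = TRUE)
}

#' @export
pot_eval.pair_bump <- function(pot, x, ...) {
  xyz <- unflatten_coords(x)
  n <- nrow(xyz)
  e <- 0
  g <- matrix(0, n, 3L)
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- xyz[j, ] - xyz[i, ]
    r <- sqrt(sum(v * v))
    d <- (r - pot$r0) / pot$width
    ee <- pot$amp * exp(-d * d)
    e <- e + ee
    dEdr <- -2 * d / pot$width * ee
    u <- v / r
    g[j, ] <- g[j, ] + dEdr * u
    g[i, ] <- g[i, ] - dEdr * u
  }
  list(energy = e, gradient = as.vector(t(g)))
}

#' Sum of potentials
#'
#' @param ... potentials sharing a coordinate space
#' @return potential of class `sum_potential` evaluating the sum of its
#'   terms' energies and gradients.
#' @export
sum_potential <- function(...) {
  terms <- list(...)
  els <- NULL
  for (t in terms) if (!is.null(t$elements)) els <- t$elements
  structure(list(terms = terms, elements = els),
            class = c("sum_potential", "dd_potential"), element_aware = TRUE)
}

#' @export
pot_eval.sum_potential <- function(pot, x, ...) {
  e <- 0; g <- numeric(length(x))
  for (t in pot$terms) {
    tt <- t
    if (is.null(tt$elements) && !is.null(pot$elements) &&
        isTRUE(attr(tt, "element_aware"))) tt$elements <- pot$elements
    r <- pot_eval(tt, x)
    e <- e + r$energy
    g <- g + r$gradient
  }
  list(energy = e, gradient = g)
}

#' @export
eval_structure.sum_potential <- function(pot, structure) {
  res <- lapply(pot$terms, eval_structure, structure = structure)
  list(energy = sum(vapply(res, `[[`, 1.0, "energy")),
       gradient = Reduce(`+`, lapply(res, `[[`, "gradient")))
}

#' Random toy molecules with surrogate-baseline labels
#'
#' Generates random non-clashing CHNO-like clusters (minimum pair
#' distance at least `min_dist`) by growing each new atom at bonding
#' distance from a random placed atom, and labels every geometry with
#' the energy and forces of a declared analytic potential.
#'
#' @param seed integer seed (the generator is a pure function of it)
#' @param n number of molecules
#' @param elements element pool to draw from
#' @param n_atoms_range inclusive range of atom counts
#' @param min_dist minimum allowed interatomic distance, Angstrom
#' @param label_potential potential supplying energies and forces
#'   (default: the pairwise Morse surrogate)
#' @param max_tries placement attempts per atom before giving up
#' @return list of [labeled_frame()] objects with forces.
#' @export
make_toy_molecules <- function(seed, n, elements = c("C", "H", "N", "O"),
                               n_atoms_range = c(3L, 5L), min_dist = 0.8,
                               label_potential = morse_baseline(),
                               max_tries = 200L) {
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    nat <- sample(n_atoms_range[1]:n_atoms_range[2], 1L)
    els <- sample(elements, nat, replace = TRUE)
    xyz <- matrix(0, nat, 3L)
    for (a in seq_len(nat)[-1L]) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        anchor <- xyz[sample.int(a - 1L, 1L), ]
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        cand <- anchor + stats::runif(1, 1.0, 1.9) * dir
        d <- sqrt(rowSums((xyz[seq_len(a - 1L), , drop = FALSE] -
                             matrix(cand, a - 1L, 3L, byrow = TRUE))^2))
        if (all(d >= min_dist)) { xyz[a, ] <- cand; placed <- TRUE; break }
      }
      if (!placed)
        stop("could not place atom ", a, " without clashes after ",
             max_tries, " tries")
    }
    s <- dd_structure(els, xyz)
    lab <- eval_structure(label_potential, s)
    out[[i]] <- labeled_frame(s, lab$energy,
                              forces = -unflatten_coords(lab$gradient),
                              level = "surrogate-low")
  }
  out
}

#' Synthetic two-level (plus transfer-level) learning task
#'
#' Emulates the delta-learning setting: a low level (pairwise Morse
#' surrogate), a "DFT-like" high level = low + a smooth pairwise
#' perturbation, and a "CC-like" transfer level = high + a second,
#' smaller perturbation.  Frames are random toy molecules labelled
#' exactly (energies and forces) at every level, so the delta labels
#' equal the perturbations by construction.
#'
#' @param seed integer seed
#' @param n_frames number of frames (at least 10)
#' @param elements element pool
#' @param bump parameters of the high-level perturbation, see
#'   [pair_bump()]
#' @param bump_transfer parameters of the additional transfer-level
#'   perturbation
#' @return list with `low`, `high`, `transfer` (potentials),
#'   `perturbation`, `perturbation_transfer` and `frames_low`,
#'   `frames_high`, `frames_transfer` (labelled frame lists).
#' @export
make_two_level_task <- function(seed, n_frames,
                                elements = c("C", "H", "N", "O"),
                                bump = list(amp = 0.02, r0 = 1.8, width = 0.5),
                                bump_transfer = list(amp = 0.006, r0 = 2.3,
                                                     width = 0.6)) {
  if (n_frames < 10L) stop("n_frames must be at least 10")
  low <- morse_baseline()
  pert <- pair_bump(bump$amp, bump$r0, bump$width)
  pert2 <- pair_bump(bump_transfer$amp, bump_transfer$r0, bump_transfer$width)
  high <- sum_potential(low, pert)
  transfer <- sum_potential(low, pert, pert2)
  frames_low <- make_toy_molecules(seed, n_frames, elements,
                                   label_potential = low)
  relabel <- function(frames, pot, tag) lapply(frames, function(f) {
    lab <- eval_structure(pot, f$structure)
    labeled_frame(f$structure, lab$energy,
                  forces = -unflatten_coords(lab$gradient), level = tag)
  })
  list(low = low, high = high, transfer = transfer,
       perturbation = pert, perturbation_transfer = pert2,
       frames_low = frames_low,
       frames_high = relabel(frames_low, high, "surrogate-high"),
       frames_transfer = relabel(frames_low, transfer, "surrogate-cc"))
}

# Analytic 2D surfaces --------------------------------------------------------

#' Analytic potential-energy surface
#'
#' Wraps a closed-form energy/gradient function as a potential with unit
#' masses and a catalog of verified stationary points.
#'
#' @param fn function(x) -> list(energy, gradient)
#' @param dim coordinate dimension
#' @param catalog data.frame of stationary points (columns `name`,
#'   coordinate columns, `energy`, `order`)
#' @param masses per-coordinate masses, amu (default unit)
#' @return potential of class `analytic_surface`.
#' @export
analytic_surface <- function(fn, dim, catalog = NULL, masses = rep(1, dim)) {
  structure(list(fn = fn, dim = dim, catalog = catalog, masses = masses),
            class = c("analytic_surface", "dd_potential"))
}

#' @export
pot_dim.analytic_surface <- function(pot) pot$dim

#' @export
pot_masses.analytic_surface <- function(pot) pot$masses

#' @export
pot_eval.analytic_surface <- function(pot, x, ...) pot$fn(x)

#' Model bifurcating reaction surface
#'
#' A 2D surface with the topology of a post-transition-state
#' bifurcation: one reactant basin, one index-1 ambimodal saddle at the
#' top of the barrier, a valley-ridge inflection beyond it where the
#' single product valley splits in two, two product wells of (optionally
#' unequal) depth, and one index-1 saddle interconverting the products.
#' The functional form is
#' `V = A ((x/q)^2 - 1)^2 + k ((y^2 - c(x))^2 - c(x)^2) + eps * y`,
#' with the saturating valley-splitting function
#' `c(x) = c_max tanh((x - x0)/w)`: where `c < 0` (reactant side) the
#' cross-valley term has a single minimum at `y = 0`; beyond the
#' valley-ridge inflection at `x = x0` it splits into wells near
#' `y = +-sqrt(c)`.  Subtracting `c^2` makes the `y = 0` line follow the
#' bare quartic, so the ridge carries no spurious stationary points.
#' `eps != 0` deepens the `y < 0` product (named P2) relative to P1.
#'
#' All five stationary points are located at generation time by a dense
#' grid scan plus Newton refinement and stored in the catalog, with
#' their Hessian index verified; parameter sets that fail to produce the
#' advertised topology raise a generation error.
#'
#' @param barrier `A`, barrier scale, Hartree
#' @param q half-distance between reactant and product region, Angstrom
#' @param k cross-valley stiffness, Hartree/Angstrom^4
#' @param c_max asymptotic valley half-splitting squared, Angstrom^2
#' @param w valley-splitting sharpness, Angstrom
#' @param x0 valley-ridge inflection position, Angstrom
#' @param asymmetry `eps`, Hartree/Angstrom (0 gives a symmetric surface
#'   with equal product wells)
#' @return an [analytic_surface()] with a catalog containing rows named
#'   `reactant`, `TS_ambimodal`, `P1`, `P2`, `TS_products`.
#' @export
make_bifurcating_surface <- function(barrier = 0.02, q = 2.0, k = 0.02,
                                     c_max = 0.9, w = 0.7, x0 = 0.5,
                                     asymmetry = 0.002) {
  A <- barrier
  fn <- function(z) {
    x <- z[1]; y <- z[2]
    u <- (x - x0) / w
    cx <- c_max * tanh(u)
    dcx <- c_max / (w * cosh(u)^2)
    t1 <- (x / q)^2 - 1
    e <- A * t1^2 + k * ((y^2 - cx)^2 - cx^2) + asymmetry * y
    gx <- 4 * A * x * t1 / q^2 - 2 * k * dcx * y^2
    gy <- 4 * k * y * (y^2 - cx) + asymmetry
    list(energy = e, gradient = c(gx, gy))
  }
  surf <- analytic_surface(fn, 2L)
  cat <- .locate_stationary_points(surf, xlim = c(-1.6 * q, 1.6 * q),
                                   ylim = c(-2.5, 2.5), n_grid = 61L)
  minima <- cat[cat$order == 0L, , drop = FALSE]
  saddles <- cat[cat$order == 1L, , drop = FALSE]
  if (nrow(minima) != 3L || nrow(saddles) != 2L)
    stop("surface generation failed: found ", nrow(minima), " minima and ",
         nrow(saddles), " index-1 saddles (need 3 and 2); ",
         "adjust barrier/k/alpha/x0")
  # name by position: reactant at x < 0; products by sign of y
  nm <- character(nrow(cat))
  for (i in seq_len(nrow(cat))) {
    if (cat$order[i] == 0L) {
      nm[i] <- if (cat$x[i] < 0) "reactant"
               else if (cat$y[i] < 0) "P2" else "P1"
    } else {
      nm[i] <- if (abs(cat$x[i]) < 0.5 * q) "TS_ambimodal" else "TS_products"
    }
  }
  cat$name <- nm
  if (!setequal(nm, c("reactant", "TS_ambimodal", "P1", "P2", "TS_products")))
    stop("surface generation failed: stationary points not in the expected ",
         "positions (", paste(nm, collapse = ", "), ")")
  if (asymmetry > 0 &&
      cat$energy[cat$name == "P2"] >= cat$energy[cat$name == "P1"])
    stop("surface generation failed: asymmetry did not deepen P2")
  surf$catalog <- cat
  surf$params <- list(barrier = barrier, q = q, k = k, c_max = c_max,
                      w = w, x0 = x0, asymmetry = asymmetry)
  surf
}

# dense grid scan + Newton refinement; returns deduplicated stationary
# points with Hessian order
.locate_stationary_points <- function(surf, xlim, ylim, n_grid = 61L,
                                      tol = 1e-10) {
  xs <- seq(xlim[1], xlim[2], length.out = n_grid)
  ys <- seq(ylim[1], ylim[2], length.out = n_grid)
  gn <- matrix(Inf, n_grid, n_grid)
  for (i in seq_len(n_grid)) for (j in seq_len(n_grid)) {
    g <- pot_eval(surf, c(xs[i], ys[j]))$gradient
    gn[i, j] <- sum(g * g)
  }
  # local minima of |grad|^2 on the grid are candidate stationary points
  cands <- list()
  for (i in 2:(n_grid - 1L)) for (j in 2:(n_grid - 1L)) {
    nb <- gn[(i - 1L):(i + 1L), (j - 1L):(j + 1L)]
    if (gn[i, j] <= min(nb)) cands[[length(cands) + 1L]] <- c(xs[i], ys[j])
  }
  pts <- list()
  for (z0 in cands) {
    z <- z0
    ok <- TRUE
    for (it in 1:100) {
      g <- pot_eval(surf, z)$gradient
      if (sqrt(sum(g * g)) < tol) break
      H <- pot_hessian(surf, z, step = 1e-4)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step)) || sqrt(sum(step^2)) > 1) {
        ok <- FALSE; break
      }
      z <- z - step
    }
    if (!ok || sqrt(sum(pot_eval(surf, z)$gradient^2)) >= 1e-8) next
    if (z[1] < xlim[1] || z[1] > xlim[2] || z[2] < ylim[1] || z[2] > ylim[2])
      next
    dup <- any(vapply(pts, function(p) sum((p$z - z)^2) < 1e-6, TRUE))
    if (dup) next
    H <- pot_hessian(surf, z, step = 1e-4)
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    pts[[length(pts) + 1L]] <-
      list(z = z, energy = pot_eval(surf, z)$energy,
           order = sum(ev < -1e-9))
  }
  data.frame(name = NA_character_,
             x = vapply(pts, function(p) p$z[1], 1.0),
             y = vapply(pts, function(p) p$z[2], 1.0),
             energy = vapply(pts, function(p) p$energy, 1.0),
             order = vapply(pts, function(p) p$order, 1L))
}
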