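# Generic potential interface ----------------------------------------------
#
# Every potential (baseline surrogates, analytic surfaces, the composite
# model) implements pot_eval(pot, x) on a flat coordinate vector
# (Angstrom; 3N Cartesians for molecular potentials, d coordinates for
# analytic surfaces) returning at least list(energy, gradient) in
# Hartree and Hartree/Angstrom.  Baselines additionally return per-atom
# partial charges and a dipole vector when they offer them.

#' Evaluate a potential at a flat coordinate vector
#'
#' @param pot a potential object
#' @param x numeric coordinate vector (Angstrom)
#' @param ... method-specific arguments
#' @return list with at least `energy` (Hartree) and `gradient`
#'   (Hartree/Angstrom, same length as `x`).
#' @export
pot_eval <- function(pot, x, ...) UseMethod("pot_eval")

#' Coordinate dimension of a potential
#' @param pot a potential object
#' @return integer number of coordinates
#' @export
pot_dim <- function(pot) UseMethod("pot_dim")

#' Masses associated with a potential's coordinates
#' @param pot a potential object
#' @return numeric vector of masses (amu), one per coordinate
#' @export
pot_masses <- function(pot) UseMethod("pot_masses")

#' @export
pot_masses.default <- function(pot) {
  if (!is.null(pot$elements)) rep(atomic_masses(pot$elements), each = 3L)
  else rep(1, pot_dim(pot))
}

#' Hessian of a potential
#'
#' The default method applies central finite differences to the
#' analytical gradient with step `step` (default 0.01 Bohr = 5.29e-3
#' Angstrom) and symmetrises the result.  Potentials with (partly)
#' analytical second derivatives override it.
#'
#' @param pot a potential object
#' @param x flat coordinate vector
#' @param step finite-difference step, Angstrom
#' @param ... method-specific arguments
#' @return symmetric `length(x)` x `length(x)` matrix, Hartree/Angstrom^2
#' @export
pot_hessian <- function(pot, x, step = 0.0052917721, ...) UseMethod("pot_hessian")

#' @export
pot_hessian.default <- function(pot, x, step = 0.0052917721, ...) {
  fd_hessian(function(y) pot_eval(pot, y)$gradient, x, step)
}

# central-difference Hessian from a gradient function, symmetrised
fd_hessian <- function(grad_fn, x, step) {
  d <- length(x)
  H <- matrix(0, d, d)
  for (q in seq_len(d)) {
    xp <- x; xp[q] <- xp[q] + step
    xm <- x; xm[q] <- xm[q] - step
    H[, q] <- (grad_fn(xp) - grad_fn(xm)) / (2 * step)
  }
  if (any(!is.finite(H)))
    stop("non-finite entries in finite-difference Hessian")
  (H + t(H)) / 2
}

#' Evaluate a molecular potential on a structure
#'
#' Checks (or, for element-agnostic surrogates constructed with
#' `elements = NULL`, adopts) the structure's element sequence and
#' evaluates the potential at its coordinates.
#'
#' @param pot a potential object
#' @param structure a [dd_structure()]
#' @return as [pot_eval()].
#' @export
eval_structure <- function(pot, structure) UseMethod("eval_structure")

#' @export
eval_structure.default <- function(pot, structure) {
  if (!is.null(pot$elements)) {
    if (!identical(structure$elements, pot$elements))
      stop("structure elements do not match the potential's element sequence")
  } else if (!is.null(attr(pot, "element_aware")) && attr(pot, "element_aware")) {
    pot$elements <- structure$elements
  }
  pot_eval(pot, flatten_coords(structure))
}

# Morse baseline surrogate ---------------------------------------------------

#' Pairwise Morse baseline surrogate
#'
#' An analytic stand-in for a semi-empirical baseline: a sum of Morse
#' pair interactions over all atom pairs,
#' `E = sum De_ij ((1 - exp(-a (r - re_ij)))^2 - 1)`, dispersion-free and
#' smooth, with analytical gradients.  Element-pair well depths and
#' equilibrium distances come from small per-element tables (geometric
#' mean / covalent-radius sum combination).  Per-atom partial charges
#' (fixed electronegativity-derived values, shifted to the total charge)
#' and the resulting dipole vector are also provided, mirroring a
#' baseline that owns the electronic-structure properties.
#'
#' @param elements element symbols in atom order, or NULL for an
#'   element-agnostic surrogate usable on any structure via
#'   [eval_structure()]
#' @param a Morse steepness, 1/Angstrom
#' @param de_scale multiplier on the well depths
#' @return potential object of class `morse_baseline` with capabilities
#'   energy, gradient, charges, dipole.
#' @export
morse_baseline <- function(elements = NULL, a = 1.8, de_scale = 1.0) {
  de_tab <- c(H = 0.16, C = 0.26, N = 0.22, O = 0.19)
  rcov <- c(H = 0.37, C = 0.77, N = 0.75, O = 0.73)
  chi <- c(H = 2.20, C = 2.55, N = 3.04, O = 3.44)
  missing <- setdiff(unique(elements), names(de_tab))
  if (length(missing) > 0L)
    stop("morse_baseline has no parameters for: ", paste(missing, collapse = ", "))
  structure(list(elements = elements, a = a,
                 de = de_scale * de_tab, rcov = rcov, chi = chi,
                 name = "morse-surrogate",
                 capabilities = c("energy", "gradient", "charges", "dipole")),
            class = c("morse_baseline", "dd_potential"),
            element_aware = TRUE)
}

#' @export
pot_dim.morse_baseline <- function(pot) 3L * length(pot$elements)

#' @export
pot_eval.morse_baseline <- function(pot, x, ...) {
  xyz <- unflatten_coords(x)
  n <- length(pot$elements)
  e <- 0
  g <- matrix(0, n, 3L)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- xyz[j, ] - xyz[i, ]
    r <- sqrt(sum(v * v))
    ei <- pot$elements[i]; ej <- pot$elements[j]
    de <- sqrt(pot$de[[ei]] * pot$de[[ej]])
    re <- pot$rcov[[ei]] + pot$rcov[[ej]]
    ex <- exp(-pot$a * (r - re))
    e <- e + de * ((1 - ex)^2 - 1)
    dEdr <- 2 * de * pot$a * ex * (1 - ex)
    u <- v / r
    g[j, ] <- g[j, ] + dEdr * u
    g[i, ] <- g[i, ] - dEdr * u
  }
  # fixed electronegativity-derived charges, shifted to the net charge
  q <- 0.12 * (mean(pot$chi[pot$elements]) - pot$chi[pot$elements])
  q <- q - (sum(q) - 0) / n
  list(energy = e, gradient = as.vector(t(g)),
       charges = unname(q), dipole = as.vector(q %*% xyz))
}

# Harmonic spring surrogate ---------------------------------------------------

#' Harmonic bond/angle spring surrogate
#'
#' Harmonic springs on a declared set of bonds (and optionally angles)
#' with reference values taken from a reference structure:
#' `E = sum k_b/2 (r - r0)^2 + sum k_a/2 (theta - theta0)^2`.
#' Useful as a baseline with a closed-form Hessian structure (e.g. a
#' harmonic diatomic has the single frequency `sqrt(k/mu)/(2 pi c)`).
#'
#' @param reference a [dd_structure()] providing elements and the
#'   equilibrium geometry
#' @param bonds 2-column integer matrix of bonded atom pairs; default:
#'   all pairs closer than 1.15 times the covalent-radius sum
#' @param angles 3-column integer matrix (i, j, k) of angles at vertex j;
#'   default: all bonded triples
#' @param k_bond bond force constant, Hartree/Angstrom^2
#' @param k_angle angle force constant, Hartree/rad^2
#' @return potential object of class `spring_model`.
#' @export
spring_model <- function(reference, bonds = NULL, angles = NULL,
                         k_bond = 0.6, k_angle = 0.15) {
  rcov <- c(H = 0.37, C = 0.77, N = 0.75, O = 0.73)
  n <- n_atoms(reference)
  xyz <- reference$coordinates
  if (is.null(bonds)) {
    bonds <- NULL
    if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      rmax <- 1.3 * (rcov[[reference$elements[i]]] + rcov[[reference$elements[j]]])
      if (atom_distance(reference, i, j) <= rmax) bonds <- rbind(bonds, c(i, j))
    }
  }
  if (is.null(bonds) || nrow(bonds) == 0L)
    stop("spring_model needs at least one bond")
  if (is.null(angles)) {
    angles <- NULL
    for (j in seq_len(n)) {
      nb <- sort(unique(c(bonds[bonds[, 1] == j, 2], bonds[bonds[, 2] == j, 1])))
      if (length(nb) >= 2L)
        for (a in seq_len(length(nb) - 1L)) for (b in (a + 1L):length(nb))
          angles <- rbind(angles, c(nb[a], j, nb[b]))
    }
  }
  r0 <- apply(bonds, 1L, function(p) sqrt(sum((xyz[p[2], ] - xyz[p[1], ])^2)))
  th0 <- if (!is.null(angles))
    apply(angles, 1L, function(t) {
      v1 <- xyz[t[1], ] - xyz[t[2], ]; v2 <- xyz[t[3], ] - xyz[t[2], ]
      acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
    })
  structure(list(elements = reference$elements, bonds = bonds, angles = angles,
                 r0 = r0, theta0 = th0, k_bond = k_bond, k_angle = k_angle,
                 name = "spring-surrogate",
                 capabilities = c("energy", "gradient")),
            class = c("spring_model", "dd_potential"))
}

#' @export
pot_dim.spring_model <- function(pot) 3L * length(pot$elements)

#' @export
pot_eval.spring_model <- function(pot, x, ...) {
  xyz <- unflatten_coords(x)
  n <- length(pot$elements)
  e <- 0
  g <- matrix(0, n, 3L)
  for (bi in seq_len(nrow(pot$bonds))) {
    i <- pot$bonds[bi, 1]; j <- pot$bonds[bi, 2]
    v <- xyz[j, ] - xyz[i, ]
    r <- sqrt(sum(v * v))
    e <- e + 0.5 * pot$k_bond * (r - pot$r0[bi])^2
    dEdr <- pot$k_bond * (r - pot$r0[bi])
    u <- v / r
    g[j, ] <- g[j, ] + dEdr * u
    g[i, ] <- g[i, ] - dEdr * u
  }
  if (!is.null(pot$angles)) for (ai in seq_len(nrow(pot$angles))) {
    i <- pot$angles[ai, 1]; j <- pot$angles[ai, 2]; k <- pot$angles[ai, 3]
    v1 <- xyz[i, ] - xyz[j, ]; v2 <- xyz[k, ] - xyz[j, ]
    r1 <- sqrt(sum(v1^2)); r2 <- sqrt(sum(v2^2))
    cth <- sum(v1 * v2) / (r1 * r2)
    cth <- max(min(cth, 1 - 1e-12), -1 + 1e-12)
    th <- acos(cth)
    e <- e + 0.5 * pot$k_angle * (th - pot$theta0[ai])^2
    pref <- pot$k_angle * (th - pot$theta0[ai]) * (-1 / sqrt(1 - cth^2))
    u1 <- v1 / r1; u2 <- v2 / r2
    dci <- (u2 - cth * u1) / r1
    dck <- (u1 - cth * u2) / r2
    g[i, ] <- g[i, ] + pref * dci
    g[k, ] <- g[k, ] + pref * dck
    g[j, ] <- g[j, ] - pref * (dci + dck)
  }
  list(energy = e, gradient = as.vector(t(g)))
}

# Simple analytic potentials and instrumentation ------------------------------

#' Harmonic bowl potential
#'
#' `E = k/2 |x - center|^2` in any dimension, with unit masses unless
#' `masses` is given.  A convenient quadratic test surface.
#'
#' @param center flat coordinate vector of the minimum
#' @param k force constant, Hartree/Angstrom^2
#' @param masses optional per-coordinate masses (amu)
#' @return potential object of class `harmonic_bowl`.
#' @export
harmonic_bowl <- function(center, k = 1.0, masses = NULL) {
  structure(list(center = center, k = k, masses = masses),
            class = c("harmonic_bowl", "dd_potential"))
}

#' @export
pot_dim.harmonic_bowl <- function(pot) length(pot$center)

#' @export
pot_masses.harmonic_bowl <- function(pot) {
  if (is.null(pot$masses)) rep(1, length(pot$center)) else pot$masses
}

#' @export
pot_eval.harmonic_bowl <- function(pot, x, ...) {
  d <- x - pot$center
  list(energy = 0.5 * pot$k * sum(d * d), gradient = pot$k * d)
}

#' @export
pot_hessian.harmonic_bowl <- function(pot, x, step = 0.0052917721, ...) {
  diag(pot$k, length(pot$center))
}

#' Wrap a potential with an evaluation counter
#'
#' Counts single-point (energy+gradient) evaluations, used to verify the
#' dynamics bookkeeping against the analytic evaluation count.
#'
#' @param pot any potential
#' @return potential of class `counted_potential`; query the count with
#'   [evaluation_count()].
#' @export
counted_potential <- function(pot) {
  env <- new.env(parent = emptyenv())
  env$count <- 0L
  structure(list(inner = pot, env = env),
            class = c("counted_potential", "dd_potential"))
}

#' @rdname counted_potential
#' @param counted a `counted_potential`
#' @return integer number of evaluations so far
#' @export
evaluation_count <- function(counted) counted$env$count

#' @export
pot_dim.counted_potential <- function(pot) pot_dim(pot$inner)

#' @export
pot_masses.counted_potential <- function(pot) pot_masses(pot$inner)

#' @export
pot_eval.counted_potential <- function(pot, x, ...) {
  pot$env$count <- pot$env$count + 1L
  pot_eval(pot$inner, x, ...)
}

#' @export
pot_hessian.counted_potential <- function(pot, x, ...) pot_hessian(pot$inner, x, ...)
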