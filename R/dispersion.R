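#' Damped pairwise dispersion term
#'
#' A pluggable London-dispersion correction of the damped `-C6/r^6` form
#' with rational damping,
#' `E = -sum_{i<j} C6_ij r^6 / ((r^6 + r0_ij^6) r^6)
#'    = -sum_{i<j} C6_ij / (r_ij^6 + r0_ij^6)`,
#' which tends to the bare `-C6/r^6` at long range and stays finite and
#' C^1-smooth at short range.  Per-element C6 coefficients combine by
#' geometric mean; damping radii `r0` by arithmetic mean of the
#' per-element radii.  Setting all C6 to zero switches the term off.
#'
#' @param elements element symbols in atom order
#' @param c6 named per-element C6 coefficients, Hartree Angstrom^6
#' @param r0 named per-element damping radii, Angstrom
#' @param scale global multiplier (0 disables the term)
#' @return potential object of class `dispersion_term`.
#' @export
dispersion_term <- function(elements = NULL,
                            c6 = c(H = 1.5, C = 8.0, N = 6.0, O = 5.0),
                            r0 = c(H = 2.6, C = 3.1, N = 3.0, O = 2.9),
                            scale = 1.0) {
  missing <- setdiff(unique(elements), names(c6))
  if (length(missing) > 0L)
    stop("dispersion parameters missing for element(s): ",
         paste(missing, collapse = ", "))
  if (any(r0 <= 0)) stop("damping radii must be positive")
  structure(list(elements = elements, c6 = c6, r0 = r0, scale = scale),
            class = c("dispersion_term", "dd_potential"),
            element_aware = TRUE)
}

#' @export
pot_dim.dispersion_term <- function(pot) 3L * length(pot$elements)

#' @export
pot_eval.dispersion_term <- function(pot, x, ...) {
  xyz <- unflatten_coords(x)
  n <- length(pot$elements)
  missing <- setdiff(unique(pot$elements), names(pot$c6))
  if (length(missing) > 0L)
    stop("dispersion parameters missing for element(s): ",
         paste(missing, collapse = ", "))
  e <- 0
  g <- matrix(0, n, 3L)
  if (pot$scale != 0 && n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ei <- pot$elements[i]; ej <- pot$elements[j]
      c6 <- pot$scale * sqrt(pot$c6[[ei]] * pot$c6[[ej]])
      r0_6 <- (0.5 * (pot$r0[[ei]] + pot$r0[[ej]]))^6
      v <- xyz[j, ] - xyz[i, ]
      r2 <- sum(v * v); r <- sqrt(r2)
      den <- r2^3 + r0_6
      e <- e - c6 / den
      dEdr <- 6 * c6 * r^5 / den^2
      u <- v / r
      g[j, ] <- g[j, ] + dEdr * u
      g[i, ] <- g[i, ] - dEdr * u
    }
  }
  list(energy = e, gradient = as.vector(t(g)))
}

#' Dispersion energy and gradient of a structure
#'
#' @param structure a [dd_structure()]
#' @param disp a [dispersion_term()] matching the structure's elements
#' @return list with `energy` (Hartree), `gradient` (flat 3N,
#'   Hartree/Angstrom) and `forces` (N x 3).
#' @export
pairwise_dispersion <- function(structure, disp) {
  stopifnot(inherits(disp, "dispersion_term"))
  r <- eval_structure(disp, structure)
  r$forces <- -unflatten_coords(r$gradient)
  r
}
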