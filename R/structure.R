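#' Molecular structure
#'
#' The universal geometric input of every stage: element symbols plus
#' Cartesian coordinates in Angstrom, with total charge and spin
#' multiplicity.  The default applicability domain is neutral,
#' closed-shell molecules made of C, H, N and O; structures outside the
#' supported element set are refused at construction.
#'
#' @param elements character vector of element symbols
#' @param coordinates numeric matrix with one row per atom and columns
#'   x, y, z in Angstrom (a length-3N vector is also accepted)
#' @param charge integer total charge in elementary charges
#' @param multiplicity positive integer spin multiplicity (2S+1)
#' @param supported_elements character vector of allowed element symbols
#' @return An object of class `dd_structure` with fields `elements`,
#'   `coordinates` (N x 3 matrix), `charge`, `multiplicity`.
#' @examples
#' water <- dd_structure(c("O", "H", "H"),
#'                       rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' n_atoms(water)
#' @export
dd_structure <- function(elements, coordinates, charge = 0L, multiplicity = 1L,
                         supported_elements = c("C", "H", "N", "O")) {
  elements <- as.character(elements)
  if (is.null(dim(coordinates)))
    coordinates <- matrix(as.numeric(coordinates), ncol = 3L, byrow = TRUE)
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  if (ncol(coordinates) != 3L)
    stop("coordinates must have 3 columns (x, y, z)")
  if (nrow(coordinates) != length(elements))
    stop("coordinate rows (", nrow(coordinates), ") do not match element count (",
         length(elements), ")")
  bad <- setdiff(unique(elements), supported_elements)
  if (length(bad) > 0L)
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(supported_elements, collapse = ","), ")")
  if (!is.finite(multiplicity) || multiplicity < 1)
    stop("multiplicity must be a positive integer")
  structure(
    list(elements = elements, coordinates = coordinates,
         charge = as.integer(charge), multiplicity = as.integer(multiplicity)),
    class = "dd_structure")
}

#' Number of atoms in a structure
#' @param x a `dd_structure`
#' @return integer atom count
#' @export
n_atoms <- function(x) length(x$elements)

#' @export
print.dd_structure <- function(x, ...) {
  cat(sprintf("<dd_structure> %d atoms [%s], charge %+d, multiplicity %d\n",
              n_atoms(x), paste(x$elements, collapse = ""),
              x$charge, x$multiplicity))
  invisible(x)
}

# flatten coordinates to a length-3N vector (row-major: atom-by-atom)
flatten_coords <- function(s) as.vector(t(s$coordinates))

# inverse of flatten_coords
unflatten_coords <- function(x) matrix(x, ncol = 3L, byrow = TRUE)

# replace coordinates of a structure with a flat vector or matrix
set_coords <- function(s, x) {
  if (is.null(dim(x))) x <- unflatten_coords(x)
  s$coordinates <- x
  s
}

#' Labeled frame: a structure with reference energy and optional forces
#'
#' Carrier for training records and trajectory frames: a geometry with a
#' total energy (Hartree), optional per-atom forces (Hartree/Angstrom)
#' and a free-text level-of-theory tag.
#'
#' @param structure a [dd_structure()]
#' @param energy scalar energy in Hartree
#' @param forces optional N x 3 matrix of forces in Hartree/Angstrom
#' @param level free-text label of the level of theory
#' @return An object of class `dd_frame`.
#' @export
labeled_frame <- function(structure, energy, forces = NULL, level = "") {
  stopifnot(inherits(structure, "dd_structure"))
  if (!is.numeric(energy) || length(energy) != 1L || !is.finite(energy))
    stop("energy must be a finite scalar (Hartree)")
  if (!is.null(forces)) {
    forces <- as.matrix(forces)
    if (!all(dim(forces) == c(n_atoms(structure), 3L)))
      stop("forces must be an N x 3 matrix matching the atom count")
  }
  structure(list(structure = structure, energy = energy, forces = forces,
                 level = level), class = "dd_frame")
}

#' @export
print.dd_frame <- function(x, ...) {
  cat(sprintf("<dd_frame> %d atoms, E = %.8f Ha%s%s\n",
              n_atoms(x$structure), x$energy,
              if (!is.null(x$forces)) ", with forces" else "",
              if (nzchar(x$level)) paste0(" [", x$level, "]") else ""))
  invisible(x)
}

# pairwise distance helpers -------------------------------------------------

# distance between atoms i and j
atom_distance <- function(s, i, j) {
  sqrt(sum((s$coordinates[i, ] - s$coordinates[j, ])^2))
}

# full pairwise distance matrix
distance_matrix <- function(s) as.matrix(stats::dist(s$coordinates))
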