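#' Composite delta-learning potential
#'
#' The composite energy model
#' `E = E_baseline + E_NN + E_dispersion`:
#' a pluggable baseline supplies the physical backbone (and the
#' electronic-structure properties: partial charges and dipole moments
#' are inherited from it), an ensemble of neural networks supplies the
#' learned correction with an uncertainty estimate, and an explicit
#' pairwise dispersion term supplies long-range attraction.  All energy
#' derivative properties are the sums of each term's derivatives.
#'
#' @param baseline a baseline potential (e.g. [morse_baseline()])
#'   offering energy and gradient
#' @param ensemble an [nn_ensemble()] (or NULL to disable the correction)
#' @param dispersion a [dispersion_term()] (or NULL to disable)
#' @param elements element symbols in atom order (default: taken from
#'   the baseline)
#' @return potential object of class `composite_potential`.
#' @export
composite_potential <- function(baseline, ensemble = NULL, dispersion = NULL,
                                elements = baseline$elements) {
  if (is.null(elements)) stop("composite_potential needs an element sequence")
  structure(list(elements = elements, baseline = baseline,
                 ensemble = ensemble, dispersion = dispersion),
            class = c("composite_potential", "dd_potential"))
}

#' @export
print.composite_potential <- function(x, ...) {
  cat(sprintf("<composite_potential> %d atoms [%s]\n  baseline:   %s\n",
              length(x$elements), paste(x$elements, collapse = ""),
              if (is.null(x$baseline$name)) class(x$baseline)[1] else x$baseline$name))
  cat(sprintf("  correction: %s\n  dispersion: %s\n",
              if (is.null(x$ensemble)) "none"
              else sprintf("%d-member NN ensemble", x$ensemble$n_members),
              if (is.null(x$dispersion)) "none" else "damped pairwise -C6/r^6"))
  invisible(x)
}

#' @export
pot_dim.composite_potential <- function(pot) 3L * length(pot$elements)

#' @export
pot_eval.composite_potential <- function(pot, x, ...) {
  s <- dd_structure(pot$elements, unflatten_coords(x),
                    supported_elements = unique(pot$elements))
  r <- composite_energy(s, pot$baseline, pot$ensemble, pot$dispersion)
  list(energy = r$energy, gradient = r$gradient, charges = r$charges,
       dipole = r$dipole, components = r$components,
       uncertainty = r$uncertainty)
}

#' @export
pot_hessian.composite_potential <- function(pot, x, step = 0.0052917721, ...) {
  s <- dd_structure(pot$elements, unflatten_coords(x),
                    supported_elements = unique(pot$elements))
  composite_hessian(s, pot$baseline, pot$ensemble, pot$dispersion,
                    fd_step = step)
}

#' Composite energy, components, gradient and uncertainty
#'
#' Evaluates the three terms of the composite model on one structure.
#' The total energy and gradient are element-wise sums of the terms; the
#' NN component is the ensemble mean; charges and dipole are copied from
#' the baseline when it offers them.
#'
#' @param structure a [dd_structure()]
#' @param baseline baseline potential (energy + gradient required)
#' @param ensemble an [nn_ensemble()] or NULL
#' @param dispersion a [dispersion_term()] or NULL
#' @return list of class `potential_result` with fields `energy`,
#'   `components` (named: baseline, nn, dispersion; Hartree), `gradient`
#'   (flat 3N), `forces` (N x 3), `member_energies`, `uncertainty`
#'   (kcal/mol), `uncertain`, `charges`, `dipole`.
#' @export
composite_energy <- function(structure, baseline, ensemble = NULL,
                             dispersion = NULL) {
  base <- tryCatch(eval_structure(baseline, structure),
                   error = function(e)
                     stop("baseline evaluation failed: ", conditionMessage(e)))
  n3 <- 3L * n_atoms(structure)
  comp <- c(baseline = base$energy, nn = 0, dispersion = 0)
  grad <- base$gradient
  member_energies <- NULL; unc <- NULL
  if (!is.null(ensemble)) {
    nn <- nn_correction(structure, ensemble, forces = TRUE)
    comp[["nn"]] <- nn$mean
    grad <- grad + nn$gradient
    member_energies <- nn$member_energies
    unc <- ensemble_uncertainty(member_energies)
  }
  if (!is.null(dispersion)) {
    dsp <- eval_structure(dispersion, structure)
    comp[["dispersion"]] <- dsp$energy
    grad <- grad + dsp$gradient
  }
  structure(list(energy = sum(comp), components = comp,
                 gradient = grad, forces = -unflatten_coords(grad),
                 member_energies = member_energies,
                 uncertainty = if (is.null(unc)) NA_real_ else unc$uncertainty,
                 uncertain = if (is.null(unc)) NA else unc$uncertain,
                 charges = base$charges, dipole = base$dipole),
            class = "potential_result")
}

#' @export
print.potential_result <- function(x, ...) {
  cat(sprintf("<potential_result> E = %.8f Ha (baseline %.8f, nn %.8f, disp %.8f)\n",
              x$energy, x$components[["baseline"]], x$components[["nn"]],
              x$components[["dispersion"]]))
  if (!is.na(x$uncertainty))
    cat(sprintf("  uncertainty %.4f kcal/mol%s\n", x$uncertainty,
                if (isTRUE(x$uncertain)) " (UNCERTAIN)" else ""))
  invisible(x)
}

#' Composite Hessian
#'
#' The final Hessian is the sum of the three terms' Hessians: the
#' baseline and dispersion blocks are obtained by central finite
#' differences of their analytical gradients (step `fd_step`), while the
#' neural networks provide analytical Hessians (exact second derivatives
#' through the network and the descriptor).  The result is symmetrised
#' as `(H + H^T)/2`.
#'
#' @param structure a [dd_structure()]
#' @param baseline baseline potential with analytical gradient
#' @param ensemble an [nn_ensemble()] or NULL
#' @param dispersion a [dispersion_term()] or NULL
#' @param fd_step finite-difference step, Angstrom (default 0.01 Bohr)
#' @return symmetric 3N x 3N matrix, Hartree/Angstrom^2.
#' @export
composite_hessian <- function(structure, baseline, ensemble = NULL,
                              dispersion = NULL, fd_step = 0.0052917721) {
  if (fd_step <= 0) stop("fd_step must be positive")
  x <- flatten_coords(structure)
  H <- tryCatch(
    fd_hessian(function(y) pot_eval(baseline, y)$gradient, x, fd_step),
    error = function(e) stop("baseline Hessian failed: ", conditionMessage(e)))
  if (!is.null(dispersion)) {
    H <- H + tryCatch(
      fd_hessian(function(y) pot_eval(dispersion, y)$gradient, x, fd_step),
      error = function(e) stop("dispersion Hessian failed: ", conditionMessage(e)))
  }
  if (!is.null(ensemble)) H <- H + nn_hessian(structure, ensemble)
  if (any(!is.finite(H))) stop("non-finite entries in composite Hessian")
  (H + t(H)) / 2
}

#' Analytical Hessian of the ensemble-mean NN correction
#'
#' Exact second derivatives of the mean correction energy: per atom,
#' `J^T H_f J` (network curvature pushed through the descriptor
#' Jacobian) plus the descriptor curvature contracted with the network
#' input-gradient, averaged over ensemble members.
#'
#' @param structure a [dd_structure()]
#' @param ensemble an [nn_ensemble()]
#' @return 3N x 3N matrix, Hartree/Angstrom^2.
#' @export
nn_hessian <- function(structure, ensemble) {
  res <- aev_with_jacobian(structure, ensemble$aev)
  n <- n_atoms(structure)
  D <- ensemble$aev$n_features
  H <- matrix(0, 3L * n, 3L * n)
  Wmean <- matrix(0, n, D)   # member-mean input gradients per atom
  for (a in seq_len(n)) {
    el <- structure$elements[a]
    g_a <- res$aev[a, ]
    Hf_mean <- matrix(0, D, D)
    for (m in seq_len(ensemble$n_members)) {
      ih <- mlp_input_hessian(ensemble$members[[m]][[el]], g_a)
      Hf_mean <- Hf_mean + ih$hess / ensemble$n_members
      Wmean[a, ] <- Wmean[a, ] + ih$grad / ensemble$n_members
    }
    J <- res$jacobian[[a]]
    H <- H + crossprod(J, Hf_mean %*% J)
  }
  H + aev_weighted_hessian(structure, ensemble$aev, Wmean)
}
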