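#' Construct a neural-network correction ensemble
#'
#' An ensemble of per-element feed-forward networks (GELU hidden
#' activations) sharing one descriptor parameterisation.  Each member
#' predicts a molecular correction energy as the sum of per-atom network
#' outputs plus per-element self-energy offsets; the ensemble prediction
#' is the member mean and the member spread is the uncertainty estimate.
#'
#' @param aev an [aev_params()] object shared by all members
#' @param hidden integer vector of hidden-layer widths
#' @param n_members number of ensemble members (default 8; at least 2
#'   for the uncertainty to be defined)
#' @param self_energies named numeric vector of per-element self-energy
#'   offsets in Hartree (default all zero)
#' @param seed integer seed for weight initialisation; member m is
#'   initialised from `seed + m`
#' @return An object of class `nn_ensemble`.
#' @export
nn_ensemble <- function(aev = aev_params(), hidden = c(32, 24, 16),
                        n_members = 8L, self_energies = NULL, seed = 1L) {
  if (n_members < 2L)
    stop("at least 2 ensemble members are required for uncertainty")
  if (is.null(self_energies)) {
    self_energies <- stats::setNames(numeric(length(aev$elements)), aev$elements)
  }
  members <- vector("list", n_members)
  for (m in seq_len(n_members)) {
    set.seed(seed + m)
    members[[m]] <- stats::setNames(
      lapply(aev$elements, function(e) init_mlp(aev$n_features, hidden)),
      aev$elements)
  }
  structure(list(aev = aev, hidden = hidden, n_members = n_members,
                 members = members, self_energies = self_energies,
                 activation = "gelu", seed = seed),
            class = "nn_ensemble")
}

#' @export
print.nn_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<nn_ensemble> %d members, elements [%s], hidden [%s], ",
                     "%d descriptor features, GELU\n"),
              x$n_members, paste(x$aev$elements, collapse = ","),
              paste(x$hidden, collapse = ","), x$aev$n_features))
  invisible(x)
}

#' Neural-network correction energy of a structure
#'
#' Evaluates every ensemble member on the structure: the member energy is
#' the sum over atoms of the element-specific network applied to that
#' atom's environment vector, plus the per-element self-energy offsets.
#' The reported correction is the ensemble mean; forces (of the mean) are
#' assembled from the descriptor Jacobian.
#'
#' @param structure a [dd_structure()]
#' @param ensemble an [nn_ensemble()]
#' @param forces logical: also compute analytical forces of the mean?
#' @return list with `member_energies` (Hartree, one per member), `mean`
#'   (Hartree), `uncertainty` (kcal/mol, population std over members) and,
#'   when requested, `forces` (N x 3, Hartree/Angstrom) and `gradient`
#'   (flat 3N vector).
#' @export
nn_correction <- function(structure, ensemble, forces = FALSE) {
  stopifnot(inherits(ensemble, "nn_ensemble"))
  res <- if (forces) aev_with_jacobian(structure, ensemble$aev)
         else list(aev = compute_aev(structure, ensemble$aev))
  G <- res$aev
  els <- structure$elements
  n <- n_atoms(structure)
  self_e <- sum(ensemble$self_energies[els])
  member_energies <- numeric(ensemble$n_members)
  grad <- if (forces) numeric(3L * n)
  # mean input-gradients per atom accumulate across members
  for (m in seq_len(ensemble$n_members)) {
    e_m <- self_e
    for (el in unique(els)) {
      rows <- which(els == el)
      net <- ensemble$members[[m]][[el]]
      if (forces) {
        bp <- mlp_backprop(net, G[rows, , drop = FALSE],
                           want_param_grads = FALSE)
        e_m <- e_m + sum(bp$y)
        for (ri in seq_along(rows)) {
          a <- rows[ri]
          grad <- grad + as.vector(bp$dX[ri, ] %*% res$jacobian[[a]]) /
            ensemble$n_members
        }
      } else {
        e_m <- e_m + sum(mlp_value(net, G[rows, , drop = FALSE]))
      }
    }
    member_energies[m] <- e_m
  }
  out <- list(member_energies = member_energies,
              mean = mean(member_energies),
              uncertainty = ensemble_uncertainty(member_energies)$uncertainty)
  if (forces) {
    out$gradient <- grad
    out$forces <- -unflatten_coords(grad)
  }
  out
}

# population (ddof = 0) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Ensemble uncertainty of a prediction
#'
#' The uncertainty is the standard deviation of the member predictions
#' (population convention), reported in kcal/mol.  A prediction is deemed
#' reliable when the uncertainty is below the calibrated threshold,
#' 0.36 kcal/mol by default.
#'
#' @param member_energies numeric vector of per-member energies, Hartree
#'   (at least 2)
#' @param threshold reliability threshold in kcal/mol
#' @return list with `uncertainty` (kcal/mol), `uncertain` (logical flag,
#'   TRUE when the uncertainty exceeds the threshold) and `threshold`.
#' @examples
#' ensemble_uncertainty(c(-1.0, -1.0))  # zero spread, reliable
#' @export
ensemble_uncertainty <- function(member_energies, threshold = 0.36) {
  if (length(member_energies) < 2L)
    stop("uncertainty requires at least 2 ensemble members")
  u <- hartree_to_kcalmol(pop_sd(member_energies))
  list(uncertainty = u, uncertain = u > threshold, threshold = threshold)
}

#' Uncertainty of a relative (reaction) energy
#'
#' The per-member relative energy is formed first as the stoichiometric
#' combination of the member's species energies; the uncertainty is then
#' the population standard deviation across members.  Member indices must
#' be aligned across species (member m of every species comes from the
#' same trained model).
#'
#' @param member_energies list of numeric vectors (one per species), each
#'   of length `n_members`, in Hartree
#' @param stoich signed stoichiometric coefficients, one per species
#' @param threshold reliability threshold in kcal/mol
#' @return list as in [ensemble_uncertainty()] plus `member_relative`
#'   (the per-member relative energies, Hartree).
#' @export
relative_energy_uncertainty <- function(member_energies, stoich,
                                        threshold = 0.36) {
  stopifnot(is.list(member_energies), length(member_energies) == length(stoich))
  lens <- vapply(member_energies, length, 1L)
  if (length(unique(lens)) != 1L)
    stop("member counts differ across species: ", paste(lens, collapse = ", "))
  if (lens[1] < 2L) stop("uncertainty requires at least 2 ensemble members")
  rel <- Reduce(`+`, Map(function(e, s) s * e, member_energies, stoich))
  out <- ensemble_uncertainty(rel, threshold)
  out$member_relative <- rel
  out
}

#' Predict correction energies for structures
#'
#' @param object an [nn_ensemble()]
#' @param newdata a `dd_structure` or list of structures
#' @param ... unused
#' @return data.frame with columns `energy_nn` (Hartree, ensemble mean),
#'   `uncertainty` (kcal/mol) and `uncertain` (flag).
#' @export
predict.nn_ensemble <- function(object, newdata, ...) {
  if (inherits(newdata, "dd_structure")) newdata <- list(newdata)
  rows <- lapply(newdata, function(s) {
    r <- nn_correction(s, object)
    u <- ensemble_uncertainty(r$member_energies)
    data.frame(energy_nn = r$mean, uncertainty = u$uncertainty,
               uncertain = u$uncertain)
  })
  do.call(rbind, rows)
}

#' Extract ensemble parameters
#'
#' @param object an [nn_ensemble()]
#' @param ... unused
#' @return named numeric vector of all member weights and biases plus the
#'   per-element self-energies.
#' @export
coef.nn_ensemble <- function(object, ...) {
  w <- unlist(lapply(seq_len(object$n_members), function(m)
    unlist(lapply(object$members[[m]], mlp_flatten))))
  c(w, object$self_energies)
}
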