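#' Save an ensemble checkpoint
#'
#' Serialises descriptor parameters, all member weights, self-energies
#' and metadata to a single portable JSON archive (plain text).
#'
#' @param ensemble an [nn_ensemble()]
#' @param path output file path (`.json`)
#' @return `path`, invisibly.
#' @export
save_ensemble <- function(ensemble, path) {
  aev <- ensemble$aev
  ck <- list(
    format = "deltadyn-ensemble-v1",
    aev = list(elements = aev$elements, rc_radial = aev$rc_radial,
               rc_angular = aev$rc_angular, eta_r = aev$eta_r,
               rs_radial = aev$rs_radial, eta_a = aev$eta_a,
               rs_angular = aev$rs_angular, theta_s = aev$theta_s,
               zeta = aev$zeta),
    hidden = ensemble$hidden,
    n_members = ensemble$n_members,
    activation = ensemble$activation,
    self_energies = as.list(ensemble$self_energies),
    stage = if (is.null(ensemble$stage)) "untrained" else ensemble$stage,
    members = lapply(ensemble$members, function(m)
      lapply(m, function(net) lapply(net, function(l)
        list(W = as.vector(l$W), dim = dim(l$W), b = l$b)))))
  jsonlite::write_json(ck, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an ensemble checkpoint
#'
#' @param path a file written by [save_ensemble()]
#' @return an [nn_ensemble()] (class `delta_ensemble` when the
#'   checkpoint was trained).
#' @export
load_ensemble <- function(path) {
  if (!file.exists(path)) stop("checkpoint file not found: ", path)
  ck <- jsonlite::read_json(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(ck$format, "deltadyn-ensemble-v1"))
    stop("not a deltadyn ensemble checkpoint: ", path)
  aev <- aev_params(elements = ck$aev$elements, rc_radial = ck$aev$rc_radial,
                    rc_angular = ck$aev$rc_angular, eta_r = ck$aev$eta_r,
                    rs_radial = ck$aev$rs_radial, eta_a = ck$aev$eta_a,
                    rs_angular = ck$aev$rs_angular, theta_s = ck$aev$theta_s,
                    zeta = ck$aev$zeta)
  members <- lapply(ck$members, function(m)
    lapply(m, function(net) lapply(net, function(l)
      list(W = matrix(unlist(l$W), l$dim[1], l$dim[2]), b = unlist(l$b)))))
  ens <- structure(
    list(aev = aev, hidden = unlist(ck$hidden), n_members = ck$n_members,
         members = members,
         self_energies = unlist(ck$self_energies),
         activation = ck$activation, stage = ck$stage),
    class = if (identical(ck$stage, "untrained")) "nn_ensemble"
            else c("delta_ensemble", "nn_ensemble"))
  ens
}
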