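#' Build a delta-learning dataset
#'
#' For every high-level frame, evaluates the baseline on the same
#' geometry and stores the difference `E_high - E_baseline` (and
#' `F_high - F_baseline` when both sides carry forces) as the training
#' label.  Frames on which the baseline fails are dropped and counted.
#'
#' @param frames_high list of [labeled_frame()] objects at the high level
#' @param baseline baseline potential (energy + gradient)
#' @param stage stage tag stored on each record: "base" or "transfer"
#' @return list of class `delta_dataset`: records with fields
#'   `structure`, `delta_energy` (Hartree), `delta_forces` (N x 3 or
#'   NULL), `stage`; attribute `n_dropped` counts failed baseline
#'   evaluations.
#' @export
build_delta_dataset <- function(frames_high, baseline, stage = "base") {
  stopifnot(stage %in% c("base", "transfer"))
  records <- list()
  n_dropped <- 0L
  for (f in frames_high) {
    if (!inherits(f, "dd_frame"))
      stop("every frame must be a labeled frame with a high-level energy")
    base <- tryCatch(eval_structure(baseline, f$structure),
                     error = function(e) NULL)
    if (is.null(base) || !is.finite(base$energy)) {
      n_dropped <- n_dropped + 1L
      next
    }
    df <- if (!is.null(f$forces))
      f$forces - (-unflatten_coords(base$gradient))
    records[[length(records) + 1L]] <-
      list(structure = f$structure, delta_energy = f$energy - base$energy,
           delta_forces = df, stage = stage)
  }
  if (length(records) == 0L)
    stop("no surviving records: baseline failed on all ", n_dropped, " frames")
  if (n_dropped > 0L)
    message("build_delta_dataset: dropped ", n_dropped,
            " frame(s) with failed baseline evaluations")
  structure(records, class = "delta_dataset", n_dropped = n_dropped)
}

#' Training configuration
#'
#' @param aev an [aev_params()] shared by all members
#' @param hidden hidden-layer widths of the per-element networks
#' @param n_members ensemble size (default 8)
#' @param w_energy energy-loss weight
#' @param w_force force-loss weight (base stage default 0.1; the
#'   transfer stage trains on energies only by default)
#' @param lr Adam learning rate
#' @param lr_decay multiplicative learning-rate decay per epoch
#' @param epochs maximum training epochs
#' @param patience early-stopping patience on validation energy MAE
#' @param val_fraction fraction of records held out per member for
#'   validation (each member uses its own split)
#' @param frozen_layers weight-bearing layer indices kept fixed during
#'   transfer learning (default first and third)
#' @param seed base seed; member m derives its split and initialisation
#'   from `seed + 1000 * m`
#' @return list of class `train_config`.
#' @export
train_config <- function(aev = aev_params(), hidden = c(32, 24, 16),
                         n_members = 8L, w_energy = 1.0, w_force = 0.1,
                         lr = 5e-3, lr_decay = 0.998, epochs = 200L,
                         patience = 30L, val_fraction = 0.1,
                         frozen_layers = c(1L, 3L), seed = 1L) {
  if (w_energy < 0 || w_force < 0) stop("loss weights must be non-negative")
  if (n_members < 2L) stop("ensemble needs at least 2 members")
  structure(list(aev = aev, hidden = hidden, n_members = as.integer(n_members),
                 w_energy = w_energy, w_force = w_force, lr = lr,
                 lr_decay = lr_decay, epochs = as.integer(epochs),
                 patience = as.integer(patience), val_fraction = val_fraction,
                 frozen_layers = as.integer(frozen_layers),
                 seed = as.integer(seed)),
            class = "train_config")
}

# fit per-element self-energy offsets by linear regression of the delta
# energies on element counts
fit_self_energies <- function(dataset, elements) {
  counts <- t(vapply(dataset, function(r)
    vapply(elements, function(e) sum(r$structure$elements == e), 1.0),
    numeric(length(elements))))
  y <- vapply(dataset, function(r) r$delta_energy, 1.0)
  fit <- stats::lm.fit(counts, y)
  se <- fit$coefficients
  se[is.na(se)] <- 0
  stats::setNames(as.numeric(se), elements)
}

# Precompute descriptors, Jacobian stacks and targets for a dataset.
# Atoms of all frames are stacked per element so each training epoch is
# a handful of dense matrix products.
prepare_training <- function(dataset, config, self_energies,
                             need_forces = config$w_force > 0) {
  aev <- config$aev
  els <- aev$elements
  n_frames <- length(dataset)
  frame_nat <- integer(n_frames)
  atom_el <- character(0); atom_frame <- integer(0)
  G_rows <- list(); J_stacks <- vector("list", n_frames)
  targets_e <- numeric(n_frames)
  targets_g <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    r <- dataset[[f]]
    s <- r$structure
    frame_nat[f] <- n_atoms(s)
    res <- if (need_forces) aev_with_jacobian(s, aev)
           else list(aev = compute_aev(s, aev))
    G_rows[[f]] <- res$aev
    if (need_forces) {
      if (is.null(r$delta_forces))
        stop("force-loss training requires delta_forces on every record")
      J_stacks[[f]] <- do.call(rbind, res$jacobian)
      targets_g[[f]] <- as.vector(t(-r$delta_forces))
    }
    atom_el <- c(atom_el, s$elements)
    atom_frame <- c(atom_frame, rep(f, n_atoms(s)))
    targets_e[f] <- r$delta_energy - sum(self_energies[s$elements])
  }
  G_all <- do.call(rbind, G_rows)
  rows_el <- lapply(stats::setNames(els, els), function(e) which(atom_el == e))
  frame_atoms <- split(seq_along(atom_frame), atom_frame)
  list(aev = aev, elements = els, n_frames = n_frames, frame_nat = frame_nat,
       G_all = G_all, rows_el = rows_el, atom_frame = atom_frame,
       frame_atoms = frame_atoms, J_stacks = J_stacks,
       targets_e = targets_e, targets_g = targets_g,
       need_forces = need_forces)
}

# per-member index cache, computed once per training run
make_loss_cache <- function(prep, frames) {
  rows_el <- lapply(prep$rows_el, function(r)
    r[prep$atom_frame[r] %in% frames])
  list(frames = frames, rows_el = rows_el,
       atoms_concat = unlist(prep$frame_atoms[frames], use.names = FALSE),
       nat = prep$frame_nat[frames])
}

# one full-batch loss + parameter-gradient evaluation on a frame subset
member_loss_grad <- function(nets, prep, cache, config) {
  D <- prep$aev$n_features
  frames <- cache$frames
  V <- matrix(0, length(prep$atom_frame), D)
  y_atom <- numeric(length(prep$atom_frame))
  caches <- list()
  for (el in prep$elements) {
    rows <- cache$rows_el[[el]]
    if (length(rows) == 0L) next
    bp <- mlp_backprop(nets[[el]], prep$G_all[rows, , drop = FALSE],
                       want_param_grads = FALSE)
    y_atom[rows] <- bp$y
    V[rows, ] <- bp$dX
    caches[[el]] <- rows
  }
  e_pred <- vapply(frames, function(f)
    sum(y_atom[prep$frame_atoms[[f]]]), 1.0)
  res_e <- e_pred - prep$targets_e[frames]
  loss_e <- mean(res_e^2)
  # energy-loss backprop seeds per atom
  seed_e <- numeric(length(prep$atom_frame))
  seed_e[cache$atoms_concat] <- rep(2 * res_e / length(frames), cache$nat)
  loss_f <- 0
  Wdual <- NULL
  if (prep$need_forces && config$w_force > 0) {
    Wdual <- matrix(0, length(prep$atom_frame), D)
    M <- sum(3L * prep$frame_nat[frames])
    for (f in frames) {
      atoms <- prep$frame_atoms[[f]]
      vstack <- as.vector(t(V[atoms, , drop = FALSE]))
      P <- as.vector(crossprod(prep$J_stacks[[f]], vstack))
      resid <- P - prep$targets_g[[f]]
      loss_f <- loss_f + sum(resid^2)
      wstack <- prep$J_stacks[[f]] %*% resid
      Wdual[atoms, ] <- matrix(2 / M * wstack, ncol = D, byrow = TRUE)
    }
    loss_f <- loss_f / M
  }
  grads <- list()
  for (el in prep$elements) {
    rows <- caches[[el]]
    if (is.null(rows)) { grads[[el]] <- NULL; next }
    X <- prep$G_all[rows, , drop = FALSE]
    ge <- mlp_backprop(nets[[el]], X, ybar = seed_e[rows])$grads
    g <- lapply(ge, function(l) list(W = config$w_energy * l$W,
                                     b = config$w_energy * l$b))
    if (!is.null(Wdual)) {
      gf <- mlp_backprop(nets[[el]], X,
                         Xdot = Wdual[rows, , drop = FALSE])$dgrads
      g <- Map(function(a, b) list(W = a$W + config$w_force * b$W,
                                   b = a$b + config$w_force * b$b), g, gf)
    }
    grads[[el]] <- g
  }
  list(loss = config$w_energy * loss_e + config$w_force * loss_f,
       loss_e = loss_e, loss_f = loss_f, grads = grads)
}

# validation energy MAE (kcal/mol) on a frame subset
member_val_mae <- function(nets, prep, frames) {
  y_atom <- numeric(length(prep$atom_frame))
  in_set <- prep$atom_frame %in% frames
  for (el in prep$elements) {
    rows <- prep$rows_el[[el]]
    rows <- rows[rows %in% which(in_set)]
    if (length(rows) == 0L) next
    y_atom[rows] <- mlp_value(nets[[el]], prep$G_all[rows, , drop = FALSE])
  }
  e_pred <- vapply(frames, function(f) sum(y_atom[prep$frame_atoms[[f]]]), 1.0)
  hartree_to_kcalmol(mean(abs(e_pred - prep$targets_e[frames])))
}

# Adam optimiser over the nested per-element layer lists
adam_init <- function(nets) {
  rapply(nets, function(x) x * 0, how = "replace")
}

adam_step <- function(nets, grads, m1, m2, t, lr, frozen = integer(0),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (el in names(grads)) {
    if (is.null(grads[[el]])) next
    for (l in seq_along(nets[[el]])) {
      if (l %in% frozen) next
      for (p in c("W", "b")) {
        g <- grads[[el]][[l]][[p]]
        if (p == "W") g <- matrix(g, nrow(nets[[el]][[l]]$W))
        m1[[el]][[l]][[p]] <- beta1 * m1[[el]][[l]][[p]] + (1 - beta1) * g
        m2[[el]][[l]][[p]] <- beta2 * m2[[el]][[l]][[p]] + (1 - beta2) * g * g
        mh <- m1[[el]][[l]][[p]] / (1 - beta1^t)
        vh <- m2[[el]][[l]][[p]] / (1 - beta2^t)
        nets[[el]][[l]][[p]] <- nets[[el]][[l]][[p]] - lr * mh / (sqrt(vh) + eps)
      }
    }
  }
  list(nets = nets, m1 = m1, m2 = m2)
}

# train one member: its own split, initialisation and Adam state
train_member <- function(prep, config, member_seed, nets_init = NULL,
                         frozen = integer(0)) {
  set.seed(member_seed)
  n <- prep$n_frames
  n_val <- max(1L, round(config$val_fraction * n))
  val_idx <- sample.int(n, n_val)
  train_idx <- setdiff(seq_len(n), val_idx)
  nets <- if (is.null(nets_init)) {
    stats::setNames(lapply(prep$elements, function(e)
      init_mlp(prep$aev$n_features, config$hidden)), prep$elements)
  } else nets_init
  m1 <- adam_init(nets); m2 <- adam_init(nets)
  best <- list(nets = nets, val = Inf, epoch = 0L)
  lr <- config$lr
  cache <- make_loss_cache(prep, train_idx)
  history <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    lg <- member_loss_grad(nets, prep, cache, config)
    if (!is.finite(lg$loss))
      stop("training diverged (non-finite loss) at epoch ", ep)
    st <- adam_step(nets, lg$grads, m1, m2, ep, lr, frozen)
    nets <- st$nets; m1 <- st$m1; m2 <- st$m2
    lr <- lr * config$lr_decay
    val <- member_val_mae(nets, prep, val_idx)
    history[[ep]] <- data.frame(epoch = ep, loss = lg$loss,
                                loss_energy = lg$loss_e, loss_force = lg$loss_f,
                                val_mae = val)
    if (val < best$val) best <- list(nets = nets, val = val, epoch = ep)
    if (ep - best$epoch >= config$patience) break
  }
  list(nets = best$nets, val_mae = best$val,
       history = do.call(rbind, history[!vapply(history, is.null, TRUE)]))
}

#' Train a delta-correction ensemble (base stage)
#'
#' The central fitting function: fits per-element self-energy offsets by
#' linear regression, then trains each ensemble member on the delta
#' labels with the loss `w_E * MSE(energy) + w_F * MSE(forces)` using
#' full-batch Adam.  Members differ in initialisation seed and
#' train/validation split; training is deterministic given the
#' configuration seed.
#'
#' @param dataset a [build_delta_dataset()] result (stage "base")
#' @param config a [train_config()]
#' @return object of class `c("delta_ensemble", "nn_ensemble")`: an
#'   [nn_ensemble()] whose `history` field holds per-member training
#'   curves and validation MAEs and whose `stage` is "base".
#' @seealso [transfer_learn()] for the second stage,
#'   [composite_potential()] to deploy the result.
#' @export
train_delta_ensemble <- function(dataset, config = train_config()) {
  if (length(dataset) == 0L) stop("empty training dataset")
  self_e <- fit_self_energies(dataset, config$aev$elements)
  need_f <- config$w_force > 0
  if (need_f && any(vapply(dataset, function(r) is.null(r$delta_forces), TRUE))) {
    stop("w_force > 0 but some records lack delta_forces")
  }
  prep <- prepare_training(dataset, config, self_e, need_forces = need_f)
  members <- vector("list", config$n_members)
  histories <- vector("list", config$n_members)
  val_maes <- numeric(config$n_members)
  for (m in seq_len(config$n_members)) {
    tm <- train_member(prep, config, member_seed = config$seed + 1000L * m)
    members[[m]] <- tm$nets
    histories[[m]] <- cbind(member = m, tm$history)
    val_maes[m] <- tm$val_mae
  }
  ens <- structure(
    list(aev = config$aev, hidden = config$hidden,
         n_members = config$n_members, members = members,
         self_energies = self_e, activation = "gelu", seed = config$seed,
         stage = "base", config = config,
         history = do.call(rbind, histories), val_maes = val_maes),
    class = c("delta_ensemble", "nn_ensemble"))
  ens
}

#' @rdname train_delta_ensemble
#' @export
train_base <- train_delta_ensemble

#' Transfer-learn an ensemble to a higher level of theory
#'
#' Continues training of a base-trained ensemble on a (typically
#' smaller) dataset of higher-level delta labels, with selected
#' weight-bearing layers frozen (default: the first and the third),
#' which reduces the number of trainable parameters and prevents
#' overfitting.  By default only the energy loss is used at this stage.
#'
#' @param ensemble a trained [train_delta_ensemble()] result
#' @param dataset_high delta dataset against the higher level
#' @param config a [train_config()]; `frozen_layers` selects the frozen
#'   layers, `w_force` defaults to 0 for this stage
#' @return the updated ensemble (class `delta_ensemble`), with stage
#'   "transfer".  Frozen-layer parameters are bit-identical to the
#'   input ensemble's.
#' @export
transfer_learn <- function(ensemble, dataset_high, config = ensemble$config) {
  stopifnot(inherits(ensemble, "nn_ensemble"))
  n_layers <- length(ensemble$members[[1]][[1]])
  if (any(config$frozen_layers < 1L | config$frozen_layers > n_layers))
    stop("frozen layer index outside the architecture (1..", n_layers, ")")
  cfg <- config
  cfg$w_force <- 0   # energies only at the transfer stage
  prep <- prepare_training(dataset_high, cfg, ensemble$self_energies,
                           need_forces = FALSE)
  if (cfg$epochs == 0L) return(ensemble)
  members <- ensemble$members
  histories <- vector("list", length(members))
  val_maes <- numeric(length(members))
  for (m in seq_along(members)) {
    tm <- train_member(prep, cfg, member_seed = cfg$seed + 1000L * m + 500L,
                       nets_init = members[[m]], frozen = cfg$frozen_layers)
    members[[m]] <- tm$nets
    histories[[m]] <- cbind(member = m, tm$history)
    val_maes[m] <- tm$val_mae
  }
  ensemble$members <- members
  ensemble$stage <- "transfer"
  ensemble$transfer_history <- do.call(rbind, histories)
  ensemble$val_maes <- val_maes
  ensemble
}

#' Scan-based calibration of the uncertainty threshold
#'
#' Finds the largest uncertainty threshold such that predictions below
#' it have a mean absolute error within `target_mae`: points are sorted
#' by uncertainty and the cumulative MAE is scanned; the threshold is
#' the uncertainty of the last point whose inclusion still meets the
#' target.  Returns `+Inf` when every prediction meets the target and
#' flags the degenerate case where no prefix does.
#'
#' @param abs_errors absolute prediction errors, kcal/mol
#' @param uncertainties ensemble uncertainties, kcal/mol (same length)
#' @param target_mae target MAE, kcal/mol
#' @return list with `threshold` (kcal/mol), `degenerate` flag and
#'   `n_reliable` (points at or below the threshold).
#' @export
threshold_scan <- function(abs_errors, uncertainties, target_mae) {
  stopifnot(length(abs_errors) == length(uncertainties))
  if (length(abs_errors) == 0L) stop("empty holdout")
  o <- order(uncertainties)
  err <- abs_errors[o]; unc <- uncertainties[o]
  cum_mae <- cumsum(err) / seq_along(err)
  ok <- which(cum_mae <= target_mae)
  if (length(ok) == 0L)
    return(list(threshold = min(unc), degenerate = TRUE, n_reliable = 0L))
  K <- max(ok)
  if (K == length(err))
    return(list(threshold = Inf, degenerate = FALSE, n_reliable = K))
  list(threshold = unc[K], degenerate = FALSE, n_reliable = K)
}

#' Calibrate the ensemble uncertainty threshold on a holdout set
#'
#' Predicts every holdout record with the ensemble, measures absolute
#' errors against the reference delta energies and ensemble
#' uncertainties, and applies [threshold_scan()].
#'
#' @param ensemble a trained [nn_ensemble()]
#' @param holdout delta dataset with reference labels
#' @param target_mae target MAE in kcal/mol
#' @return as [threshold_scan()].
#' @export
calibrate_threshold <- function(ensemble, holdout, target_mae) {
  if (length(holdout) == 0L) stop("empty holdout")
  err <- numeric(length(holdout)); unc <- numeric(length(holdout))
  for (i in seq_along(holdout)) {
    r <- holdout[[i]]
    nc <- nn_correction(r$structure, ensemble)
    err[i] <- hartree_to_kcalmol(abs(nc$mean - r$delta_energy))
    unc[i] <- nc$uncertainty
  }
  threshold_scan(err, unc, target_mae)
}

# S3 methods for the fitted ensemble -----------------------------------------

#' @export
print.delta_ensemble <- function(x, ...) {
  cat(sprintf("<delta_ensemble> stage '%s', %d members, hidden [%s]\n",
              x$stage, x$n_members, paste(x$hidden, collapse = ",")))
  cat(sprintf("  per-member validation MAE (kcal/mol): %s\n",
              paste(sprintf("%.3f", x$val_maes), collapse = ", ")))
  invisible(x)
}

#' @export
summary.delta_ensemble <- function(object, ...) {
  h <- object$history
  out <- list(stage = object$stage, n_members = object$n_members,
              self_energies = object$self_energies,
              val_maes = object$val_maes,
              epochs_run = tapply(h$epoch, h$member, max))
  class(out) <- "summary.delta_ensemble"
  out
}

#' @export
print.summary.delta_ensemble <- function(x, ...) {
  cat(sprintf("Delta-correction ensemble (stage '%s', %d members)\n",
              x$stage, x$n_members))
  cat("Self-energy offsets (Hartree):\n")
  print(x$self_energies)
  cat(sprintf("Validation MAE (kcal/mol): median %.3f, range [%.3f, %.3f]\n",
              stats::median(x$val_maes), min(x$val_maes), max(x$val_maes)))
  cat("Epochs run per member: ", paste(x$epochs_run, collapse = ", "), "\n")
  invisible(x)
}

#' Plot training curves of a fitted ensemble
#'
#' @param x a `delta_ensemble`
#' @param ... passed to [graphics::matplot()]
#' @return `x`, invisibly.
#' @export
plot.delta_ensemble <- function(x, ...) {
  h <- x$history
  members <- sort(unique(h$member))
  ep_max <- max(h$epoch)
  mat <- matrix(NA_real_, ep_max, length(members))
  for (j in seq_along(members)) {
    hm <- h[h$member == members[j], ]
    mat[hm$epoch, j] <- hm$val_mae
  }
  graphics::matplot(seq_len(ep_max), mat, type = "l", lty = 1,
                    xlab = "epoch", ylab = "validation MAE (kcal/mol)",
                    main = "per-member training curves", ...)
  invisible(x)
}

#' Residuals of a fitted ensemble on a delta dataset
#'
#' @param object a `delta_ensemble`
#' @param dataset a delta dataset (defaults to refusing politely when
#'   absent, as the training data are not stored on the object)
#' @param ... unused
#' @return numeric vector of signed errors (predicted minus reference
#'   delta energy) in kcal/mol.
#' @export
residuals.delta_ensemble <- function(object, dataset, ...) {
  if (missing(dataset))
    stop("supply the delta dataset to compute residuals against")
  vapply(dataset, function(r)
    hartree_to_kcalmol(nn_correction(r$structure, object)$mean - r$delta_energy),
    1.0)
}
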