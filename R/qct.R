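# Quasi-classical trajectory engine: harmonic quantum Boltzmann sampling
# at a transition state, paired forward/backward NVE propagation,
# trajectory stitching and outcome classification.

#' Sampling specification for quasi-classical initial conditions
#'
#' @param temperature sampling temperature, K (> 0)
#' @param n_samples number of initial conditions
#' @param seed integer random seed (recorded in the output)
#' @param imaginary_mode treatment of the imaginary mode:
#'   `"zero-displacement"` (no displacement, momentum drawn from the
#'   classical Boltzmann distribution; the sign is immaterial because
#'   each initial condition is propagated both forward and backward) or
#'   `"excluded"` (no displacement, no momentum)
#' @return list of class `sampling_spec`.
#' @export
sampling_spec <- function(temperature = 298.15, n_samples = 100L, seed = 1L,
                          imaginary_mode = c("zero-displacement", "excluded")) {
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(temperature = temperature, n_samples = as.integer(n_samples),
                 seed = as.integer(seed),
                 imaginary_mode = match.arg(imaginary_mode)),
            class = "sampling_spec")
}

#' Sample initial conditions from the harmonic quantum Boltzmann distribution
#'
#' At an index-1 saddle, each real normal mode i receives a vibrational
#' quantum number drawn with `P(n) proportional to exp(-n h nu_i / kT)`,
#' giving mode energy `E_i = (n_i + 1/2) h nu_i` (zero-point energy at
#' T -> 0).  The mode is then assigned a random phase:
#' `Q_i = A_i cos(2 pi phi_i)`, `Qdot_i = -omega_i A_i sin(2 pi phi_i)`
#' with `A_i = sqrt(2 E_i)/omega_i` in mass-weighted coordinates, and
#' transformed back to Cartesians.  The imaginary mode is handled per
#' the spec.  The sampler is a pure function of (seed, spec).
#'
#' @param ts a [characterize_point()] result of order 1
#' @param modes the [normal_modes()] at the saddle (projected)
#' @param spec a [sampling_spec()]
#' @return list of initial conditions, each `list(coords, velocities)`
#'   (Angstrom, Angstrom/fs), with attribute `mode_energies` (Hartree,
#'   one row per sample, one column per real mode).
#' @export
sample_initial_conditions <- function(ts, modes, spec) {
  if (ts$order != 1L)
    stop("initial-condition sampling requires an index-1 saddle (order ",
         ts$order, ")")
  u <- dd_units()
  lam <- modes$eigenvalues
  imag_idx <- which(lam < -1e-8)
  real_idx <- which(lam > 1e-8)
  if (length(imag_idx) != 1L)
    stop("expected exactly one imaginary mode, found ", length(imag_idx))
  if (length(real_idx) != length(lam) - 1L)
    stop("non-positive real frequency among sampled modes")
  omega <- sqrt(lam[real_idx] * u$acc_factor)          # rad/fs
  nu <- omega / (2 * pi)                               # fs^-1
  hnu <- u$h_hartree_fs * nu                           # Hartree
  kT <- u$kB_hartree * spec$temperature
  minv <- 1 / sqrt(modes$masses)
  set.seed(spec$seed)
  out <- vector("list", spec$n_samples)
  emat <- matrix(0, spec$n_samples, length(real_idx))
  for (s in seq_len(spec$n_samples)) {
    Q <- numeric(length(lam)); Qd <- numeric(length(lam))
    # geometric quantum numbers; for hnu >> kT this is surely n = 0
    p_geom <- -expm1(-pmin(hnu / kT, 700))
    n_q <- stats::rgeom(length(real_idx), p_geom)
    E <- (n_q + 0.5) * hnu                             # Hartree
    emat[s, ] <- E
    E_mw <- E * u$acc_factor                           # amu A^2/fs^2
    A <- sqrt(2 * E_mw) / omega
    phi <- stats::runif(length(real_idx))
    Q[real_idx] <- A * cos(2 * pi * phi)
    Qd[real_idx] <- -omega * A * sin(2 * pi * phi)
    if (spec$imaginary_mode == "zero-displacement") {
      Qd[imag_idx] <- stats::rnorm(1L, 0, sqrt(kT * u$acc_factor))
    }
    dx <- minv * as.vector(modes$modes %*% Q)
    v <- minv * as.vector(modes$modes %*% Qd)
    out[[s]] <- list(coords = ts$coords + dx, velocities = v)
  }
  attr(out, "mode_energies") <- emat
  attr(out, "seed") <- spec$seed
  out
}

#' Kinetic energy of a velocity vector
#'
#' @param velocities flat velocities, Angstrom/fs
#' @param masses per-coordinate masses, amu
#' @return kinetic energy, Hartree
#' @export
kinetic_energy <- function(velocities, masses) {
  0.5 * sum(masses * velocities^2) * dd_units()$mass_vel2_to_hartree
}

#' Propagate an NVE trajectory with velocity Verlet
#'
#' Backward propagation uses the identical initial coordinates with the
#' initial velocities negated.  The per-frame potential and total
#' (kinetic + potential) energies are recorded.  Exactly
#' `ceiling(t_end/dt)` new force evaluations are performed when the
#' initial gradient `g0` is supplied (it is shared between the forward
#' and backward segments of a pair); otherwise one extra evaluation
#' initialises the integrator.
#'
#' @param initial `list(coords, velocities)` (flat, Angstrom and
#'   Angstrom/fs)
#' @param potential potential providing the gradient
#' @param dt time step, fs (> 0)
#' @param t_end trajectory length, fs
#' @param direction `"forward"` or `"backward"`
#' @param g0 optional precomputed gradient at the initial coordinates
#' @return object of class `trajectory_segment`: `times` (fs), `coords`
#'   and `velocities` (frame-per-row matrices), `epot`, `etot`
#'   (Hartree), `direction`, `dt`, `blown_up` flag (TRUE when non-finite
#'   forces truncated the run), `n_force_evals`.
#' @export
propagate <- function(initial, potential, dt, t_end,
                      direction = c("forward", "backward"), g0 = NULL) {
  direction <- match.arg(direction)
  if (dt <= 0) stop("dt must be positive")
  n_steps <- ceiling(t_end / dt)
  d <- length(initial$coords)
  masses <- pot_masses(potential)
  u <- dd_units()
  x <- initial$coords
  v <- if (direction == "backward") -initial$velocities else initial$velocities
  n_evals <- 0L
  if (is.null(g0)) {
    g0 <- pot_eval(potential, x)$gradient
    n_evals <- n_evals + 1L
  }
  coords <- matrix(NA_real_, n_steps + 1L, d)
  vels <- matrix(NA_real_, n_steps + 1L, d)
  epot <- numeric(n_steps + 1L)
  # initial potential energy: evaluate once if not derivable; we accept
  # one energy call bundled with g0 by convention (pot_eval returns both)
  r <- list(gradient = g0, energy = attr(g0, "energy"))
  if (is.null(r$energy)) {
    # g0 supplied as a bare gradient: recover the energy alongside frame 0
    r$energy <- pot_eval(potential, x)$energy
  }
  coords[1L, ] <- x; vels[1L, ] <- v; epot[1L] <- r$energy
  a <- -r$gradient / masses * u$acc_factor
  blown <- FALSE
  last <- n_steps + 1L
  for (st in seq_len(n_steps)) {
    vh <- v + 0.5 * dt * a
    x <- x + dt * vh
    rn <- pot_eval(potential, x)
    n_evals <- n_evals + 1L
    if (!all(is.finite(rn$gradient)) || !is.finite(rn$energy)) {
      blown <- TRUE
      last <- st
      break
    }
    a <- -rn$gradient / masses * u$acc_factor
    v <- vh + 0.5 * dt * a
    coords[st + 1L, ] <- x
    vels[st + 1L, ] <- v
    epot[st + 1L] <- rn$energy
  }
  keep <- seq_len(last)
  coords <- coords[keep, , drop = FALSE]
  vels <- vels[keep, , drop = FALSE]
  epot <- epot[keep]
  ekin <- 0.5 * colSums(t(vels^2) * masses) * u$mass_vel2_to_hartree
  structure(list(times = (keep - 1L) * dt, coords = coords,
                 velocities = vels, epot = epot, etot = epot + ekin,
                 direction = direction, dt = dt, blown_up = blown,
                 n_force_evals = n_evals, masses = masses),
            class = "trajectory_segment")
}

#' Combine paired forward and backward segments
#'
#' The two segments must start from the same initial condition
#' (identical coordinates, opposite velocities).  Backward frames are
#' mapped to negative times in reverse order; the duplicated t = 0 frame
#' is kept once; backward velocities are negated so every frame carries
#' the velocity of motion along the signed time axis.
#'
#' @param fwd,bwd [propagate()] results with directions "forward" and
#'   "backward"
#' @param id initial-condition identifier stored on the result
#' @return object of class `combined_trajectory`: `times` (strictly
#'   increasing, spanning `[-t_bwd, +t_fwd]`), `coords`, `velocities`,
#'   `epot`, `etot`, `id`, `blown_up`.
#' @export
combine <- function(fwd, bwd, id = 1L) {
  if (fwd$direction != "forward" || bwd$direction != "backward")
    stop("combine expects one forward and one backward segment")
  if (max(abs(fwd$coords[1L, ] - bwd$coords[1L, ])) > 1e-10 ||
      max(abs(fwd$velocities[1L, ] + bwd$velocities[1L, ])) > 1e-10)
    stop("segments do not share the initial condition ",
         "(coordinates equal, velocities negated)")
  nb <- nrow(bwd$coords)
  idx <- nb:2L
  structure(list(
    times = c(-bwd$times[idx], fwd$times),
    coords = rbind(bwd$coords[idx, , drop = FALSE], fwd$coords),
    velocities = rbind(-bwd$velocities[idx, , drop = FALSE], fwd$velocities),
    epot = c(bwd$epot[idx], fwd$epot),
    etot = c(bwd$etot[idx], fwd$etot),
    id = id, blown_up = fwd$blown_up || bwd$blown_up),
    class = "combined_trajectory")
}

#' @export
print.combined_trajectory <- function(x, ...) {
  cat(sprintf("<combined_trajectory> id %s, %d frames, t in [%.1f, %.1f] fs%s\n",
              x$id, length(x$times), min(x$times), max(x$times),
              if (x$blown_up) " [BLOWN UP]" else ""))
  invisible(x)
}

#' Product definition by bond events
#'
#' A species is recognised by a set of bond events that must all hold:
#' a bond is "formed" when the distance between the atom pair is below
#' the threshold, "broken" when above.
#'
#' @param name species label
#' @param events list of events, each
#'   `list(pair = c(i, j), type = "formed"|"broken", threshold = Angstrom)`
#' @return list of class `product_definition`.
#' @examples
#' product_definition("P2", list(
#'   list(pair = c(2, 15), type = "formed", threshold = 1.6),
#'   list(pair = c(3, 13), type = "formed", threshold = 1.6)))
#' @export
product_definition <- function(name, events) {
  for (ev in events) {
    if (length(ev$pair) != 2L || any(ev$pair < 1L))
      stop("invalid atom pair in event of '", name, "'")
    if (!ev$type %in% c("formed", "broken"))
      stop("event type must be 'formed' or 'broken'")
    if (ev$threshold <= 0) stop("threshold must be positive")
  }
  structure(list(name = name, events = events), class = "product_definition")
}

# distance time series of an atom pair along a trajectory
pair_distance_series <- function(traj, pair) {
  ci <- 3L * (pair[1] - 1L) + 1:3
  cj <- 3L * (pair[2] - 1L) + 1:3
  sqrt(rowSums((traj$coords[, ci, drop = FALSE] -
                  traj$coords[, cj, drop = FALSE])^2))
}

# first time index at which `ok` begins a run lasting at least
# `persistence` fs on the time grid; NA when never
.first_persistent <- function(ok, times, persistence) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    if (times[ends[k]] - times[starts[k]] >= persistence) return(starts[k])
  }
  NA_integer_
}

#' Classify the outcome of a combined trajectory
#'
#' A species is "present" when all of its bond events hold continuously
#' for at least the persistence window (short sub-window spikes are
#' ignored).  A combined trajectory is reactive when it contains the
#' reactant and exactly one product; a trajectory containing only the
#' reactant is labelled `"reactant-only"`, one containing only products
#' `"nonreactive"`, and ambiguous cases (two products, or nothing
#' persistent) `"undetermined"` — never an exception.  The
#' first-formation time of each "formed" bond (entry into its first
#' persistent formed state) is recorded.
#'
#' @param trajectory a [combine()] result with Cartesian frames
#' @param reactant_def a [product_definition()] describing the reactant
#' @param products list of [product_definition()]s
#' @param persistence persistence window, fs
#' @return list of class `trajectory_outcome`: `label`, `reactive`,
#'   `present` (named flags), `bond_times` (per product, named numeric
#'   vector of first-formation times in fs for its "formed" events).
#' @export
classify <- function(trajectory, reactant_def, products, persistence = 50) {
  n_at <- ncol(trajectory$coords) %/% 3L
  defs <- c(list(reactant_def), products)
  present <- logical(length(defs))
  names(present) <- vapply(defs, `[[`, "", "name")
  bond_times <- list()
  for (di in seq_along(defs)) {
    def <- defs[[di]]
    ok <- rep(TRUE, length(trajectory$times))
    for (ev in def$events) {
      if (any(ev$pair > n_at)) stop("event references atom beyond atom count")
      dser <- pair_distance_series(trajectory, ev$pair)
      ok <- ok & if (ev$type == "formed") dser < ev$threshold
                 else dser > ev$threshold
    }
    present[di] <- !is.na(.first_persistent(ok, trajectory$times, persistence))
    if (di > 1L) {
      bt <- c()
      for (ev in def$events) {
        if (ev$type != "formed") next
        dser <- pair_distance_series(trajectory, ev$pair)
        idx <- .first_persistent(dser < ev$threshold, trajectory$times,
                                 persistence)
        bt[paste(ev$pair, collapse = "-")] <-
          if (is.na(idx)) NA_real_ else trajectory$times[idx]
      }
      bond_times[[def$name]] <- bt
    }
  }
  prod_present <- present[-1L]
  label <- if (present[1L] && sum(prod_present) == 1L) {
    names(prod_present)[prod_present]
  } else if (present[1L] && sum(prod_present) == 0L) {
    "reactant-only"
  } else if (!present[1L] && sum(prod_present) == 1L) {
    "nonreactive"
  } else {
    "undetermined"
  }
  structure(list(label = label,
                 reactive = present[1L] && sum(prod_present) == 1L,
                 present = present, bond_times = bond_times),
            class = "trajectory_outcome")
}

#' Classify a trajectory on an analytic surface by basin regions
#'
#' The analytic-surface analogue of [classify()].  Regions are derived
#' from the catalog: the reactant region lies on the reactant side of
#' the ambimodal saddle; the two product regions lie beyond the
#' product-interconversion saddle, separated by the sign of the
#' branching coordinate (with a dead band of `y_margin` around the
#' ridge).  Because a low-dimensional conservative system keeps enough
#' energy to recross the product ridge indefinitely, the product label
#' is the first region entered persistently when scanning frames
#' outward from the shared initial condition (increasing `|t|`) — the
#' dynamical commitment of the trajectory.
#'
#' @param trajectory a [combine()] result on a surface
#' @param surface an [analytic_surface()] with a catalog
#' @param y_margin dead band around the product ridge, Angstrom
#' @param persistence persistence window, fs
#' @return as [classify()]; `bond_times` carries the product first-entry
#'   time (on the `|t|` axis).
#' @export
classify_basin <- function(trajectory, surface, y_margin = 0.25,
                           persistence = 20) {
  cat <- surface$catalog
  x_react <- cat$x[cat$name == "reactant"]
  x_ts <- cat$x[cat$name == "TS_ambimodal"]
  x_prod <- cat$x[cat$name == "TS_products"]
  x_rcut <- 0.5 * (x_react + x_ts)     # reactant side of the barrier
  x_pcut <- 0.5 * (x_ts + x_prod)      # committed to the product valley
  # each half runs downhill from the shared initial condition; find the
  # first persistently-entered region of each half independently
  half_commit <- function(sel) {
    o <- sel[order(abs(trajectory$times[sel]))]
    x <- trajectory$coords[o, 1]; y <- trajectory$coords[o, 2]
    t_abs <- abs(trajectory$times[o])
    i_r <- .first_persistent(x < x_rcut, t_abs, persistence)
    i_p1 <- .first_persistent(x > x_pcut & y > y_margin, t_abs, persistence)
    i_p2 <- .first_persistent(x > x_pcut & y < -y_margin, t_abs, persistence)
    idx <- c(reactant = i_r, P1 = i_p1, P2 = i_p2)
    if (all(is.na(idx))) return(list(region = NA_character_, time = NA_real_))
    w <- which.min(idx)
    list(region = names(idx)[w], time = t_abs[idx[w]])
  }
  hf <- half_commit(which(trajectory$times >= 0))
  hb <- half_commit(which(trajectory$times <= 0))
  regions <- c(hf$region, hb$region)
  present <- c(reactant = "reactant" %in% regions,
               P1 = "P1" %in% regions, P2 = "P2" %in% regions)
  label <- if (anyNA(regions)) "undetermined"
    else if (present[["reactant"]] && sum(present[c("P1", "P2")]) == 1L)
      regions[regions != "reactant"][1]
    else if (all(regions == "reactant")) "reactant-only"
    else if (!present[["reactant"]] && regions[1] == regions[2]) "nonreactive"
    else "undetermined"
  bt <- list()
  if (label %in% c("P1", "P2")) {
    tt <- c(hf$time, hb$time)[regions == label]
    bt[[label]] <- c(entry = tt[1])
  }
  structure(list(label = label,
                 reactive = label %in% c("P1", "P2"),
                 present = present, bond_times = bt),
            class = "trajectory_outcome")
}

#' Planned number of single-point evaluations of a dynamics run
#'
#' `n_traj * directions * ceiling(t_end/dt)`: each direction of each
#' initial condition costs one force evaluation per time step (the
#' initial gradient is shared by the forward/backward pair).
#'
#' @param n_traj number of initial conditions
#' @param t_end segment length, fs
#' @param dt time step, fs
#' @param directions segments per initial condition (2 for paired runs)
#' @return evaluation count (numeric to avoid integer overflow).
#' @examples
#' plan_evaluations(1000, 500, 0.1)  # 1e7
#' @export
plan_evaluations <- function(n_traj, t_end, dt, directions = 2L) {
  n_traj * directions * ceiling(t_end / dt)
}

#' Run paired quasi-classical trajectories from a transition state
#'
#' Samples initial conditions, then for each launches a forward and a
#' backward segment from the same phase-space point (velocities
#' negated), sharing one initial gradient, and stitches them into
#' combined trajectories.
#'
#' @param ts a [characterize_point()] of order 1
#' @param modes [normal_modes()] at the saddle
#' @param potential the propagation potential
#' @param spec a [sampling_spec()]
#' @param dt time step, fs
#' @param t_end segment length, fs
#' @return list of class `qct_run`: `trajectories` (combined), `spec`,
#'   `n_force_evals` (actual), `planned_evals`, `dt`, `t_end`.
#' @export
run_dynamics <- function(ts, modes, potential, spec, dt = 0.1, t_end = 500) {
  ics <- sample_initial_conditions(ts, modes, spec)
  trajs <- vector("list", length(ics))
  n_evals <- 0
  for (i in seq_along(ics)) {
    r0 <- pot_eval(potential, ics[[i]]$coords)
    g0 <- r0$gradient
    attr(g0, "energy") <- r0$energy
    fwd <- propagate(ics[[i]], potential, dt, t_end, "forward", g0 = g0)
    bwd <- propagate(ics[[i]], potential, dt, t_end, "backward", g0 = g0)
    n_evals <- n_evals + fwd$n_force_evals + bwd$n_force_evals
    trajs[[i]] <- combine(fwd, bwd, id = i)
  }
  structure(list(trajectories = trajs, spec = spec,
                 n_force_evals = n_evals,
                 planned_evals = plan_evaluations(length(ics), t_end, dt),
                 dt = dt, t_end = t_end),
            class = "qct_run")
}
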