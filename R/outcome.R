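# Ensemble-level analysis of combined trajectories: product counts and
# ratios with bootstrap intervals, bond-formation time gaps, and
# energy-conservation diagnostics.

#' Format a two-product ratio the way reaction outcomes are reported
#'
#' Normalises to the smaller count: `{10, 520}` becomes `"1 : 52"`.
#'
#' @param counts numeric vector of two product counts
#' @return ratio string, or `"undefined"` when the smaller count is 0.
#' @examples
#' format_ratio(c(P1 = 10, P2 = 520))
#' @export
format_ratio <- function(counts) {
  if (length(counts) != 2L) stop("format_ratio expects exactly two counts")
  lo <- min(counts); hi <- max(counts)
  if (lo == 0) return("undefined")
  sprintf("1 : %g", round(hi / lo, if (hi / lo >= 10) 0 else 1))
}

#' Outcome statistics over a trajectory ensemble
#'
#' Aggregates classification labels: per-label counts (which partition
#' the ensemble exactly), the minor:major product ratio in the
#' `"1 : x"` reporting form, percentile bootstrap confidence intervals
#' of the major-product fraction and of the ratio under trajectory
#' resampling, the mean/median time gap between first and second bond
#' formation over trajectories that form both bonds, and per-trajectory
#' total-energy standard deviations when trajectories are supplied.
#'
#' @param outcomes list of [classify()] / [classify_basin()] results
#' @param product_names product labels to tabulate (default: the two
#'   most frequent product labels among the outcomes)
#' @param trajectories optional list of [combine()] results matching
#'   `outcomes`, used for the energy-conservation summary
#' @param bootstrap_reps bootstrap resamples
#' @param seed bootstrap seed
#' @return object of class `outcome_stats`: `counts` (all labels),
#'   `product_counts`, `ratio` (string), `ratio_value` (major/minor, NA
#'   when undefined), `ratio_ci` and `major_fraction_ci` (95 percent
#'   percentile bootstrap), `bond_gaps` (per-trajectory inter-bond gaps,
#'   fs), `mean_gap`, `median_gap`, `energy_sd` (per-trajectory
#'   kcal/mol) and `energy_sd_summary`.
#' @export
outcome_statistics <- function(outcomes, product_names = NULL,
                               trajectories = NULL, bootstrap_reps = 1000L,
                               seed = 1L) {
  labels <- vapply(outcomes, `[[`, "", "label")
  counts <- table(labels)
  if (is.null(product_names)) {
    special <- c("reactant-only", "nonreactive", "undetermined")
    cand <- setdiff(names(counts), special)
    product_names <- names(sort(counts[cand], decreasing = TRUE))[
      seq_len(min(2L, length(cand)))]
  }
  pc <- stats::setNames(vapply(product_names, function(p) sum(labels == p), 1.0),
                        product_names)
  ratio <- if (length(pc) == 2L && min(pc) > 0) format_ratio(pc) else "undefined"
  ratio_value <- if (length(pc) == 2L && min(pc) > 0) max(pc) / min(pc)
                 else NA_real_
  # bootstrap over trajectory resampling
  ratio_ci <- major_ci <- c(NA_real_, NA_real_)
  if (length(pc) == 2L && sum(pc) > 0) {
    set.seed(seed)
    major <- names(pc)[which.max(pc)]
    minor <- names(pc)[which.min(pc)]
    n <- length(labels)
    rv <- mf <- numeric(bootstrap_reps)
    for (b in seq_len(bootstrap_reps)) {
      lb <- labels[sample.int(n, n, replace = TRUE)]
      nmaj <- sum(lb == major); nmin <- sum(lb == minor)
      mf[b] <- nmaj / max(nmaj + nmin, 1L)
      rv[b] <- if (nmin > 0) nmaj / nmin else NA_real_
    }
    major_ci <- unname(stats::quantile(mf, c(0.025, 0.975), na.rm = TRUE))
    ratio_ci <- unname(stats::quantile(rv, c(0.025, 0.975), na.rm = TRUE))
  }
  # inter-bond time gaps for trajectories forming two bonds
  gaps <- numeric(0)
  for (oc in outcomes) {
    if (!isTRUE(oc$reactive)) next
    bt <- oc$bond_times[[oc$label]]
    if (is.null(bt) || length(bt) < 2L || anyNA(bt)) next
    gaps <- c(gaps, abs(bt[2L] - bt[1L]))
  }
  esd <- NULL; esd_summary <- NULL
  if (!is.null(trajectories)) {
    esd <- vapply(trajectories, function(tr)
      hartree_to_kcalmol(pop_sd(tr$etot)), 1.0)
    esd_summary <- c(median = stats::median(esd), max = max(esd))
  }
  structure(list(counts = counts, product_counts = pc, ratio = ratio,
                 ratio_value = ratio_value, ratio_ci = ratio_ci,
                 major_fraction_ci = major_ci,
                 bond_gaps = gaps,
                 mean_gap = if (length(gaps)) mean(gaps) else NA_real_,
                 median_gap = if (length(gaps)) stats::median(gaps) else NA_real_,
                 energy_sd = esd, energy_sd_summary = esd_summary,
                 n_trajectories = length(outcomes)),
            class = "outcome_stats")
}

#' @export
print.outcome_stats <- function(x, ...) {
  cat("<outcome_stats>", x$n_trajectories, "trajectories\n")
  print(x$counts)
  cat("product ratio:", x$ratio, "\n")
  if (length(x$bond_gaps))
    cat(sprintf("inter-bond time gap: mean %.1f fs, median %.1f fs (n = %d)\n",
                x$mean_gap, x$median_gap, length(x$bond_gaps)))
  if (!is.null(x$energy_sd_summary))
    cat(sprintf("total-energy std: median %.4f, max %.4f kcal/mol\n",
                x$energy_sd_summary["median"], x$energy_sd_summary["max"]))
  invisible(x)
}

#' Energy-conservation report over a trajectory ensemble
#'
#' The per-trajectory population standard deviation of the total energy
#' about its mean (in kcal/mol), with an ensemble summary, and a paired
#' comparison when a second ensemble propagated with a different time
#' step from the same initial conditions is supplied.
#'
#' @param trajectories list of [combine()] (or [propagate()]) results
#' @param trajectories_alt optional paired ensemble at another time step
#' @return object of class `energy_conservation_report`: `sd`
#'   (kcal/mol), `summary` (median, max), and when paired input is
#'   given, `sd_alt`, `ratio` (per-pair `sd_alt/sd`) and
#'   `fraction_alt_larger`.
#' @export
energy_conservation_report <- function(trajectories, trajectories_alt = NULL) {
  sd_of <- function(tr) {
    if (length(tr$etot) < 2L)
      stop("energy-conservation analysis needs more than one frame")
    hartree_to_kcalmol(pop_sd(tr$etot))
  }
  s1 <- vapply(trajectories, sd_of, 1.0)
  out <- list(sd = s1,
              summary = c(median = stats::median(s1), max = max(s1)))
  if (!is.null(trajectories_alt)) {
    if (length(trajectories_alt) != length(trajectories))
      stop("paired ensembles must have equal length")
    s2 <- vapply(trajectories_alt, sd_of, 1.0)
    out$sd_alt <- s2
    out$ratio <- s2 / s1
    out$fraction_alt_larger <- mean(s2 > s1)
  }
  structure(out, class = "energy_conservation_report")
}

#' @export
print.energy_conservation_report <- function(x, ...) {
  cat(sprintf("<energy_conservation_report> %d trajectories, median std %.4g, max %.4g kcal/mol\n",
              length(x$sd), x$summary["median"], x$summary["max"]))
  if (!is.null(x$ratio))
    cat(sprintf("  paired comparison: alt larger in %.0f%% of pairs, median ratio %.2f\n",
                100 * x$fraction_alt_larger, stats::median(x$ratio)))
  invisible(x)
}
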