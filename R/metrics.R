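# Benchmark-style error metrics: per-subset MAD and the weighted
# aggregate used by GMTKN55-style relative-energy benchmarks.

#' Reaction record
#'
#' A relative-energy benchmark entry: species with signed stoichiometric
#' coefficients, a reference relative energy, and a subset name.
#'
#' @param species character vector of structure ids
#' @param coefficients signed integer stoichiometric coefficients
#' @param reference reference relative energy, kcal/mol
#' @param subset benchmark subset name
#' @return list of class `reaction_record`.
#' @export
reaction_record <- function(species, coefficients, reference, subset) {
  if (length(species) != length(coefficients))
    stop("species and coefficients differ in length")
  if (!any(coefficients > 0) || !any(coefficients < 0))
    stop("a reaction needs at least one positive and one negative coefficient")
  if (!nzchar(subset)) stop("subset name must be non-empty")
  structure(list(species = species, coefficients = coefficients,
                 reference = reference, subset = subset),
            class = "reaction_record")
}

#' Relative (reaction) energy of a record
#'
#' `sum coeff * E(species)`, converted to kcal/mol.
#'
#' @param record a [reaction_record()]
#' @param energies named numeric vector or list mapping structure id to
#'   energy in Hartree
#' @return relative energy, kcal/mol.
#' @examples
#' r <- reaction_record(c("A", "B"), c(-2, 1), 0, "toy")
#' reaction_energy(r, c(A = -1.0, B = -2.1))  # -62.75 kcal/mol
#' @export
reaction_energy <- function(record, energies) {
  missing <- setdiff(record$species, names(energies))
  if (length(missing) > 0L)
    stop("missing species energies: ", paste(missing, collapse = ", "))
  e <- sum(record$coefficients * unlist(energies[record$species]))
  hartree_to_kcalmol(e)
}

#' Mean absolute error
#'
#' @param errors numeric vector of signed errors, kcal/mol (non-empty)
#' @return mean of absolute values, kcal/mol.
#' @export
mae <- function(errors) {
  if (length(errors) == 0L) stop("mae of an empty vector")
  mean(abs(errors))
}

#' Subset summary for the weighted aggregate
#'
#' @param subset subset name
#' @param n record count (>= 1)
#' @param mad mean absolute deviation of the method on the subset,
#'   kcal/mol
#' @param mean_abs_ref mean absolute reference relative energy of the
#'   subset, kcal/mol (> 0)
#' @return list of class `subset_summary`.
#' @export
subset_summary <- function(subset, n, mad, mean_abs_ref) {
  if (n < 1L) stop("subset must contain at least one record")
  if (mad < 0) stop("MAD must be non-negative")
  structure(list(subset = subset, n = as.integer(n), mad = mad,
                 mean_abs_ref = mean_abs_ref), class = "subset_summary")
}

#' Weighted total mean absolute deviation (WTMAD-2)
#'
#' `WTMAD-2 = sum_i N_i (C / |dE|_i) MAD_i / sum_i N_i`, weighting each
#' subset inversely to its mean absolute reference energy `|dE|_i`.  The
#' constant `C` is the published average absolute reference energy of
#' the benchmark it normalises against; it lives in configuration, not
#' code.
#'
#' @param summaries list of [subset_summary()] objects
#' @param constant the normalisation constant C, kcal/mol (default from
#'   [metric_constants()])
#' @return WTMAD-2 in kcal/mol.
#' @export
wtmad2 <- function(summaries, constant = metric_constants()$wtmad2_C) {
  if (length(summaries) == 0L) stop("no subset summaries")
  n <- vapply(summaries, `[[`, 1.0, "n")
  mad_i <- vapply(summaries, `[[`, 1.0, "mad")
  ref_i <- vapply(summaries, `[[`, 1.0, "mean_abs_ref")
  if (any(ref_i <= 0))
    stop("mean absolute reference energy must be positive in every subset")
  sum(n * (constant / ref_i) * mad_i) / sum(n)
}

#' Named metric constants
#'
#' @return list with `wtmad2_C`, the benchmark-average absolute
#'   reference energy (kcal/mol) used to normalise WTMAD-2 weights.
#' @export
metric_constants <- function() list(wtmad2_C = 56.84)

#' Read reaction records from a plain-text benchmark file
#'
#' One record per line:
#' `subset reference id1 coeff1 [id2 coeff2 ...]`, whitespace-separated.
#'
#' @param path file path
#' @return list of [reaction_record()] objects.
#' @export
read_reactions <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(seq_along(lines), function(i) {
    tok <- strsplit(lines[i], "[[:space:]]+")[[1]]
    if (length(tok) < 6L || length(tok) %% 2L != 0L)
      stop("malformed reaction line ", i, ": '", lines[i], "'")
    ids <- tok[seq(3L, length(tok), by = 2L)]
    co <- as.numeric(tok[seq(4L, length(tok), by = 2L)])
    reaction_record(ids, co, as.numeric(tok[2L]), tok[1L])
  })
}

#' Evaluate a potential-style energy map on reaction records
#'
#' Computes per-record errors against the references, per-subset
#' summaries and the WTMAD-2 aggregate.
#'
#' @param records list of [reaction_record()]s
#' @param energies named energies (Hartree) for all species
#' @return list with `errors` (per record, kcal/mol), `summaries`
#'   (per subset) and `wtmad2`.
#' @export
benchmark_metrics <- function(records, energies) {
  pred <- vapply(records, reaction_energy, 1.0, energies = energies)
  ref <- vapply(records, `[[`, 1.0, "reference")
  subset <- vapply(records, `[[`, "", "subset")
  errors <- pred - ref
  summaries <- lapply(split(seq_along(records), subset), function(idx)
    subset_summary(subset[idx[1]], length(idx), mae(errors[idx]),
                   mean(abs(ref[idx]))))
  list(errors = errors, summaries = unname(summaries),
       wtmad2 = wtmad2(unname(summaries)))
}
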