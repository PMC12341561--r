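#' Read an (extended-)XYZ file
#'
#' Reads single- or multi-frame XYZ.  The comment line may carry
#' `key=value` pairs; an `energy=<float>` entry (Hartree) and force
#' columns 5:7 (`fx fy fz`, Hartree/Angstrom) are recognised, in which
#' case frames are returned as [labeled_frame()] objects; otherwise as
#' plain [dd_structure()] objects.
#'
#' @param path file path
#' @param supported_elements allowed element symbols
#' @return list of `dd_structure` or `dd_frame` objects, one per frame;
#'   an empty file yields an empty list.
#' @export
read_xyz <- function(path, supported_elements = c("C", "H", "N", "O")) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  # drop trailing blank lines
  while (length(lines) > 0L && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 0L)
      stop("malformed atom count at line ", i, ": '", lines[i], "'")
    if (i + 1L + nat > length(lines))
      stop("truncated frame starting at line ", i,
           ": expected ", nat, " atom lines")
    comment <- lines[i + 1L]
    atom_lines <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(atom_lines), "[[:space:]]+")
    ncol_atom <- unique(vapply(toks, length, 1L))
    if (length(ncol_atom) != 1L || ncol_atom[1] < 4L)
      stop("malformed atom line(s) in frame starting at line ", i)
    elements <- vapply(toks, `[`, "", 1L)
    num <- vapply(toks, function(t) as.numeric(t[-1L]), numeric(ncol_atom - 1L))
    num <- t(num)
    coords <- num[, 1:3, drop = FALSE]
    s <- dd_structure(elements, coords, supported_elements = supported_elements)
    kv <- parse_xyz_comment(comment)
    forces <- if (ncol_atom >= 7L) num[, 4:6, drop = FALSE] else NULL
    if (!is.null(kv$energy)) {
      frames[[length(frames) + 1L]] <-
        labeled_frame(s, kv$energy, forces = forces,
                      level = if (is.null(kv$level)) "" else kv$level)
    } else {
      frames[[length(frames) + 1L]] <- s
    }
    i <- i + 2L + nat
  }
  frames
}

# parse "key=value" tokens from an XYZ comment line
parse_xyz_comment <- function(comment) {
  out <- list()
  toks <- regmatches(comment,
                     gregexpr("[A-Za-z_][A-Za-z0-9_]*=[^[:space:]]+", comment))[[1]]
  for (t in toks) {
    eq <- regexpr("=", t, fixed = TRUE)
    key <- substr(t, 1L, eq - 1L)
    val <- substr(t, eq + 1L, nchar(t))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (is.na(num)) val else num
  }
  out
}

#' Write structures or labeled frames to an (extended-)XYZ file
#'
#' Frames with energies are written with `energy=<float>` (Hartree) on
#' the comment line (plus `uncertainty=<float>` in kcal/mol when given)
#' and, when forces are present, force columns `fx fy fz`
#' (Hartree/Angstrom) after the coordinates.
#'
#' @param frames a single object or list of `dd_structure` / `dd_frame`
#' @param path output file path
#' @param digits number of significant digits for coordinates
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, digits = 12L) {
  if (inherits(frames, "dd_structure") || inherits(frames, "dd_frame"))
    frames <- list(frames)
  out <- character(0)
  for (f in frames) {
    if (inherits(f, "dd_frame")) {
      s <- f$structure
      comment <- sprintf("energy=%.*g", digits + 4L, f$energy)
      if (!is.null(f$uncertainty))
        comment <- paste0(comment, sprintf(" uncertainty=%.*g", digits, f$uncertainty))
      if (nzchar(f$level)) comment <- paste0(comment, " level=", f$level)
      forces <- f$forces
    } else if (inherits(f, "dd_structure")) {
      s <- f
      comment <- ""
      forces <- NULL
    } else stop("frames must be dd_structure or dd_frame objects")
    out <- c(out, as.character(n_atoms(s)), comment)
    for (a in seq_len(n_atoms(s))) {
      line <- sprintf("%-2s %.*g %.*g %.*g", s$elements[a],
                      digits, s$coordinates[a, 1],
                      digits, s$coordinates[a, 2],
                      digits, s$coordinates[a, 3])
      if (!is.null(forces))
        line <- paste(line, sprintf("%.*g %.*g %.*g",
                                    digits, forces[a, 1],
                                    digits, forces[a, 2],
                                    digits, forces[a, 3]))
      out <- c(out, line)
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a trajectory as multi-frame extended-XYZ
#'
#' All frames must carry energies and a consistent atom count; the
#' per-frame total energy is stored on the comment line.
#'
#' @param frames non-empty list of [labeled_frame()] objects
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, path) {
  if (length(frames) == 0L) stop("cannot write an empty trajectory")
  if (!all(vapply(frames, inherits, TRUE, "dd_frame")))
    stop("trajectory frames must be labeled frames (with energies)")
  nat <- vapply(frames, function(f) n_atoms(f$structure), 1L)
  if (length(unique(nat)) != 1L)
    stop("inconsistent atom counts across frames: ",
         paste(unique(nat), collapse = ", "))
  write_xyz(frames, path)
}

#' Export per-frame scalar labels to CSV
#'
#' @param frames list of `dd_frame` objects
#' @param path output CSV path
#' @return `path`, invisibly.
#' @export
write_frame_table <- function(frames, path) {
  df <- data.frame(
    frame = seq_along(frames),
    n_atoms = vapply(frames, function(f) n_atoms(f$structure), 1L),
    energy_hartree = vapply(frames, function(f) f$energy, 1.0),
    energy_kcalmol = hartree_to_kcalmol(vapply(frames, function(f) f$energy, 1.0)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
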