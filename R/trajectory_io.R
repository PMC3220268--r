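#' Construct a structure object
#'
#' A structure pairs an ordered atom table with an N x 3 coordinate matrix
#' in Angstrom. The atom table uses author residue numbering straight from
#' the source file; no renumbering is ever applied, so selections can cite
#' the residue numbers used in the literature (e.g. Arp3 subdomains 1-2,
#' residues 3-39, 51-151, 376-410).
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `elem`, `occ`, `alt`.
#' @param xyz N x 3 numeric matrix of coordinates (Angstrom).
#' @return an object of class `md_structure`.
#' @export
md_structure <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3L)
    abort("arpdyn_shape_error", "coordinates must be an N x 3 numeric matrix")
  if (nrow(atoms) != nrow(xyz))
    abort("arpdyn_shape_error",
          "atom table has %d rows but coordinates have %d", nrow(atoms), nrow(xyz))
  if (any(!is.finite(xyz)))
    abort("arpdyn_parse_error", "non-finite coordinates in structure")
  if (any(!nzchar(atoms$elem)))
    abort("arpdyn_parse_error", "empty element symbol after parsing")
  key <- paste(atoms$chain, atoms$resno, atoms$elety, atoms$alt)
  if (anyDuplicated(key))
    abort("arpdyn_parse_error", "duplicate atom key: %s", key[anyDuplicated(key)])
  structure(list(atoms = atoms, xyz = xyz), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf("md_structure: %d atoms, %d chains (%s)\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Construct a trajectory object
#'
#' Frames are stored as an F x 3N matrix with per-atom triplets
#' (x1,y1,z1,x2,...), one row per frame, plus a strictly increasing time
#' axis in picoseconds.
#'
#' @param topology an [md_structure()] describing every frame's atoms.
#' @param xyz F x 3N numeric matrix of frame coordinates.
#' @param times numeric vector of frame times (ps), strictly increasing.
#' @return an object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, xyz, times) {
  xyz <- as.matrix(xyz)
  n <- nrow(topology$atoms)
  if (ncol(xyz) != 3L * n)
    abort("arpdyn_shape_error",
          "frames have %d coordinates but topology has %d atoms", ncol(xyz), n)
  if (nrow(xyz) != length(times))
    abort("arpdyn_shape_error", "%d frames but %d times", nrow(xyz), length(times))
  if (length(times) > 1L && any(diff(times) <= 0))
    abort("arpdyn_parse_error", "frame times must be strictly increasing")
  structure(list(topology = topology, xyz = xyz, times = as.numeric(times)),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames x %d atoms, t = %g..%g ps\n",
              nrow(x$xyz), nrow(x$topology$atoms),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Coordinates of one frame as an N x 3 matrix
#' @param traj an `md_trajectory`.
#' @param i frame index (1-based).
#' @return N x 3 matrix (Angstrom).
#' @export
frame_xyz <- function(traj, i) xyz_unflatten(traj$xyz[i, ])

## Element inference when the PDB element column (77-78) is absent/blank.
## Crystal structures rarely carry hydrogens but MD-derived PDBs do, with
## names like "HB2" or "1HG1"; strip digits, then a leading H means hydrogen,
## otherwise the first letter is the element (C/N/O/S/P cover proteins).
infer_element <- function(elety) {
  core <- gsub("[0-9']", "", trimws(elety))
  first <- substr(core, 1L, 1L)
  ifelse(first == "H", "H", first)
}

parse_pdb_atom_lines <- function(lines, line_nums) {
  fw <- function(lo, hi) trimws(substring(lines, lo, hi))
  x <- suppressWarnings(as.numeric(substring(lines, 31, 38)))
  y <- suppressWarnings(as.numeric(substring(lines, 39, 46)))
  z <- suppressWarnings(as.numeric(substring(lines, 47, 54)))
  resno <- suppressWarnings(as.integer(fw(23, 26)))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resno))
  if (length(bad))
    abort("arpdyn_parse_error", "unparsable ATOM record at line %d: %s",
          line_nums[bad[1]], lines[bad[1]])
  occ <- suppressWarnings(as.numeric(fw(55, 60)))
  occ[is.na(occ)] <- 1
  elem <- toupper(fw(77, 78))
  elety <- fw(13, 16)
  elem[!nzchar(elem)] <- infer_element(elety[!nzchar(elem)])
  data.frame(
    chain = fw(22, 22), resno = resno, resid = fw(18, 20),
    elety = elety, elem = elem, occ = occ, alt = fw(17, 17),
    x = x, y = y, z = z, stringsAsFactors = FALSE
  )
}

## Alt-loc policy: keep 'A' or blank; if a (chain,resno,elety) group has
## neither, keep the highest-occupancy record, ties broken by file order.
collapse_altlocs <- function(at) {
  grp <- paste(at$chain, at$resno, at$elety)
  keep <- rep(TRUE, nrow(at))
  for (g in unique(grp[at$alt != ""])) {
    idx <- which(grp == g)
    if (length(idx) == 1L) next
    pref <- idx[at$alt[idx] %in% c("", "A")]
    sel <- if (length(pref)) pref[1L] else idx[which.max(at$occ[idx])]
    keep[setdiff(idx, sel)] <- FALSE
  }
  at[keep, , drop = FALSE]
}

#' Read a PDB file as a trajectory
#'
#' Parses ATOM/HETATM records; each MODEL block becomes one frame (a single
#' frame if the file has no MODEL records). All models must share an
#' identical atom roster. Alternate locations are collapsed to a single
#' conformer ('A'/blank preferred, else highest occupancy). PDB files carry
#' no time axis, so frame times default to 0, `dt_ps`, 2`dt_ps`, ...
#'
#' @param path path to a PDB-format text file.
#' @param dt_ps frame spacing to synthesise for multi-model files (ps).
#' @return an [md_trajectory()].
#' @export
read_pdb <- function(path, dt_ps = 1) {
  if (!file.exists(path)) abort("arpdyn_io_error", "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substring(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  if (!any(is_atom)) abort("arpdyn_empty_input_error", "no ATOM records in %s", path)

  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  atom_lines <- which(is_atom)
  models <- split(atom_lines, model_id[atom_lines])

  frames <- vector("list", length(models))
  topology <- NULL
  for (k in seq_along(models)) {
    at <- parse_pdb_atom_lines(lines[models[[k]]], models[[k]])
    at <- collapse_altlocs(at)
    key <- paste(at$chain, at$resno, at$elety)
    if (is.null(topology)) {
      ref_key <- key
      topology <- md_structure(at[, c("chain", "resno", "resid", "elety",
                                      "elem", "occ", "alt")],
                               as.matrix(at[, c("x", "y", "z")]))
    } else if (length(key) != length(ref_key) || any(key != ref_key)) {
      div <- if (length(key) != length(ref_key)) {
        m <- min(length(key), length(ref_key))
        first_diff <- which(key[seq_len(m)] != ref_key[seq_len(m)])
        if (length(first_diff)) ref_key[first_diff[1]] else ref_key[m + 1L]
      } else ref_key[which(key != ref_key)[1]]
      abort("arpdyn_roster_error",
            "MODEL %d atom roster diverges from MODEL 1 at atom '%s'", k, div)
    }
    frames[[k]] <- xyz_flatten(as.matrix(at[, c("x", "y", "z")]))
  }
  xyz <- do.call(rbind, frames)
  md_trajectory(topology, xyz, dt_ps * (seq_len(nrow(xyz)) - 1L))
}

#' Write a structure (or trajectory) as a PDB file
#'
#' Multi-frame input is written as MODEL/ENDMDL blocks.
#'
#' @param x an `md_structure` or `md_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "md_structure"))
    x <- md_trajectory(x, matrix(xyz_flatten(x$xyz), nrow = 1L), 0)
  at <- x$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  multi <- n_frames(x) > 1L
  for (f in seq_len(n_frames(x))) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    m <- frame_xyz(x, f)
    name <- ifelse(nchar(at$elety) < 4L, sprintf(" %-3s", at$elety),
                   at$elety)
    writeLines(sprintf(
      "ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)) %% 100000L, name, at$alt, at$resid, at$chain,
      at$resno, m[, 1], m[, 2], m[, 3], at$occ, 0, at$elem), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a plain-text coordinate trajectory
#'
#' The dialect is one atom per row, three whitespace- or comma-separated
#' floats, frames concatenated; lines starting with '#' are ignored.
#'
#' @param path text file of coordinates.
#' @param n_atoms atoms per frame.
#' @param dt_ps frame spacing (ps).
#' @param topology optional [md_structure()]; a placeholder carbon topology
#'   is synthesised when omitted.
#' @return an [md_trajectory()].
#' @export
read_table_traj <- function(path, n_atoms, dt_ps, topology = NULL) {
  if (!file.exists(path)) abort("arpdyn_io_error", "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) abort("arpdyn_empty_input_error", "no coordinate rows in %s", path)
  rows <- strsplit(gsub(",", " ", lines), "[[:space:]]+")
  if (any(lengths(rows) != 3L))
    abort("arpdyn_parse_error", "row %d does not have 3 columns",
          which(lengths(rows) != 3L)[1])
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (any(is.na(vals)))
    abort("arpdyn_parse_error", "non-numeric coordinate value in %s", path)
  n_rows <- length(lines)
  if (n_rows %% n_atoms != 0L)
    abort("arpdyn_shape_error",
          "%d coordinate rows not divisible by n_atoms = %d", n_rows, n_atoms)
  f <- n_rows %/% n_atoms
  coords <- matrix(vals, ncol = 3L, byrow = TRUE)
  if (is.null(topology)) topology <- placeholder_topology(n_atoms, coords[seq_len(n_atoms), , drop = FALSE])
  xyz <- matrix(0, f, 3L * n_atoms)
  for (k in seq_len(f))
    xyz[k, ] <- xyz_flatten(coords[((k - 1L) * n_atoms + 1L):(k * n_atoms), , drop = FALSE])
  md_trajectory(topology, xyz, dt_ps * (seq_len(f) - 1L))
}

#' Write a trajectory in the plain-text dialect read by [read_table_traj()]
#'
#' Coordinates are printed with 17 significant digits so a read/write
#' round trip reproduces them bit for bit.
#'
#' @param traj an `md_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table_traj <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d atoms per frame, %d frames", nrow(traj$topology$atoms),
                     n_frames(traj)), con)
  for (f in seq_len(n_frames(traj))) {
    m <- frame_xyz(traj, f)
    writeLines(sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

placeholder_topology <- function(n_atoms, xyz) {
  md_structure(
    data.frame(chain = "A", resno = seq_len(n_atoms), resid = "GLY",
               elety = "CA", elem = "C", occ = 1, alt = "",
               stringsAsFactors = FALSE),
    xyz
  )
}

#' Declarative atom selection
#'
#' Selections name atoms by chain, inclusive author residue-number ranges,
#' atom names and an element class, mirroring how selections are quoted in
#' the structural literature (e.g. "Calpha atoms of Arp3 residues 3-39,
#' 51-151, 376-410").
#'
#' @param chains character vector of chain identifiers, or `NULL` for all.
#' @param ranges list of length-2 inclusive `c(lo, hi)` residue ranges (or a
#'   single `c(lo, hi)`), or `NULL` for all residues.
#' @param atom_names character vector of atom names, or `"ANY"`.
#' @param element_class `"ALL"`, `"HEAVY"` (non-hydrogen) or `"CA"`
#'   (Calpha carbons).
#' @return an object of class `atom_selection`.
#' @export
atom_selection <- function(chains = NULL, ranges = NULL, atom_names = "ANY",
                           element_class = c("ALL", "HEAVY", "CA")) {
  element_class <- match.arg(element_class)
  if (!is.null(ranges)) {
    if (!is.list(ranges)) ranges <- list(ranges)
    for (r in ranges) {
      if (length(r) != 2L || r[1] > r[2])
        abort("arpdyn_selection_error",
              "residue range must be c(lo, hi) with lo <= hi, got [%s]",
              paste(r, collapse = ","))
    }
  }
  structure(list(chains = chains, ranges = ranges, atom_names = atom_names,
                 element_class = element_class),
            class = "atom_selection")
}

#' @export
format.atom_selection <- function(x, ...) {
  sprintf("chains=%s ranges=%s atoms=%s class=%s",
          if (is.null(x$chains)) "*" else paste(x$chains, collapse = ","),
          if (is.null(x$ranges)) "*" else
            paste(vapply(x$ranges, function(r) paste(r, collapse = "-"), ""),
                  collapse = ","),
          paste(x$atom_names, collapse = ","), x$element_class)
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("atom_selection:", format(x), "\n")
  invisible(x)
}

#' Resolve a selection to atom indices
#'
#' @param sel an [atom_selection()].
#' @param structure an [md_structure()] (or `md_trajectory`, whose topology
#'   is used).
#' @return sorted, duplicate-free integer vector of atom indices in topology
#'   order.
#' @export
resolve_selection <- function(sel, structure) {
  if (inherits(structure, "md_trajectory")) structure <- structure$topology
  at <- structure$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(sel$chains)) keep <- keep & at$chain %in% sel$chains
  if (!is.null(sel$ranges)) {
    in_range <- rep(FALSE, nrow(at))
    for (r in sel$ranges) in_range <- in_range | (at$resno >= r[1] & at$resno <= r[2])
    keep <- keep & in_range
  }
  if (!identical(sel$atom_names, "ANY")) keep <- keep & at$elety %in% sel$atom_names
  keep <- keep & switch(sel$element_class,
    ALL = TRUE,
    HEAVY = at$elem != "H",
    CA = at$elety == "CA" & at$elem == "C"
  )
  idx <- which(keep)
  if (!length(idx))
    abort("arpdyn_empty_selection_error", "selection matches no atoms: %s",
          format(sel))
  idx
}

#' Slice a trajectory to an analysis window
#'
#' Keeps frames with `t_start <= t <= t_end`, then every `stride`-th frame
#' starting from the first in range. This is how production analyses
#' restrict to an equilibrated tail (e.g. the last 20 ns) and subsample
#' (e.g. every 10th frame, 100 ps).
#'
#' @param traj an `md_trajectory`.
#' @param t_start,t_end window bounds in ps (inclusive).
#' @param stride keep every `stride`-th in-range frame (>= 1).
#' @return a new `md_trajectory`.
#' @export
traj_window <- function(traj, t_start, t_end, stride = 1L) {
  if (t_start >= t_end)
    abort("arpdyn_window_error", "t_start (%g) must be < t_end (%g)", t_start, t_end)
  if (stride < 1L) abort("arpdyn_window_error", "stride must be >= 1")
  in_range <- which(traj$times >= t_start & traj$times <= t_end)
  if (!length(in_range))
    abort("arpdyn_empty_window_error", "no frames in window [%g, %g] ps",
          t_start, t_end)
  keep <- in_range[seq(1L, length(in_range), by = stride)]
  md_trajectory(traj$topology, traj$xyz[keep, , drop = FALSE], traj$times[keep])
}
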