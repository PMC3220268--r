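#' Construct a rigid transform
#'
#' A proper rotation plus translation, applied to row coordinates as
#' `x' = x %*% t(rotation) + translation`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (Angstrom).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    abort("arpdyn_transform_error", "rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    abort("arpdyn_transform_error", "rotation determinant is %g, not +1",
          det(rotation))
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param coords N x 3 matrix.
#' @param tf a [rigid_transform()].
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(coords, tf) {
  sweep(coords %*% t(tf$rotation), 2L, tf$translation, "+")
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), -as.vector(t(tf$rotation) %*% tf$translation))
}

#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' the transformed mobile point set and the reference, via SVD of the
#' cross-covariance matrix. Reflections are always corrected to a proper
#' rotation (det = +1) by flipping the smallest singular direction, so a
#' mirror-image target yields the best achievable *rotation*, never an
#' improper transform.
#'
#' @param mobile,reference M x 3 matrices in 1:1 row correspondence, M >= 3.
#' @return a [rigid_transform()].
#' @export
kabsch_fit <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    abort("arpdyn_shape_error", "mobile and reference shapes differ")
  if (nrow(mobile) < 3L)
    abort("arpdyn_insufficient_points_error",
          "need >= 3 points for superposition, got %d", nrow(mobile))
  mc <- colMeans(mobile); rc <- colMeans(reference)
  xm <- sweep(mobile, 2L, mc); xr <- sweep(reference, 2L, rc)
  a <- crossprod(xm, xr)
  sv <- svd(a)
  if (sv$d[1] > 0 && sv$d[2] / sv$d[1] < 1e-10)
    warn("arpdyn_degeneracy_warning",
         "near-collinear point configuration; rotation poorly determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(r, rc - as.vector(r %*% mc))
}

#' Root-mean-square deviation between corresponded coordinate sets
#'
#' No alignment is performed; use [kabsch_fit()] first if a superposition
#' is wanted.
#'
#' @param a,b M x 3 matrices in row correspondence.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    abort("arpdyn_shape_error", "coordinate shapes differ: %dx%d vs %dx%d",
          nrow(a), ncol(a), nrow(b), ncol(b))
  sqrt(mean(rowSums((a - b)^2)))
}

## Shared kernel: for every frame, fit align-selection atoms onto the
## reference align atoms and return the transformed measure-selection
## coordinates as an F x 3M matrix. align_sel = NULL skips fitting (frames
## are assumed pre-aligned).
aligned_measure_coords <- function(traj, reference, align_sel, measure_idx,
                                   align_idx_traj = NULL, align_idx_ref = NULL) {
  if (!is.null(align_sel)) {
    align_idx_traj <- resolve_selection(align_sel, traj$topology)
    align_idx_ref <- resolve_selection(align_sel, reference)
    if (length(align_idx_traj) != length(align_idx_ref))
      abort("arpdyn_selection_error",
            "alignment selection resolves to %d atoms in trajectory but %d in reference",
            length(align_idx_traj), length(align_idx_ref))
    ref_align <- reference$xyz[align_idx_ref, , drop = FALSE]
  }
  f <- n_frames(traj)
  out <- matrix(0, f, 3L * length(measure_idx))
  for (k in seq_len(f)) {
    m <- frame_xyz(traj, k)
    if (!is.null(align_sel)) {
      tf <- kabsch_fit(m[align_idx_traj, , drop = FALSE], ref_align)
      m <- apply_transform(m, tf)
    }
    out[k, ] <- xyz_flatten(m[measure_idx, , drop = FALSE])
  }
  out
}

#' Aligned RMSD time series
#'
#' Per frame: superpose the frame onto `reference` using the atoms of
#' `align_sel`, apply that transform to the whole frame, then report the
#' RMSD of the `measure_sel` atoms against their reference positions. The
#' measured group takes no part in the fit, so the series quantifies how
#' one group moves *relative to* the alignment frame (e.g. Arp2 Calphas
#' after alignment on Arp3 subdomains 1-2).
#'
#' @param traj an `md_trajectory` (already windowed as desired).
#' @param reference an `md_structure` defining reference positions.
#' @param align_sel selection used for the fit.
#' @param measure_sel selection whose deviation is reported.
#' @param reference_tag label for the reference ("INITIAL", "ACTIVE", ...).
#' @return object of class `rmsd_series`: list with `times` (ps), `values`
#'   (Angstrom), `reference_tag` and the two selections.
#' @export
aligned_rmsd_series <- function(traj, reference, align_sel, measure_sel,
                                reference_tag = "CUSTOM") {
  measure_idx_traj <- resolve_selection(measure_sel, traj$topology)
  measure_idx_ref <- resolve_selection(measure_sel, reference)
  if (length(measure_idx_traj) != length(measure_idx_ref))
    abort("arpdyn_selection_error",
          "measure selection resolves to %d atoms in trajectory but %d in reference",
          length(measure_idx_traj), length(measure_idx_ref))
  ref_meas <- reference$xyz[measure_idx_ref, , drop = FALSE]
  am <- aligned_measure_coords(traj, reference, align_sel, measure_idx_traj)
  vals <- vapply(seq_len(nrow(am)),
                 function(k) rmsd(xyz_unflatten(am[k, ]), ref_meas), 0)
  structure(list(times = traj$times, values = vals,
                 align_selection = align_sel, measure_selection = measure_sel,
                 reference_tag = reference_tag),
            class = "rmsd_series")
}

#' Per-residue Calpha RMSD over an analysis window
#'
#' For each residue with a Calpha in `measure_sel`, the root of the
#' time-mean squared displacement of its aligned Calpha from the reference.
#' By construction the mean over residues of the squared per-residue values
#' equals the time-mean of the squared frame RMSDs over the same atoms.
#'
#' @inheritParams aligned_rmsd_series
#' @return object of class `per_residue_rmsd`: data.frame with `chain`,
#'   `resno`, `rmsd` (Angstrom).
#' @export
per_residue_rmsd <- function(traj, reference, align_sel, measure_sel) {
  measure_sel$element_class <- "CA"
  idx_traj <- resolve_selection(measure_sel, traj$topology)
  idx_ref <- resolve_selection(measure_sel, reference)
  if (length(idx_traj) != length(idx_ref))
    abort("arpdyn_selection_error", "measure selection sizes differ between trajectory and reference")
  ref_meas <- reference$xyz[idx_ref, , drop = FALSE]
  am <- aligned_measure_coords(traj, reference, align_sel, idx_traj)
  m <- length(idx_traj)
  ## squared displacement per atom, averaged over frames
  msd <- numeric(m)
  for (k in seq_len(n_frames(traj))) {
    d <- xyz_unflatten(am[k, ]) - ref_meas
    msd <- msd + rowSums(d^2)
  }
  msd <- msd / n_frames(traj)
  at <- traj$topology$atoms[idx_traj, ]
  structure(data.frame(chain = at$chain, resno = at$resno,
                       rmsd = sqrt(msd), stringsAsFactors = FALSE),
            class = c("per_residue_rmsd", "data.frame"))
}

#' Normalised histogram of a series
#'
#' Shared histogram container for RMSD series, contact counts and
#' salt-bridge distances. Defaults to 50 uniform bins over the observed
#' range; a constant series gets a unit-width window around its value so
#' exactly one bin is occupied.
#'
#' @param values numeric vector.
#' @param bins number of uniform bins.
#' @param range optional `c(lo, hi)` overriding the observed range.
#' @param normalize return densities integrating to 1 (default) or raw
#'   counts.
#' @return object of class `histogram_result`: list with `bin_edges`,
#'   `counts`, `density`, `normalized`.
#' @export
histogram_result <- function(values, bins = 50L, range = NULL, normalize = TRUE) {
  if (!length(values)) abort("arpdyn_empty_input_error", "no values to histogram")
  if (is.null(range)) range <- base::range(values)
  if (diff(range) == 0) range <- range + c(-0.5, 0.5)
  edges <- seq(range[1], range[2], length.out = bins + 1L)
  h <- graphics::hist(pmin(pmax(values, range[1]), range[2]), breaks = edges,
                      plot = FALSE, right = TRUE, include.lowest = TRUE)
  structure(list(bin_edges = edges, counts = h$counts, density = h$density,
                 normalized = normalize),
            class = "histogram_result")
}

#' Distribution of an RMSD series
#'
#' @param series an `rmsd_series` (or plain numeric vector).
#' @param bins number of bins.
#' @return a [histogram_result()].
#' @export
rmsd_distribution <- function(series, bins = 50L) {
  vals <- if (inherits(series, "rmsd_series")) series$values else series
  histogram_result(vals, bins = bins)
}

#' Build a surrogate "active-orientation" reference
#'
#' The field's active short-pitch model is not public, so an explicit,
#' config-declared rigid transform of the mobile subunit stands in for it:
#' the returned structure is `reference` with the `mobile_sel` atoms
#' rigidly moved and every other atom untouched.
#'
#' @param reference an `md_structure`.
#' @param mobile_sel selection of atoms to move.
#' @param transform a [rigid_transform()] applied to those atoms.
#' @return a new `md_structure`.
#' @export
make_active_surrogate <- function(reference, mobile_sel, transform) {
  idx <- resolve_selection(mobile_sel, reference)
  xyz <- reference$xyz
  xyz[idx, ] <- apply_transform(xyz[idx, , drop = FALSE], transform)
  md_structure(reference$atoms, xyz)
}

#' Tidy data.frame from an RMSD series
#' @param x an `rmsd_series`.
#' @param ... unused.
#' @return data.frame with `time_ps`, `value_A`, `reference`.
#' @export
as.data.frame.rmsd_series <- function(x, ...) {
  data.frame(time_ps = x$times, value_A = x$values, reference = x$reference_tag,
             stringsAsFactors = FALSE)
}
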