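#' Coordinate principal component analysis of aligned Calpha frames
#'
#' Each frame is superposed on the reference via `align_sel` (pass `NULL`
#' to skip when frames are pre-aligned), the `measure_sel` Calpha
#' coordinates are collected into an F x 3M matrix, and the covariance of
#' the centred coordinates (unbiased, n-1 denominator) is
#' eigendecomposed. The decomposition runs through the SVD of the centred
#' frame matrix, which is the dual (Gram) route whenever 3M exceeds the
#' frame count and is numerically identical to forming the 3M x 3M
#' covariance directly. Eigenvector signs follow a fixed convention - the
#' largest-magnitude component of each vector is positive - so outputs are
#' reproducible across runs.
#'
#' @param traj an `md_trajectory`, already windowed/pooled as desired.
#' @param align_sel selection fitted per frame against `reference`, or
#'   `NULL`.
#' @param measure_sel selection whose Calpha coordinates enter the PCA.
#' @param reference an `md_structure` (alignment target).
#' @return object of class `pca_model`: `mean` (3M vector), `vectors`
#'   (3M x K orthonormal), `lambda` (K eigenvalues, Angstrom^2, descending),
#'   `atom_keys` (chain/resno data.frame), `n_frames`.
#' @export
fit_pca <- function(traj, align_sel, measure_sel, reference) {
  if (n_frames(traj) < 2L)
    abort("arpdyn_insufficient_data_error", "PCA needs >= 2 frames, got %d",
          n_frames(traj))
  measure_sel$element_class <- "CA"
  idx <- resolve_selection(measure_sel, traj$topology)
  x <- aligned_measure_coords(traj, reference, align_sel, idx)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc)
  lambda <- sv$d^2 / (nrow(x) - 1L)
  lambda[lambda < 0] <- 0
  v <- sv$v
  ## sign convention: largest-|component| positive
  for (j in seq_len(ncol(v))) {
    i0 <- which.max(abs(v[, j]))
    if (v[i0, j] < 0) v[, j] <- -v[, j]
  }
  at <- traj$topology$atoms[idx, ]
  structure(list(mean = mu, vectors = v, lambda = lambda,
                 atom_keys = data.frame(chain = at$chain, resno = at$resno,
                                        stringsAsFactors = FALSE),
                 n_frames = nrow(x),
                 align_sel = align_sel, measure_sel = measure_sel),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  vf <- variance_fractions(x, min(4L, length(x$lambda)))
  cat(sprintf("pca_model: %d atoms, %d frames; PC1-%d fractions: %s\n",
              nrow(x$atom_keys), x$n_frames, length(vf$fraction),
              paste(sprintf("%.3f", vf$fraction), collapse = " ")))
  invisible(x)
}

#' Per-mode and cumulative variance fractions
#'
#' @param model a `pca_model`.
#' @param k number of leading components to report.
#' @return data.frame with `pc`, `lambda`, `fraction`,
#'   `cumulative_fraction`.
#' @export
variance_fractions <- function(model, k) {
  if (k > length(model$lambda))
    abort("arpdyn_bounds_error", "k = %d exceeds %d available components",
          k, length(model$lambda))
  total <- sum(model$lambda)
  frac <- if (total > 0) model$lambda / total else rep(0, length(model$lambda))
  data.frame(pc = seq_len(k), lambda = model$lambda[seq_len(k)],
             fraction = frac[seq_len(k)],
             cumulative_fraction = cumsum(frac)[seq_len(k)])
}

#' Project trajectory frames onto principal components
#'
#' Frames are aligned and reduced with the same selections the model was
#' fitted with, centred on the model mean, and dotted with the chosen
#' eigenvectors.
#'
#' @param traj an `md_trajectory`.
#' @param model a `pca_model`.
#' @param pcs integer vector of component indices (default first two).
#' @param reference alignment target used at fit time.
#' @param run_label label attached to every frame (for pooled-run plots).
#' @return object of class `pca_projection`: list with `times`, `scores`
#'   (F x length(pcs), Angstrom), `pcs`, `run_labels`.
#' @export
project_frames <- function(traj, model, pcs = c(1L, 2L), reference = NULL,
                           run_label = "run1") {
  if (any(pcs > ncol(model$vectors)))
    abort("arpdyn_bounds_error", "requested PC beyond model rank")
  measure_sel <- model$measure_sel
  idx <- resolve_selection(measure_sel, traj$topology)
  if (3L * length(idx) != length(model$mean))
    abort("arpdyn_model_mismatch_error",
          "selection resolves to %d atoms but model has %d",
          length(idx), length(model$mean) / 3L)
  x <- aligned_measure_coords(traj, reference, model$align_sel, idx)
  xc <- sweep(x, 2L, model$mean)
  scores <- xc %*% model$vectors[, pcs, drop = FALSE]
  structure(list(times = traj$times, scores = scores, pcs = pcs,
                 run_labels = rep(run_label, nrow(scores))),
            class = "pca_projection")
}

#' @export
as.data.frame.pca_projection <- function(x, ...) {
  df <- data.frame(time_ps = x$times, run = x$run_labels)
  for (j in seq_along(x$pcs)) df[[paste0("pc", x$pcs[j])]] <- x$scores[, j]
  df
}

#' Reconstruct frames from mean plus principal components
#'
#' @param model a `pca_model`.
#' @param scores F x K score matrix (K = number of PCs used, leading PCs
#'   assumed).
#' @return F x 3M coordinate matrix.
#' @export
reconstruct_frames <- function(model, scores) {
  k <- ncol(scores)
  sweep(scores %*% t(model$vectors[, seq_len(k), drop = FALSE]), 2L,
        model$mean, "+")
}

#' Porcupine (mode displacement) geometry for one component
#'
#' Base and tip coordinates are the mean structure displaced by
#' `-scale_sd*sqrt(lambda)` and `+scale_sd*sqrt(lambda)` along the chosen
#' eigenvector, i.e. cones drawn from one standard deviation below to one
#' above the conformer distribution when `scale_sd = 1`.
#'
#' @param model a `pca_model`.
#' @param pc_index component index.
#' @param scale_sd displacement in standard deviations of the score
#'   distribution.
#' @return object of class `mode_displacement`: `base`, `tip` (N x 3
#'   matrices), `pc_index`, `scale_sd`, `atom_keys`, and per-atom
#'   displacement `lengths` (= 2*scale_sd*sqrt(lambda)*|v_atom|).
#' @export
porcupine <- function(model, pc_index, scale_sd = 1) {
  if (pc_index < 1L || pc_index > ncol(model$vectors))
    abort("arpdyn_bounds_error", "pc_index %d out of range", pc_index)
  lam <- model$lambda[pc_index]
  if (lam == 0)
    warn("arpdyn_zero_mode_warning", "PC %d carries zero variance; cones have zero length",
         pc_index)
  v <- model$vectors[, pc_index]
  disp <- scale_sd * sqrt(lam) * v
  base <- xyz_unflatten(model$mean - disp)
  tip <- xyz_unflatten(model$mean + disp)
  seg <- tip - base
  structure(list(base = base, tip = tip, pc_index = pc_index,
                 scale_sd = scale_sd, atom_keys = model$atom_keys,
                 lengths = sqrt(rowSums(seg^2))),
            class = "mode_displacement")
}
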