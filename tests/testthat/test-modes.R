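# Build a trajectory whose centred coordinates follow a known low-rank
# Gaussian: scores on orthonormal directions with prescribed variances.
make_pca_fixture <- function(n_frames, sds = c(2, 1, 0), n_atoms = 3, seed = 51) {
  set.seed(seed)
  dim3n <- 3 * n_atoms
  v <- qr.Q(qr(matrix(rnorm(dim3n^2), dim3n)))[, seq_along(sds), drop = FALSE]
  scores <- vapply(sds, function(s) if (s > 0) rnorm(n_frames, sd = s)
                   else rep(0, n_frames), numeric(n_frames))
  mu <- rnorm(dim3n, sd = 3)
  x <- sweep(scores %*% t(v), 2, mu, "+")
  topo <- md_structure(
    data.frame(chain = "A", resno = seq_len(n_atoms), resid = "GLY",
               elety = "CA", elem = "C", occ = 1, alt = "",
               stringsAsFactors = FALSE),
    matrix(mu, ncol = 3, byrow = TRUE))
  list(traj = md_trajectory(topo, x, seq_len(n_frames) - 1), v = v, mu = mu,
       topo = topo)
}

test_that("a single displacement direction puts all variance on PC1", {
  fx <- make_pca_fixture(200, sds = c(1.5), n_atoms = 4)
  model <- fit_pca(fx$traj, NULL, atom_selection(), fx$topo)
  vf <- variance_fractions(model, 3)
  expect_equal(vf$fraction[1], 1, tolerance = 1e-10)
  expect_lt(sum(vf$fraction[-1]), 1e-10)
})

test_that("variance fractions follow the eigenvalues and the trace identity", {
  model <- structure(list(mean = rep(0, 9),
                          vectors = diag(9)[, 1:3], lambda = c(4, 1, 0),
                          atom_keys = data.frame(chain = "A", resno = 1:3),
                          n_frames = 10, align_sel = NULL,
                          measure_sel = atom_selection()),
                     class = "pca_model")
  vf <- variance_fractions(model, 3)
  expect_equal(vf$fraction, c(0.8, 0.2, 0))
  expect_equal(vf$cumulative_fraction[3], 1)
  expect_error(variance_fractions(model, 4), class = "arpdyn_bounds_error")

  # trace identity on real data: sum of eigenvalues == total variance
  fx <- make_pca_fixture(300, sds = c(2, 1, 0.5), seed = 52)
  m2 <- fit_pca(fx$traj, NULL, atom_selection(), fx$topo)
  total_var <- sum(apply(fx$traj$xyz, 2, stats::var))
  expect_equal(sum(m2$lambda), total_var, tolerance = 1e-10)
  # scree is non-increasing and sums to 1
  vf2 <- variance_fractions(m2, length(m2$lambda))
  expect_true(all(diff(vf2$fraction) <= 1e-12))
  expect_equal(sum(vf2$fraction), 1, tolerance = 1e-10)
})

test_that("a 4:1:0 Gaussian fixture recovers fractions 0.8/0.2/0", {
  fx <- make_pca_fixture(4000, sds = c(2, 1, 0), seed = 53)
  model <- fit_pca(fx$traj, NULL, atom_selection(), fx$topo)
  vf <- variance_fractions(model, 3)
  expect_equal(vf$fraction[1], 0.8, tolerance = 0.03)
  expect_equal(vf$fraction[2], 0.2, tolerance = 0.1)
  expect_lt(vf$fraction[3], 1e-10)
})

test_that("frames reconstruct exactly from mean plus all components", {
  fx <- make_pca_fixture(60, sds = c(2, 1, 0.5, 0.25), n_atoms = 5, seed = 54)
  model <- fit_pca(fx$traj, NULL, atom_selection(), fx$topo)
  proj <- project_frames(fx$traj, model, pcs = seq_along(model$lambda))
  rebuilt <- reconstruct_frames(model, proj$scores)
  expect_lt(max(abs(rebuilt - fx$traj$xyz)), 1e-8)
})

test_that("projections centre on the mean and separate clusters on PC1", {
  fx <- make_pca_fixture(100, sds = c(1), n_atoms = 3, seed = 55)
  model <- fit_pca(fx$traj, NULL, atom_selection(), fx$topo)
  mean_traj <- md_trajectory(fx$topo, rbind(model$mean, model$mean), c(0, 1))
  proj <- project_frames(mean_traj, model, pcs = 1:2)
  expect_lt(max(abs(proj$scores)), 1e-10)

  # two clusters +/-5 along a direction: opposite-sign PC1 score means
  set.seed(56)
  dirv <- qr.Q(qr(matrix(rnorm(81), 9)))[, 1]
  labels <- rep(c(-5, 5), each = 50)
  x <- outer(labels, dirv) + matrix(rnorm(100 * 9, sd = 0.3), 100)
  tr <- md_trajectory(fx$topo, sweep(x, 2, fx$mu, "+"), seq_len(100) - 1)
  m2 <- fit_pca(tr, NULL, atom_selection(), fx$topo)
  p2 <- project_frames(tr, m2, pcs = 1)
  m_lo <- mean(p2$scores[1:50, 1]); m_hi <- mean(p2$scores[51:100, 1])
  expect_lt(m_lo * m_hi, 0)
  expect_gt(abs(m_lo - m_hi), 8)

  expect_error(project_frames(make_pca_fixture(10, n_atoms = 4, seed = 57)$traj,
                              model, pcs = 1),
               class = "arpdyn_model_mismatch_error")
})

test_that("eigenvalues are invariant to a global rigid motion when aligned", {
  spec <- traj_sim_spec(n_atoms_fixed = 10, n_atoms_mobile = 10,
                        angle_schedule = seq(0, 50, length.out = 40),
                        noise_sd = 0.3, geometry_seed = 58)
  sim <- simulate_reorientation_traj(spec, seed = 6)
  ref <- md_structure(sim$traj$topology$atoms, sim$traj$topology$xyz)
  align <- atom_selection(chains = "F")
  base <- fit_pca(sim$traj, align, atom_selection(), ref)

  set.seed(59)
  moved <- sim$traj
  for (k in seq_len(n_frames(moved))) {
    rr <- random_rotation(); tt <- rnorm(3, sd = 20)
    moved$xyz[k, ] <- as.vector(t(sweep(frame_xyz(moved, k) %*% t(rr), 2, tt, "+")))
  }
  again <- fit_pca(moved, align, atom_selection(), ref)
  keep <- base$lambda > 1e-8
  expect_equal(again$lambda[keep], base$lambda[keep], tolerance = 1e-6)
})

test_that("the eigenvector sign convention is applied", {
  fx <- make_pca_fixture(150, sds = c(2, 1), seed = 60)
  model <- fit_pca(fx$traj, NULL, atom_selection(), fx$topo)
  for (j in seq_len(ncol(model$vectors))) {
    i0 <- which.max(abs(model$vectors[, j]))
    expect_gte(model$vectors[i0, j], 0)
  }
  # orthonormality
  gram <- crossprod(model$vectors)
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-8)
})

test_that("porcupine displacements scale with sqrt(lambda)", {
  fx <- make_pca_fixture(200, sds = c(2, 1), seed = 61)
  model <- fit_pca(fx$traj, NULL, atom_selection(), fx$topo)

  zero <- porcupine(model, 1, scale_sd = 0)
  expect_equal(zero$base, zero$tip)
  expect_equal(zero$base, xyz_mat <- matrix(model$mean, ncol = 3, byrow = TRUE))

  one <- porcupine(model, 1, scale_sd = 1)
  # total tip-base norm = 2 * scale * sqrt(lambda) for a unit eigenvector
  expect_equal(sqrt(sum((one$tip - one$base)^2)), 2 * sqrt(model$lambda[1]),
               tolerance = 1e-10)
  # displacement is parallel to the eigenvector
  seg <- as.vector(t(one$tip - one$base))
  expect_equal(abs(sum(seg * model$vectors[, 1])) , sqrt(sum(seg^2)),
               tolerance = 1e-10)

  # a mode concentrated on one atom moves only that atom
  conc <- structure(list(mean = rep(0, 9), vectors = cbind(c(0, 0, 0, 1, 0, 0, 0, 0, 0)),
                         lambda = 4, atom_keys = data.frame(chain = "A", resno = 1:3),
                         n_frames = 10, align_sel = NULL,
                         measure_sel = atom_selection()), class = "pca_model")
  pc <- porcupine(conc, 1, scale_sd = 1)
  expect_equal(pc$lengths, c(0, 4, 0))

  degen <- conc; degen$lambda <- 0
  expect_warning(porcupine(degen, 1), class = "arpdyn_zero_mode_warning")
})

test_that("few frames or out-of-range components are rejected", {
  fx <- make_pca_fixture(5, sds = c(1), seed = 62)
  single <- md_trajectory(fx$topo, fx$traj$xyz[1, , drop = FALSE], 0)
  expect_error(fit_pca(single, NULL, atom_selection(), fx$topo),
               class = "arpdyn_insufficient_data_error")
  model <- fit_pca(fx$traj, NULL, atom_selection(), fx$topo)
  expect_error(porcupine(model, 99), class = "arpdyn_bounds_error")
})

test_that("eigenvalues agree with bio3d's PCA on the same aligned data", {
  skip_if_not_installed("bio3d")
  fx <- make_pca_fixture(120, sds = c(2, 1, 0.5), n_atoms = 4, seed = 63)
  model <- fit_pca(fx$traj, NULL, atom_selection(), fx$topo)
  ours <- model$lambda
  theirs <- bio3d::pca.xyz(fx$traj$xyz)$L
  k <- min(length(ours), length(theirs))
  expect_equal(ours[1:k], theirs[1:k], tolerance = 1e-6)
})
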