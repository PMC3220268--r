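test_that("kabsch_fit recovers a known rigid transform exactly", {
  set.seed(21)
  m <- matrix(rnorm(30, sd = 5), 10, 3)
  r_true <- rotation_about_axis(c(0, 0, 1), 90)
  t_true <- c(1, 2, 3)
  ref <- sweep(m %*% t(r_true), 2, t_true, "+")
  tf <- kabsch_fit(m, ref)
  expect_lt(max(abs(tf$rotation - r_true)), 1e-10)
  expect_lt(max(abs(tf$translation - t_true)), 1e-10)
  expect_lt(rmsd(apply_transform(m, tf), ref), 1e-10)

  # identity case
  tf0 <- kabsch_fit(m, m)
  expect_lt(max(abs(tf0$rotation - diag(3))), 1e-10)
  expect_lt(max(abs(tf0$translation)), 1e-10)
})

test_that("mirror-image targets yield a proper rotation beating a rotation grid", {
  # chiral 4-point set; its mirror image cannot be reached by any rotation
  m <- matrix(c(0, 0, 0, 1, 0, 0, 0, 2, 0, 0, 0, 3), 4, 3, byrow = TRUE)
  ref <- m %*% diag(c(-1, 1, 1))
  tf <- kabsch_fit(m, ref)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-10)
  fitted <- rmsd(apply_transform(m, tf), ref)
  expect_gt(fitted, 0)
  # oracle: no rotation (sampled over a fine random grid) does better
  set.seed(22)
  mc <- sweep(m, 2, colMeans(m)); rc <- sweep(ref, 2, colMeans(ref))
  grid_best <- min(replicate(2000, rmsd(mc %*% t(random_rotation()), rc)))
  expect_lte(fitted, grid_best + 1e-9)
})

test_that("kabsch_fit rejects underdetermined input and warns on collinear sets", {
  expect_error(kabsch_fit(matrix(0, 2, 3), matrix(0, 2, 3)),
               class = "arpdyn_insufficient_points_error")
  line <- cbind(1:5, 0, 0)
  expect_warning(kabsch_fit(line, line), class = "arpdyn_degeneracy_warning")
})

test_that("rmsd matches its defining formula", {
  set.seed(23)
  a <- matrix(rnorm(60), 20, 3)
  expect_equal(rmsd(a, a), 0)
  expect_equal(rmsd(a, sweep(a, 2, c(3, 0, 0), "+")), 3)
  b <- matrix(rnorm(60), 20, 3)
  direct <- sqrt(sum((a - b)^2) / nrow(a))
  expect_equal(rmsd(a, b), direct, tolerance = 1e-12)
  expect_error(rmsd(a, b[1:10, ]), class = "arpdyn_shape_error")
})

test_that("post-fit RMSD is optimal against random rigid motions", {
  set.seed(24)
  m <- matrix(rnorm(45), 15, 3)
  ref <- matrix(rnorm(45), 15, 3)
  fitted <- rmsd(apply_transform(m, kabsch_fit(m, ref)), ref)
  rivals <- replicate(1000, {
    rr <- random_rotation()
    tt <- rnorm(3, sd = 2)
    rmsd(sweep(m %*% t(rr), 2, tt, "+"), ref)
  })
  expect_true(all(fitted <= rivals + 1e-9))
})

test_that("kabsch agrees with bio3d's least-squares superposition", {
  skip_if_not_installed("bio3d")
  set.seed(25)
  m <- matrix(rnorm(36, sd = 4), 12, 3)
  ref <- matrix(rnorm(36, sd = 4), 12, 3)
  tf <- kabsch_fit(m, ref)
  ours <- rmsd(apply_transform(m, tf), ref)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(ref)), mobile = as.vector(t(m))))
  theirs <- rmsd(matrix(as.vector(fitted), ncol = 3, byrow = TRUE), ref)
  expect_equal(ours, theirs, tolerance = 1e-6)
})

test_that("a group co-rigid with the alignment frame has zero aligned RMSD", {
  set.seed(26)
  s <- make_two_group_structure(matrix(rnorm(30, sd = 5), 10),
                                matrix(rnorm(30, sd = 5) + 15, 10))
  nf <- 6
  xyz <- t(vapply(seq_len(nf), function(k) {
    rr <- random_rotation()
    tt <- rnorm(3, sd = 3)
    as.vector(t(sweep(s$xyz %*% t(rr), 2, tt, "+")))
  }, numeric(3 * 20)))
  traj <- md_trajectory(s, xyz, 10 * (seq_len(nf) - 1))
  ser <- aligned_rmsd_series(traj, s, atom_selection(chains = "A"),
                             atom_selection(chains = "B"))
  expect_lt(max(ser$values), 1e-8)
})

test_that("aligned RMSD of a pure rotation matches 2*sin(theta/2)*r_rms", {
  for (theta in c(10, 30, 90)) {
    spec <- traj_sim_spec(angle_schedule = c(0, theta), noise_sd = 0,
                          geometry_seed = 27)
    sim <- simulate_reorientation_traj(spec)
    ref <- md_structure(sim$traj$topology$atoms, frame_xyz(sim$traj, 1))
    ser <- aligned_rmsd_series(sim$traj, ref, atom_selection(chains = "F"),
                               atom_selection(chains = "M"),
                               reference_tag = "INITIAL")
    expect_equal(ser$values[2], 2 * sin(theta / 2 * pi / 180) * sim$truth$r_rms,
                 tolerance = 1e-10)
  }
})

test_that("aligned RMSD series is invariant to global rigid motion of frames", {
  spec <- traj_sim_spec(n_atoms_fixed = 15, n_atoms_mobile = 15,
                        angle_schedule = seq(0, 40, length.out = 9),
                        noise_sd = 0.2, geometry_seed = 28)
  sim <- simulate_reorientation_traj(spec, seed = 3)
  ref <- md_structure(sim$traj$topology$atoms, frame_xyz(sim$traj, 1))
  align <- atom_selection(chains = "F"); measure <- atom_selection(chains = "M")
  base <- aligned_rmsd_series(sim$traj, ref, align, measure)

  set.seed(29)
  moved <- sim$traj
  for (k in seq_len(n_frames(moved))) {
    rr <- random_rotation(); tt <- rnorm(3, sd = 10)
    moved$xyz[k, ] <- as.vector(t(sweep(frame_xyz(moved, k) %*% t(rr), 2, tt, "+")))
  }
  again <- aligned_rmsd_series(moved, ref, align, measure)
  expect_equal(again$values, base$values, tolerance = 1e-8)
})

test_that("noisy reorientation series tracks the generator ground truth", {
  spec <- traj_sim_spec(angle_schedule = seq(0, 60, length.out = 61),
                        noise_sd = 0.3, geometry_seed = 30)
  sim <- simulate_reorientation_traj(spec, seed = 4)
  ref <- md_structure(sim$traj$topology$atoms,
                      matrix(sim$traj$topology$xyz, ncol = 3))
  ser <- aligned_rmsd_series(sim$traj, ref, atom_selection(chains = "F"),
                             atom_selection(chains = "M"))
  # isotropic noise inflates RMSD; allow 3 sigma of the per-frame noise floor
  expect_true(all(abs(ser$values - sim$truth$rmsd) < 3 * spec$noise_sd * 2))
  expect_gt(stats::cor(ser$values, sim$truth$rmsd), 0.99)
})

test_that("per-residue RMSD isolates a displaced residue and satisfies the
           square-mean consistency identity", {
  s <- make_chain_structure(1:6, atom_names = "CA")
  traj <- make_static_traj(s, n_frames = 4)
  ref <- s
  zero <- per_residue_rmsd(traj, ref, atom_selection(), atom_selection())
  expect_lt(max(zero$rmsd), 1e-10)

  # displace residue 3 by 5 A in every frame
  moved <- traj
  col <- (3 - 1) * 3 + 2   # y coordinate of atom 3
  moved$xyz[, col] <- moved$xyz[, col] + 5
  align <- atom_selection(ranges = list(c(1, 2), c(4, 6)))
  prr <- per_residue_rmsd(moved, ref, align, atom_selection())
  expect_equal(prr$rmsd[3], 5, tolerance = 1e-6)
  expect_true(all(prr$rmsd[-3] < 1e-6))

  # identity: mean of squared per-residue values == time-mean squared RMSD
  set.seed(31)
  noisy <- traj
  noisy$xyz <- noisy$xyz + matrix(rnorm(length(noisy$xyz)), nrow(noisy$xyz))
  prr2 <- per_residue_rmsd(noisy, ref, NULL, atom_selection())
  ser <- aligned_rmsd_series(noisy, ref, NULL, atom_selection(element_class = "CA"))
  expect_equal(mean(prr2$rmsd^2), mean(ser$values^2), tolerance = 1e-10)
})

test_that("rmsd distributions bin, normalise and reveal bimodality", {
  const <- structure(list(times = 1:10, values = rep(2.5, 10),
                          reference_tag = "INITIAL"), class = "rmsd_series")
  h <- rmsd_distribution(const, bins = 20)
  expect_equal(sum(h$counts > 0), 1)

  two_level <- structure(list(times = 1:200,
                              values = c(rep(1, 100), rep(6, 100)) +
                                rep(c(-0.05, 0.05), 100),
                              reference_tag = "INITIAL"),
                         class = "rmsd_series")
  h2 <- rmsd_distribution(two_level, bins = 25)
  occupied <- which(h2$counts > 0)
  expect_gt(max(diff(occupied)), 10)  # two separated clumps
  widths <- diff(h2$bin_edges)
  expect_equal(sum(h2$density * widths), 1, tolerance = 1e-12)
  expect_error(rmsd_distribution(numeric(0)), class = "arpdyn_empty_input_error")
})

test_that("active-orientation surrogates behave as declared rigid transforms", {
  set.seed(32)
  s <- make_two_group_structure(matrix(rnorm(30, sd = 5), 10),
                                matrix(rnorm(30, sd = 5) + 20, 10))
  mobile <- atom_selection(chains = "B")

  ident <- make_active_surrogate(s, mobile, rigid_transform())
  expect_identical(ident$xyz, s$xyz)

  rot <- rotation_about_axis(c(1, 1, 0), 25)
  idx <- resolve_selection(mobile, s)
  ctr <- colMeans(s$xyz[idx, ])
  tf <- rigid_transform(rot, ctr - as.vector(rot %*% ctr))
  surro <- make_active_surrogate(s, mobile, tf)
  back <- make_active_surrogate(surro, mobile, invert_transform(tf))
  expect_lt(max(abs(back$xyz - s$xyz)), 1e-10)

  # rotation about the group centroid: RMSD to reference is the closed form
  d <- sweep(s$xyz[idx, ], 2, ctr)
  axis <- c(1, 1, 0) / sqrt(2)
  r_rms <- sqrt(mean(rowSums((d - (d %*% axis) %*% t(axis))^2)))
  expect_equal(rmsd(surro$xyz[idx, ], s$xyz[idx, ]),
               2 * sin(12.5 * pi / 180) * r_rms, tolerance = 1e-10)
})

test_that("series vs INITIAL and vs ACTIVE satisfy the triangle bound", {
  spec <- traj_sim_spec(angle_schedule = seq(0, 45, length.out = 16),
                        noise_sd = 0.2, geometry_seed = 33)
  sim <- simulate_reorientation_traj(spec, seed = 5)
  topo <- sim$traj$topology
  initial <- md_structure(topo$atoms, matrix(topo$xyz, ncol = 3))
  mobile <- atom_selection(chains = "M")
  idx <- resolve_selection(mobile, initial)
  ctr <- colMeans(initial$xyz[idx, ])
  rot <- rotation_about_axis(c(0, 0, 1), 60)
  tf <- rigid_transform(rot, ctr - as.vector(rot %*% ctr))
  active <- make_active_surrogate(initial, mobile, tf)

  align <- atom_selection(chains = "F")
  a <- aligned_rmsd_series(sim$traj, initial, align, mobile, "INITIAL")
  b <- aligned_rmsd_series(sim$traj, active, align, mobile, "ACTIVE")
  gap <- rmsd(initial$xyz[idx, ], active$xyz[idx, ])
  expect_true(all(abs(a$values - b$values) <= gap + 1e-8))
})
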