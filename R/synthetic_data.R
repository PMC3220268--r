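#' Specification for a synthetic reorientation trajectory
#'
#' Describes a two-group system in which a mobile rigid group (chain "M")
#' rotates about a fixed axis relative to a static group (chain "F"), under
#' isotropic Gaussian coordinate noise - the minimal emulation of one
#' subunit reorienting relative to another in an MD trajectory.
#'
#' @param n_atoms_fixed,n_atoms_mobile atoms per group.
#' @param rotation_axis direction of the rotation axis (through the
#'   origin).
#' @param angle_schedule per-frame rotation angles (degrees); its length
#'   sets the frame count.
#' @param axis_offset distance (Angstrom) of the mobile-group centroid from
#'   the axis.
#' @param noise_sd isotropic Gaussian coordinate noise per atom per frame
#'   (Angstrom); the default 0.5 A is a typical Calpha thermal fluctuation.
#' @param dt_ps frame spacing (ps); 10 ps matches common trajectory output
#'   rates.
#' @param spread radius scale of each random atom blob (Angstrom).
#' @param geometry_seed seed for the random atom geometry.
#' @return object of class `traj_sim_spec`.
#' @export
traj_sim_spec <- function(n_atoms_fixed = 40L, n_atoms_mobile = 40L,
                          rotation_axis = c(0, 0, 1),
                          angle_schedule = seq(0, 30, length.out = 101L),
                          axis_offset = 20, noise_sd = 0.5, dt_ps = 10,
                          spread = 5, geometry_seed = 1L) {
  if (n_atoms_fixed < 1L || n_atoms_mobile < 1L)
    abort("arpdyn_spec_error", "both atom groups must be non-empty")
  if (noise_sd < 0) abort("arpdyn_spec_error", "noise_sd must be >= 0")
  structure(list(n_atoms_fixed = as.integer(n_atoms_fixed),
                 n_atoms_mobile = as.integer(n_atoms_mobile),
                 rotation_axis = rotation_axis / sqrt(sum(rotation_axis^2)),
                 angle_schedule = angle_schedule, axis_offset = axis_offset,
                 noise_sd = noise_sd, dt_ps = dt_ps, spread = spread,
                 geometry_seed = as.integer(geometry_seed)),
            class = "traj_sim_spec")
}

#' Simulate a rigid-body reorientation trajectory with ground truth
#'
#' The fixed group sits near the origin; the mobile group is a rigid blob
#' centred `axis_offset` Angstrom from the rotation axis and is rotated by
#' the per-frame schedule about that axis, after which isotropic Gaussian
#' noise is added to every atom of every frame. The returned ground truth
#' carries the noise-free aligned RMSD of the mobile group relative to
#' frame 0 (closed form `2*sin(theta/2)*r_rms`, with `r_rms` the
#' root-mean-square atom distance from the axis) and noise-free contact
#' counts against the fixed group.
#'
#' @param spec a [traj_sim_spec()].
#' @param seed seed for the noise stream.
#' @param contact_cutoff cutoff (Angstrom) for the ground-truth contact
#'   series.
#' @return list with `traj` (an `md_trajectory`; chain "F" fixed, chain "M"
#'   mobile, one CA atom per residue) and `truth` (list: `rmsd` noise-free
#'   aligned RMSD per frame, `contacts` noise-free counts, `r_rms`,
#'   `angles_deg`).
#' @export
simulate_reorientation_traj <- function(spec, seed = 1L, contact_cutoff = 3.5) {
  base <- with_seed(spec$geometry_seed, {
    fixed <- matrix(stats::rnorm(3L * spec$n_atoms_fixed, sd = spec$spread),
                    ncol = 3L)
    u <- spec$rotation_axis
    ## centre of the mobile blob: axis_offset away, perpendicular to u
    perp <- c(u[2], -u[1], 0)
    if (sum(perp^2) < 1e-12) perp <- c(1, 0, 0)
    perp <- perp / sqrt(sum(perp^2))
    mobile <- sweep(matrix(stats::rnorm(3L * spec$n_atoms_mobile,
                                        sd = spec$spread), ncol = 3L),
                    2L, spec$axis_offset * perp, "+")
    list(fixed = fixed, mobile = mobile)
  })
  u <- spec$rotation_axis
  ## distance of each mobile atom from the axis (through the origin)
  proj <- base$mobile %*% u
  radial <- base$mobile - proj %*% t(u)
  r_rms <- sqrt(mean(rowSums(radial^2)))

  n_frames <- length(spec$angle_schedule)
  n <- spec$n_atoms_fixed + spec$n_atoms_mobile
  topo <- md_structure(
    data.frame(
      chain = rep(c("F", "M"), c(spec$n_atoms_fixed, spec$n_atoms_mobile)),
      resno = c(seq_len(spec$n_atoms_fixed), seq_len(spec$n_atoms_mobile)),
      resid = "GLY", elety = "CA", elem = "C", occ = 1, alt = "",
      stringsAsFactors = FALSE),
    rbind(base$fixed, base$mobile))

  clean <- matrix(0, n_frames, 3L * n)
  contacts <- integer(n_frames)
  cs <- contact_spec(atom_selection(chains = "M"), atom_selection(chains = "F"),
                     cutoff = contact_cutoff)
  for (k in seq_len(n_frames)) {
    rot <- rotation_about_axis(u, spec$angle_schedule[k])
    frame <- rbind(base$fixed, base$mobile %*% t(rot))
    clean[k, ] <- xyz_flatten(frame)
    contacts[k] <- contact_count(frame, cs, topo, method = "brute")
  }
  xyz <- if (spec$noise_sd > 0) {
    with_seed(seed, clean + matrix(stats::rnorm(length(clean), sd = spec$noise_sd),
                                   nrow = n_frames))
  } else clean
  theta <- (spec$angle_schedule - spec$angle_schedule[1L]) * pi / 180
  list(
    traj = md_trajectory(topo, xyz, spec$dt_ps * (seq_len(n_frames) - 1L)),
    truth = list(rmsd = 2 * abs(sin(theta / 2)) * r_rms,
                 contacts = contacts, r_rms = r_rms,
                 angles_deg = spec$angle_schedule)
  )
}

#' Simulate a salt-bridge partner switch
#'
#' A minimum-distance series sitting near `d_low` before `switch_frame` and
#' near `d_high` after it, with additive Gaussian noise - the fixture for
#' bimodal donor-acceptor distance distributions produced when an
#' interaction is rearranged.
#'
#' @param n_frames number of frames.
#' @param d_low,d_high the two distance levels (Angstrom), `d_low < d_high`.
#' @param switch_frame first frame at the high level (1-based, in
#'   `[1, n_frames]`).
#' @param noise_sd Gaussian noise sd (Angstrom).
#' @param seed RNG seed.
#' @param dt_ps frame spacing (ps).
#' @return list with `series` (a `distance_series` with a synthetic spec
#'   label) and `truth` (`levels`, `switch_frame`).
#' @export
simulate_salt_bridge_switch <- function(n_frames, d_low, d_high, switch_frame,
                                        noise_sd = 0.1, seed = 1L, dt_ps = 10) {
  if (d_low >= d_high)
    abort("arpdyn_spec_error", "d_low (%g) must be < d_high (%g)", d_low, d_high)
  if (switch_frame < 1L || switch_frame > n_frames)
    abort("arpdyn_bounds_error", "switch_frame %d outside [1, %d]",
          switch_frame, n_frames)
  level <- ifelse(seq_len(n_frames) >= switch_frame, d_high, d_low)
  vals <- if (noise_sd > 0)
    with_seed(seed, level + stats::rnorm(n_frames, sd = noise_sd))
  else level
  vals <- pmax(vals, 1e-6)
  series <- structure(
    list(times = dt_ps * (seq_len(n_frames) - 1L), values = vals,
         spec = list(label = "synthetic-switch")),
    class = "distance_series")
  list(series = series, truth = list(levels = c(d_low, d_high),
                                     switch_frame = switch_frame))
}

#' Specification for a synthetic pyrene assembly curve
#'
#' @param filament_ends growing filament-end concentration (nM).
#' @param total_actin total actin (uM); default 4, the canonical assay
#'   condition.
#' @param critical_conc critical concentration (uM).
#' @param k_plus association rate constant (uM^-1 s^-1); default 10.
#' @param f_baseline,f_plateau fluorescence anchors (AU).
#' @param noise_sd additive fluorescence noise (AU); the default is 0.5% of
#'   the baseline-to-plateau range.
#' @param duration assay length (s).
#' @param dt sampling interval (s); default 1 s, the spectrophotometer
#'   interval.
#' @param pyrene_fraction labelled fraction; default 0.05.
#' @return object of class `curve_sim_spec`.
#' @export
curve_sim_spec <- function(filament_ends, total_actin = 4, critical_conc = 0,
                           k_plus = 10, f_baseline = 0, f_plateau = 1,
                           noise_sd = 0.005 * (f_plateau - f_baseline),
                           duration = 3000, dt = 1, pyrene_fraction = 0.05) {
  if (filament_ends < 0) abort("arpdyn_spec_error", "filament_ends must be >= 0")
  if (dt <= 0) abort("arpdyn_spec_error", "dt must be positive")
  if (f_plateau <= f_baseline)
    abort("arpdyn_spec_error", "f_plateau must exceed f_baseline")
  structure(list(filament_ends = filament_ends, total_actin = total_actin,
                 critical_conc = critical_conc, k_plus = k_plus,
                 f_baseline = f_baseline, f_plateau = f_plateau,
                 noise_sd = noise_sd, duration = duration, dt = dt,
                 pyrene_fraction = pyrene_fraction),
            class = "curve_sim_spec")
}

#' Closed-form polymer concentration for a fixed end concentration
#'
#' Solution of `dP/dt = k_plus * (A_total - cc - P) * E` from `P(0) = 0`:
#' `P(t) = (A_total - cc) * (1 - exp(-k_plus * E * t))` with `E` in uM.
#'
#' @param times time points (s).
#' @param spec a [curve_sim_spec()].
#' @return polymer concentration (uM) at `times`.
#' @export
assembly_closed_form <- function(times, spec) {
  e_uM <- spec$filament_ends / 1000
  (spec$total_actin - spec$critical_conc) *
    (1 - exp(-spec$k_plus * e_uM * times))
}

#' Simulate a pyrene assembly curve with known ground truth
#'
#' Forward model of the elongation relationship with a fixed end
#' concentration (nucleation deliberately omitted - the inversion formula
#' itself assumes a fixed end count at the readout point): the closed-form
#' polymer curve is mapped linearly onto the fluorescence anchors and
#' Gaussian noise is added.
#'
#' @param spec a [curve_sim_spec()].
#' @param seed RNG seed for the noise.
#' @return list with `curve` (an [assembly_curve()]), `calibration` (the
#'   matching [curve_calibration()]) and `truth` (list: `filament_ends_nM`,
#'   `t_half_s`, `polymer_uM`).
#' @export
simulate_assembly_curve <- function(spec, seed = 1L) {
  times <- seq(0, spec$duration, by = spec$dt)
  p <- assembly_closed_form(times, spec)
  capacity <- spec$total_actin - spec$critical_conc
  signal <- spec$f_baseline + p / capacity * (spec$f_plateau - spec$f_baseline)
  if (spec$noise_sd > 0)
    signal <- with_seed(seed, signal + stats::rnorm(length(signal),
                                                    sd = spec$noise_sd))
  t_half <- if (spec$filament_ends > 0)
    log(2) / (spec$k_plus * spec$filament_ends / 1000) else NA_real_
  list(
    curve = assembly_curve(times, signal, total_actin = spec$total_actin,
                           pyrene_fraction = spec$pyrene_fraction),
    calibration = curve_calibration(spec$f_baseline, spec$f_plateau,
                                    critical_conc = spec$critical_conc),
    truth = list(filament_ends_nM = spec$filament_ends, t_half_s = t_half,
                 polymer_uM = p)
  )
}

#' End concentration giving a target half-time
#'
#' Inverts `t_half = ln 2 / (k_plus * E)` (E in uM internally) so synthetic
#' curves can be parameterised by the half-times quoted for real assays.
#'
#' @param t_half_s target half-time (s).
#' @param k_plus association rate constant (uM^-1 s^-1).
#' @return filament-end concentration in nM.
#' @export
ends_for_half_time <- function(t_half_s, k_plus = 10) {
  1000 * log(2) / (k_plus * t_half_s)
}
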