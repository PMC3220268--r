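#' Inter-subunit contact specification
#'
#' A contact is counted on the atoms of `group_b`: a b atom is "in contact"
#' when at least one `group_a` atom lies within `cutoff` Angstrom
#' (inclusive). The census is therefore asymmetric by definition - the
#' count of Arp3 heavy atoms within 3.5 A of any Arp2 heavy atom is not the
#' count of Arp2 atoms near Arp3. Both selections are forced to heavy atoms
#' unless they already restrict the element class.
#'
#' @param group_a probe selection (e.g. Arp2 heavy atoms).
#' @param group_b counted selection (e.g. Arp3 heavy atoms).
#' @param cutoff contact distance in Angstrom (default 3.5, inclusive).
#' @return object of class `contact_spec`.
#' @export
contact_spec <- function(group_a, group_b, cutoff = 3.5) {
  if (cutoff <= 0) abort("arpdyn_spec_error", "cutoff must be positive")
  for (nm in c("group_a", "group_b")) {
    g <- get(nm)
    if (g$element_class == "ALL") g$element_class <- "HEAVY"
    assign(nm, g)
  }
  structure(list(group_a = group_a, group_b = group_b, cutoff = cutoff),
            class = "contact_spec")
}

## All-pairs census: count b atoms with min distance to any a atom <= cutoff.
contact_count_brute <- function(a_xyz, b_xyz, cutoff) {
  d2 <- outer(rowSums(b_xyz^2), rowSums(a_xyz^2), "+") - 2 * b_xyz %*% t(a_xyz)
  sum(apply(d2, 1L, min) <= cutoff^2)
}

## Cell-list census: bin a atoms into cubic cells of edge = cutoff; each b
## atom only needs its 27 neighbouring cells. Same inclusive comparison and
## the same squared-distance arithmetic as the brute-force path.
contact_count_cell <- function(a_xyz, b_xyz, cutoff) {
  cell_of <- function(m) floor(m / cutoff)
  ca <- cell_of(a_xyz); cb <- cell_of(b_xyz)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  a_by_cell <- split(seq_len(nrow(a_xyz)), key(ca))
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  b_cells <- key(cb)
  n_contact <- 0L
  for (ck in unique(b_cells)) {
    b_idx <- which(b_cells == ck)
    base <- cb[b_idx[1], ]
    neigh <- sweep(offsets, 2L, base, "+")
    cand <- unlist(a_by_cell[key(neigh)], use.names = FALSE)
    if (is.null(cand) || !length(cand)) next
    bm <- b_xyz[b_idx, , drop = FALSE]
    am <- a_xyz[cand, , drop = FALSE]
    d2 <- outer(rowSums(bm^2), rowSums(am^2), "+") - 2 * bm %*% t(am)
    n_contact <- n_contact + sum(apply(d2, 1L, min) <= cutoff^2)
  }
  n_contact
}

#' Heavy-atom contact count for one frame
#'
#' @param frame_coords N x 3 coordinates of the full topology.
#' @param spec a [contact_spec()].
#' @param topology the `md_structure` the selections resolve against.
#' @param method `"cell"` (cell-list accelerated, default) or `"brute"`
#'   (all-pairs); the two are exact equals and the brute path serves as the
#'   oracle in tests.
#' @return integer count of `group_b` atoms with >= 1 `group_a` atom within
#'   the cutoff.
#' @export
contact_count <- function(frame_coords, spec, topology,
                          method = c("cell", "brute")) {
  method <- match.arg(method)
  ia <- resolve_selection(spec$group_a, topology)
  ib <- resolve_selection(spec$group_b, topology)
  if (length(intersect(ia, ib)))
    abort("arpdyn_spec_error", "contact groups overlap (%d shared atoms)",
          length(intersect(ia, ib)))
  a <- frame_coords[ia, , drop = FALSE]
  b <- frame_coords[ib, , drop = FALSE]
  if (method == "brute") contact_count_brute(a, b, spec$cutoff)
  else contact_count_cell(a, b, spec$cutoff)
}

#' Contact-count time series
#'
#' Applies [contact_count()] to every `stride`-th frame (the convention in
#' the source analyses is every 10th frame, i.e. 100 ps).
#'
#' @param traj an `md_trajectory`.
#' @param spec a [contact_spec()].
#' @param stride frame stride (>= 1).
#' @param method passed to [contact_count()].
#' @return object of class `contact_series`: list with `times` (ps),
#'   `counts` and `spec`.
#' @export
contact_series <- function(traj, spec, stride = 1L, method = "cell") {
  if (stride < 1L) abort("arpdyn_window_error", "stride must be >= 1")
  keep <- seq(1L, n_frames(traj), by = stride)
  counts <- vapply(keep, function(k)
    contact_count(frame_xyz(traj, k), spec, traj$topology, method = method), 0L)
  structure(list(times = traj$times[keep], counts = counts, spec = spec),
            class = "contact_series")
}

#' @export
as.data.frame.contact_series <- function(x, ...) {
  data.frame(time_ps = x$times, contacts = x$counts)
}

#' Donor-acceptor pair specification for minimum-distance tracking
#'
#' @param donor_atoms selection of hydrogen-bond donor atoms (e.g. Arg
#'   NE/NH1/NH2, Lys NZ).
#' @param acceptor_atoms selection of acceptor atoms (e.g. Glu OE1/OE2,
#'   phosphothreonine phosphate oxygens).
#' @param label text label for the tracked interaction.
#' @return object of class `pair_distance_spec`.
#' @export
pair_distance_spec <- function(donor_atoms, acceptor_atoms, label = "") {
  structure(list(donor_atoms = donor_atoms, acceptor_atoms = acceptor_atoms,
                 label = label),
            class = "pair_distance_spec")
}

#' Minimum donor-acceptor distance in one frame
#'
#' @param frame_coords N x 3 coordinates.
#' @param spec a [pair_distance_spec()].
#' @param topology the `md_structure` the selections resolve against.
#' @return minimum Euclidean distance (Angstrom) over all donor-acceptor
#'   pairs.
#' @export
min_pair_distance <- function(frame_coords, spec, topology) {
  id <- resolve_selection(spec$donor_atoms, topology)
  ia <- resolve_selection(spec$acceptor_atoms, topology)
  d <- frame_coords[id, , drop = FALSE]
  a <- frame_coords[ia, , drop = FALSE]
  d2 <- outer(rowSums(d^2), rowSums(a^2), "+") - 2 * d %*% t(a)
  sqrt(max(min(d2), 0))
}

#' Minimum-distance time series for a donor-acceptor pair
#'
#' @param traj an `md_trajectory`.
#' @param spec a [pair_distance_spec()].
#' @param stride frame stride.
#' @return object of class `distance_series`: list with `times`, `values`
#'   (Angstrom), `spec`.
#' @export
distance_series <- function(traj, spec, stride = 1L) {
  if (stride < 1L) abort("arpdyn_window_error", "stride must be >= 1")
  keep <- seq(1L, n_frames(traj), by = stride)
  vals <- vapply(keep, function(k)
    min_pair_distance(frame_xyz(traj, k), spec, traj$topology), 0)
  structure(list(times = traj$times[keep], values = vals, spec = spec),
            class = "distance_series")
}

#' @export
as.data.frame.distance_series <- function(x, ...) {
  data.frame(time_ps = x$times, min_distance_A = x$values,
             label = if (inherits(x$spec, "pair_distance_spec")) x$spec$label else "")
}

#' Pooled distance distribution across replicate series
#'
#' Replicate series are concatenated before binning, matching the pooling
#' convention used when duplicate simulations are compared.
#'
#' @param series_list a `distance_series` or list of them.
#' @param bins number of bins.
#' @return a [histogram_result()].
#' @export
distance_distribution <- function(series_list, bins = 50L) {
  if (inherits(series_list, "distance_series")) series_list <- list(series_list)
  if (!length(series_list)) abort("arpdyn_empty_input_error", "no series supplied")
  vals <- unlist(lapply(series_list, function(s)
    if (inherits(s, "distance_series")) s$values else s))
  histogram_result(vals, bins = bins)
}

#' Default hydrogen-bond donor/acceptor atom roster
#'
#' Per-residue-type atom roles used to build salt-bridge selections
#' (Arg NE/NH1/NH2 and Lys NZ as donors; Glu OE1/OE2, Asp OD1/OD2 and
#' phosphothreonine O1P/O2P/O3P/OG1 as acceptors; Tyr OH as donor). Shipped
#' as a plain-text table and fully user-overridable.
#'
#' @return data.frame with `res_name`, `atom_name`, `role`.
#' @export
default_pair_roster <- function() {
  utils::read.delim(
    system.file("extdata", "donor_acceptor_roster.tsv", package = "arpdyn"),
    stringsAsFactors = FALSE
  )
}

#' Build a donor-acceptor pair spec from residue identities
#'
#' Looks up the atom roster for the two residues and returns a
#' [pair_distance_spec()] tracking the minimum distance between the donor
#' atoms of one and the acceptor atoms of the other.
#'
#' @param topology an `md_structure`.
#' @param donor_chain,donor_resno chain and residue number of the donor
#'   residue.
#' @param acceptor_chain,acceptor_resno chain and residue number of the
#'   acceptor residue.
#' @param roster roster table, defaults to [default_pair_roster()].
#' @return a [pair_distance_spec()].
#' @export
salt_bridge_spec <- function(topology, donor_chain, donor_resno,
                             acceptor_chain, acceptor_resno,
                             roster = default_pair_roster()) {
  res_at <- function(chain, resno) {
    at <- topology$atoms
    r <- unique(at$resid[at$chain == chain & at$resno == resno])
    if (!length(r))
      abort("arpdyn_selection_error", "no residue %s/%d in topology", chain, resno)
    r[1]
  }
  d_res <- res_at(donor_chain, donor_resno)
  a_res <- res_at(acceptor_chain, acceptor_resno)
  d_atoms <- roster$atom_name[roster$res_name == d_res & roster$role == "donor"]
  a_atoms <- roster$atom_name[roster$res_name == a_res & roster$role == "acceptor"]
  if (!length(d_atoms))
    abort("arpdyn_selection_error", "no donor atoms in roster for residue type %s", d_res)
  if (!length(a_atoms))
    abort("arpdyn_selection_error", "no acceptor atoms in roster for residue type %s", a_res)
  pair_distance_spec(
    atom_selection(chains = donor_chain, ranges = list(c(donor_resno, donor_resno)),
                   atom_names = d_atoms),
    atom_selection(chains = acceptor_chain,
                   ranges = list(c(acceptor_resno, acceptor_resno)),
                   atom_names = a_atoms),
    label = sprintf("%s%d(%s)-%s%d(%s)", donor_chain, donor_resno, d_res,
                    acceptor_chain, acceptor_resno, a_res)
  )
}
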