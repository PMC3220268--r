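# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

# A structure with one chain and a chosen atom roster per residue.
make_chain_structure <- function(resnos, chain = "A",
                                 atom_names = c("N", "CA", "C", "O"),
                                 resid = "ALA", spacing = 4) {
  elem_of <- function(nm) {
    core <- gsub("[0-9']", "", nm)
    ifelse(substr(core, 1, 1) == "H", "H", substr(core, 1, 1))
  }
  n_res <- length(resnos)
  atoms <- data.frame(
    chain = chain,
    resno = rep(resnos, each = length(atom_names)),
    resid = resid,
    elety = rep(atom_names, n_res),
    elem = elem_of(rep(atom_names, n_res)),
    occ = 1, alt = "",
    stringsAsFactors = FALSE
  )
  n <- nrow(atoms)
  # gentle helix so the points are never collinear
  x <- spacing * rep(seq_len(n_res), each = length(atom_names)) +
    0.3 * seq_along(atom_names)
  xyz <- cbind(x, 1.5 * sin(0.6 * x), 1.5 * cos(0.6 * x))
  md_structure(atoms, xyz)
}

# Two-chain point-cloud structure (all CA carbons) from explicit coordinates.
make_two_group_structure <- function(xyz_a, xyz_b,
                                     chain_a = "A", chain_b = "B") {
  na <- nrow(xyz_a); nb <- nrow(xyz_b)
  atoms <- data.frame(
    chain = rep(c(chain_a, chain_b), c(na, nb)),
    resno = c(seq_len(na), seq_len(nb)),
    resid = "GLY", elety = "CA", elem = "C", occ = 1, alt = "",
    stringsAsFactors = FALSE
  )
  md_structure(atoms, rbind(xyz_a, xyz_b))
}

# A static trajectory repeating one structure's coordinates.
make_static_traj <- function(structure, n_frames = 5, dt_ps = 10) {
  row <- as.vector(t(structure$xyz))
  md_trajectory(structure,
                matrix(rep(row, n_frames), nrow = n_frames, byrow = TRUE),
                dt_ps * (seq_len(n_frames) - 1))
}

# Fixed-width PDB ATOM line.
pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1, alt = "", elem = "") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, alt, resid, chain, resno, x, y, z, occ, 0, elem)
}

write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
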