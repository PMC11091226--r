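# Shared fixtures, all generated in code.

# A hand-written minimal PDB: three GLY-like residues + one HETATM ligand
# (+ optional waters), for parser contract tests.
toy_pdb_lines <- function(with_waters = FALSE) {
  atom <- function(serial, name, resname, chain, resno, x, y, z,
                   record = "ATOM", occ = 1, alt = "") {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, serial, name, alt, resname, chain, resno, x, y, z, occ, 0,
            substr(name, 1, 1))
  }
  lines <- c(
    atom(1, "N", "GLY", "A", 1, 0.000, 0.000, 0.000),
    atom(2, "CA", "GLY", "A", 1, 1.458, 0.000, 0.000),
    atom(3, "C", "GLY", "A", 1, 2.000, 1.400, 0.000),
    atom(4, "N", "GLY", "A", 2, 3.329, 1.400, 0.000),
    atom(5, "CA", "GLY", "A", 2, 4.100, 2.600, 0.000),
    atom(6, "C", "GLY", "A", 2, 5.600, 2.600, 0.000),
    atom(7, "N", "GLY", "A", 3, 6.929, 2.600, 0.000),
    atom(8, "CA", "GLY", "A", 3, 7.700, 3.800, 0.000),
    atom(9, "C", "GLY", "A", 3, 9.200, 3.800, 0.000),
    "TER",
    atom(10, "C1", "LIG", "X", 1, 2.000, 4.000, 2.000, record = "HETATM"),
    atom(11, "O1", "LIG", "X", 1, 3.200, 4.000, 2.000, record = "HETATM")
  )
  if (with_waters) {
    lines <- c(lines,
               atom(12, "O", "HOH", "W", 1, 20, 20, 20, record = "HETATM"),
               atom(13, "O", "HOH", "W", 2, 21, 21, 21, record = "HETATM"))
  }
  c(lines, "END")
}

# Standard 5-residue toy spec used across suites.
default_toy_spec <- function(probe = "lj_sphere", anchor = 3, offset = 3,
                             charge_scheme = "table", seed = 1L) {
  toy_spec(c("ALA", "SER", "ASP", "GLY", "LYS"), probe = probe,
           anchor = anchor, offset = offset, charge_scheme = charge_scheme,
           seed = seed)
}

# A random toy spec for property-style loops; deterministic per seed.
random_toy_spec <- function(seed) {
  set.seed(seed)
  n <- sample(3:6, 1)
  seq <- sample(c("GLY", "ALA", "SER", "ASP", "LYS", "PHE"), n,
                replace = TRUE)
  probe <- sample(c("lj_sphere", "diatomic_dipole", "tripeptide_mimic"), 1)
  toy_spec(seq, probe = probe, anchor = sample(seq_len(n), 1),
           offset = 3 + runif(1, 0, 2), charge_scheme = "seeded_random",
           seed = seed)
}

peptide_atoms <- function(complex) {
  do.call(rbind, lapply(complex$residues, `[[`, "atoms"))
}

# Translate selected residues rigidly (used for far-field constructions).
shift_residues <- function(complex, idx, by) {
  for (i in idx) {
    complex$residues[[i]]$atoms$x <- complex$residues[[i]]$atoms$x + by[1]
    complex$residues[[i]]$atoms$y <- complex$residues[[i]]$atoms$y + by[2]
    complex$residues[[i]]$atoms$z <- complex$residues[[i]]$atoms$z + by[3]
  }
  complex
}
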