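# Deterministic toy peptide-ligand complexes with known, strictly
# pairwise-additive energetics.
#
# Peptides are built from internal coordinates (N-CA 1.458 A, CA-C 1.525 A,
# C-N 1.329 A, standard angles, extended backbone by default) from a minimal
# residue library; probes are placed at a stated offset from an anchor
# residue's CA. Charges come from an embedded table (per-residue neutrality,
# ASP -1 / LYS +1) or seeded uniform draws; Lennard-Jones parameters from a
# small element table. Because the classical backend is exactly pairwise
# additive, the brute-force ligand-residue cross energies are the ground
# truth every pipeline stage can be checked against.

TOY_RESIDUE_LIBRARY <- c("GLY", "ALA", "SER", "ASP", "LYS", "PHE")
TOY_FORMAL_CHARGES <- c(GLY = 0L, ALA = 0L, SER = 0L, ASP = -1L, LYS = 1L,
                        PHE = 0L)

# Lennard-Jones by element: sigma (A), epsilon (kcal/mol)
TOY_LJ_TABLE <- data.frame(
  elem = c("C", "N", "O", "S", "H"),
  sigma = c(3.40, 3.25, 2.96, 3.56, 2.47),
  epsilon_lj = c(0.086, 0.170, 0.210, 0.250, 0.0157),
  stringsAsFactors = FALSE
)

# Embedded partial-charge table; each residue's charges sum exactly to its
# formal charge.
TOY_CHARGE_TABLE <- list(
  GLY = c(N = -0.40, H = 0.25, CA = 0.10, C = 0.55, O = -0.50),
  ALA = c(N = -0.40, H = 0.25, CA = 0.05, CB = 0.05, C = 0.55, O = -0.50),
  SER = c(N = -0.40, H = 0.25, CA = 0.05, CB = 0.25, OG = -0.60, HG = 0.40,
          C = 0.55, O = -0.50),
  ASP = c(N = -0.40, H = 0.25, CA = 0.05, CB = -0.05, CG = 0.70,
          OD1 = -0.80, OD2 = -0.80, C = 0.55, O = -0.50),
  LYS = c(N = -0.40, H = 0.25, CA = 0.05, CB = 0.00, CG = 0.00, CD = 0.10,
          CE = 0.25, NZ = 0.00, HZ1 = 0.70, C = 0.55, O = -0.50),
  PHE = c(N = -0.40, H = 0.25, CA = 0.05, CB = 0.10, CG = 0.00,
          CD1 = -0.01, CD2 = -0.01, CE1 = -0.01, CE2 = -0.01, CZ = -0.01,
          C = 0.55, O = -0.50)
)

TOY_PROBE_CHARGES <- list(
  lj_sphere = c(C1 = 0.25),
  diatomic_dipole = c(N1 = 0.30, O1 = -0.30),
  tripeptide_mimic = c(C1 = 0.00, C2 = 0.55, O1 = -0.55, N1 = -0.40,
                       H1 = 0.40, C3 = 0.06, C4 = -0.01, C5 = -0.01,
                       C6 = -0.01, C7 = -0.01, C8 = -0.01, C9 = -0.01)
)

#' Specify a toy peptide-ligand complex
#'
#' @param sequence Character vector of residue names from the toy library
#'   (GLY, ALA, SER, ASP, LYS, PHE); length >= 2.
#' @param probe One of `"lj_sphere"` (single atom), `"diatomic_dipole"`
#'   (two opposite partial charges 1.2 A apart) or `"tripeptide_mimic"`
#'   (an N-acetyl amide bearing a six-carbon ring proxy, with a full label
#'   map so every contact class is reachable).
#' @param anchor Index of the residue whose CA anchors the probe.
#' @param offset Scalar offset (Angstrom, applied along +z) or a length-3
#'   displacement vector from the anchor CA.
#' @param charge_scheme `"table"` (embedded charges) or `"seeded_random"`
#'   (uniform draws with per-residue neutrality enforced up to the formal
#'   charge).
#' @param seed Integer seed for `"seeded_random"`; generation is reproducible
#'   bit-for-bit per seed.
#' @param phi,psi,omega Backbone dihedrals in degrees (default extended).
#' @return An object of class `mfcc_toy_spec`.
#' @export
toy_spec <- function(sequence, probe = c("lj_sphere", "diatomic_dipole",
                                         "tripeptide_mimic"),
                     anchor = ceiling(length(sequence) / 2), offset = 3,
                     charge_scheme = c("table", "seeded_random"), seed = 1L,
                     phi = 180, psi = 180, omega = 180) {
  probe <- match.arg(probe)
  charge_scheme <- match.arg(charge_scheme)
  stopifnot(length(sequence) >= 2, anchor >= 1, anchor <= length(sequence))
  unknown <- setdiff(sequence, TOY_RESIDUE_LIBRARY)
  if (length(unknown) > 0) {
    stop("residues outside the toy library: ", paste(unknown, collapse = ", "))
  }
  structure(
    list(sequence = sequence, probe = probe, anchor = anchor,
         offset = offset, charge_scheme = charge_scheme,
         seed = as.integer(seed), phi = phi, psi = psi, omega = omega),
    class = "mfcc_toy_spec"
  )
}

# NeRF atom placement: d with |d-c| = bond, angle(d,c,b) = angle and
# dihedral(a,b,c,d) = dihedral (degrees).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(ang), cos(dih) * sin(ang), sin(dih) * sin(ang))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

toy_sidechain <- function(name, n, ca, c) {
  out <- list()
  add <- function(lst, nm, el, pos) {
    lst[[length(lst) + 1]] <- list(name = nm, elem = el, pos = pos)
    lst
  }
  if (name == "GLY") return(out)
  cb <- place_atom(c, n, ca, 1.53, 110.5, -122)
  out <- add(out, "CB", "C", cb)
  if (name == "ALA") return(out)
  if (name == "SER") {
    og <- place_atom(n, ca, cb, 1.41, 109.5, 180)
    out <- add(out, "OG", "O", og)
    out <- add(out, "HG", "H", place_atom(ca, cb, og, 0.96, 109.5, 180))
  } else if (name == "ASP") {
    cg <- place_atom(n, ca, cb, 1.52, 112, 180)
    out <- add(out, "CG", "C", cg)
    out <- add(out, "OD1", "O", place_atom(ca, cb, cg, 1.25, 118, 0))
    out <- add(out, "OD2", "O", place_atom(ca, cb, cg, 1.25, 118, 180))
  } else if (name == "LYS") {
    cg <- place_atom(n, ca, cb, 1.52, 112, 180)
    cd <- place_atom(ca, cb, cg, 1.52, 112, 180)
    ce <- place_atom(cb, cg, cd, 1.52, 112, 180)
    nz <- place_atom(cg, cd, ce, 1.47, 110, 180)
    out <- add(out, "CG", "C", cg)
    out <- add(out, "CD", "C", cd)
    out <- add(out, "CE", "C", ce)
    out <- add(out, "NZ", "N", nz)
    out <- add(out, "HZ1", "H", place_atom(cd, ce, nz, 1.01, 109.5, 180))
  } else if (name == "PHE") {
    cg <- place_atom(n, ca, cb, 1.51, 114, 180)
    cd1 <- place_atom(ca, cb, cg, 1.39, 120, 90)
    cd2 <- place_atom(ca, cb, cg, 1.39, 120, -90)
    ce1 <- place_atom(cb, cg, cd1, 1.39, 120, 180)
    ce2 <- place_atom(cb, cg, cd2, 1.39, 120, 180)
    cz <- place_atom(cg, cd1, ce1, 1.39, 120, 0)
    out <- add(out, "CG", "C", cg)
    out <- add(out, "CD1", "C", cd1)
    out <- add(out, "CD2", "C", cd2)
    out <- add(out, "CE1", "C", ce1)
    out <- add(out, "CE2", "C", ce2)
    out <- add(out, "CZ", "C", cz)
  }
  out
}

# planar template for the tripeptide_mimic probe (acetamide head + ring)
mimic_template <- function() {
  s60 <- sin(pi / 3)
  c1 <- c(0, 0, 0)
  c2 <- c(1.50, 0, 0)
  o1 <- c2 + 1.23 * c(0.5, s60, 0)
  n1 <- c2 + 1.33 * c(0.5, -s60, 0)
  h1 <- n1 + 1.01 * c(0.5, -s60, 0)
  c3 <- n1 + c(1.45, 0, 0)
  center <- c3 + c(2.90, 0, 0)
  ring <- t(vapply(seq(180, -120, by = -60), function(th) {
    center + 1.39 * c(cos(th * pi / 180), sin(th * pi / 180), 0)
  }, numeric(3)))
  pos <- rbind(c1, c2, o1, n1, h1, c3, ring)
  list(
    names = c("C1", "C2", "O1", "N1", "H1", "C3",
              "C4", "C5", "C6", "C7", "C8", "C9"),
    elems = c("C", "C", "O", "N", "H", "C", rep("C", 6)),
    pos = pos
  )
}

MIMIC_LABEL_MAP <- list(
  C1 = list(label = "i(C1)H", region = "i", ring = "none"),
  C2 = list(label = "i(C2)", region = "i", ring = "none"),
  O1 = list(label = "i(O)", region = "i", ring = "none"),
  N1 = list(label = "ii(N)H", region = "ii", ring = "none"),
  H1 = list(label = "ii(H)", region = "ii", ring = "none"),
  C3 = list(label = "ii(C3)", region = "ii", ring = "none"),
  C4 = list(label = "iii(C4)", region = "iii", ring = "A"),
  C5 = list(label = "iii(C5)", region = "iii", ring = "A"),
  C6 = list(label = "iii(C6)", region = "iii", ring = "A"),
  C7 = list(label = "iii(C7)", region = "iii", ring = "A"),
  C8 = list(label = "iii(C8)", region = "iii", ring = "A"),
  C9 = list(label = "iii(C9)", region = "iii", ring = "A")
)

#' Build a toy peptide-ligand complex
#'
#' Constructs the peptide from internal coordinates, places the probe at the
#' stated offset from the anchor residue's CA, and returns a normalized
#' complex. Identical specs give bitwise-identical coordinates. Any
#' interatomic distance below 0.8 A raises a geometry error.
#'
#' @param spec An `mfcc_toy_spec`.
#' @return An `mfcc_complex`.
#' @export
build_toy_complex <- function(spec) {
  nres <- length(spec$sequence)
  serial <- 0L
  residues <- vector("list", nres)
  prev <- NULL
  for (i in seq_len(nres)) {
    if (i == 1) {
      n <- c(0, 0, 0)
      ca <- c(1.458, 0, 0)
      th <- (180 - 111) * pi / 180
      cc <- ca + 1.525 * c(cos(th), sin(th), 0)
    } else {
      n <- place_atom(prev$n, prev$ca, prev$c, 1.329, 116.6, spec$psi)
      ca <- place_atom(prev$ca, prev$c, n, 1.458, 121.7, spec$omega)
      cc <- place_atom(prev$c, n, ca, 1.525, 111.0, spec$phi)
    }
    o <- place_atom(n, ca, cc, 1.231, 120.5, 0)
    h <- if (i == 1) {
      place_atom(cc, ca, n, 1.01, 109.5, 180)
    } else {
      place_atom(prev$o, prev$c, n, 1.01, 119, 180)
    }
    rows <- list(list(name = "N", elem = "N", pos = n),
                 list(name = "H", elem = "H", pos = h),
                 list(name = "CA", elem = "C", pos = ca),
                 list(name = "C", elem = "C", pos = cc),
                 list(name = "O", elem = "O", pos = o))
    rows <- c(rows, toy_sidechain(spec$sequence[i], n, ca, cc))
    pos <- t(vapply(rows, `[[`, numeric(3), "pos"))
    atoms <- new_atoms(serial + seq_along(rows),
                       vapply(rows, `[[`, "", "name"),
                       vapply(rows, `[[`, "", "elem"),
                       pos[, 1], pos[, 2], pos[, 3])
    serial <- serial + nrow(atoms)
    residues[[i]] <- new_residue(
      chain = "A", number = i, icode = "", name = spec$sequence[i],
      atoms = atoms, formal_charge = TOY_FORMAL_CHARGES[spec$sequence[i]],
      n_terminal = i == 1, c_terminal = i == nres
    )
    prev <- list(n = n, ca = ca, c = cc, o = o)
  }

  anchor_ca <- residues[[spec$anchor]]$atoms
  anchor_ca <- unlist(anchor_ca[anchor_ca$name == "CA", c("x", "y", "z")])
  offset <- if (length(spec$offset) == 3) as.numeric(spec$offset) else
    c(0, 0, spec$offset)
  origin <- anchor_ca + offset

  label_map <- NULL
  if (spec$probe == "lj_sphere") {
    pn <- "C1"
    pe <- "C"
    pp <- matrix(origin, nrow = 1)
  } else if (spec$probe == "diatomic_dipole") {
    pn <- c("N1", "O1")
    pe <- c("N", "O")
    pp <- rbind(origin, origin + c(1.2, 0, 0))
  } else {
    tpl <- mimic_template()
    pn <- tpl$names
    pe <- tpl$elems
    pp <- sweep(tpl$pos, 2, origin, "+")
    label_map <- MIMIC_LABEL_MAP
  }
  ligand <- new_ligand(
    name = "PRB",
    atoms = new_atoms(serial + seq_along(pn), pn, pe,
                      pp[, 1], pp[, 2], pp[, 3]),
    formal_charge = 0L, label_map = label_map
  )

  all_xyz <- rbind(do.call(rbind, lapply(residues, function(r)
    atom_xyz(r$atoms))), atom_xyz(ligand$atoms))
  dmin <- min(stats::dist(all_xyz))
  if (dmin < 0.8) {
    stop("geometry error: interatomic clash (", format(dmin), " A)")
  }

  new_complex(residues, ligand,
              metadata = list(source = "toy",
                              sequence = paste(spec$sequence, collapse = "-"),
                              probe = spec$probe))
}

#' Assign classical parameters to a toy complex
#'
#' Charges come either from the embedded table or from seeded uniform draws
#' in (-0.3, 0.3) adjusted so each residue's charges sum exactly to its
#' formal charge; Lennard-Jones parameters come from the element table.
#' Identical seeds give identical parameters.
#'
#' @param complex An `mfcc_complex` built by [build_toy_complex()].
#' @param spec The `mfcc_toy_spec` (supplies scheme and seed), or `NULL` to
#'   use `charge_scheme` / `seed` directly.
#' @param charge_scheme,seed Overrides when `spec` is `NULL`.
#' @param link_atom_policy Passed to [parameter_set()].
#' @return An `mfcc_params` covering every atom of the complex.
#' @export
assign_toy_parameters <- function(complex, spec = NULL,
                                  charge_scheme = "table", seed = 1L,
                                  link_atom_policy = "ghost") {
  if (!is.null(spec)) {
    charge_scheme <- spec$charge_scheme
    seed <- spec$seed
  }
  rng <- NULL
  if (charge_scheme == "seeded_random") {
    rng <- local({
      set.seed(seed)
      function(n) stats::runif(n, -0.3, 0.3)
    })
  }
  one_unit <- function(atoms, name, formal, is_residue) {
    if (charge_scheme == "table") {
      tab <- if (is_residue) TOY_CHARGE_TABLE[[name]] else
        TOY_PROBE_CHARGES[[name]]
      q <- tab[atoms$name]
      if (anyNA(q)) {
        stop("no table charge for atom ", atoms$name[which(is.na(q))[1]],
             " of ", name)
      }
      unname(q)
    } else {
      q <- rng(nrow(atoms))
      if (is_residue) q <- q - mean(q) + formal / nrow(atoms)
      q
    }
  }
  rows <- lapply(complex$residues, function(r) {
    data.frame(serial = r$atoms$serial,
               q = one_unit(r$atoms, r$name, r$formal_charge, TRUE),
               elem = r$atoms$elem, stringsAsFactors = FALSE)
  })
  probe_key <- complex$metadata$probe
  if (is.null(probe_key)) probe_key <- "lj_sphere"
  rows <- c(rows, list(data.frame(
    serial = complex$ligand$atoms$serial,
    q = one_unit(complex$ligand$atoms, probe_key,
                 complex$ligand$formal_charge, FALSE),
    elem = complex$ligand$atoms$elem, stringsAsFactors = FALSE
  )))
  tab <- do.call(rbind, rows)
  j <- match(tab$elem, TOY_LJ_TABLE$elem)
  if (anyNA(j)) stop("no LJ parameters for element ", tab$elem[is.na(j)][1])
  parameter_set(
    data.frame(serial = tab$serial, q = tab$q,
               sigma = TOY_LJ_TABLE$sigma[j],
               epsilon_lj = TOY_LJ_TABLE$epsilon_lj[j]),
    link_atom_policy = link_atom_policy
  )
}

#' Brute-force ground-truth decomposition
#'
#' Computes every residue's exact ligand cross energy by a direct double loop
#' over ligand x residue atom pairs, with no fragmentation involved. Under
#' the classical backend with ghost link atoms the MFCC pipeline must
#' reproduce these numbers to floating-point accuracy.
#'
#' @param complex An `mfcc_complex`.
#' @param params An `mfcc_params`.
#' @param epsilon Dielectric constant.
#' @return data.frame with `residue` and `cross_energy` (kcal/mol).
#' @export
ground_truth_decomposition <- function(complex, params, epsilon = 1) {
  data.frame(
    residue = vapply(complex$residues, residue_id, ""),
    cross_energy = vapply(complex$residues, function(r) {
      pair_cross_energy(r$atoms, complex$ligand$atoms, params, epsilon)
    }, 0),
    stringsAsFactors = FALSE
  )
}

#' Emit a toy fixture to disk
#'
#' Writes the complex as PDB together with a parameter sidecar and an
#' expected-values sidecar (both JSON) so regression suites can reload a
#' fixture without re-deriving it.
#'
#' @param complex An `mfcc_complex`.
#' @param params An `mfcc_params`.
#' @param dir Output directory (created if needed).
#' @param epsilon Dielectric used for the expected cross energies.
#' @return Named list of the files written, invisibly.
#' @export
emit_toy_fixture <- function(complex, params, dir, epsilon = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pdb <- file.path(dir, "complex.pdb")
  write_complex_pdb(complex, pdb)
  par_file <- file.path(dir, "parameters.json")
  jsonlite::write_json(
    list(link_atom_policy = params$link_atom_policy, atoms = params$atoms),
    par_file, digits = NA, auto_unbox = TRUE
  )
  exp_file <- file.path(dir, "expected.json")
  jsonlite::write_json(
    list(epsilon = epsilon,
         cross_energies = ground_truth_decomposition(complex, params,
                                                     epsilon)),
    exp_file, digits = NA, auto_unbox = TRUE
  )
  invisible(list(pdb = pdb, parameters = par_file, expected = exp_file))
}
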