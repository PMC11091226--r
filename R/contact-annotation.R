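# Simplified geometric contact classification.
#
# Each reported residue is annotated with its nearest ligand atom (mapped
# through the ligand's label scheme: atom labels, regions i/ii/iii, rings
# A/B/C) and one of five geometric contact classes. The scheme deliberately
# reduces the richer typing of commercial visualization tools (pi-alkyl,
# pi-sigma, pi-sulfur, dipole-dipole, ...) to distance/angle rules.

RESIDUE_RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

#' Contact-classification thresholds
#'
#' Community-standard geometric cutoffs: hydrogen bond at donor-acceptor
#' <= 3.5 A with donor-H-acceptor angle >= 120 degrees (N/O donor;
#' a C-H donor gives a non-conventional hydrogen bond), aromatic at
#' ring-centroid separation <= 5.5 A, hydrophobic at apolar-carbon pair
#' <= 4.5 A; anything else within report range is a polar contact.
#'
#' @param hbond_dist,hbond_angle,aromatic_dist,hydrophobic_dist Cutoffs.
#' @return A named list.
#' @export
contact_params <- function(hbond_dist = 3.5, hbond_angle = 120,
                           aromatic_dist = 5.5, hydrophobic_dist = 4.5) {
  list(hbond_dist = hbond_dist, hbond_angle = hbond_angle,
       aromatic_dist = aromatic_dist, hydrophobic_dist = hydrophobic_dist)
}

#' Read a ligand label map from JSON
#'
#' The file maps ligand atom names to their published labelling scheme:
#' `{"C8": {"label": "ii(C8)", "region": "ii", "ring": "B"}, ...}` with
#' regions i/ii/iii and rings A/B/C (or "none").
#'
#' @param path JSON file path.
#' @return Named list usable as a ligand `label_map`.
#' @export
read_label_map <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

angle_deg <- function(a, b, c) {
  v1 <- a - b
  v2 <- c - b
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

# donor-H pairs: hydrogens with their nearest heavy neighbour within 1.2 A
donor_pairs <- function(atoms) {
  h <- which(atoms$elem == "H")
  heavy <- which(atoms$elem != "H")
  if (length(h) == 0 || length(heavy) == 0) return(NULL)
  d2 <- cross_dist2(atom_xyz(atoms[h, , drop = FALSE]),
                    atom_xyz(atoms[heavy, , drop = FALSE]))
  out <- lapply(seq_along(h), function(i) {
    j <- which.min(d2[i, ])
    if (d2[i, j] <= 1.2^2) c(donor = heavy[j], hydrogen = h[i]) else NULL
  })
  do.call(rbind, out)
}

# apolar carbon: C with no N/O neighbour within 1.65 A
apolar_carbons <- function(atoms) {
  cs <- which(atoms$elem == "C")
  no <- which(atoms$elem %in% c("N", "O"))
  if (length(cs) == 0) return(integer(0))
  if (length(no) == 0) return(cs)
  d2 <- cross_dist2(atom_xyz(atoms[cs, , drop = FALSE]),
                    atom_xyz(atoms[no, , drop = FALSE]))
  cs[apply(d2, 1, min) > 1.65^2]
}

has_hbond <- function(donor_side, acceptor_side, params, donor_elems) {
  dp <- donor_pairs(donor_side)
  if (is.null(dp)) return(FALSE)
  acc <- which(acceptor_side$elem %in% c("N", "O"))
  if (length(acc) == 0) return(FALSE)
  for (r in seq_len(nrow(dp))) {
    d_at <- donor_side[dp[r, "donor"], ]
    if (!(d_at$elem %in% donor_elems)) next
    h_at <- donor_side[dp[r, "hydrogen"], ]
    for (a in acc) {
      a_at <- acceptor_side[a, ]
      dda <- sqrt(sum((c(d_at$x, d_at$y, d_at$z) -
                         c(a_at$x, a_at$y, a_at$z))^2))
      if (dda > params$hbond_dist) next
      ang <- angle_deg(c(d_at$x, d_at$y, d_at$z),
                       c(h_at$x, h_at$y, h_at$z),
                       c(a_at$x, a_at$y, a_at$z))
      if (ang >= params$hbond_angle) return(TRUE)
    }
  }
  FALSE
}

ligand_ring_centroids <- function(ligand) {
  if (is.null(ligand$label_map)) return(NULL)
  rings <- vapply(ligand$label_map, function(e) {
    r <- e$ring
    if (is.null(r)) "none" else as.character(r)
  }, "")
  rings <- rings[rings != "none"]
  if (length(rings) == 0) return(NULL)
  lapply(split(names(rings), rings), function(nm) {
    colMeans(atom_xyz(ligand$atoms[ligand$atoms$name %in% nm, , drop = FALSE]))
  })
}

residue_ring_centroid <- function(res) {
  nm <- RESIDUE_RING_ATOMS[[res$name]]
  if (is.null(nm)) return(NULL)
  ring <- res$atoms[res$atoms$name %in% nm, , drop = FALSE]
  if (nrow(ring) < 3) return(NULL)
  colMeans(atom_xyz(ring))
}

classify_contact <- function(res, ligand, params) {
  ratoms <- res$atoms
  latoms <- ligand$atoms
  if (has_hbond(ratoms, latoms, params, c("N", "O")) ||
      has_hbond(latoms, ratoms, params, c("N", "O"))) {
    return("hydrogen_bond")
  }
  if (has_hbond(ratoms, latoms, params, "C") ||
      has_hbond(latoms, ratoms, params, "C")) {
    return("nonconventional_hbond")
  }
  rc <- residue_ring_centroid(res)
  if (!is.null(rc)) {
    for (lc in ligand_ring_centroids(ligand)) {
      if (sqrt(sum((rc - lc)^2)) <= params$aromatic_dist) {
        return("aromatic")
      }
    }
  }
  ra <- apolar_carbons(ratoms)
  la <- apolar_carbons(latoms)
  if (length(ra) > 0 && length(la) > 0) {
    d2 <- cross_dist2(atom_xyz(ratoms[ra, , drop = FALSE]),
                      atom_xyz(latoms[la, , drop = FALSE]))
    if (min(d2) <= params$hydrophobic_dist^2) return("hydrophobic")
  }
  "polar_contact"
}

#' Annotate residues with their nearest ligand atom and contact class
#'
#' For every residue of an energy table, reports the nearest ligand atom
#' (mapped through the ligand label scheme when available, else the raw atom
#' name), its region and ring, the contact distance, and a simplified
#' geometric contact class. Annotation never alters energies; tables join by
#' residue id.
#'
#' @param complex An `mfcc_complex`.
#' @param residue_ies An `mfcc_residue_ie` table.
#' @param params Thresholds from [contact_params()].
#' @return data.frame with columns `residue`, `nearest_ligand_atom`,
#'   `region`, `ring`, `distance`, `contact_class`.
#' @export
annotate_contacts <- function(complex, residue_ies,
                              params = contact_params()) {
  ids <- vapply(complex$residues, residue_id, "")
  ligand <- complex$ligand
  lmap <- ligand$label_map
  rows <- lapply(residue_ies$residue, function(id) {
    res <- complex$residues[[match(id, ids)]]
    d2 <- cross_dist2(atom_xyz(res$atoms), atom_xyz(ligand$atoms))
    j <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    lat_name <- ligand$atoms$name[j[2]]
    entry <- if (!is.null(lmap)) lmap[[lat_name]] else NULL
    data.frame(
      residue = id,
      nearest_ligand_atom = if (!is.null(entry)) entry$label else lat_name,
      region = if (!is.null(entry)) entry$region else NA_character_,
      ring = if (!is.null(entry) && !is.null(entry$ring)) entry$ring
             else "none",
      distance = sqrt(min(d2)),
      contact_class = classify_contact(res, ligand, params),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(residue = character(0),
                      nearest_ligand_atom = character(0),
                      region = character(0), ring = character(0),
                      distance = numeric(0), contact_class = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
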