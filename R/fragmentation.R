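# MFCC fragmentation: excise each residue with its neighbouring-residue caps
# and saturate cut peptide bonds with link hydrogens.
#
# The cut site is the amide C(=O)-N peptide bond, so each residue keeps its
# own backbone amide. Link hydrogens are placed on the fragment-side atom of
# every cut bond, along the original bond vector, at 1.09 A (C-H) or
# 1.01 A (N-H).

LINK_BOND_LENGTHS <- c(C = 1.09, N = 1.01)
PEPTIDE_BOND_MAX <- 1.8   # A; C-N farther than this is a chain break
SS_BOND_MAX <- 2.5        # A; SG-SG closer than this is a disulfide

#' Place a link hydrogen along a cut bond
#'
#' The hydrogen sits on the unit vector from the parent (fragment-side) atom
#' towards the removed neighbour, at the standard bond length for the parent
#' element (1.09 A for carbon, 1.01 A for nitrogen).
#'
#' @param parent One-row atoms data.frame (the fragment atom whose cut bond is
#'   saturated), or a list with `elem` and `x`,`y`,`z`.
#' @param removed_neighbor_position Numeric length-3 position of the removed
#'   bonded atom.
#' @return A list with `position`, `parent_serial`,
#'   `removed_neighbor_position` and `bond_length`.
#' @export
place_link_hydrogen <- function(parent, removed_neighbor_position) {
  p <- c(parent$x, parent$y, parent$z)
  n <- as.numeric(removed_neighbor_position)
  stopifnot(length(n) == 3)
  v <- n - p
  len <- sqrt(sum(v^2))
  if (len < 1e-9) stop("geometry error: zero-length bond vector for link atom")
  bl <- LINK_BOND_LENGTHS[parent$elem]
  if (is.na(bl)) {
    stop("no link-hydrogen bond length for parent element ", parent$elem)
  }
  list(position = p + bl * v / len,
       parent_serial = parent$serial,
       removed_neighbor_position = n,
       bond_length = unname(bl))
}

link_atom_row <- function(link) {
  new_atoms(serial = NA_integer_, name = "HL", elem = "H",
            x = link$position[1], y = link$position[2], z = link$position[3],
            is_link = TRUE)
}

new_fragment <- function(role, atoms, residues_included, includes_ligand,
                         net_charge, multiplicity = 1L) {
  structure(
    list(role = role, atoms = atoms, residues_included = residues_included,
         includes_ligand = includes_ligand,
         net_charge = as.integer(net_charge),
         multiplicity = as.integer(multiplicity)),
    class = "mfcc_fragment"
  )
}

#' @export
print.mfcc_fragment <- function(x, ...) {
  cat("mfcc_fragment", x$role, "-", nrow(x$atoms), "atoms (",
      sum(x$atoms$is_link), "link ), charge", x$net_charge, "\n")
  invisible(x)
}

find_residue_index <- function(complex, residue_id) {
  ids <- vapply(complex$residues, mfccie::residue_id, "")
  i <- match(residue_id, ids)
  if (is.na(i)) stop("residue not found: ", residue_id)
  i
}

backbone_atom <- function(res, name) {
  j <- match(name, res$atoms$name)
  if (is.na(j)) {
    stop("cannot cap: residue ", residue_id(res), " (", res$name,
         ") lacks backbone atom ", name)
  }
  res$atoms[j, ]
}

# Index of the bonded previous/next residue in the same chain, or NA when the
# residue is a terminus or sits at a chain break (a gap is treated like a
# terminus). Bonding is judged by the C(i-1)-N(i) distance.
chain_neighbor <- function(complex, i, side = c("prev", "next")) {
  side <- match.arg(side)
  j <- if (side == "prev") i - 1L else i + 1L
  if (j < 1 || j > length(complex$residues)) return(NA_integer_)
  a <- complex$residues[[i]]
  b <- complex$residues[[j]]
  if (a$chain != b$chain) return(NA_integer_)
  first <- if (side == "prev") b else a
  second <- if (side == "prev") a else b
  cc <- try(backbone_atom(first, "C"), silent = TRUE)
  nn <- try(backbone_atom(second, "N"), silent = TRUE)
  if (inherits(cc, "try-error") || inherits(nn, "try-error")) {
    return(NA_integer_)
  }
  d <- sqrt(sum((c(cc$x, cc$y, cc$z) - c(nn$x, nn$y, nn$z))^2))
  if (d > PEPTIDE_BOND_MAX) NA_integer_ else j
}

check_cappable <- function(complex, idx) {
  for (i in idx) {
    res <- complex$residues[[i]]
    if (res$nonstandard) {
      stop("cannot cap: nonstandard residue ", residue_id(res),
           " (", res$name, ") lacks a complete backbone")
    }
    if (res$name == "CYS") {
      sg <- res$atoms[res$atoms$name == "SG", , drop = FALSE]
      if (nrow(sg) == 1) {
        for (k in seq_along(complex$residues)) {
          if (k == i) next
          other <- complex$residues[[k]]$atoms
          og <- other[other$name == "SG", , drop = FALSE]
          if (nrow(og) == 1) {
            d <- sqrt(sum((c(sg$x, sg$y, sg$z) - c(og$x, og$y, og$z))^2))
            if (d < SS_BOND_MAX) {
              stop("cannot cap: disulfide-bonded cysteine ", residue_id(res))
            }
          }
        }
      }
    }
  }
  invisible(TRUE)
}

#' Excise a residue with its neighbouring-residue caps (CRC fragment)
#'
#' Returns the capped tripeptide fragment for residue i: all atoms of residues
#' i-1, i, i+1 plus one link hydrogen per outer cut peptide bond. At a chain
#' terminus (or a crystal gap, treated the same way) the missing cap is simply
#' omitted and the native terminal group retained.
#'
#' @param complex An `mfcc_complex`.
#' @param residue_id Residue identifier string (see [residue_id()]).
#' @return An `mfcc_fragment` with role `"CRC"`.
#' @export
excise_capped_tripeptide <- function(complex, residue_id) {
  i <- find_residue_index(complex, residue_id)
  prev <- chain_neighbor(complex, i, "prev")
  nxt <- chain_neighbor(complex, i, "next")
  members <- c(prev, i, nxt)
  members <- members[!is.na(members)]
  check_cappable(complex, members)

  atoms <- do.call(rbind, lapply(complex$residues[members], `[[`, "atoms"))
  links <- list()
  if (!is.na(prev)) {
    before <- chain_neighbor(complex, prev, "prev")
    if (!is.na(before)) {
      cpos <- backbone_atom(complex$residues[[before]], "C")
      links <- c(links, list(place_link_hydrogen(
        backbone_atom(complex$residues[[prev]], "N"),
        c(cpos$x, cpos$y, cpos$z)
      )))
    }
  }
  if (!is.na(nxt)) {
    after <- chain_neighbor(complex, nxt, "next")
    if (!is.na(after)) {
      npos <- backbone_atom(complex$residues[[after]], "N")
      links <- c(links, list(place_link_hydrogen(
        backbone_atom(complex$residues[[nxt]], "C"),
        c(npos$x, npos$y, npos$z)
      )))
    }
  }
  atoms <- rbind(atoms, do.call(rbind, lapply(links, link_atom_row)))
  charge <- sum(vapply(complex$residues[members], `[[`, 0L, "formal_charge"))
  new_fragment("CRC", atoms,
               vapply(complex$residues[members], mfccie::residue_id, ""),
               includes_ligand = FALSE, net_charge = charge)
}

#' Excise the caps only (CC fragment)
#'
#' Returns the caps-only fragment for residue i: atoms of residues i-1 and
#' i+1, with link hydrogens at the outer cut bonds and at the two bonds cut to
#' the removed central residue. Cap coordinates are identical to those in the
#' corresponding CRC fragment; no atom is re-positioned.
#'
#' @inheritParams excise_capped_tripeptide
#' @return An `mfcc_fragment` with role `"CC"`.
#' @export
excise_caps_only <- function(complex, residue_id) {
  i <- find_residue_index(complex, residue_id)
  prev <- chain_neighbor(complex, i, "prev")
  nxt <- chain_neighbor(complex, i, "next")
  members <- c(prev, nxt)
  members <- members[!is.na(members)]
  if (length(members) == 0) {
    stop("cannot cap: residue ", residue_id, " has no bonded neighbours")
  }
  check_cappable(complex, c(members, i))
  central <- complex$residues[[i]]

  atoms <- do.call(rbind, lapply(complex$residues[members], `[[`, "atoms"))
  links <- list()
  if (!is.na(prev)) {
    before <- chain_neighbor(complex, prev, "prev")
    if (!is.na(before)) {
      cpos <- backbone_atom(complex$residues[[before]], "C")
      links <- c(links, list(place_link_hydrogen(
        backbone_atom(complex$residues[[prev]], "N"),
        c(cpos$x, cpos$y, cpos$z)
      )))
    }
    # inner cut: C(i-1) towards the removed N(i)
    npos <- backbone_atom(central, "N")
    links <- c(links, list(place_link_hydrogen(
      backbone_atom(complex$residues[[prev]], "C"),
      c(npos$x, npos$y, npos$z)
    )))
  }
  if (!is.na(nxt)) {
    # inner cut: N(i+1) towards the removed C(i)
    cpos <- backbone_atom(central, "C")
    links <- c(links, list(place_link_hydrogen(
      backbone_atom(complex$residues[[nxt]], "N"),
      c(cpos$x, cpos$y, cpos$z)
    )))
    after <- chain_neighbor(complex, nxt, "next")
    if (!is.na(after)) {
      npos <- backbone_atom(complex$residues[[after]], "N")
      links <- c(links, list(place_link_hydrogen(
        backbone_atom(complex$residues[[nxt]], "C"),
        c(npos$x, npos$y, npos$z)
      )))
    }
  }
  atoms <- rbind(atoms, do.call(rbind, lapply(links, link_atom_row)))
  charge <- sum(vapply(complex$residues[members], `[[`, 0L, "formal_charge"))
  new_fragment("CC", atoms,
               vapply(complex$residues[members], mfccie::residue_id, ""),
               includes_ligand = FALSE, net_charge = charge)
}

with_ligand <- function(fragment, ligand, role) {
  atoms <- rbind(fragment$atoms, ligand$atoms)
  new_fragment(role, atoms, fragment$residues_included,
               includes_ligand = TRUE,
               net_charge = fragment$net_charge + ligand$formal_charge,
               multiplicity = fragment$multiplicity)
}

#' Build the four-fragment quartet for one residue
#'
#' Assembles the four capped systems whose energies combine into the
#' residue-ligand interaction energy: binder+capped-tripeptide (BID_CRC),
#' capped tripeptide (CRC), binder+caps (BID_CC) and caps (CC). Ligand and
#' cap coordinates are bitwise-identical across roles; fragmentation never
#' moves an original atom.
#'
#' @inheritParams excise_capped_tripeptide
#' @return A list of class `mfcc_quartet` with elements `BID_CRC`, `CRC`,
#'   `BID_CC`, `CC` and attribute `residue_id`.
#' @export
build_quartet <- function(complex, residue_id) {
  crc <- excise_capped_tripeptide(complex, residue_id)
  cc <- excise_caps_only(complex, residue_id)
  out <- list(
    BID_CRC = with_ligand(crc, complex$ligand, "BID_CRC"),
    CRC = crc,
    BID_CC = with_ligand(cc, complex$ligand, "BID_CC"),
    CC = cc
  )
  attr(out, "residue_id") <- residue_id
  class(out) <- "mfcc_quartet"
  out
}

#' Export a fragment as XYZ
#'
#' Writes the fragment geometry in XYZ format; the comment line carries role,
#' residue id, net charge and multiplicity so external jobs can be
#' reconstructed from the file alone.
#'
#' @param fragment An `mfcc_fragment`.
#' @param file Output path (or `NULL` to return the text).
#' @param residue_id Optional residue id for the comment line.
#' @return The XYZ text, invisibly.
#' @export
write_fragment_xyz <- function(fragment, file = NULL, residue_id = "") {
  comment <- sprintf("role=%s residue=%s charge=%d multiplicity=%d",
                     fragment$role, residue_id, fragment$net_charge,
                     fragment$multiplicity)
  write_xyz(fragment$atoms, file, comment)
}
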