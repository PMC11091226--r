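# Internal structural model
#
# Atoms are plain data.frames with columns:
#   serial (integer), name (chr), elem (chr), x, y, z (numeric, Angstrom),
#   is_link (logical; TRUE only for added cap hydrogens)
# A residue is a list(chain, number, icode, name, atoms, formal_charge,
#   n_terminal, c_terminal, nonstandard); a complex is a list(residues,
#   ligand, metadata) of class "mfcc_complex".

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O", "TIP", "TIP3", "SOL")

# Formal charges assumed for standard residues at neutral pH; user-overridable.
STANDARD_CHARGES <- c(ASP = -1L, GLU = -1L, LYS = 1L, ARG = 1L, HIS = 0L)

new_atoms <- function(serial, name, elem, x, y, z, is_link = FALSE) {
  data.frame(
    serial = as.integer(serial), name = as.character(name),
    elem = as.character(elem), x = as.numeric(x), y = as.numeric(y),
    z = as.numeric(z), is_link = rep_len(as.logical(is_link), length(name)),
    stringsAsFactors = FALSE
  )
}

atom_xyz <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

#' Residue identifier string
#'
#' Builds the canonical `chain:numbericode` identifier (e.g. `"A:179"`) used
#' to join residues across energy, scan and annotation tables.
#'
#' @param residue A residue record from an `mfcc_complex`.
#' @return A single character string.
#' @export
residue_id <- function(residue) {
  paste0(residue$chain, ":", residue$number, residue$icode)
}

new_residue <- function(chain, number, icode, name, atoms, formal_charge = 0L,
                        n_terminal = FALSE, c_terminal = FALSE) {
  stopifnot(nrow(atoms) > 0)
  backbone <- c("N", "CA", "C") %in% atoms$name
  list(
    chain = as.character(chain), number = as.integer(number),
    icode = as.character(icode), name = as.character(name), atoms = atoms,
    formal_charge = as.integer(formal_charge),
    n_terminal = n_terminal, c_terminal = c_terminal,
    nonstandard = !all(backbone)
  )
}

new_ligand <- function(name, atoms, formal_charge = 0L, label_map = NULL) {
  stopifnot(nrow(atoms) > 0)
  if (!is.null(label_map)) {
    unknown <- setdiff(names(label_map), atoms$name)
    if (length(unknown) > 0) {
      stop("label_map keys not present among ligand atoms: ",
           paste(unknown, collapse = ", "))
    }
  }
  list(name = name, atoms = atoms, formal_charge = as.integer(formal_charge),
       label_map = label_map)
}

new_complex <- function(residues, ligand, metadata = list()) {
  structure(list(residues = residues, ligand = ligand, metadata = metadata),
            class = "mfcc_complex")
}

#' @export
print.mfcc_complex <- function(x, ...) {
  cat("mfcc_complex:", length(x$residues), "residues; ligand",
      x$ligand$name, "with", nrow(x$ligand$atoms), "atoms\n")
  invisible(x)
}

guess_element <- function(name) {
  core <- sub("^[0-9']*", "", name)
  two <- toupper(substr(core, 1, 2))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"),
         substr(core, 1, 2), substr(core, 1, 1))
}

# Pre-scan PDB text so malformed coordinate fields are reported with their
# line number (bio3d's own error does not carry it).
check_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in idx) {
    coords <- suppressWarnings(as.numeric(c(
      substr(lines[i], 31, 38), substr(lines[i], 39, 46),
      substr(lines[i], 47, 54)
    )))
    if (anyNA(coords)) {
      stop("malformed ATOM/HETATM record at line ", i, ": ", lines[i])
    }
  }
  invisible(TRUE)
}

#' Read a protein-ligand complex from a PDB file
#'
#' Parses a PDB source (first MODEL only), resolves alternate locations to the
#' highest-occupancy conformer (ties to altloc "A"), drops waters and
#' unrequested heteroatoms, and normalizes the result into the internal
#' complex model. Author residue numbering is preserved so residue names such
#' as Phe179 match published numbering.
#'
#' @param pdb_source Path to a PDB file, or a character vector of PDB lines.
#' @param ligand_resname Residue name of the ligand (exactly one copy must
#'   match, unless `ligand_chain` disambiguates).
#' @param keep_het Character vector of additional HETATM residue names to
#'   retain as (nonstandard) residues. Waters and ions are dropped otherwise.
#' @param ligand_chain Optional chain id selecting among multiple ligand
#'   copies.
#' @param charge_table Named integer vector of formal charges by residue name.
#' @param ligand_formal_charge Integer formal charge of the ligand (default 0,
#'   i.e. a neutral ligand).
#' @param label_map Optional ligand label map (see [read_label_map()]).
#' @return An object of class `mfcc_complex`.
#' @export
read_complex <- function(pdb_source, ligand_resname, keep_het = character(),
                         ligand_chain = NULL,
                         charge_table = STANDARD_CHARGES,
                         ligand_formal_charge = 0L, label_map = NULL) {
  if (length(pdb_source) > 1 || grepl("\n", pdb_source[1], fixed = TRUE)) {
    lines <- if (length(pdb_source) > 1) pdb_source else
      strsplit(pdb_source, "\n", fixed = TRUE)[[1]]
    src <- tempfile(fileext = ".pdb")
    on.exit(unlink(src), add = TRUE)
    writeLines(lines, src)
    source_id <- "<text>"
  } else {
    src <- pdb_source
    if (!file.exists(src)) stop("no such file: ", src)
    lines <- readLines(src, warn = FALSE)
    source_id <- basename(src)
  }
  check_pdb_lines(lines)
  pdb <- withCallingHandlers(
    bio3d::read.pdb(src, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    warning = function(w) {
      # serials are reassigned below, so duplicate ids are not a problem
      if (grepl("duplicated element numbers", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # altloc: keep highest occupancy per (chain, resno, insert, elety); ties to
  # the alphabetically first altloc (i.e. "A").
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, ]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$resid,
                             at$elety, sep = "|")), ]
  at <- at[order(as.integer(rownames(at))), ]
  if (anyDuplicated(at$eleno)) at$eleno <- seq_len(nrow(at))

  elem <- ifelse(is.na(at$elesy) | at$elesy == "", guess_element(at$elety),
                 at$elesy)

  is_lig <- at$resid == ligand_resname
  if (!any(is_lig)) stop("ligand not found: no residue named ", ligand_resname)
  lig_at <- at[is_lig, ]
  lig_copies <- unique(paste(lig_at$chain, lig_at$resno, lig_at$insert))
  if (length(lig_copies) > 1) {
    if (is.null(ligand_chain)) {
      stop("ambiguous ligand: ", length(lig_copies), " copies of ",
           ligand_resname, "; supply ligand_chain")
    }
    lig_at <- lig_at[lig_at$chain == ligand_chain, ]
    lig_copies <- unique(paste(lig_at$chain, lig_at$resno, lig_at$insert))
    if (length(lig_copies) != 1) {
      stop("ligand not found in chain ", ligand_chain)
    }
  }
  lig_idx <- rownames(at) %in% rownames(lig_at)

  drop <- !lig_idx & !(at$resid %in% keep_het) &
    (at$resid %in% WATER_NAMES | at$type == "HETATM")
  res_at <- at[!drop & !lig_idx, ]
  res_elem <- elem[!drop & !lig_idx]

  rkey <- paste(res_at$chain, res_at$resno, res_at$insert, sep = "|")
  groups <- split(seq_len(nrow(res_at)), factor(rkey, levels = unique(rkey)))
  residues <- lapply(groups, function(ii) {
    r <- res_at[ii, ]
    q <- charge_table[r$resid[1]]
    new_residue(
      chain = r$chain[1], number = r$resno[1], icode = r$insert[1],
      name = r$resid[1],
      atoms = new_atoms(r$eleno, r$elety, res_elem[ii], r$x, r$y, r$z),
      formal_charge = if (is.na(q)) 0L else q
    )
  })
  # order by chain, then author number, then icode; mark termini
  ord <- order(vapply(residues, `[[`, "", "chain"),
               vapply(residues, `[[`, 0L, "number"),
               vapply(residues, `[[`, "", "icode"))
  residues <- residues[ord]
  chains <- vapply(residues, `[[`, "", "chain")
  for (i in seq_along(residues)) {
    residues[[i]]$n_terminal <- i == 1 || chains[i] != chains[i - 1]
    residues[[i]]$c_terminal <- i == length(residues) ||
      chains[i] != chains[min(i + 1, length(residues))]
  }
  names(residues) <- NULL

  lelem <- elem[rownames(at) %in% rownames(lig_at)]
  ligand <- new_ligand(
    name = ligand_resname,
    atoms = new_atoms(lig_at$eleno, lig_at$elety, lelem,
                      lig_at$x, lig_at$y, lig_at$z),
    formal_charge = ligand_formal_charge, label_map = label_map
  )

  new_complex(residues, ligand,
              metadata = list(source = source_id,
                              ligand_resname = ligand_resname))
}

#' Minimum residue-ligand distance
#'
#' Minimum Euclidean distance over all atom pairs between a residue and the
#' ligand, optionally restricted to heavy atoms (the default, which makes the
#' pocket definition robust to hydrogen placement).
#'
#' @param residue A residue record.
#' @param ligand A ligand record (or any list with an `atoms` data.frame).
#' @param heavy_only Exclude hydrogens from both sides (default `TRUE`).
#' @return Distance in Angstrom.
#' @export
min_distance <- function(residue, ligand, heavy_only = TRUE) {
  a <- residue$atoms
  b <- ligand$atoms
  if (heavy_only) {
    a <- a[a$elem != "H", , drop = FALSE]
    b <- b[b$elem != "H", , drop = FALSE]
  }
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty atom set in min_distance")
  sqrt(min(cross_dist2(atom_xyz(a), atom_xyz(b))))
}

# squared distances between two coordinate matrices (rows = atoms)
cross_dist2 <- function(xa, xb) {
  outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
}

#' Select binding-pocket residues within a sphere radius
#'
#' Returns the residues whose minimum (by default heavy-atom) distance to the
#' ligand is at most `r`, in chain order. Selections are nested: a smaller
#' radius always yields a subset of a larger one.
#'
#' @param complex An `mfcc_complex`.
#' @param r Pocket radius in Angstrom (`r >= 0`).
#' @param heavy_only Passed to [min_distance()].
#' @return List of residue records (possibly empty), with the matched
#'   distances in attribute `"min_distance"`.
#' @export
select_pocket <- function(complex, r, heavy_only = TRUE) {
  stopifnot(r >= 0)
  d <- vapply(complex$residues, min_distance, 0, ligand = complex$ligand,
              heavy_only = heavy_only)
  keep <- which(d <= r)
  out <- complex$residues[keep]
  attr(out, "min_distance") <- d[keep]
  attr(out, "index") <- keep
  out
}

#' Write a complex back to PDB
#'
#' Writes the normalized complex as PDB (ATOM records for residues, HETATM for
#' the ligand) at standard 3-decimal coordinate precision.
#'
#' @param complex An `mfcc_complex`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_complex_pdb <- function(complex, file) {
  res <- complex$residues
  n_at <- vapply(res, function(r) nrow(r$atoms), 0L)
  atoms <- do.call(rbind, lapply(res, `[[`, "atoms"))
  lig <- complex$ligand$atoms
  all_at <- rbind(atoms, lig)
  type <- c(rep("ATOM", nrow(atoms)), rep("HETATM", nrow(lig)))
  resno <- c(rep(vapply(res, `[[`, 0L, "number"), n_at),
             rep(1L, nrow(lig)))
  resid <- c(rep(vapply(res, `[[`, "", "name"), n_at),
             rep(complex$ligand$name, nrow(lig)))
  chain <- c(rep(vapply(res, `[[`, "", "chain"), n_at),
             rep("X", nrow(lig)))
  insert <- c(rep(vapply(res, `[[`, "", "icode"), n_at),
              rep("", nrow(lig)))
  insert[insert == ""] <- " "
  bio3d::write.pdb(
    pdb = NULL, file = file, xyz = as.vector(t(atom_xyz(all_at))),
    type = type, resno = resno, resid = resid, chain = chain,
    insert = insert, eleno = seq_len(nrow(all_at)), elety = all_at$name,
    elesy = all_at$elem
  )
  invisible(file)
}

#' Write atoms as XYZ
#'
#' Plain XYZ export (atom count, comment line, element + coordinates with six
#' decimals) for fragments or whole structures.
#'
#' @param x An atoms data.frame, fragment, residue or ligand.
#' @param file Output path (or `NULL` to return the text).
#' @param comment Comment line content.
#' @return The XYZ text, invisibly (visibly when `file` is `NULL`).
#' @export
write_xyz <- function(x, file = NULL, comment = "") {
  atoms <- as_atoms(x)
  body <- sprintf("%-2s %12.6f %12.6f %12.6f",
                  atoms$elem, atoms$x, atoms$y, atoms$z)
  txt <- paste(c(nrow(atoms), comment, body), collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# Coerce fragments / residues / ligands / data.frames to an atoms data.frame.
as_atoms <- function(x) {
  if (is.data.frame(x)) return(x)
  if (!is.null(x$atoms)) return(x$atoms)
  stop("cannot interpret object as atoms")
}
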