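# Energy evaluator contract.
#
# Two backends satisfy it: a strictly pairwise-additive classical backend
# (Coulomb with dielectric screening + Lennard-Jones), which makes the MFCC
# cap algebra exactly verifiable at the desk, and an external
# quantum-chemistry interface (deck writer + output parser) for production
# DFT runs. Both return kcal/mol.

COULOMB_K <- 332.0636        # kcal A / (mol e^2)
HARTREE_KCAL <- 627.509474   # kcal/mol per hartree

# Default Lennard-Jones parameters for a "parameterized" link hydrogen.
DEFAULT_LINK_PARAMS <- list(q = 0.10, sigma = 2.47, epsilon_lj = 0.0157)

#' Construct a classical parameter set
#'
#' Per-atom partial charges and Lennard-Jones parameters keyed by atom serial,
#' plus the link-atom policy. Under the `"ghost"` policy (default) link
#' hydrogens carry zero charge and zero LJ well depth, which makes the MFCC
#' decomposition exactly equal to the direct ligand-residue cross energy under
#' pairwise additivity; `"parameterized"` gives them small real parameters.
#'
#' @param atoms data.frame with columns `serial`, `q` (e), `sigma` (Angstrom),
#'   `epsilon_lj` (kcal/mol).
#' @param link_atom_policy `"ghost"` or `"parameterized"`.
#' @param link_params List with `q`, `sigma`, `epsilon_lj` used when
#'   `link_atom_policy = "parameterized"`.
#' @return An object of class `mfcc_params`.
#' @export
parameter_set <- function(atoms, link_atom_policy = c("ghost", "parameterized"),
                          link_params = DEFAULT_LINK_PARAMS) {
  link_atom_policy <- match.arg(link_atom_policy)
  stopifnot(all(c("serial", "q", "sigma", "epsilon_lj") %in% names(atoms)),
            !anyDuplicated(atoms$serial))
  structure(list(atoms = atoms, link_atom_policy = link_atom_policy,
                 link_params = link_params),
            class = "mfcc_params")
}

# Resolve q / sigma / epsilon_lj for every atom of a fragment or atom table.
atom_parameters <- function(atoms, params) {
  q <- numeric(nrow(atoms))
  sigma <- rep(1, nrow(atoms))
  eps <- numeric(nrow(atoms))
  real <- !atoms$is_link
  j <- match(atoms$serial[real], params$atoms$serial)
  if (anyNA(j)) {
    bad <- which(real)[is.na(j)][1]
    stop("missing parameters for atom serial ", atoms$serial[bad],
         " (", atoms$name[bad], ")")
  }
  q[real] <- params$atoms$q[j]
  sigma[real] <- params$atoms$sigma[j]
  eps[real] <- params$atoms$epsilon_lj[j]
  if (params$link_atom_policy == "parameterized" && any(!real)) {
    q[!real] <- params$link_params$q
    sigma[!real] <- params$link_params$sigma
    eps[!real] <- params$link_params$epsilon_lj
  }
  list(q = q, sigma = sigma, eps = eps)
}

pair_terms <- function(qq, eij, sij, r, epsilon) {
  coul <- COULOMB_K * qq / (epsilon * r)
  sr6 <- (sij / r)^6
  lj <- 4 * eij * (sr6^2 - sr6)
  list(coulomb = sum(coul), lj = sum(lj))
}

#' Classical pairwise energy of a fragment
#'
#' Sum over all unordered atom pairs of screened Coulomb
#' (332.0636 q_i q_j / (epsilon r_ij)) plus Lennard-Jones
#' (4 e_ij ((s_ij/r)^12 - (s_ij/r)^6)) with Lorentz-Berthelot combining
#' (arithmetic-mean sigma, geometric-mean epsilon). Strictly additive and
#' deterministic; serves as the desk-scale stand-in for the external quantum
#' backend and as the oracle for the MFCC algebra.
#'
#' @param fragment An `mfcc_fragment` or atoms data.frame.
#' @param params An `mfcc_params`.
#' @param epsilon Medium dielectric constant (> 0).
#' @param components Return a list with `coulomb`, `lj`, `total` instead of
#'   the total only.
#' @return Energy in kcal/mol (or a component list).
#' @export
classical_energy <- function(fragment, params, epsilon = 1,
                             components = FALSE) {
  atoms <- as_atoms(fragment)
  stopifnot(epsilon > 0)
  n <- nrow(atoms)
  if (n < 2) {
    return(if (components) list(coulomb = 0, lj = 0, total = 0) else 0)
  }
  p <- atom_parameters(atoms, params)
  d <- as.matrix(stats::dist(atom_xyz(atoms)))
  iu <- upper.tri(d)
  r <- d[iu]
  if (any(r < 1e-9)) stop("singular geometry: coincident atoms in fragment")
  qq <- outer(p$q, p$q)[iu]
  sij <- outer(p$sigma, p$sigma, "+")[iu] / 2
  eij <- sqrt(outer(p$eps, p$eps))[iu]
  terms <- pair_terms(qq, eij, sij, r, epsilon)
  if (components) {
    c(terms, list(total = terms$coulomb + terms$lj))
  } else {
    terms$coulomb + terms$lj
  }
}

#' Cross interaction energy between two disjoint atom sets
#'
#' Same pair formula as [classical_energy()] summed over A x B pairs only.
#' This is the brute-force oracle against which the MFCC decomposition is
#' verified: under pairwise additivity,
#' `E(A u B) - E(A) - E(B) = pair_cross_energy(A, B)` exactly.
#'
#' @param atoms_a,atoms_b Atom tables (or fragments / residues / ligands).
#' @inheritParams classical_energy
#' @return Energy in kcal/mol (or a component list).
#' @export
pair_cross_energy <- function(atoms_a, atoms_b, params, epsilon = 1,
                              components = FALSE) {
  a <- as_atoms(atoms_a)
  b <- as_atoms(atoms_b)
  stopifnot(epsilon > 0)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(if (components) list(coulomb = 0, lj = 0, total = 0) else 0)
  }
  pa <- atom_parameters(a, params)
  pb <- atom_parameters(b, params)
  r2 <- cross_dist2(atom_xyz(a), atom_xyz(b))
  r <- sqrt(pmax(r2, 0))
  if (any(r < 1e-9)) stop("singular geometry: coincident atoms across sets")
  qq <- outer(pa$q, pb$q)
  sij <- outer(pa$sigma, pb$sigma, "+") / 2
  eij <- sqrt(outer(pa$eps, pb$eps))
  terms <- pair_terms(qq, eij, sij, r, epsilon)
  if (components) {
    c(terms, list(total = terms$coulomb + terms$lj))
  } else {
    terms$coulomb + terms$lj
  }
}

# Exact 32-bit FNV-1a over a string, computed in doubles (all intermediates
# stay below 2^53, so the arithmetic is exact).
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- (h - lo) + bitwXor(as.integer(lo), b)
    h0 <- h %% 65536
    h1 <- (h - h0) / 65536
    h <- ((h0 * 16777619) + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

fragment_content <- function(fragment) {
  paste(
    fragment$role, fragment$net_charge, fragment$multiplicity,
    paste(sprintf("%s:%.6f,%.6f,%.6f", fragment$atoms$elem, fragment$atoms$x,
                  fragment$atoms$y, fragment$atoms$z), collapse = ";"),
    sep = "|"
  )
}

#' Content hash of a fragment
#'
#' Deterministic id over role, net charge, multiplicity and atom geometry
#' (elements + coordinates at 1e-6 A); identical fragments always map to the
#' same key, which drives deck deduplication and the energy cache.
#'
#' @param fragment An `mfcc_fragment`.
#' @return An 8-hex-digit string.
#' @export
fragment_key <- function(fragment) {
  fnv1a32(fragment_content(fragment))
}

#' Classical energy evaluator with caching
#'
#' Wraps [classical_energy()] into the evaluator contract used by
#' [decompose()]: a function `fragment -> energy` at a fixed dielectric.
#' Identical fragment content never triggers a second evaluation; use
#' [evaluator_stats()] to inspect cache behaviour.
#'
#' @inheritParams classical_energy
#' @return A function of class `mfcc_evaluator` with attribute `epsilon`.
#' @export
classical_evaluator <- function(params, epsilon) {
  cache <- new.env(parent = emptyenv())
  stats <- new.env(parent = emptyenv())
  stats$evaluations <- 0L
  stats$cache_hits <- 0L
  f <- function(fragment) {
    key <- fragment_content(fragment)
    if (!is.null(cache[[key]])) {
      stats$cache_hits <- stats$cache_hits + 1L
      return(cache[[key]])
    }
    e <- classical_energy(fragment, params, epsilon)
    stats$evaluations <- stats$evaluations + 1L
    cache[[key]] <- e
    e
  }
  structure(f, class = c("mfcc_evaluator", "function"),
            epsilon = epsilon, source = "classical", stats = stats)
}

#' Cache statistics of an evaluator
#'
#' @param evaluator An `mfcc_evaluator`.
#' @return List with `evaluations` (fresh computations) and `cache_hits`.
#' @export
evaluator_stats <- function(evaluator) {
  s <- attr(evaluator, "stats")
  list(evaluations = s$evaluations, cache_hits = s$cache_hits)
}

#' Specify an external quantum-chemistry job
#'
#' Captures the settings of one fragment energy evaluation for an external
#' DFT engine: method and basis labels (defaults B97D / 6-311+G(d,p)), a
#' conductor-like continuum solvent (CPCM) with its dielectric constant,
#' charge, multiplicity and geometry. The package never computes DFT itself;
#' it only writes decks and harvests energies.
#'
#' @param fragment An `mfcc_fragment` supplying geometry, charge and
#'   multiplicity.
#' @param epsilon Dielectric constant of the continuum (> 0).
#' @param method,basis,solvent_model Level-of-theory labels.
#' @param title Deck title line (defaults to the fragment key).
#' @return An object of class `mfcc_qm_job`.
#' @export
qm_job_spec <- function(fragment, epsilon, method = "B97D",
                        basis = "6-311+G(d,p)", solvent_model = "CPCM",
                        title = NULL) {
  stopifnot(epsilon > 0, fragment$multiplicity >= 1)
  if (is.null(title)) {
    title <- paste0("fragment ", fragment_key(fragment), " role ",
                    fragment$role)
  }
  structure(
    list(method = method, basis = basis, solvent_model = solvent_model,
         epsilon = epsilon, charge = fragment$net_charge,
         multiplicity = fragment$multiplicity,
         atoms = fragment$atoms, title = title),
    class = "mfcc_qm_job"
  )
}

#' Write a quantum-chemistry input deck
#'
#' Emits a deterministic Gaussian-style deck: route line with method, basis
#' and continuum-solvent dielectric, title, "charge multiplicity" line and
#' element + Angstrom coordinates at six decimals. Identical specs produce
#' byte-identical output.
#'
#' @param spec An `mfcc_qm_job`.
#' @param destination Output path, or `NULL` to return the text.
#' @return Deck text (invisibly when written to a file).
#' @export
write_qm_input <- function(spec, destination = NULL) {
  route <- sprintf("# %s/%s SCRF=(%s,eps=%s)", spec$method, spec$basis,
                   spec$solvent_model, format(spec$epsilon))
  coords <- sprintf(" %-2s %12.6f %12.6f %12.6f", spec$atoms$elem,
                    spec$atoms$x, spec$atoms$y, spec$atoms$z)
  deck <- paste(c(route, "", spec$title, "",
                  sprintf("%d %d", spec$charge, spec$multiplicity),
                  coords, ""), collapse = "\n")
  if (is.null(destination)) return(deck)
  writeLines(deck, destination)
  invisible(deck)
}

#' Parse a quantum-chemistry output file
#'
#' Scans plain-text output for the last final-energy line -- either a
#' Gaussian-style `SCF Done: E(...) = <hartree>` or a generic
#' `FINAL ENERGY = <hartree>` -- converts it to kcal/mol, and flags
#' convergence from the normal-termination marker. Unconverged results are
#' excluded from decompositions.
#'
#' @param source Path to the output file, or a character vector of lines.
#' @param termination_marker Regular expression marking normal termination.
#' @return List with `energy` (kcal/mol), `energy_hartree`, `converged` and
#'   `source = "qm_parsed"`.
#' @export
parse_qm_output <- function(source,
                            termination_marker = "Normal termination") {
  lines <- if (length(source) == 1 && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    source
  }
  pat <- paste0(
    "(SCF Done:\\s*E\\([^)]*\\)\\s*=|FINAL ENERGY\\s*=)\\s*",
    "(-?[0-9]+\\.[0-9]+([DdEe][+-]?[0-9]+)?)"
  )
  hits <- regmatches(lines, regexec(pat, lines))
  vals <- vapply(hits, function(m) {
    if (length(m) < 3) NA_character_ else m[3]
  }, "")
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("no energy found in quantum-chemistry output")
  hartree <- as.numeric(sub("[Dd]", "E", vals[length(vals)]))
  list(energy = hartree * HARTREE_KCAL, energy_hartree = hartree,
       converged = any(grepl(termination_marker, lines)),
       source = "qm_parsed")
}

#' Evaluator backed by harvested quantum-chemistry outputs
#'
#' Builds an evaluator from a run manifest mapping fragment keys to parsed
#' output files. A missing or unconverged entry makes the evaluator raise an
#' error for that fragment, which [decompose()] records as a failed residue
#' without aborting the run.
#'
#' @param manifest data.frame with columns `fragment_key` and `output` (file
#'   paths), or a named character vector of paths keyed by fragment key.
#' @param epsilon Dielectric the jobs were run at (stored for reporting).
#' @return A function of class `mfcc_evaluator`.
#' @export
harvest_evaluator <- function(manifest, epsilon = NA_real_) {
  if (!is.data.frame(manifest)) {
    manifest <- data.frame(fragment_key = names(manifest),
                           output = unname(manifest),
                           stringsAsFactors = FALSE)
  }
  f <- function(fragment) {
    key <- fragment_key(fragment)
    j <- match(key, manifest$fragment_key)
    if (is.na(j)) stop("no harvested energy for fragment ", key)
    res <- parse_qm_output(manifest$output[j])
    if (!res$converged) stop("unconverged quantum job for fragment ", key)
    res$energy
  }
  structure(f, class = c("mfcc_evaluator", "function"),
            epsilon = epsilon, source = "qm_parsed",
            stats = local({
              e <- new.env(parent = emptyenv())
              e$evaluations <- 0L
              e$cache_hits <- 0L
              e
            }))
}
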