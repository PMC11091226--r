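# Per-residue interaction energies and the pocket-radius convergence scan.
#
# The residue-ligand interaction energy is assembled from the four capped
# fragment energies as
#   IE = E(BID+CRC) - E(CRC) - E(BID+CC) + E(CC)
# (negative = attractive, positive = repulsive). The scan sums these over
# nested pocket spheres on the r = R/2 grid and declares convergence when the
# cumulative energy changes by no more than 10% between successive radii.

IE_NEUTRAL_TOL <- 1e-6  # kcal/mol below which a residue is called neutral

#' Combine the four fragment energies into one interaction energy
#'
#' @param e_bid_crc,e_crc,e_bid_cc,e_cc Energies (kcal/mol) of the
#'   binder+capped-tripeptide, capped-tripeptide, binder+caps and caps
#'   fragments, in that order. Vectorized.
#' @return `e_bid_crc - e_crc - e_bid_cc + e_cc`, in kcal/mol.
#' @export
residue_interaction_energy <- function(e_bid_crc, e_crc, e_bid_cc, e_cc) {
  vals <- c(e_bid_crc, e_crc, e_bid_cc, e_cc)
  if (!all(is.finite(vals))) {
    stop("non-finite fragment energy in interaction-energy combination")
  }
  e_bid_crc - e_crc - e_bid_cc + e_cc
}

classify_ie <- function(ie, tol = IE_NEUTRAL_TOL) {
  ifelse(!is.finite(ie), NA_character_,
         ifelse(abs(ie) < tol, "neutral",
                ifelse(ie > 0, "repulsive", "attractive")))
}

#' Per-residue MFCC decomposition of a complex
#'
#' Builds the fragment quartet for every residue of the `r_max` pocket,
#' evaluates the four energies with the supplied backend, and combines them
#' into per-residue interaction energies with attractive/repulsive/neutral
#' classification. A residue whose fragments fail to evaluate is reported as
#' failed and the run continues.
#'
#' @param complex An `mfcc_complex`.
#' @param evaluator An evaluator function `fragment -> kcal/mol`, e.g. from
#'   [classical_evaluator()] or [harvest_evaluator()].
#' @param r_max Pocket radius in Angstrom defining the residues decomposed.
#' @param heavy_only Pocket-distance convention (see [min_distance()]).
#' @return data.frame of class `mfcc_residue_ie` with one row per pocket
#'   residue: identity columns, `min_distance`, the four term energies, `ie`,
#'   `classification` and `failed`; dielectric in attribute `"epsilon"`.
#' @export
decompose <- function(complex, evaluator, r_max = 10, heavy_only = TRUE) {
  pocket <- select_pocket(complex, r_max, heavy_only = heavy_only)
  dists <- attr(pocket, "min_distance")
  n <- length(pocket)
  out <- data.frame(
    residue = character(n), chain = character(n), number = integer(n),
    icode = character(n), name = character(n), min_distance = numeric(n),
    e_bid_crc = NA_real_, e_crc = NA_real_, e_bid_cc = NA_real_,
    e_cc = NA_real_, ie = NA_real_, classification = NA_character_,
    failed = FALSE, stringsAsFactors = FALSE
  )
  for (k in seq_len(n)) {
    res <- pocket[[k]]
    out$residue[k] <- residue_id(res)
    out$chain[k] <- res$chain
    out$number[k] <- res$number
    out$icode[k] <- res$icode
    out$name[k] <- res$name
    out$min_distance[k] <- dists[k]
    energies <- tryCatch({
      quartet <- build_quartet(complex, residue_id(res))
      vapply(quartet[c("BID_CRC", "CRC", "BID_CC", "CC")], evaluator, 0)
    }, error = function(e) {
      warning("residue ", residue_id(res), " failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(energies)) {
      out$failed[k] <- TRUE
      next
    }
    out$e_bid_crc[k] <- energies[1]
    out$e_crc[k] <- energies[2]
    out$e_bid_cc[k] <- energies[3]
    out$e_cc[k] <- energies[4]
    out$ie[k] <- residue_interaction_energy(energies[1], energies[2],
                                            energies[3], energies[4])
  }
  out$classification <- classify_ie(out$ie)
  attr(out, "epsilon") <- attr(evaluator, "epsilon")
  class(out) <- c("mfcc_residue_ie", "data.frame")
  out
}

#' Cumulative-energy scan over nested pocket radii
#'
#' Evaluates the cumulative interaction energy over pocket spheres on the
#' r = R/2 grid (radii `step, 2*step, ..., r_max`). Each residue's quartet is
#' computed once (by [decompose()]) and reused at every radius; the scan only
#' re-partitions membership by the stored minimum distances.
#'
#' @param residue_ies An `mfcc_residue_ie` table covering the `r_max` pocket.
#' @param r_max Largest radius of the grid, Angstrom.
#' @param step Grid spacing, Angstrom (default 0.5, i.e. r = R/2).
#' @param threshold Relative-change convergence threshold (default 0.10).
#' @return List of class `mfcc_radius_scan`: a `table` data.frame (radius,
#'   n_residues, cumulative_energy), the per-radius residue id `sets`,
#'   `threshold` and `converged_radius` (NA when never met).
#' @export
radius_scan <- function(residue_ies, r_max = 10, step = 0.5,
                        threshold = 0.10) {
  ok <- !residue_ies$failed
  radii <- seq(step, r_max, by = step)
  sets <- lapply(radii, function(r) {
    residue_ies$residue[ok & residue_ies$min_distance <= r]
  })
  cumulative <- vapply(radii, function(r) {
    sum(residue_ies$ie[ok & residue_ies$min_distance <= r])
  }, 0)
  scan <- structure(
    list(table = data.frame(radius = radii,
                            n_residues = lengths(sets),
                            cumulative_energy = cumulative),
         sets = sets, threshold = threshold,
         converged_radius = NA_real_,
         epsilon = attr(residue_ies, "epsilon")),
    class = "mfcc_radius_scan"
  )
  scan$converged_radius <- find_convergence(scan, threshold)
  scan
}

#' @export
print.mfcc_radius_scan <- function(x, ...) {
  cat("mfcc_radius_scan:", nrow(x$table), "radii up to",
      max(x$table$radius), "A; converged at",
      ifelse(is.na(x$converged_radius), "none", x$converged_radius), "\n")
  invisible(x)
}

#' Detect the converged pocket radius
#'
#' The scan is converged at the smallest radius r_k (k >= 2) at which the
#' cumulative energy changed by no more than `threshold` relative to the
#' previous radius -- `|E(r_k) - E(r_k-1)| / max(|E(r_k)|, floor)` -- with the
#' criterion also holding at every subsequent computed radius. The `floor`
#' guards the division for near-zero energies.
#'
#' @param scan An `mfcc_radius_scan`, or a numeric cumulative-energy series.
#' @param threshold Relative change threshold (default 0.10).
#' @param floor Denominator floor in kcal/mol.
#' @param radii Radii for a plain numeric series (defaults to indices).
#' @return The converged radius (or series position), or `NA` if the
#'   criterion is never met.
#' @export
find_convergence <- function(scan, threshold = 0.10, floor = 1e-6,
                             radii = NULL) {
  if (inherits(scan, "mfcc_radius_scan")) {
    series <- scan$table$cumulative_energy
    radii <- scan$table$radius
  } else {
    series <- as.numeric(scan)
    if (is.null(radii)) radii <- seq_along(series)
  }
  k <- length(series)
  if (k < 2) return(NA_real_)
  if (all(series == 0)) {
    warning("all-zero cumulative energy series; no convergence radius")
    return(NA_real_)
  }
  rel <- abs(diff(series)) / pmax(abs(series[-1]), floor)
  ok <- rel <= threshold
  holds <- rev(cumprod(rev(ok))) > 0  # ok from this change onwards
  idx <- which(holds)[1]
  if (is.na(idx)) NA_real_ else radii[idx + 1]
}

#' Rank and classify residues by interaction energy
#'
#' Sorts ascending by interaction energy (most negative, i.e. strongest
#' attraction, first), breaking ties by chain, residue number and insertion
#' code, and attaches the rank. Failed residues are dropped.
#'
#' @param residue_ies An `mfcc_residue_ie` table.
#' @return The sorted table with a `rank` column.
#' @export
rank_and_classify <- function(residue_ies) {
  out <- residue_ies[!residue_ies$failed, , drop = FALSE]
  if (nrow(out) == 0) {
    out$rank <- integer(0)
    return(out)
  }
  ord <- order(out$ie, out$chain, out$number, out$icode)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
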