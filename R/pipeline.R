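# End-to-end pipeline: read -> pocket -> quartets -> energies ->
# decomposition -> radius scan -> convergence -> contact annotation ->
# reports. Identical configuration and inputs give byte-identical outputs.

#' Assemble a run configuration
#'
#' @param input Path to a PDB file (or `NULL` when `toy` is given).
#' @param toy An `mfcc_toy_spec` for generated inputs.
#' @param ligand_resname Ligand residue name (PDB input).
#' @param r_max Pocket radius, Angstrom (default 10).
#' @param step Radius grid spacing (default 0.5, the r = R/2 grid).
#' @param epsilons Dielectric constants evaluated (default `c(10, 40)`).
#' @param backend `"classical"` (built-in), `"qm_decks"` (write decks only)
#'   or `"qm_harvest"` (combine parsed external energies).
#' @param link_atom_policy `"ghost"` or `"parameterized"`.
#' @param threshold Convergence threshold in (0, 1) (default 0.10).
#' @param outdir Output directory.
#' @param seed Integer seed (controls seeded toy charges).
#' @param params Optional `mfcc_params` (required for classical runs on PDB
#'   input).
#' @param manifest For `"qm_harvest"`: named list (by epsilon) or single
#'   manifest of fragment_key -> output file, see [harvest_evaluator()].
#' @param keep_het Extra HETATM residue names to retain when reading PDB.
#' @return A validated list of class `mfcc_run_config`.
#' @export
run_config <- function(input = NULL, toy = NULL, ligand_resname = NULL,
                       r_max = 10, step = 0.5, epsilons = c(10, 40),
                       backend = c("classical", "qm_decks", "qm_harvest"),
                       link_atom_policy = "ghost", threshold = 0.10,
                       outdir = tempfile("mfcc_run_"), seed = 1L,
                       params = NULL, manifest = NULL,
                       keep_het = character()) {
  backend <- match.arg(backend)
  stopifnot(r_max > 0, step > 0, length(epsilons) >= 1, all(epsilons > 0),
            threshold > 0, threshold < 1)
  if (is.null(input) && is.null(toy)) {
    stop("either an input PDB or a toy spec is required")
  }
  structure(
    list(input = input, toy = toy, ligand_resname = ligand_resname,
         r_max = r_max, step = step, epsilons = epsilons, backend = backend,
         link_atom_policy = link_atom_policy, threshold = threshold,
         outdir = outdir, seed = as.integer(seed), params = params,
         manifest = manifest, keep_het = keep_het),
    class = "mfcc_run_config"
  )
}

load_run_input <- function(config) {
  if (!is.null(config$toy)) {
    complex <- build_toy_complex(config$toy)
    params <- config$params
    if (is.null(params) && config$backend == "classical") {
      params <- assign_toy_parameters(complex, config$toy,
                                      link_atom_policy =
                                        config$link_atom_policy)
    }
    list(complex = complex, params = params)
  } else {
    if (is.null(config$ligand_resname)) {
      stop("ligand_resname is required for PDB input")
    }
    complex <- read_complex(config$input, config$ligand_resname,
                            keep_het = config$keep_het)
    if (config$backend == "classical" && is.null(config$params)) {
      stop("classical backend on PDB input requires a parameter set")
    }
    list(complex = complex, params = config$params)
  }
}

write_deck_tree <- function(complex, pocket_ids, config) {
  decks_dir <- file.path(config$outdir, "decks")
  rows <- list()
  seen <- character(0)
  for (eps in config$epsilons) {
    eps_dir <- file.path(decks_dir, paste0("eps", format(eps)))
    dir.create(eps_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in pocket_ids) {
      quartet <- build_quartet(complex, id)
      for (frag in quartet) {
        key <- fragment_key(frag)
        tag <- paste(format(eps), key)
        if (tag %in% seen) next
        seen <- c(seen, tag)
        path <- file.path(eps_dir, paste0(key, ".gjf"))
        write_qm_input(qm_job_spec(frag, epsilon = eps), path)
        rows[[length(rows) + 1]] <- data.frame(
          epsilon = eps, fragment_key = key, role = frag$role,
          residue = id, deck = path, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the decomposition pipeline
#'
#' Executes the full workflow for a run configuration and writes the report
#' files (see [write_reports()]). With the `"qm_decks"` backend it stops
#' after writing one deduplicated input deck per unique fragment and records
#' them in the manifest, so external jobs can be run elsewhere and combined
#' later with `"qm_harvest"`.
#'
#' @param config An `mfcc_run_config`.
#' @return The run manifest (also written as `manifest.json`), invisibly.
#'   The manifest's `n_failed` count is nonzero when any residue's fragments
#'   failed to evaluate.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mfcc_run_config"))
  set.seed(config$seed)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  inp <- load_run_input(config)
  complex <- inp$complex
  message("pipeline: ", length(complex$residues), " residues; ligand ",
          complex$ligand$name)

  pocket <- select_pocket(complex, config$r_max)
  pocket_ids <- vapply(pocket, residue_id, "")
  message("pipeline: pocket at r = ", config$r_max, " A holds ",
          length(pocket_ids), " residues")

  manifest <- list(
    package = "mfccie",
    version = as.character(utils::packageVersion("mfccie")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    backend = config$backend,
    r_max = config$r_max, step = config$step,
    epsilons = config$epsilons, threshold = config$threshold,
    link_atom_policy = config$link_atom_policy, seed = config$seed,
    source = complex$metadata$source,
    n_residues = length(complex$residues),
    pocket_size = length(pocket_ids)
  )

  if (config$backend == "qm_decks") {
    decks <- write_deck_tree(complex, pocket_ids, config)
    deck_csv <- file.path(config$outdir, "decks.csv")
    utils::write.csv(decks, deck_csv, row.names = FALSE)
    manifest$n_fragments <- nrow(decks)
    manifest$outputs <- c("decks.csv", "manifest.json")
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    message("pipeline: wrote ", nrow(decks), " unique fragment decks")
    return(invisible(manifest))
  }

  results <- list()
  scans <- list()
  for (eps in config$epsilons) {
    evaluator <- if (config$backend == "classical") {
      classical_evaluator(inp$params, eps)
    } else {
      m <- config$manifest
      if (is.list(m) && !is.data.frame(m) &&
          !is.null(m[[as.character(eps)]])) {
        m <- m[[as.character(eps)]]
      }
      harvest_evaluator(m, eps)
    }
    ies <- decompose(complex, evaluator, r_max = config$r_max)
    scan <- radius_scan(ies, r_max = config$r_max, step = config$step,
                        threshold = config$threshold)
    message("pipeline: eps = ", eps, ": cumulative ",
            sprintf("%.2f", sum(ies$ie[!ies$failed])), " kcal/mol over ",
            sum(!ies$failed), " residues; converged at r = ",
            ifelse(is.na(scan$converged_radius), "none",
                   scan$converged_radius))
    results[[format(eps)]] <- ies
    scans[[format(eps)]] <- scan
  }

  annotations <- annotate_contacts(complex, results[[1]])
  files <- write_reports(results, annotations, scans, config$outdir)

  manifest$n_fragments <- 4L * length(pocket_ids)
  manifest$n_failed <- sum(results[[1]]$failed)
  manifest$converged_radius <- lapply(scans, `[[`, "converged_radius")
  manifest$cumulative_energy <- lapply(
    results, function(r) sum(r$ie[!r$failed])
  )
  manifest$outputs <- basename(unlist(files))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

fmt2 <- function(x) {
  ifelse(is.na(x), NA, sprintf("%.2f", x))
}

#' Write the report tables
#'
#' Writes `residues.csv` (one row per pocket residue with minimum distance,
#' the four term energies and interaction energy per dielectric,
#' classification, rank and contact annotation) and `scan.csv` (radius grid,
#' pocket sizes, cumulative energies and convergence flags per dielectric).
#' Floating-point values are printed to 2 decimals; column order is stable.
#'
#' @param results Named list (by dielectric) of `mfcc_residue_ie` tables.
#' @param annotations Contact annotation table (may have zero rows).
#' @param scans Named list (by dielectric) of `mfcc_radius_scan` objects.
#' @param dir Output directory.
#' @return Named list of file paths, invisibly.
#' @export
write_reports <- function(results, annotations, scans, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- results[[1]][, c("residue", "chain", "number", "icode", "name")]
  out <- base
  out$min_distance <- fmt2(results[[1]]$min_distance)
  for (eps in names(results)) {
    r <- results[[eps]]
    if (!identical(r$residue, base$residue)) {
      stop("join error: residue sets differ across dielectrics at residue ",
           setdiff(r$residue, base$residue)[1])
    }
    ranked <- rank_and_classify(r)
    rk <- ranked$rank[match(r$residue, ranked$residue)]
    suff <- paste0("_eps", eps)
    out[[paste0("e_bid_crc", suff)]] <- fmt2(r$e_bid_crc)
    out[[paste0("e_crc", suff)]] <- fmt2(r$e_crc)
    out[[paste0("e_bid_cc", suff)]] <- fmt2(r$e_bid_cc)
    out[[paste0("e_cc", suff)]] <- fmt2(r$e_cc)
    out[[paste0("ie", suff)]] <- fmt2(r$ie)
    out[[paste0("classification", suff)]] <- r$classification
    out[[paste0("rank", suff)]] <- rk
  }
  if (nrow(annotations) > 0) {
    extra <- setdiff(annotations$residue, base$residue)
    if (length(extra) > 0) {
      stop("join error: annotated residue ", extra[1],
           " absent from energy report")
    }
    j <- match(base$residue, annotations$residue)
    out$nearest_ligand_atom <- annotations$nearest_ligand_atom[j]
    out$region <- annotations$region[j]
    out$contact_distance <- fmt2(annotations$distance[j])
    out$contact_class <- annotations$contact_class[j]
  } else {
    out$nearest_ligand_atom <- NA
    out$region <- NA
    out$contact_distance <- NA
    out$contact_class <- NA
  }
  residues_csv <- file.path(dir, "residues.csv")
  utils::write.csv(out, residues_csv, row.names = FALSE, na = "")

  stab <- scans[[1]]$table[, "radius", drop = FALSE]
  for (eps in names(scans)) {
    s <- scans[[eps]]
    suff <- paste0("_eps", eps)
    stab[[paste0("n_residues", suff)]] <- s$table$n_residues
    stab[[paste0("cumulative", suff)]] <- fmt2(s$table$cumulative_energy)
    stab[[paste0("converged", suff)]] <- !is.na(s$converged_radius) &
      s$table$radius >= s$converged_radius
  }
  scan_csv <- file.path(dir, "scan.csv")
  utils::write.csv(stab, scan_csv, row.names = FALSE, na = "")
  invisible(list(residues = residues_csv, scan = scan_csv))
}
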