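test_that("the four-term combination has the right sign bookkeeping", {
  expect_identical(residue_interaction_energy(-100, -40, -70, -15), -5)
  set.seed(7)
  for (i in 1:20) {
    a <- runif(1, -100, 100)
    b <- runif(1, -100, 100)
    expect_identical(residue_interaction_energy(a, a, b, b), 0)
  }
  expect_error(residue_interaction_energy(NaN, 0, 0, 0), "non-finite")
})

test_that("MFCC with ghost links equals the brute-force cross energy", {
  spec <- default_toy_spec()
  cx <- build_toy_complex(spec)
  params <- assign_toy_parameters(cx, spec)
  ies <- decompose(cx, classical_evaluator(params, 10), r_max = 50)
  expect_equal(nrow(ies), 5)
  gt <- ground_truth_decomposition(cx, params, 10)
  expect_equal(ies$residue, gt$residue)
  expect_lt(max(abs(ies$ie - gt$cross_energy)), 1e-9)
  # conservation: the residue sum is the whole ligand-protein cross energy
  total <- pair_cross_energy(peptide_atoms(cx), cx$ligand$atoms, params, 10)
  expect_lt(abs(sum(ies$ie) - total), 1e-9)
})

test_that("parameterized link atoms shift each residue by exactly the
           ligand-link cross energy", {
  spec <- default_toy_spec()
  cx <- build_toy_complex(spec)
  params_ghost <- assign_toy_parameters(cx, spec)
  params_real <- assign_toy_parameters(cx, spec,
                                       link_atom_policy = "parameterized")
  for (id in c("A:2", "A:3")) {
    q <- build_quartet(cx, id)
    e <- vapply(q, classical_energy, 0, params = params_real, epsilon = 10)
    ie_real <- residue_interaction_energy(e[1], e[2], e[3], e[4])
    cross <- pair_cross_energy(
      cx$residues[[match(id, vapply(cx$residues, residue_id, ""))]]$atoms,
      cx$ligand$atoms, params_ghost, 10)
    # discrepancy = ligand vs inner-link-hydrogen cross energy (the inner
    # links exist only in the CC-containing fragments)
    inner <- q$CC$atoms[q$CC$atoms$is_link, ]
    outer_keys <- apply(q$CRC$atoms[q$CRC$atoms$is_link, c("x", "y", "z")],
                        1, paste, collapse = ",")
    inner_only <- inner[!apply(inner[, c("x", "y", "z")], 1, paste,
                               collapse = ",") %in% outer_keys, ]
    lig_link <- pair_cross_energy(inner_only, cx$ligand$atoms, params_real,
                                  10)
    expect_equal(unname(ie_real - cross), -lig_link, tolerance = 1e-9)
  }
})

test_that("a residue far from the ligand contributes nothing", {
  spec <- toy_spec(rep("GLY", 5), probe = "diatomic_dipole", anchor = 1,
                   offset = 3)
  cx <- build_toy_complex(spec)
  params <- assign_toy_parameters(cx, spec)
  far <- shift_residues(cx, 4:5, c(0, 0, 500))
  ies <- decompose(far, classical_evaluator(params, 10), r_max = 600)
  expect_equal(nrow(ies), 5)
  expect_lt(abs(ies$ie[ies$residue == "A:5"]), 1e-6)
})

test_that("the radius scan accumulates nested pocket energies", {
  spec <- default_toy_spec()
  cx <- build_toy_complex(spec)
  params <- assign_toy_parameters(cx, spec)
  ies <- decompose(cx, classical_evaluator(params, 10), r_max = 10)
  scan <- radius_scan(ies, r_max = 10, step = 0.5)
  expect_equal(scan$table$radius, seq(0.5, 10, by = 0.5))
  # totality at r_max
  expect_equal(scan$table$cumulative_energy[nrow(scan$table)], sum(ies$ie))
  # nested membership
  for (k in 2:length(scan$sets)) {
    expect_true(all(scan$sets[[k - 1]] %in% scan$sets[[k]]))
  }
  # a single residue at min distance 3.2ish enters at the next half-step
  one <- ies[ies$residue == "A:3", , drop = FALSE]
  attr(one, "epsilon") <- 10
  s1 <- radius_scan(one, r_max = 5, step = 0.5)
  enter <- ceiling(one$min_distance / 0.5) * 0.5
  expect_true(all(s1$table$cumulative_energy[s1$table$radius < enter] == 0))
  expect_equal(s1$table$cumulative_energy[s1$table$radius >= enter],
               rep(one$ie, sum(s1$table$radius >= enter)))
})

test_that("the 10% convergence rule matches hand-computed series", {
  expect_equal(find_convergence(c(-10, -20, -21.5, -21.9),
                                radii = c(1, 2, 3, 4)), 3)
  expect_equal(find_convergence(rep(-5, 6)), 2)
  alternating <- -10 * cumprod(c(1, rep(c(1.5, 0.5), 5)))
  expect_true(is.na(find_convergence(alternating)))
  expect_warning(res <- find_convergence(rep(0, 4)), "all-zero")
  expect_true(is.na(res))
  # the criterion must also hold at every later radius
  expect_equal(find_convergence(c(-10, -10.2, -20, -20.5)), 4)
})

test_that("ranking orders by affinity with deterministic tie-breaks", {
  ies <- data.frame(
    residue = c("A:1", "A:2", "A:3"), chain = "A", number = 1:3,
    icode = "", name = c("PHE", "MET", "ALA"), min_distance = 3,
    e_bid_crc = 0, e_crc = 0, e_bid_cc = 0, e_cc = 0,
    ie = c(-7.93, -3.83, 1.26),
    classification = c("attractive", "attractive", "repulsive"),
    failed = FALSE, stringsAsFactors = FALSE
  )
  ranked <- rank_and_classify(ies)
  expect_equal(ranked$residue, c("A:1", "A:2", "A:3"))
  expect_equal(ranked$rank, 1:3)
  expect_equal(ranked$classification[3], "repulsive")

  tie <- ies
  tie$ie <- c(-2, -5, -5)
  expect_equal(rank_and_classify(tie)$residue[1:2], c("A:2", "A:3"))

  empty <- ies[0, ]
  expect_equal(nrow(rank_and_classify(empty)), 0)
})

test_that("failed fragments degrade gracefully", {
  spec <- default_toy_spec()
  cx <- build_toy_complex(spec)
  params <- assign_toy_parameters(cx, spec)
  # an evaluator that crashes on the tripeptide centred on residue A:3
  ev <- structure(function(fragment) {
    inc <- fragment$residues_included
    if (fragment$role %in% c("BID_CRC", "CRC") &&
        inc[ceiling(length(inc) / 2)] == "A:3") {
      stop("job crashed")
    }
    classical_energy(fragment, params, 10)
  }, class = c("mfcc_evaluator", "function"), epsilon = 10)
  expect_warning(ies <- decompose(cx, ev, r_max = 50), "A:3 failed")
  expect_equal(sum(ies$failed), 1)
  expect_true(all(is.finite(ies$ie[!ies$failed])))
  expect_false("A:3" %in% rank_and_classify(ies)$residue)
})
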