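two_atom_params <- function(q1, q2, sigma = 0, eps = 0) {
  parameter_set(data.frame(serial = 1:2, q = c(q1, q2),
                           sigma = sigma, epsilon_lj = eps))
}

two_atoms <- function(r) {
  mfccie:::new_atoms(1:2, c("A1", "A2"), c("C", "C"),
                     c(0, r), c(0, 0), c(0, 0))
}

test_that("the Coulomb term reproduces hand-checked values", {
  p <- two_atom_params(1, -1)
  expect_equal(classical_energy(two_atoms(3.320636), p, epsilon = 1),
               -100.0, tolerance = 1e-10)
  expect_equal(classical_energy(two_atoms(3.320636), p, epsilon = 40),
               -2.5, tolerance = 1e-10)

  single <- mfccie:::new_atoms(1, "A1", "C", 0, 0, 0)
  expect_identical(classical_energy(single, p, 1), 0)

  expect_error(classical_energy(two_atoms(0), p, 1), "singular")
})

test_that("missing parameters are reported by atom", {
  p <- two_atom_params(1, -1)
  atoms <- mfccie:::new_atoms(1:3, c("A1", "A2", "A3"), "C",
                              c(0, 1, 2), 0, 0)
  expect_error(classical_energy(atoms, p, 1), "serial 3")
})

test_that("cross energy satisfies the additivity identity", {
  expect_identical(
    pair_cross_energy(two_atoms(1), two_atoms(1)[0, ], two_atom_params(1, 1)),
    0)
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:9, 1)
    m <- sample(3:8, 1)
    atoms <- mfccie:::new_atoms(seq_len(n + m), paste0("A", seq_len(n + m)),
                                sample(c("C", "N", "O"), n + m, TRUE),
                                runif(n + m, 0, 8), runif(n + m, 0, 8),
                                runif(n + m, 0, 8))
    params <- parameter_set(data.frame(
      serial = atoms$serial, q = runif(n + m, -0.5, 0.5),
      sigma = runif(n + m, 2.5, 3.6), epsilon_lj = runif(n + m, 0.01, 0.3)
    ))
    a <- atoms[seq_len(n), ]
    b <- atoms[n + seq_len(m), ]
    lhs <- classical_energy(atoms, params, 10) -
      classical_energy(a, params, 10) - classical_energy(b, params, 10)
    expect_equal(lhs, pair_cross_energy(a, b, params, 10),
                 tolerance = 1e-9)
  }
})

test_that("ligand-vs-peptide cross energy partitions over residues", {
  spec <- default_toy_spec(probe = "diatomic_dipole")
  cx <- build_toy_complex(spec)
  params <- assign_toy_parameters(cx, spec)
  total <- pair_cross_energy(peptide_atoms(cx), cx$ligand$atoms, params, 10)
  per_res <- vapply(cx$residues, function(r) {
    pair_cross_energy(r$atoms, cx$ligand$atoms, params, 10)
  }, 0)
  expect_equal(sum(per_res), total, tolerance = 1e-9)
})

test_that("the Coulomb component scales exactly as 1/epsilon", {
  spec <- default_toy_spec()
  cx <- build_toy_complex(spec)
  params <- assign_toy_parameters(cx, spec)
  c10 <- pair_cross_energy(peptide_atoms(cx), cx$ligand$atoms, params, 10,
                           components = TRUE)
  c40 <- pair_cross_energy(peptide_atoms(cx), cx$ligand$atoms, params, 40,
                           components = TRUE)
  expect_identical(c10$lj, c40$lj)
  expect_equal(c10$coulomb, 4 * c40$coulomb, tolerance = 1e-12)
})

test_that("identical fragment content is evaluated only once", {
  spec <- default_toy_spec()
  cx <- build_toy_complex(spec)
  params <- assign_toy_parameters(cx, spec)
  ev <- classical_evaluator(params, 10)
  q <- build_quartet(cx, "A:3")
  e1 <- ev(q$CRC)
  e2 <- ev(q$CRC)
  expect_identical(e1, e2)
  s <- evaluator_stats(ev)
  expect_equal(s$evaluations, 1L)
  expect_equal(s$cache_hits, 1L)
})

test_that("input decks are deterministic and carry charge/multiplicity", {
  cx <- build_toy_complex(default_toy_spec())
  frag <- excise_capped_tripeptide(cx, "A:3")
  spec <- qm_job_spec(frag, epsilon = 40)
  deck <- write_qm_input(spec)
  lines <- strsplit(deck, "\n")[[1]]
  expect_match(lines[1], "B97D/6-311\\+G\\(d,p\\)")
  expect_match(lines[1], "CPCM,eps=40")
  expect_true(any(lines == "-1 1"))
  coord_lines <- grep("^ [A-Z]", lines)
  expect_length(coord_lines, nrow(frag$atoms))
  expect_identical(deck, write_qm_input(qm_job_spec(frag, epsilon = 40)))

  f <- withr::local_tempfile(fileext = ".gjf")
  write_qm_input(spec, f)
  expect_identical(paste(readLines(f), collapse = "\n"), deck)
})

test_that("quantum output parsing converts, takes the last energy, and flags
           truncation", {
  out <- c(" SCF Done:  E(RB97D) =  -1.000000000     A.U. after 9 cycles",
           " Normal termination of Gaussian 16")
  res <- parse_qm_output(out)
  expect_equal(res$energy, -627.509474, tolerance = 1e-9)
  expect_true(res$converged)

  out2 <- c(" SCF Done:  E(RB97D) =  -1.000000000   A.U.",
            " SCF Done:  E(RB97D) =  -2.500000000   A.U.",
            " Normal termination")
  expect_equal(parse_qm_output(out2)$energy_hartree, -2.5)

  trunc <- " SCF Done:  E(RB97D) =  -1.000000000   A.U."
  expect_false(parse_qm_output(c(trunc, ""))$converged)

  generic <- c("FINAL ENERGY = -0.500000", "Normal termination")
  expect_equal(parse_qm_output(generic)$energy_hartree, -0.5)

  expect_error(parse_qm_output(c("nothing here", "")), "no energy found")
})

test_that("fragment keys are stable and content-sensitive", {
  cx <- build_toy_complex(default_toy_spec())
  f1 <- excise_capped_tripeptide(cx, "A:3")
  expect_identical(fragment_key(f1),
                   fragment_key(excise_capped_tripeptide(cx, "A:3")))
  f2 <- excise_caps_only(cx, "A:3")
  expect_false(fragment_key(f1) == fragment_key(f2))
  expect_match(fragment_key(f1), "^[0-9a-f]{8}$")
})
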