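test_that("link hydrogens sit on the cut bond at the standard lengths", {
  parent_c <- mfccie:::new_atoms(1, "C", "C", 0, 0, 0)
  link <- place_link_hydrogen(parent_c, c(1.329, 0, 0))
  expect_equal(link$position, c(1.09, 0, 0), tolerance = 1e-12)

  parent_n <- mfccie:::new_atoms(2, "N", "N", 0, 0, 0)
  link <- place_link_hydrogen(parent_n, c(0, 1.329, 0))
  expect_equal(link$position, c(0, 1.01, 0), tolerance = 1e-12)

  # oblique bond vectors: exact length and collinearity
  set.seed(42)
  for (i in 1:20) {
    p <- runif(3, -5, 5)
    v <- runif(3, -2, 2)
    parent <- mfccie:::new_atoms(1, "C", "C", p[1], p[2], p[3])
    link <- place_link_hydrogen(parent, p + v)
    h <- link$position - p
    expect_lt(abs(sqrt(sum(h^2)) - 1.09), 1e-9)
    cr <- c(h[2] * v[3] - h[3] * v[2], h[3] * v[1] - h[1] * v[3],
            h[1] * v[2] - h[2] * v[1])
    expect_lt(sqrt(sum(cr^2)), 1e-9)
    expect_gt(sum(h * v), 0)
  }

  expect_error(place_link_hydrogen(parent_c, c(0, 0, 0)), "zero-length")
})

test_that("capped tripeptides carry the right atoms, links and charges", {
  spec <- default_toy_spec()
  cx <- build_toy_complex(spec)
  sizes <- vapply(cx$residues, function(r) nrow(r$atoms), 0L)

  crc <- excise_capped_tripeptide(cx, "A:3")
  expect_equal(crc$role, "CRC")
  expect_equal(nrow(crc$atoms), sizes[2] + sizes[3] + sizes[4] + 2)
  expect_equal(sum(crc$atoms$is_link), 2)
  expect_equal(crc$net_charge, -1L)  # central ASP, neutral caps
  expect_equal(crc$residues_included, c("A:2", "A:3", "A:4"))

  # N-terminal residue: no preceding cap, native terminus retained
  crc1 <- excise_capped_tripeptide(cx, "A:1")
  expect_equal(nrow(crc1$atoms), sizes[1] + sizes[2] + 1)
  expect_equal(sum(crc1$atoms$is_link), 1)

  cc <- excise_caps_only(cx, "A:3")
  expect_equal(cc$role, "CC")
  expect_equal(nrow(cc$atoms), sizes[2] + sizes[4] + 4)
  expect_equal(sum(cc$atoms$is_link), 4)
  expect_equal(cc$net_charge, 0L)
})

test_that("a 2-residue chain yields the terminus caps-only rule", {
  cx <- build_toy_complex(toy_spec(c("GLY", "ALA"), anchor = 1, offset = 3))
  cc <- excise_caps_only(cx, "A:1")
  expect_equal(cc$residues_included, "A:2")
  expect_equal(sum(cc$atoms$is_link), 1)
  expect_equal(nrow(cc$atoms), nrow(cx$residues[[2]]$atoms) + 1)
})

test_that("cap coordinates are identical across CRC and CC fragments", {
  cx <- build_toy_complex(default_toy_spec())
  crc <- excise_capped_tripeptide(cx, "A:3")
  cc <- excise_caps_only(cx, "A:3")
  cap_crc <- crc$atoms[!crc$atoms$is_link &
                         crc$atoms$serial %in% cc$atoms$serial, ]
  cap_cc <- cc$atoms[!cc$atoms$is_link, ]
  expect_equal(cap_crc$serial, cap_cc$serial)
  expect_identical(cap_crc$x, cap_cc$x)
  expect_identical(cap_crc$y, cap_cc$y)
  expect_identical(cap_crc$z, cap_cc$z)
})

test_that("fragmentation never moves an original atom", {
  cx <- build_toy_complex(default_toy_spec())
  before <- peptide_atoms(cx)
  for (id in c("A:2", "A:3", "A:4")) invisible(build_quartet(cx, id))
  expect_identical(peptide_atoms(cx), before)

  q <- build_quartet(cx, "A:3")
  orig <- q$CRC$atoms[!q$CRC$atoms$is_link, ]
  j <- match(orig$serial, before$serial)
  expect_identical(orig$x, before$x[j])
})

test_that("quartets have the four roles with consistent content", {
  spec <- default_toy_spec()
  cx <- build_toy_complex(spec)
  q <- build_quartet(cx, "A:3")
  expect_named(q, c("BID_CRC", "CRC", "BID_CC", "CC"))
  expect_true(q$BID_CRC$includes_ligand && q$BID_CC$includes_ligand)
  expect_false(q$CRC$includes_ligand || q$CC$includes_ligand)

  nlig <- nrow(cx$ligand$atoms)
  expect_equal(nrow(q$BID_CRC$atoms), nrow(q$CRC$atoms) + nlig)
  expect_equal(nrow(q$BID_CC$atoms), nrow(q$CC$atoms) + nlig)

  # ligand coordinates identical in both binder-containing fragments
  lig1 <- q$BID_CRC$atoms[q$BID_CRC$atoms$serial %in% cx$ligand$atoms$serial, ]
  lig2 <- q$BID_CC$atoms[q$BID_CC$atoms$serial %in% cx$ligand$atoms$serial, ]
  expect_identical(lig1$x, lig2$x)
  expect_identical(lig1$z, lig2$z)

  # charge bookkeeping: (q_lig + q_CRC, q_CRC, q_lig + q_CC, q_CC)
  qlig <- cx$ligand$formal_charge
  expect_equal(vapply(q, `[[`, 0L, "net_charge"),
               c(BID_CRC = qlig - 1L, CRC = -1L, BID_CC = qlig + 0L,
                 CC = 0L))
})

test_that("uncappable residues raise clear errors", {
  cx <- build_toy_complex(default_toy_spec())
  expect_error(build_quartet(cx, "A:99"), "residue not found")

  broken <- cx
  broken$residues[[2]]$atoms <-
    broken$residues[[2]]$atoms[broken$residues[[2]]$atoms$name != "CA", ]
  broken$residues[[2]]$nonstandard <- TRUE
  expect_error(excise_capped_tripeptide(broken, "A:3"), "cannot cap")
})

test_that("fragment XYZ export carries role, charge and geometry", {
  cx <- build_toy_complex(default_toy_spec())
  q <- build_quartet(cx, "A:3")
  txt <- write_fragment_xyz(q$CRC, residue_id = "A:3")
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(as.integer(lines[1]), nrow(q$CRC$atoms))
  expect_match(lines[2], "role=CRC residue=A:3 charge=-1 multiplicity=1")
  expect_length(lines, nrow(q$CRC$atoms) + 2)
})
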