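test_that("a minimal single-atom ATOM record parses into a one-residue Structure", {
  f <- tempfile(fileext = ".pdb")
  writeLines("ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
             f)
  s <- read_pdb(f)
  expect_s3_class(s, "Structure")
  expect_equal(n_residues(s), 1)
  expect_equal(nrow(s$atoms), 1)
  expect_true(s$atoms$is_backbone)
  expect_equal(s$sequence, "A")
  expect_equal(s$atoms$radius, 1.87)
})

test_that("Gly-Ala-Gly fixture has one side-chain heavy atom on the central residue", {
  s <- build_peptide("GAG", phi = -57, psi = -47)
  expect_equal(n_residues(s), 3)
  per_res <- split(s$atoms, s$atoms$res_seq)
  expect_equal(sum(!per_res[[1]]$is_backbone), 0)
  expect_equal(sum(!per_res[[2]]$is_backbone), 1)
  expect_equal(per_res[[2]]$name[!per_res[[2]]$is_backbone], "CB")
  expect_equal(sum(!per_res[[3]]$is_backbone), 0)
})

test_that("write_pdb / read_pdb round-trips coordinates to PDB precision and is idempotent", {
  s <- helix_fixture(10)
  f <- tempfile(fileext = ".pdb")
  write_pdb(s, f)
  s2 <- read_pdb(f, id = s$id)
  expect_equal(n_residues(s2), 10)
  expect_equal(s2$atoms$x, round(s$atoms$x, 3))
  expect_equal(s2$atoms$y, round(s$atoms$y, 3))
  expect_equal(s2$atoms$z, round(s$atoms$z, 3))
  expect_equal(s2$atoms$name, s$atoms$name)
  # read-write-read fixpoint
  f2 <- tempfile(fileext = ".pdb")
  write_pdb(s2, f2)
  s3 <- read_pdb(f2, id = s$id)
  expect_identical(s3$atoms, s2$atoms)
})

test_that("hydrogens, HETATM, waters and non-A altlocs are dropped", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  H   ALA A   1       0.500   0.800   0.000  1.00  0.00           H",
    "ATOM      4 1HB  ALA A   1       2.000   1.000   0.000  1.00  0.00",
    "ATOM      5  CB AALA A   1       2.000   1.100   0.500  1.00  0.00           C",
    "ATOM      6  CB BALA A   1       2.100   1.200   0.600  1.00  0.00           C",
    "HETATM    7  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O"), f)
  s <- read_pdb(f)
  expect_equal(nrow(s$atoms), 3)
  expect_false(any(s$atoms$element == "H"))
  expect_equal(s$atoms$x[s$atoms$name == "CB"], 2.000)
})

test_that("parse and validation errors carry useful context", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       bad     0.000   0.000  1.00  0.00           C"), f)
  expect_error(read_pdb(f), "line 2")

  f2 <- tempfile(fileext = ".pdb")
  writeLines("ATOM      1  CA  XYZ A   1       0.000   0.000   0.000  1.00  0.00           C",
             f2)
  expect_error(read_pdb(f2), "XYZ")

  f3 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA B   1       5.000   0.000   0.000  1.00  0.00           C"), f3)
  expect_error(read_pdb(f3), "multiple chains")
  expect_equal(n_residues(read_pdb(f3, chain = "B")), 1)

  expect_error(read_pdb(tempfile()), "not found")
  f4 <- tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f4)
  expect_error(read_pdb(f4), "no ATOM records")
})

test_that("an empty Structure cannot be written and cannot be built", {
  s <- helix_fixture(3)
  s$atoms <- s$atoms[0, ]
  expect_error(write_pdb(s, tempfile()), "empty")
  expect_error(new_structure("x", s$atoms[0, ]), "at least one atom")
})

test_that("side-chain heavy-atom counts match the canonical table for all 20 residues", {
  all20 <- paste(AA_LETTERS, collapse = "")
  s <- build_peptide(all20, phi = -120, psi = 130)
  f <- tempfile(fileext = ".pdb")
  write_pdb(s, f)
  s2 <- read_pdb(f)
  per_res <- split(s2$atoms, s2$atoms$res_seq)
  for (i in seq_along(per_res)) {
    aa <- AA_ONE[per_res[[i]]$res_name[1]]
    expect_equal(sum(!per_res[[i]]$is_backbone),
                 unname(AA_SIDECHAIN_HEAVY[aa]),
                 label = paste("sidechain count of", aa))
    expect_lte(sum(per_res[[i]]$is_backbone), 5)
  }
})

test_that("written PDB files agree with an independent reader", {
  s <- build_peptide("MKWVD", phi = -57, psi = -47)
  f <- tempfile(fileext = ".pdb")
  write_pdb(s, f)
  b <- bio3d::read.pdb(f)
  expect_equal(nrow(b$atom), nrow(s$atoms))
  expect_equal(b$atom$x, round(s$atoms$x, 3))
  expect_equal(b$atom$y, round(s$atoms$y, 3))
  expect_equal(b$atom$z, round(s$atoms$z, 3))
  expect_equal(trimws(b$atom$elety), s$atoms$name)
  expect_equal(b$atom$resid, s$atoms$res_name)
})

test_that("FASTA parsing preserves order, validates ids and characters", {
  f <- write_temp_fasta(c(">a", "GAV"))
  expect_equal(read_fasta(f), c(a = "GAV"))

  f2 <- write_temp_fasta(c(">a desc", "GAV", ">b", "AA"))
  expect_equal(names(read_fasta(f2)), c("a", "b"))

  f3 <- write_temp_fasta(c(">a", "GAV", ">a", "AA"))
  expect_error(read_fasta(f3), "duplicate")

  f4 <- write_temp_fasta(c(">a", "GAXG"))
  expect_error(read_fasta(f4), "position 3")

  f5 <- write_temp_fasta(c(">a", "GA-V", ">b", "GAAV"))
  aln <- read_fasta(f5, aligned = TRUE)
  expect_equal(unique(nchar(aln)), 4)
  expect_error(read_fasta(f5), "illegal")

  f6 <- write_temp_fasta(c(">a", "GA-V", ">b", "GAAAV"))
  expect_error(read_fasta(f6, aligned = TRUE), "ragged")
})

test_that("radii tables validate their ranges and load from config files", {
  expect_error(radii_table(values = c(C = 0.5)), "1.0, 2.5")
  expect_error(radii_table(probe = -1), "non-negative")
  f <- tempfile(fileext = ".yaml")
  writeLines(c("C: 1.70", "N: 1.55", "O: 1.52", "S: 1.80", "probe: 1.2"), f)
  r <- read_radii(f)
  expect_equal(r$values[["C"]], 1.70)
  expect_equal(r$probe, 1.2)
})
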