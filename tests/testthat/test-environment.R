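# Hand-built profile helper: a sasa_profile with prescribed per-residue areas
fake_profile <- function(res_name, total, sidechain,
                         backbone = total - sidechain,
                         polar = total / 2) {
  res <- data.frame(res_index = seq_along(res_name) - 1L, res_name = res_name,
                    total = total, backbone = backbone, sidechain = sidechain,
                    polar = polar, apolar = total - polar,
                    stringsAsFactors = FALSE)
  structure(list(id = "fake", residues = res, tsa = sum(total),
                 tps = sum(polar), tas = sum(total - polar),
                 scs = sum(sidechain), bbs = sum(backbone)),
            class = "sasa_profile")
}

fake_reference <- function(value = 100) {
  structure(setNames(rep(value, 20), AA_LETTERS), class = "gxg_reference",
            ensemble_size = 1L, seed = 0L, radii_tag = "synthetic")
}

test_that("the packaged reference is complete, positive and size-30", {
  ref <- default_reference()
  expect_equal(sort(names(ref)), sort(AA_LETTERS))
  expect_true(all(ref > 0))
  expect_equal(attr(ref, "ensemble_size"), 30L)
  expect_gt(ref[["W"]], ref[["A"]])  # bulkier side chain, larger reference
})

test_that("reference building is deterministic and handles the Gly special case", {
  r1 <- build_reference(n = 2, seed = 77, n_points = 240)
  r2 <- build_reference(n = 2, seed = 77, n_points = 240)
  expect_identical(as.numeric(r1), as.numeric(r2))
  expect_gt(r1[["W"]], r1[["A"]])

  # Gly entry equals the mean central-residue all-atom SASA (no side chain)
  confs <- gxg_conformers("G", 2, seed = (77 + which(AA_LETTERS == "G")) %%
                            .Machine$integer.max)
  areas <- vapply(confs, function(s) {
    sasa_profile(s, n_points = 240)$residues[2, "total"]
  }, numeric(1))
  expect_equal(r1[["G"]], mean(areas))
  expect_equal(vapply(confs, function(s)
    sasa_profile(s, n_points = 240)$residues[2, "sidechain"], numeric(1)),
    c(0, 0))
})

test_that("reference tables round-trip through their TSV serialization", {
  r1 <- build_reference(n = 1, seed = 5, n_points = 120)
  f <- tempfile(fileext = ".tsv")
  write_reference(r1, f)
  r2 <- read_reference(f)
  expect_equal(as.numeric(r2), as.numeric(r1), tolerance = 1e-12)
  expect_equal(attr(r2, "ensemble_size"), 1L)
  expect_equal(attr(r2, "seed"), 5L)
})

test_that("classification thresholds are strict: boundary ratios are intermediate", {
  ref <- fake_reference(100)
  prof <- fake_profile(rep("ALA", 5), total = c(80, 50, 20, 10, 0),
                       sidechain = c(50 + 1e-9, 50, 20, 20 - 1e-9, 0))
  lab <- classify_residues(prof, ref)
  expect_equal(lab$label,
               c("surface", "intermediate", "intermediate", "nucleus", "nucleus"))
  expect_equal(lab$ratio[5], 0)
})

test_that("Gly is classified by its all-atom ratio", {
  ref <- fake_reference(100)
  prof <- fake_profile(c("GLY", "ALA"), total = c(60, 60), sidechain = c(0, 0))
  lab <- classify_residues(prof, ref)
  expect_equal(lab$label, c("surface", "nucleus"))
})

test_that("classification is invariant to a common positive rescaling", {
  set.seed(21)
  prof <- fake_profile(rep("ALA", 30), total = runif(30, 0, 120),
                       sidechain = runif(30, 0, 100))
  ref <- fake_reference(90)
  for (k in c(0.01, 1, 250)) {
    prof_k <- fake_profile(rep("ALA", 30), total = k * prof$residues$total,
                           sidechain = k * prof$residues$sidechain)
    expect_equal(classify_residues(prof_k, fake_reference(90 * k))$label,
                 classify_residues(prof, ref)$label)
  }
})

test_that("raising side-chain exposure never moves a residue toward the nucleus", {
  ref <- fake_reference(100)
  ranks <- c(nucleus = 1, intermediate = 2, surface = 3)
  labs <- vapply(seq(0, 90, by = 5), function(sc) {
    classify_residues(fake_profile("ALA", 100, sc), ref)$label
  }, character(1))
  expect_true(all(diff(ranks[labs]) >= 0))
})

test_that("environment summary sums members and honors both denominators", {
  ref <- fake_reference(100)
  # ratios: 0.05 (nucleus), 0.8 (surface) -> hand arithmetic (10+30)/2 = 20
  prof <- fake_profile(c("ALA", "VAL"), total = c(10, 30),
                       sidechain = c(5, 80))
  lab <- classify_residues(prof, ref)
  s <- summarize_environment(prof, lab)
  expect_equal(s$n_nucleus, 1); expect_equal(s$n_surface, 1)
  expect_equal(s$total_ave_sasa, 20)
  expect_equal(summarize_environment(prof, lab,
                                     denominator = "length")$total_ave_sasa, 20)

  # single surface residue, denominator 1 -> its own area
  prof1 <- fake_profile("ALA", 42.5, 80)
  lab1 <- classify_residues(prof1, ref)
  expect_equal(summarize_environment(prof1, lab1)$total_ave_sasa, 42.5)

  # all intermediate -> zero totals
  prof2 <- fake_profile(rep("ALA", 3), total = rep(40, 3),
                        sidechain = rep(30, 3))
  lab2 <- classify_residues(prof2, ref)
  s2 <- summarize_environment(prof2, lab2)
  expect_equal(s2$nucleus_total, 0)
  expect_equal(s2$surface_total, 0)
  expect_equal(s2$total_ave_sasa, 0)
})

test_that("nucleus + surface + intermediate partition the total SASA", {
  s <- build_peptide("MKWVLAGDES", phi = -57, psi = -47)
  prof <- sasa_profile(s, n_points = 480)
  lab <- classify_residues(prof, default_reference())
  sm <- summarize_environment(prof, lab)
  inter <- sum(prof$residues$total[lab$label == "intermediate"])
  expect_equal(sm$nucleus_total + sm$surface_total + inter, prof$tsa,
               tolerance = 1e-9)
  expect_equal(sm$n_nucleus + sm$n_surface + sm$n_intermediate,
               nrow(prof$residues))
})
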