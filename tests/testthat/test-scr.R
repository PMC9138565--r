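test_that("two identical ungapped sequences yield one full-width region", {
  aln <- c(a = "MKWVL", b = "MKWVL")
  scrs <- identify_scrs(aln, min_len = 1, min_conservation = 1.0)
  expect_equal(nrow(scrs$regions), 1)
  expect_equal(scrs$regions$start, 0)
  expect_equal(scrs$regions$end, 5)
  expect_equal(scrs$maps$a, 0:4)
})

test_that("a gap in every candidate window vetoes all regions", {
  aln <- c(a = "MK-VL-WD", b = "MKAVLAWD")
  scrs <- identify_scrs(aln, min_len = 3, min_conservation = 0.5)
  expect_equal(nrow(scrs$regions), 0)
  expect_equal(scrs$n_columns, 0)
})

test_that("a hand-traced 3-sequence block is recovered with correct cursor maps", {
  # columns:      0123456789012345
  aln <- c(s1 = "MKWVLA--GDESWQTV",
           s2 = "MKWVLAAAGDESWRTV",
           s3 = "MKWVLAG-GDESWQTV")
  scrs <- identify_scrs(aln, min_len = 5, min_conservation = 1.0)
  # columns 0..5 are gap-free and identical; 6,7 contain gaps; 8..12 are
  # identical (length 5); 13 differs (Q/R/Q passes 2/3 but not 1.0); 14,15
  # identical but run length 2 < 5
  expect_equal(scrs$regions$start, c(0, 8))
  expect_equal(scrs$regions$end, c(6, 13))
  expect_equal(scrs$maps$s1, c(0:5, 6:10))   # s1 skips the 2-gap columns
  expect_equal(scrs$maps$s2, c(0:5, 8:12))
  expect_equal(scrs$maps$s3, c(0:5, 7:11))
})

test_that("SCR identification is permutation-equivariant in sequence order", {
  aln <- c(a = "MKWVLAGDES", b = "MKWVLAGDES", c = "MKAVLAGDWS")
  s1 <- identify_scrs(aln, min_len = 2, min_conservation = 0.6)
  s2 <- identify_scrs(aln[c("c", "a", "b")], min_len = 2,
                      min_conservation = 0.6)
  expect_equal(s1$regions, s2$regions)
  expect_equal(s1$maps$a, s2$maps$a)
  expect_equal(s1$maps$c, s2$maps$c)
})

test_that("explicit interval files define regions with gap and range validation", {
  aln <- c(a = "MKWVLAGDES", b = "MKWVLAGDES")
  f <- tempfile(fileext = ".tsv")
  writeLines(c("start\tend", "1\t4", "6\t9"), f)
  scrs <- read_scr_intervals(f, aln)
  expect_equal(scrs$n_columns, 6)
  expect_equal(scrs$maps$a, c(1:3, 6:8))

  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("start\tend", "5\t20"), f2)
  expect_error(read_scr_intervals(f2, aln), "out of range")

  aln_g <- c(a = "MK-VLAGDES", b = "MKWVLAGDES")
  f3 <- tempfile(fileext = ".tsv")
  writeLines(c("start\tend", "0\t5"), f3)
  expect_error(read_scr_intervals(f3, aln_g), "gapped")
})

test_that("fingerprints pick the mapped residues' SASA in column order", {
  aln <- c(p1 = "MKW", p2 = "MKW")
  scrs <- identify_scrs(aln, min_len = 1, min_conservation = 1.0)
  mk_prof <- function(id, vals) {
    res <- data.frame(res_index = 0:2, res_name = c("MET", "LYS", "TRP"),
                      total = vals, backbone = vals / 2, sidechain = vals / 2,
                      polar = vals / 2, apolar = vals / 2)
    structure(list(id = id, residues = res, tsa = sum(vals),
                   tps = sum(vals) / 2, tas = sum(vals) / 2,
                   scs = sum(vals) / 2, bbs = sum(vals) / 2),
              class = "sasa_profile")
  }
  profs <- list(p1 = mk_prof("p1", c(11, 22, 33)),
                p2 = mk_prof("p2", c(5, 7, 9)))
  fps <- scr_fingerprint(profs, scrs)
  expect_equal(fps$p1, c(11, 22, 33))
  expect_equal(fps$p2, c(5, 7, 9))
  expect_equal(fps$p1 / 2,
               scr_fingerprint(profs, scrs, value = "sidechain")$p1)
  expect_error(scr_fingerprint(profs["p1"], scrs), "missing SASA profile")

  # single-column SCR: fingerprints of length 1 equal that residue's total
  f <- tempfile(fileext = ".tsv")
  writeLines(c("start\tend", "1\t2"), f)
  one <- read_scr_intervals(f, aln)
  expect_equal(scr_fingerprint(profs, one), list(p1 = 22, p2 = 7))
})

test_that("correlation matrix matches the textbook Pearson formula", {
  x <- c(2, 4, 6, 9); y <- c(1, 3, 2, 7)
  long_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  m <- correlation_matrix(list(a = x, b = y))
  expect_equal(m["a", "b"], long_hand)
  expect_equal(diag(m), c(a = 1, b = 1))
  expect_equal(m, t(m))
  # self and negation-about-mean
  m2 <- correlation_matrix(list(a = x, b = x, c = 2 * mean(x) - x))
  expect_equal(m2["a", "b"], 1)
  expect_equal(m2["a", "c"], -1)
})

test_that("correlations are invariant to positive affine rescaling of one fingerprint", {
  set.seed(3)
  fps <- list(a = runif(6), b = runif(6), c = runif(6))
  m0 <- correlation_matrix(fps)
  fps$b <- 3.7 * fps$b + 11
  expect_equal(correlation_matrix(fps), m0, tolerance = 1e-12)
  fps$b <- rep(1, 6)
  expect_error(correlation_matrix(fps), "zero-variance fingerprint: b")
})

test_that("residue preferences tally SCR-mapped positions across all proteins", {
  aln <- c(a = "GGGAV", b = "GGGAV")
  scrs <- identify_scrs(aln, min_len = 1, min_conservation = 1.0)
  counts <- residue_preferences(scrs, c(a = "GGGAV", b = "GGGAV"))
  expect_equal(counts[["G"]], 6L)
  expect_equal(counts[["A"]], 2L)
  expect_equal(counts[["V"]], 2L)
  expect_equal(sum(counts), 10L)

  # brute-force tally oracle on a toy set with partial conservation
  aln2 <- c(p = "MKWVLG", q = "MKAVLG")
  scrs2 <- identify_scrs(aln2, min_len = 2, min_conservation = 0.5)
  expected <- table(factor(c(strsplit("MKWVLG", "")[[1]],
                             strsplit("MKAVLG", "")[[1]]),
                           levels = AA_LETTERS))
  got <- residue_preferences(scrs2, aln2)
  expect_equal(as.integer(got), as.integer(expected))

  # empty SCR set -> all zeros
  scrs3 <- identify_scrs(c(a = "MK", b = "WV"), min_len = 1,
                         min_conservation = 1.0)
  expect_equal(sum(residue_preferences(scrs3, c(a = "MK", b = "WV"))), 0L)
})

test_that("ragged alignments and tiny inputs are rejected", {
  expect_error(identify_scrs(c(a = "MKW", b = "MK")), "ragged")
  expect_error(identify_scrs(c(a = "MKW")), "two sequences")
  expect_error(identify_scrs(c(a = "MKW", b = "MKW"), min_len = 0), "min_len")
})
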