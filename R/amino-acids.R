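# Amino-acid constant tables used across the package.
# Sources: ExPASy ProtParam average residue masses and Bjellqvist pKa values,
# Kyte & Doolittle hydropathy, Ikai aliphatic-index coefficients,
# Chou & Fasman conformational propensities (as tabulated by Prevelige & Fasman).

#' One-letter codes of the 20 canonical amino acids (alphabetical)
#' @export
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

# Average (isotope-abundance weighted) residue masses, Da
AA_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

MASS_WATER <- 18.01524

# Kyte-Doolittle hydropathy
AA_KD <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# Bjellqvist pKa set (ExPASy Compute pI/MW defaults)
PKA_CTERM <- 3.55
PKA_NTERM <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
               V = 7.44, E = 7.70, G = 7.50)
PKA_NTERM_DEFAULT <- 7.50
PKA_SIDE_POS <- c(H = 5.98, K = 10.00, R = 12.00)
PKA_SIDE_NEG <- c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)

# Chou-Fasman conformational propensities
CF_PA <- c(
  A = 1.42, R = 0.98, N = 0.67, D = 1.01, C = 0.70,
  Q = 1.11, E = 1.51, G = 0.57, H = 1.00, I = 1.08,
  L = 1.21, K = 1.16, M = 1.45, F = 1.13, P = 0.57,
  S = 0.77, T = 0.83, W = 1.08, Y = 0.69, V = 1.06)

CF_PB <- c(
  A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19,
  Q = 1.10, E = 0.37, G = 0.75, H = 0.87, I = 1.60,
  L = 1.30, K = 0.74, M = 1.05, F = 1.38, P = 0.55,
  S = 0.75, T = 1.19, W = 1.37, Y = 1.47, V = 1.70)

CF_PT <- c(
  A = 0.66, R = 0.95, N = 1.56, D = 1.46, C = 1.19,
  Q = 0.98, E = 0.74, G = 1.56, H = 0.95, I = 0.47,
  L = 0.59, K = 1.01, M = 0.60, F = 0.60, P = 1.52,
  S = 1.43, T = 0.96, W = 0.96, Y = 1.14, V = 0.50)

# Bend frequencies f(i)..f(i+3) for the turn probability product
CF_F0 <- c(
  A = 0.060, R = 0.070, N = 0.161, D = 0.147, C = 0.149,
  Q = 0.074, E = 0.056, G = 0.102, H = 0.140, I = 0.043,
  L = 0.061, K = 0.055, M = 0.068, F = 0.059, P = 0.102,
  S = 0.120, T = 0.086, W = 0.077, Y = 0.082, V = 0.062)

CF_F1 <- c(
  A = 0.076, R = 0.106, N = 0.083, D = 0.110, C = 0.053,
  Q = 0.098, E = 0.060, G = 0.085, H = 0.047, I = 0.034,
  L = 0.025, K = 0.115, M = 0.082, F = 0.041, P = 0.301,
  S = 0.139, T = 0.108, W = 0.013, Y = 0.065, V = 0.048)

CF_F2 <- c(
  A = 0.035, R = 0.099, N = 0.191, D = 0.179, C = 0.117,
  Q = 0.037, E = 0.077, G = 0.190, H = 0.093, I = 0.013,
  L = 0.036, K = 0.072, M = 0.014, F = 0.065, P = 0.034,
  S = 0.125, T = 0.065, W = 0.064, Y = 0.114, V = 0.028)

CF_F3 <- c(
  A = 0.058, R = 0.085, N = 0.091, D = 0.081, C = 0.128,
  Q = 0.098, E = 0.064, G = 0.152, H = 0.054, I = 0.056,
  L = 0.070, K = 0.095, M = 0.055, F = 0.065, P = 0.068,
  S = 0.106, T = 0.079, W = 0.167, Y = 0.125, V = 0.053)

# Canonical number of heavy side-chain atoms per residue type
AA_SIDECHAIN_HEAVY <- c(
  A = 1, R = 7, N = 4, D = 4, C = 2, Q = 5, E = 5, G = 0, H = 6, I = 4,
  L = 4, K = 5, M = 4, F = 7, P = 3, S = 2, T = 3, W = 10, Y = 8, V = 3)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

validate_sequence <- function(seq, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq) || !nzchar(seq))
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  letters1 <- strsplit(seq, "")[[1]]
  bad <- which(!(letters1 %in% AA_LETTERS))
  if (length(bad))
    stop("illegal residue letter '", letters1[bad[1]], "' at position ",
         bad[1], " of ", what, call. = FALSE)
  invisible(letters1)
}
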