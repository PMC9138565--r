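# Ideal-geometry peptide construction by internal coordinates (NeRF-style
# atom placement). Backbone bond lengths/angles follow Engh-Huber-type
# constants; side chains come from per-residue internal-coordinate templates
# with idealized geometry (no rotamer library).

BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
BOND_C_OXT <- 1.249
BOND_CA_CB <- 1.530
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.8
ANGLE_N_CA_CB <- 110.5
TORS_CB_IMPROPER <- -122.5  # dihedral C(i)-N(i)-CA(i)-CB: L-configuration

deg2rad <- function(d) d * pi / 180

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) v / sqrt(sum(v^2))

# Place atom D given reference atoms A-B-C, |CD| = bond, angle(B,C,D) and
# dihedral(A,B,C,D) in degrees.
place_atom <- function(A, B, C, bond, angle, tors) {
  ang <- deg2rad(angle); tor <- deg2rad(tors)
  bc <- unit3(C - B)
  n <- unit3(cross3(B - A, bc))
  m <- cross3(n, bc)
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               -bond * sin(ang) * sin(tor))
  C + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

#' Dihedral angle defined by four points
#' @param A,B,C,D numeric xyz vectors
#' @return angle in degrees in (-180, 180]
#' @export
dihedral <- function(A, B, C, D) {
  b1 <- B - A; b2 <- C - B; b3 <- D - C
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# Side-chain internal-coordinate templates. Each row: atom name, element,
# three reference atom names, bond length, bond angle, chi index (NA = fixed
# torsion) and torsion offset in degrees (the placed torsion is chi + offset,
# or offset alone when chi is NA). CB is placed generically for all non-Gly
# residues before these rows apply.
sc_row <- function(name, el, a, b, c, bond, angle, chi, off) {
  list(name = name, el = el, a = a, b = b, c = c,
       bond = bond, angle = angle, chi = chi, off = off)
}

SIDECHAIN_TEMPLATES <- list(
  A = list(),
  G = list(),
  S = list(sc_row("OG", "O", "N", "CA", "CB", 1.417, 110.8, 1L, 0)),
  C = list(sc_row("SG", "S", "N", "CA", "CB", 1.808, 113.8, 1L, 0)),
  T = list(sc_row("OG1", "O", "N", "CA", "CB", 1.433, 109.6, 1L, 0),
           sc_row("CG2", "C", "N", "CA", "CB", 1.521, 110.5, 1L, -120)),
  V = list(sc_row("CG1", "C", "N", "CA", "CB", 1.527, 110.5, 1L, 0),
           sc_row("CG2", "C", "N", "CA", "CB", 1.527, 110.5, 1L, 120)),
  L = list(sc_row("CG", "C", "N", "CA", "CB", 1.530, 116.3, 1L, 0),
           sc_row("CD1", "C", "CA", "CB", "CG", 1.521, 110.7, 2L, 0),
           sc_row("CD2", "C", "CA", "CB", "CG", 1.521, 110.7, 2L, 120)),
  I = list(sc_row("CG1", "C", "N", "CA", "CB", 1.530, 110.4, 1L, 0),
           sc_row("CG2", "C", "N", "CA", "CB", 1.521, 110.5, 1L, -120),
           sc_row("CD1", "C", "CA", "CB", "CG1", 1.513, 113.8, 2L, 0)),
  M = list(sc_row("CG", "C", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
           sc_row("SD", "S", "CA", "CB", "CG", 1.803, 112.7, 2L, 0),
           sc_row("CE", "C", "CB", "CG", "SD", 1.791, 100.9, 3L, 0)),
  P = list(sc_row("CG", "C", "N", "CA", "CB", 1.492, 104.5, NA, 30),
           sc_row("CD", "C", "CA", "CB", "CG", 1.503, 106.1, NA, -35)),
  F = list(sc_row("CG", "C", "N", "CA", "CB", 1.502, 113.8, 1L, 0),
           sc_row("CD1", "C", "CA", "CB", "CG", 1.384, 120.8, 2L, 0),
           sc_row("CD2", "C", "CA", "CB", "CG", 1.384, 120.8, 2L, 180),
           sc_row("CE1", "C", "CB", "CG", "CD1", 1.382, 120.8, NA, 180),
           sc_row("CE2", "C", "CB", "CG", "CD2", 1.382, 120.8, NA, 180),
           sc_row("CZ", "C", "CG", "CD1", "CE1", 1.382, 120.0, NA, 0)),
  Y = list(sc_row("CG", "C", "N", "CA", "CB", 1.502, 113.8, 1L, 0),
           sc_row("CD1", "C", "CA", "CB", "CG", 1.384, 120.8, 2L, 0),
           sc_row("CD2", "C", "CA", "CB", "CG", 1.384, 120.8, 2L, 180),
           sc_row("CE1", "C", "CB", "CG", "CD1", 1.382, 120.8, NA, 180),
           sc_row("CE2", "C", "CB", "CG", "CD2", 1.382, 120.8, NA, 180),
           sc_row("CZ", "C", "CG", "CD1", "CE1", 1.382, 120.0, NA, 0),
           sc_row("OH", "O", "CD1", "CE1", "CZ", 1.376, 119.9, NA, 180)),
  W = list(sc_row("CG", "C", "N", "CA", "CB", 1.498, 113.6, 1L, 0),
           sc_row("CD1", "C", "CA", "CB", "CG", 1.365, 126.9, 2L, 0),
           sc_row("CD2", "C", "CA", "CB", "CG", 1.433, 126.8, 2L, 180),
           sc_row("NE1", "N", "CB", "CG", "CD1", 1.374, 110.2, NA, 180),
           sc_row("CE2", "C", "CB", "CG", "CD2", 1.409, 107.2, NA, 180),
           sc_row("CE3", "C", "CB", "CG", "CD2", 1.398, 133.9, NA, 0),
           sc_row("CZ2", "C", "CG", "CD2", "CE2", 1.394, 122.4, NA, 180),
           sc_row("CZ3", "C", "CG", "CD2", "CE3", 1.382, 118.6, NA, 180),
           sc_row("CH2", "C", "CD2", "CE2", "CZ2", 1.368, 117.5, NA, 0)),
  D = list(sc_row("CG", "C", "N", "CA", "CB", 1.516, 112.6, 1L, 0),
           sc_row("OD1", "O", "CA", "CB", "CG", 1.249, 118.4, 2L, 0),
           sc_row("OD2", "O", "CA", "CB", "CG", 1.249, 118.4, 2L, 180)),
  N = list(sc_row("CG", "C", "N", "CA", "CB", 1.516, 112.6, 1L, 0),
           sc_row("OD1", "O", "CA", "CB", "CG", 1.231, 120.8, 2L, 0),
           sc_row("ND2", "N", "CA", "CB", "CG", 1.328, 116.4, 2L, 180)),
  E = list(sc_row("CG", "C", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
           sc_row("CD", "C", "CA", "CB", "CG", 1.516, 112.6, 2L, 0),
           sc_row("OE1", "O", "CB", "CG", "CD", 1.249, 118.4, 3L, 0),
           sc_row("OE2", "O", "CB", "CG", "CD", 1.249, 118.4, 3L, 180)),
  Q = list(sc_row("CG", "C", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
           sc_row("CD", "C", "CA", "CB", "CG", 1.516, 112.6, 2L, 0),
           sc_row("OE1", "O", "CB", "CG", "CD", 1.231, 120.8, 3L, 0),
           sc_row("NE2", "N", "CB", "CG", "CD", 1.328, 116.4, 3L, 180)),
  K = list(sc_row("CG", "C", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
           sc_row("CD", "C", "CA", "CB", "CG", 1.520, 111.3, 2L, 0),
           sc_row("CE", "C", "CB", "CG", "CD", 1.520, 111.3, 3L, 0),
           sc_row("NZ", "N", "CG", "CD", "CE", 1.489, 111.9, 4L, 0)),
  R = list(sc_row("CG", "C", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
           sc_row("CD", "C", "CA", "CB", "CG", 1.520, 111.3, 2L, 0),
           sc_row("NE", "N", "CB", "CG", "CD", 1.461, 112.0, 3L, 0),
           sc_row("CZ", "C", "CG", "CD", "NE", 1.329, 124.2, 4L, 0),
           sc_row("NH1", "N", "CD", "NE", "CZ", 1.326, 120.0, NA, 0),
           sc_row("NH2", "N", "CD", "NE", "CZ", 1.326, 120.0, NA, 180)),
  H = list(sc_row("CG", "C", "N", "CA", "CB", 1.497, 113.8, 1L, 0),
           sc_row("ND1", "N", "CA", "CB", "CG", 1.371, 122.7, 2L, 0),
           sc_row("CD2", "C", "CA", "CB", "CG", 1.356, 131.2, 2L, 180),
           sc_row("CE1", "C", "CB", "CG", "ND1", 1.319, 109.3, NA, 180),
           sc_row("NE2", "N", "CB", "CG", "CD2", 1.374, 107.2, NA, 180)))

#' Number of sampled side-chain torsions per residue type
#' @param aa one-letter residue code
#' @return integer count of chi angles the builder samples or accepts
#' @export
n_chi <- function(aa) {
  tpl <- SIDECHAIN_TEMPLATES[[aa]]
  if (!length(tpl)) return(0L)
  chis <- vapply(tpl, `[[`, integer(1), "chi")
  if (all(is.na(chis))) 0L else max(chis, na.rm = TRUE)
}

#' Build an ideal-geometry peptide Structure
#'
#' Constructs a single-chain peptide with standard bond lengths and angles
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom; trans peptide unless
#' overridden), prescribed backbone dihedrals and side chains placed from
#' internal-coordinate templates. Deterministic given its arguments: the
#' chi sampling mode draws from R's RNG, so set a seed with
#' `withr::with_seed()` / `set.seed()` for reproducible sampled conformers.
#'
#' @param sequence one-letter sequence
#' @param phi,psi backbone dihedrals in degrees, recycled over residues
#'   (phi of residue 1 and psi of the last residue only orient terminal
#'   groups)
#' @param omega peptide-bond dihedral, degrees (180 = trans)
#' @param chi `"trans"` (all side-chain torsions 180), `"sample"` (uniform on
#'   (-180, 180]), or a list of per-residue numeric chi vectors
#' @param radii a [radii_table()] used to assign atom radii
#' @param id protein label
#' @return a `Structure`
#' @export
#' @examples
#' helix <- build_peptide(strrep("A", 10), phi = -57, psi = -47)
build_peptide <- function(sequence, phi = -120, psi = 130, omega = 180,
                          chi = "trans", radii = radii_table(),
                          id = "peptide") {
  letters1 <- validate_sequence(sequence)
  L <- length(letters1)
  phi <- rep_len(phi, L); psi <- rep_len(psi, L); omega <- rep_len(omega, L)

  chi_for <- function(i) {
    k <- n_chi(letters1[i])
    if (k == 0L) return(numeric(0))
    if (identical(chi, "trans")) {
      v <- rep(180, k)
      # planar rings perpendicular to the chi1 plane, as in common rotamers;
      # a 180-degree chi2 would sweep the ring into the next residue
      if (letters1[i] %in% c("F", "Y", "W", "H") && k >= 2L) v[2] <- 90
      v
    }
    else if (identical(chi, "sample")) stats::runif(k, -180, 180)
    else {
      v <- chi[[i]]
      if (length(v) < k)
        stop("residue ", i, " (", letters1[i], ") needs ", k, " chi angles",
             call. = FALSE)
      v[seq_len(k)]
    }
  }

  rows <- list()
  serial <- 0L
  add <- function(name, el, res_i, xyz) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, element = el,
      res_name = AA_THREE[[letters1[res_i]]], res_seq = res_i, chain = "A",
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  }

  a_N <- 111.2
  N <- c(0, 0, 0)
  CA <- c(BOND_N_CA, 0, 0)
  C <- CA + BOND_CA_C * c(-cos(deg2rad(a_N)), sin(deg2rad(a_N)), 0)

  for (i in seq_len(L)) {
    add("N", "N", i, N); add("CA", "C", i, CA); add("C", "C", i, C)
    add("O", "O", i, place_atom(N, CA, C, BOND_C_O, ANGLE_CA_C_O,
                                psi[i] + 180))

    aa <- letters1[i]
    if (aa != "G") {
      pos <- list(N = N, CA = CA, C = C)
      pos$CB <- place_atom(pos$C, pos$N, pos$CA, BOND_CA_CB, ANGLE_N_CA_CB,
                           TORS_CB_IMPROPER)
      add("CB", "C", i, pos$CB)
      chis <- chi_for(i)
      for (row in SIDECHAIN_TEMPLATES[[aa]]) {
        tors <- if (is.na(row$chi)) row$off else chis[row$chi] + row$off
        pos[[row$name]] <- place_atom(pos[[row$a]], pos[[row$b]], pos[[row$c]],
                                      row$bond, row$angle, tors)
        add(row$name, row$el, i, pos[[row$name]])
      }
    }

    if (i < L) {
      N_next <- place_atom(N, CA, C, BOND_C_N, ANGLE_CA_C_N, psi[i])
      CA_next <- place_atom(CA, C, N_next, BOND_N_CA, ANGLE_C_N_CA, omega[i])
      C_next <- place_atom(C, N_next, CA_next, BOND_CA_C, ANGLE_N_CA_C,
                           phi[i + 1])
      N <- N_next; CA <- CA_next; C <- C_next
    } else {
      add("OXT", "O", i, place_atom(N, CA, C, BOND_C_OXT, ANGLE_CA_C_O,
                                    psi[i]))
    }
  }

  atoms <- do.call(rbind, rows)
  atoms$radius <- atom_radius(atoms$element, radii)
  new_structure(id, atoms)
}

#' Detect steric clashes in a Structure
#'
#' Two atoms clash when their distance is below `factor` times the sum of
#' their van der Waals radii; pairs within the same residue and the
#' peptide-bond pair C(i)-N(i+1) are exempt (their short distances are
#' covalent geometry, not clashes).
#'
#' @param s a `Structure`
#' @param factor clash threshold as a fraction of the vdW-radius sum
#' @return logical: any clash present
#' @export
has_clash <- function(s, factor = 0.6) {
  a <- s$atoms
  n <- nrow(a)
  if (n < 2L) return(FALSE)
  d <- as.matrix(stats::dist(cbind(a$x, a$y, a$z)))
  lim <- factor * outer(a$radius, a$radius, "+")
  same_res <- outer(a$res_seq, a$res_seq, "==")
  pep <- (outer(a$res_seq, a$res_seq, function(p, q) q - p == 1L) &
            outer(a$name == "C", a$name == "N", "&")) |
         (outer(a$res_seq, a$res_seq, function(p, q) p - q == 1L) &
            outer(a$name == "N", a$name == "C", "&"))
  bad <- d < lim & !same_res & !pep
  any(bad[upper.tri(bad)])
}

#' Random Gly-X-Gly tripeptide conformers
#'
#' Generates `n` clash-free Gly-X-Gly structures with phi drawn uniformly
#' from (-180, 0), psi from (-180, 180), side-chain chi torsions uniform and
#' the peptide bond trans. Conformers failing the steric-clash filter
#' (distance below 0.6 of the vdW-radius sum) are resampled up to a bounded
#' retry budget. Deterministic in (x, n, seed).
#'
#' @param x one-letter code of the central residue
#' @param n number of conformers
#' @param seed RNG seed
#' @param radii a [radii_table()]
#' @param max_tries retry budget per conformer
#' @return list of `Structure`s
#' @export
gxg_conformers <- function(x, n, seed = 1L, radii = radii_table(),
                           max_tries = 200L) {
  stopifnot(x %in% AA_LETTERS, n >= 1)
  out <- vector("list", n)
  seq3 <- paste0("G", x, "G")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (k in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- build_peptide(seq3,
                         phi = stats::runif(3, -180, 0),
                         psi = stats::runif(3, -180, 180),
                         chi = "sample", radii = radii,
                         id = sprintf("GXG_%s_%03d", x, k))
      if (!has_clash(s)) { ok <- TRUE; break }
    }
    if (!ok)
      stop("could not sample a clash-free Gly-", x, "-Gly conformer in ",
           max_tries, " tries", call. = FALSE)
    out[[k]] <- s
  }
  out
}

#' Generate a synthetic family of related proteins with planted groups
#'
#' All groups share one backbone template. Between groups, the backbone
#' dihedrals are shifted by `dihedral_shift` degrees per group step and
#' `n_edits` residue substitutions are applied; within a group, members are
#' copies of the group structure with isotropic Gaussian coordinate jitter of
#' standard deviation `sigma`. Because edits are substitutions only, the
#' ground-truth alignment is the ungapped identity alignment.
#'
#' @param n_groups number of planted groups
#' @param members_per_group structures per group
#' @param length residues per protein
#' @param sigma within-group coordinate jitter, Angstrom
#' @param n_edits between-group residue substitutions per group step
#' @param dihedral_shift between-group psi shift in degrees per group step
#' @param seed RNG seed
#' @param radii a [radii_table()]
#' @return list with `structures` (named list of `Structure`s), `sequences`
#'   (named character), `alignment` (identical to `sequences`; ungapped),
#'   `labels` (named integer group labels)
#' @export
make_family <- function(n_groups = 3, members_per_group = 3, length = 30,
                        sigma = 0.2, n_edits = 4, dihedral_shift = 60,
                        seed = 1L, radii = radii_table()) {
  stopifnot(n_groups >= 1, members_per_group >= 1, length >= 6, sigma >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  base_seq <- paste(sample(setdiff(AA_LETTERS, "C"), length, replace = TRUE),
                    collapse = "")
  base_phi <- -57; base_psi <- -47

  structures <- list(); sequences <- character(0); labels <- integer(0)
  seq_g <- base_seq
  for (g in seq_len(n_groups)) {
    if (g > 1L && n_edits > 0) {
      pos <- sample(length, min(n_edits, length))
      ch <- strsplit(seq_g, "")[[1]]
      for (p in pos) ch[p] <- sample(setdiff(AA_LETTERS, c(ch[p], "C")), 1)
      seq_g <- paste(ch, collapse = "")
    }
    psi_g <- base_psi + (g - 1) * dihedral_shift
    template <- build_peptide(seq_g, phi = base_phi, psi = psi_g,
                              radii = radii, id = sprintf("g%d", g))
    for (m in seq_len(members_per_group)) {
      id <- sprintf("g%d_m%d", g, m)
      s <- template
      s$id <- id
      if (sigma > 0) {
        n_at <- nrow(s$atoms)
        s$atoms$x <- s$atoms$x + stats::rnorm(n_at, 0, sigma)
        s$atoms$y <- s$atoms$y + stats::rnorm(n_at, 0, sigma)
        s$atoms$z <- s$atoms$z + stats::rnorm(n_at, 0, sigma)
      }
      structures[[id]] <- s
      sequences[id] <- seq_g
      labels[id] <- g
    }
  }
  list(structures = structures, sequences = sequences,
       alignment = sequences, labels = labels)
}
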