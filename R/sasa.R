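#' Deterministic quasi-uniform points on the unit sphere
#'
#' Golden-spiral (Fibonacci) lattice: point i of n sits at
#' z = 1 - 2(i + 0.5)/n, azimuth i * pi * (3 - sqrt(5)). Unit norm holds by
#' construction and the lattice depends only on n.
#'
#' @param n number of points, >= 12
#' @return n x 3 matrix of unit vectors
#' @export
sphere_points <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 12)
    stop("n must be a single integer >= 12", call. = FALSE)
  n <- as.integer(n)
  i <- seq_len(n) - 1L
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Canonical molecule-fixed frame: principal axes of the atom coordinates with
# signs fixed by the skew of the projections (rotation-covariant), third axis
# completing a right-handed system. Sampling directions expressed in this
# frame rotate rigidly with the molecule, which makes the sampled areas
# invariant under rigid motion to within floating-point error.
principal_frame <- function(coords) {
  if (nrow(coords) < 3) return(diag(3))
  cc <- sweep(coords, 2, colMeans(coords))
  V <- eigen(crossprod(cc), symmetric = TRUE)$vectors
  for (k in 1:2) {
    pr <- cc %*% V[, k]
    s3 <- sum(pr^3)
    s <- if (abs(s3) > 1e-8) sign(s3) else sign(pr[which.max(abs(pr))])
    if (s < 0 && s != 0) V[, k] <- -V[, k]
  }
  V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
              V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
              V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  V
}

# Neighbor candidate lists via a uniform spatial grid with cell size equal to
# the largest expanded diameter; 27-cell lookup is then guaranteed to contain
# every atom within R_i + R_j. Returns a list of candidate index vectors.
grid_neighbors <- function(coords, radii_exp) {
  n <- nrow(coords)
  cell <- 2 * max(radii_exp)
  key3 <- floor(sweep(coords, 2, apply(coords, 2, min)) / cell)
  key <- paste(key3[, 1], key3[, 2], key3[, 3])
  cells <- split(seq_len(n), key)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  lapply(seq_len(n), function(i) {
    nb <- unlist(lapply(seq_len(27), function(o) {
      k <- paste(key3[i, 1] + offsets[o, 1], key3[i, 2] + offsets[o, 2],
                 key3[i, 3] + offsets[o, 3])
      cells[[k]]
    }), use.names = FALSE)
    nb[nb != i]
  })
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's van der Waals radius is expanded by the probe radius; `n_points`
#' lattice points are placed on the expanded sphere and the accessible area is
#' the expanded-sphere area times the fraction of points not inside any
#' neighboring expanded sphere. Test points falling exactly on a neighbor
#' sphere count as buried, which makes the computation deterministic.
#'
#' The lattice is expressed in a canonical molecule-fixed frame (principal
#' axes of the coordinates, `orient = "principal"`), so areas are invariant
#' under rigid motion of the Structure; `orient = "fixed"` keeps the lattice
#' in the laboratory frame, under which removing an atom can only ever free
#' sample points (exact occlusion monotonicity).
#'
#' @param s a `Structure`
#' @param radii a [radii_table()]; supplies the probe radius (atom radii come
#'   from the Structure itself)
#' @param n_points sphere points per atom (accuracy/speed trade-off)
#' @param orient sampling-lattice orientation, `"principal"` or `"fixed"`
#' @return numeric vector of per-atom areas in square Angstrom
#' @export
atom_sasa <- function(s, radii = radii_table(), n_points = 960,
                      orient = c("principal", "fixed")) {
  orient <- match.arg(orient)
  stopifnot(inherits(s, "Structure"))
  if (n_points < 12) stop("n_points must be >= 12", call. = FALSE)
  a <- s$atoms
  n <- nrow(a)
  coords <- cbind(a$x, a$y, a$z)
  rexp <- a$radius + radii$probe

  dup <- which(duplicated(coords) | duplicated(coords, fromLast = TRUE))
  if (length(dup)) {
    d <- as.matrix(stats::dist(coords[dup, , drop = FALSE]))
    pair <- which(d == 0 & upper.tri(d), arr.ind = TRUE)[1, ]
    stop("atoms at identical coordinates: ",
         paste(a$name[dup[pair]], a$res_name[dup[pair]],
               a$res_seq[dup[pair]], collapse = " and "), call. = FALSE)
  }

  pts <- sphere_points(n_points)
  if (orient == "principal") pts <- pts %*% t(principal_frame(coords))
  nb_list <- if (n > 1L) grid_neighbors(coords, rexp) else list(integer(0))

  areas <- numeric(n)
  for (i in seq_len(n)) {
    Ri <- rexp[i]
    cand <- nb_list[[i]]
    if (length(cand)) {
      dij <- sqrt(colSums((t(coords[cand, , drop = FALSE]) - coords[i, ])^2))
      cand <- cand[dij < Ri + rexp[cand]]
    }
    if (!length(cand)) {
      areas[i] <- 4 * pi * Ri^2
      next
    }
    test <- pts * Ri
    test <- sweep(test, 2, coords[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in cand) {
      if (!any(free)) break
      dd <- (test[free, 1] - coords[j, 1])^2 +
            (test[free, 2] - coords[j, 2])^2 +
            (test[free, 3] - coords[j, 3])^2
      free[free] <- dd > rexp[j]^2
    }
    areas[i] <- 4 * pi * Ri^2 * sum(free) / n_points
  }
  areas
}

#' Aggregate per-atom areas into a per-residue SASA profile
#'
#' Residue totals are sums over member atoms, decomposed along the atom flags
#' into backbone/side-chain and polar/apolar components; the profile carries
#' the whole-protein aggregates TSA (total), TPS (polar), TAS (apolar),
#' SCS (side chain) and BBS (backbone).
#'
#' @param s a `Structure`
#' @param per_atom per-atom areas from [atom_sasa()]
#' @return object of class `sasa_profile`: data.frame `residues` with columns
#'   res_index (0-based), res_name, total, backbone, sidechain, polar, apolar,
#'   plus fields `id`, `tsa`, `tps`, `tas`, `scs`, `bbs`
#' @export
residue_sasa <- function(s, per_atom) {
  stopifnot(inherits(s, "Structure"))
  a <- s$atoms
  if (length(per_atom) != nrow(a))
    stop("per_atom length (", length(per_atom),
         ") does not match atom count (", nrow(a), ")", call. = FALSE)
  f <- factor(a$res_index, levels = unique(a$res_index))
  sum_by <- function(w) as.numeric(tapply(per_atom * w, f, sum))
  res <- data.frame(
    res_index = as.integer(levels(f)),
    res_name  = a$res_name[!duplicated(a$res_index)],
    total     = sum_by(1),
    backbone  = sum_by(a$is_backbone),
    sidechain = sum_by(!a$is_backbone),
    polar     = sum_by(a$is_polar),
    apolar    = sum_by(!a$is_polar),
    stringsAsFactors = FALSE)
  structure(list(
    id = s$id, residues = res,
    tsa = sum(res$total), tps = sum(res$polar), tas = sum(res$apolar),
    scs = sum(res$sidechain), bbs = sum(res$backbone)),
    class = "sasa_profile")
}

#' @export
print.sasa_profile <- function(x, ...) {
  cat(sprintf(
    "sasa_profile '%s': %d residues  TSA=%.2f TPS=%.2f TAS=%.2f SCS=%.2f BBS=%.2f\n",
    x$id, nrow(x$residues), x$tsa, x$tps, x$tas, x$scs, x$bbs))
  invisible(x)
}

#' One-call per-residue SASA profile of a Structure
#'
#' @inheritParams atom_sasa
#' @return a [residue_sasa()] profile
#' @export
#' @examples
#' s <- build_peptide("GAG", phi = -57, psi = -47)
#' sasa_profile(s)
sasa_profile <- function(s, radii = radii_table(), n_points = 960) {
  residue_sasa(s, atom_sasa(s, radii, n_points))
}
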