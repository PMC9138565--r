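# Shared fixtures and independent oracles for the test suite.

# Minimal atom-table constructor for hand-built geometries
toy_atoms <- function(x, y, z, element = "C", name = NULL, res_name = "ALA",
                      res_seq = NULL, radius = NULL) {
  n <- length(x)
  if (is.null(name)) name <- paste0("C", seq_len(n))
  name[1] <- "CA"
  if (is.null(res_seq)) res_seq <- rep(1L, n)
  if (is.null(radius))
    radius <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85)[rep_len(element, n)]
  data.frame(serial = seq_len(n), name = name,
             element = rep_len(element, n),
             res_name = rep_len(res_name, n), res_seq = res_seq,
             chain = "A", x = x, y = y, z = z, radius = radius,
             stringsAsFactors = FALSE)
}

toy_structure <- function(...) new_structure("toy", toy_atoms(...))

helix_fixture <- function(n = 10) {
  build_peptide(strrep("A", n), phi = -57, psi = -47, id = "helix")
}

# Independent Monte-Carlo SASA estimate: random directions per atom, same
# probe-expansion and burial rule, no shared code with atom_sasa's lattice.
mc_sasa <- function(s, probe = 1.4, n_mc = 40000) {
  a <- s$atoms
  coords <- cbind(a$x, a$y, a$z)
  rexp <- a$radius + probe
  vapply(seq_len(nrow(a)), function(i) {
    dirs <- matrix(stats::rnorm(3 * n_mc), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    pts <- sweep(dirs * rexp[i], 2, coords[i, ], "+")
    free <- rep(TRUE, n_mc)
    for (j in seq_len(nrow(a))[-i]) {
      dd <- rowSums(sweep(pts, 2, coords[j, ])^2)
      free <- free & dd > rexp[j]^2
    }
    4 * pi * rexp[i]^2 * mean(free)
  }, numeric(1))
}

# Naive all-pairs Shrake-Rupley (no spatial grid): reference for the
# neighbor-search contract.
allpairs_sasa <- function(s, probe = 1.4, n_points = 960) {
  a <- s$atoms
  coords <- cbind(a$x, a$y, a$z)
  rexp <- a$radius + probe
  pts <- sphere_points(n_points)
  vapply(seq_len(nrow(a)), function(i) {
    test <- sweep(pts * rexp[i], 2, coords[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(nrow(a))[-i]) {
      dd <- rowSums(sweep(test, 2, coords[j, ])^2)
      free <- free & dd > rexp[j]^2
    }
    4 * pi * rexp[i]^2 * mean(free)
  }, numeric(1))
}

# Exhaustive Ward reference: greedy merging computed from raw points via the
# centroid formula d(A,B) = sqrt(2 |A||B| / (|A|+|B|)) * ||mean_A - mean_B||,
# entirely independent of the Lance-Williams implementation.
ward_oracle <- function(x) {
  n <- nrow(x)
  clusters <- lapply(seq_len(n), function(i) i)
  node <- -seq_len(n)
  merges <- data.frame(left = integer(n - 1), right = integer(n - 1),
                       height = numeric(n - 1), size = integer(n - 1))
  for (step in seq_len(n - 1)) {
    k <- length(clusters)
    best <- NULL; best_d <- Inf
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      A <- clusters[[i]]; B <- clusters[[j]]
      mA <- colMeans(x[A, , drop = FALSE]); mB <- colMeans(x[B, , drop = FALSE])
      d <- sqrt(2 * length(A) * length(B) / (length(A) + length(B)) *
                  sum((mA - mB)^2))
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    merges$left[step] <- node[i]; merges$right[step] <- node[j]
    merges$height[step] <- best_d
    merges$size[step] <- length(clusters[[i]]) + length(clusters[[j]])
    merged <- c(clusters[[i]], clusters[[j]])
    keep <- setdiff(seq_len(k), c(i, j))
    clusters <- c(clusters[keep], list(merged))
    node <- c(node[keep], step)
  }
  merges
}

write_temp_fasta <- function(text) {
  f <- tempfile(fileext = ".fasta")
  writeLines(text, f)
  f
}
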