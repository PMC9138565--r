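#' Euclidean distance matrix between labelled observation vectors
#'
#' @param vectors named list (or row-named matrix) of equal-length numeric
#'   vectors
#' @return symmetric distance matrix with zero diagonal, labelled by id
#' @export
euclidean_distances <- function(vectors) {
  if (is.matrix(vectors)) {
    m <- vectors
  } else {
    lens <- lengths(vectors)
    if (length(unique(lens)) != 1)
      stop("vector length mismatch: ",
           paste(names(vectors), lens, sep = "=", collapse = ", "),
           call. = FALSE)
    m <- do.call(rbind, vectors)
  }
  if (nrow(m) < 2) stop("need at least two vectors", call. = FALSE)
  as.matrix(stats::dist(m, method = "euclidean"))
}

#' Agglomerative Ward clustering via the Lance-Williams recurrence
#'
#' Starting from every observation as a singleton cluster, iteratively merges
#' the pair at minimal Ward distance and updates all distances through the
#' Lance-Williams recurrence on squared distances,
#' d(k, ij)^2 = ((n_i + n_k) d_ik^2 + (n_j + n_k) d_jk^2 - n_k d_ij^2) /
#' (n_i + n_j + n_k).
#' With Euclidean input distances this is the "ward.D2" convention: the merge
#' height equals sqrt(2 * increase in within-cluster sum of squares). Ties are
#' broken towards the smallest (i, j) pair in cluster-creation order, so the
#' result is deterministic.
#'
#' @param dm symmetric distance matrix with labels (from
#'   [euclidean_distances()])
#' @return object of class `linkage_tree`: `merges` data.frame with columns
#'   left, right (negative = leaf index, positive = earlier merge), height
#'   and size, plus `labels`
#' @export
ward_linkage <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  if (n < 2) stop("need at least two leaves", call. = FALSE)
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  d2 <- dm^2
  active <- seq_len(n)          # current clusters, in creation order
  node <- -seq_len(n)           # hclust-style node codes
  sizes <- rep(1L, n)
  merges <- data.frame(left = integer(n - 1), right = integer(n - 1),
                       height = numeric(n - 1), size = integer(n - 1))

  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- c(NA_integer_, NA_integer_); best_d2 <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        v <- d2[i, j]
        if (v < best_d2) { best_d2 <- v; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    ni <- sizes[i]; nj <- sizes[j]

    # Lance-Williams update against every other active cluster
    rest <- setdiff(seq_len(k), c(i, j))
    new_d2 <- vapply(rest, function(h) {
      ((ni + sizes[h]) * d2[i, h] + (nj + sizes[h]) * d2[j, h] -
         sizes[h] * best_d2) / (ni + nj + sizes[h])
    }, numeric(1))

    merges$left[step] <- node[i]
    merges$right[step] <- node[j]
    merges$height[step] <- sqrt(best_d2)
    merges$size[step] <- ni + nj

    d2 <- d2[rest, rest, drop = FALSE]
    d2 <- rbind(cbind(d2, new_d2), c(new_d2, 0))
    sizes <- c(sizes[rest], ni + nj)
    node <- c(node[rest], step)
    active <- seq_len(length(rest) + 1L)
  }
  structure(list(merges = merges, labels = labels), class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("linkage_tree: %d leaves, root height %.4f\n",
              length(x$labels), max(x$merges$height)))
  invisible(x)
}

#' Convert a linkage tree to a stats::hclust object
#' @param t a `linkage_tree`
#' @return an object of class `hclust`
#' @export
as_hclust <- function(t) {
  stopifnot(inherits(t, "linkage_tree"))
  merge <- as.matrix(t$merges[, c("left", "right")])
  dimnames(merge) <- NULL
  leaf_order <- function(node) {
    if (node < 0) return(-node)
    c(leaf_order(merge[node, 1]), leaf_order(merge[node, 2]))
  }
  structure(list(merge = merge, height = t$merges$height,
                 order = leaf_order(nrow(merge)), labels = t$labels,
                 method = "ward.D2", dist.method = "euclidean"),
            class = "hclust")
}

#' Serialize a linkage tree as a Newick string
#'
#' Leaf depths follow the midpoint convention (node depth = merge height / 2,
#' as in standard dendrogram-to-phylogram conversion), so a two-leaf tree
#' merged at height 4 becomes `(a:2,b:2);`.
#'
#' @param t a `linkage_tree`
#' @return single Newick string, terminated by `;`
#' @export
to_newick <- function(t) {
  phy <- ape::as.phylo(as_hclust(t))
  ape::write.tree(phy)
}

#' Cophenetic similarity percentages between all leaf pairs
#'
#' The default transform maps the cophenetic merge height h(i,j) to
#' 100 * (1 - h(i,j) / h_root): identical observations give 100, a pair that
#' first meets at the root gives 0.
#'
#' @param t a `linkage_tree`
#' @param transform function of (h, h_max) returning the similarity
#' @return symmetric matrix of percentages with 100 on the diagonal
#' @export
similarity_percent <- function(t,
                               transform = function(h, h_max)
                                 100 * (1 - h / h_max)) {
  hc <- as_hclust(t)
  coph <- as.matrix(stats::cophenetic(hc))
  h_max <- max(t$merges$height)
  out <- transform(coph, h_max)
  diag(out) <- 100
  out
}

#' Cut a linkage tree into k clusters
#' @param t a `linkage_tree`
#' @param k number of clusters
#' @return named integer vector of cluster memberships
#' @export
cut_clusters <- function(t, k) stats::cutree(as_hclust(t), k = k)

#' Whole-protein SASA summary observation vector
#'
#' The length-independent 9-component feature vector used to cluster
#' unequal-length proteins: TPS, TAS, TSA, SCS, BBS, nucleus and surface
#' totals, average total SASA and residue count.
#'
#' @param profile a `sasa_profile`
#' @param summary an `environment_summary` for the same protein
#' @return named numeric vector of length 9
#' @export
summary_vector <- function(profile, summary) {
  c(TPS = profile$tps, TAS = profile$tas, TSA = profile$tsa,
    SCS = profile$scs, BBS = profile$bbs,
    nucleus = summary$nucleus_total, surface = summary$surface_total,
    total_ave_sasa = summary$total_ave_sasa,
    NAA = nrow(profile$residues))
}

#' Cluster observation vectors with Ward linkage and Euclidean distance
#'
#' @param vectors named list of equal-length numeric vectors
#' @param standardize z-score each feature across observations first
#' @return a `linkage_tree`
#' @export
cluster_observations <- function(vectors, standardize = FALSE) {
  m <- do.call(rbind, vectors)
  if (standardize) {
    sds <- apply(m, 2, stats::sd)
    m <- scale(m, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  }
  ward_linkage(euclidean_distances(m))
}
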