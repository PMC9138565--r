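#' Identify structurally conserved regions from a multiple alignment
#'
#' A column is conserved when it is gap-free in every sequence and its
#' majority residue frequency is at least `min_conservation`; maximal runs of
#' conserved columns of length at least `min_len` become regions. Region
#' coordinates are 0-based half-open intervals in alignment columns, and each
#' region carries per-sequence residue-index maps computed by gap-skipping
#' cursors.
#'
#' @param alignment named character vector of equal-length gapped sequences
#' @param min_len minimum region length in columns
#' @param min_conservation minimum majority-residue frequency per column
#' @return object of class `scr_set`: list with `regions` (data.frame
#'   start/end), `maps` (per-protein list of 0-based residue indices per SCR
#'   column, concatenated region order) and `columns` (the flat 0-based
#'   column indices)
#' @export
identify_scrs <- function(alignment, min_len = 5, min_conservation = 0.5) {
  if (length(alignment) < 2)
    stop("alignment needs at least two sequences", call. = FALSE)
  if (min_len < 1) stop("min_len must be >= 1", call. = FALSE)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1)
    stop("ragged alignment: lengths ", paste(lens, collapse = ", "),
         call. = FALSE)
  mat <- do.call(rbind, strsplit(alignment, ""))
  ncol_aln <- ncol(mat)

  conserved <- vapply(seq_len(ncol_aln), function(j) {
    col <- mat[, j]
    if (any(col == "-")) return(FALSE)
    max(table(col)) / length(col) >= min_conservation
  }, logical(1))

  r <- rle(conserved)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_len)
  regions <- data.frame(start = starts[keep] - 1L, end = ends[keep])

  columns <- unlist(lapply(seq_len(nrow(regions)), function(k)
    seq(regions$start[k], regions$end[k] - 1L)), use.names = FALSE)
  if (is.null(columns)) columns <- integer(0)

  maps <- lapply(seq_len(nrow(mat)), function(i) {
    resno <- cumsum(mat[i, ] != "-") - 1L  # 0-based residue index per column
    as.integer(resno[columns + 1L])
  })
  names(maps) <- names(alignment)

  structure(list(regions = regions, maps = maps, columns = columns,
                 n_columns = length(columns)), class = "scr_set")
}

#' @export
print.scr_set <- function(x, ...) {
  cat(sprintf("scr_set: %d region(s), %d columns, %d protein(s)\n",
              nrow(x$regions), x$n_columns, length(x$maps)))
  invisible(x)
}

#' Read explicit SCR intervals from a BED-like TSV
#'
#' Columns `start` and `end` (0-based half-open, alignment coordinates), one
#' region per line; residue maps are derived from the supplied alignment.
#'
#' @param path TSV file with header `start<TAB>end`
#' @param alignment named character vector of aligned sequences
#' @return an `scr_set`
#' @export
read_scr_intervals <- function(path, alignment) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("start", "end") %in% names(df)))
    stop("interval file must have columns 'start' and 'end'", call. = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  if (any(df$start < 0 | df$end <= df$start) ||
      any(df$end > nchar(alignment[1])))
    stop("intervals out of range or empty", call. = FALSE)
  if (any(utils::head(df$end, -1) > utils::tail(df$start, -1)))
    stop("intervals overlap", call. = FALSE)
  columns <- unlist(lapply(seq_len(nrow(df)), function(k)
    seq(df$start[k], df$end[k] - 1L)), use.names = FALSE)
  mat <- do.call(rbind, strsplit(alignment, ""))
  if (any(mat[, columns + 1L] == "-"))
    stop("intervals cover gapped alignment columns", call. = FALSE)
  maps <- lapply(seq_len(nrow(mat)), function(i) {
    resno <- cumsum(mat[i, ] != "-") - 1L
    as.integer(resno[columns + 1L])
  })
  names(maps) <- names(alignment)
  structure(list(regions = df[, c("start", "end")], maps = maps,
                 columns = columns, n_columns = length(columns)),
            class = "scr_set")
}

#' SCR-SASA fingerprints
#'
#' The fingerprint of a protein is the ordered vector of its residue SASA
#' values at the SCR columns (concatenated region order) - the conserved
#' surface-area descriptor used as the clustering observation. All proteins
#' of one SCR set yield equal-length fingerprints.
#'
#' @param profiles named list of `sasa_profile`s covering every protein in
#'   the SCR set
#' @param scrs an `scr_set`
#' @param value `"total"` (default) or `"sidechain"` residue SASA
#' @return named list of numeric fingerprint vectors
#' @export
scr_fingerprint <- function(profiles, scrs, value = c("total", "sidechain")) {
  value <- match.arg(value)
  stopifnot(inherits(scrs, "scr_set"))
  missing_ids <- setdiff(names(scrs$maps), names(profiles))
  if (length(missing_ids))
    stop("missing SASA profile(s) for: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  out <- lapply(names(scrs$maps), function(id) {
    prof <- profiles[[id]]
    res <- prof$residues
    idx <- match(scrs$maps[[id]], res$res_index)
    if (anyNA(idx))
      stop("SCR map points outside protein '", id, "'", call. = FALSE)
    res[[value]][idx]
  })
  names(out) <- names(scrs$maps)
  out
}

#' Pearson correlation matrix of fingerprints
#'
#' @param fps named list of equal-length fingerprint vectors (>= 2 vectors of
#'   length >= 2)
#' @return symmetric correlation matrix with unit diagonal
#' @export
correlation_matrix <- function(fps) {
  if (length(fps) < 2) stop("need at least two fingerprints", call. = FALSE)
  lens <- lengths(fps)
  if (any(lens < 2) || length(unique(lens)) != 1)
    stop("fingerprints must share one length >= 2", call. = FALSE)
  sds <- vapply(fps, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("zero-variance fingerprint: ",
         paste(names(fps)[sds == 0], collapse = ", "), call. = FALSE)
  m <- stats::cor(do.call(cbind, fps))
  diag(m) <- 1
  m
}

#' Residue-type counts over all SCR positions of all proteins
#'
#' @param scrs an `scr_set`
#' @param sequences named character vector of (ungapped) protein sequences
#' @return named integer vector over the 20 canonical residues
#' @export
residue_preferences <- function(scrs, sequences) {
  stopifnot(inherits(scrs, "scr_set"))
  counts <- stats::setNames(integer(20), AA_LETTERS)
  for (id in names(scrs$maps)) {
    seq1 <- strsplit(sequences[[id]], "")[[1]]
    aa <- seq1[scrs$maps[[id]] + 1L]
    tab <- table(factor(aa, levels = AA_LETTERS))
    counts <- counts + as.integer(tab)
  }
  counts
}
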