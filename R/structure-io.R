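#' @importFrom utils head
NULL

#' Construct a Structure from an atom table
#'
#' A `Structure` is the geometric substrate of all surface-area computations:
#' an ordered table of heavy atoms with coordinates, residue identity, an
#' assigned van der Waals radius and backbone / polarity flags, plus the
#' derived one-letter sequence.
#'
#' @param id protein label
#' @param atoms data.frame with columns serial, name, element, res_name,
#'   res_seq, chain, x, y, z, radius
#' @return object of class `Structure`: a list with `id`, `atoms` (the table,
#'   augmented with `is_backbone`, `is_polar` and 0-based `res_index`) and
#'   `sequence`
#' @export
new_structure <- function(id, atoms) {
  need <- c("serial", "name", "element", "res_name", "res_seq",
            "chain", "x", "y", "z", "radius")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(atoms) == 0L)
    stop("Structure must contain at least one atom", call. = FALSE)
  if (any(atoms$radius <= 0))
    stop("all atom radii must be positive", call. = FALSE)
  unknown <- setdiff(unique(atoms$res_name), names(AA_ONE))
  if (length(unknown))
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(unique(atoms$chain)) > 1L)
    stop("Structure must be single-chain; found chains: ",
         paste(unique(atoms$chain), collapse = ", "), call. = FALSE)

  key <- paste(atoms$chain, atoms$res_seq, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate atom (chain, res_seq, name): ",
         key[anyDuplicated(key)], call. = FALSE)

  atoms <- atoms[order(atoms$res_seq), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms$is_backbone <- atoms$name %in% BACKBONE_ATOMS
  atoms$is_polar <- atoms$element %in% c("N", "O")
  atoms$res_index <- cumsum(!duplicated(atoms$res_seq)) - 1L

  res_names <- atoms$res_name[!duplicated(atoms$res_seq)]
  seq1 <- paste(AA_ONE[res_names], collapse = "")
  structure(list(id = id, atoms = atoms, sequence = seq1),
            class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure '%s': %d residues, %d atoms\n  %s\n",
              x$id, n_residues(x), nrow(x$atoms), x$sequence))
  invisible(x)
}

#' Number of residues in a Structure
#' @param s a `Structure`
#' @export
n_residues <- function(s) length(unique(s$atoms$res_seq))

# PDB v3.3 fixed columns for ATOM records
parse_atom_line <- function(line, lineno) {
  if (nchar(line) < 54)
    stop("malformed ATOM record at line ", lineno,
         ": fewer than 54 columns", call. = FALSE)
  fields <- list(
    serial  = substr(line, 7, 11),
    name    = substr(line, 13, 16),
    altloc  = substr(line, 17, 17),
    resname = substr(line, 18, 20),
    chain   = substr(line, 22, 22),
    resseq  = substr(line, 23, 26),
    icode   = substr(line, 27, 27),
    x       = substr(line, 31, 38),
    y       = substr(line, 39, 46),
    z       = substr(line, 47, 54),
    element = if (nchar(line) >= 78) substr(line, 77, 78) else "")
  num <- suppressWarnings(lapply(fields[c("serial", "resseq", "x", "y", "z")],
                                 function(f) as.numeric(f)))
  if (anyNA(unlist(num)))
    stop("malformed ATOM record at line ", lineno,
         ": non-numeric serial/residue-number/coordinate field",
         call. = FALSE)
  fields[c("serial", "resseq", "x", "y", "z")] <- num
  fields
}

guess_element <- function(atom_name) {
  core <- gsub("[^A-Za-z]", "", atom_name)
  if (!nzchar(core)) return("")
  # two-letter heavy elements do not occur in canonical residues; first
  # alphabetic character identifies the element (handles 1HG1-style H names)
  substr(core, 1, 1)
}

#' Read a single-chain protein structure from a PDB file
#'
#' Retains `ATOM` records only. HETATM records (including waters), hydrogens
#' and alternate locations other than blank/'A' are dropped; insertion codes
#' are folded into the residue ordering. Every retained atom is assigned a
#' van der Waals radius from `radii` and backbone / polarity flags.
#'
#' @param path PDB file
#' @param radii a [radii_table()]
#' @param chain chain identifier to select when the file holds several chains
#' @param id protein label; defaults to the file name without extension
#' @return a [new_structure()] `Structure`
#' @export
read_pdb <- function(path, radii = radii_table(), chain = NULL, id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path, call. = FALSE)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "ATOM ")
  if (!any(is_atom))
    stop("no ATOM records in ", path, call. = FALSE)

  recs <- lapply(which(is_atom), function(i) parse_atom_line(lines[i], i))
  df <- data.frame(
    serial   = vapply(recs, `[[`, numeric(1), "serial"),
    name     = trimws(vapply(recs, `[[`, character(1), "name")),
    element  = trimws(vapply(recs, `[[`, character(1), "element")),
    res_name = trimws(vapply(recs, `[[`, character(1), "resname")),
    res_seq  = as.integer(vapply(recs, `[[`, numeric(1), "resseq")),
    icode    = vapply(recs, `[[`, character(1), "icode"),
    chain    = vapply(recs, `[[`, character(1), "chain"),
    altloc   = vapply(recs, `[[`, character(1), "altloc"),
    x        = vapply(recs, `[[`, numeric(1), "x"),
    y        = vapply(recs, `[[`, numeric(1), "y"),
    z        = vapply(recs, `[[`, numeric(1), "z"),
    stringsAsFactors = FALSE)

  no_el <- !nzchar(df$element)
  df$element[no_el] <- vapply(df$name[no_el], guess_element, character(1))

  df <- df[df$altloc %in% c(" ", "", "A"), , drop = FALSE]
  df <- df[!(df$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(df) == 0L)
    stop("no heavy atoms left after filtering in ", path, call. = FALSE)

  chains <- unique(df$chain)
  if (length(chains) > 1L) {
    if (is.null(chain))
      stop("file contains multiple chains (", paste(chains, collapse = ", "),
           "); select one with the `chain` argument", call. = FALSE)
    df <- df[df$chain == chain, , drop = FALSE]
    if (nrow(df) == 0L)
      stop("chain '", chain, "' not present in ", path, call. = FALSE)
  }

  unknown <- setdiff(unique(df$res_name), names(AA_ONE))
  if (length(unknown))
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  ord <- order(df$res_seq, df$icode)
  df <- df[ord, , drop = FALSE]
  if (any(df$icode != " " & nzchar(df$icode))) {
    # fold insertion codes into a strictly increasing residue number
    res_key <- paste(df$res_seq, df$icode)
    df$res_seq <- cumsum(!duplicated(res_key)) - 1L + df$res_seq[1]
  }
  df$icode <- NULL
  df$altloc <- NULL

  df$radius <- atom_radius(df$element, radii)
  new_structure(id, df)
}

#' Write a Structure as a PDB file
#'
#' @param s a `Structure`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "Structure"))
  a <- s$atoms
  if (nrow(a) == 0L) stop("cannot write an empty Structure", call. = FALSE)
  fmt_name <- ifelse(nchar(a$name) < 4L, sprintf(" %-3s", a$name), a$name)
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    as.integer(a$serial), fmt_name, " ", a$res_name,
    ifelse(nzchar(a$chain), a$chain, "A"), as.integer(a$res_seq), " ",
    a$x, a$y, a$z, 1.0, 0.0, sprintf("%2s", a$element))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Identifiers are the header token before the first whitespace; duplicate ids
#' are an error. In alignment mode the gap character '-' is permitted and all
#' records must have equal length.
#'
#' @param path FASTA file
#' @param aligned logical; read as a rectangular gapped alignment
#' @return named character vector of sequences, in file order
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[anyDuplicated(ids)], call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  allowed <- c(AA_LETTERS, if (aligned) "-")
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!(ch %in% allowed))
    if (length(bad))
      stop("illegal character '", ch[bad[1]], "' at position ", bad[1],
           " of record '", ids[i], "'", call. = FALSE)
  }
  if (aligned && length(unique(nchar(seqs))) != 1L)
    stop("alignment is ragged: record lengths ",
         paste(nchar(seqs), collapse = ", "), call. = FALSE)
  seqs
}

#' Write sequences to a FASTA file
#' @param seqs named character vector
#' @param path output file
#' @return invisibly, `path`
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  invisible(path)
}
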