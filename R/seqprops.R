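#' Amino-acid composition of a sequence
#'
#' @param seq one-letter amino-acid sequence
#' @return named integer vector of counts over the 20 canonical residues
#'   (alphabetical by one-letter code); counts sum to the sequence length
#' @export
#' @examples
#' composition("AAA")[["A"]]
composition <- function(seq) {
  letters1 <- validate_sequence(seq)
  counts <- table(factor(letters1, levels = AA_LETTERS))
  stats::setNames(as.integer(counts), AA_LETTERS)
}

net_charge <- function(pH, comp, nterm) {
  pk_n <- if (nterm %in% names(PKA_NTERM)) PKA_NTERM[[nterm]] else PKA_NTERM_DEFAULT
  pos <- 1 / (1 + 10^(pH - pk_n))
  for (a in names(PKA_SIDE_POS))
    pos <- pos + comp[[a]] / (1 + 10^(pH - PKA_SIDE_POS[[a]]))
  neg <- 1 / (1 + 10^(PKA_CTERM - pH))
  for (a in names(PKA_SIDE_NEG))
    neg <- neg + comp[[a]] / (1 + 10^(PKA_SIDE_NEG[[a]] - pH))
  pos - neg
}

#' Isoelectric point by bisection on the modeled net charge
#'
#' Net charge is modeled with the Bjellqvist pKa set (ExPASy Compute pI
#' defaults: C-terminus 3.55, residue-specific N-terminus, D 4.05, E 4.45,
#' H 5.98, C 9.0, Y 10.0, K 10.0, R 12.0); the pH axis is bisected until the
#' absolute charge falls below `tol`.
#'
#' @param seq one-letter sequence
#' @param tol absolute net-charge tolerance at the solution
#' @return pI in pH units
#' @export
isoelectric_point <- function(seq, tol = 1e-4) {
  letters1 <- validate_sequence(seq)
  comp <- composition(seq)
  nterm <- letters1[1]
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(mid, comp, nterm)
    if (abs(q) < tol || (hi - lo) < 1e-10) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Sequence-level physiochemical descriptors
#'
#' ProtParam-convention descriptors: residue count, molecular weight from
#' average residue masses, isoelectric point (Bjellqvist pKa, bisection),
#' charged-residue counts, Ikai aliphatic index and Kyte-Doolittle GRAVY.
#'
#' @param seq one-letter amino-acid sequence
#' @return list of class `seq_descriptors` with fields `naa`, `mw`, `pi`,
#'   `neg` (Asp+Glu), `pos` (Arg+Lys), `ai`, `gravy`, `composition`
#' @export
#' @examples
#' d <- descriptors("MKLVINSG")
#' d$mw
descriptors <- function(seq) {
  validate_sequence(seq)
  comp <- composition(seq)
  naa <- sum(comp)
  mw <- sum(comp * AA_AVG_MASS[AA_LETTERS]) + MASS_WATER
  gravy <- sum(comp * AA_KD[AA_LETTERS]) / naa
  ai <- 100 * (comp[["A"]] + 2.9 * comp[["V"]] +
                 3.9 * (comp[["I"]] + comp[["L"]])) / naa
  structure(list(
    naa = naa,
    mw = mw,
    pi = isoelectric_point(seq),
    neg = comp[["D"]] + comp[["E"]],
    pos = comp[["R"]] + comp[["K"]],
    ai = ai,
    gravy = gravy,
    composition = comp), class = "seq_descriptors")
}

#' @export
print.seq_descriptors <- function(x, ...) {
  cat(sprintf(
    "seq_descriptors: naa=%d mw=%.2f pi=%.2f D+E=%d R+K=%d ai=%.2f gravy=%.3f\n",
    x$naa, x$mw, x$pi, x$neg, x$pos, x$ai, x$gravy))
  invisible(x)
}

#' Descriptor table for a set of sequences
#'
#' @param seqs named character vector of sequences
#' @return data.frame, one row per sequence, with the [descriptors()] fields
#' @export
descriptor_table <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) > 0)
  rows <- lapply(seq_along(seqs), function(i) {
    d <- descriptors(seqs[[i]])
    data.frame(id = names(seqs)[i], NAA = d$naa, MW = d$mw, pI = d$pi,
               `Asp.Glu` = d$neg, `Arg.Lys` = d$pos, AI = d$ai,
               GRAVY = d$gravy, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build a deterministic sequence with a prescribed composition
#'
#' Emits a synthetic sequence realizing exact per-residue counts: an optional
#' fixed first residue followed by the remaining residues in alphabetical
#' one-letter order. Because every descriptor computed by [descriptors()] is a
#' composition function, such a reconstruction carries the same descriptor
#' values as any real sequence with those counts.
#'
#' @param counts named count vector over the 20 canonical letters
#' @param first residue to place first (e.g. "M" for a translated ORF), or
#'   `NULL` for purely alphabetical order
#' @return one-letter sequence string
#' @export
sequence_from_composition <- function(counts, first = "M") {
  stopifnot(all(names(counts) %in% AA_LETTERS), all(counts >= 0))
  counts_full <- stats::setNames(integer(20), AA_LETTERS)
  counts_full[names(counts)] <- as.integer(counts)
  prefix <- character(0)
  if (!is.null(first)) {
    if (counts_full[[first]] < 1)
      stop("composition has no '", first, "' to place first", call. = FALSE)
    counts_full[[first]] <- counts_full[[first]] - 1L
    prefix <- first
  }
  paste(c(prefix, rep(AA_LETTERS, counts_full)), collapse = "")
}
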