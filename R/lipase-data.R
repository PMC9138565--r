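#' Published amino-acid compositions of the Amycolatopsis eburnea lipases
#'
#' Per-residue counts for the eight lipases (UniProt accessions A0A3R9KNJ9,
#' A0A3R9DUJ4, A0A427T6P4, A0A3R9KMI2, A0A3R9EQB2, A0A3R9F8T1, A0A3R9DV90,
#' A0A427T2R3), shipped as plain-text data. Because every sequence-level
#' descriptor in [descriptors()] is a composition function, these counts
#' suffice to evaluate the descriptors without the full sequences;
#' [lipase_sequences()] builds composition-exact synthetic stand-ins.
#'
#' @return data.frame with columns id, accession, length and one count column
#'   per one-letter residue code
#' @export
lipase_compositions <- function() {
  utils::read.table(system.file("extdata", "lipase_composition.tsv",
                                package = "scrsasa", mustWork = TRUE),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Synthetic stand-in sequences with the published lipase compositions
#'
#' Reconstructs one sequence per lipase from [lipase_compositions()] via
#' [sequence_from_composition()], Met-initiated (bacterial ORFs start with
#' Met; lipase 6 has no Met count and keeps alphabetical order). The residue
#' order is synthetic; every composition-level descriptor equals that of the
#' real protein.
#'
#' @return named character vector of sequences, named by lipase id
#' @export
lipase_sequences <- function() {
  tab <- lipase_compositions()
  seqs <- vapply(seq_len(nrow(tab)), function(i) {
    counts <- unlist(tab[i, AA_LETTERS])
    first <- if (counts[["M"]] > 0) "M" else NULL
    sequence_from_composition(counts, first = first)
  }, character(1))
  stats::setNames(seqs, tab$id)
}
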