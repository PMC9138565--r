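cf_extend <- function(score, start, end, win = 4L, cut = 1.0) {
  n <- length(score)
  # grow rightwards while the tetrapeptide ending at the candidate residue
  # keeps an average propensity at or above the cutoff
  while (end < n) {
    w <- score[max(1L, end + 1L - win + 1L):(end + 1L)]
    if (mean(w) >= cut) end <- end + 1L else break
  }
  while (start > 1L) {
    w <- score[(start - 1L):min(n, start - 1L + win - 1L)]
    if (mean(w) >= cut) start <- start - 1L else break
  }
  c(start, end)
}

cf_mask <- function(score, win, min_formers, cut = 1.0) {
  n <- length(score)
  mask <- logical(n)
  if (n < win) return(mask)
  for (i in 1:(n - win + 1L)) {
    idx <- i:(i + win - 1L)
    if (sum(score[idx] >= cut) >= min_formers) {
      se <- cf_extend(score, i, i + win - 1L)
      mask[se[1]:se[2]] <- TRUE
    }
  }
  mask
}

#' Chou-Fasman secondary-structure prediction
#'
#' Classic propensity-based prediction. Helices nucleate in any hexapeptide
#' with at least four residues of alpha propensity >= 1.00 and extend in both
#' directions while the trailing tetrapeptide keeps a mean alpha propensity
#' >= 1.00; sheets nucleate in pentapeptides with at least three strong
#' formers and extend analogously. A turn is flagged at position i when the
#' bend-frequency product f(i)f(i+1)f(i+2)f(i+3) exceeds 7.5e-5, the mean
#' turn propensity of the tetrapeptide exceeds 1.00, and that mean exceeds
#' both the mean alpha and mean beta propensities of the same window.
#'
#' Helix/sheet/turn masks may overlap (the reporting convention of classic
#' Chou-Fasman servers, whose percentage columns can sum above 100); a
#' resolved single-label track assigns overlaps to the state with the larger
#' mean propensity, with turns winning wherever the turn test fires.
#'
#' @param seq one-letter amino-acid sequence, length >= 6
#' @return object of class `ss_prediction`: logical masks `helix`, `sheet`,
#'   `turn`; character vector `resolved` over {H,E,T,C}; percentages
#'   `pct_helix`, `pct_sheet`, `pct_turn`
#' @export
#' @examples
#' p <- cf_predict("AEAAEAKAAEAEAAKAAE")
#' p$pct_helix
cf_predict <- function(seq) {
  letters1 <- validate_sequence(seq)
  n <- length(letters1)
  if (n < 6L)
    stop("sequence shorter than the helix nucleation window (6)", call. = FALSE)

  pa <- unname(CF_PA[letters1])
  pb <- unname(CF_PB[letters1])
  pt <- unname(CF_PT[letters1])

  helix <- cf_mask(pa, win = 6L, min_formers = 4L)
  sheet <- cf_mask(pb, win = 5L, min_formers = 3L)

  turn <- logical(n)
  if (n >= 4L) {
    f0 <- unname(CF_F0[letters1]); f1 <- unname(CF_F1[letters1])
    f2 <- unname(CF_F2[letters1]); f3 <- unname(CF_F3[letters1])
    for (i in 1:(n - 3L)) {
      idx <- i:(i + 3L)
      p_t <- f0[i] * f1[i + 1L] * f2[i + 2L] * f3[i + 3L]
      if (p_t > 7.5e-5 && mean(pt[idx]) > 1.0 &&
          mean(pt[idx]) > mean(pa[idx]) && mean(pt[idx]) > mean(pb[idx]))
        turn[i] <- TRUE
    }
  }

  resolved <- rep("C", n)
  resolved[helix & !sheet] <- "H"
  resolved[sheet & !helix] <- "E"
  both <- helix & sheet
  if (any(both)) {
    r <- rle(both)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      resolved[idx] <- if (mean(pa[idx]) >= mean(pb[idx])) "H" else "E"
    }
  }
  resolved[turn] <- "T"

  structure(list(
    helix = helix, sheet = sheet, turn = turn, resolved = resolved,
    pct_helix = 100 * sum(helix) / n,
    pct_sheet = 100 * sum(sheet) / n,
    pct_turn = 100 * sum(turn) / n), class = "ss_prediction")
}

#' @export
print.ss_prediction <- function(x, ...) {
  cat(sprintf("ss_prediction: helix %.1f%%, sheet %.1f%%, turn %.1f%%\n",
              x$pct_helix, x$pct_sheet, x$pct_turn))
  invisible(x)
}

#' Secondary-structure percentage table for a set of sequences
#' @param seqs named character vector of sequences
#' @return data.frame with columns id, Helix, Sheet, Turn (percent)
#' @export
ss_table <- function(seqs) {
  rows <- lapply(seq_along(seqs), function(i) {
    p <- cf_predict(seqs[[i]])
    data.frame(id = names(seqs)[i], Helix = p$pct_helix,
               Sheet = p$pct_sheet, Turn = p$pct_turn,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
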