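#' @title Composition and coverage signatures
#' @name signatures
#' @description Windowed %G+C (120 nt windows, 30 nt step, the scale used
#'   to inspect scaffold regions), tetranucleotide frequency vectors (5000
#'   nt tiling windows, the scale used for ESOM-style binning), and mean
#'   scaffold read coverage from per-base depth tables.
NULL

#' Windowed %G+C
#'
#' Per window, `100 * (G + C) / (A + C + G + T)`; `N` is excluded from the
#' denominator. Windows slide by `step`; trailing partial windows are
#' dropped. Sequences shorter than one window yield an empty profile with
#' a warning.
#'
#' @param seq nucleotide string (or `DNAString`).
#' @param window window size in nt (default 120).
#' @param step step size in nt (default 30); requires `window >= step >= 1`.
#' @return data.frame `start` (1-based window start), `gc` (percent;
#'   `NaN` for all-N windows).
#' @export
gc_windows <- function(seq, window = 120L, step = 30L) {
  if (!(window >= step && step >= 1)) stop("need window >= step >= 1")
  s <- Biostrings::DNAString(toupper(as.character(seq)))
  if (length(s) < window) {
    warning("sequence shorter than one window; empty profile")
    return(data.frame(start = integer(), gc = numeric()))
  }
  starts <- seq.int(1L, length(s) - window + 1L, by = step)
  v <- Biostrings::Views(s, start = starts, width = window)
  freq <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
  denom <- rowSums(freq)
  data.frame(start = starts,
             gc = 100 * (freq[, "G"] + freq[, "C"]) / denom)
}

#' Tetranucleotide frequency vectors over tiling windows
#'
#' Windows tile the sequence every `window` nt; the trailing partial
#' window is kept when at least 4 nt long. Overlapping tetramers are
#' counted per window (tetramers containing `N` are skipped) and
#' normalized to frequencies summing to 1 per window (all-zero windows
#' stay zero). Counting is on the given strand only, 256 columns in
#' lexicographic order; `collapse = TRUE` merges each tetramer with its
#' reverse complement into the 136 canonical columns.
#'
#' @param seq nucleotide string (or `DNAString`); case-insensitive.
#' @param window tiling window size (default 5000).
#' @param collapse merge reverse-complement tetramer pairs.
#' @return matrix windows x tetramers, rownames = 1-based window starts.
#' @export
tetra_freq <- function(seq, window = 5000L, collapse = FALSE) {
  s <- Biostrings::DNAString(toupper(as.character(seq)))
  n <- length(s)
  starts <- seq.int(1L, max(1L, n), by = window)
  starts <- starts[n - starts + 1L >= 4L]
  if (length(starts) == 0L)
    return(matrix(numeric(0), nrow = 0, ncol = 256))
  ends <- pmin(starts + window - 1L, n)
  v <- Biostrings::Views(s, start = starts, width = ends - starts + 1L)
  counts <- Biostrings::oligonucleotideFrequency(v, width = 4L, step = 1L)
  if (collapse) {
    tets <- colnames(counts)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(tets)))
    canon <- ifelse(tets <= rc, tets, rc)
    counts <- t(rowsum(t(counts), canon))
    # self-complementary tetramers were not doubled; nothing to halve
  }
  tot <- rowSums(counts)
  tot[tot == 0] <- 1
  freq <- counts / tot
  rownames(freq) <- starts
  freq
}

#' Mean read coverage of a scaffold
#'
#' Sum of per-base depths divided by the declared scaffold length;
#' positions absent from the table contribute depth 0. The length must be
#' declared explicitly (e.g. from the assembly FASTA) so zero-depth tails
#' are averaged correctly.
#'
#' @param depths data.frame with columns `pos` and `depth` for one
#'   scaffold (see [read_depth_table()]).
#' @param scaffold_length declared scaffold length (>= max position).
#' @return mean depth (numeric scalar).
#' @export
mean_coverage <- function(depths, scaffold_length) {
  if (scaffold_length < 1) stop("scaffold_length must be >= 1")
  if (nrow(depths) && any(depths$pos > scaffold_length))
    stop("depth position exceeds declared scaffold length")
  if (nrow(depths) && any(depths$depth < 0)) stop("negative depth value(s)")
  sum(depths$depth) / scaffold_length
}
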