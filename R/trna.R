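#' @title tRNA anticodon-loop nucleotide usage
#' @name trna_usage
#' @description Nucleotide usage at the anticodon-loop positions 38, 39
#'   and 40 (standard numbering; the residues immediately 3' of the
#'   anticodon) per tRNA isotype, and group-vs-group comparison. These
#'   positions are the targets of pseudouridine synthase A (TruA); in
#'   lineages that have lost *truA*, reduced T usage at the modified
#'   positions is the compensatory signature this analysis measures.
#'   Position mapping uses fixed offsets from the anticodon (+4, +5, +6),
#'   valid for canonical cloverleaves; `U` is read as `T` throughout (DNA
#'   space).
NULL

#' Nucleotides at standard positions 38, 39, 40 of a tRNA
#'
#' With the anticodon at standard positions 34-36, positions 38/39/40 are
#' the bases at offsets `anticodon_start + 4, + 5, + 6` (0-based).
#' Records too short to contain position 40 are rejected (callers
#' typically skip them; see [usage_matrix()]).
#'
#' @param seq tRNA sequence (DNA space; `U` mapped to `T`).
#' @param anticodon the 3-nt anticodon; must match the sequence at
#'   `anticodon_start`.
#' @param anticodon_start 0-based index of the anticodon within `seq`.
#' @return named character vector of bases at positions `"38"`, `"39"`,
#'   `"40"`, or `NULL` when the record is too short.
#' @export
loop_positions <- function(seq, anticodon, anticodon_start) {
  seq <- toupper(chartr("U", "T", seq))
  anticodon <- toupper(chartr("U", "T", anticodon))
  if (is.na(anticodon_start)) return(NULL)
  ac <- substr(seq, anticodon_start + 1L, anticodon_start + 3L)
  if (ac != anticodon)
    stop("anticodon mismatch: sequence has '", ac, "', record says '",
         anticodon, "'")
  if (anticodon_start + 6L >= nchar(seq)) return(NULL)
  bases <- strsplit(substr(seq, anticodon_start + 5L, anticodon_start + 7L),
                    "", fixed = TRUE)[[1]]
  stats::setNames(bases, c("38", "39", "40"))
}

#' Nucleotide-usage matrix at positions 38-40 per isotype
#'
#' Counts are pooled across all records in the group (phylum-level
#' pooling); isotypes with zero usable records are omitted. Records too
#' short for position 40 are skipped with a warning.
#'
#' @param records data.frame of tRNA records with columns `isotype`,
#'   `seq`, `anticodon`, `anticodon_start` (see [read_trnascan_table()]
#'   and [generate_trna_set()]).
#' @param group label stored on the result.
#' @return a `usage_matrix`: data.frame with one row per (isotype,
#'   position): counts `A`, `C`, `G`, `T`, total `n`, and frequencies
#'   `freq_A` ... `freq_T`; attribute `group`.
#' @export
usage_matrix <- function(records, group = "group") {
  usable <- !is.na(records$seq) & !is.na(records$anticodon_start)
  records <- records[usable, ]
  if (nrow(records) == 0L) stop("no usable tRNA records")
  rows <- list()
  n_skip <- 0L
  for (i in seq_len(nrow(records))) {
    lp <- loop_positions(records$seq[i], records$anticodon[i],
                         records$anticodon_start[i])
    if (is.null(lp)) { n_skip <- n_skip + 1L; next }
    rows[[length(rows) + 1L]] <-
      data.frame(isotype = records$isotype[i], position = names(lp),
                 base = unname(lp), stringsAsFactors = FALSE)
  }
  if (n_skip > 0L)
    warning(n_skip, " record(s) too short for position 40 skipped")
  if (length(rows) == 0L) stop("no usable tRNA records")
  long <- do.call(rbind, rows)
  long <- long[long$base %in% c("A", "C", "G", "T"), ]
  tab <- table(paste(long$isotype, long$position, sep = "\r"), long$base)
  keys <- strsplit(rownames(tab), "\r", fixed = TRUE)
  out <- data.frame(isotype = vapply(keys, `[`, character(1), 1),
                    position = as.integer(vapply(keys, `[`, character(1), 2)),
                    stringsAsFactors = FALSE)
  for (b in c("A", "C", "G", "T"))
    out[[b]] <- if (b %in% colnames(tab)) as.integer(tab[, b]) else 0L
  out$n <- out$A + out$C + out$G + out$T
  for (b in c("A", "C", "G", "T"))
    out[[paste0("freq_", b)]] <- out[[b]] / out$n
  out <- out[order(out$isotype, out$position), ]
  rownames(out) <- NULL
  attr(out, "group") <- group
  class(out) <- c("usage_matrix", "data.frame")
  out
}

#' Compare nucleotide usage between two groups
#'
#' Per shared (isotype, position) cell, the frequency difference
#' `freq_a - freq_b` for one nucleotide, with both cell counts. Cells
#' where either group has fewer than `min_n` records are masked (dropped).
#'
#' @param matrix_a,matrix_b [usage_matrix()] results.
#' @param nucleotide which base to compare (default `"T"`, the TruA
#'   target).
#' @param min_n minimum records per cell in both groups (default 5).
#' @return data.frame `isotype`, `position`, `freq_a`, `freq_b`, `delta`,
#'   `n_a`, `n_b`.
#' @export
compare_usage <- function(matrix_a, matrix_b, nucleotide = "T", min_n = 5L) {
  fc <- paste0("freq_", nucleotide)
  m <- merge(matrix_a[, c("isotype", "position", fc, "n")],
             matrix_b[, c("isotype", "position", fc, "n")],
             by = c("isotype", "position"), suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) stop("the two matrices share no (isotype, position) cell")
  m <- m[m$n_a >= min_n & m$n_b >= min_n, ]
  out <- data.frame(isotype = m$isotype, position = m$position,
                    freq_a = m[[paste0(fc, "_a")]],
                    freq_b = m[[paste0(fc, "_b")]],
                    n_a = m$n_a, n_b = m$n_b,
                    stringsAsFactors = FALSE)
  out$delta <- out$freq_a - out$freq_b
  out <- out[order(out$isotype, out$position),
             c("isotype", "position", "freq_a", "freq_b", "delta",
               "n_a", "n_b")]
  rownames(out) <- NULL
  out
}
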