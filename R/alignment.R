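#' @title Exact protein local alignment
#' @name alignment
#' @description Smith-Waterman optimal local alignment with affine gaps,
#'   the engine behind BBH orthology and pan-genome accumulation. Scoring
#'   defaults follow BLASTp (BLOSUM62, gap open 11, gap extend 1; a gap of
#'   length k costs `open + k * extend`). Identity and positives are
#'   computed over aligned columns with all columns (including gaps) as the
#'   denominator; coverage is the aligned span divided by each sequence's
#'   full length. The dynamic program is exact (no heuristic seeding), so
#'   results are deterministic.
NULL

# substitution matrices come from Biostrings' data; cached per session
sub_matrix <- local({
  cache <- list()
  function(name = "BLOSUM62") {
    if (is.null(cache[[name]])) {
      e <- new.env()
      ok <- tryCatch({
        utils::data(list = name, package = "Biostrings", envir = e)
        TRUE
      }, warning = function(w) FALSE)
      if (!ok || is.null(e[[name]])) stop("unknown substitution matrix: ", name)
      cache[[name]] <<- e[[name]]
    }
    cache[[name]]
  }
})

encode_seqs <- function(seqs, alphabet) {
  lapply(strsplit(unname(seqs), "", fixed = TRUE), function(ch) {
    idx <- match(ch, alphabet)
    if (anyNA(idx)) stop("residue(s) outside the substitution matrix alphabet")
    idx - 1L
  })
}

#' Smith-Waterman local alignment of two protein sequences
#'
#' @param a,b residue strings (non-empty).
#' @param matrix_name substitution matrix name (a Biostrings matrix, e.g.
#'   `"BLOSUM62"`, `"BLOSUM45"`, `"PAM250"`).
#' @param gap_open,gap_extend affine gap parameters; a gap of length k costs
#'   `gap_open + k * gap_extend`. Requires `gap_open >= gap_extend >= 0`.
#' @return An `alignment_hit`: one-row data.frame with `query_id`,
#'   `subject_id`, `score`, `pct_identity`, `pct_positives`, `q_cov`,
#'   `s_cov`, `aln_length`, `q_start`, `q_end`, `s_start`, `s_end`
#'   (1-based inclusive). If no positive-scoring local alignment exists the
#'   score is 0 and no span is reported (coordinates 0, `NA` statistics).
#' @export
align_local <- function(a, b, matrix_name = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (!(gap_open >= gap_extend && gap_extend >= 0))
    stop("need gap_open >= gap_extend >= 0")
  S <- sub_matrix(matrix_name)
  enc <- encode_seqs(c(a = toupper(a), b = toupper(b)), rownames(S))
  r <- .sw_pair(enc[[1]], enc[[2]], S, gap_open, gap_extend)
  hit_frame(r, nchar(a), nchar(b))
}

hit_frame <- function(r, len_a, len_b) {
  no_hit <- r$score <= 0
  data.frame(
    query_id = NA_character_, subject_id = NA_character_,
    score = r$score,
    pct_identity = if (no_hit) NA_real_ else 100 * r$n_ident / r$aln_length,
    pct_positives = if (no_hit) NA_real_ else 100 * r$n_pos / r$aln_length,
    q_cov = if (no_hit) 0 else (r$q_end - r$q_start + 1) / len_a,
    s_cov = if (no_hit) 0 else (r$s_end - r$s_start + 1) / len_b,
    aln_length = r$aln_length,
    q_start = r$q_start, q_end = r$q_end,
    s_start = r$s_start, s_end = r$s_end,
    stringsAsFactors = FALSE)
}

#' All-vs-all local alignment between two proteomes
#'
#' Aligns every query x subject pair and reports hits whose raw score
#' reaches `min_score`. In `prefilter = "none"` mode (the default) every
#' pair is evaluated with the exact dynamic program. `prefilter = "kmer"`
#' restricts the dynamic program to pairs sharing at least
#' `min_shared_kmers` exact k-mers (k = `kmer_k`) -- a deterministic screen
#' used at scale; at the package's default divergence (<= 30%) true homolog
#' pairs share hundreds of 5-mers, so the screen is effectively lossless
#' (see the methods vignette).
#'
#' @param A,B [proteome()] objects. Self-mode (`A` identical to `B`) skips
#'   self-pairs so each gene's best hit is its closest paralog.
#' @param matrix_name,gap_open,gap_extend scoring parameters, as
#'   [align_local()].
#' @param min_score reporting floor on the raw score.
#' @param prefilter `"none"` or `"kmer"`.
#' @param kmer_k,min_shared_kmers prefilter parameters.
#' @return data.frame of hits in the [align_local()] layout with
#'   `query_id`/`subject_id` filled in.
#' @export
all_vs_all <- function(A, B, matrix_name = "BLOSUM62",
                       gap_open = 11, gap_extend = 1, min_score = 40,
                       prefilter = c("none", "kmer"),
                       kmer_k = 5L, min_shared_kmers = 3L) {
  prefilter <- match.arg(prefilter)
  stopifnot(inherits(A, "proteome"), inherits(B, "proteome"))
  S <- sub_matrix(matrix_name)
  alpha <- rownames(S)
  ea <- encode_seqs(A$seqs, alpha)
  eb <- encode_seqs(B$seqs, alpha)
  self_mode <- identical(A$genome_id, B$genome_id)
  if (prefilter == "kmer") {
    pairs <- .kmer_candidates(ea, eb, as.integer(kmer_k),
                              as.integer(min_shared_kmers), length(alpha))
  } else {
    pairs <- as.matrix(expand.grid(seq_along(ea) - 1L, seq_along(eb) - 1L))
    storage.mode(pairs) <- "integer"
  }
  if (self_mode && nrow(pairs))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty_hits())
  res <- .sw_batch(ea, eb, pairs, S, gap_open, gap_extend, min_score)
  if (nrow(res) == 0L) return(empty_hits())
  len_a <- nchar(A$seqs)[res$query_idx]
  len_b <- nchar(B$seqs)[res$subject_idx]
  out <- data.frame(
    query_id = A$ids[res$query_idx],
    subject_id = B$ids[res$subject_idx],
    score = res$score,
    pct_identity = 100 * res$n_ident / res$aln_length,
    pct_positives = 100 * res$n_pos / res$aln_length,
    q_cov = (res$q_end - res$q_start + 1) / len_a,
    s_cov = (res$s_end - res$s_start + 1) / len_b,
    aln_length = res$aln_length,
    q_start = res$q_start, q_end = res$q_end,
    s_start = res$s_start, s_end = res$s_end,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Hits for every ordered genome pair of a set
#'
#' Runs [all_vs_all()] once per unordered genome pair and derives the
#' reverse direction by symmetry (under a symmetric substitution matrix
#' the optimal local score is symmetric; identity, positives and length
#' carry over and the query/subject roles of coverage and coordinates
#' swap). This halves the alignment work and makes reciprocal best-hit
#' relations exactly symmetric.
#'
#' @param proteomes named list of [proteome()] objects.
#' @inheritParams all_vs_all
#' @return data.frame of hits covering all ordered pairs.
#' @export
all_pairs_hits <- function(proteomes, matrix_name = "BLOSUM62",
                           gap_open = 11, gap_extend = 1, min_score = 40,
                           prefilter = "none", kmer_k = 5L,
                           min_shared_kmers = 3L) {
  stopifnot(length(proteomes) >= 2L)
  idx <- utils::combn(seq_along(proteomes), 2)
  out <- vector("list", 2L * ncol(idx))
  for (k in seq_len(ncol(idx))) {
    h <- all_vs_all(proteomes[[idx[1, k]]], proteomes[[idx[2, k]]],
                    matrix_name = matrix_name, gap_open = gap_open,
                    gap_extend = gap_extend, min_score = min_score,
                    prefilter = prefilter, kmer_k = kmer_k,
                    min_shared_kmers = min_shared_kmers)
    out[[2 * k - 1L]] <- h
    out[[2 * k]] <- swap_hits(h)
  }
  do.call(rbind, out)
}

swap_hits <- function(h) {
  data.frame(query_id = h$subject_id, subject_id = h$query_id,
             score = h$score, pct_identity = h$pct_identity,
             pct_positives = h$pct_positives,
             q_cov = h$s_cov, s_cov = h$q_cov,
             aln_length = h$aln_length,
             q_start = h$s_start, q_end = h$s_end,
             s_start = h$q_start, s_end = h$q_end,
             stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             score = numeric(), pct_identity = numeric(),
             pct_positives = numeric(), q_cov = numeric(),
             s_cov = numeric(), aln_length = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             stringsAsFactors = FALSE)
}

#' Convert internal hits to the 12/15-column BLAST tabular layout
#'
#' Mismatches are approximated as non-identical columns (gap columns
#' excluded are not distinguished); e-values are not computed and written
#' as 0. Mainly for interchange with [write_blast_tabular()].
#'
#' @param hits data.frame from [all_vs_all()].
#' @return data.frame in the tabular layout (extended columns included).
#' @export
hits_to_tabular <- function(hits) {
  data.frame(
    query_id = hits$query_id, subject_id = hits$subject_id,
    pct_identity = round(hits$pct_identity, 3),
    aln_length = hits$aln_length,
    mismatches = as.integer(round(hits$aln_length *
                                    (1 - hits$pct_identity / 100))),
    gap_opens = 0L,
    q_start = hits$q_start, q_end = hits$q_end,
    s_start = hits$s_start, s_end = hits$s_end,
    evalue = 0, bit_score = hits$score,
    q_cov = round(hits$q_cov, 4), s_cov = round(hits$s_cov, 4),
    pct_positives = round(hits$pct_positives, 3),
    stringsAsFactors = FALSE)
}

#' Convert tabular hits (e.g. external BLAST output) to internal hits
#'
#' 12-column input lacks coverage and positives; these are reconstructed
#' from the aligned spans (`q_cov`, `s_cov`) using sequence lengths from
#' the supplied proteomes, and `pct_positives` falls back to
#' `pct_identity` (a conservative floor) unless present.
#'
#' @param tab data.frame from [read_blast_tabular()].
#' @param A,B the query and subject [proteome()]s (for sequence lengths).
#' @return data.frame in the [all_vs_all()] layout.
#' @export
tabular_to_hits <- function(tab, A, B) {
  len_a <- stats::setNames(nchar(A$seqs), A$ids)[tab$query_id]
  len_b <- stats::setNames(nchar(B$seqs), B$ids)[tab$subject_id]
  if (anyNA(len_a) || anyNA(len_b))
    stop("hit ids absent from the supplied proteomes")
  q_cov <- tab$q_cov %||% ((tab$q_end - tab$q_start + 1) / len_a)
  s_cov <- tab$s_cov %||% ((tab$s_end - tab$s_start + 1) / len_b)
  data.frame(
    query_id = tab$query_id, subject_id = tab$subject_id,
    score = tab$bit_score,
    pct_identity = tab$pct_identity,
    pct_positives = tab$pct_positives %||% tab$pct_identity,
    q_cov = unname(q_cov), s_cov = unname(s_cov),
    aln_length = tab$aln_length,
    q_start = tab$q_start, q_end = tab$q_end,
    s_start = tab$s_start, s_end = tab$s_end,
    stringsAsFactors = FALSE)
}
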