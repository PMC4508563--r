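# Independent oracles and small fixtures used across the suite.

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Brute-force optimal local alignment score by exhaustive enumeration of all
# monotone residue matchings (equal-length index subsets of both sequences).
# Gap runs between consecutive matched columns are penalized affinely
# (open + extend * length, per sequence). Enumerates every legal local
# alignment that starts and ends on a substitution column, so its maximum
# equals the Smith-Waterman optimum. Exponential: lengths <= 8 only.
bf_local_score <- function(a, b, S, gap_open = 11, gap_extend = 1) {
  A <- match(strsplit(a, "", fixed = TRUE)[[1]], rownames(S))
  B <- match(strsplit(b, "", fixed = TRUE)[[1]], rownames(S))
  m <- length(A)
  n <- length(B)
  best <- 0
  for (L in seq_len(min(m, n))) {
    ia_list <- utils::combn(m, L, simplify = FALSE)
    ib_list <- utils::combn(n, L, simplify = FALSE)
    for (ia in ia_list) {
      ga <- if (L > 1) diff(ia) - 1L else integer(0)
      pen_a <- sum((gap_open + gap_extend * ga)[ga > 0])
      rowsA <- A[ia]
      for (ib in ib_list) {
        gb <- if (L > 1) diff(ib) - 1L else integer(0)
        pen <- pen_a + sum((gap_open + gap_extend * gb)[gb > 0])
        sc <- sum(S[cbind(rowsA, B[ib])]) - pen
        if (sc > best) best <- sc
      }
    }
  }
  best
}

random_aa <- function(len, alphabet = c("A", "C", "D", "E", "F", "G", "H",
                                        "I", "K", "L", "M", "N", "P", "Q",
                                        "R", "S", "T", "V", "W", "Y")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Pairwise-disjoint proteomes by construction: each genome draws from its
# own residue block, and every cross-block BLOSUM62 substitution score is
# non-positive, so no cross-genome local alignment can score above zero.
disjoint_proteomes <- function(sizes, len = 60, seed = 42) {
  blocks <- list(c("A", "V", "L", "I"),
                 c("D", "E", "K", "R"),
                 c("F", "Y", "W", "H"))
  stopifnot(length(sizes) <= length(blocks))
  S <- blosum62()
  for (i in seq_along(sizes)) for (j in seq_along(sizes)) if (i != j)
    stopifnot(max(S[blocks[[i]], blocks[[j]]]) <= 0)
  set.seed(seed)
  out <- lapply(seq_along(sizes), function(i) {
    gid <- sprintf("D%02d", i)
    seqs <- vapply(seq_len(sizes[i]), function(j)
      random_aa(len, blocks[[i]]), character(1))
    names(seqs) <- sprintf("%s_g%03d", gid, seq_len(sizes[i]))
    proteome(gid, seqs)
  })
  names(out) <- vapply(out, `[[`, character(1), "genome_id")
  out
}

# truth labels for clustering comparison: planted family, or the gene's own
# id for planted-unique genes
truth_labels <- function(truth, gene_ids) {
  fam <- truth$gene_to_family[gene_ids]
  ifelse(fam == "UNIQUE", gene_ids, fam)
}

recovered_labels <- function(table) {
  ifelse(is.na(table$genes$family_id), table$genes$gene_id,
         table$genes$family_id)
}
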