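#' @title BBH orthology with an AAI-adaptive identity filter
#' @name orthology
#' @description Bidirectional best hits are computed per genome pair; a hit
#'   qualifies only if the aligned region covers at least `min_cov` (70% by
#'   default) of the protein length on both sequences. The percent
#'   identities of the provisional BBH set define the genome pair's average
#'   amino-acid identity (AAI); pairs whose identity falls more than
#'   `aai_window` (2 by default) standard deviations below the AAI are
#'   discarded. The filtered pairs across all genome pairs form a weighted
#'   gene graph that is clustered into ortholog families with the Markov
#'   Cluster (MCL) algorithm.
NULL

#' Best hit per query gene
#'
#' For each query, the subject with maximal score; ties broken by higher
#' percent identity, then lexicographically smaller subject id. Queries
#' with no hits are absent from the result.
#'
#' @param hits data.frame of hits from one ordered genome pair
#'   ([all_vs_all()] layout).
#' @return named character vector query gene -> best subject gene.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(stats::setNames(character(0), character(0)))
  ord <- order(hits$query_id, -hits$score, -hits$pct_identity,
               hits$subject_id, method = "radix")
  h <- hits[ord, ]
  first <- !duplicated(h$query_id)
  stats::setNames(h$subject_id[first], h$query_id[first])
}

#' Bidirectional best hits for one genome pair, with the AAI filter
#'
#' Stage 1: reciprocal best-hit pairs whose A->B hit passes the coverage
#' filter form the provisional BBH set (coverage on both sequences when
#' `cov_mode = "both"`, on the query only when `"query"`). Stage 2: the
#' mean and SD of their percent identities define the genome pair's AAI.
#' Stage 3: pairs with identity below `mean - aai_window * SD` are removed
#' (one-sided; discarding pairs for being too similar would be
#' nonsensical).
#'
#' @param bh_ab,bh_ba best-hit maps from [best_hits()] for the two
#'   directions.
#' @param hits the A->B hit table (for coverage/identity lookup).
#' @param min_cov minimum aligned-span coverage (default 0.70).
#' @param aai_window SD multiplier of the identity filter (default 2).
#' @param cov_mode `"both"` or `"query"`.
#' @return list with `pairs` (data.frame `gene_a`, `gene_b`,
#'   `pct_identity`, `score`) and `aai` (list `mean_identity`,
#'   `sd_identity`, `n_pairs`; all `NA`/0 and `defined = FALSE` when no
#'   provisional pair exists).
#' @export
bbh_pairs <- function(bh_ab, bh_ba, hits, min_cov = 0.70, aai_window = 2.0,
                      cov_mode = c("both", "query")) {
  cov_mode <- match.arg(cov_mode)
  empty <- list(pairs = data.frame(gene_a = character(),
                                   gene_b = character(),
                                   pct_identity = numeric(),
                                   score = numeric()),
                aai = list(mean_identity = NA_real_, sd_identity = NA_real_,
                           n_pairs = 0L, defined = FALSE))
  if (length(bh_ab) == 0L || length(bh_ba) == 0L) return(empty)
  a <- names(bh_ab)
  b <- unname(bh_ab)
  recip <- !is.na(bh_ba[b]) & bh_ba[b] == a
  recip[is.na(recip)] <- FALSE
  a <- a[recip]; b <- b[recip]
  if (length(a) == 0L) return(empty)
  key <- paste(hits$query_id, hits$subject_id, sep = "\r")
  idx <- match(paste(a, b, sep = "\r"), key)
  h <- hits[idx, ]
  pass <- if (cov_mode == "both") h$q_cov >= min_cov & h$s_cov >= min_cov
          else h$q_cov >= min_cov
  a <- a[pass]; b <- b[pass]; h <- h[pass, ]
  if (length(a) == 0L) return(empty)
  m <- mean(h$pct_identity)
  s <- if (length(a) > 1L) stats::sd(h$pct_identity) else 0
  keep <- h$pct_identity >= m - aai_window * s
  list(pairs = data.frame(gene_a = a[keep], gene_b = b[keep],
                          pct_identity = h$pct_identity[keep],
                          score = h$score[keep],
                          stringsAsFactors = FALSE),
       aai = list(mean_identity = m, sd_identity = s,
                  n_pairs = length(a), defined = TRUE))
}

#' Build the ortholog graph from filtered BBH pairs
#'
#' Nodes are genes (all genes of all proteomes, so unmatched genes appear
#' as isolated nodes); edges are the accepted pairs, weighted by
#' `pct_identity / 100` (or raw score).
#'
#' @param pairs data.frame with `gene_a`, `gene_b`, `pct_identity`,
#'   `score` -- typically row-bound output of [bbh_pairs()] over all genome
#'   pairs.
#' @param genes character vector of all gene ids (isolated nodes included).
#' @param weight `"identity"` or `"score"`.
#' @return an [igraph::graph] (undirected, weighted).
#' @export
build_graph <- function(pairs, genes, weight = c("identity", "score")) {
  weight <- match.arg(weight)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(genes), name = genes)
  if (nrow(pairs)) {
    w <- if (weight == "identity") pairs$pct_identity / 100 else pairs$score
    g <- igraph::add_edges(g, rbind(pairs$gene_a, pairs$gene_b),
                           weight = w)
  }
  g
}

# MCL on one dense column-stochastic matrix; returns membership integer
# vector (per column/node).
mcl_dense <- function(A, inflation, max_iter, prune_threshold, tol) {
  n <- ncol(A)
  diag(A) <- apply(A, 2, max)          # self-loops at max incident weight
  diag(A)[diag(A) == 0] <- 1           # isolated nodes
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                      # expansion
    M2 <- M2^inflation                 # inflation
    M2[M2 < prune_threshold] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    if (max(abs(M2 - M)) < tol) { M <- M2; converged <- TRUE; break }
    M <- M2
  }
  # clusters are read off attractor rows (nonzero diagonal); overlapping
  # attractor systems are merged
  attract <- which(diag(M) > prune_threshold)
  member <- rep(NA_integer_, n)
  cl <- 0L
  for (a in attract) {
    nodes <- which(M[a, ] > prune_threshold)
    nodes <- union(nodes, a)
    hit <- unique(stats::na.omit(member[nodes]))
    if (length(hit)) {
      tgt <- hit[1L]
      member[nodes] <- tgt
      if (length(hit) > 1L) member[member %in% hit[-1L]] <- tgt
    } else {
      cl <- cl + 1L
      member[nodes] <- cl
    }
  }
  orphan <- which(is.na(member))
  if (length(orphan)) {
    member[orphan] <- cl + seq_along(orphan)
  }
  list(membership = member, converged = converged)
}

#' Markov clustering of the ortholog graph
#'
#' Column-normalizes the weighted adjacency matrix with self-loops (weight
#' = the node's maximum incident edge weight), then alternates expansion
#' (matrix squaring) and inflation (elementwise power `inflation`, then
#' renormalization), pruning entries below `prune_threshold`, until the
#' iterate changes by less than `tol` or `max_iter` is reached. Clusters
#' are read off attractor rows. The graph is first split into connected
#' components and MCL run per component (components never merge under
#' MCL, and this keeps the matrices small). Isolated nodes become
#' singletons.
#'
#' @param graph weighted undirected [igraph::graph] from [build_graph()].
#' @param inflation inflation exponent (> 1; default 2).
#' @param max_iter iteration cap (default 200); non-convergence returns the
#'   current clustering with a warning.
#' @param prune_threshold entries below this are zeroed (default 1e-5).
#' @param tol convergence tolerance on the max elementwise change.
#' @return named integer vector: gene id -> cluster id.
#' @export
mcl_cluster <- function(graph, inflation = 2.0, max_iter = 200L,
                        prune_threshold = 1e-5, tol = 1e-8) {
  if (inflation <= 1) stop("inflation must be > 1")
  comp <- igraph::components(graph)
  genes <- igraph::V(graph)$name
  member <- integer(length(genes))
  names(member) <- genes
  next_id <- 0L
  any_nonconv <- FALSE
  for (ci in seq_len(comp$no)) {
    nodes <- which(comp$membership == ci)
    if (length(nodes) == 1L) {
      next_id <- next_id + 1L
      member[nodes] <- next_id
      next
    }
    sub <- igraph::induced_subgraph(graph, nodes)
    A <- as.matrix(igraph::as_adjacency_matrix(sub, attr = "weight",
                                               sparse = TRUE))
    r <- mcl_dense(A, inflation, max_iter, prune_threshold, tol)
    if (!r$converged) any_nonconv <- TRUE
    member[nodes] <- r$membership + next_id
    next_id <- next_id + max(r$membership)
  }
  if (any_nonconv)
    warning("MCL did not converge within max_iter on some component(s); ",
            "returning the current clustering")
  member
}

#' Assemble an ortholog table from a clustering
#'
#' Clusters with two or more members become families; single-member
#' clusters are singletons. Family ids are deterministic: families are
#' numbered by decreasing size, ties broken by the lexicographically
#' smallest member gene id.
#'
#' @param membership named integer vector from [mcl_cluster()].
#' @param gene_genomes named character vector gene id -> genome id.
#' @param aai optional data.frame of per-genome-pair AAI records.
#' @return an `ortholog_table`: list with `genes` (data.frame `gene_id`,
#'   `genome_id`, `family_id` -- `NA` for singletons), `families`
#'   (data.frame `family_id`, `n_genes`, `n_genomes`), `n_genomes`, `aai`.
#' @export
ortholog_table <- function(membership, gene_genomes, aai = NULL) {
  genes <- names(membership)
  if (is.null(genes)) stop("membership must be named by gene id")
  genome <- unname(gene_genomes[genes])
  if (anyNA(genome)) stop("gene(s) missing from gene_genomes")
  size <- table(membership)
  multi <- names(size)[size >= 2L]
  first_member <- vapply(split(genes, membership), min, character(1))
  ord <- multi[order(-as.integer(size[multi]), first_member[multi])]
  fam_ids <- stats::setNames(sprintf("F%05d", seq_along(ord)), ord)
  family_id <- unname(fam_ids[as.character(membership)])
  df <- data.frame(gene_id = genes, genome_id = genome,
                   family_id = family_id, stringsAsFactors = FALSE)
  fam <- df[!is.na(df$family_id), ]
  fams <- data.frame(
    family_id = unname(fam_ids[ord]),
    n_genes = as.integer(size[ord]),
    n_genomes = vapply(split(fam$genome_id, fam$family_id)[unname(fam_ids[ord])],
                       function(g) length(unique(g)), integer(1)),
    stringsAsFactors = FALSE)
  rownames(fams) <- NULL
  structure(list(genes = df, families = fams,
                 n_genomes = length(unique(genome)), aai = aai),
            class = "ortholog_table")
}

#' @export
print.ortholog_table <- function(x, ...) {
  cat(sprintf(
    "<ortholog_table> %d genes over %d genomes: %d families (%d genes), %d singletons\n",
    nrow(x$genes), x$n_genomes, nrow(x$families),
    sum(x$families$n_genes), sum(is.na(x$genes$family_id))))
  invisible(x)
}

#' Presence/absence (copy-count) matrix of an ortholog table
#'
#' @param table an `ortholog_table`.
#' @param include_singletons include singleton genes as one-row families
#'   named after the gene.
#' @return integer matrix families x genomes.
#' @export
presence_absence <- function(table, include_singletons = FALSE) {
  df <- table$genes
  genomes <- sort(unique(df$genome_id))
  fam <- df[!is.na(df$family_id), ]
  rows <- table$families$family_id
  m <- matrix(0L, nrow = length(rows), ncol = length(genomes),
              dimnames = list(rows, genomes))
  if (nrow(fam)) {
    t2 <- table(fam$family_id, fam$genome_id)
    m[rownames(t2), colnames(t2)] <- as.integer(t2)
  }
  if (include_singletons) {
    sing <- df[is.na(df$family_id), ]
    if (nrow(sing)) {
      m2 <- matrix(0L, nrow = nrow(sing), ncol = length(genomes),
                   dimnames = list(sing$gene_id, genomes))
      m2[cbind(seq_len(nrow(sing)), match(sing$genome_id, genomes))] <- 1L
      m <- rbind(m, m2)
    }
  }
  m
}

#' Flag multi-copy families (putative contamination / paralogy)
#'
#' @param table an `ortholog_table`.
#' @return data.frame `family_id`, `genome_id`, `copy_count` for every
#'   (family, genome) with two or more members, sorted by count descending.
#' @export
flag_multicopy <- function(table) {
  fam <- table$genes[!is.na(table$genes$family_id), ]
  if (nrow(fam) == 0L)
    return(data.frame(family_id = character(), genome_id = character(),
                      copy_count = integer()))
  t2 <- as.data.frame(table(family_id = fam$family_id,
                            genome_id = fam$genome_id),
                      stringsAsFactors = FALSE)
  t2 <- t2[t2$Freq >= 2L, ]
  out <- data.frame(family_id = t2$family_id, genome_id = t2$genome_id,
                    copy_count = as.integer(t2$Freq),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$copy_count, out$family_id, out$genome_id), ]
  rownames(out) <- NULL
  out
}

#' Infer ortholog families across a genome set
#'
#' Runs the full orthology stage: all-vs-all alignment (or externally
#' supplied hits), per-genome-pair bidirectional best hits with the
#' coverage and AAI-adaptive identity filters, graph construction, and MCL
#' clustering.
#'
#' @param proteomes named list of [proteome()] objects (>= 2).
#' @param hits optional precomputed hits: a data.frame in the
#'   [all_vs_all()] layout covering all ordered genome pairs (e.g. imported
#'   external search results via [tabular_to_hits()]). When `NULL` the
#'   built-in aligner is used.
#' @param min_cov,aai_window,cov_mode BBH filter parameters, see
#'   [bbh_pairs()].
#' @param inflation MCL inflation.
#' @param prefilter,min_score alignment parameters passed to
#'   [all_vs_all()] (ignored when `hits` is given).
#' @param weight edge weighting for the graph, see [build_graph()].
#' @return an [ortholog_table()] with the per-pair AAI table attached.
#' @export
infer_orthologs <- function(proteomes, hits = NULL,
                            min_cov = 0.70, aai_window = 2.0,
                            cov_mode = "both", inflation = 2.0,
                            prefilter = "none", min_score = 40,
                            weight = "identity") {
  if (length(proteomes) < 2L) stop("need at least two proteomes")
  gene_genomes <- unlist(unname(lapply(proteomes, function(p)
    stats::setNames(rep(p$genome_id, n_genes(p)), p$ids))))
  if (anyDuplicated(names(gene_genomes)))
    stop("gene ids must be unique across genomes")
  gids <- vapply(proteomes, `[[`, character(1), "genome_id")
  if (is.null(hits))
    hits <- all_pairs_hits(proteomes, prefilter = prefilter,
                           min_score = min_score)
  hit_qg <- gene_genomes[hits$query_id]
  hit_sg <- gene_genomes[hits$subject_id]
  pair_idx <- utils::combn(seq_along(proteomes), 2)
  all_pairs <- list()
  aai_rows <- list()
  for (k in seq_len(ncol(pair_idx))) {
    i <- pair_idx[1, k]; j <- pair_idx[2, k]
    h_ab <- hits[which(hit_qg == gids[i] & hit_sg == gids[j]), ]
    h_ba <- hits[which(hit_qg == gids[j] & hit_sg == gids[i]), ]
    bb <- bbh_pairs(best_hits(h_ab), best_hits(h_ba), h_ab,
                    min_cov = min_cov, aai_window = aai_window,
                    cov_mode = cov_mode)
    all_pairs[[k]] <- bb$pairs
    aai_rows[[k]] <- data.frame(genome_a = gids[i], genome_b = gids[j],
                                mean_identity = bb$aai$mean_identity,
                                sd_identity = bb$aai$sd_identity,
                                n_pairs = bb$aai$n_pairs,
                                stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, all_pairs)
  aai <- do.call(rbind, aai_rows)
  pp_log("ortho", sprintf(
    "%d genomes, %d genes, %d accepted BBH pairs", length(proteomes),
    length(gene_genomes), nrow(pairs)))
  g <- build_graph(pairs, names(gene_genomes), weight = weight)
  member <- mcl_cluster(g, inflation = inflation)
  ortholog_table(member, gene_genomes, aai = aai)
}
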