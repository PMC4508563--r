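mk_hits <- function(q, s, score, pid = 90, qc = 1, sc = 1) {
  data.frame(query_id = q, subject_id = s, score = score,
             pct_identity = pid, pct_positives = pmax(pid, 50),
             q_cov = qc, s_cov = sc, aln_length = 100L,
             q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
             stringsAsFactors = FALSE)
}

test_that("best_hits takes max score with identity then id tie-breaks", {
  h <- mk_hits(c("a1", "a1", "a2"), c("b1", "b2", "b9"),
               score = c(100, 100, 55), pid = c(90, 80, 70))
  bh <- best_hits(h)
  expect_equal(unname(bh["a1"]), "b1")   # identity tie-break
  expect_equal(unname(bh["a2"]), "b9")
  h2 <- mk_hits(c("a1", "a1"), c("b2", "b1"), score = c(70, 70), pid = c(85, 85))
  expect_equal(unname(best_hits(h2)["a1"]), "b1")  # lexicographic tie-break

  # random tables equal a brute-force per-query max scan
  set.seed(6)
  for (rep in 1:10) {
    n <- 40
    h3 <- mk_hits(sample(paste0("q", 1:8), n, TRUE),
                  sample(paste0("s", 1:8), n, TRUE),
                  score = sample(50:60, n, TRUE),
                  pid = runif(n, 50, 99))
    h3 <- h3[!duplicated(h3[, c("query_id", "subject_id")]), ]
    bh3 <- best_hits(h3)
    for (q in unique(h3$query_id)) {
      sub <- h3[h3$query_id == q, ]
      sub <- sub[order(-sub$score, -sub$pct_identity, sub$subject_id), ]
      expect_equal(unname(bh3[q]), sub$subject_id[1])
    }
  }
})

test_that("bbh coverage filter excludes low-coverage pairs on either side", {
  h_ab <- mk_hits(c("a1", "a2"), c("b1", "b2"), score = c(90, 95),
                  pid = c(88, 91), qc = c(0.65, 0.9), sc = c(0.95, 0.9))
  h_ba <- mk_hits(c("b1", "b2"), c("a1", "a2"), score = c(90, 95))
  bb <- bbh_pairs(best_hits(h_ab), best_hits(h_ba), h_ab)
  expect_equal(bb$pairs$gene_a, "a2")  # a1-b1 fails 70% query coverage
  # the laxer single-sided reading admits subject-side shortfalls
  h_ab2 <- mk_hits("a1", "b1", 90, pid = 88, qc = 0.9, sc = 0.5)
  h_ba2 <- mk_hits("b1", "a1", 90)
  expect_equal(nrow(bbh_pairs(best_hits(h_ab2), best_hits(h_ba2),
                              h_ab2)$pairs), 0L)
  expect_equal(nrow(bbh_pairs(best_hits(h_ab2), best_hits(h_ba2), h_ab2,
                              cov_mode = "query")$pairs), 1L)
})

test_that("the AAI 2-SD filter removes stray low-identity pairs only", {
  # 20 genuine pairs near 90% (sd ~2) plus one stray at 35%
  set.seed(8)
  pid <- c(rnorm(20, 90, 2), 35)
  q <- paste0("a", 1:21); s <- paste0("b", 1:21)
  h_ab <- mk_hits(q, s, score = rep(100, 21), pid = pid)
  h_ba <- mk_hits(s, q, score = rep(100, 21), pid = pid)
  bb <- bbh_pairs(best_hits(h_ab), best_hits(h_ba), h_ab)
  expect_false("a21" %in% bb$pairs$gene_a)
  expect_equal(nrow(bb$pairs), 20L)
  expect_equal(bb$aai$n_pairs, 21L)
  # SD = 0 degenerates to equality: everything retained
  h_eq <- mk_hits(q[1:5], s[1:5], score = rep(100, 5), pid = rep(80, 5))
  h_eq_r <- mk_hits(s[1:5], q[1:5], score = rep(100, 5), pid = rep(80, 5))
  bb2 <- bbh_pairs(best_hits(h_eq), best_hits(h_eq_r), h_eq)
  expect_equal(nrow(bb2$pairs), 5L)
  # widening the window never removes an accepted pair
  bb3 <- bbh_pairs(best_hits(h_ab), best_hits(h_ba), h_ab, aai_window = 30)
  expect_true(all(bb$pairs$gene_a %in% bb3$pairs$gene_a))
})

test_that("zero provisional pairs yield an empty set with undefined AAI", {
  bb <- bbh_pairs(setNames(character(0), character(0)),
                  setNames(character(0), character(0)), mk_hits("a", "b", 10))
  expect_equal(nrow(bb$pairs), 0L)
  expect_false(bb$aai$defined)
})

test_that("graph construction keeps isolated genes and triangle components", {
  pairs <- data.frame(gene_a = c("x1", "x1", "x2"),
                      gene_b = c("x2", "x3", "x3"),
                      pct_identity = 90, score = 100)
  g <- build_graph(pairs, genes = c("x1", "x2", "x3", "lonely"))
  comp <- igraph::components(g)
  expect_equal(comp$no, 2L)
  expect_equal(sort(comp$csize), c(1L, 3L))
  g0 <- build_graph(pairs[0, ], genes = c("x1", "x2"))
  expect_equal(igraph::components(g0)$no, 2L)
})

test_that("MCL separates disjoint triangles, barbells, and keeps singletons", {
  tri <- data.frame(gene_a = c("a1", "a1", "a2", "b1", "b1", "b2"),
                    gene_b = c("a2", "a3", "a3", "b2", "b3", "b3"),
                    pct_identity = 90, score = 1)
  g <- build_graph(tri, genes = c(paste0("a", 1:3), paste0("b", 1:3)))
  m <- mcl_cluster(g)
  expect_equal(length(unique(m)), 2L)
  expect_equal(length(unique(m[c("a1", "a2", "a3")])), 1L)

  g1 <- build_graph(tri[0, ], genes = "solo")
  expect_equal(unname(mcl_cluster(g1)), 1L)

  # barbell: two 4-cliques joined by one weak edge splits at inflation 2
  cl <- function(p, w) {
    e <- t(utils::combn(p, 2))
    data.frame(gene_a = e[, 1], gene_b = e[, 2], pct_identity = w, score = 1)
  }
  barbell <- rbind(cl(paste0("L", 1:4), 90), cl(paste0("R", 1:4), 90),
                   data.frame(gene_a = "L1", gene_b = "R1",
                              pct_identity = 10, score = 1))
  gb <- build_graph(barbell, genes = c(paste0("L", 1:4), paste0("R", 1:4)))
  mb <- mcl_cluster(gb, inflation = 2.0)
  expect_equal(length(unique(mb)), 2L)
  expect_equal(length(unique(mb[paste0("L", 1:4)])), 1L)
  expect_equal(length(unique(mb[paste0("R", 1:4)])), 1L)
})

test_that("package MCL agrees with a plain dense reference iteration", {
  # reference: the bare expansion/inflation iteration, no pruning, no
  # component splitting, clusters read off attractor rows
  ref_mcl <- function(A, inflation = 2, iters = 200) {
    diag(A) <- apply(A, 2, max)
    diag(A)[diag(A) == 0] <- 1
    M <- sweep(A, 2, colSums(A), "/")
    for (i in seq_len(iters)) {
      M <- M %*% M
      M <- M^inflation
      M <- sweep(M, 2, colSums(M), "/")
    }
    att <- which(diag(M) > 1e-6)
    lab <- rep(NA_integer_, ncol(A))
    for (a in att) lab[M[a, ] > 1e-6] <- a
    lab
  }
  set.seed(9)
  for (rep in 1:5) {
    n <- 8
    A <- matrix(0, n, n)
    # two planted blocks with strong internal weights, sparse weak noise
    A[1:4, 1:4] <- 0.9; A[5:8, 5:8] <- 0.9
    A[1, 5] <- A[5, 1] <- 0.05 * rep
    diag(A) <- 0
    genes <- paste0("n", 1:n)
    pairs <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
    pdf <- data.frame(gene_a = genes[pairs[, 1]], gene_b = genes[pairs[, 2]],
                      pct_identity = 100 * A[pairs], score = 1)
    m_pkg <- mcl_cluster(build_graph(pdf, genes))
    m_ref <- ref_mcl(A)
    # same partition up to label names
    expect_equal(length(unique(m_pkg)), length(unique(m_ref)))
    expect_true(all(tapply(m_ref, m_pkg[genes], function(v)
      length(unique(v))) == 1))
  }
})

test_that("MCL on its own cluster cliques is idempotent", {
  gs <- generate_genome_set(generator_params(
    n_genomes = 4L, n_core_families = 15L, n_flex_families = 5L,
    n_unique_per_genome = 3L, n_marker_families = 5L,
    mean_protein_len = 90, seed = 17L))
  tb <- infer_orthologs(gs$proteomes)
  fam <- tb$genes[!is.na(tb$genes$family_id), ]
  cliques <- do.call(rbind, lapply(split(fam$gene_id, fam$family_id),
                                   function(g) {
    e <- t(utils::combn(g, 2))
    data.frame(gene_a = e[, 1], gene_b = e[, 2], pct_identity = 90, score = 1)
  }))
  g2 <- build_graph(cliques, genes = tb$genes$gene_id)
  m2 <- mcl_cluster(g2)
  tb2 <- ortholog_table(m2, setNames(tb$genes$genome_id, tb$genes$gene_id))
  expect_identical(tb2$genes$family_id, tb$genes$family_id)
})

test_that("the gene partition is conserved and multicopy flags are exact", {
  gs <- generate_genome_set(generator_params(
    n_genomes = 5L, n_core_families = 30L, n_flex_families = 10L,
    n_unique_per_genome = 5L, n_marker_families = 10L,
    mean_protein_len = 100, seed = 23L))
  tb <- infer_orthologs(gs$proteomes)
  expect_equal(nrow(tb$genes),
               sum(tb$families$n_genes) + sum(is.na(tb$genes$family_id)))
  expect_true(all(tb$families$n_genes >= 2))
  expect_equal(nrow(flag_multicopy(tb)), 0L)

  # duplications planted directly in the table are flagged exactly
  member <- c(1L, 1L, 1L, 2L, 2L, 3L)
  genes <- sprintf("h%02d", 1:6)
  genomes <- c("GA", "GA", "GB", "GA", "GB", "GB")
  tb3 <- ortholog_table(setNames(member, genes), setNames(genomes, genes))
  fl <- flag_multicopy(tb3)
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$genome_id, "GA")
  expect_equal(fl$copy_count, 2L)
  expect_equal(fl$family_id,
               tb3$genes$family_id[tb3$genes$gene_id == "h01"])
})

test_that("BBH acceptance is symmetric on generated data", {
  gs <- generate_genome_set(generator_params(
    n_genomes = 2L, n_core_families = 20L, n_flex_families = 0L,
    n_unique_per_genome = 5L, n_marker_families = 5L,
    mean_protein_len = 100, seed = 29L))
  A <- gs$proteomes[[1]]; B <- gs$proteomes[[2]]
  h_ab <- all_vs_all(A, B)
  h_ba <- all_vs_all(B, A)
  bb_ab <- bbh_pairs(best_hits(h_ab), best_hits(h_ba), h_ab)
  bb_ba <- bbh_pairs(best_hits(h_ba), best_hits(h_ab), h_ba)
  expect_equal(sort(paste(bb_ab$pairs$gene_a, bb_ab$pairs$gene_b)),
               sort(paste(bb_ba$pairs$gene_b, bb_ba$pairs$gene_a)))
})
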