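test_that("partition applies the >= 13/17-style core rule", {
  # families over 17 genomes at presence 13, 12, 1 (3 copies), plus singleton
  member <- c(rep(1L, 13), rep(2L, 12), rep(3L, 3), 4L)
  genomes <- c(sprintf("G%02d", 1:13), sprintf("G%02d", 1:12),
               rep("G01", 3), "G05")
  genes <- sprintf("g%03d", seq_along(member))
  tb <- ortholog_table(setNames(member, genes), setNames(genomes, genes))
  tb$n_genomes <- 17L
  pr <- partition(tb, n_genomes = 17L)
  expect_equal(pr$core_min_genomes, 13L)
  cls <- setNames(pr$units$class, pr$units$unit_id)
  fam_of <- function(gene) tb$genes$family_id[tb$genes$gene_id == gene]
  expect_equal(unname(cls[fam_of("g001")]), "CORE")
  expect_equal(unname(cls[fam_of("g014")]), "SHARED_NON_CORE")
  expect_equal(unname(cls[fam_of("g026")]), "UNIQUE")  # one genome, 3 copies
  expect_equal(unname(cls["g029"]), "UNIQUE")          # singleton
  expect_error(partition(tb, n_genomes = 17L, core_min_genomes = 18L),
               "exceeds")
})

test_that("partition class counts equal an exhaustive per-family scan", {
  set.seed(10)
  for (rep in 1:5) {
    G <- sample(5:12, 1)
    n_fam <- 40
    pres <- matrix(rbinom(n_fam * G, size = 2, prob = 0.4), n_fam, G)
    keep <- rowSums(pres) > 0
    pres <- pres[keep, , drop = FALSE]
    member <- integer(0); genomes <- character(0); genes <- character(0)
    k <- 0
    for (f in seq_len(nrow(pres))) for (g in seq_len(G))
      if (pres[f, g] > 0) for (c in seq_len(pres[f, g])) {
        k <- k + 1
        member <- c(member, f)
        genomes <- c(genomes, sprintf("G%02d", g))
        genes <- c(genes, sprintf("g%04d", k))
      }
    tb <- ortholog_table(setNames(member, genes), setNames(genomes, genes))
    core_min <- as.integer(ceiling(13 / 17 * G))
    pr <- partition(tb, n_genomes = G)
    # brute force straight off the presence matrix
    n_genomes_fam <- rowSums(pres > 0)
    n_genes_fam <- rowSums(pres)
    multi <- n_genes_fam >= 2
    cls <- ifelse(n_genomes_fam >= core_min, "CORE",
                  ifelse(n_genomes_fam == 1, "UNIQUE", "SHARED_NON_CORE"))
    cls[!multi] <- ifelse(n_genomes_fam[!multi] >= core_min, "CORE", "UNIQUE")
    # single-member clusters are singletons -> UNIQUE regardless
    cls[n_genes_fam == 1] <- "UNIQUE"
    exp_genes <- vapply(c("CORE", "SHARED_NON_CORE", "UNIQUE"), function(cl)
      sum(n_genes_fam[cls == cl]), numeric(1))
    got <- setNames(pr$class_counts$n_genes, pr$class_counts$class)
    expect_equal(unname(got[names(exp_genes)]), unname(exp_genes))
  }
})

test_that("identical proteomes share everything after step one", {
  set.seed(12)
  seqs <- setNames(vapply(rep(60, 20), random_aa, character(1)),
                   sprintf("x%03d", 1:20))
  prots <- lapply(1:3, function(i)
    proteome(paste0("P", i), setNames(seqs, sprintf("P%d_%03d", i, 1:20))))
  names(prots) <- paste0("P", 1:3)
  cv <- accumulate(prots, trials = 100, seed = 4)
  pan <- cv$summary[cv$summary$stat == "n_pan", ]
  expect_equal(pan$raw_mean, rep(20, 3))
  expect_equal(pan$norm_mean, rep(1, 3))
  new2 <- cv$summary[cv$summary$stat == "n_new" & cv$summary$step > 1, ]
  expect_equal(new2$raw_mean, c(0, 0))
})

test_that("disjoint proteomes match hand enumeration over all 6 orders", {
  sizes <- c(8L, 10L, 12L)
  prots <- disjoint_proteomes(sizes, len = 60, seed = 44)
  cv <- accumulate(prots, trials = 100, seed = 5)
  # the exhaustion rule: exactly 3! = 6 distinct orders
  expect_equal(cv$n_trials, 6L)
  expect_equal(nrow(unique(as.data.frame(cv$orders))), 6L)
  for (t in seq_len(6)) {
    ord <- cv$orders[t, ]
    sz <- sizes[ord]
    # all genes are new at every step; pan is the running sum
    expect_equal(unname(cv$trials[, "n_new", t]), sz)
    expect_equal(unname(cv$trials[, "n_pan", t]), cumsum(sz))
    # normalized new counts: added size over the median of included sizes
    med <- vapply(1:3, function(k) median(sz[1:k]), numeric(1))
    expect_equal(unname(cv$trials_norm[, "n_new", t]), sz / med)
    # nothing is shared once a second (disjoint) genome enters
    expect_equal(unname(cv$trials[2:3, "n_shared", t]), c(0, 0))
  }
  # endpoint order-invariance: pan total identical across orders
  expect_equal(unique(cv$trials[3, "n_pan", ]), sum(sizes))
})

test_that("per-trial accounting identities hold on generated data", {
  gs <- generate_genome_set(generator_params(
    n_genomes = 4L, n_core_families = 15L, n_flex_families = 10L,
    n_unique_per_genome = 4L, n_marker_families = 5L,
    mean_protein_len = 90, seed = 37L))
  cv <- accumulate(gs$proteomes, trials = 100, seed = 6)
  expect_equal(cv$n_trials, 24L)
  for (t in seq_len(cv$n_trials)) {
    nn <- cv$trials[, "n_new", t]
    np <- cv$trials[, "n_pan", t]
    expect_equal(np, cumsum(nn))
    expect_true(all(diff(np) >= 0))
    expect_true(all(diff(cv$trials[, "n_shared", t]) <= 0))
  }
  expect_equal(length(unique(cv$trials[4, "n_pan", ])), 1L)
})

test_that("new-gene labels recover planted novelty at 90% identity", {
  gs <- generate_genome_set(generator_params(
    n_genomes = 3L, n_core_families = 20L, n_flex_families = 0L,
    n_unique_per_genome = 8L, n_marker_families = 5L,
    mean_protein_len = 120, seed = 41L))
  hits <- all_pairs_hits(gs$proteomes)
  shared <- shared_genes(gs$proteomes, added = "G03",
                         prior = c("G01", "G02"), hits = hits)
  fam <- gs$truth$gene_to_family[names(shared)]
  expect_true(all(shared[fam != "UNIQUE"]))
  expect_false(any(shared[fam == "UNIQUE"]))
})

test_that("power fits recover exact parameters on noiseless data", {
  xs <- 1:10
  f1 <- fit_power(xs, 5 * xs^0.3)
  expect_equal(f1$a, 5, tolerance = 1e-9)
  expect_equal(f1$b, 0.3, tolerance = 1e-9)
  expect_lt(f1$rss, 1e-15)
  f2 <- fit_power(xs, rep(7, 10))
  expect_equal(f2$b, 0, tolerance = 1e-12)
  f3 <- fit_power(xs, 2 * xs^-0.8)
  expect_equal(f3$b, -0.8, tolerance = 1e-9)
  expect_error(fit_power(c(1, 2), c(0, 3)), "index 1")
  expect_error(fit_power(1, 1), "at least 2")
})

test_that("fitted pan-curve exponents are reproducible across seeds", {
  # flexible-heavy synthetic set: an open pan-genome by construction
  gs <- generate_genome_set(generator_params(
    n_genomes = 5L, n_core_families = 10L, n_flex_families = 40L,
    flex_presence_prob = 0.4, n_unique_per_genome = 10L,
    n_marker_families = 5L, mean_protein_len = 90, seed = 53L))
  hits <- all_pairs_hits(gs$proteomes, prefilter = "kmer")
  bs <- vapply(1:5, function(s) {
    cv <- accumulate(gs$proteomes, hits = hits, trials = 30, seed = s)
    fit_pan_curve(cv)$pan_total$b
  }, numeric(1))
  expect_gt(mean(bs), 0)  # open pan-genome: growing total
  expect_lt(max(bs) - min(bs), 0.05)
})

test_that("category breakdown buckets multiples and unknowns correctly", {
  member <- c(1L, 1L, 2L)
  genes <- c("g1", "g2", "g3")
  genomes <- c("GA", "GB", "GA")
  tb <- ortholog_table(setNames(member, genes), setNames(genomes, genes))
  pr <- partition(tb, n_genomes = 2L, core_min_genomes = 2L)
  m <- category_breakdown(pr, list(g1 = "J", g2 = "KL", g3 = ""))
  expect_equal(m["J", "CORE"], 1)
  expect_equal(m["Multiple assignments", "CORE"], 1)
  expect_equal(m["Unassigned", "UNIQUE"], 1)
  expect_equal(unname(m["Total", "Total"]), 3)
  expect_warning(category_breakdown(pr, list(g1 = "?", g2 = "K", g3 = "J")),
                 "unknown category")

  # random maps equal a brute-force tally
  set.seed(14)
  gene_ids <- names(pr$gene_class)
  cats <- lapply(gene_ids, function(g)
    paste(sample(c("J", "K", "L"), sample(0:2, 1)), collapse = ""))
  names(cats) <- gene_ids
  m2 <- category_breakdown(pr, cats)
  n_multi <- sum(vapply(cats, nchar, numeric(1)) >= 2)
  n_unass <- sum(vapply(cats, nchar, numeric(1)) == 0)
  expect_equal(unname(m2["Multiple assignments", "Total"]), n_multi)
  expect_equal(unname(m2["Unassigned", "Total"]), n_unass)
})
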