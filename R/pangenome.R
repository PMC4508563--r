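#' @title Core/flexible partitioning and pan-genome accumulation
#' @name pangenome
#' @description The ortholog table is partitioned into core families
#'   (present in at least `core_min_genomes` genomes; the study rule is 13
#'   of 17, generalized as `ceiling(13/17 * G)`), shared non-core families,
#'   and unique genes. Pan-genome accumulation follows the Tettelin
#'   protocol: genomes are added one at a time in random order; a gene of
#'   the added genome counts as shared if it has a hit at >= 50% similarity
#'   (BLAST-style positives) over more than 50% of the protein length in
#'   some previously included genome, new otherwise. Counts are also
#'   reported normalized by the median protein count of the genomes
#'   included so far. Orders are distinct sampled permutations; if the
#'   number of possible orders does not exceed the requested trials, all
#'   orders are enumerated (the exhaustion rule). A power law is fitted to
#'   the resulting curves by log-log least squares.
NULL

#' Partition an ortholog table into core / shared non-core / unique
#'
#' A family is CORE when present in at least `core_min_genomes` distinct
#' genomes, UNIQUE when confined to a single genome (regardless of copy
#' number), SHARED_NON_CORE otherwise. Singleton genes are UNIQUE.
#'
#' @param table an [ortholog_table()].
#' @param n_genomes number of genomes in the comparison (defaults to the
#'   table's count).
#' @param core_min_genomes core presence threshold; default
#'   `ceiling(13/17 * n_genomes)`.
#' @return a `partition_result`: list with `units` (data.frame `unit_id`
#'   -- family id or singleton gene id --, `is_singleton`, `n_genomes`,
#'   `n_genes`, `class`), `gene_class` (named vector per gene),
#'   `class_counts` (genes and units per class), `core_min_genomes`,
#'   `n_genomes`.
#' @export
partition <- function(table, n_genomes = table$n_genomes,
                      core_min_genomes = NULL) {
  if (is.null(core_min_genomes))
    core_min_genomes <- as.integer(ceiling(13 / 17 * n_genomes))
  if (core_min_genomes > n_genomes)
    stop("core_min_genomes (", core_min_genomes,
         ") exceeds n_genomes (", n_genomes, ")")
  fams <- table$families
  fam_class <- ifelse(fams$n_genomes >= core_min_genomes, "CORE",
                      ifelse(fams$n_genomes == 1L, "UNIQUE",
                             "SHARED_NON_CORE"))
  sing <- table$genes[is.na(table$genes$family_id), ]
  units <- rbind(
    data.frame(unit_id = fams$family_id, is_singleton = FALSE,
               n_genomes = fams$n_genomes, n_genes = fams$n_genes,
               class = fam_class, stringsAsFactors = FALSE),
    if (nrow(sing)) data.frame(unit_id = sing$gene_id, is_singleton = TRUE,
                               n_genomes = 1L, n_genes = 1L,
                               class = "UNIQUE", stringsAsFactors = FALSE))
  gene_class <- character(nrow(table$genes))
  names(gene_class) <- table$genes$gene_id
  fam_lookup <- stats::setNames(fam_class, fams$family_id)
  has_fam <- !is.na(table$genes$family_id)
  gene_class[has_fam] <- fam_lookup[table$genes$family_id[has_fam]]
  gene_class[!has_fam] <- "UNIQUE"
  classes <- c("CORE", "SHARED_NON_CORE", "UNIQUE")
  class_counts <- data.frame(
    class = classes,
    n_units = vapply(classes, function(cl) sum(units$class == cl), integer(1)),
    n_genes = vapply(classes, function(cl)
      sum(units$n_genes[units$class == cl]), integer(1)))
  rownames(class_counts) <- NULL
  structure(list(units = units, gene_class = gene_class,
                 class_counts = class_counts,
                 core_min_genomes = core_min_genomes,
                 n_genomes = n_genomes),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> core >= %d of %d genomes\n",
              x$core_min_genomes, x$n_genomes))
  print(x$class_counts)
  invisible(x)
}

# Per-gene x genome qualifying-hit incidence used by the accumulation:
# share[[g]][gene, j] is TRUE when the gene of genome g has a hit in genome
# j at pct_positives >= sim_threshold over coverage > cov_threshold.
# Coverage is required on both sequences by default so the relation is
# symmetric, which is what makes the pan-genome endpoint order-invariant.
pan_share_matrix <- function(proteomes, hits, sim_threshold = 50,
                             cov_threshold = 0.5,
                             cov_side = c("both", "query")) {
  cov_side <- match.arg(cov_side)
  gids <- vapply(proteomes, `[[`, character(1), "genome_id")
  gene_genome <- unlist(unname(lapply(proteomes, function(p)
    stats::setNames(rep(p$genome_id, n_genes(p)), p$ids))))
  cov_ok <- if (cov_side == "both")
    hits$q_cov > cov_threshold & hits$s_cov > cov_threshold
  else hits$q_cov > cov_threshold
  q <- hits[hits$pct_positives >= sim_threshold & cov_ok,
            c("query_id", "subject_id")]
  qg <- gene_genome[q$query_id]
  sg <- gene_genome[q$subject_id]
  share <- lapply(seq_along(proteomes), function(i) {
    p <- proteomes[[i]]
    m <- matrix(FALSE, nrow = n_genes(p), ncol = length(proteomes),
                dimnames = list(p$ids, gids))
    sel <- qg == p$genome_id & sg != p$genome_id
    if (any(sel))
      m[cbind(q$query_id[sel], sg[sel])] <- TRUE
    m
  })
  names(share) <- gids
  share
}

#' Label the genes of an added genome as shared or new
#'
#' A gene of the added genome is shared with the prior set when some hit
#' against a prior genome reaches `sim_threshold` percent similarity
#' (BLAST-style positives) over more than `cov_threshold` of the protein
#' length; new otherwise. Coverage is required on both sequences by
#' default (`cov_side = "both"`), which makes sharing symmetric and the
#' accumulated pan-genome total independent of genome order.
#'
#' @param proteomes named list of proteomes covering all genomes involved.
#' @param added genome id of the genome being added.
#' @param prior character vector of previously included genome ids.
#' @param hits all-vs-all hit table covering the relevant ordered pairs.
#' @param sim_threshold percent-similarity cutoff (default 50).
#' @param cov_threshold coverage cutoff, exclusive (default 0.5).
#' @param cov_side `"both"` (symmetric, default) or `"query"` (the
#'   classified gene's side only).
#' @return named logical vector per gene of the added genome: TRUE =
#'   shared.
#' @export
shared_genes <- function(proteomes, added, prior, hits,
                         sim_threshold = 50, cov_threshold = 0.5,
                         cov_side = "both") {
  share <- pan_share_matrix(proteomes, hits, sim_threshold, cov_threshold,
                            cov_side)
  m <- share[[added]]
  if (length(prior) == 0L)
    return(stats::setNames(rep(FALSE, nrow(m)), rownames(m)))
  apply(m[, prior, drop = FALSE], 1, any)
}

#' Pan-genome accumulation over random genome orders
#'
#' @param proteomes named list of >= 2 proteomes.
#' @param hits optional precomputed all-vs-all hits; computed with the
#'   built-in aligner otherwise (`prefilter` passed through).
#' @param trials number of genome orders (default 100). If the number of
#'   possible orders is `<= trials` all orders are enumerated; otherwise
#'   distinct orders are sampled uniformly without replacement.
#' @param seed RNG seed for order sampling.
#' @param sim_threshold,cov_threshold qualifying-hit cutoffs (50 / 0.5).
#' @param cov_side coverage-side rule, see [shared_genes()].
#' @param median_mode `"step"` (median protein count over the genomes
#'   included so far in that trial, the default) or `"global"` (median
#'   over all genomes).
#' @param prefilter alignment prefilter when `hits` is computed here.
#' @return a `pan_curve`: list with `summary` (data.frame per step x
#'   statistic: mean/sd of raw and normalized `n_new`, `n_pan`,
#'   `n_shared`), `trials` (array step x stat x trial of raw counts),
#'   `orders` (matrix of genome orders used), `n_trials`, `seed`.
#'   `n_shared` follows the Tettelin core-curve convention: genes of the
#'   first genome in the order with qualifying hits in every other genome
#'   included so far.
#' @export
accumulate <- function(proteomes, hits = NULL, trials = 100L, seed = 1L,
                       sim_threshold = 50, cov_threshold = 0.5,
                       cov_side = "both",
                       median_mode = c("step", "global"),
                       prefilter = "none") {
  median_mode <- match.arg(median_mode)
  G <- length(proteomes)
  if (G < 2L) stop("need at least two proteomes")
  gids <- vapply(proteomes, `[[`, character(1), "genome_id")
  names(proteomes) <- gids
  if (is.null(hits))
    hits <- all_pairs_hits(proteomes, prefilter = prefilter)
  share <- pan_share_matrix(proteomes, hits, sim_threshold, cov_threshold,
                            cov_side)
  sizes <- stats::setNames(vapply(proteomes, n_genes, integer(1)), gids)

  orders <- sample_orders(G, trials, seed)
  n_trials <- nrow(orders)
  stats_raw <- array(NA_real_, dim = c(G, 3, n_trials),
                     dimnames = list(NULL, c("n_new", "n_pan", "n_shared"),
                                     NULL))
  stats_norm <- stats_raw
  med_global <- stats::median(sizes)
  for (t in seq_len(n_trials)) {
    ord <- gids[orders[t, ]]
    first <- ord[1L]
    pan <- 0
    for (k in seq_len(G)) {
      g <- ord[k]
      prior <- ord[seq_len(k - 1L)]
      if (k == 1L) {
        n_new <- sizes[[g]]
        n_shared <- sizes[[g]]
      } else {
        m <- share[[g]][, prior, drop = FALSE]
        n_new <- sum(!apply(m, 1, any))
        others <- ord[2:k]
        mf <- share[[first]][, others, drop = FALSE]
        n_shared <- sum(apply(mf, 1, all))
      }
      pan <- pan + n_new
      med <- if (median_mode == "step")
        stats::median(sizes[ord[seq_len(k)]]) else med_global
      stats_raw[k, , t] <- c(n_new, pan, n_shared)
      stats_norm[k, , t] <- stats_raw[k, , t] / med
    }
  }
  summ <- do.call(rbind, lapply(seq_len(G), function(k) {
    do.call(rbind, lapply(c("n_new", "n_pan", "n_shared"), function(st) {
      data.frame(step = k, stat = st,
                 raw_mean = mean(stats_raw[k, st, ]),
                 raw_sd = stats::sd(stats_raw[k, st, ]),
                 norm_mean = mean(stats_norm[k, st, ]),
                 norm_sd = stats::sd(stats_norm[k, st, ]),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL
  pp_log("accumulate", sprintf("%d genomes, %d trial orders, seed %d",
                               G, n_trials, seed))
  structure(list(summary = summ, trials = stats_raw,
                 trials_norm = stats_norm,
                 orders = orders, n_trials = n_trials, seed = seed),
            class = "pan_curve")
}

# distinct permutations of 1..G: full enumeration when G! <= trials,
# otherwise uniform rejection sampling without replacement
sample_orders <- function(G, trials, seed) {
  total <- factorial(G)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  if (!is.infinite(total) && total <= trials) {
    perms <- all_permutations(G)
    return(perms)
  }
  seen <- character(0)
  out <- matrix(NA_integer_, nrow = trials, ncol = G)
  t <- 0L
  while (t < trials) {
    p <- sample.int(G)
    key <- paste(p, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    t <- t + 1L
    out[t, ] <- p
  }
  out
}

all_permutations <- function(G) {
  if (G == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(G - 1L)
  do.call(rbind, lapply(seq_len(G), function(i) {
    rest <- setdiff(seq_len(G), i)
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' @export
print.pan_curve <- function(x, ...) {
  cat(sprintf("<pan_curve> %d steps, %d trial orders, seed %d\n",
              dim(x$trials)[1], x$n_trials, x$seed))
  print(utils::head(x$summary, 9))
  invisible(x)
}

#' Fit a power law y = a * x^b by log-log least squares
#'
#' Exact on noiseless power-law input. For new-gene curves, step 1 is
#' conventionally excluded before fitting (the first step is the full
#' genome, not an accumulation observation); see [fit_pan_curve()].
#'
#' @param xs,ys positive numeric vectors of equal length >= 2.
#' @return a `power_fit`: list with `a`, `b`, `rss` (residual sum of
#'   squares on the original scale), `n_points`.
#' @export
fit_power <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("xs and ys must have equal length")
  if (length(xs) < 2L) stop("need at least 2 points")
  bad <- which(xs <= 0 | ys <= 0)
  if (length(bad))
    stop("non-positive value at index ", bad[1L])
  fit <- stats::lm(log(ys) ~ log(xs))
  a <- exp(unname(stats::coef(fit)[1]))
  b <- unname(stats::coef(fit)[2])
  structure(list(a = a, b = b,
                 rss = sum((ys - a * xs^b)^2),
                 n_points = length(xs)),
            class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("<power_fit> y = %.6g * x^%.6g (rss %.3g, n %d)\n",
              x$a, x$b, x$rss, x$n_points))
  invisible(x)
}

#' Fit power laws to a pan-genome curve
#'
#' Fits the mean new-gene curve (excluding step 1 by default) and the mean
#' pan-genome total curve.
#'
#' @param curve a `pan_curve` from [accumulate()].
#' @param normalized fit the median-normalized means (default) or raw.
#' @param include_step1 include step 1 in the new-gene fit.
#' @return list with `new_genes` and `pan_total` [fit_power()] results.
#' @export
fit_pan_curve <- function(curve, normalized = TRUE, include_step1 = FALSE) {
  s <- curve$summary
  col <- if (normalized) "norm_mean" else "raw_mean"
  new <- s[s$stat == "n_new", ]
  if (!include_step1) new <- new[new$step > 1L, ]
  pan <- s[s$stat == "n_pan", ]
  list(new_genes = fit_power(new$step, new[[col]]),
       pan_total = fit_power(pan$step, pan[[col]]))
}

#' Category breakdown of a partition
#'
#' Cross-tabulates gene classes against externally supplied functional
#' category letters (e.g. COG). Genes with two or more categories are
#' counted once under `"Multiple assignments"`; genes with none (or only
#' unknown letters) under `"Unassigned"`.
#'
#' @param part a [partition()] result.
#' @param gene_categories named character vector or list: gene id ->
#'   category letters (a string like `"KL"` or a character vector; `""` or
#'   missing genes are unassigned).
#' @param known_categories the recognized single-letter categories;
#'   unknown letters trigger a warning and count as unassigned.
#' @return integer matrix: rows = categories plus `"Multiple assignments"`
#'   and `"Unassigned"`, columns = CORE / SHARED_NON_CORE / UNIQUE, plus a
#'   `"Total"` row and column.
#' @export
category_breakdown <- function(part, gene_categories,
                               known_categories = LETTERS) {
  classes <- c("CORE", "SHARED_NON_CORE", "UNIQUE")
  genes <- names(part$gene_class)
  cats <- lapply(genes, function(g) {
    v <- gene_categories[[g]]
    if (is.null(v) || length(v) == 0L || all(!nzchar(v))) return(character(0))
    letters <- unique(unlist(strsplit(v, "", fixed = TRUE)))
    letters[letters != " "]
  })
  unknown <- setdiff(unique(unlist(cats)), known_categories)
  if (length(unknown)) {
    warning("unknown category letter(s) treated as unassigned: ",
            paste(unknown, collapse = ", "))
    cats <- lapply(cats, function(v) setdiff(v, unknown))
  }
  used <- sort(intersect(unique(unlist(cats)), known_categories))
  rows <- c(used, "Multiple assignments", "Unassigned")
  m <- matrix(0L, nrow = length(rows), ncol = length(classes),
              dimnames = list(rows, classes))
  for (i in seq_along(genes)) {
    cl <- part$gene_class[[genes[i]]]
    v <- cats[[i]]
    row <- if (length(v) == 0L) "Unassigned"
           else if (length(v) >= 2L) "Multiple assignments"
           else v
    m[row, cl] <- m[row, cl] + 1L
  }
  m <- rbind(m, Total = colSums(m))
  cbind(m, Total = rowSums(m))
}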