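#' Parameters for the synthetic genome-set generator
#'
#' The generator emulates a set of reconstructed genome bins from one
#' phylum: a planted core of families present in every genome, flexible
#' families present in each genome independently with some probability,
#' genome-unique genes, controlled within-family sequence divergence, and
#' random gene dropout emulating bin incompleteness. Defaults reproduce the
#' study conditions used throughout the test suite: 17 genomes, 200 core +
#' 150 flexible families at 50% presence, 125 unique genes per genome
#' (~400 genes/genome), 90% within-family identity, no dropout, 105 marker
#' families.
#'
#' @param n_genomes number of genomes.
#' @param n_core_families families placed in every genome.
#' @param n_flex_families families placed per genome with
#'   `flex_presence_prob`.
#' @param flex_presence_prob per-genome presence probability of a flexible
#'   family.
#' @param n_unique_per_genome fresh unrelated genes per genome.
#' @param mean_protein_len mean ancestral protein length (residues).
#' @param len_dispersion coefficient of variation of the gamma length
#'   distribution (lengths floored at 50).
#' @param within_family_identity target expected pairwise identity between
#'   two members of one family, in (0.2, 1].
#' @param dropout_rate per-gene deletion probability (bin incompleteness).
#' @param n_marker_families conserved single-copy marker families, drawn
#'   from the core.
#' @param seed master RNG seed; per-genome streams are derived from it so
#'   adding genomes never perturbs earlier ones.
#' @return a validated `generator_params` list.
#' @export
generator_params <- function(n_genomes = 17L,
                             n_core_families = 200L,
                             n_flex_families = 150L,
                             flex_presence_prob = 0.5,
                             n_unique_per_genome = 125L,
                             mean_protein_len = 250,
                             len_dispersion = 0.3,
                             within_family_identity = 0.9,
                             dropout_rate = 0,
                             n_marker_families = 105L,
                             seed = 1L) {
  p <- list(n_genomes = as.integer(n_genomes),
            n_core_families = as.integer(n_core_families),
            n_flex_families = as.integer(n_flex_families),
            flex_presence_prob = flex_presence_prob,
            n_unique_per_genome = as.integer(n_unique_per_genome),
            mean_protein_len = mean_protein_len,
            len_dispersion = len_dispersion,
            within_family_identity = within_family_identity,
            dropout_rate = dropout_rate,
            n_marker_families = as.integer(n_marker_families),
            seed = as.integer(seed))
  counts <- c("n_genomes", "n_core_families", "n_flex_families",
              "n_unique_per_genome", "n_marker_families")
  for (cc in counts)
    if (is.na(p[[cc]]) || p[[cc]] < 0L) stop(cc, " must be a count >= 0")
  if (p$n_genomes < 1L) stop("n_genomes must be >= 1")
  for (pr in c("flex_presence_prob", "dropout_rate"))
    if (p[[pr]] < 0 || p[[pr]] > 1) stop(pr, " must be in [0, 1]")
  if (p$within_family_identity <= 0.2 || p$within_family_identity > 1)
    stop("within_family_identity must be in (0.2, 1]")
  if (p$n_marker_families > p$n_core_families)
    stop("n_marker_families cannot exceed n_core_families")
  if (p$mean_protein_len < 50) stop("mean_protein_len must be >= 50")
  class(p) <- "generator_params"
  p
}

# Per-branch substitution probability so that two members mutated
# independently from a common ancestor have expected pairwise identity t:
# identity = (1-p)^2 + p^2/19 (uniform replacement over 19 alternatives).
branch_sub_prob <- function(target_identity) {
  t <- target_identity
  # (20/19) p^2 - 2 p + (1 - t) = 0, smaller root
  a <- 20 / 19
  disc <- 4 - 4 * a * (1 - t)
  (2 - sqrt(disc)) / (2 * a)
}

random_protein <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, p_sub) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < p_sub
  if (any(hit)) {
    repl <- vapply(chars[hit], function(ch)
      sample(setdiff(AA_ALPHABET, ch), 1L), character(1))
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

draw_length <- function(n, mean_len, cv) {
  if (cv <= 0) return(rep(round(mean_len), n))
  shape <- 1 / cv^2
  pmax(50L, as.integer(round(stats::rgamma(n, shape = shape,
                                           scale = mean_len / shape))))
}

#' Generate a synthetic genome set with planted ortholog structure
#'
#' For each family an ancestral random protein is drawn (gamma-distributed
#' length, minimum 50 residues); each member genome receives an
#' independently mutated copy with per-site substitution probability solved
#' so the expected pairwise identity between any two members equals
#' `within_family_identity`. Core families are placed in every genome,
#' flexible families in each genome independently with
#' `flex_presence_prob`, and unique genes are drawn fresh. Finally each
#' gene is deleted with probability `dropout_rate`. Gene order within each
#' genome is randomized. Fully deterministic under `params$seed`; each
#' genome consumes its own derived RNG stream.
#'
#' @param params a [generator_params()].
#' @return list with `proteomes` (list of [proteome()]) and `truth`, a
#'   `synthetic_truth` object with elements `gene_to_family` (named vector,
#'   `"UNIQUE"` for unique genes), `family_class` (named `"CORE"`/`"FLEX"`),
#'   `marker_families`, `dropped_genes`, and `params`.
#' @export
generate_genome_set <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  p_sub <- branch_sub_prob(params$within_family_identity)
  fam_ids <- c(sprintf("core%04d", seq_len(params$n_core_families)),
               sprintf("flex%04d", seq_len(params$n_flex_families)))
  fam_class <- stats::setNames(
    rep(c("CORE", "FLEX"),
        c(params$n_core_families, params$n_flex_families)), fam_ids)

  # ancestral sequences from their own stream: stable across genome counts
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(derive_seed(params$seed, "ancestors"))
  anc_len <- draw_length(length(fam_ids), params$mean_protein_len,
                         params$len_dispersion)
  ancestors <- stats::setNames(
    vapply(anc_len, random_protein, character(1)), fam_ids)
  marker_families <- sort(sample(names(fam_class)[fam_class == "CORE"],
                                 params$n_marker_families))

  gene_to_family <- character(0)
  dropped <- character(0)
  proteomes <- vector("list", params$n_genomes)
  for (g in seq_len(params$n_genomes)) {
    gid <- sprintf("G%02d", g)
    set.seed(derive_seed(params$seed, paste0("genome:", gid)))
    present_flex <- fam_ids[fam_class == "FLEX"][
      stats::runif(params$n_flex_families) < params$flex_presence_prob]
    fams <- c(fam_ids[fam_class == "CORE"], present_flex)
    seqs <- vapply(fams, function(f) mutate_protein(ancestors[[f]], p_sub),
                   character(1))
    n_u <- params$n_unique_per_genome
    if (n_u > 0) {
      ulen <- draw_length(n_u, params$mean_protein_len, params$len_dispersion)
      useqs <- vapply(ulen, random_protein, character(1))
      seqs <- c(seqs, useqs)
      fams <- c(fams, rep("UNIQUE", n_u))
    }
    ids <- sprintf("%s_g%04d", gid, seq_along(seqs))
    names(seqs) <- ids
    gene_to_family <- c(gene_to_family, stats::setNames(fams, ids))
    keep <- stats::runif(length(seqs)) >= params$dropout_rate
    dropped <- c(dropped, ids[!keep])
    seqs <- seqs[keep]
    if (length(seqs) == 0L)
      stop("genome ", gid, " is empty after dropout; ",
           "reduce dropout_rate or add genes")
    ord <- sample(length(seqs))
    proteomes[[g]] <- proteome(gid, seqs[ord])
  }
  names(proteomes) <- vapply(proteomes, `[[`, character(1), "genome_id")
  truth <- structure(list(gene_to_family = gene_to_family,
                          family_class = fam_class,
                          marker_families = marker_families,
                          dropped_genes = dropped,
                          params = params),
                     class = "synthetic_truth")
  pp_log("synth", sprintf(
    "%d genomes, %d families (%d core), %d genes emitted, %d dropped, seed %d",
    params$n_genomes, length(fam_ids), params$n_core_families,
    length(gene_to_family) - length(dropped), length(dropped), params$seed))
  list(proteomes = proteomes, truth = truth)
}

#' Marker (CSCG) hit table from a synthetic genome set
#'
#' Every surviving member of a marker family yields one hit row
#' (`genome_id`, `gene_id`, `marker`). Optionally injects duplicated-marker
#' contamination rows for testing multi-copy flagging: for each entry of
#' `inject_multicopy` (named vector genome -> marker), one extra copy row is
#' appended.
#'
#' @param truth a `synthetic_truth`.
#' @param proteomes the matching proteome list.
#' @param inject_multicopy optional named character vector, names = genome
#'   ids, values = marker family ids to duplicate.
#' @return data.frame of marker hits.
#' @export
generate_marker_hits <- function(truth, proteomes, inject_multicopy = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  rows <- list()
  for (pr in proteomes) {
    fams <- truth$gene_to_family[pr$ids]
    is_marker <- fams %in% truth$marker_families
    if (any(is_marker))
      rows[[pr$genome_id]] <- data.frame(
        genome_id = pr$genome_id,
        gene_id = pr$ids[is_marker],
        marker = unname(fams[is_marker]),
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(inject_multicopy)) {
    for (i in seq_along(inject_multicopy)) {
      g <- names(inject_multicopy)[i]
      mk <- inject_multicopy[[i]]
      out <- rbind(out, data.frame(
        genome_id = g,
        gene_id = sprintf("%s_dup_%s", g, mk),
        marker = mk, stringsAsFactors = FALSE))
    }
  }
  out
}

# canonical (DNA-space) anticodons per isotype, bacterial usage
CANONICAL_ANTICODONS <- list(
  Ala = c("AGC","GGC","CGC","TGC"), Arg = c("ACG","GCG","CCG","TCG","CCT","TCT"),
  Asn = c("GTT","ATT"), Asp = c("GTC","ATC"), Cys = c("GCA","ACA"),
  Gln = c("TTG","CTG"), Glu = c("TTC","CTC"),
  Gly = c("GCC","ACC","CCC","TCC"), His = c("GTG","ATG"),
  Ile = c("GAT","AAT","TAT","CAT"), Leu = c("AAG","GAG","CAG","TAG","CAA","TAA"),
  Lys = c("TTT","CTT"), Met = c("CAT"), fMet = c("CAT"),
  Phe = c("GAA","AAA"), Pro = c("AGG","GGG","CGG","TGG"),
  SeC = c("TCA"), Ser = c("AGA","GGA","CGA","TGA","ACT","GCT"),
  Thr = c("AGT","GGT","CGT","TGT"), Trp = c("CCA"),
  Tyr = c("GTA","ATA"), Val = c("AAC","GAC","CAC","TAC"))

TRNA_LEN <- 76L          # canonical cloverleaf length
ANTICODON_OFFSET <- 33L  # 0-based start; standard positions 34-36

#' Generate a synthetic tRNA set with controlled anticodon-loop usage
#'
#' Emits tRNA-like DNA sequences of a fixed canonical layout (length 76,
#' anticodon at standard positions 34-36) with the bases at anticodon-loop
#' positions 38, 39 and 40 sampled from `usage_spec`. The anticodon is
#' sampled from the isotype's canonical set. Remaining positions are random.
#'
#' @param n_per_isotype named integer vector: records per isotype.
#' @param usage_spec nested list `usage_spec[[isotype]][[as.character(pos)]]`
#'   giving a length-4 probability vector over `A,C,G,T` for positions 38,
#'   39, 40; unspecified cells default to uniform. Each distribution must
#'   sum to 1 within 1e-9.
#' @param seed RNG seed.
#' @param genome_id genome label stamped on the records.
#' @return data.frame of tRNA records in the layout of
#'   [read_trnascan_table()] (with `seq` and `anticodon_start`).
#' @export
generate_trna_set <- function(n_per_isotype, usage_spec = list(), seed = 1L,
                              genome_id = "synthetic") {
  bases <- c("A", "C", "G", "T")
  for (iso in names(usage_spec))
    for (pos in names(usage_spec[[iso]])) {
      d <- usage_spec[[iso]][[pos]]
      if (length(d) != 4L || abs(sum(d) - 1) > 1e-9)
        stop("usage_spec[", iso, "][", pos,
             "] must be 4 probabilities summing to 1")
    }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  rows <- list()
  n_total <- 0L
  for (iso in names(n_per_isotype)) {
    if (!iso %in% names(CANONICAL_ANTICODONS))
      stop("no canonical anticodons known for isotype ", iso)
    n <- n_per_isotype[[iso]]
    for (r in seq_len(n)) {
      n_total <- n_total + 1L
      body <- sample(bases, TRNA_LEN, replace = TRUE)
      ac <- sample(CANONICAL_ANTICODONS[[iso]], 1L)
      body[ANTICODON_OFFSET + 1:3] <- strsplit(ac, "")[[1]]
      for (pos in c(38L, 39L, 40L)) {
        d <- usage_spec[[iso]][[as.character(pos)]] %||% rep(0.25, 4)
        # loop position = anticodon_start + 4/5/6 (0-based), here 1-based
        body[ANTICODON_OFFSET + (pos - 34L) + 1L] <-
          sample(bases, 1L, prob = d)
      }
      rows[[n_total]] <- data.frame(
        scaffold = sprintf("trna%05d", n_total), trna_no = 1L,
        begin = 1L, end = TRNA_LEN, strand = "+",
        isotype = iso, anticodon = ac,
        intron_begin = 0L, intron_end = 0L, score = 50.0,
        seq = paste(body, collapse = ""),
        anticodon_start = ANTICODON_OFFSET,
        genome_id = genome_id, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
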