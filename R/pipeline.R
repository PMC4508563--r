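#' @title End-to-end pipeline
#' @name cli_pipeline
#' @description [run_all()] drives the whole analysis from one validated
#'   configuration: synthetic genome-set generation, all-vs-all alignment,
#'   BBH/MCL orthology, core/flexible partitioning, pan-genome
#'   accumulation, CSCG completeness, and tRNA usage, writing every
#'   stage's outputs plus a manifest into a run directory. Per-stage seeds
#'   are derived deterministically from the master seed, so stages can be
#'   re-run independently and reruns are bit-identical.
NULL

CONFIG_DEFAULTS <- list(
  n_genomes = 17L, n_core_families = 200L, n_flex_families = 150L,
  flex_presence_prob = 0.5, n_unique_per_genome = 125L,
  mean_protein_len = 250, len_dispersion = 0.3,
  within_family_identity = 0.9, dropout_rate = 0,
  n_marker_families = 105L,
  min_cov = 0.70, aai_window = 2.0, inflation = 2.0,
  sim_threshold = 50, cov_threshold = 0.5,
  core_min_fraction = 13 / 17, trials = 100L,
  gc_window = 120L, gc_step = 30L, tetra_window = 5000L,
  prefilter = "kmer", min_score = 40,
  seed = 1L)

#' Validated run configuration
#'
#' All pipeline parameters with their defaults: the generator's study
#' conditions (17 genomes, 200 core + 150 flexible families, 105
#' markers), the orthology filters (coverage 0.70, AAI window 2 SD,
#' inflation 2.0), the accumulation cutoffs (similarity 50, coverage 0.5,
#' 100 trials), the core fraction 13/17, and the composition window
#' sizes. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults, by name.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(CONFIG_DEFAULTS, over)
  core_min <- as.integer(ceiling(cfg$core_min_fraction * cfg$n_genomes))
  if (core_min > cfg$n_genomes)
    stop("core_min_fraction yields a threshold (", core_min,
         ") above n_genomes (", cfg$n_genomes, ")")
  if (cfg$trials < 1L) stop("trials must be >= 1")
  # generator-side validation happens up front, before any stage runs
  do.call(generator_params, cfg[names(cfg) %in% names(formals(generator_params))])
  structure(cfg, class = "run_config")
}

#' Read a flat key=value config file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Values are coerced to the type of the corresponding default.
#'
#' @param path config file.
#' @return a [run_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- which(lengths(kv) != 2L)
  if (length(bad)) stop("config line ", bad[1L], ": expected 'key = value'")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  over <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    dflt <- CONFIG_DEFAULTS[[k]]
    over[[k]] <- if (is.null(dflt) || is.character(dflt)) vals[i]
                 else if (is.integer(dflt)) as.integer(vals[i])
                 else as.numeric(vals[i])
  }
  do.call(run_config, over)
}

#' Run the full pipeline into a directory
#'
#' Stages, in dependency order: `synth` (genome set + truth + marker
#' hits + tRNA set), `align` (all-vs-all hits), `ortho` (BBH + MCL
#' ortholog table, AAI matrix, presence/absence, multicopy flags),
#' `partition` (core / shared non-core / unique), `accumulate`
#' (pan-genome curve + power fits), `complete` (per-genome CSCG and
#' relative completeness against the most complete genome as standard),
#' `trna` (usage matrix). A `manifest.json` records package version,
#' parameters, per-stage seeds and output checksums.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created; must not contain a previous
#'   manifest unless `overwrite = TRUE`).
#' @param overwrite allow writing into an existing run directory.
#' @return list of in-memory stage results, invisibly; side effect: files
#'   under `out_dir`.
#' @export
run_all <- function(config = run_config(), out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(out_dir) && file.exists(file.path(out_dir, "manifest.json"))
      && !overwrite)
    stop("out_dir already contains a run; use overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages_done <- character(0)
  run_stage <- function(name, fn) {
    pp_log(name, "starting")
    r <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    stages_done <<- c(stages_done, name)
    r
  }

  gp <- do.call(generator_params, c(
    config[names(config) %in% setdiff(names(formals(generator_params)), "seed")],
    list(seed = derive_seed(config$seed, "synth"))))

  synth <- run_stage("synth", function() {
    gs <- generate_genome_set(gp)
    for (p in gs$proteomes)
      write_fasta(p, file.path(out_dir, paste0(p$genome_id, ".faa")))
    truth_df <- data.frame(
      gene_id = names(gs$truth$gene_to_family),
      family = unname(gs$truth$gene_to_family),
      class = ifelse(gs$truth$gene_to_family == "UNIQUE", "UNIQUE",
                     unname(gs$truth$family_class[gs$truth$gene_to_family])),
      dropped = names(gs$truth$gene_to_family) %in% gs$truth$dropped_genes)
    utils::write.table(truth_df, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mh <- generate_marker_hits(gs$truth, gs$proteomes)
    utils::write.table(mh, file.path(out_dir, "marker_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    trna <- generate_trna_set(
      c(Lys = 50L, Phe = 50L, Met = 50L, Ala = 50L, Val = 50L),
      seed = derive_seed(config$seed, "trna"))
    write_trnascan_table(trna, file.path(out_dir, "trna.txt"))
    list(genomes = gs, marker_hits = mh, trna = trna)
  })

  hits <- run_stage("align", function() {
    h <- all_pairs_hits(synth$genomes$proteomes,
                        prefilter = config$prefilter,
                        min_score = config$min_score)
    write_blast_tabular(hits_to_tabular(h),
                        file.path(out_dir, "hits.tsv"), extended = TRUE)
    h
  })

  table <- run_stage("ortho", function() {
    tb <- infer_orthologs(synth$genomes$proteomes, hits = hits,
                          min_cov = config$min_cov,
                          aai_window = config$aai_window,
                          inflation = config$inflation)
    utils::write.table(tb$genes, file.path(out_dir, "ortholog_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_pa_matrix(presence_absence(tb),
                    file.path(out_dir, "presence_absence.tsv"))
    utils::write.table(tb$aai, file.path(out_dir, "aai.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(flag_multicopy(tb),
                       file.path(out_dir, "multicopy_flags.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tb
  })

  part <- run_stage("partition", function() {
    pr <- partition(table,
                    core_min_genomes =
                      as.integer(ceiling(config$core_min_fraction *
                                           config$n_genomes)))
    utils::write.table(pr$units, file.path(out_dir, "partition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pr
  })

  curve <- run_stage("accumulate", function() {
    cv <- accumulate(synth$genomes$proteomes, hits = hits,
                     trials = config$trials,
                     seed = derive_seed(config$seed, "accumulate"),
                     sim_threshold = config$sim_threshold,
                     cov_threshold = config$cov_threshold)
    utils::write.table(cv$summary, file.path(out_dir, "pan_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fits <- fit_pan_curve(cv)
    jsonlite::write_json(
      list(new_genes = fits$new_genes[c("a", "b", "rss", "n_points")],
           pan_total = fits$pan_total[c("a", "b", "rss", "n_points")]),
      file.path(out_dir, "pan_fit.json"), auto_unbox = TRUE, digits = NA)
    cv
  })

  compl <- run_stage("complete", function() {
    mh <- synth$marker_hits
    markers <- synth$genomes$truth$marker_families
    reports <- lapply(split(mh, mh$genome_id), score_completeness,
                      marker_set = markers)
    cpct <- vapply(reports, `[[`, numeric(1), "completeness_exact")
    standard <- names(which.max(cpct))
    ref <- family_complement(table, standard)
    rel <- vapply(names(reports), function(g)
      relative_completeness(table, g, ref), numeric(1))
    out <- data.frame(
      genome_id = names(reports),
      completeness_pct = vapply(reports, `[[`, integer(1),
                                "completeness_pct"),
      relative_completeness_pct = round(rel, 1),
      n_multicopy = vapply(reports, function(r)
        length(r$markers_multicopy), integer(1)),
      standard = standard, stringsAsFactors = FALSE)
    utils::write.table(out, file.path(out_dir, "completeness.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(reports = reports, table = out, standard = standard)
  })

  usage <- run_stage("trna", function() {
    um <- usage_matrix(synth$trna, group = "synthetic")
    utils::write.table(um, file.path(out_dir, "trna_usage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    um
  })

  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package = "parcupan",
    version = as.character(utils::packageVersion("parcupan")),
    seed = config$seed,
    stage_seeds = list(synth = derive_seed(config$seed, "synth"),
                       trna = derive_seed(config$seed, "trna"),
                       accumulate = derive_seed(config$seed, "accumulate")),
    parameters = unclass(config),
    stages = stages_done,
    outputs = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(synth = synth, hits = hits, table = table,
                 partition = part, curve = curve, completeness = compl,
                 trna_usage = usage, manifest = manifest))
}
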