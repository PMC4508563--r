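#' @title CSCG completeness and contamination scoring
#' @name completeness
#' @description Genome-bin quality from conserved single-copy genes
#'   (CSCGs): completeness is the percentage of an expected marker set
#'   (105 by default in this package's generator) found at least once;
#'   markers found in multiple copies flag putative contamination
#'   (misplaced scaffolds). Relative completeness scores a bin against the
#'   ortholog-family complement of a designated reference genome -- useful
#'   when the marker set itself is depleted in the lineage, as in the
#'   highly reduced Parcubacteria, where a closed genome (RAAC4-style)
#'   serves as the comparison standard.
NULL

#' Score CSCG completeness for one genome
#'
#' Completeness = 100 x (distinct markers found) / (markers expected),
#' reported as an integer percent (rounding half away from zero); the
#' full-precision value is retained. Hits to markers outside `marker_set`
#' are ignored with a warning.
#'
#' @param marker_hits data.frame with columns `gene_id` and `marker` for
#'   one genome (e.g. rows of [generate_marker_hits()]).
#' @param marker_set character vector of expected marker ids.
#' @param genome_id label for the report.
#' @return a `cscg_report`: list with `genome_id`, `n_markers_expected`,
#'   `markers_found`, `markers_multicopy` (named copy counts >= 2),
#'   `completeness_pct` (integer percent), `completeness_exact`.
#' @export
score_completeness <- function(marker_hits, marker_set,
                               genome_id = marker_hits$genome_id[1]) {
  if (length(marker_set) == 0L) stop("marker_set is empty")
  mk <- marker_hits$marker
  outside <- setdiff(unique(mk), marker_set)
  if (length(outside)) {
    warning("hit(s) to marker(s) outside marker_set ignored: ",
            paste(outside, collapse = ", "))
    marker_hits <- marker_hits[mk %in% marker_set, ]
    mk <- marker_hits$marker
  }
  counts <- table(mk)
  found <- names(counts)
  multi <- counts[counts >= 2L]
  exact <- 100 * length(found) / length(marker_set)
  structure(list(genome_id = genome_id,
                 n_markers_expected = length(marker_set),
                 markers_found = sort(found),
                 markers_multicopy = stats::setNames(as.integer(multi),
                                                     names(multi)),
                 completeness_pct = as.integer(sign(exact) *
                                                 floor(abs(exact) + 0.5)),
                 completeness_exact = exact),
            class = "cscg_report")
}

#' @export
print.cscg_report <- function(x, ...) {
  cat(sprintf("<cscg_report> %s: %d/%d markers (%d%%), %d multicopy\n",
              x$genome_id, length(x$markers_found), x$n_markers_expected,
              x$completeness_pct, length(x$markers_multicopy)))
  invisible(x)
}

#' Family complement of one genome
#'
#' The set of ortholog family ids with at least one member in the genome.
#'
#' @param table an [ortholog_table()].
#' @param genome_id genome to extract.
#' @return character vector of family ids.
#' @export
family_complement <- function(table, genome_id) {
  df <- table$genes
  sort(unique(df$family_id[df$genome_id == genome_id &
                             !is.na(df$family_id)]))
}

#' Relative completeness against a reference gene complement
#'
#' 100 x |families of the genome intersected with the reference
#' complement| / |reference complement|, where the reference complement is
#' the ortholog-family set of the designated standard genome. The standard
#' genome scored against its own complement is exactly 100.
#'
#' @param table an [ortholog_table()].
#' @param genome_id genome to score.
#' @param reference_complement character vector of reference family ids,
#'   e.g. [family_complement()] of the standard genome.
#' @return percent (numeric scalar).
#' @export
relative_completeness <- function(table, genome_id, reference_complement) {
  if (length(reference_complement) == 0L)
    stop("reference complement is empty")
  fams <- family_complement(table, genome_id)
  100 * length(intersect(fams, reference_complement)) /
    length(unique(reference_complement))
}

#' Multi-copy marker contamination flags
#'
#' @param report a [score_completeness()] result.
#' @return data.frame `marker`, `copy_count` (>= 2), sorted by count
#'   descending.
#' @export
contamination_flags <- function(report) {
  m <- report$markers_multicopy
  if (length(m) == 0L)
    return(data.frame(marker = character(), copy_count = integer()))
  out <- data.frame(marker = names(m), copy_count = unname(m),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$copy_count, out$marker), ]
  rownames(out) <- NULL
  out
}
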