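#' @title Sequence and table I/O
#' @name seqio
#' @description Readers and writers for the external formats the pipeline
#'   touches: protein/nucleotide FASTA, 12-column BLAST tabular hits (with an
#'   extended 15-column dialect carrying coverage and positives),
#'   tRNAscan-SE-style tRNA tables, per-base depth tables, and
#'   presence/absence matrices. All coordinates at the I/O boundary are
#'   1-based inclusive, the Bioconductor convention, and are kept 1-based
#'   inclusive internally so there is a single convention package-wide.
NULL

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

#' Construct a proteome
#'
#' A proteome is one genome's protein (or nucleotide) complement: a named
#' character vector of sequences plus the genome identifier. Gene ids must be
#' unique and sequences non-empty; protein sequences may contain the 20
#' canonical residues plus `X` and `*` (trailing stops are stripped).
#'
#' @param genome_id single string identifying the genome (bin).
#' @param seqs named character vector, names are gene ids.
#' @param descriptions optional character vector of free-text descriptions.
#' @param type `"protein"` or `"nucleotide"`; controls alphabet validation.
#' @return An object of class `proteome` with elements `genome_id`, `ids`,
#'   `seqs`, `descriptions`, `type`.
#' @export
proteome <- function(genome_id, seqs, descriptions = NULL,
                     type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  if (!is.character(genome_id) || length(genome_id) != 1L || !nzchar(genome_id))
    stop("genome_id must be a non-empty string")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all sequences must have non-empty ids")
  if (anyDuplicated(ids))
    stop("duplicate gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(seqs)
  if (type == "protein") seqs <- sub("\\*+$", "", seqs)
  if (any(!nzchar(seqs))) stop("empty sequence(s) present")
  allowed <- if (type == "protein") c(AA_ALPHABET, "X") else c("A","C","G","T","N")
  bad <- !grepl(paste0("^[", paste(allowed, collapse = ""), "]+$"), seqs)
  if (any(bad))
    stop("sequence(s) with characters outside the ",
         type, " alphabet: ", paste(utils::head(ids[bad], 3), collapse = ", "))
  structure(list(genome_id = genome_id, ids = unname(ids),
                 seqs = stats::setNames(unname(seqs), ids),
                 descriptions = descriptions, type = type),
            class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("<proteome> %s: %d %s sequences\n",
              x$genome_id, n_genes(x), x$type))
  invisible(x)
}

#' Number of genes in a proteome
#' @param x a `proteome`.
#' @return integer count.
#' @export
n_genes <- function(x) length(x$seqs)

#' Read a FASTA file into a proteome
#'
#' One record per header, file order preserved, residues upper-cased.
#' The record id is the first whitespace-delimited token of the header;
#' the remainder is kept as the description.
#'
#' @param path FASTA file.
#' @param genome_id genome identifier; defaults to the file name without
#'   extension.
#' @param type `"protein"` or `"nucleotide"`.
#' @return a [proteome()].
#' @export
read_fasta <- function(path, genome_id = NULL,
                       type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  set <- if (type == "protein") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  if (any(!nzchar(ids))) stop("malformed header (empty id) in ", path)
  if (anyDuplicated(ids))
    stop("duplicate id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  proteome(genome_id, stats::setNames(as.character(set), ids),
           descriptions = desc, type = type)
}

#' Write a proteome to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param x a `proteome` or a named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "proteome")) x$seqs else x
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

BLAST_COLS <- c("query_id", "subject_id", "pct_identity", "aln_length",
                "mismatches", "gap_opens", "q_start", "q_end",
                "s_start", "s_end", "evalue", "bit_score")
BLAST_EXT_COLS <- c(BLAST_COLS, "q_cov", "s_cov", "pct_positives")

#' Read BLAST-style tabular hits
#'
#' Accepts the standard 12-column tab-separated dialect (query, subject,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore) or the package's extended 15-column dialect that appends
#' `q_cov`, `s_cov` and `pct_positives`. The column count must be uniform;
#' a line with any other width is an error naming that line.
#'
#' @param path tab-separated hit file.
#' @return a data.frame of hits with typed columns.
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 12)), BLAST_COLS))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  ncol_exp <- nf[1L]
  if (!ncol_exp %in% c(12L, 15L))
    stop("line 1: expected 12 or 15 tab-separated columns, got ", ncol_exp)
  bad <- which(nf != ncol_exp)
  if (length(bad))
    stop("line ", bad[1L], ": expected ", ncol_exp,
         " tab-separated columns, got ", nf[bad[1L]])
  m <- matrix(unlist(fields), ncol = ncol_exp, byrow = TRUE)
  cols <- if (ncol_exp == 12L) BLAST_COLS else BLAST_EXT_COLS
  out <- stats::setNames(as.data.frame(m, stringsAsFactors = FALSE), cols)
  num <- setdiff(cols, c("query_id", "subject_id"))
  int <- c("aln_length", "mismatches", "gap_opens",
           "q_start", "q_end", "s_start", "s_end")
  for (cc in num) out[[cc]] <- as.numeric(out[[cc]])
  for (cc in int) out[[cc]] <- as.integer(out[[cc]])
  if (any(is.na(out$pct_identity)) ||
      any(out$pct_identity < 0 | out$pct_identity > 100))
    stop("pct_identity outside [0, 100]")
  if (any(out$q_start > out$q_end) || any(out$s_start > out$s_end))
    stop("alignment coordinates must satisfy start <= end")
  out
}

#' Write hits in BLAST tabular format
#'
#' @param hits data.frame with the 12 standard columns (and optionally
#'   `q_cov`, `s_cov`, `pct_positives` for the extended dialect).
#' @param path output file.
#' @param extended emit the 15-column extended dialect.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(hits, path, extended = FALSE) {
  cols <- if (extended) BLAST_EXT_COLS else BLAST_COLS
  miss <- setdiff(cols, names(hits))
  if (length(miss)) stop("missing hit column(s): ", paste(miss, collapse = ", "))
  out <- hits[, cols, drop = FALSE]
  out$evalue <- formatC(out$evalue, format = "g", digits = 3)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

TRNA_ISOTYPES <- c("Ala","Arg","Asn","Asp","Cys","Gln","Glu","Gly","His",
                   "Ile","Leu","Lys","Met","fMet","iMet","Phe","Pro","SeC",
                   "Ser","Sup","Thr","Trp","Tyr","Val","Undet","Pseudo")

#' Read a tRNAscan-SE tabular output file
#'
#' Parses the classic tRNAscan-SE tabular format (3 header lines, then one
#' row per tRNA: sequence name, tRNA number, begin, end, isotype, anticodon,
#' intron begin/end, score). Rows with begin > end are minus-strand
#' predictions; their coordinates are normalized (begin <= end) and the
#' strand recorded. Unknown isotype strings are kept with isotype set to
#' `"Undet"` and a warning. `U` in anticodons is read as `T` (DNA space).
#'
#' If `sequences` (a named character vector or `DNAStringSet` of source
#' scaffolds) is supplied, each record's tRNA sequence is extracted
#' (reverse-complemented for minus-strand rows) and the anticodon is located
#' within it, preferring the canonical offset (0-based 33) so anticodon-loop
#' positions can be read with [loop_positions()].
#'
#' @param path tRNAscan-SE tabular file.
#' @param sequences optional source scaffold sequences, named.
#' @return data.frame with columns `scaffold`, `trna_no`, `begin`, `end`,
#'   `strand`, `isotype`, `anticodon`, `intron_begin`, `intron_end`, `score`,
#'   and (when `sequences` is given) `seq` and `anticodon_start` (0-based).
#' @export
read_trnascan_table <- function(path, sequences = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) > 0 && grepl("^Sequence|^Name|^-+", lines[1L])) {
    is_hdr <- grepl("^Sequence\\b|^Name\\b|^-{4,}", lines)
    lines <- lines[!is_hdr & nzchar(lines)]
  } else {
    lines <- lines[nzchar(lines)]
  }
  if (length(lines) == 0L)
    return(data.frame(scaffold = character(), trna_no = integer(),
                      begin = integer(), end = integer(),
                      strand = character(), isotype = character(),
                      anticodon = character(), intron_begin = integer(),
                      intron_end = integer(), score = numeric()))
  fields <- strsplit(trimws(lines), "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 9L)
  if (length(bad))
    stop("line ", bad[1L], ": expected >= 9 tab-separated columns, got ",
         nf[bad[1L]])
  m <- t(vapply(fields, function(f) f[1:9], character(9)))
  rec <- data.frame(scaffold = trimws(m[, 1]),
                    trna_no = as.integer(m[, 2]),
                    begin = as.integer(m[, 3]),
                    end = as.integer(m[, 4]),
                    isotype = trimws(m[, 5]),
                    anticodon = toupper(chartr("U", "T", trimws(m[, 6]))),
                    intron_begin = as.integer(m[, 7]),
                    intron_end = as.integer(m[, 8]),
                    score = as.numeric(m[, 9]),
                    stringsAsFactors = FALSE)
  rec$strand <- ifelse(rec$begin > rec$end, "-", "+")
  flip <- rec$strand == "-"
  tmp <- rec$begin[flip]
  rec$begin[flip] <- rec$end[flip]
  rec$end[flip] <- tmp
  unk <- !(rec$isotype %in% TRNA_ISOTYPES)
  if (any(unk)) {
    warning("unknown isotype string(s) set to 'Undet': ",
            paste(unique(rec$isotype[unk]), collapse = ", "))
    rec$isotype[unk] <- "Undet"
  }
  rec <- rec[, c("scaffold", "trna_no", "begin", "end", "strand",
                 "isotype", "anticodon", "intron_begin", "intron_end",
                 "score")]
  if (!is.null(sequences)) {
    sequences <- stats::setNames(toupper(as.character(sequences)),
                                 names(sequences))
    rec$seq <- NA_character_
    rec$anticodon_start <- NA_integer_
    for (i in seq_len(nrow(rec))) {
      src <- sequences[[rec$scaffold[i]]]
      if (is.null(src) || is.na(src)) next
      s <- substr(src, rec$begin[i], rec$end[i])
      if (rec$strand[i] == "-") s <- revcomp(s)
      rec$seq[i] <- s
      rec$anticodon_start[i] <- locate_anticodon(s, rec$anticodon[i])
    }
  }
  rec
}

# prefer the canonical anticodon offset (0-based 33), else first occurrence
locate_anticodon <- function(seq, anticodon) {
  if (nchar(seq) >= 36L && substr(seq, 34L, 36L) == anticodon) return(33L)
  p <- regexpr(anticodon, seq, fixed = TRUE)
  if (p < 0) NA_integer_ else as.integer(p - 1L)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Write records in tRNAscan-SE tabular format
#'
#' Emits the classic 3-line header followed by one row per record;
#' minus-strand records are written with begin > end, restoring the
#' tRNAscan coordinate convention.
#'
#' @param records data.frame as returned by [read_trnascan_table()] or
#'   [generate_trna_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trnascan_table <- function(records, path) {
  hdr <- c("Sequence\t\ttRNA\tBounds\ttRNA\tAnti\tIntron Bounds\tCove",
           "Name\ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore",
           "--------\t------\t-----\t---\t----\t-----\t-----\t----\t-----")
  b <- records$begin; e <- records$end
  flip <- records$strand == "-"
  tmp <- b[flip]; b[flip] <- e[flip]; e[flip] <- tmp
  rows <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%.1f",
                  records$scaffold, records$trna_no, b, e,
                  records$isotype, records$anticodon,
                  records$intron_begin, records$intron_end, records$score)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a per-base depth table
#'
#' Three tab-separated columns: scaffold, 1-based position, depth (the
#' `samtools depth` layout). Positions need not be contiguous; positions
#' absent from the table count as depth 0 when averaging over a declared
#' scaffold length (see [mean_coverage()]).
#'
#' @param path depth TSV.
#' @return data.frame with columns `scaffold`, `pos`, `depth`.
#' @export
read_depth_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("scaffold", "pos", "depth"),
                         colClasses = c("character", "integer", "numeric"))
  if (any(d$depth < 0)) stop("negative depth value(s)")
  if (any(d$pos < 1)) stop("positions must be 1-based (>= 1)")
  d
}

#' Write / read a presence-absence matrix
#'
#' Families x genomes integer copy-count matrix as TSV with row and column
#' names. Write-then-read is the identity.
#'
#' @param mat integer matrix, rownames = family ids, colnames = genome ids.
#' @param path TSV file.
#' @return `path` (write) or the matrix (read).
#' @export
write_pa_matrix <- function(mat, path) {
  utils::write.table(mat, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_pa_matrix
#' @export
read_pa_matrix <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE)
  as.matrix(m)
}
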