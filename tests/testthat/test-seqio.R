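test_that("FASTA reading preserves order, ids and case-normalized residues", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">g1 first protein", "MKVL", ">g2", "mkRT"), f)
  p <- read_fasta(f, genome_id = "gX")
  expect_equal(n_genes(p), 2L)
  expect_equal(p$ids, c("g1", "g2"))
  expect_equal(unname(p$seqs), c("MKVL", "MKRT"))
  expect_equal(p$descriptions[1], "first protein")
})

test_that("FASTA degenerate inputs give distinct errors", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "no records")
  writeLines(c(">g1", "MK", ">g1", "MR"), f)
  expect_error(read_fasta(f), "duplicate id")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("FASTA write-then-read is the identity (60-column wrapping)", {
  set.seed(1)
  seqs <- vapply(c(10, 59, 60, 61, 200), random_aa, character(1))
  names(seqs) <- paste0("gene", 1:5)
  p <- proteome("G1", seqs)
  f <- withr::local_tempfile(fileext = ".faa")
  write_fasta(p, f)
  lines <- readLines(f)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  p2 <- read_fasta(f, genome_id = "G1")
  expect_equal(p2$seqs, p$seqs)
})

test_that("proteome constructor enforces its invariants", {
  expect_error(proteome("G", c(a = "MKQJ")), "alphabet")
  expect_error(proteome("G", setNames("MK", "")), "non-empty ids")
  expect_error(proteome("G", c(a = "MK", a = "MR")), "duplicate")
  # trailing stop codons are stripped, internal X tolerated
  p <- proteome("G", c(a = "MKX*"))
  expect_equal(unname(p$seqs), "MKX")
})

test_that("BLAST tabular hits parse, validate, and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("g1\tg2\t97.5\t200\t5\t0\t1\t200\t1\t200\t1e-50\t380", f)
  h <- read_blast_tabular(f)
  expect_equal(h$pct_identity, 97.5)
  expect_equal(h$bit_score, 380)
  expect_equal(h$query_id, "g1")

  writeLines(c("g1\tg2\t97.5\t200\t5\t0\t1\t200\t1\t200\t1e-50\t380",
               "g1\tg3\t90\t100\t5\t0\t1\t100\t1\t100\t1e-10"), f)
  expect_error(read_blast_tabular(f), "line 2")

  tab <- data.frame(query_id = c("a", "b"), subject_id = c("x", "y"),
                    pct_identity = c(99.1, 45.2), aln_length = c(100L, 80L),
                    mismatches = c(1L, 40L), gap_opens = c(0L, 2L),
                    q_start = c(1L, 5L), q_end = c(100L, 84L),
                    s_start = c(1L, 3L), s_end = c(100L, 82L),
                    evalue = c(1e-30, 0.002), bit_score = c(200, 50.5))
  write_blast_tabular(tab, f)
  back <- read_blast_tabular(f)
  expect_equal(back, tab, tolerance = 1e-12)
})

test_that("tRNAscan tables parse with strand normalization and round-trip", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "Sequence\t\ttRNA\tBounds\ttRNA\tAnti\tIntron Bounds\tCove",
    "Name\ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore",
    "--------\t------\t-----\t---\t----\t-----\t-----\t----\t-----",
    "scaf1\t1\t100\t175\tLys\tTTT\t0\t0\t65.3",
    "scaf1\t2\t900\t820\tPhe\tGAA\t0\t0\t50.0"), f)
  r <- read_trnascan_table(f)
  expect_equal(r$isotype, c("Lys", "Phe"))
  expect_equal(r$strand, c("+", "-"))
  expect_equal(r$begin[2], 820L)
  expect_equal(r$end[2], 900L)

  # unknown isotype becomes Undet with a warning
  writeLines(c("scaf1\t1\t1\t76\tXyz\tTTT\t0\t0\t60.0"), f)
  expect_warning(r2 <- read_trnascan_table(f), "Undet")
  expect_equal(r2$isotype, "Undet")

  # generator output round-trips through write/read
  g <- generate_trna_set(c(Lys = 5L, Val = 4L), seed = 9)
  write_trnascan_table(g, f)
  back <- read_trnascan_table(f)
  expect_equal(back[, c("scaffold", "begin", "end", "strand", "isotype",
                        "anticodon", "score")],
               g[, c("scaffold", "begin", "end", "strand", "isotype",
                     "anticodon", "score")])
  # and sequences are recoverable from the source FASTA
  back2 <- read_trnascan_table(f, sequences = setNames(g$seq, g$scaffold))
  expect_equal(back2$seq, g$seq)
  expect_equal(back2$anticodon_start, g$anticodon_start)
})

test_that("depth tables validate and feed zero-filled averaging", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\t1\t10", "s1\t2\t10"), f)
  d <- read_depth_table(f)
  expect_equal(mean_coverage(d, 2), 10)
  # half of a length-4 scaffold at depth 8 averages 4 with zero-fill
  writeLines(c("s1\t1\t8", "s1\t2\t8"), f)
  expect_equal(mean_coverage(read_depth_table(f), 4), 4.0)
  writeLines("s1\t1\t-3", f)
  expect_error(read_depth_table(f), "negative depth")
})

test_that("randomized sparse depth equals brute-force zero-filled mean", {
  set.seed(7)
  for (rep in 1:5) {
    len <- sample(20:200, 1)
    pos <- sort(sample(len, sample(seq_len(len), 1)))
    depth <- sample(0:50, length(pos), replace = TRUE)
    full <- numeric(len)
    full[pos] <- depth
    d <- data.frame(scaffold = "s", pos = pos, depth = depth)
    expect_equal(mean_coverage(d, len), sum(full) / len)
  }
})

test_that("presence/absence matrices round-trip bit-exactly", {
  m <- matrix(sample(0:3, 12, replace = TRUE), 4, 3,
              dimnames = list(paste0("F", 1:4), paste0("G", 1:3)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pa_matrix(m, f)
  expect_identical(read_pa_matrix(f), m)
})
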