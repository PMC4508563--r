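# parcupan

Comparative pan-genome analysis for sets of reconstructed bacterial genome
bins — built for lineages like the Parcubacteria (OD1), a candidate phylum
known only from metagenome-assembled and single-cell genomes, whose bins
are incomplete, highly reduced, and deeply divergent.

For microbial genomicists comparing such bins, the package provides:

* **Exact protein alignment** — affine-gap Smith–Waterman (BLOSUM62, gap
  open 11 / extend 1) with identity, BLAST-style positives, and two-sided
  coverage per hit; all-vs-all with an optional deterministic exact-k-mer
  candidate screen for scale. External BLAST tabular hits can substitute.
* **Orthology** — bidirectional best hits filtered by ≥ 70% coverage on
  both sequences and an AAI-adaptive identity rule (a pair is dropped when
  its identity falls more than 2 SD below the genome pair's average
  amino-acid identity), then Markov clustering (MCL, inflation 2.0) of the
  accepted-pair graph into ortholog families.
* **Core / flexible partition** — families present in ≥ ⌈13/17·G⌉ genomes
  are core (13 of 17 at the study scale, tolerant of bin incompleteness);
  single-genome families and singletons are unique; the rest shared
  non-core. COG-style category breakdowns of the three classes.
* **Pan-genome accumulation** — Tettelin-style: genomes added in random
  orders (all orders when G! ≤ trials, else 100 distinct sampled orders),
  genes counted new when no prior genome has a hit at ≥ 50% positives over
  > 50% of both protein lengths, counts normalized by the median protein
  count of the genomes included so far, and power laws *y = a·x^b* fitted
  by log–log least squares.
* **Bin quality** — conserved single-copy gene (CSCG) completeness
  (percent of an expected marker set found), multi-copy contamination
  flags, and relative completeness against a designated standard genome's
  ortholog-family complement.
* **Composition signatures** — %G+C in 120 nt / 30 nt sliding windows,
  tetranucleotide frequency vectors in 5 kb tiling windows, and mean
  scaffold coverage from per-base depth tables.
* **tRNA anticodon-loop usage** — nucleotide usage at standard positions
  38–40 (the pseudouridine synthase A targets) per isotype, and
  group-vs-group frequency comparisons.
* **A synthetic genome-set generator with planted truth** — core/flexible
  families at controlled divergence, unique genes, dropout-simulated
  incompleteness, marker tables, and tRNA sets with controlled loop-base
  usage — so the whole pipeline is testable end-to-end with no external
  data.

See the methods vignette (`vignettes/parcupan-methods.Rmd`) for the models,
parameter choices, and limitations.

## Worked example

Six synthetic genome bins (60 core + 30 flexible families, 10 unique genes
per genome, 90% within-family identity, 10% gene dropout emulating
incomplete bins), analyzed end-to-end:

```r
library(parcupan)

params <- generator_params(n_genomes = 6, n_core_families = 60,
                           n_flex_families = 30, n_unique_per_genome = 10,
                           n_marker_families = 25, mean_protein_len = 150,
                           dropout_rate = 0.1, seed = 42)
gs <- generate_genome_set(params)

tb <- infer_orthologs(gs$proteomes, prefilter = "kmer")
tb
#> <ortholog_table> 449 genes over 6 genomes: 83 families (385 genes), 64 singletons

partition(tb)
#> <partition_result> core >= 5 of 6 genomes
#>             class n_units n_genes
#> 1            CORE      54     300
#> 2 SHARED_NON_CORE      29      85
#> 3          UNIQUE      64      64

cv <- accumulate(gs$proteomes, trials = 100, seed = 42, prefilter = "kmer")
fit_pan_curve(cv)$new_genes
#> <power_fit> y = 0.447359 * x^-0.689116 (rss 0.000761, n 5)

mh <- generate_marker_hits(gs$truth, gs$proteomes)
score_completeness(mh[mh$genome_id == "G01", ], gs$truth$marker_families)
#> <cscg_report> G01: 23/25 markers (92%), 0 multicopy

ref <- family_complement(tb, "G02")
relative_completeness(tb, "G01", ref)
#> [1] 81.48148
```

Reading the output: 449 genes survive dropout; the 83 recovered
multi-member families plus 64 singletons partition them exactly
(385 + 64 = 449). With 10% dropout the ≥ 5/6 core rule still calls 54 of
the 60 planted core families (dropout removes some families from two or
more genomes). The normalized new-gene curve decays as a power law — each
added genome contributes new genes worth ~45% of the median gene
complement at step 1, falling with the −0.69 exponent. G01 carries 23 of
the 25 markers (92% complete) and 81.5% of the family complement of the
G02 standard; a standard genome scored against its own complement is
always exactly 100%.

The full pipeline (generation → alignment → orthology → partition →
accumulation → completeness → tRNA usage, with TSV outputs and a
manifest) runs as one call:

```r
run_all(run_config(n_genomes = 6, seed = 42), out_dir = "run1")
```

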