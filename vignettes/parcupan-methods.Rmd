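---
title: "Methods: comparative pan-genome analysis for reduced genome bins"
author: "parcupan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative pan-genome analysis for reduced genome bins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parcupan)
```

## The problem

Parcubacteria (OD1) and similar candidate phyla are known almost entirely
from metagenome-assembled and single-cell genome bins. Those bins are
incomplete, their gene complements are highly reduced and divergent, and
the questions asked of them are comparative: which gene families form a
phylum core, how open is the pan-genome, how complete is each bin, and
what compensatory signatures (such as altered tRNA anticodon-loop
composition) accompany gene loss. `parcupan` implements that comparative
toolchain end-to-end, together with a synthetic genome-set generator with
planted truth, so every stage can be validated without any external data.

## Orthology: BBH with an AAI-adaptive identity filter

For each ordered genome pair, every protein's best hit is the
highest-scoring local alignment (ties broken by higher percent identity,
then lexicographically smaller subject id, so results are reproducible).
Reciprocal best pairs qualify provisionally if the aligned region covers
at least 70% of the protein length. The mean and standard deviation of
the provisional pairs' percent identities define that genome pair's
average amino-acid identity (AAI); pairs more than 2 SD *below* the mean
are then discarded. This adaptive filter scales the stringency to each
genome pair's evolutionary distance instead of using one global identity
cutoff.

Three genuinely open readings were settled as follows:

* **Coverage side.** The 70% rule is enforced on *both* query and subject
  lengths (`cov_mode = "both"`). The one-sided reading admits domain-only
  matches between proteins of very different length, which inflates
  families; the stricter reading is the default and the laxer one remains
  available (`cov_mode = "query"`).
* **Direction of the SD window.** The identity filter is one-sided
  (identity ≥ mean − 2 SD). Discarding pairs for being *too similar*
  has no biological interpretation.
* **When AAI is computed.** In a single pass from the coverage-passing
  provisional pairs, with no iteration: re-estimating AAI after each
  removal would couple the filter to its own output.

Accepted pairs across all genome pairs form an undirected graph (edge
weight = identity/100) that is clustered with the Markov Cluster
algorithm: column-normalize the adjacency matrix with self-loops (each
node's self-loop at its maximum incident edge weight), then alternate
expansion (matrix squaring) and inflation (elementwise power, default
2.0, then renormalization), pruning entries below 1e-5, to convergence
(max elementwise change < 1e-8) or 200 iterations. The graph is split
into connected components first — MCL can never merge disconnected
components, and per-component matrices stay small. Clusters with two or
more members become families, numbered deterministically by decreasing
size then smallest member id; single nodes are singletons. The historical
Multiparanoid consolidation and gene-neighborhood splitting steps are
deliberately not reproduced: MCL-only clustering is simpler, fully
specified, and recovers planted families essentially perfectly at the
divergences this package targets.

## Alignment engine

Alignments are exact affine-gap Smith–Waterman (BLOSUM62, gap open 11,
extend 1; a gap of length *k* costs 11 + *k*). "Similarity" thresholds are
implemented as BLAST-style *positives* (aligned columns with positive
substitution score) over all aligned columns including gaps; coverage is
the aligned span over each sequence's full length. There is no heuristic
seeding, so hit lists are deterministic and reproducible; scores are
validated in the test suite against exhaustive enumeration of all local
alignments for short sequences.

Complete all-vs-all DP is quadratic in genes and in residues. At the
package's default study scale (17 genomes × ~400 proteins of ~250
residues) that is ~10^12 DP cells, so `all_vs_all()` offers a
deterministic exact-k-mer candidate screen (`prefilter = "kmer"`): only
pairs sharing ≥ 3 exact 5-mers enter the DP. Two proteins at the
package's default 90% identity share ~145 5-mers in expectation, while
two unrelated ~250-residue proteins share ~0.02, so the screen is
effectively lossless at divergences up to ~30% and its false-negative
risk is negligible precisely where the BBH criteria could be met.
`prefilter = "none"` (the default) evaluates every pair. Externally
computed hits in BLAST tabular format can substitute for the built-in
aligner everywhere (`read_blast_tabular()` + `tabular_to_hits()`).

## Core / flexible partition

Family presence is the number of distinct genomes with ≥ 1 member. With
incomplete bins, requiring presence in *all* genomes would reject true
core families at a rate compounding each bin's incompleteness, so the
core rule is presence in ≥ ⌈13/17 · G⌉ genomes (13 of 17 at the study
scale). Families confined to one genome — and all singletons — are
UNIQUE; the rest are SHARED_NON_CORE. `category_breakdown()`
cross-tabulates these classes against externally supplied functional
category letters, counting multi-category genes once under "Multiple
assignments".

## Pan-genome accumulation and power fits

Following the Tettelin protocol, genomes are added one at a time in a
random order. A gene of the added genome is *shared* if some prior
genome contains a hit at ≥ 50% similarity (positives) over > 50% of the
protein length — deliberately laxer than the 70%/2-SD orthology
criterion, because the two protocols answer different questions (novelty
detection vs. confident orthology). The coverage requirement applies to
both sequences by default (`cov_side = "both"`): this makes the sharing
relation symmetric, which in turn makes the final pan-genome total a
set-level quantity, identical across genome orders; the asymmetric
query-side-only reading (`cov_side = "query"`) loses that invariance. Per step the new-gene count, cumulative
pan-genome size, and the shared count (genes of the first genome with
qualifying hits in every genome included so far — the classic core-curve
convention, since the reference genome of "shared" is otherwise
ambiguous) are recorded.

Counts are reported raw and normalized by the *median protein count of
the genomes included so far in that trial* — the step-contextual reading
of median normalization; a global-median mode is available
(`median_mode = "global"`). Orders are distinct permutations: all of
them when G! ≤ trials (the exhaustion rule; 6 orders at G = 3), else
uniform sampling without replacement, 100 trials by default.

Power laws *y* = *a·x^b* are fitted by least squares on log *y* vs
log *x*; the fit is exact on noiseless power-law data. For the new-gene
curve, step 1 is excluded by default: the first "new gene" count is the
whole first genome, not an accumulation observation
(`include_step1 = TRUE` restores it).

## Completeness and contamination

Completeness is the percentage of an expected conserved single-copy gene
(CSCG) set found at least once (integer percent, half away from zero;
the exact value is retained). Markers found in ≥ 2 copies are
contamination flags. Relative completeness is defined on ortholog
families: 100 × |families of the bin ∩ families of the designated
standard genome| / |families of the standard|. Defining it as a ratio of
CSCG percentages would be both unstable (the marker set is itself
depleted in reduced lineages) and inconsistent with using a closed
genome's *gene complement* as the standard; by construction the standard
scores exactly 100 against itself.

## Composition signatures

%G+C is computed over 120 nt windows stepping by 30 nt (N excluded from
the denominator; trailing partial windows dropped). Tetranucleotide
vectors use 5000 nt tiling windows (trailing window kept when ≥ 4 nt),
overlapping 4-mers, N-containing 4-mers skipped, normalized to sum to 1
per window. Counting is single-stranded over all 256 tetramers by
default since strand conventions differ between binning tools; a
canonical 136-dimensional reverse-complement-collapsed mode is available
(`collapse = TRUE`). Mean scaffold coverage requires the declared
scaffold length so that positions absent from the depth table count as
zero — using the maximum observed position instead would silently trim
zero-depth tails.

## tRNA anticodon-loop usage

Positions 38–40 are read at fixed offsets +4/+5/+6 from the anticodon
start (standard positions 34–36). Canonical cloverleaves have no length
variation between the anticodon and position 40, so full Sprinzl
alignment is unnecessary; records too short for position 40 are skipped.
Counts are pooled across genomes within a group (the phylum-level view),
`U` is read as `T`, and group comparisons report per-(isotype, position)
frequency differences for one base (default `T`, the pseudouridine
synthase A target), masking cells with fewer than 5 records in either
group — frequencies from 1–2 genes are noise.

## The synthetic generator

`generate_genome_set()` plants: a core of families present in every
genome; flexible families present per genome independently with
probability `flex_presence_prob`; fresh unique genes; and uniform random
dropout emulating bin incompleteness. Family ancestors are random
proteins (gamma lengths, CV 0.3, minimum 50 residues); members are
derived by i.i.d. substitutions with per-branch probability *p* solving
(1−*p*)² + *p*²/19 = target identity, so expected pairwise identity
between any two members equals `within_family_identity` regardless of
order — the substitution model is uniform over the 19 alternative
residues because it is analytically invertible and symmetric. Unique
genes are drawn fresh rather than diverged, so truth labels are clean.
Per-genome RNG streams are derived from the master seed, so adding
genomes never perturbs earlier ones; gene order is shuffled within each
genome.

Defaults are the package's study conditions: 17 genomes, 200 core + 150
flexible families at 50% presence, 125 unique genes per genome (~400
genes/genome), 90% within-family identity, 105 marker families, no
dropout. Within-phylum identity distributions for lineages like this are
not well characterized, so 90% was chosen once for testability — high
enough that orthology should be recoverable, low enough that the AAI
filter and coverage rules do real work — and is not tuned thereafter.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: indel evolution (members differ only by
substitutions, so coverage is rarely the binding constraint), rate
variation across sites and lineages, paralogy and horizontal transfer,
chimeric contamination beyond duplicated markers, and realistic
nucleotide-level genome structure. The tRNA generator
(`generate_trna_set()`) emits fixed-layout cloverleaf-like records with
controlled base distributions at positions 38–40 only.

## Numerical choices and degenerate inputs

* Alignment ties: the DP prefers starting fresh over extending a
  zero-score prefix, so reported spans never include score-neutral
  prefixes.
* `bbh_pairs()` with zero provisional pairs returns an empty set with
  the AAI flagged undefined rather than erroring, so one empty genome
  pair cannot abort a 136-pair run; SD of a single pair is 0 (the
  window degenerates to equality and keeps the pair).
* MCL non-convergence at 200 iterations returns the current clustering
  with a warning rather than failing.
* `fit_power()` refuses non-positive values, naming the offending index.
* Depth tables reject negative depths and positions beyond the declared
  length.
* Probability vectors (tRNA usage specs) must sum to 1 within 1e-9.

## Problem sizes used in validation

The test suite exercises the full study conditions (17 genomes, ~6,800
genes) for family recovery and the core rule, and smaller sets (2–6
genomes, 50–120-residue proteins) elsewhere; the alignment oracle checks
exhaustive enumeration on hundreds of length-≤8 pairs. The acceptance
script runs a 6-genome set with 10% dropout. These sizes were chosen so
the whole validation cycle completes on a laptop in minutes while still
covering the regime where each filter matters.

## Interfaces

The package's functions are the interface, driven from R:
`run_config()` + `run_all()` orchestrate the whole pipeline into a run
directory with a manifest (package version, parameters, derived
per-stage seeds, output checksums); every stage is also exported on its
own. Flat `key = value` config files are read with `read_config()`.
Per-stage seeds are derived deterministically from the master seed and
the stage name, so any stage can be re-run independently and whole-run
reruns are bit-identical.

## Known limitations

* In-paralog resolution is MCL-only; no synteny or tree-based splitting.
* E-values are not computed (exact DP has no Karlin–Altschul context);
  score floors play that role.
* Relative completeness depends on the ortholog table containing the
  standard genome; it is not defined across independently built tables.
* The 136-dimensional tetramer collapse assumes perfect
  reverse-complement symmetry of the underlying counting, which holds
  for the built-in counter but not necessarily for imported profiles.
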