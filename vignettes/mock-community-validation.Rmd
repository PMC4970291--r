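---
title: "Validating V1-V3 amplicon pipelines with a mock community"
author: "ampmock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating V1-V3 amplicon pipelines with a mock community}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampmock)
```

## The problem

Long 16S rRNA gene amplicons such as the V1-V3 region (~490 bp) offer
better taxonomic resolution than the short V4 fragment, but on paired-end
short-read instruments the assembled contigs carry a higher error load. In
practice the damage concentrates in a long tail of *low-frequency
sequences*: unique reads that occur once (cross-sample singletons) or twice
(doubletons) among all samples of a run. These are mostly sequencing
artifacts, chimeras, and trace contamination rather than rare organisms,
and because OTU calling requires an all-pairs distance matrix, carrying
them through clustering is quadratically expensive as well as misleading —
richness estimates inflate by more than an order of magnitude.

`ampmock` packages the validation workflow for this situation: a defined
(mock) community with known 16S gene sequences is sequenced (or simulated)
in replicates, and every downstream claim — error rate, OTU richness, alpha
diversity, taxonomy — can be checked against ground truth with and without
removal of the low-frequency tail.

## The mock community design

A balanced mock community gives every member the same share of 16S gene
copies. Because genomes differ in size and in per-genome 16S copy number,
equal *mass* is not equal *copies*; the package uses the standard
double-stranded DNA arithmetic

$$\text{copies}/\mu g = \frac{10^{-6}\,\mathrm{g} \times N_A}
 {\text{genome size} \times 650\ \mathrm{g\,mol^{-1}\,bp^{-1}}}
 = \frac{9.2646\times 10^{14}}{\text{genome size}}$$

and the balancing equation

$$\text{mass}_i\ (\mu g) = \frac{\text{target copies}_i}
 {n_{16S,i} \times \text{copies}/\mu g_i}.$$

`mock_community_members()` ships the composition of a 20-member community
(19 bacteria plus one archaeon included as a control for non-specific
amplification) with genome sizes, copy numbers, and the published
copies-per-microgram estimates; the computed values agree with the
published ones to within one unit in the third significant digit (two rows
of the published table appear truncated rather than rounded, hence the
one-unit tolerance). `design_equal_mock()` turns any such table plus a
total copy target into per-member masses; the total is a required argument
because a stock total is a lab choice, not a property of the community.

One deliberate quirk is preserved: one member (*Haemophilus*-analogue)
carries two 16S gene copies that are only 94% identical, so at the
conventional 97% OTU threshold the 19 bacterial genomes yield **20**
bacterial OTUs, not 19.

## The simulator and what it emulates

No public accession exists for the original reads, so the package
generates ground-truthed runs. `generate_references()` draws random
templates and can constrain selected pairs to a target identity (the 94%
copy pair); `mock_reference_set()` assembles the full 21-template analogue
(20 bacterial + archaeal control), splits each member's equal weight over
its gene copies, and optionally under-amplifies two members (efficiencies
0.01 and 0.05) to mimic primer-binding-site mismatches.

`simulate_run()` then draws, per replicate sample, reads that are (i)
template copies with per-base substitution/insertion/deletion errors, (ii)
two-parent chimeras joined at a uniform interior breakpoint, or (iii) a
low-frequency noise tail: reads drawn from a pool of random contaminant
templates, emulating unclassifiable spurious sequences such as between-run
carry-over. Every read's provenance, breakpoint and injected error counts
are recorded in a truth table. Defaults describe run-scale conditions
(12 replicates × 8000 assembled 490 bp amplicons; substitution 5×10⁻³,
indels 5×10⁻⁴ per base, 1% chimeras, 5% noise reads) — the replicate count
matches the original design and the error magnitudes are plausible for
assembled long-fragment MiSeq contigs, chosen once as free parameters
since no quantitative error model is published for that run.

What the simulator does **not** model: quality scores, paired-end overlap
assembly (reads are born as assembled amplicons, since the method under
test operates downstream of assembly), run-to-run flow-cell contamination
dynamics, and PCR-cycle-resolved chimera formation. Passing tests
therefore demonstrate correctness of the *analysis*, not fidelity of any
particular instrument model.

## The filtering contribution

`dereplicate()` collapses reads to a unique-sequence × sample count table.
"Cluster" at this stage means an exact-identity unique-sequence group (the
objects of the size spectrum), not a 97% OTU. `rarefy()` subsamples each
sample to a fixed depth (default 6654 reads, the depth the workflow was
validated at) without replacement, a single draw per seed.
`remove_rare(table, t)` retains sequences whose *pooled* (cross-sample)
count is at least `t`: `t = 2` removes cross-sample singletons, `t = 3`
also removes doubletons, `t = 1` is the identity. The default stage order
is rarefy-then-filter, matching the order in which the original workflow
states the steps; both `validate()` and the CLI expose a switch to filter
first, since the source description is ambiguous on this point.

## Alignment conventions

All identity computations use one compiled global Needleman-Wunsch with
match +1, mismatch −1, gap −2 per base. Two conventions matter:

* **Terminal gaps are scored like internal gaps.** A fully ends-free
  ("overlap") scoring is degenerate for unrelated sequences of similar
  length: the optimal path is a chance handful of identical bases scored
  as a perfect micro-overlap, which reports ~100% identity between
  unrelated sequences and would collapse the distance matrix. Penalizing
  end gaps forces spanning alignments.
* **Terminal gap runs are excluded from the reported counts.** Identity is
  `matches / (matches + mismatches + internal gap bases)` over the
  terminal-trimmed region, so a query identical to a prefix of its
  reference still scores 100%. Traceback ties are resolved so that
  equally-scoring gap placements consolidate into terminal runs.

`error_rate()` is abundance-weighted: each mismatched, inserted or deleted
base of each unique sequence counts once per read carrying it, divided by
the total aligned bases. Sequences flagged by the reference-based bimera
test are excluded by default (a flag includes them). The bimera test
splits a query at five evenly spaced candidate breakpoints and flags it
when the best left- and right-segment parents differ and the two-parent
identity beats the best single parent by ≥2 percentage points — a
deliberately simple test that is valid here precisely because the true
parents are known; it is not a general-purpose chimera detector. A chimera
of two identical parents is undetectable by construction.

## Clustering and diversity

`pairwise_distances()` builds `d = 1 − identity/100`;
`cluster_otus()` applies average-linkage (average neighbor) agglomeration,
merging while the mean inter-cluster distance stays within the cutoff
(0.03 for 97% OTUs). `alpha_diversity()` reports, per sample:

* observed OTUs $S_{obs}$;
* bias-corrected Chao richness $S_{obs} + n_1(n_1-1)/(2(n_2+1))$, defined
  even when no doubleton OTUs exist;
* Shannon index with natural logarithm;
* the unbiased finite-sample inverse Simpson index
  $1 / \sum n_i(n_i-1)/(N(N-1))$ — a single-read sample returns `NA`
  rather than a number, and a sample of all-singleton OTUs returns
  `Inf` (its unbiased coincidence probability is zero).

Summaries are means ± standard error across the replicate samples.
`estimated_total_otus()` stands in for parametric total-richness
estimators with the same bias-corrected Chao point estimate plus an
approximate normal interval from the classic Chao variance; it is labeled
as such and mixture-model estimators are out of scope.

## Spectrum diagnostics

`cluster_size_spectrum()` tallies how many unique-sequence clusters
contain exactly *n* reads; `loglog_spectrum()`, `fit_linear()` and
`lowess_fit()` reproduce the log-log size/frequency analysis whose
low-frequency deviation motivates the filtering. Numerical choices: the
regression is unweighted over distinct-size points (each size one point);
lowess uses the classic span 2/3 with 3 robustifying iterations, computed
exactly (`delta = 0`) because the spectra are small; when the non-robust
smooth already interpolates the points (collinear input) the robustifying
iterations are skipped — they would otherwise divide by a zero median
residual. `filtering_improves_fit()` compares r² across the three
filtering branches and marks spectra with fewer than three distinct sizes
as not evaluable. At small simulated depths the filtered spectra have few
distinct sizes and their r² is noisy; the monotone-improvement signature
is a property of deep spectra.

## Taxonomy

Because the community is defined, classification reduces to
nearest-reference assignment: an OTU's representative (most abundant
member sequence, ties to the lexicographically smallest) takes the genus
of its best-identity reference if that identity reaches 80%, else
`unclassified`. Reads assigned to the archaeal control are counted and, by
default, excluded from bacterial genus summaries. The 80% default is
permissive enough that every genuine read clears it after several percent
of errors, while random contaminant sequences (~50-60% identity) fall
well below it.

## The three-way validation

`validate()` runs dereplication → rarefaction → {all / no singletons / no
singletons+doubletons}, and for each branch: error analysis, OTU
clustering, the diversity panel, taxonomy, and the spectrum fit. Alignment
to references, the chimera scan and the distance matrix are computed once
on the unfiltered table and subset per branch. The result is one
table-shaped summary (one row per branch) plus per-branch genus summaries,
all writable to re-loadable TSVs.

## Problem sizes and what the tests show

The packaged tests and the acceptance script exercise the pipeline at
12 samples × 100 reads × 200 bp templates with a 15% noise tail drawn
from a 500-template contaminant pool — sizes chosen so the all-sequences
branch distance matrix (the deliberately retained worst case) stays small
while every qualitative signature survives: pooled richness inflates
roughly ninefold over the 21-template truth before filtering and returns
to it after; the error rate drops by an order of magnitude when
cross-sample singletons are removed and again when doubletons follow; the
unclassified fraction shrinks the same way; and the error estimator
recovers an injected 1.4% substitution rate within binomial sampling
error. Estimator correctness is pinned separately by closed-form cases
and by brute-force oracles (exhaustive dynamic-programming alignment
scores; greedy average-linkage partitions) on small instances.

## Known limitations

* Identity is alignment-based on full-length sequences; no k-mer
  screening, so distance matrices are O(n²) alignments — filter first for
  large runs (that is the point of the method).
* The chimera flagger assumes the true parents are among the references.
* The noise tail is a structural stand-in for contamination; it does not
  model any specific contamination mechanism.
* Rarefaction is a single subsample per seed, not an average over draws.
* The Chao-type stand-in for total richness shares Chao's sensitivity to
  the singleton count; that sensitivity is exactly what the unfiltered
  branch is meant to display.
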