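# ampmock

Mock-community validation of V1–V3 16S rRNA amplicon pipelines.

Profiling bacterial communities by sequencing the V1–V3 region of the 16S
rRNA gene (~490 bp) buys taxonomic resolution at the price of a higher
error load on short-read instruments: after quality control, runs still
contain a long tail of unique sequences seen only once or twice across
*all* samples (cross-sample singletons and doubletons). These
low-frequency sequences are mostly artifacts, they inflate richness and
diversity estimates dramatically, and — because OTU calling needs an
all-pairs distance matrix — they dominate compute cost. `ampmock` is for
microbiome researchers and pipeline developers who want to *measure* that
effect against ground truth: it designs balanced mock communities,
simulates ground-truthed multi-sample amplicon runs, and quantifies how
removing the low-frequency tail changes the error rate, OTU richness,
alpha diversity and taxonomic assignment.

## What it computes

* **Mock design.** Copies per microgram of dsDNA,
  `9.2646e14 / genome_size` (650 g·mol⁻¹·bp⁻¹, N_A = 6.022e23), and the
  balancing mass `target_copies / (n_16S × copies_per_µg)` so each of the
  20 packaged members (19 bacteria + 1 archaeal control) contributes 5% of
  the community's 16S copies.
* **Filtering.** Exact dereplication into a unique-sequence × sample count
  table, rarefaction to a fixed depth (default 6654 reads/sample), and
  cross-sample abundance filtering: pooled count ≥ 2 removes singletons,
  ≥ 3 also removes doubletons.
* **Error analysis.** Abundance-weighted per-base error rate
  `Σ count·(mismatches + indel bases) / Σ count·alignment length` from
  global alignment of each unique sequence to its best-matching known
  reference (compiled Needleman–Wunsch, match +1 / mismatch −1 / gap −2,
  terminal gap runs excluded from the counts), with a reference-based
  bimera flagger.
* **OTUs and diversity.** Average-linkage clustering at distance 0.03
  (97% OTUs); observed richness, bias-corrected Chao
  `S_obs + n1(n1−1)/(2(n2+1))`, Shannon (natural log), and the unbiased
  inverse Simpson `1 / Σ nᵢ(nᵢ−1)/(N(N−1))`, as mean ± SEM over replicate
  samples.
* **Diagnostics and taxonomy.** Log-log cluster-size spectra with OLS and
  lowess fits, and nearest-reference genus assignment with an
  unclassified bin.

A deliberate detail of the community: one member's two 16S gene copies are
only 94% identical, so the 19 bacterial genomes produce **20** bacterial
OTUs at the 97% threshold.

## Worked example

Simulate 12 replicates of the mock community (100 reads/sample, 200 bp
templates, 0.3% substitutions, 0.5% chimeras, 15% contaminant noise
reads) and run the three-way comparison:

```r
library(ampmock)
refs <- mock_reference_set(length = 200, seed = 1)
cfg <- sim_config(n_samples = 12, depth = 100, sub_rate = 0.003,
                  ins_rate = 2e-4, del_rate = 2e-4, chimera_prob = 0.005,
                  noise_rate = 0.15, n_noise_templates = 500, seed = 2)
run <- simulate_run(refs, cfg)
report <- validate(run, config = pipeline_config(rarefy_depth = 100, seed = 3))
report
```

```
Mock-community validation (12 samples, rarefied to 100 reads/sample)

                   branch observed_otus  chao shannon invsimpson error_rate_pct
                      all         34.25 72.77   3.236      25.92          7.914
            no_singletons         17.17 18.82   2.708      19.30          1.159
 no_singletons_doubletons         16.17 17.06   2.658      18.36          0.000
```

Reading the rows: with everything retained, the contaminant tail inflates
the per-sample OTU mean to 34 and the Chao estimate to 73 against a true
community of 21 templates, and drives a 7.9% apparent error rate.
Removing cross-sample singletons collapses richness back toward truth and
drops the error rate to 1.2%; removing doubletons as well removes the
remaining contaminants entirely at this depth. The pooled (all-samples)
richness in `report$summary$total_otus` shows the same collapse —
roughly ninefold inflation before filtering. Per-branch genus summaries
(`report$genus_summary`) give the replicate-averaged relative abundances
with their SEMs, including the `unclassified` bin.

The design arithmetic, for a 2×10⁹-copy stock:

```r
rec <- design_equal_mock(as_mock_members(mock_community_members()), 2e9)
rec$table[1:3, c("name", "copies_per_ug", "mass_ug")]
```

```
                                            name copies_per_ug mass_ug
1                     Campylobacter jejuni 11168      5.64e+08  0.0591
2 Salmonella enterica serovar Typhimurium SL1344      1.90e+08  0.0878
3                        Escherichia coli mg1655      1.99e+08  0.0718
```

i.e. 0.0718 µg of *E. coli* DNA carries the 10⁸ 16S copies that are its
equal share (7 copies/genome × 1.99×10⁸ genomes/µg).

A thin command-line front end over the same functions ships in
`inst/cli/ampmock` (subcommands `design`, `simulate`, `filter`, `error`,
`cluster`, `diversity`, `diagnose`, `validate`).

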