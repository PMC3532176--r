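---
title: "Cross-species screening for conserved stage-dependent expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species screening for conserved stage-dependent expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

During the final phase of oogenesis an oocyte acquires *developmental
competence* — the capacity to be fertilized and develop into a normal
embryo. The somatic cells that surround it (granulosa/theca layers in
fish and amphibians, cumulus cells in mammals) are believed to drive
much of this process. If the same regulatory programme operates in the
somatic compartment across vertebrates, then orthologous genes should
change expression in the *same direction* across the same transitions
of competence acquisition in distant species.

`orthoscreen` implements that comparative screen for a three-stage
design sampled in up to four species:

* **NC1** — developmentally incompetent or poorly competent prophase-I
  oocytes,
* **C1** — competent prophase-I oocytes,
* **C2** — competent metaphase-II oocytes,

with expression measured in the surrounding somatic cells by
single-channel microarrays. The screen's unit of evidence is the
**concordant ortholog group**: an ortholog group in which every species
of a chosen subset contributes at least one member gene with the same
direction of significant change between the same pair of stages.

## The analysis chain

For each species separately:

1. **Presence filtering.** A probe is kept when its spot is present in
   at least 80% of the replicates of *every* stage group
   (`apply_presence_filter()`, `min_frac = 0.8`). The presence mask is
   an input; the package does not model scanner-level flagging.
2. **Median scale normalization.** Each array is multiplied by
   `reference / its median present intensity`, with the reference taken
   as the median of the per-array medians (`median_scale_normalize()`).
   Using the median-of-medians rather than an arbitrary array preserves
   the intensity scale and makes the result independent of sample
   order. Post-condition: all arrays share one median, to floating
   tolerance.
3. **Differential expression.** A classical one-factor ANOVA across the
   three stages is run per probe on log2 present intensities, with
   Benjamini–Hochberg correction over the tested probes and
   significance at adjusted p < 0.01 (`call_de()`). All statistics are
   computed on the log2 scale; fold changes are reported on the linear
   scale. ANOVA on raw intensities was rejected because microarray
   noise is multiplicative (approximately log-normal), making the
   log2 scale the variance-stabilized one.
4. **Direction calls.** For each significant probe and each ordered
   stage pair (NC1,C1), (C1,C2), (NC1,C2), a Welch two-sample t test at
   p < 0.05 assigns which pairs changed and in which direction
   (`pairwise_directions()`). Welch rather than pooled t because the
   stage groups are unbalanced (6/14/8 by default). The global ANOVA
   gates eligibility; the per-pair test only adjudicates *which* pairs
   — setting `pair_alpha = 1` degrades to reading directions off the
   stage means, for users who prefer the ANOVA alone.
5. **Gene-level calls.** Probes are mapped to gene accessions either
   directly from platform annotation (`map_probes_direct()`) or, for a
   species without a reference genome, through a two-step homology
   chain probe → contig → proxy protein with a strict e-value < 1e-3
   at both steps (`map_probes_by_homology()`), collapsing to unique
   accessions. Conflicting probe signs on one gene are resolved by
   majority; exact ties drop the call and are logged
   (`probe_to_gene_directions()`).

Across species:

6. **Ortholog groups.** From an all-vs-all protein similarity table the
   package computes reciprocal best hits per species pair
   (`rbh_pairs()`; best = lowest e-value, ties by bit score then
   lexicographic id, so output is order-invariant), within-species
   in-paralog pairs (`find_inparalogs()`: pairs mutually more similar
   than either gene's best cross-species hit, anchored to at least one
   gene with an ortholog), builds a weighted graph with
   `-log10(e-value)` weights (e-value 0 capped at 300) normalized by
   the mean weight of each edge class — ortholog edges per species
   pair, in-paralog edges per species (`build_graph()`) — and
   partitions it by Markov clustering (`mcl()`). Externally computed
   groups in the `groups.txt` dialect can be supplied instead
   (`load_groups()`). Following usual practice, ortholog inference in
   the pipeline is restricted to the differentially expressed genes.
7. **Concordance screen.** `screen_concordance()` reports every group
   with a (stage pair, sign) witness carried by at least one member
   gene of every species in the subset. `subset_sweep()` repeats the
   screen for every subset of two or more species; because a witness
   for a superset is a witness for each of its subsets, the counts are
   non-increasing in subset size and the all-species group set is
   nested inside every smaller subset's — the structural signature the
   sweep is designed to expose.
8. **Profile clustering.** Per-gene mean log2 intensities per stage are
   standardized to zero mean and unit variance across the three stages
   (population normalization: the three stage means *are* the profile,
   not a sample) and clustered by average-linkage hierarchical
   clustering under 1 − centred Pearson distance, cut into k = 3
   clusters by default: the two major classes (up at C2, down at C2)
   plus the minor transient class peaking at C1.
9. **Enrichment.** Gene lists (typically the concordant genes of one
   species) are scored against a GMT annotation with the one-sided
   Fisher exact test, BH-corrected across terms, significant at
   q < 0.05, with the full mapped platform as the background. The
   EASE-style conservative variant (testing k−1) is available behind
   `ease = TRUE`, off by default. BH is applied within one annotation
   source at a time; users testing KEGG and GO should call `enrich()`
   separately per source.

`ortho_screen()` chains all of this and returns a single object with
`print`, `summary` and `plot` methods. The package exposes the pipeline
as a fitting-style function returning a classed S3 object; `coef`,
`predict` or `residuals` methods would be meaningless here (nothing is
a fitted parametric model), so only the methods the object admits are
provided.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_presence` | 0.8 | fraction of present replicates required per stage |
| `alpha` | 0.01 | BH-adjusted ANOVA significance level |
| `pair_alpha` | 0.05 | per-stage-pair Welch significance level |
| `evalue_max` | 1e-3 | strict e-value threshold (homology mapping and RBH) |
| `inflation` | 1.5 | MCL granularity (OrthoMCL's default) |
| `require_same_pair` | TRUE | concordance witness must share the stage pair |
| `k_clusters` | 3 | profile clusters to cut |

Two readings of "similar differential expression" are possible: the
strict one (same stage pair, same sign in every species — the default,
because it is the biologically interpretable statement that the same
transition is conserved) and a loose one (same sign on any pair,
`require_same_pair = FALSE`). Both are implemented; neither is asserted
to be the uniquely correct reading, and for species whose stage
profiles are progressive rather than switch-like the loose reading may
be the fairer one.

## The synthetic benchmark

`sim_config()` / `simulate_experiment()` generate a multi-species study
with known ground truth: per species, intensities
`2^(baseline + stage_offset * effect_size + N(0, noise_sd))` with
per-probe baselines `N(8, 2)` on the log2 scale, an i.i.d. per-spot
dropout mask, and a head block of probes organised into planted
ortholog groups sharing one of three effect profiles (up at C2, down at
C2, peak at C1). Defaults mirror the trout design: replicates 6/14/8
per stage, two-fold effects (`effect_size = 1` in log2 units), log2
noise s.d. 0.35. Each species consumes its own RNG stream derived from
the master seed, so appending a species never perturbs the data of the
existing ones.

`simulate_similarity()` emits self-hits (e-value 0) for the whole gene
universe, one alignment strength per within-group pair reported in both
directions with a small jitter (real reciprocal BLAST e-values are
nearly symmetric; fully independent directional draws would differ by
tens of orders of magnitude and destroy reciprocal-best-hit structure
no real data would destroy), in-paralog pairs stronger than any
cross-species hit (they are post-speciation duplicates — and under the
in-paralog definition used here they would otherwise be undetectable in
principle), and optional spurious cross-group hits that stay at or
above e-value 1e-2, removable by any sensible threshold.
`simulate_annotation()` plants a configurable fraction of terms
enriched in the planted genes.

Dropout defaults to 0.02. This is the one place where realism had to be
balanced explicitly: under the 80% presence rule with 6/14/8
replicates, a dropout rate d removes a fraction
`1 − P(pass NC1)·P(pass C1)·P(pass C2)` of probes per species (≈ 11% at
d = 0.05, ≈ 2% at d = 0.02), and a four-species screen's attainable
recall scales with the fourth power of the per-species survival. A few
percent of flagged spots is typical of a good single-colour
hybridization; 2% keeps the benchmark's recall ceiling near 1 so that
the benchmark measures the screen, not the mask.

What the generator does **not** emulate: spatial array artifacts,
probe-level cross-hybridization, correlated (batch) noise, multiple
probes per gene, non-orthologous sequence similarity (domain sharing),
and progressive rather than switch-like stage profiles. Passing the
benchmark therefore shows the chain is correct and calibrated under
idealised conditions, not that real cross-platform studies will reach
the same precision and recall.

## Numerical choices and degenerate inputs

* ANOVA with zero within-group variance returns F = 0, p = 1 for equal
  means and F = ∞, p = 0 otherwise; the Welch gate treats two constant
  equal groups as p = 1.
* Profiles whose three stage means are equal standardize to (0, 0, 0)
  and are assigned correlation 0 (distance 1) to everything; an
  all-flat profile set degenerates to a single `flat` cluster.
* Cluster labels are assigned by nearest ideal shape under centred
  correlation rather than by per-stage argmax/argmin rules: for the
  symmetric ideal shapes two stage means coincide in expectation (NC1
  and C1 for the falling class; NC1 and C2 for the transient class), so
  an argmax rule would label such clusters by the sign of pure noise.
* MCL adds identity self-loops, prunes entries below 1e-5, iterates to
  a 1e-6 maximum-change tolerance (cap 100 iterations, warning on
  non-convergence), resolves overlapping attractor claims by larger
  column mass with lexicographic ties, and runs per connected component
  — a partition is always returned. The co-ortholog edge class of later
  OrthoMCL versions is deliberately omitted (RBH + in-paralog edges
  only), which is logged here as a simplification.
* In-paralog "mutual e-value" is the worse of the two directed
  e-values when both are present (conservative; OrthoMCL averages).
* Best-hit selection everywhere tie-breaks by e-value, then bit score,
  then lexicographic subject id, making every stage deterministic and
  row-order invariant.
* All e-value thresholds are strict (`<`), matching the e-value < 1e-3
  convention of the homology mapping, and the same threshold is applied
  to both steps of the two-step probe mapping (the first step's
  threshold is otherwise unspecified).

## Benchmark scale and what the tests assert

The packaged studies (`benchmark_null()`, `benchmark_planted()`) use
5000 probes × 4 species for the null study and 2000 probes × 4 species
with 50 planted groups for the recovery study — large enough for the
binomial error on a 1% FDR bound to be meaningful and small enough to
run in seconds, which is the scale a routine check should have. On
them the test suite asserts: realized null DE fraction ≤ 0.01 + 3
binomial SE per species, at most one spurious all-species concordant
group, enrichment false-positive rate ≤ 0.05 in expectation; screen
precision and recall ≥ 0.9 (pooled over three seeded replicates —
recall's expectation under these conditions is ≈ 0.92, dominated by
single-member species whose one gene misses the DE cut, so a pooled
estimate is the stable one), adjusted Rand ≥ 0.95 for the inferred
ortholog partition, ≥ 90% planted-profile label recovery, and planted
terms significant at q < 0.05. Exact-arithmetic oracles (hand sums of
squares, the definitional BH scan, hypergeometric tail enumeration, a
dense MCL fixed-point iteration, brute-force witness enumeration) pin
the core statistics to ≤ 1e-10 – 1e-12.

## Known limitations

* Orthology inference quality is bounded by the similarity input; no
  alignment, synteny or tree reconciliation is performed.
* The screen counts witnesses; it does not score concordance
  continuously, so a group with many discordant members and one
  concordant witness per species still qualifies (the member counts in
  the output make this visible).
* Published group counts from any particular study depend on platform
  annotation versions and OrthoMCL/DAVID versions and are treated as
  qualitative anchors (the nesting structure), not reproduction
  targets.
* With `pair_alpha` at its default, genes with significant ANOVA but no
  significant pair (diffuse changes) yield no direction call.
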