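---
title: "Scoring miRNA microarray results: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring miRNA microarray results: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnascore)
```

## The problem

miRNA microarrays report relative fluorescence intensities. Normalization
(RMA and relatives) makes a given miRNA comparable *across samples*, but not
different miRNAs comparable *within a sample*: probe affinity varies
enormously between sequences, so many probes report high intensities for
miRNAs that sequencing shows are simply not present. Sequencing of the same
tissues finds that a few dozen miRNAs carry well over 90% of the expression
mass, while arrays hand high values to hundreds. Any downstream use of an
array profile as a ranking of miRNAs therefore starts with a large
false-positive burden.

`mirnascore` post-processes an already-normalized expression table by
attaching to each mature miRNA a *reliability score* in $[0, 1]$: the closer
to 1, the more plausible it is that the miRNA is genuinely expressed in the
profiled samples.

## The model

Three per-miRNA quantities are computed:

* $m$ — the median expression across all samples, on the scale of the input
  table (log2-like RMA intensities, or RPM for sequencing tables);
* $N$ — the integer suffix of the miRBase MIMAT accession. Accessions are
  chronological: low numbers were assigned to early-discovered, heavily
  validated miRNAs, while very large numbers are enriched for annotations
  that later proved spurious. Empirically, the miRNAs that sequencing
  confirms as expressed concentrate at MIMAT numbers below about 5000;
* $c$ — the Spearman correlation between the mature miRNA's expression
  profile and its precursor's (pre-miRNA) profile across the same samples.
  Mature and precursor abundances are mechanistically coupled through
  biogenesis, so co-variation is evidence that the probe tracks a real
  transcript rather than cross-hybridization.

Each is scaled to $[0, 1]$:

$$A = \frac{m}{m_{\max}}, \qquad B = 1 - \frac{N}{N_{\max}}, \qquad
  C = \frac{c + 1}{2},$$

with the maxima taken over the analyzed miRNA set, and combined as

$$\mathrm{score} = w_A A + w_B B + w_C C, \qquad
  (w_A, w_B, w_C) = (0.5,\ 0.3,\ 0.2)\ \text{by default}.$$

The score is a convex combination of numbers in $[0, 1]$ and therefore lies
in $[0, 1]$; it is non-decreasing in $m$ and $c$ and non-increasing in $N$.
Medians and rank correlations (rather than means and Pearson correlations)
keep the score robust to outlying samples. The default weights are the ones
that maximize the specificity ratio (below) on paired array/sequencing
breast-tumor data; `optimize_weights()` re-derives weights for any dataset
with a sequencing reference by exhaustive search over the simplex lattice.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `w_a`, `w_b`, `w_c` | 0.5 / 0.3 / 0.2 | component weights, renormalized to sum to 1 |
| `min_samples` | 5 | fewest samples for which a Spearman correlation is attempted; below it $c$ is absent |
| `absent_corr` | `"neutral"` | absent $c$ maps to $C = 0.5$; `"drop_weight"` instead zeroes $w_C$ and renormalizes, the recommended fallback when sample counts are too low for rank correlations |
| `n_max` | annotation-set maximum | scope of $N_{\max}$; override it (e.g. with the whole-miRBase maximum) for cross-study comparability |
| `score_threshold` | 0.75 | strict cutoff defining "reliable" miRNAs in validation |
| `rpm_threshold` | 10 | strict median-RPM cutoff defining "expressed" in sequencing |
| `top_quantile` | 0.90 | array-median quantile defining "highly expressed" in false-positive calling |
| `expressed_cutoff` | 0 | RPM at or below which a miRNA counts as not expressed |
| `max_mismatches` | 2 | substitution budget for genomic occurrence counting |

Decisions the model itself leaves open, fixed here once:

* **$m$ scale.** Medians are taken on the input scale as given; negative
  values are rejected (opt-in `min_shift` shifts by the minimum), because
  $A = m/m_{\max}$ is only meaningful for non-negative $m$.
* **Multiple precursors.** A mature miRNA excised from several genomic loci
  uses the *maximum* correlation over its precursors: co-variation with any
  one locus is already biogenesis evidence.
* **Absent correlations.** Neutrality ($C = 0.5$) is the default so that
  miRNAs without a precursor probe are neither promoted nor penalized.
* **$m_{\max}$ scope.** Taken over the scored set (the intersection of
  expression features and annotation) and logged; the model's "maxima across
  all miRNAs" is read as the analyzed set.
* **Ordering.** Output rows sort by descending score with ties broken by
  ascending MIMAT number — deterministic, and consistent with the prior that
  early accessions are more credible.
* **Thresholds are strict** (score $> 0.75$, RPM $> 10$), matching their
  verbal definitions.

## Validation procedures

`concordance()` quantifies specificity: of the miRNAs with score above the
threshold, how many does sequencing confirm (RPM above threshold)? The
*baseline* selects the same number of miRNAs by raw median expression; the
ratio of baseline-discordant to score-discordant counts is the specificity
gain, and the objective of `optimize_weights()`. When scoring produces no
discordant selections the ratio is reported as undefined (treated as $+\infty$
in optimization, with ties broken toward more confirmed selections, then
lexicographically by descending weights).

`rank_separation()` quantifies sensitivity: a two-sided Mann–Whitney U test
comparing scores of sequencing-confirmed miRNAs against the rest, reported
with group means and sample (n−1) standard deviations. The U statistic uses
average ranks (tied cross-pairs count half); p-values are exact by
enumeration when both groups have at most 8 observations — a convention that
remains well-defined under ties, where the classical exact distribution does
not apply — and otherwise use the normal approximation with tie correction
and continuity correction, matching `stats::wilcox.test`.

`cumulative_coverage()` reproduces the coverage curve: with entries sorted by
decreasing RPM, element $k$ is the percentage of total expression mass in the
top $k$ miRNAs.

## False-positive sequence features

`identify_false_positives()` operationalizes "high on the array, absent in
sequencing": array median at or above the empirical `top_quantile` cutoff
(type-7 quantile, boundary-inclusive) *and* reference RPM at or below
`expressed_cutoff` (exact zero by default; miRNAs missing from the reference
count as zero, since sequencing quantifiers report everything they detect).

Two sequence features are then compared between the called group and the
remainder with a one-sided Mann–Whitney test (`compare_feature()`):

* **GC-content** (`gc_content()`): G+C fraction over non-N bases. GC pairs
  form three hydrogen bonds versus two for AT, so GC-rich probes hybridize
  more stably — including to imperfectly matching off-target sequences.
* **Genomic occurrences** (`count_genomic_occurrences()`): the number of
  alignment positions, on both strands, whose Hamming distance to the probe
  sequence is at most `max_mismatches` (substitutions only, no gaps — the
  search a `-v`-mode short-read aligner performs). Overlapping sites each
  count; `N` counts as a mismatch against anything, including another `N`;
  coordinates are 0-based half-open on the forward strand where reported.
  Frequent near-matches in the genome mean many potential cross-hybridizing
  transcripts.

## The synthetic generator

`generate_synthetic_dataset()` builds paired array/sequencing data with
planted ground truth so every procedure is testable without downloads:

* 50 true + 150 false miRNAs over 30 samples by default;
* array baselines uniform on the log2-like range 6–13 for *both* groups, so
  raw median expression cannot separate them — separation must come from the
  MIMAT and correlation factors, which is exactly what the score claims;
* true miRNAs get MIMAT numbers in $[1, 5000]$, false ones in
  $[5001, 35000]$ (disjoint by construction, mirroring the concentration of
  confirmed miRNAs at low accession numbers);
* true miRNAs share a latent factor with their precursor profile. The target
  Spearman level (0.8) is converted to the Pearson correlation of the latent
  bivariate normal by numerically inverting Moran's finite-$n$ expectation
  $E[r_s] = \frac{6}{\pi(n+1)}\left(\arcsin\rho + (n-2)\arcsin\tfrac{\rho}{2}\right)$,
  so the *sample* Spearman is centered on the target at the configured
  sample size (the familiar $\rho = 2\sin(\pi\rho_s/6)$ is its asymptotic
  limit). At $n = 30$ about 96% of realized correlations fall within
  $\pm 0.15$ of the target;
* sequencing RPM is log-normal (median ≈ 200) for true miRNAs and exactly 0
  for false ones;
* mature sequences are 22 nt, sampled base-by-base with GC probability 0.45
  (true) or 0.60 (false); the genome plants each true sequence once and each
  false sequence three times with 0–2 random substitutions per copy, between
  random spacers of genome-like GC (0.41).

What the generator does *not* emulate: probe-level hybridization physics,
read-level sequencing error, correlated expression between miRNAs, and —
importantly — the composition of real arrays, where false positives are a
small minority (a few hundred among thousands). At the generator's 3:1
false:true ratio the *remainder* group of a top-decile false-positive call is
itself mostly planted-false and GC-rich, so the GC comparison through the
calling path is much weaker than on real data; the detection property is
therefore tested on the planted groups, and passing it demonstrates the
statistics, not array-scale realism.

## Numerical conventions

* Even-length medians average the two central order statistics.
* Spearman correlations use average ranks for ties (`stats::cor`).
* $B$ clips at 0 when an $N$ exceeds a user-supplied $N_{\max}$ override.
* The weight constructor renormalizes to sum 1; degenerate all-zero weights
  are rejected.
* The occurrence scanner is an exact vectorized sliding-window count, checked
  in the test suite against a substitution-neighbor enumeration oracle and
  against `Biostrings::countPattern` on N-free inputs.
* All randomness in the generator flows from one integer seed through R's
  default RNG; identical seeds give bit-identical datasets, and the CLI
  pipeline is byte-identical across repeated runs.

## Problem sizes used in the test suite

The packaged checks run the scoring oracle comparison on 1000 random tables
of at most 10 miRNAs × 10 samples, the occurrence oracle on 200 random
pattern/genome pairs (patterns ≤ 30 nt, genomes ≤ 200 nt), the GC-direction
property on 100 generator seeds at the default 200-miRNA size, and the
planted-truth separation on the default 50 + 150 × 30 fixture. These sizes
make the whole suite run in well under a minute while leaving each property
statistically meaningful.

## Known limitations

* The score ranks reliability within one dataset; $A$ and $B$ depend on the
  analyzed set through $m_{\max}$ and $N_{\max}$, so scores are not directly
  comparable across datasets unless both maxima are fixed by override.
* With very few samples the correlation factor is unavailable; the
  drop-weight fallback loses the sensitivity that factor provides.
* MIMAT chronology is a prior, not evidence: a genuinely expressed,
  recently discovered miRNA is penalized by $B$. The weights bound that
  penalty at $w_B$.
* The occurrence counter is designed for desk-scale genomes (it streams per
  record, but a full mammalian genome scan in pure R is slow; practitioners
  map probes with a dedicated aligner and feed the counts in as a feature).
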