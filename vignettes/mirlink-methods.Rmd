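---
title: "Methods: inverse-correlation screening and seed-match prediction in mirlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inverse-correlation screening and seed-match prediction in mirlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlink)
```

## The model

`mirlink` looks for miRNA–mRNA pairs where the miRNA plausibly degrades
the transcript. Two independent lines of evidence are required:

* **Expression**: across samples of one histological group, the gene's
  expression is a decreasing monotone function of the miRNA's expression.
  Monotonicity (not linearity) is the modelling assumption, so the screen
  uses Spearman rank correlation. This only captures cleavage-type
  regulation — translational repression leaves mRNA levels unchanged and
  is invisible to this design.
* **Sequence**: the transcript carries a canonical binding site whose seed
  (miRNA positions 2–8 from the 5′ end) is Watson–Crick complementary to
  the mRNA, supported by favourable duplex pairing beyond the seed.

A pair becomes a final call only when both predictors agree, the
correlation beats a group-size-dependent strict threshold, and a
seed-weighted ranking of all transcripts confirms the gene as a
high-ranking target of that miRNA. Requiring several weak, independent
filters rather than one strong one is deliberate: strong negative
correlations also arise from co-regulation, and seed matches arise by
chance (a specific 8mer occurs once per ~65 kb of random sequence), but
their conjunction is rare under either null.

## Preprocessing

Order: detection filter → quantile normalization → `log2(x + 1)` →
per-batch mean centering.

* *Detection*: a feature must be detected (value strictly positive) in at
  least `ceiling(n/2)` samples. "Detected = positive" is a convention;
  RPM and normalized-count matrices encode non-detection as 0.
* *Quantile normalization* equalizes sample distributions
  (`limma::normalizeQuantiles`, ties receive the mean of their destination
  quantiles). Note it maps each value through its within-sample rank, so
  with very small feature panels (tens of features) it coarsens the
  across-sample rank structure; the package's benchmarks therefore use
  realistic panel sizes (hundreds of features or more).
* *Pseudocount*: `log2(x + 1)` keeps undetected values at 0. The offset is
  configurable; 1 is the natural choice for RPM/count-scale data.
* *Batch centering* subtracts, per feature, each batch's mean. It is exact
  for additive per-batch per-feature offsets, idempotent, and makes no
  distributional assumptions — deliberately simpler than model-based
  batch correction, and verifiable (`pca_qc()` silhouettes of batch labels
  drop to noise level after centering).
* An alternative order (log before normalization) is exposed via
  `preprocess_pipeline(order = "log_then_normalize")` for cohorts
  processed that way; the two orders give slightly different values, so
  the choice is surfaced as configuration rather than guessed.

## Differential expression

Fold changes between groups use **group medians** on the linear scale
(`2^x − 1`, clipped at 0): a single outlier sample cannot move the
statistic. The ratio thresholds 1.25 / 0.8 are on the linear scale, which
is why the back-transformation matters; medians of log values would change
the thresholds' meaning. A small pseudocount (1e-9) guards zero medians.
Testing uses Welch's *t* (no equal-variance assumption; a pooled option
exists), BH-adjusted across the features that survive a variance filter
(features below the first quartile of per-feature variance are dropped;
with all variances equal, everything is kept, since the strict rule would
otherwise empty the matrix). The FDR family defaults to the filtered
feature count, with an `m_total` override for the stricter convention of
adjusting against a platform-wide feature count. Top-marker panels
(`select_top_markers()`, default k = 8) take the lowest-FDR significant
features, ties broken by |log2 MBFC|.

## The all-pairs screen

Within one group of n samples, every (miRNA, gene) pair is correlated:
ranks are computed once per feature, standardized, and correlations
obtained as chunked matrix products — `O(chunk_size × n)` additional
memory, bit-identical (to 1e-9) to the pairwise statistic, including
average-rank tie handling. p-values use the *t* approximation; at millions
of pairs, exact or permutation p-values are infeasible, and the
approximation is accurate at the sample sizes where the screen is
meaningful (n ≥ ~30). BH adjustment runs over the full pair grid of the
group (constant features yield NA records and are excluded from the
family). The screen keeps ρ < −0.6 (strict inequality), and the
confirmation stage tightens this to −0.65 / −0.70 / −0.80 for groups of
roughly 300 / 100 / 35 samples — smaller groups need stronger observed
correlations for the same evidence.

## Sequence predictors

The published target-prediction tools are large, versioned programs; re-
implementing them bit-for-bit is out of scope. `mirlink` instead provides
simplified scorers that capture each tool's decision logic, plus
`load_external_predictions()` to import real tool output for fidelity
runs.

* `find_seed_sites()` classifies canonical sites by exact complementarity
  to the seed: 6mer (positions 2–7), 7mer-m8 (2–8), 7mer-A1 (6mer + A
  opposite position 1), 8mer (7mer-m8 + A). Each match location is
  reported once under its most specific class. T/U are interchangeable on
  input. All three transcript regions (5′UTR, CDS, 3′UTR) are scanned and
  the region is recorded per site.
* `miranda_like_score()` is an affine-gap local duplex alignment
  (Watson–Crick +5, G:U wobble +1, mismatch −3, gap open −8, extend −2,
  seed-position contributions doubled). A window around each candidate
  site — the site plus miRNA-length + 5 nt upstream (where the miRNA 3′
  region pairs) and 5 nt downstream — must reach 140 (≈ a near-full-length
  complementary duplex) for the miRanda-style verdict.
* `targetrank_like()` scores each gene as the weighted sum of its 3′UTR
  sites (8mer 1.0, 7mer-m8 0.75, 7mer-A1 0.5, 6mer 0.25), ranks genes per
  miRNA (ties by gene ID), and confirms rank ≤ 100 with score ≥ 0.25.
  These weights and cutoffs are configuration, not claims of equivalence
  to the original tool's trained scores.

## The synthetic cohort generator

`simulate_expression()` emulates the features of a paired cohort that the
pipeline's statistics actually touch:

* **Groups and batches**: samples carry a histotype group (defaults scaled
  from a 321/99/35 classical/follicular/tall-cell split, i.e. 100/31/11)
  and one of 16 batches, assigned at random; batch effects are additive
  per-batch per-feature normal offsets (sd 1 on the log2 scale, comparable
  to the biological signal — batch structure should be visible in PCA
  before removal, as it is in real cohorts).
* **Implanted regulations**: on the log2 scale,
  `gene = μ − s·(ρ·z_miRNA + √(1−ρ²)·ε)` with `ρ = 2 sin(π·strength/6)`,
  the classical relation making the *population Spearman* correlation
  equal −strength for bivariate normal variables. Only rank structure
  matters downstream, so the linear link on the log scale is sufficient.
  Default strength 0.85 with 20 implanted pairs on distinct genes.
* **Detection**: values below the matrix-wide `dropout_rate` quantile
  (default 0.3) of the linear values are recorded as 0. Detection in
  sequencing data is abundance-driven — zeros are sub-detection events,
  not random erasures — and modelling them otherwise would corrupt the
  rank structure of well-expressed features in a way real data does not.
  A `rare_fraction` (default 0.3) of unplanted features is simulated at
  sub-detection baselines (log2 μ in 0–3 vs 3–12) and is expected to fail
  the prevalence filter, giving that filter real work. Implanted features
  are drawn from the well-expressed range (μ in 6–12): a screen can only
  discover signals among detected features, so the benchmark implants
  them there.
* **Differential features**: a fraction of unplanted features (default
  0.1) receives a ±2 log2 shift between the first two groups.
* **Sequences**: `simulate_sequences()` writes random-composition mature
  miRNAs (21–23 nt) and per-gene regions (5′UTR 200, CDS 900, 3′UTR
  1000 nt). Each regulated gene's 3′UTR receives the reverse complement
  of its miRNA's positions 2–end followed by an A — a canonical 8mer with
  full 3′ pairing, recoverable by both predictors. Regulated miRNAs get a
  5′-terminal U, the dominant base at that position in real mature
  miRNAs. Chance sites occur at the background k-mer rate and downstream
  code must tolerate them.

What the generator does **not** emulate: negative-binomial count noise
(irrelevant to a rank-based screen), isoform families sharing seeds,
correlated co-expression modules, or group-specific regulation (implanted
couplings act in all samples; the ground truth labels them with the
largest group, where the screen is evaluated). Passing the benchmarks
therefore shows the pipeline's statistics and plumbing are correct — not
that real cohorts will yield comparable sensitivity, since real effect
sizes and confounders are outside the generator's vocabulary.

## Numerical and design choices

* Spearman p-values: `ρ = ±1` returns p = 0; constant features return NA
  and are logged, never silently dropped inside the statistic.
* Quantile method for the variance filter's quartile: linear interpolation
  (R type 7), configurable in principle via the quantile call; documented
  because quartile conventions differ across tools.
* Isoform IDs are canonical `chrom:start-end:strand` strings, 1-based
  inclusive like GFF3. Mapping to mature names takes the mature locus with
  the largest overlap on the same chromosome and strand; ties break to the
  lexicographically smallest name, so output is deterministic. Isoforms
  spanning two mature loci are a genuinely ambiguous case; max-overlap is
  the documented convention.
* Funnel naming `{group}_{k}` numbers the both-predictor candidates by ρ
  ascending, ties by miRNA then gene ID. The ranking stage is evaluated
  lazily, only for candidates that already pass the strict threshold with
  both predictors.
* All simulation randomness flows from a single seed in the configuration;
  reruns are bit-identical.

## Benchmarks and their problem sizes

The package's own acceptance checks (test suite and
`scripts/acceptance.R`) use: a 200 miRNA × 1000 gene, 100-sample,
16-batch panel with 20 implanted regulations at strength 0.85 for
end-to-end recovery (10 seeds; sensitivity ≥ 0.9, false-discovery
proportion ≤ 0.1 at the default thresholds); 500 genes with 50 planted
log2-shift-2 features at n = 40/40 for differential recovery; 50 × 50
random matrices for the chunked-vs-naive screen equivalence; 10^4 random
p-values for the BH oracle; and 200 random miRNA/UTR draws for the
seed-site oracle. These sizes make each property cheap to verify while
keeping the statistics in their intended regime (e.g. quantile
normalization needs realistic feature counts, see above).

## Known limitations

* Marginal correlations only — no partial correlations or mediation;
  co-regulation can still pass the expression filter and is only pruned
  by the sequence stages.
* The simplified predictors have no thermodynamic (free-energy) term, no
  conservation or context features, and no non-canonical (bulged or
  centered) sites; use `load_external_predictions()` when fidelity to the
  published tools matters.
* Batch centering assumes additive offsets; multiplicative or
  variance-distorting batch effects need model-based correction upstream.
* The tall-cell-like group size (~35 samples) makes its screen thresholds
  very strict by design; candidate lists from small groups should be read
  cautiously.
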