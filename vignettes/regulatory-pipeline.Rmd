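---
title: "Methods: open-chromatin motif scanning and reporter-assay statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: open-chromatin motif scanning and reporter-assay statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacreg)
```

This vignette documents the statistical models and procedures implemented in
`atacreg`, the assumptions behind them, the defaults and why they were
chosen, and what the synthetic-data generators do and do not establish about
real data.

## Consensus open chromatin

Replicate ATAC-seq peak calls are combined under a literal reading of
"recovered in both replicates": any ≥ 1 bp overlap between a replicate-1 and
a replicate-2 peak contributes its **intersection**; when one peak overlaps
several partners, every intersection is computed and overlapping results are
merged, so the final set is pairwise disjoint. The length filter
(`min_length`, default 100 bp) applies to the merged consensus interval,
because it is the retained region — not the raw calls — that downstream
scanning consumes. The repeat filter defaults to `max_repeat_fraction = 0`:
any overlap with repeat annotation removes the peak, matching the strictest
reading of repeat exclusion; the fraction is configurable for softer
policies. Alternative consensus definitions (union of the pair,
reciprocal-overlap requirements) are deliberately not implemented as
defaults — the intersection rule is deterministic, order-independent
(`consensus_peaks(a, b) == consensus_peaks(b, a)`), and testable against a
brute-force interval oracle.

Peak-to-gene annotation assigns one category per peak by the position of its
**midpoint**, with priority promoter > exon > intron > intergenic. A
promoter is `promoter_up` (default 1000 bp) upstream to `promoter_down`
(default 100 bp) downstream of a TSS in transcription orientation — a
conventional window for compact invertebrate genomes; category-by-midpoint
was chosen over any-overlap because single-label assignment is what a
category split (promoter/exon/intron/intergenic fractions) requires.
Whether published category splits of this kind count by midpoint, by any
overlap, or by an annotation tool's internal priority is generally not
decidable from methods text; the midpoint convention is this package's own
and is stated wherever fractions are reported. All coordinates are BED-style
0-based half-open internally; GFF3 input is converted on read.

## Motif models and scanning

A PWM is a length-L matrix of per-position base probabilities. On
construction a pseudocount (default 10⁻³) is added and each position
renormalized: this keeps log-odds finite for unobserved bases while
perturbing scores by less than ~0.006 bits per position. Regularization is
intentionally not idempotent (every read adds the pseudocount), so
round-trip file fidelity is exact only at pseudocount 0 — the I/O writes 10
significant digits to support that.

Window scoring is standard log-odds in bits against background base
frequencies; `N` bases contribute 0 bits (a neutral treatment that can
neither create nor destroy a pass). Reverse-strand scores are computed by
scoring the forward sequence with the reverse-complemented matrix against
complement-swapped background frequencies, which is algebraically identical
to scoring the reverse-complemented window. When the two strands tie at an
offset — numerically, within 10⁻⁹ bits, which happens at palindromic
windows — the forward strand is reported, keeping output deterministic.

**Threshold calibration.** The scan threshold at false-positive rate `fpr`
(default 0.01, the conventional setting for genome-scale motif scans) is the
empirical (1 − fpr) quantile of the per-sequence maximum score over both
strands and all offsets of the background set, using the inclusive lower
empirical quantile: ascending sort, index ⌈(1 − fpr)·n⌉. This convention is
conservative and exactly reproducible; with a continuous score distribution
the held-out per-sequence FPR is then ≈ fpr. Two caveats matter in
practice. First, the Monte-Carlo error of a held-out FPR estimate combines
the held-out binomial noise **and** the order-statistic noise of the
threshold itself (the threshold's exceedance probability is approximately
Beta-distributed with variance ≈ fpr(1 − fpr)/n_train); calibration checks
in the test suite use `3·sqrt(fpr(1-fpr)(1/n_train + 1/n_heldout))`.
Second, calibration assumes a near-continuous score distribution; motifs
whose columns take only a few distinct probability values produce heavily
tied maxima and an inflated held-out rate, which is why the motif simulator
draws Dirichlet-distributed columns.

**Clustering.** Motif similarity is the maximum Pearson correlation of the
flattened overlapping probability columns over all relative offsets and both
orientations, requiring ≥ 6 overlapping columns (`MIN_OVERLAP`); clustering
is greedy agglomeration — a motif joins the best-matching cluster whose
running average it matches at similarity ≥ 0.8, else seeds a new cluster —
and a cluster's consensus is the position-wise mean of its aligned members,
renormalized without re-adding the pseudocount (so the average of identical
motifs is exactly that motif). The similarity metric and the 0.8 default are
standard motif-clustering practice rather than a published prescription, and
both are configurable. No attempt is made to reproduce any specific
clustering tool's internals. Matches are reported at full PWM length;
whether flanking low-information columns should be trimmed is left to the
caller, since trimming conventions vary between tools.

## Enrichment testing

Over-representation of a motif in a peak class versus background is tested
at the **sequence level** — a region either contains ≥ 1 passing site or it
does not — with the one-sided Fisher exact (hypergeometric upper-tail)
probability under the pooled-proportion null. Sequence-level counting was
chosen over site-level counting because it is insensitive to region-length
differences between classes. Bonferroni correction multiplies by the number
of motif × class tests performed in one profile call. Being an exact test,
Fisher controls the type-I rate from below: at moderate counts the null
rejection rate at α sits at ~0.03–0.04 rather than 0.05, approaching α as
counts grow. The calibration tests assert exactly that behaviour (control
plus approximate attainment at large counts) rather than a symmetric band
the test cannot meet.

## Expression rules

**2^−ΔΔCt.** Per replicate, ΔCt = Ct(target) − Ct(reference); per tissue,
ΔΔCt is the difference of mean ΔCt from the calibrator tissue's mean, and
RQ = 2^−ΔΔCt. The 95% interval is a t-interval (df = n − 1) on the tissue's
mean ΔCt transformed through 2^−x with ends swapped — computed on the Ct
scale, where the noise is approximately Gaussian, and transformed so the
bounds stay positive. The calibrator's own uncertainty is not propagated
(it anchors the scale); amplification efficiency is assumed to be exactly 2
per cycle. Tissue panels are conventionally renormalized so the
highest-expressing tissue sits at 1.0 (`normalize_to_max_tissue`), which
preserves all between-tissue ratios.

**Organ-enriched genes.** A gene qualifies when *both* focal digestive
samples show higher mean expression than *every* other organ with one-sided
p < α (default 0.05, raw — the conjunction across ~2 × (k − 1) comparisons
is itself a strong multiplicity control; an optional BH adjustment is
provided). The internal test is a one-sided Welch t on log2(x + 1)
abundances — a pragmatic default chosen because the bespoke content here is
the conjunction rule, not the differential-expression engine; externally
computed DE tables (e.g. from a count-model package) can be supplied via
`de_table` and are pushed through the identical rule. "Compared to other
organs" is read as each organ pairwise (default); a pooled-others mode is
provided because the alternative reading is defensible.

**Reciprocal best hits.** Best hit = maximum bitscore with E ≤ 10⁻⁵, ties
broken by lower E-value then lexicographic subject id (determinism); a pair
is reported only when the best-hit relation holds in both directions, which
makes the output an injective partial matching by construction.

## Reporter-assay statistics

Relative activity is firefly/Renilla per well divided by the mean ratio of
the blank-effector control group, making the control mean exactly 1.00.
Technical replicates are averaged into their biological replicate before
any test, treating the biological replicate as the experimental unit.
Dose-response comparisons use the two-sided pooled-variance Student t
(matching the classical presentation of such assays; Welch is available by
editing one argument) with Holm step-down correction across adjacent-dose
pairs; a pair with zero variance in both groups is flagged degenerate
rather than tested.

**The pooled-sum synergy test.** The null object is the pool of all
n_A × n_B pairwise sums of the two single-effector groups' activities; its
central percentile interval (linear-interpolation quantiles, default 95%)
describes the activity sum expected under additivity, and significance
comes from resampling `m = |combined group|` values from the pool with
replacement (default n_boot = 100,000) and counting bootstrap means at or
above the observed combined mean, with the add-one correction
`p = (1 + #{≥}) / (n_boot + 1)` so p is never 0. The test is one-sided
(upper tail) because the scientific claim is directional — combined
activity *higher* than the sum. Resampling is with replacement, the
standard bootstrap choice.

Two effect scales need distinguishing. On the relative-activity scale,
*biological* additivity of two effectors over the baseline of 1 gives a
combined expectation (μ_A − 1) + (μ_B − 1) + 1, which is **less** than the
pooled-sum null's centre μ_A + μ_B. The pooled-sum test therefore tests the
stronger claim — exceeding the plain sum including the double-counted
baseline — and is conservative with respect to biological additivity. The
luciferase generator exposes both: `mode = "additive"` implements the
biological-additivity expectation (under which a calibrated synergy test
essentially never rejects), and `mode = "sum"` draws each combined well as
an independent A-draw plus B-draw (noise sd √2 larger), the exact null of
the test, used for calibration checks.

The test's finite-sample calibration depends on the design. The pool's
location carries the sampling error of the observed group means; when the
effector groups are as small as the combined group that error is comparable
to the observed-mean variability and the test over-rejects (measured ~0.17
at n = 3 everywhere). With effector groups much larger than the combined
group the test is calibrated (measured 0.052 at n_A = n_B = 200, m = 3,
α = 0.05). The calibration test therefore runs in the large-effector-group
regime; at a typical bench design of three biological replicates per group
the bootstrap p should be read as approximate, a limitation inherent to the
test rather than to this implementation.

## ChIP-qPCR fold enrichment

The signal-over-background form is implemented: per replicate,
signal = E^−(Ct_IP − Ct_input′) for the specific antibody and the mock IgG,
where Ct_input′ corrects the input Ct for its dilution factor and the
amplification efficiency E defaults to 2 (no efficiency correction, the
common assumption when none is published; E is a parameter). Fold
enrichment is the specific/mock signal ratio — input corrections cancel
when inputs are shared, and FE is invariant to any global Ct shift.
Significance is the one-sided one-sample t of the replicate FEs against 1.
Because FE is log-normal under Gaussian Ct noise, its mean exceeds 1
slightly under the null (≈ +1% at Ct noise 0.15); at realistic noise this
bias is negligible against the t test's tolerance, and the measured null
rejection rate is ≈ 0.046 at α = 0.05.

## What the synthetic data do and do not show

The generators are pure functions of configuration and seed, and every
dataset ships a truth table. They emulate: replicate peak structure with
boundary jitter and dropout; motif sites sampled from the PWM's own
distribution (rejection-sampled above the calibrated threshold, so recall
targets are well defined); i.i.d. genomic background at observed base
frequencies; log-normal expression baselines with Gaussian log-scale
replicate noise; Gaussian well/Ct noise on the measurement scales. Default
scales mirror a small invertebrate regulatory study: two replicates, ~100
peaks of ~300 bp at desk scale, FPR 0.01, three biological × two technical
luciferase replicates, four ChIP replicates, a digestive-gland +
hepatopancreas focal pair against three other organs, fold enrichments near
2, noise sd ≈ 0.1–0.15 on the relevant scales.

They do **not** emulate: Tn5 insertion or fragment-length structure, peak
callers' signal models, positional dependence within motifs, dinucleotide
or repeat-like background structure, count-based expression noise
(negative binomial), plate or batch effects, or antibody efficiency
differences. Passing calibration and recovery tests therefore demonstrates
the correctness and internal calibration of the statistics under their
stated assumptions — not that real chromatin or real plates satisfy those
assumptions.

## Numerical conventions, degenerate inputs, and problem sizes

- Quantiles: threshold calibration uses the inclusive lower empirical
  quantile (sort ascending, index ⌈(1 − fpr)·n⌉); pooled-sum intervals use
  linear-interpolation (type-7) quantiles.
- Ties: scan strand ties (within 10⁻⁹ bits) go forward; RBH bitscore ties
  break by E-value then subject id; cluster membership goes to the
  best-matching cluster above threshold, first-come on exact ties.
- Degenerate inputs: regions shorter than the motif yield zero hits (not an
  error); all-N regions score 0 everywhere and pass nothing at a positive
  threshold; single-replicate tissues return an RQ with NA interval; a
  dose pair with zero variance in both groups is flagged, not tested;
  empty similarity tables give an empty RBH set.
- Errors are raised, naming the offending record, for: invalid intervals,
  malformed motif rows, zero-probability motif columns, missing reference
  or mock/input wells, non-positive Renilla or Ct values, dangling region
  ids, and thresholds applied to the wrong motif.

Test-suite problem sizes were chosen to give three-sigma Monte-Carlo
resolution at desk scale: FPR calibration at 5,000 training / 10,000
held-out sequences of 300 nt; pooled-sum coverage with 200-per-group pools
against 10,000 fresh sums; 500 synergy datasets, 2,000 Fisher null tables
and 1,500 ChIP null datasets for the type-I checks; 1,000 simulations for
the 2.2-fold ChIP recovery; exhaustive Fisher-versus-enumeration
equivalence over every 2×2 table with total ≤ 40.

## Known limitations

- The enrichment profile calibrates one threshold per motif per call;
  motif-specific backgrounds (e.g. GC-matched per class) are not provided.
- Promoter/enhancer classes are taken as given region sets; the package
  does not infer enhancer status.
- The synergy bootstrap's approximate calibration at small effector groups
  (above) is inherited from the method itself.
- The internal Welch-on-log2 DE test is a placeholder engine for the
  conjunction rule, not a replacement for count-model DE inference on real
  RNA-seq.
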