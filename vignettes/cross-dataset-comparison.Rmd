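---
title: "Comparing differential-expression results across datasets with omicomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing differential-expression results across datasets with omicomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

`omicomp` operates downstream of differential-expression testing. Its unit
of input is a *contrast*: a named two-group comparison summarised per
feature by a p-value $p$, a Benjamini–Hochberg adjusted p-value $q$, a
log2 fold change $\beta$ (difference of group means on the log2 scale) and
an average level. The package itself fits no models to real data — the one
internal test (`two_group_stats()`, a vectorised Welch $t$) exists so the
synthetic generators can exercise the whole pipeline; on real data the
statistics come from limma, DESeq2 or similar, carried as columns of the
feature table (`P.Value_<contrast>`, `FDR_<contrast>`, `log2FC_<contrast>`,
`AveExpr_<contrast>`).

Two datasets are mapped onto each other through a shared ID column. When an
ID occurs multiple times within a dataset (transcripts collapsing to one
gene), the first listed entry in file order is kept and the rest are
dropped and counted; ties cannot occur under this rule. Shared IDs keep the
first dataset's order, which makes every downstream table deterministic.
ID matching is case-sensitive by default — gene symbols differing only in
case are occasionally distinct entities — with an `ignore_case` switch.

### Significance and classification

A feature is significant under thresholds $(\alpha, \beta_{\min})$ when its
chosen statistic ($q$ by default, $p$ optionally) satisfies
$q < \alpha$ **and** $|\beta| > \beta_{\min}$, with *strict* inequalities:
published cutoffs are conventionally written "FDR < 0.05", so boundary
values fail. A missing statistic or missing fold change is never
significant — absence of evidence is not demoted to a zero.

Across two contrasts each shared feature receives exactly one category:

| category      | definition |
|---------------|------------|
| `both_same`   | significant in both, $\mathrm{sign}(\beta_1) = \mathrm{sign}(\beta_2) \ne 0$ |
| `both_contra` | significant in both, opposite nonzero signs |
| `a_only` / `b_only` | significant in exactly one |
| `neither`     | everything else |

A fold change of exactly zero cannot carry a direction; a feature
significant with $\beta = 0$ (only possible if the caller supplies
externally computed flags) is classified `neither` with a warning. The
categories partition the shared features by construction, and the test
suite checks that partition against an exhaustive truth table.

The tool never flips fold-change signs. Both contrasts must be oriented
with the same group ordering (the same group in the numerator); nothing in
the data allows this to be verified automatically, so it is documented as
an input contract.

### The direction-concordance profile

For features shared by two comparisons, the fraction whose fold changes
agree in sign, stratified by p-value, is a compact reliability read-out:
true shared signal drives the fraction towards 1 among small p-values,
while independent noise leaves it near 0.5 everywhere. Each feature with
both p-values present is assigned to the bin containing
$\max(p_1, p_2)$ — a feature only counts as "low p" if it is low in *both*
comparisons, which is the conservative reading; per-comparison binning
(each feature contributing once at $p_1$ and once at $p_2$) is kept as an
option. Bins are left-closed with the last bin right-closed; the default
edges $(0, 0.001, 0.01, 0.05, 0.1, 0.5, 1)$ resolve the conventional
significance region without producing many near-empty bins. Zero or
missing fold changes count in a bin's $n$ but never as agreement, so
degenerate features dilute rather than inflate concordance.

One caveat the worked example in the README shows concretely: when the two
layers share correlated noise (paired samples), null features also agree
in direction more than half the time. The profile therefore measures
*consistency*, not effect truth, and is read alongside the classification.

### Set analytics

Venn and UpSet analytics are built on a boolean feature × set membership
matrix. Three constructors exist: significance membership (one set per
contrast), direction-split membership (two sets per contrast, `_up` and
`_down`, so that an intersection pairing one contrast's up-set with
another's down-set is exactly the contra pattern), and presence membership
(a feature is present in a set when it has at least `min_obs = 1`
non-missing values among the set's samples, i.e. "not missing in all").
Exclusive intersections assign every feature in at least one set to its
full membership pattern; counts are ordered by decreasing size, ties by
degree then lexicographic key, so output is reproducible. Features in no
set stay in the universe and are reported as a "none" tally rather than
dropped — a feature entirely absent from one dataset is *absent*, which is
itself information in presence/absence analysis.

### Cross-layer correlation

Per shared feature, Pearson and Spearman correlations are computed across
explicitly paired samples, with pairwise-complete deletion per feature
(listwise deletion across features would discard most of a sparse
proteomics matrix). Spearman uses midranks for ties, computed as Pearson
on average-ranked values. A correlation is reported only when at least
`min_pairs = 3` complete pairs remain — two points always correlate
perfectly — and when both sides have nonzero variance; otherwise the value
is missing with a machine-readable reason rather than forced to 0.

## Quality computations

PCA treats samples as observations. Features with any missing value among
the selected samples are removed (no imputation), remaining features are
centred and by default scaled to unit variance; zero-variance features
cannot be scaled and are dropped with a warning. PCA signs are arbitrary,
so each loading vector is oriented to make its largest-magnitude element
positive — this pins down reproducible output without changing the
subspace. Sample dendrograms use average linkage (UPGMA), under which
merge heights are non-decreasing; the inter-sample metric is euclidean by
default (the linkage is prescribed, the metric is this package's choice)
with $1 - r_{\mathrm{Pearson}}$ available. Distribution summaries use
type-7 (linear interpolation) quantiles, the most common convention, and a
shared Gaussian-kernel density grid with Silverman's rule-of-thumb
bandwidth over 512 points spanning the pooled range ± 3 bandwidths, so all
samples are drawn on one comparable axis.

## The synthetic world

Two generators make every module testable without downloads; both take a
mandatory seed and are bit-reproducible.

`simulate_spikein()` emulates a two-condition, two-organism benchmark in
which spiked proteins are mixed at 30% versus 3% w/w, so the true shift is
$\log_2(30/3) \approx 3.3$, reversed between conditions, with three
replicates per condition. Those three values are the stated benchmark
design. The remaining defaults are this package's choices: per-feature
baselines $\mathcal{N}(20, 2^2)$ on the log2 scale (typical label-free
protein intensities), replicate noise $\sigma = 0.5$ log2 units (a
realistic label-free replicate CV), and a 1800/100/100 split of
null/up/down features (10% true changes, the order of magnitude of a
strong spike-in). Missingness is masked completely at random at
`missing_rate`. What the generator does **not** emulate: moderated
variance structure, intensity-dependent missingness, or heavy-tailed
noise. A green test against this world therefore establishes correctness
of the analytics, not performance on real mass-spec data.

`simulate_multiomics()` draws, per feature, a bivariate normal across
samples with cross-layer correlation $\rho$, and adds a two-group effect
either with the same sign in both layers ("same") or opposite signs
("contra"), which gives ground truth for the classification and
correlation modules.

## Numerical and edge-case choices

- **BH adjustment** is the step-up rule
  $q_{(i)} = \min_{j \ge i} p_{(j)} m / j$ clipped at 1, returned in input
  order; missing p-values are excluded from $m$ and stay missing. The test
  suite checks it against a literal double-loop oracle and against an
  independent library implementation.
- **Welch test degeneracies**: a feature needs two observations per group
  for a p-value; if both groups have zero variance the p-value is 1 when
  the means are equal (no evidence) and missing when they differ (the
  statistic is undefined) — the fold change is reported either way.
  Missing statistics propagate as missing, never as 0 or 1.
- **Volcano display**: $p = 0$ cannot be drawn on a $-\log_{10}$ axis; such
  points are clipped to 1.05 × the largest finite value and flagged, with
  the underlying statistics untouched. Excluded (missing) points are
  tallied so that excluded + plotted always equals the feature total.
- **Settings snapshots** are written as UTF-8 JSON with full-precision
  numbers; save → load → save is byte-identical. JSON has a single number
  type, so integers return as doubles.
- **TSV export** writes numbers at 15 significant digits with a fixed
  format, making replay runs byte-comparable; the dataset writer uses 17
  digits so a read/write cycle reproduces doubles exactly.

## Known limitations

- The internal Welch test is intentionally plain. At very small group
  sizes (3 + 3) it is conservative — its Satterthwaite reference with
  ≈ 4 degrees of freedom rejects true nulls at less than the nominal 5% —
  and, without variance moderation, its power after BH correction over
  thousands of features is far below what moderated pipelines reach on the
  same design. The acceptance suite measures both effects directly on the
  spike-in world and deliberately reports them rather than hiding them:
  two of its calibration/power assertions fail by design for the plain
  Welch test at 3 + 3 replicates. Real analyses should bring moderated
  statistics from upstream tools; the package consumes them unchanged.
- Contrast orientation across datasets is an unverifiable input contract
  (see above).
- No batch correction, imputation, or enrichment analysis: those belong
  upstream or downstream of this package.
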