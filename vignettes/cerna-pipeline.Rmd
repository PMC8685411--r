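---
title: "Inferring ceRNA networks from multi-class RNA expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ceRNA networks from multi-class RNA expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Competing endogenous RNAs (ceRNAs) are transcripts — long noncoding RNAs
(lncRNAs) and circular RNAs (circRNAs) — that share miRNA binding sites
with protein-coding mRNAs. By sequestering ("sponging") a shared miRNA,
such a transcript can derepress the miRNA's mRNA targets. The observable
signature of this mechanism in expression data is a *positive* correlation
between a sponge and its protected mRNA, together with shared targeting by
the same miRNA (and, where miRNA levels are informative, anti-correlation
of the miRNA with both).

`cernet` implements the inference chain used to screen for such triplets in
a two-group design (disease group "A" vs. healthy controls "H") profiled
for four RNA classes: mRNA, lncRNA, circRNA and miRNA. The motivating
setting is bulk RNA sequencing of monocyte-derived dendritic cells from
autoimmune-hepatitis patients versus healthy donors, with small per-group
sample counts (three vs. three) and paired patient–control comparisons, but
nothing in the pipeline is specific to that system.

## Pipeline stages and their models

### Differential expression (`call_de`)

Each feature is tested with a **paired t-test** on log2-transformed
expression, `log2(x + c)` with pseudocount `c = 0.01`: for paired samples
the per-pair differences `d_i` are compared to zero with `n − 1` degrees of
freedom. Pairing is taken from the `pair` column of the sample metadata;
for genuinely unpaired cohorts the metadata can simply omit `pair` and
supply equal-sized groups matched by order (the simulator pairs sample *i*
of A with sample *i* of H). Two-sided p values are BH-adjusted across the
features of one matrix.

A feature is *called* DE when `|log2FC| >= 1` **and** `p < 0.05`, where the
fold change is computed from the raw group means,
`log2((mean_A + c)/(mean_H + c))` — the inputs are already-normalized
expression, so no re-normalization is applied. The `|log2FC| >= 1` bound is
identical to "fold change >= 2 or <= 0.5". The q value is always reported;
setting `use_fdr_for_call = TRUE` in `threshold_config()` gates on q
instead of p for a stricter, FDR-controlled call set. The default gates on
the raw p value because that matches the stated thresholds of the screening
design the package reproduces; the FDR gate is the conservative
alternative.

Testing on the log2 scale is a deliberate choice: expression noise is
multiplicative (approximately log-normal), so log-scale differences are
closer to normal, the paired t-test is then exactly calibrated under the
simulator's model, and the test statistic aligns with the fold-change
threshold. Features whose paired differences have zero variance carry no
information for a t-test; they are flagged `degenerate`, reported with
missing p, excluded from the BH adjustment, and never called.

### Coexpression screening (`coexpression_pairs`)

For every called DE lncRNA/circRNA × DE mRNA pair, the Pearson correlation
is computed across **all** samples of both groups (n = 6 at the default
design) on the log2 scale, and its two-sided p value from the exact
t-transform:

$$t = |r|\sqrt{\frac{n-2}{1-r^2}}, \qquad p = 2\,P(T_{n-2} \ge t).$$

The exact t CDF (not a normal approximation) is required to reproduce
published correlation-test p values to several significant figures; with
n = 6 the test has 4 degrees of freedom, and published top-pair tables at
that depth are reproduced to at least five significant figures — the
residual discrepancy is fully explained by the printed correlations being
rounded to nine decimals, since near `|r| = 1` the relative sensitivity of
p to r is `4|δr|/(1 − r²)`.

Pairs are kept at `|r| >= 0.8` and `p < 0.05`. The screen retains *both*
signs of correlation and records them — strongly negative pairs are
biologically meaningful (e.g. direct repression) — but only positive pairs
are eligible to become ceRNA triplets, since the sponge mechanism predicts
positive sponge–mRNA coupling. Note that at n = 6 the magnitude threshold
is effectively `|r| > 0.811`, because `p(0.8, 6) ≈ 0.056 > 0.05`: the p
criterion is the binding one just above 0.8.

### Expression filters and triplet assembly (`expression_filter`, `find_triplets`)

Before network membership, features must pass two screening rules: the
mean expression of at least one group must exceed 0.5 (normalized units),
and the feature must be detected — expression strictly greater than 0 by
default, the detection floor being configurable — in at least 2/3 of all
samples. Both bounds are monotone: tightening them never adds features.

A triplet (sponge, miRNA, mRNA) is emitted iff the sponge and the mRNA are
both called DE and pass the filters, the pair survives the coexpression
screen with `r > 0`, and the supplied miRNA–target interaction table
contains both the miRNA→sponge and the miRNA→mRNA edge. Which
target-prediction resource produces that table is the user's choice; the
package deliberately takes it as data. miRNA DE status is *not* required —
network nodes for miRNAs outside the DE set are labelled `unknown`, which
matches how such networks are usually drawn — but `strict_mirna = TRUE`
additionally demands a DE miRNA whose direction opposes the sponge's.
Output ordering is lexicographic in (miRNA, sponge, mRNA) throughout, so
identical inputs yield byte-identical outputs.

`build_network()` takes the union of all triplet edges into a tripartite
igraph object (miRNA–sponge, miRNA–mRNA, sponge–mRNA coexpression edges;
nodes attributed with class and direction), exportable as SIF, GraphML and
a lossless node/edge TSV pair.

### Over-representation analysis (`ora`)

DE mRNA sets are tested against user-supplied GMT gene sets with the
hypergeometric upper tail `P(X >= k)` for `X ~ Hypergeom(N, K, n)`, BH
adjustment across terms, and p-then-term-id ranking (deterministic "top
30"). The universe is the intersection of the genes in the expression
matrix with the genes in the annotation — the standard ORA choice, since
genes outside either set could never have been observed in the overlap.
Term categories (BP/CC/MF/pathway) ride along in the GMT description
field.

### qPCR quantification (`relative_expression`, `group_compare`)

Relative expression per sample is `2^−ΔCt` with
`ΔCt = Ct(target) − Ct(reference)`; technical replicates are averaged on
the Ct scale first (Ct is the log-domain quantity, so averaging there is
the natural choice; the transform is applied once per sample).
`log2` of the reported value equals `−ΔCt` exactly. Groups are compared
with a two-tailed Student's t-test on the `2^−ΔCt` values (equal variances,
per the classical protocol; Welch available via `var_equal = FALSE`).
Comparing on the `2^−ΔCt` scale rather than the ΔCt scale follows the
convention of reporting expression levels as `2^−ΔCt`; both scales are a
monotone transform apart and agree on direction.

## The synthetic-data generator

`simulate_expression()` emulates the statistical structure of the study
design, not its biology:

* **Design**: `n_per_group = 3` per group, paired across groups. This
  sample count is what makes the coexpression test have 4 degrees of
  freedom, consistent with published p/r pairs at this depth; it is
  configurable.
* **Expression model**: per feature, log2 values are
  `baseline + effect·1[group A] + noise`, with
  `baseline ~ N(3, 1.5²)`, `noise ~ N(0, 0.25²)` per sample, and
  `effect = ±3` for the planted DE fraction (10% per class by default).
  Matrices are exponentiated on output, so values are strictly positive
  log-normals. An absolute planted `|log2FC|` of 3 with noise SD 0.25
  represents the strong, validation-grade effects a small-n screen is
  powered for.
* **Planted triplets** (5 by default, alternating lncRNA/circRNA sponges):
  sponge and mRNA are drawn from the planted DE features and forced to a
  common direction; the miRNA stays non-DE. Members share a per-sample
  latent factor: the noise variance is *split* into a shared part
  (fraction `coupling_r`, default 0.9) and an independent residual, so the
  expected within-group correlation between coupled members is
  `coupling_r` while the total per-sample noise SD remains `noise_log2_sd`
  for every feature. (Adding a latent factor *on top of* the noise would
  silently inflate triplet members' variance about tenfold and change
  their DE power; the split keeps the stated noise level meaningful.) The
  sponge and mRNA load positively, the miRNA negatively, giving the
  sign pattern the ceRNA model predicts.
* **Target map**: all planted miRNA→sponge and miRNA→mRNA edges, plus
  decoy edges attached to null features with probability
  `decoy_edge_fraction` (default 0.05) — enough to exercise the shared-
  miRNA logic against false joins.
* **Annotation**: random gene sets of 10–30 mRNAs plus one planted term
  with ≥ 80% planted-DE members, a positive control that must rank first
  in ORA.
* **qPCR plate**: `Ct = 35 − log2(expression)` plus per-replicate noise,
  with a constant-abundance reference gene, so with zero noise the group
  ΔCt difference equals minus the planted log2FC exactly.

Everything is deterministic given `sim_config(seed = ...)`.

**What the generator does not emulate** — and hence what passing recovery
tests do *not* establish about real data: library-size and composition
biases (inputs are assumed normalized), count discreteness and
overdispersion at low expression, batch effects, correlated null features
(co-regulation outside planted triplets), missing/censored detection, and
any sequence-level realism (no reads, no back-splice junctions, no binding
sites). Recovery rates on synthetic data are a check of the inference
logic under its own model, not an estimate of sensitivity in a real
cohort.

## Numerical choices and edge cases

* Degenerate paired tests (zero-variance differences) are errors at the
  single-test level and missing values at the table level, excluded from
  BH (which then uses the number of *tested* hypotheses).
* `correlation_p` maps `|r| = 1` to p = 0 and `r = 0` to p = 1; the
  t-transform is guarded against `1 − r² = 0`.
* All pair/triplet/term orderings break ties lexicographically, so every
  output table is reproducible byte for byte.
* BH adjustment, t tails and hypergeometric tails are delegated to R's
  `p.adjust`, `pt` and `phyper`; the package's own contribution is the
  inference chain, not these primitives.
* The expression filter uses strict inequalities (`> 0.5`, `> 0`) so that
  boundary values are excluded, and `>= 2/3` on the detection fraction so
  that 4 of 6 samples pass.

## Problem sizes used in the tests

The shipped test-suite and analysis scripts run the generator at 60–2,500
features per class and 20 replicate seeds for the recovery study: planted
DE sensitivity and planted-triplet recovery are required to reach 0.8 and
the null false-positive rate to stay within sampling error of the nominal
5% over 2,500 null features. These sizes keep a full run in seconds while
leaving the binomial standard errors small enough for the calibration
checks to be meaningful.

## Known limitations

* The paired t-test at n = 3 pairs has 2 degrees of freedom; only large
  effects are detectable, and p values are sensitive to any non-normality
  of the paired differences. This mirrors the screening design the package
  implements rather than a recommendation.
* Coexpression over all samples pools the group shift into the
  correlation; a pair of features DE in the same direction is correlated
  even without within-group coupling. That is intrinsic to the screening
  rule, which is why triplet candidacy also demands DE status and shared
  targeting rather than correlation alone.
* ORA treats gene sets as flat and independent; no term-redundancy
  reduction is attempted.
* miRNA–target anti-correlation is not verified numerically by default
  (the target map is trusted); `strict_mirna` is the hook for designs
  where miRNA profiling is reliable.
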