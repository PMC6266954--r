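---
title: "Typing miRNA-target interactions from multi-omics expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing miRNA-target interactions from multi-omics expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mirtype)
```

## The problem

A validated miRNA-target pair says that, in some experimental system, the
miRNA can repress that gene. It does not say whether the interaction is
active in a particular tissue, nor by which mechanism: a bound transcript
can be *degraded* (miRNA up, mRNA down) or merely *translationally
inhibited* (mRNA unchanged, protein down). The second mechanism is
invisible to any analysis that only looks at miRNA and mRNA abundances —
it requires protein data.

`mirtype` takes a cohort of matched miRNA, gene, and (optionally) protein
expression profiles for one tissue and condition, plus a catalog of
validated pairs, and answers two questions per pair:

1. Is the pair's expression statistically associated in this cohort, and in
   which direction? (miRNA–gene and gene–protein, separately.)
2. If so, which mechanism does the sign pattern indicate?

## The association test

For one response profile $y$ (length $n$ over matched samples) and $m$
covariate profiles $x_1,\dots,x_m$, let $r = y - \bar y$ and standardize
each covariate column. The score-form global statistic is

$$Q \;=\; \frac{1}{m\,s^2}\sum_{j=1}^m (x_j^\top r)^2,
\qquad s^2 = \frac{r^\top r}{n}.$$

$Q$ is the average squared covariance between the residual response and the
covariates, scaled to be free of the measurement units. It decomposes
additively into per-covariate contributions, and the sign of $x_j^\top r$
gives the direction of each covariate's association — for a miRNA tested
against the group of its targets, the strongest *negative* contributions
are the candidate active interactions.

Because $Q$ is a monotone function of the squared Pearson correlation when
$m = 1$, the pairwise test is a two-sided correlation test; the group form
($m > 1$) is what distinguishes it from plain per-gene correlation.

### Null distributions

The distribution of the response given the covariates is never modelled
parametrically; significance comes from permuting the response across
samples:

* **exhaustive** (`p_value_exhaustive`): all $n!$ permutations, for
  $n \le 9$. This is the reference null used by the test-suite oracles.
* **permutation** (`p_value_permutation`, default, $B = 10{,}000$): seeded
  Monte-Carlo with the standard correction $p = (b+1)/(B+1)$, so $p$ is
  never 0 and is bit-reproducible given `(input, n_perm, seed)`. The
  identity permutation is counted with a $10^{-12}$ relative tolerance so
  that summation-order rounding in the vectorized null can never push the
  observed statistic out of its own tail.
* **gamma** (`p_value_gamma`, opt-in fast mode): under permutation the
  centered response has covariance $\frac{S_2}{n-1}(I - J/n)$ with
  $S_2 = r^\top r$, so $Q = r^\top A r$ with
  $A = X X^\top/(m s^2)$ behaves like $\sum_k \lambda_k \chi^2_{1}$, where
  $\lambda_k = \frac{S_2}{n-1} \times$ the eigenvalues of
  $X^\top X/(m s^2)$. A gamma distribution is matched to the mean
  $\sum_k\lambda_k$ — which equals the exact permutation mean of $Q$ — and
  variance $2\sum_k\lambda_k^2$. It agrees with the permutation p-value
  well inside a factor of two at moderate $n$ and holds its nominal size in
  null simulations, but the permutation method remains the default because
  it is assumption-light and auditable.

### Conventions, and why

* **Orientation**: the regulatory target is the response — gene ~ miRNA,
  protein ~ gene — following the causal arrow of repression. The group test
  (`group_target_test`) uses the opposite, miRNA-as-response orientation,
  which is the natural one when a single miRNA is screened against many
  targets; for $m = 1$ both give identical p-values.
* **Transform**: `log2(v + 1)` for miRNA/gene FPKM (heavy-tailed;
  correlation on the raw scale is dominated by outliers), nothing for
  protein intensities, which arrive normalized and possibly negative.
* **Standardization**: covariates are standardized and the response
  centered, making $Q$ invariant to positive affine transforms of either
  profile.
* **Missing data**: complete-case filtering *per pair*, to maximize the
  usable $n$ for each pair; `n_used` is recorded in every output row.
* **min_samples = 8**: below this, permutation p-values are too coarse
  (the smallest attainable two-sided p at $n = 7$ is already $1/5040$
  only for a perfect monotone pattern) and sign estimates unstable, so
  smaller pairs are flagged `untestable` rather than tested.

## The classification

With significance threshold `alpha` (default 0.05, no multiple-testing
correction by default; Benjamini–Hochberg per test family is available via
`mt_correction = "bh"`):

| miRNA–gene | gene–protein | call |
|------------|--------------|------|
| negative   | positive     | degradation |
| negative   | negative     | degradation |
| positive   | negative     | inhibition |
| positive   | positive     | no_interaction |
| negative   | absent       | degradation |
| positive   | absent       | no_interaction_star |

The (negative, negative) row is deliberate: transcript decay with a
discordant protein readout is still called degradation, because mRNA levels
are imperfect proxies for protein abundance and the miRNA–gene
anti-correlation is the primary signature. The starred call marks pairs
whose typing is limited by missing protein data. Two artifact states
complete the output so every catalog pair gets exactly one call:
`no_evidence` (a required test not significant — shown, not suppressed, so
that downstream filters decide) and `untestable` (degenerate input). A
cross-product of exactly zero is treated as non-significant rather than
given an arbitrary direction.

When `require_both_significant = FALSE`, a significant miRNA–gene test
whose gene–protein companion is not significant falls back to the
protein-absent branch instead of `no_evidence`; the default is the stricter
gate.

## The synthetic cohort generator

`simulate_cohort()` emulates the data layout of a tumor-atlas cohort:
log-normal FPKM marginals for miRNA and gene assays (log2-scale mean 3, sd
1.5 by default — right-skewed abundances with median around 8 FPKM),
an RPPA-style normalized protein assay covering a fraction of genes
(default 0.8; genes carrying a planted typed pair are always covered, and
`protein_coverage = 0` produces a protein-free cohort, as for normal
tissue), and planted linear dependencies on the log scale whose
coefficients are solved so the population correlation magnitude equals the
requested `strength`:

* degradation: gene $= -b\,\cdot$ miRNA $+$ noise, protein $= +c\,\cdot$ gene $+$ noise;
* inhibition: gene $= +b\,\cdot$ miRNA $+$ noise, protein $= -c\,\cdot$ gene $+$ noise;
* null: fully independent decoy pairs, included in the catalog so that the
  false-typing rate is measurable.

The reference study conditions used throughout the tests and the
acceptance script are $n = 150$ samples, planted correlation 0.6, 10
degradation + 10 inhibition + 100 decoy pairs, permutation test with
$B = 4999$ and seed-fixed streams. Everything is deterministic given the
config seed, end to end through characterization and recovery scoring.

What the generator does **not** emulate: the covariance structure of real
tumor transcriptomes (co-expression modules, copy-number effects, batch
effects), miRNA family cross-talk (one miRNA regulating many catalog genes
simultaneously), antibody cross-reactivity in protein arrays, or dropout
patterns of single-cell data. Passing the recovery tests therefore shows
the engine detects and types planted first-order monotone dependencies at
realistic cohort sizes — not that real-tissue calls are correct at the same
rates.

```{r, eval = FALSE}
co <- simulate_cohort(simulation_config(
  n_samples = 150,
  planted = planted_design(10, 10, 100, strength = 0.6),
  seed = 2024))
cv <- cohort_view(co$matrices, tissue = "SYNTH", condition = "tumor")
rows <- characterize_cohort(cv, co$catalog, gt_config(n_perm = 4999, seed = 7))
evaluate_recovery(rows, co$truth)
```

## Sample matching

Assays are joined on sample identifiers before testing. `exact`
intersects identical ids; `prefix` groups TCGA-style barcodes on their
first 15 characters (through the sample-type field), averaging multiple
aliquots of one sample within an assay by arithmetic mean on the abundance
scale before any transform (log-then-average would weight aliquots
differently; users preferring another pooling can pre-aggregate); `mapfile`
follows an explicit per-assay mapping table. The matched sample set is
sorted, so matching is invariant to input column order. Cohorts with fewer
than `min_samples` matched samples are rejected with the limiting assay
named.

## Numerical and design notes

* Permutation seeding uses a private RNG stream (saved and restored), so
  library calls never perturb user-level randomness; within a cohort run
  the single run-level seed drives every pair's permutation null, which
  keeps results independent of catalog order.
* Untestable pairs (constant profile, too few complete cases) carry a
  reason string and an NA p-value; they are never silently dropped, and
  classification maps them to `untestable`.
* Characterization output is sorted by miRNA–gene p-value with a
  lexicographic (miRNA, gene) tie-break, so result files are deterministic.
* Protein features are expected to be keyed by gene symbol; unmapped
  protein rows are simply never matched. How antibody targets map to gene
  symbols is left to the data provider.
* When protein data exist for a gene but the gene–protein test is not
  significant, the default stricter gate yields `no_evidence` rather than a
  starred call; the starred call is reserved for pairs where no protein
  test was possible at all.
* The gamma method drops eigenvalues below `1e-12` of the largest before
  moment matching, so rank-deficient covariate groups (duplicated genes)
  are handled without complexity blow-up.

## Known limitations

* Per-pair p-values are marginal; with many catalog pairs, use
  `mt_correction = "bh"` when downstream use requires error-rate control.
  The default (`none`) reports raw p-values, matching the common practice
  of ranking pairs by p-value and filtering interactively.
* The test detects monotone (after log transform, linear) association
  only; saturating or threshold regulation attenuates power.
* The two-gate design means inhibition sensitivity is bounded by protein
  assay coverage and noise; the protein-ablation property (no inhibition
  calls without protein data) is a structural guarantee, not a statistical
  one.
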