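---
title: "Signature-reversal drug repurposing for DNA-repair-deficient cohorts: methods and design"
author: "repurposeDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-reversal drug repurposing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`repurposeDR` implements a biomarker-driven, multi-cancer drug-repurposing
workflow for tumors with DNA-repair deficiencies. The premise is that
hormone-dependent cancers (breast, prostate, ovarian) share molecular
aberrations in their DNA-repair pathways, so patients can be pooled across
organs into pathway-defined cohorts — homologous recombination (HR), base
excision repair (BER), mismatch repair (MMR), nucleotide excision repair
(NER) and non-homologous end joining (NHEJ) — and treatments sought per
deficiency rather than per organ. The pipeline has five stages:

1. **Cohort stratification**: patients with at least one deleterious
   somatic variant in a pathway's gene set join that pathway's cohort
   (overlapping membership allowed).
2. **Differential expression**: each cohort's tumor samples are compared
   against adjacent-normal tissue with an empirical-Bayes moderated
   t-statistic; Benjamini–Hochberg FDR yields a signed disease signature.
3. **Reversal scoring**: drugs are ranked by how strongly their exposure
   rank profiles *reverse* the signature (a two-sided Kolmogorov–Smirnov
   connectivity score), with a gene-set permutation null.
4. **Upstream regulators**: chemicals/drugs/toxicants (CDTs) with signed
   edges onto genes are scored by a confidence-weighted z-score that asks
   whether the observed expression changes look like the *absence* of the
   compound.
5. **Validation**: rankings are evaluated against a gold standard of
   approved/investigational drugs with NDCG and sensitivity-at-cutoff
   curves, benchmarked against random orderings.

Because the original inputs (tumor atlas expression and variants,
exposure-profile compendia, a proprietary interaction knowledge base) are
external and partly proprietary, the package ships a fully seeded
synthetic-data generator that emulates the statistical structure each stage
assumes. Every stage is therefore exercisable, and testable against planted
truth, offline.

# The statistical machinery

## Moderated t and the variance prior

For gene $g$, with $n_T$ tumor and $n_N$ normal samples on the log2 scale,
the effect is $\mathrm{lfc}_g = \bar{x}_{T,g} - \bar{x}_{N,g}$ and the
pooled variance $s_g^2$ has $d_g = n_T + n_N - 2$ residual degrees of
freedom. Gene-wise variances are modeled as draws from a scaled
inverse-chi-square prior with $d_0$ degrees of freedom and scale $s_0^2$.
The posterior (shrunken) variance is

$$\tilde{s}_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

and the moderated statistic
$t_g = \mathrm{lfc}_g / (\tilde{s}_g \sqrt{1/n_T + 1/n_N})$ is referred to
a t distribution on $d_0 + d_g$ degrees of freedom (standard normal when
$d_0 = \infty$). Setting $d_0 = 0$ recovers the ordinary pooled t exactly;
both limits are unit-tested, and the statistic is cross-checked against
limma's `lmFit`/`eBayes` under a shared prior.

`fitVariancePrior()` estimates $(d_0, s_0^2)$ by method of moments on the
log sample variances: since
$\operatorname{var}(\log s_g^2) = \psi_1(d_g/2) + \psi_1(d_0/2)$ (with
$\psi_1$ the trigamma function), the equation
$\psi_1(d_0/2) = \operatorname{var}(\log s^2) - \psi_1(d_g/2)$ is solved by
Newton inversion of the trigamma; $s_0^2$ then matches the mean of the log
variances through the corresponding digamma identity. When the observed
dispersion does not exceed the pure sampling contribution the equation has
no positive root; the fit then returns $d_0 = \infty$ with $s_0^2$ equal to
the mean variance (complete shrinkage to a common variance). Genes with
zero residual variance are excluded from the fit, with a warning, but are
still tested through the prior.

## Signed signatures

`buildSignature()` applies two gates: $s(g) = +1$ iff $q_g < \alpha_q$ and
$\mathrm{lfc}_g \ge +\tau$; $s(g) = -1$ iff $q_g < \alpha_q$ and
$\mathrm{lfc}_g \le -\tau$; otherwise $s(g) = 0$. Defaults are
$\alpha_q = 0.05$ and $\tau = 0$ (the main pipeline uses FDR only);
$\tau = 0.6$ reproduces the stricter setting used for cell-line
re-analyses. A fold-change of exactly zero is never assigned a direction,
which resolves the boundary case at $\tau = 0$ without affecting any
realistic input (a gene with $\mathrm{lfc} = 0$ has $t = 0$, $p = 1$).

## Connectivity (reversal) scores

A drug's exposure profile is a permutation rank vector over the gene
universe: rank 1 is the gene most up-regulated under exposure. For a gene
set with sorted profile ranks $p_{(1)} < \dots < p_{(t)}$ in a universe of
size $n$, the two-sided KS component is

$$a = \max_j\left(\frac{j}{t} - \frac{p_{(j)}}{n}\right), \qquad
  b = \max_j\left(\frac{p_{(j)}}{n} - \frac{j-1}{t}\right),$$

returning $a$ if $a > b$, else $-b$. The raw connectivity score is
$\mathrm{ks}_{up} - \mathrm{ks}_{down}$, zeroed when the two components
share a sign — the classical connectivity-map composite. A drug that
pushes disease-up genes to the bottom of its profile and disease-down
genes to the top scores negative; scores are normalized per collection by
the maximum absolute raw score so they land on the $[-1, +1]$ scale with
the strongest-magnitude reverter at exactly $-1$. Ranking is ascending
(largest negative first), with lexicographic drug-id tie-breaks so the
ordering is total and reproducible.

Significance uses a gene-label permutation null: each permutation redraws
disjoint random up/down sets of the observed sizes from the universe and
recomputes the raw score; the add-one-smoothed two-sided p-value is
$p = (1 + \#\{|raw^*| \ge |raw|\})/(1 + B)$, followed by BH across drugs.
The inner loop is implemented in C++ (driven by R's RNG, so it is
reproducible under `set.seed`) and is checked against an R reference
implementation in the test suite.

**A structural property worth knowing**: under a pure null, the same-sign
zeroing rule sets roughly half of all raw scores to exactly 0, and a drug
with $|raw| = 0$ has $p = 1$ by construction. Null p-values are therefore
*not* uniform on $(0, 1)$: they are near-uniform below $\sim 0.5$ with an
atom at 1. They remain valid — sub-uniform at every level,
$P(p \le \alpha) \le \alpha$ — which is exactly what BH requires, and the
acceptance suite measures the sub-uniformity margin directly. A
Kolmogorov–Smirnov test of these p-values against Uniform(0,1) rejects by
design, not by defect.

## Upstream regulators

The interaction network is a directed graph from CDT nodes to genes; each
edge carries a sign $s(e)$ (+1 activation, −1 inhibition) and a confidence
weight $w \in (0, 1]$; `(source, target)` pairs are unique. Two hypotheses
are considered per CDT: **HA** (regulator active in the condition) is
supported by a DE target whose expression sign matches its incoming edge
sign; **HI** (regulator inhibited) by a mismatch. Treating disease as the
state associated with a therapeutic compound's *absence*, a reverting drug
looks inhibited. The evidence is combined over the CDT's edges onto DE
genes:

$$z = \frac{\sum_{e,g} w_e\, s(e)\, s(g)}{\sqrt{\sum_e w_e^2}},$$

mapped to a normal-tail p-value. The left (inhibited) tail is the default
therapeutic reading; the tail is configurable because the choice is a
modeling convention. Consistency *counts* are per gene (any-edge rule)
and reported as "15/19"-style HI-consistent/DE-target ratios, while the
z-score sums per edge; with unique (source, target) pairs the two views
coincide. Multi-cohort analysis intersects the CDTs significant in every
cohort, ordered by the first cohort's p-value.

## Ranking evaluation

Relevance is binary: a ranked drug is relevant iff it appears in the
gold-standard set for the indication (approved and investigational drugs
are treated alike). NDCG at cutoff $p$ is
$\mathrm{DCG}_p / \mathrm{IDCG}_p$ with
$\mathrm{DCG}_p = \sum_{i=1}^{p} (2^{rel_i}-1)/\log_2(i+1)$ and the ideal
ordering truncated at $p$; it is defined as 0 when no listed drug is
relevant. Sensitivity at cutoff $k$ is $|\text{top-}k \cap G|/|G|$ — plain
recall against the gold set $G$; specificity-type metrics are deliberately
out of scope because true negatives are unavailable in repurposing.
Random controls permute the *same* candidate list uniformly (1,000
orderings by default) and report the mean curve with an empirical 5–95%
band; the expected control sensitivity at cutoff $k$ is $\approx k/n$.

# The synthetic scenario

`syntheticScenario()` fixes the study conditions; all generators are pure
functions of (parameters, seed), and every generated file round-trips
through the package's readers. Defaults, and why:

- **2,000 genes, 40 tumor + 40 normal samples**: large enough for the
  empirical-Bayes machinery to be in its intended regime, small enough
  that the full pipeline runs in seconds.
- **Pathway sizes HR 41, BER 33, MMR 23, NER 47, NHEJ 13**: the scale of
  the corresponding curated repair pathways. The generator draws the sets
  *disjointly* so that planted cohort membership is exactly recoverable;
  real pathways overlap slightly, and overlapping membership is still
  exercised because one patient can be mutated in several pathways.
- **Per-pathway mutation probabilities 0.35/0.20/0.30/0.25/0.15**: chosen
  so every cohort retains at least a handful of expression samples at 40
  tumors; real deficiency prevalences are lower (a few percent), which
  matters for cohort size, not for the correctness properties tested.
  Background noise adds Silent variants in pathway genes (excluded by the
  default `excludeClasses = "Silent"`) and deleterious variants outside
  all pathways, neither of which can perturb membership.
- **5% DE fraction, effect $\delta = 2$ log2 units, prior $d_0 = 4$,
  $s_0^2 = 0.05$**: a sparse, strong signature over moderate gene-wise
  variances drawn from the exact prior family the moderated t assumes —
  deliberately well-specified, so hyperparameter recovery is a meaningful
  test rather than a robustness study.
- **100 drugs with 5 perfect reverters (ρ = 1), remainder null**:
  mimickers are available (`nMimickers`) and used in the unit tests, but
  the reference conditions plant reverters only. The reversal strength ρ
  selects the fraction of signature genes placed at the profile extremes,
  interpolating from perfect placement (ρ = 1) to a fully random profile
  (ρ = 0), so score monotonicity in ρ is testable.
- **50 CDTs with 2 therapeutic, 20 edges each, unit weights**: 20 edges
  matches the scale of a well-characterized drug regulator's DE-target
  count; weights default to 1 because published analyses do not expose
  confidence weights, and a $(0,1]$ uniform range is available.

What the generator does *not* emulate: gene–gene correlation, batch
effects, mutation spectra and signatures, dose/cell-line structure in
exposure profiles, or pathway overlap. Passing tests therefore demonstrate
the correctness and calibration of the machinery under its own
assumptions, not performance on real tumor data.

# Numerical and design choices

- **Pooled normals**: each cohort's tumors are compared against *all*
  adjacent-normal samples of the cancer type, not patient-matched pairs —
  deficiency cohorts can be small (e.g. a 14-patient HR cohort), and
  matched normals would leave too few degrees of freedom.
- **Log2 input convention**: expression is taken as already log2; callers
  opting into `log2Transform()` declare the input raw
  (default pseudocount 1). The transform is never applied implicitly and
  no idempotence is assumed.
- **Gene identifiers** are opaque, case-sensitive strings; no aliasing.
- **"Mutation"** means any variant record whose class is not excluded;
  the default exclusion is `Silent` only — no consequence prediction.
- **BH adjustment** delegates to `p.adjust(method = "BH")` after domain
  validation, and is verified against a brute-force step-up oracle.
- **Permutation determinism**: all stochastic steps take explicit seeds;
  the pipeline splits one root seed deterministically per stage and
  cohort, and library code restores the caller's RNG state.
- **Degenerate inputs**: zero-variance genes are dropped from the prior
  fit but tested through the prior; a gene with zero posterior variance
  (only possible with a zero prior) is reported as missing with a
  warning; empty signatures, empty rankings, and CDTs without DE-gene
  edges are warnings/omissions, not silent zeros; a cohort failure is
  isolated, marked `FAILED`, and does not abort other cohorts.
- **Problem sizes in the checks**: the test suite runs the reference
  conditions across 100 seeds for planted-drug and regulator recovery and
  50 seeds for DE power/FDR; permutation calibration uses 500 null drugs
  with 1,000 permutations; the acceptance script reduces replicate counts
  (10–20 seeds per quantity) to keep a full rerun under a minute while
  measuring the same quantities.

# Known limitations

- Only direct CDT→gene edges are scored; indirect (two-hop) regulation
  and co-expression effects are out of scope.
- Binary relevance and sensitivity-only validation inherit the field's
  missing-true-negative problem; NDCG and sensitivity say nothing about
  specificity.
- The connectivity score is the classical rank-based composite; modern
  moderated-z exposure signatures and cell-line aggregation are not
  ingested.
- Cohort calling is variant-presence only: no copy number, methylation,
  germline/somatic distinction, or scar-based deficiency scores.

# A minimal run

```{r example}
library(repurposeDR)

dat <- generateScenarioData(syntheticScenario(seed = 7))
paths <- writeScenarioData(dat, "sim")
manifest <- runPipeline(c(paths, list(outDir = "sim/run", seed = 99)))
```

The output directory then holds, per cohort, `signature_*.tsv`,
`drug_ranking_*.tsv`, `regulators_*.tsv` and `validation_*.tsv`, plus
`cohorts.tsv`, the cross-cohort `intersection.tsv` and a `manifest.json`
recording versions, parameters, seed and per-stage counts. Rerunning with
the same config and seed reproduces every file bit for bit.
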