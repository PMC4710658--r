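---
title: "Methods: differential expression, blinded classification, toxicity profiles and biomarker quality in crestmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression, blinded classification, toxicity profiles and biomarker quality in crestmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crestmark)
```

crestmark analyses compound screens in human neural crest cells in which
six migration-inhibiting toxicants were profiled on expression microarrays
against matched solvent controls. This vignette is the package's own
account of the statistical machinery: the models, their assumptions, the
tunable parameters, the synthetic data used for validation, and the places
where the design was genuinely open and a choice had to be made.

## Study design and the paired contrast

The design the package expects (and its generator reproduces) is six
compounds with five biological replicates each — three used for training a
classifier, two kept blinded for testing — and fifteen control samples
organised in three control groups: one shared by geldanamycin-like, PBDE-
like and triadimefon-like exposures, one shared by the two HDAC-inhibitor
analogues, and one for arsenic-like exposures run separately. The sample
sheet encodes this pairing explicitly (`control_group`, `batch`) rather
than inferring it, so it is validated at load time: every treated sample
must resolve to at least one control of its group *in its own batch*.

All statistics start from the **paired contrast**: treated minus matched
control, per probe, on the log2 scale. When a batch has as many controls in
the group as treated replicates, pairing is by replicate index (this
preserves the replicate as the unit of error); otherwise the control-group
mean is subtracted. The pairing key is a declared convention — the design
being emulated states a paired analysis but not the key — and replicate-
index pairing was chosen because it keeps n differences per probe rather
than collapsing the controls to one value.

Inputs are assumed already normalized (RMA-type background correction and
quantile normalization upstream); values must lie in the instrument range
of 3–15 log2 units, and loading enforces this.

## Moderated t and DEG calling

Per probe the one-sample moderated t against zero is

$$t_g = \frac{\bar d_g}{s_{\mathrm{post},g}/\sqrt{n}}, \qquad
s^2_{\mathrm{post},g} = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}, \quad d = n-1,$$

with p-values from a t distribution on $d_0 + d$ degrees of freedom
(two-sided throughout; responses occur in both directions). The prior
$(d_0, s_0^2)$ is estimated by the method of moments on the log sample
variances under the scaled inverse-chi-square hierarchical model: with
$e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$,
$\operatorname{Var}(e) = \psi'(d/2) + \psi'(d_0/2)$ gives $d_0$ by inverting
the trigamma function (Newton iteration, relative tolerance $10^{-8}$), and
the mean of $e$ gives $s_0^2$. If the moment estimate of $\psi'(d_0/2)$ is
non-positive — the observed variances are less dispersed than sampling
alone would produce — the prior degrees of freedom are set to $\infty$
(fully pooled variance). The limits are exposed directly: `d0 = 0`
reproduces the ordinary one-sample t, `d0 = Inf` the fixed-variance
statistic; the unit tests verify both and check the full estimate against
an independent empirical-Bayes implementation.

Degenerate inputs: a probe with all-zero differences gets $t = 0$, $p = 1$
(its posterior variance is positive as long as $d_0 > 0$); a data set in
which *every* probe has zero variance cannot support the model and is
rejected.

A probe is a DEG when the BH-adjusted p-value is at most `fdr_max` (default
0.05) **and** |fold change| is at least `fc_min` (default 1.8, i.e.
$|\log_2 FC| \ge \log_2 1.8 \approx 0.847$); both boundaries inclusive. The
threshold is applied at probe level; gene-level rollups (any probe of the
gene) are reported separately where gene lists are needed. BH adjustment is
the standard step-up procedure (`stats::p.adjust`), and the test suite
checks it against a brute-force implementation built from the definition
for every ordering of up to six p-values.

## Blinded classification

Features are the `k = 100` probe sets with the highest variance across all
control-subtracted *training* samples jointly (ties broken lexicographically
by probe id so selection is reproducible). Each of the $\binom{6}{2} = 15$
class pairs gets a linear-kernel SVM. The cost parameter is selected by a
grid over powers of two, $2^{-5} \ldots 2^{5}$, scored by
leave-one-replicate-out cross-validation of the full multiclass rule, with
ties resolved towards the smallest cost (strongest regularization). The
grid and the CV scheme are declared substitutes: the procedure being
modelled states a grid search "over supplied parameter ranges" without
giving the ranges or the inner validation loop, and with three replicates
per class leave-one-replicate-out is the only resampling that respects the
replicate structure.

Each pairwise decision value is mapped to a probability with a Platt
sigmoid fitted on the training decision values (Newton descent with
backtracking on the cross-entropy of smoothed targets, the standard remedy
for complete separation at these sample sizes). The multiclass posterior
solves the pairwise-coupling quadratic program

$$\min_p \sum_i \sum_{j \ne i} (r_{ji} p_i - r_{ij} p_j)^2
\quad \text{s.t.} \quad \textstyle\sum_i p_i = 1,\; p \ge 0$$

by the usual iterative scaling method (KKT residual tolerance $10^{-12}$,
hard failure with the residual if $10^{-8}$ is not reached). Pairwise
probabilities are clamped to $[10^{-7}, 1-10^{-7}]$ before coupling. The
two-class case has the closed form $p = (r_{12}, r_{21})/(r_{12}+r_{21})$.
A grid-search minimizer over the probability simplex serves as the
independent oracle in the tests.

Prediction reports carry best and second-best classes with posteriors;
percentages are rounded to whole percent only in the printed report, full
precision is kept in the machine output. Grouped scoring treats designated
shared-mechanism compounds (the HDACi analogues) as one class, since their
near-identical signatures make within-pair assignment uninformative.

## Enrichment: classic and elim

Over-representation uses the one-sided Fisher test (hypergeometric upper
tail) of a DEG gene list against each term, BH-adjusted **within one
namespace and one direction** — never across. The universe is all annotated
genes of the collection, the conventional choice when the array defines
what could have been observed. Up- and downregulated lists are analysed
separately where profiles per direction are needed, and pooled where a
term's biology mixes directions (the superordinate ring summaries).

For the GO-like DAG the **elim** variant is implemented: terms are visited
from the deepest level upward (ties by term id, so the order is total and
reproducible); whenever a term's raw p-value is at or below `elim_cutoff`
(default 0.01, the conventional default for this algorithm — the source
procedure names the algorithm but not the cutoff), its current member genes
are removed from all ancestors before those are tested. Reported counts and
p-values are post-elimination; `elim_cutoff = 0` provably reduces to the
classic analysis. Which algorithm applies to which compound is a per-
compound configuration choice, mirroring analyses in which one compound is
treated with the classic method and the rest with elim; no default
inference is attempted.

Annotation loading propagates DAG term membership to ancestors (true-path
rule), verifies acyclicity, and accepts GMT, OBO-lite (`id`/`name`/`is_a`)
and two-column edge files. Probes without a gene symbol carry the sentinel
`"unannotated"`; such probes take part in probe-level statistics (DEG
counts, variance selection) but are excluded from gene-level steps
(enrichment lists, gene rank averaging), which is the documented policy for
the open question of how unmapped probes are handled.

Reported terms pass a relevance filter: adjusted p ≤ 0.05 and either at
least 3 DEG in the term or — for small terms — at least 50% of the term's
genes differentially expressed.

## Toxicity profiles

Each compound is summarised on six axes: DEG up, DEG down, enriched GO
terms up, GO down, KEGG pathways up, KEGG down, using the *filtered*
enrichment rows. Axes are normalized to the study-wide maximum per axis
(an axis whose maximum is 0 normalizes to 0), so exactly one compound
attains 1.0 per axis barring ties. A configuration switch normalizes by
category instead (one maximum shared by both directions of DEG, GO, KEGG),
since figure legends and methods text of the modelled study describe the
normalization both ways; the six-maxima variant is the default. The ToxPi
score is the weighted mean of normalized axes with default weights
(1, 1, 2, 2, 2, 2): GO and KEGG double-weighted, the two DEG axes carrying
20% of the total. Scores are invariant to common rescaling of the raw
counts and monotone in every axis.

Enriched terms are tallied into six superordinate biological-process
classes (migration/adhesion, metabolism, differentiation, signalling,
stress response, other). The mapping is an input table because the original
assignment was expert curation; a keyword fallback ships for exploration
and labels anything unmatched as "other".

## Biomarker selection and the SU metric

The **joint toxicant signature** keeps genes DEG in at least four of the
six compounds, ignoring direction for membership (a gene consistently
regulated but in opposite directions across compounds is still a usable
marker) while reporting the per-compound direction.

The **scorecard** admits genes that, in at least one compound, have a DEG
probe with control expression of at least 5 log2 units (clearly above array
noise on the 3–15 scale). Points, one each: control expression at or above
the median array level; more than one probe set of the gene regulated in
the same direction (confirmation); another family member in the pooled DEG
list (related gene); membership in a kept enriched GO term; membership in a
kept enriched KEGG pathway; best adjusted p at or below $10^{-4}$
(statistical strength). Genes totalling ≥ 3 are shortlisted. The exact
point values of the original scoring sheet are only partly documented, so
the scheme here is a faithful but configurable reconstruction; the
thresholds are arguments, the structure (minimum criteria, then additive
points, shortlist at 3) is fixed.

The final panel replaces a manual curation step with a declared
deterministic rule: per compound, shortlisted DEG genes ordered by score
descending, then best adjusted p ascending, then gene id — taken up to 12,
with a warning when fewer than 8 are available. The panel is the union with
the joint signature, with the overlap flagged. This surrogate trades the
original's expert judgement for reproducibility, and is documented as such.

**Separation units.** Per compound, a pooled-variance two-sample T score
per probe (treated vs matched controls; Welch available as an option — the
pooled form matches the equal-replicate design), probes retained only if at
least one compound reaches raw p < 0.05 (the source procedure states the
filter without an FDR qualifier), |T| averaged over each annotated gene's
probes, genes rank-normalized per compound to $r \in [0,1]$ using average
ranks for ties (the 0–1 mapping is stated, the tie rule is ours), and

$$SU = \sqrt{\bar r_{GA}^2 + \bar r_{TDF}^2 + \bar r_{PBDE}^2 +
\bar r_{TSA}^2 + \bar r_{VPA}^2 + \bar r_{As_2O_3}^2} \in [0, \sqrt 6].$$

Candidate genes outside the filtered pool receive $r = 0$ (conservative: it
penalizes the candidate set rather than silently shrinking it) and are
logged. The null distribution draws random same-size gene sets from the
filtered pool without replacement; the candidate is reported with the null
mean, SD, percentile and standardized distance z. The metric is rank-based,
hence invariant to monotone rescaling of the T scores.

## The synthetic-study generator

`study_design()` fixes the study conditions: 6 compounds × (3 + 2)
replicates, 15 controls in the three-group sharing structure, per-probe
baselines uniform in 6–12 log2 units (inside the 3–15 instrument range),
homoscedastic Gaussian noise with SD 0.25 log2 units per sample, planted
per-compound signatures whose relative sizes follow the response types of
the modelled compounds (up-dominant, down-dominant, mixed), planted |log2
effects| drawn from 0.9–2.0 by default (the real effect-size distribution
is unpublished, so this range — modest to strong regulation around the 1.8-
fold threshold — is the generator's declared placeholder), 1–3 probes per
gene, 2% unannotated probes, and the HDACi analogue pair sharing one
signature up to independent jitter of SD 0.05 (effect correlation ≥ 0.95 by
construction). Values are clipped to [3, 15]; a run in which more than 10%
of values clip is flagged. With noise 0 every planted contrast is recovered
exactly, which the tests assert.

An optional per-probe noise SD drawn from a scaled inverse-chi-square prior
would match the empirical-Bayes model exactly; the default keeps
homoscedastic noise because parameter-recovery behaviour is then analytic
(contrast SE $= \sigma\sqrt{2/n}$) and the moderated t simply estimates a
large $d_0$.

What the generator does **not** emulate: probe-level hybridization
artifacts, spatial array effects, batch effects beyond the control-group
structure, correlated noise between probes of one gene, and heavy-tailed
intensity distributions. Passing tests on this generator therefore
demonstrate the correctness and calibration of the *procedures* under the
stated noise model, not performance on real arrays.

`plant_biomarker_scenario()` adds a designated 39-gene set, disjoint from
all other signatures, with |log2 effect| 2.5 in every compound — a positive
control that the SU machinery must place far above its bootstrap null.

## Problem sizes and numerical conventions

The test suite and acceptance script run the generator at 400–1000 genes
(roughly 800–2050 probes), bootstrap nulls at 2,000–10,000 replicates, and
resampling at 5–6 splits; these sizes were chosen so the full validation
suite exercises every stage at statistically meaningful scale while staying
desk-sized. Production-scale nulls (up to $10^6$ replicates) are a single
argument.

All tables are tab-separated with a header; floats are written with 6
decimals so identical config + seed gives byte-identical run directories
(asserted in the tests). PCA uses the centered SVD with the sign convention
that each component's largest-magnitude loading is positive. All RNG flows
from the single seed recorded in every machine-readable output.

## Limitations

The package neither performs array preprocessing nor judges biological
plausibility of selected genes; candidate biomarkers are exactly that —
candidates, selected by transparent rules, requiring independent
confirmation on new compounds and platforms before any claim of being
validated markers. The SU metric assumes approximate independence between
the per-compound mean ranks; compounds with strongly overlapping signatures
(the HDACi pair) violate this mildly, which inflates neither bound but
makes SU an index rather than a calibrated probability statement.
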