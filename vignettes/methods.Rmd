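---
title: "Methods: connectivity and master-regulator screening of perturbational signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity and master-regulator screening of perturbational signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigconnect)
```

## The problem this package addresses

Crude natural products — animal venoms in particular — are mixtures of many
uncharacterised components with no prior dosing or target information. One
route to early therapeutic hypotheses is purely transcriptomic: expose a
human cell line to the substance at a calibrated sub-toxic dose, sequence,
build a differential-expression signature, and then ask two questions in
parallel:

1. **Which known drugs does this perturbation look like?** (connectivity
   analysis against a reference compendium of drug-induced expression
   profiles, aggregated to drug classes / mechanisms of action), and
2. **Which disease-linked regulatory programs does it perturb?**
   (master-regulator analysis: regulon enrichment followed by
   transcription-factor-to-disease mapping).

`sigconnect` implements this workflow end to end, with seeded synthetic-data
generators for every input so each stage is testable without any external
download.

## Dose calibration: Hill fits and GI20

Exposure concentrations are calibrated by growth-inhibition assays fit to
the four-parameter Hill equation

$$y = \mathrm{Bottom} + \frac{\mathrm{Top} - \mathrm{Bottom}}
{1 + 10^{(\log GI_{50} - x)\,h}}$$

with $x = \log_{10}$(concentration in µg/µL) and $y$ percent growth versus
untreated. We fit on the log-concentration scale: the equation's
$\log GI_{50}$ form is only dimensionally meaningful there, and assay designs
are 2-fold dilution series, which are uniform in $\log_{10}$. The exposure
dose is GI20, the concentration at $y = 80\%$ (20% growth inhibition — strong
enough to perturb expression, weak enough to avoid transcriptional signatures
of cell death), obtained in closed form:

$$x^* = \log GI_{50} - \frac{1}{h}\log_{10}
\left(\frac{\mathrm{Top}-\mathrm{Bottom}}{y^*-\mathrm{Bottom}} - 1\right),
\qquad GI_{20} = 10^{x^*}.$$

Fitting uses nonlinear least squares started from data-driven values
(Top = max $y$, Bottom = min $y$, $\log GI_{50}$ = the dose nearest the
response midpoint, $h = -1$) with a Nelder–Mead polish; curves with fewer
than 4 distinct doses or essentially constant response are rejected rather
than fit. `gi20_from_fit()` refuses targets outside the fitted asymptotes
("no GI20 in range"), mirroring substances that never reach 20% inhibition
and are instead assayed at a fixed concentration.

A worked example from a published growth-inhibition table (Bottom −2.096,
Top 92.572, logGI50 −0.640, h −1.928) inverts to ≈ 0.0866 µg/µL at
$y = 80\%$, while the same table prints a GI20 of 0.0926 µg/µL — about 7%
apart, more than rounding of the printed parameters can explain. We do not
force agreement: the implementation reports the algebraic inversion of the
fitted parameters, and the test suite asserts the 0.0866 value.

## Differential expression: a minimal NB Wald test

The signature builder is intentionally a *minimal* negative-binomial Wald
procedure — the workflow contract is just "disjoint up/down gene lists plus
per-gene statistics", and any external DE method can be substituted.

- **Normalisation**: median-of-ratios size factors (reference set = genes
  with nonzero counts in every sample).
- **Dispersion** $\alpha_i$: method of moments on normalised counts,
  computed separately per group as $(s^2 - \bar q)/\bar q^2$; the **larger**
  of the two group estimates is used, floored at $10^{-8}$. Taking the
  maximum is the one deliberate conservatism: with 3 treated vs 21 control
  samples, a pooled or single-group estimate understates the treated-arm
  variability often enough to visibly inflate the false discovery rate.
- **Fold change**: $\log_2(\bar q_T/\bar q_C)$ with a 0.5 pseudocount
  substituted only where a group mean is exactly zero, so the fold change of
  ordinarily expressed genes is exactly invariant to global count scaling.
- **Wald statistic**: $\log_2 FC / SE$, with the SE from the NB variance
  model $\mathrm{Var}(K/s) = \mu/s + \alpha\mu^2$ propagated through the
  delta method; two-sided p from the normal reference; BH-FDR across tested
  genes; signature = genes with $p_{adj} < \alpha$ (default 0.05, kept as a
  parameter because published effective thresholds are ambiguous).

What this deliberately omits: dispersion shrinkage across genes, outlier
(Cook's) filtering, GLM-based fold-change estimation. Consequences: slightly
lower power than shrinkage-based tools at small $n$, and no protection
against single-sample outliers. On the package's stated simulation world
(2000 genes, 100 planted at $|\log_2 FC| = 2$, NB dispersion 0.1, 3 vs 21)
this recovers ≥ 80% of planted genes at an empirical FDR ≤ 0.10.

## Connectivity scoring

For a query $q$ (up list, down list) and a reference profile $r$ (gene-wise
z-scores over an $n$-gene universe, ranked descending, ties broken by gene
id so ranking is deterministic), with $V(j)$ the ascending positions of the
$t$ query genes:

$$a = \max_j\left(\tfrac{j}{t} - \tfrac{V(j)}{n}\right),\qquad
  b = \max_j\left(\tfrac{V(j)}{n} - \tfrac{j-1}{t}\right),$$

and the signed KS-like enrichment score is $ES = a$ if $a > b$, $-b$ if
$a < b$, and 0 on an exact tie (the source formulation defines only the two
strict cases). An empty gene list scores 0. Positive ES means the set
concentrates at the top of the ranking, so an up-list scoring positive and a
down-list scoring negative is concordant regulation.

The **weighted connectivity score** is
$w = (ES_{up} - ES_{down})/2$ when the two ES have strictly opposite signs
and **0 otherwise** — this zero branch is what makes connectivity score
distributions sparse. **Normalisation** divides positive $w$ by the mean
positive $w$ of its (cell line × perturbagen type) group and negative $w$ by
the absolute mean negative $w$ of the group; dividing by $|\mu^-|$ rather
than $\mu^-$ preserves sign (a literal reading would flip every negative
score). Note that a group lacking positive scores has nothing for a positive
mean to scale, so the global-mean fallback documented in
`normalize_connectivity()` is defensive only.

**τ** is the signed strict quantile of $|NCS|$ within the query's row over
all $N$ references, scaled to ±100:
$\tau_r = \mathrm{sgn}(NCS_r)\,\frac{100}{N}\,\#\{i: |NCS_i| < |NCS_r|\}$.
The printed source formula compares a term to itself — an evident typo — and
is ambiguous about the comparison population; we use the query's row, which
matches "$N$ is the number of all expression signatures in the reference
database" and keeps τ in $[-100, 100]$. Ties (including the all-zero case)
give τ = 0 by strictness.

**PCL aggregation** is a maximum-quantile rule: the nearest-rank 67th and
33rd percentiles of the member τ values are computed and whichever has the
larger absolute value is kept (tie → the upper one). The procedure's name is
fixed in the source but its parameters are not; $q = 67$ with nearest-rank
percentiles is this package's choice, exposed as a parameter. The rule
rewards a class with a consistent strong tail in either direction while
ignoring stragglers.

## Master-regulator analysis

Counts are transformed to $\log_2(\mathrm{CPM}+1)$ and each gene gets a
Welch two-sample t-test; the two-sided p maps to a signed z-score
$z = \mathrm{sgn}(t)\,\Phi^{-1}(1 - p/2)$, capped at ±8 (the cap bounds
z-scores for p-values below double precision). The null model re-runs the
same statistic on label-permuted data — distinct relabellings only, the
original excluded, seeded and reproducible — which preserves gene–gene
correlation, unlike gene-wise parametric nulls.

Regulon enrichment is a **declared approximation** of msVIPER: the raw
statistic is the weight-normalised signed mean
$S(TF) = \sum_k w_k m_k z_{t_k} / \sum_k w_k$ over the regulon's targets
(mode $m_k = \pm 1$ for activated/repressed, confidence weight
$w_k \in (0,1]$), normalised to $NES = (S - \mu_{null})/\sigma_{null}$
against the same regulon applied to each permutation column. We did not
reimplement msVIPER's three-tail aREA, shadow analysis, or pleiotropy
correction: the workflow specifies the inputs (z-scores, permuted nulls,
regulons) and the output contract (enrichment score, p, FDR per regulon),
and the weighted-mean statistic meets that contract transparently. The
empirical two-sided p uses add-one smoothing on null scores centred at
their own mean, $p = (1 + \#\{|S_{null}-\mu_{null}| \ge
|S-\mu_{null}|\})/(P+1)$; centring makes two-sidedness well-defined when
the null is slightly off-centre. Regulons with fewer than 5 usable targets
are skipped; a degenerate null sd flags the TF rather than fabricating an
NES.

Significant regulons (FDR < 0.05 by default) join to diseases through a
curated TF–disease table, keeping only diseases supported by **at least two
significant regulons** — the workflow's only evidence filter, since
significance criteria for the final venom–disease associations are
explicitly unsettled in this literature. Whether only up-regulated regulons
or both directions are mapped is configurable (`direction`, default
`"both"`) because the source material describes both conventions in
different places. Disease ICD-9 code lists roll up to a single top-level
chapter; when codes span chapters the specific disease chapter wins over
residual buckets (injury/poisoning, ill-defined symptoms, supplementary
V/E classifications), e.g. {401, 997.91} → circulatory, matching the
stated "avoid 'not elsewhere classified'" rule; remaining ties break by the
chapter of the lowest code.

## Technical validation statistics

`within_pcl_test()` compares, per annotated query drug, its τ scores to
members of its own PCL ("within") against its τ scores to **all**
PCL-member references ("null"; the full set, since no subsampling scheme is
stated), using an independent two-sample Student's t-test (equal variances,
as named) and reporting effect size = mean(within) − mean(null) — exactly
recomputable from the emitted score sets — with BH correction across rows.

`rank_percentiles()` ranks all PCLs by mean τ (descending; ties get the
mean rank, which keeps the percentile unbiased under ties) within a
grouping (cell line or drug), locates the expected PCL, and divides by the
number of PCLs. Under no preference the percentiles are uniform on (0, 1];
the group-level p-value tests the mean against 0.5. The source does not
name the test behind its FDR column; a one-sample t-test is the default and
a one-sample KS test against U(0,1) is available behind a flag.

## The synthetic-data world

The generators state one world and the tests measure it; none of the
following values were adjusted after seeing a test outcome.

- **Counts**: NB draws with log-normal baselines (median ≈ 100 counts,
  $\sigma_{\log} = 1$), dispersion 0.1, 3 treated vs 21 controls (12
  solvent + 9 untreated — the design of the motivating experiments), 100 of
  2000 genes planted at $|\log_2 FC| = 2$.
- **Reference compendium**: 20 classes × 10 members over 978 genes (the
  landmark-gene scale of the L1000 platform), member = class template ×
  SNR + unit noise, SNR 2, 9 cell lines round-robin (the compendium's core
  cell-line count), one PCL per class. Queries drawn from a class take the
  top/bottom 50 genes of a fresh class draw.
- **Regulons**: 20 TFs × 20 disjoint targets over 1000 genes, random modes,
  weights uniform on [0.2, 1]; the planted TF's targets shift by
  $|\log_2 FC| = 1$ in the treated arm, signed by each target's mode; 100
  permutations in the null. The smaller gene universe keeps 100-simulation
  acceptance runs inside a minute-scale budget without changing the
  per-gene model.
- **Dose–response**: truth (0, 100, −1, −2), 12-point 2-fold dilution grid
  from 2.0 µg/µL (spanning 3.3 log10 units), Gaussian response noise σ = 2
  percentage points.

Every generator draws from a stream seeded by (seed, generator name), so
adding a generator never perturbs another's output and all outputs are
byte-reproducible.

What the generators do **not** emulate: library-size artefacts and
batch/plate effects, count outliers, correlated gene–gene structure in the
DE arm (each gene is drawn independently), overlapping regulons, reference
profiles with heavy-tailed or platform-specific score distributions, and
multi-PCL membership. A green planted-recovery test therefore establishes
that the scoring chain is implemented correctly and has reasonable power in
a clean world — not that real compendium-scale performance is reproduced.

## Numerical conventions and degenerate inputs

- Reference ranking ties break lexicographically by gene id; ES ties
  ($a = b$) give 0; empty gene lists give ES 0.
- τ uses strict inequality, so tied |NCS| (including all-zero rows) give 0.
- Dispersion floor $10^{-8}$; z-cap ±8; null-sd floor $10^{-12}$ (below it
  the TF is flagged, not scored).
- Queries with genes outside the reference universe are scored on the
  intersection with a logged count; a fully unmapped query is skipped with
  a warning, not scored as zero.
- All randomised procedures take explicit integer seeds; the permutation
  sampler rejects duplicates and the original labelling, and errors when
  asked for more distinct relabellings than exist.
- With heavily unbalanced arms (3 vs 21) the per-gene permutation-null mean
  of z is *not* tightly centred (NB skew); balance the arms when a
  symmetric gene-wise null matters.

## Known limitations

- The NB Wald test is not a substitute for shrinkage-based DE tools at very
  small sample sizes; it is the workflow's default, not its ceiling.
- The regulon statistic ignores target overlap between regulons (no shadow
  analysis), so correlated TFs can co-rank.
- PCL aggregation with few members is dominated by single scores
  (nearest-rank percentile of ≤ 2 members is an order statistic).
- The connectivity normalisation groups are taken from reference metadata
  as-is; the package does not infer or validate perturbagen-type levels.
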