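---
title: "Methods: combining differential expression and target over-representation to rank miRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combining differential expression and target over-representation to rank miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimrda)
```

## The model

A disease-relevant miRNA should show two signatures at once: its own
expression shifts between tumor and normal tissue, and the mRNAs it is
validated to target are themselves over-represented among the
differentially expressed (DE) mRNAs of the same dataset. `mimrda` scores
each measured miRNA on both axes and combines them.

**Differential expression (P_miRNA).** For a two-group design with
$n_1$ tumor and $n_0$ normal samples, each feature $g$ gets the tumor-minus-
normal log2 fold change and the pooled within-group variance $s_g^2$ on
$d = n_1 + n_0 - 2$ degrees of freedom. Variances are moderated by an
inverse-chi-square prior with parameters $(d_0, s_0^2)$ estimated from all
features by method of moments on $\log s_g^2$: writing
$e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$, the excess of
$\widehat{\mathrm{Var}}(e)$ over $\psi'(d/2)$ identifies $d_0$ through the
trigamma function (inverted by Newton iteration), and the mean of $e$
identifies $s_0^2$. The moderated statistic

$$\tilde t_g = \frac{\mathrm{logFC}_g}{\tilde s_g\sqrt{1/n_1 + 1/n_0}},
\qquad
\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}$$

is referred to a $t$ distribution on $d + d_0$ degrees of freedom (the
normal limit when $d_0 = \infty$; the classical pooled t-test when
$d_0 = 0$, exposed as `ordinary_t = TRUE` for oracle testing). P_miRNA is
the raw two-sided p-value. The DE *sets* (mRNA and miRNA) are defined by
Benjamini-Hochberg adjusted p below `alpha` (default 0.01 for both).

**Target over-representation (P_NDE).** Let the universe contain $M$
mRNAs, $k$ of them DE. A miRNA with $m$ targets in the universe, $x$ of
them DE, gets the upper-tail hypergeometric probability
$P_{NDE} = \sum_{j \ge x} \binom{m}{j}\binom{M-m}{k-j}/\binom{M}{k}$,
exactly 1 at $x = 0$. The dataset-wide DE-mRNA count $N$ is reported
alongside but does not enter the statistic: a hypergeometric draw is fully
specified by $(M, k, m)$, so $N$ is carried as bookkeeping only.

**Combination.** $c = P_{NDE} \cdot P_{miRNA}$ and
$P_G = c\,(1 - \ln c)$, the exact CDF at $c$ of a product of two
independent Uniform(0,1) variables — so under the joint null $P_G$ is
itself uniform, and it is strictly increasing in $c$, meaning improving
either component can never worsen a rank. $P_G$ is computed in log space
(extreme products do not underflow prematurely); $c = 0$ yields
$P_G = 0$ with a warning. One BH pass over all $P_G$ values gives
`p_g_fdr`; ranking is by ascending $P_G$ with deterministic tie-breaks
(ascending $P_{NDE}$, then $P_{miRNA}$, then identifier).

## Design choices where the design was open

* **Raw vs adjusted P_miRNA in the product.** The raw moderated-t p-value
  enters the product; multiplicity is controlled once, at the $P_G$ level.
  Adjusting both inputs and the combination would double-count
  multiplicity.
* **All measured miRNAs are ranked.** Restricting to DE miRNAs first is
  available (`prefilter_de_mirnas = TRUE`) but off by default: top-k
  reporting needs scores for the full panel, and the prefilter only
  removes rows, never changes scores.
* **Universe definition.** The default universe is the intersection of
  targeted and measured mRNAs (`measured_intersection`), which keeps the
  sampling model coherent with the data actually tested;
  `interaction_table` mode uses every mRNA in the interaction table.
* **$m$ is the target-set size** within the universe and $x$ the DE-target
  count; distinct genes only, since the interaction table has set
  semantics.
* **miRNAs without usable target sets** ($m = 0$, or below
  `min_targets`) receive $P_{NDE} = 1$ and a flag rather than exclusion,
  so every measured miRNA still gets a global score.
* **Hazard-ratio estimator.** The survival verification pairs the log-rank
  test with the observed/expected estimator
  $\widehat{HR} = (O_h/E_h)/(O_l/E_l)$ from the same log-rank quantities,
  avoiding a second model (no proportional-hazards regression). Tied event
  times use the standard hypergeometric variance.
* **Median split.** Samples with expression strictly above the per-miRNA
  median are "high"; ties at the median go "low" (a deterministic rule); a
  split that empties a group is a degenerate-split error.
* **"4:1" as stratified 5-fold CV.** The random-forest evaluation reads
  the 4:1 train/test ratio as stratified 5-fold cross-validation; each
  repetition re-draws folds, trains a probability forest restricted to the
  candidate panel, and records the AUC of pooled out-of-fold tumor
  probabilities. Panel comparisons use an unpaired two-sided Wilcoxon
  rank-sum test across repetitions (the repetitions of the two arms share
  no coupling that would justify pairing).

## The synthetic-data generators

The generators emulate exactly the structure the method assumes, so that
every pipeline stage has a ground truth:

* `simulate_expression()`: per-feature baselines Normal(8, 2) on the log2
  scale, Normal(0, `sigma`) noise, a planted fraction of features shifted
  by `effect_size` in tumor samples.
* `simulate_interactions()`: negative-binomial degrees around
  `mean_degree` (dispersion 0 = constant), targets sampled without
  replacement.
* `plant_disease_mirnas()`: rewires each disease miRNA's target set until
  a fraction `enrichment_rho` of its targets is DE, preserving all
  degrees and touching nothing else.
* `simulate_survival()`: exponential event times with hazard ratio `hr`
  between expression-high and -low groups; censoring times Uniform(0, b)
  with b solved numerically so the expected censored fraction equals
  `censor_rate`.

The **desk-scale preset** (`simulate_dataset()` defaults) is 2,000 mRNAs,
300 miRNAs, 30 + 30 samples, mean degree 40, 10% DE features, effect size
1.5 log2 units, sigma 1, 20 disease miRNAs with enrichment rho 0.4. These
sizes give the pipeline clear but not saturated power (about 200 DE mRNAs
at BH < 0.01, disease-miRNA ORA signals around $x \approx 16$ vs an
expected 4) while a full run takes well under a second. A single master
seed fans out to per-component seeds by fixed offsets (1 mRNA expression,
2 miRNA expression, 3 network, 4 disease-miRNA choice, 5 rewiring), so
components can be regenerated independently.

What the generators deliberately do **not** model: RNA-seq count noise and
library-size effects (values are Gaussian on the log scale), repression
coupling between a miRNA's expression and its targets' expression
(differential expression and network enrichment are planted
independently), and identifier harmonization issues (IDs are opaque
strings). Passing tests therefore demonstrate the statistical machinery
under its own assumptions, not robustness to count-data artifacts or ID
mismatches in real repositories.

## Numerical choices and degenerate inputs

* Zero variances: excluded from prior estimation (with a message) but
  still scored; $\tilde s^2 = 0$ with zero effect gives $p = 1$, with
  nonzero effect $p = 0$ plus a warning (exact separation).
* If the spread of $\log s^2$ does not exceed what the residual degrees of
  freedom alone explain, $d_0 = \infty$ and $s_0^2$ is the bias-corrected
  geometric-mean variance $\exp(\bar e)$.
* Trigamma inversion runs Newton iterations to a relative step below
  1e-12; the prior-recovery test checks the residual of the moment
  equation directly.
* `hypergeom_sf` validates $x \le \min(m, k)$, $m \le M$, $k \le M$ and
  returns exactly 1 at $x = 0$; probabilities are clamped to $[0, 1]$
  against floating error.
* Score tables serialize doubles as `%.17g`, so write-then-read
  round-trips are bit-exact.
* Group labels other than tumor/normal, unpaired `time`/`event` columns,
  duplicate identifiers, non-numeric cells and empty universes each raise
  a distinct classed error; pipeline stages rethrow with the stage name
  attached.

## What the tests establish

The test suite verifies each statistic against an independent oracle:
exhaustive subset enumeration for the hypergeometric tail (all universes
up to $M = 12$), a 10-million-draw Monte Carlo tail for the Fisher
combination, a hand-written step-up for BH, the classical pooled t-test
for the $d_0 = 0$ reduction and an independent moderated-fit
implementation (limma) for the full empirical-Bayes path, a six-subject
hand-computed O/E table for the log-rank chi-square, and
generator-as-oracle recovery simulations for the prior, the hazard ratio
and the planted disease miRNAs. Null calibration is checked at the preset
scale: 200 global-null pipeline replicates for type-I control of all
three p-values, and uniformity of $P_G$ on 10,000 independent uniform
pairs. The end-to-end property — the combined ranking places planted
disease miRNAs higher than differential expression alone — holds in
every seeded replicate batch the suite runs (100 replicates), and the
random-forest comparison separates top-ranked from random panels at
rank-sum p < 0.001 for panel sizes 5–20 (200 repetitions each). All
simulation sizes quoted are the ones the shipped tests execute.

## Known limitations

Two-group designs only (no covariates, batches, or paired samples); no
count-based models (supply log-scale values, or use `log2_transform` for
raw quantifications); validated-interaction input only (no target
prediction); the O/E hazard-ratio estimator is coarser than a Cox fit for
small event counts; and miRNA/mRNA identifiers are matched as exact
strings after whitespace trimming — reconciling precursor/mature naming
conventions between expression matrices and interaction databases is the
caller's responsibility.
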