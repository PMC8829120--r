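# mimrda

Rank disease-associated microRNAs from paired tumor/normal miRNA and mRNA
expression profiles.

## The problem and the method

Differential expression alone is a weak criterion for calling a miRNA
disease-relevant: many miRNAs shift between tumor and normal tissue without
driving anything. `mimrda` combines two independent lines of evidence for
every measured miRNA *i*:

1. **P_miRNA** — the probability, under the null of no group difference,
   of the miRNA's own expression change. Computed with an empirical-Bayes
   moderated t-test: per-feature pooled variances are shrunk toward a prior
   (d₀, s₀²) estimated by method-of-moments on the log variances, and the
   statistic `t = logFC / (s̃ · √(1/n₁ + 1/n₂))` is referred to a
   t-distribution on `df + d₀` degrees of freedom.
2. **P_NDE** — the probability that the miRNA's experimentally validated
   mRNA targets contain as many differentially expressed (DE) mRNAs as
   observed just by chance. With a universe of *M* mRNAs of which *k* are DE
   (BH-adjusted p < 0.01), and *x* DE genes among the miRNA's *m* targets,
   this is the upper-tail hypergeometric probability
   `P_NDE = Σ_{j≥x} C(m,j) C(M−m, k−j) / C(M,k)`.

The two are combined through Fisher's product `c = P_NDE · P_miRNA` into the
**global probability**

```
P_G = c · (1 − ln c)
```

which is the exact tail probability of a product of two independent uniform
p-values. `P_G` is Benjamini-Hochberg adjusted across miRNAs and used to
rank them; a low `P_G` requires both strong differential expression and an
enriched target set.

The package also implements the verification procedures used to assess such
rankings: top-k overlap percentages against curated label sets, a
three-statistic ranking comparison (`P_G` vs `P_miRNA` vs `P_NDE`),
median-split Kaplan-Meier/log-rank survival analysis with an
observed/expected hazard-ratio estimate, and a stratified 5-fold
cross-validated random-forest AUC test of ranked miRNA panels — plus fully
seeded synthetic-data generators so every stage is testable without any
external download.

## Worked example

```r
library(mimrda)

sim <- simulate_dataset(seed = 1)   # desk-scale preset, see the vignette
res <- run_mimrda(sim$mrna, sim$mirna, sim$meta, sim$interactions)
print(res)
```

```
mimrda_result: 300 miRNAs ranked | N = 201 DE mRNAs | M = 1999, k = 201
top of the ranking:
  mirna_id      p_mirna        p_nde          p_g      p_g_fdr rank
1 mir-0057 2.319163e-06 3.772353e-18 4.732446e-22 1.419734e-19    1
2 mir-0104 6.318344e-09 1.432076e-12 4.266450e-19 5.518286e-17    2
3 mir-0115 1.393466e-11 8.445754e-10 5.518286e-19 5.518286e-17    3
4 mir-0282 1.116857e-12 7.824580e-08 3.922376e-18 2.941782e-16    4
5 mir-0134 1.142739e-18 1.944129e-01 9.764263e-18 5.858558e-16    5
```

`N` is the dataset-wide DE-mRNA count, `M` the size of the mRNA universe
(targeted ∩ measured), and `k` the DE mRNAs inside it. Each row shows the
two evidence streams and their combination: `mir-0057` tops the list
because its target set is massively enriched (`p_nde ≈ 4e-18`) *and* it is
itself differentially expressed; `mir-0134` is strongly DE but has an
unremarkable target set, so `P_G` demotes it below miRNAs with both
signals.

Of this run's 20 planted disease miRNAs, 18 sit in the top 20:

```r
topk_overlap_percentage(res$scores$mirna_id, sim$truth$disease_mirnas, 20)
#> [1] 90
```

Survival verification on simulated times (true hazard ratio 0.4 between
expression-high and -low groups):

```r
surv <- simulate_survival(300, 0.4, censor_rate = 0.2, seed = 99)
logrank_test(surv[surv$group == "high", ], surv[surv$group == "low", ])
#> log-rank: chi2 = 41.9, p = 9.609e-11, HR (high vs low) = 0.4593
```

A thin command-line front end over the same functions is installed at
`inst/cli/mimrda.R` with subcommands `simulate`, `run`, `evaluate` and
`survival`.

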