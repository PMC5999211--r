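# matesel

Mating patterns and sexual selection in harvested lobster populations,
estimated from microsatellite parentage of egg broods.

## The problem

In clawed lobsters (*Homarus*), females preferentially mate with males
larger than themselves, and male body size (carapace length, CL) and
crusher-claw size (claw width, CW) are sexually selected. Size-selective
fishing removes exactly those phenotypes, so harvesting can both truncate
the trait distribution and weaken the sexual selection acting on it.
Comparing a no-take reserve with an adjacent fished area makes this
measurable: genotype mothers, their egg broods and a large pool of
candidate males at a panel of microsatellite loci, assign paternity, and
compare size-assortative mating and selection estimates between areas.

`matesel` implements that whole chain as a reusable, tested pipeline, with
a synthetic-population generator standing in for field data so that every
stage is verifiable against planted truth:

* **Synthetic population** — per-area/sex size distributions, claw
  allometry, log-linear size-biased mate choice with a Gaussian
  assortative kernel on the male/female size ratio, skewed multiple
  paternity, Mendelian broods with an allelic-dropout (ε₁) / false-allele
  (ε₂) observation layer, and a mark–recapture growth series.
* **Genotype I/O and QC** — tabular and GenePop dialects, the
  ≥5-missing-loci exclusion rule, duplicate-genotype (tag-loss) detection.
* **Population genetics** — unbiased heterozygosity, exact Hardy–Weinberg
  tests (full enumeration or Monte-Carlo), Weir–Cockerham θ with
  permutation tests, genotypic linkage disequilibrium, Chakraborty
  null-allele estimates, and second-parent exclusion probabilities
  (EXP), combined across loci as 1 − Π(1 − EXPₗ).
* **Parentage** — genotyping-error-aware trio likelihoods
  log P(egg | mother, candidate, ε) / P(egg | mother, random father),
  a simulation-calibrated Δ threshold realizing 95% assignment
  confidence, and the study's acceptance rules for multiple paternity
  (≥5 mismatching, fully observed loci against the primary sire).
* **prDM power** — Monte-Carlo probability of detecting multiple paternity
  for a brood size, locus panel and paternal skew; bounded above by the
  sampling bound 1 − Σ cₖⁿ.
* **Growth adjustment** — moult-probability (logistic) and increment
  (linear) sub-models from mark–recapture records; male CL adjusted to the
  mating year as CL + (yearₓ − yearₘ) · ĝ(CL) · p̂(CL).
* **Selection analysis** — standardized selection differentials,
  AICc-ranked logistic mating-success models, Janzen–Stern approximate
  gradients β_avggrad = b · mean(ŵ(1−ŵ))/w̄ and mean-standardized
  gradients β_μ, size-assortative-mating regressions with an
  additive-vs-interaction likelihood-ratio test, and within-pair size gaps.

## Worked example

```r
library(matesel)

cfg <- run_config(
  sim = population_config(
    n = list(reserve_m = 120, fished_m = 120, reserve_f = 30, fished_f = 30),
    missing_rate = 0.01),
  seed = 2026, calib_reps = 300, prdm_reps = 2000, fst_permutations = 199)
report <- run_pipeline(cfg)
report
#> Pipeline report (seed 2026)
#> Assignment summary
#>   offspring assigned: 301 / 600 (50.2%)
#>   fathers: 45 / 240 candidates (18.8%)
#>   known matings: 60 (reserve share 48.3%)
#>   multiply-sired broods: 1 / 60 (1.7%)
#> Selection differentials:
#>      area trait     S        p   n n_success
#> 1 reserve    CL 0.785 5.21e-06  98        22
#> 2 reserve    CW 0.823 1.51e-05  98        22
#> ...
```

Half the eggs get a father at 95% confidence (the calibration assumes only
half the true fathers are in the candidate pool), differentials on body
and claw size are strongly positive because the generator's females prefer
large, large-clawed males, and the multiply-sired brood carries the
configured 9:1 paternal skew. Downstream pieces of the same report:

```r
report$power
#>   n_eggs    skew  prdm      se sampling_bound
#> 1     10 0.5:0.5 0.998 0.00112          0.998
#> 2     10 0.9:0.1 0.634 0.01077          0.651
report$growth$model
#> Growth model (400 records, 315 moulted)
#>   p(moult): logit^-1(14.606 -0.1155 CL)
#>   increment: 18.38 -0.0741 CL mm/yr (sigma 1.22)
report$selection$gradients
#>   model  trait     b    se    z       p beta_avggrad beta_mu
#> 1    CW     CW 1.744 0.533 3.27 0.00106        0.916    3.79
#> 2    CL     CL 1.609 0.477 3.37 0.00075        0.846    6.34
#> 3 CWres CW_res 0.452 0.343 1.32 0.18731        0.336      NA
```

A brood of ten eggs detects two equally contributing sires essentially
always (99.8%), but a 9:1 skew is detectable only ~65% of the time — the
sampling bound 1 − 0.9¹⁰ = 0.6513 dominates no matter how informative the
loci are. The β_μ column gives mean-standardized gradients, defined only
for the absolute traits (CL, CW), not for residual claw size.

The reference ten-locus panel (allele counts 9–19, expected
heterozygosities 0.587–0.870, published error rates) ships as
`lobster_locus_table()` / `lobster_panel()`.

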