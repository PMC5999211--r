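---
title: "Methods: parentage-based estimation of mating patterns and sexual selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parentage-based estimation of mating patterns and sexual selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matesel)
```

`matesel` estimates mating patterns and sexual selection in a harvested
lobster population from microsatellite parentage. This vignette explains
the models, the tunable parameters, the synthetic data the package tests
itself against, and the numerical choices that were genuinely open.

## 1. The inference chain

Egg-bearing females are genotyped together with their broods (ten eggs per
female) and a large pool of candidate males. Because the mother of every
egg is known, each egg determines a set of possible paternal alleles per
locus, and paternity assignment reduces to comparing candidate males
through trio likelihoods. Assigned matings then feed three analyses:
size-assortative mating, standardized selection differentials, and
logistic-regression selection gradients on male body size (carapace
length, CL), claw width (CW) and relative claw size (CW residuals on CL).

## 2. Genotype model and error layer

A locus panel stores allele labels, frequencies and two error rates per
locus: allelic dropout (ε₁ — a true heterozygote observed as a homozygote,
each allele surviving with probability ½) and false alleles (ε₂ — each
observed allele independently replaced by a uniformly random panel
allele). The same channel is used by the generator (forward) and by the
paternity likelihood (integrated over true genotypes), so the assignment
model is exactly the observation model of the data it is applied to.
Mother and candidate genotypes are treated as observed; error is
integrated on the egg side only, where DNA quality is poorest. Missing
loci contribute zero to all log-likelihoods.

The default panel reproduces the published per-locus summary
(`lobster_locus_table()`): for each locus the allele frequencies are a
geometric series over the published allele count, with the ratio tuned by
bisection until expected heterozygosity matches the published value
(within 0.005; the tuning is deterministic). Real allele-frequency
spectra are not geometric, but for every quantity the package computes —
heterozygosity, exclusion power, detection power — the spectrum enters
only through low-order frequency sums that the tuning pins down.

## 3. Exclusion and detection power

The second-parent exclusion probability EXP is computed exactly: sum over
the mother's genotype (Hardy–Weinberg weights), the maternally transmitted
allele and a population paternal allele; given the resulting
mother–offspring pair the paternal-allele set *S* is determined and a
random male escapes exclusion only if he carries an allele of *S*, so the
exclusion term is (1 − P(S))². Loci combine as 1 − Π(1 − EXPₗ). On the
published per-locus values this gives 0.9998, reproduced by
`combined_exclusion()` and recomputed by the acceptance script.

Multiple-paternity detection (`detect_multiple()`) is error-free Mendelian
incompatibility with *any* single father. Because a father's genotypes at
different loci are independent, joint single-father satisfiability
decomposes per locus into a two-allele covering problem over the per-egg
paternal-allele sets; the implementation is verified against brute-force
search over all candidate father genotypes. `prdm()` Monte-Carlo-simulates
mother and sires from the panel, allocates eggs multinomially by the
contribution vector and reports the detection fraction. Its analytic
envelope is the sampling bound 1 − Σₖ cₖⁿ (undetectable whenever all
sampled eggs come from one sire); with ten informative loci the 9:1,
ten-egg case sits essentially on the bound (≈0.65), which is why the power
calculation deliberately excludes genotyping error — error could only
blur an already sampling-limited quantity, and the error-free rule keeps
the brute-force oracle exact.

## 4. Assignment confidence

Rather than a full-pedigree posterior, assignment uses the Δ statistic
(best minus second-best candidate log-likelihood) with a threshold
calibrated by simulation (`calibrate_confidence()`): offspring are
simulated with fathers inside the candidate pool at an assumed sampling
fraction, and the threshold is the smallest Δ at which at least 95% of
accepted assignments are correct. Ties (Δ = 0), eggs with
mother-mismatching loci, and candidates that fail to beat the
population-frequency "unsampled father" are never accepted. This
reproduces the *behaviour* of the study's 95% acceptance rule; the
numerical confidence values are not comparable to a pedigree-MCMC
posterior, which is the package's declared deviation. With known mothers
and ten informative loci, per-egg trio assignment loses little: on
error-free synthetic data with complete father sampling it recovers >98%
of eggs and every brood's primary sire.

A brood is accepted as multiply sired only when an egg mismatches the
primary sire at ≥5 loci, carries no mother-mismatch flag, and the
evidence loci are fully observed; 1–4 mismatching loci yield "ambiguous".
These are the study's published acceptance rules and they are intentional
under-callers: the detection-power analysis (§3) quantifies exactly how
much multiple paternity they miss at a 9:1 skew.

## 5. Growth adjustment

Males are often measured a year off the mating year, so measured CL is
adjusted by CL + (Yearₓ − Yearₘ) · ĝ(CL) · p̂(CL), with p̂ a logistic
moult-probability curve and ĝ a linear increment model, both fitted to
mark–recapture records of males captured in consecutive years. A moult is
inferred when the year-to-year difference is ≥5 mm; shrinkage beyond
−5 mm flags a suspect record. The adjustment is a single-step
extrapolation evaluated at the measured CL (not iterated year by year):
the defining formula multiplies the year difference directly, and for the
±1–2-year differences that occur, iteration would change predictions by
less than the increment-model noise. Negative differences subtract
growth. p̂ is not clamped: the fitted curve is trusted over the prior
belief that annual moulting probability stays above one half.

Generator defaults: p(moult) = logit⁻¹(12.36 − 0.0996·CL), which gives
p ≈ 0.97 at 85 mm and p < 0.75 above ~113 mm, and increment
18 − 0.07·CL mm (SD 1.2). The increment line is deliberately kept above
the 5-mm detection threshold across the simulated 60–140 mm range so the
generator is consistent with its own detection rule; otherwise the
threshold left-truncates the increment sample and biases the fitted line
— a real phenomenon in mark–recapture growth data that the package's
recovery tests are not meant to model.

## 6. Selection estimators

Traits are mean-centred and scaled to unit SD within each area–year
group; candidate males are first restricted to CL ≥ 80 mm (a conservative
maturity cut). The selection differential is the mean standardized trait
of successful fathers minus the mean over all candidates, with a
two-tailed Welch t-test (the unequal-variance form is used everywhere —
successful and unsuccessful males have no reason to share a variance).
The gradient models are the standard nine logistic regressions of mating
success on standardized CL, CW and CW residuals with and without area
interactions, ranked by AICc = AIC + 2p(p+1)/(n−p−1). Gradients are
transformed to the approximate selection gradient
β_avggrad = b · mean(ŵ(1−ŵ)) / w̄, which converges to the
Lande–Arnold OLS gradient of relative fitness in the weak-selection limit
(tested); mean-standardized gradients β_μ = β_avggrad · mean/SD are
reported only for CL and CW, because a residual trait has no meaningful
mean. Gradient estimation defaults to males captured in the mating year,
mirroring the study design in which only that cohort represents the
population at reproduction.

Assortative mating is the linear model of adjusted male CL on female CL
and area; the interaction form is compared to the additive form by a 1-df
likelihood-ratio test. Interarea pairs are excluded first. The
within-pair size gap is (CLₘ − CL_f)/CL_f × 100 — "per cent larger than
the female", which is the reading consistent with reporting positive gaps
where males exceed females.

## 7. The synthetic population

The generator draws group sizes, trait distributions and error rates from
the published summaries: carapace length is normal per area × sex (means
99/88/97/92 mm, CVs 0.18/0.15/0.12/0.11 — mean/CV are the only published
moments, making the normal the minimal assumption; sizes are truncated at
zero), claw width follows CW = −27 + 0.82·CL + N(0, 6) (slope and spread
chosen to reproduce the published group means and the r ≈ 0.9 trait
correlation), and each female chooses a sire among her area's males with
probability ∝ exp(b_size·z_CL + b_claw·z_CWres) times a Gaussian kernel
on the male/female size ratio centred at δ (defaults b_size = 0.8,
b_claw = 0.5, δ = 1.2, kernel SD 0.15 — qualitative field knowledge says
"females choose large males"; the functional form is configurable because
no study measures it directly). Broods are multiply sired with
probability 0.02 at a 9:1 skew (the observed rate and skew), with egg
counts multinomial in the contributions. Male capture years spread over
mating-year ± 1 (70% off-year, the published fraction), and measured
sizes are propagated to the mating year through the true moult process,
so growth adjustment has real signal to recover.

What the generator does *not* emulate: spatial structure and movement,
larval dispersal, year-to-year population dynamics, non-normal size
distributions, linkage between loci, and null alleles as a mechanistic
process (apparent homozygote excess arises only through dropout). Passing
tests therefore demonstrate that the estimators recover the truth of this
generating model at field-realistic sizes and error rates — not that the
field data satisfy these assumptions.

Parameter-recovery checks run twenty seeded replicates per quantity
(preference coefficients via the conditional choice likelihood — the
matched estimator whose CIs have nominal coverage; assortative slope;
moult and increment coefficients) and require ≥18/20 CIs to cover the
generating values. Scale choices throughout the test-suite (e.g. 60–240
males per area, 10,000 power replicates, 200–600 calibration replicates)
keep each property statistically sharp while the whole suite completes in
about a minute.

## 8. Numerical choices and degenerate inputs

* HWE exact test: full enumeration of genotype arrays when a cheap upper
  bound on their number (product over heterozygote cells of
  min(aᵢ, aⱼ)+1) stays below 10⁶, otherwise Monte-Carlo allele shuffling;
  array probabilities are compared on the log scale with a 10⁻⁹ slack so
  ties at the observed array are included, matching the two-allele
  closed-form sum.
* Monomorphic loci: EXP = 0, F_IS and F(null) reported as missing,
  HWE p = 1; LD against a monomorphic partner returns p = 1.
* θ permutation p-values use the (hits+1)/(perms+1) estimator; θ itself
  may be slightly negative in undifferentiated samples and is not
  clipped.
* Duplicate detection compares unordered allele pairs, skips loci missing
  in either member, and requires a minimum number of compared loci so
  that missingness cannot manufacture matches; resolution keeps the
  record with fewer missing loci, then the later capture year.
* Complete separation in the moult logistic (e.g. every record moulted)
  falls back to a lightly ridge-penalized fit (λ = 10⁻³) and flags the
  model.
* Degenerate distributions are honoured rather than rejected: CV → 0
  collapses sizes onto the mean, zero claw residual SD makes CW an exact
  line in CL, and a single-sire contribution vector short-circuits
  prDM to exactly 0.

## 9. Known limitations

Per-egg trio assignment ignores sibship information across eggs except
through the known mother, so a handful of eggs can be assigned to a
compatible non-father that outscores the true father by allele-frequency
luck; brood-level primary sires are robust. Unsampled fathers are
represented by the population-frequency father — their genotypes are
never reconstructed, so male mating counts are lower bounds. The
confidence calibration requires an assumed sampled-father fraction; if
that assumption is badly wrong the realized confidence differs from the
nominal 95%. F_IS uses the single-sample form 1 − H_O/H_E rather than the
multi-sample Weir–Cockerham estimator, a third-decimal difference at
these sample sizes.
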