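# aldorecur

Tools for the computational analyses behind the genetic dissection of
early-onset primary aldosteronism (PA) caused by a recurrent
gain-of-function mutation in *CACNA1H*, the gene encoding the Ca_V_3.2
T-type calcium channel. The package is aimed at statistical geneticists
and channel biophysicists who want the complete chain of analyses — from
cohort-level variant statistics to single-channel noise analysis — as
reusable, tested functions, with synthetic-data generators standing in
for raw patient and patch-clamp data.

## What it computes

**Recurrent-mutation significance.** For a variant observed de novo in
several probands, the per-site probability of two or more de novo hits
among *n* cases is the exact binomial tail
P(X ≥ 2), X ~ Bin(n, μ), corrected for the protein-altering exome
target size *T* by multiplication (the Bonferroni-exact form
1 − (1 − P_site)^T is exposed as a cross-check). The probability of *k*
additional carriers among *m* unrelated subjects is Bin(m, q) at an
assumed allele frequency q (the conservative convention equates the
per-subject carrier probability with q itself). Independent sets
multiply. Under Hardy–Weinberg, a cumulative loss-of-function allele
frequency q gives a biallelic frequency q².

**Clinical screening.** The aldosterone:renin ratio (ARR) with censored
laboratory values ("<0.1", ">200") propagated by interval arithmetic,
and the PA screening rule (ARR > 20 ng/dl per ng/ml/hr with aldosterone
> 15 ng/dl; aldosterone/direct renin > 2.4; marginal elevation with
hypokalemia), evaluated conservatively under censoring.

**Cohort variant searches.** Recurrent previously-unreported
protein-altering variants, and per-gene carrier burden versus a control
cohort by two-sided Fisher exact test with Bonferroni adjustment.

**Haplotype sharing and mutation age.** The maximal interval shared by
phased carrier haplotypes around a focal variant; the conservative
unphased bound from homozygous-discordant markers; and a
maximum-likelihood estimate of the generations *g* since the carriers'
common ancestor from the per-carrier, per-side first discordance with
the ancestral haplotype. The ancestral segment survives past marker k
with probability (1 − θ_k)^g (Haldane map); beyond the breakpoint,
alleles match by chance with the population frequencies; marker
mutation adds a (1 − (1 − μ_m)^g) term. Profile likelihood gives the
95% CI.

**Whole-cell electrophysiology.** Peak I–V extraction; Boltzmann
activation fits I(V) = G_max (V − V_rev) / (1 + exp((V_1/2 − V)/k));
mono-exponential inactivation and recovery kinetics; the fraction of
non-inactivated channels after 5-s prepulses; window current as the
overlap of activation and steady-state inactivation curves; and
non-stationary noise analysis, σ² = i⟨I⟩ − ⟨I⟩²/N, with the unitary
current i from the initial slope of the variance–mean relation.

**Simulators.** A deterministic and a stochastic m²h gating model
(exact per-step transition probabilities, so σ² = N i² p(1−p) holds by
construction), a descendant-haplotype generator matching the age
likelihood, and toy cohort variant/lab tables. Calibrated wild-type and
M1549V parameter sets reproduce the benchmark measurements through the
full analysis pipeline.

## Worked example

```r
library(aldorecur)

# How surprising are 2 de novo + 3 inherited occurrences of one variant?
rep <- recurrence_report(recurrence_params(mu_dn = 1.4e-8,
                                           target_bp = 24.75e6,
                                           allele_freq = 1e-5),
                         n_cases_de_novo = 41,
                         n_cases_inherited = 38, k_carriers = 3)
print(rep)
#> Recurrent-mutation significance
#>   P(recurrent de novo, exome-wide, 41 cases): 3.98e-06
#>   P(3 carriers among 38 subjects at q = 1e-05): 8.43e-12
#>   Combined: 3.35e-17

# Screening arithmetic with a censored renin value
print(compute_arr(20, "<0.1"))
#> >200 ng/dl per ng/ml/hr
classify_pa(lab_panel(37, pra = 0.42, potassium = 3.7))
#> Panel: indicative of PA (ARR > 20 with aldosterone > 15 ng/dl); ratio 88.1 ng/dl per ng/ml/hr

# Electrophysiology of the calibrated mutant model
act <- run_activation_fit(default_gating_params("M1549V"))$fit
print(act)
#> Boltzmann activation fit (current mode)
#>   V_half = -44.2 mV,  k = 4.93 mV,  G_max = 5.77 nS (V_rev fixed at 60 mV)
```

The combined probability ~3×10⁻¹⁷ is the chance of seeing the same
variant five times by coincidence; ratios above 20 with aldosterone
above 15 ng/dl flag autonomous aldosterone production; the ~5 mV
hyperpolarizing shift of V_1/2 is the mutant's gain of function.

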