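---
title: "Ancestry-interaction models, partial polygenic scores, and average-effect correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry-interaction models, partial polygenic scores, and average-effect correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Polygenic scores trained in European-ancestry cohorts lose accuracy when
applied to individuals of African ancestry, and it remains contested how
much of that loss reflects genuine gene-by-ancestry interaction rather than
differences in allele frequency and linkage disequilibrium (LD). Recently
admixed genomes — e.g. African American genomes, mosaics of African and
European segments inherited over roughly the past 15 generations — let us
pose the question sharply, because ancestry varies both *locally* (the
ancestral origin of each haplotype segment) and *globally* (the genome-wide
African proportion $\bar a_i$ of individual $i$).

`admixpgs` implements two generative models of individual-level causal
effects in a two-way admixed cohort, simulates phenotypes and polygenic
scores under them, and evaluates the closed-form predictions that make the
models testable.

# The models

For $n$ diploid individuals and $p$ causal variants we carry phased binary
haplotype matrices $X^{(1)}, X^{(2)}$ and matching local-ancestry call
matrices $A^{(1)}, A^{(2)}$ with $a_{ij}^{(h)} = 1$ for African ancestry.
Per variant, a pair of ancestry-specific causal effects is drawn from a
mean-zero bivariate normal
$$(\beta^{Eur}_j, \beta^{Afr}_j) \sim N\!\left(0, \begin{pmatrix}
\sigma^2_{Eur} & \tau \\ \tau & \sigma^2_{Afr}\end{pmatrix}\right),
\qquad
\sigma^2_{Eur} = \frac{r^2}{2\sum_j f^{Eur}_j(1-f^{Eur}_j)},$$
with $\sigma^2_{Afr}$ analogous and
$\tau = r^2\rho \,/\, (2\sqrt{\sum_j f^{Eur}_j(1-f^{Eur}_j)\sum_j
f^{Afr}_j(1-f^{Afr}_j)})$. The parameter $r^2$ is the phenotypic variance
explained by genetic effects in an ancestrally homogeneous cohort, and
$\rho$ the cross-ancestry correlation of causal effects; at $\rho = 1$ the
two effect vectors are exactly proportional (`draw_ancestral_effects()`
uses the conditional decomposition so this holds to machine precision).

The two models differ in how those effects reach an admixed individual:

* **local model** (*cis* interaction): the effect on haplotype $h$ at
  variant $j$ is $\beta^{Eur}_j$ or $\beta^{Afr}_j$ according to the local
  call $a_{ij}^{(h)}$;
* **global model** (non-specific *trans* epistasis, or ancestry-correlated
  G$\times$E): every haplotype of individual $i$ carries the blend
  $\beta^{Eur}_j(1-\bar a_i) + \beta^{Afr}_j \bar a_i$, a continuous
  function of global ancestry.

Phenotypes are built from *demeaned* dosages,
$\hat x_{ij}^{(h)} = x_{ij}^{(h)} - f^{anc(i,j,h)}_j$, subtracting the
allele frequency of the haplotype's local ancestry; this makes every
cumulative quantity invariant to allele labeling. The environmental noise
variance is set per draw to $\max(0, 1 - \widehat{Var}(g))$ with $g$ the
realized genetic component, so each simulated phenotype has approximately
unit variance. We chose per-draw (rather than per-parameter-set)
calibration because it keeps every draw on exactly the same phenotypic
scale; its only cost is a slight negative coupling between the realized
genetic and noise variances, negligible at the problem sizes used.

# Conditional average effects and LAACor

Averaging the individual effects at a variant over all carrier haplotypes
of one local ancestry gives the *conditional average effect*. Under the
local model these are the ancestry-specific effects themselves, so their
correlation across variants equals $\rho$. Under the global model the
carrier averages are blends: with $\omega_2$ (resp. $\omega_4$) the mean
global ancestry over African-call (resp. European-call) carrier haplotypes
and $\omega_1 = 1-\omega_2$, $\omega_3 = 1-\omega_4$,
$$\bar\beta_{j|Afr} = \omega_{1,j}\beta^{Eur}_j + \omega_{2,j}\beta^{Afr}_j,
\qquad
\bar\beta_{j|Eur} = \omega_{3,j}\beta^{Eur}_j + \omega_{4,j}\beta^{Afr}_j,$$
an identity the test suite asserts exactly. The induced covariance
($u_j$, $v_j$, $w_j$ in `prop1_covariance()`) yields the per-variant
local-ancestry average-effect correlation $w_j/\sqrt{u_jv_j}$ — **LAACor**.
Because a single locus's local ancestry predicts global ancestry only
weakly, $\omega_2 - \omega_4$ is small and global-model LAACor sits near 1
even when $\rho$ is modest: high observed average-effect similarity does
not rule out gene-by-ancestry interaction.

We pool variants as $\sum_j w_j / \sqrt{\sum_j u_j \sum_j v_j}$. This is
the population value of the across-variant sample correlation of the
(mean-zero) conditional average effects, which is also how the empirical
counterpart is computed (`empirical_laacor()`); the two are validated
against each other by Monte Carlo rather than against any external
formula. Variants with carriers of only one ancestry are excluded from
pooled quantities, not imputed.

The $\omega$ weights are computed at haplotype level — a haplotype is a
carrier and contributes its individual's $\bar a_i$; a diploid
double-carrier contributes twice. This is forced by defining the
conditional average as the carrier-haplotype mean of the individual
effects.

# Polygenic scores

Tagging effects are obtained from causal effects by the classic scaling
$\beta_j = \beta'_j\,\lambda_j\sqrt{f'_j(1-f'_j)/(f_j(1-f_j))}$ per
ancestry, where $\lambda_j$ is the ancestry-specific haplotypic
correlation between causal and tagging alleles. Effects are treated as
estimated without bias (an additive noise hook exists, off by default),
and we do not re-standardize tagging effects to force the tagging-variant
genetic variance back to $r^2$: the scaled distribution is taken as-is.

Two scores are computed with European effect sizes, as when weights come
from a European-ancestry GWAS:

* `total_pgs()`: weights applied to every demeaned allele;
* `partial_pgs()`: weights applied only where the haplotype's local
  ancestry is European.

With causal variants known, the expected squared score-phenotype
correlations are
$$E[\mathrm{Cor}^2(\mathrm{TotPGS}, y)] \approx r^2(1-\bar a+\rho\bar a)^2
\ \text{(both models)},$$
$$E_{Glo}[\mathrm{Cor}^2(\mathrm{ParPGS}, y)] \approx
r^2(1-\bar a)(1-\bar a+\rho\bar a)^2, \qquad
E_{Loc}[\mathrm{Cor}^2(\mathrm{ParPGS}, y)] \approx r^2(1-\bar a).$$
So the total score cannot distinguish the models, while the partial score
can; under the local model the partial score beats the total one exactly
when $1-\bar a \ge [\rho/(1-\rho)]^2$, i.e. below
$\rho^* = \sqrt{1-\bar a}/(1+\sqrt{1-\bar a})$ (`parpgs_advantage_threshold()`;
0.31 at $\bar a = 0.8$ — we read the threshold from the boundary equality,
which is the only reading consistent with that two-decimal value). These
approximations assume (A) frequencies uniform across markers, (B) a shared
ancestry distribution, (C) concordant haplotype ancestries, (D) small
ancestry frequency gaps and (E) near-independent haplotypes.
`conditions_diagnostics()` reports how far a cohort departs from each;
nothing is enforced, since the forms degrade gracefully and the simulation
drivers confirm them well outside the conditions.

# The synthetic cohort generator

The generator emulates the structure of a large two-way admixed
African/European hospital-biobank cohort:

* **Global ancestry**: i.i.d. Beta(7.48, 1.94). The shapes were fitted
  offline by least squares so the quartile-subgroup means of the Beta
  distribution match the reference cohort's printed values
  (0.61, 0.79, 0.85, 0.92); a two-parameter Beta cannot hit all four
  exactly, and the fit attains (0.62, 0.77, 0.85, 0.93). Only those four
  means are known, so the full distributional shape is our choice; pooled
  LAACor values depend on the implied spread of $\bar a$ (variance
  ~0.016 here).
* **Local ancestry**: `independent` mode draws each call
  Bernoulli($\bar a_i$) i.i.d. across markers — the clean analogue of a
  panel of approximately independent markers, and the mode used by every
  statistical experiment. `tract` mode is a two-state Markov chain along a
  genetic map with relaxation rate `generations` per Morgan (default 15)
  and stationary probability $\bar a_i$, the standard pulse-admixture
  approximation, for users who need realistic tract lengths.
* **Allele frequencies**: Balding-Nichols draws around a
  Uniform(0.05, 0.95) ancestral frequency with default $F_{ST} = 0.15$,
  typical of African-European differentiation; values are clipped to
  [0.01, 0.99] to protect the $1/\sqrt{f(1-f)}$ scalings.
* **Causal-tagging pairs**: per haplotype, the two alleles are drawn from
  the bivariate Bernoulli implied by the ancestry-specific frequencies and
  target $\lambda$; infeasible ($f, f', \lambda$) triples — those whose
  joint $P(1,1)$ would violate the Fréchet bounds — are refused with the
  offending pairs named. The tagging-study driver builds feasible profiles
  by jittering causal frequencies (tightly linked variants have similar
  frequencies) and clipping $\lambda$ draws to the feasible maximum, with
  the clip count reported.
* **Diploids** are two independently simulated haplotypes, consistent
  with assumption (E).

What the generator does **not** emulate: realistic LD beyond each
causal-tagging pair, phasing error, local-ancestry miscalls, relatedness,
assortative mating, or ancestry-correlated environments. Tests passing on
these cohorts therefore validate the statistical machinery and the
closed forms under the stated generative assumptions — not robustness of
the models to real-data artifacts.

# Experiment drivers and problem sizes

`run_sim_study1()` (causal variants known) and `run_sim_study2()` (tagging
variants, with European weights re-estimated from a simulated homogeneous
European panel by default) report mean squared correlations with Monte
Carlo standard errors, overall and by global-ancestry quartile.
`distinguishability_grid()` compares the per-draw squared correlations of
the two models per $(\rho, r^2)$ cell with a two-sided Wilcoxon rank-sum
test at $\alpha = 0.01$ and reports the proportion significant; with
`null = TRUE` both arms come from the same model, which calibrates the
test (rejection proportion $\approx \alpha$). The comparison of per-draw
accuracy distributions is our concrete realization of "distinguishing the
models from score behavior"; no multiplicity correction is applied within
the grid, matching the raw-proportion convention.

Default sizes are scaled to desk hardware as a deliberate design choice:
cohorts of $n = 2{,}000$ and $p = 1{,}000$ independent markers with 100
effect/phenotype redraws for the study drivers; $n = 5{,}000$,
$p = 2{,}000$ and 20 redraws for pooled LAACor evaluations; $n = 400$,
$p = 200$ with 500 comparisons for null calibration of the Wilcoxon test.
All sizes are configurable, and every driver flows all randomness from a
single master seed through named substreams (`derive_seed()`), so results
are bit-reproducible.

# Numerical choices and degenerate inputs

* Correlations are Pearson; zero-variance inputs raise rather than return
  a silent 0, and monomorphic-within-stratum LD raises an undefined-LD
  error.
* Demeaning defaults to sample-conditional frequencies (the quantity
  available in practice); `true_generating` mode exists for oracle tests.
  Variants lacking carriers of one ancestry fall back to the pooled
  frequency on the missing side so demeaning stays defined.
* `wilcox.test()` is used with the normal approximation (arm sizes of 100
  ties are essentially absent for continuous $r^2$ values); all-tied arms
  are skipped and logged via the returned comparison count.
* Subgroup splitting ranks with first-occurrence tie-breaking, giving
  equal-size (within 1) groups regardless of ties.
* Real-data ingestion fixes ancestry coding at 1 = African, treats msp
  windows as closed position intervals, and refuses unphased or
  multi-allelic records by name.

# Limitations

The package evaluates model behavior with *known* generated effects; it
does not estimate $\rho$, $r^2$ or LAACor from phenotype data, perform
GWAS, or train scores. Closed forms for the tagging-variant scenario are
out of scope; tagging behavior is assessed by simulation only. Admixture
is strictly two-way.
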