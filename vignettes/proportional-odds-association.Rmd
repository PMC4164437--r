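---
title: "Reverse-regression association testing with the proportional odds model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse-regression association testing with the proportional odds model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podscore)
```

## The model

Complex disorders are rarely described by a single trait: a study may record
a binary disease status together with quantitative measurements such as blood
pressure or cholesterol, and analyzing the traits jointly is generally more
powerful than testing them one at a time. Jointly modelling traits of mixed
types given the genotype is awkward; **reverse regression** sidesteps this by
swapping the roles of response and covariates. At a biallelic marker the
genotype $G \in \{0, 1, 2\}$ (copies of one allele) is an ordinal trinomial
response, and any collection of $q$ phenotypes — binary, ordinal or
continuous, coded numerically — enters as an ordinary covariate vector $y$.

Assuming allele effects are monotone in dose (over-dominance is rare), the
natural ordinal model is the proportional odds (cumulative logit) model:
$$
\operatorname{logit} P(G = 0 \mid y) = \alpha_1 + \beta^\top y, \qquad
\operatorname{logit} P(G \le 1 \mid y) = \alpha_2 + \beta^\top y,
$$
with $\alpha_1 < \alpha_2$ and a single slope vector $\beta$ shared across
cut-points (the "proportional odds" property: the covariate effect on the
cumulative log-odds does not depend on the cut-point). No additive, dominant
or recessive assumption on the genetic effect is needed. The association
null hypothesis is $H_0\!: \beta = 0$ against $H_1\!: \beta \neq 0$,
a $q$-degree-of-freedom test whatever mixture of trait types is supplied.

The sign convention above attaches $+\beta^\top y$ to the *lower* cumulative
probabilities; the test statistics below are invariant to this choice, which
only flips the sign of the reported $\hat\beta$.

## The score test

Under $H_0$ the model collapses to a plain trinomial, whose MLEs are the
sample genotype proportions $\hat p_0, \hat p_1, \hat p_2$, with cumulative
proportions $\hat\gamma_1 = \hat p_0$ and
$\hat\gamma_2 = \hat p_0 + \hat p_1$. Differentiating the log-likelihood in
$\beta$ at $(\hat\alpha_1, \hat\alpha_2, 0)$ assigns each genotype category
the weight
$$
c_0 = 1 - \hat\gamma_1, \qquad
c_1 = 1 - \hat\gamma_1 - \hat\gamma_2, \qquad
c_2 = -\hat\gamma_2,
$$
which satisfy $\sum_j \hat p_j c_j = 0$ exactly. The score vector and its
null variance are
$$
U = \sum_i c(G_i)\,(y_i - \bar y), \qquad
V = \bar w \sum_i (y_i - \bar y)(y_i - \bar y)^\top, \qquad
\bar w = \sum_j \hat p_j c_j^2,
$$
and the statistic $T = U^\top V^{-1} U$ is asymptotically
$\chi^2_q$ under $H_0$. $U$ is a contrast of phenotype sums weighted by
genotype category, so $T$ needs one pass over the data and no iterative fit
— the property that makes it practical genome-wide. Because the weights sum
to zero, centring $y$ is a no-op algebraically (we centre anyway for
numerical stability), and $T$ is invariant under any affine transform
$y \mapsto Ay + b$ and under allele relabelling $G \mapsto 2 - G$ (which
maps the weights to $(-c_2, -c_1, -c_0)$).

Rather than trusting the weight algebra, the test suite pins it to the
likelihood: on random instances the analytic $U$ must equal the central
difference numeric gradient of `po_loglik()` at the null MLE to relative
tolerance $10^{-6}$, and the full analytic gradient/Hessian used by the
Newton fitter is checked against numeric differentiation away from the null
as well.

The likelihood-ratio test (`po_lrt()`) fits the alternative by
Newton–Raphson and refers $2(\ell_1 - \ell_0)$ to $\chi^2_q$. It is
asymptotically equivalent to the score test; the score test is the cheap
one.

## Power for case-control designs

When the phenotype is a single case indicator, everything is analytic.
A single-locus disease model is specified by the risk-allele frequency $p$
(genotype frequencies $q_j$ by Hardy–Weinberg equilibrium), the prevalence
$K$, and genotype relative risks $(1, R_1, R_2)$. Penetrances follow from
$f_j = R_j f_0$ and $K = \sum_j q_j f_j$; Bayes inversion gives the genotype
distributions in cases, $q_j f_j / K$, and controls, $q_j(1-f_j)/(1-K)$.
With a fraction $\phi$ of cases in a sample of $n$, the pooled genotype
distribution determines the score weights $c_j$ and $\bar w$ as above, and
the non-centrality parameter of $T$ is
$$
\lambda = n\,\phi(1-\phi)\,
  \frac{\bigl[\sum_j (g^{case}_j - g^{ctrl}_j)\, c_j\bigr]^2}{\bar w},
$$
so power at level $\alpha$ is the upper tail of the noncentral
$\chi^2_1(\lambda)$ beyond the central $1-\alpha$ quantile
(`power_from_ncp()`, computed with R's noncentral chi-square, not a normal
approximation). $\lambda$ is linear in $n$ and maximal at $\phi = 1/2$.

The bundled model grid (`analytic_study_models()`) crosses prevalences
$K \in \{0.01, 0.1\}$ with allele frequencies and risk presets
recessive $(1, 1, 1.5)$, additive $(1, 1.25, 1.5)$, dominant
$(1, 1.5, 1.5)$. Each preset keeps $R_2 = 1.5$ fixed and varies how the
heterozygote shares the risk, so the three modes are comparable at equal
"top" effect size. A notable consequence, reproduced by the power study:
for recessive models the reverse-regression test is *less* powerful than
Pearson's chi-square or the Cochran–Armitage trend test, because the
proportional-odds weights are poorly matched to a penetrance pattern that
separates genotype 2 from genotypes 0 and 1 when the risk allele is not
rare. The method's appeal is multivariate phenotypes, not single binary
traits.

## What the simulators emulate

`simulate_case_control()` draws genotype counts multinomially from the
case/control genotype distributions above — exactly the population the NCP
formula describes, so the mean of simulated $T$ must match $1 + \lambda$
(checked within Monte-Carlo error).

`simulate_multiphen()` emulates a cohort with three phenotypes and one QTL:
$G \sim \mathrm{Binomial}(2, \mathrm{maf})$ under HWE, and each associated
phenotype $k$ is $y_k = b_k\beta(G - 2\,\mathrm{maf}) + e_k$ with residuals
$e$ trivariate normal, unit variances, and a single common pairwise
correlation $r_E$ (equicorrelation). Directions are $b_1 = b_2 = +1$ with
$b_3$ switchable to $-1$. Centring $G$ at its population mean gives the
variance-explained calibration a closed form:
$\beta^2 = h / \bigl((1-h)\,2\,\mathrm{maf}(1-\mathrm{maf})\bigr)$ for a
target fraction $h$ (`effect_var`). Scenario presets associate phenotype 1
(scenario I), phenotypes 1–2 (II) or all three (III).

Defaults `n = 1000` and `effect_var = 0.005` (0.5% of trait variance per
associated phenotype — a realistic single-SNP effect for a complex trait)
were fixed once to put power in a usefully discriminating 0.1–0.7 range at
$\alpha = 0.005$; the multiphenotype study asserts the *equivalence* of
score and LRT power cell by cell and the exact symmetry of scenario I in
$b_3$, not absolute power values, which depend on these two knobs.

These generators idealize real data: one marker at a time (no linkage
disequilibrium), Hardy–Weinberg genotypes, Gaussian equicorrelated
residuals, no covariates, ascertainment only of the case-control type.
Passing studies therefore demonstrate correctness of the statistics under
the stated models, not robustness to population structure, non-normal
traits, or covariate confounding.

## Numerical choices

* **Variance scaling.** $V$ uses the sum-of-squares form with $\bar w$
  from sample proportions (a $1/n$ convention); an $1/(n-1)$ choice differs
  by $O(1/n)$ and is immaterial at GWAS sample sizes — the type-I-error
  study at $n = 2000$ validates the calibration.
* **Newton–Raphson** (`po_mle()`): analytic gradient and Hessian,
  initialization at the closed-form null fit, step-halving whenever a step
  does not increase the likelihood, convergence at gradient max-norm
  $< 10^{-8}$, at most 50 iterations. Parameter values that invert the
  cut-point order or zero out an observed category return $-\infty$
  likelihood so that step-halving retreats. Quasi-separation is flagged by
  a slope-norm guard ($\lVert\beta\rVert > 10^3$); the achieved likelihood
  is still usable for an LRT. Duplicated $(G, y)$ rows (binary traits) are
  collapsed to frequency weights, making each iteration $O(\text{unique
  rows})$.
* **Degenerate inputs.** Monomorphic markers yield a flagged `NA` result,
  never an exception, so scans proceed. Singular phenotype scatter
  (collinear traits) is a hard error by default; `pseudo_inverse = TRUE`
  switches to the Moore–Penrose inverse with rank-adjusted degrees of
  freedom. Missing genotypes or phenotype entries are removed per variant
  (complete-case), with the dropped count reported.
* **Genotype coding.** Integer 0/1/2 only; imputed dosages are rejected —
  the trinomial likelihood has no natural fractional-category extension.
  VCF genotypes count ALT alleles by default (`count_ref` flips); all
  statistics are invariant to the flip.
* **Reproducibility.** Every simulator and study takes a seed and is a
  pure function of (parameters, seed); study TSVs are byte-identical
  across runs. The multiphenotype study derives one RNG stream per grid
  cell from the master seed and the parameters that actually enter the
  generator, so results are independent of grid order and scenario I is
  *exactly* invariant to $b_3$.

## Study problem sizes

The default study sizes were chosen so that the full suite exercises every
claim at meaningful Monte-Carlo resolution while remaining routine to run:
type-I error at 2,000 replicates per null model (binomial SE at level 0.1
is 0.007; a 10,000-replicate mode is a flag away), power studies at 2,000
replicates, and the multiphenotype score-vs-LRT comparison at 1,000
replicates per grid cell, mirroring the replicate count at which that
equivalence is conventionally reported. The analytic NCP/power surface is
exact and instantaneous.

## Limitations

* Covariate adjustment is out of scope: phenotypes are the only
  covariates in the cumulative logit.
* The proportional-odds assumption itself is not tested; if it is a
  concern, a multinomial (non-proportional) logit is the classical
  alternative, and for a 2×3 case-control table its score test coincides
  with Pearson's chi-square, which the package already provides.
* Only the case-control specialization of the non-centrality parameter is
  analytic; power for multivariate phenotype designs is estimated by
  Monte-Carlo.
* Permutation p-values, exact small-sample tests, LD-aware multi-marker
  models, and binary PLINK/BGEN formats are not provided.
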