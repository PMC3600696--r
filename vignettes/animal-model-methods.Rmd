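---
title: "Pedigree-based quantitative genetics for an F2 intercross: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based quantitative genetics for an F2 intercross: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(f2qg)
```

## The problem

An F2 resource population crosses two founder lines that diverge strongly in
the traits of interest — here, a minipig line predisposed to obesity against
lean production breeds — so that trait-affecting alleles segregate maximally
in the second generation. Before any gene mapping is attempted, the genetic
architecture of the measured traits has to be quantified: how much of the
phenotypic variation is additive-genetic (heritability), how traits co-vary
genetically (genetic correlations), and whether the design has the power to
detect loci of realistic effect size. `f2qg` implements that entire analysis
chain — pedigree machinery, REML animal models, derived obesity traits, and
F2 QTL power — together with a gene-drop simulator of the three-generation
design, so every stage can be validated by parameter recovery even though
the original study data are not publicly deposited.

## The animal model

For a single trait the model is

$$ y = X\beta + Z a + e, \qquad
   a \sim N(0, A\sigma^2_a), \quad e \sim N(0, I\sigma^2_e), $$

where $\beta$ holds the intercept, sex, season-of-birth (a three-level batch
factor), a regression on age at measurement, and — for mass-type traits
where the founder lines differ in conformation — a regression on body
length. $A$ is the additive (numerator) relationship matrix of the pedigree,
computed by the tabular method; its diagonal is $1 + F_i$ with $F_i$ the
inbreeding coefficient. Heritability is $h^2 = \sigma^2_a/(\sigma^2_a +
\sigma^2_e)$.

Two traits are analysed jointly by stacking the per-trait systems
block-diagonally, with

$$ \mathrm{var}\begin{pmatrix} a_1 \\ a_2 \end{pmatrix}
   = G \otimes A, \qquad
   \mathrm{var}(e) \text{ diagonal per trait, with covariance } \sigma_{e12}
   \text{ only for animals recording both traits}. $$

The genetic correlation is $r_g = \sigma_{a12}/\sqrt{\sigma^2_{a1}
\sigma^2_{a2}}$ and the phenotypic correlation
$r_p = (\sigma_{a12}+\sigma_{e12}) / \sqrt{(\sigma^2_{a1}+\sigma^2_{e1})
(\sigma^2_{a2}+\sigma^2_{e2})}$.

### REML estimation

Variance components maximize the restricted log-likelihood
$-\tfrac12[\log|V| + \log|X^\top V^{-1} X| + y^\top P y]$ with
$V = ZAZ^\top\sigma^2_a + I\sigma^2_e$. The optimizer runs a few
expectation-maximization (EM) iterations from the safe starting value
$\sigma^2_a = \sigma^2_e = \tfrac12 \hat\sigma^2_{OLS}$ — EM cannot decrease
the likelihood, which the test suite asserts on a hundred random datasets —
and then switches to average-information (AI) updates, which converge
quadratically. Any AI step that would decrease the likelihood or leave the
feasible region is halved up to ten times and finally replaced by one EM
step. Convergence requires a relative likelihood change below $10^{-9}$ and
a maximum relative parameter change below $10^{-6}$; fits whose likelihood
has been flat for three consecutive iterations while a parameter sits on a
constraint (a variance at its floor, a correlation at its admissibility cap)
are reported as converged boundary solutions. Non-convergence is a flag on
the result, never an exception.

In the bivariate fit the two univariate solutions serve as warm starts, so a
single EM pass replaces the univariate EM phase before AI updates begin;
the EM fallback for a failed AI step is the matrix-form EM update of $G$
and $R$ built from the conditional moments $E[u^\top A^{-1} u \mid y]$ and
$E[ee^\top \mid y]$. Feasibility is enforced directly on the components —
variances floored at $10^{-6}$ of the phenotypic variance, correlations
capped at $\pm 0.999$ — with step halving, which keeps the AI matrix
expressed in the natural parameters; its inverse at the optimum is the
sampling covariance used for all standard errors.

Standard errors of $h^2$, $r_g$ and $r_p$ come from the first-order delta
method applied to that sampling covariance; the tests check them against
numeric-gradient propagation at $10^{-8}$. When a genetic variance is
estimated at the floor the genetic correlation is undefined and reported
missing. Breeding values (EBVs) for every pedigree animal — unphenotyped
founders included — solve Henderson's mixed-model equations at the REML
estimates, using the sparse A-inverse assembled by Henderson's rules with
inbreeding; prediction-error variances come from the inverse coefficient
matrix.

Heritabilities can be estimated by the univariate model or read off any
bivariate model containing the trait; following standard practice for this
design, `select_heritability()` returns the candidate with the smallest
standard error, ties going to the univariate fit.

## What the simulator emulates

`simulate_design()` rebuilds the three-generation structure: 14 founder
boars of the obese minipig line mated pairwise to 7 + 7 sows of two lean
breeds (28 F0), 127 F1 born in 14 litters, 81 F1 selected as parents
(roughly one sire per two dams, sires never mated to litter-mates, each
serving one or two litters where feasible), 474 F2 born in litters of 2–12,
5 early deaths and 15 removals leaving 454 retained animals, three
season-of-birth cohorts of about 250/124/100, and per-timepoint measurement
ages drawn truncated-normal at the design spreads (64 ± 11 d at the
two-month scan, 115 ± 27 d, 220 ± 45 d). These defaults are the study
conditions and are not adjusted per analysis; every count is configurable
for other designs. The study reported 474 born, 469 alive at five weeks and
454 analysed; the simulator exposes the early-death and removal counts as
separate configuration fields rather than guessing which subset the
removals came from.

`simulate_breeding_values()` gene-drops breeding values: founders from
$N(0, G)$, descendants as the parent average plus a Mendelian-sampling
deviate with variance $(0.5 - 0.25(F_s + F_d))\,G$, so the realized vector
has covariance $A \otimes G$ exactly (verified against the tabular $A$ by
replicated simulation). Phenotypes add configured sex, season and age
effects, optional length covariates, founder-line mean offsets inherited as
mid-parent expectations, and per-animal residuals from $N(0, R)$;
missingness is a per-trait observed count applied at random within the
retained generation (the fasting-glucose scenario keeps 146 of 454).

Two deliberate simplifications matter when interpreting recovery results.
Line divergence is modelled as a fixed founder-line offset, not extra
genetic variance; since the analysis model omits line (as the study's model
does), a non-zero divergence inflates apparent additive variance — that is
the design's purpose, and the recovery scenarios therefore set divergence
to zero so the generating heritability is the estimand. And with only 28
founders the realized genetic variance fluctuates substantially between
replicates, so single-replicate estimates scatter widely (occasionally to
the $h^2 = 1$ boundary) even though the replicate mean is unbiased; the
recovery checks are therefore stated on means over 30–100 replicates. The
simulator contains no selection, no dominance or epistasis, no maternal or
litter environmental effects, and no marker genotypes, so passing recovery
tests demonstrates correctness of the estimation machinery under the
additive model, not robustness to effects outside it.

## Derived traits

Lean-meat percentage uses the optical-probe prediction equation
$66.7393 - 0.2655\,X_1 - 0.5432\,X_2 + 0.0838\,X_3$ (backfat depths at two
positions and muscle depth, mm); probe measurements taken at reflectance
strictly above 65 are set missing, since the probe misreads very fat
carcasses. BMI is weight/length² with length in metres — the human
convention, which reproduces the magnitudes of the reference tables, whose
printed unit is internally inconsistent — and the body adiposity index is
abdominal circumference/length^1.5 with both in cm. Daily gains are slopes
of the weight record: whole period, birth to weaning, weaning to slaughter;
because the study weaned at six to eight weeks without stating which record
anchors the split, the boundary defaults to the recorded weight nearest 42
days and is configurable. Descriptive tables report the sample SD (n−1) and
CV = 100·sd/mean over non-missing values. Outlier screening beyond the
reflectance rule is deliberately manual: values beyond 4 SD are flagged for
review, not removed.

## QTL power

For an F2 intercross the single-locus test has noncentrality
$\lambda = n p/(1-p)$, with $p$ the fraction of phenotypic variance
explained by the locus (a genetic-variance fraction is converted by
multiplying by $h^2$). Imperfect map coverage shrinks $\lambda$ by
$(1-2r)^2$, the squared QTL–marker correlation with the marker half a
spacing away under the Haldane map. Power is the upper tail of a noncentral
$\chi^2$ (1 df additive, 2 df with dominance) past the threshold implied by
the significance level; genome-wide control uses a Šidák correction across
`genome_length/spacing` effective tests, defaulting to a 2300 cM, 18
autosome pig map at 1 cM spacing. Those defaults are echoed into every
report because the original study named its software but not its
assumptions; for the same reason the package validates power against its
own Monte-Carlo rejection-rate oracle rather than against any printed power
claim. Heritabilities of categorical traits convert to the liability scale
by the Dempster–Lerner factor $p(1-p)/z^2$.

## Numerical choices

* Variance floor $10^{-6} \times$ phenotypic variance; correlation cap
  $\pm 0.999$. Estimates on these bounds are flagged.
* Reference coding for factors with the alphabetically first level as
  reference; covariates centered. Variance components are invariant to this
  choice; fixed-effect solutions are reported in that parameterization.
* The residual covariance of a trait pair is estimated only from animals
  recording both traits and fixed at zero (with a warning) when fewer than
  ten animals overlap.
* The tabular $A$ is stored dense (populations here are a few hundred
  animals; a configurable ceiling of 5000 guards against accidental huge
  pedigrees), $A^{-1}$ sparse. Topological sorting is stable, so outputs
  are reproducible run to run.
* One global seed drives every simulation; per-stage seeds are derived
  deterministically from it, making whole pipeline runs byte-identical.

## Problem sizes used in validation

The packaged checks run univariate recovery on 50 replicates of the full
454-animal design (and 100 replicates of the 146-animal glucose subset),
bivariate recovery on 30 replicates, oracle equivalence of AI-REML against
a 200×200 grid search with local refinement on 30-animal datasets, EM
ascent on 100 random small datasets, and Monte-Carlo power comparisons at
2000 simulated datasets per design point. These sizes give Monte-Carlo
standard errors comfortably below the stated tolerances (for example,
the mean of 50 replicate $\hat h^2$ has standard error ≈ 0.02 against a
±0.05 band).

## Known limitations

Multi-trait models beyond two traits are out of scope (the study's own
attempt hit singularity problems); there are no maternal, litter or
dominance components; the power module covers single-QTL detection, not
interval-mapping thresholds by permutation; and the REML engine targets
populations of hundreds, not national evaluations — all matrices involved
fit comfortably in memory at that scale.
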