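# f2qg — quantitative genetics of F2 intercross resource populations

`f2qg` is an R package for the pedigree-based quantitative-genetic analysis
of F2 intercross designs, built around the classic divergent-founder pig
obesity resource population: an obese minipig line crossed with lean
production breeds, 28 F0 founders, 81 F1 parents and 454 phenotyped F2
animals (a 563-animal analysis pedigree). It is aimed at quantitative
geneticists characterizing such a population before QTL mapping or GWAS:
how heritable is each trait, how do traits co-vary genetically, and does the
design have the power to detect realistic loci?

The core is the **animal model** fitted by REML:

y = Xβ + Za + e,  a ~ N(0, A σ²ₐ),  e ~ N(0, I σ²ₑ)

with A the pedigree additive-relationship matrix, and its bivariate
extension var(a₁, a₂) = G ⊗ A for genetic correlations. Estimation uses EM
warm starts followed by average-information (AI) REML; h², r_g and r_p get
delta-method standard errors from the inverse AI matrix, and BLUP breeding
values come from Henderson's mixed-model equations with the sparse
A-inverse. Around that core the package provides:

* pedigree parsing/validation, inbreeding, tabular A, Henderson A⁻¹,
  pruning to phenotyped animals plus ancestors;
* a gene-drop simulator reproducing the three-generation design (litters,
  season-of-birth cohorts, measurement-age schedules, trait-specific
  missingness) for testing every stage by parameter recovery;
* derived obesity traits: the lean-meat probe equation, reflectance
  filtering, BMI, body adiposity index, daily gains, descriptive tables;
* analytic F2 QTL-detection power with genome-wide Šidák thresholds, map
  attenuation, and Dempster–Lerner liability-scale conversion;
* a configuration-driven pipeline (`run_pipeline()`) writing descriptive,
  heritability, correlation, EBV and power reports, plus a thin CLI at
  `inst/cli/f2qg.R`.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` / `autoplot()` methods on fitted models.

## Worked example

Simulate the reference design with a fat-percentage-like trait of true
h² = 0.57, fit the animal model, and predict breeding values:

```r
library(f2qg)

design <- simulate_design(design_config(), seed = 42)
arch <- genetic_architecture(
  "dxa_fat_pct", var_p = 1, h2 = 0.57, means = c(dxa_fat_pct = 18.6),
  fixed_effects = list(dxa_fat_pct = list(
    sex = 0.3, sob = c(0, 0.2, 0.4), age_slope = 0.01, age_column = "age_m2")))
sim <- simulate_phenotypes(design, arch, seed = 42)

ped    <- prune_to_phenotyped(design$pedigree, sim$phenotypes$animal)
relmat <- relationship_matrix(ped)

fit <- sim$phenotypes |>
  build_design(trait_spec("dxa_fat_pct"), ped = ped) |>
  reml_univariate(relmat)
fit
#> <f2qg_reml> univariate animal model for 'dxa_fat_pct'
#>   sigma2_a = 0.4349, sigma2_e = 0.5244, h2 = 0.453 (SE 0.118)
#>   logLik = -197.9248, converged = TRUE

tidy(fit)
#> # A tibble: 3 × 3
#>   term     estimate std.error
#>   <chr>       <dbl>     <dbl>
#> 1 sigma2_a    0.435    0.140
#> 2 sigma2_e    0.524    0.0920
#> 3 h2          0.453    0.118

head(predict_ebv(fit), 3)
#> # A tibble: 3 × 5
#>   animal trait          ebv   pev accuracy
#>   <chr>  <chr>        <dbl> <dbl>    <dbl>
#> 1 F0B01  dxa_fat_pct -0.340 0.301    0.555
#> 2 F0B02  dxa_fat_pct  0.181 0.302    0.553
#> 3 F0B03  dxa_fat_pct -0.280 0.310    0.537
```

The single-replicate estimate (0.45 ± 0.12) scatters around the generating
value 0.57 — with only 28 founders the realized genetic variance varies
between replicates; across 50 replicates the mean estimate recovers the
truth (see the acceptance script below). Unphenotyped founders receive
EBVs shrunk from progeny information.

Power of this design for a QTL explaining 5% of phenotypic variance, at a
genome-wide 5% threshold on a 2300 cM / 1 cM map:

```r
f2_qtl_power(n = 454, var_fraction = 0.05)
#> power 0.725, noncentrality 23.4, threshold 17.98 (df 1)
f2_sample_size(0.8, var_fraction = 0.05)
#> [1] 501
```

Full pipeline runs are driven by a YAML config (see `default_config()`):

```r
res <- run_pipeline(default_config(), output_dir = "results", seed = 1)
```

writing `descriptives.tsv`, `heritability.tsv` (univariate and lowest-SE
selection), `correlations.tsv` (r_g above the diagonal, r_p below, SEs in
parentheses), EBV tables and histogram data, `power.tsv`, a full-precision
`fits.json`, and a `manifest.json` with the seed and config hash — the same
config and seed reproduce the bundle byte for byte.

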