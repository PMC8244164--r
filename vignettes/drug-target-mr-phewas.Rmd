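---
title: "Sex-specific drug-target MR phenome scans: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-specific drug-target MR phenome scans: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrphewas)
```

## The problem

Drug-target Mendelian randomization uses genetic variants in (or near) a
drug's target gene as lifelong proxies for pharmacological modulation of
that target: a variant in *HMGCR* that lowers LDL-cholesterol mimics statin
treatment, a variant in *PCSK9* mimics PCSK9 inhibition, and so on. Because
alleles are randomly allocated at conception, associations of such variants
with downstream phenotypes are largely free of the confounding that plagues
observational drug-effect studies. Scanning one instrument (or a small
correlated panel, or a polygenic exposure score) against hundreds or
thousands of phenotypes — a phenome-wide association study, PheWAS — and
doing so separately in men and women, surfaces candidate pleiotropic drug
effects and candidate sex differences.

`mrphewas` implements that design end to end over GWAS *summary statistics*
only: readers for tab-separated association tables, allele harmonization,
instrument pruning, the causal estimators, phenome filtering with
family-wise control, anchor-scaled reporting, and the sex-difference test.
A seeded generator of synthetic summary statistics with known ground truth
exists so that every statistical claim the package makes can be tested as a
calibration property rather than taken on faith.

## Models and estimators

### Wald ratio

For a single instrument, the causal effect of exposure $X$ on outcome $Y$ is
estimated by the Wald ratio
$\hat\beta = \hat\beta_{Y}/\hat\beta_{X}$ with first-order standard error
$\mathrm{se}(\hat\beta_Y)/|\hat\beta_X|$. Exposure-side uncertainty is
ignored (the usual no-measurement-error convention); with the strong
instruments this design assumes, the neglected second-order delta-method
term is at the percent level, and the tests verify that.

### IVW with correlated instruments and multiplicative random effects

With $J \ge 2$ instruments, per-variant effects are combined by generalized
weighted least squares through the origin. Writing $x_j, y_j$ for the
harmonized exposure and outcome betas, $s_j$ for the outcome standard
errors and $\rho_{jk}$ for the signed correlation between variants $j$ and
$k$:

$$\Omega_{jk} = s_j s_k \rho_{jk}, \qquad
  \hat\beta = (x^\top \Omega^{-1} x)^{-1} x^\top \Omega^{-1} y .$$

With $\rho = I$ this reduces exactly to the textbook fixed-effect IVW
weighted mean of Wald ratios with weights $x_j^2/s_j^2$; the test suite
asserts the equality against an independently coded scalar route, and the
correlated case against a Gaussian-elimination GLS solve written for the
tests.

Heterogeneity between instruments is absorbed by *multiplicative random
effects*: with residual sum $Q = (y - x\hat\beta)^\top \Omega^{-1}
(y - x\hat\beta)$, the dispersion is $\phi = \max(1, Q/(J-1))$ and the
standard error is inflated by $\sqrt\phi$. The floor at 1 means
homogeneous data fall back to the fixed-effect error rather than being
anti-conservatively shrunk. Random effects are applied when $J \ge 3$; at
$J = 2$ there is effectively no residual degree of freedom for a dispersion
estimate, so the fixed-effect error is reported and the method label says
so (`ivw_fixed`). A single instrument dispatches to the Wald ratio. This
dispatch is what `mr_estimate_auto()` (and hence the scan) uses.

Near-singular $\Omega$ — practically, two instruments in near-perfect LD —
is a hard error naming the offending pair (condition number above $10^8$),
never a silent ridge fix: the right response is pruning, and silently
regularizing would misstate the effective instrument count.

### MR-Egger

MR-Egger refits the same weighted regression *with* an intercept after
orienting all pairs to positive exposure effects. The intercept estimates
the average directional pleiotropy (instrument effects on the outcome that
bypass the exposure); its two-sided test is the pleiotropy alarm, and the
slope remains a consistent causal estimate when the exclusion restriction
fails in this directional way. Dispersion is $\phi = \max(1, Q/(J-2))$.
When a correlation matrix is present the same $\Omega$ is used; since the
classical Egger formulation assumes independent instruments, estimates made
on a correlated panel carry a `correlation_adjusted` flag in the output.

P-values and confidence intervals use the standard normal reference
everywhere, not Student-t: one convention, stated, rather than a silent mix.
The t-quantile alternative would widen $J=3$ Egger intervals considerably;
anyone wanting it can form intervals from the reported `se_hat`.

### Multivariable MR

`mr_mvmr()` regresses outcome betas on several exposures' beta columns
jointly (no intercept, weights $1/s_j^2$, $\phi = \max(1, Q/(J-E))$),
separating direct effects — the classic use here being a drug-target effect
on basal metabolic rate adjusted for BMI. Rank-deficient exposure matrices
are an error naming the collinear columns. An exposure column that is
entirely zero is dropped with a warning and reported as `NA` (its direct
effect is unidentified); with one usable column the fit reduces exactly to
univariable IVW, which the tests assert.

### Binary traits: the case-fraction odds-ratio conversion

Biobank GWAS of binary traits are commonly fitted by *linear* regression on
the 0/1 indicator. For presentation, such linear-probability estimates are
converted to odds ratios by

$$\log \mathrm{OR} = \frac{\beta}{k(1-k)},$$

where $k$ is the case fraction; the standard error scales identically, so
the interval is symmetric on the log-odds scale. The conversion is exactly
invertible (`or_to_linear_beta()`), and its adequacy is tested by
regenerating individual-level data at prevalences 0.1–0.5 and comparing
against logistic fits: agreement is at the $10^{-3}$ level for the small
per-allele effects this design produces. Significance in the scan is always
flagged on the linear-scale p-value — the conversion is presentation only.

## Harmonization and pruning

The Wald ratio only makes sense when numerator and denominator refer to the
same allele. `harmonize()` re-expresses each outcome association on the
exposure's effect allele: direct matches pass through, swapped alleles
negate the beta and flip the frequency, and strand complements are resolved
before the same rule. Palindromic variants (A/T, C/G) cannot be resolved
from alleles at all; they are kept only when both effect-allele frequencies
fall outside $0.5 \pm w$ *and* on the same side of 0.5, otherwise dropped
as ambiguous. The window default $w = 0.08$ follows common two-sample MR
practice; the choice is exposed as a parameter because no single value is
canonical. Harmonization is idempotent, and every exclusion carries a
reason code — nothing is dropped silently.

`ld_prune()` reduces a panel to approximate linkage independence: variants
are taken in ascending exposure p-value order (lexicographic id as the
tie-break, so the result is reproducible) and kept iff their squared
correlation with every already-kept variant stays below the threshold
(default $r^2 < 0.01$, the "independent variants from different genomic
regions" convention). On panels of up to six variants the tests compare the
result against exhaustive subset enumeration.

## The phenome scan

`filter_phenotypes()` applies the inclusion rules in a fixed order, each
exclusion recorded with its first matching reason: duplicates; binary
phenotypes with fewer than 100 cases; continuous/ordered phenotypes with
$n < 10{,}000$ (strictly less than — $n = 10{,}000$ is kept); ICD-coded
binary phenotypes lacking a main code or carrying an external-cause code
(Z00–Z99 by default); and categories on a configurable exclusion list
(family history, lifestyle, administrative fields and the like — the list
is a config input because no canonical machine-readable list exists). The
rule *order* affects only the recorded reasons, never the kept set, and
filtering is invariant to manifest row order. The number kept, $N_p$, is
the Bonferroni denominator: the family-wise threshold is $\alpha/N_p$,
reported at full precision and at two significant figures (e.g.
$0.05/1701 = 2.9\times10^{-5}$).

Because a manifest row being "ICD-coded but lacking a main code" is not
derivable from a missing code alone, the manifest carries an explicit
logical `icd_coded` column (defaulting to `!is.na(icd_code)`).

`run_phewas()` then estimates every target × phenotype × stratum
combination with `mr_estimate_auto()`, flags significance at $\alpha/N_p$,
converts binary-trait estimates for presentation, and emits the long
results table, the per-category significant-hit counts, a Manhattan-style
table, the exclusion ledger, and a skipped-combination log (a missing
stratum file is logged, never silent). Because "number of significant
associations" can be counted over phenotypes or over phenotype × stratum
pairs, the summary reports both.

Effect sizes are reported *anchor-scaled*: each estimate divided by the
absolute effect on an anchor phenotype (conventionally LDL-c) in the same
target and stratum, so the anchor row reads $\pm 1.00$ exactly and every
other effect reads as a fraction of the LDL-c effect. Scaling is free of
the exposure units (the tests assert invariance under rescaling).

The sex-difference test is the two-sided z-test
$z = (\beta_m - \beta_w)/\sqrt{s_m^2 + s_w^2}$, applied to the *unscaled*,
SE-bearing estimates — scaled relative effects have no attached standard
error, so a z-test on them would be meaningless. Sex-difference p-values
are reported raw alongside the Bonferroni-gated main associations, not
themselves multiplicity-corrected, and the same test serves primary vs
replication comparisons (`compare_replication()`). When only an effect and
a p-value are available from a printed table, `se_from_beta_p()` recovers
the implied standard error by inverting the normal tail, accepting log10
p-values for entries below double underflow (published tables print values
down to $10^{-324}$).

## What the generator emulates — and what it does not

`synthetic_truth()` + `simulate_pair()` draw two-sample summary statistics
under the linear model

$$\beta_{Y,j} = \theta\,\beta_{X,j} + \alpha_j + \varepsilon_j, \qquad
  \alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2), \quad
  \varepsilon \sim N(0,\; D\rho D),$$

with $D = \mathrm{diag}(s_j)$, $s_j = 1/\sqrt{2p_j(1-p_j)n}$ for allele
frequency $p_j$ and GWAS size $n$. Exposure betas are *conditioned on* —
fixed across replicates within a scenario — matching the two-sample
convention of treating instrument–exposure associations as known up to
their standard error; they are drawn once per scenario uniformly on
`exposure_beta_scale`·[0.5, 1.5] and sorted descending, so the first
variant is the lead (strongest) instrument, as a lead SNP is in practice.
Binary traits emit linear-probability betas $\theta\,k(1-k)$ (with $\theta$
the log odds ratio) and residual variance scaled by $k(1-k)$, which is what
links the generator to the odds-ratio conversion. One global seed drives
counter-based substreams per trait, stratum and replicate, so fixtures are
reproducible file by file.

Default sizes emulate the sex-stratified biobank setting this design is
used in: outcome GWAS of 361,194 (both), 167,020 (men) and 194,174 (women);
an exposure GWAS of 188,577; exposure effects around 0.1 SD per allele; and
three instrument regimes — a single lead variant, six correlated proxies in
one LD block ($\rho = 0.6$), and a 56-variant independent score — matching
how a lead SNP, a correlated gene-region panel, and a polygenic exposure
score are actually used. The phenome fixture
(`simulate_phewas_fixture()`) adds an LDL-c anchor at $\theta = -1$ in
every stratum, strong signals at 0.5–0.9 of the anchor effect, a women-only
signal at a quarter of the anchor effect ($\theta_m = 0 \ne \theta_w$, the
pattern the sex-difference test exists for), nulls across several
categories, and manifest rows engineered to trip each filter rule once.

What the generator does *not* emulate, and what passing tests therefore do
not establish about real data: weak instruments (exposure betas are
bounded away from zero, so weak-instrument bias is out of frame); sample
overlap between exposure and outcome GWAS; non-normal effect
distributions; allele-frequency spectra and imputation quality;
selection/participation bias; and real LD structure beyond exchangeable
within-block correlation. The calibration results (coverage, family-wise
error, Egger power) are statements about the estimators under their own
assumptions, not about any particular biobank.

## Numerical and design choices

* **Dispersion floor.** $\phi = \max(1, Q/\mathrm{df})$ with df $J-1$ (IVW)
  and $J-2$ (Egger). The floor makes random-effects p-values mildly
  conservative when true dispersion is 1; this is the prevailing
  convention and is preferred to occasionally deflated errors.
* **Single-variant scans stay exact.** The primary scan regime is one lead
  variant per target, where the Wald p-value is exactly normal under the
  null; the family-wise error and uniformity calibrations are run in that
  regime. Multi-instrument random-effects p-values are conservative by
  construction (previous point).
* **Exposure-side uncertainty** is ignored throughout (first-order Wald
  SEs, conditioned-on exposure betas in MVMR) — the strong-instrument
  convention; the delta-method test quantifies the neglected term.
* **Egger power scenario.** The directional-pleiotropy calibration uses
  $J = 56$, $\mu_\alpha = 0.01$, $\sigma_\alpha = 0.005$ at the default
  sample sizes. These values were fixed analytically beforehand: with
  intercept standard error
  $\approx \sigma_{\mathrm{eff}} \sqrt{\overline{x^2}/(J\,\mathrm{var}(x))}$
  they give analytic power ≈ 0.85 at the 5% level, comfortably detectable
  but far from trivial.
* **Problem sizes.** The long-running calibrations use 1000 replicates for
  parameter recovery ($J=56$), 1000 replicate scans of a 100-phenotype
  global-null fixture for family-wise error, 1000 null and 500
  directional-pleiotropy Egger replicates, and 20 logistic-regression
  replicates at $n = 2\times10^5$ per prevalence. These sizes put
  Monte-Carlo error well below the margins being asserted while keeping
  the default suite runnable on a single CPU in minutes.
* **Degenerate inputs** are errors with instructions, not warnings: zero
  exposure beta (Wald), $J$ below the method's identifiability limit,
  missing correlation matrix when pruning, near-singular $\Omega$,
  rank-deficient MVMR design, case fraction outside (0, 1).
* **Output dialect.** All tables are tab-separated UTF-8 with period
  decimals and `NA` for missing; p-values serialize in 3-significant-digit
  scientific notation with full precision preserved in `log10_pval`
  companions where relevant; every table carries a `# run_manifest:`
  header naming the config hash so outputs are attributable to inputs.

## Worked example

```{r example, eval = FALSE}
fx <- simulate_phewas_fixture(n_phenotypes = 50, n_signals = 5, seed = 1)
scan <- run_phewas(fx$manifest, fx$store,
                   fx$instruments[c("statin_lead", "ldl_score")],
                   fx$config, anchor_id = fx$anchor_id)
scan
build_table1(scan)[1:6, 1:5]
```

The same pipeline is scriptable from a shell through the installed
`phewas` executable (`simulate`, `filter`, `run`, `threshold`, `sexdiff`,
`report`, `config` subcommands); the README shows the full chain.

## Known limitations

Beyond the generator caveats above: no weighted-median, mode-based or
outlier-removal estimators are provided (deliberately — the scan design
relies on Wald/IVW/Egger/MVMR); replication against external consortia is
supported only as a z-test between two estimate sets, not as data
retrieval; no remote GWAS-database queries, VCF parsing or coordinate
liftover — variants are rsID-keyed summary rows; and the correlated-Egger
path is an extension beyond the classical independent-instrument
formulation, flagged as such in its output.
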