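# mrphewas

Sex-specific drug-target Mendelian randomization (MR) phenome scans over
GWAS summary statistics.

## What it is for

Variants in a drug's target gene act as lifelong proxies for
pharmacological modulation of that target: an LDL-lowering variant in
*HMGCR* genetically "mimics" statin treatment, a *PCSK9* variant mimics
PCSK9 inhibition, a *NPC1L1* variant mimics ezetimibe, and a polygenic SNP
score proxies the exposure (LDL-cholesterol) itself. Scanning such
instruments against a whole phenome of GWAS results — separately in men
and women — surfaces candidate pleiotropic drug effects and candidate sex
differences while avoiding the confounding of observational drug studies.

`mrphewas` is for epidemiologists and statistical geneticists who have
per-phenotype, per-stratum summary-statistic tables plus an instrument
definition, and want the whole scan as tested, reproducible code:

* **sumstats** — tab-separated readers/writers with a configurable
  column-synonym dialect (Neale-style headers by default, gzip supported),
  allele harmonization with palindromic-variant handling, r²-based
  instrument pruning (`r² < 0.01` by default), and recovery of standard
  errors from printed beta/p pairs (log10-p input for values below double
  underflow);
* **estimators** — Wald ratio; inverse-variance weighting as generalized
  least squares `β̂ = (XᵀΩ⁻¹X)⁻¹XᵀΩ⁻¹Y` with `Ω_jk = s_j s_k ρ_jk` taking
  instrument correlations into account, with multiplicative random effects
  `φ = max(1, Q/(J−1))` when `J ≥ 3`; MR-Egger with the
  directional-pleiotropy intercept test; multivariable MR; and the
  case-fraction odds-ratio conversion `log OR = β/(k(1−k))` for
  linear-regression binary-trait GWAS;
* **phewas** — manifest filtering (≥100 cases for binary traits,
  n ≥ 10,000 for quantitative ones, external-cause ICD codes and
  configurable subcategories excluded, duplicates dropped — every
  exclusion ledgered with a reason), Bonferroni control at `α/Np`,
  effects scaled relative to an LDL-c anchor, two-sided z-tests for
  sex differences and replication, Manhattan/category summary tables;
* **synthetic data** — a seeded generator of two-sample summary statistics
  and full phenome fixtures with known ground truth (LD blocks,
  directional pleiotropy, sex-specific effect layers, binary traits on the
  linear-probability scale), used to test the pipeline's calibration;
* **reporting/CLI** — a `phewas` executable with `simulate`, `filter`,
  `run`, `threshold`, `sexdiff`, `report` and `config` subcommands, and
  provenance-hashed TSV outputs.

## Worked example

Simulate a 50-phenotype fixture (five true signals plus a women-only one,
an LDL-c anchor at −1, filter-trap rows), scan it with the single
lead-variant target and the 56-SNP exposure score, and build the wide
comparison table:

```r
library(mrphewas)
fx <- simulate_phewas_fixture(n_phenotypes = 50, n_signals = 5, seed = 1)
scan <- run_phewas(fx$manifest, fx$store,
                   fx$instruments[c("statin_lead", "ldl_score")],
                   fx$config, anchor_id = fx$anchor_id)
scan
#> <phewas_scan>
#>   phenotypes tested (Np): 50, Bonferroni threshold 0.001
#>   estimates: 300 rows; significant: 34 rows over 6 phenotype(s)
#>   excluded phenotypes: 6; skipped combinations: 0
```

All six engineered non-null phenotypes (and only those) cross the
Bonferroni threshold `0.05/50 = 1e-3`. The wide table reads like the
conventional presentation: effects as fractions of the LDL-c effect, the
anchor pinned at −1.00, and the women-only trait (`shbg`) flagged by the
sex-difference z-test:

```r
head(build_table1(scan)[, c("phenotype_id", "statin_lead.men.scaled_beta",
                            "statin_lead.women.scaled_beta",
                            "statin_lead.sexdiff_p")], 7)
#>     phenotype_id statin_lead.men.scaled_beta statin_lead.women.scaled_beta
#> 1          ldl_c                     -1.0000                     -1.000000
#> 2           apob                     -0.8630                     -0.913581
#> 3          hba1c                      0.5809                      0.546386
#> 4 platelet_count                     -0.4852                     -0.489512
#> 5       chol_med                     -0.1760                     -0.166594
#> 6           shbg                      0.0630                     -0.242489
#> 7       null_001                      0.0261                     -0.000612
#>   statin_lead.sexdiff_p
#> 1              8.53e-01
#> 2              2.19e-01
#> 3              2.91e-01
#> 4              9.76e-01
#> 5              5.22e-01
#> 6              4.36e-17
#> 7              9.34e-02
```

The estimators are available directly; here the 56-instrument score
recovers its generating effect of −1 per SD of exposure:

```r
sp <- simulate_pair(synthetic_truth(n_instruments = 56, seed = 1))
mr_ivw(sp$instruments, sp$outcomes)
#> <mr_estimate> ivw_mre (J = 56)
#>   beta -1.003 (se 0.003829), 95% CI [-1.01, -0.9951], p 2.23e-308
#>   dispersion phi 1.37, Q 75.2
mr_egger(sp$instruments, sp$outcomes)
#> <mr_estimate> egger (J = 56)
#>   beta -0.9927 (se 0.01391), 95% CI [-1.02, -0.9654], p 2.23e-308
#>   dispersion phi 1.38, Q 74.4
#>   Egger intercept -0.001115 (se 0.001495), p 0.456
```

The same chain from a shell:

```sh
phewas simulate --seed 1 --n-phenotypes 50 --n-signals 5 --out fx/
phewas run --manifest fx/manifest.tsv --sumstats-dir fx/ \
       --instruments fx/instruments.tsv --correlation fx/correlation.tsv \
       --config fx/config.yaml --target ldl_score --anchor ldl_c --out out/
phewas report --results out/ --out out/table1.tsv
phewas threshold --np 1701
# 2.9e-05
```

See the methods vignette (`vignettes/drug-target-mr-phewas.Rmd`) for the
models, the generator's assumptions, and the reasoning behind the
numerical choices.

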