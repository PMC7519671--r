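# trpdesign

Model-guided combinatorial promoter engineering of tryptophan metabolism
in baker's yeast, as one reproducible design–build–test–learn cycle.

Tryptophan biosynthesis sits downstream of the shikimate pathway, whose
precursors (erythrose 4-phosphate and phosphoenolpyruvate) are drained or
replenished by central carbon metabolism. Engineering higher tryptophan
flux therefore means re-balancing expression of precursor-supply genes —
here PCK1, TAL1, TKL1, CDC19 and PFK1, each controlled by one of six
promoters, a 6^5 = 7776-member combinatorial design space. The package is
written for metabolic engineers who want to (i) pick such gene targets
from a stoichiometric model, (ii) design and audit the one-pot
combinatorial library, (iii) turn biosensor plate-reader screens into
quality-controlled GFP synthesis rates (MFI/h, the tryptophan productivity
proxy), (iv) learn a genotype → rate model, and (v) decide what to build
next.

## What it computes

* **Gene-target scores** from parsimonious flux balance analysis: growth
  is fixed at 11 suboptimal fractions (30–80% of µ_max) with all remaining
  capacity directed to a tryptophan sink; each reaction is scored by its
  mean absolute flux fold change against the maximum-growth reference,
  s_r = mean_f (|v_f| + δ)/(|v_ref| + δ), and gene scores are means of
  associated reaction scores (s_g > 1 → overexpress, s_g < 1 →
  downregulate). Pathway overrepresentation of the target set is tested by
  two-sided Fisher exact tests.
* **Library design**: design-space enumeration, DNA parts accounting
  (13-part assemblies from a 38-part pool for the default catalog), Monte
  Carlo library coverage (unique genotypes among n colonies at a given
  correct-assembly rate), and genotyping QC summaries.
* **Phenotyping**: per-plate media background subtraction, five-criterion
  strain QC, windowed GFP synthesis rates (endpoint or regression slope on
  the OD600 interval 0.075–0.150), replicate aggregation, and two outlier
  filters (global 1%-percentile and per-strain median/MAD).
* **Learning**: a Bayesian stacked ensemble — eight base regressors whose
  simplex weights are inferred by MCMC from out-of-fold predictions under
  y ~ N(Σ w_m g_m(x), σ²) — with cross-validated MAE and learning curves.
* **Recommendation**: exhaustive ranking of all unseen designs by
  predictive mean (exploit) or expected improvement
  EI = (µ−f*)Φ(z) + σφ(z) (explore), plus overlap statistics between
  recommendation sets.
* **Synthetic data**: a seeded generator producing ground-truth response
  surfaces (rates spanning 40–260 MFI/h, reference design at 145 MFI/h),
  strain libraries with realistic defect rates (82% correct assembly, 92%
  cured, 3.7% duplicates), replicate noise at 4.3% CV of the mean, and raw
  82-point plate-reader time series.

## Worked example

A complete in-silico screen: generate a mock study, phenotype it, fit the
ensemble, and ask for the next 30 designs to build.

```r
library(trpdesign)

catalog <- default_catalog()
study <- generate_mock_study(n_strains = 120, seed = 42)

phen <- phenotype_plates(study$reads, study$map, study$metadata)
keep <- phen[phen$qc_pass & phen$n >= 2, ]
nrow(keep)
#> [1] 82

fit <- trp_ensemble(study$strains$key[match(keep$strain, study$strains$strain)],
                    keep$rate_mean, catalog = catalog,
                    mcmc = mcmc_control(chains = 2, draws = 2000, burn = 500),
                    seed = 1)
fit
#> Bayesian stacked ensemble: 8 base learners, 82 training genotypes
#> Posterior mean weights:
#>        linear    log_linear         ridge         lasso random_forest
#>         0.194         0.154         0.288         0.211         0.044
#>   extra_trees       svm_rbf           knn
#>         0.031         0.033         0.044
#> Posterior noise sd: 13.92 MFI/h; mean MH acceptance 0.44

rec <- recommend_designs(fit, n = 30, mode = "exploit",
                         exclude = study$strains$key)
as.data.frame(rec)[1, c("key", "mu", "sigma")]
#>                                                       key       mu    sigma
#> 1 PCK1:pPCK1|TAL1:pADH1|TKL1:pGPD1|CDC19:pTPK2|PFK1:pSED1 261.7155 14.50455

round(mean(true_rate(study$truth, rec$key)), 1)
#> [1] 242.5
```

Of 120 generated strains, 82 pass the five QC criteria (the generator
injects assembly, curing and duplicate-genotype defects at the library's
observed rates). The fitted ensemble puts most weight on the linear family
— the simulated promoter effects are near-multiplicative — and estimates a
posterior noise sd of ~14 MFI/h. The 30 recommended unseen designs have a
mean *true* synthesis rate of 242.5 MFI/h, close to the ceiling of the
simulated surface (260 MFI/h) and far above the training mean, i.e., the
cycle recommends designs genuinely better than what it was trained on.

The same flow runs as one call with a validated config and a hashed run
manifest:

```r
man <- run_pipeline(run_config(seed = 7, out_dir = "runs/demo"))
```

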