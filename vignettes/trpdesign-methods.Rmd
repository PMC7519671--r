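---
title: "Methods: model-guided combinatorial promoter engineering with trpdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model-guided combinatorial promoter engineering with trpdesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trpdesign)
```

# Overview

`trpdesign` implements one design–build–test–learn cycle for combinatorial
promoter engineering of tryptophan biosynthesis in *Saccharomyces
cerevisiae*, from constraint-based gene-target selection through biosensor
phenotyping to machine-learning-guided design recommendation. Five
precursor-supply genes around the shikimate pathway entry points (PCK1,
TAL1, TKL1, CDC19, PFK1) are each controlled by a bin of six promoters,
giving a 6^5 = 7776-member design space. A GFP-coupled tryptophan biosensor
turns plate-reader time series into per-strain GFP synthesis rates (MFI/h),
the proxy for tryptophan productivity, and a Bayesian ensemble of
regression learners maps one-hot-encoded genotypes to rates and ranks
unbuilt designs.

Every stage is driven by explicit seeds and is reproducible bit-for-bit;
a synthetic-data generator emulates the statistical structure of the screen
so the whole pipeline can be exercised and tested without any external
data.

# Gene-target scoring from a stoichiometric model

Targets are scored by simulating how flux redistributes as production
shifts from biomass to tryptophan. For a stoichiometric model with flux
bounds and a growth objective, `solve_pfba()` performs a three-stage
parsimonious FBA: maximize growth to find $\mu_{max}$; fix growth at a
fraction $f\,\mu_{max}$ and maximize flux into the tryptophan sink; fix
both and minimize total absolute flux. `suboptimal_scan()` repeats this
over a fraction grid, by default $f = 0.30, 0.35, \ldots, 0.80$ — eleven
suboptimal growth conditions with all remaining capacity oriented toward
tryptophan. The grid spacing is the unique equal spacing that puts eleven
points between 30% and 80%; it is overridable.

Per reaction, the score is the mean absolute flux fold change against the
maximum-growth reference,
$$s_r = \frac{1}{|F|}\sum_{f \in F}\frac{|v_f| + \delta}{|v_{ref}| + \delta},$$
with a pseudo-flux $\delta$ (default $10^{-4}$ mmol/gDW/h) guarding zero
reference fluxes. Reactions below $\delta$ in the reference *and* in every
scan condition are reported unscored rather than artificially neutral, and
reactions whose flux changes direction are flagged separately instead of
having the sign folded into the score. Gene scores are plain unweighted
means of associated reaction scores — AND/OR structure of gene–reaction
rules is deliberately ignored — and classify genes as overexpression
($s_g > 1$), downregulation ($s_g < 1$) or neutral targets. Carbon-source
regimes are handled as independent scans of differently configured models;
`target_overlap()` intersects the classified sets.

Pathway overrepresentation of the resulting target set uses a two-sided
Fisher exact test per pathway over an explicit gene universe
(`pathway_enrichment()`). The universe is a required input because results
depend materially on it.

The LPs are solved by a package-internal dense two-phase simplex with
Bland's rule and a fixed variable order, so repeated runs return identical
flux vectors. This targets the small, curated models the package works
with (tens of reactions), not genome-scale reconstructions; the test suite
cross-checks every solve against an independent `scipy.optimize.linprog`
oracle.

# Combinatorial library design and coverage

`promoter_catalog()` holds the per-gene promoter bins with relative
strengths and *pick probabilities* — the frequency at which each promoter
appears among correctly assembled colonies. The observed pick distribution
of a real one-pot library is known only summarily (rarest promoter about
1%, commonest about 35%), so the default catalog ships uniform picks plus
a parameterised skew anchored at those two extremes; coverage results
under the skew should be read qualitatively.

`simulate_coverage()` estimates library coverage by Monte Carlo: each
replicate draws colonies, keeps each with the correct-assembly probability
(default 0.82), samples one promoter per gene independently from the pick
probabilities, and counts unique genotypes. Under uniform picks the mean
agrees with the occupancy closed form $G(1 - (1 - 1/G)^{np})$, which the
tests verify within Monte Carlo error; skewed picks can only lower the
expected unique count. Whether the original library sampled promoters
independently per gene is not documented; independence is assumed and
flagged here.

`summarize_genotyping()` computes the library QC percentages on their
natural denominators (cured and correctly assembled out of *growing*
colonies; duplicate genotype calls out of *fully filtered library* calls,
controls excluded) and never rounds — rounding belongs to the report
layer.

# Biosensor phenotyping

Raw plate-reader series (OD600 and GFP every 15 min, 82 points) are
background-corrected per plate by subtracting the per-time-point mean of
that plate's media wells (`subtract_background()`). Strains pass QC only
if all five criteria hold: growth covering the OD range up to 0.15
(excludes uninoculated and weakly growing wells), complete sequencing,
exact assembly, cured complementation plasmid, and a single genotype; a
missing metadata field fails its criterion explicitly rather than passing
silently.

The GFP synthesis rate of a well is computed inside the OD600 window
[0.075, 0.150], where per-cell fluorescence is stable. The default
estimator is the literal endpoint difference quotient
$(\mathrm{GFP}_{last} - \mathrm{GFP}_{first})/(t_{last} - t_{first})$; a
least-squares slope over the in-window points is available and preferable
when measurement noise dominates (about 13–15 points typically fall in the
window). Two choices the data do not dictate: the window is the *first
contiguous* run of in-window points (later OD re-entries are ignored), and
boundary-nearest points are used rather than interpolated window
crossings. Replicates aggregate to mean, SEM $= s/\sqrt{n}$ and the CV of
the mean (SEM/mean).

Two outlier filters mirror the two modeling routes:

* `outlier_filter_percentile()` flags the globally most extreme 1% of
  relative replicate deviations and removes the owning strains whole.
* `outlier_filter_robust()` flags replicates deviating from their strain
  median by more than 3 scaled MADs (the canonical univariate robust
  rule; the cutoff is configurable). For two-replicate strains a per-strain
  MAD is powerless — both deviations are equal by symmetry — so the scale
  falls back to the MAD of deviations pooled across strains, which removes
  both replicates of a grossly discordant duplicate pair. Strains left
  with fewer than two replicates are dropped entirely, as a lone replicate
  carries no reproducibility information.

# The Bayesian stacked ensemble

`trp_ensemble()` models the rate as a weighted vote of $M = 8$ base
regressors over one-hot genotype encodings (30 binary columns, one 1 per
gene block). The defaults span linear and log-linear least squares (the
log-scale member reflects that promoter effects act multiplicatively on
rates), ridge and lasso, a random forest, extremely randomized trees, an
RBF support vector machine and k-nearest neighbours (a gradient-boosting
learner is available but not in the defaults); any list of objects satisfying
the `fit(X, y)`/`predict(model, X)` contract can be substituted, and a
learner that fails to fit is excluded with a warning.

The ensemble weights $w$ live on the simplex and are treated as random:
$$y_i \sim \mathcal{N}\!\Big(\sum_m w_m\, g_m(x_i),\; \sigma^2\Big),
\qquad w \sim \mathrm{Dirichlet}(1,\ldots,1),$$
with a weakly-informative half-normal prior (scale $2\,\mathrm{sd}(y)$) on
$\sigma$. Crucially the $g_m(x_i)$ entering the likelihood are
*out-of-fold* predictions from an internal 5-fold split (stacking);
fitting weights on in-sample predictions would hand all weight to the most
overfit learner. Sampling is random-walk Metropolis on stick-breaking
transformed weights plus $\log\sigma$ (default 4 chains × 5000 draws, 1000
burn-in, acceptance typically 0.3–0.6; all Jacobians included). The
predictive mean for a genotype is the posterior mean of $\sum_m w_m
g_m(x)$; the predictive variance adds the posterior variance of that
weighted vote (model disagreement) to the posterior mean noise variance.
Both moments are computed exactly from the posterior sample mean and
covariance of $w$.

Accuracy is quantified by `cross_validate()` (random fold assignment,
pooled held-out MAE; 10-fold by default — a 90/10 split, with the folds
argument accommodating the 80/20 convention as well) and by
`learning_curve()`, which subsamples the dataset at several sizes,
computes the train MAE on the *whole* dataset after fitting on the
subsample, the test MAE by cross-validation inside the subsample, and 95%
confidence half-widths over the repeats.

# Recommendation

`recommend_designs()` enumerates the full 7776-member space exhaustively —
at this size exact search dominates any stochastic optimizer, so Parallel
Tempering-style search is deliberately replaced by enumeration — excludes
already-built designs by default, and ranks candidates by either the
predictive mean (exploit) or the expected improvement (explore)
$$\mathrm{EI} = (\mu - f^*)\,\Phi(z) + \sigma\,\phi(z), \quad
z = (\mu - f^*)/\sigma,$$
with $f^*$ the best observed training mean (the standard Bayesian
optimization convention; the source screen does not state its incumbent
choice). Ties break lexicographically on the genotype key so runs are
reproducible. When the weight posterior is concentrated, the model
disagreement term is small and predictive sds vary little across
candidates; exploit and explore rankings then largely coincide — the
diversity of explore recommendations grows with ensemble disagreement,
not by construction.

# The synthetic-data generator

`make_ground_truth()` draws per-gene per-promoter effects on a latent
log-rate scale (sd 0.35) plus small pairwise gene-by-gene interactions
(sd 0.08, on by default: a purely additive surface would make exploit
recommendation trivially solvable, whereas the real screen's winners were
non-intuitive combinations). The latent surface is calibrated with a
monotone exponential-affine link so that the minimum and maximum over all
7776 designs hit 40 and 260 MFI/h and the all-native reference design hits
145 MFI/h — the observed span and reference point of the screen. The link
preserves the multiplicative structure of the effects; its curvature is
fully determined by where the reference design falls in the latent range.
A caveat found while validating the end-to-end pipeline: random draws that
place the reference design near the top of the latent range force a
sharply convex link (a needle-peaked surface), and on such surfaces the
achievable margin of recommended over trained designs shrinks toward
zero for *any* method. Repetition studies therefore hold one drawn surface
fixed (one underlying biology) and vary sampling and fitting randomness
across runs, the way the screen's own modeling repetitions were run.

`sample_training_set()` draws distinct genotypes from the catalog's pick
distribution, applies multiplicative replicate noise calibrated so the CV
of the replicate mean is 4.3% (noise proportional to signal, consistent
with fluorescence measurements), and injects metadata defects at the
screen's rates: 18% incorrect assemblies, 8% uncured, 3.7% duplicate
genotypes. `render_timeseries()` produces raw plate-reader series: noisy
logistic growth from OD 0.025 (maximum specific growth rate 0.28/h,
carrying capacity 0.6 — values placing 13 of the 82 grid points inside
the OD window), GFP integrating at the strain's true rate while the
culture is inside the window (ramping below, per-cell decline above), and
media background offsets (OD 0.04, GFP 30). With noise disabled, the
windowed endpoint estimator recovers the true rate exactly by
construction, so estimator error can be attributed entirely to noise. The
82-point 15-min grid spans 20.25 h. What the generator does *not* emulate:
growth-rate differences between genotypes, biosensor saturation and
dose-response nonlinearity, plate edge effects, and batch effects between
plates — so green tests certify the statistical machinery, not robustness
to those real-data features.

# Reproducibility and numerical choices

All randomness flows from explicit integer seeds; stage seeds are derived
from a root seed through named substreams (`substream_seed()`), so a
single seed reproduces a whole `run_pipeline()` run, artifact hashes
included. Tolerances: mass balance and LP optimality are checked at 1e-6;
simplex pivots use 1e-9; ensemble weights are valid on the simplex to
1e-9. Degenerate inputs have defined behavior: zero-effect ground truths
collapse to the anchor rate, flat GFP gives rate 0, single replicates have
undefined SEM (kept, but excluded from model training by default), and
zero-denominator percentages are `NA`, never 0.

Problem sizes in the test suite are chosen to keep the full run within a
few minutes on one CPU: random LP models with up to 16 reactions, coverage
at 400–1000 Monte Carlo replicates, ensemble fits on 30–250 genotypes with
2 × 1500–2500 MCMC draws, and ten end-to-end recovery runs at the full
study scale of 250 genotypes × 3 replicates.

# Known limitations

* The simplex solver is dense and unsuited to genome-scale models; the
  scoring procedure is the contribution, not an LP engine.
* Gene scoring ignores gene–reaction rule structure (as specified), which
  overweights genes appearing in many isoenzyme complexes.
* The Fisher-test universe choice is left to the user; no default universe
  is shipped because enrichment is sensitive to it.
* Predictive uncertainty reflects ensemble disagreement plus homoscedastic
  noise; replicate-level heteroscedasticity (CV proportional to signal) is
  not propagated into $\sigma$.
* The exact robust-outlier variant used by the original explorative
  modeling route is not documented; the MAD rule here is the canonical
  choice, and its two-replicate fallback is this package's own.
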