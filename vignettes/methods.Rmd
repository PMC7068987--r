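---
title: "Models and methods behind giltvs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind giltvs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
the models, their assumptions, the tunable parameters, the numerical
choices, and what the synthetic data can and cannot tell you about real
populations. The README shows the user-facing flow; here we explain why
each piece is the way it is.

## The animal model and its REML fitter

Variance components for each vulva-size trait come from the univariate
mixed model

$$y_{ijkl} = \mu + L_i + CG_j + \beta \cdot BW_k + a_k + d_l + e_{ijkl}$$

with line $L$ and contemporary group $CG$ as fixed factors, body weight
$BW$ (kg) as a fixed covariate, an additive-genetic animal effect
$a \sim N(0, A\sigma^2_a)$ with $A$ the pedigree numerator relationship
matrix, a common litter environment $d \sim N(0, I\sigma^2_d)$, and
residual $e \sim N(0, I\sigma^2_e)$. Heritability and the litter ratio are
$h^2 = \sigma^2_a/\sigma^2_p$ and $c^2 = \sigma^2_d/\sigma^2_p$ with
$\sigma^2_p = \sigma^2_a + \sigma^2_d + \sigma^2_e$. Bivariate fits stack
two traits with unstructured 2x2 genetic, litter and residual covariance
blocks, giving $r_G$ and $r_P$.

Assumptions worth stating: one record per animal per trait; litter effects
independent of pedigree; no maternal genetic effects, no repeated records,
no genomic REML (variance estimation is always pedigree-based here,
matching the design of the breeding-program analyses this package
targets).

The fitter (`fit_univariate()`, `fit_bivariate()`) is an
average-information (AI) REML in the dense V-matrix form — appropriate at
the cohort sizes this package targets (hundreds to a couple of thousand
records), where an $n \times n$ Cholesky per iteration is cheap and no
sparse MME machinery is warranted. Numerical details:

* **Scoring.** AI steps with step halving; an update that leaves the
  parameter space falls back to a projected step (variances clamped at
  their bounds, covariance blocks projected to the nearest PSD matrix) and,
  as a last resort, the always-feasible multiplicative EM-style update
  $\theta \leftarrow \theta \cdot (y'PB Py)/\mathrm{tr}(PB)$, which for
  covariance blocks preserves the block correlation while rescaling.
* **Active set.** A variance pinned at its bound whose gradient points
  outward is frozen for that iteration; this keeps the AI matrix well
  conditioned when a component (often the litter variance) hits zero.
* **Bounds.** Variances are constrained to at least $10^{-8}$ times the
  phenotypic variance; estimates at the bound are flagged
  (`at_boundary` in `tidy()` output).
* **Convergence.** Successive log-likelihood change below
  `tol * (1 + |logL|)` (default `tol` 1e-8 univariate, 1e-7 bivariate)
  together with parameter stability; a persistent stall, or chatter on a
  PSD boundary with no real improvement over ten iterations, also ends the
  fit, returning the best visited point. Non-convergence within `max_iter`
  is an error carrying the likelihood trace.
* **Uncertainty.** Standard errors of $h^2$, $c^2$, $r_G$, $r_P$ by the
  delta method on the inverse AI matrix. With few litters $\sigma^2_a$ and
  $\sigma^2_d$ separate weakly; the fit reports their sampling correlation
  (`separation_cor`) so users can see when the data cannot tell them apart.
* **Centering.** The BW covariate is centered before fitting — purely for
  conditioning; variance estimates are unchanged.

`heritability_from_components()` implements the identity used to
cross-check published tables: given $\sigma^2_a$, $\sigma^2_e$ and $c^2$,
phenotypic variance is reconstructed as
$(\sigma^2_a + \sigma^2_e)/(1 - c^2)$ so that the reported litter ratio is
honoured, and $h^2 = \sigma^2_a/\sigma^2_p$.

## Genotype QC

The QC rules are: calls with GenCall quality below 0.20 are replaced by the
within-breed mean dosage of the marker; samples and markers below 0.8 call
rate are dropped; markers below 1% minor allele frequency are dropped. The
order of these rules is a genuine free choice (sources typically list them
unordered), and `apply_genotype_qc()` fixes it as: impute low-quality
calls, then sample call rate, then marker call rate, then MAF on the
retained samples, then mean-impute any residual missing calls. Rationale:
imputing before the call-rate filters avoids double-penalising markers that
were called but with low confidence, and computing MAF last uses the final
sample set. Imputed dosages stay real-valued (mean imputation is
variance-preserving for downstream mixed-model use); MAF uses
$\hat p = \bar{x}/2$ over non-missing calls. The final imputation pass is
what lets every downstream method assume complete dosage matrices.

## Pedigree and genomic relationships

`build_A()` uses the tabular method ($a_{ii} = 1 + 0.5 a_{sd}$,
$a_{ij} = 0.5(a_{j,s} + a_{j,d})$, unknown parents contributing zero, no
genetic groups); inbreeding is `diag(A) - 1`, and the herd summary
`mean_inbreeding()` averages only animals with $F > 0$, the convention used
when a mean over "inbred animals" is quoted. The test suite checks the
tabular method against an independent recursive-kinship oracle on random
pedigrees.

The genomic relationship matrix is VanRaden method 1,
$G = WW'/(2\sum_k p_k(1-p_k))$ with dosages centered at $2p_k$. Reported
analyses of this kind rarely state their G construction; method 1 with
observed-sample frequencies is the field default and has the property that the mean
off-diagonal relationship is ~0 in the sample used to compute the
frequencies, matching the way fold-level relationship summaries are usually
read. `fold_relationship_summary()` averages off-diagonal pairs only within
folds (self-relationships would inflate the within-fold mean) and reports
the mean diagonal separately.

## Bayes-alphabet whole-genome regression

`fit_bayes()` runs a single-site Gibbs sampler (Rcpp) for
$y = Wb + \sum_j x_j \alpha_j \delta_j + e$: fixed effects with flat
priors; marker inclusion $\delta_j$ sampled from the marginalised
likelihood ratio against the point mass at zero with prior
$P(\delta_j = 1) = 1 - \pi$; BayesB draws a per-marker effect variance from
a scaled-inverse-$\chi^2$, BayesC/C0 share one, BayesCπ additionally draws
$\pi \sim \mathrm{Beta}(\#\text{excluded}+1, \#\text{included}+1)$. The
litter effect is deliberately absent from this model — the GWAS/prediction
model carries only line, CG and BW beside the markers.

Hyperparameters: the marker-effect scale is derived from the animal-model
estimates as $\sigma^2_a / ((1-\pi)\sum_k 2p_kq_k)$ with
$\nu_\alpha = 4.2$; the residual prior uses $\sigma^2_e$ with
$\nu_e = 10$. Beyond anchoring the scales at the REML estimates these
constants are conventions of this sampler family, adopted here as a
documented package choice. Dosages are centered
by within-analysis-set means (or supplied training means, for validation
sets). Chains are reproducible bit-for-bit given `seed`; thinning defaults
to 1. Divergent residual-variance draws abort with the iteration index.

Reference chain lengths are 50,000 iterations with 5,000 burn-in; the
package defaults mirror that, while tests and examples use desk-scale
chains (500–5,000 iterations), which the statistical checks show are ample
for the simulated data sizes.

## Window GWAS: %TGVM and PPI

`assign_windows()` bins markers into half-open 1-Mb windows
$[k, k+1)$ Mb per chromosome. For %TGVM, each retained draw's window
genomic values $u_w = X_w \alpha_w$ (centered dosages) give a window
variance across animals; the **draw-level share**
$\mathrm{var}(u_w)/\sum_w \mathrm{var}(u_w)$ is averaged over draws and
multiplied by 100. The alternative — ratio of posterior-mean variances — is
available (`average = "variance_ratio"`); the draw-level default propagates
the joint uncertainty of all windows and is the convention behind
window-share reports from this sampler family. Draws with no included
marker have undefined shares and are skipped (count reported). %TGVM sums
to 100 by construction; centering makes it translation-invariant.

PPI is the fraction of retained draws in which at least one marker of the
window is included. With $\pi \approx 0.99$ this "any marker" convention
produces the 0.5–0.9 range typical of reported windows; variance-threshold
alternatives exist but are not the default.

`call_qtl()` seeds regions at `tgvm_min` (default 4.0, the conventional
discussion threshold; configurable because reported tables sometimes keep
regions down to ~3.4%) and merges same-chromosome seed windows separated by
at most `merge_gap_mb` (default 1). Region %TGVM is the sum over its
windows, PPI the maximum — sums are meaningful because shares partition the
marker variance; a max is the natural region-level "contains signal"
summary.

## Cross-validated genomic prediction

`make_folds()` groups randomly shuffled sires five at a time; daughters
inherit their sire's fold, so paternal half-sib families are never split
and within-fold relationships stay high. Leftover sires go to the smallest
folds. GPA uses the two published formulas: a plain
$r(GEBV, y^*)/\sqrt{h^2}$ for a single validation set (between-breed), and
the fold-size-weighted mean of fold correlations over $\sqrt{h^2}$ for
cross-validated strategies, with the across-fold SD of $r_i/\sqrt{h^2}$ as
the spread. $h^2$ is always the validation breed's pedigree estimate — an
input, never re-estimated per fold. GPA can exceed 1 (perfect correlation
with $h^2 < 1$).

Three choices were genuinely open and are fixed as follows:

* **Fixed effects for $y^*$** come from each training fit; validation
  animals' own records never inform their adjustment (leakage-safe).
  Unseen factor levels are treated as baseline with a warning.
* **Between-breed prediction** is a single train/validate split per
  direction (reported between-breed results carry no fold SD, implying no
  folds were used).
* **Marker centering for validation** uses training-set allele
  frequencies; markers absent from or monomorphic in training contribute
  zero effects, and between-breed runs intersect post-QC marker sets.

SNP subsets (`build_snp_sets()`) follow the estimate-on-all,
predict-on-subset design: training always uses all markers, so effect
estimates stay conditional on the whole genome; per-QTL sets take markers
inside each region, QTL their union, and REST everything at least
`flank_mb` (default 3) Mb away from every region boundary, excluding
flanking markers in partial LD with the QTL. Because GEBVs use centered
dosages, subset GEBVs are exactly additive: QTL + REST + flank = ALL.

## The synthetic-data generator

`simulate_study()` emulates the study design: a closed purebred population
with discrete generations (founder sires and dams, one litter per dam per
generation, the final all-female generation being the phenotyped gilt
cohort); line and contemporary-group fixed effects; BW ~ N(120, 12²) kg
with a regression on the trait; litter effects shared within birth litter.
Genotypes: founder haplotypes via a Gaussian copula in which markers within
a block share a latent variable with correlation `ld_rho` (block-level LD
with the configured founder MAF spectrum preserved), then gene dropping
with 1 cM/Mb recombination. The breed presets carry the published
operating points — "yorkshire-like" uses VA variances 69,807.7 / 71,990.1
with c² = 0.06 (h² = 0.46) at ~700 gilts, "landrace-like" 21,953.3 /
89,166.2 with c² = 0.17 (h² = 0.16) at ~475 — with desk-scale genomes
(2,000 markers on 5 chromosomes) chosen so a full pipeline run is a
minutes-scale exercise.

Genetic architecture: `n_qtl` sparse QTL with fixed per-QTL shares of
$\sigma^2_a$, scaled against the cohort's realised dosage variance so
planted shares are accurate; the remainder is a polygenic background. By
default that background is **marker-based** (many small effects on random
SNPs): those effects are gene-dropped with the genotypes, so relatives'
genetic covariance still follows $A$ in expectation, and — important for
GWAS checks — the whole of $\sigma^2_a$ is marker-explained, so a QTL
planted at 50% of genetic variance should show ~50% TGVM rather than ~100%
of a marker-visible sliver. A latent pedigree-based polygenic term
(parent average plus Mendelian sampling scaled by $(1-\bar F)/2$, founders
at full variance) is available via `polygenic = "pedigree"` for designs
where markers should not tag the polygenic part. Multi-trait QTL are
pleiotropic with shared signs; the polygenic cross-trait correlation is
set to $(r_G^{target} - w_{QTL})/(1 - w_{QTL})$ so the total genetic
correlation lands near the target. Mendelian-sampling variance ignores
inbreeding beyond parental-F scaling (a documented simplification).

What the generator does **not** emulate: realistic recombination maps and
LD decay (block LD only), selection across generations, genotyping error
and missingness mechanisms (quality scores and missingness are optional
add-ons, not error models), maternal effects, and the fine-scale family
structure of a real nucleus herd. Passing parameter-recovery tests
therefore demonstrates correctness of the estimators under the stated
model, not robustness to everything real data can do.

## Validation strategy and problem sizes

The suite validates each stage against an independent route: the tabular A
against recursive kinship on random pedigrees; REML against a direct
dense-likelihood optimiser on ~40 records, against the paternal half-sib
ANOVA estimator (50 sires x 20 daughters, 20 replicates), and against
generator truth over replicate simulations (~240-gilt cohorts); BayesC0
GEBVs against the closed-form ridge/GBLUP solution (60 animals, 200
markers); window %TGVM against brute-force variance computation and a
planted-QTL design (600 gilts, 2,000 markers, one window at 50% of genetic
variance, 10 replicate seeds); prediction against closed-form GPA fixtures
and a two-breed design with disjoint QTL (600 gilts per breed, 1,000
markers, 10 seeds) in which within-breed accuracy is high and between-breed
accuracy is centred at zero. These sizes are the package's chosen
desk-scale operating points; all are configurable upward.

## Known limitations

* The REML engine is dense: fine to a few thousand records, not built for
  national-evaluation scale.
* Bivariate fits near singular covariance structures (e.g. a trait pair
  that is numerically the same trait) converge to the PSD boundary and can
  report correlations slightly inside ±1 rather than exactly at it.
* BayesB's per-marker variance mixes slowly at very high π on small data;
  the window-level summaries are much more stable than single-marker
  inclusion frequencies.
* `run_pipeline()` rerun reproducibility is bit-exact for fixed seeds on a
  given platform; across BLAS builds the REML third decimals can move.
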