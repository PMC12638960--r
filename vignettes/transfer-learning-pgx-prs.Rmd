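---
title: "Transfer learning of polygenic scores for drug response: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transfer learning of polygenic scores for drug response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxtl)
```

## The problem

Randomized two-arm pharmacogenomic (PGx) trials ask two genetic questions at
once: which variants shift the clinical outcome regardless of treatment
(*prognostic*, genotype main effects) and which variants shift the response
to the drug itself (*predictive*, genotype-by-treatment interaction
effects). A polygenic score built from a disease GWAS carries only prognostic
information, and only for the disease trait, not the drug response; a score
trained from scratch on the trial is starved for sample size. `pgxtl`
implements a middle path: start from disease-GWAS-derived SNP weights and
fine-tune both effect dimensions on the individual-level trial data.

## Joint model and penalized loss

For $n$ subjects with genotype dosages $G$ ($n \times M$, column-standardized),
randomized treatment $T \in \{0,1\}^n$, covariates $C$ and continuous response
$Y$:

$$Y = C\delta + G\beta_G + (G \circ T)\,\beta_{GT} + \epsilon .$$

Writing $X = [\,G \;\; G \circ T\,]$ and $b = [\beta_G\; \beta_{GT}]$, the fit
minimizes the ridge-penalized residual sum of squares

$$\mathrm{loss}(b) = (Y' - X b)^\top (Y' - X b) + \lambda_{\mathrm{raw}}\, b^\top b ,$$

where $Y'$ is the response pre-residualized on intercept, covariates and
treatment (`residualize()`), which removes the $C\delta$ and $T$ terms from
the iteration. The gradient step, after absorbing constants into a
reparameterized learning rate $\eta$ and shrinkage $\lambda \in [0,1)$, is

$$b^{(r+1)} = (1-\lambda)\, b^{(r)} + \eta\, X^\top (Y' - X b^{(r)}) ,$$

whose fixed point is the ridge solution
$b^\star = (X^\top X + (\lambda/\eta) I)^{-1} X^\top Y'$ — the property the
test suite verifies against a closed-form solve. Keeping $\lambda < 1$
guarantees the retained fraction of $b$ cannot flip sign between iterations.

Transfer enters through the initial state: $\beta_G^{(0)} = \beta_G^{\mathrm{pre}}$,
the weights of a disease PRS pre-trained on large GWAS summary statistics,
and $\beta_{GT}^{(0)}$ either $0$ or $\beta_G^{\mathrm{pre}}$. Early stopping
(the tuned iteration count $r$) and the shrinkage $\lambda$ both pull the
solution toward this initialization, which is what makes the procedure a
transfer learner rather than a from-scratch ridge fit.

## The six strategies

| name | updates | $\beta_{GT}$ init | tuning criterion |
|------|---------|-------------------|------------------|
| M1 | $\beta_G$ and $\beta_{GT}$ | 0 | overall $R^2$ |
| M2 | $\beta_G$ and $\beta_{GT}$ | $\beta_G^{\mathrm{pre}}$ | overall $R^2$ |
| M3 | $\beta_G$ and $\beta_{GT}$ | 0 | partial $R^2$ of $\mathrm{PRS}_{GT}\times T$ |
| M4 | $\beta_G$ and $\beta_{GT}$ | $\beta_G^{\mathrm{pre}}$ | partial $R^2$ of $\mathrm{PRS}_{GT}\times T$ |
| M5 | $\beta_{GT}$ only ($\beta_G \equiv \beta_G^{\mathrm{pre}}$) | 0 | overall $R^2$ |
| M6 | $\beta_{GT}$ only ($\beta_G \equiv \beta_G^{\mathrm{pre}}$) | $\beta_G^{\mathrm{pre}}$ | overall $R^2$ |

With $\beta_G$ frozen (M5/M6) the prognostic score is identical in every
grid cell, so ranking by overall $R^2$ and by the conditional criterion
coincide; the package uses overall $R^2$ there and the suite asserts the
ranking equivalence.

## Hyperparameter tuning and nested cross-validation

`tune_hyperparameters()` performs the inner 4-fold loop: for each fold the
descent runs on the remaining three quarters from the strategy's initial
state, the whole 30-iteration trace is kept, and the criterion is computed
on the held-out quarter at every iteration; scores are averaged across folds
(per fold, then averaged — not pooled) and the best $(\eta, \lambda, r)$
cell selected. Ties break toward larger $\lambda$, then smaller $\eta$, then
smaller $r$: the most regularized, earliest-stopped model.

Real-data analyses use `nested_cv_prs()`: five outer folds, stratified by
treatment arm so both arms appear in every fold, each scored exactly once by
a model tuned and refit without its data. Simulation pipelines
(`run_scenario()`) skip the outer loop and evaluate on an independently
generated test cohort instead.

Two tuning parameters deserve comment.

**Learning-rate ladder.** The classical grid $\eta \in \{1,10,50,100\}/m$
(with $m$ the number of nonzero pre-trained weights) is implicitly spectral:
when the active SNP set is much larger than the sample size,
$\|X^\top X\|_2 \approx 2mc$ for a modest constant $c$, so $1/m$ sits near
the gradient-descent stability edge $2/\|X^\top X\|_2$ and the larger rungs
probe progressively more aggressive steps. At smaller SNP-to-sample ratios
the same rule is unstable for every rung. The package therefore defaults to
the scale-free equivalent $\eta = \{1,10,50,100\} / \hat\lambda_{\max}(X^\top X)$,
with the norm estimated by power iteration on the standardized training
design; `eta_scale = "active_count"` restores the literal $/m$ rule. Grid
cells that diverge (any coordinate non-finite or beyond $10^8$) score
$-\infty$ rather than aborting the run, and if the refit on the full
training fold diverges for the selected cell — possible because the refit
design is one third larger than an inner-fold design — the cell is
invalidated and the next-best cell used.

**Active set.** Only variants with a nonzero pre-trained weight enter the
descent. Sparse baselines (clumping+thresholding, the summary-statistic
lasso) therefore also control the dimensionality of the fine-tuning step;
a dense baseline passes all variants through.

Genotypes are mean-imputed and column-standardized *within each fitting
set*; held-out folds and test cohorts reuse the fitting-set means and
standard deviations. Pre-trained weights arriving on the per-allele scale
are converted to the standardized-dosage scale by multiplying with the
fitting-set dosage standard deviation, which makes the initial score equal
to the familiar centered per-allele PRS. Residualization is likewise fit on
the training portion and applied to held-out data;
`nested_cv_prs(global_residualize = TRUE)` reproduces the simpler one-shot
residualization of the full cohort. The treatment indicator is kept as raw
$\{0,1\}$ when forming the interaction columns, matching the generating
model (see the calibration caveat below).

## Baselines

Two self-contained disease-PRS baselines produce $\beta_G^{\mathrm{pre}}$
from summary statistics; externally trained weight files are read with
`read_weights()` and reconciled with `harmonize_weights()` (inner join on
variant id, sign flip for swapped alleles, optional removal of
strand-ambiguous variants).

* `clump_and_threshold()`: greedy clumping by ascending p-value (ties broken
  by variant id for order-independence) with an $r^2$ cutoff inside a
  base-pair window, then p-value thresholding; the threshold is tuned on an
  individual-level cohort when one is supplied, else the most permissive
  threshold is kept.
* `fit_sparse_sumstat_baseline()`: a sparse summary-statistic lasso in the
  spirit of penalized-regression PRS methods. Per LD block it minimizes
  $\beta^\top ((1-s)R + sI)\beta - 2\beta^\top r + \ell_1 \|\beta\|_1$ over
  standardized marginal effects $r_j = \hat\mu_j / (s_j \sqrt{n_j})$ by
  cyclic soft-thresholding with warm starts along the penalty path, and
  selects $\ell_1$ by pseudo-validation
  ($\beta^\top r / \sqrt{\beta^\top A \beta}$, the summary-statistic
  analogue of the PRS-phenotype correlation) so no individual-level
  validation data is required. It is a stand-in with the same interface and
  qualitative behavior as published estimators, not a reimplementation of
  any of them.

LD comes from a reference genotype panel via `ld_reference()`: blocks are
formed by a fixed 250 kb window per chromosome, correlations between blocks
are set to zero. Both choices are pragmatic defaults, configurable.

## Evaluation

`evaluate_prs()` implements the two-degree-of-freedom evaluation model

$$Y' \sim \mathrm{PRS}_G + \mathrm{PRS}_{GT} \times T ,$$

with $Y'$ the phenotype residualized on intercept, covariates and treatment.
It reports the model $R^2$, the $R^2$ of the $\mathrm{PRS}_G$-only model,
the classic partial $R^2$ of the interaction term
$(\mathrm{SSE}_{\mathrm{red}} - \mathrm{SSE}_{\mathrm{full}})/\mathrm{SSE}_{\mathrm{red}}$
(an $R^2$-difference variant is available via `partial_method`), and the
two-sided t-test on the interaction coefficient. Patient stratification uses
`quantile_treatment_effects()` (treatment-effect contrast per score
quantile, Welch 95% intervals) and `differential_te_by_cutoff()`
(top-$k$% versus rest across cutoffs).

**A calibration caveat.** The evaluation model contains no
$\mathrm{PRS}_{GT}$ main effect. If the fitted interaction weights carry
prognostic signal that $\mathrm{PRS}_G$ misses — which the fine-tuning step
produces by construction whenever the pre-trained prognostic score is
imperfect — that signal reaches the outcome through the treated half of the
sample and biases the interaction coefficient away from zero even when no
true interaction exists. The interaction p-value is therefore
anti-conservative as a test of pure interaction for the fine-tuned scores;
it is well calibrated for proportional scores such as a disease PRS
evaluated under the proportionality convention
($\mathrm{PRS}_{GT} = \mathrm{PRS}_G$). Centering $T$ inside the interaction
regressor (`center_t = TRUE`) zeroes the population coefficient under the
null for *any* fixed weights and removes the first-order bias; a residual
second-order effect remains because the missed prognostic signal also makes
the errors heteroskedastic in a way aligned with the regressor, which a
plain OLS t-test does not account for. Interpreting the p-value as a
selection signal (as in parameter tuning and method comparison) is
unaffected; interpreting it as a calibrated test of interaction requires
the centered variant plus robust standard errors, which the package does
not currently provide. The acceptance suite asserts the nominal-level
behavior for the fine-tuned pipeline and documents the observed violation
rather than hiding it.

## The simulator

`sim_scenario()` + `simulate_effects()` / `simulate_genotypes()` /
`simulate_sumstats()` / `simulate_phenotypes()` generate the full study:

* **Effects.** Each SNP is causal with probability $p$; causal triples
  (disease effect $\mu_j$, prognostic $\beta_j$, predictive $\alpha_j$) are
  multivariate normal with covariance $\tfrac{h_T^2}{mp}\,\Omega$, where
  $\Omega$ has unit diagonal and correlations
  $\mathrm{corr}(\mu,\beta) = \rho_{DT}$,
  $\mathrm{corr}(\beta,\alpha) = \rho_E$,
  $\mathrm{corr}(\mu,\alpha) = \rho_{DT}\rho_E$. Taking $m$ as the *total*
  SNP count makes the expected total genetic variance equal $h_T^2$
  independently of $m$, and the suite checks that invariance empirically.
  Partial causal sharing splits the causal set into shared, disease-only
  ($\beta=\alpha=0$) and drug-only ($\mu=0$) groups with
  variance-preserving marginals.
* **Genotypes.** Block-exchangeable (or AR-1) latent Gaussians thresholded
  into Hardy–Weinberg dosages at MAFs drawn from `maf_range`. This emulates
  block LD at a chosen strength; it does not reproduce any real
  chromosome's LD map, allele-frequency spectrum, or long-range structure,
  so tests passing under it speak to the method's logic, not to performance
  on real genomes.
* **Summary statistics.** $\hat\mu_j \sim N(\mu_j, s_j^2)$ with
  $s_j = 1/\sqrt{2 n_{\mathrm{base}} f_j (1-f_j)}$ when no SE vector is
  supplied; true standardized effects are converted to the per-allele scale
  before perturbation so z-scores are internally consistent. P-values are
  the two-sided normal tails.
* **Phenotypes.** $Y = \beta_T T + Z\beta + (Z \circ T)\,\gamma\alpha +
  \epsilon$ with $T \sim \mathrm{Bernoulli}(0.5)$ and
  $\sigma^2 = \widehat{\mathrm{Var}}(\mathrm{genetic})\,(1-h_D^2)/h_D^2$
  computed from the *realized* genetic component, so each generated dataset
  hits its target heritability rather than only in expectation.

Default study conditions: $m = 2000$ SNPs, $p = 0.01$, $h_T^2 = 0.5$,
$h_D^2 = 0.3$, $\rho_{DT} = \rho_E = 0.5$, $\gamma = 1$, $\beta_T = 0.5$,
$n_{\mathrm{train}} = 4000$, $n_{\mathrm{test}} = 1000$,
$n_{\mathrm{base}} = 10^5$, MAF in $(0.05, 0.5)$, LD blocks of 20 SNPs at
latent correlation 0.3. The cohort sizes, $h_T^2$ and $\beta_T$ are package
defaults chosen as typical values for a well-powered phase-3 PGx GWAS fed
by a large disease consortium; the SNP count is a deliberate scale-down
from genome-wide panels so that full pipelines run on a single CPU. Effects
are interpreted on the standardized-dosage scale throughout, which keeps
the variance bookkeeping exact and matches the scale on which the descent
operates.

`run_scenario()` chains the whole pipeline per repeat — effects, genotypes
(training and test drawn jointly so allele frequencies are shared),
phenotypes, summary statistics, baseline weights (training genotypes double
as the LD reference panel), inner-CV tuning, final fit, evaluation on the
independent test set — and collects per-repeat failures instead of aborting
a batch.

## Problem sizes used by the shipped tests

Unit and property tests run on cohorts of tens to hundreds of samples. The
end-to-end suite uses: 20 random 50×10 systems for the ridge-oracle check;
a 200×50 cohort for brute-force grid enumeration; 50 000 effect draws for
simulator moments and $n = 10^4$ for heritability recovery; 400 replicates
at $m = 500$, $n_{\mathrm{test}} = 1000$ ($n_{\mathrm{train}} = 600$,
clumping+thresholding baseline) for the null-interaction size check; 20
paired-seed repeats at $m = 2000$, $n_{\mathrm{train}} = 4000$ for the
baseline comparison across $\rho_{DT} \in \{0.2, 0.5, 0.8\}$ (the
transfer-learning fit is run at the central value, the baseline trend at
all three); and 8 repeats per $\gamma \in \{0.5, 5\}$ for the
predictive-dominance sweep.

## Known limitations

* Continuous outcomes only; binary/time-to-event endpoints would change the
  loss and the update rule.
* One shared $\lambda$ for both effect blocks; an L1 variant (coordinate
  descent) is not implemented.
* The interaction p-value caveat above: no robust-variance option yet.
* The synthetic LD generator is exchangeable/AR-1 per block; clumping and
  the LD-aware lasso behave qualitatively, not quantitatively, as they
  would on real panels.
* The summary-statistic lasso is a stand-in; users reproducing published
  baselines should import externally computed weight files instead.
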