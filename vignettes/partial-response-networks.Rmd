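---
title: "Partial response networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial response networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Clinical risk models for tabular registry data face a tension: flexible
classifiers (neural networks, boosted ensembles) capture nonlinearities and
interactions, but clinicians must be able to see *why* a patient is scored
high or low, both to trust the model and to audit it for encoded bias. The
partial response network (PRN) resolves this by extracting from a trained
black-box classifier an additive model whose terms are explicit functions
of one or two predictors, and then retraining that additive structure so
no predictive performance is given away.

Write the black box's log-odds as $g(x) = \mathrm{logit}\,P(Y=1\mid x)$.
With all predictors standardized so the data median maps to the zero
vector, the *anchored* (cut-type) functional ANOVA decomposes $g$ around
the anchor $c = 0$:

$$
g(x) = g(c) + \sum_i f_i(x_i) + \sum_{i<j} f_{ij}(x_i, x_j) + \cdots
$$

with

$$
f_i(t) = g(c_{\,i \to t}) - g(c), \qquad
f_{ij}(s,t) = g(c_{\,i \to s,\, j \to t}) - f_i(s) - f_j(t) - g(c),
$$

where $c_{\,i\to t}$ means "the anchor with coordinate $i$ replaced by
$t$". Including all orders the identity is exact; truncating after pairs
leaves a residual that is entirely attributable to third- and higher-order
components. Each $f_i$ is a *partial response*: the additive contribution
of predictor $i$ to the log-odds, which is exactly zero when the patient
sits at the median. That anchoring is what makes the later imputation and
explanation conventions coherent: a median-imputed value contributes
nothing, and a per-patient explanation is a sum of term contributions plus
a global intercept.

The full procedure is:

1. **Fit** a single-hidden-layer MLP to the standardized, imputed table.
2. **Decompose** its logit into all univariate and bivariate partial
   responses anchored at the median.
3. **Select** by treating each response, evaluated on the data, as one
   feature of an L1-penalized logistic regression (a GAM over responses):
   the lasso collapses uninformative responses to exactly zero.
4. **Rebuild and retrain**: map the selected GAM onto a modular
   self-explaining network — one subnetwork per retained response, each a
   replica of the base network's hidden layer restricted to its own
   variable(s) — initialized to reproduce the lasso-GAM *exactly*, then
   retrained by backpropagation.
5. **Re-decompose and re-select** on the retrained network's logit. The
   result is the final PRN-Lasso, a sparse GAM with main effects and
   pairwise interactions whose interpretation is the model itself.

```{r pipeline}
library(prnet)
spec  <- registry_spec(n = 20000, seed = 1)
data  <- simulate_registry(spec)
anchor <- compute_anchor(data)
std   <- impute_zero(standardize(data, anchor))

mlp    <- fit_mlp(std, seed = 1)
decomp <- decompose_logit(mlp, std)
feats  <- response_features(decomp, std)
gam    <- select_responses(fit_response_lasso(feats, std$outcome, seed = 1))
prn    <- retrain_prn(build_prn(mlp, gam), std, seed = 1)
final  <- prn_to_lasso(prn, std, seed = 1)

explain(final, std[1:3, ])
export_nomogram(final, anchor = anchor)
```

## Anchoring, standardization and imputation

`compute_anchor()` centres every continuous column at its sample median
(even `n`: the mean of the central pair) and every binary or indicator
column at its modal value, with an exact 50/50 tie anchored at 0 so
explanations stay reproducible. The scale is the sample standard
deviation; centring at the median is the load-bearing choice (it fixes
where all responses vanish), while the scale only conditions network
training, so the SD is used for compatibility with standard initialization
heuristics. Constant columns are rejected.

Two imputation schemes mirror registry practice. For scoring and
validation, `impute_zero()` sets missing standardized entries to 0 — the
column median — so a missing value contributes nothing to any partial
response. For model development, `impute_donors()` implements stacked
multiple imputation: each missing cell is replaced `m = 10` times by an
observed value drawn uniformly *with replacement* from the same column
within the same stratum (e.g. a transplant-era band), and the 10 completed
copies are concatenated into one table. No Rubin's-rules pooling is
applied; the stacked table is the derivation cohort, and the random
fluctuations across copies counterweight each other. Sampling with
replacement is one defensible reading of donor-based "probability
imputation"; it is flagged here because without-replacement or weighted
donors would be equally defensible. Rows with a missing outcome are
rejected rather than imputed.

## The base network and its training

The black box is deliberately modest: one tanh hidden layer, logistic
output, full-batch Adam on the binomial log-loss with an L2 weight penalty
(default `1e-3`), early stopping on a 20% held-out split (patience 20,
cap 500 epochs), and width chosen by validation loss over `{4, 8, 16}`.
This echoes the scale of clinical ANNs for tabular registry data; deeper
or ensembled architectures are out of scope. Smoothness matters more than
raw accuracy here: the L2 penalty keeps the anchored cuts — 1-d and 2-d
slices through the fitted surface — smooth enough to be meaningful
response estimates. All randomness (initialization, split) derives from
one seed, and a serialized model (`write_model()`, 17 significant digits)
reloads bit-exactly.

## Decomposition details and numerical choices

- **Grids.** Continuous responses are tabulated on 101 equally spaced
  training-data quantiles with the anchor inserted and duplicates removed;
  binary columns on their two standardized levels. Grids exist for
  serialization, plotting, nomograms and explanations only.
- **Model-direct evaluation.** Features for the lasso and reconstruction
  residuals always call the model itself rather than interpolating the
  stored curves; that keeps the exactness identities testable to 1e-8
  rather than to interpolation error.
- **Exact zeros.** Within each grid batch the anchor row of the same batch
  is subtracted, so the anchored-zero and slice-zero identities hold
  *exactly* in floating point, not merely to rounding, regardless of BLAS
  batching.
- **Interpolation contract.** Off-grid evaluation is piecewise linear,
  with linear extrapolation from the terminal segment — deliberately, so a
  monotone era effect can be projected forward in time. Binary axes are
  exact lookups; any other value errors.
- **Pair budget.** All `d(d-1)/2` pairs are enumerated by default;
  `max_pairs` keeps the top pairs by grid variance for wide tables.

## Selection

Response features are *not* re-standardized before penalization: they
already live on the logit scale, where a coefficient of 1 means "this
response passes through to the log-odds as estimated". Equal penalization
on that scale is the interpretable default; `standardize = TRUE` is
available for sensitivity analysis. The path uses 100 log-spaced lambdas
down to `1e-4` of the all-zero lambda (glmnet's conventions), 10-fold
cross-validated deviance with seeded fold assignment, and the CV-minimum
rule by default with the 1-SE rule available. The entry order of responses
along the path (which terms survive the harshest penalty) is reported as
part of the selection diagnostics.

## The modular network

Each retained response becomes a module: a replica of the base hidden
layer restricted to the response's variable(s), all other inputs clamped
at the anchor. Because the standardized anchor is the zero vector,
clamping is just zeroing the non-member input weights. A univariate module
outputs $s\,(h(x_i) - h(0))$ and a bivariate module the shared-weight
inclusion-exclusion $s\,(h(x_i,x_j) - h(x_i,0) - h(0,x_j) + h(0,0))$, with
the output scale $s$ initialized to the lasso coefficient and the global
intercept to the lasso intercept. Two consequences are worth stating:

- **Initialization exactness.** The PRN's logit equals the lasso-GAM's
  logit identically at build time (the output bias cancels in the
  differences), which is asserted to 1e-8 on random rows in the tests.
- **Structural invariants.** Modularity (a module's output cannot depend
  on a non-member input) and the anchored-zero identities are properties
  of the architecture, not of the training state; they survive any number
  of retraining epochs without a re-centering pass, because the
  inclusion-exclusion form subtracts the module's own anchor evaluation
  with the current weights. The re-centering shift that would otherwise be
  absorbed into the intercept is identically zero.

Retraining updates module weights, output scales and the intercept
jointly (full-batch Adam, learning rate 0.01, patience 20, cap 500 epochs,
seeded 20% validation split); the lasso coefficients are absorbed into the
trainable scales rather than frozen. The second selection pass restricts
candidates to the network's own modules — the PRN cannot contain effects
outside them, and re-admitting new pairs would reintroduce the noise the
first pass removed. For an additive-by-construction network the anchored
decomposition recovers each module's own function exactly, so the
second-pass features are the module outputs themselves; the tests verify
this identity against generic anchored cuts of an opaque wrapper.

## Evaluation statistics

Discrimination is the AUROC under the mid-rank convention, with DeLong
structural-component variance for confidence intervals and the paired
DeLong test for comparing two models on the same rows (two-sided
throughout; identical score vectors return p = 1 with a warning).
Calibration uses the Hosmer-Lemeshow chi-square on deciles of risk —
equal-count groups by sorted probability with ties kept together, the
Stata-compatible convention, since grouping conventions change the
statistic — with `groups - 2` degrees of freedom, plus the
expected/observed event ratio and calibration-in-the-large (the intercept
of a logistic recalibration at slope fixed to 1, per TRIPOD; the free
recalibration slope is reported alongside). These engines are implemented
from their definitions and cross-checked in the tests against pROC and
against bootstrap and null-simulation oracles.

## The synthetic registry and what it does (not) show

Real transplant-registry data are restricted-access, so the package ships
a generator whose defaults emulate the *structure* of such a table: two
age-like bells (recipient 54 ± 13 truncated to adults, donor 33 ± 11), an
ischemic-time bell (184 ± 64 min), a right-skewed creatinine
(log-normal, median 106), a continuous era drift (1997–2019), and rare
binary flags (ventilator 2.6%, infection 10%, female 25%, ICM diagnosis
38%). The generating logit contains three shaped main effects — a U-shaped
recipient-age effect (amplitude 0.25 per squared SD), a linear donor-age
effect (0.4 per SD), an ischemic-time hinge switching on at 210 min (3.5
h; 0.5 per SD) — one recipient-age-by-ICM interaction (0.4 per SD,
protective for younger ICM recipients), five null columns, and an
intercept of −2.45 giving a prevalence near 0.12, matching the scale of
1-year mortality in the motivating cohorts. Missingness, when requested,
is MCAR on predictors only.

Because every effect is stored in closed form, the generator doubles as an
oracle: re-anchoring the truth at the empirical median conserves the
generating logit to 1e-10, and the recovery checks compare the final
PRN-Lasso's responses against the anchored truth over the central 90%
data mass of each variable. What passing these checks does *not* show:
robustness to correlated predictors (the generator draws columns
independently), to informative missingness, or to the measurement drift
of real registries. The interaction's anchored slice at the unexposed flag
level is identically zero, so the anchored truth also induces a small
main-effect component for the flag (of order 0.01 logits here); components
below 0.05 logits are treated as null in recovery summaries.

## Problem sizes and reproducibility

The heavier checks run the whole pipeline on 20 replicates of the default
preset (20,000 training and 5,000 held-out rows each); engine-calibration
checks use 1,000 simulation replicates (paired-test size at n = 200,
interval coverage at n = 500, goodness-of-fit null at n = 5,000). These
sizes were chosen so that selection frequencies and rejection rates have
usable Monte Carlo precision on a single CPU. Every stochastic stage
derives its seed deterministically from one global seed plus the stage
name; `run_pipeline()` writes a manifest of MD5 hashes, and re-running an
identical configuration reproduces the artifacts byte for byte (model
files are exact to 1e-12 across platforms where BLAS summation order
differs; on one platform they are bit-identical).

## Known limitations

- Partial responses carry no uncertainty bands; sparse extremes (very high
  creatinine, long ischemic times) are exactly where the curves are least
  stable, and a confidence procedure is future work.
- The CV-minimum selection rule is liberal: the first pass often retains
  small spurious responses, relying on retraining plus the second pass to
  prune them. The 1-SE rule is stricter and available throughout.
- The anchored decomposition attributes shared signal between correlated
  predictors to whichever cut meets it first; on strongly collinear
  tables the univariate attributions should be read jointly.
- Donor imputation samples uniformly with replacement; informative
  missingness would bias both imputation schemes.
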