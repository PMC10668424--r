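---
title: "Validating multiclass risk models for adnexal masses: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating multiclass risk models for adnexal masses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ovarisk` compares algorithms that estimate, before surgery, the
probability that an adnexal mass is benign, borderline, stage I primary
invasive, stage II–IV primary invasive, or a secondary metastasis. This
vignette explains the statistical machinery, the assumptions behind it,
and the design decisions taken where more than one defensible choice
existed.

## The evaluation problem

A five-class risk model maps nine clinical and ultrasound predictors to
a probability vector $p = (p_1,\dots,p_5)$, $\sum_k p_k = 1$. External
validation asks three questions: does the model *rank* patients
correctly (discrimination), are the probabilities *numerically right*
(calibration), and does acting on them *help* (clinical utility)?
Because validation data come from many centers with different case mix,
every summary here can be computed per center and pooled by
random-effects meta-analysis, with a 95% prediction interval describing
the performance to expect in a new center.

## Discrimination

The **Polytomous Discrimination Index** generalizes the AUROC: draw one
patient from each class and a target class $k$ at random; the model
scores when the class-$k$ patient has the largest $p_k$ in the tuple.
Ties receive fractional credit $1/m$ when $m$ tuple members (including
the class-$k$ patient) share the maximum. This tie rule is not optional
bookkeeping: it is what makes a constant model score exactly
$1/K = 0.2$ and an indicator model exactly 1, the two anchor points of
the index. The package computes PDI three ways — exhaustive tuple
enumeration, an algebraically identical per-class rank count
($O(n\log n)$, used for real cohorts), and Monte-Carlo sampling with a
standard error. The estimators are cross-checked against each other in
the test suite on random instances; `estimator = "auto"` enumerates
exhaustively up to $10^6$ tuples and rank-counts beyond.

**Pairwise c-statistics** use the conditional-risk construction: for
classes $k,l$ the score $p_l/(p_k+p_l)$ is ranked among patients truly
in one of the two classes (Mann–Whitney ties at 1/2). When
$p_k+p_l = 0$ the pair carries no information and the conditional risk
is set to 0.5 rather than dropping the patient — this keeps $n$ fixed
and reads naturally as "no information". The binary
benign-vs-malignant AUROC uses $1-p_{\text{benign}}$ as the risk of any
malignancy.

## Calibration

Per class, a **flexible calibration curve** smooths the one-vs-rest
event indicator on the predicted probability by local *linear*
regression (span 0.75, evaluated on a 101-point grid over the observed
range, clipped to $[0,1]$). The span, degree and grid are fixed for
reproducibility and exposed as arguments. Center-specific curves
(minimum 20 patients and both outcome levels; smaller centers are
logged and contribute to the pooled evaluation only) are averaged
pointwise with $\sqrt{n_c}$ weights, on grid points covered by at least
two centers.

Curves are summarized by the **rescaled Estimated Calibration Index**:

$$\mathrm{ECI} = \frac{\frac1n\sum_i (p_i - c(p_i))^2}
                      {\frac1n\sum_i (p_i - \bar y)^2},$$

where $c(\cdot)$ is the calibration curve and $\bar y$ the event rate.
The denominator is the unique simple scaling that satisfies both
defining endpoints — 0 when the curve coincides with the diagonal, 1
when it is horizontal at the event rate; values above 1 (calibration
worse than no predictive ability) are possible and reported as is. The
index is undefined (and errors) when all predictions equal the event
rate. ECI is computed against the pooled, center-averaged curve using
all patients.

## Clinical utility

Net Benefit at threshold $t$ is $TP/n - (FP/n)\,t/(1-t)$, with
"positive" meaning estimated malignancy risk $\ge t$ (closed at the
threshold, matching the clinical referral rule "risk of at least
10%"). Decision curves cover $t$ from 5% to 40% in 1% steps, against
treat-all and treat-none. Center-specific Net Benefit is pooled by the
same random-effects method as the discrimination metrics, with
within-center variances from the binomial delta method
($\mathrm{Var} = [p_{tp}(1-p_{tp}) + w^2 p_{fp}(1-p_{fp}) +
2wp_{tp}p_{fp}]/n$, $w = t/(1-t)$). A deterministic frequentist
DerSimonian–Laird model is used throughout — including for Net Benefit,
where a Bayesian hierarchical model is sometimes used instead; the
frequentist intervals will not match a Bayesian model's exactly, which
we accept for determinism and zero extra dependencies. The
treat-all/model difference is also re-expressed as net unnecessary
referrals avoided per patient, $(NB_{model} - NB_{all})(1-t)/t$.

## Meta-analysis

Pooling uses DerSimonian–Laird: method-of-moments $\tau^2$ from
Cochran's $Q$, inverse-variance weights $1/(v_c+\tau^2)$, Wald 95% CI,
and the Higgins–Thompson 95% prediction interval
$\mu \pm t_{k-2,0.975}\sqrt{\tau^2 + SE(\mu)^2}$ (undefined for
$k = 2$, flagged). Proportions and c-statistics are pooled on the logit
scale with delta-method variances. Within-center variances come from a
seeded nonparametric bootstrap (200 replicates) unless a closed form is
supplied. A center contributes to a metric only where the metric is
computable — PDI needs all five classes present, so its pool may use
fewer centers than the binary AUROC's; exclusions are logged, never
silent. Known limitation, verified in our simulations: the prediction
interval holds its nominal 95% coverage when between-center
heterogeneity dominates within-center noise, but undercovers (~90%)
when $\tau^2$ is comparable to the within-center variances — a
documented property of the DerSimonian–Laird/Higgins–Thompson
combination, not of this implementation.

## The model zoo

Six algorithms, each with and without CA125. For the MLR variants,
continuous predictors (age, log CA125, solid proportion, diameter)
enter via restricted cubic splines with 3 knots at the 10th/50th/90th
percentiles (truncated-power basis, linear tails; cross-checked against
the natural-spline function space in the tests). CA125 is
log-transformed before spline expansion because of its heavy right
skew. We apply splines in *both* standard and ridge MLR — the ridge
model penalizes all non-intercept coefficients of its standardized
design, and there is no reason to grant it a poorer functional form.
Papillations enter as an ordinal 0–4 score for MLR/NN/SVM and as a
categorical factor for the tree ensembles. NN and SVM inputs are
standardized with training-set constants. SVM probabilities come from
per-pair Platt scaling combined by pairwise coupling (the libsvm
route). Random intercepts by center are deliberately not used.

Hyperparameters are tuned by stratified 10-fold cross-validation,
maximizing the mean out-of-fold multinomial log-likelihood — a proper
scoring rule, chosen over accuracy-type criteria for consistency with
the calibration focus. The default grids (ridge $\lambda \in
10^{-4..4}$, 25 points; RF mtry/min-node; XGBoost depth/eta/subsample
with rounds by early stopping on the folds; NN size/decay; SVM
$C/\gamma$) are conventional for tabular data of a few thousand rows
and are configuration, not code. If the smallest class has fewer
members than folds, the fold count drops with a warning. The selected
candidate is refit on the full development data. With multiple
imputation, tuning is done once on the first completed development
dataset and the selected hyperparameters are reused across completed
datasets — retuning per imputation would multiply cost for little
benefit, since completed datasets differ only in 30% of one column.

## Missing CA125 and multiple imputation

CA125 is missing for roughly 30% of patients, and *less* often for
suspicious tumors (measurement follows suspicion). Since CA125 is the
only incomplete variable by design, chained equations reduce to a
single imputation model: Bayesian linear regression of log CA125 on the
eight other predictors plus the outcome class (outcome-inclusive
imputation is standard in prediction research), with predictive mean
matching (donor pool 5) so imputed values are always observed, positive,
realistically skewed CA125 values. Development and validation cohorts
are imputed independently. Downstream, a with-CA125 model is trained on
each completed development dataset and its predictions averaged over
all $m \times m'$ development/validation completions before any metric
is computed; without-CA125 models ignore CA125 entirely and use a
single non-imputed path. The per-patient averaging rule is the simplest
defensible combination; users evaluating single completions will see
(slightly) different numbers.

## The synthetic cohort generator

The generator emulates the multicenter structure the analysis assumes:
uneven center sizes; center-level class prevalences drawn from a
Dirichlet around the global prevalences (default 62% benign, 8%
borderline, 7% stage I, 18% stage II–IV, 5% secondary metastatic, the
case mix of a validation-type cohort of 3199 patients across 25
centers); oncology referral centers tilted toward malignancy with the
non-oncology centers compensatingly deflated so the marginal case mix
stays at the configured prevalences. Predictor marginals per class:
truncated-normal age (sd 14, means rising 45→58 from benign to
advanced), log-normal CA125 (medians 16→300 U/mL) and diameter,
zero-inflated Beta solid proportion (point mass at 0 reproducing the
all-cystic quartile), class-specific Bernoulli/categorical binaries and
papillations. Parameters were calibrated once so that at large $n$ the
cohort lands near the intended descriptive profile (median age ≈ 49,
median CA125 in the 15–45 U/mL band, median diameter ≈ 70 mm, 25th
percentile of solid proportion = 0, class proportions within 3 points)
— the tests assert those bands. CA125 missingness is injected with
measurement probability logistic in a suspicion score (solid
proportion + ascites + papillation score), the intercept calibrated by
root finding to hit the target rate exactly in expectation.

What the generator does **not** emulate: the true joint dependence
structure of ultrasound predictors beyond class-conditional marginals,
examiner and kit effects on CA125, or center-predictor interactions.
Passing tests on synthetic cohorts therefore demonstrates correctness
of the *evaluation machinery* and of the fitting pipeline, not clinical
performance on real patients.

A second mechanism, `generate_from_latent_mlr()`, draws outcomes from a
known multinomial-logistic truth (softmax of a user-supplied
$10 \times 4$ coefficient matrix over intercept + nine features, benign
as reference) and returns every patient's true probability vector. This
gives the package an internal oracle: parameter recovery of the MLR
fit, PDI of the fitted model versus PDI of the true probabilities, and
the class-frequency identity $\mathbb{E}[p_k] = \Pr(Y = k)$ are all
tested against it.

## Numerical choices and degenerate cases

* Probability rows are validated to sum to 1 within $10^{-8}$; model
  outputs are clipped to $[0,1]$ and renormalized.
* Log-likelihoods clip probabilities at $10^{-12}$.
* Loess uses `statistics = "none"` and approximate trace, making the
  100{,}000-patient calibration fits take well under a second without
  affecting the fitted surface.
* Spline knot placement falls back to a linear term when a predictor
  has too few distinct values for strictly increasing knots.
* Bootstrap replicates that lose a required outcome class are dropped;
  a center whose variance cannot be stabilized (fewer than a quarter of
  replicates usable) is excluded with a logged reason.
* Within-center variances are floored at $10^{-10}$ in the pooling
  weights to tolerate homogeneous centers.
* All randomness flows from one root seed, from which named sub-seeds
  (generation, imputation, folds, model fitting, bootstrap) are derived
  and recorded in the experiment manifest; reruns are byte-identical.

## Problem sizes

The shipped experiment configuration runs the full comparison at a
deliberately desk-friendly scale — development 1500 / validation 800
patients over 5 centers, all six algorithms in both CA125 variants,
$m = 2$ imputations, compact tuning grids — which completes in a few
minutes on one CPU while exercising every code path, including
meta-analysis, curve averaging and all exports. Simulation-based test
targets use $n$ between 10{,}000 and 100{,}000 where a law-of-large-
numbers argument sets the tolerance. These sizes are the package's own
validation choices; real analyses should use the default grids and
$m = 10$.

## Known limitations

* The rescaled ECI depends on the fitted curve near the boundary of
  the predicted range, where loess is noisiest; with heavily clustered
  predictions the index is less stable than in the interior.
* Prediction-interval undercoverage in low-heterogeneity regimes (see
  above).
* The SVM's coupled probabilities are a post-hoc transformation of
  margins; its calibration is structurally worse than that of the
  likelihood-based models, and the ECI reflects that honestly.
* No multivariate meta-analysis across categories, no meta-regression,
  no cost-weighted utility beyond binary Net Benefit.
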