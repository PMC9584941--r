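---
title: "Methods: node-level evaluation of sensitivity-calibrated PET/CT classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: node-level evaluation of sensitivity-calibrated PET/CT classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodalpet)
```

## Scope and unit of analysis

`nodalpet` evaluates classifiers that predict, for an individual sampled
lymph node of a stage-III NSCLC patient, whether EBUS-TBNA histopathology
will find tumour. The node — not the patient — is the unit of analysis:
one patient contributes several nodes across up to three echelons of the
lymphatic drainage (1 = ipsilateral hilum, 2 = ipsilateral central
mediastinum, 3 = upper/contralateral mediastinum or contralateral hilum).
All patient-level covariates are denormalised onto node rows, and a single
CSV schema serves both real-world exports (no latent truth) and synthetic
cohorts (truth present).

## The generative model

The synthetic generator emulates the statistical structure of a published
cohort of 180 patients and 675 sampled nodes, so that calibration and
cross-validation code can be exercised — and its parameter-recovery
behaviour verified — without access to patient data.

Per patient $i$: primary-tumour SUVmax is log-normal with median 14.65 and
5th–95th percentiles 4.85–30.35; laterality is right-sided with
probability 337/675 and histology adenocarcinoma with probability 304/675;
the node count per echelon is Poisson with means 169/180, 297/180 and
209/180, giving 675 nodes in expectation (a patient drawing zero nodes is
redrawn once, then accepted).

Per node $j$ at echelon $e$: latent involvement is Bernoulli with
prevalence 0.86, 0.42 or 0.096 by echelon. Involved nodes follow

$$\log \mathrm{SUV}_{ij} = \beta_0 + 0.55 \,\log \mathrm{SUV}^{\mathrm{prim}}_i
  + \delta_e + \varepsilon_{ij},\qquad \varepsilon_{ij} \sim N(0, \sigma^2_{\mathrm{res}}),$$

with echelon offsets $\delta_1 = 0$, $\delta_2 = -0.328$,
$\delta_3 = -0.422$. The intercept is calibrated so the median echelon-1
involved node at the median primary has SUVmax 10.6
(`calibrate_positive_intercept()`, giving $\beta_0 \approx 0.885$).
Uninvolved nodes draw log SUVmax from a log-normal with median 2.43 and
5th–95th percentiles 0.90–5.30, independent of the primary. CT short-axis
diameters are log-normal per echelon-by-status cell, fitted to the
published median/interquartile summaries. EBUS observes truth with
configurable sensitivity (default 1; 0.85 in combined-test experiments)
and perfect specificity.

Distributional choices and their rationale:

* **Log-normal throughout.** Node uptake and size are positive and
  right-skewed, and log-uptake of involved nodes is close to normal; a
  two-parameter family fitted from a median plus one quantile pair
  (`lognormal_from_quantiles()`) matches the median exactly and the
  quantile *ratio* exactly. An asymmetric pair (such as the negative-node
  5th–95th percentiles) over-determines two parameters; the fit keeps the
  median and the spread, which is what the downstream checks use. When
  both an IQR and a 5–95% range are available, the IQR wins: it is more
  central and less tail-sensitive.
* **Residual spread by variance decomposition.** The marginal sd of log
  SUVmax of echelon-1 involved nodes is 0.668 (from the quartile ratio
  6.5–16.0); subtracting the part explained by the primary,
  $0.55^2 \cdot \sigma^2_{\mathrm{prim}}$, leaves
  $\sigma_{\mathrm{res}} \approx 0.59$. This is computed at config time
  and overridable. (A published fit correlation of ≈ 0.45 for the
  covariance model would imply a somewhat different residual; the
  quartile-matching default was chosen and kept.)
* **Truncation instead of rejection.** EBUS samples nodes of ≥ 0.5 cm, and
  conglomerate/diffuse-infiltration masses belong to the largest size
  group (≥ 6 cm). Both constraints are imposed by exact inverse-CDF
  truncation of the log-normal, which is distribution-identical to
  rejection sampling but cannot stall when the constraint sits far in a
  tail. Conglomerate nodes (Bernoulli, 3%) draw their diameter from the
  widest involved-node distribution (echelon 1) truncated at 6 cm.
* **Independence given echelon.** Node involvement is independent across
  nodes given the echelon. Real cohorts show intra-patient correlation of
  spread (the station-4R crossover flag and the largest echelon-2 SUVmax
  are exactly such features); the generator produces those features
  marginally but does not model the correlation, so passing tests
  demonstrate calibration of the marginals and of the uptake regression,
  not of within-patient dependence.
* **Seeding.** One root seed; draws occur in a documented order (patients
  in sequence; within a patient: primary, laterality, histology, counts,
  then nodes echelon-ascending; the auxiliary echelon-2 background draw
  last), so a fixed seed reproduces a cohort bit for bit.

The feature `largest_suv_echelon2` for a patient with no sampled echelon-2
node is one auxiliary draw from the uninvolved-node distribution — an
unsampled background node — keeping the covariate defined everywhere
without leaking truth.

## Classifiers

The multivariable logistic model uses the raw covariates (SUV units, cm),
echelon dummies with echelon 1 as reference, and SUVmax-by-echelon
interaction products; reference (dummy) coding was chosen because the
reported contrasts are "versus echelon-1" (an effect-coding variant would
change the intercept's meaning but not the fitted probabilities). Case
weights implement the sensitivity calibration: weight $w$ for
EBUS-positive nodes, 1 for negatives, normalised to sum to the sample
size so the Fisher information stays on the unweighted scale.

Fitting is iteratively reweighted least squares on the weighted Bernoulli
log-likelihood with step-halving on any likelihood decrease, tolerance
$10^{-8}$ on the maximum coefficient change, and at most 100 iterations.
Complete separation is detected when a coefficient exceeds 30 on
internally standardised inputs; the core fitter raises an error, while the
cross-validation trainer (`logistic_trainer()`) instead stops at the guard
and keeps the finite coefficients — a separated training subsample should
still score its leave-out fold, and its saturated predictions are exactly
what the selection rule needs. The trainer also drops linearly dependent
columns of a subsample (a rare binary flag can be constant within a fold)
before fitting. Wald $\chi^2$ tests use the inverse weighted Fisher
information; the echelon dummies and the interaction pair are tested
jointly on 2 df.

The tree-ensemble backend is a probability random forest (`ranger`, 200
trees by default) and reports both the number of splitting rules per
variable and out-of-bag permutation loss reduction, which can legitimately
be negative for uninformative inputs. Case weights are not used by this
backend; its operating point is set through the probability cut-off alone.
The feed-forward backend is a single-hidden-layer perceptron (`nnet`,
8 units, weight decay 0.01, cross-entropy loss) supporting case weights;
one hidden layer of modest width is adequate for 12 tabular features and
keeps the training deterministic and fast. Hyperparameters are config
values, not search targets.

## Calibration and nested cross-validation

An operating point is a (weight, cut-off) pair. `cutoff_for_sensitivity()`
returns the **largest** observed score $c$ whose rule
$\mathrm{score} \ge c$ reaches the target sensitivity — the most specific
qualifying threshold under the at-or-above convention.
`weight_for_sensitivity()` walks an increasing integer grid (default 1–20,
which contains the classically used weights 3 and 9) and returns the
smallest weight whose cross-validated sensitivity at a fixed cut-off of
0.5 reaches the target; the calibration is data-driven, never hard-coded,
and a failed calibration is an error object carrying the best achieved
value. The experiment driver treats weight calibration as centring the
operating point near 0.5: if no grid weight reaches the lowest target on a
given cohort, the best-achieving weight is kept and the cut-off step —
which can always reach any target on the cross-validated scores — enforces
the ladder. Calibration sensitivities are always computed on
cross-validated scores, not resubstitution.

Cross-validation is threefold: uniform random keys, sorted, split into
near-equal blocks. The nested inner loop subdivides each outer training
set into five samples *with equal probability* (so inner sizes are
random); each of the five candidate models trains on the other four
samples, and candidates are ranked **on their own training data** at
cut-off 0.5 by highest sensitivity first, highest specificity second —
the stated selection rule, kept despite its optimism because the ranking,
not an unbiased error estimate, is its purpose. Ties break towards the
lowest inner-sample id (no tie rule is stated anywhere; a deterministic
one is required for reproducibility). An empty inner sample is redrawn
with an incremented seed and logged. Every record is scored exactly once,
by a model that never saw it.

One caveat on determinism: the fold assignment consumes one uniform draw
per record in record order, so scores are reproducible given the seed and
record order; permuting records permutes the random keys and hence the
folds. Determinism is therefore specified as "same seed, same data, same
order".

## Evaluation statistics

Confusion cells are real-valued so that expected (fractional) counts from
the combined-test arithmetic flow through the same `metrics()` code
(sensitivity, specificity, MCR, FDR; undefined ratios return `NA` rather
than raising). `reconstruct_confusion()` inverts the common reporting
format (MCR + false negatives + totals) into a full table, rounding
$\mathrm{MCR}\cdot n$ to the nearest integer.

The weighted exact McNemar test generalises the classical one: each
discordant record (exactly one classifier correct) contributes its
normalised case weight — `weight_mcn` for reference-positive records, 1
for negatives, renormalised to sum to $n$ — and the weighted discordant
totals are rounded to integers $b^\*, c^\*$ before the two-sided exact
binomial $p = \min(1,\, 2\,P(\mathrm{Bin}(b^\*+c^\*, 1/2) \le \min(b^\*,c^\*)))$.
Normalise-then-round is an interpretation of how weighted frequencies
enter an exact test (the weighting procedure's reference implementation
does not document its convention); at weight 1 the path is exactly the
classical exact test, verified against enumeration. Fisher's exact test,
the Kruskal–Wallis test and the linear models delegate to `stats`; AUC
variances and paired AUC contrasts use the DeLong estimator via `pROC`,
with ties at half credit and Wald intervals clipped to [0, 1]. Type III
F tests are computed by full-versus-reduced model comparison (drop-last),
equivalent to the usual Type III sums under the coding used.

## Combined tests

For the OR-combination of two tests, independence gives
$SE_{ab} = SE_a + SE_b - SE_a SE_b$ and $SP_{ab} = SP_a SP_b$. Observed
combined sensitivities on real data tend to fall *below* the independence
prediction because both tests miss the same hard nodes (positively
dependent errors); the package's Monte-Carlo property tests verify
equality under engineered independence, which is the boundary case.

The expected-error arithmetic at an assumed prevalence
(`expected_errors()`) reproduces a printed-arithmetic convention in which
the called-positive count of the combined classifier∨EBUS test is the
classifier-alone count (349), not the count augmented by the 16 EBUS-only
positives (365). Both bookkeepings are provided
(`combined_test_analysis(augment_positives = )`); the printed-arithmetic
mode is the default and the discrepancy is surfaced in the documentation
rather than silently corrected.

## The experiment driver

`run_experiment()` chains the stages: generate (or accept) a cohort,
score every configured classifier by nested CV, calibrate to the target
ladder (default 94.5/97.9/99.3%), and emit a performance table
(MCR, FN, weighted McNemar p-values against the reference), a
per-echelon table (MER, FN, FDR, plus OR-combined rows), the analytic
combined-test report, and ECDF coordinate tables for SUVmax and diameter
by echelon and status. The McNemar reference is a *pseudo-expert*: the
fixed SUVmax-threshold rule calibrated to 94.5% sensitivity on latent
truth, a stand-in for the human rater that a real dataset would provide,
and labelled as such in outputs. Every table carries the seed and a hash
of the configuration; the run log records each calibration decision. The
package is used from R (functions and scripts); there is no shell
subcommand layer.

## Problem sizes and runtime choices

The test-suite and acceptance computations use: one default cohort
(180 patients, ≈ 675 nodes) for slope recovery and calibration ladders;
200 replicate cohorts for the echelon-1 prevalence check; $10^5$ draws for
the negative-node median; oracle comparisons at $n \le 500$ (IRLS, AUC
pair counting) and exhaustive enumeration at $n \le 30$/40 (McNemar,
Fisher); 2000 replicates for the McNemar size simulation; and reduced
cohorts (60 patients) plus smaller forests for the end-to-end driver
tests. These sizes give the Monte-Carlo bands quoted in the tests while
keeping a full run on one CPU in about a minute.

## Known limitations

* Involvement is independent across a patient's nodes given echelon; no
  pattern-of-spread model, so per-patient operating characteristics are
  not faithfully simulated.
* The generator is calibrated to summary statistics of one published
  cohort, not fitted to patient-level data; data-dependent results (AUCs,
  McNemar p-values, per-echelon FDRs of the real cohort) are not
  reproducible by construction and are not claimed.
* EBUS specificity is fixed at 1; false-positive histopathology is not
  modelled.
* The feed-forward backend has a single hidden layer; deeper
  architectures would need a different engine and are out of scope.
* Backward variable elimination is available implicitly by refitting on a
  reduced design, but the pipeline fits and reports the full covariate
  set by default.
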