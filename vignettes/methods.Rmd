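---
title: "Methods: metaheuristic AutoML for rhinoplasty prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metaheuristic AutoML for rhinoplasty prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what its tests do and do not
demonstrate.

## The prediction problem

Two prognosis targets after autologous costal cartilage rhinoplasty
(ACCR): a binary composite complication within one month (infection,
haematoma or graft displacement) and the continuous 1-year Rhinoplasty
Outcome Evaluation (ROE) satisfaction score on 0–100. Sixteen predictors
are organised in a fixed data dictionary (`data_dictionary()`):
demographics (age, sex, BMI, education), preoperative factors (enlarged
nasal pores, surgical history, preoperative ROE), surgical variables
(hospital stay ≥ 5 days, surgery duration ≥ 8 h) and first-month
behavioural/event factors (nasal collision, antibiotic duration,
folliculitis, animal contact, spicy food, smoking, alcohol). Binary
variables enter the learners coded 0/1 at the dictionary's `positive`
level; continuous ones pass through untransformed.

## The optimizer

`mh_optimize()` minimises over a box with one of four population
algorithms behind one interface. The core update ("npdoa") moves each
individual by three drives — attraction to the global best, coupling to
the population mean state, and a pairwise-difference term whose
amplitude decays as `exp(-4 t/Tmax)` — plus Gaussian jitter scaled by
the current per-coordinate population spread, with greedy (keep-if-
better) selection. The spread-proportional jitter keeps refining as the
population contracts, so the core converges geometrically on smooth
unimodal landscapes; because every step scale is tied to the population
spread, a population that has collapsed into one basin cannot re-open —
the classic premature-convergence weakness of contraction-based swarm
cores. The published core equations of the algorithm this emulates are
not public in detail, so the update is deliberately kept behind a single
`npdoa_step()` function that any population-based rule could replace.

The improved variant ("inpdoa") adds exactly two mechanisms:

* **Bernoulli-map initialisation.** The initial population is spread by
  iterating the chaotic shift map `x ← x/(1−β)` for `x < 1−β`, else
  `(x−(1−β))/β`, with `β = 0.4` and a seeded start point redrawn if it
  lands on the map's fixed point or breakpoint. The map's invariant
  density is uniform, which the tests verify by a χ² check.
* **Lévy-flight perturbation.** With probability 0.3 per individual per
  iteration, a Mantegna-construction stable step (`β_levy = 1.5`,
  scaled by 1 % of the box width) is added after the core update. The
  heavy tail produces occasional long jumps that can escape a collapsed
  basin; greedy selection keeps the jump only if it lands somewhere
  better. The application probability and scale are configuration
  values (`mh_control()`), since no canonical setting exists; 0.3 and
  0.01 are common practice for Lévy-augmented metaheuristics.

Boundary handling is clipping; candidates whose objective value is not
finite are assigned `+∞` and the run continues; a best-so-far archive
makes the trace monotone for stationary objectives. Baselines: a
real-coded GA (tournament size 3, BLX-0.5 crossover, per-gene Gaussian
mutation with SD 10 % of the box width, one elite) and the standard
whale optimization algorithm with `a` decreasing linearly 2 → 0. These
follow textbook formulations because only the algorithms' names, not
their settings, are fixed by the protocol being emulated.

## The benchmark suite

`build_suite(dim, seed)` constructs 12 functions on `[-100, 100]^d`
following the CEC2022 class structure: one shifted-rotated unimodal
function (Zakharov), four shifted-rotated basic multimodal functions
(Rosenbrock, expanded Schaffer F6, Rastrigin, Levy), three hybrids
(coordinate blocks routed to different basics) and four compositions
(distance-weighted mixtures of shifted basics). Shifts are uniform in
`[-80, 80]^d`; rotations come from QR decomposition of a seeded Gaussian
matrix. The official instance data files are deliberately not
reproduced: the comparison needs the difficulty structure, not
byte-level instances, and the suite records `known_optimum = f(shift)`
by construction so the anchor identity is testable. For composition
functions the shift anchors the first component (weight → 1 there);
whether some other point attains a marginally lower value is irrelevant
to the paired-seed comparison the suite exists for.

`run_comparison()` derives one seed per repeat from a master seed and
gives the *same* seed sequence to every algorithm, so comparisons are
paired; summaries (median, IQR, boxplot outlier count) are a pure
function of the raw run records.

## The AutoML layer

A candidate solution is `(k | δ | λ)`: learner family, binary feature
mask, hyperparameters. The optimizer searches `[0,1]^(1+m+n_max)`
(m = 16, n_max = 4) and `decode_solution()` maps slot 1 to
`k = 1 + ⌊4u⌋`, mask slots through a 0.5 threshold (an all-zero mask is
repaired by forcing the strongest slot on), and hyperparameter slots
affinely — log-affinely for scale-type parameters — into the active
family's bounds, rounding integer-typed ones. Families: penalised
logistic/linear regression (glmnet: penalty strength and elastic-net
mixing), RBF-SVM (cost, kernel width), depth-wise gradient boosting
(learning rate, depth 2–8, 20–120 rounds, L2 penalty) and leaf-wise
histogram boosting (leaf count 4–64 instead of depth). SVM
classification probabilities are a logistic link on the signed margin —
a deterministic monotone calibration chosen over Platt scaling because
the latter's internal cross-validation is not seedable from R.

The fitness combines cross-validated accuracy, sparsity and an
iteration-decay term under weights `w1(t) = 0.80 − 0.35·t/Tmax`,
`w2(t) = 0.10 + 0.35·t/Tmax`, `w3 = 0.10`. The schedule's shape was an
open choice; a linear ramp is the simplest curve satisfying the three
qualitative constraints the design imposes (accuracy-dominant start,
rising sparsity pressure, terminal `w1 = w2`), and the weights sum to 1
at every iteration by construction. The decay term `exp(-t/Tmax)` is
shared by all candidates at a given iteration; it shifts the fitness
scale over time without reordering candidates, and is retained for
fidelity to the weighted three-term form.

The accuracy term defaults to plain ACC at threshold 0.5 for
classification, with a `metric = "auc"` switch; the two readings are
both legitimate (the printed fitness uses ACC; the surrounding protocol
quantifies performance by cross-validated AUC), so both are first-class
and the choice is recorded in every run's resolved configuration. For
AUC-targeted evaluation the AUC term is the right setting and is what
`run_study()` uses by default. The regression accuracy term is
out-of-fold R² clipped to [0, 1] — the weighted sum needs a bounded
term, and no regression fitness is prescribed anywhere. Inner CV is
stratified 10-fold (stratification by outcome class, or by outcome
decile for regression; the folds are fixed per search so candidate
scores are comparable), SMOTE is applied inside each training fold only
during the search, and to the whole training partition for the final
refit. Accuracy values are memoised on the decoded solution, so
revisits of a configuration are free. `T` in the decay term is the
iteration counter `t`; no second counter exists.

Prediction contracts: classification returns a probability in [0, 1]
(linear families through the sigmoid; tree ensembles return their
native probability, since a linear-output equation cannot literally
describe them); regression predictions are clipped to the ROE range
[0, 100].

## The synthetic cohort generator

No patient-level ACCR data are deposited anywhere, so the generator *is*
the study population here. Marginals are parameterised from the
published descriptive table for each of the three cohorts (training
n = 264, internal test n = 66, external validation n = 117): normal
marginals for age, BMI and preoperative ROE (means/SDs as printed),
proportions for the binary predictors. Two printed rows are internally
inconsistent (a test-column count of 10/50 against a cohort of 66; two
different sizes reported for the validation centre); the generator takes
proportions rather than raw counts and uses the size (117) every other
section uses. Predictors are sampled independently except one documented
coupling: the probability of >high-school education falls with the
preoperative ROE score (logit slope −0.08, marginal preserved by
numerical calibration), giving the Shapley interaction export a real
signal to find.

Outcomes carry planted effects the rest of the package can be scored
against. The complication truth is logistic with three strong drivers —
nasal collision (+5.0), folliculitis (+4.0), smoking (+3.8) — and milder
effects for preoperative ROE (−0.20/point), hospital stay (+1.2) and
surgery duration (+1.4); the intercept is solved numerically so the
marginal event rate matches the cohort's published proportion (26.52 %
for the training profile). The 1-year ROE truth is linear (preoperative
ROE +1.5/point dominant, education −5, hospital stay −5, male sex −6,
complication −10) with Gaussian noise SD 3, ceiling-clipped at 100; the
intercept is set from the configured marginals so the pre-clipping mean
matches the published 87.96. Effect sizes were fixed once, at design
time, to put the truth model's own discriminability comfortably above
the package's internal recovery bars (truth-model AUC ≈ 0.92, truth R²
≈ 0.95 on held-out data): weaker effects would make "recovery" untestable,
not because the pipeline fails but because the information is not in the
data. The clipped ROE ceiling (~20 % of draws) is a deliberate
realism feature — satisfaction scales saturate — and is the main reason
fitted R² sits below the pre-clipping signal share.

What the generator does *not* emulate: predictor correlations beyond the
one coupling, informative missingness (gaps are injected completely at
random at rate 1.3 %), measurement error, site effects, or any
distribution shift between centres beyond the printed marginals.
Passing recovery tests therefore shows the pipeline extracts planted
structure from clean tabular data; it says nothing about robustness to
confounding or drift in real cohorts.

## Data handling

`stratified_split()` allocates 8:2 within strata defined by the
preoperative ROE stratum (Low 0–25, Medium 26–35, High > 35; boundary
scores belong to the lower stratum, matching the printed integer
ranges) crossed with complication status, using largest-remainder
rounding so the global training size is exactly `round(0.8 n)`; strata
with fewer than 2 rows go wholly to training and are recorded. Rows with
a missing stratification score form their own stratum rather than being
dropped. Imputation (`impute_cohort()`) fills continuous gaps with the
training-partition median and categorical gaps with the training mode —
never with statistics that saw held-out rows; the values used are
attached to the result. SMOTE (`apply_smote()`) oversamples the minority
class to parity, interpolating continuous coordinates between a minority
sample and one of its k = 5 minority nearest neighbours and copying
binary coordinates from the nearer parent; k shrinks automatically for
tiny minorities.

## Evaluation and explanation

ROC-AUC is computed as the normalised rank-sum statistic (ties counted
one half) and is tested against a brute-force all-pairs oracle and
against an independent reference implementation; PR-AUC uses step
integration at distinct score cuts. Precision and F1 with zero positive
predictions are reported as explicit NA with an `undefined` flag — the
em-dash convention of published comparison tables — never silently
zeroed. The decision curve reports the model, treat-all and treat-none
policies on a 0.01–0.99 grid; net benefit is bounded above by
prevalence, and the default classification threshold is 0.5 (exposed,
since no threshold is prescribed). MAPE is reported in percentage points
on the ROE scale, skipping zero-valued outcomes with a logged count.

Shapley attribution uses interventional semantics: a coalition's value
is the mean model output with out-of-coalition features replaced by
background rows. Exact enumeration (all 2^m coalitions, m ≤ 12) is the
oracle; the permutation sampler handles larger m and is itself tested
against the oracle. The variant choice (interventional rather than
tree-path-dependent) is dictated by the mixed learner catalogue: it is
the only semantics that treats all four families identically. Exported
summary data record feature values as normalised ranks — the high/low
colouring of beeswarm plots is a rendering concern, not data.

## Numerical choices and degenerate inputs

Tie-breaks and guards, in one place: feature-importance ties resolve by
dictionary order; an all-zero feature mask is repaired, not rejected;
single-feature designs are padded with a zero column for the penalised
family (which requires two columns) and the pad carries zero weight;
degenerate CV folds (single-class training part) are skipped, and a
fully degenerate split yields `-Inf` fitness so the search discards the
candidate; zero-variance outcomes flag R² undefined; the Bernoulli map
guards its fixed point and rounding at the top edge; orbit closure keeps
all values in [0, 1). Fitness decomposition is exact to 10⁻¹² because
the components are stored with the value rather than recomputed.

## Problem sizes used by the test suite

The suite exercises the full published optimizer protocol where it is
cheap (10-dimensional suite, population 30, 500 iterations, 20 seeds for
the sphere contract) and a reduced comparison budget (10 runs × 200
iterations across all 12 functions and 4 algorithms) for the
INPDOA-vs-core dominance property, which is directional: the improved
variant should match or beat its plain core on a majority of functions
under paired seeds. AutoML recovery runs at the study's cohort sizes
(330 split 264/66) with a deliberately small search budget (population
10 × 30 iterations, 310 accuracy evaluations): recovery of planted
structure at a small budget is the stronger claim, and it keeps the
whole suite to desk scale. The canonical seed for single-run checks is
1 throughout; multi-seed properties use seeds 1–10 or 1–20.

## Known limitations

The core update stands in for an algorithm whose defining equations are
not public in detail; conclusions about "the improvements" are
conclusions about Bernoulli initialisation and Lévy perturbation layered
on *this* core. The generator's independence structure makes feature
recovery easier than in collinear clinical data. Published headline
performance numbers for the real cohorts are not reproducible from this
package, by construction: the patient data are unavailable, and the
synthetic regime is calibrated to published marginals, not to
individual-level structure. The comparison harness reports medians,
IQRs and outlier counts only; formal rank tests across functions are out
of scope.
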