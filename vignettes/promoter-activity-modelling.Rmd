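---
title: "Modelling promoter activity from DNA sequence windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling promoter activity from DNA sequence windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promoterlearn)
```

## The modelling problem

Promoter activity — the rate at which a promoter drives reporter-protein
production, per cell per second — is, for yeast ribosomal-protein (RP)
promoters, largely encoded in local DNA sequence composition rather than in
any explicit catalogue of transcription-factor binding sites. promoterlearn
implements the window-based strategy that exploits this: promoter sequences
are segmented into non-overlapping windows anchored at the translation start
site (TrSS), per-window sequence features are extracted, a cross-validated
linear-regression wrapper selects the predictive features, and an averaged
ensemble of epsilon-SVM regressors maps the selected features to activity.
The package also implements the four-statistic permutation-based evaluation
scheme used to score competing predictions in community challenges, and a
synthetic promoter generator with planted feature–activity structure that
lets the entire pipeline be validated end to end.

Coordinates everywhere are TrSS-relative, half-open offsets with position
−1 the last promoter base: window 1 is `[-100, 0)`, the 100 bp immediately
upstream of the TrSS. This anchoring matters — in the RP promoter study the
proximal window is the only one with strong predictive signal, so the
package indexes windows from the proximal end and drops distal partial
fragments from the fixed tiling (sequences whose length is not a multiple of
the window width keep their distal remainder only inside the full-promoter
window; the study never specified a convention, so we chose the one that
keeps window indices comparable across promoters of different lengths).

## Features

Per window, three feature families are computed, each namespaced in the
feature names so selections are portable:

* **k-mer frequencies** (`kmer3:ACC`): overlapping occurrence counts divided
  by $L - k + 1$, for $k = 1..5$, on the given strand only. Promoters are
  orientation-defined, so no reverse-complement collapsing is applied; all
  $4^k$ words are reported (zeros included) and each k-block sums to 1.
* **tract lengths** (`tract:T`, `tract:TA`): the length in bases of the
  longest run of a base (poly(dT)) or the longest perfect two-base
  alternation (poly(dT–dA)), the conventional statistics for
  nucleosome-excluding tracts. Alternating tracts are counted
  phase-agnostically, so `TATAT` scores 5. The maximum was chosen over total
  coverage as the standard poly(dA:dT) statistic; coverage is available via
  `feature_config(tract_statistic = "coverage")`.
* **mechanical property means** (`mech:deformability_mean`): the mean of a
  positional profile obtained by looking up a di- or trinucleotide parameter
  scale at every position. Mean rather than sum is the default so the
  feature is comparable between the fixed windows and the variable-length
  full window; `window_property_mean(..., statistic = "sum")` gives the sum.

Windows containing `N` are rejected with an error rather than imputed:
silently treating ambiguous bases as any particular nucleotide would bias
the frequency features.

### Property scales

The bendability, deformability, bending-stiffness and nucleosome-preference
scales shipped under `inst/extdata/scales/` are **synthetic stand-ins**
(file names say so): the original parameter tables live in the
supplementary material of the primary literature and are not redistributed
here. The stand-ins reproduce the qualitative structure practitioners
expect — pyrimidine–purine steps (TA, CA, CG) most deformable, stiffness
anti-correlated with deformability, A/T-rich trinucleotides rigid and
nucleosome-disfavouring — with deterministic jitter so all entries are
distinct. Nothing in the package's statistics depends on particular
parameter values: every profile computation is validated against toy and
randomized scales, and users with access to published tables can drop them
in as TSV files (`word<TAB>value` plus `#name=/#unit=/#source=` headers)
and pass the path to `load_scale()`.

## Feature selection

`wrapper_select()` is a greedy forward search scored by `cross_val_score()`:
ordinary least squares is fitted on each training fold and the **pooled**
held-out predictions are correlated with the observed activities (one
Pearson r over all held-out points, which is stabler at n = 90 with 10
folds than averaging per-fold correlations; `score = "neg_rmse"` is the
alternative). The search starts from the empty set, always accepts the best
singleton, and stops when the best improvement is ≤ `improvement_tol`
(default 1e-3) or `max_features` is reached. `"forward-backward"` search
additionally attempts single removals after each addition. Ties are broken
lexicographically and the fold partition is drawn once per search from the
seed, so selection is fully deterministic.

Two numerical caveats are worth knowing:

* **Null bias.** Pooled cross-validated correlations are biased *negative*
  under the null (about −0.18 at n = 90, 10 folds, one feature; our own
  simulations). False "predictive" scores on noise are therefore rare, but
  symmetric bands around zero are the wrong mental model; the tests derive
  null bands empirically from calibration simulations.
* **Selection optimism.** Selection is run once on the full training set
  (matching the study protocol, where the selected feature set was fixed
  before ensemble training), so the CV score of the *selected* set is
  optimistic — it is a search maximum, not an unbiased estimate. With many
  candidate features and few samples the wrapper can assemble large
  apparently-predictive subsets from noise; judge generalization by the
  ensemble's held-out member correlations or a fresh test set, not by the
  selection score.

`window_scan()` repeats matrix-building and selection for every fixed
window present in at least `min_fraction` (default 0.8) of the promoters,
plus the full-promoter window, and ranks windows by the selection score,
reporting 5-fold and 10-fold CV correlations of each window's selected set.

## The SVM ensemble

`train_ensemble()` implements the challenge-winning protocol: 500
epsilon-SVM regressors trained on seeded random 80/20 splits plus one on a
66/34 split (501 members at the defaults), every member using the same
selected features. Features are standardized per member on its own training
split — no test leakage — with zero-variance training columns given unit
scale and a warning. The member SVMs are libsvm epsilon-regressions
(`e1071::svm`); the kernel and hyperparameters of the original study were
never published, so the defaults are the faithful analogue of an SMO
regression with defaults: linear kernel, C = 1, epsilon = 0.1, all exposed
in `training_protocol()`. Predictions are the arithmetic mean of member
outputs, exactly (this identity is tested, not approximated). Member
held-out Pearson correlations are stored, and `holdout_performance()`
reproduces the repeated-66/34-split benchmark for a single SVM.

Models serialize to plain JSON (support vectors, dual coefficients, bias,
standardization per member), and the deserialized model predicts
identically to full double precision — the kernel expansion is evaluated
from the stored dual representation, which is also cross-checked in tests
against the in-memory libsvm predictions.

The top-level `promoter_model()` bundles matrix building, selection and
ensemble training into one fitted S3 object with `print`, `summary`,
`coef` (averaged standardized linear weights, the ensemble analogue of SVM
feature importances), `predict` (accepts raw promoter sets and re-extracts
features for the stored window), `fitted`, `residuals` and `plot` methods.

## Challenge evaluation

`evaluate_submission()` scores a prediction vector against observed
activities with four statistics: Pearson correlation, Spearman correlation
(Pearson on average ranks), a chi-square distance and a rank distance. The
exact chi-square and rank normalizations used by the original challenge
were published separately and are not recoverable from the study itself;
the defaults here are declared and configurable: chi-square distance
$\sum_i (p_i - o_i)^2 / o_i$ (requires positive observations;
`denom = "uniform"` gives the plain squared-error sum) and rank distance
$\frac{1}{n}\sum_i (r^{pred}_i - r^{obs}_i)^2$ (a `"sum"` variant is
selectable). For a fully reversed ranking of $n$ distinct items the mean
variant equals $(n^2 - 1)/3$, a closed form the tests pin down.

P-values come from a permutation null built from a pool of competing
submissions: each replicate draws, independently per promoter, that
promoter's prediction from a uniformly random pool member (the
`whole_vector` scheme, drawing one entire competing submission per
replicate, is available — the original wording is ambiguous between the
two). "At least as good" means ≥ for correlations and ≤ for distances, and
the add-one correction $p = (1 + b)/(1 + B)$ keeps p-values in (0, 1]. The
four p-values are combined as their product and as the −log10 geometric
mean. Under the null the p-values are uniform on their discrete grid; the
test suite checks this with a KS test across independently drawn
pool/submission pairs (independence across draws is what KS assumes, so
each draw gets its own pool).

`error_profile()` supports the post-hoc error analyses: per-promoter
absolute error, a Welch t-test between promoter groups (natural vs mutated
variants), and the correlation between observed activity and error.
Welch's unequal-variance test is used wherever the study said only
"t-test", as the statistically safer default.

## The synthetic study

`generate_promoters()` draws promoters i.i.d. per base (default AT-rich
yeast-like composition A = T = 0.31, C = G = 0.19) with lengths uniform on
200–1200 bp — the real promoters were defined as up to 1200 bp upstream of
the gene, truncated at the neighbouring gene — and computes activities as
an exact linear function of designated window-1 features plus Gaussian
noise. The defaults plant negative dependence on G frequency and positive
dependence on T- and TA-tract lengths (weights −8, 0.25, 0.25), echoing the
directions found in the real data, with noise sd 10% of the noiseless
activity spread unless set explicitly; effects are evaluated on window 1
only so the window scan has a planted correct answer. The ground truth
returned alongside the promoter set satisfies
`activity = sum(weight * feature) + noise` exactly, per record.

A configurable fraction of promoters are mutated copies of natural ones
(per-base substitution at `mutation_rate`, uniform over the three
alternatives), mirroring the challenge's test design of 20 natural + 33
mutated promoters. Because the generator recomputes each mutated promoter's
activity from its own sequence, the planted feature–activity mapping holds
for mutated promoters too — so, unlike in the real study, the model has no
systematic reason to predict them worse. That gap in realism is deliberate:
the i.i.d. generator exercises every pipeline stage with known answers, but
passing its tests says nothing about out-of-distribution behaviour on real
regulatory variants, Markov-structured genomic background, or measurement
noise that correlates with activity. Synthetic activities can also be
negative (predictions are unconstrained reals); file-based workflows that
need positive fluorescence-like values shift them, as the `simulate` CLI
command does.

## Problem sizes and numerical choices

The validation suite runs at the study's design scale: 90 training and 53
test promoters, 501 ensemble members, 1000 random 66/34 splits for the
single-SVM benchmark, and 10 000 permutation replicates in the acceptance
script (tests use a few hundred where the check is distributional).
Reproducibility is managed by explicit integer seeds everywhere a random
draw occurs — fold partitions, member splits, permutation nulls, sequence
generation — through one internal helper that restores the caller's RNG
state, so package calls never perturb a user's session randomness.
Degenerate inputs have defined behaviour rather than accidents: constant
activities are an error for correlation-based scores; rank-deficient OLS
folds fall back to the pivoted pseudo-solution with a warning;
zero-variance features in a member's training split get unit scale;
perfectly separated constant groups in the regional t-test report the
limiting t = ±Inf, p = 0; and profile smoothing shrinks its window at the
boundaries so `half_width = 0` is the identity.

## Known limitations

* The shipped mechanical scales are qualitative stand-ins, so *values* of
  mechanical features are not comparable to literature numbers; only their
  within-dataset contrasts are meaningful.
* Wrapper selection is not nested within the ensemble's resampling; the
  selection CV score is optimistic (see above).
* The i.i.d. generator does not model nucleosome-positioning sequence
  grammar, Markov dependence, or the out-of-distribution character of
  engineered promoter variants.
* Challenge statistics use declared default normalizations; to reproduce a
  specific consortium's leaderboard one must substitute its exact formulas
  via the `denom`/`variant` arguments.
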