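---
title: "Grading gliomas with conditional linear Gaussian Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading gliomas with conditional linear Gaussian Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliobayes)
```

## The problem

Preoperative grading of cerebral gliomas — deciding whether a tumor is low
grade (WHO I–II) or high grade (WHO III–IV) — guides therapy and prognosis,
but the histopathological gold standard requires an invasive biopsy that
samples only a small part of a heterogeneous tumor. Several MRI modalities
carry complementary non-invasive grading signal:

* **T1W+C** (contrast-enhanced T1-weighted imaging): blood–brain-barrier
  breakdown shows as enhancement, summarized here as a three-state category
  (*negative*, *slight*, *apparent*).
* **PWI** (perfusion-weighted imaging): five perfusion parameters (rCBV,
  MTT, rCBF, T0, TTP), each normalized by a contralateral normal region
  (prefix "n"), reflecting tumoral microvascularization.
* **MRSI** (MR spectroscopic imaging): metabolite ratios Cho/Cr, NAA/Cr,
  Lac/Cr and Lip13/Cr, reflecting tumor presence, neuronal loss, and
  necrosis.

In practice not every patient receives every modality. The cohort this
package emulates has 56 patients (30 high grade, 26 low grade), all with
T1W+C, 51 with PWI, 26 with MRSI, and only 21 with both — *block
missingness* at the modality level. The package's purpose is a classifier
that (a) fuses whatever evidence is available per patient, and (b) can be
*learned* from such incomplete data.

## The model

All variables are nodes of a Bayesian network. Grade $G$ (2 states) and the
enhancement category $E$ (3 states) are discrete; all nine imaging features
are Gaussian. The network is a **conditional linear Gaussian (CLG)**
network: discrete nodes have only discrete parents, and each continuous
node $X$ with discrete parents $D$ and continuous parents
$U = (U_1,\dots,U_k)$ follows

$$ X \mid D = d,\; U = u \;\sim\; \mathcal N\!\big(\beta_{0,d} +
\beta_d^\top u,\; \sigma^2_d \big), $$

with a separate intercept, coefficient vector and variance per
configuration $d$. The source study states only that the feature nodes were
"treated as Gaussian"; the linear-in-continuous-parents,
parameters-per-discrete-configuration form adopted here is the standard
hybrid-network realization that keeps exact inference closed-form, and is a
deliberate design choice of this package.

CLG admissibility (no Gaussian parent of a discrete node) is enforced
structurally. It costs nothing for this application: grade and enhancement
are sources in every learned topology.

### Parameter estimation

`fit_mle()` estimates every conditional distribution by maximum likelihood
on the rows where the node's whole family (child plus parents) is observed
— available-case analysis per family. This realizes learning from the
modality-complete subsets (51 and 26 rows for the two network parts)
without an EM algorithm, which is deliberately out of scope. Discrete CPTs
are relative frequencies (optional add-$k$ smoothing); Gaussian nodes are
per-configuration least-squares fits with the MLE residual variance
($n$ denominator, not $n-1$). Two guards handle small strata:

* a discrete parent configuration with zero cases falls back to the child's
  marginal distribution (recorded in the fit metadata);
* a configuration with fewer cases than coefficients + 1 falls back to the
  pooled (configuration-marginal) regression, and variances are floored at
  `var_floor = 1e-6` (squared feature units) so that densities stay proper.

### Exact inference with missing modalities

For a full assignment of the discrete nodes, the continuous nodes are
jointly Gaussian; `joint_gaussian_for_config()` compiles mean and
covariance by propagating $\mu_X = \beta_0 + \beta^\top \mu_U$ and the
covariance identities in topological order. `posterior_grade()` then sums,
over every configuration of the *unobserved* discrete nodes jointly with
each grade state, the discrete probability product times the marginal
density of the observed continuous evidence — unobserved Gaussian nodes are
marginalized by dropping their rows and columns, which is exact for
multivariate normals. All weights are accumulated in log space; evidence
whose likelihood underflows in every configuration raises an error rather
than returning a 0/0 posterior. Predictions take the posterior argmax; an
exact tie (difference below $10^{-12}$) resolves to *high* grade, the
clinically conservative direction.

## Feature screening

Before network construction, features are screened with a two-group
Kruskal–Wallis rank test (tie-corrected $H$, $\chi^2_1$ approximation), and
features with $p > \alpha = 0.05$ are excluded; $p = 0.05$ exactly is
retained. The test runs per feature on its non-missing rows. With the
default generator parameters, nT0 (high 1.048 ± 0.212 vs low 1.030 ± 0.120)
is the feature this rule usually removes, matching its published $p =
0.977$.

Two conventions are worth noting. The $\chi^2$ approximation is compared in
the test suite against the exact permutation distribution using the
*mid-p* convention ($P(H > h) + \tfrac12 P(H = h)$): with a discrete
statistic the plain permutation p of an extreme split is systematically
larger than the asymptotic p (0.10 vs 0.05 at $n = 3+3$), and mid-p is the
standard correction for that discreteness. Even then the agreement band of
0.02 holds universally only at the balanced $5+5$ design (worst case
0.0194 over all 252 splits, which the suite checks exhaustively); smaller
or unbalanced splits can disagree by more, which is a property of the
approximation, not of this implementation. No multiple-testing correction
is applied, mirroring the screening rule being reproduced.

## Structure learning

`k2_search()` implements the K2 greedy search: under a fixed node ordering,
each node starts parentless and repeatedly adds the single predecessor
whose addition most increases the family score, stopping when no addition
helps or `max_parents` (default 3, the largest in-degree plausible for
networks of this size) is reached. Ties break toward the earlier ordering
position, so results are deterministic.

The classical K2 metric applies only to fully discrete data, and the source
study does not name the score it used for its hybrid network, so the score
is an open design point. This package uses **BIC over the CLG likelihood**:
family log-likelihood minus $\tfrac12 k \log n$, with $n$ the family's
available-case count. BIC is decomposable (so per-node search is valid),
consistent, and hyperparameter-free. `exhaustive_best_dag()` maximizes the
same score exactly over all order-consistent DAGs for up to 5 nodes and
serves as the reference in the tests.

The default node ordering puts grade first, then T1W+C, then the retained
features by ascending screening p-value. Grade-first orderings mean grade
can only ever be a parent — consistent with every published topology for
this problem — and make the two-part merge below trivially acyclic.

### Two-part composition

Because only 21 patients have both PWI and MRSI, a single K2 run on
all-modality-complete rows would learn from very little data. Instead
`build_two_part_network()` learns one part over {grade, T1W+C, retained
perfusion features} on the 51 perfusion-complete rows and a second over
{grade, retained MRSI features} on the 26 MRSI-complete rows, then merges
them on the shared grade node and re-validates the result.

## Evaluation protocol

`loocv_evaluate()` implements leave-one-out cross-validation with the
structure held fixed and parameters refitted per fold on the remaining
rows (the protocol being reproduced mentions per-fold *parameter* learning
only; structure re-learning per fold is available to callers by looping
`build_two_part_network()` themselves). Per-case scores are the posterior
$P(\text{high})$.

An *observation pattern* names the modalities used as evidence. Two sets of
cases must be distinguished: who is **evaluated** and what is **observed**.
The published per-pattern accuracies use denominators of 56 / 51 / 26 —
the cases complete for a block modality — while observing the other listed
modalities *where available*. `loocv_evaluate()` therefore takes both a
`pattern` (evidence) and a `require` argument (denominator); the default
`require = pattern` is the strict reading (every evaluated case has the
whole pattern observed), and the block-style experiments pass, e.g.,
`pattern = c("T1WC", "perfusion", "MRSI"), require = "T1WC"`.

ROC curves sweep thresholds over the unique scores; tied scores share one
threshold, producing diagonal segments, so the trapezoidal AUC equals the
Mann–Whitney concordant-pair statistic with ties counted one half (the
suite asserts this identity to $10^{-12}$). With T1W+C-only evidence the
score takes at most three distinct values, so the ROC has at most three
interior points — which is how a discrete-evidence model can report a
non-trivial AUC at all.

## The synthetic cohort generator

No patient data accompany the source study, so `generate_cohort()` stands
in for it and defines the package's study conditions. What it emulates:

* group sizes 30/26 and the 56/51/26/21 modality-availability counts,
  reproduced *exactly* for every seed (allocation by seeded shuffle,
  independent of grade, since no grade-by-modality cross-tabulation is
  published);
* per-grade means and SDs of all nine continuous features, equal to the
  published group statistics;
* distribution families: Lac/Cr and Lip13/Cr are nonnegative and heavily
  right-skewed (SD > mean in at least one group), so they are drawn from
  log-normals *moment-matched* to the published mean/SD (closed form,
  checkable to $10^{-9}$); the remaining features are Gaussian. A
  zero-truncated Gaussian was rejected because truncation would distort
  the published moments.
* enhancement-state probabilities per grade. These are **not published**;
  the defaults (high: 0.10/0.17/0.73, low: 0.62/0.23/0.15 over
  negative/slight/apparent) are chosen so that an enhancement-only grader
  misclassifies roughly 8 of 56 cases, the error level reported for that
  setting, and they are configurable rather than ground truth.

What it does not emulate: within-grade correlation between features (the
published table provides only marginals, so features are conditionally
independent given grade), measurement error in enhancement reading, or any
image-level processing. Consequently, passing the end-to-end checks shows
the *pipeline* behaves as published under matched marginals and
missingness — it cannot validate the clinical accuracy numbers themselves,
which depend on the real joint distribution.

Randomness derives from one master seed through per-label sub-streams
(hashed from "feature:<name>", "t1wc", "missingness"), so adding or
reordering features leaves other columns' draws unchanged.

## Numerical choices and degenerate inputs

* All likelihoods in log space; log-sum-exp for mixtures; Cholesky-based
  multivariate-normal densities.
* Variance floor $10^{-6}$; collinear regression columns get coefficient 0
  via a QR solve rather than failing.
* The full-tie Kruskal–Wallis case is defined as $H = 0$, $p = 1$.
* An empty cohort spec yields a header-only table; an empty evidence list
  yields the fitted grade marginal.
* CSV missing cells are written empty and read as either empty or "NA".
* Serialization uses 17 significant digits, which uniquely identifies an
  IEEE double, so save/load round trips are bit-exact.

## Problem sizes used in the checks

The test suite exercises: 200 randomized networks of ≤ 5 nodes against a
fine-grid inference oracle (grid step $10^{-3}\sigma$ over $\pm 8\sigma$);
parameter recovery at $n = 5{,}000$ over 20 seeds, with the known network
designed so every checked parameter has about four standard errors of
headroom inside the stated tolerances; 100 random 4-node structure-learning
datasets at $n = 300$ against the exhaustive optimum; 10,000 null
replicates of the rank test at the cohort's 25/26 group sizes; 1,000
random score vectors for the AUC identity; and 50 full synthetic cohorts
for the end-to-end ordering check (all-modality evidence beats
enhancement-only). These sizes were chosen to make the statistical
assertions sharp at desk scale.

## Known limitations

* Gaussian node models are mis-specified for the log-normal features
  (Lac/Cr especially, SD ≈ 2× mean); posteriors driven by those features
  are discriminative but not calibrated. A log-transform front end would
  be the natural extension.
* No EM: families unobservable as a block (e.g., a hypothetical edge
  between a PWI and an MRSI feature, estimable only on the 21 dual-modality
  patients) are fitted on whatever complete rows exist, or not at all.
* The K2 score and node ordering of the original analysis are unreported;
  learned structures can be compared only qualitatively (e.g., whether
  nTTP attaches to grade directly).
* LOOCV with per-fold refits is quadratic in cohort size; fine at
  $n \approx 56$, slow for cohorts orders of magnitude larger.
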