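---
title: "Profiling chemicals with QSA(P)R models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling chemicals with QSA(P)R models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarprofiler)
```

Quantitative structure–activity (property) relationships — QSA(P)Rs — map
molecular descriptors to an endpoint such as a partition coefficient, an
aquatic toxicity, or a biotransformation half-life. Applying such a model to
a new chemical is trivial arithmetic; deciding whether the resulting number
deserves any trust is not. This package implements the machinery around
that decision for the two model families most common in regulatory QSAR
practice, multiple linear regression (MLR) and linear discriminant analysis
(LDA): prediction uncertainty, structural and endpoint applicability
domains (AD), inverse-variance consensus averaging, and similarity-based
neighbor analysis, together with an XML exchange format so users can define
and audit their own models.

## Regression models

`qsar_mlr()` fits ordinary least squares with an intercept on `p`
descriptors over `n` training chemicals. Everything downstream is driven by
four quantities stored in the fit:

* the residual standard error $s = \sqrt{\sum_n (y_n - \hat y_n)^2 /(n-p-1)}$;
* the hat-matrix diagonal $h_{ii}$, computed with the intercept-augmented
  design $\tilde X = [\mathbf 1\,|\,X]$, so that
  $h = \tilde x\,(\tilde X^\top \tilde X)^{-1}\tilde x^\top$ for any
  chemical, $\mathrm{tr}(H) = p' = p+1$, and a chemical at the descriptor
  centroid has the minimum $h = 1/n$;
* the training endpoint range $[\min y, \max y]$;
* the range of training prediction-interval halfwidths.

The leverage convention deserves a note: one sometimes sees the leverage
written with the Gram matrix in the order $x_i (X X^\top)^{-1} x_i^\top$,
which is dimensionally inconsistent for $n \ne p$. The intercept-augmented
hat form used here is the one under which the conventional cutoff
$3p'/n$ is stated, and it is what makes the trace identity and the
centroid property hold; both are verified in the test-suite on random
fixtures against an explicitly materialized hat matrix.

### Prediction intervals

The uncertainty attached to a single prediction is the two-sided
$1-\alpha$ prediction-interval halfwidth

$$\sigma = t_{1-\alpha/2,\,n-p-1}\; s\,\sqrt{1 + h},$$

with $\alpha = 0.05$ by default (2.5% per tail), configurable per call.
The `1` under the square root carries the single-item random variation, so
these intervals are deliberately wider than confidence intervals for the
mean response; the per-tail non-coverage of the interval on correctly
specified simulated data is checked empirically by the acceptance suite
(10,000 replicates at $n=30$, $p=3$, unit Gaussian noise) and lands on
$\alpha/2$ within Monte-Carlo error.

### Structural applicability domain

A chemical is outside the structural domain when $h \ge 3p'/n$ — the
boundary itself is out. When $n \le 3p'$ the cutoff exceeds 1 and can never
fire; the fit warns about this degenerate configuration instead of
pretending the domain check is informative. The leverage and cutoff are
always recorded in the verdict so a Williams plot (`plot()` on the fitted
model: standardized residuals against leverage, with the cutoff and
$\pm 2.5$ bands) can be reproduced from any report.

### Endpoint applicability domain

Three rules, each reported separately with its numeric evidence:

* **standardized residual** — $r' = (y_\mathrm{obs} - \hat y)/(s\sqrt{1-h})$;
  $|r'| > 2.5$ fails (exactly 2.5 is in). The rule needs an observed
  endpoint and $h<1$; otherwise it is `not_applicable`. For target
  chemicals with unknown endpoint the domain verdict therefore rests on the
  remaining rules.
* **experimental range** — a prediction outside the training $[\min y,
  \max y]$ fails (the endpoints of the range are in).
* **interval range** — a query whose prediction-interval halfwidth falls
  outside the range of training halfwidths fails. The rule is applied to
  halfwidths, not to the intervals' absolute positions: the halfwidth is
  the model's own uncertainty currency (it is what enters the consensus
  weights), and comparing positions would duplicate the experimental-range
  rule.

By default any applicable failing rule puts the chemical out of the
endpoint domain; this is deliberately conservative, since a literal
conjunctive reading ("residual > 2.5 **and** outside the range") would wave
through extreme extrapolations whenever the observed endpoint is unknown
and the residual rule cannot apply. The conjunctive reading remains
available (`strict_and = TRUE`) and is recorded in the verdict when used.

## Classification models

`qsar_lda()` is standard pooled-covariance LDA with empirical priors.
Posteriors are the softmax of the linear discriminant scores; the predicted
label is the argmax, with exact ties broken by declared class order and
flagged as maximal-entropy predictions. The closed-form two-class
discriminant direction $\Sigma^{-1}(\mu_1-\mu_2)$ and the posteriors of
`MASS::lda` serve as independent cross-checks in the tests.

Prediction uncertainty is the Shannon entropy of the posterior vector,
$-\sum_k p_k \log_2 p_k$, reported in bits so that a binary model maxes out
at exactly 1; the base is configurable. Entropy is an uncertainty label,
not a standard deviation — see the consensus section.

### Similarity-based structural domain

The structural domain of a classifier is scored by cosine similarity. Two
choices here were genuinely open and are worth recording:

* **Reference vector.** Scores are computed against the training centroid
  after dividing each descriptor by its training standard deviation —
  scaling without centering. Full autoscaling (center *and* scale) would
  map the centroid to the origin and make the cosine undefined; scale-only
  normalization keeps the percentile rule well defined, equalizes
  descriptor units, is $O(1)$ per query, and gives a chemical exactly at
  the centroid the maximum score of 1. A max-similarity-to-any-training-
  chemical mode can be emulated through the neighbor machinery.
* **Percentile direction.** The conventional rule places a chemical out of
  the domain when its score is "below the 95th percentile of all training
  scores". Read literally, that condemns ~95% of the training set as
  outside its own domain. The default cutoff is therefore the 5th
  percentile of the training scores, keeping ~95% of the training set
  in-domain, with `literal_percentile = TRUE` reproducing the verbatim
  rule. Either way the percentile computation itself is identical —
  `quantile()` type 7, the linear-interpolation convention — and the
  acceptance suite verifies on a 1,000-chemical fixture that the fraction
  of training scores strictly below the 95th percentile is 95% to within
  the convention's granularity.

### Posterior-band endpoint domain

An LDA prediction is out of the endpoint domain when the event-class
posterior lies strictly inside $(0.25, 0.75)$ — an uncommitted prediction.
The bounds themselves are in-domain ("between" read as an open interval);
for binary models the band is symmetric, so the choice of event class does
not affect the verdict. The event class defaults to the first declared
class and is stored in the model and its XML serialization.

## Consensus predictions

When several MLR models predict the same endpoint (same subgroup, same
units), `combine_predictions()` forms the inverse-variance weighted
average: $w_i = 1/\sigma_i^2$, combined value $\sum w_i \hat y_i / \sum
w_i$, combined uncertainty $\sqrt{1/\sum w_i}$. The combined value always
lies within the member extremes and the combined uncertainty is strictly
below every member's for $N \ge 2$; both identities are tested
exhaustively on random member sets. Consensus membership policies are
`user_selected` (mirroring interactive click-to-combine use), `all`, and
`in_ad_only` — averaging out-of-domain predictions is statistically
indefensible, so exclusions are always recorded with reasons.

Classification models never enter a consensus: an entropy is not a
$\sigma$ and has no place in $1/\sigma^2$ weighting.

## Chemistry, descriptors, fingerprints

SMILES parsing, canonicalization, ring perception and the
molecular-weight/TPSA/H-bond counts come from the OpenBabel backend via
ChemmineR/ChemmineOB; the backend name travels with every structure for
auditability. Eight documented descriptors are computed natively on the
heavy-atom graph (`descriptor_names()`); anything else must be supplied
through a CSV descriptor table, which is the same mechanism that supports
models built on experimental measures or on descriptors from external
software. Supplied and computed values are distinguished by provenance
flags in every descriptor vector.

Three fingerprint kinds back the neighbor machinery: hashed linear paths
(1–7 heavy atoms onto 1024 bits), and a dictionary of ~55 structural keys
(binary and count variants), each documented with its SMARTS-equivalent
notation in `structural_keys()`. These are this package's own exactly
reproducible definitions — published fingerprint standards are not
re-implemented bit-for-bit, and `make_fingerprint()` is the adapter point
for plugging in external fingerprints. Similarity indices are Tanimoto,
Dice and cosine, with the natural real-valued generalizations for count
fingerprints; two empty fingerprints score 1 with a warning (0/0 carries
no information), an empty against a non-empty scores 0. Which
index–fingerprint pair to use is a per-call parameter: different pairs
legitimately find different neighbors, and the choice belongs to the
analyst.

## Model exchange format

Models travel as XML (`parse_model_xml()` / `write_model_xml()`); the
schema is documented in `?parse_model_xml`. The training data are the
authoritative content: every statistic (coefficients, $s$, leverages,
ranges, similarity cutoffs) is recomputed at parse time. Documents may
additionally carry published coefficients, which are then *verified*
against the recomputed fit to 1e-6 — a disagreement is a validation error,
never a silent override. Coefficients without training data are rejected
outright, because every applicability-domain statistic requires the
training matrix. Reals are serialized with 17 significant digits, which
round-trips IEEE doubles exactly; the test-suite checks write→parse
equality on 100 random models. Registries are plain key-value
configuration files mapping model directories into a group/subgroup
hierarchy, with per-file load decisions logged and unparseable files
isolated as diagnostics.

## Numerical choices and degenerate inputs

* Rank deficiency (design condition number $> 10^{10}$) is a hard error
  naming the collinear descriptors — AD statistics on a deficient design
  are meaningless, so no silent pseudo-inverse.
* The fit requires $n \ge p+2$ (at least one residual degree of freedom).
* Standardized residuals guard $h \to 1$: saturated chemicals yield `NA`
  with a warning rather than a division blow-up; a noiseless model
  ($s = 0$) returns zeros.
* $0 \log 0 = 0$ in the entropy.
* Zero descriptor vectors make the cosine score undefined; such training
  sets are rejected at fit time, and a zero-vector query is placed out of
  domain with a recorded reason.
* All percentiles use `quantile()` type 7.
* Boundary conventions, fixed and documented: leverage equal to the cutoff
  is **out**; $|r'| = 2.5$ is **in**; posteriors exactly 0.25 or 0.75 are
  **in**; range endpoints are **in**.

## What the synthetic fixtures emulate — and what they do not

The package is exercised end-to-end on synthetic fixtures
(`make_mlr_fixture()`, `make_lda_fixture()`, `toy_chemical_set()`), all
reproducible from a seed. The regression generator draws independent
standard-Gaussian descriptors and adds Gaussian noise (defaults $n=30$,
$p=3$, noise SD 1 — the conditions under which the interval-calibration
check is run); held-out queries include points placed 10 training-SDs from
the centroid, guaranteed beyond the leverage cutoff, so the structural
domain machinery is exercised on labeled ground truth. The classification
generator uses two Gaussian classes at a chosen separation (default 6
pooled SDs) along a random direction. Problem sizes in the checks — 10,000
replicates for interval calibration, 1,000 chemicals for the percentile
rule, 100 fixtures for the algebraic oracles, 1,000 replicates for bias —
were chosen so Monte-Carlo error is comfortably below the assertion
tolerances.

Passing these checks demonstrates that the statistical machinery is
implemented correctly; it does not demonstrate predictive validity on real
chemistry. Real descriptor matrices are correlated, heavy-tailed and
heteroscedastic; real training sets are curated, not sampled; real
endpoints carry measurement error. The applicability-domain rules exist
precisely because the Gaussian idealization fails in practice — the
fixtures verify the rules' arithmetic, not their scientific sufficiency.

## Known limitations

* Descriptor coverage is intentionally small; numeric compatibility with
  external descriptor packages is a non-goal, and models relying on such
  descriptors must ship their values in tables.
* Aromaticity and canonicalization follow the OpenBabel conventions;
  formal charges are not modelled in the implicit-hydrogen assignment used
  by the structural keys.
* Metabolite expansion is a pure-function hook
  (`expand_metabolites()`); no metabolism simulator is bundled.
* Report export is CSV (four tables: predictions, consensus, neighbors,
  AD details with numeric evidence); CSV is the canonical bit-exact format
  and round-trips in the tests.
* Quadratic discriminant analysis, regularized covariance estimators, and
  performance-weighted (rather than inverse-variance) consensus are out of
  scope.
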