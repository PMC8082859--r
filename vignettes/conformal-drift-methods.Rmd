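---
title: "Methods: conformal calibration diagnostics under data drift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformal calibration diagnostics under data drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In vitro toxicity datasets are released in waves: a large historical batch
used for training, an intermediate batch, and a newer prospective batch on
which predictions are actually wanted. Models validated by internal
cross-validation on the first batch often look fine yet behave badly on the
newest data, because the batches are not draws from one distribution — the
chemical space moves. `cpdrift` packages a conformal-prediction workflow to
*diagnose* this drift as a calibration failure and to *repair* it by
updating either the training set or only the calibration set.

# Conformal layer

For a binary endpoint, an underlying score model yields per-class scores
$(s_0, s_1)$, $s_0 + s_1 = 1$. The margin nonconformity of an example under
a hypothesised label $y$ is

$$ nc(y) = \tfrac{1}{2} - \tfrac{s_y - s_{1-y}}{2} \in [0, 1]. $$

An inductive conformal predictor (ICP) splits the training data into a
proper training set (fits the score model) and a calibration set. In the
Mondrian (class-conditional) setting used throughout, each test example
gets one p-value per class, ranking its hypothesised-label nonconformity
against the calibration examples *of that class only*:

$$ p_y = \frac{\#\{i : nc_i \ge nc_{test}\} + 1}{n_y + 1}, $$

and the prediction set at significance level $\varepsilon$ contains every
label with $p_y > \varepsilon$ (strict). Under exchangeability the observed
per-class error rate is then at most $\varepsilon$ up to Monte-Carlo noise
— this is the property whose failure diagnoses drift.

Numerical choices: p-values are non-smoothed with ties counted in the
numerator (conservative; a randomised-tie variant sits behind
`smoothed = TRUE`); set inclusion uses the strict inequality; an empty
calibration class is an error at fit time rather than a silent $p = 1$.
With $n$ same-class calibration examples only $n + 1$ p-values are
achievable, so rare-class calibration is resolution-limited by
construction (8 actives give 9 levels); this drives the small-data
behaviour discussed below.

# Aggregation: ACP and SCP

* **ACP** fits 20 ICPs on independent stratified 70/30 splits of the same
  training set and aggregates p-values per class by the **median**
  (even count: mean of the two middle values — the usual convention). The
  median of valid p-values is not itself guaranteed valid, which is exactly
  why the workflow cross-checks with SCP.
* **SCP** draws one fixed stratified 30% calibration set and partitions the
  remaining proper training set into 4 equal stratified parts, one score
  model each. Nonconformities — of calibration and test examples alike —
  are **averaged over the sub-models before** the p-value ranking, so the
  rank statistic keeps its exchangeability guarantee.

Degenerate cases are exact identities (ACP with one ICP is that ICP; SCP
with one partition is the ICP on the same split) and are tested as such.

# Score models

The production score model is a support-vector classifier with RBF kernel
(`C = 50`, `gamma = 0.002`) whose per-class scores come from Platt-style
probability calibration (`e1071`); its internal randomness is pinned by an
explicit seed so refits are bit-reproducible. Because the conformal layer
only consumes scores summing to one, a deterministic nearest-centroid model
(softmax over negative squared distances) is provided and used in most
tests; every conformal property must and does hold for both.

# Evaluation

`calibration_curve()` recomputes prediction sets from the same p-values on
a significance grid and reports observed error and single-label-set
fraction (efficiency), overall and per class; per-class efficiency is
computed over compounds of that *true* class. The RMSD calibration summary
is $\sqrt{\mathrm{mean}_\varepsilon (err(\varepsilon) - \varepsilon)^2}$
over the grid. The default grid is $\{0, 0.1, \dots, 1\}$ inclusive: the
endpoints contribute exactly zero deviation for any conformal predictor
(at $\varepsilon = 0$ every set contains both labels, at $\varepsilon = 1$
every set is empty), so their inclusion mildly rescales the summary but
cannot change orderings; the grid is recorded in every result file. Rates
over an empty class propagate as `NA` and are excluded from means with a
warning, never reported as 0.

# The six experiments

A single persisted `split_plan` (stratified fivefold CV plus per-fold,
per-ICP 70/30 splits, JSON round-trip bit-identical) is shared so that all
experiments see identical per-fold training compounds:

1. fivefold internal CV of an ACP on the training batch;
2. the same CV models predict the external batch (drift diagnostic);
3. SCP per fold on the same training compounds predicts the external batch
   (rules the aggregation method in or out as the cause);
4. training-set update: fold training data plus the intermediate batch,
   fresh stratified splits, refit, predict;
5. calibration-set update: every ICP keeps its fitted model and
   recalibrates on the *entire* intermediate batch (the batch plays the
   role of "the new calibration set", so all ICPs share it; resampling it
   per ICP is config-overridable but not the default);
6. calibration-set update with a stratified half of the external batch,
   predicting the other half — calibration and test are then exchangeable
   by construction.

The headline reporting level is $\varepsilon = 0.2$; full-grid curves are
always stored. Fold models persist through a small versioned RDS archive
(`save_experiment()` / `load_experiment()`).

# Synthetic scenarios: what they emulate and what they do not

`drift_scenario()` emulates the three-batch chronology with class-conditional
Gaussians: inactive mean at the origin, active mean `class_sep = 2` noise
SDs away along a seed-fixed unit vector $u$, unit noise, 10% actives
(Tox21-like imbalance), `d = 50` features, 2000 examples per batch. Drift
translates all class means of the later batches by `drift_delta` noise SDs.

**Drift direction.** A uniformly random direction in 50 dimensions is
almost orthogonal to $u$, and a margin-based nonconformity only responds
to the component of a shift along the score gradient — a purely orthogonal
translation leaves every nonconformity distribution, and hence the
calibration, untouched. A "random direction" drift dial therefore mostly
dials nothing. The generator instead fixes the cosine between drift and
class axis at `drift_align = 0.7` (remainder along a random orthogonal
direction), which makes `drift_delta` a genuine, monotone dial on
miscalibration while still moving the batch through feature space. A
label-flip drift mode is available for robustness checks.

What the generator does **not** emulate: sparse, heavy-tailed count
features (a sparse Poisson variant exists for IO integration tests),
assay noise, label imbalance drift, or the cluster structure of real
chemical series. Passing the synthetic suite therefore demonstrates the
statistical machinery, not predictive performance on real toxicity data.

# Monte-Carlo validity checking

`validity_mc()` evaluates marginal validity the way cross-validated
calibration plots are reported: the observed per-class error at each
$\varepsilon$ is the mean over five replicate predictors. The standard
error of that *measured statistic* has two binomial components — the
test-set draw, $\varepsilon(1-\varepsilon)/n_{class}$, and the
calibration-rank noise shared by all predictions of a replicate,
$\varepsilon(1-\varepsilon)/n_{cal}$, reduced by the number of independent
replicate calibration draws — combined in quadrature; the acceptance band
is three such SEs. A variance analysis shows why the naive test-only
binomial band would false-alarm on a provably correct Mondrian ICP: with
60 active calibration examples the calibration-rank term alone
($\approx 0.065$ at $\varepsilon = 0.5$) approaches the whole naive band.

# Problem sizes

The bundled analyses and tests run at 2000 examples per batch, $d = 50$,
five folds, 20 ICPs per ACP, chosen so the full six-experiment suite with
the SVM model completes in about a minute on a single core while keeping
per-class counts large enough for 3-SE bands to be meaningful. The
molecule fixtures are 30 small structures covering every preprocessing
branch (salt, charged species, conflicting and agreeing duplicates,
too-small and inorganic rejections, an unparseable entry).

# Molecule standardisation and descriptors

Standardisation keeps the largest covalently connected organic
(carbon-containing) fragment, applies a deliberately small neutralisation
table — O$^-$/S$^-$ protonated unless adjacent to a positive centre
(preserving nitro and N-oxide), N$^+$/P$^+$ deprotonated when an implicit
hydrogen exists and no negative neighbour — and rejects structures that are
unparseable, inorganic, or smaller than four heavy atoms. Identity is the
full standard InChI of the standardised structure; duplicate conflict
removal runs both before and after standardisation because salt stripping
can merge formerly distinct parents. Parsing and InChI generation are
delegated to ChemmineR/OpenBabel; the rule table is intentionally *not* a
reimplementation of any full standardiser, so compound counts on real
datasets will differ from pipelines using one.

The signature descriptor counts, for every heavy atom and heights 1–3, the
induced subgraph of atoms within that many bonds, encoded as the
lexicographically minimal rooted depth-first traversal string (atom token
= element + charge sign; bond tokens `-`, `=`, `#`, `:`; ring closures as
back-references to visit positions). The minimisation is exact (pruned
exhaustive search over DFS edge orders), so the key is invariant under any
atom relabelling — property-tested with random permutations. Aromatic
systems are encoded as parsed (Kekulé forms from the SMILES reader), which
is injective but means the exact fragment strings are a dialect of this
package; matrices are therefore always paired with their vocabulary file.
Test/score matrices are restricted to the training vocabulary; molecules
sharing no fragment with it become all-zero rows, kept and logged.

# Known limitations

* ACP median aggregation has no finite-sample validity proof; the workflow
  treats SCP as the theoretically valid control, mirroring how the two are
  used together in the drift experiments.
* Per-class guarantees degrade with rare classes through p-value
  resolution; nothing in the implementation can (or should) hide this.
* The standardiser is a documented simplification; tautomers and
  stereochemistry are not normalised.
* Synthetic conclusions transfer to real descriptor matrices only insofar
  as the margin nonconformity is representation-agnostic; no claim is made
  about reproducing any particular real-data figure.
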