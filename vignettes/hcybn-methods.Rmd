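---
title: "Methods: Bayesian-network risk-factor analysis for hyperhomocysteinemia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian-network risk-factor analysis for hyperhomocysteinemia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analytical problem

Hyperhomocysteinemia (HHcy, serum homocysteine > 15 µmol/L) is a common
condition in middle-aged and elderly populations, linked to
cardiovascular and cerebrovascular disease. Logistic regression is the
standard tool for finding its risk factors, but it treats predictors as
exchangeable inputs: it cannot distinguish direct from indirect risk
factors, cannot express the dependence structure *among* the factors,
and cannot answer sequential probabilistic queries when only part of a
patient's profile is known. A discrete Bayesian network — a directed
acyclic graph (DAG) with one conditional probability table (CPT)
per node, `P(X_i | pa(X_i))` — addresses all three, at the cost of a
hard structure-learning problem.

`hcybn` implements the complete analysis chain: guideline-based coding
of clinical measurements into categories, chi-square screening,
stepwise logistic selection, score-based structure learning (tabu
search and hill climbing), maximum-likelihood CPT estimation, exact
inference, and ROC-based model comparison. A calibrated synthetic
population with known generating structure makes every stage testable.

## Variable coding

Twenty categorical risk-factor variables plus the binary outcome are
defined in `hhcy_schema()`. Where a variable is measured on a numeric
scale, a `coding_rule()` maps measurements to categories. Interval
closure follows the explicit inequalities of the clinical definitions:

* SBP: Low < 120 ≤ Normal < 140 ≤ High (mmHg); DBP analogous at 80/90.
* FPG: Normal < 6.1, Impaired 6.1–7.0 (inclusive), High > 7.0 (mmol/L).
* BMI: Underweight < 18.5 ≤ Normal < 24 ≤ Overweight < 28 ≤ Obesity.
* Hcy: HHcy strictly > 15 µmol/L, so 15.0 itself codes Normal.
* ACR ≥ 30 mg/g abnormal; MCR > 23 mg/g abnormal, where
  ACR = mAlb/Ucr × 8.84 and MCR = α1-MG/Ucr × 8.84 (`derive_ratios()`).
* Bands written without explicit closure (e.g. 120 ~ 140) adopt
  lower-closed/upper-open `[a, b)`, the only convention consistent with
  every explicitly printed inequality.

Every rule partitions the real line totally; boundary behaviour is
property-tested (`x ± 1e-9` around every cut-off falls in adjacent
categories). Missing data are handled by complete-case deletion only
(`apply_exclusions()`, which also enforces the minimum enrolment age of
40); no imputation is attempted, matching the study design that
excluded incomplete records.

## Screening and stepwise selection

`screen_variables()` tests each candidate against the outcome with the
Pearson statistic `Σ (O − E)² / E`, df = (r−1)(c−1). For 2×2 tables the
Yates continuity correction is applied by default. The published 2×2
p-values are reproduced only with the correction while the multi-row
p-values are reproduced only without it, so correction-on-2×2-only is
the package default; it is configurable off (`correct = FALSE`). No
multiple-testing adjustment is applied across the twenty screens, as
none was used in the source analysis. Significance level: 0.05.

`stepwise_select()` runs forward/backward selection on a binary
logistic model fitted by IRLS (`stats::glm`, relative deviance change
< 1e-10, ≤ 100 iterations; standard errors from the inverse observed
information). Design choices:

* **Score coding.** Multi-level predictors enter as single ordinal
  integers (0, 1, 2, … in state order), giving one coefficient — one
  odds ratio per band — which is how the published model reports one OR
  for four age bands or three glucose classes. Dummy coding is an
  option (`coding = "dummy"`).
* **Entry/removal statistic.** Likelihood-ratio tests
  (α_in = 0.05, α_out = 0.10). The source software's choice (score
  test in, Wald out, in SPSS convention) is not stated; the LRT is used
  here as the likelihood-consistent default and is documented as a
  possible deviation.
* **Determinism.** Ties in p-values break lexicographically; revisited
  model states terminate the search with a warning. The trace records
  every add/remove with its p-value.
* The 95% CIs use the constant 1.96 (not `qnorm(0.975)` to more
  digits); this reproduces the published interval arithmetic exactly.

Stepwise selection with these thresholds retains a false candidate with
appreciable probability (each eligible null faces repeated 5% entry
tests); the pipeline therefore asserts recovery of the generating
factors, not an exact selected count.

## Network score and structure search

The decomposable BIC score (natural logarithms) of a structure is the
sum over nodes of `family_score()`:

```
score(G) = Σ_i [ Σ_{j,k} N_ijk ln(N_ijk / N_ij) − (ln n / 2)(r_i − 1) q_i ]
```

with `r_i` the node's state count, `q_i` its number of parent
configurations, and `0 ln 0 = 0`. AIC and the raw log-likelihood are
options; BIC is the default because it is the standard default of
score-based structure learners in this field. Scores are cached per
(node, parent-set) so a search rescoring one or two families per move
stays fast.

The move set is single-edge addition, deletion and reversal, filtered
for acyclicity and an optional parent bound, enumerated in a fixed
lexicographic order (`dag_moves()`); whitelists and blacklists are
supported but empty by default.

`hill_climb()` applies the best strictly improving move from the empty
graph until none exists (improvement threshold 1e-9 to absorb float
noise).

`tabu_search()` follows the classic six-step scheme: initialise; test
convergence; enumerate the neighbourhood; apply the *aspiration*
("contempt") rule — a tabu move is admissible only if it would strictly
beat the best score seen; otherwise take the best non-tabu move even
when it worsens the score; push the inverse move onto the tabu list;
repeat. Defaults:

* `tenure = 10` iterations. The tabu list stores *inverse moves*, not
  whole structures: move hashing is O(1) and matches the algorithm's
  description as recording the mobile search steps.
* `max_nonimproving = 15` consecutive iterations without a new best
  score (the convergence criterion, which the source leaves
  unspecified), `max_iter = 10000`.
* Initial structure: the empty DAG. The search is fully deterministic;
  no randomness is used.

The returned structure is the best visited, so the best-score trace is
non-decreasing and tabu search can never return a worse score than the
point at which hill climbing stalls, given budget to reach it. With
`tenure = 0, max_nonimproving = 1` it degenerates to hill climbing's
answer. On XOR-type landscapes — where a collider's two parents are
marginally independent of the child, so no single-edge move improves
the empty graph — greedy search provably stalls while tabu's worsening
moves cross the plateau; the test suite constructs exactly this
landscape and verifies tabu attains the exhaustively enumerated optimum
(all 543 four-node DAGs).

## Parameters and inference

`fit_mle()` estimates CPTs as conditional relative frequencies,
`P(x | pa) = (N(x, pa) + c)/(N(pa) + c·r)` with pseudocount `c = 0` by
default (pure maximum likelihood, as in the source analysis); a parent
configuration never observed yields a uniform fallback row, and a
Laplace pseudocount is available for downstream numerical stability.
Parent configurations enumerate row-major in the structure's declared
parent order, so serialized tables (`write_bn()`/`read_bn()`, JSON) are
byte-stable.

`marginal()` and `posterior()` perform exact variable elimination.
The elimination order is min-fill with deterministic name tie-breaks —
purely a performance choice, since exact answers are order-invariant
(property-tested across random orders). Evidence accumulates by list
concatenation, so sequential reasoning (high SBP, then advanced age,
then abnormal MCR) is the same computation as joint conditioning.
Zero-probability evidence is an error naming the assignment.

`predict_proba()` scores each subject as `P(target | all other
variables)`. Only the target's Markov-blanket families contribute
(all other factors cancel), which vectorises over rows; a row whose
full evidence has probability zero under the network — possible with
pure MLE zeros — is rescored after greedily dropping a minimal set of
conflicting assignments, with a warning. This keeps ROC evaluation
computable on held-out data; a hard-error alternative is to pre-screen
rows. Junction-tree propagation was deliberately not implemented:
at ten nodes variable elimination is already instantaneous.

## Evaluation

`roc_auc()` computes the AUC by the exact Mann–Whitney rank formula
(ties ½) and the 95% CI by DeLong's estimator (via pROC); both the
rank AUC and an O(n²) pair-counting oracle are compared in tests. ROC
for non-outcome nodes (the source reports AUC for sex and MCR) is
implemented literally: predict that node from all others and score
against its observed states. Evaluation is in-sample by default, as the
source does not describe a held-out split; `compare_structures()`
provides SHD and skeleton precision/recall/F1 for structure-level
comparison.

## The synthetic population

`make_hhcy_population()` samples from a fixed 21-node ground-truth
network (`hhcy_truth_network()`) by ancestral sampling (Mersenne-
Twister, explicit integer seed). The generator emulates:

* **Marginals**: every variable's marginal distribution equals the
  published baseline frequencies exactly (root nodes take them
  directly; conditional nodes are logistic or proportional-odds models
  whose intercepts are solved by deterministic root-finding against the
  exact parent joint).
* **Core structure**: homocysteine status depends on the nine
  multivariate risk factors with effects on the logit scale of the
  magnitude reported in the published multivariate table (strong: age
  0.35/band, sex −0.85, MCR 0.45, FPG −0.30, diet −0.55, SBP 0.30;
  weak: smoking 0.17, GHb −0.35, BMI 0.093), plus the indirect pathways
  SBP ← {Age, BMI}, FPG ← {MCR, GHb}, Smoking ← Sex. The core subgraph
  has 10 nodes and 14 directed edges — the published network size — and
  is returned as the recovery target (`core_dag`).
* **Screening pattern**: Exercise and ACR are independent roots; the
  remaining ten non-core variables are downstream correlates
  (education and income from age, lipids from diet and BMI, DBP from
  SBP, alcohol from sex and smoking, salt from diet), so on a large
  sample univariate screening finds exactly the published split —
  all associated except Exercise and ACR — while none of them carries
  information about the outcome beyond the core nine.

Effect sizes were fixed once from the published univariate and
multivariate magnitudes; where two pathways of opposite sign meet (the
lipid variables see diet negatively and BMI positively with respect to
the outcome) the coefficients weight the diet pathway, matching the
published direction of those associations.

What the generator does **not** emulate: the real joint dependence
beyond the published marginals and qualitative structure (unknowable
without the raw data); continuous pre-discretisation lab values;
survey nonresponse and recall bias; any cluster structure across the
ten survey regions. Consequently, passing tests demonstrate that the
pipeline recovers a known truth of realistic size and strength — not
that the published structure itself is correct. The published
raw-data-dependent outputs (the specific learned figures, coefficient
values, posteriors 0.701/0.746/0.779 and the printed AUCs) are treated
as non-reproducible; the package reproduces their *mechanics* and the
printed-table arithmetic (chi-square p-values, the 0.665 prior, OR
intervals) exactly.

One bookkeeping note: the study text reports 12,269 enrolled subjects
while the baseline table's groups sum to 12,285 (4,110 + 8,175); the
package follows the table, whose counts it uses cell-for-cell, and
does not attempt to resolve the discrepancy.

## Problem sizes and numerical tolerances

The test suite validates inference against full joint enumeration
(≤ 5 nodes, ≤ 3 states, 1e-10), structure search against exhaustive
DAG enumeration (≤ 4 variables), and the end-to-end pipeline on
simulated populations of 4,000–50,000 subjects, with 200,000 used where
marginal-convergence checks need tight binomial error. These sizes were
chosen so that every asserted property holds with large statistical
margin (several binomial standard errors) at the fixed fixture seed;
the structure-recovery and CPT-accuracy checks run at n = 50,000, the
reference size for the recovery experiment. CPT row normalisation is
enforced to 1e-12; score decomposability to 1e-9; a strict-improvement
threshold of 1e-9 guards greedy moves against floating-point ties.

A caveat worth stating plainly: an absolute accuracy bound of 0.02 on
refit CPT entries whose parent configuration has ≥ 500 supporting
samples is *not* statistically guaranteed — a configuration with ~500
samples has binomial SE up to 0.022, and across a few hundred
qualifying entries the largest deviation is expected near 3 SE. The
suite therefore also checks the sound version of the property (every
error within 4.5 binomial SEs), which is what a correct
maximum-likelihood estimator can promise.

## Known limitations

* Score-based search returns one DAG per run; Markov-equivalent
  structures score identically, so learned edge *directions* within an
  equivalence class are not identifiable and only skeletons are
  compared against truth.
* The stepwise procedure inherits the classical multiplicity behaviour
  of α-threshold selection (occasional false inclusions).
* In-sample AUC overstates out-of-sample discrimination; a holdout
  split is left to the user (the evaluation functions take arbitrary
  score/label vectors).
* Variable elimination is exponential in treewidth; fine at this
  domain's size, not intended for networks with hundreds of nodes.
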