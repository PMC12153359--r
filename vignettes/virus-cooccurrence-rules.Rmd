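---
title: "Mining and validating virus co-occurrence rules from presence/absence surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and validating virus co-occurrence rules from presence/absence surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virorules)
```

## The problem

Fungal strain collections surveyed by RT-PCR yield a binary matrix: rows are
strains, columns are viruses, and a cell records whether a given mycovirus
was detected in a given strain. In such surveys most strains carry several
viruses at once, which raises the question this package answers: do viruses
co-occur (or avoid each other) more often than chance, and can those
patterns be written down as rules that predict the virus composition of a
strain's clonal offspring?

## The model: association rules over present/absent items

Each virus contributes two items, `v=T` (present) and `v=F` (absent). A rule
is an implication `LHS => RHS` with an antecedent itemset of one, two, or
three items over distinct viruses ("one-to-one", "two-to-one",
"three-to-one") and a single consequent item. Three metrics, estimated as
empirical frequencies over the mined strains, quantify each rule:

* **Support** `= P(LHS ∩ RHS)` — the fraction of strains satisfying every
  item of the rule;
* **Confidence** `= P(LHS ∩ RHS) / P(LHS)` — how often the consequent holds
  among strains satisfying the antecedent;
* **Lift** `= P(LHS ∩ RHS) / [P(LHS) · P(RHS)]` — 1 under independence,
  above 1 for positive association, below 1 for avoidance.

Rules are enumerated with the Apriori algorithm: frequent itemsets are grown
level-wise and any superset of an infrequent itemset is skipped
(anti-monotonicity of support). Contradictory itemsets containing both
states of one virus are discarded structurally rather than by a support
test. Rules are **ordered**: `{A=T} => {B=T}` and `{B=T} => {A=T}` are
distinct candidates (their Supports and Lifts coincide; their Confidences
generally do not). Candidate output is canonically sorted (rule form, then
antecedent items lexicographically by virus id, then consequent), so runs
are bit-identical.

### Default thresholds

`mining_config()` defaults minimum Support and Confidence to `3/V`, `V`
being the number of virus species in the matrix: in cohorts where almost
every strain carries three or more viruses, a pattern involving fewer than
three strains' worth of co-occurrence mass is unresolvable. Both thresholds
are exposed because published analyses sometimes report a post-hoc floor
(e.g. the minimum Support among retained rules) that differs from the mining
cutoff; `filter_significant_rules()` accepts such floors separately
(`min_support`, `min_lift`) so both readings can be reproduced.

Probabilities are estimated over the mined strain subset. The default mask
drops strains that carry no virus at all (`mined_strains = "infected"`): a
virus-free strain is evidence about prevalence, not about co-occurrence, and
keeping it would shrink every `v=F` conditional toward the margin. Pass
`"all"` to keep every strain.

## Significance: permutation null and the dynamic Lift threshold

Lift is 1 under independence only in expectation; its sampling spread
depends strongly on how common the two viruses are. A rule built from two
rare viruses can reach Lift 3 by chance, while Lift 1.05 can be wildly
unlikely for two common ones. A single Lift cutoff therefore cannot control
the false-positive rate. The package instead calibrates a **dynamic
threshold**:

1. Each virus column is permuted independently across strains
   (`permute_matrix_columns()`). This preserves every per-virus prevalence
   and the strain count exactly while destroying cross-virus association —
   the independence null conditioned on the observed margins. (An
   independent-Bernoulli null with plug-in prevalences is available via
   `null_model = "bernoulli"` for sensitivity analysis.)
2. The same mining configuration is run on `n_permutations` (default 200)
   permuted matrices and all null (Support, Confidence, Lift) triples are
   pooled (`build_null_lift_distribution()`).
3. The pool is stratified into a (Support bin × Confidence bin) grid —
   by default deciles of the pooled null metrics, clipped to cover [0, 1] —
   and each stratum's threshold is the empirical `1 - alpha` quantile of its
   null Lifts (`calibrate_dynamic_thresholds()`). Strata that received no
   null rules are flagged and fall back to the global `1 - alpha` quantile.
4. A candidate is retained only if its Lift **strictly exceeds** the
   threshold of the stratum it falls in (`filter_significant_rules()`).

**Quantile convention.** Thresholds use R's default type-7 empirical
quantile. The convention matters at permutation counts in the hundreds (for
the null lifts 0.01, 0.02, …, 1.00 at `alpha = 0.05`, type 7 gives 0.9505,
type 1 gives 0.95); it is fixed, documented here, and pinned by a test.

**What "FPR" means here.** The implemented definition is the expected
proportion of *candidate* rules passing the threshold when all viruses are
mutually independent. Other readings (per-rule error rate, proportion of
retained rules that are false) coincide under the full null but not in
general; this package's guarantee is the stated one, verified empirically by
`estimate_null_fpr()`: on fully independent synthetic cohorts the mean
retained proportion stays at or below `alpha` up to Monte-Carlo error.
Strict inequality at the threshold and the type-7 quantile both err on the
conservative side.

**Seed policy.** One master seed (in `calibration_config()`) drives the
experiment; per-permutation seeds are derived from it deterministically, so
a fixed (matrix, config, seed) triple yields an identical calibration table
and retained set.

## Rule typology

One-to-one rules fall into four classes, a function of item states only:
Type I (`A=F => B=F`, absence explains absence), Type II (`A=T => B=T`),
Type III (`A=T => B=F`, exclusion), Type IV (`A=F => B=T`). Multi-antecedent
rules are labelled by their state tuple (`"TT=>F"`, `"TFF=>T"`, …) with
antecedent states sorted T-before-F, because the antecedent itemset is
unordered — `{A=T, B=F}` and `{B=F, A=T}` are the same rule. Sixteen
three-to-one state patterns exist under this collapsing (8 unordered
antecedent patterns × 2 consequent states); `type_census()` reports whatever
patterns are present without asserting a particular partition.
`group_rules()` is the tabular stand-in for balloon-plot figures: one cell
per (antecedent itemset, consequent item) with count, maximum Lift and
maximum Support.

## Validating rules against offspring

During conidiation co-infecting viruses pass unevenly into spores, so the
virus sets of single-spore offspring (or protoplast regenerants, or
transfectants) are natural held-out tests of mined rules. The semantics,
chosen where the procedure was genuinely open and fixed here:

* **Predicted** rules for a parent strain are the significant rules whose
  full virus set (antecedent and consequent viruses) is a subset of the
  parent's detected viruses — those are the rules its offspring could
  falsify. The alternative reading (antecedent presence-items carried by the
  parent) is available via `semantics = "lhs_satisfiable"`.
* On each offspring, a rule is read as a **material implication**: it holds
  when the antecedent is unsatisfied (vacuously) or when antecedent and
  consequent both hold. This is the only reading under which a
  presence/absence table can falsify a rule at all.
* A rule is **confirmed** iff it holds in *every* offspring — the strictest
  conjunction, consistent with reporting near-100% accuracies only when no
  counterexample offspring exists. Accuracy is
  `100 × confirmed / predicted`, reported per strain and per rule form, with
  zero-predicted cases reported as undefined (`NA`), never as 0.

Transfectant lineages are treated identically to single-spore ones; the
report format does not distinguish origins beyond the label.

## The synthetic world

`synthetic_config()` describes a stand-in for a 405-strain × 76-virus
survey; it is a stated world, not a tuning knob:

* **Prevalences** default to 76 values log-spaced from 1/405 to 0.8,
  emulating a survey whose most common virus infects ~80% of strains while
  several viruses appear once. The long rare tail deliberately stresses the
  low-support calibration strata.
* **Planted pairs** `(A, B, p(B|A), p(B|¬A))` and **planted conditionals**
  (a 4-entry table for C given the A,B states) give the pipeline a
  recoverable ground truth; generation follows a topological order of the
  planted graph, so the implied Lift of `{A=T}=>{B=T}` has the closed form
  `p(B|A) / [P(A)·p(B|A) + (1−P(A))·p(B|¬A)]`, which tests check at large n.
* **Lineages**: each offspring keeps each parental virus independently with
  `retention_prob` (default 0.8, ~the loss rates visible in single-spore
  panels), then planted incompatible pairs are resolved by dropping one
  member at random. Offspring never gain viruses — horizontal acquisition in
  the field is real but out of scope, and allowing it would break the
  subset-screening semantics above.

What a green test on this world does **not** establish: the generator draws
strains i.i.d. (no site or host-plant structure, no phylogenetic
correlation among viruses), plants only low-order dependencies, and knows
nothing about detection error in RT-PCR. Recovery and FPR results transfer
to real surveys only to the extent those assumptions hold.

## Numerical and degenerate-input choices

* Empirical quantiles: type 7, strict `>` at the threshold (both
  conservative).
* Contradictory itemsets: support 0 by definition in `itemset_support()`;
  pruned structurally in enumeration.
* Rules whose antecedent or consequent has zero support are skipped
  (metrics undefined), and `compute_rule_metrics()` errors on them
  explicitly.
* Long-format input lists present pairs only; unlisted pairs are absent.
* Ties in canonical ordering cannot occur (items are unique per rule);
  string ordering uses radix (C-locale) sorting for platform stability.
* An all-zero matrix mines to an empty rule set under the default mask only
  if at least one strain remains; the mask erroring on an empty remainder is
  deliberate, since every probability would be 0/0.

## Limitations

* Lift-threshold significance is the procedure implemented; no parametric
  (Fisher/chi-square) tests and no FDR machinery beyond the calibrated FPR.
* Candidate counts from published analyses depend on unstated details
  (whether confidence filtering preceded the reported counts, the exact
  post-hoc floors), so external count reproduction requires the original
  supplementary tables as input.
* Validation is qualitative presence/absence; titer differences among
  offspring are invisible to it.
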