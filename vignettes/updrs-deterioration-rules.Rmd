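---
title: "Rough-set rules for UPDRS motor-state deterioration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rough-set rules for UPDRS motor-state deterioration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(updrsalert)
```

## The model

The unit of analysis is a pair of UPDRS motor examinations of one patient —
a historical and a current one, typically around eight months apart. From
the 13 motor items (UPDRS 13, 14, 20, 21, 23, 24, 25, 26, 28, 29, 31, 32,
39), lateral expansion produces 21 attributes: item 20 (rest tremor) per
limb, items 21/23/24/25 per hand, item 26 (leg agility) per leg, the rest
axial or global. The condition vector of a training object is the per-item
integer change `Δa = current − historical ∈ [−4, 4]`; the decision is one
expert's verdict in {0 stable, 1 warning, 2 alarm}. Several experts rate the
same pair, and their votes are kept as separate objects: a pair on which
experts split produces contradictory rows, which is the intended input of
the rough-set layer, not an error.

**Deduplication.** Repeated entries are removed *within each expert's
decision table*: a duplicate is a row identical on all deltas, the decision
and the expert. Two experts casting the same vote on the same pair are two
distinct training objects (they also carry real information: the vote
multiplicity of a delta pattern feeds rule support and the β-purity of
blocks). This convention is what makes the cohort bookkeeping work out: 74
pairs × 4 experts = 296 raw objects, and with four unchanged-score
follow-up pairs (three repeated entries in each of the four experts' tables)
deduplication leaves exactly 284 records, split 142 + 142 by the stratified
50:50 protocol. Had duplicates been defined on (deltas, decision) alone,
each pair would lose at least one of its four votes by the pigeonhole
principle and a 284-record table would be unreachable — so the per-expert
reading is the only internally consistent one.

## Rough-set machinery

For an attribute subset *B*, records agreeing on every attribute of *B* form
the blocks of the indiscernibility partition. A decision class *X* is
approximated from below (union of blocks entirely inside *X*: records
*certainly* in *X*) and above (blocks intersecting *X*). The positive region
is the union of all lower approximations; γ = |POS|/|U| equals 1 exactly on
consistent tables. Reducts — minimal attribute subsets preserving the
positive region — are computed either exhaustively (≤ 15 attributes; γ is
monotone in the attribute set, so minimality reduces to single-attribute
removal tests) or by Johnson's greedy heuristic on the discernibility
matrix, with lexicographic tie-breaking and a final γ-preserving pruning
pass, so results are deterministic. Contradictory pairs (equal deltas,
different decisions) have empty discernibility entries; they are skipped by
the covering and surfaced by `inconsistency_report()` instead.

## Discretization cuts

The printed rule style uses strict integer inequalities
(`-1<ΔUPDRS14<2`), which presupposes cuts between observed integer values.
Candidate cuts sit at midpoints between consecutive observed values per
attribute. Retention is greedy Boolean reasoning: repeatedly take the cut
with the best score until every discernible decision-differing record pair
is discerned, then drop cuts that became redundant (last selected first).

The score is *balanced*: (still-undiscerned decision-differing pairs the cut
discerns) − (same-decision pairs it splits within the cells of the current
discretization). The penalty term matters. Scoring by discerned pairs alone
lets attributes that are merely correlated with the decision by sampling
accident win late rounds — any attribute splits roughly half of a small
residual pair set by chance — which plants cuts on clinically irrelevant
attributes and, downstream, rules that key alarms on noise. A cut on a true
class boundary splits almost no same-class pair within its cells, so the
balanced score separates signal cuts from accidental ones at essentially no
cost; on consistent tables generated by the built-in labeler it recovers
exactly the boundary cuts of the label-relevant attributes. Ties are broken
by attribute name and threshold, so the cut set is deterministic.

## Rule induction

**RS.** Sequential covering in the LEM2 style, per class over the class's
lower approximation in the cut space: grow a conjunction of half-space
conditions (choosing, each step, the condition covering the most uncovered
goal records; ties by fewest negatives, then attribute order) until every
matched record lies in the lower approximation; prune conditions — whole
attributes first, then single bounds — while that invariant holds; remove
covered records and repeat; finally drop rules redundant for the class's
coverage. On a consistent table every rule is certain (confidence 1), which
also guarantees 100% training accuracy: any rule matching a training record
must carry that record's class.

**RS-g.** The generalized variant uses the variable-precision model: a block
belongs to a class's β-lower approximation when at least a fraction β of its
records carry the class (β ∈ (0.5, 1], default 0.8 — the midpoint of the
usual variable-precision operating range; β = 1 recovers the classical
model). After covering, each rule is shortened greedily: at every step the
condition whose removal leaves the highest confidence is dropped, as long as
confidence stays ≥ β (ties prefer the larger support, then condition
order). Shortening is where the generalization happens in practice: with
four experts per pair and at most a few distinct votes per delta pattern,
blocks are small and β = 0.8 admits few extra blocks, but the shortened
rules match far more unseen records at a bounded training error. Identical
shortened rules are merged, so the RS-g set is usually smaller than the RS
set from the same table.

## Classification and evaluation

All matching rules are collected. One matching class → that class; several →
the class with the largest sum of confidence × support; no full match → the
rules with the highest fraction of satisfied conditions vote the same way;
any remaining tie resolves to the most severe class. The severity bias is
deliberate clinical conservatism: the cost of a missed alarm exceeds the
cost of a spurious one. The same reasoning fixes the nearest-neighbour
baseline's class tie-break.

Evaluation reports the 3×3 confusion matrix and three efficiency cases:
case 1 is plain 3-class accuracy; case 2 merges {stable, warning} against
{alarm} (high-priority-alarm recognition); case 3 merges {warning, alarm}
against {stable} (any-alert recognition). Collapsing moves error cells onto
the diagonal and can never lower accuracy, so case 2, case 3 ≥ case 1 for
every matrix. Percentages are rendered to one decimal in reports; the
underlying values are kept at full precision. The 50:50 split is stratified
(per-class proportions preserved to within one record) and seeded; whether
the original protocol stratified is unknown, so stratification with a fixed
default seed was chosen for reproducibility.

## The synthetic cohort

The simulator emulates the statistical shape of the clinical setting, not
any real dataset:

* 47 patients, 74 exam pairs (27 patients contribute a second historical
  exam), 4 experts, exams 240 ± 30 days apart;
* baseline scores per item from a mid-weighted distribution over 0–4;
* a latent progression state per pair — 40% stable, 40% mild, 20% severe —
  driving independent per-attribute integer increments in −1…3 (stable
  patients nearly static, severe ones frequently worsening by two points on
  single items), clipped so scores stay in 0–4. Independence across
  attributes yields the left/right asymmetry of the disease;
* a deterministic ground-truth labeler: severity = max over attributes of
  weight × positive delta, class 2 at severity ≥ 2, class 1 at ≥ 1, else 0.
  Default weights put all mass on the axial triad — falling (13), freezing
  of gait (14), gait (29) — reflecting that experts were instructed to weigh
  symptom importance rather than sum points, and that axial worsening is the
  canonical red flag of deterioration. The weights, thresholds and
  aggregation are configuration, not a claim about true clinical weighting;
  an explicit rule set can be substituted as ground truth;
* expert noise: each expert reports the true class with probability
  1 − `expert_noise` (default 0.15) and otherwise an adjacent class —
  clinicians plausibly confuse neighbouring severity grades, never stable
  with alarm directly.

What the simulator does *not* emulate: medication on/off fluctuations,
longitudinal trajectories beyond one pair, correlated progression across
items, systematic inter-expert bias (each expert errs independently), and
any faithful joint distribution of real expert votes. Passing tests
therefore demonstrate correctness of the machinery under a controlled,
plausible data-generating process — not clinical performance.

The bookkeeping fixture (`make_cohort_fixture()`) additionally pins the
cohort arithmetic: four of its 74 pairs are unchanged-score follow-ups (the
all-zero delta vector) and the remaining 70 delta vectors are made pairwise
distinct by a deterministic one-point adjustment, so the 296-row table
always deduplicates to exactly 284 records.

## Numerical and degenerate-case choices

* Deltas are discrete symbols at the rough-set layer; intervals exist only
  through cuts. Cut thresholds are half-integers, rendered as strict
  inequalities on integers (`Δ < 0.5` prints as `Δ < 1`).
* A single-class table induces one unconditional rule (`Iftrue=>…`).
* Classes absent from a (β-)lower approximation produce a warning and no
  rules; records uncoverable by a certain rule (contradictory support) are
  dropped from the goal with a warning rather than silently mislabeled.
* β-purity comparisons are exact (small-integer rationals in doubles).
* All stochastic components run on an isolated RNG stream so library calls
  never perturb user-level random state; one integer seed reproduces
  simulations, splits and reports byte for byte.

## Problem sizes used by the tests

The shipped suite exercises: the 296/284/142+142 fixture; 200 random tables
(≤ 8 attributes, ≤ 40 records) checked exactly against a brute-force
set-comprehension oracle for approximations, positive regions, γ and (≤ 6
attributes) exhaustive reducts; noiseless recovery — rules induced from 284
independently generated noiseless records reproduce the ground-truth labeler
on 1,000 fresh records without error; 1,000 random confusion matrices for
collapse monotonicity; and 20 seeded replicates at expert noise 0.15
comparing RS and RS-g (β = 0.8) on clean-labeled held-out samples of 500
records, where RS-g wins the majority of replicates and shows the smaller
mean train−test gap. These sizes keep the suite's runtime modest while
leaving each property statistically unambiguous.

## Known limitations

* Rule induction is the single covering path; value-reduct enumeration and
  dominance-based or fuzzy extensions are out of scope, as are missing
  values (inputs are complete by construction).
* The certain-rule semantics caps training accuracy on inconsistent tables:
  records in boundary regions can only be classified by partial matching.
  This is a property of the model, not a defect — with conflicting expert
  labels, 100% coverage is impossible by construction.
* Exhaustive reduct search is exponential and deliberately refused above 15
  attributes; the greedy reduct is a single reduct, not the family.
* The simulator's independence assumptions make its tables somewhat easier
  than clinical data; accuracy figures obtained on it do not transfer to
  real cohorts.
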