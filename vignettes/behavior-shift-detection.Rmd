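---
title: "Detecting shifts from frequent behaviors in smart-home event logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting shifts from frequent behaviors in smart-home event logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adlshift)
```

## The problem

An ambient-assisted-living environment reduces its sensor stream to a log
of discrete, labelled actions (`'Pill, on'`, `'Water Off'`, …) — the
package starts where that transformation ends. Residents have *frequent
behaviors*: recurring routines such as a morning ritual or the fixed action
sequence of cooking oatmeal. Two questions arise for every newly observed
episode. Is it one of the known routines, and if so how common is this
particular variant? And if it is not, *what exactly* is different, and does
the difference matter? Gradual drift in routines is an early behavioral
marker of conditions such as depression or Alzheimer's disease, so an
explanation ("the medication step is missing", criticality high) is far
more useful than an unexplained anomaly score.

`adlshift` answers both questions with an interpretable, fully
deterministic pipeline: Markov-chain likelihoods for recognition, and
minimum edit-modification sets against the chain's enumerated paths for
explanation, weighted by an expert-supplied criticality mapping.

## The model and its assumptions

A frequent behavior is a Markov chain over action labels with three pieces:
an initial distribution `P0`, a transition matrix `P`, and a per-state
*end probability* — the chance that the routine finishes at that state.
For every state, outgoing transition probabilities plus the end probability
sum to 1; a *terminal* state is simply a state with end probability 1. End
probabilities are a small generalization of the usual "terminal = no
outgoing transitions" convention, needed because a realistic routine can
revisit an action: in the smart-apartment "Eat" activity the resident opens
the same cabinet at the start and the end, so the routine's final action is
a state that elsewhere continues. With all end probabilities 0 or 1 the
model reduces exactly to the plain convention.

The likelihood of an observed episode `C = c_1 … c_n` is the product of
its consecutive transition probabilities. The episode is treated as one
complete realization over its full length: likelihood 0 when any action is
unknown, the first action is not a start state, any transition is absent,
or the episode stops where the behavior cannot end. Two modelling choices
deserve note:

* **The initial and end probabilities gate but do not multiply.** A
  positive initial probability and a positive end probability are required,
  but the reported likelihood is the pure transition product (this
  reproduces the worked reference values, where the single start is
  certain). `include_initial_prob = TRUE` switches the multiplication on
  for chains with genuinely uncertain starts.
* **No length normalization.** The product over all `n − 1` transitions is
  reported as-is; a geometric-mean variant would misstate the worked
  values (e.g. a single 0.6 branch would become `0.6^(1/8) ≈ 0.94`).

First-order dependence is assumed throughout: the next action depends only
on the current one. Duration information (how long between actions) is
deliberately out of scope — timestamps order events within an episode and
play no role in the algorithms.

## Paths, modifications, criticality, risk

All complete start-to-end traversals (*paths*) of a chain above a
likelihood threshold are enumerated depth-first. Pruning a branch as soon
as its running product falls below the threshold is sound because
transition probabilities never exceed 1, and — together with a hard length
cap — it guarantees termination on chains with loops. Defaults are a
threshold of 0.01 and a cap of 100 actions, both exposed in
`shift_config()`; the threshold is a floor on "variants worth considering
as repair targets" and the cap only matters for looping chains.

A shifted episode (zero likelihood everywhere) is compared to every path
with a Damerau–Levenshtein dynamic program over four unit-cost operations:
insertion of a forgotten action, deletion of an extra one, substitution,
and transposition of two adjacent actions. The recurrence carries the
diagonal on a match and otherwise takes `1 + min(delete, insert,
substitute)` with the adjacent-transposition case `d[m−2, n−2] + 1` when
the two trailing actions are crossed; boundary cells are `d[m, 0] = m` and
`d[0, n] = n`. Cell provenance records which operation achieved each
minimum so the modification set can be read back; where several operations
tie, the deterministic preference *match > swap > substitute > delete >
insert* picks one, chosen so that the most structured explanation wins and
results are reproducible. Each aligned position is edited at most once (a
transposition consumes both of its positions), which is the natural
reading of "the set of modifications the user's behavior needs". Replaying
the backtraced set on the episode reproduces the path exactly, and the set
size always equals the bottom-right matrix cell; both are enforced by
property tests. Positions in modification tables are 1-based, following R
convention.

Criticality is a mapping from modifications to `[0, 1]`, *lower = more
critical*, supplied by domain experts (a missed pill ≈ 0.2; a skipped
shower ≈ 1). Rules may name full operands or leave them as op-level
wildcards; the most specific matching rule wins and unmapped modifications
take the map's default (1). A modification set aggregates by the
**minimum** by default — one critical member should dominate, not be
diluted by harmless edits — with `product` and `mean` available where an
accumulating penalty is wanted. The risk factor combines count and
severity as `φ = |M| · (1 − Cr(M))`: zero exactly when no modification is
needed or all modifications are fully non-critical, increasing in both the
number of edits and their severity. The anomaly threshold defaults to 1 —
strictly more than one fully-critical modification's worth of risk — and
is deliberately configurable, since what counts as anomalous is an
application decision. Among a behavior's paths the reported repair is the
one with the fewest modifications, ties broken by higher path likelihood,
then lower criticality.

## Learning chains from episodes

`learn_behavior()` is a transition-frequency estimator: actions appearing
in at least `min_support` of the episodes become states (default 0.5;
infrequent actions are removed from the episodes rather than treated as
gaps, keeping the chain connected), transition probabilities are
row-normalized consecutive-pair counts, the initial distribution is the
empirical distribution of first actions, and each state's end probability
is the fraction of its occurrences that closed an episode. Counting makes
the learner deterministic given the corpus. It stands in for a full
behavior-mining system: ordering discovery, time relationships, and
condition mining are out of scope because the shift-detection algorithms
consume only the resulting chain.

One learner option matters scientifically. A first-order chain over bare
action labels cannot represent a fixed routine that revisits an action:
label-level counting of the "Eat" sequence invents never-observed
orderings (medicine returned before it is taken out) as extra paths of
equal likelihood, which makes some single-edit repairs genuinely ambiguous.
`distinguish_occurrences = TRUE` treats the *k*-th occurrence of a label
within an episode as its own chain state, restoring the observed ordering.
The tagging is purely internal — episodes, enumerated paths and sampled
episodes always carry plain labels. The default is `FALSE`, which is the
right setting for estimating a genuinely stochastic process (e.g.
recovering the transition matrix of a looping chain); the cross-validation
harness and the ADL fixtures use `TRUE` because fixed-order routines are
exactly the case the tagging exists for.

## What the synthetic generator emulates

`sample_episode()` draws a start state from `P0`, then repeatedly ends
(with the state's end probability) or follows a transition; all randomness
flows through explicit integer seeds, so identical calls are
byte-identical. `sample_adl_corpus()` builds the validation corpus: `n`
episodes realizing five smart-apartment ADLs — make a phone call, wash
hands, cook, eat, clean — as their fixed recorded action sequences,
balanced across activities and shuffled into a seeded order.
`perturb_episode()` injects controlled corruptions (remove an action,
add a spurious one, replace one, transpose an adjacent pair) and returns
the ground truth as *repairs*, the modification set the detector should
report; multiple corruptions are placed at pairwise non-adjacent positions
so repairs cannot interact or cancel.

The generator emulates what matters to the algorithms — realization
frequencies, completeness of episodes, localized corruptions — and nothing
else. It does not model sensor noise or mislabeled actions, dwell times,
interleaved activities in one unsegmented stream, or gradual drift across
weeks. Passing validation on this corpus therefore demonstrates that the
pipeline recognizes routine realizations and exactly recovers localized
deviations; it does not certify performance on noisy real-world
transformation-layer output.

## The adapted cross-validation

`cross_validate()` mirrors how such a detector is validated in the field:
episodes are split into *k* folds (round-robin after a seeded shuffle,
seed 17 by default); per fold, behaviors are learned from the training
episodes and the detector runs on each held-out episode twice. The
unperturbed arm checks that a correct episode is identified as a path
match — positive likelihood, zero modifications. The perturbed arm injects
exactly one seeded corruption (delete, substitute, or swap) and checks
that the reported modification set equals the ground-truth repair,
compared as a multiset of operations with operands; positions are ignored
because with repeated actions several positions describe the same repair.
A drawn corruption whose result still has positive likelihood under some
learned model is redrawn: such an episode *is* a frequent behavior to a
first-order chain, so there is no shift to detect — the redraw is part of
the protocol, not a concession.

At the package's reference scale — 200 episodes, 10 folds — both rates are
100% across seeds: every unperturbed episode is identified as a path match
and every injected modification set is recovered exactly. The n = 200/10-fold size was chosen as comfortably
larger than the point where the rates stabilize; the acceptance script
(`scripts/acceptance.R`) recomputes both rates from scratch at that size.

## Numerical choices and degenerate inputs

* Probability tolerance: model invariants (rows plus end probability
  summing to 1, `P0` summing to 1) are checked to 1e-9 absolute.
* Action labels are compared exactly after whitespace normalization
  (trim + collapse internal runs); case is preserved and significant.
* Empty episodes are rejected; single-action episodes are valid and have
  likelihood 1 when the action is a start state where the behavior can end.
* A chain whose every complete path is pruned yields an empty path table
  with a warning (not an error); `calculate_shifts()` records the warning
  and skips that behavior.
* Ties everywhere (equal-cost edits, equally good paths) resolve by fixed
  documented preference orders, so every result is reproducible.
* `validate_behavior()` reports violations as data instead of raising, so
  malformed hand-written models can be inspected; computational entry
  points reject invalid models outright.

## Limitations

The pipeline inherits the first-order Markov assumption: routines whose
continuation depends on more than the current action (beyond what
occurrence tagging captures) are approximated. Edit costs are uniform by
design — criticality weights the *reported* modifications rather than
steering the matrix, so the minimal repair is found on counts alone. The
detector is offline and episode-based; segmenting a continuous stream into
episodes, recognizing actions from raw sensors, and issuing real-time
reminders are all upstream or downstream of this package.
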