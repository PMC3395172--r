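---
title: "Joint and stacked biomedical event extraction: models and methods"
author: "eventstack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint and stacked biomedical event extraction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventstack)
```

This vignette is the package's own account of the science it implements:
the event representation, the two extractors, how they are combined, what
the synthetic corpora do and do not emulate, and every numerical choice a
user might want to question.

## The task and its representation

A biomolecular event is a typed state change anchored at a trigger token,
with role-labeled arguments. Protein mentions are given (`.a1`); triggers
and events are the extraction target (`.a2`). The valences are part of the
task definition: *simple* types (`Gene_expression`, `Transcription`,
`Localization`, `Catabolism`, `Phosphorylation`) take exactly one THEME;
`Binding` may take several THEMEs (the molecules bound together);
regulation types take one THEME — possibly another event — and at most one
CAUSE, and only regulation types (plus `Catalysis` in the epigenetics
inventory) are cause-licensed. `type_inventory()` encodes these families;
presets `"ge"`, `"id"` and `"epi"` cover the usual track configurations.

Both extractors work on a *token graph* projection of this representation:
vertices are tokens, active anchors carry a type label, role-labeled edges
run from anchors to argument head tokens, and an unordered protein-pair
relation records co-membership in one Binding. `events_to_graph()` and
`graph_to_events()` convert between the two views.

The conversion back from graphs to events is genuinely underdetermined —
the graph view collapses events that share a trigger. Our rules, chosen to
make projection/reconstruction an exact inverse on graphs produced from
valid documents: a simple or regulation anchor emits one event per THEME
edge (CAUSE edges distribute round-robin over those events, which
preserves the edge set when projecting back); a Binding anchor's protein
THEME targets are grouped into events by the maximal cliques of the
pair relation (singletons for unpaired targets). Maximal cliques are the
weakest-assumption inverse of the pair-witnessing semantics: the pair
relation asserts only co-membership, and cliques add nothing beyond
closure. Predicted graphs can in rare cases contain anchor-anchor cycles
(the joint constraint set does not forbid them); serialization breaks them
deterministically by dropping the cycle edge with the largest source
index, then cascading away anchors left without a THEME.

Head tokens: a multiword annotation span maps to its annotated head token
when the token table marks one (the generator always does), otherwise to
the last anchor-capable token overlapping the span. This keeps the module
self-contained where no syntactic parser is available.

## The joint extractor

Variables: `e_(i,t)` — token `i` has anchor label `t`; `a_(i,j,r)` — an
event anchored at `i` takes the mention or event headed at `j` in role
`r`; `b_(p,q)` — protein tokens `p` and `q` appear in the same Binding.
The score of an assignment is the sum of local linear scores of active
variables only. Anchor features are the token's word, word class and a
type bias; argument features conjoin roles with source word, target kind,
direction and binned distance; pair features use distance and a bias.
With stacked systems present, the indicator `f_(S,t',t_S)(i,t)` fires when
system `S` labels token `i` with `t_S` and the candidate label is `t'`
(an explicit `NONE` encodes silence), and analogous indicators attach to
argument slots; `conjoin_features()` optionally crosses every base
feature with the stacked label, which multiplies the feature space and is
therefore off by default (data sparsity tends to cancel the benefit).

**Constraint set.** An assignment is well-formed iff (1) every active
anchor has at least one THEME; (2) CAUSE edges leave only cause-licensed
labels; (3) every anchor used as an argument is itself active; (4) every
active pair is witnessed by a Binding anchor with THEME edges to both
endpoints. `check_constraints()` tests exactly these four conditions.

**Inference.** `infer_dd()` maximizes the score over that set by dual
decomposition with three subproblems: (1) the best label and outgoing edge
set per candidate anchor (constraints 1 and 2 enforced locally; for a
Binding label the protein-THEME subset is searched exactly so that pair
bonuses can pull in negative edges); (2) the best label and incoming edge
set per token (constraint 3 enforced locally); (3) the pair variables,
active iff their score beats the current multiplier. The anchor and
argument variables are duplicated between subproblems (1) and (2) with
symmetric multipliers; the witnessing constraint couples subproblem (3) to
subproblem (1) through nonnegative multipliers on `b_(p,q) <= witness`.
Subgradient steps use `eta_t = eta0 / (1 + #dual increases)`, `eta0 = 1`,
at most 100 iterations. Every iteration extracts a constraint-repaired
primal candidate from the outgoing solution; the result is certified
`OPTIMAL` only when the best primal score meets the best dual bound within
1e-9 — a sound certificate, because the dual is an upper bound on the
constrained maximum by construction (the per-anchor witness bonus can in
principle double-count a pair witnessed twice, which only loosens the
bound and is caught by the gap test). Otherwise the best primal candidate
seen is returned as `HEURISTIC`. On random instances with up to 3 anchors
and 3 proteins the certificate fires on roughly nine in ten instances, and
certified solutions equal exhaustive enumeration exactly.

**Learning.** 1-best MIRA: decode with current weights; if the gold
assignment does not beat the prediction by the Hamming distance over the
three variable sets, move the weights along the feature difference by
`tau = min(C, (loss - margin) / ||dphi||^2)`. Weights are averaged over
all online steps for prediction. The loss, cap `C` (default 0.1), epoch
count (default 10) and shuffle seed are configuration; the Hamming loss is
the simplest loss that decomposes over the variable formulation. Training
dynamics note: with a small cap the updates are deliberately conservative,
so small-corpus experiments that need convergence within 10 epochs (the
separability checks below) use `C = 0.5`; the default stays conservative
for realistic noisy corpora. Tie-breaks everywhere are lexicographic in
(token index, type, role), making training and decoding deterministic
given the seed.

## The stacked parser

The second view treats event structure as dependency parsing.
`project_to_tree()` reduces a document to a tree: words taking part in no
event are dropped, multiword anchors are replaced by their heads, and a
node with several parents keeps the head whose token appears earliest
(ties: THEME before CAUSE) — a deterministic stand-in for the projection's
unavoidable information loss. Remaining roots attach to a virtual root
placed left of the sentence. `tree_to_events()` inverts the projection
with valences enforced: Binding anchors collect all THEME children into
one event, regulation anchors keep their first THEME and at most one
CAUSE, simple anchors emit one event per THEME child, and anchors without
THEME children emit nothing.

Decoding is first-order and exact in both regimes: Eisner's algorithm for
the projective decoder ("1P"; with the root at the left edge its output
provably contains no crossing arcs) and Chu–Liu–Edmonds maximum spanning
arborescence for the non-projective decoder ("1N", whose search space
contains every projective tree, so its score always dominates). Role
labels are decoded jointly by maximizing over roles per edge slot.
Second-order decoding is deliberately out of scope — exact second-order
non-projective inference is NP-complete — and the stacking interface is
decoder-agnostic. Training is averaged structured perceptron against the
chosen decoder, with a local averaged-perceptron type scorer for anchors
(classes: the inventory types plus `NONE`).

**Stacked predictions without leakage.** If the stacking model saw
training-set predictions made by a parser that had seen those same
documents, it would learn to over-trust them. `stacked_predictions()`
therefore partitions the corpus into `n_folds` near-equal folds (seeded)
and predicts each document with a parser trained on the other folds only;
an audit table records that every document is predicted exactly once by a
model that never saw it. Held-out data should be predicted by a parser
trained on the full training material (`train_parser()` +
`predict_parser()`). `merge_corpora()` implements the domain-adaptation
recipe of replicating a small in-domain corpus alongside one copy of a
larger out-of-domain one.

## Combination, origins, and novel events

Union and intersection operate per document under event matching rather
than strict identity: `combine_union()` keeps all of the first corpus plus
unmatched events of the second (imported transitively with their
arguments, matched nested arguments remapped onto the first corpus's
version); `combine_intersection()` keeps first-corpus events matched in
the second, closed under argument reference. `classify_origins()` places
every event of a combined output in exactly one of `BOTH`,
`ONLY_STACKER`, `ONLY_STACKED`, `NOVEL` by containment matching against
the two standalone outputs under the strict recursive policy. Novelty is
defined against the *union* of the base outputs so the four classes
partition the output (defining it against their intersection would
overlap the only-one classes). `remove_novel()` drops the novel class
with cascade deletion; because novel events were vetted by neither base
model they are empirically low-precision, so removal buys precision at a
small recall cost — the package's acceptance checks verify the direction
of both effects on planted-correctness corpora.

## Matching and scoring

`events_match()` implements recursive event equality: equal types,
trigger spans equal within the policy's slack, and a role-preserving
bijection between argument sets, protein arguments matched by mention
span, event arguments recursively. The *strict* policy uses slack 0 and
full argument sets at every level. The *approximate* policy uses slack 1
— the predicted span must lie within the gold span extended by one word on
each side, our reading of the shared task's approximate-span relaxation —
and compares nested event arguments on their core (type, trigger, THEME
arguments), forgiving nested CAUSE differences. The exact semantics of
the official scorer are defined by its implementation, not a formula;
both readings are isolated behind `match_policy()` and validated against
an exhaustive argument-bijection oracle in the tests. `score_corpus()`
matches greedily one-to-one per document (predictions in serialization
order, first unconsumed matching gold) and aggregates micro-style; the
tests bound the greedy matcher against a maximum bipartite matching
oracle.

## The synthetic corpus generator

The generator emulates the structural statistics the extractors exploit,
not biomedical language: documents are single sentences of token strings
(`PROT17`, type-keyed trigger words, filler) with exact offsets, a
Genia-like type mix dominated by `Gene_expression`, regulation nesting
(probability 0.35, depth ≤ 2), multi-THEME Bindings (0.4), CAUSE
arguments (0.3), decoy anchor tokens, occasional multiword triggers
(0.15), and a non-projectivity injection rate ρ defaulting to 0.2 —
chosen to mirror the familiar observation that roughly a fifth of
biomedical abstracts contain at least one crossing dependency arc.
Non-projectivity is injected by the canonical regulation-CAUSE
interleaving: token order `[t_simple, t_reg, prot_A, t_bind, prot_B]`
with the regulation taking the Binding as THEME and the simple event as
CAUSE, so the simple event's THEME arc crosses the regulation's THEME
arc. Every node in the motif has a single parent, so the crossing
survives tree projection — necessary for the projective/non-projective
decoder comparisons to see it. All other layouts are nested, so a
document is non-projective iff it received the motif; at n = 1000 the
realized fraction is binomially concentrated within ±3 points of ρ.

The `trigger_ambiguity` parameter controls how much of the trigger
vocabulary is drawn from a shared pool used by every type. At 0 the
corpus is lexically separable (each trigger word determines its type);
at 1 anchor types are unlearnable from local lexical features alone —
the regime in which stacked predictions carry genuinely complementary
signal. The default 0.25 represents ordinary ambiguity.

`corrupt_corpus()` simulates a base extractor of stated quality by
degrading gold: anchor misses, type confusion, argument-arc drops and
hallucinations, trigger-span jitter. Under arc misses alone, realized
recall matches the analytic per-event survival product, which the tests
verify.

What passing tests on this generator do *not* show: robustness to real
tokenization and parsing noise, to lexical sparsity of real biomedical
text, to multi-sentence discourse, or to annotation idiosyncrasies of the
licensed corpora. The generator's role is to exercise every structural
code path under controlled conditions, not to predict shared-task scores.

## Numerical choices and degenerate inputs

* Offsets 0-based half-open; serialization renumbers triggers in span
  order and events topologically, making output canonical and diffable.
* Duplicate triggers (same span and type) merge on read; modification
  lines pass through uninterpreted.
* Empty corpora are errors; empty documents are valid and score 0/0 as
  precision = recall = 0 by convention.
* Dual decomposition: gap tolerance 1e-9; exact protein-subset search in
  the Binding subproblem up to 14 proteins per sentence (beyond that,
  thresholding without pair bonuses — far beyond the generator's range).
* Experiment scales used by the test suite and acceptance script (chosen
  as the smallest sizes at which every property is stable across seeds):
  500 random instances for inference exactness, 1000 sentences for
  constraint soundness and decoder guarantees, 200 score draws for
  decoder exactness, corpora of 500 documents with an 80-train /
  120-dev split over 10 (tests) or 5 (script) seeds for the stacking
  effect, 10 seeds for novel-event removal, n = 1000 for generator
  calibration.
* The stacking-effect experiments use corrupted gold as the stacked
  input: the corruption module is precisely the package's model of "a
  base system of stated quality", and under `trigger_ambiguity = 1` it
  carries type signal the joint model's own features cannot express —
  the cleanest way to make the complementarity assumption true by
  construction. Cross-validated parser stacking is exercised separately
  (protocol audit, leakage comparison, decoder recall comparisons).

## Known limitations

* Site, negation and speculation annotations are preserved but never
  modeled or scored.
* The greedy corpus matcher can in principle fall below the optimal
  one-to-one matching on tangled match graphs; the tests bound the
  discrepancy against a bipartite oracle and flag it.
* The parser's type scorer is local; anchor typing shares none of the
  tree's structure beyond the THEME-child gate.
* Reconstruction of events from graphs and trees is a documented
  interpretation wherever the representation is lossy (clique grouping,
  CAUSE distribution, multi-parent elimination).
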