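---
title: "Maximum parsimony for morphological matrices: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum parsimony for morphological matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitchkit)
```

## The problem

Morphological systematists score discrete osteological characters across taxa
— extant skeletons and fragmentary fossils — and seek the tree topologies that
explain the observations with the fewest character-state changes (maximum
parsimony). A typical study of this kind works with a matrix of tens of taxa
by several hundred unordered, equally weighted characters, a pair of distant
outgroups for rooting, and fossils that can be scored for only a few percent
of characters because whole anatomical regions (skull, pectoral girdle, ...)
are not preserved. The analysis pipeline around the optimality search is
standardized: heuristic tree search, strict consensus of the most
parsimonious trees (MPTs), bootstrap and Bremer support, incongruence tests
between anatomical partitions, constrained searches for published alternative
hypotheses, paired-sites tests comparing those alternatives with the optimum,
and per-clade lists of unambiguous synapomorphies. `fitchkit` implements that
whole pipeline for matrices of this shape.

## Data model

A `char_matrix` stores one *state set* per cell as a 10-bit mask over the
digit states 0–9. Observed cells are singletons; polymorphic cells (`(01)`)
are larger sets satisfiable by any member at zero cost; missing (`?`) and
inapplicable (`-`) cells carry the full state set. Missing and inapplicable
are deliberately kept as distinct *flavors* for reporting (completeness
summaries count both as unscored) but are identical in all scoring, which is
the standard parsimony treatment — an inapplicable observation constrains the
tree no more than a missing one.

## Fitch scoring

Characters are unordered and equally weighted (weights are retained as a
vector so that bootstrap resampling and constraint penalties reuse the same
kernel). On a binary tree the per-character step count is the classic Fitch
count of union events. Polytomies — which arise from consensus trees and from
zero-length-branch collapsing — use the state-count generalisation: a node
with $k$ children whose most widely shared state occurs in $K$ child sets
contributes $k - K$ steps; for $k = 2$ this reduces exactly to the
intersection/union rule. This generalisation guarantees that a collapsed tree
rescores to the same length as the binary tree it came from, a property the
test suite asserts.

Per-character bounds support the ensemble fit indices:

* the *minimum* $m_i$ is the minimum over all trees, computed exactly as (the
  size of a minimum hitting set of the cell state sets) − 1. The naive rule
  "number of states present minus one" overstates the minimum when a state
  occurs only inside polymorphic cells, so the hitting-set form is used (state
  count ≤ 10 keeps the enumeration trivial);
* the *maximum* $g_i$ for an unordered character is the number of
  unambiguously scored taxa minus the largest single-state frequency among
  them; ambiguous and missing cells contribute nothing.

The ensemble consistency and retention indices follow the standard
definitions $CI = \sum m_i / \sum s_i$ and
$RI = (\sum g_i - \sum s_i)/(\sum g_i - \sum m_i)$, with characters where
$g_i = m_i$ excluded from the RI sums. By default all characters enter the CI
sums (the convention of the major parsimony programs); an `informative_only`
switch restricts every sum to parsimony-informative characters.

## Heuristic search

`heuristic_search()` runs random addition sequence (RAS) replicates refined
by tree bisection–reconnection (TBR). Each replicate builds a starting tree
by greedy stepwise addition (ties broken by the seeded RNG) and then hill
climbs: all TBR rearrangements are enumerated, strictly shorter trees are
accepted, and once no improvement exists the plateau of equal-length trees is
explored by swapping on every saved tree until it closes or the per-replicate
cap (`maxtrees`) is reached. The global pool keeps all distinct shortest
trees across replicates.

The TBR enumeration is the hot path and lives in C++. For each bisected
branch the two fragments are preprocessed once: a down-pass/up-pass over each
fragment yields, for every branch, the Fitch state set of a virtual root
placed on that branch. Because Fitch length is invariant to rooting, the
length of any reconnection is then
`len(A) + len(B) + (weighted count of characters whose two virtual-root sets
are disjoint)` — a constant-time test per character per candidate. Every
move's predicted length is differentially tested against naive rescoring.

Branch collapsing follows the strict "lacks support under any
most-parsimonious reconstruction" reading: a branch is collapsed exactly when
its minimum number of changes over all MPRs is zero, which is equivalent to
edge contraction leaving the tree length unchanged — the form the
implementation evaluates. The alternative rule (collapse only when *no* MPR
places a change) is available via `rule = "max"`, since MPT counts are
sensitive to this choice. MPTs are deduplicated by canonical bipartition-set
keys after collapsing.

An exhaustive enumerator (≤ 9 taxa, all $(2n-5)!!$ topologies) provides the
in-package optimality oracle; the test suite also cross-checks Fitch lengths
against an independent implementation (`phangorn::fitch`).

## Constraints

Positive constraints are compiled into data rather than into search logic:

* a monophyly constraint on taxon set $S$ appends one binary character with
  state 1 for $S$ and 0 elsewhere;
* a backbone constraint appends one such character per nontrivial backbone
  split, with free taxa (fossils, and anything absent from the backbone)
  coded missing.

Each penalty character has weight larger than any attainable data length and
scores exactly one step if and only if the tree displays the required split,
so the unconstrained machinery performs constrained searches unchanged; the
constant is subtracted from reported lengths and satisfaction is re-verified
on every returned tree. Converse constraints ("clade must NOT be
monophyletic", the Bremer device) cannot be expressed as a Fitch character
and are instead enforced by examining candidate TBR moves in length order and
rejecting clade-containing trees. Under-searching a converse constraint can
only overestimate decay, never underestimate it.

Monophyly is evaluated on the tree rooted by the outgroup; backbone
compatibility ("the candidate restricted to the backbone's taxa refines the
backbone") is root-invariant. Note that collapsing can remove a constrained
branch afterwards when the data themselves lend it no support — satisfaction
is enforced on the binary MPTs.

## Consensus methods

Strict and majority-rule consensus are built from canonical split keys; any
collection of pairwise-compatible splits oriented away from a reference taxon
is laminar and therefore realisable as a single cluster tree. Majority-rule
frequencies are weighted so that each bootstrap pseudoreplicate contributes
total weight 1 regardless of how many equally short trees it saved. Adams
consensus uses the classical recursive product-of-root-partitions
construction on outgroup-rooted trees; it retains the deepest common position
of "wandering" taxa that strict consensus would collapse away. Strict and
majority-rule results are cross-checked against `ape::consensus` in the
tests; Adams has no installed reference and is validated on hand-checkable
cases.

## Support

*Bootstrap*: characters are resampled with replacement — implemented as
integer resampling weights so the bitmask data are shared — and each
pseudoreplicate runs a capped search (the classic protocol: 10 addition
replicates, `maxtrees` 100; scaled down in the packaged tests). *Bremer
decay*: for each clade of the strict consensus, a converse-constraint search
finds the shortest tree lacking the clade; the decay is the length
difference.

## Incongruence length difference test

$D = L(\text{combined}) - \sum_k L(\text{partition}_k)$, with the null
distribution obtained by randomly reassigning the pooled characters into sets
of the original sizes. The combined length is permutation-invariant and
computed once. The p-value uses the add-one convention
$p = (1 + \#\{D^\ast \ge D\})/(1 + N)$, so it is never zero and matches the
resolution of the published values (0.002 ≈ 1/501 at $N = 500$). Fossils are
expected to be removed first (they are unscorable for whole partitions);
an `informative_only` switch exists because retaining uninformative
characters is a known inflation factor for this test's type-I error. On
small clean matrices the test is *conservative*: $D$ is often exactly 0, so
the null p-distribution has substantial mass at 1 rather than being uniform —
the calibration test asserts validity (rejection rate at 0.05 stays at or
below nominal) and spread, not strict uniformity.

## Paired-sites topology tests

All three tests consume the per-character step differences
$d_i = s_i(T_{alt}) - s_i(T_{opt})$, whose weighted sum always equals the
whole-tree length difference:

* *winning sites*: exact two-tailed binomial test at $p = 1/2$ on the signs
  (zeros dropped), via `binom.test`;
* *Templeton*: Wilcoxon signed ranks with midrank ties; exact by enumeration
  of all $2^n$ sign assignments for $n \le 12$ nonzero differences, otherwise
  the normal approximation with tie-corrected variance and continuity
  correction. Under heavy ties the exact null is a coarse step function, so
  exact and approximate p agree only approximately near the boundary size
  (the test suite bounds the gap at 0.15, with mean below 0.06);
* *KH test*, parsimony form: two-tailed one-sample t on all differences
  (zeros included, df = n − 1), with the halved p reported alongside: the
  p-value an SH test would give is bounded below by KH p/2, so
  `half_p > 0.05` licenses "cannot reject the alternative" while small values
  remain inconclusive about the SH outcome.

When the alternative is a set of constrained MPTs, `compare_topologies()`
evaluates every pair and reports the *best-fitting* (maximal-p) row per
alternative — the conservative convention for published comparison tables.

## Character optimization

MPR state sets are computed exactly by leaf augmentation: state $s$ occurs at
node $v$ in some most-parsimonious reconstruction if and only if attaching a
pendant test leaf fixed to $s$ at $v$ leaves the step count unchanged. This
avoids fragile up-pass formulas entirely and is validated against brute-force
enumeration of all assignments on small trees. ACCTRAN and DELTRAN are
implemented as tie-break policies in the backtrace of a unit-cost Sankoff
dynamic programme, which guarantees each produces a true MPR (total changes
equal the Fitch steps, asserted for every character in the tests): ACCTRAN
prefers the state differing from the parent at ties (changes as early as
possible, favouring reversals), DELTRAN prefers the parent's state (changes
as late as possible, favouring parallelisms). Two further conventions:
root-state ties are resolved from the smaller root subtree, i.e. from the
outgroup side under outgroup rooting; and leaves always keep the parent's
state when their cell allows it, so missing-data leaves never generate
pendant changes.

A clade's *unambiguous synapomorphies* are the changes whose branch endpoints
have singleton, differing MPR sets in every supplied MPT — the changes every
reconstruction of every tree agrees on — rendered in the conventional
`"index:from->to"` notation with 1-based indices. A character is
*homoplasy-free* on a tree set when its realized steps equal its minimum on
every tree (per-character CI = 1).

## Synthetic data

`simulate_matrix()` evolves unordered characters under a symmetric Mk-type
model: uniform root state, Poisson substitution events along branches, every
event logged so tests can compare against the true history (parsimony length
on the generating tree never exceeds the number of simulated events).
Characters draw 2–4 states, partitions can carry different relative rates,
and a small polymorphism probability converts scored cells into state pairs.
`apply_fossilization()` degrades chosen taxa to target scored fractions,
removing whole anatomical partitions first — the signature missingness
pattern of fossils.

`simulate_osteo59()` is the study-shaped preset: 59 taxa (2 outgroups, 49
extant ingroup, 8 fossils) × 464 characters in partitions 95/11/188/169/1,
with the eight fossils degraded to their published completeness fractions
(3.0–54.1%; plotopterids lose the cranial block, prophaethontids most of the
pectoral block). The default mean branch length (0.03 expected changes per
character) was calibrated once so the realized homoplasy matches the real
dataset's regime — ensemble CI in the 0.4–0.5 range and tree lengths on the
order of 1200–1700 steps across seeds. The preset emulates the *shape* of the real data (size,
partitions, missingness, homoplasy level), not its content: synthetic
characters are independent and tree-generated, with none of the correlated,
hierarchically structured homoplasy of real morphology. Tests passing on it
demonstrate algorithmic correctness and pipeline behaviour, not anything
about waterbird relationships.

One property of the generator matters for interpreting recovery experiments:
with exponential branch lengths it regularly produces internal branches short
enough to accumulate no changes at realistic character counts, and no method
can recover those splits. The recovery checks therefore use trees with equal
internal branch lengths, where every split carries expected signal.

## Numerical and scale choices

* Lengths are exact integer step counts held in doubles (penalty weights make
  totals large but exact); comparisons use a 1e-9 slack.
* All randomness flows through R's RNG; every search, bootstrap, ILD run and
  simulation is bit-reproducible given its seed.
* Test and example problem sizes are deliberately small: oracle checks use
  ≤ 8 taxa (where exhaustive enumeration is the gold standard), pipeline runs
  on the 59 × 464 preset use a handful of addition replicates with
  `maxtrees` ≈ 10. These are the package's chosen study sizes for routine
  verification; the algorithms themselves accept the full-scale settings
  (thousands of replicates, `maxtrees` 100) used in published analyses.

## Known limitations

* Only unordered (Fitch) characters with digit states 0–9: no ordered/Wagner
  characters, step matrices, or implied weighting.
* The NEXUS reader covers the DATA/CHARACTERS + SETS constructs used for
  morphological matrices (interleaving, polymorphisms, charsets, taxsets),
  not the full NEXUS grammar, and no TNT/PHYLIP dialects.
* ACCTRAN/DELTRAN renderings assume rooted trees; synapomorphy reports
  require the clade to be present in every supplied MPT.
* The ILD implementation re-searches every pseudoreplicate partition; at
  published scales (hundreds of pseudoreplicates × dozens of addition
  replicates) this is the dominant cost, and the defaults here are scaled
  down accordingly.
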