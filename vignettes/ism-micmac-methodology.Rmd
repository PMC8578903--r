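---
title: "Interpretive structural modeling with ismic: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretive structural modeling with ismic: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ismic)
```

## The model

Interpretive structural modeling starts from a qualitative premise: a
panel of experts can judge, pair by pair, whether factor i "leads to"
factor j, even when no statistical data on the system exist. The method
then does the minimum mathematics needed to turn those judgments into a
hierarchy: it treats them as a directed graph, imposes transitivity, and
reads levels off the reachability structure. The core assumptions are

- influence is a binary relation (present/absent, no strengths);
- the relation should be transitive — if i drives j and j drives k, i
  drives k — so closure is a modeling step, not a data correction;
- every factor trivially reaches itself (unit diagonal), which is why
  the diagonal counts in both driving and dependence powers.

Level partitioning removes, at each iteration, the factors whose
reachability set (restricted to the remaining factors) equals its
intersection with their antecedent set. Such factors drive nothing that
does not also drive them: they are the current top. On a transitively
closed matrix every iteration removes at least one factor (the top
strata of the condensation are non-empty), so the procedure terminates
in at most n iterations; on a non-closed matrix it can stall, which
`partition_levels()` reports as an error suggesting a closure mode
rather than looping. The levels produced on a closed matrix are exactly
the longest-path-to-sink strata of the condensation of strongly
connected components — a fact the test suite exploits (see below).

MICMAC re-reads the same matrix geometrically: factor i sits at
(dependence, driving). We use the scale-centric boundary n/2 with "high"
meaning *strictly greater*. For the packaged 11-factor study the
boundary is 5.5, which no integer power attains, so the strict/non-strict
choice is immaterial there; for even n the strict rule keeps a factor
sitting exactly on the boundary "low", the conservative reading. The
boundary is a `micmac_config()` parameter, so midpoint variants such as
(n+1)/2 are one argument away.

The "effectiveness" score is implemented as driving minus dependence.
The source study prints this column without defining it; the difference
reproduces all eleven printed values exactly, and it is the natural net
balance of influence (it sums to zero over any square matrix). We state
this inference openly rather than hiding it.

## Aggregation and tie handling

Panels judge each pair with one of four symbols, so "majority rule" can
only mean plurality in general. `aggregate_judgments()` counts symbols
per pair, takes the most frequent, and annotates whether that was an
absolute majority (count > E/2) or a mere plurality. Ties cannot be
silently resolved either way; the default policy breaks them by the
priority order X > V > A > O — preferring any asserted relation over "no
relation", and the symmetric X over the directional symbols — and always
flags the pair in the tally, so downstream users can inspect every
contested judgment. `tie_policy = "error"` makes ties fatal for studies
that prefer to re-elicit.

Roster ratification uses the same philosophy: a factor is included iff
yes-votes strictly exceed no-votes; deadlocks are resolved by an explicit
policy (default: include, matching the disposition the packaged study's
authors chose for their 5–5 tie) and are always flagged.

## Transitivity modes and the published-matrix audit

Hand-built "final" reachability matrices in the literature are rarely a
mechanical closure of the initial matrix. The engine therefore exposes
three modes rather than one:

- `full` — Warshall reflexive–transitive closure; the default for new
  analyses, since partitioning is only guaranteed to terminate on closed
  input.
- `one_pass` — adds exactly the length-2 compositions (M ∨ M·M). This is
  what a single manual round of "check every 0 for a two-step path"
  produces, and it reproduces hand-marked tables far more often than
  `full` does.
- `as_given` — no change; the mode for reproducing a published table
  bit-exact.

Cells added by closure are marked `transitive` (written `1*`), and
direct cells are never downgraded, so provenance survives every
transformation including the conical permutation.

`audit_closure_consistency()` compares an as-given matrix against both
closures of a base matrix and re-runs partitioning and MICMAC under all
three modes. For the packaged study this audit shows: the printed final
matrix equals the one-pass closure of the initial matrix except for one
extra cell, (7,1), which no two-step path supports; and a full closure
would merge the middle of the model, collapsing the printed four levels
to two. Neither finding is "fixed" — the fixtures are stored exactly as
printed, analyses of them run `as_given`, and the audit reports the
difference. This is a deliberate design decision: silently correcting
published data would make reproduction claims unfalsifiable.

## The conical matrix and the digraph

The conical matrix is a symmetric permutation into (level, code) order —
Level I block first, codes ascending within a level, matching the
ordering convention of published condensed tables. The digraph condenses
strongly connected components (igraph supplies the SCC computation),
then transitively reduces the condensation. Reduction is computed as the
Hasse diagram of the strict closure — the unique minimal edge set with
the same reachability, well-defined only because the condensation is
acyclic; mutual pairs inside a component are kept as bidirectional
decorations rather than edges. On matrices that are not closed the SCC
structure can disagree with the printed level assignment (in the
packaged final matrix the stray (7,1) cell makes factors 1 and 7
mutually reachable, fusing nearly everything into one component); the
digraph is therefore most meaningful under `full` closure.

## The synthetic-data generator

`generate_hierarchy()` plants a ground truth the pipeline should
recover: factors are spread over `level_count` non-empty levels; every
factor at level k > 1 gets at least one direct edge to a factor at level
k − 1; extra edges run from deeper to strictly shallower levels with
probability `extra_edge_prob`; adjacent within-level pairs become mutual
(X) with probability `mutual_pair_prob`. By construction the
longest-path-to-sink strata of the relation's condensation equal the
planted levels, so noise-free recovery is a theorem, and the test suite
asserts it as one (fraction exactly 1.0 over seeded replicates) rather
than hoping for it. Expert noise is symmetric symbol replacement: each
expert reports a pair's true symbol with probability p, otherwise one of
the three wrong symbols uniformly — simple, and analytically comparable
with the plurality-recovery rate of the aggregator.

Defaults mirror the packaged study's scale: n = 11 factors, 4 levels, a
panel of E = 10. The remaining defaults were fixed once on domain
grounds: `extra_edge_prob = 0.3` and `mutual_pair_prob = 0.15` give
relation densities comparable to the study's initial matrix (about half
the off-diagonal cells nonzero after closure), and `agreement_prob =
0.9` models the high-but-imperfect consensus typical of a screened
expert panel. What the generator does *not* emulate: correlated expert
errors, systematic optimism/pessimism biases, incomplete questionnaires,
or factor rosters whose true relation is not level-structured. Passing
recovery tests therefore shows the pipeline is correct and stable under
symmetric noise, not that any real panel's judgments are reliable.

## Numerical and procedural choices

- Everything is exact integer/boolean arithmetic; there are no
  tolerances. Warshall closure on logical matrices is O(n³), trivial at
  elicitation scale (n rarely exceeds 20 in this literature).
- Iteration order is deterministic (ascending factor code) everywhere:
  partition levels list codes ascending, conical ties break by code,
  digraph nodes order by smallest member. Repeated runs are
  byte-identical; the only randomness in the package lives in the
  synthetic generator and is seed-controlled.
- Degenerate inputs: a zero diagonal in a matrix file is normalized to 1
  with a warning (the self-reachability convention); an empty or
  non-square grid, an unknown symbol, a lower-triangle SSIM entry and a
  non-binary cell are all hard errors naming the offending location.
- Problem sizes in the test suite were chosen so that brute-force
  oracles stay trivially cheap: closure properties on random matrices up
  to n = 8 (200 cases), partition-vs-condensation equivalence up to
  n = 7 (100 cases), 100 noise-free recovery replicates at the study's
  own scale. The whole suite runs in a few seconds.

## Limitations

- The method inherits ISM's epistemology: the model is only as good as
  the panel; the package quantifies internal consistency, not validity.
- Binary relations only — no fuzzy or weighted ISM, no DEMATEL, no
  iterated-multiplication MICMAC (the classification uses direct powers,
  as the classical scale-centric variant does).
- The key-factor flag marks *all* deepest-level independent factors;
  with a single such factor (as in the packaged study) this matches the
  usual reading, but multi-factor bottoms are reported without further
  ranking.
- `one_pass` is order-free (it composes the whole matrix at once); a
  human marking cells sequentially within one round could produce yet
  another matrix. No attempt is made to model such orderings.
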