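# ismic — interpretive structural modeling and MICMAC analysis

`ismic` turns expert pairwise judgments about directed influence among a
set of factors into a leveled hierarchical model (interpretive structural
modeling, ISM) and a driving–dependence classification (MICMAC). It is
aimed at researchers running expert-elicitation studies — health policy,
operations, management — who need the full classical pipeline: panel
voting to ratify a factor roster, aggregation of per-expert V/A/X/O
judgments into a structural self-interaction matrix (SSIM), reachability
analysis, level partitioning, and quadrant classification, with every
intermediate matrix available for audit.

## The method

For factors 1..n, each expert judges every pair (i, j), i < j, under the
contextual relation "leads to": `V` (i leads to j), `A` (j leads to i),
`X` (both), `O` (neither). Judgments are aggregated per pair by majority
rule (plurality over the four symbols, ties broken by a configurable
priority order and always flagged). The SSIM decodes into a binary
reachability matrix M with unit diagonal:

- `V` → M[i,j] = 1, M[j,i] = 0; `A` → the reverse; `X` → both 1; `O` → both 0.

Transitivity (i→j and j→k imply i→k) is applied under an explicit mode:
`full` (reflexive–transitive closure, Warshall), `one_pass` (only
length-2 compositions, M ∨ M·M — what one manual marking round
produces), or `as_given` (matrix used exactly as supplied, for published
tables). Cells added by closure keep a `1*` provenance mark.

From the closed matrix:

- **driving power** drv(i) = Σⱼ M[i,j], **dependence power** dep(j) = Σᵢ M[i,j];
- **levels**: iteratively remove every factor whose reachability set
  equals its intersection with its antecedent set (the current top);
  removed factors form Level I, then II, … — the deepest level holds the
  driving, most critical factors;
- **conical matrix**: the symmetric permutation of M into level order;
- **digraph**: the SCC condensation, transitively reduced (Hasse
  diagram), one rank per level;
- **MICMAC**: each factor plotted at (dep, drv); with boundary n/2 and
  "high" meaning strictly greater, quadrants are independent (high drv,
  low dep), dependent (low, high), linkage (high, high), autonomous
  (low, low). The net influence drv − dep ("effectiveness") summarizes
  each factor's balance.

## Worked example

The package ships the complete printed data of a published ISM + MICMAC
study of 11 determinants of the effectiveness of COVID-19 SOPs in mass
gatherings (roster, 10-expert voting sheet, SSIM, initial and final
reachability matrices, published levels and summary), loaded with
`sop_fixtures()`. Analysing the published final matrix exactly as
printed:

```r
library(ismic)
fx  <- sop_fixtures()
fit <- ism(fx$final_rm, closure = "as_given", roster = fx$roster)
summary(fit)
```

```
ISM summary (as_given closure): 4 levels, key factor(s): 1
 code                                            label driving dependence
    1                              Nature of gathering      11          2
    2                      Type of gathering community       9         10
    3      Available physical space at gathering place      10          8
    4               Existence of penal clauses in SOPs      10          9
    5             Campaign of awareness regarding SOPs      10         10
    6                 Legal environment of the country      10         11
    7                           Practicability of SOPs      11         11
    8               Perceived benefit of adapting SOPs       4         11
    9 Possibilities of implementation of penal clauses      10         10
   10              Possibilities of avoiding gathering       9         11
   11                 Seriousness of SOPs implementers       9         10
 net_influence    quadrant level key_factor
             9 independent    IV       TRUE
            -1     linkage    II      FALSE
             2     linkage   III      FALSE
             1     linkage   III      FALSE
             0     linkage    II      FALSE
            -1     linkage     I      FALSE
             0     linkage     I      FALSE
            -7   dependent     I      FALSE
             0     linkage    II      FALSE
            -2     linkage     I      FALSE
            -1     linkage    II      FALSE
```

Reading the output: "nature of gathering" (code 1) sits alone at Level
IV — the bottom of the model — reaches all 11 factors (driving 11) and is
reached only by itself and factor 7 (dependence 2), so MICMAC places it
in the independent quadrant: it is the key determinant. "Perceived
benefit of adapting SOPs" (8) reaches only 4 factors but is reached by
all 11 — dependent, net influence −7. The nine remaining determinants
are linkage factors (high on both axes, an unsettled system). `plot(fit)`
draws the MICMAC plane; `plot(fit, type = "model")` the leveled digraph.

Published matrices are not always mechanically consistent, so nothing is
silently corrected; the audit reports where the printed matrix departs
from a closure of the initial one:

```r
audit_closure_consistency(fx$final_rm, fx$initial_rm)
```

```
Closure-consistency audit
  vs one_pass: extra (7,1) | missing none 
  vs full:     extra (7,1) | missing (8,2) (8,3) (10,3) (11,3) (2,4) (8,4) (8,5) (8,9) (8,11) 
  mode as_given  4 levels (6,7,8,10 | 2,5,9,11 | 3,4 | 1)
  mode one_pass  4 levels (6,7,8,10 | 2,5,9,11 | 3,4 | 1)
  mode full      2 levels (2,3,4,5,6,7,8,9,10,11 | 1)
```

For new analyses, `ism(aggregate_judgments(panel)$ssim, closure = "full")`
is the recommended route; `run_pipeline(pipeline_config(...))` drives the
whole file-in/file-out workflow (CSV in, CSV + DOT + markdown report
out), and `generate_hierarchy(hierarchy_spec(...))` produces seeded
synthetic panels with a known level structure for validation.

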