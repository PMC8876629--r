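---
title: "Methods: H-type pseudoknot prediction by grammar parsing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: H-type pseudoknot prediction by grammar parsing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkscan)
```

## The problem and the model

An H-type pseudoknot is the simplest crossing fold in an RNA secondary
structure: half of one base pair sits between the two halves of another, so
the two stems cannot be drawn as a nested structure. pkscan predicts exactly
this motif — one pseudoknot per sequence — and nothing else: no nested
hairpins outside the pseudoknot, no bulges or interior loops inside its
stems, and no K-, L- or M-type pseudoknots.

The detection model is syntactic. A candidate *core* — the two crossing
pairs — is a string of the form

```
x . l1 . y . d . z . l2 . w
```

where `(x, z)` and `(y, w)` are Watson-Crick pairs (A-U or C-G, either
orientation), `l1` and `l2` are nonempty loop runs, and `d` is a short gap
(0 to `max_dd` bases, default 2) between the two crossing stem halves. The
package expresses this family as an ambiguous context-free grammar: 16
S-rules (one per ordered combination of core-stem letter pairs), rules
making `L` derive every nonempty base string, and a chain of `max_dd`
optional-terminal nonterminals (`K`, `N`, `N3`, ...) deriving the bounded
gap. G-U wobble pairs are deliberately *not* core-stem letters — the rule
table contains no wobble S-rule — and enter only as an option during stem
extension.

```{r}
format_grammar(build_grammar(2))[7]   # the C..U..G..A core rule
```

## Detection: two engines, one contract

**Grammar engine.** Every substring window whose endpoints could be the
outermost core bases is parsed with an Earley chart parser (compiled code).
A state is the triple (rule, dot, origin); each of the `n + 1` chart sets
is closed under Predictor/Scanner/Completer, re-scanning the current set to
a fixpoint so completions of the epsilon-deriving gap nonterminals in the
same set are not missed. Because an Earley chart is prefix-incremental —
set `k` of the chart for a suffix equals the final set of the chart for the
length-`k` window — one chart per start position serves every window end.
All derivations of a window are read off the chart's completed `L` and `D`
constituents; each derivation is identified by (rule id, left-loop length,
gap length) and maps to the candidate coordinates `(i1, i2, j1, j2)`.

**Brute-force engine.** Directly enumerates Watson-Crick pair couples
`(i1, j1)`, `(i2, j2)` with `i1 < i2 < j1 < j2`, nonempty loops and the
bounded gap (vectorized R). Both engines emit the identical candidate set in
the same canonical order — by construction here, and asserted by the
equivalence tests; the original system's two engines disagreed on one
dataset sequence, a divergence this package intentionally does not
reproduce.

`detect_parallel()` chunks start positions over forked workers and re-sorts
after the join, so the output is bit-identical for any worker count.

## Decoration and scoring

Each core stem is extended outward greedily, one contiguous pair at a time,
stopping at the first non-complementary pair or region boundary: stem 2
pairs left-loop bases with bases beyond `j2`, stem 1 pairs bases before
`i1` with right-loop bases. The four extension regions are disjoint, so
decoration order is immaterial. Extension pairing is Watson-Crick, plus
G-U when `allow_gu` is set. Loops may be consumed down to zero unpaired
bases (`min_loop = 0` default; the source model is silent on a guard, so a
tightening knob is provided rather than a hidden rule).

The decorated structure is rendered in extended dot-bracket notation with
square brackets for stem 1 and round brackets for stem 2 — the layer
convention of the reference worked example, kept literally.

Scoring uses the pseudoknot energy heuristic

$$G_{pseudo} = \beta_1 + \beta_2 B_p + \beta_3 U_p$$

with defaults $\beta_1 = 9.6$ (pseudoknot existence), $\beta_2 = \beta_3 =
0.1$ (per core stem, per unpaired base; dimensionless kcal/mol-like units).
Two readings required a decision:

* $B_p$ is read literally as *the number of core stems* (always 2 for
  H-type), making the $\beta_2$ term constant; `energy_params(count_pairs
  = TRUE)` switches to counting all pairs, since the upstream
  thermodynamic model plausibly intends that. The default is the literal
  reading.
* $U_p$ counts positions strictly inside the outermost paired span that
  are unpaired after decoration. The source only says "unpaired bases
  inside the pseudoknot"; this definition makes the worked example score
  $9.6 + 0.1 \cdot 2 + 0.1 \cdot 4 = 10.2$.

Stacking energies are supported through an optional user-supplied table
(`stack_table`), summed over stacked adjacencies and added to the energy;
no table is bundled because the reference parameters are not published with
the model. Selection behavior can therefore differ when a table is
configured. Energies are computed over the pseudoknot span only, not the
full molecule.

**Selection.** Structures are ranked by pair count; the energy is computed
lazily only for the maximal-pair subset (the model's stated optimization),
and the minimum-energy structure wins. Remaining ties break by smallest
`i1`, then `j2`, then `i2` — an invented but documented total order that
makes selection independent of candidate enumeration order, engine and
worker count.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive in every user-facing structure; the
  compiled core works 0-based and conversion is confined to the interface.
* Sequences shorter than the 6-nt analytic minimum, or without any
  Watson-Crick crossing, predict the all-dots structure.
* Metric denominators of zero report the affected metric as 0 with a
  warning flag rather than NaN.
* Table reproduction uses 3-decimal round-half-up; raw metric values are
  kept unrounded internally.
* Input normalization (case folding, T to U) warns; characters outside
  the alphabet are errors naming the offending position.

## Evaluation toolkit

Confusion counts are **per base**, not per pair: each position is
paired/unpaired in prediction and reference (`tp` paired in both, `tn`
unpaired in both, `fp`/`fn` the mismatches). The per-base convention is
forced by the arithmetic of the published benchmark tables, whose row sums
equal the dataset's total base count. A `strict` mode additionally demands
the identical partner for `tp`. PPV, recall, F1 and MCC follow the standard
formulas; `evaluate_dataset()` micro-averages (sums counts before
computing metrics) and bins by length with the closed-left convention.
Core-stem location is compared under one-position slippage: a pair may
shift one coordinate by at most `slip` (default 1), per pair, not both
coordinates at once.

## The synthetic generator, and what green tests establish

`generate_planted()` emits sequences with a single planted pseudoknot:
stems of chosen depth, loops, gap and flanks, uniform random bases
elsewhere. Two safeguards keep the ground truth exact: the bases just
outside each stem are redrawn so greedy decoration stops exactly at the
planted depth, and whole draws are rejected (brute-force verified) until
the planted structure is the *unique* maximal-pair candidate. Infeasible
specifications — e.g. 2-deep stems inside long random flanks, where a
competing candidate of equal depth almost always appears — exhaust the
rejection budget and error, which is why the test fixtures draw stem
depths of at least 3.

The generator emulates the *topology* of curated pseudoknot benchmarks,
not their biology: real sequences have composition bias, wobble-rich
stems, hairpins in the loops and non-canonical pairs, none of which are
modeled. A green planted-recovery test therefore establishes that the
pipeline finds an unambiguous planted signal — not that it matches curated
structures at any published accuracy. The published dataset-wide accuracy
and timing numbers depend on an external 262-sequence benchmark and
specific hardware and are out of scope here; the metric formulas
themselves are verified against every printed count row.

## Known limitations

* One pseudoknot per sequence; the best candidate is reported even when
  several high-scoring alternatives exist (inspect `candidates_table()`
  for the full ranking).
* No nested secondary structure outside the pseudoknot, no bulges or
  interior loops within stems, no K/L/M-type folds.
* The energy model is a three-parameter heuristic; it ranks candidates, it
  does not estimate physical free energies.
* The grammar engine is quadratic in the number of windows; for long
  sequences prefer the brute-force engine (the default) or
  `detect_parallel()`.
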