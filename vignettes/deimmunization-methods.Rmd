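---
title: "Methods: epitope scoring, allowed substitutions, and globally optimal design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epitope scoring, allowed substitutions, and globally optimal design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deimmune)
```

## The design problem

Given a target protein `S` of length `n`, the package seeks a variant `S'`
minimizing the total predicted T-cell epitope content

    E(S') = sum over window starts i of e(S'[i..i+8]),

subject to `S'[i] ∈ M(i)` at every position, where `e` counts the panel
alleles predicted to recognize a 9-mer and `M` maps each position to the
substitutions considered safe for stability and activity (always including
the wild type). Immunogenicity and stability are deliberately decoupled:
the epitope count is the single objective, and stability predicates act as
hard per-position feasibility constraints. This keeps the optimum
interpretable — "the fewest predicted epitopes reachable with conservative
substitutions" — and lets different stability models be swapped or
intersected without changing the optimizer.

Two modeling assumptions matter. First, epitope recognition is additive
across the nine groove positions (the pocket-profile model). Second,
substitutions are treated independently of one another: no pairwise or
higher-order stability coupling is modeled. Optimal designs should
therefore be treated as a ranked shortlist for downstream structural and
experimental vetting, not as guaranteed-stable molecules.

## Scoring and threshold semantics

A pocket-profile matrix holds one weight per (window position, residue).
Published pocket-profile tables carry one decimal, so weights are read at
one-decimal precision and scaled ×10 to integers internally. Every score,
threshold and dynamic-programming comparison is exact integer arithmetic;
there are no floating-point tie ambiguities anywhere in the objective.

A peptide is a predicted binder when `score ≥ θ` (inclusive — "within the
top k%" includes the boundary score). Thresholds come from two sources:

* **Supplied tables.** `#threshold` lines in the matrix TSV dialect attach
  an allele's published percentile cutoffs. Supplied values always override
  calibration; reproducing printed reference results requires the original
  tool's own thresholds, whose derivation set is not part of this package.
* **Exact calibration.** Otherwise `calibrate_threshold()` convolves the
  nine per-position score distributions (each uniform over the alphabet)
  into the exact distribution over all `20^9` peptides, and sets θ to the
  smallest *attained* score whose inclusive tail probability is at most
  `percent/100`. Choosing the smallest attained score (rather than any
  smaller grid point with the same tail) makes θ coincide with the score of
  the worst peptide still recognized, which is how percentile cutoffs are
  conventionally reported; the recognized set is identical either way. A
  degenerate all-constant distribution yields θ one grid step above the
  constant — nothing is recognized — with a warning.

The window length is fixed at 9 on the public surface. The engine is
written against a general window and alphabet solely so that tests can run
a reduced engine (4 letters, window 3) against complete enumeration of all
peptides; nothing in the package relaxes the 9/20 surface for users.

Non-standard residues (B, J, O, U, X, Z) are rejected outright rather than
skipped: a silently skipped window would silently change `E`.

## Allowed-residue predicates and penalties

Each builder returns both the per-position allowed sets and a penalty
table used for reporting (penalties are summed over the *chosen*
substitutions only, so a wild-type row always reports 0):

* **BLOSUM-62** (`blosum_allowed`): residue `a` is allowed at `i` when
  `B(wt,wt) − B(wt,a) ≤ max_diff` (default 4). The penalty is the 0/1
  "disallowed" flag. The table is the standard published BLOSUM-62.
  Allowed-set sizes include the wild type; on the packaged 17-residue
  staphylokinase peptide this convention gives a mean of 4.2 residues per
  position and exactly 1338 two-substitution variants, both verified in
  the test suite.
* **Conservation** (`conservation_allowed`): the weighted frequency of `a`
  at position `i` is the total weight of family sequences carrying `a` in
  the aligned column over the total weight of sequences with any non-gap
  residue there (the gap convention: gapped rows simply drop out of the
  denominator). Residues with frequency ≥ 5% (default) are allowed. The
  admission rule is frequency-at-least-threshold: admitting only residues
  *rarer* than the cutoff would invert the stated intent of keeping
  family-supported substitutions. Penalties are `−ln f` in natural-log
  units — natural logs make the landmark penalties 3.00 at 5% and 4.61 at
  1% frequency — capped at `−ln 10⁻⁶` for residues absent from the family
  (which are never allowed, but appear finitely in reports). An all-gap
  column allows only the wild type and warns.
* **Sequence weighting** (`gsc_weights`): to avoid over-counting
  near-duplicate family members, leaves of a phylogenetic tree are
  weighted by bottom-up branch-length apportionment: visiting edges from
  the leaves toward the root, each edge's length is shared among the
  leaves below it in proportion to their accumulated weights (equally when
  all are zero). A root edge, if present, is apportioned like any other
  edge. An all-zero-length tree yields uniform weights with a warning, as
  does omitting the tree entirely. The characteristic invariant — splitting
  one leaf into two identical leaves at zero distance halves that leaf's
  weight and leaves all others untouched — is tested.
* **ΔΔG° scan** (`foldx_allowed`): an imported per-position substitution
  table is re-referenced so each position's wild-type self entry is 0;
  mutants with relative ΔΔG° ≤ 0.25 kcal/mol (default, boundary inclusive)
  are allowed. The energy calculation itself is out of scope; only its
  exported table is consumed.

Tightening any predicate's parameter can only shrink allowed sets, and
every builder admits the wild type unconditionally — both are tested
properties.

## The dynamic program

Define `T[i, X]` as the best total epitope count for the prefix ending at
position `i ≥ 9` whose last 8 residues form `X`, with `T[8, X] = 0` for
every feasible 8-mer `X`. The step

    T[i, (x1..x8)] = min over a in M(i−8) of
                     T[i−1, (a, x1..x7)] + c(a·x1..x8)

pays the count `c` of the one window completed at `i`; the optimum is
`min_X T[n, X]`. Optimal substructure is immediate (each window is scored
exactly once, when its last residue is placed), so the optimum is global —
mutations that would delete one epitope while creating an overlapping one
are priced correctly.

Budgeted design adds an exact substitution-cost index:
`R[8, X, cost(X)] = 0` and

    R[i, (x1..x8), s] = min over a of
                        R[i−1, (a, x1..x7), s − cost(i, x8)] + c(a·x1..x8)

with unit costs by default or any non-negative integer substitution score
(wild type costs 0). "At most s" is the minimum over `s' ≤ s`; it is
non-increasing in `s` and reaches the unconstrained optimum once the
budget stops binding.

Implementation choices worth knowing:

* **State layout.** Tables are stored per column as flat arrays over the
  product of the *allowed* sets of the last 8 positions — never the dense
  `n × 20⁸` table. With conservative predicates (a handful of residues per
  position) the whole table is small; memory scales with the product of
  adjacent allowed-set sizes, which is also the honest cost driver for
  permissive predicates.
* **Tie-breaking** is a total, deterministic order: score, then
  substitution count, then lexicographic comparison in a per-position
  residue order that places the wild type first. The wild-type preference
  on score ties is the required behavior; the remainder makes every result
  bit-reproducible.
* **Near-optimal enumeration** walks the tables backward carrying the
  accumulated score, extending to a predecessor only while
  `accumulated + window + table ≤ optimum + ε`. Every feasible variant
  within ε is produced exactly once (suffix states make trace and sequence
  one-to-one; sequences are still used as the deduplication key), then
  ranked by the order above and truncated to the requested limit. ε is
  expressed in integer window-allele-count units — the natural grid of the
  objective; the fraction-of-panel display is a cosmetic transform.
* **The per-window cap** (`window_cap = TRUE`) assigns `+∞` to any window
  combination scoring above its wild-type count, enforcing
  "never introduce a new epitope" as a constraint. It is off by default:
  on realistic inputs optimal designs tend to satisfy it anyway, and the
  unconstrained optimum is the cleaner quantity; the flag exists because
  the DP admits it at no asymptotic cost.
* **Degenerate inputs.** Sequences shorter than the window, negative
  budgets or ε, and non-positive limits are rejected up front; an exact
  budget with no attaining variant returns an explicitly empty result
  (and the command-line front end maps it to its own exit code) rather
  than guessing.

## Synthetic fixtures and what the tests show

The package tests itself end-to-end without any external data:

* `random_panel()` draws one-decimal weights and calibrates thresholds by
  exact convolution. `random_design_problem()` additionally replaces the
  percentile thresholds with explicitly supplied ones at a denser tail
  fraction (default 0.3) — percentile-calibrated thresholds at 1–10% make
  random short sequences nearly epitope-free, which would leave the
  optimizer nothing to do; the override also exercises the
  supplied-threshold code path that published matrix sets use.
* `planted_problem()` builds instances whose optima are known in closed
  form: one designated "hot" residue triggers the whole panel in every
  window containing it, and each planted position offers one cold
  alternative, so the exact optimum for every budget follows from subset
  bookkeeping over the planted positions — including promiscuous plants
  where one substitution clears several overlapping windows.
* The acceptance suite runs the dynamic programs against the brute-force
  oracle on 200 seeded random instances (lengths 9–14, at most 3 allowed
  residues per position, enumeration capped at 2500 sequences per
  instance — sizes chosen so the exhaustive oracle itself stays exact and
  fast), checking optimality, budget consistency, near-optimal set
  equality at ε ∈ {0, 1, 2}, wild-type tie preference, and planted
  closed-form recovery.

Passing these tests demonstrates that the optimizer is exactly what it
claims to be *for the additive scoring model*. Synthetic matrices make no
attempt to imitate real HLA-DR binding motifs (anchor-position structure,
residue covariances, allele correlations), so the tests say nothing about
predictive accuracy on real immunological data — that fidelity rests on
the published pocket-profile matrices, which the user must supply: the
test suite's fidelity block checks printed reference anchors (wild-type
counts 16/8 at 10%/5% on the packaged peptide, the 2-substitution optimum
of 5 with five co-optimal variants among 1338, the V79T elimination rates,
and the 26.63%/1.12% random-peptide recognition fractions) whenever a
converted matrix set is present at `inst/extdata/propred_drb1.tsv`, and
reports its absence otherwise.

## Known limitations

* Stability is per-position and additive; compensating or clashing
  substitution pairs are invisible to the optimizer and must be vetted
  downstream.
* The percentile calibration is a documented stand-in for published
  threshold tables whose derivation set is unknown; supplied tables take
  precedence and are required to reproduce published counts exactly.
* Only the 9-mer core is modeled; flanking-residue effects on MHC-II
  binding are out of scope, as is any machine-learned affinity predictor
  (an externally computed score can be merged into reports as the `S`
  column but is never computed here).
* Enumeration within a large ε can be combinatorially large; the
  enumerator carries an explicit solution-count guard rather than
  truncating silently before ranking.
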