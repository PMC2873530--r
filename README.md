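# deimmune

Globally optimal epitope-deletion design for protein deimmunization.

Therapeutic proteins of non-human origin commonly provoke an anti-drug
immune response. A key driver is the display of T-cell epitopes: 9-mer
peptide cores that bind in the groove of MHC class II (HLA-DR) molecules on
antigen-presenting cells. `deimmune` is an R toolkit for engineers of such
proteins: it predicts the epitope content of every 9-mer window of a target
sequence, restricts each position to substitutions deemed safe for
stability and activity, and then finds **provably optimal** (and
near-optimal) substitution sets minimizing the total predicted epitope
count — rather than patching one immunodominant peptide at a time.

## The model

**Epitope scoring.** Each HLA-DR allele is described by a pocket-profile
matrix: additive, position-specific binding weights for the nine core
positions of the binding groove. A 9-mer `p` scores
`score(p) = Σ_{k=1..9} w[k, p_k]`, and is a predicted binder for that
allele when `score ≥ θ`, the allele's threshold at a chosen percentile
level (1–10%; a peptide at the 10% level is among the best-recognized 10%
of all 20⁹ peptides). The epitope score of a window is the number of panel
alleles recognizing it (conventionally an 8-allele HLA-DRB1 panel), and the
sequence-level objective is

```
E(S) = Σ_{i=1..n-8} #{ alleles a : score_a(S[i..i+8]) ≥ θ_a }
```

Thresholds are either supplied with the matrices or calibrated exactly: the
package convolves the nine per-position score distributions to obtain the
full score distribution over all 20⁹ peptides — no sampling — and places θ
at the smallest attained score whose inclusive tail holds at most the
requested percent. Weights carry one decimal and all arithmetic is integer
(×10), so threshold and optimizer comparisons have no floating-point ties.

**Allowed substitutions.** A map `M(i)` gives the residues permitted at
each position (always including the wild type), built from any of:

* **BLOSUM-62** — allow residue `a` at position `i` when
  `B(wt,wt) − B(wt,a) ≤ 4` (relative score; the standard published table);
* **family conservation** — allow residues with tree-weighted alignment
  frequency ≥ 5%, with sequences weighted by bottom-up branch-length
  apportionment so redundant family members are not over-counted;
* **ΔΔG° scan** — allow substitutions predicted (by an external
  structure-energetics tool whose per-position table is imported) to
  destabilize by at most 0.25 kcal/mol relative to wild type;
* explicit sets, or the intersection of several predicates.

**Optimization.** A dynamic program over 8-mer suffix states:
`T[i, X]` is the best total epitope count of any feasible prefix ending at
position `i` whose last 8 residues spell `X`. Each step extends by one
residue and pays the count of the single completed window, so global
optimality is guaranteed; only states composed of allowed residues are ever
materialized. A second index `R[i, X, s]` counts substitutions exactly,
giving optima under a substitution budget (or an integer substitution
score), and a slack-carrying traceback enumerates *all* variants within ε
of the optimum, ranked deterministically with the wild type preferred on
ties. A brute-force oracle cross-checks all of this on small instances.

## Worked example

Design two substitutions out of the staphylokinase C3-region peptide
(residues 71–87, the packaged fixture) against a synthetic 8-allele panel
with exactly calibrated 10% thresholds, restricting substitutions to
BLOSUM-conservative ones:

```r
library(deimmune)
pep   <- read_target_fasta(system.file("extdata", "sakstar_71-87.fasta",
                                       package = "deimmune"))
panel <- random_panel(8, seed = 42, percents = c(10, 5))
M     <- blosum_allowed(pep, max_diff = 4)
fit   <- deimmunize(pep, panel, M, percent = 10, budget = 2, offset = 71)
print(fit)
#> Deimmunization design (10% threshold, panel of 8 allele(s))
#>   wild-type epitope count E = 8
#>   substitution budget: 2 (atmost)
#>   optimum total score = 2 over 3 returned variant(s)
#>
#>    variant        dot_string mutations E10 E5 B   C ddG   S total_score
#>  wild type .................         0   8  5 0 n/a n/a n/a           8
#>  V79T,S84D ........T....D...         2   2  1 0 n/a n/a n/a           2
#>  V79T,S84K ........T....K...         2   2  2 0 n/a n/a n/a           2
#>  V78L,V79M .......LM........         2   2  2 0 n/a n/a n/a           2
```

The wild type carries 8 predicted epitopes at the 10% level (5 at 5%);
three distinct substitution pairs are tied at the optimal score of 2, i.e.
each deletes 6 of the 8 predicted epitopes (3 per substitution — single
substitutions at "promiscuous" positions delete several overlapping
windows at once). `E10`/`E5` rescans each rendered variant at both levels;
`B` counts substitutions the BLOSUM rule would disallow (0 here by
construction); `C` and `ddG` would sum conservation and ΔΔG° penalties if
those tables were supplied; `S` is reserved for an externally computed
score and is never computed internally.

`summary(fit)` adds elimination statistics, `plot(fit)` overlays wild-type
and variant per-window epitope profiles, and `enumerate_near_optimal()`,
`optimize_budget()`, `brute_force_search()` expose the machinery directly.
A thin command-line front end (verbs `scan`, `design`, `evaluate`,
`exhaust` over a YAML run configuration) lives at
`system.file("cli", "deimmune.R", package = "deimmune")`.

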