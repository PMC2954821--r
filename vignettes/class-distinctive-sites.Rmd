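---
title: "Class-distinctive site discovery: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-distinctive site discovery: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specsites)
library(tibble)
```

## The statistic and why it is pairwise

Given an alignment whose sequences are partitioned into functional classes,
the per-column mutual information between amino-acid value $x$ and class
label $y$,

$$ I_i \;=\; \sum_{x,y} P_i(x,y)\,\log_2\!\frac{P_i(x,y)}{P_i(x)\,P(y)}, $$

is zero exactly when the classes' value distributions at column $i$
coincide, and maximal when the value determines the class. A single
calculation over all four classes cannot isolate the pattern of interest —
*one* class diverging from a value conserved in the rest — because any
between-class variation raises the score. Running the statistic for each of
the six class pairs and reading the exact zero/nonzero pattern does isolate
it: a column distinctive for class $C$ scores exactly zero for the three
pairs not involving $C$ and nonzero for the three involving it.

Because the pattern consumes *exact* zeros, zero-ness is decided on the
integer count vectors (proportionality of the two classes' symbol counts),
never by thresholding the floating-point score. The reported score is
normalized to $[0,1]$ by $H(Y)$, the entropy of the two-class label
partition; that is the tightest bound that holds for every column, and since
classification uses only the zero/nonzero pattern, the normalization choice
cannot change any site call.

The site calls themselves are implemented on symbols (single non-gap value
across classes, η-conservation, ∂-detection) rather than by matching the MI
pattern; the equivalence of the two views on gap-free columns is a tested
property rather than an assumption.

## The reduced alphabet

All column statistics run on a 15-value encoding that treats residues with
similar side chains as identical: the groups are
{G} {A} {V} {I,L} {M} {P} {F,Y} {W} {S,T} {N} {Q} {C} {K,R} {H} {D,E}.
Counting a conservative K↔R or D↔E exchange as no change makes conservation
claims evolutionarily plausible; the package exposes `full20` and custom
alphabets for contrast, and the bundled analysis reports both. On the
synthetic study-scale alignment the strict 20-letter alphabet finds roughly
a third fewer distinctive sites, because columns whose η or ∂ value is
realized by a mix of within-group letters lose their conservation under
strict letters.

Whether *invariance* should also be judged on the reduced alphabet is
genuinely open: "identical amino acid values" can be read either way. The
package evaluates invariance on the active alphabet (reduced by default),
and every summary reports the strict-letter count alongside, so the
sensitivity is visible rather than hidden.

## Gap policy

The gap is a value of its own, never merged with any residue group. The
consequences are asymmetric by design, biased against false positives:

* a gap anywhere kills an invariant call;
* a gap in any of the three non-distinct classes disqualifies
  η-conservation (a gap carries no residue identity, so it cannot *witness*
  conservation);
* a gap inside the distinct class is ignored for ∂-detection — it is
  neither η nor ∂.

Under this policy gaps can only remove site calls relative to the gap-free
column, never add them; the property is exercised by the generator's
gap-injection mode at rate 0.05.

## d sites and interfaces

The strict η criterion misses sites where a second class also happened to
diverge. A column labeled *other* is rescued as a **d site** when a residue
mapped to it lies strictly within 5 Å (minimum heavy-atom distance) of a
residue at a distinctive column, one value is conserved in at least two
classes, variation occurs in the anchoring site's distinct class, and
variation is confined to that class plus at most one more — with more than
two varying classes no value could confidently be called the conserved one.
The "conserved in ≥ 2 classes" reading is forced: with three conserving
classes the column would already have been distinctive.

Interface composition asks a different question of the same machinery: of
the receptor-chain residues strictly within 4 Å of a partner chain, what
fraction carries core functionality (invariant or distinctive)? A small,
core-dominated interface indicates an interaction built by modifying
parental functionality; a large, half-core interface indicates de novo
recruitment of previously unconstrained residues.

Both cutoffs are strict (`<`), heavy atoms only (crystal structures carry no
hydrogens; adding them would silently change cutoff semantics), model 1
only, and highest-occupancy conformers for alternate locations. Which single
active-state structure to use for the 5 Å screen is a configuration choice,
not something the method can decide; the analysis reports d sites per
structure and their union. Whether interface counts should use all heavy
atoms or a side-chain subset is equally open; all-heavy-atom is the default.

Column↔residue mapping is built by globally aligning the chain's observed
sequence to the chosen alignment row (BLOSUM62, gap open 10 / extend 0.5).
Strict-letter mismatches are tolerated but counted and messaged — the
structures of interest include engineered chimeras — and a chain that maps
fewer than half of the row's residues is rejected as the wrong chain.

## Signatures and acquisition tracking

A class's signature is its distinctive-site residues concatenated N→C,
indexed 1..N. Per sequence and site the status is `delta` (symbol in the
site's ∂ set), `eta`, `missing` (gap), or `other` — the last arises only in
tracking-only sequences, since analysis-set sequences define the ∂ sets.
Acquisition tracking is deliberately tree-free: "first appearance" is rank
order over a user-supplied lineage table, equally-ranked organisms are
interchangeable (a tested invariance), and a reversion flag requires both a
witnessed ∂ at an earlier rank and a witnessed η later. Fragmentary
orthologs (e.g. sequences missing their N-terminus) show `missing` at the
affected sites rather than being dropped.

## The synthetic generator

The generator is first-class, tested code: it plants invariant columns,
distinctive columns (with chosen class, η, ∂ set and subtype-variation
category), d-candidate columns (one value conserved in two classes, one
deviating sequence in each of the anchor class and one extra class), and
free columns, then records the truth table. Free columns draw letters
i.i.d. uniform — maximally adversarial for false invariance at small n — and
are rejection-sampled to be genuinely "other", so recovery is exact by
construction at gap rate 0. Planting is combinatorial: no substitution
model, no tree, no rate heterogeneity. Passing the recovery suite therefore
shows the implementation honors its definitions, *not* that the definitions
are robust to real evolutionary noise; the gap-injection mode and the
full20 contrast probe the nearest failure modes.

Default scale emulates a curated mammalian four-class analysis set: 4
classes, 14 subtypes, ~4 sequences per subtype. The bundled analysis and the
acceptance script use 58 sequences and 380 columns with a planted census of
106 invariant, 59 distinctive (14/10/16/19 by class) and 16 d-candidate
columns — the shape of the motivating Gα family — so every pipeline stage
runs at realistic size in seconds on one CPU.

Toy structures place one 3-atom residue per non-gap row position on a
widely spaced grid (30 Å; no incidental contacts) and realize each planted
contact exactly by axis-aligned placement, writing standard PDB so the real
reader and mapping path are exercised. Coordinates are kept on the 0.001 Å
grid the PDB format can represent, which keeps realized distances equal to
planted ones to floating-point accuracy.

## Numerical and degenerate-input choices

* Zero MI: integer proportionality, as above; `0·log 0` terms contribute 0.
* Minimum distances form coordinate differences directly (no expansion of
  the squared norm), avoiding catastrophic cancellation at large
  coordinates.
* Empty classes, unknown ids, length mismatches, duplicate ids, ambiguous
  letters (B/Z/X/U/O/J — rejected unless explicitly masked to gaps),
  classes ≠ 4 without explicit override, contradictory generator plans, and
  infeasible geometry are all hard errors naming the offender.
* A class with zero distinctive sites yields an empty signature with a
  warning, not an error.
* The 4-class requirement generalizes to k ≥ 3 via `n_classes`; distinctive
  then means exactly one deviating class with all (k−1 choose 2)
  non-involving pairs at zero.

## Limitations

The method sees only what its criteria define: sites distinctive for two
classes at once are invisible by design (d-site rescue recovers the subset
near existing ∂ residues), and no significance is attached to nonzero MI —
the calls are combinatorial, not statistical, so a single deviating sequence
suffices to flag a column. Alignment quality is assumed: the pipeline
consumes a finished MSA and never revisits it. Lineage ranking is user
input, not inference. Structure choice for the 5 Å screen materially
affects the d-site list, which is why it is reported per structure.
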