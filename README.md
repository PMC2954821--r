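# specsites

Discovering class-distinctive residues in protein families from a classified
multiple sequence alignment, with structural context.

## The problem

Large signaling families — the heterotrimeric G-protein Gα subunits are the
motivating case — diversified by gene duplication into a handful of
functional classes (G(io), G(q), G(s), G(12)), each coupling to its own set
of receptors, effectors and regulators. The residues that *made* a class
functionally distinct are the ones that are conserved everywhere except in
exactly that class. `specsites` finds them.

For every alignment column *i*, the package computes the mutual information
between amino-acid value *x* and family label *y* for each pair of classes:

```
I_i = Σ_{x,y} P_i(x,y) · log2[ P_i(x,y) / (P_i(x) · P(y)) ]
```

over a **reduced 15-value amino-acid alphabet** (I=L, F=Y, S=T, K=R, D=E
merged; gap a value of its own), normalized to [0, 1] by the family-label
entropy H(Y). With four classes there are six pairwise calculations, and the
exact zero/nonzero pattern — decided by integer-count proportionality, never
a float threshold — classifies each column:

* **invariant** — one non-gap value in every analysis-set sequence
  (all six scores exactly 0);
* **class-distinctive** — the three other classes share one value **η**
  while at least one sequence of the distinct class carries a different
  value **∂** (the three pairs not involving the class score exactly 0, the
  three involving it score > 0); η may still occur inside the class;
* **other** — everything else.

Two structure-based extensions follow: **d sites** (columns otherwise
"other" that lie strictly within 5 Å heavy-atom distance of a ∂ residue in
an active-state structure, conserved in ≥ 2 classes with variation confined
to the anchor's class plus at most one more) and **interface composition**
(share of invariant-or-distinctive "core" residues among receptor residues
strictly within 4 Å of a partner chain). Per-class **signature sequences**
(the distinctive-site residues concatenated N→C) track when each site
acquired its ∂ value across a ranked ortholog series, including the unusual
∂→η reversions.

## Worked example

```r
library(specsites)
library(tibble)

spec <- alignment_spec(n_columns = 60, seed = 7)   # 4 classes, 14 subtypes
gen  <- generate_alignment(spec)                   # alignment + ground truth
ab   <- aa_alphabet("reduced15")
sites <- classify_sites(gen$aln, ab)
table(sites$category)
#> distinctive   invariant       other
#>           9          17          34

# toy structure with the planted d-candidates 4.2 A from their anchors
row1 <- analysis_ids(gen$aln)[1]
st  <- generate_structure(gen$aln, row1, tempfile(fileext = ".pdb"),
         contacts = tibble(column_a = c(2L, 29L), column_b = c(4L, 52L),
                           distance = 4.2))
model <- read_structure(st$path)
map   <- map_columns_to_structure(gen$aln, row1, model, "A")
find_d_sites(gen$aln, sites, model, map, ab)$column
#> [1]  4 52
```

The category counts match the generator's planted plan exactly (17 invariant,
9 distinctive and 2 d-candidate columns were planted at seed 7), and both
planted d-candidate columns are recovered at the 5 Å cutoff.

The `analysis/` directory holds the same pipeline as a five-stage narrative
(`01_simulate.R` … `05_signatures.R`), writing its tables under `results/`:
study-scale simulation (58 sequences, 380 columns), classification under
both alphabets, d-site rescue, the contrast between a small core-dominated
interface (15 residues, 80% core) and a large half-core one (30 residues,
50%), and acquisition tracking over a seven-organism lineage.

To analyze a real family instead, point `read_alignment()` at an aligned
FASTA plus a metadata TSV (`id species class subtype analysis_set`),
`read_structure()` at PDB/mmCIF files, and proceed with the same calls; the
acceptance tests under `tests/testthat/test-acceptance.R` show the complete
recipe (they expect the curated Gα inputs under `inst/extdata/galpha/` and
fail until those are supplied).

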