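# molenum

Exhaustive, duplicate-free enumeration of the **constitutional isomers** of a
molecular formula, followed by enumeration of all unique **stereoisomers**
(tetrahedral and cis/trans), reported as stereo-annotated canonical SMILES
strings.

## The problem and the method

Given a molecular formula such as C₅H₈Br₂, how many distinct molecules — and
which ones — are compatible with it under fixed atom valences?  This question
arises when mapping chemical space, checking database coverage, elucidating
structures from spectroscopic constraints, and building combinatorial
molecule families for force-field calibration.

A molecule is modeled as a connected labeled multigraph: a label vector **α**
of atom types, a valence vector **δ**, a partition vector **λ**, and a
symmetric adjacency matrix **A** ∈ ℕ₀^(N×N) of bond orders.  Two matrices
describe the same molecule iff one arises from the other by a permutation of
same-type atom indices, so each isomer is represented by its *canonical*
matrix — the lexicographically largest under all type-preserving relabelings,
reading the upper triangle row by row.

- **Constitutional isomers** are generated by *orderly enumeration*
  (Read–Faradzev style): the upper triangle is filled top-left to
  bottom-right in lexicographically decreasing order under valence bounds,
  with row-wise semi-canonicity pruning; completed matrices are tested for
  connectivity (depth-first search) and canonicity.  Hydrogens are absorbed
  into *united atoms* with reduced valences before the filling starts.
- The canonicity test doubles as the producer of the **automorphism group**
  Aut(**A**) — all permutations π with Pᵀ**A**P = **A**.
- **Stereoisomers** of each constitutional isomer are enumerated from
  Aut(**A**): true tetrahedral and cis/trans stereocenters are detected
  (a center is *not* true when some automorphism fixes it while swapping two
  of its substituents); binary counting over configuration vectors, with
  local-parity transport along each automorphism (even permutation of the
  SMILES neighbor order preserves the @/@@ or cis/trans encoding, odd flips
  it), keeps only the lexicographically smallest representative of each
  orbit.  *Para* stereocenters — centers whose substituents differ only in
  stereo configuration — are handled per true stereoisomer through the
  subgroups Aut^true ⊇ Aut^para, with inactive centers marked −1.
- Results are written as canonical SMILES (iterative-refinement atom
  ranking) inside an XML document, with per-stereoisomer stereocenter counts
  and enantiomer cross-references.

Formulas are given in a small language (`C[1-20]H[4-42]`, `H[0,2,4,5]`,
`{CH1}1{CH2}2{OH1}3` for pinned hydrogen counts), and runs can be restricted
by unsaturations, bond-order tallies, cycle counts, and Ullmann substructure
occurrence filters.

## Worked example

```r
library(molenum)

countIsomers("C7H16")
#> $constitutional
#> [1] 9
#> $spatial
#> [1] 11

stereoisomers("ClC(Br)CC(Br)Cl", inputOrder = TRUE)
#>                      smiles config nTet nCt enantiomer
#> 1 Cl[C@@H](Br)C[C@@H](Br)Cl  [0,0]    2   0         NA
#> 2  Cl[C@@H](Br)C[C@H](Br)Cl  [0,1]    2   0          3
#> 3  Cl[C@H](Br)C[C@@H](Br)Cl  [1,0]    2   0          2
```

Heptane has 9 carbon skeletons; two of them carry one stereocenter each, so
the spatial count is 11.  The dibromide has two true tetrahedral centers:
of the four configuration vectors, [1,1] is the meso partner of [0,0]
(no enantiomer reference), while [0,1] and [1,0] form an enantiomer pair —
three unique stereoisomers.

```r
r <- countIsomers("C5H8Br2", restrictionSet(cycles = 0))
r$spatial
#> [1] 106
```

A shell front end with the same options (`--formula`, `--count-only`,
`--restrictions`, `--substructures`, `--out`, `--max-bond-order`,
`--progress-every`) ships at `inst/cli/enumol`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","enumol",package="molenum"))')" \
  --formula C4H10 --count-only
#> constitutional 2
#> spatial 2
```

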