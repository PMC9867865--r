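---
title: "Isomer enumeration: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isomer enumeration: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molenum)
```

## The molecular-graph model

molenum treats a molecule as a connected labeled multigraph with fixed atom
valences: carbon 4, nitrogen 3, oxygen 2, hydrogen and the halogens 1.  A
molecule is a symmetric adjacency matrix **A** of integer bond orders (0–4,
zero diagonal) over an atom vector sorted by united-atom type.  Charges,
isotopes, radicals and variable-valence elements (S, P) are outside the
model, as is 3D geometry: a structure is reported when its graph satisfies
the valences, regardless of steric strain.

Hydrogens never enter the matrix.  A pre-processing step distributes them
onto the heavy atoms, producing *united atoms* — e.g. a CH2 group is one
vertex of effective valence 2.  Two different attached-hydrogen multisets can
never give isomorphic united graphs, so the per-partition enumerations are
disjoint and simply concatenated.  The united-atom types are ordered by
decreasing effective valence, ties broken by element symbol and then by
decreasing hydrogen count.  Any fixed ordering gives the same isomer sets and
counts; the choice only pins down which matrix is "the" canonical one.

## Orderly enumeration and canonicity

The canonical representative of an isomer is the lexicographically largest
matrix over all type-preserving relabelings (upper triangle, read row by
row).  Matrices are generated in strictly decreasing lexicographic order by
filling the upper triangle cell by cell: each cell receives the largest value
compatible with the remaining valences of its row and column and with a
capacity bound (the remaining cells of the row must still be able to absorb
the row's remaining valence); when a cell cannot be filled, the last filled
cell is decremented.

After each completed row the partial matrix is tested against all
permutations that preserve types and map the filled rows onto themselves; if
any such relabeling is lexicographically larger, the whole subtree is
abandoned.  This interleaved semi-canonicity pruning is what makes the
search practical: for a single C14 hydrogen partition the number of labeled
completions can exceed 10^8, while the pruned tree is tiny.  Completed
matrices are tested for connectivity (stack-based depth-first search) and
full canonicity.

The canonicity test builds candidate relabelings row by row over an ordered
partition of atoms into interchangeable cells, comparing the best achievable
permuted row against the actual row and refining the cells on equality.  A
cell offering a larger entry proves non-canonicity immediately; smaller-only
cells kill the branch.  Relabelings that survive with equality everywhere are
exactly the automorphisms, so the full group Aut(**A**) falls out of the test
at no extra cost — it drives the entire stereo layer.

## Stereocenter detection and configuration enumeration

Candidate tetrahedral centers are valence-4 atoms with four singly-bonded
substituents (implicit hydrogens included); candidate cis/trans centers are
pairs of valence-4 atoms joined by a double bond, each with two singly-bonded
substituents, with both atoms outside any cycle (an edge lies in a cycle iff
its removal keeps the graph connected).  A candidate with two identical
valence-1 substituents is never a stereocenter.  Otherwise the automorphism
group decides: if some automorphism fixes the candidate while swapping two of
its substituents, the substituents are constitutionally identical — the
center is not *true*, but is kept as a *potential para* center, because the
substituents may still become stereochemically distinct.  Para candidates are
retained only if they lie in a cycle or at the midpoint (equal graph distance
along a shortest path) between two true stereocenters swapped by some
automorphism; for cis/trans para pairs either half may sit at the midpoint.

Configurations are binary vectors over the true centers, counted in
increasing order; a vector is reported iff no automorphism transports it to a
lexicographically smaller one.  Transport uses the local-parity rule on
neighbor orders frozen from the SMILES writer before enumeration begins: for
tetrahedral centers the neighbor order is previous atom, implicit hydrogen,
ring closures, then following atoms (for the first atom of the string the
hydrogen counts as the neighbor visited before it); an even induced
permutation copies the source configuration, an odd one negates it.  For
cis/trans centers the directionality neighbor of each half is its
first-encountered *explicit* singly-bonded neighbor — the convention forced
by the chained-diene example below — and the configuration is negated exactly
when one of the two directionality neighbors maps onto the image half's
directionality neighbor and the other does not.

Para centers are processed per true stereoisomer through two subgroup
restrictions: Aut^true keeps automorphisms that only swap true centers of
matching absolute configuration, and Aut^para further requires matching
configurations for swapped para centers — a center mapped onto *itself*
imposes no constraint, since a fixed center whose substituents are swapped is
precisely the signal that it is not active in the current configuration.  Its
entry is then set to −1 and the deactivation loop repeats until a fixed point
(deactivation is monotone, so at most one round per center; a non-terminating
loop would be an internal error).  Duplicates are eliminated against smaller
para vectors with −1 compared as 0.  Enantiomers are found by flipping every
active tetrahedral entry and locating the equivalent reported vector; a
self-match is a meso form.

Two published merge patterns for ClC(Br)CC(Br)Cl — "[0,0] ≡ [1,1]" and
"[0,1] ≡ [1,0]" — are both correct: they refer to different atom orders of
the SMILES string, and the local encoding depends on that order.
`stereoisomers(..., inputOrder = TRUE)` freezes neighbor orders from the
input string so such worked examples are reproduced literally.

```{r}
stereoisomers("ClC(Br)CC(Br)Cl", inputOrder = TRUE)
```

## SMILES writing

Atom ranks come from iterative refinement of invariant tuples (element,
effective valence, degree, hydrogen count, bond-order multiset), refined by
sorted neighbor ranks; remaining ties are broken by individualizing one atom
of the first tied class and re-refining.  When a tied class spans several
automorphism orbits, each orbit is tried and the lexicographically smallest
resulting string wins, so the output is independent of the input atom
labeling.  Strings use the Daylight dialect: implicit hydrogens except inside
stereocenter brackets, ring-closure digits in discovery order (`%nn` above
9), bond symbols `= # $`, `@`/`@@` for counter-clockwise/clockwise
tetrahedral configuration, and directional slashes for cis/trans.  Cis/trans
centers are encoded in string order; a half-center whose directionality bond
already carries a slash (conjugated chains) adapts the second half
accordingly, which yields `Br/C=C\C=C/Br` — never the invalid `Br/C=C\/C=C\Br`
— for the cis,cis diene:

```{r}
st <- stereoisomers("BrC=CC=CBr", inputOrder = TRUE)
st[st$config == "[1,1]", "smiles"]
```

The exact byte sequence of a canonical string is a property of this writer,
not a contract; equivalence with other toolkits is at the molecule level
(the test suite parses every emitted string with RDKit and compares
canonical forms).

## Filters, substructures and aromatic rings

Restrictions are admissible-value sets for unsaturations, total bonds,
bond-order tallies, cycle counts (cyclomatic number of the simple skeleton —
a double bond is not a cycle), plus a bond-order cap (default 3; 4 opens
quadruple bonds).  The unsaturation filter is applied to each concrete
formula before enumeration via the degree-sum form
(2 + Σₑ nₑ(δₑ − 2))/2; all other filters are checked per emitted isomer, and
stereo expansion runs only on survivors.  Bond tallies refer to the
united-atom graph, i.e. bonds to implicit hydrogens are not counted.

Substructure occurrence uses Ullmann backtracking with candidate refinement.
A match is an atom set plus a bond set (automorphic images of one embedding
count once); matches are sorted by their matched-index tuples and accepted
greedily under the convention that two accepted matches may share at most one
atom.  The convention reproduces the published counts — `CC` occurs three
times in `CCCC`, `CCC` once — but other maximality definitions exist; greedy
acceptance in canonical order is deterministic, which we value over
maximizing the count.

Six-rings with alternating single/double bonds can make two non-isomorphic
matrices describe one aromatic molecule.  Recognition is a post-hoc
normalization (`aromaticDedup = TRUE`): each record's ring flips are
canonicalized through the SMILES writer and only the smallest representative
is kept.  It is off by default so that the default output remains exhaustive
over distinct adjacency matrices — note that for unsubstituted rings
(benzene, pyridine) the two Kekulé matrices are already related by a ring
symmetry and are one isomer either way; the switch matters for
ortho-disubstituted rings and similar cases.

## Known limitations

Deliberately mirrored limitations of the method: no stereochemistry for
double bonds in cycles or cumulated systems, no centers of valence above
four, and para stereocenters that depend only on rings (e.g. cis/trans
1,4-dimethylcyclohexane) are not counted.  A double bond with one true and
one para half-center is treated as no stereocenter.  Aromatic recognition
covers only alternating six-rings.  Element aliases with AND/XOR/OR logic and
pseudoatoms are not implemented.

## What the tests do and do not show

The suite certifies, at full scale: the alkane constitutional and spatial
series C₁–C₁₄ against the published table; brute-force oracle equality of
constitutional counts for *every* C/N/O/H formula with up to six heavy atoms
(an independent odometer enumerator with exhaustive-permutation
deduplication); stereo-count equality for every acyclic C/O/Cl/Br/H molecule
with up to six heavy atoms against an orbit-counting oracle that assigns raw
parities and transports them with permutation signs over sorted-index
reference orders; exhaustive canonicity of sampled emissions up to seven
atoms; and RDKit-validated validity, uniqueness and round-tripping of every
emitted SMILES string on multi-formula corpora.  These sizes make the
combinatorial claims airtight on the covered space; they do not exercise
charged species, exotic valences, or geometric realizability, which the model
excludes by construction.
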