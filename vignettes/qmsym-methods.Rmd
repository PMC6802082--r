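---
title: "Symmetry machinery for Cnh molecules: models, conventions, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetry machinery for Cnh molecules: models, conventions, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmsym)
```

## The model

A molecular point group is a finite set of orthogonal operations leaving a
nuclear frame invariant. This package handles five groups: C1, the three
*C*~n~*h* groups C2h, C3h, C4h (an *n*-fold rotation about the principal
axis plus the horizontal mirror σ~h~; for even *n* the inversion *i*
follows), and D6h, the parent group of benzene. Every group is stored as
explicit 3×3 matrices in a fixed frame: **the principal axis is z and σ~h~
is the xy-plane**, everywhere — generation, checking, reduction and the
dipole analysis all share this convention, which is what makes the
dipole-operator symmetries derivable from the matrices instead of being
typed in. Input structures in another orientation are *not* auto-aligned;
a misoriented molecule simply fails its check, and that behaviour is
deliberate (silent realignment would hide upstream frame bugs).

Characters are indexed **per operation, not per class**, so the reduction
formula

$$a_i = \frac{1}{h}\sum_R \chi_r(R)\,\overline{\chi_i(R)}$$

is implemented as the literal sum over all *h* operations. The
complex-conjugate 1-D pairs of C3h and C4h (the printed "E" rows) are
stored as two separate complex irreps sharing a pair label; this keeps
every multiplicity $a_i$ an exact integer, while `character_table(...,
merged = TRUE)` sums the partners into the familiar real rows. D6h is the
one group in scope with genuinely two-dimensional irreps (E1g, E2g, E1u,
E2u, with χ(E) = 2); its table is generated from the analytic D6 class
formulas (χ(E~k~) = 2 cos kθ, etc.) tensored with the inversion group
rather than typed in, and the same dimension-agnostic reduction formula
covers it.

Selection rules follow from the transition-moment integral
$I \propto \int \psi_i \otimes \mu \otimes \psi_j\, d\tau$: the integral
can be non-zero only if the elementwise product of the three character
vectors contains the totally symmetric irrep. The operator irreps per
polarization axis are obtained by reducing the representation carried by
the coordinate subspaces (z alone, and the xy block), which yields
x/y → Bu and z → Au in C2h, the Eu pair in C4h, and A2u/E1u in D6h. For
conjugate pairs a transition is reported bright if *any* member
combination is allowed — the physical orbital is the degenerate pair. The
package reports allowed/forbidden plus the multiplicity only; intensities
require wavefunctions and are out of scope.

## Geometry checking

`check_symmetry()` centres the molecule at its centroid, applies each
operation and matches transformed atoms onto originals within each
element. The matcher is greedy nearest-neighbour first; when that is not a
bijection (near-degenerate positions) it switches to an exact bottleneck
assignment — binary search over candidate distance thresholds with a
bipartite perfect-matching test — so a near-symmetric structure is never
failed by an unlucky greedy choice. Tolerances: **0.1 Å is the "loose"
default** used for validating optimized structures, 0.01 Å the strict one
used for generated (exact) geometry. The loose value is a package
decision; typical symmetrization tolerances sit in this range and results
depend on it, so it is explicit and configurable everywhere.

Orbit decomposition (`reduce_to_primitive()`) partitions atoms into the N
rotational images of an asymmetric unit plus on-axis atoms: subgroups are
the cycles of the C~n~ permutation, and the sign list pairs each atom's
subgroup ID with a position ID shared across subgroups. Expansion
(`expand_primitive()`) replicates the unit under the N rotations only;
the unit must therefore be closed under σ~h~ (atoms in the mirror plane or
in ±z pairs), which is verified. A single-digit subgroup ID limits records
to N ≤ 9 — ample for the groups in scope — and N ≥ 10 is rejected loudly.

`radius_of_rotation()` is defined as the **maximum** distance from the
principal axis, max~i~ √(x~i~² + y~i~²). The quantity has no standard
formula (max vs RMS vs heavy-atom-only are all defensible); max is the
documented interpretation here.

## The generator

Raw structures are grown from three seeds: benzene (D6h, ring radius
1.3915 Å, aromatic C–H 1.08 Å), a planar square four-membered carbon ring
with radial hydrogens (C4h — a square ring is the only four-ring that
realizes the group), and staggered ethane with the C–C bond along x
(C2h: with that orientation {E, C2z, i, σ~h~} is genuinely a subgroup of
the molecule's D3d). Two move types grow them:

- **Chain extension** replaces every hydrogen of an orbit by an all-anti
  -(CH~2~)~k−1~CH~3~ zigzag built in the σ~h~ plane with C–C 1.54 Å, C–H
  1.09 Å and tetrahedral angles; CH~2~/CH~3~ hydrogens sit in ±z pairs.
  One site's chain is replicated to the other sites through the group's
  C~n~/σ~h~ operations, which is what guarantees exact symmetry without
  any optimization. Only in-plane sites can be extended (an out-of-plane
  chain cannot preserve σ~h~), and D6h cannot survive extension at all —
  its in-plane C2 axes would require a chain invariant under a two-fold
  axis along the bond, which a tetrahedral zigzag is not — so extension
  on a D6h molecule declares the largest surviving C*n*h subgroup (C3h
  for the full six-site orbit).
- **Halogen substitution** replaces the hydrogens of an orbit (or of a
  sub-orbit closed under a candidate subgroup) by F/Cl/Br along the
  original C–H direction at 1.35/1.77/1.94 Å. A full orbit retains the
  group; a closed sub-orbit reduces it (C4h → C2h for two opposite
  sites). Sub-orbits not closed under any candidate subgroup other than
  C1 are rejected — the collection keeps only genuinely symmetric
  structures.

All bond parameters are conventional input values for pre-optimization
("raw") structures; only the symmetry is exact, and every emitted molecule
is re-verified at 0.01 Å. Sampling is uniform over feasible choices with
1–3 moves per molecule — no sampling schedule is canonical for this kind
of enumeration, so the scheme is kept simple and fully seeded: the
(configuration, seed) → output map is a pure function. Stability
filtering is geometric plus one valence rule: structures containing a
bonded path of three or more nitrogens (prone to N~2~ elimination) are
rejected; bonds come from the Cordero covalent radii with a 1.2
radius-sum factor. Boron substitution is not implemented as no generation
rule for it is defined; the element whitelist still admits B in parsed
files.

## The file dialect

The annotated record is: line 1 the atom count N·n~a~ (+ axis atoms);
line 2 the property string — group label, 19 numeric fields (bandgap,
LUMO, HOMO, three rotational constants, four dipole entries read as
magnitude + components, polarizability, spatial extent, ZPVE in both
J/mol and kcal/mol, four energy sums, heat capacity), the two
pipe-delimited orbital blocks, then one sign token per atom — followed by
`element x y z charge` lines grouped subgroup-by-subgroup with axis atoms
last. Unpopulated fields hold the literal `NA` sentinel, never zero (zero
is a legal value). Coordinates and charges are written at 8 significant
digits, properties at 6; the parser accepts any decimal or scientific
notation. Fields are whitespace-separated — the source material specifies
content and order but not a byte layout, so the delimiter is a documented
dialect decision.

The orbital blocks list one entry per *level*, with degenerate orbitals
sharing an entry ("1|2|1|1" + "BU|BG|AU|AG" is five orbitals over four
levels). The boundary between occupied and virtual levels is not marked in
the block, so the parser places it at the minimal level prefix whose
summed degeneracy reaches six orbitals — the window is built as at least
five orbitals on either side of the gap, extended across degeneracies, so
this recovers the writer's split for any complete window. Frontier labels
are degeneracy-aware: a level below a doubly degenerate HOMO is HOMO−2,
and degenerate partners get no separate row in the transition table.

`validate_record()` is deliberately redundant: besides structural counts
and the geometry check it *recomputes* the orbit decomposition from the
coordinates and compares partition, axis set and per-position elements
against the record's sign list, so a record whose annotations drifted from
its geometry is flagged even when both are internally well-formed.

## Numerical choices and degenerate inputs

Matrix comparisons (closure, conjugacy, operation lookup) use 1e-8;
orthogonality of operations is exact to 1e-10; reduction multiplicities
must be integral to 1e-6 and reconstruct the input to 1e-6, otherwise the
input is rejected as not a representation. Atom-collision well-formedness
uses 0.7 Å (a format sanity check, not a chemistry claim). A single atom
at the origin is invariant under every orthogonal map and is therefore
assigned D6h, the highest candidate; an empty molecule is an error for
the rotation radius. Orbits of the C~n~ rotation must have size exactly
N off-axis — anything else means the structure and the claimed group
disagree.

## Test problem sizes

The property suites run on sizes chosen to keep the full check fast on one
core while still exercising every branch: exhaustive closure and
orthogonality for all five groups (≤ 24×24 products), all irrep-product
reductions, the 32-case literal-sum oracle for C2h, 1,000 synthetic
record round trips, and 500 generated molecules (fixed seed) for the
reduce/expand round trip and rotation-invariance properties.

## Known limitations

- No quantum chemistry: properties are carried, never computed; orbital
  labels must come from an external calculation.
- Only the five groups above; no general point-group perception, no
  symmetrization (snapping atoms onto exact positions), no automatic
  axis alignment.
- The generator's move set (chains + halogens) does not introduce N, O or
  B into skeletons; its outputs are raw pre-optimization geometries.
- Synthetic test fixtures emulate the record format and exact symmetry of
  curated structures, not the conformational noise of optimized ones, so
  green tests certify the machinery, not the behaviour of any external
  dataset.
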