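# qmsym

Group-theory and file-format machinery for *C*<sub>n</sub>*h*-symmetric
organic molecules, of the kind collected in symmetrized quantum-chemistry
datasets. The package is for computational chemists who want to build,
check or consume symmetry-annotated molecular structures without a quantum
chemistry code in the loop:

- **Point groups as data.** `build_group()` constructs C1, C2h, C3h, C4h and
  D6h as explicit 3×3 operation matrices (principal axis = *z*, σ<sub>h</sub>
  = the *xy*-plane) with per-operation character tables, including the
  complex conjugate "E" pairs of C3h/C4h. `direct_product()` multiplies
  characters elementwise and `reduce_representation()` applies the
  reduction formula *a*<sub>i</sub> = (1/*h*) Σ<sub>R</sub>
  χ<sub>r</sub>(R) χ<sub>i</sub>*(R).
- **Geometry vs symmetry.** `check_symmetry()` verifies a structure against
  a claimed group under a loose tolerance (element-preserving min–max atom
  assignment per operation); `assign_point_group()` picks the highest-order
  passing candidate; `reduce_to_primitive()` / `expand_primitive()` convert
  between a full molecule and its asymmetric unit plus subgroup sign list
  (benzene ⇌ "CH" under D6h); `radius_of_rotation()` is the maximal
  distance from the rotation axis.
- **A symmetric-molecule generator.** `generate()` grows molecules from
  three seeds — an ethane-derived C2h template, a planar square C4 ring
  (C4h) and benzene (D6h) — by symmetry-preserving aliphatic chain
  extension and symmetry-retaining or -reducing halogen (F/Cl/Br)
  substitution, with clash and nitrogen-chain (N–N–N) stability filters.
- **Annotated xyz I/O.** `parse_record()` / `write_record()` implement the
  extended xyz dialect whose comment line carries 44 property fields, the
  pipe-delimited orbital degeneracy/symmetry blocks around the HOMO–LUMO
  gap, and the per-atom sign list (`"110"` = subgroup 1, position 10;
  `"0"`-prefixed = on the rotation axis). `validate_record()` re-derives
  the orbit decomposition and cross-checks it against the sign list.
- **Selection rules.** `transition_allowed()` classifies an orbital
  excitation ψ<sub>i</sub> → ψ<sub>j</sub> as bright or dark from
  *I* ∝ ∫ ψ<sub>i</sub> ⊗ μ ⊗ ψ<sub>j</sub> dτ: the transition is allowed
  iff the reduced direct product contains the totally symmetric irrep for
  some polarization of the dipole operator μ (in C2h: μ = Bu for x/y,
  Au for z).

## Worked example

```r
library(qmsym)

g <- build_group("C2h")
character_table(g)
#>    irrep E C2  i sigma_h linear
#> Ag    Ag 1  1  1       1     Rz
#> Bg    Bg 1 -1  1      -1 Rx, Ry
#> Au    Au 1  1 -1      -1      z
#> Bu    Bu 1 -1 -1       1   x, y

# HOMO (Bg) -> LUMO (Ag) is dark; HOMO-2 (Au) -> LUMO is z-bright:
transition_allowed(g, "Bg", "Ag", "any")$allowed
#> [1] FALSE
t <- transition_allowed(g, "Au", "Ag", "z")
Re(t$product_characters); t$allowed
#> [1] 1 1 1 1
#> [1] TRUE

# benzene is "CH" under D6h:
bz <- seed_structures()$benzene$molecule
red <- reduce_to_primitive(bz, "D6h", 0.01)
red$unit$unit_atoms$elements; red$N; radius_of_rotation(bz)
#> [1] "C" "H"
#> [1] 6
#> [1] 2.4715

# generate five symmetric molecules and write annotated records:
cfg <- generation_config(5, rng_seed = 42)
res <- generate(cfg)
vapply(res, `[[`, "", "group")
#> [1] "C2h" "C4h" "C4h" "C2h" "C2h"
writeLines(write_record(qmsym_record(res[[2]]$molecule, res[[2]]$group))[1:2])
#> 8
#> C4h NA NA ... NA NA 11 12 21 22 31 32 41 42
```

A command-line wrapper is installed at `inst/scripts/qmsym`
(`qmsym group --name C2h --table`, `qmsym check --group C2h file.xyz`,
`qmsym generate -n 100 --seed 42 -o out/`, ...).

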