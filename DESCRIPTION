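Package: qmsym
Title: Point-Group Machinery for Cnh-Symmetric Molecules and
    Symmetry-Annotated XYZ Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating Cnh-symmetric organic
    molecules of the kind collected in symmetrized quantum-chemistry
    datasets. Provides explicit point groups (C1, C2h, C3h, C4h, D6h) with
    per-operation character tables, direct products and representation
    reduction; geometry utilities that verify a structure against a claimed
    point group under a loose tolerance, decompose molecules into symmetry
    subgroups (orbits) and expand asymmetric units back to full molecules; a
    combinatorial generator that grows symmetric molecules from ethane,
    square-ring and benzene seeds by chain extension and halogen
    substitution; a reader/writer for the symmetry-annotated extended xyz
    dialect (44-field property line, orbital degeneracy/symmetry blocks,
    subgroup sign lists); and group-theoretical electric-dipole selection
    rules that classify orbital transitions as bright or dark.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
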