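test_that("the three seed templates carry their declared groups", {
  seeds <- seed_structures()
  expect_length(seeds, 3L)
  expect_setequal(vapply(seeds, `[[`, "", "group"), c("C2h", "C4h", "D6h"))
  bz <- seeds$benzene$molecule
  expect_equal(n_atoms(bz), 12L)
  expect_equal(sum(bz$elements == "C"), 6L)
  for (s in seeds) {
    expect_true(check_symmetry(s$molecule, s$group, 0.01)$passed,
                info = s$name)
    expect_equal(assign_point_group(s$molecule, 0.01), s$group,
                 info = s$name)
  }
})

test_that("site orbits partition equivalent positions", {
  bz <- benzene()
  d6 <- site_orbits(bz, "D6h", "H")
  expect_length(d6, 1L)
  expect_length(d6[[1]], 6L)
  c2 <- site_orbits(bz, "C2h", "H")
  expect_length(c2, 3L)
  expect_equal(sort(vapply(c2, length, 0L)), c(2L, 2L, 2L))
  expect_length(site_orbits(bz, "D6h", "Br"), 0L)
  # orbit sizes divide the group order
  for (s in seed_structures()) {
    for (o in site_orbits(s$molecule, s$group, "H")) {
      expect_equal(build_group(s$group)$order %% length(o), 0)
    }
  }
})

test_that("full-orbit substitution retains the group, half-orbit reduces it", {
  ring <- c4_ring()
  orbit <- site_orbits(ring, "C4h", "H")[[1]]
  full <- substitute_halogen(ring, orbit, orbit, "F", "C4h")
  expect_equal(full$group, "C4h")
  expect_true(check_symmetry(full$molecule, "C4h", 0.01)$passed)
  expect_equal(sum(full$molecule$elements == "F"), 4L)

  centered <- center_molecule(ring)
  ang <- atan2(centered$coords[orbit, 2], centered$coords[orbit, 1])
  two_opposite <- orbit[order(ang)][c(1, 3)]
  half <- substitute_halogen(ring, orbit, two_opposite, "F", "C4h")
  expect_equal(half$group, "C2h")
  expect_true(check_symmetry(half$molecule, "C2h", 0.01)$passed)
  expect_false(check_symmetry(half$molecule, "C4h", 0.01)$passed)

  # adjacent (non-closed) pair is rejected
  two_adjacent <- orbit[order(ang)][c(1, 2)]
  expect_error(substitute_halogen(ring, orbit, two_adjacent, "F", "C4h"),
               "not closed")

  same <- substitute_halogen(ring, orbit, integer(0), "F", "C4h")
  expect_equal(same$molecule$coords, ring$coords)
  expect_equal(same$group, "C4h")
})

test_that("chain extension preserves the declared Cnh group", {
  bz <- benzene()
  alt3 <- site_orbits(bz, "C3h", "H")[[1]]
  expect_length(alt3, 3L)
  m3 <- extend_chain(bz, alt3, 2, "C3h")
  expect_true(check_symmetry(m3, "C3h", 0.01)$passed)
  expect_equal(sum(m3$elements == "C"), 6L + 3L * 2L)

  expect_identical(extend_chain(bz, alt3, 0, "C3h"), bz)

  full6 <- site_orbits(bz, "D6h", "H")[[1]]
  m1 <- extend_chain(bz, full6, 1, "D6h")
  expect_equal(sum(m1$elements != "H"), 12L)
  expect_true(check_symmetry(m1, m1$group, 0.01)$passed)

  expect_error(extend_chain(bz, full6, 2, "D6h", max_atoms = 13),
               "budget")
})

test_that("bond perception uses covalent-radius thresholds", {
  ch <- mol_from_rows(c("C", 0, 0, 0), c("H", 1.09, 0, 0))
  expect_true(perceive_bonds(ch)[1, 2])
  far <- mol_from_rows(c("C", 0, 0, 0), c("C", 5, 0, 0))
  expect_false(any(perceive_bonds(far)))
  one <- molecule("C", matrix(0, 1, 3))
  expect_false(any(perceive_bonds(one)))
  adj <- perceive_bonds(benzene())
  expect_true(isSymmetric(unclass(adj)))
  expect_false(any(diag(adj)))
})

test_that("nitrogen chains of three or more atoms are rejected", {
  nnn <- mol_from_rows(c("N", 0, 0, 0), c("N", 1.3, 0, 0),
                       c("N", 2.6, 0, 0))
  expect_true(nitrogen_chain_filter(nnn))
  nn <- mol_from_rows(c("N", 0, 0, 0), c("N", 1.3, 0, 0),
                      c("C", 5, 0, 0), c("N", 6.4, 0, 0))
  expect_false(nitrogen_chain_filter(nn))
  expect_false(nitrogen_chain_filter(benzene()))
  # branched N star also contains a 3-N path
  star <- mol_from_rows(c("N", 0, 0, 0), c("N", 1.3, 0, 0),
                        c("N", -0.65, 1.13, 0))
  expect_true(nitrogen_chain_filter(star))
})

test_that("generation is deterministic and honours its contracts", {
  cfg <- generation_config(8, rng_seed = 42)
  run1 <- generate(cfg)
  run2 <- generate(cfg)
  text <- function(run) {
    unlist(lapply(run, function(r) {
      write_record(qmsym_record(r$molecule, r$group))
    }))
  }
  expect_identical(text(run1), text(run2))
  for (r in run1) {
    expect_true(check_symmetry(r$molecule, r$group, 0.01)$passed)
    expect_true(all(r$molecule$elements %in%
                      c("H", "B", "C", "N", "O", "F", "Cl", "Br")))
    expect_false(nitrogen_chain_filter(r$molecule))
    expect_lte(n_atoms(r$molecule), cfg$max_atoms)
    expect_gte(min_interatomic_distance(r$molecule), cfg$min_distance)
    expect_true(length(r$provenance$seed) == 1L)
  }
})

test_that("a C4h-only run with reduction yields only C4h and C2h", {
  seeds <- seed_structures()["c4-ring"]
  cfg <- generation_config(6, rng_seed = 7, seeds = seeds,
                           allow_reduction = TRUE, max_chain_length = 0L)
  out <- generate(cfg)
  expect_true(all(vapply(out, `[[`, "", "group") %in% c("C4h", "C2h")))
})

test_that("with no moves available the seeds repeat unchanged", {
  cfg <- generation_config(4, rng_seed = 3, halogen_set = character(0),
                           max_chain_length = 0L)
  out <- generate(cfg)
  seed_sizes <- sort(unique(vapply(seed_structures(),
                                   function(s) n_atoms(s$molecule), 0L)))
  expect_true(all(vapply(out, function(r) n_atoms(r$molecule), 0L) %in%
                    seed_sizes))
  expect_true(all(vapply(out, function(r) length(r$provenance$moves), 0L)
                  == 0L))
})

test_that("infeasible configurations are rejected", {
  expect_error(generation_config(1, max_atoms = 2L), "infeasible")
  expect_error(generation_config(1, halogen_set = "Xe"), "subset")
})
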