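test_that("applying operations transforms coordinates as expected", {
  g <- build_group("C2h")
  ops <- setNames(g$operations, vapply(g$operations, `[[`, "", "label"))
  m <- molecule(c("C", "O"), rbind(c(1, 0, 0), c(1, 2, 3)))
  expect_equal(apply_operation(m, ops$E)$coords, m$coords)
  expect_equal(apply_operation(m, ops$C2)$coords[1, ], c(-1, 0, 0))
  expect_equal(apply_operation(m, ops$i)$coords[2, ], c(-1, -2, -3))
})

test_that("operations are isometries: pairwise distances are preserved", {
  set.seed(5)
  m <- molecule(sample(c("C", "N", "H"), 8, TRUE),
                matrix(runif(24, -3, 3), 8))
  d0 <- dist(m$coords)
  for (nm in all_group_names) {
    for (op in build_group(nm)$operations) {
      expect_lt(max(abs(dist(apply_operation(m, op)$coords) - d0)), 1e-10)
    }
  }
})

test_that("benzene passes D6h; a displaced hydrogen fails", {
  bz <- benzene()
  expect_true(check_symmetry(bz, "D6h", 0.01)$passed)
  bad <- bz
  bad$coords[12, ] <- bad$coords[12, ] + c(0.5, 0, 0)
  rep_ <- check_symmetry(bad, "D6h", 0.1)
  expect_false(rep_$passed)
  expect_gt(rep_$max_deviation, 0.1)
})

test_that("C2h operations are a subset of D6h's, so benzene passes C2h", {
  d6 <- lapply(build_group("D6h")$operations, `[[`, "matrix")
  for (op in build_group("C2h")$operations) {
    hits <- vapply(d6, function(m) max(abs(m - op$matrix)) < 1e-8, TRUE)
    expect_equal(sum(hits), 1L, info = op$label)
  }
  expect_true(check_symmetry(benzene(), "C2h", 0.01)$passed)
})

test_that("a molecule passing D6h passes C2h and C3h at the same tolerance", {
  set.seed(42)
  for (mol in list(benzene(), expand_primitive(random_unit("D6h"))$molecule)) {
    expect_true(check_symmetry(mol, "D6h", 0.01)$passed)
    expect_true(check_symmetry(mol, "C2h", 0.01)$passed)
    expect_true(check_symmetry(mol, "C3h", 0.01)$passed)
  }
})

test_that("symmetry checks are invariant under z-rotation and relabeling", {
  set.seed(7)
  bz <- benzene()
  # Cnh operations commute with any rotation about z; D6h does not (its
  # in-plane C2 axes are direction-fixed), so it is exercised at 60 degrees
  for (theta in c(runif(3, 0, 2 * pi), NA)) {
    gname <- if (is.na(theta)) "D6h" else "C3h"
    if (is.na(theta)) theta <- pi / 3
    rot <- matrix(c(cos(theta), -sin(theta), 0,
                    sin(theta), cos(theta), 0, 0, 0, 1), 3, byrow = TRUE)
    rotated <- apply_operation(bz, rot)
    expect_true(check_symmetry(rotated, gname, 0.01)$passed)
    # relabeling within an element: shuffle all atoms, composition unchanged
    perm <- sample(12)
    shuffled <- molecule(rotated$elements[perm], rotated$coords[perm, ])
    expect_true(check_symmetry(shuffled, gname, 0.01)$passed)
  }
})

test_that("the highest-order passing candidate group is assigned", {
  expect_equal(assign_point_group(benzene()), "D6h")
  expect_equal(assign_point_group(ethane()), "C2h")
  expect_equal(assign_point_group(c4_ring()), "C4h")
  lone <- molecule("C", matrix(0, 1, 3))
  expect_equal(assign_point_group(lone), "D6h")
})

test_that("a CH unit expands to benzene-like C6H6 with its sign list", {
  unit <- asymmetric_unit(
    molecule(c("C", "H"), rbind(c(1.3915, 0, 0), c(2.4715, 0, 0))), "D6h")
  out <- expand_primitive(unit)
  expect_equal(n_atoms(out$molecule), 12L)
  expect_equal(sum(out$molecule$elements == "C"), 6L)
  expect_equal(sum(out$molecule$elements == "H"), 6L)
  expect_equal(length(out$signs), 12L)
  expect_equal(out$signs[1:2], c("11", "12"))
  expect_true(check_symmetry(out$molecule, "D6h", 0.01)$passed)
})

test_that("expansion handles axis-only units and rejects on-axis unit atoms", {
  axis_only <- asymmetric_unit(NULL, "C2h",
                               molecule("O", matrix(0, 1, 3)))
  out <- expand_primitive(axis_only)
  expect_equal(n_atoms(out$molecule), 1L)
  expect_equal(out$signs, "01")

  expect_error(
    asymmetric_unit(molecule("C", matrix(c(0, 0, 1.2), 1)), "C2h"),
    "axis")
})

test_that("expansion collisions are caught", {
  # two images of a site straddling the rotation axis collide
  unit <- asymmetric_unit(molecule("C", matrix(c(0.2, 0.1, 0), 1)), "C2h")
  expect_error(expand_primitive(unit), "collision")
})

test_that("reduction finds the asymmetric unit and sign list", {
  red <- reduce_to_primitive(benzene(), "D6h", 0.01)
  expect_equal(red$n_a, 2L)
  expect_equal(red$N, 6L)
  expect_setequal(red$unit$unit_atoms$elements, c("C", "H"))

  lone <- molecule("N", matrix(0, 1, 3))
  red1 <- reduce_to_primitive(lone, "C2h", 0.01)
  expect_equal(red1$n_a, 0L)
  expect_true(is.null(red1$unit$unit_atoms) ||
                n_atoms(red1$unit$unit_atoms) == 0L)
  expect_equal(red1$signs, "01")

  skewed <- benzene()
  skewed$coords[1, ] <- skewed$coords[1, ] + c(1, 0, 0)
  expect_error(reduce_to_primitive(skewed, "D6h", 0.01), "not satisfy")
})

test_that("a 2x10 + axis structure reduces to n_a = 10, N = 2", {
  # a C2h sign list of two 10-atom subgroups plus one axis atom
  set.seed(21)
  unit <- random_unit("C2h", n_sites = 7, with_axis = FALSE)
  while (n_atoms(unit$unit_atoms) != 10)
    unit <- random_unit("C2h", n_sites = 7, with_axis = FALSE)
  unit <- asymmetric_unit(unit$unit_atoms, "C2h",
                          molecule("C", matrix(0, 1, 3)))
  mol <- expand_primitive(unit)$molecule
  red <- reduce_to_primitive(mol, "C2h", 0.01)
  expect_equal(red$n_a, 10L)
  expect_equal(red$N, 2L)
  expect_equal(sum(startsWith(red$signs, "0")), 1L)
})

test_that("expand after reduce reproduces the molecule up to atom order", {
  set.seed(31)
  for (gname in c("C2h", "C3h", "C4h", "D6h")) {
    for (k in 1:5) {
      mol <- expand_primitive(random_unit(gname))$molecule
      red <- reduce_to_primitive(mol, gname, 0.01)
      back <- expand_primitive(red$unit)$molecule
      expect_equal(n_atoms(back), n_atoms(mol))
      key <- function(m) {
        ord <- order(m$elements, round(m$coords[, 1], 6),
                     round(m$coords[, 2], 6), round(m$coords[, 3], 6))
        cbind(m$elements[ord], round(m$coords[ord, ], 6))
      }
      expect_equal(key(back), key(center_molecule(mol)))
    }
  }
})

test_that("radius of rotation is the maximum distance from the z-axis", {
  expect_equal(radius_of_rotation(molecule("C", matrix(c(0, 0, 2.5), 1))), 0)
  expect_equal(radius_of_rotation(benzene()), 2.4715)
  lifted <- benzene()
  lifted$coords[, 3] <- lifted$coords[, 3] + 4.2
  expect_equal(radius_of_rotation(lifted), 2.4715)
  expect_error(radius_of_rotation(molecule(character(0),
                                           matrix(0, 0, 3))), "empty")
})

test_that("plain xyz files round-trip", {
  path <- withr::local_tempfile(fileext = ".xyz")
  bz <- benzene()
  write_xyz(bz, path, comment = "benzene template")
  got <- read_xyz(path)
  expect_equal(got$elements, bz$elements)
  expect_lt(max(abs(got$coords - bz$coords)), 1e-7)
})
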