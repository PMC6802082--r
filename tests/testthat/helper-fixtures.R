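# Fixtures are built in code; nothing is read from disk.

# printed C2h character table, frozen as literal integers (operation order
# E, C2, i, sigma_h) -- used as the independent oracle for the reduction
# formula and the selection rules
c2h_table <- rbind(Ag = c(1, 1, 1, 1),
                   Bg = c(1, -1, 1, -1),
                   Au = c(1, 1, -1, -1),
                   Bu = c(1, -1, -1, 1))

all_group_names <- c("C1", "C2h", "C3h", "C4h", "D6h")

benzene <- function() seed_structures()$benzene$molecule
ethane <- function() seed_structures()$ethane$molecule
c4_ring <- function() seed_structures()[["c4-ring"]]$molecule

# a bare molecule from element / coordinate rows (no symmetry claims)
mol_from_rows <- function(...) {
  rows <- list(...)
  molecule(vapply(rows, `[[`, "", 1L),
           t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3))))
}

# random sigma_h-closed asymmetric unit for a Cnh group: atoms either in
# the mirror plane or in +/-z pairs, distinct radii, angles inside one
# rotational sector so orbit images never collide
random_unit <- function(group_name, n_sites = NULL, with_axis = NA) {
  n <- rotational_order(group_name)
  if (is.null(n_sites)) n_sites <- sample(1:3, 1)
  els <- c("H", "B", "C", "N", "O", "F", "Cl", "Br")
  elements <- character(0)
  coords <- NULL
  for (j in seq_len(n_sites)) {
    r <- 1.5 + 1.1 * j
    # D6h needs the unit on a C2' axis so the in-plane two-fold axes and
    # vertical mirrors are satisfied; Cnh units may sit anywhere in a sector
    ang <- if (group_name == "D6h") 0 else runif(1, 0.15, 2 * pi / n - 0.15)
    el <- sample(els, 1)
    if (runif(1) < 0.5) {
      elements <- c(elements, el)
      coords <- rbind(coords, c(r * cos(ang), r * sin(ang), 0))
    } else {
      z <- runif(1, 0.6, 1.4)
      elements <- c(elements, el, el)
      coords <- rbind(coords, c(r * cos(ang), r * sin(ang), z),
                      c(r * cos(ang), r * sin(ang), -z))
    }
  }
  unit_mol <- molecule(elements, coords)
  axis_mol <- NULL
  if (is.na(with_axis)) with_axis <- runif(1) < 0.5
  if (with_axis) {
    if (runif(1) < 0.5) {
      axis_mol <- molecule(sample(els, 1), matrix(c(0, 0, 0), 1))
    } else {
      el <- sample(els, 1)
      z <- runif(1, 2, 3)
      axis_mol <- molecule(c(el, el), rbind(c(0, 0, z), c(0, 0, -z)))
    }
  }
  asymmetric_unit(unit_mol, group_name, axis_mol)
}

# synthetic QM-sym record with random properties and orbital blocks
random_record <- function(group_name = sample(c("C2h", "C3h", "C4h"), 1)) {
  unit <- random_unit(group_name)
  mol <- expand_primitive(unit)$molecule
  mol$charges <- round(runif(n_atoms(mol), -0.5, 0.5), 4)
  props <- empty_properties()
  for (nm in names(props)) {
    if (runif(1) < 0.8) {
      props[[nm]] <- round(runif(length(props[[nm]]), -10, 10), 3)
    }
  }
  irreps <- unique(vapply(build_group(group_name)$irreps, function(ir) {
    toupper(if (is.na(ir$pair)) ir$label else ir$pair)
  }, ""))
  rand_block <- function() {
    deg <- integer(0)
    while (sum(deg) < 6L) deg <- c(deg, sample(1:2, 1))
    data.frame(degeneracy = deg, label = sample(irreps, length(deg), TRUE))
  }
  orb <- if (runif(1) < 0.7) list(occupied = rand_block(),
                                  virtual = rand_block()) else NULL
  qmsym_record(mol, group_name, properties = props, orbitals = orb)
}
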