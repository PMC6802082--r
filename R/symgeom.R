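# Elements the database dialect admits, with Cordero covalent radii (A).
.qmsym_elements <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71,
                     O = 0.66, F = 0.57, Cl = 1.02, Br = 1.20)

#' Construct a molecule
#'
#' A molecule is an ordered list of atoms: element symbols, Cartesian
#' coordinates in Angstrom, optional per-atom (Mulliken) charges, and an
#' optional declared point-group label.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric n x 3 matrix of positions (A).
#' @param charges optional numeric vector (e), NA when unknown.
#' @param group optional declared point-group name.
#' @param allowed element whitelist; defaults to the eight database elements.
#' @return object of class `qmsym_molecule`.
#' @export
molecule <- function(elements, coords, charges = NULL, group = NA_character_,
                     allowed = names(.qmsym_elements)) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  stopifnot(length(elements) == nrow(coords))
  bad <- setdiff(unique(elements), allowed)
  if (length(bad)) {
    stop("element(s) outside the allowed set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(charges)) charges <- rep(NA_real_, length(elements))
  stopifnot(length(charges) == length(elements))
  if (!is.na(group)) group <- canonical_group_name(group)
  structure(list(elements = as.character(elements), coords = coords,
                 charges = as.numeric(charges), group = group),
            class = "qmsym_molecule")
}

#' @export
print.qmsym_molecule <- function(x, ...) {
  comp <- table(x$elements)
  cat("Molecule: ", paste0(names(comp), comp, collapse = " "),
      " (", n_atoms(x), " atoms)",
      if (!is.na(x$group)) paste0(", declared group ", x$group), "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `qmsym_molecule`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) length(mol$elements)

#' Minimum interatomic distance
#' @param mol a `qmsym_molecule`.
#' @return smallest pairwise distance (A), Inf for fewer than two atoms.
#' @export
min_interatomic_distance <- function(mol) {
  if (n_atoms(mol) < 2L) return(Inf)
  min(stats::dist(mol$coords))
}

#' Check molecular well-formedness (no atom collisions)
#' @param mol a `qmsym_molecule`.
#' @param min_distance minimum allowed interatomic distance (A).
#' @return TRUE invisibly; errors on a violation.
#' @export
assert_no_clash <- function(mol, min_distance = 0.7) {
  d <- min_interatomic_distance(mol)
  if (d < min_distance) {
    stop(sprintf("atoms closer than %.2f A (min distance %.3f A)",
                 min_distance, d), call. = FALSE)
  }
  invisible(TRUE)
}

#' Translate a molecule so its centroid is at the origin
#' @param mol a `qmsym_molecule`.
#' @return centered molecule.
#' @export
center_molecule <- function(mol) {
  mol$coords <- sweep(mol$coords, 2L, colMeans(mol$coords))
  mol
}

#' Apply a symmetry operation to a molecule
#'
#' Every atom position is left-multiplied by the operation matrix; element
#' order, charges and the declared group are preserved.
#'
#' @param mol a `qmsym_molecule`.
#' @param op a `SymmetryOperation` (list with `label` and 3x3 `matrix`) from
#'   a built group, or a bare 3x3 matrix.
#' @return transformed molecule.
#' @export
apply_operation <- function(mol, op) {
  m <- if (is.matrix(op)) op else op$matrix
  mol$coords <- mol$coords %*% t(m)
  mol
}

# Element-preserving assignment of transformed atoms onto original atoms.
# Greedy nearest-neighbour first; if that is not a bijection (near-degenerate
# positions) fall back to a bottleneck (min-max distance) assignment found by
# binary search over candidate thresholds with a bipartite matching test.
.match_atoms <- function(elements, orig, transformed) {
  n <- nrow(orig)
  perm <- rep(NA_integer_, n)
  maxdev <- 0
  for (el in unique(elements)) {
    idx <- which(elements == el)
    d <- as.matrix(stats::dist(rbind(transformed[idx, , drop = FALSE],
                                     orig[idx, , drop = FALSE])))
    d <- d[seq_along(idx), length(idx) + seq_along(idx), drop = FALSE]
    pick <- apply(d, 1L, which.min)
    if (anyDuplicated(pick) == 0L) {
      perm[idx] <- idx[pick]
      maxdev <- max(maxdev, d[cbind(seq_along(idx), pick)])
    } else {
      sol <- .bottleneck_assignment(d)
      perm[idx] <- idx[sol$assignment]
      maxdev <- max(maxdev, sol$bottleneck)
    }
  }
  list(perm = perm, max_deviation = maxdev)
}

.bottleneck_assignment <- function(d) {
  thresholds <- sort(unique(as.vector(d)))
  lo <- 1L; hi <- length(thresholds)
  best <- NULL
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    m <- .perfect_matching_under(d, thresholds[mid])
    if (!is.null(m)) {
      best <- list(assignment = m, bottleneck = thresholds[mid])
      hi <- mid - 1L
    } else {
      lo <- mid + 1L
    }
  }
  if (is.null(best)) stop("internal: no perfect matching exists")
  best
}

.perfect_matching_under <- function(d, thr) {
  n <- nrow(d)
  edges <- which(d <= thr + 1e-12, arr.ind = TRUE)
  if (nrow(edges) < n) return(NULL)
  g <- igraph::make_bipartite_graph(
    types = rep(c(FALSE, TRUE), each = n),
    edges = as.vector(t(cbind(edges[, 1L], n + edges[, 2L]))))
  m <- igraph::max_bipartite_match(g)
  if (m$matching_size < n) return(NULL)
  as.integer(m$matching[seq_len(n)]) - n
}

#' Verify a molecule against a claimed point group
#'
#' The molecule is centered at its centroid, each group operation is applied,
#' and the transformed atoms are matched element-preservingly onto the
#' originals minimizing the maximum pair distance. The check passes when
#' every operation's assignment stays within `tol`.
#'
#' The principal axis is assumed to be z and sigma_h the xy-plane; input
#' molecules in another orientation are not auto-aligned and will fail.
#'
#' @param mol a `qmsym_molecule`.
#' @param group group name or `qmsym_group`.
#' @param tol maximum allowed displacement (A); 0.1 is the "loose" default,
#'   0.01 the strict one.
#' @return object of class `qmsym_symreport` with `group`, `passed`,
#'   `max_deviation`, `per_operation_deviation`, `atom_permutations`.
#' @export
check_symmetry <- function(mol, group, tol = 0.1) {
  stopifnot(tol > 0)
  group <- .as_group(group)
  mol <- center_molecule(mol)
  devs <- numeric(0)
  perms <- list()
  for (op in group$operations) {
    transformed <- mol$coords %*% t(op$matrix)
    m <- .match_atoms(mol$elements, mol$coords, transformed)
    devs[[op$label]] <- m$max_deviation
    perms[[op$label]] <- m$perm
  }
  structure(list(group = group$name,
                 passed = max(devs) <= tol,
                 tol = tol,
                 max_deviation = max(devs),
                 per_operation_deviation = devs,
                 atom_permutations = perms),
            class = "qmsym_symreport")
}

#' @export
print.qmsym_symreport <- function(x, ...) {
  cat(sprintf("Symmetry check vs %s: %s (max deviation %.4g A, tol %.3g A)\n",
              x$group, if (x$passed) "PASS" else "FAIL",
              x$max_deviation, x$tol))
  invisible(x)
}

#' Assign the highest-order candidate point group
#'
#' Tries the candidates D6h, C4h, C3h, C2h, C1 in decreasing order and
#' returns the first whose [check_symmetry()] passes. C1 always passes.
#'
#' @param mol a `qmsym_molecule`.
#' @param tol symmetry tolerance (A).
#' @return group name.
#' @export
assign_point_group <- function(mol, tol = 0.1) {
  for (name in c("D6h", "C4h", "C3h", "C2h")) {
    if (check_symmetry(mol, name, tol)$passed) return(name)
  }
  "C1"
}

#' Construct an asymmetric (primitive) unit
#'
#' The minimal atom set that regenerates a full molecule under the group's
#' rotations: `unit_atoms` (none of which may lie on the principal axis)
#' plus `on_axis_atoms` that sit on the rotation axis and are shared by all
#' subgroups.
#'
#' @param unit_atoms `qmsym_molecule` (or NULL) of off-axis unit atoms.
#' @param group group name.
#' @param on_axis_atoms `qmsym_molecule` (or NULL) of on-axis atoms.
#' @param axis_tol distance to the z-axis below which an atom counts as
#'   on-axis (A).
#' @return object of class `qmsym_unit`.
#' @export
asymmetric_unit <- function(unit_atoms, group, on_axis_atoms = NULL,
                            axis_tol = 1e-4) {
  group <- canonical_group_name(group)
  if (!is.null(unit_atoms) && n_atoms(unit_atoms) > 0L) {
    r <- sqrt(rowSums(unit_atoms$coords[, 1:2, drop = FALSE]^2))
    if (any(r <= axis_tol)) {
      stop("unit atom lies on the principal axis; move it to on_axis_atoms",
           call. = FALSE)
    }
  }
  if (!is.null(on_axis_atoms) && n_atoms(on_axis_atoms) > 0L) {
    r <- sqrt(rowSums(on_axis_atoms$coords[, 1:2, drop = FALSE]^2))
    if (any(r > axis_tol)) {
      stop("on-axis atom lies off the principal axis", call. = FALSE)
    }
  }
  structure(list(unit_atoms = unit_atoms, on_axis_atoms = on_axis_atoms,
                 group = group),
            class = "qmsym_unit")
}

#' Expand an asymmetric unit to the full molecule
#'
#' Replicates the unit atoms under the N = n rotational images of the group
#' (one image per subgroup), appends the on-axis atoms once, and emits the
#' matching sign list: subgroup ID (1..N) followed by the within-subgroup
#' position ID, with "0"-prefixed tokens for on-axis atoms.
#'
#' The unit must be closed under sigma_h (atoms in the mirror plane or in
#' +/-z pairs) for the expansion to carry the full Cnh symmetry; this is
#' verified unless `verify = FALSE`.
#'
#' @param unit a `qmsym_unit`.
#' @param min_distance collision threshold for the expanded structure (A).
#' @param verify check the expanded molecule against the unit's group.
#' @return list with `molecule` (declared group set) and `signs`
#'   (character vector, one token per atom in coordinate order).
#' @export
expand_primitive <- function(unit, min_distance = 0.7, verify = TRUE) {
  stopifnot(inherits(unit, "qmsym_unit"))
  n_rot <- rotational_order(unit$group)
  ua <- unit$unit_atoms
  n_a <- if (is.null(ua)) 0L else n_atoms(ua)
  elements <- character(0); coords <- NULL; charges <- numeric(0)
  signs <- character(0)
  if (n_a > 0L) {
    for (k in seq_len(n_rot) - 1L) {
      rot <- .rot_z(2 * pi * k / n_rot)
      elements <- c(elements, ua$elements)
      coords <- rbind(coords, ua$coords %*% t(rot))
      charges <- c(charges, ua$charges)
      signs <- c(signs, paste0(k + 1L, seq_len(n_a)))
    }
  }
  oa <- unit$on_axis_atoms
  if (!is.null(oa) && n_atoms(oa) > 0L) {
    elements <- c(elements, oa$elements)
    coords <- rbind(coords, oa$coords)
    charges <- c(charges, oa$charges)
    signs <- c(signs, paste0("0", n_a + seq_len(n_atoms(oa))))
  }
  if (length(elements) == 0L) stop("empty asymmetric unit", call. = FALSE)
  mol <- molecule(elements, coords, charges, group = unit$group)
  if (min_interatomic_distance(mol) < min_distance) {
    stop("expansion collision: replicated atoms closer than ",
         min_distance, " A", call. = FALSE)
  }
  if (verify) {
    rep_ <- check_symmetry(mol, unit$group, tol = 1e-6)
    if (!rep_$passed) {
      stop("expanded molecule does not satisfy ", unit$group,
           "; the unit is not closed under sigma_h", call. = FALSE)
    }
  }
  list(molecule = mol, signs = signs)
}

#' Reduce a molecule to its asymmetric unit and sign list
#'
#' Partitions the atoms into N rotational orbits of size N (the subgroups)
#' plus on-axis atoms, picks one representative per orbit as the unit, and
#' derives the sign list in the molecule's atom order.
#'
#' @param mol a `qmsym_molecule`.
#' @param group group name or `qmsym_group` the molecule satisfies.
#' @param tol symmetry tolerance (A).
#' @return list with `unit` (a `qmsym_unit`), `signs` (token per atom in the
#'   input atom order), `N` (subgroup count) and `n_a` (atoms per subgroup).
#' @export
reduce_to_primitive <- function(mol, group, tol = 0.1) {
  group <- .as_group(group)
  rep_ <- check_symmetry(mol, group, tol)
  if (!rep_$passed) {
    stop("molecule does not satisfy ", group$name, " at tol ", tol, " A",
         call. = FALSE)
  }
  mol <- center_molecule(mol)
  n_rot <- rotational_order(group)
  axis_tol <- max(tol, 1e-6)
  r_axis <- sqrt(rowSums(mol$coords[, 1:2, drop = FALSE]^2))
  on_axis <- which(r_axis <= axis_tol)
  off_axis <- setdiff(seq_len(n_atoms(mol)), on_axis)

  signs <- character(n_atoms(mol))
  unit_idx <- integer(0)
  if (length(off_axis)) {
    rot <- .rot_z(2 * pi / n_rot)
    transformed <- mol$coords %*% t(rot)
    perm <- .match_atoms(mol$elements, mol$coords, transformed)$perm
    # orbits = cycles of the Cn permutation restricted to off-axis atoms
    seen <- logical(n_atoms(mol))
    pos_id <- 0L
    for (i in off_axis) {
      if (seen[i]) next
      cyc <- i
      j <- perm[i]
      while (j != i) { cyc <- c(cyc, j); j <- perm[j] }
      if (length(cyc) != n_rot) {
        stop("rotational orbit of size ", length(cyc), " != ", n_rot,
             "; structure inconsistent with ", group$name, call. = FALSE)
      }
      seen[cyc] <- TRUE
      pos_id <- pos_id + 1L
      unit_idx <- c(unit_idx, i)
      signs[cyc] <- paste0(seq_len(n_rot), pos_id)
    }
  }
  n_a <- length(unit_idx)
  if (length(on_axis)) {
    signs[on_axis] <- paste0("0", n_a + seq_along(on_axis))
  }
  sub <- function(idx) {
    if (!length(idx)) return(NULL)
    molecule(mol$elements[idx], mol$coords[idx, , drop = FALSE],
             mol$charges[idx])
  }
  unit <- asymmetric_unit(sub(unit_idx), group$name, sub(on_axis),
                          axis_tol = axis_tol)
  list(unit = unit, signs = signs, N = if (n_a > 0L) n_rot else 0L, n_a = n_a)
}

#' Radius of rotation
#'
#' Maximum distance of any atom from the principal (z) axis,
#' max_i sqrt(x_i^2 + y_i^2). The maximum (rather than an RMS) is a
#' documented interpretation; the quantity has no standard formula.
#'
#' @param mol a `qmsym_molecule`.
#' @return radius in A.
#' @export
radius_of_rotation <- function(mol) {
  if (n_atoms(mol) == 0L) stop("empty molecule", call. = FALSE)
  max(sqrt(rowSums(mol$coords[, 1:2, drop = FALSE]^2)))
}

#' Read a plain xyz file
#' @param path file path.
#' @return a `qmsym_molecule` (a trailing numeric column, if present, is
#'   read as per-atom charges).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n)) stop("line 1 of ", path, " is not an atom count", call. = FALSE)
  atoms <- lines[3L:(2L + n)]
  parts <- strsplit(trimws(atoms), "\\s+")
  el <- vapply(parts, `[[`, "", 1L)
  coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  charges <- vapply(parts, function(p) {
    if (length(p) >= 5L) suppressWarnings(as.numeric(p[5L])) else NA_real_
  }, numeric(1))
  molecule(el, coords, charges)
}

#' Write a plain xyz file
#' @param mol a `qmsym_molecule`.
#' @param path file path.
#' @param comment comment line content.
#' @return the path, invisibly.
#' @export
write_xyz <- function(mol, path, comment = "") {
  lines <- c(as.character(n_atoms(mol)), comment,
             sprintf("%-2s %15.8f %15.8f %15.8f", mol$elements,
                     mol$coords[, 1L], mol$coords[, 2L], mol$coords[, 3L]))
  writeLines(lines, path)
  invisible(path)
}
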