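# Conventional raw-structure geometry (A, degrees). These are input values
# for pre-optimization structures: only the symmetry must be exact.
.geom <- list(
  cc_sp3 = 1.54, cc_aromatic = 1.3915,
  ch_aromatic = 1.08, ch_sp3 = 1.09,
  cx = c(F = 1.35, Cl = 1.77, Br = 1.94),
  tetrahedral = 109.4712206
)

.deg2rad <- function(d) d * pi / 180

.benzene_template <- function() {
  rc <- .geom$cc_aromatic                    # ring radius = aromatic C-C
  rh <- rc + .geom$ch_aromatic
  ang <- 2 * pi * (0:5) / 6
  coords <- rbind(cbind(rc * cos(ang), rc * sin(ang), 0),
                  cbind(rh * cos(ang), rh * sin(ang), 0))
  molecule(c(rep("C", 6), rep("H", 6)), coords, group = "D6h")
}

.c4_ring_template <- function() {
  # planar square four-membered carbon ring with radial in-plane H
  rc <- .geom$cc_sp3 / sqrt(2)
  rh <- rc + .geom$ch_aromatic
  ang <- 2 * pi * (0:3) / 4
  coords <- rbind(cbind(rc * cos(ang), rc * sin(ang), 0),
                  cbind(rh * cos(ang), rh * sin(ang), 0))
  molecule(c(rep("C", 4), rep("H", 4)), coords, group = "C4h")
}

.ethane_template <- function() {
  # staggered ethane, C-C along x so that C2 = z, sigma_h = xy-plane:
  # exactly the C2h subgroup {E, C2z, i, sigma_h} of D3d.
  half_cc <- .geom$cc_sp3 / 2
  lch <- .geom$ch_sp3
  th <- .deg2rad(180 - .geom$tetrahedral)     # H direction from +x, at C1
  c1 <- c(half_cc, 0, 0)
  ax <- lch * cos(th)
  perp <- lch * sin(th)
  h_c1 <- rbind(
    c1 + c(ax, perp, 0),                                    # in-plane H
    c1 + c(ax, perp * cos(2 * pi / 3),  perp * sin(2 * pi / 3)),
    c1 + c(ax, perp * cos(2 * pi / 3), -perp * sin(2 * pi / 3)))
  coords <- rbind(c1, -c1, h_c1, -h_c1)       # C2 side by inversion
  molecule(c("C", "C", rep("H", 6)), coords, group = "C2h")
}

#' Seed structures for the generator
#'
#' The three built-in templates the generator grows from: a staggered-ethane
#' template constrained to C2h, a planar square four-membered carbon ring
#' (C4h) and benzene (D6h). Each satisfies its declared group exactly.
#'
#' @return named list of templates, each a list with `name`, `molecule`,
#'   `group`.
#' @export
seed_structures <- function() {
  mk <- function(name, mol) list(name = name, molecule = mol, group = mol$group)
  list(ethane = mk("ethane", .ethane_template()),
       `c4-ring` = mk("c4-ring", .c4_ring_template()),
       benzene = mk("benzene", .benzene_template()))
}

#' Orbits of symmetry-equivalent atoms of one element
#'
#' Partitions all atoms of the given element into orbits under the group's
#' operations (sets of sites mapped onto each other).
#'
#' @param mol a `qmsym_molecule` satisfying the group.
#' @param group group name or `qmsym_group`.
#' @param element element symbol.
#' @param tol symmetry tolerance (A).
#' @return list of integer index vectors (atom indices into `mol`).
#' @export
site_orbits <- function(mol, group, element, tol = 0.01) {
  group <- .as_group(group)
  rep_ <- check_symmetry(mol, group, tol)
  if (!rep_$passed) {
    stop("molecule does not satisfy ", group$name, call. = FALSE)
  }
  idx <- which(mol$elements == element)
  if (!length(idx)) return(list())
  # union-find over the per-operation permutations
  parent <- seq_len(n_atoms(mol))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (perm in rep_$atom_permutations) {
    for (i in idx) {
      a <- find(i); b <- find(perm[i])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(idx, find, integer(1))
  unname(split(idx, roots))
}

# proper-subgroup candidates (z-axis convention), largest first
.subgroup_candidates <- function(group_name) {
  switch(group_name,
    D6h = c("C3h", "C2h", "C1"),
    C4h = c("C2h", "C1"),
    C3h = c("C1"),
    C2h = c("C1"),
    C1 = character(0))
}

# is the site set closed under every operation of `group`?
.sites_closed_under <- function(coords, sites, group, tol = 0.01) {
  pts <- coords[sites, , drop = FALSE]
  for (op in group$operations) {
    moved <- pts %*% t(op$matrix)
    for (r in seq_len(nrow(moved))) {
      d <- sqrt(colSums((t(pts) - moved[r, ])^2))
      if (min(d) > tol) return(FALSE)
    }
  }
  TRUE
}

#' Substitute halogens at symmetry-equivalent hydrogen sites
#'
#' Replaces each hydrogen in `sub_orbit` by a halogen placed along the
#' original C-H bond direction at the standard C-X bond length. Replacing a
#' full orbit retains the declared group; replacing a closed sub-orbit
#' reduces it to the largest candidate subgroup under which the sub-orbit is
#' closed (e.g. C4h -> C2h for two opposite sites of a 4-orbit).
#'
#' @param mol a `qmsym_molecule`.
#' @param orbit integer indices of a hydrogen orbit (from [site_orbits()]).
#' @param sub_orbit subset of `orbit` actually substituted.
#' @param element halogen symbol: "F", "Cl" or "Br".
#' @param group group name or `qmsym_group` the molecule satisfies.
#' @param tol symmetry tolerance (A).
#' @param min_distance steric-clash threshold (A).
#' @return list with `molecule` (declared group updated) and `group`.
#' @export
substitute_halogen <- function(mol, orbit, sub_orbit, element, group,
                               tol = 0.01, min_distance = 0.7) {
  group <- .as_group(group)
  stopifnot(element %in% c("F", "Cl", "Br"))
  if (!all(sub_orbit %in% orbit)) {
    stop("sub_orbit must be a subset of orbit", call. = FALSE)
  }
  if (!length(sub_orbit)) {
    return(list(molecule = mol, group = group$name))
  }
  if (!all(mol$elements[sub_orbit] == "H")) {
    stop("substitution sites must be hydrogens", call. = FALSE)
  }
  new_group <- if (setequal(sub_orbit, orbit)) {
    group$name
  } else {
    found <- NA_character_
    # C1 is excluded: the database keeps only genuinely symmetric results
    for (cand in setdiff(.subgroup_candidates(group$name), "C1")) {
      if (.sites_closed_under(center_molecule(mol)$coords, sub_orbit,
                              build_group(cand), tol)) {
        found <- cand
        break
      }
    }
    if (is.na(found)) {
      stop("sub_orbit is not closed under any candidate subgroup",
           call. = FALSE)
    }
    found
  }
  heavy <- which(mol$elements != "H")
  for (i in sub_orbit) {
    d <- sqrt(colSums((t(mol$coords[heavy, , drop = FALSE]) -
                         mol$coords[i, ])^2))
    carbon <- heavy[which.min(d)]
    dir <- mol$coords[i, ] - mol$coords[carbon, ]
    dir <- dir / sqrt(sum(dir^2))
    mol$coords[i, ] <- mol$coords[carbon, ] + .geom$cx[[element]] * dir
    mol$elements[i] <- element
  }
  mol$group <- new_group
  assert_no_clash(mol, min_distance)
  if (!check_symmetry(mol, new_group, tol)$passed) {
    stop("substitution did not preserve the declared group ", new_group,
         call. = FALSE)
  }
  list(molecule = mol, group = new_group)
}

# in-plane all-anti zigzag -(CH2)_{k-1}CH3 chain replacing hydrogen `h_idx`;
# CH2/CH3 hydrogens sit in +/-z pairs so sigma_h is preserved exactly.
.build_chain_atoms <- function(c0, h_pos, k) {
  w <- h_pos - c0
  w <- w / sqrt(sum(w^2))
  turn <- .deg2rad(180 - .geom$tetrahedral)   # angle between bond vectors
  rotx <- function(v, ang) {                  # in-plane rotation about z
    c(cos(ang) * v[1] - sin(ang) * v[2], sin(ang) * v[1] + cos(ang) * v[2], 0)
  }
  # chain carbons (k of them) plus one phantom continuing the zigzag
  pos <- matrix(0, k + 1L, 3L)
  prev <- c0
  dirv <- w
  sgn <- 1
  for (j in seq_len(k + 1L)) {
    pos[j, ] <- prev + .geom$cc_sp3 * dirv
    prev <- pos[j, ]
    dirv <- rotx(dirv, sgn * turn)
    sgn <- -sgn
  }
  half <- .deg2rad(.geom$tetrahedral / 2)
  elements <- character(0)
  coords <- NULL
  h_pair <- function(cj, to_prev, to_next) {
    bis <- -(to_prev / sqrt(sum(to_prev^2)) + to_next / sqrt(sum(to_next^2)))
    bis <- bis / sqrt(sum(bis^2))
    rbind(cj + .geom$ch_sp3 * (cos(half) * bis + sin(half) * c(0, 0, 1)),
          cj + .geom$ch_sp3 * (cos(half) * bis - sin(half) * c(0, 0, 1)))
  }
  for (j in seq_len(k)) {
    cj <- pos[j, ]
    prev_at <- if (j == 1L) c0 else pos[j - 1L, ]
    nxt <- pos[j + 1L, ]
    elements <- c(elements, "C", "H", "H")
    coords <- rbind(coords, cj, h_pair(cj, prev_at - cj, nxt - cj))
    if (j == k) {                             # terminal H along the phantom
      elements <- c(elements, "H")
      dirn <- nxt - cj
      coords <- rbind(coords,
                      cj + .geom$ch_sp3 * dirn / sqrt(sum(dirn^2)))
    }
  }
  list(elements = elements, coords = coords)
}

#' Extend aliphatic chains at a hydrogen orbit
#'
#' Replaces every hydrogen of the orbit by a -(CH2)_{k-1}CH3 chain built
#' with standard bond lengths and tetrahedral angles. One site's chain is
#' constructed in the sigma_h plane and replicated through the group
#' operations to the other sites, which preserves the declared group
#' exactly. All orbit sites must lie in the sigma_h plane.
#'
#' @param mol a `qmsym_molecule`.
#' @param orbit hydrogen orbit indices (closed under `group`).
#' @param chain_length k >= 0 (0 leaves the molecule unchanged).
#' @param group group name or `qmsym_group`.
#' @param tol symmetry tolerance (A).
#' @param min_distance steric-clash threshold (A).
#' @param max_atoms atom budget for the result.
#' @return extended `qmsym_molecule`.
#' @export
extend_chain <- function(mol, orbit, chain_length, group, tol = 0.01,
                         min_distance = 0.7, max_atoms = Inf) {
  if (chain_length == 0L) return(mol)
  group <- .as_group(group)
  if (!all(mol$elements[orbit] == "H")) {
    stop("chain extension sites must be hydrogens", call. = FALSE)
  }
  mol <- center_molecule(mol)
  if (any(abs(mol$coords[orbit, 3L]) > 1e-6)) {
    stop("chain extension requires sites in the sigma_h plane", call. = FALSE)
  }
  rep0 <- orbit[[1L]]
  heavy <- which(mol$elements != "H")
  d <- sqrt(colSums((t(mol$coords[heavy, , drop = FALSE]) -
                       mol$coords[rep0, ])^2))
  c0 <- mol$coords[heavy[which.min(d)], ]
  chain <- .build_chain_atoms(c0, mol$coords[rep0, ], chain_length)

  # replicate through the Cnh part only (z-rotations and their sigma_h
  # products): a frozen zigzag chain is sigma_h-symmetric but not invariant
  # under the in-plane C2 axes of D6h, which those axes would require
  cnh_ops <- Filter(function(op) {
    m <- op$matrix
    (abs(m[3, 3] - 1) < 1e-9 && det(m) > 0) ||
      (abs(m[3, 3] + 1) < 1e-9 && det(m) < 0)
  }, group$operations)

  new_el <- character(0); new_xyz <- NULL
  for (site in orbit) {
    op_found <- NULL
    for (op in cnh_ops) {
      img <- as.vector(op$matrix %*% mol$coords[rep0, ])
      if (sqrt(sum((img - mol$coords[site, ])^2)) <= max(tol, 1e-6)) {
        op_found <- op
        break
      }
    }
    if (is.null(op_found)) {
      stop("orbit is not closed under the group operations", call. = FALSE)
    }
    new_el <- c(new_el, chain$elements)
    new_xyz <- rbind(new_xyz, chain$coords %*% t(op_found$matrix))
  }
  keep <- setdiff(seq_len(n_atoms(mol)), orbit)
  out <- molecule(c(mol$elements[keep], new_el),
                  rbind(mol$coords[keep, , drop = FALSE], new_xyz),
                  c(mol$charges[keep], rep(NA_real_, length(new_el))),
                  group = group$name)
  if (n_atoms(out) > max_atoms) {
    stop("atom budget exceeded: ", n_atoms(out), " > ", max_atoms,
         call. = FALSE)
  }
  assert_no_clash(out, min_distance)
  # D6h cannot survive chain extension (in-plane C2 axes are broken);
  # fall back to the largest Cnh candidate that still holds
  for (cand in c(group$name, .subgroup_candidates(group$name))) {
    if (cand == "C1" || check_symmetry(out, cand, tol)$passed) {
      out$group <- cand
      return(out)
    }
  }
  stop("chain extension did not preserve any candidate group", call. = FALSE)
}

#' Perceive bonds from geometry
#'
#' Atoms i and j are bonded iff their distance is at most
#' `scale * (r_cov(i) + r_cov(j))` with the Cordero covalent radii.
#'
#' @param mol a `qmsym_molecule`.
#' @param scale radius-sum multiplier.
#' @return symmetric logical adjacency matrix (class `qmsym_bondgraph`),
#'   no self-edges.
#' @export
perceive_bonds <- function(mol, scale = 1.2) {
  r <- .qmsym_elements[mol$elements]
  if (anyNA(r)) {
    stop("unknown element(s): ",
         paste(unique(mol$elements[is.na(r)]), collapse = ", "), call. = FALSE)
  }
  n <- n_atoms(mol)
  adj <- matrix(FALSE, n, n)
  if (n >= 2L) {
    d <- as.matrix(stats::dist(mol$coords))
    thr <- scale * outer(r, r, `+`)
    adj <- d <= thr
    diag(adj) <- FALSE
  }
  structure(adj, class = c("qmsym_bondgraph", "matrix"))
}

#' Reject molecules containing nitrogen chains of three or more atoms
#'
#' Long N-N chains tend to decompose and eliminate N2; structures with a
#' bonded path of three or more nitrogens are filtered out. An isolated
#' N-N pair is accepted.
#'
#' @param mol a `qmsym_molecule`.
#' @param bonds optional precomputed bond graph.
#' @return TRUE if the molecule is rejected.
#' @export
nitrogen_chain_filter <- function(mol, bonds = perceive_bonds(mol)) {
  nidx <- which(mol$elements == "N")
  if (length(nidx) < 3L) return(FALSE)
  sub <- bonds[nidx, nidx, drop = FALSE]
  # a simple path of >= 3 N exists iff some N has >= 2 N neighbours
  any(rowSums(sub) >= 2L)
}

#' Generation configuration
#'
#' @param n_molecules number of structures to emit.
#' @param rng_seed integer seed; the (config, seed) -> output map is pure.
#' @param halogen_set subset of c("F", "Cl", "Br") available for
#'   substitution (empty disables substitution).
#' @param max_chain_length maximum aliphatic chain length k (0 disables
#'   chain extension).
#' @param max_atoms atom budget per molecule.
#' @param min_distance steric-clash threshold (A).
#' @param allow_reduction permit symmetry-reducing partial substitutions.
#' @param seeds seed templates (defaults to [seed_structures()]).
#' @return list of class `qmsym_genconfig`.
#' @export
generation_config <- function(n_molecules, rng_seed = 1L,
                              halogen_set = c("F", "Cl", "Br"),
                              max_chain_length = 3L, max_atoms = 40L,
                              min_distance = 0.7, allow_reduction = TRUE,
                              seeds = seed_structures()) {
  stopifnot(n_molecules >= 1L, min_distance > 0, max_chain_length >= 0L)
  if (!all(halogen_set %in% c("F", "Cl", "Br"))) {
    stop("halogen_set must be a subset of F, Cl, Br", call. = FALSE)
  }
  if (max_atoms < min(vapply(seeds, function(s) n_atoms(s$molecule), 0L))) {
    stop("max_atoms is below every seed size; infeasible config",
         call. = FALSE)
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 rng_seed = as.integer(rng_seed),
                 halogen_set = halogen_set,
                 max_chain_length = as.integer(max_chain_length),
                 max_atoms = as.integer(max_atoms),
                 min_distance = min_distance,
                 allow_reduction = isTRUE(allow_reduction),
                 seeds = seeds),
            class = "qmsym_genconfig")
}

# one random move; returns NULL when the move is infeasible
.try_move <- function(mol, group_name, cfg) {
  group <- build_group(group_name)
  orbits <- tryCatch(site_orbits(mol, group, "H"), error = function(e) list())
  if (!length(orbits)) return(NULL)
  moves <- character(0)
  if (cfg$max_chain_length >= 1L) moves <- c(moves, "chain")
  if (length(cfg$halogen_set)) moves <- c(moves, "halogen")
  if (!length(moves)) return(NULL)
  move <- if (length(moves) == 1L) moves else sample(moves, 1L)
  if (move == "chain") {
    centered <- center_molecule(mol)
    planar <- Filter(function(o) all(abs(centered$coords[o, 3L]) < 1e-6),
                     orbits)
    if (!length(planar)) return(NULL)
    orbit <- planar[[sample.int(length(planar), 1L)]]
    k <- sample.int(cfg$max_chain_length, 1L)
    out <- tryCatch(
      extend_chain(mol, orbit, k, group, min_distance = cfg$min_distance,
                   max_atoms = cfg$max_atoms),
      error = function(e) NULL)
    if (is.null(out)) return(NULL)
    return(list(molecule = out, group = out$group,
                log = sprintf("chain(k=%d, orbit=%s -> %s)", k,
                              paste(orbit, collapse = ","), out$group)))
  }
  orbit <- orbits[[sample.int(length(orbits), 1L)]]
  halogen <- if (length(cfg$halogen_set) == 1L) cfg$halogen_set else
    sample(cfg$halogen_set, 1L)
  sub_orbit <- orbit
  target <- group_name
  if (cfg$allow_reduction && stats::runif(1) < 0.5) {
    cands <- setdiff(.subgroup_candidates(group_name), "C1")
    if (length(cands)) {
      cand <- if (length(cands) == 1L) cands else sample(cands, 1L)
      sub <- build_group(cand)
      centered <- center_molecule(mol)
      parent <- seq_along(orbit)
      # sub-orbits of the orbit under the candidate subgroup
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (op in sub$operations) {
        moved <- centered$coords[orbit, , drop = FALSE] %*% t(op$matrix)
        for (a in seq_along(orbit)) {
          d <- sqrt(colSums((t(centered$coords[orbit, , drop = FALSE]) -
                               moved[a, ])^2))
          b <- which.min(d)
          if (d[b] < 0.01) {
            ra <- find(a); rb <- find(b)
            if (ra != rb) parent[rb] <- ra
          }
        }
      }
      roots <- vapply(seq_along(orbit), find, integer(1))
      pieces <- split(orbit, roots)
      if (length(pieces) > 1L) {
        sub_orbit <- pieces[[sample.int(length(pieces), 1L)]]
        target <- cand
      }
    }
  }
  out <- tryCatch(
    substitute_halogen(mol, orbit, sub_orbit, halogen, group,
                       min_distance = cfg$min_distance),
    error = function(e) NULL)
  if (is.null(out)) return(NULL)
  list(molecule = out$molecule, group = out$group,
       log = sprintf("halogen(%s, sites=%s -> %s)", halogen,
                     paste(sub_orbit, collapse = ","), out$group))
}

#' Generate Cnh-symmetric molecules
#'
#' Grows molecules from the seed templates by randomly sampled
#' symmetry-preserving chain extensions and symmetry-retaining or -reducing
#' halogen substitutions. Every emitted structure satisfies its declared
#' group at 0.01 A, contains no atom clash, passes the nitrogen-chain
#' filter and stays within the atom budget. Identical configuration and
#' seed give an identical output sequence.
#'
#' @param config a `qmsym_genconfig` from [generation_config()].
#' @return list of records, each with `molecule`, `group` and `provenance`
#'   (seed name, move log, final group).
#' @export
generate <- function(config) {
  stopifnot(inherits(config, "qmsym_genconfig"))
  seeds <- Filter(function(s) n_atoms(s$molecule) <= config$max_atoms,
                  config$seeds)
  if (!length(seeds)) stop("no seed fits max_atoms", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$rng_seed)
  out <- vector("list", config$n_molecules)
  for (i in seq_len(config$n_molecules)) {
    repeat {
      seed <- seeds[[sample.int(length(seeds), 1L)]]
      mol <- seed$molecule
      group <- seed$group
      logs <- character(0)
      n_moves <- sample.int(3L, 1L)
      for (m in seq_len(n_moves)) {
        res <- .try_move(mol, group, config)
        if (is.null(res)) next
        mol <- res$molecule
        group <- res$group
        logs <- c(logs, res$log)
      }
      mol$group <- group
      ok <- !nitrogen_chain_filter(mol) &&
        n_atoms(mol) <= config$max_atoms &&
        min_interatomic_distance(mol) >= config$min_distance &&
        check_symmetry(mol, group, 0.01)$passed
      if (ok) break
    }
    out[[i]] <- list(molecule = mol, group = group,
                     provenance = list(seed = seed$name, moves = logs,
                                       final_group = group,
                                       rng_seed = config$rng_seed))
  }
  out
}
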