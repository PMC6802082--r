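# Groups in scope. Cnh = n-fold rotation about z plus the horizontal mirror
# sigma_h (the xy-plane); even n additionally contains the inversion i.
# D6h is the benzene parent group (adds the 6 in-plane C2 axes and the
# vertical mirrors).
.qmsym_group_names <- c("C1", "C2h", "C3h", "C4h", "D6h")

#' Canonicalize a point-group name
#'
#' Group names are matched case-insensitively ("c2H" is accepted) and
#' returned in the conventional "C2h" capitalization.
#'
#' @param name character scalar.
#' @return canonical group name.
#' @export
canonical_group_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  hit <- match(tolower(name), tolower(.qmsym_group_names))
  if (is.na(hit)) {
    stop("unsupported point group '", name, "'; supported groups: ",
         paste(.qmsym_group_names, collapse = ", "), call. = FALSE)
  }
  .qmsym_group_names[hit]
}

# rotation by `theta` radians about z
.rot_z <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3L, 3L, byrow = TRUE)
}

# proper rotation by pi about an in-plane axis at azimuth `phi` from x
.rot_c2_inplane <- function(phi) {
  c2 <- cos(2 * phi); s2 <- sin(2 * phi)
  matrix(c(c2, s2, 0, s2, -c2, 0, 0, 0, -1), 3L, 3L, byrow = TRUE)
}

.sigma_h <- diag(c(1, 1, -1))
.inversion <- diag(c(-1, -1, -1))

.op <- function(label, matrix) list(label = label, matrix = matrix)

# label for the proper rotation by k/n turns about z
.rot_label <- function(k, n) {
  if (k %% n == 0) return("E")
  g <- .gcd(k, n)
  p <- k / g; q <- n / g
  if (p == 1) paste0("C", q) else paste0("C", q, "^", p)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

# label for the improper operation sigma_h %*% rot_z(2*pi*k/n)
.improper_label <- function(k, n) {
  k <- k %% n
  if (k == 0) return("sigma_h")
  g <- .gcd(k, n)
  p <- k / g; q <- n / g
  if (q == 2) return("i")                 # sigma_h . C2 = i
  # S_q^p requires odd p (even powers of S_q are proper); lift into the
  # odd representative p + q when needed.
  if (p %% 2 == 0) p <- p + q
  if (p == 1) paste0("S", q) else paste0("S", q, "^", p)
}

.irrep <- function(label, characters, pair = NA_character_) {
  list(label = label, characters = characters, pair = pair,
       linear = character(0))
}

# Cnh irreps: products of the Cn irreps (chi(C_n^k) = exp(2*pi*i*m*k/n))
# with the sigma_h parity. 1-D throughout; complex-conjugate partners are
# tagged with a shared `pair` label (the printed "E" rows).
.cnh_irreps <- function(n) {
  # Mulliken labels for the Cn part, m = 0 .. n-1
  part_labels <- function(n) {
    if (n == 2) return(c("A", "B"))
    if (n == 3) return(c("A", "Ea", "Eb"))
    if (n == 4) return(c("A", "Ea", "B", "Eb"))  # m = 0,1,2,3
    stop("internal: unexpected n")
  }
  pair_of <- function(lab) if (startsWith(lab, "E")) "E" else NA_character_
  labs <- part_labels(n)
  # parity suffix: even n has inversion -> g/u; odd n uses '/'' (sigma_h parity)
  suffixes <- if (n %% 2 == 0) c("g", "u") else c("'", "''")
  irreps <- list()
  for (s in seq_along(suffixes)) {
    parity <- if (s == 1) 1 else -1
    for (m in seq_len(n) - 1L) {
      lab <- labs[m + 1L]
      rot_chars <- exp(2i * pi * m * (seq_len(n) - 1L) / n)
      chars <- c(rot_chars, parity * rot_chars)
      base <- sub("[ab]$", "", lab)
      memb <- if (startsWith(lab, "E")) substring(lab, 2L) else ""
      full <- paste0(base, suffixes[s], if (nzchar(memb)) memb else "")
      pair <- if (startsWith(lab, "E")) paste0("E", suffixes[s]) else NA_character_
      irreps[[full]] <- .irrep(full, chars, pair)
    }
  }
  irreps
}

.build_cnh <- function(n) {
  k <- seq_len(n) - 1L
  proper <- lapply(k, function(kk) .op(.rot_label(kk, n), .rot_z(2 * pi * kk / n)))
  if (n %% 2 == 0) {
    # list improper ops as i * (proper rotations), the printed table order
    improper <- lapply(k, function(kk) {
      m <- .inversion %*% .rot_z(2 * pi * kk / n)
      .op(.improper_label(kk + n / 2, n), m)
    })
  } else {
    improper <- lapply(k, function(kk) {
      m <- .sigma_h %*% .rot_z(2 * pi * kk / n)
      .op(.improper_label(kk, n), m)
    })
  }
  list(operations = c(proper, improper), irreps = .cnh_irreps(n))
}

# D6 characters at a proper rotation by k/6 turns, and at the two classes of
# in-plane C2 axes; E1/E2 from 2*cos(k*theta). Tensored with {E, i} below.
.d6_char <- function(lab, kind, k = 0) {
  th <- pi * k / 3
  switch(lab,
    A1 = if (kind == "rot") 1 else 1,
    A2 = if (kind == "rot") 1 else -1,
    B1 = if (kind == "rot") (-1)^k else if (kind == "c2p") 1 else -1,
    B2 = if (kind == "rot") (-1)^k else if (kind == "c2p") -1 else 1,
    E1 = if (kind == "rot") 2 * cos(th) else 0,
    E2 = if (kind == "rot") 2 * cos(2 * th) else 0,
    stop("internal: unknown D6 irrep"))
}

.build_d6h <- function() {
  k <- 0:5
  proper_z <- lapply(k, function(kk) .op(.rot_label(kk, 6), .rot_z(pi * kk / 3)))
  # C2' axes along x, 60, 120 degrees; C2'' along the bisectors 30, 90, 150
  c2p <- lapply(1:3, function(j) .op(paste0("C2'_", j), .rot_c2_inplane((j - 1) * pi / 3)))
  c2pp <- lapply(1:3, function(j) .op(paste0("C2''_", j), .rot_c2_inplane((2 * j - 1) * pi / 6)))
  proper <- c(proper_z, c2p, c2pp)
  improper <- lapply(seq_along(proper), function(idx) {
    o <- proper[[idx]]
    m <- .inversion %*% o$matrix
    lab <- if (idx <= 6) {
      .improper_label((idx - 1) + 3, 6)       # i . Cz(k) = sigma_h . Cz(k+3)
    } else if (idx <= 9) {
      paste0("sigma_d", idx - 6)              # i . C2' = mirror through C2'' axis
    } else {
      paste0("sigma_v", idx - 9)              # i . C2'' = mirror through C2' axis
    }
    .op(lab, m)
  })
  operations <- c(proper, improper)
  kinds <- c(rep("rot", 6), rep("c2p", 3), rep("c2pp", 3))
  irreps <- list()
  for (parity in c("g", "u")) {
    pf <- if (parity == "g") 1 else -1
    for (lab in c("A1", "A2", "B1", "B2", "E1", "E2")) {
      chars_proper <- vapply(seq_len(12), function(idx) {
        .d6_char(lab, kinds[idx], k = if (idx <= 6) idx - 1 else 0)
      }, numeric(1))
      chars <- as.complex(c(chars_proper, pf * chars_proper))
      full <- paste0(lab, parity)
      irreps[[full]] <- .irrep(full, chars)
    }
  }
  list(operations = operations, irreps = irreps)
}

# conjugacy classes by matrix conjugation (exhaustive; groups are tiny)
.conjugacy_classes <- function(operations) {
  mats <- lapply(operations, `[[`, "matrix")
  n <- length(mats)
  class_id <- rep(NA_integer_, n)
  next_id <- 0L
  find_op <- function(m) {
    for (j in seq_len(n)) if (max(abs(mats[[j]] - m)) < 1e-8) return(j)
    stop("group not closed under conjugation", call. = FALSE)
  }
  for (idx in seq_len(n)) {
    if (!is.na(class_id[idx])) next
    next_id <- next_id + 1L
    for (g in seq_len(n)) {
      conj_m <- mats[[g]] %*% mats[[idx]] %*% t(mats[[g]])
      class_id[find_op(conj_m)] <- next_id
    }
  }
  class_id
}

# reduce the representation carried by a coordinate subspace and return the
# labels of irreps that appear (used to annotate x/y/z and Rx/Ry/Rz)
.subspace_irreps <- function(group, chars) {
  mult <- reduce_representation(chars, group)
  names(mult)[mult > 0]
}

#' Build a molecular point group
#'
#' Constructs one of the supported point groups (C1, C2h, C3h, C4h, D6h) as
#' an explicit list of 3x3 orthogonal operation matrices together with its
#' irreducible-representation character table, indexed per operation. The
#' principal rotation axis is z and sigma_h is the xy-plane throughout.
#'
#' Characters of the C3h/C4h conjugate "E" pairs are stored as separate
#' complex 1-D irreps tagged with a shared pair label; use
#' [character_table()] with `merged = TRUE` for the printed real form.
#'
#' @param name group name, case-insensitive ("C2h", "d6h", ...).
#' @return an object of class `qmsym_group` with elements `name`, `order`,
#'   `operations` (list of `label` + `matrix`), `class_id`, `irreps`
#'   (list of `label`, `characters`, `pair`, `linear`) and `dipole`
#'   (polarization axis -> irrep labels).
#' @examples
#' g <- build_group("C2h")
#' sapply(g$operations, `[[`, "label")
#' @export
build_group <- function(name) {
  name <- canonical_group_name(name)
  built <- switch(name,
    C1  = list(operations = list(.op("E", diag(3))),
               irreps = list(A = .irrep("A", as.complex(1)))),
    C2h = .build_cnh(2L),
    C3h = .build_cnh(3L),
    C4h = .build_cnh(4L),
    D6h = .build_d6h())
  group <- structure(list(
    name = name,
    order = length(built$operations),
    operations = built$operations,
    class_id = .conjugacy_classes(built$operations),
    irreps = built$irreps
  ), class = "qmsym_group")

  # dipole operator symmetry from how (x, y) and z transform
  mats <- lapply(group$operations, `[[`, "matrix")
  z_chars <- as.complex(vapply(mats, function(m) m[3, 3], numeric(1)))
  xy_chars <- as.complex(vapply(mats, function(m) m[1, 1] + m[2, 2], numeric(1)))
  z_irr <- .subspace_irreps(group, z_chars)
  xy_irr <- .subspace_irreps(group, xy_chars)
  # rotations transform as axial vectors: extra det(R) factor
  dets <- vapply(mats, det, numeric(1))
  rz_irr <- .subspace_irreps(group, z_chars * dets)
  rxy_irr <- .subspace_irreps(group, xy_chars * dets)
  for (lab in z_irr)  group$irreps[[lab]]$linear <- union(group$irreps[[lab]]$linear, "z")
  for (lab in xy_irr) group$irreps[[lab]]$linear <- union(group$irreps[[lab]]$linear, c("x", "y"))
  for (lab in rz_irr) group$irreps[[lab]]$linear <- union(group$irreps[[lab]]$linear, "Rz")
  for (lab in rxy_irr) group$irreps[[lab]]$linear <- union(group$irreps[[lab]]$linear, c("Rx", "Ry"))
  group$dipole <- list(x = xy_irr, y = xy_irr, z = z_irr)
  group
}

.as_group <- function(group) {
  if (inherits(group, "qmsym_group")) group else build_group(group)
}

#' Rotational order n of a supported group
#' @param group group name or `qmsym_group`.
#' @return integer n (1 for C1, 2 for C2h, ..., 6 for D6h).
#' @export
rotational_order <- function(group) {
  name <- if (inherits(group, "qmsym_group")) group$name else canonical_group_name(group)
  c(C1 = 1L, C2h = 2L, C3h = 3L, C4h = 4L, D6h = 6L)[[name]]
}

#' Character vector of an irrep
#'
#' Resolves an irrep label case-insensitively. A conjugate-pair label
#' ("Eu", "E'", ...) resolves to the summed (real) characters of the two
#' members unless `member` selects one.
#'
#' @param group group name or `qmsym_group`.
#' @param label irrep label (case-insensitive; file-style "BU" accepted).
#' @param member optional: "a" or "b" to pick one member of a pair.
#' @return complex character vector, one entry per group operation.
#' @export
irrep_characters <- function(group, label, member = NULL) {
  group <- .as_group(group)
  members <- resolve_irrep_members(group, label)
  if (!is.null(member)) {
    pick <- members[endsWith(tolower(names(members)), tolower(member))]
    if (length(pick) != 1L) stop("no member '", member, "' for irrep '", label, "'")
    return(pick[[1L]])
  }
  Reduce(`+`, members)
}

#' Resolve an irrep label to its member character vectors
#'
#' @inheritParams irrep_characters
#' @return named list of complex character vectors: one element for a plain
#'   irrep, two for a conjugate-pair label.
#' @export
resolve_irrep_members <- function(group, label) {
  group <- .as_group(group)
  key <- tolower(gsub("\\s", "", label))
  labs <- vapply(group$irreps, `[[`, "", "label")
  hit <- labs[tolower(labs) == key]
  if (length(hit) == 1L) {
    out <- list(group$irreps[[hit]]$characters)
    names(out) <- hit
    return(out)
  }
  pairs <- vapply(group$irreps, function(ir) ir$pair %||% NA_character_, "")
  hits <- labs[!is.na(pairs) & tolower(pairs) == key]
  if (length(hits) >= 1L) {
    out <- lapply(hits, function(l) group$irreps[[l]]$characters)
    names(out) <- hits
    return(out)
  }
  stop("unknown irrep label '", label, "' in group ", group$name, call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Direct product of representation characters
#'
#' The characters of a direct-product representation are the elementwise
#' products of the factors' characters.
#'
#' @param a,b complex character vectors on the same group's operation order.
#' @return complex character vector.
#' @export
direct_product <- function(a, b) {
  if (length(a) != length(b)) {
    stop("character vectors have different lengths (", length(a), " vs ",
         length(b), "); not representations of the same group", call. = FALSE)
  }
  as.complex(a) * as.complex(b)
}

#' Reduce a representation into irreducible components
#'
#' Applies the reduction formula a_i = (1/h) * sum_R chi_r(R) * conj(chi_i(R))
#' over the full operation list (not per class).
#'
#' @param chars complex (or numeric) character vector, one entry per group
#'   operation in the group's operation order.
#' @param group group name or `qmsym_group`.
#' @param tol integrality tolerance for the multiplicities.
#' @return named non-negative integer vector of multiplicities a_i, one per
#'   irrep (conjugate-pair members separately).
#' @export
reduce_representation <- function(chars, group, tol = 1e-6) {
  group <- .as_group(group)
  if (length(chars) != group$order) {
    stop("representation has ", length(chars), " characters but group ",
         group$name, " has ", group$order, " operations", call. = FALSE)
  }
  chars <- as.complex(chars)
  h <- group$order
  a <- vapply(group$irreps, function(ir) {
    sum(chars * Conj(ir$characters)) / h
  }, complex(1))
  if (any(abs(Im(a)) > tol) || any(abs(Re(a) - round(Re(a))) > tol) ||
      any(round(Re(a)) < 0)) {
    stop("characters do not form a representation of ", group$name,
         " (non-integral multiplicities)", call. = FALSE)
  }
  out <- as.integer(round(Re(a)))
  names(out) <- names(group$irreps)
  # reconstruction must be exact
  rec <- Reduce(`+`, Map(function(ir, m) m * ir$characters, group$irreps, out))
  if (max(abs(rec - chars)) > 1e-6) {
    stop("characters do not form a representation of ", group$name,
         " (reconstruction failed)", call. = FALSE)
  }
  out
}

#' Totally symmetric irrep label of a group
#' @param group group name or `qmsym_group`.
#' @return label of the irrep with all characters +1.
#' @export
totally_symmetric_irrep <- function(group) {
  group <- .as_group(group)
  for (ir in group$irreps) {
    if (max(abs(ir$characters - 1)) < 1e-10) return(ir$label)
  }
  stop("internal: no totally symmetric irrep found")
}

#' Dipole-operator irreps per polarization axis
#'
#' Returns, for each Cartesian polarization, the irrep label(s) spanned by
#' that coordinate, derived from the operation matrices. For C2h this is
#' x -> Bu, y -> Bu, z -> Au.
#'
#' @param group group name or `qmsym_group`.
#' @param merged merge conjugate-pair members under the pair label.
#' @return named list with entries `x`, `y`, `z` of irrep labels.
#' @export
dipole_irreps <- function(group, merged = FALSE) {
  group <- .as_group(group)
  out <- group$dipole
  if (merged) {
    out <- lapply(out, function(labs) {
      unique(vapply(labs, function(l) {
        p <- group$irreps[[l]]$pair
        if (is.na(p)) l else p
      }, ""))
    })
  }
  out
}

.format_complex <- function(z, digits = 4) {
  vapply(z, function(x) {
    re <- signif(Re(x), digits); im <- signif(Im(x), digits)
    if (abs(im) < 1e-10) {
      format(re, trim = TRUE)
    } else {
      sprintf("%s%+gj", format(re, trim = TRUE), im)
    }
  }, "")
}

#' Character table of a group
#'
#' @param group group name or `qmsym_group`.
#' @param merged if TRUE, conjugate-pair members are merged under the pair
#'   label with summed (real) characters, matching printed tables.
#' @return data.frame with one row per irrep: `irrep`, one column per
#'   operation (complex entries formatted "a+bj"), and `linear`.
#' @export
character_table <- function(group, merged = TRUE) {
  group <- .as_group(group)
  irreps <- group$irreps
  if (merged) {
    done <- character(0)
    kept <- list()
    for (ir in irreps) {
      if (is.na(ir$pair)) {
        kept[[ir$label]] <- ir
      } else if (!(ir$pair %in% done)) {
        done <- c(done, ir$pair)
        partner <- Filter(function(j) identical(j$pair, ir$pair) &&
                            j$label != ir$label, irreps)[[1L]]
        merged_ir <- .irrep(ir$pair, ir$characters + partner$characters)
        merged_ir$linear <- union(ir$linear, partner$linear)
        kept[[ir$pair]] <- merged_ir
      }
    }
    irreps <- kept
  }
  op_labels <- vapply(group$operations, `[[`, "", "label")
  rows <- lapply(irreps, function(ir) {
    vals <- as.list(.format_complex(ir$characters))
    names(vals) <- make.unique(op_labels)
    c(list(irrep = ir$label), vals,
      list(linear = paste(ir$linear, collapse = ", ")))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}

#' @export
print.qmsym_group <- function(x, ...) {
  cat("Point group ", x$name, " (order h = ", x$order, ")\n", sep = "")
  cat("Operations:", paste(vapply(x$operations, `[[`, "", "label"),
                           collapse = " "), "\n")
  tbl <- character_table(x, merged = TRUE)
  print(tbl, row.names = FALSE)
  dip <- dipole_irreps(x, merged = TRUE)
  cat("Dipole: x,y -> ", paste(dip$x, collapse = "/"),
      "; z -> ", paste(dip$z, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Export a character table to CSV
#' @param group group name or `qmsym_group`.
#' @param path output file path.
#' @param merged merge conjugate pairs (see [character_table()]).
#' @return the path, invisibly.
#' @export
write_character_table <- function(group, path, merged = TRUE) {
  utils::write.csv(character_table(group, merged = merged), path,
                   row.names = FALSE)
  invisible(path)
}
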