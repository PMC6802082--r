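# Scalar property slots of the 44-field property line, in storage order
# (after the leading group label). Bv has 3 entries, mu 4 (magnitude +
# x,y,z components), zpve 2 (J/mol and kcal/mol).
.prop_slots <- c(Eg = 1L, Ec = 1L, Ev = 1L, Bv = 3L, mu = 4L, alpha = 1L,
                 R2 = 1L, zpve = 2L, e_zpe = 1L, e_tot = 1L, e_h = 1L,
                 e_g = 1L, Cv = 1L)

#' Empty (sentinel-filled) property block
#'
#' All DFT-derived fields of the property line, blank-filled with the NA
#' sentinel (written as the literal token "NA"; zero is a legal value and is
#' never used as a blank).
#'
#' @return named list of numeric fields.
#' @export
empty_properties <- function() {
  out <- lapply(.prop_slots, function(k) rep(NA_real_, k))
  names(out) <- names(.prop_slots)
  out
}

#' Construct a QM-sym record
#'
#' Bundles a molecule with its declared group into the annotated-xyz record
#' structure: atoms reordered subgroup-by-subgroup (axis atoms last), the
#' matching sign list, the property block and optional orbital blocks.
#'
#' @param mol a `qmsym_molecule`.
#' @param group declared group (defaults to the molecule's).
#' @param properties property block (see [empty_properties()]).
#' @param orbitals NULL, or a list with `occupied` and `virtual` data frames
#'   (`degeneracy`, `label`), each ordered by increasing energy.
#' @param tol symmetry tolerance used to derive the subgroup partition (A).
#' @return object of class `qmsym_record`.
#' @export
qmsym_record <- function(mol, group = mol$group,
                         properties = empty_properties(),
                         orbitals = NULL, tol = 0.01) {
  if (is.na(group)) stop("record needs a declared group", call. = FALSE)
  group <- canonical_group_name(group)
  red <- reduce_to_primitive(mol, group, tol)
  mol <- center_molecule(mol)
  ord <- order(substr(red$signs, 1L, 1L) == "0",          # axis atoms last
               as.integer(substr(red$signs, 1L, 1L)),     # subgroup-major
               as.integer(substring(red$signs, 2L)))      # then position
  structure(list(
    molecule = molecule(mol$elements[ord], mol$coords[ord, , drop = FALSE],
                        mol$charges[ord], group = group),
    group = group,
    signs = red$signs[ord],
    N = red$N, n_a = red$n_a,
    has_axis_atoms = any(startsWith(red$signs, "0")),
    properties = properties,
    orbitals = orbitals
  ), class = "qmsym_record")
}

#' @export
print.qmsym_record <- function(x, ...) {
  cat("QM-sym record: ", x$group, ", ", n_atoms(x$molecule), " atoms (",
      x$N, " subgroups x ", x$n_a, " atoms",
      if (x$has_axis_atoms) " + axis atoms", ")\n", sep = "")
  invisible(x)
}

.fmt_num <- function(x, digits) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else formatC(v, digits = digits, format = "g")
  }, "")
}

#' Parse a QM-sym sign list
#'
#' Each token is a subgroup ID (single character; "0" marks atoms on the
#' rotation axis) followed by a position ID. Tokens sharing a position ID
#' across subgroups denote atoms of the same element at equivalent
#' positions.
#'
#' @param tokens character vector of sign tokens, in coordinate-line order.
#' @param N subgroup count; derived from the tokens when NULL. Must be <= 9
#'   (single-digit subgroup IDs).
#' @return data.frame with columns `subgroup` and `position`.
#' @export
parse_sign_list <- function(tokens, N = NULL) {
  if (!length(tokens)) stop("empty sign list", call. = FALSE)
  sub_id <- suppressWarnings(as.integer(substr(tokens, 1L, 1L)))
  pos_id <- suppressWarnings(as.integer(substring(tokens, 2L)))
  bad <- which(is.na(sub_id) | is.na(pos_id) | nchar(tokens) < 2L)
  if (length(bad)) {
    stop("malformed sign token '", tokens[bad[1L]], "' at index ", bad[1L],
         call. = FALSE)
  }
  n_seen <- max(sub_id)
  if (is.null(N)) N <- n_seen
  if (N > 9L) stop("subgroup count ", N, " > 9 not representable by ",
                   "single-digit subgroup IDs", call. = FALSE)
  if (n_seen > N) {
    stop("sign token with subgroup ID ", n_seen, " > N = ", N, call. = FALSE)
  }
  for (s in unique(sub_id)) {
    p <- pos_id[sub_id == s]
    if (anyDuplicated(p)) {
      stop("duplicate position ID in subgroup ", s, call. = FALSE)
    }
  }
  data.frame(subgroup = sub_id, position = pos_id)
}

#' Parse the orbital degeneracy/symmetry blocks
#'
#' The two pipe-delimited fields of the property line: degeneracy counts and
#' matching irrep labels, one entry per level (degenerate orbitals share one
#' level). "1|2|1|1" with "BU|BG|AU|AG" describes 4 levels and 5 orbitals.
#'
#' @param degeneracy_field pipe-delimited counts.
#' @param label_field pipe-delimited irrep labels.
#' @return data.frame with columns `degeneracy` (integer) and `label`.
#' @export
parse_orbital_block <- function(degeneracy_field, label_field) {
  degs <- strsplit(degeneracy_field, "|", fixed = TRUE)[[1L]]
  labs <- strsplit(label_field, "|", fixed = TRUE)[[1L]]
  if (length(degs) != length(labs)) {
    stop("orbital blocks disagree: ", length(degs), " degeneracies vs ",
         length(labs), " labels", call. = FALSE)
  }
  d <- suppressWarnings(as.integer(degs))
  if (anyNA(d) || any(d < 1L)) {
    stop("orbital degeneracy entries must be positive integers (got '",
         degeneracy_field, "')", call. = FALSE)
  }
  data.frame(degeneracy = d, label = labs)
}

# occupied block = minimal level prefix whose summed degeneracy covers the
# HOMO-5..HOMO window (>= 6 orbitals, extended across degeneracies)
.split_orbital_window <- function(levels, window = 6L) {
  cum <- cumsum(levels$degeneracy)
  k <- which(cum >= window)[1L]
  if (is.na(k) || k == nrow(levels)) {
    stop("cannot locate the HOMO/LUMO boundary in the orbital block",
         call. = FALSE)
  }
  list(occupied = levels[seq_len(k), , drop = FALSE],
       virtual = levels[(k + 1L):nrow(levels), , drop = FALSE])
}

#' Write a QM-sym record as text
#'
#' Line 1 is the atom count, line 2 the property string in table order
#' (group label, 19 numeric fields, the two pipe-joined orbital blocks,
#' then the sign list), followed by the coordinate lines
#' "element x y z charge" grouped by subgroup with axis atoms last.
#'
#' @param rec a `qmsym_record`.
#' @param path optional file path; when NULL the text is returned.
#' @return character vector of lines (invisibly when writing to a file).
#' @export
write_record <- function(rec, path = NULL) {
  stopifnot(inherits(rec, "qmsym_record"))
  mol <- rec$molecule
  if (length(rec$signs) != n_atoms(mol)) {
    stop("sign list length != atom count; refusing to write", call. = FALSE)
  }
  props <- rec$properties
  scalars <- unlist(lapply(names(.prop_slots), function(nm) {
    v <- props[[nm]] %||% rep(NA_real_, .prop_slots[[nm]])
    if (length(v) != .prop_slots[[nm]]) {
      stop("property '", nm, "' must have ", .prop_slots[[nm]], " value(s)",
           call. = FALSE)
    }
    v
  }))
  if (is.null(rec$orbitals)) {
    dfield <- "NA"; sfield <- "NA"
  } else {
    lv <- rbind(rec$orbitals$occupied, rec$orbitals$virtual)
    dfield <- paste(lv$degeneracy, collapse = "|")
    sfield <- paste(lv$label, collapse = "|")
  }
  line2 <- paste(c(rec$group, .fmt_num(scalars, 6L), dfield, sfield,
                   rec$signs), collapse = " ")
  coord_lines <- sprintf("%-2s %s %s %s %s", mol$elements,
                         .fmt_num(mol$coords[, 1L], 8L),
                         .fmt_num(mol$coords[, 2L], 8L),
                         .fmt_num(mol$coords[, 3L], 8L),
                         .fmt_num(mol$charges, 8L))
  lines <- c(as.character(n_atoms(mol)), line2, coord_lines)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

.parse_num_token <- function(tok, what, index) {
  if (tok == "NA") return(NA_real_)
  v <- suppressWarnings(as.numeric(tok))
  if (is.na(v)) {
    stop("property line field ", index, " (", what, "): '", tok,
         "' is not numeric", call. = FALSE)
  }
  v
}

#' Parse a QM-sym record
#'
#' Parses and cross-validates one annotated-xyz record: the line-1 count
#' against the coordinate lines, the sign-list length against the atoms,
#' subgroup IDs against the subgroup count, and the per-subgroup grouping
#' of the coordinate block.
#'
#' @param text character vector of lines, a single string with newlines, or
#'   a file path.
#' @return a `qmsym_record`.
#' @export
parse_record <- function(text) {
  lines <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    readLines(text)
  } else if (length(text) == 1L) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    text
  }
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) <= 2L]
  if (length(lines) < 3L) stop("record has fewer than 3 lines", call. = FALSE)
  count <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(count) || count < 1L) {
    stop("line 1: '", lines[1L], "' is not a positive atom count",
         call. = FALSE)
  }
  if (length(lines) != 2L + count) {
    stop("line 1 declares ", count, " atoms but ", length(lines) - 2L,
         " coordinate lines follow", call. = FALSE)
  }
  toks <- strsplit(trimws(lines[2L]), "\\s+")[[1L]]
  n_scalar <- sum(.prop_slots)            # 19 numeric fields
  need <- 1L + n_scalar + 2L + count
  if (length(toks) != need) {
    stop("property line has ", length(toks), " fields; expected ", need,
         " (group, ", n_scalar, " properties, 2 orbital blocks, ", count,
         " sign tokens)", call. = FALSE)
  }
  group <- canonical_group_name(toks[1L])
  vals <- vapply(seq_len(n_scalar), function(i) {
    .parse_num_token(toks[1L + i], "property", 1L + i)
  }, numeric(1))
  props <- empty_properties()
  at <- 0L
  for (nm in names(.prop_slots)) {
    k <- .prop_slots[[nm]]
    props[[nm]] <- vals[at + seq_len(k)]
    at <- at + k
  }
  dfield <- toks[1L + n_scalar + 1L]
  sfield <- toks[1L + n_scalar + 2L]
  orbitals <- if (dfield == "NA" && sfield == "NA") {
    NULL
  } else {
    .split_orbital_window(parse_orbital_block(dfield, sfield))
  }
  sign_toks <- toks[(1L + n_scalar + 3L):length(toks)]
  signs <- parse_sign_list(sign_toks)
  N <- max(signs$subgroup)

  parts <- strsplit(trimws(lines[3L:(2L + count)]), "\\s+")
  bad <- which(vapply(parts, length, 0L) < 4L)
  if (length(bad)) {
    stop("coordinate line ", 2L + bad[1L], " has fewer than 4 fields",
         call. = FALSE)
  }
  el <- vapply(parts, `[[`, "", 1L)
  coords <- t(vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[2:4]))
    if (anyNA(v)) stop("non-numeric coordinate", call. = FALSE)
    v
  }, numeric(3)))
  charges <- vapply(parts, function(p) {
    if (length(p) >= 5L && p[5L] != "NA") {
      suppressWarnings(as.numeric(p[5L]))
    } else NA_real_
  }, numeric(1))

  # structural cross-checks: subgroup-major order, equal subgroup sizes,
  # axis atoms last, matching elements across subgroups at equal positions
  sub_sizes <- table(factor(signs$subgroup, levels = 0:N))
  n_a <- if (N > 0L) as.integer(sub_sizes[as.character(1L)]) else 0L
  if (N > 0L && length(unique(sub_sizes[as.character(1:N)])) != 1L) {
    stop("subgroups have unequal sizes: ",
         paste(sub_sizes[as.character(1:N)], collapse = ", "), call. = FALSE)
  }
  if (N > 0L) {
    first_axis <- which(signs$subgroup == 0L)[1L]
    if (!is.na(first_axis) && any(signs$subgroup[first_axis:count] != 0L)) {
      stop("axis-atom sign tokens must come last", call. = FALSE)
    }
    for (p in unique(signs$position[signs$subgroup > 0L])) {
      els <- unique(el[signs$subgroup > 0L & signs$position == p])
      if (length(els) != 1L) {
        stop("position ID ", p, " carries different elements across ",
             "subgroups: ", paste(els, collapse = ", "), call. = FALSE)
      }
    }
  }
  mol <- molecule(el, coords, charges, group = group)
  structure(list(molecule = mol, group = group, signs = sign_toks,
                 N = N, n_a = n_a,
                 has_axis_atoms = any(signs$subgroup == 0L),
                 properties = props, orbitals = orbitals),
            class = "qmsym_record")
}

#' Validate a QM-sym record
#'
#' Runs three independent checks: (i) the geometry satisfies the declared
#' group at `tol`; (ii) an independently recomputed orbit decomposition
#' agrees with the record's sign list (same partition into subgroups and
#' axis atoms, same element at equal position IDs); (iii) structural counts
#' are consistent.
#'
#' @param rec a `qmsym_record`.
#' @param tol symmetry tolerance (A).
#' @return data.frame of checks (`check`, `passed`, `detail`) with
#'   attribute `passed` (all checks green); class `qmsym_validation`.
#' @export
validate_record <- function(rec, tol = 0.1) {
  checks <- list()
  add <- function(name, ok, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = name, passed = ok,
                                                 detail = detail)
  }
  mol <- rec$molecule
  n <- n_atoms(mol)
  add("counts", length(rec$signs) == n &&
        (rec$N == 0L || rec$N * rec$n_a <= n),
      sprintf("%d atoms, %d sign tokens", n, length(rec$signs)))
  geo <- check_symmetry(mol, rec$group, tol)
  add("geometry", geo$passed,
      sprintf("max deviation %.4g A vs %s", geo$max_deviation, rec$group))
  sign_ok <- FALSE
  detail <- ""
  if (geo$passed) {
    red <- tryCatch(reduce_to_primitive(mol, rec$group, tol),
                    error = function(e) NULL)
    if (!is.null(red)) {
      claimed <- parse_sign_list(rec$signs)
      computed <- parse_sign_list(red$signs)
      part_of <- function(s) {
        off <- s$subgroup > 0L
        list(axis = which(!off),
             orbits = unname(split(which(off), s$position[off])))
      }
      a <- part_of(claimed); b <- part_of(computed)
      same_axis <- setequal(a$axis, b$axis)
      canon <- function(orbs) {
        sort(vapply(orbs, function(o) paste(sort(o), collapse = ","), ""))
      }
      same_orbits <- identical(canon(a$orbits), canon(b$orbits))
      el_ok <- all(vapply(a$orbits, function(o) {
        length(unique(mol$elements[o])) == 1L
      }, TRUE))
      sign_ok <- same_axis && same_orbits && el_ok
      detail <- sprintf("axis %s, orbits %s, elements %s",
                        same_axis, same_orbits, el_ok)
    } else {
      detail <- "orbit decomposition failed"
    }
  } else {
    detail <- "skipped (geometry failed)"
  }
  add("sign_consistency", sign_ok, detail)
  out <- do.call(rbind, checks)
  attr(out, "passed") <- all(out$passed)
  class(out) <- c("qmsym_validation", class(out))
  out
}

#' @export
print.qmsym_validation <- function(x, ...) {
  cat("Record validation:", if (attr(x, "passed")) "PASS" else "FAIL", "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Read all QM-sym records in a directory
#' @param path directory containing `*.xyz` records.
#' @return named list of `qmsym_record`s.
#' @export
read_qmsym_dir <- function(path) {
  files <- list.files(path, pattern = "\\.xyz$", full.names = TRUE)
  out <- lapply(files, parse_record)
  names(out) <- basename(files)
  out
}

#' Read QM-sym records from a tar archive
#' @param tarfile archive path (the dataset ships as a `.tar`).
#' @return named list of `qmsym_record`s.
#' @export
read_qmsym_tar <- function(tarfile) {
  dir <- tempfile("qmsym_tar_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  utils::untar(tarfile, exdir = dir)
  files <- list.files(dir, pattern = "\\.xyz$", full.names = TRUE,
                      recursive = TRUE)
  out <- lapply(files, parse_record)
  names(out) <- basename(files)
  out
}

#' Property table across a record set
#' @param records list of `qmsym_record`s.
#' @return data.frame with one row per record (scalar properties flattened).
#' @export
properties_table <- function(records) {
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    p <- r$properties
    data.frame(record = names(records)[i] %||% as.character(i),
               group = r$group, n_atoms = n_atoms(r$molecule),
               N = r$N, n_a = r$n_a,
               Eg = p$Eg, Ec = p$Ec, Ev = p$Ev,
               Bv1 = p$Bv[1], Bv2 = p$Bv[2], Bv3 = p$Bv[3],
               mu = p$mu[1], mu_x = p$mu[2], mu_y = p$mu[3], mu_z = p$mu[4],
               alpha = p$alpha, R2 = p$R2,
               zpve_J = p$zpve[1], zpve_kcal = p$zpve[2],
               e_zpe = p$e_zpe, e_tot = p$e_tot, e_h = p$e_h, e_g = p$e_g,
               Cv = p$Cv)
  })
  do.call(rbind, rows)
}
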