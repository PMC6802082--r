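# Electric-dipole selection rules: a transition psi_i -> psi_j driven by the
# transition-moment operator mu is allowed (bright) iff the direct product
# psi_i (x) mu (x) psi_j contains the totally symmetric irrep, i.e. iff
# a_1 = (1/h) sum_R chi_i(R) chi_mu(R) chi_j(R) >= 1.

.pol_axes <- function(polarization) {
  switch(polarization,
         x = "x", y = "y", z = "z",
         xy = c("x", "y"),
         any = c("x", "y", "z"),
         stop("polarization must be one of x, y, z, xy, any", call. = FALSE))
}

# multiplicity of the totally symmetric irrep in psi_i (x) mu (x) psi_j,
# summed over conjugate-pair members of each factor
.ts_multiplicity <- function(group, chars_i, chars_mu, chars_j) {
  total <- 0L
  prod_chars <- NULL
  for (ci in chars_i) for (cm in chars_mu) for (cj in chars_j) {
    p <- direct_product(direct_product(ci, cm), cj)
    if (is.null(prod_chars)) prod_chars <- p else prod_chars <- prod_chars + p
    total <- total + as.integer(round(Re(sum(p)) / group$order))
  }
  list(multiplicity = total, product_characters = prod_chars)
}

#' Is an orbital transition electric-dipole allowed?
#'
#' Computes the direct product of the initial-orbital, dipole-operator and
#' final-orbital characters and reduces it; the transition is bright iff
#' the totally symmetric irrep appears for at least one requested
#' polarization. Conjugate-pair labels ("Eu", "E'") are expanded into both
#' members and the transition is allowed if any member combination is.
#'
#' @param group group name or `qmsym_group`.
#' @param from,to irrep labels of the initial and final orbitals
#'   (case-insensitive; file-style "BU" accepted).
#' @param polarization "x", "y", "z", "xy" (in-plane) or "any".
#' @return object of class `qmsym_transition`: `allowed`,
#'   `totally_symmetric_multiplicity`, `per_polarization` (x/y/z logical),
#'   `product_characters` (for the requested polarization set).
#' @export
transition_allowed <- function(group, from, to, polarization = "any") {
  group <- .as_group(group)
  axes <- .pol_axes(polarization)
  chars_i <- resolve_irrep_members(group, from)
  chars_j <- resolve_irrep_members(group, to)
  per_pol <- c(x = NA, y = NA, z = NA)
  mults <- c(x = 0L, y = 0L, z = 0L)
  prod_chars <- NULL
  for (ax in c("x", "y", "z")) {
    mu_labels <- group$dipole[[ax]]
    chars_mu <- lapply(mu_labels, function(l) group$irreps[[l]]$characters)
    r <- .ts_multiplicity(group, chars_i, chars_mu, chars_j)
    mults[[ax]] <- r$multiplicity
    per_pol[[ax]] <- r$multiplicity >= 1L
    if (ax %in% axes) {
      prod_chars <- if (is.null(prod_chars)) r$product_characters else
        prod_chars + r$product_characters
    }
  }
  structure(list(group = group$name, from = from, to = to,
                 polarization = polarization,
                 allowed = any(per_pol[axes]),
                 totally_symmetric_multiplicity = max(mults[axes]),
                 per_polarization = per_pol,
                 product_characters = prod_chars),
            class = "qmsym_transition")
}

#' @export
print.qmsym_transition <- function(x, ...) {
  cat(sprintf("%s -> %s (%s, polarization %s): %s\n", x$from, x$to, x$group,
              x$polarization, if (x$allowed) "bright" else "dark"))
  cat("per polarization: ",
      paste(names(x$per_polarization), ifelse(x$per_polarization, "bright",
                                              "dark"), sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

# offset labels for levels ordered low -> high energy
.occupied_labels <- function(deg) {
  # last level is the HOMO; a level's offset is the number of orbitals
  # above it in the occupied block (degeneracy-weighted), so a level below
  # a doubly degenerate HOMO is HOMO-2
  m <- length(deg)
  off <- rev(cumsum(c(0, rev(deg)[-m])))
  ifelse(off == 0, "HOMO", paste0("HOMO-", off))
}

.virtual_labels <- function(deg) {
  off <- c(0, cumsum(deg))[seq_along(deg)]
  ifelse(off == 0, "LUMO", paste0("LUMO+", off))
}

#' Bright/dark classification of all frontier transitions in a record
#'
#' Evaluates [transition_allowed()] for every occupied -> virtual level pair
#' in the record's orbital window. Degenerate orbitals share one level and
#' one classification.
#'
#' @param record a `qmsym_record` with populated orbital blocks.
#' @return data.frame with columns `from`, `to` (offset labels such as
#'   "HOMO-2", "LUMO"), `from_irrep`, `to_irrep`, `xy` and `z` (bright per
#'   polarization class) and `allowed`.
#' @export
bright_transitions <- function(record) {
  orb <- record$orbitals
  if (is.null(orb) || !nrow(orb$occupied) || !nrow(orb$virtual)) {
    if (is.null(orb) || !nrow(orb$occupied)) {
      stop("record lacks orbital symmetry labels", call. = FALSE)
    }
    return(data.frame(from = character(0), to = character(0),
                      from_irrep = character(0), to_irrep = character(0),
                      xy = logical(0), z = logical(0), allowed = logical(0)))
  }
  group <- build_group(record$group)
  occ <- orb$occupied
  vir <- orb$virtual
  occ$offset <- .occupied_labels(occ$degeneracy)
  vir$offset <- .virtual_labels(vir$degeneracy)
  rows <- list()
  for (i in rev(seq_len(nrow(occ)))) for (j in seq_len(nrow(vir))) {
    t_xy <- transition_allowed(group, occ$label[i], vir$label[j], "xy")
    t_z <- transition_allowed(group, occ$label[i], vir$label[j], "z")
    rows[[length(rows) + 1L]] <- data.frame(
      from = occ$offset[i], to = vir$offset[j],
      from_irrep = occ$label[i], to_irrep = vir$label[j],
      xy = t_xy$allowed, z = t_z$allowed,
      allowed = t_xy$allowed || t_z$allowed)
  }
  do.call(rbind, rows)
}

#' Exhaustive transition table for a group
#'
#' All (initial irrep, final irrep, polarization class) combinations with
#' their bright/dark flags; symmetric under swapping initial and final.
#' Conjugate pairs appear once under their merged label.
#'
#' @param group group name or `qmsym_group`.
#' @return data.frame with columns `from`, `to`, `polarization`
#'   ("xy" or "z") and `allowed`.
#' @export
transition_table <- function(group) {
  group <- .as_group(group)
  labs <- unique(vapply(group$irreps, function(ir) {
    if (is.na(ir$pair)) ir$label else ir$pair
  }, ""))
  out <- expand.grid(from = labs, to = labs, polarization = c("xy", "z"),
                     stringsAsFactors = FALSE)
  out$allowed <- mapply(function(f, t, p) {
    transition_allowed(group, f, t, p)$allowed
  }, out$from, out$to, out$polarization)
  out
}
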