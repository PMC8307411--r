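# Perception of atom parity from wedge/hash bonds and of double-bond
# cis/trans geometry from 2D coordinates.

GEOM_TOL <- 1e-6

ATOMIC_NUMBER <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Si = 14,
  P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Fe = 26, Cu = 29, Zn = 30,
  Se = 34, Br = 35, I = 53, R = 0
)

.atomic_number <- function(el) {
  z <- ATOMIC_NUMBER[el]
  z[is.na(z)] <- 0
  unname(z)
}

#' Perceive atom parity from wedge bonds
#'
#' For every stereocenter candidate (an atom with at least three distinct
#' non-hydrogen neighbors and at least one wedge or hash bond whose narrow
#' end sits at the atom), parity is computed from the signed orientation of
#' its neighbors, ordered by atom index, with the wedged neighbor lifted out
#' of the drawing plane (up = towards the viewer).  Candidates without any
#' wedge information get parity `"unknown"` rather than `"none"`.  A wedge
#' bond whose narrow end is not at the candidate atom is ignored with a
#' warning and the parity left `"unknown"`.
#'
#' A reflection of the 2D coordinates flips every perceived parity.
#'
#' @param mol A [molecule()] with 2D coordinates.
#' @return The molecule with `atoms$parity` filled in.
#' @export
assign_atom_parity <- function(mol) {
  hc <- hydrogen_counts(mol)
  is_h <- mol$atoms$element == "H"
  for (i in seq_len(n_atoms(mol))) {
    if (is_h[i]) next
    nbr <- neighbors_of(mol, i)
    heavy_nbr <- sort(nbr[!is_h[nbr]])
    if (length(heavy_nbr) < 3L) next
    # wedge bonds incident to i; narrow end is at bonds$a by convention
    binc <- which((mol$bonds$a == i | mol$bonds$b == i) & mol$bonds$wedge != "none")
    if (length(binc) == 0L) {
      mol$atoms$parity[i] <- "unknown"
      next
    }
    at_i <- binc[mol$bonds$a[binc] == i]
    if (length(at_i) == 0L) {
      warning(sprintf(
        "wedge bond at atom %d has its narrow end elsewhere; parity left unknown", i
      ), call. = FALSE)
      mol$atoms$parity[i] <- "unknown"
      next
    }
    k <- at_i[1L]
    wnbr <- mol$bonds$b[k]
    zlift <- if (mol$bonds$wedge[k] == "up") 1 else -1
    use <- heavy_nbr
    if (!(wnbr %in% use)) use <- sort(c(heavy_nbr, wnbr))
    v <- lapply(use, function(j) c(
      mol$atoms$x[j] - mol$atoms$x[i],
      mol$atoms$y[j] - mol$atoms$y[i],
      if (j == wnbr) zlift else 0
    ))
    d <- if (length(use) == 3L) {
      det(rbind(v[[1L]], v[[2L]], v[[3L]]))
    } else {
      det(rbind(v[[2L]] - v[[1L]], v[[3L]] - v[[1L]], v[[4L]] - v[[1L]]))
    }
    mol$atoms$parity[i] <-
      if (abs(d) < GEOM_TOL) "unknown" else if (d > 0) "ccw" else "cw"
  }
  mol
}

# rank substituent priority: higher atomic number first, then the richer
# one-iteration neighborhood string; returns a sortable key (larger = higher
# priority) or marks ties
.substituent_key <- function(mol, root, exclude) {
  z <- .atomic_number(mol$atoms$element[root])
  env <- one_bond_color(mol, root)
  sprintf("%03d|%s", as.integer(z), env)
}

#' Classify the cis/trans geometry of a double bond
#'
#' Priority is assigned to the substituent groups on each end of the double
#' bond: a lone substituent is prioritized outright, otherwise groups are
#' ranked by atomic number and then local neighborhood.  The drawing plane is
#' split by the line through the two double-bond atoms; if the prioritized
#' groups fall on the same side the bond is cis, otherwise trans.  The method
#' works for heteroatom double bonds such as C=N, not only C=C.
#'
#' @param mol A [molecule()].
#' @param bond Row index into `mol$bonds`, or a length-2 vector of atom
#'   indices.
#' @return `"cis"`, `"trans"`, `"none"` (no stereoisomerism possible or the
#'   substituents are priority-equivalent) or `"unresolved"` (a prioritized
#'   substituent lies on the dividing line within tolerance).
#' @export
classify_double_bond <- function(mol, bond) {
  if (length(bond) == 2L) bond <- bond_between(mol, bond[1L], bond[2L])
  if (length(bond) != 1L || is.na(bond)) {
    mh_precondition_error("bond not found")
  }
  if (mol$bonds$order[bond] != "2") {
    mh_precondition_error("cis/trans classification requires a double bond")
  }
  u <- mol$bonds$a[bond]; v <- mol$bonds$b[bond]
  is_h <- mol$atoms$element == "H"
  pick <- function(end, other) {
    subs <- setdiff(neighbors_of(mol, end), other)
    subs <- subs[!is_h[subs]]
    if (length(subs) == 0L) return(NA_integer_)
    if (length(subs) == 1L) return(subs)
    keys <- vapply(subs, function(s) .substituent_key(mol, s, end), character(1))
    best <- which(keys == max(keys))
    if (length(best) > 1L) return(-1L)  # priority-equivalent
    subs[best]
  }
  su <- pick(u, v); sv <- pick(v, u)
  if (is.na(su) || is.na(sv)) return("none")
  if (su == -1L || sv == -1L) return("none")
  # signed side of the line through u -> v
  dx <- mol$atoms$x[v] - mol$atoms$x[u]
  dy <- mol$atoms$y[v] - mol$atoms$y[u]
  side <- function(s) {
    dx * (mol$atoms$y[s] - mol$atoms$y[u]) - dy * (mol$atoms$x[s] - mol$atoms$x[u])
  }
  cu <- side(su); cv <- side(sv)
  scale <- sqrt(dx^2 + dy^2)
  if (abs(cu) < GEOM_TOL * max(1, scale) || abs(cv) < GEOM_TOL * max(1, scale)) {
    message(sprintf("substituent colinear with double bond %d-%d; unresolved", u, v))
    return("unresolved")
  }
  if (sign(cu) == sign(cv)) "cis" else "trans"
}

#' Label every double bond of a molecule with its cis/trans geometry
#'
#' @param mol A [molecule()].
#' @return The molecule with `bonds$cis_trans` filled in (`"none"` where no
#'   stereoisomerism is possible).
#' @export
assign_double_bond_stereo <- function(mol) {
  dbl <- which(mol$bonds$order == "2")
  for (k in dbl) {
    mol$bonds$cis_trans[k] <- classify_double_bond(mol, k)
  }
  mol
}
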