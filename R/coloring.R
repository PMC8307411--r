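# Neighborhood-specific graph coloring.
#
# Every heavy atom receives an iteratively refined color string: the base
# invariant is the element plus charge plus hydrogen-count annotation (plus
# stereo descriptors in detailed mode); each refinement round appends the
# sorted list of (bond token, neighbor color) terms.  Refinement stops when
# the partition of atoms into color classes is stable across one round,
# capped at the atom count, so equal final strings imply equal rooted
# neighborhoods out to the stabilization depth.  Automorphic atoms always
# receive identical colors and the result is independent of input atom order.

.base_invariant <- function(view, mode) {
  el <- view$atoms$element
  chg <- view$atoms$charge
  hc <- attr(view, "hcount")
  base <- paste0(
    el,
    ifelse(chg != 0L, sprintf("%+d", chg), ""),
    "H", hc
  )
  if (mode == "detailed") {
    par <- view$atoms$parity
    base <- paste0(base, ifelse(par %in% c("cw", "ccw"), paste0("@", par), ""))
  }
  base
}

.bond_token <- function(view, mode) {
  tok <- view$bonds$order
  if (mode == "detailed") {
    ct <- view$bonds$cis_trans
    tok <- paste0(tok, ifelse(ct %in% c("cis", "trans"), paste0("/", ct), ""))
  }
  tok
}

#' Color every atom by its chemical neighborhood
#'
#' Computes neighborhood-specific colors for the hydrogen-suppressed graph.
#' In `"loose"` mode the base invariant is element + charge + hydrogen count;
#' `"detailed"` mode additionally layers in atom parity and double-bond
#' cis/trans labels, so stereoisomers separate.
#'
#' @param mol A [molecule()].
#' @param mode `"loose"` or `"detailed"`.
#' @return `data.frame` with columns `atom_index` (original 1-based index),
#'   `color` and `depth` (refinement iterations used).
#' @export
color_atoms <- function(mol, mode = c("loose", "detailed")) {
  mode <- match.arg(mode)
  view <- suppressed_view(mol)
  orig <- attr(view, "orig_index")
  n <- n_atoms(view)
  adj <- adjacency(view)
  btok <- .bond_token(view, mode)
  color <- base <- .base_invariant(view, mode)
  depth <- 0L
  nclass <- length(unique(color))
  for (it in seq_len(max(1L, n))) {
    nxt <- vapply(seq_len(n), function(i) {
      nb <- adj[[i]]
      if (nrow(nb) == 0L) return(base[i])
      terms <- sort(paste0("(", btok[nb$bond], ":", color[nb$nbr], ")"))
      paste0(base[i], paste(terms, collapse = ""))
    }, character(1))
    depth <- it
    ncl <- length(unique(nxt))
    stable <- ncl == nclass
    color <- nxt
    nclass <- ncl
    if (stable) break
  }
  data.frame(atom_index = orig, color = color, depth = depth,
             stringsAsFactors = FALSE)
}

#' Compound coloring identifier
#'
#' A canonical string identifier for a molecule: a molecular-formula header
#' followed by the sorted multiset of final atom colors.  Isomorphic
#' molecules receive bit-identical identifiers regardless of atom order.  The
#' loose identifier ignores all stereo descriptors; the detailed identifier
#' changes whenever any atom parity or double-bond cis/trans label changes.
#'
#' @param mol A [molecule()].
#' @param mode `"loose"` or `"detailed"`.
#' @return An object of class `"compound_identifier"`: a string with
#'   attribute `mode`.
#' @export
compound_identifier <- function(mol, mode = c("loose", "detailed")) {
  mode <- match.arg(mode)
  colors <- color_atoms(mol, mode)$color
  value <- paste0(formula_string(mol), "|", paste(sort(colors), collapse = "|"))
  structure(value, mode = mode, class = "compound_identifier")
}

#' One-bond atom color
#'
#' The atom identifier derived from a single refinement iteration: the
#' element followed by the sorted list of `(bond order : neighbor element)`
#' terms over heavy neighbors.  Hydrogen counts and charges are excluded so
#' the color is robust to explicit-hydrogen and protonation differences
#' between databases.  The one-bond color of an atom changes exactly when a
#' bond incident to it is made, broken or changes order, which is what makes
#' it the building block of the mapping-consistency metric.
#'
#' @param mol A [molecule()].
#' @param atom_index 1-based original atom index (vectorized).
#' @return Character vector of colors.
#' @export
one_bond_color <- function(mol, atom_index) {
  is_h <- mol$atoms$element == "H"
  vapply(atom_index, function(i) {
    if (i < 1L || i > n_atoms(mol)) mh_precondition_error("atom index out of range")
    b <- mol$bonds
    inc <- which((b$a == i | b$b == i))
    terms <- character(0)
    for (k in inc) {
      j <- if (b$a[k] == i) b$b[k] else b$a[k]
      if (is_h[j]) next
      terms <- c(terms, paste0("(", b$order[k], ":", mol$atoms$element[j], ")"))
    }
    paste0(mol$atoms$element[i], paste(sort(terms), collapse = ""))
  }, character(1))
}

#' Partition heavy atoms into symmetry classes
#'
#' Atoms with identical final loose colors are grouped together.  The
#' refinement partition is never finer than the true automorphism orbits on
#' small graphs; on pathological regular graphs it may merge non-automorphic
#' atoms, which is accepted and bounded by brute-force oracles in the tests.
#'
#' @param mol A [molecule()].
#' @return List of integer vectors of original atom indices (heavy atoms
#'   only), ordered by smallest member.
#' @export
symmetry_classes <- function(mol) {
  col <- color_atoms(mol, "loose")
  cl <- split(col$atom_index, col$color)
  cl <- cl[order(vapply(cl, min, integer(1)))]
  names(cl) <- NULL
  lapply(cl, as.integer)
}

#' Export compound identifiers as TSV
#'
#' @param mols Named list of molecules.
#' @param file Output path.
#' @param mode `"loose"`, `"detailed"` or both.
#' @return Invisibly, the written data.frame.
#' @export
write_identifier_tsv <- function(mols, file, mode = c("loose", "detailed")) {
  rows <- do.call(rbind, lapply(mols, function(m) {
    do.call(rbind, lapply(mode, function(md) {
      data.frame(compound_id = m$id, mode = md,
                 identifier = as.character(compound_identifier(m, md)),
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
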