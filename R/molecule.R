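# Molecular graph container.
#
# A molecule is a labeled graph over the atoms of a connection table.  Atom
# indices are 1-based and follow molfile atom-block order everywhere.  Bond
# orders are kept as character codes "1", "2", "3" and "a" (aromatic, molfile
# order code 4).  Explicit hydrogens are parsed and stored; all matching and
# coloring operates on the hydrogen-suppressed view with a per-heavy-atom
# hydrogen count annotation.

R_GROUP_SYMBOLS <- c("R", "R#", "*", "A", "X", "Q")

PARITY_LEVELS <- c("none", "cw", "ccw", "unknown")

#' Construct a molecule
#'
#' @param id Compound identifier string.
#' @param atoms `data.frame` with one row per atom: `element` (symbol, `"R"`
#'   for generic placeholders, `"H"` for explicit hydrogen), `charge`
#'   (integer), `x`, `y` (2D coordinates), `parity` (one of `"none"`, `"cw"`,
#'   `"ccw"`, `"unknown"`), `kegg_type` (opaque KEGG atom-type label or `NA`),
#'   `is_r` (logical).  Missing columns are filled with defaults.
#' @param bonds `data.frame` with columns `a`, `b` (1-based atom indices),
#'   `order` (`"1"`, `"2"`, `"3"`, `"a"`), `wedge` (`"none"`, `"up"`,
#'   `"down"`), `cis_trans` (`"none"`, `"cis"`, `"trans"`, `"unresolved"`).
#' @param source Either `"molfile"` or `"kcf"`.
#' @return An object of class `"molecule"`.
#' @export
molecule <- function(id, atoms, bonds = NULL, source = "molfile") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  n <- nrow(atoms)
  if (n == 0L) mh_structural_error("molecule must contain at least one atom")
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$x)) atoms$x <- 0
  if (is.null(atoms$y)) atoms$y <- 0
  if (is.null(atoms$parity)) atoms$parity <- "none"
  if (is.null(atoms$kegg_type)) atoms$kegg_type <- NA_character_
  atoms$element <- as.character(atoms$element)
  r_flag <- atoms$element %in% R_GROUP_SYMBOLS
  atoms$element[r_flag] <- "R"
  atoms$is_r <- atoms$element == "R"
  atoms$charge <- as.integer(atoms$charge)
  rownames(atoms) <- NULL

  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(
      a = integer(), b = integer(), order = character(),
      wedge = character(), cis_trans = character(),
      stringsAsFactors = FALSE
    )
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    if (is.null(bonds$wedge)) bonds$wedge <- "none"
    if (is.null(bonds$cis_trans)) bonds$cis_trans <- "none"
    bonds$a <- as.integer(bonds$a)
    bonds$b <- as.integer(bonds$b)
    bonds$order <- as.character(bonds$order)
    if (any(bonds$a == bonds$b)) {
      mh_structural_error("bond with identical endpoints")
    }
    if (any(bonds$a < 1L | bonds$a > n | bonds$b < 1L | bonds$b > n)) {
      mh_structural_error(sprintf(
        "bond references a missing atom index (molecule has %d atoms)", n
      ))
    }
    key <- paste(pmin(bonds$a, bonds$b), pmax(bonds$a, bonds$b))
    if (anyDuplicated(key)) mh_structural_error("duplicate bond")
    if (any(bonds$cis_trans != "none" & bonds$order != "2")) {
      mh_structural_error("cis/trans label on a non-double bond")
    }
    rownames(bonds) <- NULL
  }

  structure(
    list(id = as.character(id), atoms = atoms, bonds = bonds, source = source),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  f <- mol_formula(x)
  cat(sprintf(
    "<molecule %s: %d atoms, %d bonds, %s>\n",
    x$id, nrow(x$atoms), nrow(x$bonds),
    paste0(names(f), f, collapse = "")
  ))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

#' Molecular formula
#'
#' Counts each element separately; explicit hydrogens count towards `H` and
#' R-group placeholders towards `R`.
#'
#' @param mol A [molecule()].
#' @return Named integer vector, names sorted alphabetically.
#' @export
mol_formula <- function(mol) {
  tab <- table(mol$atoms$element)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(names(out))]
}

formula_string <- function(mol) {
  f <- mol_formula(mol)
  paste0(names(f), f, collapse = "")
}

# Adjacency list: for atom i, a data.frame(nbr, order, bond) where `bond` is
# the row index into mol$bonds.
adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- rep(list(data.frame(nbr = integer(), order = character(),
                             bond = integer(), stringsAsFactors = FALSE)), n)
  if (nrow(mol$bonds) == 0L) return(adj)
  ends <- c(mol$bonds$a, mol$bonds$b)
  other <- c(mol$bonds$b, mol$bonds$a)
  ord <- rep(mol$bonds$order, 2L)
  bidx <- rep(seq_len(nrow(mol$bonds)), 2L)
  sp <- split(seq_along(ends), ends)
  for (k in names(sp)) {
    i <- sp[[k]]
    adj[[as.integer(k)]] <- data.frame(
      nbr = other[i], order = ord[i], bond = bidx[i], stringsAsFactors = FALSE
    )
  }
  adj
}

neighbors_of <- function(mol, i) {
  b <- mol$bonds
  c(b$b[b$a == i], b$a[b$b == i])
}

bond_between <- function(mol, i, j) {
  b <- mol$bonds
  which((b$a == i & b$b == j) | (b$a == j & b$b == i))
}

#' Explicit hydrogen counts per atom
#'
#' @param mol A [molecule()].
#' @return Integer vector over all atoms; hydrogens themselves get 0.
#' @export
hydrogen_counts <- function(mol) {
  n <- n_atoms(mol)
  hc <- integer(n)
  h <- which(mol$atoms$element == "H")
  if (length(h) == 0L) return(hc)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    if (b$a[k] %in% h && !(b$b[k] %in% h)) hc[b$b[k]] <- hc[b$b[k]] + 1L
    if (b$b[k] %in% h && !(b$a[k] %in% h)) hc[b$a[k]] <- hc[b$a[k]] + 1L
  }
  hc
}

heavy_indices <- function(mol, drop_r = FALSE) {
  keep <- mol$atoms$element != "H"
  if (drop_r) keep <- keep & !mol$atoms$is_r
  which(keep)
}

#' Restrict a molecule to a subset of its atoms
#'
#' Atom indices are renumbered 1..k in ascending order of `keep`; bonds with
#' an endpoint outside the subset are dropped.  The original indices are
#' returned in the attribute `"orig_index"`.
#'
#' @param mol A [molecule()].
#' @param keep Atom indices to retain.
#' @return A [molecule()].
#' @export
subset_molecule <- function(mol, keep) {
  keep <- sort(unique(as.integer(keep)))
  remap <- integer(n_atoms(mol))
  remap[keep] <- seq_along(keep)
  b <- mol$bonds
  bk <- b[b$a %in% keep & b$b %in% keep, , drop = FALSE]
  bk$a <- remap[bk$a]
  bk$b <- remap[bk$b]
  out <- molecule(mol$id, mol$atoms[keep, , drop = FALSE], bk, mol$source)
  attr(out, "orig_index") <- keep
  out
}

# Hydrogen-suppressed (optionally R-suppressed) view.
suppressed_view <- function(mol, drop_r = FALSE) {
  keep <- heavy_indices(mol, drop_r = drop_r)
  if (length(keep) == 0L) {
    mh_precondition_error("molecule is empty after suppression")
  }
  sub <- subset_molecule(mol, keep)
  attr(sub, "hcount") <- hydrogen_counts(mol)[keep]
  sub
}

# TRUE for bonds that lie on a cycle (removing the bond keeps its endpoints
# connected).
ring_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(logical(0))
  bb <- mol$bonds
  vapply(seq_len(nb), function(k) {
    a <- bb$a[k]; b <- bb$b[k]
    seen <- a
    queue <- a
    while (length(queue) > 0L) {
      cur <- queue[1L]; queue <- queue[-1L]
      use <- which(((bb$a == cur) | (bb$b == cur)) & seq_len(nb) != k)
      nbr <- ifelse(bb$a[use] == cur, bb$b[use], bb$a[use])
      new <- setdiff(nbr, seen)
      if (b %in% new) return(TRUE)
      seen <- c(seen, new)
      queue <- c(queue, new)
    }
    FALSE
  }, logical(1))
}
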