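# Synthetic-data generators with known ground truth.  All generators are
# deterministic per seed and produce chemically plausible (valence-
# respecting) connected molecular graphs with explicit hydrogens, so the
# tautomer and ring-chain validators can reason about hydrogen positions.
#
# Valence table used for generation: C 4, N 3, O 2, S 2, P 5, H 1, R 1.

VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 5L, H = 1L, R = 1L)

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards.
#'
#' @param seed Integer seed (`NULL` = leave RNG alone).
#' @param code Expression to evaluate.
#' @export
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- .GlobalEnv$.Random.seed
    set.seed(seed)
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    })
  }
  force(code)
}

.bond_order_sum <- function(order) sum(as.integer(order))

#' Add explicit hydrogens to fill standard valences
#'
#' @param mol A [molecule()] without explicit hydrogens.
#' @return The molecule with H atoms appended (file order preserved for the
#'   heavy atoms).
#' @export
fill_hydrogens <- function(mol) {
  atoms <- mol$atoms
  bonds <- mol$bonds
  n <- nrow(atoms)
  for (i in seq_len(n)) {
    el <- atoms$element[i]
    if (el == "H" || !(el %in% names(VALENCE))) next
    inc <- which(bonds$a == i | bonds$b == i)
    used <- if (length(inc) > 0L) .bond_order_sum(bonds$order[inc]) else 0L
    nh <- VALENCE[[el]] - used - abs(atoms$charge[i])
    if (nh <= 0L) next
    for (k in seq_len(nh)) {
      atoms <- rbind(atoms, data.frame(
        element = "H", charge = 0L, x = atoms$x[i] + 0.2 * k, y = atoms$y[i] - 0.2,
        parity = "none", kegg_type = NA_character_, is_r = FALSE,
        stringsAsFactors = FALSE
      ))
      bonds <- rbind(bonds, data.frame(
        a = i, b = nrow(atoms), order = "1", wedge = "none", cis_trans = "none",
        stringsAsFactors = FALSE
      ))
    }
  }
  molecule(mol$id, atoms, bonds, mol$source)
}

#' Randomly permute the atom order of a molecule
#'
#' @param mol A [molecule()].
#' @param perm Optional permutation (`perm[i]` = new index of old atom `i`);
#'   random when omitted.
#' @return The relabeled molecule, with attribute `"perm"`.
#' @export
permute_molecule <- function(mol, perm = NULL) {
  n <- n_atoms(mol)
  if (is.null(perm)) perm <- sample.int(n)
  atoms <- mol$atoms
  atoms[perm, ] <- mol$atoms
  b <- mol$bonds
  b$a <- perm[b$a]; b$b <- perm[b$b]
  out <- molecule(mol$id, atoms, b, mol$source)
  attr(out, "perm") <- perm
  out
}

#' Generate a random connected molecule
#'
#' Builds a random valence-respecting tree of heavy atoms (occasional double
#' bonds), optionally appends R-group placeholder atoms, and fills the open
#' valences with explicit hydrogens.  Coordinates are laid out on a grid.
#'
#' @param size Number of heavy atoms (excluding R and H).
#' @param seed Optional seed (generation is deterministic per seed).
#' @param id Compound id.
#' @param p_double Probability of attempting a double bond at each attach.
#' @param n_r Number of R atoms to append.
#' @param add_h Fill open valences with explicit hydrogens.
#' @param ensure_branch Force atom 1 to carry three heavy neighbors (used to
#'   plant stereocenters); requires `size >= 4`.
#' @param elements Sampling weights for heavy elements.
#' @return A [molecule()].
#' @export
gen_molecule <- function(size, seed = NULL, id = "mol", p_double = 0.15,
                         n_r = 0L, add_h = TRUE, ensure_branch = FALSE,
                         elements = c(C = 0.65, N = 0.15, O = 0.15, S = 0.05)) {
  if (size < 1L) mh_precondition_error("size must be >= 1")
  with_seed(seed, {
    for (attempt in 1:50) {
      el <- c("C", sample(names(elements), size - 1L, replace = TRUE,
                          prob = elements))
      if (ensure_branch && size >= 4L) el[1:4] <- "C"
      free <- unname(VALENCE[el])
      bonds <- data.frame(a = integer(), b = integer(), order = character(),
                          stringsAsFactors = FALSE)
      ok <- TRUE
      for (i in seq_len(size)[-1]) {
        if (ensure_branch && i <= 4L) {
          j <- 1L
          if (free[j] < 1L) { ok <- FALSE; break }
          ord <- 1L
        } else {
          cand <- which(free[seq_len(i - 1L)] >= 1L)
          if (length(cand) == 0L) { ok <- FALSE; break }
          j <- if (length(cand) == 1L) cand else sample(cand, 1L)
          ord <- if (stats::runif(1) < p_double && free[j] >= 2L &&
                     free[i] >= 2L) 2L else 1L
        }
        bonds <- rbind(bonds, data.frame(a = j, b = i, order = as.character(ord),
                                         stringsAsFactors = FALSE))
        free[j] <- free[j] - ord; free[i] <- free[i] - ord
      }
      if (!ok) next
      if (n_r > 0L) {
        spots <- which(free >= 1L)
        if (length(spots) < n_r) next
        for (k in seq_len(n_r)) {
          spots <- which(free >= 1L)
          j <- if (length(spots) == 1L) spots else sample(spots, 1L)
          el <- c(el, "R")
          free[j] <- free[j] - 1L
          free <- c(free, 0L)
          bonds <- rbind(bonds, data.frame(a = j, b = length(el), order = "1",
                                           stringsAsFactors = FALSE))
        }
      }
      n <- length(el)
      atoms <- data.frame(
        element = el, charge = 0L,
        x = (seq_len(n) - 1L) %% 6, y = (seq_len(n) - 1L) %/% 6,
        parity = "none", kegg_type = NA_character_, stringsAsFactors = FALSE
      )
      mol <- molecule(id, atoms, bonds)
      if (add_h) mol <- fill_hydrogens(mol)
      return(mol)
    }
    mh_structural_error("failed to generate a valence-respecting molecule")
  })
}

#' Annotate a molecule with synthetic KEGG-style atom types
#'
#' Heavy atoms receive labels of the form element + heavy degree + letter,
#' where the letter distinguishes different one-bond chemical environments
#' within the same element/degree group — a deliberately simplified analog
#' of the KEGG atom-type scheme, sufficient for exercising RDM-based
#' mapping.
#'
#' @param mol A [molecule()].
#' @return The molecule with `atoms$kegg_type` filled for heavy atoms.
#' @export
assign_kegg_types <- function(mol) {
  is_h <- mol$atoms$element == "H"
  heavy <- which(!is_h)
  hdeg <- vapply(heavy, function(i) {
    sum(!is_h[neighbors_of(mol, i)])
  }, integer(1))
  obc <- one_bond_color(mol, heavy)
  grp <- paste0(mol$atoms$element[heavy], hdeg)
  type <- character(length(heavy))
  for (g in unique(grp)) {
    rows <- which(grp == g)
    lv <- sort(unique(obc[rows]))
    type[rows] <- paste0(g, letters[match(obc[rows], lv)])
  }
  mol$atoms$kegg_type[heavy] <- type
  mol
}

# ---------------------------------------------------------------------------
# planted compound pairs

.singleton_symmetry <- function(mol) {
  all(vapply(symmetry_classes(mol), length, integer(1)) == 1L)
}

# stereocenter = atom with >= 3 heavy neighbors in a singleton symmetry class
.find_stereocenter <- function(mol) {
  is_h <- mol$atoms$element == "H"
  cls <- symmetry_classes(mol)
  singles <- unlist(cls[vapply(cls, length, integer(1)) == 1L])
  for (i in singles) {
    if (sum(!is_h[neighbors_of(mol, i)]) >= 3L) return(i)
  }
  NA_integer_
}

.gen_with_stereocenter <- function(size, id) {
  for (k in 1:60) {
    m <- gen_molecule(size, id = id, ensure_branch = TRUE, p_double = 0)
    sc <- .find_stereocenter(m)
    if (!is.na(sc)) return(list(mol = m, center = sc))
  }
  mh_structural_error("could not plant a stereocenter")
}

# keto/enol tautomer pair over a shared heavy skeleton.  Returns a (keto:
# C=O with an alpha hydrogen) and b (enol: C=C with hydroxyl), hydrogens
# filled per form.
.gen_tautomer <- function(size, id_a, id_b) {
  for (k in 1:60) {
    base <- gen_molecule(size, id = "base", p_double = 0, add_h = FALSE,
                         elements = c(C = 0.8, N = 0.2))
    free <- unname(VALENCE[base$atoms$element])
    for (bi in seq_len(nrow(base$bonds))) {
      free[base$bonds$a[bi]] <- free[base$bonds$a[bi]] - 1L
      free[base$bonds$b[bi]] <- free[base$bonds$b[bi]] - 1L
    }
    p_cand <- which(base$atoms$element == "C" & free >= 2L)
    if (length(p_cand) == 0L) next
    p <- if (length(p_cand) == 1L) p_cand else sample(p_cand, 1L)
    atoms <- rbind(base$atoms, data.frame(
      element = c("C", "O"), charge = 0L, x = c(7, 8), y = c(7, 7),
      parity = "none", kegg_type = NA_character_, is_r = FALSE,
      stringsAsFactors = FALSE
    ))
    c1 <- nrow(base$atoms) + 1L; o <- c1 + 1L
    mk <- function(ord_pc1, ord_c1o, id) {
      b <- rbind(
        base$bonds[, c("a", "b", "order")],
        data.frame(a = c(p, c1), b = c(c1, o), order = c(ord_pc1, ord_c1o))
      )
      fill_hydrogens(molecule(id, atoms, b))
    }
    a <- mk("1", "2", id_a)   # keto form
    b <- mk("2", "1", id_b)   # enol form
    if (!.singleton_symmetry(a)) next
    return(list(a = a, b = b, p = p, c1 = c1, o = o, base = base))
  }
  mh_structural_error("could not plant a tautomer pair")
}

# linear aldose-like chain and its cyclic hemiacetal form
.gen_ring_chain <- function(id_ring, id_chain, n_c = 5L) {
  # chain C1..Cn, aldehyde O on C1, ring-closing hydroxyl O on C(n-1),
  # decorative hydroxyl on C2
  nc <- n_c
  el <- c(rep("C", nc), "O", "O", "O")  # o_cb (carbonyl), o_ring, o_dec
  o_cb <- nc + 1L; o_ring <- nc + 2L; o_dec <- nc + 3L
  close_c <- nc - 1L
  atoms <- data.frame(
    element = el, charge = 0L, x = seq_along(el), y = 0,
    parity = "none", kegg_type = NA_character_, stringsAsFactors = FALSE
  )
  chain <- data.frame(a = seq_len(nc - 1L), b = 2:nc, order = "1",
                      stringsAsFactors = FALSE)
  linear <- fill_hydrogens(molecule(id_chain, atoms, rbind(
    chain,
    data.frame(a = c(1L, close_c, 2L), b = c(o_cb, o_ring, o_dec),
               order = c("2", "1", "1"))
  )))
  ring <- fill_hydrogens(molecule(id_ring, atoms, rbind(
    chain,
    data.frame(a = c(1L, close_c, 2L, o_ring), b = c(o_cb, o_ring, o_dec, 1L),
               order = c("1", "1", "1", "1"))
  )))
  list(ring = ring, chain = linear, anomeric_c = 1L, o_carbonyl = o_cb,
       o_ring = o_ring)
}

#' Generate a planted compound pair
#'
#' Produces a pair of molecules realizing one of the harmonization pair
#' categories together with the expected validation outcome:
#' \describe{
#'   \item{equivalence}{the same structure with relabeled atoms}
#'   \item{generic_specific}{a terminal branch replaced by an R group in
#'     compound a (expected direction a to b)}
#'   \item{stereo_specific}{compound b carries an atom parity that a lacks
#'     (generic-specific through chemical details, direction a to b)}
#'   \item{loose}{conflicting parity planted at a unique stereocenter}
#'   \item{tautomer}{a keto/enol hydrogen shift applied to one form}
#'   \item{ring_chain}{a hemiacetal ring closure of a linear carbonyl form
#'     (a is the cyclic form, b the linear)}
#' }
#'
#' @param category Pair category (see Details).
#' @param seed Optional seed.
#' @param size Heavy-atom count of the base structure.
#' @param id_a,id_b Compound ids.
#' @return List with `a`, `b`, and `expected` (list of `kind`, `direction`,
#'   `origin`).
#' @export
gen_pair <- function(category = c("equivalence", "generic_specific",
                                  "stereo_specific", "loose", "tautomer",
                                  "ring_chain"),
                     seed = NULL, size = 7L, id_a = "cpd_a", id_b = "cpd_b") {
  category <- match.arg(category)
  with_seed(seed, {
    switch(category,
      equivalence = {
        a <- gen_molecule(size, id = id_a)
        b <- permute_molecule(a); b$id <- id_b
        list(a = a, b = b,
             expected = list(kind = "equivalence", direction = "none",
                             origin = "identifier"))
      },
      generic_specific = {
        for (k in 1:60) {
          b <- gen_molecule(size, id = id_b, p_double = 0,
                            elements = c(C = 0.6, N = 0.1, O = 0.2, S = 0.1))
          is_h <- b$atoms$element == "H"
          term <- which(!is_h & vapply(seq_len(n_atoms(b)), function(i) {
            sum(!is_h[neighbors_of(b, i)]) == 1L
          }, logical(1)) & b$atoms$element == "C")
          if (length(term) == 0L) next
          t <- if (length(term) == 1L) term else sample(term, 1L)
          # generic form: drop the branch atom (and its hydrogens), put an R
          # in its place
          hs <- neighbors_of(b, t)
          hs <- hs[b$atoms$element[hs] == "H"]
          keep <- setdiff(seq_len(n_atoms(b)), c(t, hs))
          a <- subset_molecule(b, keep)
          parent_old <- setdiff(neighbors_of(b, t), hs)
          parent <- match(parent_old, attr(a, "orig_index"))
          a$atoms <- rbind(a$atoms, data.frame(
            element = "R", charge = 0L, x = 9, y = 9, parity = "none",
            kegg_type = NA_character_, is_r = TRUE, stringsAsFactors = FALSE
          ))
          a$bonds <- rbind(a$bonds, data.frame(
            a = parent, b = nrow(a$atoms), order = "1", wedge = "none",
            cis_trans = "none", stringsAsFactors = FALSE
          ))
          a <- molecule(id_a, a$atoms, a$bonds)
          b2 <- permute_molecule(b); b2$id <- id_b
          return(list(a = a, b = b2,
                      expected = list(kind = "generic_specific",
                                      direction = "a_to_b",
                                      origin = "generic_validation")))
        }
        mh_structural_error("could not plant a generic pair")
      },
      stereo_specific = {
        g <- .gen_with_stereocenter(size, id_a)
        a <- g$mol
        b <- permute_molecule(a); b$id <- id_b
        b$atoms$parity[attr(b, "perm")[g$center]] <- "cw"
        list(a = a, b = b,
             expected = list(kind = "generic_specific", direction = "a_to_b",
                             origin = "identifier"))
      },
      loose = {
        g <- .gen_with_stereocenter(size, id_a)
        a <- g$mol
        a$atoms$parity[g$center] <- "cw"
        b <- permute_molecule(a); b$id <- id_b
        b$atoms$parity[attr(b, "perm")[g$center]] <- "ccw"
        list(a = a, b = b,
             expected = list(kind = "loose", direction = "none",
                             origin = "identifier"))
      },
      tautomer = {
        tp <- .gen_tautomer(size, id_a, id_b)
        b <- permute_molecule(tp$b); b$id <- id_b
        list(a = tp$a, b = b,
             expected = list(kind = "equivalence", direction = "none",
                             origin = "tautomer"))
      },
      ring_chain = {
        rc <- .gen_ring_chain(id_a, id_b, n_c = sample(4:6, 1L))
        b <- permute_molecule(rc$chain); b$id <- id_b
        a <- permute_molecule(rc$ring); a$id <- id_a
        list(a = a, b = b,
             expected = list(kind = "equivalence", direction = "none",
                             origin = "ring_chain"))
      }
    )
  })
}

#' Generate a planted non-pair (negative control)
#'
#' Perturbations that must be rejected by the validators:
#' \describe{
#'   \item{skeleton}{same formula, different heavy skeleton (a terminal atom
#'     re-attached elsewhere) — the tautomer validator must reject}
#'   \item{illegal_shift}{the double bond moved to a bond not adjacent to
#'     the original position — not a 1,3-hydrogen shift}
#'   \item{missing_hemiacetal}{ring form whose anomeric carbon lost its
#'     hydroxyl — the ring-chain validator finds no candidate bond}
#' }
#'
#' @param category Perturbation kind.
#' @param seed Optional seed.
#' @param size Heavy-atom count of the base structure.
#' @return List with `a`, `b` and `validator` (`"tautomer"` or
#'   `"ring_chain"`).
#' @export
gen_non_pair <- function(category = c("skeleton", "illegal_shift",
                                      "missing_hemiacetal"),
                         seed = NULL, size = 7L) {
  category <- match.arg(category)
  with_seed(seed, {
    switch(category,
      skeleton = {
        for (k in 1:80) {
          tp <- .gen_tautomer(size, "np_a", "np_b")
          a <- tp$a
          # move a terminal heavy atom of the base skeleton elsewhere in b
          sk <- rbind(tp$base$bonds[, c("a", "b", "order")],
                      data.frame(a = c(tp$p, tp$c1), b = c(tp$c1, tp$o),
                                 order = c("1", "2")))
          atoms <- a$atoms[a$atoms$element != "H", , drop = FALSE]
          deg <- tabulate(c(sk$a, sk$b), nbins = nrow(atoms))
          free <- unname(VALENCE[atoms$element]) -
            vapply(seq_len(nrow(atoms)), function(i) {
              inc <- which(sk$a == i | sk$b == i)
              if (length(inc)) .bond_order_sum(sk$order[inc]) else 0L
            }, integer(1))
          term <- which(deg == 1L & atoms$element == "C" &
                          seq_len(nrow(atoms)) <= nrow(tp$base$atoms))
          if (length(term) == 0L) next
          t <- term[1L]
          kb <- which(sk$a == t | sk$b == t)
          parent <- setdiff(c(sk$a[kb], sk$b[kb]), t)
          w_cand <- which(free >= 1L & seq_len(nrow(atoms)) != t &
                            seq_len(nrow(atoms)) != parent)
          if (length(w_cand) == 0L) next
          w <- w_cand[1L]
          sk2 <- sk[-kb, , drop = FALSE]
          sk2 <- rbind(sk2, data.frame(a = w, b = t, order = "1"))
          b <- fill_hydrogens(molecule("np_b", atoms, sk2))
          if (!identical(mol_formula(a), mol_formula(b))) next
          if (as.character(compound_identifier(.collapse_doubles(a), "loose")) ==
              as.character(compound_identifier(.collapse_doubles(b), "loose"))) next
          return(list(a = a, b = permute_molecule(b), validator = "tautomer"))
        }
        mh_structural_error("could not plant a skeleton-change non-pair")
      },
      illegal_shift = {
        for (k in 1:80) {
          tp <- .gen_tautomer(size, "np_a", "np_b")
          # the skeleton bijection must be unique once double bonds collapse,
          # otherwise a symmetric relabeling could legalize the shift
          if (!.singleton_symmetry(.collapse_doubles(tp$a))) next
          base <- tp$base
          # place the double bond on a base bond not touching the keto group
          free <- unname(VALENCE[base$atoms$element])
          for (bi in seq_len(nrow(base$bonds))) {
            free[base$bonds$a[bi]] <- free[base$bonds$a[bi]] - 1L
            free[base$bonds$b[bi]] <- free[base$bonds$b[bi]] - 1L
          }
          cand <- which(vapply(seq_len(nrow(base$bonds)), function(bi) {
            q1 <- base$bonds$a[bi]; q2 <- base$bonds$b[bi]
            free[q1] >= 1L && free[q2] >= 1L && q1 != tp$p && q2 != tp$p
          }, logical(1)))
          if (length(cand) == 0L) next
          bi <- cand[1L]
          bb <- rbind(base$bonds[, c("a", "b", "order")],
                      data.frame(a = c(tp$p, tp$c1), b = c(tp$c1, tp$o),
                                 order = c("1", "1")))
          bb$order[bi] <- "2"
          atoms <- tp$a$atoms[tp$a$atoms$element != "H", , drop = FALSE]
          b <- fill_hydrogens(molecule("np_b", atoms, bb))
          if (!identical(mol_formula(tp$a), mol_formula(b))) next
          return(list(a = tp$a, b = permute_molecule(b), validator = "tautomer"))
        }
        mh_structural_error("could not plant an illegal-shift non-pair")
      },
      missing_hemiacetal = {
        rc <- .gen_ring_chain("np_a", "np_b", n_c = sample(5:6, 1L))
        ring <- rc$ring
        # move the anomeric hydroxyl from C1 to C3
        o2 <- rc$o_carbonyl
        b <- ring$bonds
        kb <- which((b$a == rc$anomeric_c & b$b == o2) |
                      (b$b == rc$anomeric_c & b$a == o2))
        b$a[kb] <- 3L; b$b[kb] <- o2
        atoms <- ring$atoms[ring$atoms$element != "H", , drop = FALSE]
        b <- b[b$a <= nrow(atoms) & b$b <= nrow(atoms), , drop = FALSE]
        bad_ring <- fill_hydrogens(molecule("np_a", atoms, b))
        list(a = bad_ring, b = rc$chain, validator = "ring_chain")
      }
    )
  })
}

# ---------------------------------------------------------------------------
# planted reactions with atom mappings

#' Generate a substrate/product pair with a ground-truth RDM mapping
#'
#' The substrate is a random asymmetric molecule (all symmetry classes are
#' singletons); the product is the substrate with `n_center_edits` terminal
#' branches removed.  The emitted RDM descriptions are consistent with the
#' edits (reaction center = the branch attachment atom, difference region =
#' the removed branch's atom type) and the ground-truth atom mapping is
#' recorded.  Product atoms are randomly relabeled.
#'
#' @param seed Optional seed.
#' @param n_center_edits Number of planted branch removals (>= 1).
#' @param size Heavy-atom count of the substrate.
#' @return List with `substrate`, `product`, `rdms`, `truth`
#'   (`data.frame(atom_a, atom_b)`), `centers` (substrate-side center
#'   atoms).
#' @export
gen_reaction_with_mapping <- function(seed = NULL, n_center_edits = 1L,
                                      size = 9L) {
  if (n_center_edits < 1L) {
    mh_precondition_error("n_center_edits must be >= 1")
  }
  with_seed(seed, {
    for (attempt in 1:200) {
      s <- gen_molecule(size, id = "sub", add_h = FALSE, p_double = 0.1)
      if (!.singleton_symmetry(s)) next
      s <- assign_kegg_types(s)
      deg <- tabulate(c(s$bonds$a, s$bonds$b), nbins = n_atoms(s))
      term <- which(deg == 1L)
      if (length(term) < n_center_edits) next
      # choose edits with distinct parents whose other neighbors do not
      # share the removed branch's atom type (so difference-region bond
      # removal is unambiguous)
      picks <- list()
      used_parents <- integer(0)
      for (t in term[sample.int(length(term))]) {
        parent <- neighbors_of(s, t)
        if (parent %in% used_parents) next
        sib <- setdiff(neighbors_of(s, parent), t)
        if (any(s$atoms$kegg_type[sib] == s$atoms$kegg_type[t])) next
        if (length(candidate_centers(s, s$atoms$kegg_type[parent])) != 1L) next
        picks[[length(picks) + 1L]] <- c(t = t, parent = parent)
        used_parents <- c(used_parents, parent)
        if (length(picks) == n_center_edits) break
      }
      if (length(picks) < n_center_edits) next
      ts <- vapply(picks, `[[`, integer(1), "t")
      parents <- vapply(picks, `[[`, integer(1), "parent")
      keep <- setdiff(seq_len(n_atoms(s)), ts)
      p <- subset_molecule(s, keep)
      p$id <- "prod"
      p$atoms$kegg_type <- NA_character_
      p <- assign_kegg_types(p)
      porig <- attr(p, "orig_index")
      if (any(vapply(parents, function(c_at) {
        lab <- p$atoms$kegg_type[match(c_at, porig)]
        length(candidate_centers(p, lab)) != 1L
      }, logical(1)))) next
      perm <- sample.int(n_atoms(p))
      p2 <- permute_molecule(p, perm)
      p2$id <- "prod"
      truth <- data.frame(atom_a = keep, atom_b = perm[match(keep, porig)])
      rdms <- lapply(seq_along(parents), function(i) {
        c_at <- parents[i]; t_at <- ts[i]
        sib <- setdiff(neighbors_of(s, c_at), t_at)
        structure(list(
          center = c(substrate = s$atoms$kegg_type[c_at],
                     product = p$atoms$kegg_type[match(c_at, porig)]),
          diff_s = s$atoms$kegg_type[t_at],
          diff_p = character(0),
          matched_s = s$atoms$kegg_type[sib],
          matched_p = p$atoms$kegg_type[match(sib, porig)]
        ), class = "rdm_description")
      })
      return(list(substrate = s, product = p2, rdms = rdms, truth = truth,
                  centers = parents))
    }
    mh_structural_error("could not plant an RDM mapping fixture")
  })
}

#' Engineered combinatorial-explosion RDM case
#'
#' A fully symmetric carbon ring in which every atom carries the same
#' synthetic atom type, described by `n_centers` identical RDM entries: the
#' center-assignment combination count is `ring_size^(2*n_centers)`, far
#' beyond any practical cap.
#'
#' @param ring_size Number of ring atoms.
#' @param n_centers Number of identical RDM entries.
#' @return List with `a`, `b` (the same ring) and `rdms`.
#' @export
gen_combinatorial_case <- function(ring_size = 12L, n_centers = 6L) {
  atoms <- data.frame(
    element = rep("C", ring_size), charge = 0L,
    x = cos(2 * pi * seq_len(ring_size) / ring_size),
    y = sin(2 * pi * seq_len(ring_size) / ring_size),
    parity = "none", kegg_type = "C2a", stringsAsFactors = FALSE
  )
  bonds <- data.frame(a = seq_len(ring_size),
                      b = c(seq_len(ring_size)[-1], 1L),
                      order = "1", stringsAsFactors = FALSE)
  ring <- molecule("ring", atoms, bonds)
  rdm <- structure(list(
    center = c(substrate = "C2a", product = "C2a"),
    diff_s = character(0), diff_p = character(0),
    matched_s = "C2a", matched_p = "C2a"
  ), class = "rdm_description")
  list(a = ring, b = ring, rdms = rep(list(rdm), n_centers))
}

#' Generate a bond-edit mapping fixture for the consistency metric
#'
#' The product is the substrate with `k` pairwise non-adjacent bonds
#' removed and all atoms kept, mapped by identity, so exactly `2k` of the
#' `n` mapped atoms change their one-bond color: the planted changed-color
#' fraction is `2k/n`.
#'
#' @param seed Optional seed.
#' @param k Number of bond edits.
#' @param size Heavy-atom count.
#' @return List with `a`, `b`, `mapping` (long form), `expected_fraction`.
#' @export
gen_bond_edit_reaction <- function(seed = NULL, k = 1L, size = 10L) {
  with_seed(seed, {
    for (attempt in 1:100) {
      a <- gen_molecule(size, id = "sub_a", add_h = FALSE, p_double = 0)
      picked <- integer(0)
      touched <- integer(0)
      for (bi in sample(nrow(a$bonds))) {
        ends <- c(a$bonds$a[bi], a$bonds$b[bi])
        if (any(ends %in% touched)) next
        picked <- c(picked, bi)
        touched <- c(touched, ends)
        if (length(picked) == k) break
      }
      if (length(picked) < k) next
      b <- molecule("sub_b", a$atoms, a$bonds[-picked, , drop = FALSE])
      mapping <- data.frame(
        compound_a = "sub_a", atom_a = seq_len(n_atoms(a)),
        compound_b = "sub_b", atom_b = seq_len(n_atoms(a)),
        stringsAsFactors = FALSE
      )
      return(list(a = a, b = b, mapping = mapping,
                  expected_fraction = 2 * k / n_atoms(a)))
    }
    mh_structural_error("could not plant non-adjacent bond edits")
  })
}

#' Build a carboxylate-bearing molecule for resonance tests
#'
#' A short carbon chain ending in a carboxylate group (C bonded to one
#' double-bond O and one negatively charged single-bond O); the two terminal
#' oxygens are resonance-interchangeable.
#'
#' @param n_chain Chain carbons before the carboxylate carbon.
#' @param id Compound id.
#' @return List with `mol`, `o_double`, `o_single`.
#' @export
gen_carboxylate <- function(n_chain = 2L, id = "carb") {
  nc <- n_chain + 1L
  atoms <- data.frame(
    element = c(rep("C", nc), "O", "O"),
    charge = c(rep(0L, nc), 0L, -1L),
    x = seq_len(nc + 2L), y = 0, parity = "none",
    kegg_type = NA_character_, stringsAsFactors = FALSE
  )
  bonds <- rbind(
    if (nc > 1L) data.frame(a = seq_len(nc - 1L), b = 2:nc, order = "1",
                            stringsAsFactors = FALSE),
    data.frame(a = c(nc, nc), b = c(nc + 1L, nc + 2L), order = c("2", "1"),
               stringsAsFactors = FALSE)
  )
  list(mol = fill_hydrogens(molecule(id, atoms, bonds)),
       o_double = nc + 1L, o_single = nc + 2L)
}
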