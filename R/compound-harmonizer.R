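# Compound harmonization: detecting compound pairs across two databases and
# classifying each pair as an equivalence, a directed generic-specific, or a
# loose relationship, with dedicated validators for R-group (generic) pairs,
# tautomers and ring-chain (cyclic vs linear sugar) representations.
#
# "Chemical details" means atom parity plus double-bond cis/trans labels;
# charges and hydrogen counts are structural and enter the identifiers
# instead.  Unknown stereo is treated as absent (subset-compatible), never as
# conflicting.

REL_KINDS <- c("equivalence", "generic_specific", "loose")

#' Construct a relationship type
#'
#' @param kind `"equivalence"`, `"generic_specific"` or `"loose"`.
#' @param direction For `generic_specific` only: `"a_to_b"` or `"b_to_a"`,
#'   pointing from the general to the specific compound.  Equivalence and
#'   loose relationships always have direction `"none"`.
#' @export
relationship <- function(kind, direction = "none") {
  kind <- match.arg(kind, REL_KINDS)
  if (kind != "generic_specific" && direction != "none") {
    mh_precondition_error("only generic_specific relationships carry a direction")
  }
  if (kind == "generic_specific" && !direction %in% c("a_to_b", "b_to_a")) {
    mh_precondition_error("generic_specific requires direction a_to_b or b_to_a")
  }
  structure(list(kind = kind, direction = direction), class = "relationship")
}

#' @export
print.relationship <- function(x, ...) {
  cat(sprintf("<%s%s>\n", x$kind,
              if (x$direction != "none") paste0(" ", x$direction) else ""))
  invisible(x)
}

rel_rank <- function(rel) match(rel$kind, c("loose", "generic_specific", "equivalence"))

#' Absent-result sentinel
#'
#' Validators return this (rather than a [compound_pair()]) when a candidate
#' pair fails validation; `reason` says why.
#'
#' @param reason Short machine-readable reason string.
#' @export
absent <- function(reason = "invalid") {
  structure(list(reason = reason), class = "mh_absent")
}

#' @rdname absent
#' @param x Object to test.
#' @export
is_absent <- function(x) is.null(x) || inherits(x, "mh_absent")

#' @export
print.mh_absent <- function(x, ...) {
  cat(sprintf("<absent: %s>\n", x$reason))
  invisible(x)
}

reverse_relationship <- function(rel) {
  if (rel$kind != "generic_specific") return(rel)
  relationship("generic_specific",
               if (rel$direction == "a_to_b") "b_to_a" else "a_to_b")
}

#' Construct a compound pair
#'
#' @param id_a,id_b Compound ids in database A and B.
#' @param rel A [relationship()].
#' @param mapping Optional `data.frame(pattern, target)` atom mapping (atom
#'   indices of compound A to compound B); absent for identifier-detected
#'   pairs.
#' @param origin One of `"identifier"`, `"generic_validation"`, `"tautomer"`,
#'   `"ring_chain"`.
#' @export
compound_pair <- function(id_a, id_b, rel, mapping = NULL,
                          origin = c("identifier", "generic_validation",
                                     "tautomer", "ring_chain")) {
  origin <- match.arg(origin)
  structure(
    list(id_a = id_a, id_b = id_b, relationship = rel,
         mapping = mapping, origin = origin),
    class = "compound_pair"
  )
}

#' @export
print.compound_pair <- function(x, ...) {
  cat(sprintf("<pair %s ~ %s: %s%s [%s]>\n", x$id_a, x$id_b,
              x$relationship$kind,
              if (x$relationship$direction != "none")
                paste0(" ", x$relationship$direction) else "",
              x$origin))
  invisible(x)
}

.parity_present <- function(p) p %in% c("cw", "ccw")
.ct_present <- function(ct) ct %in% c("cis", "trans")

# Compare chemical details (atom parity, double-bond cis/trans) across a
# mapping.  skip_atoms_a: a-side atom indices whose sites are ignored.
# Returns list(conflict, a_extra, b_extra).
.compare_details <- function(a, b, map_df, skip_atoms_a = integer(0)) {
  conflict <- a_extra <- b_extra <- FALSE
  m <- stats::setNames(map_df$target, map_df$pattern)
  skip_b <- unname(m[as.character(skip_atoms_a)])
  for (r in seq_len(nrow(map_df))) {
    i <- map_df$pattern[r]; j <- map_df$target[r]
    if (i %in% skip_atoms_a) next
    pa <- .parity_present(a$atoms$parity[i])
    pb <- .parity_present(b$atoms$parity[j])
    if (pa && pb) {
      if (a$atoms$parity[i] != b$atoms$parity[j]) conflict <- TRUE
    } else if (pa) a_extra <- TRUE else if (pb) b_extra <- TRUE
  }
  # double-bond details over bonds whose both endpoints are mapped
  for (k in seq_len(nrow(a$bonds))) {
    i1 <- a$bonds$a[k]; i2 <- a$bonds$b[k]
    j1 <- m[as.character(i1)]; j2 <- m[as.character(i2)]
    if (is.na(j1) || is.na(j2)) next
    if (i1 %in% skip_atoms_a || i2 %in% skip_atoms_a) next
    tb <- bond_between(b, j1, j2)
    if (length(tb) != 1L) next
    ca <- a$bonds$cis_trans[k]; cb <- b$bonds$cis_trans[tb]
    pa <- .ct_present(ca); pb <- .ct_present(cb)
    if (pa && pb) {
      if (ca != cb) conflict <- TRUE
    } else if (pa) a_extra <- TRUE else if (pb) b_extra <- TRUE
  }
  list(conflict = conflict, a_extra = a_extra, b_extra = b_extra)
}

.details_relationship <- function(cmp) {
  if (cmp$conflict) return(relationship("loose"))
  if (!cmp$a_extra && !cmp$b_extra) return(relationship("equivalence"))
  if (cmp$a_extra && cmp$b_extra) return(relationship("loose"))
  if (cmp$b_extra) relationship("generic_specific", "a_to_b")
  else relationship("generic_specific", "b_to_a")
}

#' Classify a compound pair by its chemical details
#'
#' Given a full heavy-atom bijection between two structurally matched
#' compounds, the sets of chemical details (atom parities and double-bond
#' cis/trans labels) are compared site by site across the mapping: equal
#' sets give an equivalence relationship; one set a strict subset of the
#' other gives a generic-specific relationship directed from the
#' less-specified to the more-specified compound; any conflicting detail, or
#' details on both sides that the other lacks, gives a loose relationship.
#' Unknown stereo counts as absent.
#'
#' @param a,b [molecule()] objects.
#' @param mapping An `atom_match` or `data.frame(pattern, target)` covering
#'   all heavy atoms of both molecules.
#' @return A [relationship()].
#' @export
classify_chemical_details <- function(a, b, mapping) {
  map_df <- if (inherits(mapping, "atom_match")) mapping$mapping else mapping
  nha <- length(heavy_indices(a)); nhb <- length(heavy_indices(b))
  if (nrow(map_df) != nha || nrow(map_df) != nhb) {
    mh_precondition_error(sprintf(
      "mapping must be a full heavy-atom bijection (%d mapped, %d vs %d heavy atoms)",
      nrow(map_df), nha, nhb
    ))
  }
  .details_relationship(.compare_details(a, b, map_df))
}

# pick the strongest relationship over a set of candidate bijections
.best_over_isos <- function(a, b, isos, skip_fun = NULL) {
  best <- NULL
  for (iso in isos) {
    skip <- if (is.null(skip_fun)) integer(0) else skip_fun(iso)
    rel <- .details_relationship(.compare_details(a, b, iso$mapping, skip))
    if (is.null(best) || rel_rank(rel) > rel_rank(best$rel)) {
      best <- list(rel = rel, iso = iso)
    }
    if (rel_rank(best$rel) == 3L) break
  }
  best
}

#' Detect compound pairs by loose coloring identifier
#'
#' All cross-database pairs with equal loose compound coloring identifiers
#' are detected and each is classified by [classify_chemical_details()] over
#' the possible heavy-atom bijections, keeping the strongest relationship
#' (one compound may pair with several partners).
#'
#' @param db_a,db_b Lists of [molecule()] objects.
#' @param max_isos Cap on bijections examined per pair.
#' @return List of [compound_pair()] objects (origin `"identifier"`).
#' @export
detect_pairs_by_identifier <- function(db_a, db_b, max_isos = 500L) {
  ids_a <- vapply(db_a, function(m) as.character(compound_identifier(m, "loose")), character(1))
  ids_b <- vapply(db_b, function(m) as.character(compound_identifier(m, "loose")), character(1))
  pairs <- list()
  for (i in seq_along(db_a)) {
    hits <- which(ids_b == ids_a[i])
    for (j in hits) {
      isos <- all_isomorphisms(db_a[[i]], db_b[[j]], max_hits = max_isos)
      if (length(isos) == 0L) next
      best <- .best_over_isos(db_a[[i]], db_b[[j]], isos)
      pairs[[length(pairs) + 1L]] <- compound_pair(
        db_a[[i]]$id, db_b[[j]]$id, best$rel, mapping = NULL,
        origin = "identifier"
      )
    }
  }
  pairs
}

#' Validate a generic compound pair
#'
#' Checks whether generic compound `a` (containing R groups) can stand for
#' compound `b`: the R- and H-suppressed graph of `a` must embed in `b`, and
#' every connected unmatched branch of `b` must hang off a matched atom that
#' carries an (unused) R group in `a` — one R group absorbs exactly one
#' branch, and every R group must absorb one.  On success the chemical
#' details of the matched region decide the relationship: details of `a`
#' included in `b` give a generic-specific relationship directed a to b,
#' anything else is loose.
#'
#' @param a A [molecule()] with at least one R atom.
#' @param b A [molecule()].
#' @return A [compound_pair()] (origin `"generic_validation"`) or an
#'   [absent()] sentinel when the pair is invalid.
#' @export
validate_generic_pair <- function(a, b) {
  if (!any(a$atoms$is_r)) {
    mh_precondition_error("compound a must contain at least one R group")
  }
  r_atoms <- which(a$atoms$is_r)
  embeddings <- subgraph_search(a, b, ignore_r_h = TRUE)
  heavy_b <- heavy_indices(b)
  best <- NULL
  for (emb in embeddings) {
    matched_b <- emb$mapping$target
    unmatched <- setdiff(heavy_b, matched_b)
    inv <- stats::setNames(emb$mapping$pattern, emb$mapping$target)
    # connected components of the unmatched region of b
    comps <- .components(b, unmatched)
    # each branch must attach through exactly one bond to a matched atom
    # whose preimage in a carries an R group; assign branches to R atoms
    # injectively
    cand_rs <- vector("list", length(comps))
    ok <- TRUE
    for (ci in seq_along(comps)) {
      att <- .attachments(b, comps[[ci]], matched_b)
      if (nrow(att) != 1L) { ok <- FALSE; break }
      p_at <- inv[as.character(att$matched)]
      rs <- intersect(neighbors_of(a, as.integer(p_at)), r_atoms)
      if (length(rs) == 0L) { ok <- FALSE; break }
      cand_rs[[ci]] <- rs
    }
    if (!ok) next
    if (length(comps) != length(r_atoms)) next
    if (!.injective_assignment(cand_rs, r_atoms)) next
    cmp <- .compare_details(a, b, emb$mapping)
    rel <- if (cmp$conflict || cmp$a_extra) relationship("loose")
           else relationship("generic_specific", "a_to_b")
    if (is.null(best) || rel_rank(rel) > rel_rank(best$rel)) {
      best <- list(rel = rel, emb = emb)
    }
    if (best$rel$kind == "generic_specific") break
  }
  if (is.null(best)) return(absent("no valid embedding"))
  compound_pair(a$id, b$id, best$rel, mapping = best$emb$mapping,
                origin = "generic_validation")
}

# connected components of the subgraph of mol induced on `atoms`
.components <- function(mol, atoms) {
  comps <- list()
  remaining <- atoms
  while (length(remaining) > 0L) {
    seed <- remaining[1L]
    comp <- seed
    queue <- seed
    while (length(queue) > 0L) {
      cur <- queue[1L]; queue <- queue[-1L]
      nb <- intersect(neighbors_of(mol, cur), remaining)
      new <- setdiff(nb, comp)
      comp <- c(comp, new)
      queue <- c(queue, new)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps
}

# bonds connecting a branch to the matched region
.attachments <- function(mol, branch, matched) {
  out <- data.frame(branch = integer(), matched = integer())
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
    if (a %in% branch && b %in% matched) {
      out <- rbind(out, data.frame(branch = a, matched = b))
    } else if (b %in% branch && a %in% matched) {
      out <- rbind(out, data.frame(branch = b, matched = a))
    }
  }
  out
}

# can each slot be assigned a distinct value from its candidate set?
.injective_assignment <- function(cand, universe) {
  if (length(cand) == 0L) return(TRUE)
  assign_next <- function(i, used) {
    if (i > length(cand)) return(TRUE)
    for (v in setdiff(cand[[i]], used)) {
      if (assign_next(i + 1L, c(used, v))) return(TRUE)
    }
    FALSE
  }
  assign_next(1L, integer(0))
}

.collapse_doubles <- function(mol) {
  b <- mol$bonds
  b$order[b$order == "2"] <- "1"
  b$cis_trans <- "none"
  molecule(mol$id, mol$atoms, b, mol$source)
}

#' Validate a tautomer pair
#'
#' Two compounds with the identical chemical formula (hydrogens included)
#' are tautomers when their skeletons agree after converting every double
#' bond to a single bond and all remaining double-bond mismatches are
#' hydrogen-shift patterns: a double bond moved to an adjacent bond whose
#' far atom gains or loses exactly one hydrogen.  Chemical details away from
#' the changeable positions decide the relationship of a valid pair.
#'
#' @param a,b [molecule()] objects with equal formulas.
#' @param max_isos Cap on skeleton bijections examined.
#' @return A [compound_pair()] (origin `"tautomer"`) or an [absent()]
#'   sentinel.
#' @export
validate_tautomer_pair <- function(a, b, max_isos = 500L) {
  if (!identical(mol_formula(a), mol_formula(b))) {
    mh_precondition_error("tautomer validation requires identical chemical formulas")
  }
  isos <- all_isomorphisms(.collapse_doubles(a), .collapse_doubles(b),
                           max_hits = max_isos)
  hca <- hydrogen_counts(a); hcb <- hydrogen_counts(b)
  best <- NULL
  for (iso in isos) {
    m <- stats::setNames(iso$mapping$target, iso$mapping$pattern)
    inv <- stats::setNames(iso$mapping$pattern, iso$mapping$target)
    # diff sets: double bonds present on one side only (under the mapping)
    Da <- list(); Db <- list()
    for (k in which(a$bonds$order == "2")) {
      i1 <- a$bonds$a[k]; i2 <- a$bonds$b[k]
      if (a$atoms$element[i1] == "H" || a$atoms$element[i2] == "H") next
      tb <- bond_between(b, m[as.character(i1)], m[as.character(i2)])
      if (length(tb) == 1L && b$bonds$order[tb] != "2") {
        Da[[length(Da) + 1L]] <- c(i1, i2)
      }
    }
    for (k in which(b$bonds$order == "2")) {
      j1 <- b$bonds$a[k]; j2 <- b$bonds$b[k]
      if (b$atoms$element[j1] == "H" || b$atoms$element[j2] == "H") next
      p1 <- inv[as.character(j1)]; p2 <- inv[as.character(j2)]
      if (is.na(p1) || is.na(p2)) next
      ab <- bond_between(a, p1, p2)
      if (length(ab) == 1L && a$bonds$order[ab] != "2") {
        Db[[length(Db) + 1L]] <- c(as.integer(p1), as.integer(p2))  # a-side indices
      }
    }
    if (length(Da) != length(Db)) next
    change_atoms <- unique(c(unlist(Da), unlist(Db)))
    # hydrogen counts must agree away from the changeable positions
    steady <- setdiff(iso$mapping$pattern, change_atoms)
    if (!all(hca[steady] == hcb[unname(m[as.character(steady)])])) next
    if (length(Da) > 0L) {
      if (!.match_shifts(Da, Db, m, hca, hcb)) next
    }
    cmp <- .compare_details(a, b, iso$mapping, skip_atoms_a = change_atoms)
    rel <- .details_relationship(cmp)
    if (is.null(best) || rel_rank(rel) > rel_rank(best$rel)) {
      best <- list(rel = rel, iso = iso)
    }
    if (rel_rank(best$rel) == 3L) break
  }
  if (is.null(best)) return(absent("skeleton or shift mismatch"))
  compound_pair(a$id, b$id, best$rel, mapping = best$iso$mapping,
                origin = "tautomer")
}

# pair each a-side lost double bond with an adjacent b-side gained double
# bond obeying the one-hydrogen shift rule; shift pairs must not share atoms
.match_shifts <- function(Da, Db, m, hca, hcb) {
  try_pairing <- function(ia, used_b, used_atoms) {
    if (ia > length(Da)) return(TRUE)
    da <- Da[[ia]]
    for (jb in setdiff(seq_along(Db), used_b)) {
      db <- Db[[jb]]
      shared <- intersect(da, db)
      if (length(shared) != 1L) next
      y <- shared
      xa <- setdiff(da, y)   # far end of the vanished double bond
      za <- setdiff(db, y)   # far end of the appearing double bond
      if (length(xa) != 1L || length(za) != 1L || xa == za) next
      if (any(c(xa, y, za) %in% used_atoms)) next
      if (hcb[m[as.character(xa)]] != hca[xa] + 1L) next
      if (hca[za] != hcb[m[as.character(za)]] + 1L) next
      if (hca[y] != hcb[m[as.character(y)]]) next
      if (try_pairing(ia + 1L, c(used_b, jb), c(used_atoms, xa, y, za))) {
        return(TRUE)
      }
    }
    FALSE
  }
  try_pairing(1L, integer(0), integer(0))
}

#' Validate a ring-chain pair
#'
#' Validates that a cyclic (hemiacetal/hemiketal) representation and a linear
#' (open-chain carbonyl) representation describe the same compound.  Each
#' ring C-O bond whose carbon also bears a hydroxyl is a candidate anomeric
#' bond: it is broken, the carbonyl C=O restored (the hydroxyl hydrogen
#' migrating to the freed ring oxygen, reversing the intramolecular
#' addition), and the loose compound coloring identifier of the modified
#' structure compared with the linear form's identifier.
#'
#' @param circular,linear [molecule()] objects with equal formulas.
#' @return A [compound_pair()] (origin `"ring_chain"`) or an [absent()]
#'   sentinel whose `reason` is `"no hemiacetal bond"` or
#'   `"identifier mismatch"`.
#' @export
validate_ring_chain_pair <- function(circular, linear) {
  if (!identical(mol_formula(circular), mol_formula(linear))) {
    mh_precondition_error("ring-chain validation requires identical chemical formulas")
  }
  hc <- hydrogen_counts(circular)
  rb <- ring_bonds(circular)
  el <- circular$atoms$element
  heavy_deg <- vapply(seq_len(n_atoms(circular)), function(i) {
    sum(el[neighbors_of(circular, i)] != "H")
  }, integer(1))
  cands <- list()
  for (k in which(rb & circular$bonds$order == "1")) {
    ends <- c(circular$bonds$a[k], circular$bonds$b[k])
    if (!setequal(el[ends], c("C", "O"))) next
    cc <- ends[el[ends] == "C"]; oo <- ends[el[ends] == "O"]
    # hydroxyl on the anomeric carbon: a terminal O (heavy degree 1) with H
    ohs <- setdiff(neighbors_of(circular, cc), oo)
    ohs <- ohs[el[ohs] == "O" & heavy_deg[ohs] == 1L & hc[ohs] >= 1L]
    for (o2 in ohs) cands[[length(cands) + 1L]] <- c(bond = k, c = cc, o = oo, o2 = o2)
  }
  if (length(cands) == 0L) {
    return(absent("no hemiacetal bond"))
  }
  target_id <- as.character(compound_identifier(linear, "loose"))
  for (cd in cands) {
    mod <- .open_ring(circular, cd)
    if (as.character(compound_identifier(mod, "loose")) == target_id) {
      iso <- all_isomorphisms(mod, linear, max_hits = 200L)
      if (length(iso) == 0L) next
      best <- .best_over_isos(mod, linear, iso,
                              skip_fun = function(i) as.integer(cd[c("c", "o", "o2")]))
      return(compound_pair(circular$id, linear$id, best$rel,
                           mapping = best$iso$mapping, origin = "ring_chain"))
    }
  }
  absent("identifier mismatch")
}

# break the anomeric C-O ring bond, restore C=O on the hydroxyl oxygen and
# move that hydroxyl hydrogen onto the freed ring oxygen
.open_ring <- function(mol, cd) {
  b <- mol$bonds
  b <- b[-cd[["bond"]], , drop = FALSE]
  kb <- which((b$a == cd[["c"]] & b$b == cd[["o2"]]) |
              (b$b == cd[["c"]] & b$a == cd[["o2"]]))
  b$order[kb] <- "2"
  # move one explicit H from o2 to o
  hs <- neighbors_of(mol, cd[["o2"]])
  hs <- hs[mol$atoms$element[hs] == "H"]
  h <- hs[1L]
  kh <- which((b$a == h & b$b == cd[["o2"]]) | (b$b == h & b$a == cd[["o2"]]))
  b$a[kh] <- h; b$b[kh] <- cd[["o"]]
  atoms <- mol$atoms
  atoms$parity[c(cd[["c"]], cd[["o"]], cd[["o2"]])] <- "none"
  molecule(mol$id, atoms, b, mol$source)
}

#' Export compound pairs as TSV
#'
#' @param pairs List of [compound_pair()] objects.
#' @param file Output path (or `""` for stdout).
#' @return Invisibly, the written data.frame.
#' @export
write_pairs_tsv <- function(pairs, file) {
  rows <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(
      id_a = p$id_a, id_b = p$id_b,
      relationship = p$relationship$kind,
      direction = p$relationship$direction,
      origin = p$origin,
      mapping = if (is.null(p$mapping)) "" else
        paste(sprintf("%d:%d", p$mapping$pattern, p$mapping$target), collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
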