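# Chemically aware substructure search: subgraph monomorphism enumeration,
# full graph isomorphism and anchored maximum-common-subgraph detection on
# hydrogen-suppressed molecular graphs.  The search is a VF2-style
# backtracking with a fail-first candidate order (least compatible target
# atoms tried first through connectivity-driven ordering); results are
# deterministic and sorted canonically.

.order_compatible <- function(po, to, order_strict) {
  if (!order_strict) return(TRUE)
  po == to
}

.label_compatible <- function(p_el, p_is_r, t_el) {
  if (p_is_r) return(TRUE)        # an R pattern atom matches any heavy atom
  p_el == t_el
}

# search order over pattern view atoms: connected sweep, highest-degree first
.search_order <- function(adj, n) {
  if (n == 0L) return(integer(0))
  deg <- vapply(adj, nrow, integer(1))
  ord <- integer(0)
  remaining <- seq_len(n)
  while (length(remaining) > 0L) {
    frontier <- if (length(ord) == 0L) integer(0) else {
      unique(unlist(lapply(ord, function(i) adj[[i]]$nbr)))
    }
    cand <- intersect(frontier, remaining)
    if (length(cand) == 0L) cand <- remaining
    nxt <- cand[order(-deg[cand], cand)][1L]
    ord <- c(ord, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  ord
}

.new_atom_match <- function(pattern_view, target_view, map_pos) {
  porig <- attr(pattern_view, "orig_index")
  torig <- attr(target_view, "orig_index")
  mapped <- which(!is.na(map_pos))
  mp <- data.frame(
    pattern = porig[mapped],
    target = torig[map_pos[mapped]]
  )
  mp <- mp[order(mp$pattern), , drop = FALSE]
  rownames(mp) <- NULL
  # matched bonds: pattern bonds whose image is a bond in the target
  pb <- pattern_view$bonds
  mb <- data.frame(a = integer(), b = integer())
  if (nrow(pb) > 0L) {
    keep <- logical(nrow(pb))
    for (k in seq_len(nrow(pb))) {
      ia <- pb$a[k]; ib <- pb$b[k]
      if (is.na(map_pos[ia]) || is.na(map_pos[ib])) next
      tb <- bond_between(target_view, map_pos[ia], map_pos[ib])
      keep[k] <- length(tb) == 1L
    }
    mb <- data.frame(a = porig[pb$a[keep]], b = porig[pb$b[keep]])
  }
  structure(list(mapping = mp, matched_bonds = mb), class = "atom_match")
}

#' @export
print.atom_match <- function(x, ...) {
  cat(sprintf("<atom_match: %d atoms, %d bonds>\n",
              nrow(x$mapping), nrow(x$matched_bonds)))
  invisible(x)
}

.match_views <- function(pattern, target, ignore_r_h) {
  pv <- suppressed_view(pattern, drop_r = ignore_r_h)
  tv <- suppressed_view(target, drop_r = FALSE)
  list(pattern = pv, target = tv)
}

#' Enumerate substructure embeddings
#'
#' Finds every distinct injective, label- and bond-preserving embedding of
#' `pattern` into `target` on the hydrogen-suppressed graphs.  An R pattern
#' atom matches any heavy target atom.  With `ignore_r_h = TRUE`, R atoms are
#' removed from the pattern before matching (explicit hydrogens are always
#' suppressed).  With `order_strict = FALSE` bond orders are not compared,
#' which is what the tautomer validator relies on after collapsing double
#' bonds.
#'
#' @param pattern,target [molecule()] objects.
#' @param ignore_r_h Drop R atoms from the pattern before matching.
#' @param order_strict Require exact bond-order agreement (aromatic matches
#'   only aromatic).
#' @param max_hits Stop after this many embeddings.
#' @return List of `atom_match` objects (possibly empty), sorted canonically
#'   by their mapping vectors.
#' @export
subgraph_search <- function(pattern, target, ignore_r_h = FALSE,
                            order_strict = TRUE, max_hits = Inf) {
  vw <- .match_views(pattern, target, ignore_r_h)
  pv <- vw$pattern; tv <- vw$target
  np <- n_atoms(pv); nt <- n_atoms(tv)
  if (np == 0L) mh_precondition_error("pattern is empty after applying ignore options")
  if (np > nt) return(list())
  padj <- adjacency(pv); tadj <- adjacency(tv)
  ord <- .search_order(padj, np)
  p_el <- pv$atoms$element; p_r <- pv$atoms$is_r
  t_el <- tv$atoms$element

  results <- list()
  map <- rep(NA_integer_, np)
  used <- rep(FALSE, nt)

  recurse <- function(pos) {
    if (length(results) >= max_hits) return()
    if (pos > np) {
      results[[length(results) + 1L]] <<- map
      return()
    }
    i <- ord[pos]
    nb <- padj[[i]]
    mapped_nb <- nb[!is.na(map[nb$nbr]), , drop = FALSE]
    cands <- if (nrow(mapped_nb) > 0L) {
      # intersect target neighborhoods of mapped pattern neighbors
      sets <- lapply(seq_len(nrow(mapped_nb)), function(r) {
        tn <- tadj[[map[mapped_nb$nbr[r]]]]
        tn$nbr[vapply(tn$order, .order_compatible, logical(1),
                      po = mapped_nb$order[r], order_strict = order_strict)]
      })
      Reduce(intersect, sets)
    } else {
      seq_len(nt)
    }
    for (j in cands) {
      if (used[j]) next
      if (!.label_compatible(p_el[i], p_r[i], t_el[j])) next
      # verify every bond back into the mapped region
      ok <- TRUE
      if (nrow(mapped_nb) > 0L) {
        for (r in seq_len(nrow(mapped_nb))) {
          tb <- bond_between(tv, j, map[mapped_nb$nbr[r]])
          if (length(tb) != 1L ||
              !.order_compatible(mapped_nb$order[r], tv$bonds$order[tb],
                                 order_strict)) {
            ok <- FALSE; break
          }
        }
      }
      if (!ok) next
      map[i] <<- j; used[j] <<- TRUE
      recurse(pos + 1L)
      map[i] <<- NA_integer_; used[j] <<- FALSE
    }
  }
  recurse(1L)

  out <- lapply(results, function(m) .new_atom_match(pv, tv, m))
  keys <- vapply(out, function(m) paste(m$mapping$target, collapse = ","), character(1))
  out[order(keys)]
}

#' Test two molecules for graph isomorphism
#'
#' Full bijection test on the hydrogen-suppressed graphs with element labels
#' and (by default) bond orders preserved.
#'
#' @inheritParams subgraph_search
#' @param a,b [molecule()] objects.
#' @return An `atom_match` bijection, or `NULL` when none exists.
#' @export
graph_isomorphism <- function(a, b, ignore_r_h = FALSE, order_strict = TRUE) {
  hits <- all_isomorphisms(a, b, ignore_r_h, order_strict, max_hits = 1L)
  if (length(hits) == 0L) NULL else hits[[1L]]
}

#' Enumerate all isomorphisms between two molecules
#'
#' @inheritParams graph_isomorphism
#' @param max_hits Stop after this many bijections.
#' @return List of `atom_match` objects.
#' @export
all_isomorphisms <- function(a, b, ignore_r_h = FALSE, order_strict = TRUE,
                             max_hits = Inf) {
  vw <- .match_views(a, b, ignore_r_h)
  pv <- vw$pattern; tv <- vw$target
  if (n_atoms(pv) != n_atoms(tv)) return(list())
  if (nrow(pv$bonds) != nrow(tv$bonds)) return(list())
  if (!identical(sort(pv$atoms$element), sort(tv$atoms$element))) return(list())
  if (order_strict &&
      !identical(sort(pv$bonds$order), sort(tv$bonds$order))) return(list())
  # a monomorphism between graphs of equal atom and bond counts is an
  # isomorphism
  subgraph_search(a, b, ignore_r_h = ignore_r_h, order_strict = order_strict,
                  max_hits = max_hits)
}

#' Maximum common connected subgraph
#'
#' Finds a common subgraph of maximum atom count grown by connected
#' extension, optionally seeded with (and consistent with) an injective
#' label-preserving anchor mapping.  Ties are broken by (1) more matched
#' bonds, then (2) the lexicographically smallest mapping.
#'
#' @param a,b [molecule()] objects.
#' @param anchors Optional `data.frame(pattern, target)` of original atom
#'   indices seeding the mapping (e.g. reaction centers).
#' @param order_strict Require exact bond-order agreement.
#' @return An `atom_match`, or `NULL` when nothing is mappable.
#' @export
maximum_common_subgraph <- function(a, b, anchors = NULL, order_strict = TRUE) {
  av <- suppressed_view(a); bv <- suppressed_view(b)
  na <- n_atoms(av); nb_ <- n_atoms(bv)
  aorig <- attr(av, "orig_index"); borig <- attr(bv, "orig_index")
  a_el <- av$atoms$element; a_r <- av$atoms$is_r
  b_el <- bv$atoms$element
  aadj <- adjacency(av); badj <- adjacency(bv)

  seed_map <- rep(NA_integer_, na)
  seed_used <- rep(FALSE, nb_)
  if (!is.null(anchors) && nrow(anchors) > 0L) {
    for (r in seq_len(nrow(anchors))) {
      i <- match(anchors$pattern[r], aorig)
      j <- match(anchors$target[r], borig)
      if (is.na(i) || is.na(j)) mh_precondition_error("anchor references a missing atom")
      if (!.label_compatible(a_el[i], a_r[i], b_el[j])) {
        mh_precondition_error(sprintf(
          "anchor (%d -> %d) violates element labels", anchors$pattern[r], anchors$target[r]
        ))
      }
      if (!is.na(seed_map[i]) || seed_used[j]) {
        mh_precondition_error("anchor mapping is not injective")
      }
      seed_map[i] <- j; seed_used[j] <- TRUE
    }
  }

  count_bonds <- function(map) {
    cnt <- 0L
    for (k in seq_len(nrow(av$bonds))) {
      ia <- av$bonds$a[k]; ib <- av$bonds$b[k]
      if (is.na(map[ia]) || is.na(map[ib])) next
      tb <- bond_between(bv, map[ia], map[ib])
      if (length(tb) == 1L &&
          .order_compatible(av$bonds$order[k], bv$bonds$order[tb], order_strict)) {
        cnt <- cnt + 1L
      }
    }
    cnt
  }

  best <- NULL   # list(map, natoms, nbonds, key)
  consider <- function(map) {
    natoms <- sum(!is.na(map))
    nbonds <- count_bonds(map)
    key <- paste(sprintf("%06d", ifelse(is.na(map), 0L, map)), collapse = ",")
    if (is.null(best) || natoms > best$natoms ||
        (natoms == best$natoms && nbonds > best$nbonds) ||
        (natoms == best$natoms && nbonds == best$nbonds && key < best$key)) {
      best <<- list(map = map, natoms = natoms, nbonds = nbonds, key = key)
    }
  }

  extend <- function(map, used, min_seed_a, excluded) {
    consider(map)
    mapped <- which(!is.na(map))
    # prune: even mapping everything remaining cannot beat the best
    avail_a <- na - length(mapped) - length(excluded)
    ub <- length(mapped) + min(avail_a, nb_ - sum(used))
    if (!is.null(best) && ub < best$natoms) return()
    # candidate extensions: pairs adjacent to the mapped region via a
    # compatible bond on both sides
    cands <- list()
    for (i in mapped) {
      nbs <- aadj[[i]]
      tnb <- badj[[map[i]]]
      for (r in seq_len(nrow(nbs))) {
        ia <- nbs$nbr[r]
        if (!is.na(map[ia]) || ia < min_seed_a || ia %in% excluded) next
        for (s in seq_len(nrow(tnb))) {
          jb <- tnb$nbr[s]
          if (used[jb]) next
          if (!.label_compatible(a_el[ia], a_r[ia], b_el[jb])) next
          if (!.order_compatible(nbs$order[r], tnb$order[s], order_strict)) next
          cands[[length(cands) + 1L]] <- c(ia, jb)
        }
      }
    }
    if (length(cands) == 0L) return()
    cands <- unique(cands)
    # branch on the smallest candidate a-atom: map it each possible way, or
    # exclude it from this growth permanently
    ia0 <- min(vapply(cands, `[`, integer(1), 1L))
    for (p in cands) {
      if (p[1L] != ia0) next
      map2 <- map; used2 <- used
      map2[ia0] <- p[2L]; used2[p[2L]] <- TRUE
      extend(map2, used2, min_seed_a, excluded)
    }
    extend(map, used, min_seed_a, c(excluded, ia0))
  }

  if (any(!is.na(seed_map))) {
    extend(seed_map, seed_used, 0L, integer(0))
  } else {
    # unanchored: grow from every compatible seed pair; restricting growth to
    # a-atoms >= the seed atom makes each connected subgraph discovered from
    # its smallest member exactly once
    for (i in seq_len(na)) {
      for (j in seq_len(nb_)) {
        if (!.label_compatible(a_el[i], a_r[i], b_el[j])) next
        map <- rep(NA_integer_, na); used <- rep(FALSE, nb_)
        map[i] <- j; used[j] <- TRUE
        extend(map, used, i, integer(0))
      }
    }
  }

  if (is.null(best) || best$natoms == 0L) return(NULL)
  .new_atom_match(av, bv, best$map)
}
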