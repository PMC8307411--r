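# KEGG RCLASS RDM machinery: parsing DEFINITION strings into reaction-center
# (R), difference-region (D) and matched-region (M) atom-type triples, and
# deriving compound-pair atom mappings by enumerating center assignments,
# removing changed bonds and running an anchored maximum-common-subgraph
# search.  A configurable cap turns combinatorial explosions into an
# explicit error instead of an open-ended search.

.split_labels <- function(s) {
  if (s == "*") return(character(0))
  strsplit(s, "+", fixed = TRUE)[[1]]
}

.parse_rdm_triple <- function(tok) {
  parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L) {
    mh_parse_error(sprintf("malformed RDM triple '%s' (need R:D:M)", tok))
  }
  sides <- lapply(parts, function(p) {
    s <- strsplit(p, "-", fixed = TRUE)[[1]]
    if (length(s) != 2L) {
      mh_parse_error(sprintf("malformed RDM region '%s' in '%s'", p, tok))
    }
    s
  })
  center <- sides[[1]]
  if (any(center == "*")) {
    mh_parse_error(sprintf("reaction center may not be empty in '%s'", tok))
  }
  matched_s <- .split_labels(sides[[3]][1])
  matched_p <- .split_labels(sides[[3]][2])
  if (length(matched_s) != length(matched_p)) {
    mh_parse_error(sprintf(
      "matched regions of '%s' differ in length (%d vs %d)",
      tok, length(matched_s), length(matched_p)
    ))
  }
  structure(
    list(center = c(substrate = center[1], product = center[2]),
         diff_s = .split_labels(sides[[2]][1]),
         diff_p = .split_labels(sides[[2]][2]),
         matched_s = matched_s, matched_p = matched_p),
    class = "rdm_description"
  )
}

#' @export
print.rdm_description <- function(x, ...) {
  cat(sprintf("<RDM %s-%s | D: %s-%s | M: %s-%s>\n",
              x$center[1], x$center[2],
              paste(x$diff_s, collapse = "+"), paste(x$diff_p, collapse = "+"),
              paste(x$matched_s, collapse = "+"), paste(x$matched_p, collapse = "+")))
  invisible(x)
}

#' Parse a KEGG RCLASS DEFINITION
#'
#' A DEFINITION consists of RDM triples `r_s-r_p:d_s-d_p:m_s-m_p` where each
#' region side lists KEGG atom-type labels joined by `+` and `*` denotes an
#' empty region.  Triples are separated by whitespace (or newlines); a `+`
#' standing between complete triples also separates them.  Labels are kept
#' verbatim.
#'
#' @param definition DEFINITION string.
#' @return List of `rdm_description` objects, one per triple.
#' @export
parse_rclass <- function(definition) {
  toks <- strsplit(trimws(definition), "[[:space:]]+")[[1]]
  toks <- toks[toks != "+" & nzchar(toks)]
  out <- list()
  for (tok in toks) {
    # a "+" may join complete triples; split only when every part parses as
    # a full triple, otherwise the "+" belongs to a multi-label region
    if (grepl("+", tok, fixed = TRUE)) {
      parts <- strsplit(tok, "+", fixed = TRUE)[[1]]
      if (all(vapply(parts, function(p) {
        length(strsplit(p, ":", fixed = TRUE)[[1]]) == 3L
      }, logical(1)))) {
        for (p in parts) out[[length(out) + 1L]] <- .parse_rdm_triple(p)
        next
      }
    }
    out[[length(out) + 1L]] <- .parse_rdm_triple(tok)
  }
  if (length(out) == 0L) mh_parse_error("empty RCLASS definition")
  out
}

.atom_type_labels <- function(mol) {
  kt <- mol$atoms$kegg_type
  if (all(is.na(kt))) {
    warning(sprintf(
      "molecule %s has no KEGG atom types; falling back to element prefixes", mol$id
    ), call. = FALSE)
    return(mol$atoms$element)
  }
  kt
}

#' Atoms that can serve as a given reaction center
#'
#' Atoms whose KEGG atom type equals the label; when the molecule carries no
#' KEGG types (plain molfile input), matching falls back to the element
#' prefix of the label.
#'
#' @param mol A [molecule()].
#' @param label KEGG atom-type label (e.g. `"S2a"`).
#' @return Integer vector of candidate atom indices.
#' @export
candidate_centers <- function(mol, label) {
  kt <- mol$atoms$kegg_type
  if (all(is.na(kt))) {
    el <- .kegg_type_element(label)
    return(which(mol$atoms$element == el))
  }
  which(!is.na(kt) & kt == label)
}

pair_atom_mapping <- function(compound_a, compound_b, pairs, centers) {
  structure(
    list(compound_a = compound_a, compound_b = compound_b,
         pairs = pairs, centers = centers),
    class = "pair_atom_mapping"
  )
}

#' @export
print.pair_atom_mapping <- function(x, ...) {
  cat(sprintf("<mapping %s ~ %s: %d atoms, %d centers>\n",
              x$compound_a, x$compound_b, nrow(x$pairs), nrow(x$centers)))
  invisible(x)
}

# remove bonds from an assigned center to neighbors whose atom-type label
# matches a difference-region label
.remove_changed_bonds <- function(mol, center, diff_labels) {
  if (length(diff_labels) == 0L) return(mol)
  types <- .atom_type_labels(mol)
  el_fallback <- all(is.na(mol$atoms$kegg_type))
  match_label <- function(i, lab) {
    if (el_fallback) mol$atoms$element[i] == .kegg_type_element(lab)
    else !is.na(types[i]) && types[i] == lab
  }
  b <- mol$bonds
  drop <- logical(nrow(b))
  for (k in seq_len(nrow(b))) {
    other <- if (b$a[k] == center) b$b[k] else if (b$b[k] == center) b$a[k] else next
    if (any(vapply(diff_labels, function(l) match_label(other, l), logical(1)))) {
      drop[k] <- TRUE
    }
  }
  if (!any(drop)) return(mol)
  molecule(mol$id, mol$atoms, b[!drop, , drop = FALSE], mol$source)
}

# enumerate injective assignments: one atom per slot from its candidate set
.injective_tuples <- function(cands) {
  out <- list()
  pick <- function(i, acc) {
    if (i > length(cands)) {
      out[[length(out) + 1L]] <<- acc
      return()
    }
    for (v in setdiff(cands[[i]], acc)) pick(i + 1L, c(acc, v))
  }
  pick(1L, integer(0))
  out
}

#' Derive a compound-pair atom mapping from RDM descriptions
#'
#' Every combination of reaction-center assignments on the two sides is
#' enumerated (each RDM description contributes one center per side).  For
#' each assignment the bonds changed according to the difference region are
#' removed and an anchored maximum-common-subgraph search maps the remaining
#' structures.  The optimal mapping maximizes the mapped-atom count, with
#' ties broken by the least changed one-bond-color ratio and then canonical
#' order.  When the number of center-assignment combinations exceeds `limit`
#' a `mh_combinatorial_limit` error carrying the count is raised.
#'
#' @param a,b [molecule()] objects (substrate side, product side), ideally
#'   with KEGG atom-type annotations.
#' @param rdms List of `rdm_description` objects (from [parse_rclass()]).
#' @param limit Cap on center-assignment combinations (default `1e5`).
#' @return A `pair_atom_mapping`.
#' @export
derive_pair_mapping <- function(a, b, rdms, limit = 1e5) {
  if (limit <= 0) mh_precondition_error("limit must be positive")
  if (inherits(rdms, "rdm_description")) rdms <- list(rdms)
  cands_a <- lapply(rdms, function(r) candidate_centers(a, r$center[["substrate"]]))
  cands_b <- lapply(rdms, function(r) candidate_centers(b, r$center[["product"]]))
  if (any(vapply(cands_a, length, integer(1)) == 0L) ||
      any(vapply(cands_b, length, integer(1)) == 0L)) {
    mh_precondition_error("a reaction center label matches no atom")
  }
  count <- prod(vapply(cands_a, length, integer(1))) *
    prod(vapply(cands_b, length, integer(1)))
  if (count > limit) mh_combinatorial_limit(count, limit)

  tup_a <- .injective_tuples(cands_a)
  tup_b <- .injective_tuples(cands_b)
  best <- NULL
  for (ta in tup_a) {
    a_mod <- a
    for (i in seq_along(rdms)) {
      a_mod <- .remove_changed_bonds(a_mod, ta[i], rdms[[i]]$diff_s)
    }
    for (tb in tup_b) {
      # centers must join atoms of the same element
      if (!all(a$atoms$element[ta] == b$atoms$element[tb])) next
      b_mod <- b
      for (i in seq_along(rdms)) {
        b_mod <- .remove_changed_bonds(b_mod, tb[i], rdms[[i]]$diff_p)
      }
      anchors <- data.frame(pattern = ta, target = tb)
      mcs <- tryCatch(
        maximum_common_subgraph(a_mod, b_mod, anchors = anchors),
        mh_precondition_error = function(e) NULL
      )
      if (is.null(mcs)) next
      natoms <- nrow(mcs$mapping)
      ratio <- mean(one_bond_color(a, mcs$mapping$pattern) !=
                    one_bond_color(b, mcs$mapping$target))
      key <- paste(sprintf("%06d:%06d", mcs$mapping$pattern, mcs$mapping$target),
                   collapse = ",")
      if (is.null(best) || natoms > best$natoms ||
          (natoms == best$natoms && ratio < best$ratio - 1e-12) ||
          (natoms == best$natoms && abs(ratio - best$ratio) <= 1e-12 && key < best$key)) {
        best <- list(mcs = mcs, natoms = natoms, ratio = ratio, key = key,
                     ta = ta, tb = tb)
      }
    }
  }
  if (is.null(best)) {
    mh_precondition_error("no center assignment admits a common subgraph")
  }
  pair_atom_mapping(
    a$id, b$id,
    pairs = data.frame(atom_a = best$mcs$mapping$pattern,
                       atom_b = best$mcs$mapping$target),
    centers = data.frame(atom_a = best$ta, atom_b = best$tb)
  )
}

#' Export a pair atom mapping as TSV
#'
#' @param mapping A `pair_atom_mapping`.
#' @param file Output path.
#' @return Invisibly, the written data.frame.
#' @export
write_mapping_tsv <- function(mapping, file) {
  df <- data.frame(
    compound_a = mapping$compound_a, atom_a = mapping$pairs$atom_a,
    compound_b = mapping$compound_b, atom_b = mapping$pairs$atom_b,
    is_center = paste(mapping$pairs$atom_a, mapping$pairs$atom_b) %in%
      paste(mapping$centers$atom_a, mapping$centers$atom_b),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Export an RDM as a paired-substructure file
#'
#' Writes the two structures and the atom index map into one text file: two
#' molfile blocks separated by `$$$$` delimiters followed by an index-map
#' section, a self-contained paired-substructure representation of a
#' reaction-center transformation.
#'
#' @param a,b [molecule()] objects.
#' @param mapping A `pair_atom_mapping` between them.
#' @param file Output path.
#' @export
write_rdm_substructure_pair <- function(a, b, mapping, file) {
  lines <- c(
    write_molfile(a), "$$$$",
    write_molfile(b), "$$$$",
    "> <atom_map>",
    sprintf("%d %d %s", mapping$pairs$atom_a, mapping$pairs$atom_b,
            ifelse(paste(mapping$pairs$atom_a, mapping$pairs$atom_b) %in%
                     paste(mapping$centers$atom_a, mapping$centers$atom_b),
                   "center", "matched"))
  )
  writeLines(lines, file)
  invisible(file)
}
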