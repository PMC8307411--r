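# Atom-mapping consistency evaluation: the changed one-bond atom color
# fraction, resonance normalization of interchangeable atoms (e.g. the two
# carboxylate oxygens), mapping comparison, and assembly of compound-level
# mappings into reaction-level mappings.

# coerce a pair_atom_mapping or data.frame into the canonical long form
# data.frame(compound_a, atom_a, compound_b, atom_b)
.mapping_df <- function(mapping) {
  if (inherits(mapping, "pair_atom_mapping")) {
    return(data.frame(
      compound_a = mapping$compound_a, atom_a = mapping$pairs$atom_a,
      compound_b = mapping$compound_b, atom_b = mapping$pairs$atom_b,
      stringsAsFactors = FALSE
    ))
  }
  as.data.frame(mapping, stringsAsFactors = FALSE)
}

#' Fraction of mapped atoms with a changed one-bond atom color
#'
#' The fraction, over all mapped atoms, of atoms whose one-bond atom color
#' differs between the two sides of the mapping.  Because a one-bond color
#' changes exactly when an incident bond is made, broken, or changes order,
#' this fraction estimates the proportion of mapped atoms sitting at a
#' reaction center.
#'
#' @param mapping A `pair_atom_mapping` or `data.frame(compound_a, atom_a,
#'   compound_b, atom_b)`.
#' @param mols Named list of [molecule()] objects covering every compound id
#'   in the mapping.
#' @return A fraction in `[0, 1]`.
#' @export
changed_color_fraction <- function(mapping, mols) {
  df <- .mapping_df(mapping)
  if (nrow(df) == 0L) {
    mh_precondition_error("changed-color fraction is undefined for zero mapped atoms")
  }
  changed <- vapply(seq_len(nrow(df)), function(r) {
    ma <- mols[[df$compound_a[r]]]; mb <- mols[[df$compound_b[r]]]
    if (is.null(ma) || is.null(mb)) {
      mh_precondition_error(sprintf("missing structure for %s or %s",
                                    df$compound_a[r], df$compound_b[r]))
    }
    one_bond_color(ma, df$atom_a[r]) != one_bond_color(mb, df$atom_b[r])
  }, logical(1))
  mean(changed)
}

# Resonance classes of a molecule: symmetry classes, additionally merging
# terminal oxygens that hang off the same central atom with equal hydrogen
# counts once bond orders are collapsed (carboxylate / phosphate pattern).
.resonance_classes <- function(mol) {
  classes <- symmetry_classes(mol)
  cl_id <- integer(n_atoms(mol))
  for (ci in seq_along(classes)) cl_id[classes[[ci]]] <- ci
  hc <- hydrogen_counts(mol)
  el <- mol$atoms$element
  is_h <- el == "H"
  heavy_deg <- vapply(seq_len(n_atoms(mol)), function(i) {
    sum(!is_h[neighbors_of(mol, i)])
  }, integer(1))
  for (c_at in which(!is_h & el != "O")) {
    term_o <- neighbors_of(mol, c_at)
    term_o <- term_o[el[term_o] == "O" & heavy_deg[term_o] == 1L]
    if (length(term_o) < 2L) next
    for (h in unique(hc[term_o])) {
      grp <- term_o[hc[term_o] == h]
      if (length(grp) < 2L) next
      tgt <- min(cl_id[grp])
      cl_id[grp] <- tgt
    }
  }
  cl_id
}

#' Normalize a mapping over resonance-equivalent atoms
#'
#' Atoms that are chemically interchangeable (full symmetry-class members,
#' and terminal oxygens of carboxylate- or phosphate-like groups) may be
#' permuted in a mapping without changing its chemistry.  This returns the
#' canonical (lexicographically smallest) representative of the mapping's
#' equivalence class: within every group of mapped pairs joining one
#' resonance class of side A to one resonance class of side B, source and
#' target atoms are re-paired in ascending index order.
#'
#' @inheritParams changed_color_fraction
#' @return The normalized mapping, same type as the input.
#' @export
resonance_normalize <- function(mapping, mols) {
  df <- .mapping_df(mapping)
  if (nrow(df) == 0L) return(mapping)
  cls_cache <- list()
  get_cls <- function(id) {
    if (is.null(cls_cache[[id]])) cls_cache[[id]] <<- .resonance_classes(mols[[id]])
    cls_cache[[id]]
  }
  grp <- vapply(seq_len(nrow(df)), function(r) {
    ca <- get_cls(df$compound_a[r])[df$atom_a[r]]
    cb <- get_cls(df$compound_b[r])[df$atom_b[r]]
    paste(df$compound_a[r], ca, df$compound_b[r], cb)
  }, character(1))
  for (g in unique(grp)) {
    rows <- which(grp == g)
    if (length(rows) < 2L) next
    df$atom_a[rows] <- sort(df$atom_a[rows])
    df$atom_b[rows] <- sort(df$atom_b[rows])
  }
  df <- df[order(df$compound_a, df$atom_a), , drop = FALSE]
  rownames(df) <- NULL
  if (inherits(mapping, "pair_atom_mapping")) {
    keep <- paste(mapping$centers$atom_a, mapping$centers$atom_b) %in%
      paste(df$atom_a, df$atom_b)
    return(pair_atom_mapping(
      mapping$compound_a, mapping$compound_b,
      pairs = data.frame(atom_a = df$atom_a, atom_b = df$atom_b),
      centers = mapping$centers[keep, , drop = FALSE]
    ))
  }
  df
}

#' Compare two atom mappings of the same compounds
#'
#' Both mappings are resonance-normalized and their pair sets compared; the
#' verdict is `"same"` exactly when the normalized sets coincide.  The
#' changed one-bond-color fractions of both mappings are reported (these are
#' the coordinates of the consistency scatter plots).
#'
#' @param m1,m2 Mappings (see [changed_color_fraction()]) addressing the
#'   same molecules.
#' @param mols Named list of [molecule()] objects.
#' @return A `consistency_report`: list with `verdict`, `fraction_a`,
#'   `fraction_b`, `mapped_counts`, `resonance_corrected`.
#' @export
compare_mappings <- function(m1, m2, mols) {
  d1 <- .mapping_df(m1); d2 <- .mapping_df(m2)
  mols_1 <- sort(unique(c(d1$compound_a, d1$compound_b)))
  mols_2 <- sort(unique(c(d2$compound_a, d2$compound_b)))
  if (!identical(mols_1, mols_2)) {
    mh_precondition_error("the two mappings address different molecules")
  }
  key <- function(d) sort(paste(d$compound_a, d$atom_a, d$compound_b, d$atom_b))
  raw_same <- identical(key(d1), key(d2))
  n1 <- resonance_normalize(d1, mols)
  n2 <- resonance_normalize(d2, mols)
  same <- identical(key(n1), key(n2))
  structure(
    list(
      verdict = if (same) "same" else "inconsistent",
      fraction_a = changed_color_fraction(n1, mols),
      fraction_b = changed_color_fraction(n2, mols),
      mapped_counts = c(nrow(d1), nrow(d2)),
      resonance_corrected = same && !raw_same
    ),
    class = "consistency_report"
  )
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<%s: fractions %.3f / %.3f, %d / %d atoms%s>\n",
              x$verdict, x$fraction_a, x$fraction_b,
              x$mapped_counts[1], x$mapped_counts[2],
              if (x$resonance_corrected) ", resonance-corrected" else ""))
  invisible(x)
}

#' Assemble compound-pair mappings into a reaction-level mapping
#'
#' Takes the union of the pair mappings.  Source atoms mapped to multiple
#' targets (as happens when one compound participates in several compound
#' pairs with contradictory RDM descriptions) are retained and flagged in
#' the conflict set rather than silently dropped.
#'
#' @param pair_mappings List of `pair_atom_mapping` objects (or long-form
#'   data.frames).
#' @return List with `pairs` (the union, long form) and `conflicts` (rows of
#'   `pairs` whose source atom is multiply mapped).
#' @export
reaction_level_mapping <- function(pair_mappings) {
  if (length(pair_mappings) == 0L) {
    return(list(pairs = data.frame(compound_a = character(), atom_a = integer(),
                                   compound_b = character(), atom_b = integer()),
                conflicts = data.frame()))
  }
  df <- do.call(rbind, lapply(pair_mappings, .mapping_df))
  df <- unique(df)
  rownames(df) <- NULL
  src <- paste(df$compound_a, df$atom_a)
  dup <- src %in% src[duplicated(src)]
  list(pairs = df, conflicts = df[dup, , drop = FALSE])
}

#' Write a consistency scatter report as TSV
#'
#' One row per compared mapping pair with the two changed-color fractions
#' (`x` = first mapping, `y` = second), ready for external plotting.
#'
#' @param reports List of `consistency_report` objects, optionally named.
#' @param file Output path.
#' @return Invisibly, the written data.frame.
#' @export
write_consistency_tsv <- function(reports, file) {
  rows <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(
      id = if (!is.null(names(reports))) names(reports)[i] else as.character(i),
      verdict = r$verdict, fraction_a = r$fraction_a, fraction_b = r$fraction_b,
      n_a = r$mapped_counts[1], n_b = r$mapped_counts[2],
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
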