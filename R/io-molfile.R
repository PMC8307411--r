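# MDL molfile (V2000) and KEGG KCF connection-table readers, plus a
# deterministic molfile writer.  Only the fields the harmonization machinery
# needs are parsed: elements, charges, 2D coordinates, bond orders, wedge
# codes and (for KCF) KEGG atom types.

# molfile charge codes (atom block column 6): 0 = neutral, 1 = +3, 2 = +2,
# 3 = +1, 4 = doublet radical (ignored), 5 = -1, 6 = -2, 7 = -3
.charge_from_code <- function(code) {
  c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
    `5` = -1L, `6` = -2L, `7` = -3L)[as.character(code)]
}

.split_fields <- function(line) {
  strsplit(trimws(line), "[[:space:]]+")[[1]]
}

#' Parse an MDL molfile (V2000) block
#'
#' Reads the counts line, atom block, bond block and `M  CHG` property lines.
#' Atoms keep their 1-based file order.  R-group placeholder symbols
#' (`"R"`, `"R#"`, `"*"`, `"A"`, `"X"`, `"Q"`) are normalized to element
#' `"R"` with `is_r = TRUE`.  If any `M  CHG` property line is present it
#' supersedes all atom-line charge codes, as the format prescribes.
#'
#' @param text A single string or character vector of lines.
#' @param id Compound id; defaults to the molfile header name line if
#'   non-empty.
#' @return A [molecule()].
#' @export
parse_molfile <- function(text, id = NULL) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (length(lines) < 4L) mh_parse_error("molfile block shorter than 4 lines")
  counts <- .split_fields(lines[4L])
  na <- suppressWarnings(as.integer(counts[1L]))
  nb <- suppressWarnings(as.integer(counts[2L]))
  if (is.na(na) || is.na(nb) || na < 1L) {
    mh_parse_error(sprintf("malformed counts line: %s", lines[4L]))
  }
  if (length(lines) < 4L + na + nb) {
    mh_parse_error(sprintf(
      "counts line declares %d atoms and %d bonds but block has %d lines",
      na, nb, length(lines)
    ))
  }

  atom_lines <- lines[4L + seq_len(na)]
  atoms <- data.frame(
    element = character(na), charge = 0L, x = 0, y = 0,
    parity = "none", kegg_type = NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(na)) {
    f <- .split_fields(atom_lines[i])
    if (length(f) < 4L) {
      mh_parse_error(sprintf("malformed atom line %d: %s", i, atom_lines[i]))
    }
    atoms$x[i] <- as.numeric(f[1L])
    atoms$y[i] <- as.numeric(f[2L])
    atoms$element[i] <- f[4L]
    if (length(f) >= 6L) {
      chg <- .charge_from_code(f[6L])
      if (!is.na(chg)) atoms$charge[i] <- chg
    }
  }

  bonds <- NULL
  if (nb > 0L) {
    bond_lines <- lines[4L + na + seq_len(nb)]
    bonds <- data.frame(
      a = integer(nb), b = integer(nb), order = character(nb),
      wedge = "none", cis_trans = "none", stringsAsFactors = FALSE
    )
    for (i in seq_len(nb)) {
      f <- .split_fields(bond_lines[i])
      if (length(f) < 3L) {
        mh_parse_error(sprintf("malformed bond line %d: %s", i, bond_lines[i]))
      }
      a <- as.integer(f[1L]); b <- as.integer(f[2L])
      if (is.na(a) || is.na(b) || a < 1L || b < 1L || a > na || b > na) {
        mh_structural_error(sprintf(
          "bond line %d references atom outside 1..%d: %s", i, na, bond_lines[i]
        ))
      }
      bonds$a[i] <- a
      bonds$b[i] <- b
      bonds$order[i] <- switch(f[3L], `4` = "a", f[3L])
      if (length(f) >= 4L) {
        bonds$wedge[i] <- switch(f[4L], `1` = "up", `6` = "down", "none")
      }
    }
  }

  # property block: the first M CHG encountered resets all charges
  prop <- grep("^M  CHG", lines, value = TRUE)
  if (length(prop) > 0L) {
    atoms$charge <- 0L
    for (p in prop) {
      f <- .split_fields(sub("^M  CHG", "", p))
      k <- as.integer(f[1L])
      vals <- as.integer(f[-1L])
      for (j in seq_len(k)) {
        idx <- vals[2L * j - 1L]
        if (is.na(idx) || idx < 1L || idx > na) {
          mh_parse_error(sprintf("M CHG references atom %s outside 1..%d", idx, na))
        }
        atoms$charge[idx] <- vals[2L * j]
      }
    }
  }

  if (is.null(id)) {
    id <- trimws(lines[1L])
    if (!nzchar(id)) id <- "unnamed"
  }
  molecule(id, atoms, bonds, source = "molfile")
}

#' Write a molecule as an MDL molfile (V2000) block
#'
#' Field widths are fixed so output is byte-deterministic.  Charges are
#' emitted as `M  CHG` property lines.
#'
#' @param mol A [molecule()].
#' @return A single string (no trailing newline).
#' @export
write_molfile <- function(mol) {
  na <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  head <- c(mol$id, "  metharmonize", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb)
  at <- vapply(seq_len(na), function(i) {
    sym <- mol$atoms$element[i]
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            mol$atoms$x[i], mol$atoms$y[i], 0, sym)
  }, character(1))
  bd <- character(0)
  if (nb > 0L) {
    ocode <- vapply(mol$bonds$order, function(o) if (o == "a") "4" else o, character(1))
    wcode <- vapply(mol$bonds$wedge, function(w) {
      switch(w, up = "1", down = "6", "0")
    }, character(1))
    bd <- sprintf("%3d%3d%3d%3d  0  0  0",
                  mol$bonds$a, mol$bonds$b,
                  as.integer(ocode), as.integer(wcode))
  }
  props <- character(0)
  chg <- which(mol$atoms$charge != 0L)
  if (length(chg) > 0L) {
    props <- vapply(chg, function(i) {
      sprintf("M  CHG  1 %3d %3d", i, mol$atoms$charge[i])
    }, character(1))
  }
  paste(c(head, counts, at, bd, props, "M  END"), collapse = "\n")
}

# element symbol from a KEGG atom-type label: leading alphabetic prefix's
# element letter ("C1a" -> "C", "S2a" -> "S", "N1y" -> "N")
.kegg_type_element <- function(type) {
  m <- regmatches(type, regexpr("^[A-Za-z]+", type))
  if (length(m) == 0L || !nzchar(m)) return(NA_character_)
  substr(m, 1L, 1L)
}

KEGG_TYPE_PREFIXES <- c("C", "N", "O", "S", "P", "R", "H", "X", "Z")

#' Parse a KEGG KCF block
#'
#' KCF is a molfile-like connection table whose ATOM section carries KEGG
#' atom-type labels (e.g. `"C1a"`).  Column 2 of each ATOM line is stored as
#' `kegg_type` and the element is inferred from the label's leading letter.
#' Lines whose second field looks like an element symbol followed by a type
#' (index, type, element, x, y) are also accepted.
#'
#' @param text A single string or character vector of lines.
#' @param id Compound id; defaults to the ENTRY name when present.
#' @return A [molecule()] with `source = "kcf"`.
#' @export
parse_kcf <- function(text, id = NULL) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  atom_head <- grep("^ATOM", lines)
  if (length(atom_head) == 0L) mh_parse_error("KCF block has no ATOM section")
  na <- as.integer(.split_fields(lines[atom_head[1L]])[2L])
  if (is.na(na) || na < 1L) {
    mh_parse_error(sprintf("malformed ATOM count: %s", lines[atom_head[1L]]))
  }
  atoms <- data.frame(
    element = character(na), charge = 0L, x = 0, y = 0,
    parity = "none", kegg_type = NA_character_, stringsAsFactors = FALSE
  )
  for (i in seq_len(na)) {
    f <- .split_fields(lines[atom_head[1L] + i])
    if (length(f) < 2L) {
      mh_parse_error(sprintf("malformed KCF ATOM line %d", i))
    }
    type <- f[2L]
    atoms$kegg_type[i] <- type
    el <- .kegg_type_element(type)
    if (is.na(el) || !(el %in% KEGG_TYPE_PREFIXES)) {
      warning(sprintf("unknown KEGG atom type '%s' on ATOM line %d; kept verbatim", type, i),
              call. = FALSE)
      if (is.na(el)) el <- "C"
    }
    # explicit element column, when present, wins over the inferred prefix
    if (length(f) >= 3L && grepl("^[A-Z][a-z]?$", f[3L])) {
      el <- f[3L]
      xy <- suppressWarnings(as.numeric(f[4:5]))
    } else {
      xy <- suppressWarnings(as.numeric(f[3:4]))
    }
    atoms$element[i] <- el
    if (!is.na(xy[1L])) atoms$x[i] <- xy[1L]
    if (!is.na(xy[2L])) atoms$y[i] <- xy[2L]
  }

  bonds <- NULL
  bond_head <- grep("^BOND", lines)
  if (length(bond_head) > 0L) {
    nb <- as.integer(.split_fields(lines[bond_head[1L]])[2L])
    if (!is.na(nb) && nb > 0L) {
      bonds <- data.frame(
        a = integer(nb), b = integer(nb), order = character(nb),
        wedge = "none", cis_trans = "none", stringsAsFactors = FALSE
      )
      for (i in seq_len(nb)) {
        f <- .split_fields(lines[bond_head[1L] + i])
        if (length(f) < 4L) mh_parse_error(sprintf("malformed KCF BOND line %d", i))
        bonds$a[i] <- as.integer(f[2L])
        bonds$b[i] <- as.integer(f[3L])
        bonds$order[i] <- switch(f[4L], `4` = "a", f[4L])
      }
    }
  }

  if (is.null(id)) {
    ent <- grep("^ENTRY", lines, value = TRUE)
    id <- if (length(ent) > 0L) .split_fields(ent[1L])[2L] else "unnamed"
  }
  molecule(id, atoms, bonds, source = "kcf")
}
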