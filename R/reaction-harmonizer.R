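# Reaction harmonization: pairing reactions across two databases through
# shared EC numbers and the compound-pair list, hierarchical classification
# of reaction pairs, the iterative compound/reaction discovery loop, and
# atom-balance quality checks.

#' Parse an Enzyme Commission number
#'
#' Accepts 4-level (`"1.1.1.168"`) and 3-level (`"1.1.1.-"` or `"1.1.1"`)
#' forms; a trailing dash lowers the specified depth.
#'
#' @param text EC number string.
#' @return An object of class `"ec_number"`: list with `levels` (integer,
#'   `NA` for the unspecified field) and `specified_depth` (3 or 4).
#' @export
parse_ec <- function(text) {
  parts <- strsplit(trimws(text), ".", fixed = TRUE)[[1]]
  if (length(parts) == 3L) parts <- c(parts, "-")
  if (length(parts) != 4L) {
    mh_parse_error(sprintf("EC number '%s' must have 3 or 4 fields", text))
  }
  levels <- rep(NA_integer_, 4L)
  depth <- 4L
  for (i in seq_len(4L)) {
    if (parts[i] == "-") {
      if (i < 4L) mh_parse_error(sprintf("EC number '%s': only the last field may be '-'", text))
      depth <- 3L
    } else {
      v <- suppressWarnings(as.integer(parts[i]))
      if (is.na(v) || v < 0L) {
        mh_parse_error(sprintf("EC number '%s': field %d is not a non-negative integer", text, i))
      }
      levels[i] <- v
    }
  }
  structure(list(levels = levels, specified_depth = depth, text = text),
            class = "ec_number")
}

#' @export
print.ec_number <- function(x, ...) {
  cat(sprintf("<EC %s (depth %d)>\n", x$text, x$specified_depth))
  invisible(x)
}

.ec_key <- function(ec, depth) paste(ec$levels[seq_len(depth)], collapse = ".")

# EC tier between two sets of EC strings: "full", "three_level" or NA
.ec_tier <- function(ecs_a, ecs_b) {
  pa <- lapply(ecs_a, parse_ec)
  pb <- lapply(ecs_b, parse_ec)
  full_a <- vapply(Filter(function(e) e$specified_depth == 4L, pa), .ec_key, character(1), depth = 4L)
  full_b <- vapply(Filter(function(e) e$specified_depth == 4L, pb), .ec_key, character(1), depth = 4L)
  if (length(intersect(full_a, full_b)) > 0L) return("full")
  k3a <- vapply(pa, .ec_key, character(1), depth = 3L)
  k3b <- vapply(pb, .ec_key, character(1), depth = 3L)
  if (length(intersect(k3a, k3b)) > 0L) return("three_level")
  NA_character_
}

#' Construct a reaction
#'
#' @param id Reaction id.
#' @param ecs Character vector of EC numbers (each with at least three
#'   specified levels).
#' @param substrates,products `data.frame(compound, coef)`; a plain
#'   character vector is taken as unit coefficients.
#' @param mapping Optional reaction-level atom mapping:
#'   `data.frame(cpd_s, atom_s, cpd_p, atom_p)`.
#' @return Object of class `"reaction"`.
#' @export
reaction <- function(id, ecs, substrates, products, mapping = NULL) {
  fix_side <- function(x) {
    if (is.character(x)) x <- data.frame(compound = x, coef = 1L)
    x$coef <- as.integer(x$coef)
    x
  }
  for (e in ecs) parse_ec(e)   # validate
  structure(
    list(id = id, ecs = as.character(ecs),
         substrates = fix_side(substrates), products = fix_side(products),
         mapping = mapping),
    class = "reaction"
  )
}

#' @export
print.reaction <- function(x, ...) {
  side <- function(s) paste(sprintf("%d %s", s$coef, s$compound), collapse = " + ")
  cat(sprintf("<reaction %s [%s]: %s => %s>\n", x$id,
              paste(x$ecs, collapse = ","), side(x$substrates), side(x$products)))
  invisible(x)
}

#' Is a reaction generic?
#'
#' A reaction is generic when at least one participant compound contains an
#' R group.
#'
#' @param r A [reaction()].
#' @param compounds Named list of [molecule()] objects.
#' @export
is_generic_reaction <- function(r, compounds) {
  ids <- c(r$substrates$compound, r$products$compound)
  any(vapply(ids, function(i) {
    m <- compounds[[i]]
    !is.null(m) && any(m$atoms$is_r)
  }, logical(1)))
}

# lookup structure for compound pairs: keys "ida\rb idb"
.pair_lookup <- function(pairs) {
  lk <- new.env(parent = emptyenv())
  for (p in pairs) {
    key <- paste0(p$id_a, "\r", p$id_b)
    cur <- lk[[key]]
    if (is.null(cur) || rel_rank(p$relationship) > rel_rank(cur$relationship)) {
      assign(key, p, envir = lk)
    }
  }
  lk
}

.lookup_pair <- function(lk, id_a, id_b) {
  p <- lk[[paste0(id_a, "\r", id_b)]]
  if (!is.null(p)) return(p)
  if (identical(id_a, id_b)) {
    return(compound_pair(id_a, id_b, relationship("equivalence"),
                         origin = "identifier"))
  }
  NULL
}

# Match one reaction side's participant multiset against another under the
# compound-pair relation.  Returns the list of compound_pairs used (one per
# matched instance) maximizing the summed relationship rank, or NULL when no
# complete matching exists (unmatched instances are allowed only for
# ignorable entities).
.match_side <- function(ids_a, ids_b, lk, ignore) {
  best <- NULL
  nb <- length(ids_b)
  used <- rep(FALSE, nb)
  search <- function(i, acc, score) {
    if (i > length(ids_a)) {
      leftover <- ids_b[!used]
      if (!all(leftover %in% ignore)) return()
      if (is.null(best) || score > best$score) best <<- list(pairs = acc, score = score)
      return()
    }
    x <- ids_a[i]
    for (j in seq_len(nb)) {
      if (used[j]) next
      p <- .lookup_pair(lk, x, ids_b[j])
      if (is.null(p)) next
      used[j] <<- TRUE
      search(i + 1L, c(acc, list(p)), score + rel_rank(p$relationship))
      used[j] <<- FALSE
    }
    if (x %in% ignore) search(i + 1L, acc, score)
  }
  search(1L, list(), 0)
  best
}

reaction_pair <- function(id_a, id_b, rel, ec_tier, used) {
  structure(
    list(id_a = id_a, id_b = id_b, relationship = rel,
         ec_tier = ec_tier, compound_pairs_used = used),
    class = "reaction_pair"
  )
}

#' @export
print.reaction_pair <- function(x, ...) {
  cat(sprintf("<reaction pair %s ~ %s: %s (%s EC)>\n", x$id_a, x$id_b,
              x$relationship$kind, x$ec_tier))
  invisible(x)
}

#' Classify a reaction pair from its compound pairs
#'
#' All equivalence pairs give an equivalence relationship; equivalences plus
#' at least one generic-specific pair all pointing in the same database
#' direction give a generic-specific relationship; any loose pair, or
#' generic-specific pairs with inconsistent directions, gives a loose
#' relationship.
#'
#' @param used Non-empty list of [compound_pair()] objects.
#' @return A [relationship()].
#' @export
classify_reaction_pair <- function(used) {
  if (length(used) == 0L) mh_precondition_error("no compound pairs to classify")
  kinds <- vapply(used, function(p) p$relationship$kind, character(1))
  if (any(kinds == "loose")) return(relationship("loose"))
  dirs <- unique(vapply(used[kinds == "generic_specific"],
                        function(p) p$relationship$direction, character(1)))
  if (length(dirs) == 0L) return(relationship("equivalence"))
  if (length(dirs) > 1L) return(relationship("loose"))
  relationship("generic_specific", dirs)
}

#' Pair reactions across two databases
#'
#' A reaction pair forms when the two reactions share an EC number at the
#' requested tier and there is a perfect matching between the participant
#' multisets (stoichiometry-expanded) under the compound-pair relation,
#' allowing unmatched entities only from the ignorable set (`"H+"` by
#' default).  Both substrate/product orientations are tried and the
#' orientation yielding the strongest relationship wins.  With
#' `ec_mode = "three_level"`, pairs lacking a full 4-level EC match are
#' still formed when the first three levels agree, and are flagged
#' `ec_tier = "three_level"`.
#'
#' @param rxns_a,rxns_b Lists of [reaction()] objects.
#' @param pairs List of [compound_pair()] objects relating the databases.
#' @param ec_mode `"full"` or `"three_level"`.
#' @param ignore Compound ids that may be left unmatched.
#' @return List of `reaction_pair` objects.
#' @export
pair_reactions <- function(rxns_a, rxns_b, pairs, ec_mode = c("full", "three_level"),
                           ignore = "H+") {
  ec_mode <- match.arg(ec_mode)
  lk <- .pair_lookup(pairs)
  out <- list()
  for (ra in rxns_a) {
    for (rb in rxns_b) {
      tier <- .ec_tier(ra$ecs, rb$ecs)
      if (is.na(tier)) next
      if (tier == "three_level" && ec_mode == "full") next
      exp_side <- function(s) rep(s$compound, s$coef)
      combos <- list(
        list(a_s = exp_side(ra$substrates), a_p = exp_side(ra$products),
             b_s = exp_side(rb$substrates), b_p = exp_side(rb$products)),
        list(a_s = exp_side(ra$substrates), a_p = exp_side(ra$products),
             b_s = exp_side(rb$products), b_p = exp_side(rb$substrates))
      )
      best <- NULL
      for (cb in combos) {
        m1 <- .match_side(cb$a_s, cb$b_s, lk, ignore)
        if (is.null(m1)) next
        m2 <- .match_side(cb$a_p, cb$b_p, lk, ignore)
        if (is.null(m2)) next
        used <- c(m1$pairs, m2$pairs)
        if (length(used) == 0L) next
        rel <- classify_reaction_pair(used)
        if (is.null(best) || rel_rank(rel) > rel_rank(best$rel)) {
          best <- list(rel = rel, used = used)
        }
      }
      if (!is.null(best)) {
        out[[length(out) + 1L]] <- reaction_pair(ra$id, rb$id, best$rel, tier, best$used)
      }
    }
  }
  out
}

# Near-miss reaction pairs: shared EC at the requested tier, at least one
# matched compound pair, and some unmatched (non-ignorable) compounds.
.near_misses <- function(rxns_a, rxns_b, lk, ec_mode, ignore) {
  out <- list()
  for (ra in rxns_a) {
    for (rb in rxns_b) {
      tier <- .ec_tier(ra$ecs, rb$ecs)
      if (is.na(tier)) next
      if (tier == "three_level" && ec_mode == "full") next
      ids_a <- unique(c(ra$substrates$compound, ra$products$compound))
      ids_b <- unique(c(rb$substrates$compound, rb$products$compound))
      has_pair_a <- vapply(ids_a, function(x) {
        any(vapply(ids_b, function(y) !is.null(.lookup_pair(lk, x, y)), logical(1)))
      }, logical(1))
      has_pair_b <- vapply(ids_b, function(y) {
        any(vapply(ids_a, function(x) !is.null(.lookup_pair(lk, x, y)), logical(1)))
      }, logical(1))
      n_matched <- sum(has_pair_a)
      un_a <- setdiff(ids_a[!has_pair_a], ignore)
      un_b <- setdiff(ids_b[!has_pair_b], ignore)
      if (n_matched >= 1L && (length(un_a) > 0L || length(un_b) > 0L)) {
        out[[length(out) + 1L]] <- list(
          ra = ra, rb = rb, unmatched_a = un_a, unmatched_b = un_b
        )
      }
    }
  }
  out
}

# flip a compound pair validated with the generic compound taken from
# database B so it is stored in (A, B) orientation
.flip_pair <- function(p) {
  mp <- p$mapping
  if (!is.null(mp)) mp <- data.frame(pattern = mp$target, target = mp$pattern)
  compound_pair(p$id_b, p$id_a, reverse_relationship(p$relationship),
                mapping = mp, origin = p$origin)
}

#' Iterative compound and reaction harmonization
#'
#' Round 0 seeds the compound-pair list from the loose coloring identifiers.
#' Each round pairs the reactions, then inspects near-miss reaction pairs
#' (shared EC, at least one matched compound pair, some unmatched
#' compounds): R-containing compounds are paired against every compound of
#' the partner reaction and validated as generic pairs, and unmatched
#' same-formula compounds are run through the tautomer and ring-chain
#' validators.  Newly validated pairs are appended and the process repeats
#' until no new compound pairs are discovered; the pair list grows
#' monotonically within a finite universe, so termination is guaranteed.
#'
#' @param db_a,db_b Lists of [molecule()] objects (database A and B).
#' @param rxns_a,rxns_b Lists of [reaction()] objects.
#' @param ec_mode `"full"` or `"three_level"`.
#' @param ignore Ignorable entity ids (default `"H+"`).
#' @param max_rounds Safety cap on rounds.
#' @param verbose Emit one summary line per round.
#' @return List with `compound_pairs`, `reaction_pairs`, `rounds`, and
#'   `new_by_round` (number of compound pairs discovered in each round;
#'   round 1 covers the identifier seeding).
#' @export
harmonization_loop <- function(db_a, db_b, rxns_a, rxns_b,
                               ec_mode = c("full", "three_level"),
                               ignore = "H+", max_rounds = 25L,
                               verbose = FALSE) {
  ec_mode <- match.arg(ec_mode)
  names(db_a) <- vapply(db_a, `[[`, character(1), "id")
  names(db_b) <- vapply(db_b, `[[`, character(1), "id")
  pairs <- detect_pairs_by_identifier(db_a, db_b)
  new_by_round <- length(pairs)
  tried <- character(0)
  round <- 1L
  repeat {
    round <- round + 1L
    if (round > max_rounds) break
    lk <- .pair_lookup(pairs)
    nm <- .near_misses(rxns_a, rxns_b, lk, ec_mode, ignore)
    found <- list()
    have <- vapply(pairs, function(p) paste0(p$id_a, "\r", p$id_b), character(1))
    add_candidate <- function(p) {
      key <- paste0(p$id_a, "\r", p$id_b)
      if (!(key %in% have)) {
        found[[length(found) + 1L]] <<- p
        have <<- c(have, key)
      }
    }
    for (x in nm) {
      ids_a <- unique(c(x$ra$substrates$compound, x$ra$products$compound))
      ids_b <- unique(c(x$rb$substrates$compound, x$rb$products$compound))
      # generic candidates: R compounds of one reaction vs all compounds of
      # the partner reaction
      for (ga in ids_a) {
        ma <- db_a[[ga]]
        if (is.null(ma) || !any(ma$atoms$is_r)) next
        for (cb in ids_b) {
          mb <- db_b[[cb]]
          if (is.null(mb)) next
          key <- paste("g", ga, cb)
          if (key %in% tried) next
          tried <- c(tried, key)
          p <- validate_generic_pair(ma, mb)
          if (!is_absent(p)) add_candidate(p)
        }
      }
      for (gb in ids_b) {
        mb <- db_b[[gb]]
        if (is.null(mb) || !any(mb$atoms$is_r)) next
        for (ca in ids_a) {
          ma <- db_a[[ca]]
          if (is.null(ma)) next
          key <- paste("gb", gb, ca)
          if (key %in% tried) next
          tried <- c(tried, key)
          p <- validate_generic_pair(mb, ma)
          if (!is_absent(p)) add_candidate(.flip_pair(p))
        }
      }
      # same-formula unmatched compounds: tautomer / ring-chain validation
      for (ua in x$unmatched_a) {
        ma <- db_a[[ua]]
        if (is.null(ma) || any(ma$atoms$is_r)) next
        for (ub in x$unmatched_b) {
          mb <- db_b[[ub]]
          if (is.null(mb) || any(mb$atoms$is_r)) next
          if (!identical(mol_formula(ma), mol_formula(mb))) next
          key <- paste("t", ua, ub)
          if (key %in% tried) next
          tried <- c(tried, key)
          p <- validate_tautomer_pair(ma, mb)
          if (is_absent(p)) {
            p <- validate_ring_chain_pair(ma, mb)
            if (is_absent(p)) {
              p2 <- validate_ring_chain_pair(mb, ma)
              p <- if (is_absent(p2)) p2 else .flip_pair(p2)
            }
          }
          if (!is_absent(p)) add_candidate(p)
        }
      }
    }
    new_by_round <- c(new_by_round, length(found))
    if (verbose) {
      message(sprintf("round %d: %d new compound pairs", round, length(found)))
    }
    if (length(found) == 0L) break
    pairs <- c(pairs, found)
  }
  rps <- pair_reactions(rxns_a, rxns_b, pairs, ec_mode, ignore)
  list(compound_pairs = pairs, reaction_pairs = rps,
       rounds = length(new_by_round), new_by_round = new_by_round)
}

#' Quality-check an atom-resolved reaction
#'
#' Classifies a reaction as `"complete"`, `"incomplete_reaction"`
#' (stoichiometry-weighted element counts differ between the two sides),
#' `"incorrect_mapping"` (an atom mapping joins atoms of different
#' elements), or `"incomplete_mapping"` (fewer atoms mapped than the
#' balanceable heavy atoms of a side).
#'
#' @param r A [reaction()].
#' @param compounds Named list of [molecule()] objects.
#' @param exclude_h Exclude hydrogen from the balance and coverage checks
#'   (default `TRUE`; databases disagree on explicit protons).
#' @return One of the four category strings.
#' @export
quality_check_reaction <- function(r, compounds, exclude_h = TRUE) {
  count_side <- function(side) {
    tot <- integer(0)
    for (i in seq_len(nrow(side))) {
      m <- compounds[[side$compound[i]]]
      if (is.null(m)) mh_precondition_error(sprintf("missing structure for %s", side$compound[i]))
      f <- mol_formula(m) * side$coef[i]
      for (el in names(f)) tot[el] <- (if (el %in% names(tot)) tot[el] else 0L) + f[el]
    }
    if (exclude_h) tot <- tot[names(tot) != "H"]
    tot[tot > 0L]
  }
  fs <- count_side(r$substrates); fp <- count_side(r$products)
  fs <- fs[order(names(fs))]; fp <- fp[order(names(fp))]
  if (!identical(fs, fp)) return("incomplete_reaction")
  mp <- r$mapping
  if (!is.null(mp) && nrow(mp) > 0L) {
    for (i in seq_len(nrow(mp))) {
      es <- compounds[[mp$cpd_s[i]]]$atoms$element[mp$atom_s[i]]
      ep <- compounds[[mp$cpd_p[i]]]$atoms$element[mp$atom_p[i]]
      if (!identical(es, ep)) return("incorrect_mapping")
    }
  }
  balanceable <- sum(vapply(seq_len(nrow(r$substrates)), function(i) {
    m <- compounds[[r$substrates$compound[i]]]
    r$substrates$coef[i] * length(heavy_indices(m))
  }, numeric(1)))
  n_mapped <- if (is.null(mp)) 0L else nrow(mp)
  if (n_mapped < balanceable) return("incomplete_mapping")
  "complete"
}

#' Export reaction pairs as TSV
#'
#' @param rpairs List of `reaction_pair` objects.
#' @param file Output path.
#' @return Invisibly, the written data.frame.
#' @export
write_reaction_pairs_tsv <- function(rpairs, file) {
  rows <- do.call(rbind, lapply(rpairs, function(p) {
    data.frame(
      id_a = p$id_a, id_b = p$id_b,
      relationship = p$relationship$kind,
      direction = p$relationship$direction,
      ec_tier = p$ec_tier,
      compound_pairs = paste(vapply(p$compound_pairs_used, function(cp) {
        paste0(cp$id_a, "~", cp$id_b)
      }, character(1)), collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}

#' Read reactions from a JSON file
#'
#' The file holds an array of objects with fields `id`, `ecs`, `substrates`,
#' `products` (objects of `compound`/`coef`) and optional `mapping`.
#'
#' @param file Path to a JSON file.
#' @return List of [reaction()] objects.
#' @export
read_reactions_json <- function(file) {
  raw <- jsonlite::fromJSON(file, simplifyDataFrame = TRUE)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  lapply(raw, function(x) {
    if (is.data.frame(x)) x <- as.list(x)
    reaction(
      id = x$id[[1]], ecs = unlist(x$ecs),
      substrates = as.data.frame(x$substrates),
      products = as.data.frame(x$products),
      mapping = if (!is.null(x$mapping) && length(x$mapping) > 0)
        as.data.frame(x$mapping) else NULL
    )
  })
}

#' Write reactions to a JSON file
#'
#' @param rxns List of [reaction()] objects.
#' @param file Output path.
#' @export
write_reactions_json <- function(rxns, file) {
  payload <- lapply(rxns, function(r) {
    list(id = r$id, ecs = as.list(r$ecs),
         substrates = r$substrates, products = r$products,
         mapping = r$mapping)
  })
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
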