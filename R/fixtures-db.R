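# Planted mini-databases for end-to-end harmonization: two compound
# collections plus reaction sets realizing every pair category, with the
# ground truth recorded.  The layout is chosen so that generic, tautomer and
# ring-chain pairs are only discoverable through the reaction near-miss
# mechanism, and the ring-chain pair only after a tautomer pair has been
# discovered (a second round of iteration).

# distinctive-element tagging keeps the generic validations from matching
# unintended partners: generic compounds and their specific partners carry
# sulfur, nothing else in their reactions does.
.gen_tagged_generic <- function(seed_off, id_a, id_b, size = 6L) {
  for (k in 1:60) {
    gp <- gen_pair("generic_specific", size = size, id_a = id_a, id_b = id_b)
    if (sum(gp$b$atoms$element == "S") >= 1L) return(gp)
  }
  mh_structural_error("could not tag a generic pair with sulfur")
}

#' Generate planted mini-databases for the harmonization loop
#'
#' Builds two compound databases (30 compounds each by default) and 12
#' reactions per side realizing all five pair categories: equivalence, loose
#' (conflicting parity), generic-specific via chemical details, generic
#' R-group pairs (different formula, discoverable only through reactions),
#' tautomers, and one ring-chain pair that becomes discoverable only after a
#' tautomer pair has entered the pair list.  All planted relationships and
#' the expected reaction-pair classifications are returned as ground truth.
#'
#' @param seed Seed for the generators.
#' @param n_equivalence,n_loose,n_stereo,n_generic,n_tautomer Planted counts
#'   per category (defaults realize a 30-compound database per side).
#' @param n_fillers Unpaired compounds per side.
#' @return List with `db_a`, `db_b` (lists of molecules), `rxns_a`, `rxns_b`
#'   (lists of reactions), and `truth` (`compound_pairs` and
#'   `reaction_pairs` data.frames; compound truth carries the earliest round
#'   in which a pair is discoverable, 1 = identifier seeding).
#' @export
gen_harmonization_fixture <- function(seed = 1L, n_equivalence = 8L,
                                      n_loose = 3L, n_stereo = 2L,
                                      n_generic = 3L, n_tautomer = 2L,
                                      n_fillers = 11L) {
  stopifnot(n_equivalence >= 8L, n_loose >= 3L, n_stereo >= 2L,
            n_generic >= 3L, n_tautomer >= 2L)
  with_seed(seed, {
    db_a <- list(); db_b <- list()
    truth_cp <- data.frame()
    add_cp <- function(id_a, id_b, kind, direction, origin, round) {
      truth_cp <<- rbind(truth_cp, data.frame(
        id_a = id_a, id_b = id_b, kind = kind, direction = direction,
        origin = origin, round = round, stringsAsFactors = FALSE
      ))
    }
    seen_ids <- character(0)
    # identifier families must be globally distinct in loose identifier so
    # no unplanned identifier pair forms
    fresh <- function(make) {
      for (k in 1:80) {
        out <- make()
        keys <- unique(c(as.character(compound_identifier(out$a, "loose")),
                         as.character(compound_identifier(out$b, "loose"))))
        if (!any(keys %in% seen_ids)) {
          seen_ids <<- c(seen_ids, keys)
          return(out)
        }
      }
      mh_structural_error("could not generate a fresh compound family")
    }

    for (i in seq_len(n_equivalence)) {
      gp <- fresh(function() gen_pair("equivalence", size = 5L + (i %% 4L),
                                      id_a = sprintf("A_eq%d", i),
                                      id_b = sprintf("B_eq%d", i)))
      db_a[[gp$a$id]] <- gp$a; db_b[[gp$b$id]] <- gp$b
      add_cp(gp$a$id, gp$b$id, "equivalence", "none", "identifier", 1L)
    }
    for (i in seq_len(n_loose)) {
      gp <- fresh(function() gen_pair("loose", size = 6L + (i %% 3L),
                                      id_a = sprintf("A_ls%d", i),
                                      id_b = sprintf("B_ls%d", i)))
      db_a[[gp$a$id]] <- gp$a; db_b[[gp$b$id]] <- gp$b
      add_cp(gp$a$id, gp$b$id, "loose", "none", "identifier", 1L)
    }
    for (i in seq_len(n_stereo)) {
      gp <- fresh(function() gen_pair("stereo_specific", size = 6L + (i %% 3L),
                                      id_a = sprintf("A_st%d", i),
                                      id_b = sprintf("B_st%d", i)))
      if (i == 2L) {
        # flip the second family so its direction is b_to_a
        tmp <- gp$a; gp$a <- gp$b; gp$b <- tmp
        gp$a$id <- sprintf("A_st%d", i); gp$b$id <- sprintf("B_st%d", i)
        gp$expected$direction <- "b_to_a"
      }
      db_a[[gp$a$id]] <- gp$a; db_b[[gp$b$id]] <- gp$b
      add_cp(gp$a$id, gp$b$id, "generic_specific", gp$expected$direction,
             "identifier", 1L)
    }
    for (i in seq_len(n_generic)) {
      gp <- fresh(function() .gen_tagged_generic(i, sprintf("A_g%d", i),
                                                 sprintf("B_sp%d", i)))
      db_a[[gp$a$id]] <- gp$a; db_b[[gp$b$id]] <- gp$b
      add_cp(gp$a$id, gp$b$id, "generic_specific", "a_to_b",
             "generic_validation", 2L)
    }
    for (i in seq_len(n_tautomer)) {
      gp <- fresh(function() gen_pair("tautomer", size = 5L + (i %% 3L),
                                      id_a = sprintf("A_t%d", i),
                                      id_b = sprintf("B_t%d", i)))
      db_a[[gp$a$id]] <- gp$a; db_b[[gp$b$id]] <- gp$b
      add_cp(gp$a$id, gp$b$id, "equivalence", "none", "tautomer", 2L)
    }
    rc <- fresh(function() gen_pair("ring_chain", id_a = "A_rc1", id_b = "B_rc1"))
    db_a[["A_rc1"]] <- rc$a; db_b[["B_rc1"]] <- rc$b
    add_cp("A_rc1", "B_rc1", "equivalence", "none", "ring_chain", 3L)

    for (i in seq_len(n_fillers)) {
      fa <- fresh(function() {
        m <- gen_molecule(4L + (i %% 5L), id = sprintf("A_x%d", i))
        list(a = m, b = m)
      })
      db_a[[fa$a$id]] <- fa$a
      fb <- fresh(function() {
        m <- gen_molecule(5L + (i %% 4L), id = sprintf("B_x%d", i))
        list(a = m, b = m)
      })
      db_b[[fb$a$id]] <- fb$a
    }

    # reactions: one EC per planted reaction pair so only planted pairings
    # share EC numbers
    mk <- function(id, ec, subs, prods) reaction(id, ec, subs, prods)
    rxns_a <- list(
      mk("A_R1", "1.1.1.1", c("A_eq1", "A_eq2"), "A_eq3"),
      mk("A_R2", "1.1.1.2", "A_eq4", c("A_eq5", "H+")),
      mk("A_R3", "1.1.1.3", c("A_g1", "A_eq6"), "A_eq7"),
      mk("A_R4", "1.1.1.4", c("A_g2", "A_eq8"), "A_eq1"),
      mk("A_R5", "1.1.1.5", c("A_t1", "A_eq2"), "A_eq3"),
      mk("A_R6", "1.1.1.6", c("A_t2", "A_eq4"), "A_eq5"),
      mk("A_R7", "1.1.1.7", "A_t2", "A_rc1"),
      mk("A_R8", "1.1.1.8", c("A_ls1", "A_eq7"), "A_eq8"),
      mk("A_R9", "1.1.1.9", c("A_g3", "A_st2"), "A_eq2"),
      mk("A_R10", "1.1.1.10", c("A_st1", "A_eq3"), "A_eq4"),
      mk("A_R11", "1.1.1.11", c("A_eq5", "A_ls2"), "A_ls3"),
      mk("A_R12", "1.2.3.4", "A_eq1", "A_eq2")
    )
    rxns_b <- list(
      mk("B_R1", "1.1.1.1", c("B_eq1", "B_eq2"), "B_eq3"),
      mk("B_R2", "1.1.1.2", "B_eq4", "B_eq5"),
      mk("B_R3", "1.1.1.3", c("B_sp1", "B_eq6"), "B_eq7"),
      mk("B_R4", "1.1.1.4", c("B_sp2", "B_eq8"), "B_eq1"),
      mk("B_R5", "1.1.1.5", c("B_t1", "B_eq2"), "B_eq3"),
      mk("B_R6", "1.1.1.6", c("B_t2", "B_eq4"), "B_eq5"),
      mk("B_R7", "1.1.1.7", "B_t2", "B_rc1"),
      mk("B_R8", "1.1.1.8", c("B_ls1", "B_eq7"), "B_eq8"),
      mk("B_R9", "1.1.1.9", c("B_sp3", "B_st2"), "B_eq2"),
      mk("B_R10", "1.1.1.10", c("B_st1", "B_eq3"), "B_eq4"),
      mk("B_R11", "1.1.1.11", c("B_eq5", "B_ls2"), "B_ls3"),
      mk("B_R12", "1.2.3.7", "B_eq1", "B_eq2")
    )
    truth_rp <- data.frame(
      id_a = sprintf("A_R%d", 1:11), id_b = sprintf("B_R%d", 1:11),
      kind = c("equivalence", "equivalence", "generic_specific",
               "generic_specific", "equivalence", "equivalence",
               "equivalence", "loose", "loose", "generic_specific", "loose"),
      direction = c("none", "none", "a_to_b", "a_to_b", "none", "none",
                    "none", "none", "none", "a_to_b", "none"),
      stringsAsFactors = FALSE
    )
    list(db_a = db_a, db_b = db_b, rxns_a = rxns_a, rxns_b = rxns_b,
         truth = list(compound_pairs = truth_cp, reaction_pairs = truth_rp))
  })
}

#' Write a fixture tree to disk
#'
#' Serializes the planted databases as molfile trees plus reaction JSON
#' files, the on-disk layout the command-line interface consumes.
#'
#' @param fixture Output of [gen_harmonization_fixture()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_fixture_tree <- function(fixture, dir) {
  for (side in c("a", "b")) {
    mdir <- file.path(dir, paste0("compounds_", side))
    dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    for (m in fixture[[paste0("db_", side)]]) {
      writeLines(write_molfile(m), file.path(mdir, paste0(m$id, ".mol")))
    }
    # ignorable proton entity referenced by some reactions
    proton <- molecule("H+", data.frame(element = "H", charge = 1L))
    writeLines(write_molfile(proton), file.path(mdir, "H+.mol"))
    write_reactions_json(fixture[[paste0("rxns_", side)]],
                         file.path(dir, paste0("reactions_", side, ".json")))
  }
  invisible(dir)
}

#' Read a directory of molfiles
#'
#' @param dir Directory containing `.mol` files.
#' @return Named list of molecules (ids from file names).
#' @export
read_molfile_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.mol$", full.names = TRUE))
  mols <- lapply(files, function(f) {
    parse_molfile(readLines(f), id = sub("\\.mol$", "", basename(f)))
  })
  stats::setNames(mols, vapply(mols, `[[`, character(1), "id"))
}
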