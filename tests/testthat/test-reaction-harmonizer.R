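eqrel <- function() relationship("equivalence")
gsrel <- function(d) relationship("generic_specific", d)

cp <- function(a, b, rel) compound_pair(a, b, rel, origin = "identifier")

test_that("EC numbers parse with depth from the dash convention", {
  e <- parse_ec("1.1.1.168")
  expect_equal(e$levels, c(1L, 1L, 1L, 168L))
  expect_equal(e$specified_depth, 4L)
  expect_equal(parse_ec("2.7.1.-")$specified_depth, 3L)
  expect_equal(parse_ec("2.7.1")$specified_depth, 3L)
  expect_error(parse_ec("abc"), class = "mh_parse_error")
  expect_error(parse_ec("1.2"), class = "mh_parse_error")
  expect_error(parse_ec("1.-.3.4"), class = "mh_parse_error")
})

test_that("reaction pairing requires a shared EC and fully paired compounds", {
  ra <- reaction("ra", "1.1.1.1", c("a1", "a2"), "a3")
  rb <- reaction("rb", "1.1.1.1", c("b1", "b2"), "b3")
  pairs <- list(cp("a1", "b1", eqrel()), cp("a2", "b2", eqrel()),
                cp("a3", "b3", eqrel()))
  rp <- pair_reactions(list(ra), list(rb), pairs)
  expect_length(rp, 1L)
  expect_equal(rp[[1]]$relationship$kind, "equivalence")
  expect_equal(rp[[1]]$ec_tier, "full")

  # an unpaired compound blocks the pair
  rp2 <- pair_reactions(list(ra), list(rb), pairs[-1])
  expect_length(rp2, 0L)

  # an extra H+ on one side is ignorable
  ra_h <- reaction("rah", "1.1.1.1", c("a1", "a2"), c("a3", "H+"))
  rp3 <- pair_reactions(list(ra_h), list(rb), pairs)
  expect_length(rp3, 1L)

  # a non-ignorable extra entity is not
  ra_w <- reaction("raw", "1.1.1.1", c("a1", "a2"), c("a3", "H2O"))
  expect_length(pair_reactions(list(ra_w), list(rb), pairs), 0L)
})

test_that("substrate/product orientation is tried both ways", {
  ra <- reaction("ra", "1.1.1.1", "a1", "a2")
  rb <- reaction("rb", "1.1.1.1", "b2", "b1")
  pairs <- list(cp("a1", "b1", eqrel()), cp("a2", "b2", eqrel()))
  rp <- pair_reactions(list(ra), list(rb), pairs)
  expect_length(rp, 1L)
})

test_that("three-level EC relaxation forms pairs the full mode misses", {
  ra <- reaction("ra", "1.1.1.5", "a1", "a2")
  rb <- reaction("rb", "1.1.1.9", "b1", "b2")
  pairs <- list(cp("a1", "b1", eqrel()), cp("a2", "b2", eqrel()))
  expect_length(pair_reactions(list(ra), list(rb), pairs, ec_mode = "full"), 0L)
  rp <- pair_reactions(list(ra), list(rb), pairs, ec_mode = "three_level")
  expect_length(rp, 1L)
  expect_equal(rp[[1]]$ec_tier, "three_level")
  # a full match never gets the three_level tier
  rb2 <- reaction("rb2", "1.1.1.5", "b1", "b2")
  rp2 <- pair_reactions(list(ra), list(rb2), pairs, ec_mode = "three_level")
  expect_equal(rp2[[1]]$ec_tier, "full")
})

test_that("reaction pair classification aggregates compound relationships", {
  expect_equal(classify_reaction_pair(list(cp("a", "b", eqrel()),
                                           cp("c", "d", eqrel())))$kind,
               "equivalence")
  rel <- classify_reaction_pair(list(cp("a", "b", eqrel()),
                                     cp("c", "d", gsrel("a_to_b"))))
  expect_equal(rel$kind, "generic_specific")
  expect_equal(rel$direction, "a_to_b")
  expect_equal(classify_reaction_pair(list(cp("a", "b", gsrel("a_to_b")),
                                           cp("c", "d", gsrel("b_to_a"))))$kind,
               "loose")
  # adding a loose pair can only move the class toward loose
  for (used in list(
    list(cp("a", "b", eqrel())),
    list(cp("a", "b", gsrel("a_to_b"))),
    list(cp("a", "b", gsrel("b_to_a")), cp("c", "d", gsrel("b_to_a")))
  )) {
    before <- classify_reaction_pair(used)
    after <- classify_reaction_pair(c(used, list(cp("x", "y", relationship("loose")))))
    expect_equal(after$kind, "loose")
    expect_lte(metharmonize:::rel_rank(after), metharmonize:::rel_rank(before))
  }
  expect_error(classify_reaction_pair(list()), class = "mh_precondition_error")
})

test_that("pairing is symmetric under swapping the databases", {
  fx <- gen_harmonization_fixture(seed = 3)
  pairs <- detect_pairs_by_identifier(fx$db_a, fx$db_b)
  fwd <- pair_reactions(fx$rxns_a, fx$rxns_b, pairs)
  flipped <- lapply(pairs, metharmonize:::.flip_pair)
  bwd <- pair_reactions(fx$rxns_b, fx$rxns_a, flipped)
  key <- function(rp, swap = FALSE) {
    sort(vapply(rp, function(p) {
      ids <- if (swap) c(p$id_b, p$id_a) else c(p$id_a, p$id_b)
      dir <- p$relationship$direction
      if (swap && dir != "none") dir <- if (dir == "a_to_b") "b_to_a" else "a_to_b"
      paste(ids[1], ids[2], p$relationship$kind, dir)
    }, character(1)))
  }
  expect_equal(key(fwd), key(bwd, swap = TRUE))
})

test_that("quality check separates the three defect categories", {
  mols <- list(
    m1 = mk_mol(c("C", "C", "O"), path_bonds(3), id = "m1"),
    m2 = mk_mol(c("C", "C", "O"), path_bonds(3), id = "m2"),
    m_short = mk_mol(c("C", "O"), path_bonds(2), id = "m_short")
  )
  full_map <- data.frame(cpd_s = "m1", atom_s = 1:3, cpd_p = "m2", atom_p = 1:3)

  balanced <- reaction("r1", "1.1.1.1", "m1", "m2", mapping = full_map)
  expect_equal(quality_check_reaction(balanced, mols), "complete")

  # a missing product carbon unbalances the reaction
  short <- reaction("r2", "1.1.1.1", "m1", "m_short")
  expect_equal(quality_check_reaction(short, mols), "incomplete_reaction")

  # mapping a carbon onto an oxygen is an incorrect mapping
  bad_map <- data.frame(cpd_s = "m1", atom_s = c(1L, 3L), cpd_p = "m2",
                        atom_p = c(3L, 1L))
  wrong <- reaction("r3", "1.1.1.1", "m1", "m2", mapping = bad_map)
  expect_equal(quality_check_reaction(wrong, mols), "incorrect_mapping")

  partial <- reaction("r4", "1.1.1.1", "m1", "m2",
                      mapping = full_map[1, , drop = FALSE])
  expect_equal(quality_check_reaction(partial, mols), "incomplete_mapping")
})

test_that("reactions serialize to JSON and back", {
  tf <- withr::local_tempfile(fileext = ".json")
  rxns <- list(
    reaction("r1", c("1.1.1.1", "2.2.2.2"), c("a", "b"), "c"),
    reaction("r2", "1.1.1.2", data.frame(compound = "x", coef = 2L), "y",
             mapping = data.frame(cpd_s = "x", atom_s = 1L, cpd_p = "y", atom_p = 1L))
  )
  write_reactions_json(rxns, tf)
  back <- read_reactions_json(tf)
  expect_length(back, 2L)
  expect_equal(back[[1]]$ecs, c("1.1.1.1", "2.2.2.2"))
  expect_equal(back[[2]]$substrates$coef, 2L)
  expect_equal(back[[2]]$mapping$atom_s, 1L)
})
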