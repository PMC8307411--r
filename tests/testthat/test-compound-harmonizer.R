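identity_map <- function(n) data.frame(pattern = seq_len(n), target = seq_len(n))

test_that("chemical-detail classification follows the trichotomy", {
  m <- gen_pair("stereo_specific", seed = 41)
  iso <- graph_isomorphism(m$a, m$b)

  # self pair: equivalence
  nh <- length(metharmonize:::heavy_indices(m$a))
  expect_equal(classify_chemical_details(m$a, m$a, identity_map(nh))$kind,
               "equivalence")

  # subset: generic-specific pointing at the more specified compound,
  # reversing when the arguments swap
  rel <- classify_chemical_details(m$a, m$b, iso)
  expect_equal(rel$kind, "generic_specific")
  expect_equal(rel$direction, "a_to_b")
  rev_map <- data.frame(pattern = iso$mapping$target, target = iso$mapping$pattern)
  rel_rev <- classify_chemical_details(m$b, m$a, rev_map)
  expect_equal(rel_rev$kind, "generic_specific")
  expect_equal(rel_rev$direction, "b_to_a")

  # conflicting parity at one mapped atom: loose
  lp <- gen_pair("loose", seed = 42)
  iso2 <- graph_isomorphism(lp$a, lp$b)
  expect_equal(classify_chemical_details(lp$a, lp$b, iso2)$kind, "loose")

  # partial mappings violate the precondition
  expect_error(classify_chemical_details(m$a, m$b, iso$mapping[-1, ]),
               class = "mh_precondition_error")
})

test_that("conflicting cis/trans labels classify as loose", {
  a <- mk_mol(rep("C", 4), path_bonds(4, c("1", "2", "1")), id = "a")
  b <- mk_mol(rep("C", 4), path_bonds(4, c("1", "2", "1")), id = "b")
  a$bonds$cis_trans[2] <- "cis"; b$bonds$cis_trans[2] <- "trans"
  expect_equal(classify_chemical_details(a, b, identity_map(4))$kind, "loose")
  b$bonds$cis_trans[2] <- "cis"
  expect_equal(classify_chemical_details(a, b, identity_map(4))$kind, "equivalence")
  b$bonds$cis_trans[2] <- "none"
  rel <- classify_chemical_details(a, b, identity_map(4))
  expect_equal(rel$kind, "generic_specific")
  expect_equal(rel$direction, "b_to_a")
})

test_that("identifier detection pairs equal structures across databases", {
  eth_a <- parse_molfile(ethanol_molfile, id = "A1")
  eth_b <- parse_molfile(ethanol_molfile, id = "B1")
  pairs <- detect_pairs_by_identifier(list(eth_a), list(eth_b))
  expect_length(pairs, 1L)
  expect_equal(pairs[[1]]$relationship$kind, "equivalence")
  expect_equal(pairs[[1]]$origin, "identifier")
  expect_null(pairs[[1]]$mapping)

  disjoint <- detect_pairs_by_identifier(list(eth_a), list(fix_butane()))
  expect_length(disjoint, 0L)
})

test_that("generic pair validation absorbs branches into R groups", {
  p <- validate_generic_pair(fix_generic_a(), fix_generic_b())
  expect_false(is_absent(p))
  expect_equal(p$relationship$kind, "generic_specific")
  expect_equal(p$relationship$direction, "a_to_b")

  # extra branch attached where the pattern has no R
  expect_true(is_absent(validate_generic_pair(fix_generic_a(), fix_generic_bad())))

  # both generic, the larger one's extra branch ends in its own R
  a <- fill_hydrogens(mk_mol(c("R", "C", "O"), path_bonds(3), id = "genA"))
  b <- fill_hydrogens(mk_mol(c("C", "C", "O", "R"),
                             data.frame(a = c(1, 2, 1), b = c(2, 3, 4), order = "1"),
                             id = "genB"))
  p2 <- validate_generic_pair(a, b)
  expect_false(is_absent(p2))
  expect_equal(p2$relationship$kind, "generic_specific")

  expect_error(validate_generic_pair(fix_generic_b(), fix_generic_b()),
               class = "mh_precondition_error")
})

test_that("generic validity bounds the heavy atom counts", {
  for (seed in 1:10) {
    gp <- gen_pair("generic_specific", seed = seed)
    p <- validate_generic_pair(gp$a, gp$b)
    expect_false(is_absent(p))
    expect_equal(p$relationship$direction, "a_to_b")
    expect_lte(length(metharmonize:::heavy_indices(gp$a, drop_r = TRUE)),
               length(metharmonize:::heavy_indices(gp$b)))
  }
})

test_that("tautomer validation accepts keto-enol shifts and rejects others", {
  p <- validate_tautomer_pair(fix_keto(), fix_enol())
  expect_false(is_absent(p))
  expect_equal(p$relationship$kind, "equivalence")

  # identical molecules: trivially valid, equivalence
  p2 <- validate_tautomer_pair(fix_keto(), fix_keto())
  expect_false(is_absent(p2))
  expect_equal(p2$relationship$kind, "equivalence")

  # same formula, different skeleton
  expect_true(is_absent(validate_tautomer_pair(fix_butane(), fix_isobutane())))

  expect_error(validate_tautomer_pair(fix_keto(), fix_butane()),
               class = "mh_precondition_error")
})

test_that("ring-chain validation opens the hemiacetal bond", {
  rc <- gen_pair("ring_chain", seed = 8)
  p <- validate_ring_chain_pair(rc$a, rc$b)
  expect_false(is_absent(p))
  expect_equal(p$origin, "ring_chain")

  # two identical acyclic molecules: no candidate bond
  res <- validate_ring_chain_pair(fix_generic_b(), fix_generic_b())
  expect_true(is_absent(res))
  expect_equal(res$reason, "no hemiacetal bond")

  np <- gen_non_pair("missing_hemiacetal", seed = 9)
  res2 <- validate_ring_chain_pair(np$a, np$b)
  expect_true(is_absent(res2))
  expect_equal(res2$reason, "no hemiacetal bond")
})

test_that("tautomer and ring-chain validators conserve atom counts", {
  tp <- gen_pair("tautomer", seed = 55)
  expect_identical(mol_formula(tp$a), mol_formula(tp$b))
  rc <- gen_pair("ring_chain", seed = 56)
  expect_identical(mol_formula(rc$a), mol_formula(rc$b))
})

test_that("pair TSV export round-trips the relationship fields", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  pairs <- list(
    compound_pair("a1", "b1", relationship("equivalence"), origin = "identifier"),
    compound_pair("a2", "b2", relationship("generic_specific", "a_to_b"),
                  mapping = data.frame(pattern = 1:2, target = 2:1),
                  origin = "generic_validation")
  )
  rows <- write_pairs_tsv(pairs, tf)
  back <- read.delim(tf, stringsAsFactors = FALSE)
  expect_equal(back$relationship, c("equivalence", "generic_specific"))
  expect_equal(back$mapping[2], "1:2,2:1")
})
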